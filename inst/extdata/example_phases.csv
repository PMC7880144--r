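label,start_s,end_s
low,0,2.5
high,2.5,5
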