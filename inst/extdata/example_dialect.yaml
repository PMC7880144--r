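# Column mapping for the bundled synthetic example recording
time: t
x: x
"y": y
units: degrees
time_unit: s
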