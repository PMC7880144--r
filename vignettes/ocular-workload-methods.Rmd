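---
title: "Methods: ocular cognitive-load estimation"
author: "ocuload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ocular cognitive-load estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocuload)
```

This vignette documents the models and procedures the package
implements, the parameters that matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the underlying methods leave the
design open.

## The measurement problem

Cognitive load changes oculomotor behaviour: under higher load operators
fixate more often within a smaller region of the visual field, produce
more saccadic intrusions, and show more short-timescale pupil-diameter
activity. A wearable tracker delivers a ~100 Hz stream of 2-D gaze
positions and pupil diameters; the package turns that stream into
workload indices and compares them across task conditions or flight
phases. The internal gaze unit is *degrees of visual angle*, because all
detection thresholds are angular; pixel-native input is converted on
load with the linear mapping `pixels = angle × resolution / fov` about
the scene-camera centre. The mapping deliberately omits a tangent
correction: at the gaze eccentricities involved (a few degrees) the
difference is far below tracker accuracy, and the constant
pixels-per-degree convention keeps the conversion exactly invertible.

## Event detection

### Velocity-threshold classification (I-VT)

Angular speed is estimated by a central difference of position across a
symmetric window (default 3 samples, i.e. ±10 ms at 100 Hz). Two-point
differencing at 100 Hz amplifies tracker jitter — at 0.05° RMS noise it
contributes roughly 7°/s of speed noise versus half that for the 3-point
window — so the window is configurable but never narrower than 3.

Samples with speed below `velocity_threshold` (default 30°/s, the
conventional wearable-tracker threshold) are fixation samples, the rest
saccade samples. Classification then reduces to run-length merging:

* runs of undefined speed shorter than `max_gap_fill` (default 75 ms)
  are bridged when the class on both sides agrees, so a one-or-two
  sample dropout does not split a fixation;
* fixation runs shorter than `min_fixation_duration` (default 60 ms)
  are left unclassified rather than forced into either class;
* events are half-open intervals `[t_start, t_end)` and tile the
  classified portion of the recording without overlap.

The 60/75 ms defaults follow common velocity-threshold practice; both
are exposed in `ivt_params()` because vendor implementations differ.
Saccade amplitude is the angular distance between the centroids of the
bounding fixations — more robust than endpoint samples, which sit
mid-flight; at the recording edges the run endpoints are used instead.

The implementation is validated sample-for-sample against an
independent brute-force oracle (per-sample thresholding plus sequential
run merging) on hundreds of random streams, and the classifier's
fixation time is non-decreasing in the threshold by construction.

### Saccadic intrusions

An intrusion is operationalised as an excursion-and-return episode: from
a fixated reference (mean gaze over the preceding 100 ms), horizontal
gaze departs by more than `min_deviation` (default 0.4°) and the gaze
position returns to within `return_tolerance` (default also 0.4°) after
a delay between `min_return` (60 ms) and `max_return` (870 ms). Two
stability conditions are part of the operational definition: the
reference window itself must be fixated, and after the return the gaze
must hold near the reference for 100 ms. Without them, any saccade
sequence that revisits the same horizontal coordinate within 870 ms is
indistinguishable from an intrusion, and on realistic synthetic streams
roughly half of all detections are such coincidences. The excursion
measure is X-only (intrusions are conjugate horizontal movements); the
return and stability checks use both coordinates, since "returning to
the same position" is a statement about position, not its horizontal
projection. All five parameters are configurable in `si_params()`.

### Rates

Events are attributed to phases and windows by *onset* time, so
windowed counts over a partition sum exactly to the whole-interval
count. Rates divide the count by the phase duration (not the span of
retained samples), matching how per-phase parameters are normalised
when a flight is annotated into take-off, climb, cruise, maneuver,
descent and landing.

## The pupillometric index

The Measure of Pupillary Cognition is computed per buffer (default 1 s):
remove the buffer mean, apply the discrete Fourier transform, form the
single-sided magnitude spectrum with the 2/N convention (1/N at DC and
Nyquist, so values are comparable across buffer lengths), and sum the
magnitudes of all bins whose centre frequency lies in `[1, 5]` Hz,
inclusive at both edges. With 1 s buffers at 100 Hz the in-band bins sit
exactly at 1–5 Hz, and a bin-centred sinusoid of amplitude A contributes
exactly A; the index is therefore linear in in-band amplitude, invariant
to DC offset, and (for stationary signals) constant across buffers.

Numerical choices: mean removal is applied by default even though the
index is nominally computed on the raw signal — without it, leakage
from the DC component dominates the 1 Hz bin for any realistic baseline
diameter (3–5 mm versus in-band amplitudes of hundredths of a
millimetre). A rectangular window is the default, staying closest to a
plain FFT; a Hann taper is available where off-bin leakage matters.
Because magnitude scaling and windowing conventions vary across
implementations, absolute index values are convention-dependent:
orderings and ratios are the comparable quantities, which is how the
package uses them (per-condition means and an ordering check of the
high-load condition against the others).

Buffers containing missing samples are flagged invalid rather than
interpolated into existence. The preprocessing step fills only gaps
shorter than 500 ms (blinks are 100–300 ms; longer gaps usually mean
tracking loss) by linear interpolation; edge gaps always stay missing.

The per-phase pupil variability summary is the plain sample standard
deviation of diameter over the phase.

## The tracking task and inceptor metrics

The target pitch is a sum of five sinusoids. The numeric amplitudes and
frequencies of the original task are not published, so the default
`sos_spec()` uses five incommensurate frequencies spanning 0.05–0.6 Hz
with decreasing amplitudes (2.0–0.5°) — a conventional unpredictable
forcing function, configurable and documented as a package default, not
a measured value. Boundaries shrink geometrically:
`w(t) = w0 (1 - s)^floor(t / T)` with defaults w0 = 5°, s = 0.2,
T = 60 s, anchored at task start.

Duty cycle is the percentage of samples with |stick rate| above
`movement_threshold`; the threshold separating "significant" movement
from holding is not standardised, so it defaults to 1°/s and is
config-exposed. Aggressiveness is the RMS stick rate. Both use the same
central-difference rate estimator as gaze velocity (one estimator,
consistently). Tracking error is own pitch minus target pitch; a
boundary hit is a contiguous violation episode (|error| at or beyond
the prevailing half-width), counted once per episode. Per-boundary-step
tables report fixation/saccade counts, duty cycle, aggressiveness and
median |error| on complete 60 s steps only.

## The synthetic-data generator

The generator's purpose is ground truth: every recording it emits comes
with the exact event list and parameter values that produced it, so
each detector can be scored against truth rather than against another
implementation.

*Gaze* is an alternating renewal process. Fixation durations are drawn
from a gamma distribution (shape 2) shifted by the 100 ms minimum, with
mean set so the realised fixation rate matches the profile in
expectation; saccades last 40 ms, relocate gaze by a lognormal amplitude
(σ_log = 0.35) in a uniform direction, and are reflected into a ±15°
field. During a saccade the sampled position follows a cosine ramp — a
smooth ballistic profile whose peak speed comfortably exceeds the 30°/s
threshold for any amplitude above ~0.5°. A relocating saccade that
would land back on the immediately preceding fixation position (within
0.5° on both axes) is redrawn: such an out-and-back pair is
observationally identical to a saccadic intrusion, and intrusions are
injected and labeled separately, so leaving them in would make the
ground truth inconsistent with the emitted recording. Intrusions are
square horizontal excursions of 0.8–1.5° lasting 150–500 ms, placed
inside sufficiently long fixations with 120 ms clean margins — inside
the detection envelope (> 0.4° deviation, return within 60–870 ms) by
construction. Gaussian position noise (default 0.05° RMS, a typical
wearable-tracker figure) is added last.

*Pupil* is baseline + slow drift (0.02 Hz, 0.2 mm) + five random-phase
sinusoids at exactly 1, 2, 3, 4, 5 Hz, each of amplitude
`pupil_band_power`, + white noise, with 100–300 ms blink gaps at a
configurable rate. Aligning the in-band component with the index's bin
structure makes band-power recovery exact in expectation, which is what
lets the tests assert strict monotonicity of mean MPC across generator
levels.

*Tracking* is a proportional–derivative pursuit of the sum-of-sines
target: stick command u = g·(k_p e + k_d ė) with a first-order lag on
the smoothed error derivative (50 ms) and on the stick itself (80 ms,
a neuromuscular lag), pitch rate proportional to stick deflection, and
gain g growing 30% per boundary step — shrinking boundaries compel a
tighter, more aggressive control strategy. A Gaussian remnant scaled by
the gain models neuromotor noise; it is what makes duty cycle and
aggressiveness rise monotonically across steps while tracking error
falls. Degenerate limits are exact: zero gain leaves the aircraft
untouched (error RMS equals the target RMS), infinite gain is ideal
pursuit (zero error). Configurations whose stick saturates more than
20% of the time are rejected as unstable with a diagnostic.

*Flight* glues the above per phase and adds an altitude channel. Dives
follow a raised-cosine descend-and-recover profile — smooth, with
sign-correct vertical speed and a single extremum — and during a dive
the instantaneous fixation-rate parameter is
`r(t) = r_phase + c·|rate of descent|`. The default dive (6000 ft over
90 s, peak |ROD| ≈ 209 ft/s) and coupling c = 0.015 (events/s)/(ft/s)
over a 1.2 /s dive-phase baseline were fixed by an a-priori
signal-to-noise calculation: with 5 s counting windows the expected
count swings from ~6 to ~22 across the dive while Poisson counting
noise is ~4, putting the expected correlation between windowed fixation
rate and |ROD| in the 0.8–0.9 range — the qualitative regime (inverted-U
vertical-speed profile mirrored by fixation rate, r > 0.7) the
generator is meant to emulate.

What the generator does *not* emulate: head movement and
vestibulo-ocular dynamics, smooth pursuit, vergence, G-load effects on
the eye, luminance-driven pupil responses, and realistic spatial
structure of scanpaths (fixation targets are uniformly directed). Tests
passing on this synthetic data therefore show that the detectors and
indices are correct *given* the stated signal model — not that the
model captures all properties of in-flight recordings. In particular,
lighting changes affect the pupil channel in real cockpits, and the
pupillometric index should be interpreted cautiously wherever
illumination is uncontrolled.

## Statistics

The condition comparisons use classical tools: one-way between-groups
ANOVA (base R `aov`) with effect size reported as eta-squared
(SS_between/SS_total, equivalently df1·F/(df1·F + df2)); pairwise
two-sample t-tests (pooled by default, paired optional) with no
multiple-comparison correction by default and Holm et al. available via
`p_adjust`; the unequal-variance Welch test with Satterthwaite degrees
of freedom for two-sample comparisons of windowed counts; and Pearson
correlation throughout, with an interpolation utility to align
differently-clocked series onto a common grid before correlating.
Exact p-values are always reported; the significance level is the
user's choice. Degenerate inputs are handled explicitly: zero
within-group variance yields an infinite F with a `degenerate` flag and
effect size 1 rather than an error or NaN, and zero-variance inputs to
the correlation raise an informative error.

Rate of descent is the signed central-difference derivative of
altitude — negative while descending — because onboard recorders often
log only the magnitude of vertical velocity and the sign must be
recovered from the altitude trace.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic
data: detector-recovery checks use 60–300 s recordings at 100 Hz,
oracle-equivalence checks use 200 random 1.5 s streams, the flight
scenario is a 540 s profile with one 90 s dive, and the statistical
oracles use 3 × 13 observations. These sizes put every stochastic check
well past the small-sample regime while keeping a full run in tens of
seconds. Every stochastic component is a pure function of its
parameters and an integer seed, so all results in the README and the
acceptance output are exactly reproducible.

```{r demo}
g <- simulate_gaze(workload_profile("demo", 60, fixation_rate = 2),
                   noise_sd = 0.05, seed = 1)
ev <- ivt_classify(g$recording)
c(truth = sum(g$truth$events$kind == "fixation"),
  detected = sum(ev$kind == "fixation"))
```

## Known limitations

* The linear pixel/degree mapping ignores projection geometry; fine for
  small eccentricities, wrong for gaze far into a wide-angle camera's
  periphery.
* Smooth pursuit is classified as fixation (low velocity) — a known
  property of velocity-threshold filters, acceptable for HUD-centred
  tasks, wrong for tasks dominated by pursuit.
* Absolute MPC values depend on FFT scaling conventions; only
  orderings and ratios transfer across implementations.
* Eye-blink parameters are out of scope: a consumer tracker cannot
  reliably distinguish blinks from tracking loss under vibration, so
  gaps are treated uniformly as missing data.
* The between-groups ANOVA does not model repeated measures; a
  mixed-effects re-analysis is deliberately out of scope.
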