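---
title: "Predicting voluntary head rotation from pre-movement EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting voluntary head rotation from pre-movement EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Voluntary movements are preceded by slow cortical potentials — the readiness
potential, a negativity over central and frontal motor areas that can begin
hundreds of milliseconds to seconds before movement onset, and its
lateralized component, which differs between left- and right-sided movements
a few hundred milliseconds before onset. `headbci` implements a complete
analysis chain for asking whether a *single* upcoming head rotation (left,
right, or none) can be predicted from a short (250 ms) window of 32-channel
EEG recorded *before* the movement starts, and how long in advance a
streaming classifier's output diverges in the correct direction.

Because no public recordings exist for this task, the package ships a
first-class synthetic-session generator. Every downstream stage — onset
detection, preprocessing, epoching, classification, pseudo-online streaming,
ERP topography — is exercised and tested end-to-end against sessions whose
ground truth is known exactly.

## Synthetic sessions

`synth_session()` produces one recording block: 32-channel EEG at 512 Hz
(so downsampling to the 128 Hz analysis rate is a real, testable step) plus
a co-registered head-yaw angular-velocity trace at 128 Hz (rightward
positive).

**Schedule.** Self-paced center-outward rotations with inter-onset gaps of
at least 2 s, at a mean rate of 6 rotations/min. Over two 20-minute blocks
this yields roughly 240 rotations, i.e. about 840 jittered pre-onset windows
per class before balancing — the same order as the per-participant interval
counts the experimental protocol produces. Directions are a seeded fair
coin; balancing is left to the epochs stage. Each rotation is an
out–hold–return excursion: a raised-cosine velocity pulse (peak 250 deg/s,
duration 0.5 s, displacement ≈ 62 deg), a uniform 0.3–0.8 s hold at the
side, and an opposite-sign return pulse, so integrated position returns to
center and the center-outward filter has real work to do.

**IMU noise.** Gaussian, sd 0.1 deg/s, in the range of consumer gyroscopes.
This matters: the onset detector's systematic delay is the time the velocity
pulse needs to cross threshold = 3 × noise sd, and at these kinematics that
crossing happens within about one 7.8-ms frame, which is what makes the
detector's two-frame precision requirement attainable at all.

**EEG signal model.** Background activity is pink-ish noise (white noise
spectrally shaped toward 1/f, flattened below 0.25 Hz), standardized to sd
`noise_sd` (default 10 recorded units) per channel. The pre-movement
signature is deliberately simple and analytically checkable: a linear ramp
from zero at `onset − rp_lead` (default 0.45 s) to a negativity of magnitude
`rp_amplitude` at onset, weighted across the scalp by a fixed montage map
(largest over C3/Cz/C4 and fronto-central sites, zero at
posterior/neck-adjacent electrodes), plus a lateralized component of
magnitude `lateralization_fraction × rp_amplitude` whose sign is exactly
antisymmetric across the midline and flips with rotation direction
(contralateral hemisphere more negative). A linear ramp matches the "slow
negativity" account of the readiness potential and gives closed-form
onset-locked averages: the mean of the ramp over its lead is −A/2, and the
mean over the whole second before onset is −A·lead/2. Artifact intervals
(Poisson, default 0.5/min, 0.2–0.6 s long) receive a raised-cosine burst of
amplitude 200, well above the 80-unit rejection threshold even after
band-passing.

What the generator does *not* emulate: volume conduction and realistic
source mixing, ocular artifacts with frontal topography, mu-band
desynchronization (the pipeline's 0.75–8 Hz time-series features exclude it
by design), and movement-execution EEG after onset. Passing tests therefore
show that the pipeline is correct and sensitive to a planted lateralized
slow potential of known geometry — not that real head rotations are
predictable at any particular accuracy.

## Onset detection

A sliding 125-ms window moves over the yaw velocity. An onset is declared at
the first frame whose absolute velocity exceeds the threshold and stays
above it for the full window; sub-window spikes are rejected and sub-window
dips inside a movement do not split it ("remained there" is not defined more
precisely by the protocol; the sustained-window rule is our
operationalization). The threshold is 3 × the sd of the velocity over a
stationary segment (automatically the quietest 2-s chunk); the multiplier is
exposed because the protocol fixes only the variance-based construction.
Onsets are reported at IMU-frame resolution (7.8125 ms), without sub-frame
interpolation. Only rotations launched from center — integrated yaw within
5 deg of zero at onset — are scored, because only for those is the upcoming
direction unknown; returns-to-center are detected, labeled, and excluded by
this filter.

## Preprocessing

Band-pass 0.75–8 Hz (slow time-series components only), implemented as a
zero-phase forward–backward Butterworth cascade (high-pass order 2, low-pass
order 4; design configurable). Filtering runs at the native 512 Hz and
doubles as the anti-alias stage before decimation to 128 Hz. Intervals whose
raw absolute amplitude exceeds 80 recorded units on any channel are
discarded — strictly "over" 80, at epoch-selection time only; the continuous
record is never mutilated, so streaming classification sees every frame.
The threshold's unit is "recorded units" on purpose: the synthetic data is
calibrated in the same units, so behavior is well defined whatever the
physical scale of a real recording.

One numerical caveat we verified explicitly: a 0.75-Hz high-pass reshapes a
0.45-s ramp (droop), so no waveform landmark of the ramp survives
band-passing at one-frame precision. The chain's *timing* fidelity is
therefore established differently — the decimation stage preserves the
ramp's half-amplitude crossing within one frame, and the band-pass has zero
group delay on pass-band tones.

## Epochs, balancing, and the split

Each scored rotation contributes seven partially overlapping 250-ms
windows; the closest ends 188 ms and the furthest starts 488 ms before
onset, so the seven start offsets are evenly spaced over [−488, −438] ms and
the middle window is centered at −338 ms. Even spacing is our deterministic
reading of "jittered": the printed endpoints and middle center force
symmetric coverage, and determinism buys exact reproducibility. Window times
snap to the 128-Hz grid. No-rotation windows are drawn uniformly (seeded)
from frames that overlap no rotation span and end at least 1000 ms before
the next onset. Features are the flattened channel-major 32 × 32 window —
1024 values.

Balancing undersamples every class to `min(n_left, n_right)` (seeded).
The split reserves one contiguous segment of 10% of the session (by
default the end of block 2) as the test stream; epochs wholly inside it form
the test set, epochs straddling its boundary are dropped, and the remainder
splits 72:18 within each block. All seven windows of one rotation stay in
the same partition. This is the conservative choice: we verified empirically
that epoch-level random splits leak — overlapping windows of one rotation
share noise, and the network reaches perfect left/right "accuracy" on data
with *zero* planted direction information simply by recognizing windows.
Balancing is applied within each partition after the split, which is what
makes equal per-class counts in both training and test sets achievable.

## The classifier

A dense multi-layer perceptron, 1024 → 512 → 256 → 6 → 3: ReLU hidden
layers with L2 penalty (coefficient 1e-4, configurable — only the presence
of L2 is fixed by the protocol), 10% dropout on the first two hidden layers,
and three independent sigmoid output units ordered (none, left, right).
Training: 150 epochs of Adam (learning rate 0.001) in mini-batches of 150,
categorical cross-entropy. Because the outputs are independent sigmoids, the
cross-entropy is taken on sum-normalized activations; raw sigmoids are what
`predict()` reports, and they need not sum to one. The gradient of this loss
is implemented in the singularity-free form dL/dz = (1 − s)(s/Σs − y).
"Normalized batches" is interpreted as per-feature standardization with
training-set statistics, applied identically at inference — batch-wise
renormalization would be ill-defined for single streaming windows.
Everything (initialization, shuffling, dropout masks) is driven by one seed;
two runs with the same seed produce identical weights.

The absolute scale of the sigmoid outputs is not anchored by the loss: a
trained model may emit triples like (0.003, 0.025, 0.002). Argmax
classification is unaffected; for onset-locked probability *curves* the
package normalizes each triple to proportions (`lock_to_onsets(...,
normalize = TRUE)`), which is the scale on which "the no-rotation
probability starts to decrease" is a meaningful statement.

`chance_threshold(n, c, alpha)` gives the exact binomial upper bound of
chance accuracy: the smallest k with CDF(k; n, 1/c) ≥ 1 − alpha, as k/n.
For 330 balanced 3-class intervals at alpha 0.05 this is 124/330 ≈ 37.6%,
i.e. about 38%.

## Pseudo-online evaluation

`stream_classify()` slides the model over the withheld continuous stream
one frame at a time (n − 31 positions). Each probability triple is indexed
at the *center* of its 250-ms window; since the window must have elapsed
before its classification exists, the information is really available 125 ms
after the plotted time, and this delay is carried in the object. Locking the
(normalized) trace to center-outward onsets yields mean ± sd curves per
class. On strong-signal synthetic participants the no-rotation curve leaves
its baseline band a little over 400 ms before onset — inside the planted
information horizon of rp_lead + 125 ms = 575 ms — and the correct
direction's curve rises while the wrong one stays low. One synthetic-data
idiosyncrasy worth knowing: near t = 0 the curves can swing back toward
"none", because streaming windows there cover ramp segments the classifier
never saw in training (training windows all end ≥ 188 ms before onset); the
planted ramp makes window position highly informative, a "tuning" that real
recordings did not show.

## Pre-onset ERP topography

`pre_onset_erp()` averages the second before onset per electrode, baselining
each epoch at −1000 ms. The default baseline is the mean of 3 frames rather
than a single sample — a one-sample baseline injects that sample's noise
into the whole epoch. `lateralization_map()` equalizes left and right event
counts within participant (seeded subsample), takes the left-minus-right
per-electrode window mean, and `grand_topography()` averages participants
with equal weight. On default synthetic data the map is antisymmetric across
the midline, largest at C3/C4, and near zero at posterior electrodes — by
construction, since the generator plants nothing there. ERPs are computed on
whatever stage of data they are given; the pipeline feeds them preprocessed
(0.75–8 Hz, 128 Hz) EEG for consistency, at the cost of high-pass droop on
slow components.

## Orchestration and reproducibility

`run_experiment()` executes the whole chain per participant — two blocks,
detection, preprocessing, epoching, split, balancing, three training
repetitions, test evaluation against the participant's chance threshold,
streaming with onset-locked averages, lateralization topography — from one
`experiment_config()` (or YAML file). All randomness flows from one master
seed through named sub-streams (synthesis, no-rotation sampling, balancing,
split, per-repetition model seeds), so any stage can be reproduced in
isolation and a rerun reproduces the report exactly. Outputs carry an
8-hex-digit hash of the full configuration. Sessions round-trip through
standard formats: EDF (16-bit) for EEG, `time_s,yaw_velocity` CSV for the
IMU trace, JSON for ground truth, TSV for events, traces, and topographies.

## Problem sizes and numerical choices

Tests and the worked examples run on shortened blocks (100–300 s instead of
1200 s) and reduced training passes (12–40 instead of 150); these sizes
exercise every code path at a few hundred epochs per class, which we judged
sufficient for the properties being asserted — chance-level behavior is
checked on pooled counts across ten seeds against exact binomial bands, and
signal recovery uses a planted amplitude large enough that a penalized
multinomial logistic regression (the independent oracle) separates the
classes, after which the network is required to do as well. Degenerate
inputs are explicit: empty schedules signal themselves, a zero-variance
stationary segment is an error, upsampling is refused, epochs exactly at the
rejection threshold are kept ("over" is strict), and a test stream without
rotation events aborts the split with advice to move it.

## Known limitations

The generator's linear-ramp signature makes the classification problem more
geometric than real EEG; accuracies on synthetic sessions say nothing
quantitative about real participants, whose signal strength reflects biology
and recording quality we do not model. The EDF
writer covers the continuous 16-bit subset the pipeline needs, not the full
format. Offsets of detected events are used only for labeling spans; their
precision is not specified or tested beyond the sustained-return rule.
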