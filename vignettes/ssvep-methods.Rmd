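---
title: "SSVEP frequency recognition: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSVEP frequency recognition: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepr)
```

## The recognition problem

A steady-state visual evoked potential (SSVEP) interface shows K targets
flickering at distinct frequencies above ~6 Hz. Attending one of them
entrains occipital/parietal EEG at the stimulus frequency and its harmonics,
after an initial transient stage (the N75/P100/N135 wave complex, roughly the
first 200 ms after flicker onset). The decoding task: given a short window of
N-channel EEG, decide which of the K frequencies drives it. `ssvepr`
implements three detectors over a common data model (`epoch_array`: trials x
channels x samples at a fixed sampling rate, labeled by stimulus) and the
evaluation layer used to compare them.

All default protocol constants follow the 12-target layout the package is
organized around: frequencies 9.25-14.75 Hz in 0.5 Hz steps, 256 Hz sampling,
8 channels (O1, O2, Oz, PO7, PO3, POz, PO4, PO8), 4 s trials, 15 blocks of
one trial per stimulus, and a 1 s gaze-shift period before each trial.

## Detectors

### Canonical correlation analysis

For stimulus k a reference matrix stacks `sin(2*pi*h*f_k*t)` and
`cos(2*pi*h*f_k*t)` rows for harmonics `h = 1..Nh` at the window's sample
times. `cca_fit()` solves the standard CCA problem between the channel rows
of the window and the reference rows by whitening both covariances
(symmetric eigendecomposition) and taking the SVD of the whitened
cross-covariance; the decision is the stimulus with the largest leading
canonical correlation, ties toward the smallest index. Because each
reference contains both sin and cos rows, the score is invariant to the
window's phase — CCA needs no training and no phase locking.

Numerics: covariances receive a tiny relative ridge (`1e-12 * trace`) and
the whitening floors eigenvalues at `1e-10` of the largest, warning when the
floor engages. This keeps noise-free windows (whose channel covariance is
exactly rank one when every channel carries a scaled copy of one source)
solvable while leaving canonical correlations invariant, to well below 1e-8,
under invertible recombinations of either view's rows. A window with no
variance at all is refused at fit level; the classifier converts it into a
flagged lowest-index decision so batch runs never abort.

### LASSO contribution scoring

One design matrix stacks the (unit-normalized) harmonic regressors of all K
stimuli; each channel's window is regressed against it under
`||y - X b||_2^2 + lambda * ||b||_1`, solved by cyclic coordinate descent
with soft thresholding (tolerance 1e-7 on the largest per-sweep coefficient
change, 10 000 sweep cap; non-convergence is an error carrying the last
iterate). Stimulus k's score is the channel-averaged sum of its
coefficients; the decision is the argmax.

Two conventions deserve comment. First, the coefficient vector is indexed by
frequency and harmonic, but a single regressor per (frequency, harmonic)
cannot represent an unknown phase, so the design carries both sin and cos
columns per harmonic and the per-frequency sum runs over all of them.
Second, the sum is of *signed* coefficients by default — the aggregation as
written in the detection rule — which makes the score phase-sensitive: a
window whose phase puts weight on a negative cos coefficient can cancel its
own evidence. `use_abs = TRUE` switches to magnitude summing, which is
phase-agnostic; the signed default is retained because it is the documented
rule, and the evaluation below locks phase instead (see *Phase handling*).

The penalty is specified either absolutely or, by default, as a fixed
fraction (0.1) of each channel's deactivation bound `2*max|X'y|` — the
smallest penalty that forces the all-zero solution — which adapts the
penalty to the channel's scale. `lasso_calibrate_lambda()` grid-searches
this fraction for maximum detection accuracy on a synthetic calibration set,
the offline, subject-independent selection the method assumes.

### Robust nonlinear CCA

The package's core replaces CCA's linear projections with double-barreled
single-hidden-layer tanh networks (`u` from the channel vector, `v` from the
reference vector, one observation per time sample) trained by minimizing

```
C1 = -bicor(u, v) + <u>^2 + <v>^2 + (<u^2>^(1/2) - 1)^2 + (<v^2>^(1/2) - 1)^2
     + P1 * (sum W_x^2 + sum W_y^2)
```

— negative robust correlation, zero-mean/unit-second-moment constraints on
both variates, and an L2 penalty on the hidden-layer weights only. The
correlation is the biweight midcorrelation: deviations from the median,
scaled by nine times the raw median absolute deviation (no Gaussian
consistency factor), downweighted by the Tukey biweight `(1 - u^2)^2` with
zero weight outside `|u| < 1`, normalized to unit sum of squares. It is
bounded in [-1, 1], tracks Pearson closely on clean Gaussian data, and is
indifferent to a single gross outlier that ruins Pearson. The indicator in
the weight is the standard two-sided `I(|u| < 1)`; a
`one_sided_indicator` flag reproduces the literal one-sided variant some
write-ups print, which keeps full weight on extreme negative deviations.

Inverse-mapping networks reconstruct each view from its variate under
`C2/C3 = elementwise mean reconstruction error + P * sum(input weights^2)`,
with the mean absolute error as the robust default (MSE selectable). For
optimization the absolute value is smoothed as `sqrt(e^2 + 1e-8)`; reported
diagnostics use the exact MAE.

**Training.** Inputs are standardized per column (constants stored in the
model). The forward stage runs BFGS on analytic gradients, 5 random restarts
from small (sd 0.1) initial weights, 500 iteration cap, relative tolerance
1e-6 on cost change; the restart with the lowest final C1 wins and per-restart
initial/final costs are kept as diagnostics. The inverse maps are then fitted
the same way. Everything is deterministic given the seed. A healthy fit shows
C1 near -1 and small C2/C3.

**The gradient.** The derivative of `bicor` printed in the usual references
treats the median and MAD as constants. That form is exposed as
`bicor_gradient()` (and verified against finite differences of the
frozen-statistic function), but it is *not* used as the training direction:
`bicor` is invariant to positive affine maps of its argument, and only the
median/MAD terms of the chain rule encode that invariance. Using the frozen
form as a gradient of C1 leaves BFGS fighting the variance-constraint terms
and stalling (on the quadratic benchmark below it reaches |bicor| ~ 0.003
where the exact gradient reaches ~ 0.98). Training therefore backpropagates
the exact almost-everywhere gradient, including median and MAD subgradients
(mass 1/2 on the two middle order statistics for even n), which matches true
central finite differences of `bicor` to ~1e-9.

**Hyperparameters.** Hidden size 4 per barrel and inverse map (small
networks resist overfitting on 256-sample windows); penalties
`P1 = 0.1, P2 = P3 = 0.01` — large P1 shrinks hidden weights toward the
linear regime, and the linear-limit behavior (agreement with linear CCA's
leading correlation within 0.05 on linear data, monotonically shrinking
nonlinearity as P1 grows through 0.01-10) is part of the test suite. All are
exposed as arguments.

**Templates and classification.** One model is trained per stimulus: the
x-view stacks the per-sample channel vectors of that stimulus' training
windows; the y-view is the stimulus' sinusoidal reference (repeated per
trial). The reference is used as the y-view — rather than, say, an averaged
EEG template — because it is noise-free, available without extra data, and
fixes the meaning of `v` across trials. The stored template `v_k` is the
y-barrel variate of the reference over one window. A new window is mapped
through each stimulus' x-barrel and scored by `bicor(u_hat_k, v_k)`; argmax
decides, lowest index on ties, and a best score below 0.3 flags the decision
as low-confidence. Inference uses the forward maps only; the inverse
networks serve as regularizing reconstruction checks during training.

For block-structured recordings, training on complete blocks and testing on
held-out blocks (leave-one-block-out) avoids leakage between a stimulus'
training windows and its test trials; the evaluation helpers take explicit
trial subsets so any split can be expressed.

## Preprocessing

Recordings are bandpassed 6-80 Hz with a 4th-order Butterworth applied
forward and backward (zero phase distortion; amplitude response applied
twice). Edges are handled by odd-reflection padding of three filter lengths,
which suppresses startup transients on windows as short as one second.
Filtering is per trial. Window extraction is 0-based with sample 0 at the
stored trial start: fixed mode takes one window per trial; sliding mode
takes every position from the trim offset to the last feasible start, in
one-sample steps by default (3.9 ms at 256 Hz). The transient trim is 50
samples (195.3 ms), matching the ~200 ms transient stage.

## The synthetic generator

`generator_config()`/`generate_dataset()` produce recordings with exactly
the structure the detectors assume:

- steady-state response: `sum_h a_h * sin(2*pi*h*f_k*t + h*phi)` with
  relative harmonic amplitudes `a = (1, 0.5, 0.25)` by default — real
  harmonic amplitude profiles are subject-specific and unreported, so a
  geometric decay is used as a convention;
- a transient stage modeled as three raised-cosine lobes (60 ms wide)
  centered at 75/100/135 ms with signed amplitudes (-1, +2, -1) relative to
  the fundamental, zeroed beyond the 200 ms transient window — the
  N75/P100/N135 morphology without any claim of physiological fidelity;
- background noise: Gaussian, spectrally shaped to `1/f` power (exponent
  configurable), bandlimited 1-100 Hz, scaled per channel so the
  steady-state-to-noise power ratio hits `snr_db` (default 0 dB, a
  realistic single-trial narrowband SSVEP level);
- channel mixing: identity plus small (0.1 sd) seeded cross-talk, giving
  each channel a different gain so multichannel methods have something to
  gain while the problem stays well-conditioned;
- per-trial phase `phi`: uniform by default, or 0 in stimulus-locked mode.

The generator does **not** emulate eye-blink/EMG artifacts, nonstationary
alpha rhythms, electrode drift, inter-subject variability, or realistic
volume conduction. Passing tests on this generator therefore demonstrates
the estimators' correctness and their behavior under controlled SNR and
phase conditions — not performance on real recordings.

### Phase handling

Real SSVEPs are phase-locked to flicker onset: trials of one stimulus share
a reproducible phase, and what varies is the *window position* relative to
onset — which is exactly why sliding-window evaluations expose phase
effects. The generator's random per-trial phase models the extreme opposite
(complete latency jitter) and is the right stress test for the
sliding-window machinery. Template-based NLCCA and signed-sum LASSO are,
however, phase-sensitive by construction (a template correlated at lag zero
cannot match an arbitrarily shifted copy), so the end-to-end detection
properties (detection ceilings at high SNR, NLCCA vs CCA at low SNR) are
evaluated under stimulus-locked phase — the physically correct condition for
template methods — while CCA, being phase-invariant, is unaffected either
way.

## Evaluation layer

Accuracy is percent-correct (the confusion-count formula reduces to it in
multi-class batch use). Bits per trial follow the Wolpaw formula, continuous
at P = 1 and zero at chance; ITR multiplies by the decision rate
`60/(window + gaze)` with a 1 s gaze-shift overhead per decision by default
— the convention under which all the benchmark operating points reproduce
exactly. The sliding-window experiment records accuracy and ITR per window
start (769 positions for 1 s windows on 4 s trials, 719 after the 50-sample
trim), summarized by mean, SD and coefficient of variation; the
window-length sweep reports each detector's maximum-ITR operating point.
One-way ANOVA across approaches is computed with `stats::aov` (an
independent two-pass computation is the test oracle), and Tukey's critical
difference `q * sqrt(MSE/n)` declares pairwise differences, with `q` from
`stats::qtukey` unless supplied. Multi-user aggregation is an unweighted
column mean with an option to drop the user with the lowest mean of a chosen
column first (the generic form of excluding one anomalous participant).

## Problem sizes and runtime choices

The test suite favors configurations that keep the full run around a minute
on one core while preserving each property's force: detection ceilings use
60 held-out trials (5 blocks x 12 stimuli) at 1 s windows; NLCCA training in
tests uses 1-2 restarts and 120-400 iterations (the defaults are 5 and 500);
the NLCCA-vs-CCA comparison at -5 dB runs 10 seeded replicates and applies a
sign test to discordant replicates; the quadratic-relation benchmark uses
n = 2000 samples. Monte-Carlo tolerances (e.g. bicor within 0.03 of Pearson
at n = 10 000) follow the sampling error at the stated sizes.

## Known limitations

- NLCCA inference assumes the test window's phase matches training; under
  genuine latency jitter its templates degrade where CCA does not.
- The signed LASSO score can cancel evidence under adverse phases; use
  `use_abs = TRUE` or phase-locked windows.
- The MAT reader supports the plain Level-5 dialect (uncompressed or
  zlib-compressed double arrays) with a `[stimulus, channel, sample, trial]`
  tensor; other container layouts are rejected as unsupported rather than
  guessed at.
- The ANOVA treats sliding-window observations as exchangeable; adjacent
  window positions are in truth heavily autocorrelated, so its F statistics
  compare conditions but overstate absolute significance — a property shared
  by the benchmark design it mirrors.
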