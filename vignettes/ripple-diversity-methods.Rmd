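---
title: "Laminar ripple diversity: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar ripple diversity: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ripplelamina` implements an analysis pipeline for hippocampal sharp-wave
ripple (SWR) diversity. The scientific premise is that individual CA1 ripples
are not interchangeable events: their laminar current-source-density (CSD)
profiles fall on a continuum between events whose dominant current sink sits
in *stratum radiatum* (Rad-sink; CA3-driven) and events whose dominant sink
sits in *stratum lacunosum-moleculare* (LM-sink; entorhinal-facing), and the
two profiles recruit different neuronal populations with different offline
reactivation dynamics. This vignette explains each model and estimator, the
parameters that matter, and the decisions taken where the design was open.
No empirical number appears here that the test suite or
`scripts/acceptance.R` does not itself compute.

## Ripple detection and validation

Detection operates on the pyramidal-layer LFP referenced against a
ripple-free channel. The differential trace is filtered in the ripple band
(80--250 Hz) and a high-frequency control band (200--500 Hz), both with
4th-order zero-phase Butterworth filters (zero-phase because forward-only
filtering would bias every event time by the filter's group delay).
Candidate events are Hilbert-envelope peaks above five times the session
median envelope; peaks within 20 ms merge to the larger one; onset and
offset are the half-threshold crossings. Four validation criteria follow:
ripple-band power at least twice the reference channel's, mean frequency
above 80 Hz, at least four complete cycles (unwrapped phase difference over
2*pi between onset and offset), and ripple-band power at least twice the
control-band power. The median of the envelope is taken over the whole
session; the 5x-median threshold applies to the 80--250 Hz envelope (the
control band is used only as a validation contrast).

## Per-event CSD signatures and laminar classes

The CSD is the negated second spatial difference of the laminar LFP,
`-(LFP[n-1] - 2 LFP[n] + LFP[n+1])`; negative values are sinks. Volume
conductivity is omitted, so CSD values are on the uV scale of the second
difference; every downstream statistic normalizes to unit variance, which
makes the constant irrelevant. Laminar smoothing uses a Gaussian kernel with
a 50 um standard deviation expressed in channel units, so probes with
different spacings yield comparable profiles; per-ripple signatures are
computed on the smoothed CSD (the same resolution-equalization argument
applies per event). A signature is the per-channel time mean over the
half-open 50-ms window `[peak - 25 ms, peak + 25 ms)`.

Two classification routes are provided. The continuum route takes the first
principal component of the signature matrix, sign-fixed so its weights are
negative in *stratum radiatum*, and labels events above the 70th percentile
of PC1 strength as Rad-sink, below the 30th as LM-sink, the rest
intermediate (boundary ties resolve to intermediate). The ground-truth route
for the waveform classifier uses the normalized LM CSD: the signature mean
over the central LM channel and its two neighbours divided by its SD across
events, lowest 30% LM-sink, top 30% Rad-sink.

## Waveform classifier

The pyramidal LFP carries enough low-frequency (sharp-wave) information to
predict the laminar class. Each 200-ms peri-peak trace is low-passed at
30 Hz, z-scored per trace, and projected on six principal components fit on
training data only; a linear discriminant classifier is trained per
leave-one-subject-out fold with classes downsampled to the smallest class,
repeated (default 100, scaled to 1000 for full runs), each repeat paired
with a label-shuffled null model. The chance-normalized gain is
`100 * (acc_true - acc_null) / acc_null`; the normalization of the printed
percentage is this package's declared convention. The per-trace z-score and
fold-local PCA prevent information leaking from test folds, which the
label-shuffle audit verifies (null gains centred on zero).

## Up/Down states, chains and occurrence profiles

Dentate-gyrus molecular-layer CSD energy (mean rectified CSD, 1-s median
filter, 5 Hz, z-scored) is bimodal when cortical Up/Down dynamics reach the
hippocampus. A two-component Gaussian mixture initializes a two-state
Gaussian HMM (uniform transition initialization, ten random restarts,
Baum-Welch refinement, Viterbi decoding); the higher-mean state is Up. A
session is flagged low-confidence when a one-component mixture is preferred
by BIC or the refined emission separation is below half a pooled SD. Energy
bins for the LM-proportion analysis are ten equal bins over [-2.5, 2.5] z.
Ripple chains are maximal runs with inter-event gaps under 250 ms, and the
transition matrix over within-chain consecutive pairs is normalized by
subtracting the mean of 1000 label shuffles that preserve class counts.

## Population analyses and the margin-preserving shuffle

Population vectors (PVs) are spike counts in the 50-ms peak-centred window.
PETHs use 0.8-ms bins over +/-200 ms around isolated events (no neighbour
within +/-250 ms) with 5-ms Gaussian smoothing. The key control throughout
is the margin-preserving shuffle: the full list of per-spike unit labels is
permuted and reassigned to events in their original per-event counts, so
every unit's total and every event's population count are conserved exactly
while coactivity is destroyed. Ripple-type decoding uses ridge-stabilized
logistic regression on z-scored PVs from random 15-unit subsets with
class-balanced resampling and 20x 80/20 cross-validation; accuracy is the
plug-in mutual information (base-2, no bias correction -- the plug-in bias
at the event counts used here is below 0.02 bit, which the tests calibrate)
of the pooled test confusion table.

## Coactivity graphs and dimensionality

Population-conditioned coactivity regresses each unit on a partner unit
plus the summed activity of the remaining units, symmetrizes, and zeroes
the diagonal; fully-conditioned coactivity is a ridge regression of each
unit on all others (closed-form L2 penalty on z-scored counts, matching the
plain penalized least-squares definition; the penalty -> 0 limit equals
ordinary least squares, which the tests check against `lm()`). Structural
balance is the proportion of closed triads with zero or two negative edges,
computed by trace identities and verified against an exhaustive census.
Edges with |weight| below 1e-12 count as absent. Gini sparsity uses the
ascending-order definition (the alternative fixed-rank ordering is not a
Gini index; the ascending form equals the mean-absolute-difference form to
1e-9 in the tests).

Angle-based intrinsic dimensionality (ABID) evaluates, per query vector,
the squared cosine similarities among the normalized difference vectors to
its k = 50 nearest neighbours: `D = k^2 / sum(S^2)`. The raw construction
is biased downward in inhomogeneous samples because neighbours share a
drift toward the local density mode; by default the package subtracts the
neighbourhood mean displacement before normalizing, which removes the drift
term and calibrates the estimate to within 10% of the true dimension for
isotropic Gaussians at d = 2, 3, 5 (the package's own acceptance check).
The raw variant remains available (`center = FALSE`); it is the right
choice for k = 2 arithmetic, where the centered variant is degenerate.
Sessions are summarized over 100-PV subsamples repeated up to 1000 times,
with k capped at the subsample size minus one. The participation ratio is
computed on covariance eigenvalues (squared singular values) of the
z-scored event matrix.

## Motifs, activation, and contribution gain

Coactivity motifs come from the standard PCA/ICA assembly method: the
number of correlation-matrix eigenvalues above the Marcenko-Pastur edge
`(1 + sqrt(N_units / N_events))^2` fixes the number of motifs, and a
symmetric fixed-point FastICA (tanh contrast, ten restarts keeping the
highest negentropy) on the significant subspace yields unit-length weight
vectors, sign-fixed so the largest-magnitude weight is positive. Motif
membership (where needed) is |weight| > 2 SD of that motif's weights, the
common assembly-literature convention. Activation is the inner product with
a z-scored PV, with the probed unit's weight zeroed for leave-one-out
statistics. The contribution gain of a unit to an LM-derived motif is its
correlation with the leave-one-out activation in Rad events minus that in
LM events, z-scored against margin-preserving surrogates of both classes;
units beyond the surrogate 97.5th percentile count as "aggregated".

## Recent-to-prior balance and drift

Coactivity matrices from pre-sleep ripples (A_pre) and exploration theta
cycles (A_theta) define the transform `W_recent = A_theta %*% solve(A_pre)`,
a whitening of pre-sleep structure that passes wake-gained patterns
through. Estimated coactivity matrices have zero diagonal, so their spectra
straddle zero and the raw inverse is dominated by near-null noise
directions; the package therefore restores the unit self-coactivity by
default (`diag_load = 1`, i.e. `(A_theta + I)(A_pre + I)^-1`), which makes
the inverted matrix a positive-definite correlation-like matrix. The raw
definition is available with `diag_load = 0` and satisfies the exact
algebraic identities (A_theta = 2 A_pre gives W = 2I). Per-ripple balance
is the quadratic form `v' W v` on the z-scored PV; session scores are
scaled to unit SD so sessions are comparable, binned into non-overlapping
10-minute windows over (10, 70] minutes of post-sleep (the first ten
minutes are excluded as rest-to-sleep transition), and normalized by
subtracting the session grand mean across bins and classes.

The flat model (k = 1) and the exponential `a * exp(-t / tau) + c` (k = 3)
are compared with `BIC = k log(n) + n log(SSE / n)`. Because the
exponential is linear in (a, c) given tau, the fit profiles tau over a
logarithmic grid with closed-form least squares and refines the best grid
point with Levenberg-Marquardt; this always converges and is deterministic.
Bootstrap over sessions yields percentile CIs for tau and the fit
correlation r.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, with
ground truth for every planted feature. LFP events are Gaussian-windowed
sinusoids (147 Hz for Rad-sink, 125 Hz for LM-sink events, durations
40--100 ms) over Gaussian-profile laminar deflections: Rad events carry a
negative radiatum deflection at the peak; LM events carry an LM deflection
leading the peak by 17 ms, a weaker radiatum deflection 12 ms after it, and
a positive pyramidale deflection. Deflection widths (12--14 ms SD) are in
the physiological sharp-wave range; narrower deflections would make the
50-ms signature window fragile to envelope-peak jitter on long events.
Event times are Poisson (0.4 events/s by default -- occurrence is only
qualitatively constrained by the source recordings, so the default is a
realistic NREM rate) with a minimum separation enforced by redrawing
offending times, which keeps the count exactly Poisson.

Spike sessions plant a sparse deep-biased core motif (expressed in LM
ripples), a composite of core plus superficial extra units (expressed in
Rad ripples), and a wake-gained "recent" motif that overlaps the composite
extras but adds wake-specific members. Three design points matter and were
learned from failed generator designs rather than assumed:

* **Stochastic, nested expression.** If every event expressed its motif,
  the motif units would carry no across-event variance and
  population-conditioning would explain them away entirely. Motifs are
  expressed stochastically (0.8 per LM event; 0.8/0.6 nested for
  core/extras in Rad events, so extras co-vary with the core's activation).
* **Compensated expression.** Expression redistributes spikes toward motif
  members instead of adding them: background rates rise in non-expressing
  events so the expected principal-population total per event is
  class-constant. Without this, the per-event population count is itself
  the expression signal and the margin-preserving surrogates retain the
  structure they are meant to destroy. A consequence is that each node's
  positive within-motif and negative motif-to-background couplings roughly
  cancel, so mean node strength does not differ between classes in the
  generator even though it does in cortex-scale recordings; the tests
  therefore check the planted block structure rather than mean strength.
* **Sparse participation.** Rates are set so units are active in a minority
  of events (roughly 10--40%), matching sparse CA1 ripple participation.
  Dense participation inverts the z-score geometry of the balance quadratic
  form: the *inactivity* of dense units dominates the projections.

Prior-to-recent drift operates on the event-level motif choice (an LM event
expresses the prior motif with probability `exp(-t / tau_min)`, default
tau = 13 minutes), never on unit rates, so occurrence frequency and
sparsity stay constant over time and the feature-attribution control can
isolate log-time. Spike counts per window are binomial draws of the 1-ms
Bernoulli-bin model with uniform in-window placement, giving exact marginal
control for the shuffle tests. A shared log-normal per-event excitability
gain (SD 0.3) couples all units to the population rate, as real shared
drive does.

What the generator does **not** emulate: biophysical fields, travelling
waves along the probe, REM physiology, position-dependent place-cell
structure, spike sorting artefacts, bursting/refractory spike-train
statistics, and the node-strength contrast noted above. Passing tests
demonstrate that the estimators recover planted structure under these
idealized conditions; they do not certify performance on real recordings.

## Problem sizes and numerical choices

The test suite and acceptance script run the pipeline at desk scale: 600-s
laminar records for detection (about 240 events), three 120-s synthetic
subjects for the classifier, six spike sessions (20-min pre-sleep, 10-min
exploration, 70-min post-sleep; 40 units) for the drift analyses, and a
long pre-sleep session (80 min) for motif extraction, where about 550 LM
events make the ICA separation of the core motif from the compensation
mode reliable. Resample counts are configurable and default to reduced
values in tests (e.g. 100 balanced-resampling repeats, 100--400 surrogates
or bootstrap draws); full-scale analyses would use the 1000/10000/100000
conventions of the field. All stochastic steps take explicit seeds; a
session-level seed derives per-stage seeds deterministically, and equal
seeds reproduce outputs bit for bit.

Known limitations: the headline numbers of the motivating in-vivo datasets
(sink proportions, per-class frequencies, dimensionality values, the
13-minute drift constant) are statistics of recordings this package cannot
access; the synthetic conditions are built so the *procedures* are
validated against known ground truth, with those published values serving
as qualitative anchors for the generator's parameters (147/125 Hz
oscillations, tau = 13 min, LM fraction 0.16 where the dominant-sink mix is
examined).
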