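---
title: "Broadband spectral encoding and directed connectivity for visual-narrative iEEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{narrband methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`narrband` implements a complete analysis pipeline for stereotactic-EEG
(sEEG) experiments that contrast *sequential* (narrative-ordered, "Seq")
against *scrambled* ("Scr") image viewing, together with a synthetic
local-field-potential (LFP) generator with known ground truth so every stage
of the pipeline can be validated without patient data. This vignette is the
package's own account of the models, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not demonstrate.

## The experimental design being modeled

Each condition block presents 7 image series of 5 images, every image shown
for 2 s, with a 6 s gray screen separating series; the scrambled block is
shown first, then the sequential block (35 images per condition, shown
once). The unit of analysis is the *transition* between stimuli, captured by
a 600-sample window from 100 ms before to 500 ms after each image onset at
1 kHz. Transitions are classed as `first_of_experiment` (the block's first
image), `isi_to_image` (gray screen to image, the "First" transition of each
later series), `image_to_image` (within-series, the "Rest" transitions), and
`image_to_isi` (gray-screen onsets, usable as ISI controls).

The `image_to_image` class is the default trial universe: 28 transitions per
condition, 56 trials in all. This is the only reading consistent with the
split sizes the analysis uses throughout — an 80/20 stratified split with
floor rounding gives a 44-trial train/validate pool and a 12-trial test set,
and each Monte-Carlo fold trains on 17 and validates on the remaining 27.
The `isi_to_image` + `first_of_experiment` trials (7 per condition) are kept
as a separate class for the first-vs-rest habituation analysis rather than
being mixed into the encoding trial pool.

## The synthetic LFP generator

Each site's signal is

* a 1/f background (`noise_spec(exponent = 1, amplitude = 1)`), generated by
  spectral shaping of white noise, plus
* a band-limited 10–100 Hz *broadband* component
  (`broadband_amplitude = 1`), whose amplitude inside the 100–500 ms
  post-onset window of every image is multiplied by a region x condition x
  phase gain (`effect_spec()`), plus
* optional directed coupling (`coupling_spec()`): each edge adds
  `coefficient x source(t - lag)` to a sink site, only inside the post-onset
  windows of the edge's condition.

The broadband component is injected *multiplicatively on a band-limited
component* rather than as a narrowband oscillation because the phenomenon
the pipeline is built to detect is a coherent power elevation across a wide
frequency range (>10 Hz), the signature of aggregate population activity;
this construction guarantees that the dominant variance axis of the
normalized spectra is broadband, which the PCA-recovery tests then verify.

Default gains encode the habituation/novelty motif with a contrast ratio of
1.5: frontal `rest` gains are 1.5 (Scr) vs 1.0 (Seq), temporal `rest` gains
are 1.5 (Seq) vs 1.0 (Scr), and `first` gains are elevated but equal (1.25)
in both regions, so first transitions carry no condition information.
Habituation is two-level (first vs rest) rather than a continuous decay
because the analyses only ever contrast those two groups. No published
effect-size estimates exist for this paradigm, so the 1.5 ratio and
unit-amplitude components were chosen once as a regime where single-site
encoding is reliably detectable at 28 trials per condition while single
trials remain visibly noisy — a testability choice, not a fidelity claim.

One interaction between the two effect channels is worth flagging: coupling
adds condition-specific signal power to sink-region sites during *all*
transitions of its condition, including first transitions, so under the
default coupled generator the first-transition condition-equality is exact
only for regions that are not coupling sinks. Analyses that assert the
first-transition null (and the recovery tests that check it) disable
coupling; the full default keeps both channels on, as both phenomena
coexist in the modeled experiment.

Coupling defaults mirror the narrative-network motif (temporal leads
frontal, parietal and insula during Seq; parietal leads temporal during
Scr), with lag 5 ms and coefficient 0.5. Lagged-linear (VAR-style) coupling
is used precisely so that Granger-causal ground truth is well defined; the
lag is kept at or below the default AR model order so the fitted model spans
the true dependency. Stability requires |coefficient| < 1, enforced at
construction. Within a subject, the i-th source-region site is paired with
the i-th sink-region site.

All randomness flows from one integer seed per simulation; identical seeds
give bit-identical recordings. Signals are generated directly at 1 kHz (the
clinical acquisition-rate/resampling path is out of scope).

What the generator does *not* emulate: epileptiform artifacts, saccades and
eye movements, volume conduction, inter-subject anatomical variability,
non-stationary background power, photodiode synchronization jitter, and any
realistic spatial correlation structure beyond the injected coupling.
Passing tests therefore demonstrate that the pipeline recovers what it is
supposed to recover *when the generating model holds* — they are estimates
of correctness and statistical calibration, not of performance on clinical
recordings.

## Preprocessing

Sites flagged as excluded (the analogue of seizure-zone or out-of-cortex
exclusions) are dropped from every downstream stage. Each subject is
re-referenced to its common average over included sites; this requires at
least two included sites, and with exactly two the pair becomes exactly
antisymmetric — a degenerate configuration that the connectivity stage
rejects as singular, so connectivity analyses should use subjects with three
or more sites. Two baseline windows are parameterized rather than
hard-coded: −100..+50 ms for time-domain display and −100..+100 ms as the
DC-offset correction of the connectivity path.

## Spectral estimation

Single-trial spectra use Welch's method under a fixed convention: the
600-sample epoch is z-scored, split into eight Hamming-tapered segments with
50% overlap (segment length `floor(600/4.5)` = 133 samples), each segment
zero-padded to 1000 samples so the periodogram lands exactly on a 1 Hz grid,
and evaluated at 2–100 Hz with the 56–63 Hz line-noise bins removed (91
bins). Eight segments of a 600-sample window force short segments with
native resolution ≈ 7.5 Hz; zero-padding to the 1 Hz grid is the only
convention consistent with both the segment count and the grid. The absolute
one-sided scaling constant is irrelevant downstream because of z-scoring and
the ratio normalization; the scale-invariance property test asserts exactly
this.

Each site's trial spectra are then normalized bin-wise by the mean over
*all* of that site's trials (both conditions pooled — the most direct
reading of "across all experimental conditions"; using condition-averaged
denominators instead would only rescale both conditions identically), so the
per-bin mean of the normalized values is 1 and condition differences reflect
spectral shape and post-onset dynamics only. Condition averages (one Scr and
one Seq spectrum per site) feed the PCA.

## PCA and projections

Pooled PCA is centered (variance fractions are only meaningful for centered
PCA; the source procedure is silent on centering) and uses the full
deterministic decomposition, so it is seed-free. PC1's sign is fixed by
requiring a positive mean loading above 10 Hz, i.e. PC1 points in the
broadband power-increase direction; every downstream statistic is invariant
to this choice (sign-equivariance is tested), it only makes weight signs
readable. Per-subject projections are leave-one-subject-out: the PCA is
refitted on the condition-averaged spectra of the other subjects
(condition-averaged rather than single-trial rows, mirroring the pooled-PCA
input), and the held-out subject's single-trial spectra are centered with
the fitted mean and projected onto oriented PC1.

## Encoding model

Per site, projections are regressed on a binary design with a scrambled
indicator, a sequential indicator and an intercept. The two indicators are
exhaustive, so the design is rank-deficient; the minimum-norm least-squares
solution is used, and the exported "predicted weight" of a condition is the
model's *predicted projection* for that condition (indicator weight +
intercept), which is invariant to the parameterization and equals the
per-condition training mean. Accuracy is the mean over 10 Monte-Carlo folds
(17 train / 27 validation, folds drawn independently with trials reused
across folds — the reading implied by random sampling) of the Pearson
correlation between predicted and observed validation projections;
degenerate folds score 0 with a warning. Significance comes from a
condition-swap permutation null that recomputes the accuracy under permuted
labels with the same fold sets, with the add-one estimator
`p = (1 + #{null ≥ obs}) / (n_perm + 1)` so p is never exactly 0. No fixed
correlation threshold is hard-coded: the permutation quantile defines
significance for each dataset. α = 0.05 throughout; `n_perm` defaults to
1000 at desk scale (10000 reproduces the source convention at ~10x cost).

The first-vs-rest analysis groups single-trial projections (not refitted
models — the simplest consistent reading) into condition x phase cells per
region and compares cells with rank-based Kruskal–Wallis tests.

## Decoding

Trials are stimulus-indexed and pooled across subjects: every subject saw
the identical sequence, so "trial k" is well defined across subjects and a
cross-subject pattern vector per trial is meaningful even though no
within-trial simultaneity across subjects exists. This pooling is an
interpretation, flagged as such. Sites are ranked by encoding accuracy
(ties broken lexicographically so the ranking is deterministic); for each
ensemble size n the top-n sites are taken and a uniform random half is
drawn, 10 times. Each held-out test trial's measured pattern is correlated
with per-condition patterns predicted by leave-one-trial-out condition
regressions over the full 56-trial pool (the tested trial is excluded even
when it is a test trial); the larger correlation wins, exact ties and
zero-variance patterns score as failures (conservative). Chance is 50%.

Pattern-correlation decoding has signal only when site weights are
heterogeneous: if every site carried the same condition contrast the
predicted pattern would be nearly constant and its correlation with any
measured pattern undefined or noise-dominated. The generator's
opposite-signed frontal/temporal effects provide that heterogeneity, as do
the synthetic projection fixtures used in tests.

## Connectivity

Pairwise Granger causality is computed per condition for every
within-subject pair (cross-subject pairs are physically meaningless), on the
100–500 ms post-onset windows after DC-offset correction. Trials are treated
as realizations: lagged regressions pool rows across trials without ever
crossing a trial boundary. For each direction the full model regresses the
target on its own and the source's past, the restricted model on its own
past only; the statistic is `ln(σ²_restricted / σ²_full) ≥ 0` and each
direction gets a one-directional F-test on the added lags (the
model-comparison form of the two-Wald-statistics formulation). A couplet is
called when the larger-GC direction is significant at α; exact ties yield no
couplet. The AR order is not recoverable from the source toolbox call, so it
is configurable with a default of 5 samples (5 ms) — chosen to cover the
generator's 5 ms coupling lag — and an AIC-based selector over a common
estimation sample is provided (`select_gc_order`); AICs computed on
different sample lengths are not comparable, hence the common-sample
restriction.

Couplets pool across subjects into 6x6 source-region x sink-region count
tables per condition (raw pooled counts, not availability-normalized). The
omnibus contrast flattens the cells into a 2 x cells condition-by-cell
layout, drops cells empty under both conditions (zero expected count,
reported back), and computes the Pearson chi-square; post-hoc per-cell
standardized adjusted residuals are converted to two-sided normal p-values
and Bonferroni-corrected over the tested cells ("adjusted p-value" is not
otherwise specified at the source, Bonferroni is the conservative choice).
Lateralization questions use Fisher's exact test on the 2x2
condition x (specific lateralized pair vs other couplets) table.

Two statistical caveats are inherent to the couplet rule and verified by
simulation in the test suite: under the null the couplet false-positive rate
is approximately `1 − (1 − α)² ≈ 0.098` at α = 0.05, not α, because the
significant direction is selected as the larger of two statistics; and the
F-test p-values themselves are calibrated (≈ α false-positive rate per
direction).

## Problem sizes and reproducibility

The analysis scripts run a 13-subject cohort with 6 sites per subject
(2 frontal, 2 temporal, 1 parietal, 1 insular) and `n_perm = 1000`; the
test suite validates calibration at 200 null sites and recovery at 24
effect-bearing sites, sizes chosen so the whole suite completes in a few
minutes on one CPU while keeping binomial intervals informative. The
acceptance script re-estimates the null decoding benchmark from 100
independent 20-site null simulations. Every stochastic function takes an
explicit seed and the pipeline fans one master seed out to fixed per-stage
offsets, so identical configurations reproduce byte-identical tables.

## Known limitations

* The generator's effect sizes, noise amplitudes and coupling coefficients
  are testability choices; absolute accuracies and site counts on synthetic
  data do not transfer to clinical recordings.
* Common-average referencing over few sites leaves residual correlation
  between sites (and exact antisymmetry for two-site subjects), which
  inflates apparent connectivity; the analysis configuration uses ≥ 3 sites
  per subject and within-subject pairs only.
* The Welch segmentation convention (133-sample segments zero-padded to
  1 kHz) yields strongly correlated neighboring 1 Hz bins; the 91-bin grid
  should be read as a smooth spectral profile, not 91 independent estimates.
* Pairwise (bivariate) Granger causality cannot distinguish direct from
  mediated influence; no conditional or spectral variant is provided.
* The signal container is a plain-text matrix CSV plus event/site CSVs —
  adequate for desk-scale synthetic cohorts, not for full-length clinical
  recordings.
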