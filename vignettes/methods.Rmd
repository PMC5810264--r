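---
title: "Methods: single-trial ERP analysis with trialerp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-trial ERP analysis with trialerp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialerp)
```

## The problem

Traditional ERP analysis averages EEG trials within participants and
conditions and compares the averages with repeated-measures ANOVA. That
discards everything that varies from trial to trial — response times,
accuracy, stimulus identity — and weights every participant's average
equally regardless of how many clean trials contributed to it. trialerp
implements the alternative: keep **every trial of every participant** in one
3-D array (channels × samples × trials), matched row-for-row with a
behavioral metadata table in the original recording order, and run the
statistics on single trials with (generalized) linear mixed models. A
cluster-based permutation test over the channel × time space selects regions
and time windows of interest without investigator degrees of freedom.

## Preprocessing model

The chain is fixed and deterministic: average reference (with recovery of
the recording reference as a data channel) → zero-phase band-pass → epoch →
baseline correction → artifact flagging. Ocular correction is deliberately
out of scope; users can insert their own between referencing and filtering.

- **Average reference.** With *n* recorded scalp channels referenced
  against an electrode *R*, the re-referenced value of channel *i* is
  `x_i − sum(x_scalp)/(n+1)` and `R` is recovered as `−sum(x_scalp)/(n+1)`;
  the per-sample mean over all *n+1* scalp channels is then exactly zero
  (tested to 1e-9 µV). Non-scalp channels (EOG) are re-expressed but never
  enter the average.
- **Filter realization.** Only the cutoffs (0.5 and 40 Hz by default) are
  part of the contract; the realization is a 4th-order Butterworth
  high-pass and low-pass cascade, each applied forward–backward
  (`signal::filtfilt`), chosen because zero phase preserves component
  latencies. A symmetric pulse keeps its peak to within one sample.
- **Windows are half-open.** The epoch window `[−200, 800)` ms at 500 Hz
  contains exactly 500 samples; the sample at *t* = 0 is the first
  post-stimulus sample and the baseline `[−200, 0)` excludes it. With 65
  channels this yields 65 × 400 = 26,000 analyzable post-stimulus values
  per trial.
- **Artifacts are flags, not deletions.** A trial is invalid iff any
  channel exceeds ±150 µV at any sample or any consecutive-sample
  difference exceeds 50 µV. The gradient step is one sample (2 ms at
  500 Hz), matching common amplifier-software semantics; both thresholds
  are configurable. Flags are applied after baseline correction
  (configurable by reordering the calls) and the data stay in the store, so
  behavioral analyses keep the full trial count while ERP extraction masks
  invalid trials as `NaN`.
- **Edge events are dropped**, with their indices logged, rather than
  zero-padded: padding would fabricate data.

## The trial store

`build_store()` aligns EEG and behavior strictly by
*(participant, ordinal position in recording order)* — never by content —
and any count mismatch is a hard error naming the participant. This is the
contract that makes every downstream subset trustworthy:
`subset_trials(store, response == "hit" & rt_ms < 1000)` composes like a
conjunction and preserves order. The container persists to HDF5 with a
versioned schema (arrays as float64, factor levels stored explicitly) and
round-trips losslessly; a file with a different schema version is rejected
rather than guessed at. Deviant position keeps all four levels at
ingestion; the left/right dichotomy is produced by the analysis filters,
not hard-coded into the data.

## Cluster-based permutation test

The test asks whether two within-subject conditions could be exchangeable.
At every (channel, sample) point a paired *t* statistic is computed across
participants from condition averages; points with |t| beyond the two-tailed
Student quantile at `cluster_forming_p` (default 0.05, df = n−1) are
clustered. Two suprathreshold points connect iff they carry the same sign
and are either the same channel at consecutive samples (±1 sample) or
adjacent channels (Euclidean distance ≤ `max_dist` in montage units) at the
same sample. Each cluster's mass is the sum of its member *t* values. The
null distribution of the **maximum absolute cluster mass** is built by
flipping each participant's condition labels independently (equivalently,
sign-flipping the difference waves) `n_permutations` times; when
`n_permutations ≥ 2^n` all sign patterns are enumerated and the test is
exact. Implementation note: squares are invariant under sign flips, so all
permutation *t* maps are obtained from a single matrix product.

Numerical choices:

- the Monte-Carlo p value is `(1 + #{null ≥ |mass|}) / (n_permutations + 1)`,
  which includes the observed statistic and guarantees the validity of the
  test; under exact enumeration the plain proportion is used;
- zero-variance points get `t = ±Inf` with the sign of the mean difference
  (suprathreshold by construction) — this only arises in degenerate
  synthetic data and is documented rather than hidden;
- positive and negative clusters are formed separately but compared against
  the shared max-|mass| null (a two-sided test);
- no minimum-neighbor-count constraint is imposed; isolated channels can
  form single-channel clusters (a warning is raised if the distance
  threshold leaves channels without neighbors);
- only the paired (within-subject) design is implemented.

The central guarantee — family-wise error control on exchangeable data —
is measured empirically by the test suite and the acceptance script: on 200
simulated null experiments (12 participants, 16 channels, 50 samples,
spatially correlated 1/f noise, 500 permutations) the proportion of
experiments with any significant cluster at α = 0.05 must stay within two
binomial standard errors of 0.05.

## ERP estimation

`condition_averages()` computes participant × condition cell means, records
per-cell trial counts, and flags empty cells instead of zeroing them.
`regression_erp()` fits ordinary least squares independently at each
(channel, sample) point from the trial metadata; with a one-hot condition
design it reproduces the condition means exactly (to 1e-8 µV) — averaging
is a special case of least squares — and with continuous covariates it
estimates amplitude slopes. The design matrix is solved once by QR with an
explicit rank check naming collinear columns. ERP images (`erp_image()`)
are raw single-trial rows sorted stably by a behavioral key; no smoothing
is applied because the statistics must come from unsmoothed data.

## Mixed models

The solver is lme4 (with lmerTest's Satterthwaite degrees of freedom for
gaussian fits); the package owns the modeling policy around it:

- **Sliding-difference contrasts** on every factor: each coefficient is the
  difference between successive levels and the intercept is the unweighted
  grand mean of cell means, which keeps multi-predictor models
  interpretable. For two levels the codes are ±1/2.
- **Singular-term pruning** (`prune_singular_random_terms()`): while a fit
  is singular or any random-effect SD falls below 1e-6 × residual SD
  (1e-6 absolute for binomial models), the smallest offending term is
  removed — slopes always before their group's intercept, and the last
  intercept never — and the model refit. The removal order is
  deterministic and logged.
- **Stepwise fixed-effect reduction** (`reduce_fixed_effects()`): only
  terms not marginal to a retained interaction are candidates; the
  candidate with the worst coefficient p value (ties: higher order first)
  is dropped and the smaller model tested against the larger by a
  likelihood-ratio test on ML refits. Reduction stops when the smaller
  model is significantly worse (p < α). Each step records ΔX², ΔAIC, ΔBIC.
- **REML vs ML**: variance components are reported from REML fits; all
  likelihood-ratio comparisons refit with ML, since REML likelihoods are
  not comparable across fixed-effect structures.
- **Nested follow-ups** (`nested_followup()`): a significant interaction is
  decomposed by refitting with `outer + outer:inner` replacing the inner
  main effect and the interaction — identical otherwise, including the
  random structure — which yields the inner effect at each outer level.
  Unused factor levels (e.g. the top/bottom deviant rows after filtering)
  are dropped before nesting; a declared level that is present but has no
  usable data is an error naming it.
- **Partial effects** (`partial_effects()`): remef-style adjusted
  responses `y − X_removed b_removed − Zu`, for visualizing one effect with
  others (and optionally all random effects) removed. Removing nothing is
  the identity; removing everything leaves the residuals.
- **Rescaling** (`rescale_amplitudes()`): dividing µV covariates by 10
  keeps the optimizer well conditioned next to millisecond responses;
  slopes then read "per 10 µV" and scale exactly inversely.

## The synthetic generator

`ground_truth()` encodes the emulated study: 40 participants × 1920 trials
in 5 blocks of a 2 (perceptual certainty: blurred/intact) × 4 (deviant
position: left/right/top/bottom) visual search, a 200 ms stimulus and 2 s
response timeout, 500 Hz epochs from −200 to 800 ms, and two ERP
components — a fronto-central negative N2 (250–350 ms, ROI FC1, FC2, C1,
Cz, C2) and a centro-parietal positive P3b (400–550 ms, ROI CP3, CP1, CPz,
CP2, CP4, P3, Pz, P4, PO3, POz, PO4). Latent single-trial component
amplitudes carry fixed condition effects plus crossed by-participant and
by-item random intercepts and slopes; epochs are those amplitudes times a
Gaussian spatial profile and a squared-sine temporal kernel, plus noise;
behavior is generated from the *same* latent amplitudes (RT: gaussian
around a linear predictor, truncated at the timeout into misses; accuracy:
Bernoulli through a logistic link), so brain–behavior effects are
recoverable by construction. Spatial weights are normalized so the
noise-free ROI/window mean equals the latent amplitude exactly, which makes
recovery tests sharp.

Default magnitudes sit at the scale of published single-trial estimates
for this paradigm: an RT certainty effect near −30 ms with by-participant
intercept/slope SDs near 50/15 ms and a residual SD near 90 ms; N2 around
−3.4 µV with a −0.9 µV certainty effect; P3b around +4.2 µV with +1.2 µV;
RT slopes of roughly +13 and −32 ms per 10 µV of N2 and P3b. The noise
model is spatially smoothed 1/f-plus-white noise (default 8 µV per sample,
60% pink), because the permutation test's calibration must hold under the
spatio-temporal correlation that real EEG exhibits and that the cluster
method exploits. Artifacts are injected as 400 µV pulses at a 2% trial
rate.

What the generator does **not** emulate: volume-conducted component
overlap beyond the two templates, eye movements and their correction,
non-stationary noise, impedance drifts, or any biophysical forward model.
Passing tests therefore demonstrate the pipeline's statistical and
algorithmic correctness under realistic correlation structure — not that
any particular empirical dataset would yield particular clusters.

## Problem sizes and reproducibility

Tests and the acceptance script run at desk scale by choice: 2–20
participants, 8–64 trials, 16 channels, and 100 Hz sampling where full
temporal resolution adds nothing to the property under test; the
paper-scale defaults (40 × 1920 at 500 Hz) remain the generator's defaults
and are exercised for design arithmetic. Every stochastic step takes an
explicit seed; child seeds are derived by one draw from a seeded stream, so
a single `--seed` reproduces a whole pipeline run bit-for-bit (the cluster
table and manifest contain no timestamps).

## Known limitations

- The CBPT operates on participant-level condition averages, so it cannot
  model item variance or continuous covariates; it is a screening tool,
  and its conclusions can differ from the single-trial mixed models run on
  the windows it selects.
- `partial_effects()` is defined for gaussian fits only.
- BrainVision support covers the dominant dialect (binary, multiplexed,
  INT_16 / IEEE_FLOAT_32); vectorized and ASCII files are rejected
  explicitly.
- Satterthwaite p values come from the backend; if a future backend lacks
  them the package falls back to a normal approximation and says so.
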