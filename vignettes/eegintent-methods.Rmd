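---
title: "Subject-wise EEG classification of malicious intent: models, parameters, and design choices"
author: "eegintent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-wise EEG classification of malicious intent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A scenario-reading paradigm for insider-threat screening presents a subject
with short written scenarios — ten describing situations in which the reader
is pressured to act as a malicious insider at a nuclear facility, and ten
describing everyday conflicts — while 21-channel scalp EEG (extended 10-20
montage, 500 Hz) is recorded for 30 s per scenario, followed by a yes/no
answer. Two binary questions are asked of the signals, always *within* a
single subject:

* **intent**: among the insider scenarios, did this subject answer *yes*
  (affirming the malicious act) or *no*?
* **scenario type**: was the scenario being read an insider-threat scenario
  or an everyday-conflict scenario?

The neurophysiological premise is that contemplating a harmful act shifts
the balance of fast and slow cortical rhythms — beta-band power rises while
alpha-band power falls — and that the two scenario families engage
measurably different levels of arousal and signal complexity.

This package implements the entire computational chain as reusable,
seed-deterministic functions: a synthetic-data generator that emulates the
recordings (which were never deposited), the cleaning and epoching recipe,
a 65-feature-per-channel catalogue, two random-forest-based automatic
feature selectors, and the subject-wise leave-one-question-out evaluation
with per-fold classifier tuning and epoch majority voting. The numbered
scripts under `analysis/` narrate a small end-to-end run; every step they
take is a package function covered by the test suite.

## The synthetic-data generator

`make_design()` lays out the cohort: by default 25 subjects x 20 questions
(10 insider + 10 conflict) in per-subject random order. Answers are drawn
with the empirical rates of the original cohort (96/242 *yes* among
answered insider questions, 150/248 among conflict questions), and 2% of
questions are dropped as unanswered (10/500 in expectation).

`synthesize_question_recording()` builds each 21 x 15000 sample trial as a
sum of

* a 1/f background (power density ~ 1/f, floored below 0.5 Hz; ~8 uV RMS),
* band-limited Gaussian oscillations for theta (4-8 Hz), alpha (8-13 Hz)
  and beta (13-25 Hz), each split into a *shared* source projected through
  a smooth scalp gain profile (alpha posterior-dominant, beta anterior) and
  a *channel-local* part — scalp rhythms are strongly but not perfectly
  coherent across channels, and the shared part is what gives neighboring
  channels the correlation that bad-channel detection relies on,
* a small broadband white component (1.5 uV RMS), and
* per-subject random log-amplitude offsets (SD `subject_variability`,
  default 0.1) that give each subject a stable spectral profile.

Two effect dials plant ground truth. `intent_effect` shifts beta-band
log power up and alpha-band log power down for *yes* answers within insider
questions; `scenario_effect` applies the same contrast between insider and
conflict questions and additionally scales the broadband component, which
moves the entropy features. A subtlety worth recording: the analysis chain
ends in an average re-reference, which removes the across-channel mean of
every shared source. The band scale factors are therefore solved *in
re-referenced terms* — a per-band scale uniform across channels commutes
with the average reference, so the generator can compensate exactly for the
in-band 1/f and broadband background and deliver the requested mean
log-power shift in the signal the features actually see. Without this, a
nominal shift of 1.0 arrived at the feature tables as roughly 0.25 and no
classifier could meet the strong-signal expectations. At zero effects the
two classes are exchangeable by construction, which the tests verify
distributionally (two-sample KS on beta/alpha ratios).

Artifacts (`inject_artifacts()`) are additive and individually switchable:
a 50 Hz mains sinusoid (the study's mains frequency; configurable),
slow sinusoidal drift below 0.5 Hz, ~300 ms raised-cosine blink transients
concentrated on FP1/FPz/FP2 with 25% spillover onto the frontal row, and an
optional dead (flat) channel. An all-zero configuration is the identity.

The effect is constant over the 30 s of a question; a ramping profile is a
plausible alternative the generator does not currently model. Other known
non-realisms: no eye-movement or muscle spectra, no heavy-tailed artifact
bursts, no nonstationary alpha blocking, and channel-local noise is white
or 1/f rather than physiological. A green test therefore establishes that
the *pipeline* recovers planted band-power and complexity contrasts at
realistic amplitudes — not that it would perform identically on human data.

## Preprocessing

`preprocess_recording()` applies, in fixed order: anti-aliased decimation
to 250 Hz (8th-order zero-phase Butterworth at 0.8 x the new Nyquist);
a zero-phase 4th-order 1 Hz Butterworth high-pass; zero-phase notches
(1 Hz bandwidth) at the mains frequency and its first harmonic; flat-line
(variance < 1e-10 uV^2) and low-neighbor-correlation (max |r| < 0.4)
bad-channel detection with inverse-squared-distance interpolation on the
unit-sphere montage; and an average re-reference across all 21 channels.
More than 50% bad channels rejects the recording with an error. Every step
is appended to a log carried by the recording.

The interactive stages of the original EEGLAB recipe — artifact subspace
reconstruction and ICA with visual component inspection — are deliberately
replaced by the automated bad-channel stage plus an optional
amplitude-threshold epoch rejection (off by default); the log makes the
substitution explicit so real cleaning can be slotted in upstream.

Epoching (`epoch_question()`) cuts full 2 s windows at 1 s steps, so a 30 s
question yields exactly 29 epochs. The "1 s moving average" of the source
description is read as a 1 s sliding step — the only reading consistent
with 29 epochs — and the "< 1 s removed" rule is applied to whole short
recordings (a 1-2 s recording becomes one short epoch; under 1 s, none),
not as an extra partial tail window, which would contradict the printed 29.

## The feature catalogue

65 features per channel per epoch, in four families (all deterministic):

* **Time domain (9)** — mean, mean square, median, peak-to-peak,
  bias-uncorrected skewness, Pearson (non-excess) kurtosis, and the Hjorth
  parameters: activity (variance), mobility `sqrt(var(dx)/var(x))`,
  complexity `mobility(dx)/mobility(x)`. For a sampled sinusoid of
  frequency f, mobility has the closed form `2 sin(pi f / fs)`, which the
  tests check against direct differencing.
* **Wavelet (24)** — a 5-level Daubechies-4 decomposition; per subband
  (D1..D5, A5): relative energy, Shannon entropy of the within-subband
  coefficient energy fractions (natural log), maximum squared coefficient,
  and the variance of squared coefficients. The transform uses *periodized*
  boundary handling with the epoch truncated to a multiple of `2^levels`
  samples (480 of 500), which makes it exactly orthonormal: subband
  energies sum to signal energy to machine precision, and at 250 Hz D1
  covers 62.5-125 Hz. Symmetric padding was considered and rejected
  because it breaks energy conservation, which the acceptance suite
  requires at 1e-6.
* **Spectral (28)** — a single Hann-windowed periodogram per epoch (0.5 Hz
  resolution at 2 s; Welch averaging has no room at this length); per band
  (delta 1-4, theta 4-8, alpha 8-13, beta 13-25, high beta 25-30, gamma
  30-40, high gamma 40-50 Hz, half-open `[low, high)` with the last band
  closed at 50): absolute power, relative power (over the seven bands),
  maximum spectral value, and its frequency.
* **Nonlinear (4)** — approximate and sample entropy (m = 2,
  r = 0.2 x SD, Chebyshev distance; parameters are conventional since the
  source states none), permutation entropy (order 3, delay 1, normalized by
  log 3!), and the Grassberger-Procaccia correlation dimension (delay =
  first autocorrelation zero crossing capped at 10 samples, embedding
  dimensions 2-8, radii log-spaced over the 10th-50th percentile of
  pairwise distances, slope by least squares in log-log coordinates,
  estimate = median slope of the three largest dimensions; point clouds
  are stride-subsampled to 200 points to bound the quadratic cost).

Degenerate inputs (constant or all-zero signals) return zeros with a flag
rather than erroring, and the flags are surfaced in the feature table's
`degeneracies` attribute and the pipeline report.

Normalization is a `fit_scaler()`/`apply_scaler()` pair: per-column z
scores learned from *training rows only*. The source text's "across the
subjects and trials" wording would leak test-fold statistics into training
if taken globally; this implementation deliberately fits per training fold
and documents the deviation here.

## Feature selection

Both selectors ride on a compact random forest implemented in this package
(gini-split CART ensemble with bootstrap, out-of-bag error, impurity and
permutation importance) because the execution environment provides no
random-forest package. Two choices matter and were made on measured
evidence, not convenience:

* **Importance measure.** The Boruta-style wrapper ranks by *z-scored OOB
  permutation importance* (mean over trees divided by its standard error),
  the published default. Raw impurity importance is offered as a fast
  option but was measurably anticonservative on the planted benchmark
  (false confirmations in pure-noise runs).
* **Shadow pool width.** Shadows are fresh permutations of *every* original
  column at every iteration. If shadows shrink with the active set, late
  iterations compare the surviving columns against an ever-weaker
  max-shadow reference, and the sequential binomial test then converts
  fixed chance associations into confirmations (observed: 14/20 pure-noise
  runs with false confirmations before the fix; 0/20 after).

The Boruta-style wrapper runs at most 100 iterations, testing each
undecided column's hit count (importance above the best shadow) against
Binomial(n, 1/2) with two one-sided tests at alpha = 0.01, Bonferroni-
corrected across columns; testing starts after five rounds. Confirmed plus
still-tentative columns are passed downstream (the inclusive policy keeps
small folds from ending empty). The varSelRF-style eliminator ranks once by
permutation importance on an initial 500-tree forest, drops the worst 20%
per round (floor two columns), refits 200-tree forests recording OOB error,
and returns the smallest set within one standard error of the minimum;
importance is not recomputed during elimination, matching the published
default. The original tree counts (5000/2000) are scaled to 500/200 for
desk-size folds.

When the evaluation layer calls a selector it passes question IDs, and the
forests then bootstrap *whole questions*: with an epoch-level bootstrap,
out-of-bag epochs come from questions present in the bag, so importance
rewards within-question memorization — on synthetic data this made Boruta
reject genuinely informative band-power features while confirming none of
its own. Grouped resampling makes importance measure exactly the
across-question generalization that the outer cross-validation demands.
The iid selection benchmark (no groups) is unaffected.

## Evaluation

`run_subject_cv()` evaluates one subject with leave-one-question-out folds:
the intent task trains on the subject's other nine insider questions, the
scenario task on the other 19 questions. Per fold — strictly on training
rows — the scaler is fitted, the selector is run, and the classifier is
tuned by question-grouped 3-fold internal validation over its grid:
kNN k in {1,3,5,7,9}; RBF-SVM C in 10^(-1..3), gamma in 10^(-4..0)
(trained by SMO); Gaussian naive Bayes untuned; one-hidden-layer MLP with
width in {5,10,20} (tanh hidden layer, logistic output, 200 full-batch
gradient-descent epochs with momentum 0.9, seeded initialization). Ties in
the grid break to the earlier row, so tuning is deterministic given the
seed. kNN comes from FNN; the SVM and MLP are implemented here (no
e1071/nnet in the environment).

The held-out question is decided by epoch majority vote: the score is the
fraction of epochs predicted positive and the label is positive iff the
score strictly exceeds 0.5 — ties (possible only for truncated questions)
go to the negative class ("no" / "conflict"), the conservative choice.
Folds whose training side lacks a class are skipped with a warning and the
accuracy denominator adjusted. Leakage is asserted mechanically: the scaler
records the question IDs it saw and every fold re-derives that the held-out
question is absent.

`aggregate_summary()` averages per-subject accuracies into the selector x
classifier cells; `roc_points()` sweeps thresholds over the observed
question scores (the positive-epoch fraction is one defensible reading of
how question-level ROC curves can be built from majority-vote outputs) and
integrates trapezoidally. `channel_subset_run()` repeats everything on a
named channel subset's 3 x 65 columns — the frontopolar row FP1/FPz/FP2 and
mid-frontal row F3/Fz/F4 mirror the study's helmet-oriented analyses.

### What "chance level" means at zero effect

A label-independent classifier with positive-prediction rate q on questions
whose true positive rate is p has expected accuracy `p q + (1-p)(1-q)` —
*not* the majority-class rate `max(p, 1-p)`; the two coincide only for a
classifier that always predicts the majority. The calibration suite
therefore checks, for every selector x classifier cell at zero effects,
that accuracy lies within the 95% binomial band of the exchangeability
value computed from the cell's own marginals, *and* does not exceed the
majority-rate band's upper edge (the leakage bound). Requiring the cell
mean to sit in a band centered on the majority rate would demand that kNN
at null behave like a majority-class predictor, which is statistically
unfounded; measured cells at null ran 46-55% against a majority rate of
65%.

## Orchestration and reproducibility

`run_pipeline()` drives generate -> clean -> extract -> select -> evaluate
from a single validated configuration (`validate_config()` merges partial
JSON or lists over `default_config()`, rejects unknown keys, and aggregates
range errors). All randomness descends from one master seed through a
Lehmer-style splitting rule (`derive_seed()`), so any subject, question or
fold can be re-simulated in isolation and a rerun at the same seed
reproduces the summary CSVs byte for byte (numeric output is printed with
fixed formatting for exactly that reason). Recordings interchange as plain
numeric text with a JSON sidecar; EDF was dropped because the environment
has no EDF reader and the layout carries the same information. Feature
tables serialize at 17 significant digits, making the CSV round-trip
bit-exact.

## Scale choices in the tests

The acceptance suite runs the full chain at reduced scale and says so:
chance-level calibration uses 10 subjects x 10 insider questions of 6 s
(duration is irrelevant under the null), and the effect-monotonicity grid
uses 3 subjects x 8 questions of 15 s, where the strong-signal check
(boruta + naive Bayes at intent effect 1.0) clears 90% accuracy. Short
questions weaken question-level discriminability — epochs within a question
share one realization of the band sources, so the effective sample size is
the question count — which is why the strong-signal checks use 15 s rather
than the 5-6 s used for shape and smoke tests.

## Known limitations

* The classifiers are binary, which covers both defined tasks; the random
  forest beneath the selectors is K-class-capable.
* The correlation dimension estimator is a bounded-cost approximation
  (subsampled points, fixed radius band); it is stable and monotone on the
  test signals but not a research-grade invariant estimator.
* Boruta's sequential binomial testing has no formal family-wise error
  guarantee across iterations; the measured false-confirmation level at the
  benchmark scale is the justification for the defaults.
* The pipeline's stage isolation writes features and summaries to disk, but
  recordings are only serialized on request (`write_recordings`), so a
  disk-only restart is possible from the feature stage downward.
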