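---
title: "Methods: predicting noise-vocoded speech intelligibility from a cognitive battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting noise-vocoded speech intelligibility from a cognitive battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Noise-vocoded speech replaces the fine spectral structure of a speech
signal with band-limited noise modulated by the slowly varying energy
envelope of each frequency band. It is the standard behavioural model of
the percept delivered by a cochlear implant (CI). Listeners differ
enormously in how much of such speech they understand, and a central
clinical question is whether cognitive tests administered *before*
implantation can predict who will do well. `vocopred` implements the
complete analysis chain for that question: the vocoder itself, scoring of
open-set sentence repetition, derivation of a thirteen-variable cognitive
battery, and a partial least squares (PLS) inference engine that selects
predictive variables without leaking information across cross-validation
folds. Because subject-level data of this kind are rarely shareable, a
calibrated synthetic generator stands in for the human sample, so every
stage is testable end to end.

## The channel vocoder

`vocode()` follows the classic CI-simulation recipe at 16 kHz sampling: a
128-point short-time FFT with 75 % overlap (32-sample hop), FFT bins
grouped into 10 non-overlapping, logarithmically spaced bands, the band
envelope computed as the square root of the total band energy per frame,
and each envelope used to amplitude-modulate a noise carrier whose power
spectrum is flat inside the band and decays at 3.5 dB/octave beyond the
band edges, emulating current spread in an electrically stimulated
cochlea. Modulated carriers are summed and the output is rescaled to the
input RMS.

Choices the recipe leaves open, and what this implementation does:

* **Analysis window.** Periodic Hann, which satisfies constant
  overlap-add at 75 % overlap.
* **Band frequency range.** The low edge defaults to **350 Hz**, the
  high edge to Nyquist. With a 128-point FFT at 16 kHz the bin spacing
  is 125 Hz, and ten log-spaced bands starting lower than about 350 Hz
  leave at least one band with *no* FFT bin; `design_filterbank()`
  refuses empty bands rather than silently merging them, and the default
  is the smallest round low edge at which all ten default bands are
  non-empty. Both edges are configurable for other FFT sizes.
* **Carriers.** Seeded white Gaussian noise shaped in the FFT domain
  (exact expected slope), drawn band after band from a single RNG
  stream, so `vocode()` is bit-reproducible given `noise_seed`.
* **Envelope upsampling.** Linear interpolation between frame centers.
* **Level.** Output RMS is matched to the input (presentation level in
  dB SPL is out of scope).

Properties verified by the test suite: per-frame Parseval consistency of
the band-energy decomposition (to 1e-6 and better), envelope
nonnegativity and homogeneity, carrier spectral slope within
±0.5 dB/octave of the nominal 3.5, band-selectivity of pure tones, and
bit-exact seed determinism.

## Scoring and the response variable

Open-set sentence repetition is scored as the number of accurately
reported words per seven-word sentence (`score_sentence()`): tokens are
lower-cased and stripped of punctuation, matching is order-free, and each
target word is creditable once. No lemmatization or morphological
normalization is attempted — scoring conventions of the original German
corpora are not public, so exact surface match is the declared rule.

The subject-level response is the **median** words-correct over the 60
test sentences (`median_performance()`); medians of 60 integer scores
live on the half-integer lattice 0, 0.5, ..., 7. Learning curves
(`learning_curve()`) use blocks of ten sentences (six blocks) and
aggregate across subjects by the median of per-subject block medians;
the within-group aggregation rule is a package choice, since "median
over blocks" does not itself specify the across-subject summary.
`group_summary()` reports both the pooled (df = n1 + n2 − 2) and Welch
two-sample t statistics for the young/old contrast.

## The thirteen predictors

`derive_predictors()` maps raw records of eight cognitive tests onto the
canonical predictors (see `battery_variables()`): TRT and WST correct
counts, Operation Span letters, the verbal-learning sum over trials 1–5,
delayed-minus-immediate recall, recognition hits, two lexical-decision
reaction-time differences, four trail-making switching costs (subtest k
minus subtest 1), and the Stroop interference cost. The **recall sign**
is implemented literally as trial 7 minus trial 5; published group means
for this variable are positive, which hints the original convention may
have been the reverse, so `recall_convention = "t5_minus_t7"` flips it.
Missing raw fields propagate to missing predictors and
`validate_dataset()` excludes (never imputes) incomplete subjects,
mirroring the Operation Span dropouts that reduce a 41-subject sample to
39.

## PLS regression and VIP

`pls_fit()` implements single-response PLS by the orthogonal-scores
algorithm. For one response the weight vector of each component is
closed-form, `w = E'f / ||E'f||`; scores are `t = E w`, predictor and
response blocks are deflated by `t p'` and `t q` respectively, and
regression coefficients for any number of components come from
`W (P'W)^{-1} q`. Predictors are **standardized to unit variance by
default**: the battery mixes counts with reaction times in milliseconds
and seconds, and covariance-scale PLS would be dominated by the
largest-variance RT difference. `scale = FALSE` reproduces the
covariance-scale alternative, and the acceptance-level tests exercise the
scaled mode while the invariance tests cover both.

Variable importance in projection follows the standard Wold/Chong–Jun
definition: `VIP_j^2 = p * sum_a SS_a w_ja^2 / sum_a SS_a` with
`SS_a = q_a^2 t_a't_a` the response variance explained by component a,
so `sum_j VIP_j^2 = p` identically. `explained_variance()` reports
per-component percentages of predictor-block and response variance;
`loadings_report()` tabulates signed loadings (reaction-time variables
load negatively on a performance component).

Numerical safeguards: zero-variance predictors raise an error naming the
variable; requested components beyond `min(n - 1, p)` or beyond the
effective rank are truncated with a warning; a response carrying no
covariance with the predictors yields the intercept-only model. At full
rank the fit coincides with ordinary least squares to 1e-10, and random
problems agree with an independent reference PLS implementation
(`mixOmics`) to 1e-8 — that package is used only as a cross-check oracle
in the tests, never as the implementation.

## Selection inside the cross-validation loop

The inference engine (`loocv_with_selection()`) reproduces the two-step
design: for every left-out subject, a preliminary 2-component PLS on the
*training subjects only* ranks all thirteen variables by VIP (ties broken
by canonical order), the top *j* are kept, a 2-component model is fitted
on the training set, and the held-out subject is predicted with 0
(training mean), 1 and 2 components. Keeping selection inside the fold
is the point: selecting on the full sample first leaks response
information into the "out-of-fold" errors. The deliberately leaky
variant is available (`select_within_fold = FALSE`) purely to demonstrate
that bias, and the acceptance suite confirms on zero-signal data that
in-fold selection yields the larger (honest) MSEP.

Component significance uses a **paired sign-flip permutation test**
(`paired_permutation_test()`): the statistic is the mean of the paired
squared-error differences (reference minus candidate), the null is
generated by independent random sign flips, and the one-sided p-value is
`(#{permuted >= observed} + 1)/(B + 1)` with B = 10000 by default. The
precedent for comparing cross-validated prediction errors is a
randomization test on paired model errors; the exact statistic of the
original analysis is not documented, so this choice is declared rather
than inferred, and the function is a swappable component. Type-I error
at the 5 % level is verified by simulation to sit in [0.035, 0.065].

`sweep_variable_counts()` repeats the analysis for j = 2..13 and
tabulates p-values and MSEP per component — the machine-readable
equivalent of the p-value/MSEP-versus-variable-count figures.
`subgroup_tests()` restricts the paired error differences to each age
group while always training on the whole sample. `evaluate_final()`
cross-validates the chosen variable set without further selection and
reports the Pearson correlation between out-of-fold predictions and the
observed response; its permutation p permutes the response labels and
**recomputes the entire LOOCV per permutation**, which is cheap at
n ≈ 40 and avoids the optimism of permuting against fixed predictions.
No multiple-testing correction is applied across the j-sweep, matching
the presentation style this mirrors. `exhaustive_subset_regression()`
provides the independent best-subset OLS cross-check (exact LOOCV via
the hat-matrix identity), and `rerun_excluding_zero_scores()` repeats
the whole analysis without floor-scoring subjects and reports the
overlap of the selected sets.

## The synthetic battery generator

`generate_battery()` draws each subject's thirteen predictors and
response from a **single latent factor** model ("cognitive efficiency"):
on the standardized scale predictor j is
`lambda_j * g + sqrt(1 - lambda_j^2) * e`, then shifted/scaled to the
configured group mean and SD, so marginal group moments are exact in
expectation. One factor with signed loadings is the simplest structure
that reproduces a single dominant predictive component with
reaction-time variables loading negatively; the default loading pattern
is chosen so that implied predictor-response correlations
(`lambda_j * beta`, response loading beta = 0.75) mirror the observed
univariate correlation pattern — strongest for TRT and Operation Span,
negative for the trail-making cost, weak for vocabulary.

The response is driven by the same latent factor, mapped to the
half-integer median lattice, clipped to [0, 7], and **floor-inflated**:
with probability `floor_mass` (default 0.15, the observed rate of
zero scorers: six of forty-one subjects) a subject scores 0. Rounding,
clipping and floor inflation all bias a naive normal mean, so the
generator solves analytically (normal lattice-bin probabilities +
`uniroot`) for the pre-transform center that makes the *post-transform*
expected response equal the configured group mean. Group response SDs
are consequently approximate; means are exact, and the acceptance suite
confirms the six calibration targets within 3 Monte-Carlo standard
errors at 500 replicates.

`generate_trial_records()` adds 60 sentence trials per subject (integer
scores with a mild block-wise learning trend, repaired so the median
equals the subject's response exactly) and one row of raw test records
built to invert `derive_predictors()`. Count-valued raw fields are
integers clamped to their feasible test ranges (e.g. at most 15 words
per learning trial), so the predictor round-trip is exact for
reaction-time measures and within integer rounding for counts, except
for the rare subjects whose Gaussian battery draw falls outside a
feasible range.

What the generator does **not** emulate: test-retest reliability,
session-order effects, age-specific correlation structure beyond the
group mean/SD shifts, non-Gaussian predictor tails, and any dependence
of trial difficulty on sentence material. Passing tests therefore show
that the pipeline recovers structure *of this kind*; they cannot certify
behaviour on real batteries with richer dependence.

## Problem sizes and seeds used in the checks

The packaged checks run at desk scale, sized to keep the full suite
around half a minute: 50 random problems for the OLS-equivalence check;
2000 replicates at B = 999 for permutation calibration; 200 replicates
of n = 39, p = 13 zero-signal batteries for the anti-leakage property;
200 replicates of the strong-loading configuration (five signal
variables at |0.85|) for selection recovery; 500 replicates for
generator calibration. All simulations are seeded; identical
config + seed reproduces identical datasets, reports and p-values.

## Known limitations

* The headline numbers of the human study (six selected variables,
  43 %/54 % explained variance, cross-validated r of 0.53/0.63) depend
  on a non-deposited 39-subject sample and are not reproducible here;
  the package reproduces the *procedure* and its statistical properties.
* The sign-flip scheme for comparing prediction errors and the
  label-permutation scheme for cross-validated correlations are declared
  design choices; other randomization schemes are defensible.
* The vocoder band edges at the default FFT resolution cannot extend
  below about 350 Hz (see above); use a longer FFT for lower bands.
* `evaluate_final()` with the default B = 10000 recomputes 10000 full
  LOOCVs; at n = 40 this takes on the order of a minute.
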