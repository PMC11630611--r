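---
title: "Likelihood-ratio evaluation of vowel-formant evidence: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-ratio evaluation of vowel-formant evidence: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formantlr)
```

## The problem

Forensic voice comparison asks how strongly a piece of acoustic evidence
supports the hypothesis that two speech samples come from the same speaker
(Hs) rather than from different speakers (Hd). `formantlr` evaluates one
family of such evidence — vowel formant frequencies F1–F4 (vocal-tract
resonance peaks, in Hz) — under the likelihood-ratio (LR) paradigm, for
male Brazilian Portuguese speakers producing the seven oral monophthongs
/i e ɛ a ɔ o u/ in two speaking styles, spontaneous *dialogue* and
*interview*. The central question the pipeline answers is how much
speaker-discriminatory power individual formants and formant combinations
retain when the compared samples come from the same style (matched) versus
from different styles (mismatched: interview as the known *reference*
material, dialogue as the *questioned* material — the configuration of a
typical casework comparison).

## The scoring model

Evidence is scored per vowel and per formant subset by a two-level
multivariate kernel-density (MVKD) model fit on a background population of
`m` speakers:

* **Within-speaker variation** is multivariate normal with pooled
  covariance `W`, estimated by summing each background speaker's centered
  token cross-products and dividing by `N − m`.
* **Between-speaker variation** is a kernel density over the background
  speakers' mean vectors: an equal-weight mixture of normal kernels
  centred at the `m` means with covariance `h²B`, where `B` is the
  covariance of the means (divisor `m − 1`) and
  `h = (4 / ((2d + 1) m))^(1/(d+4))` is the normal-reference bandwidth for
  dimension `d`.

For a questioned sample with mean vector `ȳ_q` (n_q tokens) and a
reference sample with mean `ȳ_r` (n_r tokens), the same-source numerator
integrates a common unknown source mean over the kernel density, giving an
equal-weight mixture of bivariate (2d-dimensional) normals with block
covariance `[[h²B + W/n_q, h²B], [h²B, h²B + W/n_r]]`; the
different-source denominator is the product of the two marginal mixture
densities. The score is the log10 of the ratio. Scores are clamped to
[−10, 10]: beyond ten orders of magnitude the evidence is saturated for
any practical purpose, and bounding the range keeps cost metrics from
being dominated by floating-point underflow. The same clamp is applied to
calibrated scores before metrics, for the same reason.

Only the sample means enter the evidence (the token-level spread enters
through `W` and the `W/n` terms). All Gaussian algebra is exact (Cholesky
factorisations); unit tests verify the d = 1 score against direct
numerical quadrature of the same two-level integral to a relative 1e−6,
and against an independently derived closed form in the single-component
limit.

## Calibration and fusion

Raw MVKD scores for the seven vowels are combined into a single LR per
comparison by binary logistic regression of the hypothesis label on the
vector of per-vowel log10 LRs — fusion and calibration in one step; with
a single input dimension the operation reduces to plain calibration. Two
conventions matter:

* **Equal priors.** Hs and Hd development comparisons are weighted so each
  class carries total weight 1/2. Under this weighting the fitted linear
  predictor is an equal-prior log-posterior-odds, i.e. a calibrated
  natural-log LR, and the balanced negative log-likelihood equals
  `ln 2 × Cllr` of the fitted scores — the fit directly minimises a
  penalised Cllr over affine score maps.
* **Regularisation.** The per-fold development sets are small (28 Hd + 8
  Hs comparisons at group size 10, Kish effective sample size ≈ 25 under
  class balancing) while the input has up to 7 highly correlated
  dimensions. The unpenalised maximum-likelihood fit is frequently
  separable, and — worse — often sign-unstable without being separable,
  turning comparisons whose raw per-vowel scores all point one way into
  confident fused scores pointing the other way. The fit therefore always
  carries an L2 penalty on the weights (intercept unpenalised), with
  default `λ = d / (2 n_eff)`: the expected spurious log-likelihood gain
  per fitted parameter, so a score dimension retains weight only insofar
  as it beats chance on the development data. The rule vanishes as
  development data grow, recovering the unpenalised fits used with
  large-scale calibration pools; `ridge_lambda` overrides it with any
  fixed value. Fitting is Newton/IRLS to a 1e−12 step tolerance, verified
  against an independent BFGS optimiser of the same objective.

A vowel missing from a comparison (below the 3-token minimum in either
sample) has its dimension imputed with the development-set mean for that
vowel — a documented bias that keeps the fold usable rather than
discarding the comparison.

## Cross-validation protocol

Speakers are organised into random groups of 10 with a hard constraint:
identical twin siblings never co-occur in a group (with 20 speakers in 10
twin pairs and group size 10, every group takes exactly one member per
pair, drawn by a fair coin; other configurations use rejection sampling).
Within a group, every one of the 45 unordered pairs is tested in its own
fold: the remaining 8 members form the background population for the MVKD
models *and* supply the fusion development scores (28 background Hd pairs
plus each background member's same-speaker comparison). Tested speakers'
tokens never enter background fitting or development scoring — the
leakage-free reading of a background-population protocol; tests audit
this per fold. Each fold emits a calibrated score for the tested Hd pair
and for each tested member's Hs comparison (so a group contributes 45 Hd
and 90 Hs calibrated scores per iteration).

Because group formation is random, the design uses many groups (150 in
the full-scale design), and because minority-class downsampling is random
it is repeated (100 times at full scale), crossed with the groups. Groups
× repetitions at full scale multiply out to millions of scored
comparisons; the package's `desk` scale preset caps runs at 10 groups ×
5 repetitions, which keeps a full three-condition, three-subset run in
the tens of seconds on one core while leaving ≥ 10 metric cells per
condition × subset — enough to average over sampling noise for the
qualitative contrasts the test-suite asserts. The `paper` preset removes
the caps.

## Preprocessing

* **Outlier screening:** within each speaker × style × vowel cell, each
  formant independently, values outside `[Q1 − 2.5·IQR, Q3 + 2.5·IQR]`
  flag the token; a flagged token is removed entirely (downstream scoring
  needs complete F1–F4 vectors). Quartiles use linear interpolation
  (type 7) — removal counts depend on this convention, so it is fixed and
  stated. The screen runs once, not iterated.
* **Downsampling:** within a style, every speaker's token count is
  reduced by uniform sampling without replacement to the minority
  speaker's count; the minority speaker passes through unsampled, and the
  natural vowel distribution is deliberately preserved (no per-vowel
  balancing). For mismatched comparisons, counts are equalised to the
  global per-speaker-per-style minimum across both styles, so reference
  and questioned samples carry equal data for every speaker.
* **Same-speaker construction:** in matched conditions each speaker's
  downsampled tokens are split 50/50 at random (per repetition) into
  reference and questioned halves; Hd comparisons use one speaker's
  questioned half against the other's reference half, symmetric with the
  Hs construction. In the mismatched condition there is no split: Hs is a
  speaker's own interview sample against their own dialogue sample.
* **Mismatched background:** background models are fit on each background
  speaker's combined interview + dialogue tokens, so the within-speaker
  covariance absorbs style variation — the typicality model appropriate
  when the compared samples themselves straddle styles. Matched
  conditions fit the background on the style's own downsampled tokens.

## Validity metrics

* **Cllr** (log-LR cost): `½ (mean_Hs log2(1 + 1/LR) + mean_Hd log2(1 +
  LR))`. 0 is perfect; an uninformative system that always outputs LR = 1
  scores exactly 1; badly calibrated systems exceed 1.
* **EER** (equal error rate): thresholds are swept over the pooled score
  set with FRR(t) = fraction of Hs scores below t and FAR(t) = fraction
  of Hd scores at or above t (ties count as false accepts); the reported
  value is `(FAR + FRR)/2` where the two rates cross, linearly
  interpolated between adjacent empirical thresholds. This is the
  standard crossing-point convention with chance level 0.5. A published
  variant of the formula carries an extra factor ½ (chance level 0.25),
  which contradicts the crossing-point definition the same sources state;
  `eer(..., variant = "as-printed")` reproduces that literal formula, the
  crossing convention is the default and the reported quantity.
* **Aggregation:** Cllr and EER values are screened independently per
  condition × subset cell with the same 2.5·IQR rule before summarising
  (`k = Inf` disables screening).

## The synthetic corpus generator

The generator exists so the full pipeline is testable, with known ground
truth, in the absence of the recordings it emulates. Its model: token
formant vector = per-vowel mean + per-speaker offset + speaker-specific
style offset + independent token noise, all Gaussian; twin siblings'
offsets are correlated (`twin_similarity`, default 0.9); tokens violating
`0 < F1 < F2 < F3 < F4 < 5000 Hz` are redrawn (a slight truncation of the
Gaussian model). Defaults, chosen once:

* **Per-vowel means** (`default_vowel_means()`): male BP monophthong
  targets calibrated so dialogue per-vowel F1 means span ≈ 331–586 Hz,
  F2 ≈ 1074–2027 Hz, F3 ≈ 2368–2655 Hz, F4 ≈ 3387–3570 Hz — the
  descriptive ranges reported for this speaker population.
* **Variance components:** between-speaker SDs (45, 60, 140, 160) Hz and
  within-speaker SDs (60, 170, 150, 170) Hz for F1–F4. No
  within/between magnitudes are published for this corpus, so these are
  set to plausible male-speaker values with one deliberate structural
  property: the between-to-within ratio is high for F3/F4 (and moderate
  for F1), low for F2 — higher formants reflect speaker anatomy while F2
  is tightly constrained by vowel identity. Ordering claims the test
  suite asserts (F3+F4 outperforming F1+F2, fusion best) are therefore
  *reproductions of behaviour under a construction designed to have that
  structure*, not independent confirmations of the empirical finding.
* **Style shifts:** speaker-specific interview offsets with SDs
  (25, 45, 55, 65) Hz — style affects each speaker differently, and
  enough to degrade mismatched comparisons measurably.
* **Token counts:** per speaker × style drawn uniformly from a range
  (default 200–550, straddling the source corpus's per-speaker minima);
  one designated minority speaker is forced to the range minimum so the
  downsampling arithmetic has a unique minority class. Per-style ranges
  (e.g. dialogue 382–450, interview 202–280) reproduce the published
  per-iteration token accounting exactly.
* **Vowel frequencies:** the published token distribution
  5995 : 2910 : 1838 : 1684 : 1479 : 1063 : 973 for /a i u ɛ e o ɔ/,
  normalised.

What the generator does **not** emulate: token durations as a correlate
of anything, prosodic or segmental context, measurement error structure
of LPC formant tracking (gross octave errors, bandwidth effects),
non-Gaussian or skewed formant distributions, session/channel
variability, or realistic phonotactics. Passing tests therefore show the
pipeline's statistical machinery is correct and behaves as designed under
a clean additive Gaussian world; they do not show that real recordings
would yield the same absolute Cllr/EER levels.

`recover_variance_components()` closes the loop: one-way
ANOVA method-of-moments estimates (per formant within vowel × style
cells, pooled by degrees of freedom) recover the generator's configured
between/within SDs, and the test suite requires recovery within 15% at 20
speakers × 400 tokens.

## Numerical and degenerate-input choices

* Quartiles: type 7 (linear interpolation) everywhere quartiles appear.
* EER ties: Hd scores equal to the threshold count as false accepts.
* Score clamp: log10 LR ∈ [−10, 10], raw and calibrated; clamping is
  recorded on raw scores (`attr(, "clamped")`).
* Singular pooled covariance (e.g. constant tokens) is an error at
  `fit_background()`; inside the cross-validation protocol an
  unestimable vowel is skipped for that fold rather than aborting the
  run, and a vowel below 3 tokens in either sample is skipped for that
  comparison.
* IQR screening of an all-identical cell removes nothing (IQR 0 flags
  only values strictly outside the degenerate band).
* Vowel-space polygon area needs ≥ 3 vowel-category means; fewer give
  `NA`. Hulls with fewer than 3 distinct vertices have zero area.
* Formant-range percent differences use `(max − min) / mean(min, max) ×
  100`; published percentage figures for these ranges are not exactly
  reproducible under any of the obvious conventions, so the convention
  here is stated rather than asserted as anyone else's.
* All randomness (group formation, downsampling, splits, generation)
  derives deterministically from user-supplied seeds; identical seeds
  reproduce runs bit-for-bit.

## Known limitations

* The per-fold development sets fixed by the protocol are small;
  calibration quality at this scale depends on the regularisation rule
  described above, and absolute Cllr levels are sensitive to it in a way
  they would not be with pooled large-scale calibration material.
* MVKD typicality estimates rest on kernel densities over only 8
  background means; in 4 dimensions such densities are coarse, and
  atypical-speaker comparisons inherit that coarseness.
* Twin-pair exclusion is supported and enforced, but twin-vs-twin
  comparison itself is out of scope.
* The package renders no figures; outputs are tables designed for
  downstream plotting.
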