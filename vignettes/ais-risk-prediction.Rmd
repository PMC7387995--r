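---
title: "Predicting adolescent idiopathic scoliosis from school-screening postural signs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting adolescent idiopathic scoliosis from school-screening postural signs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scolioscreen)
```

## The problem

Adolescent idiopathic scoliosis (AIS) is a three-dimensional structural
deformity of the spine, diagnosed when the radiographic Cobb angle reaches
10 degrees. School screening programmes try to find it early without
radiography, using cheap observable signs: visual postural asymmetries
(shoulder-height difference, scapular tilt, lumbar concave, pelvic tilt,
and sagittal-profile flags such as flat back or kyphosis) and scoliometer
readings of the angle of trunk rotation (ATR) in the forward-bending
position, where a rotation beyond 5 degrees to either side triggers
radiographic referral. Screening referral decisions based on single signs
have notoriously poor positive predictive value, so the question this
package addresses is: how much better does a *combination* of signs do,
when combined in a logistic regression risk model?

The package implements the full analysis pipeline for a case-control
screening cohort — 895 controls (Cobb < 10°) and 884 AIS cases
(Cobb ≥ 10°) in the calibration study — from descriptive contingency
statistics through model fitting, per-sign ROC analysis, coefficient
re-weighting, and train/test evaluation. The original individual-level
data are not public; the package therefore ships a seeded synthetic-cohort
generator calibrated to the published group-conditional frequencies, so
every downstream stage is testable end to end.

## The synthetic cohort generator

`default_cohort_spec()` encodes, for each of the twelve categorical
screening variables plus school category, the published frequency of each
level *conditional on AIS status* (e.g. control-group scapular tilt
764/895 normal, 85/895 left, 46/895 right), together with the published
within-group age distributions: normal with mean 12.67 (SD 1.96) years in
controls and 13.14 (SD 1.87) in cases, truncated to 6–19 years — the age
span of grades 1–12 that the screening programme covers.

`generate_cohort()` draws exact group sizes (sizes are design constants of
a case-control study, not random), and draws each subject's signs through
a Gaussian copula: a latent standard-normal vector per subject, one
dimension per variable (`latent_order()`), mapped through per-variable
cumulative-probability thresholds. With no dependence matrix the latent
dimensions are independent, so **signs are conditionally independent given
AIS status**. This is the weakest assumption consistent with the published
tables, which report only marginal-by-status frequencies, never the joint
distribution. Supplying a latent correlation matrix (symmetric, unit
diagonal, positive semi-definite) induces rank dependence between signs
while preserving every marginal exactly — useful for stress-testing the
multivariate fit.

One integer seed governs an entire cohort; the generator never touches the
caller's RNG state, and the same seed reproduces a cohort byte for byte.
Pipeline runs derive one child seed per stage from the master seed by a
fixed affine rule (`child_seed()`), so adding or removing a stage does not
shift the randomness of the others.

**What the generator does *not* emulate.** Real postural signs are
correlated beyond what AIS status explains (they share anatomical causes),
and real measurement involves two raters with imperfect agreement. Under
conditional independence each sign contributes fully independent evidence,
so the simulated twelve-sign model discriminates somewhat *better* than
the published one: test-set accuracy on synthetic cohorts runs around
87–88%, versus 82.6% reported on the real data, and simulated specificity
exceeds 90% in roughly a fifth of runs. Passing tests on synthetic cohorts
therefore validate the *machinery* (estimation, weighting, evaluation) and
the per-variable marginal behaviour — per-sign AUCs do land inside the
published confidence intervals — but not the joint discrimination level of
real screening data.

## Descriptive statistics

`tabulate_by_status()` cross-tabulates one sign against AIS status;
`chi_square()` applies the Pearson test, with the Yates continuity
correction available as an explicit flag for 2×2 tables. The correction is
*not* auto-triggered on small expected counts: the published table applies
it to exactly one variable (lumbar kyphosis, its sparsest sign), and
reproducing that column requires the caller — here
`describe_cohort(continuity_for = "lumbar_kyphosis")` — to say so.

`two_sample_t()` compares age between groups, oriented control minus case
(older cases give negative t). Welch's unequal-variance form is the
default because the source analysis does not state pooled vs unequal
variances; both are available, and `welch_t_summary()` computes the Welch
statistic directly from published summary statistics. On the published
age summaries (12.67 ± 1.96, n = 895 vs 13.14 ± 1.87, n = 884) the
closed-form Welch statistic is −5.18; the published value −4.63 is not
recoverable from the printed summaries under either variance assumption,
so it is reported here but not targeted by any check.

## Association models

`univariate_or()` computes the classical closed-form odds ratio of one
level against the reference level from the 2×2 sub-table, with the Wald
interval `exp(log OR ± 1.959964 · SE)`, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`.
Wald (not profile-likelihood) intervals are used throughout because the
published univariate intervals match the Wald closed form to the printed
digit (girls: 3.26, CI 2.69–3.96). A zero cell triggers the
Haldane–Anscombe correction (+0.5 to all four cells) and flags the
estimate.

`fit_multivariate()` fits the twelve-covariate logistic model by maximum
likelihood (IRLS, convergence tolerance 1e-10, at most 100 iterations)
under either of two encodings:

* `dummy_expanded` — each three-level sign becomes two indicators against
  "normal", yielding per-level adjusted odds ratios;
* `single_score` — one number per covariate (normal = 0, left = 1,
  right = 2 for three-level signs; 0/1 for binary flags; raw years for
  age), the encoding of the published risk equations. Whether the original
  equations scored three-level signs 0/1/2 is not stated; 0/1/2 is the
  default here, with any scoring reachable via custom encoding of the
  contingency tables.

Numerical policy: a coefficient magnitude above 15 on the log-odds scale
is flagged as possible complete separation with a warning naming the term
(the fit is returned — quasi-separation of the rarest signs, present in
only 2–9 subjects per group, is common in resampled cohorts, and the fit
remains usable for prediction); a rank-deficient design is an error,
except that `drop_constant = TRUE` drops covariates constant in the sample
(a sign nobody shows) with coefficient fixed at 0. The published
multivariate AORs themselves cannot be reproduced without the real joint
data; the accuracy contract for this stage is parameter recovery:
`coefficient_recovery()` refits simulated cohorts and verifies that the
categorical coefficients recover their generating log-odds (which, under
conditional independence, are exactly the population log odds ratios —
`generating_log_odds()`) with ~95% Wald CI coverage.

## ROC analysis

For a categorical predictor given as level counts, `empirical_auc()`
computes the ties-corrected rank AUC in closed form —
`(#{case above control} + ½·#ties) / (n_case · n_control)` — without
expanding records; the test suite checks it against brute-force pair
enumeration. The default scoring collapses to binary (normal vs any
abnormality), which reproduces five of the published per-sign AUCs exactly
at two decimals from the published counts (shoulder-height 0.70, pelvic
tilt 0.59, and the three ATR signs 0.66/0.54/0.67); ordinal 0/1/2 scoring
is an option, and the AUC is invariant to any strictly increasing
re-scoring. Two published AUCs (gender 0.65, lumbar concave 0.71) differ
by ~0.01 from their count-derived values, consistent with having been
computed on the 70% training split; they are not targeted. Age uses the
closed-form binormal AUC `Φ(Δμ / sqrt(σ₁² + σ₀²))`, which gives 0.57 from
the published summaries.

Confidence intervals use the Hanley–McNeil variance
(`Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`), and the AUC = 0.5 test uses the
normal approximation `z = (A − 0.5)/SE`. The original CI method (Hanley–
McNeil vs DeLong) is unstated; Hanley–McNeil needs only the AUC and group
sizes, matches the published intervals to within one unit in the second
decimal, and is the choice here.

## The weighted prediction models

The published analysis reports four logistic models: the plain
multivariate fit, and variants "weighted by" AOR, AUC, and AOR+AUC — with
the weighting transform itself never defined. The contract implemented by
`apply_weighting()` is one concrete, documented choice, deliberately
pluggable (any positive weight vector may be supplied):

* the coefficient of covariate *j* becomes `β_j · w_j / mean(w)` —
  multiplicative, mean-normalized, so uniform weights are the identity and
  the scale of the raw weights is irrelevant;
* the intercept is then recalibrated so the mean predicted probability on
  the training data equals the observed case fraction, preserving the
  calibration-in-the-large property that maximum likelihood gives the
  plain fit by construction;
* AOR weights are the model's own adjusted odds ratios mapped to the
  probability scale, `w = AOR/(1 + AOR)` (`aor_to_weight()`); AUC weights
  are the per-variable discrimination AUCs on the training data; the
  combined scheme multiplies the two mean-normalized vectors.

The probability-scale mapping of AOR weights deserves its own paragraph,
because it is the one place the package departs from the most literal
reading ("weights are the AOR values"). Raw AORs span roughly 0.3 to 10
across these covariates — and explode past 10³ when a rare sign
quasi-separates — so raw-AOR multiplicative rescaling distorts relative
coefficient magnitudes by factors of 5–10 and costs the weighted model
~10 accuracy points on synthetic cohorts, contradicting the published
finding that all four models perform near-identically. `AOR/(1+AOR)` is
the natural bounded transform of an odds ratio (the probability that the
exposed member of a discordant pair is the case): it maps no-association
to 0.5 and strong association toward 1, exactly the scale on which the
AUC weights already live, making the two schemes commensurable and
keeping any single covariate from dominating. With this choice the four
schemes' test accuracies agree within two percentage points in ~97% of
simulated runs, reproducing the published qualitative result; the printed
equations themselves remain available verbatim via `printed_equation()`
(provenance `"printed_equation"`), since their coefficients came from the
original, unavailable training split and are fixtures, not refit targets.

Classification uses a 0.5 probability threshold by default — the single
operating point at which the published models are reported — with ties at
the threshold classifying positive (documented convention:
`classify(0.5)` is 1).

## Evaluation protocol

`split_cohort()` partitions 7:3 (training:testing), stratified by AIS
label by default — the source protocol does not say whether its split was
stratified, but stratification stabilises the prevalence-dependent PPV
and NPV at no cost. Each stratum contributes `round(0.7 · n_group)`
records to training, giving 1245/534 at the study size.
`confusion_metrics()` reports the usual battery (Se, Sp, PPV, NPV, total
accuracy, Youden's index Se+Sp−1) exactly from counts, on the proportion
scale internally and as two-decimal percentages in reports; a rate with a
zero denominator is NA, never silently 0. Metrics are computed on the
test split only, as the source protocol states. The published Table-3
metrics themselves are not desk-reproducible — they depend on the real
data and an unrecorded split seed — so the evaluation contract is the
property suite: near-identical accuracy across schemes, optimism
(training metrics exceed test metrics on average), and the algebraic
identity Ac = prevalence-weighted mean of Se and Sp.

## Problem sizes and runtime choices

The simulation experiments in the test suite and the acceptance script
use cohorts at the study's own size (n = 1779) throughout: 500 replicates
for CI-coverage of the multivariate coefficients (measured coverage
~95.5%, with ~99.8% of estimates within 3 SE of their generating values),
200 replicates for the scheme-spread property, and 40–100 replicates for
per-sign AUC band checks and null-calibration checks. These sizes give
binomial standard errors of about 1–2 percentage points on the asserted
proportions, small relative to every asserted margin, while the full
suite runs in well under a minute.

## Known limitations

* Conditional independence given status overstates joint discrimination
  (see above); absolute Se/Sp/Ac levels on synthetic cohorts exceed the
  published operating point by ~5 points.
* The weighting transform is a reconstruction; the original is undefined
  in the source. Alternative transforms can be supplied as weight vectors,
  but none can be validated against the original beyond the qualitative
  near-identity of performance.
* School category is generated (it appears in the published descriptive
  table) but is not a model covariate, matching the published equations,
  which carry twelve covariates.
* The published multivariate AORs, the printed equations' coefficients,
  and the published Table-3 metrics all depend on the original data or
  its unrecorded 70% training split and are treated as fixtures or
  non-targets, never as fitting objectives.
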