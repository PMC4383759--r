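---
title: "Q-learning for a two-stage SMART: models, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Q-learning for a two-stage SMART: models, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `qsmart`, the design of
its synthetic cohort generator, and every numerical choice a user might want
to audit. It states no empirical result beyond what the package's test suite
and acceptance script compute themselves.

## The decision problem

A two-stage SMART for acute bipolar depression randomizes subjects at entry
to adjunctive Bupropion, adjunctive Paroxetine, or placebo (all on a mood
stabilizer). After six weeks, *responders* — at least 50% improvement on the
depression subscale SUMD (0–22, higher is worse) and no (hypo)mania — stay
the course. Non-responders on a drug escalate to the high dose of the same
drug; non-responders on placebo are re-randomized 1:1 between the two
high-dose drugs. The outcome Y is SUMD at week 12, coded lower-is-better.

The feasible sets encode this topology: every subject has all three options
at stage 1; at stage 2 only placebo non-responders face a real decision.
A dynamic treatment regime is a pair of decision rules mapping histories to
feasible treatments; the optimal regime minimizes expected Y.

## Q-learning with linear working models

Backward induction replaces unknown conditional expectations with
regressions:

1. **Stage 2.** OLS of Y on `[h20, a2 * h21]` over placebo non-responders
   only (the one randomized stratum at stage 2). `a2 = 1` is high-dose
   Bupropion, `a2 = 0` high-dose Paroxetine.
2. **Pseudo-outcome.** For placebo non-responders, the best achievable
   predicted outcome `h20'b20 + min(0, h21'b21)`; everyone else keeps their
   observed Y. Drug non-responders keep Y because dose escalation is a
   design rule, not a decision.
3. **Stage 1.** OLS of the pseudo-outcome on `[h10, a11 * h11, a12 * h12]`
   over all subjects, with Bupropion/Paroxetine dummies against the placebo
   reference.

Assumptions: sequential randomization (guaranteed by the SMART design),
consistency, and correctness of the linear working models for the
Q-functions. When the stage-1 model is misspecified (the pseudo-outcome's
true conditional mean involves a minimum, hence is not exactly linear), the
fitted rule is the best linear approximation; the test suite's
dynamic-programming oracle uses a *saturated* discrete design precisely so
that this approximation error vanishes and the regime can be compared
cell-by-cell against brute-force enumeration.

With multiply imputed data the Q-learning fit is run per completed dataset
and the deployed rule is the argmin of the *imputation-averaged*
Q-functions. Ties are broken deterministically: toward placebo at stage 1
and toward high-dose Paroxetine at stage 2 (the `a2 = 0` reference). Ties
have measure zero under continuous covariates; the rule exists for
reproducibility.

Default term lists are the selected models reported for this trial:
`h20 = (1, SUMM1, SUMD1, SIDE3)`, `h21 = (1, SUMM1, SIDE3)`,
`h10 = (1, AGE, SUMM0, SUMD0, PRONSET1, PRONSET2)` and
`h11 = h12 = (1, AGE, PRONSET1, PRONSET2)`. `PRONSET1`/`PRONSET2` are
remission/(hypo)manic dummies against a mixed-episode reference. (The
interaction blocks follow the printed coefficient tables, which interact the
treatment dummies with AGE.)

## The synthetic cohort generator

No subject-level data are distributed with the study, so the generator is
the package's substrate for testing every pipeline stage against a known
truth. It emulates the published cohort description:

* **Baseline covariates.** Numeric variables (AGE, SUMD0, SUMM0) are drawn
  from truncated normals on their printed ranges whose parameters are
  *moment-matched* so that the truncated distribution has the printed mean
  and SD (a plain truncated draw at the printed parameters would not).
  Categorical and binary variables are sampled at the printed frequencies;
  the nine side-effect indicators are independent, since no correlation
  structure is published.
* **Stage-1 allocation** defaults to the published empirical arm frequencies
  (0.233, 0.255, 0.512), because no protocol ratio is stated.
* **Intermediate outcomes.** SUMD1 and SUMM1 are linear in baseline scores,
  prior-episode dummies and treatment dummies plus Gaussian noise, truncated
  to the score ranges. Their intercepts, the SUMM0 slope and the noise SDs
  (4.0 and 1.05 points) were calibrated once, by simulation at n = 50,000,
  to the printed marginal means and SDs of SUMD1 (4.49, 3.07) and SUMM1
  (0.95, 1.30); SUMM1's SD exceeds its mean, which a truncated normal cannot
  produce per subject, so the calibration uses a steep SUMM0 slope to induce
  the required between-subject overdispersion. A logistic model drives the
  (hypo)mania indicator; responder status then follows the 50% rule, with
  the boundary counted as response ("at least 50%" read inclusively).
* **Outcomes.** Placebo non-responders draw Y from the published
  second-stage Q-function point estimates; everyone else draws from the
  published first-stage point estimates. This makes the published
  coefficients the generative truth, so parameter-recovery tests are
  anchored to printed numbers. Stage-2 recovery is tested end-to-end; the
  stage-1 regression is tested at the operation level (response generated
  from the first-stage form), because the pseudo-outcome of placebo
  non-responders is a minimum and therefore has no exactly-linear stage-1
  truth in a full pipeline run.
* **Missingness.** Masking is missing-at-random by default: each masked
  column's missingness probability is logistic in standardized AGE and the
  placebo indicator (both always observed), with the intercept calibrated on
  the realized scores to hit the requested marginal rate; an MCAR switch
  sets the slopes to zero. The published missingness figure prints no
  percentages, so rates are configuration parameters; the default profile
  uses 0.28 for the end-of-stage-1 scores — echoing the 104/365 subjects
  lost at stage 1 — and 0.10–0.15 for socioeconomic baseline fields. The
  outcome and stage-2 treatment are not masked by default so that
  generator-truth evaluations stay exact.
* **Truth oracles.** The pre-masking cohort rides along as an attribute, and
  `true_regime_value()` evaluates any regime by forced-assignment
  simulation from the configured models — a route entirely independent of
  the IPWE estimator it is used to check.

What passing tests on this generator do **not** show: robustness to
correlated side effects, to informative (MNAR) dropout, to outcome
missingness, or to real-data model misspecification beyond the
linear-plus-truncation family the generator itself uses.

## Multiple imputation

Chained equations with one conditional model per incomplete column:
predictive mean matching (PMM) for continuous targets, logistic regression
for binary targets, and multinomial logistic regression for the 3-level
categoricals (a natural extension of the binary rule, which is all that is
specified for this design). Parameter draws use the Bayesian sampling
distribution under flat priors (scaled inverse-chi-square for the residual
variance, normal for the coefficients), so imputations are proper. PMM
draws one of the 5 nearest observed donors by predicted mean, guaranteeing
imputed values live on the observed support. Predictors for each
conditional model come from forward stepwise BIC on complete cases — the
same criterion as the Q-model selection, for internal consistency.

Unspecified-by-source constants, all configurable and recorded in the run
manifest: m = 25 imputations, 10 chained-equation sweeps, 5 PMM donors.
Columns are visited in order of increasing missingness. Two structural
choices: responder status is not masked by default (its deterministic
relation to SUMD0/SUMD1/mania would otherwise need a passive-imputation
rule), and `Trt2` is excluded from conditional models because it is
structurally missing for responders.

## Model selection

Forward stepwise minimization of the BIC averaged over the m imputed
datasets, stage 2 first, then stage 1 with the selected stage-2
specification fixed (the stage-1 score depends on the pseudo-outcomes that
specification produces). Choices the source leaves open, fixed as follows:

* **BIC form**: Gaussian-profile `n log(RSS/n) + k log(n)` on the rows
  entering that stage's regression; additive constants cancel in
  comparisons.
* **Base model**: intercept plus treatment dummies, which every reported
  fitted model contains.
* **Moves**: a candidate enters as a main effect, or as a treatment
  interaction once its main effect is present (weak hierarchy — consistent
  with every reported model, e.g. a SUMD1 main effect without an
  interaction). Trinary covariates move as a dummy pair.
* **Tie-breaks**: equal-BIC moves resolve to the earlier candidate in the
  published predictor-table order, mains before interactions.
* **Stage-2 pool**: admits the end-of-stage-1 scores; stage-1 treatment is
  constant on the placebo-non-responder estimation subset, so Trt1-derived
  terms are inestimable there and are not offered.

## Bootstrap inference and non-regularity

`bootstrap_ci()` resamples subjects with replacement and re-runs imputation
(when needed) plus Q-learning per replicate; intervals are inverse-ECDF
percentile intervals (at B = 2 they degenerate to the replicate min/max,
which the tests pin down). Term specifications are selected once on the
original data and frozen inside replicates: re-selecting per replicate would
change the estimand away from the single reported model. Replicates with a
degenerate stage-2 subset are dropped and counted; more than 10% dropped
aborts. Inside replicates the imputation count defaults to m = 5 for
tractability — a documented deviation knob, recorded in the manifest.

The stage-1 estimand is non-regular: the pseudo-outcome's minimum is
non-smooth wherever the stage-2 contrast `c = h21'b21` is near zero. The
exact correction used in the original analysis is not recoverable from the
report, so the package implements a transparent soft-threshold: replace `c`
by `c (1 - lambda/c^2)+` with `lambda = Var(c) z^2`, `z` the normal quantile
matching the interval level, before taking the minimum — shrinking to zero
exactly those contrasts statistically indistinguishable from zero — plus a
`"none"` mode. Both modes are reported in the output metadata. Bootstrap
coverage of a regular stage-2 coefficient is verified in the acceptance
suite at n = 500, B = 200 over 200 outer replications; sizes chosen to make
the coverage check sharp at desk scale.

## Regime values

`ipwe()` implements the normalized (Hajek) estimator, which is bounded by
the observed outcome range — a deliberate guard against the instability of
unnormalized IPW under small propensities; whether the original analysis
normalized is unstated, so the propensity source is also configurable:
empirical per-stage frequencies by default (stage-1 shares overall, stage-2
shares among placebo non-responders), or known design probabilities.
Consistency multiplies over decisions actually made: responders and
drug-arm non-responders contribute only the stage-1 factor. The
estimated-regime row is evaluated on the same data that produced the rule,
matching the reported comparison's construction; `compare_regimes()`
computes all rows on common bootstrap resamples so differences between rows
are meaningful. The five-row preset mirrors the published table: the
estimated regime plus four static regimes.

The pipeline wrapper evaluates values on the first completed dataset (point
estimates across imputations differ only by imputation noise; the
coefficient table, not the value table, is the pooled object).

## Problem sizes used in the verification suite

Chosen to keep every check sharp but desk-scale: marginal fidelity at
n = 50,000 (3 Monte-Carlo SEs); DP-oracle equivalence at n = 5,000 on the
saturated discrete toy; coefficient recovery at n = 10,000 with unit noise
(±0.15, several Monte-Carlo SEs wide); IPWE against forced-assignment truth
at n = 20,000 versus 200,000 simulated subjects (2 combined SEs); selection
consistency over 50 seeds at n = 4,000, m = 5 (≥ 90% exact support
recovery); bootstrap coverage in [0.85, 0.95] over 200 outer replications;
imputation validity at n = 2,000, m = 10 (2 SEs, inflated by the
finite-m factor sqrt(1 + 1/m)).

## Known limitations

Two stages only; linear Q-models only (no outcome-weighted learning or
policy search); no m-out-of-n bootstrap or sandwich intervals; no doubly
robust value estimation; (hypo)mania is a single indicator rather than
DSM-IV symptom logic; the generator has no weekly visit structure, only the
two decision points and the distal outcome.
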