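---
title: "Planning, imputing and reporting incomplete observational data with misspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning, imputing and reporting incomplete observational data with misspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misspipe)
```

## The problem

Observational cohorts almost always carry missing values in the outcome,
the exposure and the confounders of the substantive analysis. The two
workhorse responses — restricting to complete records (CRA) and multiple
imputation (MI) — make different, untestable assumptions about why data
are missing, and each can be badly biased when its assumption fails.
`misspipe` implements a disciplined three-stage workflow around a simple
exposure-outcome estimand (the adjusted mean difference from a linear
regression of a continuous outcome on a binary exposure and confounders):

1. **Plan**: diagnose the extent, patterns and predictors of missingness,
   and select a primary strategy with an auditable rule trace.
2. **Analyse**: run chained-equations MI, pool by Rubin's rules, and fit
   the CRA comparator.
3. **Report**: emit the results table with pattern-mixture sensitivity
   rows and an explicit agreement note.

Because real cohort data of this kind are access-controlled, the package
ships a synthetic-cohort generator with explicit missingness mechanisms,
so that every stage is testable against a known ground truth.

## The synthetic cohort and its missingness mechanisms

`generate_cohort()` draws confounders from a Gaussian copula with
exchangeable latent correlation 0.3 (four binary, four continuous in the
bundled preset), a binary exposure from a logistic model on the
confounders, and a continuous outcome

y = b0 + beta_true * x + c'z + e,  e ~ N(0, sigma^2),

clamped to the score range [0, 100]. The preset keeps the clamped
fraction below 1% so the linear model stays essentially correct; the
complete-data OLS fit is the recovery oracle used throughout the tests.

`impose_missingness()` deletes each targeted cell independently with
probability `expit(a + c'w + delta_true * value)`. Setting every
coefficient to zero gives MCAR; coefficients on observed variables give
MAR; a nonzero self-coefficient `delta_true` gives MNAR by construction.
Deleted values are retained under a provenance flag so tests can compare
deleted-cell and retained-cell distributions directly.

`alspac_like_preset()` emulates the structure of a well-known birth-cohort
analysis of teenage smoking and educational attainment: a 0-100
attainment outcome, a smoking exposure with ~51% missingness, eight
confounders, and earlier-wave smoking proxies as auxiliaries (sensitivity
0.8 / specificity 0.95 against true exposure for the stronger proxy).
Calibration choices, made once:

* **Missingness rates** are hit exactly in expectation by solving each
  mechanism's intercept numerically against the realized linear
  predictors (51% for the exposure; rates for the outcome and four
  confounders chosen so that ~23% of records are complete on the
  analysis-model variables, within a +/- 5 point band).
* **Attrition is monotone**: participants missing the outcome wave are
  missing the exposure (and paternal smoking) too, and the sporadic parts
  of those two mechanisms depend on the *observed* attainment score
  (-0.05 log-odds per point) alongside behaviour and parental education.
  No deletion probability ever depends on an unobserved value when
  `delta_true = 0`, so the preset mechanism is exactly MAR — which is
  what makes the MI-recovers/CRA-fails benchmark interpretable. Routing
  outcome-selection through two analysis variables compounds the
  selection of the complete-record set (so the CRA bias is clearly
  visible above Monte-Carlo noise) without strengthening either single
  channel.
* **Marginal smoking prevalence** is 0.2. The source analysis does not
  report this figure, so it is a documented free parameter of the
  emulation, not a reproduced quantity.
* The strength of the outcome dependence (-0.05 per point per channel,
  about -0.8 log-odds per outcome SD) was chosen so that selection on
  the outcome biases the CRA visibly (about +1 score point of
  attenuation at these settings) while remaining in the range where the
  extreme "impute all missing as smokers" analysis still attenuates the
  effect — with much stronger selection on the exposure channel the
  low-attainment composition of the missing group would dominate
  misclassification dilution and push that worst-case estimate away from
  the null instead.

What the generator does *not* emulate: the real cohort's longitudinal
12-wave design, its actual covariate distributions, linkage artifacts,
or item-level questionnaire structure. Passing tests therefore show the
*methods* behave as theory predicts under a faithful missingness
structure, not that the package reproduces the source cohort's numbers.

## Strategy selection

`recommend_strategy()` encodes the planning flowchart as three questions
with explicit evidence:

* **Q1** — CRA acceptable iff the incomplete-record proportion is
  *strictly* below 5% (configurable) and there is no evidence that
  completeness depends on the outcome (both the substantive flag and the
  completeness-model outcome term).
* **Q2** — MI beneficial iff Q1 fails and there is something for MI to
  exploit: declared auxiliaries or incomplete confounders.
* **Q3** — sensitivity analysis required iff MNAR is suspected on
  substantive grounds or completeness associates with declared proxies of
  the incomplete variable.

Substantive-knowledge inputs (`mnar_suspected`,
`outcome_association_flag`) are deliberately config flags, not data-driven
inferences: they are judgements the analyst must own. When MNAR is
suspected but missingness appears unrelated to the outcome, the engine
attaches a caveat (in that corner MI itself can be biased while CRA is
not) rather than silently reversing the recommendation, because the
condition is unverifiable from data alone. The boundary convention
(exactly 5% incomplete counts as *not* low) is arbitrary but documented
and tested.

## The chained-equations engine

`run_chained()` is a from-scratch fully-conditional-specification
implementation with three column models:

* `bayes_linear` — proper Bayesian draw: residual variance from its
  scaled inverse-chi-square posterior, coefficients from the conditional
  normal, imputation = linear predictor + delta + noise.
* `bayes_logistic` — logistic MLE (IRLS with deviance-based step-halving;
  this matters on strongly predictive auxiliary designs where naive IRLS
  overshoots), coefficient draw from the asymptotic normal approximation,
  imputation = Bernoulli(expit(eta + delta)). Exact Bayes for the
  logistic column is deliberately out of scope; the asymptotic draw is
  the mainstream choice.
* `pmm` — predictive mean matching with k = 5 donors, tie-break at the
  lowest row index, type-1 matching (both predictions from the drawn
  coefficient vector).

Numerical choices: rank-deficient linear designs fall back to a ridge of
1e-6 times the largest diagonal of the normal equations, with a warning;
suspected separation (|coef| > 15 or non-convergence) triggers a
ridge-penalized logistic refit, again warned and counted. Categorical
variables with more than two levels are imputed by one-vs-rest logistic
draws normalized to a categorical draw — a documented simplification that
keeps the engine to two regression primitives.

Defaults `m = 25` imputations and `10` cycles follow common chained-
equations practice; both are exposed. The visit order is ascending
missingness count (most-missing last, ties by declaration order), which
stabilizes early cycles and is fixed for reproducibility. Initial values
are drawn from each variable's observed marginal.

RNG discipline: every operation draws from a named substream of the user
seed (`substream_seed(seed, "chained", i)` for imputation i, one stream
per deleted variable in the generator, and so on). Two consequences are
load-bearing: runs are bit-reproducible, and two runs differing only in
the pattern-mixture offset consume identical random numbers, so
sensitivity-grid differences are attributable to delta rather than Monte
Carlo noise. Bernoulli imputations are realized as `u < p` against a
shared uniform stream, which makes imputed binary values monotone
non-decreasing in delta under common random numbers.

## Pooling

`pool_rubin()` combines per-imputation estimates Q_i with squared
standard errors U_i:

Qbar = mean(Q_i), Ubar = mean(U_i), B = var(Q_i),
T = Ubar + (1 + 1/m) B.

Inference uses a t reference with Barnard-Rubin small-sample degrees of
freedom by default (correct behaviour at modest n); the classic
(m-1)(1+1/riv)^2 form is available via `df_method = "classic"` for
cross-checking against other software, which matters because published
analyses rarely state which df they used. The fraction of missing
information is (riv + 2/(df+3))/(1+riv). The pooling algebra is verified
in the test suite against an independent brute-force recomputation at
tolerance 1e-12. Estimates are always reported in raw outcome-score
points, never standardized.

## Sensitivity analysis

The pattern-mixture offset delta shifts the *log-odds* of a binary
target (or the linear predictor of a continuous one) during imputation
only — observed cells are untouched, and the offset is applied at every
FCS cycle (matching the offset semantics of mainstream implementations;
applying it only at the final draw would leave the earlier cycles
assuming MAR). The sign convention: positive delta raises the probability
of the "1" level among the unobserved.

`run_delta_grid()` evaluates the default grid {0, 0.1, 0.25, 0.5, 1, 10}
(10 representing an extreme MNAR mechanism; 0 is the anchor that must
reproduce the primary analysis bit-for-bit). `worst_case_impute()` is the
cruder extreme: every missing value set to a fixed level.
`find_tipping_point()` walks a delta grid (optional bisection refinement)
until a conclusion-change criterion — by default "the 95% CI includes
zero" — flips, and reports the full evaluated trace; the refinement
assumes the criterion is monotone in delta.

Only single-variable offsets are exercised by the test suite;
multi-variable offsets are accepted by the configuration but are
explicitly untested territory. Elicitation of delta from experts, and
fully general not-at-random chained equations, are out of scope.

A design note on the MNAR recovery benchmark: when the deletion model is
logistic with self-coefficient delta_true, the conditional log-odds of
the target differ between unobserved and observed records by *exactly*
delta_true, provided the imputation model conditions on the variables the
deletion model uses. The matched-offset benchmark in the tests therefore
restricts the imputation predictors to the analysis-model variables in
that scenario. With the strong smoking proxies added, the MAR model
already classifies most missing smokers correctly, the attenuation signal
at delta = 0 shrinks toward the engine's small-sample wobble, and the
benchmark would be testing noise rather than the offset identity.

## Problem sizes in the test suite

The replication studies in the acceptance tests use the sizes at which
the statistical properties are both meaningful and stable: 200 replicates
at n = 2000, m = 25 for the MAR-recovery/coverage benchmark; 100
replicates at n = 2000, m = 10 for the matched-offset MNAR benchmark;
n = 20000 single cohorts for calibration and direction checks. At these
sizes the Monte-Carlo standard error of a mean estimate is about 0.1
score points, an order of magnitude below the effects being detected.

## Known limitations

* The estimand is a single linear-regression coefficient; non-linear
  summaries, multi-parameter pooling, multilevel and time-to-event
  extensions are out of scope.
* The logistic posterior draw is asymptotic, so in tiny samples the
  propagated parameter uncertainty is approximate.
* At n = 2000 with ~51% exposure missingness the MI point estimate shows
  a small finite-sample bias away from the null (about 0.2-0.3 score
  points on an effect of 10, absent under MCAR at the same settings);
  it shrinks with n and is well inside the acceptance band, but users
  analysing small cohorts should expect it.
* The agreement flag in the report compares point estimates against an
  absolute contextual threshold (default 2.0 score points) — a
  substantive judgement, deliberately not a statistical test.
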