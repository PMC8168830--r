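# misspipe

Treatment and reporting of missing data in observational studies: a
tested R pipeline covering planning, chained-equations multiple
imputation, Rubin's-rules pooling, and pattern-mixture sensitivity
analysis.

## Who this is for

Epidemiologists and biostatisticians estimating an exposure–outcome
association from a cohort with missing values in the outcome, the
exposure and/or the confounders, who need to (a) choose defensibly
between a complete-records analysis (CRA) and multiple imputation (MI),
(b) run the chosen analysis reproducibly, and (c) report how sensitive
the conclusion is to the missing-data assumptions. Because cohort data
of this kind are typically access-controlled, the package also ships a
synthetic-cohort generator with explicit missingness mechanisms so the
entire workflow is testable against a known ground truth.

## The statistics in brief

The substantive model is a linear regression
`y = b0 + beta * x + c'z + e` — `beta` is the adjusted mean difference
in a 0–100 outcome score between exposed and unexposed. Missingness per
variable follows a logistic selection model
`P(missing) = expit(a + c'w + delta_true * value)`; `delta_true = 0`
gives missingness at random (MAR) given observed data, `delta_true != 0`
makes it missing not at random (MNAR).

MI fills each missing cell m times from its predictive distribution
(fully conditional specification with Bayesian linear, Bayesian logistic
and predictive-mean-matching column models), fits the analysis model to
each completed data set, and pools with Rubin's rules:

    Qbar = mean(Q_i)          Ubar = mean(U_i)       B = var(Q_i)
    T    = Ubar + (1 + 1/m) B

with t inference on Barnard–Rubin degrees of freedom and the fraction of
missing information `(riv + 2/(df+3))/(1+riv)`. Sensitivity analysis
adds a pattern-mixture offset delta to the log-odds (or linear
predictor) of the imputed variable — the assumed difference between
unobserved and observed records — over a grid, plus worst-case filling
and tipping-point search.

## Worked example

```r
library(misspipe)

# a synthetic cohort emulating a teenage-smoking / attainment analysis:
# true adjusted mean difference -10 points, ~51% of the exposure missing
ps  <- alspac_like_preset(n = 4000, seed = 1, delta_true = 0)
tab <- ps$table
model <- default_substantive_model(tab)

summarize_missingness(tab)$prop_complete
#> [1] 0.24975

rec <- recommend_strategy(summarize_missingness(tab),
                          predictors_of_missingness(tab, c("sex", "mat_educ")),
                          plan_thresholds(outcome_association_flag = TRUE,
                                          mnar_suspected = TRUE))
rec$primary_method
#> [1] "multiple_imputation"

spec  <- imputation_spec(tab, m = 25, cycles = 10, seed = 2)
stack <- run_chained(tab, spec)
fit_and_pool(stack, model)
#> multiple_imputation: estimate -9.999, 95% CI (-11.328, -8.670), p = 2.718e-28
#>   n = 4000, m = 25, T = 0.4500 (Ubar 0.2465, B 0.1957), df = 111.4, fmi = 0.462

fit_complete_records(tab, model)
#> complete_records: estimate -7.156, 95% CI (-9.246, -5.065), p = 3.109e-11
#>   n = 999, m = 1, T = 1.1346 (Ubar 1.1346, B 0.0000), df = 989.0, fmi = NA

grid <- run_delta_grid(tab, spec, "smoke_14",
                       c(0, 0.1, 0.25, 0.5, 1, 10), model)
print(grid)
#> delta = 0     estimate   -9.999  CI (-11.328, -8.670)  % imputed positive: 25.9
#> delta = 0.1   estimate  -10.032  CI (-11.391, -8.673)  % imputed positive: 26.5
#> delta = 0.25  estimate  -10.083  CI (-11.414, -8.751)  % imputed positive: 27.2
#> delta = 0.5   estimate  -10.184  CI (-11.517, -8.851)  % imputed positive: 28.6
#> delta = 1     estimate  -10.313  CI (-11.657, -8.969)  % imputed positive: 31.8
#> delta = 10    estimate   -8.964  CI (-9.851, -8.077)  % imputed positive: 99.8
```

Reading the output: the MI estimate recovers the generating effect of
−10 with a CI shrunk relative to the CRA (which uses only ~25% of the
records and is attenuated by its outcome-dependent selection). Along the
delta grid the share of missing smoking values imputed as smokers rises
with the assumed MNAR log-odds shift; the estimate stays close to −10
for plausible deltas and only the extreme delta = 10 (virtually all
missing imputed as smokers) pulls it toward the null — so the
qualitative conclusion is robust. `build_results_table()` +
`build_report()` render exactly this as a reporting table with an
agreement note, and `find_tipping_point()` searches for the delta at
which the CI first includes zero.

A thin command-line front end with `simulate` / `diagnose` / `plan` /
`pipeline` subcommands is in `inst/cli/misspipe.R`.

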