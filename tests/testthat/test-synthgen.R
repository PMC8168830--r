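test_that("generated cohorts are complete, in range, and deterministic", {
  ps <- alspac_like_preset(1000, seed = 1)
  complete <- generate_cohort(ps$config)
  expect_false(anyNA(complete$data))
  expect_true(all(complete$data$smoke_14 %in% c(0, 1)))
  prev <- mean(complete$data$smoke_14)
  expect_gt(prev, 0.05)
  expect_lt(prev, 0.95)
  expect_true(all(complete$data$attain_16 >= 0 & complete$data$attain_16 <= 100))
  # determinism: same config twice gives bit-identical tables
  again <- generate_cohort(ps$config)
  expect_identical(complete$data, again$data)
  # a different seed gives a different table
  cfg2 <- ps$config; cfg2$seed <- 2L
  expect_false(identical(generate_cohort(cfg2)$data, complete$data))
})

test_that("complete-data substantive fit recovers beta_true", {
  ps <- alspac_like_preset(20000, seed = 5, beta_true = -10)
  complete <- generate_cohort(ps$config)
  fit <- fit_substantive(complete$data, default_substantive_model(complete))
  # OLS on the complete simulated table is the oracle; 3 SE band
  expect_lt(abs(fit$estimate - (-10)), 3 * fit$se)
})

test_that("invalid configurations are rejected with the offending variable named", {
  expect_error(
    simulation_config(100, -10, confounder_spec = list(
      list(name = "bad", scale = "binary", prevalence = 1.5,
           coef_exposure = 0, coef_outcome = 0))),
    "bad")
  expect_error(
    simulation_config(100, -10, confounder_spec = list(
      list(name = "a", scale = "continuous", mean = 0, sd = 1,
           coef_exposure = 0, coef_outcome = 0),
      list(name = "a", scale = "binary", prevalence = 0.5,
           coef_exposure = 0, coef_outcome = 0))),
    "unique")
})

test_that("imposed missingness matches its logistic mechanism", {
  ps <- alspac_like_preset(50000, seed = 9)
  complete <- generate_cohort(ps$config)
  # intercept-only mechanism at logit(0.3): binomial bound at n = 50000
  mech <- missingness_mechanism("smoke_14", intercept = qlogis(0.3))
  out <- impose_missingness(complete, mech, seed = 2)
  expect_gt(mean(is.na(out$data$smoke_14)), 0.29)
  expect_lt(mean(is.na(out$data$smoke_14)), 0.31)
  # probability-zero mechanism leaves the table untouched
  none <- impose_missingness(complete,
                             missingness_mechanism("smoke_14", intercept = -Inf),
                             seed = 2)
  expect_identical(none$data, complete$data)
  # unknown predictor is a configuration error
  expect_error(
    impose_missingness(complete,
                       missingness_mechanism("smoke_14",
                                             coefficients = c(nope = 1)),
                       seed = 1),
    "unknown variable")
})

test_that("positive self-coefficient shifts deleted-cell prevalence upward", {
  ps <- alspac_like_preset(50000, seed = 4)
  complete <- generate_cohort(ps$config)
  mech <- missingness_mechanism("smoke_14", intercept = qlogis(0.3),
                                self_coefficient = 2)
  out <- impose_missingness(complete, mech, seed = 6)
  prov <- cell_provenance(out)[, "smoke_14"]
  deleted <- out$truth$smoke_14[prov == "simulated-then-deleted"]
  retained <- out$data$smoke_14[prov == "observed"]
  expect_gt(mean(deleted), mean(retained))
})

test_that("the case-study-like preset hits its calibration bands", {
  ps <- alspac_like_preset(20000, seed = 7, delta_true = 0)
  expo_missing <- mean(is.na(ps$table$data$smoke_14))
  expect_gt(expo_missing, 0.46)
  expect_lt(expo_missing, 0.56)
  cr <- mean(complete_record(ps$table))
  expect_gt(cr, 0.18)
  expect_lt(cr, 0.28)
  # clamping kept rare so the linear model stays valid
  complete <- generate_cohort(ps$config)
  expect_lt(mean(complete$data$attain_16 %in% c(0, 100)), 0.01)
})

test_that("preset with delta_true > 0 deletes smokers preferentially", {
  ps <- alspac_like_preset(20000, seed = 7, delta_true = 1)
  prov <- cell_provenance(ps$table)[, "smoke_14"]
  truth <- ps$table$truth$smoke_14
  miss_rate_smokers <- mean(prov[truth == 1] == "simulated-then-deleted")
  miss_rate_nonsmokers <- mean(prov[truth == 0] == "simulated-then-deleted")
  expect_gt(miss_rate_smokers, miss_rate_nonsmokers)
})

test_that("preset passes table invariants at small n", {
  ps <- alspac_like_preset(200, seed = 12, delta_true = 0.5)
  expect_s3_class(ps$table, "study_table")
  expect_identical(sum(ps$table$roles == "outcome"), 1L)
  expect_identical(sum(ps$table$roles == "exposure"), 1L)
  obs <- ps$table$data$smoke_14[!is.na(ps$table$data$smoke_14)]
  expect_true(all(obs %in% c(0, 1)))
})

test_that("MCAR mechanism produces missingness independent of the data", {
  ps <- alspac_like_preset(2000, seed = 21)
  complete <- generate_cohort(ps$config)
  pvals <- vapply(1:30, function(s) {
    out <- impose_missingness(
      complete, missingness_mechanism("smoke_14", intercept = qlogis(0.3)),
      seed = s)
    suppressWarnings(
      chisq.test(table(is.na(out$data$smoke_14), complete$data$mat_smoke))$p.value)
  }, 0)
  # p-values approximately uniform across replicate seeds
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
  expect_lt(mean(pvals < 0.05), 0.25)
})

test_that("study tables round-trip through CSV + YAML sidecar", {
  ps <- small_preset(300, seed = 8)
  path <- file.path(tempdir(), "tbl.csv")
  write_study_table(ps$table, path, write_truth = TRUE)
  back <- read_study_table(path, truth_path = file.path(tempdir(), "tbl_truth.csv"))
  expect_identical(back$roles, ps$table$roles)
  expect_identical(back$scales, ps$table$scales)
  expect_equal(back$data, ps$table$data, tolerance = 1e-12)
  expect_equal(back$truth$smoke_14, ps$table$truth$smoke_14)
})
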