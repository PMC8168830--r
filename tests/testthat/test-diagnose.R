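test_that("missingness summary counts a toy table exactly", {
  s <- summarize_missingness(toy_table())
  pv <- s$per_variable
  expect_equal(pv$n_missing[pv$variable == "y"], 1)
  expect_equal(pv$n_missing[pv$variable == "x"], 2)
  expect_equal(s$n_complete, 2)
  expect_equal(s$prop_complete, 0.5)
  expect_equal(nrow(s$patterns), 3)
  expect_setequal(s$patterns$count, c(1, 1, 2))
  expect_equal(sum(s$patterns$count), s$n_records)
  # complete-record count equals the all-observed pattern's count
  all_obs <- apply(s$patterns[s$analysis_variables], 1, all)
  expect_equal(s$patterns$count[all_obs], s$n_complete)
})

test_that("fully observed tables summarize to a single complete pattern", {
  tab <- linear_table(50)
  s <- summarize_missingness(tab)
  expect_true(all(s$per_variable$prop_missing == 0))
  expect_equal(nrow(s$patterns), 1)
  expect_equal(s$prop_complete, 1)
})

test_that("summary is invariant under row permutation", {
  ps <- small_preset(500, seed = 2)
  s1 <- summarize_missingness(ps$table)
  shuffled <- ps$table
  set.seed(1); perm <- sample(nrow(shuffled$data))
  shuffled$data <- shuffled$data[perm, ]
  shuffled$truth <- shuffled$truth[perm, ]
  s2 <- summarize_missingness(shuffled)
  expect_identical(s1$per_variable$n_missing, s2$per_variable$n_missing)
  expect_identical(sort(s1$patterns$count), sort(s2$patterns$count))
})

test_that("summary agrees with the preset's calibration at scale", {
  ps <- alspac_like_preset(20000, seed = 7, delta_true = 0)
  s <- summarize_missingness(ps$table)
  expect_gt(s$prop_complete, 0.18)
  expect_lt(s$prop_complete, 0.28)
})

test_that("complete vs incomplete comparison separates forced groups", {
  # incomplete records all have exposure 1, complete all 0
  tab <- study_table(
    data.frame(y = c(1, 2, NA, NA), x = c(0, 0, 1, 1), z = c(1, 2, 3, 4)),
    roles = c(y = "outcome", x = "exposure", z = "confounder"),
    scales = c(y = "continuous", x = "binary", z = "continuous"))
  cmp <- compare_by_completeness(tab)
  xrow <- cmp[cmp$variable == "x", ]
  expect_equal(xrow$complete_2, 0)     # % exposed among complete
  expect_equal(xrow$incomplete_2, 100) # % exposed among incomplete
  expect_equal(attr(cmp, "n_complete"), 2)
  expect_equal(attr(cmp, "n_incomplete"), 2)
})

test_that("a cell with no observed values is not estimable, never zero", {
  tab <- study_table(
    data.frame(y = c(1, 2, NA), x = c(0, 1, 1), z = c(5, 6, NA)),
    roles = c(y = "outcome", x = "exposure", z = "confounder"),
    scales = c(y = "continuous", x = "binary", z = "continuous"))
  cmp <- compare_by_completeness(tab)
  zrow <- cmp[cmp$variable == "z", ]
  expect_true(is.na(zrow$incomplete_1))
})

test_that("single-group tables warn instead of failing", {
  expect_warning(compare_by_completeness(linear_table(20)), "single")
})

test_that("outcome-dependent missingness shows up in the group means", {
  ps <- alspac_like_preset(20000, seed = 13)
  cmp <- compare_by_completeness(ps$table)
  yrow <- cmp[cmp$variable == "attain_16", ]
  # the mechanism deletes low scorers preferentially, so complete records
  # have the higher observed mean outcome
  expect_gt(yrow$complete_1, yrow$incomplete_1)
})

test_that("the completeness model recovers a known generating coefficient", {
  set.seed(77)
  n <- 50000
  x <- rnorm(n)
  covar <- rnorm(n)
  complete <- rbinom(n, 1, plogis(-1 + 1 * x))
  y <- rnorm(n)
  y[complete == 0] <- NA
  tab <- study_table(
    data.frame(y = y, e = rbinom(n, 1, 0.4), x = x, covar = covar),
    roles = c(y = "outcome", e = "exposure", x = "confounder",
              covar = "confounder"),
    scales = c(y = "continuous", e = "binary", x = "continuous",
               covar = "continuous"))
  fit <- predictors_of_missingness(tab, c("x", "covar"))
  est <- fit$estimates
  bx <- est$estimate[est$term == "x"]
  expect_gt(bx, 0.9)
  expect_lt(bx, 1.1)
  # independent oracle: optim on the binomial log-likelihood
  nll <- function(b) -sum(dbinom(complete, 1,
                                 plogis(b[1] + b[2] * x + b[3] * covar),
                                 log = TRUE))
  ora <- optim(c(0, 0, 0), nll, method = "BFGS")$par
  expect_equal(bx, ora[2], tolerance = 1e-3)
  expect_true(fit$converged)
  # odds ratio consistent with the coefficient
  expect_equal(est$odds_ratio, exp(est$estimate), tolerance = 1e-12)
  expect_true(all(est$ci_lower < est$ci_upper))
})

test_that("MCAR completeness shows no joint association with predictors", {
  lr_ps <- vapply(1:20, function(s) {
    ps <- alspac_like_preset(2000, seed = 300 + s)
    complete <- generate_cohort(ps$config)
    mcar <- impose_missingness(
      complete, missingness_mechanism("smoke_14", intercept = qlogis(0.5)),
      seed = s)
    predictors_of_missingness(mcar, c("sex", "mat_educ", "pat_educ"))$lr_p
  }, 0)
  expect_gt(mean(lr_ps > 0.01), 0.9)
})

test_that("degenerate predictors are flagged", {
  tab <- toy_table()
  tab$data$const <- 1
  tab$roles <- c(tab$roles, const = "confounder")
  tab$scales <- c(tab$scales, const = "continuous")
  fit <- predictors_of_missingness(tab, "const")
  expect_identical(fit$degenerate_terms, "const")
  expect_true(fit$few_events)
})
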