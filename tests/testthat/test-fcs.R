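test_that("initialization draws from the observed marginal", {
  tab <- study_table(
    data.frame(y = c(1, 1, 1, NA, NA), x = c(0, 1, 0, 1, 0), z = 1:5),
    roles = c(y = "outcome", x = "exposure", z = "confounder"),
    scales = c(y = "continuous", x = "binary", z = "continuous"))
  filled <- initialize_fill(tab, seed = 1)
  # single-valued donor pool: both missing cells must be 1
  expect_equal(filled$y[4:5], c(1, 1))
  expect_false(anyNA(filled))
  # a complete table violates the precondition
  expect_error(initialize_fill(linear_table(10), seed = 1), "no missing")
  # the initialized marginal tracks the observed marginal at scale
  ps <- small_preset(4000, seed = 5)
  filled <- initialize_fill(ps$table, seed = 9)
  obs <- ps$table$data$smoke_14[!is.na(ps$table$data$smoke_14)]
  init <- filled$smoke_14[is.na(ps$table$data$smoke_14)]
  expect_lt(abs(mean(init) - mean(obs)), 0.05)
})

test_that("bayesian linear imputation satisfies its limits and offset contract", {
  set.seed(10)
  n <- 100
  x <- rnorm(n)
  X_obs <- cbind(1, x)
  X_mis <- cbind(1, rnorm(20))
  # degenerate-noise limit: y exactly linear => imputations on the line
  y_exact <- 2 + 3 * x
  set.seed(1)
  vals <- impute_bayes_linear(y_exact, X_obs, X_mis)
  expect_equal(vals, 2 + 3 * X_mis[, 2], tolerance = 1e-8)
  # additive-offset contract: identical streams, delta shifts by exactly +5
  y <- y_exact + rnorm(n)
  set.seed(33); v0 <- impute_bayes_linear(y, X_obs, X_mis, delta = 0)
  set.seed(33); v5 <- impute_bayes_linear(y, X_obs, X_mis, delta = 5)
  expect_equal(v5 - v0, rep(5, 20), tolerance = 1e-12)
})

test_that("bayesian linear posterior concentrates at the truth", {
  set.seed(11)
  n <- 10000
  x <- rnorm(n)
  y <- 2 + 3 * x + rnorm(n)
  X_obs <- cbind(1, x)
  X_mis <- cbind(1, rep(1, 500))
  vals <- replicate(20, impute_bayes_linear(y, X_obs, X_mis))
  # mean imputed value at x = 1 approaches E[y|x=1] = 5
  expect_gt(mean(vals), 4.9)
  expect_lt(mean(vals), 5.1)
})

test_that("bayesian logistic imputation respects delta and its bounds", {
  set.seed(12)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.3)      # independent of x, prevalence 0.3
  X_obs <- cbind(1, x)
  X_mis <- cbind(1, rnorm(1000))
  set.seed(5)
  v0 <- impute_bayes_logistic(y, X_obs, X_mis, delta = 0)
  expect_true(all(v0 %in% c(0, 1)))
  expect_gt(mean(v0), 0.27 - 0.05)
  expect_lt(mean(v0), 0.33 + 0.05)
  # delta = 10 forces nearly all ones: expit(eta + 10) >= 0.993 for |eta| <= 5
  set.seed(5)
  v10 <- impute_bayes_logistic(y, X_obs, X_mis, delta = 10)
  expect_gt(mean(v10), 0.99)
  # monotone in delta under common random numbers
  expect_true(all(v10 >= v0))
  # one-class target is degenerate
  expect_error(impute_bayes_logistic(rep(1, n), X_obs, X_mis), "one class")
})

test_that("pmm imputes only observed donor values, nearest donor when k = 1", {
  set.seed(13)
  n <- 50
  x <- rnorm(n)
  y <- 4 + 2 * x          # exact line: drawn beta collapses to truth
  X_obs <- cbind(1, x)
  X_mis <- cbind(1, x[7]) # predicted mean ties exactly with observed row 7
  v <- impute_pmm(y, X_obs, X_mis, k = 1)
  expect_equal(v, y[7])
  # donor-pool membership at realistic noise
  y2 <- y + rnorm(n)
  X_mis2 <- cbind(1, rnorm(30))
  v2 <- impute_pmm(y2, X_obs, X_mis2, k = 5)
  expect_true(all(v2 %in% y2))
  expect_error(impute_pmm(y2[1:3], X_obs[1:3, ], X_mis2, k = 5), "exceeds")
})

test_that("pmm accuracy is comparable to bayesian linear imputation", {
  set.seed(14)
  mse <- function(fun) {
    errs <- replicate(40, {
      n <- 600
      x <- rnorm(n)
      y <- x + rnorm(n)
      mis <- sample(n, 150)
      X <- cbind(1, x)
      truth <- y[mis]
      imp <- fun(y[-mis], X[-mis, ], X[mis, ])
      mean((imp - truth)^2)
    })
    mean(errs)
  }
  m_lin <- mse(function(yo, Xo, Xm) impute_bayes_linear(yo, Xo, Xm))
  m_pmm <- mse(function(yo, Xo, Xm) impute_pmm(yo, Xo, Xm, k = 5))
  expect_lt(abs(m_pmm - m_lin) / m_lin, 0.10)
})

test_that("the chained run is deterministic and preserves observed cells", {
  ps <- small_preset(800, seed = 17)
  spec <- imputation_spec(ps$table, m = 3, cycles = 3, seed = 4)
  s1 <- run_chained(ps$table, spec)
  s2 <- run_chained(ps$table, spec)
  expect_identical(s1$imputations, s2$imputations)
  spec2 <- imputation_spec(ps$table, m = 3, cycles = 3, seed = 5)
  expect_false(identical(run_chained(ps$table, spec2)$imputations,
                         s1$imputations))
  # observed cells bit-identical to the input in every copy
  for (d in s1$imputations) {
    for (v in names(ps$table$data)) {
      obs <- !is.na(ps$table$data[[v]])
      expect_identical(d[[v]][obs], ps$table$data[[v]][obs])
    }
    expect_false(anyNA(d))
  }
})

test_that("imputation spec validation enforces its invariants", {
  ps <- small_preset(400, seed = 2)
  expect_error(imputation_spec(ps$table, m = 1), "m must be at least 2")
  pm <- lapply(names(ps$table$data), function(v) setdiff(names(ps$table$data), v))
  names(pm) <- names(ps$table$data)
  pm$smoke_14 <- c(pm$smoke_14, "smoke_14")
  expect_error(imputation_spec(ps$table, predictor_matrix = pm), "self-prediction")
  pm$smoke_14 <- "ghost"
  expect_error(imputation_spec(ps$table, predictor_matrix = pm), "absent")
  # compatibility: dropping a substantive variable from a predictor set fails
  pm$smoke_14 <- setdiff(names(ps$table$data), c("smoke_14", "attain_11"))
  expect_error(imputation_spec(ps$table, predictor_matrix = pm), "incompatible")
})

test_that("between-imputation variance is positive and uncertainty propagates", {
  ps <- small_preset(800, seed = 19)
  spec <- imputation_spec(ps$table, m = 5, cycles = 3, seed = 6)
  stack <- run_chained(ps$table, spec)
  pooled <- fit_and_pool(stack, default_substantive_model(ps$table))
  expect_gt(pooled$b, 0)
  expect_gte(pooled$t_var, pooled$ubar)
})

test_that("single incomplete continuous variable reduces to bayes-linear draws", {
  set.seed(20)
  n <- 400
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n)
  mis <- sample(n, 100)
  y_obs_full <- y; y_obs_full[mis] <- NA
  tab <- study_table(
    data.frame(y = y_obs_full, x = rbinom(n, 1, 0.5), z = x),
    roles = c(y = "outcome", x = "exposure", z = "confounder"),
    scales = c(y = "continuous", x = "binary", z = "continuous"))
  spec <- imputation_spec(tab, m = 2, cycles = 4, seed = 3)
  stack <- run_chained(tab, spec)
  # cycling is idle for a single incomplete variable: imputed values are a
  # proper draw around the regression line; check calibration of the mean
  imp <- stack$imputations[[1]]$y[mis]
  expect_lt(abs(mean(imp) - mean(1 + 2 * x[mis])), 0.5)
})

test_that("imputed stacks round-trip losslessly through CSV + manifest", {
  ps <- small_preset(300, seed = 23)
  spec <- imputation_spec(ps$table, m = 2, cycles = 2, seed = 8)
  stack <- run_chained(ps$table, spec)
  dir <- file.path(tempdir(), "stack_rt")
  write_imputed_stack(stack, dir)
  back <- read_imputed_stack(dir)
  for (i in seq_along(stack$imputations))
    expect_equal(back$imputations[[i]], stack$imputations[[i]],
                 tolerance = 0)
  expect_equal(lapply(back$imputed_cells, as.integer),
               lapply(stack$imputed_cells, as.integer))
})
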