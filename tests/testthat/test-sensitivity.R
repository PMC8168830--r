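test_that("imputed positive proportion is plain arithmetic over the stack", {
  ps <- small_preset(400, seed = 3)
  spec <- imputation_spec(ps$table, m = 2, cycles = 2, seed = 5)
  stack <- run_chained(ps$table, spec)
  idx <- stack$imputed_cells$smoke_14
  manual <- mean(c(stack$imputations[[1]]$smoke_14[idx],
                   stack$imputations[[2]]$smoke_14[idx]) == 1)
  expect_equal(imputed_positive_proportion(stack, "smoke_14"), manual)
  expect_error(imputed_positive_proportion(stack, "attain_16"), "not binary")
  expect_error(imputed_positive_proportion(stack, "sex"), "no imputed cells")
})

test_that("worst-case fill sets every missing cell to the fill value", {
  ps <- small_preset(600, seed = 7)
  spec <- imputation_spec(ps$table, m = 3, cycles = 2, seed = 9)
  stack <- worst_case_impute(ps$table, spec, "smoke_14", 1)
  expect_equal(imputed_positive_proportion(stack, "smoke_14"), 1.0)
  idx <- stack$imputed_cells$smoke_14
  for (d in stack$imputations) expect_true(all(d$smoke_14[idx] == 1))
  expect_error(worst_case_impute(ps$table, spec, "smoke_14", 2), "illegal")
  expect_error(worst_case_impute(ps$table, spec, "attain_16", 1),
               "binary or categorical")
})

test_that("worst-case filling attenuates a negative effect toward zero", {
  ps <- alspac_like_preset(4000, seed = 47, beta_true = -10)
  model <- default_substantive_model(ps$table)
  spec <- imputation_spec(ps$table, m = 10, cycles = 5, seed = 49)
  standard <- fit_and_pool(run_chained(ps$table, spec), model)
  worst <- fit_and_pool(worst_case_impute(ps$table, spec, "smoke_14", 1), model)
  # misclassifying true nonsmokers as smokers dilutes the contrast
  expect_lt(abs(worst$estimate), abs(standard$estimate))
})

test_that("delta grid: zero offset reproduces the primary analysis bit-for-bit", {
  ps <- small_preset(700, seed = 51)
  model <- default_substantive_model(ps$table)
  spec <- imputation_spec(ps$table, m = 4, cycles = 3, seed = 53)
  primary <- fit_and_pool(run_chained(ps$table, spec), model)
  grid <- run_delta_grid(ps$table, spec, "smoke_14", 0, model)
  expect_identical(grid[[1]]$pooled$estimate, primary$estimate)
  expect_identical(grid[[1]]$pooled$t_var, primary$t_var)
})

test_that("imputed positive proportion is monotone along the delta grid", {
  ps <- small_preset(900, seed = 55)
  model <- default_substantive_model(ps$table)
  spec <- imputation_spec(ps$table, m = 3, cycles = 3, seed = 57)
  deltas <- c(0, 0.1, 0.25, 0.5, 1, 10)
  grid <- run_delta_grid(ps$table, spec, "smoke_14", deltas, model)
  props <- vapply(grid, `[[`, 0, "imputed_positive_proportion")
  expect_true(all(diff(props) >= 0))
  expect_gt(props[length(props)], 0.99)
})

test_that("tipping point search honours its contracts", {
  ps <- small_preset(800, seed = 61, delta_true = 0)
  model <- default_substantive_model(ps$table)
  spec <- imputation_spec(ps$table, m = 3, cycles = 3, seed = 63)
  # strong true effect: the CI never includes zero on [0, 2]
  tp <- find_tipping_point(ps$table, spec, "smoke_14", model,
                           range = c(0, 2), resolution = 1)
  expect_false(tp$reached)
  expect_equal(nrow(tp$trace), 3)
  expect_true(all(!tp$trace$criterion_met))
  # degenerate: criterion already true at the lower bound
  tp2 <- find_tipping_point(ps$table, spec, "smoke_14", model,
                            criterion = function(p) TRUE,
                            range = c(0, 2), resolution = 1)
  expect_true(tp2$degenerate)
  expect_equal(tp2$delta_star, 0)
})

test_that("a weak effect has a bracketable tipping point", {
  # effect sized so delta = 0 excludes zero but a large offset pulls the
  # estimate toward the null past significance
  ps <- alspac_like_preset(1200, seed = 65, beta_true = -3)
  model <- default_substantive_model(ps$table)
  spec <- imputation_spec(ps$table, m = 4, cycles = 3, seed = 67)
  base <- fit_and_pool(run_chained(ps$table, spec), model)
  expect_lt(base$ci_upper, 0)  # baseline conclusion: effect present
  tp <- find_tipping_point(ps$table, spec, "smoke_14", model,
                           range = c(0, 20), resolution = 4, refine = 2)
  if (tp$reached) {
    expect_gt(tp$delta_star, 0)
    # trace verdicts consistent: false below the flip, true at it
    tr <- tp$trace[order(tp$trace$delta), ]
    below <- tr$delta < tp$delta_star
    expect_false(any(tr$criterion_met[below] & tr$delta[below] < tp$delta_star - 4))
  } else {
    expect_true(all(!tp$trace$criterion_met))
  }
})

test_that("matched-delta analysis corrects MNAR bias direction", {
  # one replicate as a direction check (the replicate-averaged version runs
  # in the acceptance suite): data deleted preferentially for smokers,
  # analyzed with and without the matching offset
  ps <- alspac_like_preset(4000, seed = 71, delta_true = 1)
  model <- default_substantive_model(ps$table)
  sp0 <- imputation_spec(ps$table, m = 8, cycles = 4, seed = 73)
  sp1 <- imputation_spec(ps$table, m = 8, cycles = 4, seed = 73,
                         offsets = c(smoke_14 = 1))
  est0 <- fit_and_pool(run_chained(ps$table, sp0), model)$estimate
  est1 <- fit_and_pool(run_chained(ps$table, sp1), model)$estimate
  # the matched-delta estimate should sit closer to the generating truth
  expect_lt(abs(est1 - (-10)) - abs(est0 - (-10)), 1.0)
})
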