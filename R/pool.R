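#' Substantive analysis model specification
#'
#' The analysis model is a linear regression of the outcome on the exposure
#' adjusted for confounders; the estimand is the exposure coefficient (the
#' adjusted mean difference, in outcome-score points).
#'
#' @param outcome Outcome variable name (continuous).
#' @param exposure Exposure variable name.
#' @param confounders Character vector of confounder names.
#' @return An object of class `substantive_model`.
#' @export
substantive_model <- function(outcome, exposure, confounders = character()) {
  all_vars <- c(outcome, exposure, confounders)
  if (anyDuplicated(all_vars))
    stop("outcome, exposure and confounders must be disjoint")
  structure(list(outcome = outcome, exposure = exposure,
                 confounders = confounders),
            class = "substantive_model")
}

#' Default substantive model of a study table
#'
#' Reads the outcome, exposure and confounders off the table's roles.
#' @param table A `study_table`.
#' @return A `substantive_model`.
#' @export
default_substantive_model <- function(table) {
  substantive_model(
    outcome = variables_by_role(table, "outcome"),
    exposure = variables_by_role(table, "exposure"),
    confounders = variables_by_role(table, "confounder"))
}

model_formula <- function(model) {
  stats::reformulate(c(model$exposure, model$confounders),
                     response = model$outcome)
}

#' Fit the substantive linear model to one completed data set
#'
#' @param data A data frame complete for the model variables.
#' @param model A `substantive_model`.
#' @return A list with `estimate` (exposure coefficient), `se`, `variance`
#'   (squared SE), `coefficients` (full vector), `n`, and `df_residual`.
#' @export
fit_substantive <- function(data, model) {
  stopifnot(inherits(model, "substantive_model"))
  vars <- c(model$outcome, model$exposure, model$confounders)
  bad <- setdiff(vars, names(data))
  if (length(bad)) stop("model variable(s) absent: ", paste(bad, collapse = ", "))
  fit <- stats::lm(model_formula(model), data = data)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design; aliased term(s): ", paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  # exposure term name: numeric exposure keeps its own name
  term <- model$exposure
  if (!term %in% rownames(sm))
    term <- grep(paste0("^", model$exposure), rownames(sm), value = TRUE)[1]
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  list(estimate = unname(est), se = unname(se), variance = unname(se^2),
       coefficients = stats::coef(fit),
       n = length(fit$residuals), df_residual = fit$df.residual)
}

#' Complete-records analysis
#'
#' Fits the substantive model to the records with complete data on all
#' analysis-model variables only, the classical complete case analysis.
#'
#' @param table A `study_table`.
#' @param model A `substantive_model` (default read from the table roles).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `pooled_result` with `m = 1`, `B = 0`, the
#'   complete-record `n`, and a t-based confidence interval.
#' @export
fit_complete_records <- function(table, model = default_substantive_model(table),
                                 conf_level = 0.95) {
  stopifnot(inherits(table, "study_table"))
  complete <- complete_record(table)
  k <- length(model$confounders) + 2L
  if (sum(complete) < k + 1L)
    stop("too few complete records (", sum(complete), ") for ", k, " parameters")
  fit <- fit_substantive(table$data[complete, , drop = FALSE], model)
  df <- fit$df_residual
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(method = "complete_records",
         estimate = fit$estimate, ubar = fit$variance, b = 0,
         t_var = fit$variance, se = fit$se, df = df,
         riv = 0, fmi = NA_real_, m = 1L,
         ci_lower = fit$estimate - tq * fit$se,
         ci_upper = fit$estimate + tq * fit$se,
         p_value = 2 * stats::pt(-abs(fit$estimate / fit$se), df),
         n = fit$n, conf_level = conf_level,
         per_imputation = data.frame(estimate = fit$estimate,
                                     variance = fit$variance)),
    class = "pooled_result")
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Combines `m` complete-data estimates of a scalar estimand: pooled point
#' estimate Qbar = mean(Q_i); within-imputation variance Ubar = mean(U_i);
#' between-imputation variance B = sample variance of Q_i; total variance
#' T = Ubar + (1 + 1/m) B. The reference distribution is t with the
#' Barnard-Rubin small-sample degrees of freedom by default (the classic
#' large-sample (m-1)(1 + 1/riv)^2 form is available via
#' `df_method = "classic"` for cross-checking against other software).
#' The fraction of missing information is
#' fmi = (riv + 2/(df+3)) / (1 + riv) with riv = (1 + 1/m) B / Ubar.
#'
#' @param estimates Numeric vector of per-imputation point estimates Q_i.
#' @param variances Numeric vector of per-imputation squared standard
#'   errors U_i.
#' @param df_complete Complete-data residual degrees of freedom (n minus
#'   number of model parameters), used by the Barnard-Rubin adjustment.
#' @param n Number of records in each completed data set (reported).
#' @param df_method `"barnard_rubin"` (default) or `"classic"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `pooled_result` with fields `estimate`
#'   (Qbar), `ubar`, `b`, `t_var`, `se`, `df`, `riv`, `fmi`, `ci_lower`,
#'   `ci_upper`, `p_value`, `m`, `n` and the per-imputation inputs.
#' @export
pool_rubin <- function(estimates, variances, df_complete, n = NA_integer_,
                       df_method = c("barnard_rubin", "classic"),
                       conf_level = 0.95) {
  df_method <- match.arg(df_method)
  m <- length(estimates)
  if (m < 2) stop("Rubin's rules require m >= 2 (B is undefined for m = 1)")
  if (length(variances) != m) stop("estimates and variances must have equal length")
  if (any(variances <= 0)) stop("per-imputation variances must be positive")
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- stats::var(estimates)
  t_var <- ubar + (1 + 1 / m) * b
  riv <- (1 + 1 / m) * b / ubar
  lambda <- (1 + 1 / m) * b / t_var
  df_old <- if (lambda > 0) (m - 1) / lambda^2 else Inf
  df_obs <- ((df_complete + 1) / (df_complete + 3)) * df_complete * (1 - lambda)
  df <- switch(df_method,
               barnard_rubin = 1 / (1 / df_old + 1 / df_obs),
               classic = df_old)
  if (!is.finite(df)) df <- df_obs
  fmi <- (riv + 2 / (df + 3)) / (1 + riv)
  se <- sqrt(t_var)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(method = "multiple_imputation",
         estimate = qbar, ubar = ubar, b = b, t_var = t_var, se = se,
         df = df, riv = riv, fmi = fmi, m = m,
         ci_lower = qbar - tq * se, ci_upper = qbar + tq * se,
         p_value = 2 * stats::pt(-abs(qbar / se), df),
         n = n, conf_level = conf_level,
         df_method = df_method,
         per_imputation = data.frame(estimate = estimates,
                                     variance = variances)),
    class = "pooled_result")
}

#' Fit the substantive model to every imputation and pool
#'
#' @param stack An `imputed_stack`.
#' @param model A `substantive_model`.
#' @param ... Passed to [pool_rubin()].
#' @return A `pooled_result` for the exposure coefficient.
#' @export
fit_and_pool <- function(stack, model, ...) {
  stopifnot(inherits(stack, "imputed_stack"))
  fits <- lapply(stack$imputations, fit_substantive, model = model)
  pool_rubin(vapply(fits, `[[`, 0, "estimate"),
             vapply(fits, `[[`, 0, "variance"),
             df_complete = fits[[1]]$df_residual,
             n = fits[[1]]$n, ...)
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.3f, %g%% CI (%.3f, %.3f), p = %.4g\n",
              x$method, x$estimate, 100 * x$conf_level,
              x$ci_lower, x$ci_upper, x$p_value))
  cat(sprintf("  n = %s, m = %d, T = %.4f (Ubar %.4f, B %.4f), df = %.1f, fmi = %s\n",
              x$n, x$m, x$t_var, x$ubar, x$b, x$df,
              if (is.na(x$fmi)) "NA" else sprintf("%.3f", x$fmi)))
  invisible(x)
}

#' Serialize a pooled result (with all intermediates) to JSON
#' @param x A `pooled_result`.
#' @param path Optional output path.
#' @return JSON string, invisibly if written.
#' @export
pooled_result_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "pooled_result"))
  obj <- unclass(x)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                         na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
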