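#' Summarize the extent and patterns of missing data
#'
#' The first of the three data-examination outputs: per-variable missing
#' counts and proportions, the complete-record count and proportion (a
#' record is complete iff all analysis-model variables — outcome, exposure,
#' confounders — are observed; auxiliaries are excluded from the
#' denominator definition), and the table of distinct observed/missing
#' patterns over the analysis-model variables sorted by frequency.
#'
#' @param table A `study_table` with at least one record.
#' @return An object of class `missingness_summary` with elements
#'   `per_variable` (data frame: variable, role, n_missing, prop_missing),
#'   `n_records`, `n_complete`, `prop_complete`, `patterns` (data frame of
#'   pattern strings, per-variable observed flags and counts) and
#'   `auxiliary_vars`.
#' @export
summarize_missingness <- function(table) {
  stopifnot(inherits(table, "study_table"))
  n <- nrow(table$data)
  if (n == 0) stop("table has no records")
  vars <- names(table$data)
  n_miss <- colSums(is.na(table$data))
  per_variable <- data.frame(
    variable = vars, role = unname(table$roles[vars]),
    n_missing = unname(n_miss), prop_missing = unname(n_miss) / n,
    row.names = NULL)
  av <- analysis_variables(table)
  obs <- !is.na(table$data[av])
  pat_str <- apply(obs, 1, function(r) paste(ifelse(r, "O", "."), collapse = ""))
  tab <- sort(table(pat_str), decreasing = TRUE)
  pat_flags <- do.call(rbind, strsplit(names(tab), ""))
  patterns <- data.frame(pattern = names(tab), count = as.integer(tab),
                         row.names = NULL)
  for (j in seq_along(av)) patterns[[av[j]]] <- pat_flags[, j] == "O"
  complete <- complete_record(table)
  structure(
    list(per_variable = per_variable,
         analysis_variables = av,
         n_records = n,
         n_complete = sum(complete),
         prop_complete = mean(complete),
         patterns = patterns,
         auxiliary_vars = variables_by_role(table, "auxiliary")),
    class = "missingness_summary")
}

#' @export
print.missingness_summary <- function(x, ...) {
  cat("Missingness summary: ", x$n_records, " records, ",
      x$n_complete, " complete (",
      sprintf("%.1f%%", 100 * x$prop_complete), ")\n", sep = "")
  print(x$per_variable, ...)
  invisible(x)
}

#' Compare observed characteristics of complete vs incomplete records
#'
#' The second data-examination output: for every variable, the mean and SD
#' (continuous) or count and percentage per level (binary/categorical)
#' among complete records and among incomplete records, each computed over
#' that group's observed values only. A cell with no observed values in a
#' group is reported as `NA` (not estimable), never as zero.
#'
#' @param table A `study_table`.
#' @return A data frame with class `completeness_comparison`: one row per
#'   variable (or variable level), with group sizes in attributes
#'   `n_complete` / `n_incomplete` and a `single_group` warning flag when
#'   all records fall in one group.
#' @export
compare_by_completeness <- function(table) {
  stopifnot(inherits(table, "study_table"))
  complete <- complete_record(table)
  single_group <- all(complete) || all(!complete)
  if (single_group)
    warning("all records are in a single completeness group; ",
            "returning one-group comparison")
  rows <- list()
  grp_stats <- function(x, scale, idx) {
    x <- x[idx]
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_))
    if (scale == "continuous") c(mean(x), stats::sd(x))
    else c(sum(as.numeric(x) == 1), 100 * mean(as.numeric(x) == 1))
  }
  for (v in names(table$data)) {
    sc <- table$scales[[v]]
    if (sc == "categorical") {
      lv <- levels(factor(table$data[[v]]))
      for (l in lv) {
        ind <- as.numeric(as.character(table$data[[v]]) == l)
        ind[is.na(table$data[[v]])] <- NA
        cc <- grp_stats(ind, "binary", complete)
        ic <- grp_stats(ind, "binary", !complete)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = l, statistic = "count / %",
          complete_1 = cc[1], complete_2 = cc[2],
          incomplete_1 = ic[1], incomplete_2 = ic[2])
      }
    } else {
      cc <- grp_stats(table$data[[v]], sc, complete)
      ic <- grp_stats(table$data[[v]], sc, !complete)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_,
        statistic = if (sc == "continuous") "mean / SD" else "count / %",
        complete_1 = cc[1], complete_2 = cc[2],
        incomplete_1 = ic[1], incomplete_2 = ic[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_complete") <- sum(complete)
  attr(out, "n_incomplete") <- sum(!complete)
  attr(out, "single_group") <- single_group
  class(out) <- c("completeness_comparison", "data.frame")
  out
}

#' Model the predictors of being a complete record
#'
#' The third data-examination output: a maximum-likelihood logistic
#' regression of the complete-record indicator on a user-supplied set of
#' (fully or nearly fully observed) predictors, with Wald confidence
#' intervals and odds ratios. Records with any missing predictor are
#' dropped and their count reported. Perfect separation and degenerate
#' (constant) predictors are detected and flagged rather than silently
#' penalized, since a diagnostic must not mask pathologies.
#'
#' @param table A `study_table`.
#' @param predictors Character vector of predictor variable names.
#' @param alpha Confidence level complement for the Wald intervals.
#' @return An object of class `completeness_model` with elements
#'   `estimates` (data frame: term, estimate, se, odds_ratio, ci_lower,
#'   ci_upper, p_value), `n_used`, `n_dropped`, `n_events`, `converged`,
#'   `separation`, `degenerate_terms`, `lr_statistic`, `lr_df`, `lr_p`
#'   (likelihood-ratio test of all predictors jointly) and `few_events`.
#' @export
predictors_of_missingness <- function(table, predictors, alpha = 0.05) {
  stopifnot(inherits(table, "study_table"))
  missing_preds <- setdiff(predictors, names(table$data))
  if (length(missing_preds))
    stop("unknown predictor(s): ", paste(missing_preds, collapse = ", "))
  complete <- complete_record(table)
  df <- table$data[predictors]
  usable <- stats::complete.cases(df)
  n_dropped <- sum(!usable)
  df <- df[usable, , drop = FALSE]
  y <- as.numeric(complete[usable])
  degenerate <- predictors[vapply(df, function(x) length(unique(x)) < 2, TRUE)]
  fit_df <- cbind(.complete = y, df)
  fit <- suppressWarnings(
    stats::glm(.complete ~ ., data = fit_df, family = stats::binomial()))
  null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  co <- summary(fit)$coefficients
  # separation heuristic: diverging coefficients or exploding SEs
  separation <- any(abs(co[, "Estimate"]) > 15 | co[, "Std. Error"] > 100)
  z <- stats::qnorm(1 - alpha / 2)
  estimates <- data.frame(
    term = rownames(co), estimate = co[, "Estimate"], se = co[, "Std. Error"],
    odds_ratio = exp(co[, "Estimate"]),
    ci_lower = co[, "Estimate"] - z * co[, "Std. Error"],
    ci_upper = co[, "Estimate"] + z * co[, "Std. Error"],
    p_value = co[, "Pr(>|z|)"], row.names = NULL)
  lr_stat <- as.numeric(null_fit$deviance - fit$deviance)
  lr_df <- length(stats::coef(fit)) - 1L - length(degenerate)
  n_events <- min(sum(y == 1), sum(y == 0))
  structure(
    list(estimates = estimates,
         n_used = nrow(df), n_dropped = n_dropped, n_events = n_events,
         converged = fit$converged && !separation,
         separation = separation,
         degenerate_terms = degenerate,
         lr_statistic = lr_stat, lr_df = lr_df,
         lr_p = if (lr_df > 0) stats::pchisq(lr_stat, lr_df, lower.tail = FALSE) else NA_real_,
         few_events = n_events < 10),
    class = "completeness_model")
}

#' @export
print.completeness_model <- function(x, ...) {
  cat("Logistic model for being a complete record (n = ", x$n_used,
      ", events = ", x$n_events, ")\n", sep = "")
  if (!x$converged) cat("** fit flagged: separation or non-convergence **\n")
  if (length(x$degenerate_terms))
    cat("** degenerate (constant) predictors: ",
        paste(x$degenerate_terms, collapse = ", "), " **\n", sep = "")
  print(x$estimates, digits = 3, ...)
  cat(sprintf("LR test of all predictors: chi2(%d) = %.2f, p = %.4g\n",
              x$lr_df, x$lr_statistic, x$lr_p))
  invisible(x)
}
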