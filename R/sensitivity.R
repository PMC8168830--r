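#' Proportion of imputed cells equal to 1
#'
#' For a binary imputed variable, the count of imputed cells equal to 1
#' across all m completed copies divided by the total number of imputed
#' cells across all copies — the "% of missing values imputed positive"
#' summary reported alongside pattern-mixture sensitivity analyses.
#'
#' @param stack An `imputed_stack`.
#' @param variable Name of a binary variable with imputed cells.
#' @return A proportion in [0, 1].
#' @export
imputed_positive_proportion <- function(stack, variable) {
  stopifnot(inherits(stack, "imputed_stack"))
  if (!identical(unname(stack$scales[[variable]]), "binary"))
    stop("`", variable, "` is not binary")
  idx <- stack$imputed_cells[[variable]]
  if (is.null(idx) || !length(idx))
    stop("`", variable, "` has no imputed cells; proportion undefined")
  vals <- unlist(lapply(stack$imputations, function(d) d[[variable]][idx]))
  mean(vals == 1)
}

#' Worst-case deterministic imputation of one variable
#'
#' The crude extremal sensitivity analysis: every missing cell of
#' `variable` is set to `fill_value` in every imputation (e.g. "all
#' missing smoking statuses are smokers"), while the remaining incomplete
#' variables are imputed normally per the specification.
#'
#' @param table A `study_table`.
#' @param spec An `imputation_spec` for the table.
#' @param variable Binary or categorical variable to fill.
#' @param fill_value A legal level of `variable`.
#' @return An `imputed_stack`.
#' @export
worst_case_impute <- function(table, spec, variable, fill_value) {
  stopifnot(inherits(table, "study_table"), inherits(spec, "imputation_spec"))
  sc <- table$scales[[variable]]
  if (is.null(sc) || !sc %in% c("binary", "categorical"))
    stop("worst-case fill requires a binary or categorical variable")
  legal <- if (sc == "binary") c(0, 1) else
    table$levels[[variable]] %||% levels(factor(table$data[[variable]]))
  if (!fill_value %in% legal)
    stop("illegal fill value `", fill_value, "` for `", variable, "`")
  spec$column_models[[variable]] <- "fill"
  spec$fill_values[[variable]] <- fill_value
  run_chained(table, spec)
}

#' Pattern-mixture delta-offset sensitivity grid
#'
#' Re-runs the chained-equations imputation with the sensitivity offset
#' delta applied to the named variable's column model (log-odds units for
#' a binary target), fits and pools the substantive model for each delta,
#' and reports the proportion of imputed cells at the adjusted level. The
#' same seed is used at every delta (common random numbers), so
#' differences along the grid are attributable to delta rather than Monte
#' Carlo noise; delta = 0 reproduces the primary analysis bit-for-bit.
#'
#' @param table A `study_table`.
#' @param spec An `imputation_spec`.
#' @param variable Variable receiving the offset.
#' @param deltas Numeric vector of offsets (finite).
#' @param model A `substantive_model`.
#' @return A list of class `sensitivity_grid`: one element per delta, each
#'   with `delta`, `pooled` (a `pooled_result`), and
#'   `imputed_positive_proportion` (binary targets; `NA` otherwise). A
#'   failed delta is recorded with an `error` field rather than aborting
#'   the grid.
#' @export
run_delta_grid <- function(table, spec, variable, deltas, model) {
  stopifnot(all(is.finite(deltas)))
  results <- lapply(deltas, function(d) {
    sp <- spec
    off <- sp$offsets
    off[[variable]] <- d
    sp$offsets <- unlist(off)
    tryCatch({
      stack <- run_chained(table, sp)
      pooled <- fit_and_pool(stack, model)
      ipp <- if (identical(unname(table$scales[[variable]]), "binary"))
        imputed_positive_proportion(stack, variable) else NA_real_
      list(delta = d, pooled = pooled, imputed_positive_proportion = ipp)
    }, error = function(e)
      list(delta = d, pooled = NULL, imputed_positive_proportion = NA_real_,
           error = conditionMessage(e)))
  })
  structure(results, class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  for (r in x) {
    if (!is.null(r$error)) {
      cat(sprintf("delta = %g: FAILED (%s)\n", r$delta, r$error))
    } else {
      cat(sprintf("delta = %-5g estimate %8.3f  CI (%.3f, %.3f)  %% imputed positive: %s\n",
                  r$delta, r$pooled$estimate, r$pooled$ci_lower, r$pooled$ci_upper,
                  if (is.na(r$imputed_positive_proportion)) "-" else
                    sprintf("%.1f", 100 * r$imputed_positive_proportion)))
    }
  }
  invisible(x)
}

#' Default conclusion-change criterion: the CI includes zero
#' @param conf_level Unused; the interval stored in the result is used.
#' @return A predicate on a `pooled_result`.
#' @export
ci_includes_zero <- function(conf_level = 0.95) {
  function(pooled) pooled$ci_lower <= 0 && pooled$ci_upper >= 0
}

#' Tipping-point search over the sensitivity parameter
#'
#' Finds the smallest delta at which a conclusion-change criterion
#' (default: the confidence interval for the exposure coefficient includes
#' zero) flips from false to true, by grid search at the stated resolution
#' with optional bisection refinement. The refinement assumes the
#' criterion is monotone in delta, which holds for the offset mechanism
#' when increasing delta moves imputed values toward the null.
#'
#' @param table A `study_table`.
#' @param spec An `imputation_spec`.
#' @param variable Variable receiving the offset.
#' @param model A `substantive_model`.
#' @param criterion Predicate on a `pooled_result` (default
#'   [ci_includes_zero()]).
#' @param range Numeric length-2 search interval for delta.
#' @param resolution Grid step.
#' @param refine Bisection refinement steps after the grid (0 = none).
#' @return An object of class `tipping_point`: `delta_star` (or `NA` if
#'   not reached), `reached`, `degenerate` (criterion already true at the
#'   lower bound), and `trace` (data frame of every evaluated delta with
#'   estimate, CI and criterion verdict).
#' @export
find_tipping_point <- function(table, spec, variable, model,
                               criterion = ci_includes_zero(),
                               range = c(0, 10), resolution = 1,
                               refine = 0) {
  grid <- seq(range[1], range[2], by = resolution)
  trace <- list()
  eval_delta <- function(d) {
    res <- run_delta_grid(table, spec, variable, d, model)[[1]]
    if (!is.null(res$error)) stop("delta = ", d, " failed: ", res$error)
    flip <- isTRUE(criterion(res$pooled))
    trace[[length(trace) + 1L]] <<- data.frame(
      delta = d, estimate = res$pooled$estimate,
      ci_lower = res$pooled$ci_lower, ci_upper = res$pooled$ci_upper,
      criterion_met = flip)
    flip
  }
  first <- eval_delta(grid[1])
  if (first) {
    return(structure(list(delta_star = grid[1], reached = TRUE,
                          degenerate = TRUE, trace = do.call(rbind, trace)),
                     class = "tipping_point"))
  }
  delta_star <- NA_real_
  lower <- grid[1]
  for (d in grid[-1]) {
    if (eval_delta(d)) { delta_star <- d; break }
    lower <- d
  }
  if (!is.na(delta_star) && refine > 0) {
    hi <- delta_star; lo <- lower
    for (i in seq_len(refine)) {
      mid <- (lo + hi) / 2
      if (eval_delta(mid)) hi <- mid else lo <- mid
    }
    delta_star <- hi
  }
  structure(
    list(delta_star = delta_star, reached = !is.na(delta_star),
         degenerate = FALSE,
         searched_range = range, resolution = resolution,
         trace = do.call(rbind, trace)),
    class = "tipping_point")
}

#' @export
print.tipping_point <- function(x, ...) {
  if (x$reached)
    cat("Tipping point: delta* =", x$delta_star,
        if (x$degenerate) "(criterion already met at lower bound)" else "", "\n")
  else
    cat("Tipping point not reached on [", x$searched_range[1], ",",
        x$searched_range[2], "]\n")
  print(x$trace, digits = 4, ...)
  invisible(x)
}

#' Serialize a tipping-point trace to JSON
#' @param x A `tipping_point`.
#' @param path Optional output path.
#' @return JSON string, invisibly if written.
#' @export
tipping_point_to_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = I(17), na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
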