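#' Thresholds and substantive-knowledge inputs for strategy selection
#'
#' The strategy flowchart is qualitative; these are the quantitative
#' anchors and substantive-judgement flags it consumes. The 5\% ceiling for
#' an acceptable complete-records analysis is the conventional anchor;
#' everything else is an exposed, documented artifact choice.
#'
#' @param max_incomplete_for_cra Proportion of incomplete records below
#'   which (strict inequality) a complete-records analysis may be
#'   acceptable. Default 0.05.
#' @param missingness_association_alpha Significance level used on the
#'   completeness-model likelihood-ratio test as evidence that completeness
#'   is associated with observed variables. Default 0.05.
#' @param outcome_association_flag Substantive judgement: is missingness
#'   plausibly related to the outcome?
#' @param mnar_suspected Substantive judgement: is residual dependence of
#'   missingness on the unobserved values themselves suspected?
#' @return An object of class `plan_thresholds`.
#' @export
plan_thresholds <- function(max_incomplete_for_cra = 0.05,
                            missingness_association_alpha = 0.05,
                            outcome_association_flag = FALSE,
                            mnar_suspected = FALSE) {
  stopifnot(max_incomplete_for_cra > 0, max_incomplete_for_cra < 1,
            missingness_association_alpha > 0, missingness_association_alpha < 1)
  structure(
    list(max_incomplete_for_cra = max_incomplete_for_cra,
         missingness_association_alpha = missingness_association_alpha,
         outcome_association_flag = isTRUE(outcome_association_flag),
         mnar_suspected = isTRUE(mnar_suspected)),
    class = "plan_thresholds")
}

#' Recommend a missing-data strategy from the diagnostics
#'
#' A deterministic, fully auditable rule engine over the three planning
#' questions: Q1 — is a complete-records analysis (CRA) likely to give
#' valid inference? Q2 — is multiple imputation (MI) likely to give
#' important bias reduction and/or increased precision? Q3 — is a
#' sensitivity analysis regarding the missingness mechanism required?
#'
#' Verdicts: Q1 passes iff the incomplete-record proportion is strictly
#' below `max_incomplete_for_cra` AND there is no evidence that
#' completeness depends on the outcome (`outcome_association_flag` is
#' false and, if the completeness model contains an outcome term, that term
#' is non-significant). Q2 passes iff Q1 fails AND (auxiliary variables
#' are declared OR the incomplete variables include confounders). Q3
#' requires sensitivity analysis iff MNAR is suspected on substantive
#' grounds OR completeness is associated with declared proxies (auxiliary
#' variables) of the incomplete variable.
#'
#' When MNAR is suspected but there is no evidence that missingness is
#' related to the outcome, a warning is attached (not an automatic
#' reversal): in that special case MI itself can be biased even though a
#' CRA is not.
#'
#' @param summary A `missingness_summary`.
#' @param completeness_model A `completeness_model` (or `NULL` if
#'   unavailable; verdicts degrade to "unknown" with explicit trace
#'   entries).
#' @param thresholds A `plan_thresholds`.
#' @return An object of class `mi_recommendation` with fields
#'   `primary_method` ("complete_records" or "multiple_imputation"),
#'   `sensitivity_required`, `cra_as_secondary`, `rationale` (ordered data
#'   frame of question, verdict, evidence) and `warnings`.
#' @export
recommend_strategy <- function(summary, completeness_model, thresholds) {
  stopifnot(inherits(summary, "missingness_summary"),
            inherits(thresholds, "plan_thresholds"))
  incomplete_prop <- 1 - summary$prop_complete
  rationale <- list()
  note <- function(question, verdict, evidence)
    rationale[[length(rationale) + 1L]] <<- data.frame(
      question = question, verdict = verdict, evidence = evidence)

  # --- Q1: is CRA likely valid? -------------------------------------------
  below <- incomplete_prop < thresholds$max_incomplete_for_cra
  note("Q1", if (below) "low-missingness" else "substantial-missingness",
       sprintf("incomplete-record proportion %.3f %s threshold %.3f (strict)",
               incomplete_prop, if (below) "<" else ">=",
               thresholds$max_incomplete_for_cra))

  outcome_term_sig <- NA
  if (!is.null(completeness_model)) {
    av_out <- summary$per_variable$variable[summary$per_variable$role == "outcome"]
    est <- completeness_model$estimates
    row <- est[est$term %in% av_out, , drop = FALSE]
    if (nrow(row)) {
      outcome_term_sig <- any(row$p_value < thresholds$missingness_association_alpha)
      note("Q1",
           if (outcome_term_sig) "outcome-associated" else "no-outcome-association",
           sprintf("completeness-model outcome term p = %.3g (alpha %.2f)",
                   min(row$p_value), thresholds$missingness_association_alpha))
    } else {
      note("Q1", "unknown", "completeness model contains no outcome term")
    }
  } else {
    note("Q1", "unknown", "no completeness model supplied")
  }
  outcome_dependence <- thresholds$outcome_association_flag ||
    isTRUE(outcome_term_sig)
  if (thresholds$outcome_association_flag)
    note("Q1", "outcome-associated",
         "substantive knowledge: missingness plausibly related to the outcome")
  q1_pass <- below && !outcome_dependence
  note("Q1", if (q1_pass) "CRA-acceptable" else "CRA-not-primary",
       if (q1_pass)
         "little missing information and no evidence completeness depends on the outcome"
       else "missingness substantial or outcome-dependent; CRA may be biased/inefficient")

  # --- Q2: is MI likely beneficial? ---------------------------------------
  aux_declared <- length(summary$auxiliary_vars) > 0
  incomplete_confounders <- any(
    summary$per_variable$role == "confounder" & summary$per_variable$n_missing > 0)
  q2_pass <- !q1_pass && (aux_declared || incomplete_confounders)
  note("Q2", if (q2_pass) "MI-beneficial" else "MI-not-indicated",
       sprintf("auxiliaries declared: %s (%s); incomplete confounders: %s",
               aux_declared,
               if (aux_declared) paste(summary$auxiliary_vars, collapse = ", ") else "none",
               incomplete_confounders))

  # --- Q3: is a sensitivity analysis required? ----------------------------
  proxy_assoc <- FALSE
  if (!is.null(completeness_model) && aux_declared) {
    est <- completeness_model$estimates
    prox <- est[est$term %in% summary$auxiliary_vars, , drop = FALSE]
    proxy_assoc <- nrow(prox) > 0 &&
      any(prox$p_value < thresholds$missingness_association_alpha)
    if (nrow(prox))
      note("Q3", if (proxy_assoc) "proxy-associated" else "no-proxy-association",
           sprintf("completeness vs auxiliary proxies, min p = %.3g", min(prox$p_value)))
  }
  q3_required <- thresholds$mnar_suspected || proxy_assoc
  note("Q3", if (q3_required) "sensitivity-required" else "sensitivity-not-required",
       if (thresholds$mnar_suspected)
         "substantive knowledge: missingness may depend on the value itself (MNAR)"
       else if (proxy_assoc)
         "completeness associated with proxies of the incomplete variable"
       else "no MNAR suspicion and no proxy association evidence")

  primary <- if (!q1_pass && q2_pass) "multiple_imputation" else "complete_records"
  warnings <- character()
  if (!q1_pass && !q2_pass)
    warnings <- c(warnings,
                  "CRA retained as primary despite substantial missingness: no auxiliaries and no incomplete confounders, so MI offers little")
  if (thresholds$mnar_suspected && !outcome_dependence)
    warnings <- c(warnings,
                  "MNAR suspected with missingness unrelated to the outcome: MI itself may be biased while CRA is not; interpret with care")

  rationale <- do.call(rbind, rationale)
  structure(
    list(primary_method = primary,
         sensitivity_required = q3_required,
         cra_as_secondary = primary == "multiple_imputation",
         rationale = rationale,
         warnings = warnings,
         evidence = list(incomplete_prop = incomplete_prop,
                         outcome_term_significant = outcome_term_sig,
                         aux_declared = aux_declared,
                         incomplete_confounders = incomplete_confounders,
                         proxy_assoc = proxy_assoc,
                         thresholds = thresholds)),
    class = "mi_recommendation")
}

#' @export
print.mi_recommendation <- function(x, ...) {
  cat("Recommended primary analysis:", x$primary_method, "\n")
  cat("Sensitivity analysis required:", x$sensitivity_required, "\n")
  cat("CRA as secondary analysis:", x$cra_as_secondary, "\n\n")
  print(x$rationale, right = FALSE, ...)
  for (w in x$warnings) cat("Warning:", w, "\n")
  invisible(x)
}

#' Serialize a recommendation to JSON
#' @param x An `mi_recommendation`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
recommendation_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "mi_recommendation"))
  obj <- list(primary_method = x$primary_method,
              sensitivity_required = x$sensitivity_required,
              cra_as_secondary = x$cra_as_secondary,
              rationale = x$rationale, warnings = x$warnings)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Render a recommendation as a markdown rationale block
#' @param x An `mi_recommendation`.
#' @return Character vector of markdown lines.
#' @export
recommendation_to_markdown <- function(x) {
  stopifnot(inherits(x, "mi_recommendation"))
  lines <- c("## Missing-data strategy",
             "",
             paste0("* **Primary analysis:** ",
                    gsub("_", " ", x$primary_method)),
             paste0("* **Sensitivity analysis required:** ", x$sensitivity_required),
             paste0("* **Complete-records analysis as secondary:** ", x$cra_as_secondary),
             "", "### Rationale", "")
  for (i in seq_len(nrow(x$rationale)))
    lines <- c(lines, sprintf("* %s — %s: %s", x$rationale$question[i],
                              x$rationale$verdict[i], x$rationale$evidence[i]))
  for (w in x$warnings) lines <- c(lines, "", paste0("> **Warning:** ", w))
  lines
}
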