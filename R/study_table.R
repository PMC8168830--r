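#' Participant-by-variable study table
#'
#' The container every pipeline stage consumes or produces: a rectangular
#' data frame (one row per participant) together with per-variable metadata
#' assigning each column a role in the substantive analysis and a
#' measurement scale. Missing cells are `NA` in `data`. When the table was
#' produced by simulation followed by deletion, `truth` holds the
#' pre-deletion values so that recovery error and mechanism properties can
#' be computed; cells that are `NA` in `data` but present in `truth` carry
#' provenance "simulated-then-deleted".
#'
#' @param data A data frame; missing cells as `NA`. Binary variables must be
#'   coded 0/1, categorical variables as factors (or values from `levels`).
#' @param roles Named character vector mapping every column of `data` to one
#'   of `"outcome"`, `"exposure"`, `"confounder"`, `"auxiliary"`.
#' @param scales Named character vector mapping every column to one of
#'   `"continuous"`, `"binary"`, `"categorical"`.
#' @param levels Named list of level sets for categorical variables.
#' @param truth Optional complete data frame of pre-deletion values (same
#'   shape as `data`), used for provenance.
#' @return An object of class `study_table`.
#' @export
study_table <- function(data, roles, scales, levels = NULL, truth = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  vars <- names(data)
  if (!setequal(names(roles), vars) || !setequal(names(scales), vars))
    stop("roles and scales must name exactly the columns of `data`")
  roles <- roles[vars]
  scales <- scales[vars]
  ok_roles <- c("outcome", "exposure", "confounder", "auxiliary")
  ok_scales <- c("continuous", "binary", "categorical")
  if (!all(roles %in% ok_roles)) stop("unknown role: ", paste(setdiff(roles, ok_roles), collapse = ", "))
  if (!all(scales %in% ok_scales)) stop("unknown scale: ", paste(setdiff(scales, ok_scales), collapse = ", "))
  if (sum(roles == "outcome") != 1L) stop("exactly one outcome variable required")
  if (sum(roles == "exposure") != 1L) stop("exactly one exposure variable required")
  for (v in vars[scales != "categorical"]) {
    if (!is.numeric(data[[v]]))
      stop("variable `", v, "` must be numeric for scale ", scales[[v]])
    data[[v]] <- as.numeric(data[[v]])  # store doubles uniformly
  }
  for (v in vars[scales == "binary"]) {
    x <- data[[v]][!is.na(data[[v]])]
    if (length(x) && !all(x %in% c(0, 1)))
      stop("binary variable `", v, "` must take values in {0, 1}")
  }
  for (v in vars[scales == "categorical"]) {
    if (!is.factor(data[[v]])) data[[v]] <- factor(data[[v]], levels = levels[[v]])
    if (!is.null(levels[[v]]) &&
        !all(stats::na.omit(as.character(data[[v]])) %in% levels[[v]]))
      stop("categorical variable `", v, "` has values outside its level set")
  }
  if (!is.null(truth)) {
    stopifnot(is.data.frame(truth), nrow(truth) == nrow(data),
              identical(names(truth), vars))
  }
  structure(
    list(data = data, roles = roles, scales = scales,
         levels = levels, truth = truth),
    class = "study_table"
  )
}

#' @export
print.study_table <- function(x, ...) {
  cat("<study_table> ", nrow(x$data), " participants x ", ncol(x$data),
      " variables\n", sep = "")
  miss <- colSums(is.na(x$data))
  info <- data.frame(role = x$roles, scale = x$scales,
                     n_missing = miss, pct_missing = round(100 * miss / nrow(x$data), 1))
  print(info, ...)
  invisible(x)
}

#' @export
dim.study_table <- function(x) dim(x$data)

#' Variable names by role
#' @param table A `study_table`.
#' @param roles Character vector of roles to select.
#' @return Character vector of variable names.
#' @export
variables_by_role <- function(table, roles) {
  names(table$roles)[table$roles %in% roles]
}

#' Names of the analysis-model variables (outcome, exposure, confounders)
#' @param table A `study_table`.
#' @return Character vector of variable names.
#' @export
analysis_variables <- function(table) {
  variables_by_role(table, c("outcome", "exposure", "confounder"))
}

#' Logical indicator of complete records
#'
#' A record is complete iff all analysis-model variables (outcome, exposure
#' and confounders; auxiliaries excluded) are observed.
#'
#' @param table A `study_table`.
#' @return Logical vector of length `nrow(table$data)`.
#' @export
complete_record <- function(table) {
  av <- analysis_variables(table)
  stats::complete.cases(table$data[av])
}

#' Per-cell provenance flags
#'
#' @param table A `study_table`.
#' @return A character matrix with entries `"observed"`,
#'   `"simulated-then-deleted"` (missing in `data` but recoverable from
#'   `truth`) or `"missing"`.
#' @export
cell_provenance <- function(table) {
  prov <- matrix("observed", nrow(table$data), ncol(table$data),
                 dimnames = list(NULL, names(table$data)))
  miss <- as.matrix(is.na(table$data))
  prov[miss] <- "missing"
  if (!is.null(table$truth)) {
    recoverable <- miss & !as.matrix(is.na(table$truth))
    prov[recoverable] <- "simulated-then-deleted"
  }
  prov
}

#' Write a study table to CSV with a YAML metadata sidecar
#'
#' Missing cells are written as empty fields. The sidecar (`<path>.yml`)
#' declares each variable's role, scale and categorical level set so the
#' table round-trips losslessly. If the table carries pre-deletion truth it
#' is optionally written alongside (`<stem>_truth.csv`) for test harnesses.
#'
#' @param table A `study_table`.
#' @param path Output CSV path.
#' @param write_truth Also write the ground-truth table if present.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path, write_truth = FALSE) {
  utils::write.csv(table$data, path, row.names = FALSE, na = "")
  meta <- list(
    variables = lapply(names(table$data), function(v) {
      m <- list(name = v, role = unname(table$roles[[v]]),
                scale = unname(table$scales[[v]]))
      if (!is.null(table$levels[[v]])) m$levels <- table$levels[[v]]
      m
    })
  )
  yaml::write_yaml(meta, paste0(path, ".yml"))
  if (write_truth && !is.null(table$truth)) {
    truth_path <- sub("\\.csv$", "_truth.csv", path)
    utils::write.csv(table$truth, truth_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a study table written by [write_study_table()]
#'
#' @param path CSV path; `<path>.yml` must exist.
#' @param truth_path Optional path to a ground-truth CSV.
#' @return A `study_table`.
#' @export
read_study_table <- function(path, truth_path = NULL) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  roles <- vapply(meta$variables, `[[`, "", "role")
  scales <- vapply(meta$variables, `[[`, "", "scale")
  vars <- vapply(meta$variables, `[[`, "", "name")
  names(roles) <- names(scales) <- vars
  lv <- lapply(meta$variables, function(m) if (is.null(m$levels)) NULL else as.character(m$levels))
  names(lv) <- vars
  lv <- Filter(Negate(is.null), lv)
  col_classes <- ifelse(scales == "categorical", "character", "numeric")
  data <- utils::read.csv(path, na.strings = "", colClasses = unname(col_classes))
  truth <- if (!is.null(truth_path))
    utils::read.csv(truth_path, na.strings = "", colClasses = unname(col_classes))
  study_table(data, roles, scales, levels = if (length(lv)) lv else NULL,
              truth = truth)
}
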