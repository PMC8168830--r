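#' Simulation configuration for a synthetic cohort
#'
#' Describes a complete-data generating model for an observational cohort
#' with one continuous bounded outcome (a 0-100 attainment-style score), one
#' binary exposure, a set of confounders and a set of auxiliary variables.
#' The exposure follows a logistic model on the confounders; the outcome is
#' linear in exposure and confounders with coefficient `beta_true` on the
#' exposure (the true adjusted mean difference) plus Gaussian noise, clamped
#' to [0, 100].
#'
#' @param n_participants Positive integer number of records.
#' @param beta_true True adjusted mean difference (outcome points per unit
#'   exposure).
#' @param confounder_spec List of confounder descriptions, each a list with
#'   `name`, `scale` ("binary" or "continuous"), distribution parameters
#'   (`prevalence` for binary; `mean`, `sd` for continuous), `coef_exposure`
#'   (log-odds contribution to the exposure model) and `coef_outcome`
#'   (outcome-points contribution).
#' @param auxiliary_spec List of auxiliary descriptions, each a list with
#'   `name`, `scale`, and either (`linked_to = "exposure"`, `sensitivity`,
#'   `specificity`) for a binary proxy of the exposure, or
#'   (`linked_to = "outcome"`, `correlation`, `mean`, `sd`) for a continuous
#'   correlate of the outcome.
#' @param exposure_prevalence Target marginal exposure prevalence; the
#'   exposure-model intercept is solved numerically to hit it.
#' @param outcome_intercept Outcome model intercept (score points).
#' @param outcome_noise_sd Positive residual SD of the outcome (score points).
#' @param confounder_correlation Exchangeable latent correlation between
#'   confounders (Gaussian copula).
#' @param outcome_name,exposure_name Variable names.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants,
                              beta_true,
                              confounder_spec = list(),
                              auxiliary_spec = list(),
                              exposure_prevalence = 0.2,
                              outcome_intercept = 58,
                              outcome_noise_sd = 12,
                              confounder_correlation = 0.3,
                              outcome_name = "outcome",
                              exposure_name = "exposure",
                              seed = 1L) {
  stopifnot(n_participants >= 1, outcome_noise_sd > 0,
            exposure_prevalence > 0, exposure_prevalence < 1,
            confounder_correlation >= 0, confounder_correlation < 1)
  nm <- c(outcome_name, exposure_name,
          vapply(confounder_spec, `[[`, "", "name"),
          vapply(auxiliary_spec, `[[`, "", "name"))
  if (anyDuplicated(nm)) stop("variable names must be unique")
  for (cs in confounder_spec) {
    if (identical(cs$scale, "binary")) {
      if (is.null(cs$prevalence) || cs$prevalence <= 0 || cs$prevalence >= 1)
        stop("invalid distribution parameters for confounder `", cs$name, "`")
    } else if (identical(cs$scale, "continuous")) {
      if (is.null(cs$sd) || cs$sd <= 0)
        stop("invalid distribution parameters for confounder `", cs$name, "`")
    } else stop("confounder `", cs$name, "` must be binary or continuous")
  }
  structure(
    list(n_participants = as.integer(n_participants), beta_true = beta_true,
         confounder_spec = confounder_spec, auxiliary_spec = auxiliary_spec,
         exposure_prevalence = exposure_prevalence,
         outcome_intercept = outcome_intercept,
         outcome_noise_sd = outcome_noise_sd,
         confounder_correlation = confounder_correlation,
         outcome_name = outcome_name, exposure_name = exposure_name,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Generate a complete synthetic cohort
#'
#' Returns a [study_table()] with no missing cells. Confounders are drawn
#' from a Gaussian copula with exchangeable correlation; the exposure from a
#' logistic model on the confounders with the intercept solved so the
#' realized-cohort mean probability equals `exposure_prevalence`; the
#' outcome as a clamped Gaussian linear model with coefficient `beta_true`
#' on the exposure; binary auxiliaries as sensitivity/specificity proxies of
#' the exposure and continuous auxiliaries as correlates of the outcome.
#'
#' @param config A `simulation_config`.
#' @return A complete `study_table`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_participants
  with_seed(substream_seed(config$seed, "generate_cohort"), {
    p <- length(config$confounder_spec)
    conf <- list()
    if (p > 0) {
      rho <- config$confounder_correlation
      # exchangeable latent MVN via a shared factor
      shared <- stats::rnorm(n)
      z <- vapply(seq_len(p), function(j)
        sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n),
        numeric(n))
      for (j in seq_len(p)) {
        cs <- config$confounder_spec[[j]]
        conf[[cs$name]] <- if (cs$scale == "binary") {
          as.numeric(z[, j] > stats::qnorm(1 - cs$prevalence))
        } else {
          (cs$mean %||% 0) + cs$sd * z[, j]
        }
      }
    }
    # exposure: logistic on confounders, intercept solved for target prevalence
    lp <- rep(0, n)
    for (cs in config$confounder_spec)
      lp <- lp + (cs$coef_exposure %||% 0) * conf[[cs$name]]
    alpha <- solve_logit_intercept(lp, config$exposure_prevalence)
    exposure <- stats::rbinom(n, 1, stats::plogis(alpha + lp))

    # outcome: linear in exposure and confounders, clamped to [0, 100]
    mu <- config$outcome_intercept + config$beta_true * exposure
    for (cs in config$confounder_spec)
      mu <- mu + (cs$coef_outcome %||% 0) * conf[[cs$name]]
    outcome <- pmin(100, pmax(0, mu + stats::rnorm(n, 0, config$outcome_noise_sd)))

    aux <- list()
    for (as_ in config$auxiliary_spec) {
      if (identical(as_$linked_to, "exposure")) {
        pr <- ifelse(exposure == 1, as_$sensitivity, 1 - as_$specificity)
        aux[[as_$name]] <- stats::rbinom(n, 1, pr)
      } else {
        r <- as_$correlation
        ystd <- (outcome - mean(outcome)) / stats::sd(outcome)
        aux[[as_$name]] <- (as_$mean %||% 0) +
          (as_$sd %||% 1) * (r * ystd + sqrt(1 - r^2) * stats::rnorm(n))
      }
    }

    data <- as.data.frame(c(
      stats::setNames(list(outcome, exposure),
                      c(config$outcome_name, config$exposure_name)),
      conf, aux))
    roles <- c(
      stats::setNames(c("outcome", "exposure"),
                      c(config$outcome_name, config$exposure_name)),
      stats::setNames(rep("confounder", length(conf)), names(conf)),
      stats::setNames(rep("auxiliary", length(aux)), names(aux)))
    scales <- c("continuous", "binary",
                vapply(config$confounder_spec, `[[`, "", "scale"),
                vapply(config$auxiliary_spec, `[[`, "", "scale"))
    names(scales) <- c(config$outcome_name, config$exposure_name,
                       names(conf), names(aux))
    study_table(data, roles, scales)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Solve the logistic-model intercept so mean(plogis(a + lp)) == target over
# the realized linear predictors.
solve_logit_intercept <- function(lp, target) {
  f <- function(a) mean(stats::plogis(a + lp)) - target
  stats::uniroot(f, c(-40, 40), tol = 1e-10)$root
}

#' Missingness mechanism for one target variable
#'
#' A logistic model for the probability that the target's value is missing:
#' `expit(intercept + sum(coefficients * predictors) + self_coefficient *
#' own value)`. With all predictor coefficients zero and
#' `self_coefficient = 0` the mechanism is MCAR by construction; a nonzero
#' `self_coefficient` (delta_true) makes it MNAR, since missingness then
#' depends on the unobserved value itself given everything observed.
#'
#' @param target Name of the variable whose cells may be deleted.
#' @param intercept Log-odds intercept (may be `-Inf` for never-missing).
#'   Ignored when `target_proportion` is given.
#' @param coefficients Named numeric vector of log-odds coefficients on
#'   other variables (may include the outcome).
#' @param self_coefficient Log-odds coefficient on the target's own value
#'   (the MNAR sensitivity-generating parameter, often written delta).
#' @param target_proportion Optional: solve the intercept numerically so the
#'   realized-cohort mean missingness probability equals this value.
#' @param monotone_dropout Whether missingness of this variable is nested
#'   within missingness of an earlier-wave variable (name or `NULL`).
#' @return An object of class `missingness_mechanism`.
#' @export
missingness_mechanism <- function(target, intercept = -Inf,
                                  coefficients = numeric(),
                                  self_coefficient = 0,
                                  target_proportion = NULL,
                                  monotone_dropout = NULL) {
  if (length(coefficients) && (!all(is.finite(coefficients)) || is.null(names(coefficients))))
    stop("mechanism coefficients must be finite and named")
  if (!is.finite(self_coefficient)) stop("self_coefficient must be finite")
  structure(
    list(target = target, intercept = intercept,
         coefficients = coefficients, self_coefficient = self_coefficient,
         target_proportion = target_proportion,
         monotone_dropout = monotone_dropout),
    class = "missingness_mechanism"
  )
}

#' Impose missingness on a complete study table
#'
#' Deletes each targeted cell independently with probability given by its
#' mechanism's logistic model evaluated on the complete (pre-deletion)
#' data. Realized values are retained in the table's `truth` slot under
#' provenance "simulated-then-deleted" so recovery error and
#' mechanism-direction properties can be computed downstream.
#'
#' @param table A complete `study_table`.
#' @param mechanisms A single `missingness_mechanism` or a list of them
#'   (one per target variable).
#' @param seed Integer seed; deletion is deterministic given it.
#' @return A `study_table` with missing cells and `truth` set.
#' @export
impose_missingness <- function(table, mechanisms, seed) {
  stopifnot(inherits(table, "study_table"))
  if (inherits(mechanisms, "missingness_mechanism")) mechanisms <- list(mechanisms)
  if (anyNA(table$data)) stop("table must be complete before imposing missingness")
  data <- table$data
  truth <- table$data
  n <- nrow(data)
  for (mech in mechanisms) {
    if (!mech$target %in% names(data))
      stop("mechanism targets unknown variable `", mech$target, "`")
    unknown <- setdiff(names(mech$coefficients), names(data))
    if (length(unknown))
      stop("mechanism for `", mech$target, "` references unknown variable(s): ",
           paste(unknown, collapse = ", "))
    lp <- rep(0, n)
    for (v in names(mech$coefficients))
      lp <- lp + mech$coefficients[[v]] * as.numeric(truth[[v]])
    lp <- lp + mech$self_coefficient * as.numeric(truth[[mech$target]])
    # monotone nesting: cells of an already-missing earlier variable are
    # deleted with probability one, so their missingness never depends on
    # any unobserved value
    forced <- if (!is.null(mech$monotone_dropout))
      is.na(data[[mech$monotone_dropout]]) else rep(FALSE, n)
    intercept <- if (!is.null(mech$target_proportion)) {
      f <- function(a) mean(ifelse(forced, 1, stats::plogis(a + lp))) -
        mech$target_proportion
      if (f(40) < 0)
        stop("target_proportion for `", mech$target,
             "` unattainable given forced dropout")
      stats::uniroot(f, c(-40, 40), tol = 1e-10)$root
    } else mech$intercept
    pr <- ifelse(forced, 1, stats::plogis(intercept + lp))
    del <- with_seed(substream_seed(seed, "impose_missingness", mech$target),
                     stats::runif(n) < pr)
    data[[mech$target]][del] <- NA
  }
  study_table(data, table$roles, table$scales, levels = table$levels,
              truth = truth)
}

#' Synthetic cohort emulating the smoking/attainment case study
#'
#' Generates a cohort whose structure mirrors a well-known birth-cohort
#' analysis of teenage smoking and educational attainment: a continuous
#' 0-100 attainment outcome at 16 years, a binary smoking exposure at 14
#' years with roughly 51\% missingness, eight confounders (four binary,
#' four continuous), and two strongly predictive earlier-wave smoking
#' auxiliaries that remain observed when the exposure is missing. Exposure
#' missingness depends on the outcome and on confounders (and, through
#' `delta_true`, optionally on smoking itself, making it MNAR); missingness
#' rates are calibrated by numerically solved intercepts so that about 23\%
#' of records are complete on the analysis-model variables.
#'
#' @param n Number of participants (at least 200).
#' @param seed Integer seed.
#' @param delta_true Log-odds coefficient of exposure missingness on the
#'   true exposure value itself; 0 gives a MAR mechanism.
#' @param beta_true True adjusted mean difference (default -10 score
#'   points, smokers vs nonsmokers).
#' @param exposure_prevalence Marginal smoking prevalence (default 0.2).
#' @return A list with elements `table` (the incomplete `study_table` with
#'   truth retained), `config` (the `simulation_config`) and `mechanisms`
#'   (the list of `missingness_mechanism` objects).
#' @export
alspac_like_preset <- function(n, seed = 1L, delta_true = 0,
                               beta_true = -10, exposure_prevalence = 0.2) {
  stopifnot(n >= 200)
  confounders <- list(
    list(name = "sex",        scale = "binary", prevalence = 0.49,
         coef_exposure = 0.20, coef_outcome = 1.5),
    list(name = "firstborn",  scale = "binary", prevalence = 0.45,
         coef_exposure = -0.10, coef_outcome = 1.0),
    list(name = "mat_smoke",  scale = "binary", prevalence = 0.25,
         coef_exposure = 0.60, coef_outcome = -2.0),
    list(name = "pat_smoke",  scale = "binary", prevalence = 0.30,
         coef_exposure = 0.50, coef_outcome = -1.5),
    list(name = "mat_educ",   scale = "continuous", mean = 0, sd = 1,
         coef_exposure = -0.30, coef_outcome = 3.0),
    list(name = "pat_educ",   scale = "continuous", mean = 0, sd = 1,
         coef_exposure = -0.20, coef_outcome = 2.5),
    list(name = "behav_diff", scale = "continuous", mean = 0, sd = 1,
         coef_exposure = 0.40, coef_outcome = -3.0),
    list(name = "attain_11",  scale = "continuous", mean = 0, sd = 1,
         coef_exposure = -0.40, coef_outcome = 8.0)
  )
  auxiliaries <- list(
    list(name = "smoke_13", scale = "binary", linked_to = "exposure",
         sensitivity = 0.80, specificity = 0.95),
    list(name = "smoke_10", scale = "binary", linked_to = "exposure",
         sensitivity = 0.50, specificity = 0.98)
  )
  config <- simulation_config(
    n_participants = n, beta_true = beta_true,
    confounder_spec = confounders, auxiliary_spec = auxiliaries,
    exposure_prevalence = exposure_prevalence,
    outcome_intercept = 58, outcome_noise_sd = 12,
    outcome_name = "attain_16", exposure_name = "smoke_14", seed = seed)
  complete <- generate_cohort(config)

  mechanisms <- list(
    # outcome: linkage missingness depending on confounders only
    missingness_mechanism(
      "attain_16",
      coefficients = c(mat_educ = -0.30, behav_diff = 0.30, firstborn = -0.20),
      target_proportion = 0.16),
    # exposure: attrition is monotone (participants missing the outcome
    # wave are missing smoking too), and the sporadic part depends on the
    # observed (low) attainment, behaviour and maternal education, plus
    # delta_true on smoking itself; this keeps the mechanism exactly MAR
    # at delta_true = 0 because no deletion probability ever depends on an
    # unobserved value
    missingness_mechanism(
      "smoke_14",
      coefficients = c(attain_16 = -0.05, behav_diff = 0.30, mat_educ = -0.20),
      self_coefficient = delta_true, target_proportion = 0.51,
      monotone_dropout = "attain_16"),
    missingness_mechanism("behav_diff", target_proportion = 0.21),
    missingness_mechanism(
      "attain_11", coefficients = c(mat_educ = -0.20),
      target_proportion = 0.21),
    missingness_mechanism("mat_smoke", target_proportion = 0.16),
    # paternal smoking shares the attrition wave and its sporadic part also
    # depends on the observed outcome, compounding the outcome-selection of
    # the complete-record set while staying MAR
    missingness_mechanism(
      "pat_smoke", coefficients = c(attain_16 = -0.05, pat_educ = -0.20),
      target_proportion = 0.22, monotone_dropout = "attain_16")
  )
  table <- impose_missingness(complete, mechanisms, seed = seed)
  list(table = table, config = config, mechanisms = mechanisms)
}
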