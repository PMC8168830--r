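#' Specification of a chained-equations multiple-imputation run
#'
#' Full description of a fully-conditional-specification (FCS) run: which
#' column model imputes each incomplete variable, the predictor set for
#' each, the number of imputations `m`, the number of FCS cycles, any
#' pattern-mixture offsets, the predictive-mean-matching donor count, and
#' the seed. The predictor matrix must keep the imputation model compatible
#' with the substantive model: every substantive-model variable appears as
#' a predictor of every imputed variable.
#'
#' @param table The `study_table` the run will be applied to.
#' @param m Number of imputations (>= 2; Rubin's between-imputation
#'   variance is undefined otherwise). Default 25.
#' @param cycles FCS iterations per imputation. Default 10.
#' @param column_models Named character vector mapping incomplete variables
#'   to one of `"bayes_linear"`, `"bayes_logistic"`, `"pmm"`,
#'   `"polytomous"`, `"fill"`. Defaults by scale: continuous ->
#'   bayes_linear, binary -> bayes_logistic, categorical -> polytomous.
#' @param predictor_matrix Named list mapping each imputed variable to its
#'   character vector of predictors. Default: all other variables.
#' @param offsets Named numeric: pattern-mixture sensitivity offset delta
#'   per variable (log-odds units for binary targets, outcome units for
#'   continuous targets). Applied only while imputing the flagged variable,
#'   never to observed cells. Default none.
#' @param pmm_donors Donor-pool size k for predictive mean matching.
#' @param fill_values Named list of deterministic fill values for variables
#'   with column model `"fill"` (worst-case imputation).
#' @param seed Integer seed; the run is a pure function of it.
#' @return An object of class `imputation_spec`.
#' @export
imputation_spec <- function(table, m = 25, cycles = 10,
                            column_models = NULL, predictor_matrix = NULL,
                            offsets = numeric(), pmm_donors = 5,
                            fill_values = list(), seed = 1L) {
  stopifnot(inherits(table, "study_table"))
  if (m < 2) stop("m must be at least 2 (between-imputation variance requires it)")
  stopifnot(cycles >= 1, pmm_donors >= 1)
  vars <- names(table$data)
  incomplete <- vars[colSums(is.na(table$data)) > 0]
  if (is.null(column_models)) {
    column_models <- vapply(incomplete, function(v)
      switch(table$scales[[v]],
             continuous = "bayes_linear",
             binary = "bayes_logistic",
             categorical = "polytomous"), "")
  }
  unknown <- setdiff(names(column_models), vars)
  if (length(unknown)) stop("column model for unknown variable: ",
                            paste(unknown, collapse = ", "))
  uncovered <- setdiff(incomplete, names(column_models))
  if (length(uncovered)) stop("incomplete variable(s) without a column model: ",
                              paste(uncovered, collapse = ", "))
  ok_models <- c("bayes_linear", "bayes_logistic", "pmm", "polytomous", "fill")
  if (!all(column_models %in% ok_models))
    stop("unknown column model: ",
         paste(setdiff(column_models, ok_models), collapse = ", "))
  if (is.null(predictor_matrix)) {
    predictor_matrix <- lapply(names(column_models), function(v) setdiff(vars, v))
    names(predictor_matrix) <- names(column_models)
  }
  subst <- analysis_variables(table)
  for (v in names(column_models)) {
    if (column_models[[v]] == "fill") next
    preds <- predictor_matrix[[v]]
    if (is.null(preds)) stop("no predictors declared for `", v, "`")
    if (v %in% preds) stop("self-prediction declared for `", v, "`")
    bad <- setdiff(preds, vars)
    if (length(bad)) stop("predictor(s) absent from the table for `", v, "`: ",
                          paste(bad, collapse = ", "))
    missing_subst <- setdiff(setdiff(subst, v), preds)
    if (length(missing_subst))
      stop("imputation model for `", v, "` is incompatible with the ",
           "substantive model; missing predictor(s): ",
           paste(missing_subst, collapse = ", "))
  }
  if (length(offsets)) {
    stopifnot(!is.null(names(offsets)), all(is.finite(offsets)))
    bad <- setdiff(names(offsets), vars)
    if (length(bad)) stop("offset for unknown variable: ", paste(bad, collapse = ", "))
  }
  structure(
    list(m = as.integer(m), cycles = as.integer(cycles),
         column_models = column_models, predictor_matrix = predictor_matrix,
         offsets = offsets, pmm_donors = as.integer(pmm_donors),
         fill_values = fill_values, seed = as.integer(seed)),
    class = "imputation_spec")
}

#' Initialize missing cells from the observed marginals
#'
#' Fills every missing cell with a uniform random draw from that variable's
#' observed values, the standard starting point for FCS cycling.
#'
#' @param table A `study_table` with at least one missing cell.
#' @param seed Integer seed.
#' @return The data frame of `table$data` with all `NA`s filled.
#' @export
initialize_fill <- function(table, seed) {
  stopifnot(inherits(table, "study_table"))
  data <- table$data
  if (!anyNA(data)) stop("table has no missing cells to initialize")
  for (v in names(data)) {
    mis <- is.na(data[[v]])
    if (!any(mis)) next
    obs <- data[[v]][!mis]
    if (!length(obs)) stop("variable `", v, "` has no observed values; unimputable")
    data[[v]][mis] <- with_seed(
      substream_seed(seed, "initialize", v),
      obs[sample.int(length(obs), sum(mis), replace = TRUE)])
  }
  data
}

# Design matrix (with intercept) over the given predictors; factors expand
# to dummies via model.matrix.
design_matrix <- function(data, predictors) {
  if (!length(predictors))
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  stats::model.matrix(~ ., data = data[predictors])
}

# Iteratively reweighted least squares for logistic regression on a design
# matrix, with optional ridge penalty (used as the separation fallback).
# Returns beta, the inverse observed information (vcov) and a convergence
# flag. No RNG is consumed.
fast_logistic <- function(X, y, ridge = 0, max_iter = 40, tol = 1e-6,
                          start = NULL) {
  p <- ncol(X)
  if (!is.null(start) && length(start) == p && all(is.finite(start))) {
    beta <- start
  } else {
    beta <- numeric(p)
    beta[1] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  }
  deviance <- function(b) {
    eta <- drop(X %*% b)
    pen <- if (ridge > 0) 0.5 * ridge * sum(b^2) else 0
    # numerically stable -2 loglik: log(1+exp(eta)) - y*eta
    2 * sum(ifelse(eta > 30, eta, log1p(exp(eta))) - y * eta) + pen
  }
  dev <- deviance(beta)
  ch <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    A <- crossprod(X * sqrt(w))
    if (ridge > 0) A <- A + diag(ridge, p)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
      ridge <- max(ridge * 10, 1e-4)
      next
    }
    score <- crossprod(X, y - mu) - if (ridge > 0) ridge * beta else 0
    step <- drop(backsolve(ch, forwardsolve(t(ch), score)))
    # step-halving keeps IRLS from overshooting on near-separated or
    # strongly predictive designs
    beta_new <- beta + step
    dev_new <- deviance(beta_new)
    halvings <- 0L
    while ((!is.finite(dev_new) || dev_new > dev + 1e-8) && halvings < 15L) {
      step <- step / 2
      beta_new <- beta + step
      dev_new <- deviance(beta_new)
      halvings <- halvings + 1L
    }
    if (!is.finite(dev_new) || dev_new > dev + 1e-8) break
    moved <- max(abs(step))
    beta <- beta_new
    dev <- dev_new
    if (moved < tol) {
      converged <- TRUE
      break
    }
  }
  if (is.null(ch)) ch <- diag(1e-3, p)
  # vcov = A^{-1} = (R'R)^{-1}; a N(0, vcov) draw is backsolve(R, z)
  list(beta = beta, chol_info = ch, converged = converged)
}

# Draw regression coefficients and residual variance from the standard
# conjugate posterior (non-informative prior) given observed rows.
# Rank-deficient designs fall back to a small ridge on the normal equations
# with a warning. Consumes exactly 1 chi-square + p normal draws.
draw_linear_posterior <- function(X, y, ridge = 1e-6) {
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in linear imputation inputs")
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2) stop("too few observed rows (", n, ") for ", p, " parameters")
  A <- crossprod(X)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    warning("rank-deficient design; applying ridge fallback",
            call. = FALSE)
    ch <- chol(A + diag(ridge * max(diag(A)), p))
  }
  beta_hat <- backsolve(ch, forwardsolve(t(ch), crossprod(X, y)))
  resid <- y - drop(X %*% beta_hat)
  df <- n - p
  ss <- sum(resid^2)
  sigma2 <- ss / stats::rchisq(1, df)
  beta <- drop(beta_hat) + sqrt(sigma2) * drop(backsolve(ch, stats::rnorm(p)))
  list(beta = beta, beta_hat = drop(beta_hat), sigma2 = sigma2)
}

#' Proper Bayesian linear imputation of a continuous variable
#'
#' Draws the residual variance from its scaled inverse-chi-square posterior
#' and the coefficients from their conditional normal posterior (so
#' parameter uncertainty is propagated), then imputes each missing row as
#' linear predictor + delta + Gaussian noise.
#'
#' @param y_obs Observed target values.
#' @param X_obs,X_mis Design matrices (with intercept) at observed and
#'   missing rows.
#' @param delta Pattern-mixture offset added to every imputed value
#'   (outcome units). Default 0.
#' @return Numeric vector of imputed values, one per row of `X_mis`.
#' @export
impute_bayes_linear <- function(y_obs, X_obs, X_mis, delta = 0) {
  post <- draw_linear_posterior(X_obs, y_obs)
  n_mis <- nrow(X_mis)
  drop(X_mis %*% post$beta) + delta +
    stats::rnorm(n_mis, 0, sqrt(post$sigma2))
}

#' Proper Bayesian logistic imputation of a binary variable
#'
#' Fits the logistic MLE on observed rows, draws a coefficient vector from
#' the asymptotic normal approximation to its posterior, and imputes each
#' missing row as Bernoulli(expit(linear predictor + delta)). The Bernoulli
#' draws use a shared uniform stream so the imputed values are monotone
#' non-decreasing in delta under common random numbers. Separation or
#' non-convergence triggers a ridge-penalized refit with a warning.
#'
#' @inheritParams impute_bayes_linear
#' @param y_obs Observed target values in {0, 1}; both classes must be
#'   present.
#' @param delta Pattern-mixture offset on the log-odds scale. Default 0.
#' @param start Optional starting coefficient vector for the IRLS fit (a
#'   warm start from a previous FCS cycle; affects only iteration count,
#'   never the fitted solution).
#' @return Numeric vector of imputed 0/1 values.
#' @export
impute_bayes_logistic <- function(y_obs, X_obs, X_mis, delta = 0, start = NULL) {
  if (length(unique(y_obs)) < 2)
    stop("degenerate target: only one class observed")
  if (!all(is.finite(X_obs)) || !all(is.finite(X_mis)))
    stop("non-finite values in logistic imputation inputs")
  fit <- fast_logistic(X_obs, y_obs, start = start)
  if (!fit$converged || max(abs(fit$beta)) > 15) {
    warning("possible separation in logistic imputation model; ",
            "ridge-penalized fallback used", call. = FALSE,
            immediate. = FALSE)
    fit <- fast_logistic(X_obs, y_obs, ridge = 1e-2 * nrow(X_obs) / 1000)
  }
  p <- length(fit$beta)
  beta <- fit$beta + drop(backsolve(fit$chol_info, stats::rnorm(p)))
  pr <- stats::plogis(drop(X_mis %*% beta) + delta)
  out <- as.numeric(stats::runif(nrow(X_mis)) < pr)
  attr(out, "beta_hat") <- fit$beta
  out
}

#' Predictive mean matching imputation
#'
#' Computes predicted means for observed and missing rows from a drawn
#' coefficient vector; for each missing row, selects the `k` observed rows
#' with nearest predicted mean (ties broken by lowest row index) and
#' imputes the observed value of one uniformly chosen donor. All imputed
#' values are therefore members of the observed donor pool.
#'
#' @inheritParams impute_bayes_linear
#' @param k Donor-pool size.
#' @return Numeric vector of imputed values drawn from the observed pool.
#' @export
impute_pmm <- function(y_obs, X_obs, X_mis, k = 5) {
  if (length(y_obs) < k) stop("donor count k exceeds observed rows")
  post <- draw_linear_posterior(X_obs, y_obs)
  yhat_obs <- drop(X_obs %*% post$beta)
  yhat_mis <- drop(X_mis %*% post$beta)
  n_mis <- length(yhat_mis)
  out <- numeric(n_mis)
  for (i in seq_len(n_mis)) {
    d <- abs(yhat_obs - yhat_mis[i])
    donors <- order(d)[seq_len(k)]  # order() is stable: ties by lowest index
    out[i] <- y_obs[donors[sample.int(k, 1)]]
  }
  out
}

# Categorical imputation via a sequence of one-vs-rest logistic draws
# normalized to a categorical draw. One uniform per missing row.
impute_polytomous <- function(y_obs, X_obs, X_mis) {
  lev <- levels(factor(y_obs))
  if (length(lev) < 2) stop("degenerate target: only one class observed")
  n_mis <- nrow(X_mis)
  pr <- matrix(0, n_mis, length(lev))
  for (j in seq_along(lev)) {
    yj <- as.numeric(factor(y_obs) == lev[j])
    fit <- fast_logistic(X_obs, yj)
    if (!fit$converged || max(abs(fit$beta)) > 15)
      fit <- fast_logistic(X_obs, yj, ridge = 1e-2 * nrow(X_obs) / 1000)
    p <- length(fit$beta)
    beta <- fit$beta + drop(backsolve(fit$chol_info, stats::rnorm(p)))
    pr[, j] <- stats::plogis(drop(X_mis %*% beta))
  }
  pr <- pr / rowSums(pr)
  u <- stats::runif(n_mis)
  cum <- t(apply(pr, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  factor(lev[idx], levels = lev)
}

#' Run chained-equations multiple imputation
#'
#' For each of `m` imputations independently: initialize missing cells from
#' the observed marginals, then for each of `cycles` iterations visit the
#' incomplete variables in a fixed order (ascending missingness count, so
#' the most-missing variable is visited last; ties by declaration order),
#' regressing each on its predictors' current completed values and
#' redrawing its missing cells with the declared column model. Observed
#' cells are never altered. Each imputation uses its own named RNG
#' substream of `spec$seed`, so the run is bit-reproducible and the random
#' numbers are common across runs that differ only in offsets.
#'
#' @param table A `study_table` with missing cells.
#' @param spec An `imputation_spec`.
#' @return An object of class `imputed_stack`: `imputations` (list of `m`
#'   completed data frames), `imputed_cells` (named list of row indices per
#'   variable), `spec`, `roles`, `scales`, and `n_separation_warnings`.
#' @export
run_chained <- function(table, spec) {
  stopifnot(inherits(table, "study_table"), inherits(spec, "imputation_spec"))
  data <- table$data
  mis_idx <- lapply(data, function(x) which(is.na(x)))
  incomplete <- names(mis_idx)[lengths(mis_idx) > 0]
  if (!length(incomplete)) stop("table has no missing cells")
  uncovered <- setdiff(incomplete, names(spec$column_models))
  if (length(uncovered)) stop("incomplete variable(s) without a column model: ",
                              paste(uncovered, collapse = ", "))
  # visit order: ascending missingness count (most-missing last), ties by
  # declaration order
  ord <- incomplete[order(lengths(mis_idx)[incomplete])]
  n_sep <- 0L
  # all-numeric tables take a matrix fast path; categorical variables fall
  # back to data-frame storage with model.matrix dummy expansion
  numeric_path <- all(vapply(data, is.numeric, TRUE))
  obs_rows <- lapply(mis_idx, function(idx) setdiff(seq_len(nrow(data)), idx))
  imputations <- vector("list", spec$m)
  for (j in seq_len(spec$m)) {
    imputations[[j]] <- with_seed(substream_seed(spec$seed, "chained", j), {
      warm <- list()  # IRLS warm starts per variable; no effect on draws
      completed <- if (numeric_path) as.matrix(data) else data
      for (v in incomplete) {
        model_v <- spec$column_models[[v]]
        if (model_v == "fill") {
          fv <- spec$fill_values[[v]]
          if (is.null(fv)) stop("no fill value declared for `", v, "`")
          completed[mis_idx[[v]], v] <- fv
        } else {
          obs <- data[[v]][obs_rows[[v]]]
          if (!length(obs)) stop("variable `", v, "` has no observed values; unimputable")
          completed[mis_idx[[v]], v] <-
            obs[sample.int(length(obs), length(mis_idx[[v]]), replace = TRUE)]
        }
      }
      for (cyc in seq_len(spec$cycles)) {
        for (v in ord) {
          model_v <- spec$column_models[[v]]
          if (model_v == "fill") next
          idx <- mis_idx[[v]]
          orow <- obs_rows[[v]]
          X <- if (numeric_path)
            cbind(`(Intercept)` = 1, completed[, spec$predictor_matrix[[v]], drop = FALSE])
          else design_matrix(completed, spec$predictor_matrix[[v]])
          y_obs <- data[[v]][orow]
          delta <- if (v %in% names(spec$offsets)) spec$offsets[[v]] else 0
          vals <- withCallingHandlers(
            tryCatch(
              switch(model_v,
                     bayes_linear = impute_bayes_linear(
                       y_obs, X[orow, , drop = FALSE], X[idx, , drop = FALSE], delta),
                     bayes_logistic = impute_bayes_logistic(
                       y_obs, X[orow, , drop = FALSE], X[idx, , drop = FALSE], delta,
                       start = warm[[v]]),
                     pmm = impute_pmm(
                       y_obs, X[orow, , drop = FALSE], X[idx, , drop = FALSE],
                       spec$pmm_donors),
                     polytomous = impute_polytomous(
                       y_obs, X[orow, , drop = FALSE], X[idx, , drop = FALSE])),
              error = function(e)
                stop("column model for `", v, "` failed in imputation ", j,
                     ", cycle ", cyc, ": ", conditionMessage(e), call. = FALSE)),
            warning = function(w) {
              n_sep <<- n_sep + 1L
              invokeRestart("muffleWarning")
            })
          if (!is.null(attr(vals, "beta_hat"))) {
            warm[[v]] <- attr(vals, "beta_hat")
            attributes(vals) <- NULL
          }
          completed[idx, v] <- vals
        }
      }
      if (numeric_path) as.data.frame(completed) else completed
    })
  }
  if (n_sep > 0)
    warning(n_sep, " column-model fit(s) required a penalized fallback ",
            "(possible separation)", call. = FALSE)
  structure(
    list(imputations = imputations,
         imputed_cells = mis_idx[incomplete],
         spec = spec, roles = table$roles, scales = table$scales),
    class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("<imputed_stack> m = ", length(x$imputations), " imputations of ",
      nrow(x$imputations[[1]]), " records; imputed variables: ",
      paste(names(x$imputed_cells), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write an imputed stack to CSV files plus a JSON manifest
#'
#' One CSV per imputation (`imp_<i>.csv`, numerics rendered at full
#' precision so the round trip is lossless) and `manifest.json` recording
#' the generating specification, the seed and the imputed-cell index.
#'
#' @param stack An `imputed_stack`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_imputed_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "imputed_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    for (v in names(df))
      if (is.numeric(df[[v]])) df[[v]] <- sprintf("%.17g", df[[v]])
    df
  }
  for (i in seq_along(stack$imputations))
    utils::write.csv(fmt(stack$imputations[[i]]),
                     file.path(dir, sprintf("imp_%d.csv", i)), row.names = FALSE)
  manifest <- list(
    m = stack$spec$m, cycles = stack$spec$cycles, seed = stack$spec$seed,
    column_models = as.list(stack$spec$column_models),
    predictor_matrix = stack$spec$predictor_matrix,
    offsets = as.list(stack$spec$offsets),
    pmm_donors = stack$spec$pmm_donors,
    roles = as.list(stack$roles), scales = as.list(stack$scales),
    imputed_cells = stack$imputed_cells)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}

#' Read an imputed stack written by [write_imputed_stack()]
#' @param dir Directory containing `imp_<i>.csv` and `manifest.json`.
#' @return An `imputed_stack`.
#' @export
read_imputed_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  m <- manifest$m
  imputations <- lapply(seq_len(m), function(i)
    utils::read.csv(file.path(dir, sprintf("imp_%d.csv", i))))
  imputed_cells <- lapply(manifest$imputed_cells, as.integer)
  structure(
    list(imputations = imputations, imputed_cells = imputed_cells,
         spec = manifest[c("m", "cycles", "seed", "column_models",
                           "predictor_matrix", "offsets", "pmm_donors")],
         roles = unlist(manifest$roles), scales = unlist(manifest$scales)),
    class = "imputed_stack")
}
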