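# Sliding-window Gaussian-kernel conditional trajectories over age and time
# since diagnosis, with age residualisation.

#' Least-squares residualisation
#'
#' Residuals of `y` on an intercept plus the given covariates; with no
#' covariates this is mean-centring. Rank-deficient designs are rejected with
#' the offending columns named.
#'
#' @param y Numeric outcome vector.
#' @param covariates Data.frame or matrix of covariates (may have zero
#'   columns), row-aligned with `y`.
#' @return Residual vector (mean ~ 0).
#' @export
residualize <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cv <- as.data.frame(covariates)
    X <- stats::model.matrix(~ ., data = cv)
  }
  if (nrow(X) != n) stop_npdim("covariates must be row-aligned with y")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_npdim("rank-deficient design; aliased columns: ",
               paste(aliased, collapse = ", "))
  }
  as.numeric(qr.resid(qr_x, y))
}

#' Time since diagnosis
#'
#' Questionnaire age minus the earliest available diagnosis age across
#' record sources (self-report, hospital, primary care). Positive values are
#' post-diagnosis, negative values prodromal; participants with no recorded
#' diagnosis get `NA`.
#'
#' @param age_at_questionnaire Numeric vector of ages (years) at
#'   questionnaire completion.
#' @param diagnosis_ages Numeric vector, matrix or data.frame of per-source
#'   diagnosis ages (years), `NA` where a source has no record.
#' @return Numeric vector of years since diagnosis.
#' @export
time_since_diagnosis <- function(age_at_questionnaire, diagnosis_ages) {
  dx <- as.matrix(diagnosis_ages)
  if (nrow(dx) != length(age_at_questionnaire)) {
    stop_npdim("diagnosis_ages must be row-aligned with age_at_questionnaire")
  }
  if (any(age_at_questionnaire < 0, na.rm = TRUE) || any(dx < 0, na.rm = TRUE)) {
    stop_npdim("negative ages are not allowed")
  }
  earliest <- suppressWarnings(apply(dx, 1, min, na.rm = TRUE))
  earliest[!is.finite(earliest)] <- NA_real_
  age_at_questionnaire - earliest
}

#' Trajectory estimation configuration
#'
#' @param kernel_fraction Gaussian kernel SD as a fraction of the quantile
#'   range (default 0.20).
#' @param grid_size Number of evaluation quantiles (default 100).
#' @param ci_method `"weighted_se"` (normal-theory band from the
#'   kernel-weighted SE with effective sample size) or `"bootstrap"`.
#' @param bootstrap_reps Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return List of class `trajectory_config`.
#' @export
trajectory_config <- function(kernel_fraction = 0.20, grid_size = 100,
                              ci_method = c("weighted_se", "bootstrap"),
                              bootstrap_reps = 500, seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (kernel_fraction <= 0 || kernel_fraction > 1) {
    stop_npdim("kernel_fraction must lie in (0, 1]")
  }
  if (grid_size < 2) stop_npdim("grid_size must be >= 2")
  structure(list(kernel_fraction = kernel_fraction, grid_size = grid_size,
                 ci_method = ci_method, bootstrap_reps = bootstrap_reps,
                 seed = as.integer(seed)),
            class = "trajectory_config")
}

#' Sliding-window Gaussian-kernel conditional mean
#'
#' Ranks the observations in `x`, places a grid of evaluation quantiles along
#' the rank range, and at each grid point computes the Gaussian-kernel
#' weighted mean of `y` with weights
#' `w_i = exp(-(u_i - p_j)^2 / (2 sigma^2))`, `u_i = rank_i / n`, `sigma`
#' equal to `kernel_fraction` of the quantile range. Because the kernel acts
#' in quantile space, the curve is invariant to any rank-preserving
#' transformation of `x`. The reported `x_grid` is the weighted mean of the
#' raw `x` at each point so curves plot in natural units. The 95% band uses
#' the weighted SE with effective sample size `(sum w)^2 / sum w^2`, or a
#' seeded bootstrap.
#'
#' @param x Numeric conditioning variable (age, time since diagnosis).
#' @param y Numeric outcome.
#' @param config A [trajectory_config()].
#' @return Object of class `conditional_curve`: data.frame with `quantile`,
#'   `x`, `mean`, `ci_low`, `ci_high`, `se`, `n_eff`; the configuration in
#'   `attr(, "config")`.
#' @export
conditional_curve <- function(x, y, config = trajectory_config()) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 10) stop_npdim("need at least 10 finite (x, y) pairs, got ", n)
  u <- rank(x, ties.method = "average") / n
  p_grid <- seq(min(u), max(u), length.out = config$grid_size)
  sigma <- config$kernel_fraction
  est <- lapply(p_grid, function(p) {
    w <- exp(-(u - p)^2 / (2 * sigma^2))
    st <- weighted_mean_se(y, w)
    st$x <- sum(w * x) / sum(w)
    st
  })
  mean_j <- vapply(est, `[[`, 0, "mean")
  se_j <- vapply(est, `[[`, 0, "se")
  n_eff <- vapply(est, `[[`, 0, "n_eff")
  x_j <- vapply(est, `[[`, 0, "x")
  if (config$ci_method == "bootstrap") {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(config$seed)
    boot <- matrix(NA_real_, config$bootstrap_reps, length(p_grid))
    for (b in seq_len(config$bootstrap_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      ub <- rank(x[idx], ties.method = "average") / n
      yb <- y[idx]
      boot[b, ] <- vapply(p_grid, function(p) {
        w <- exp(-(ub - p)^2 / (2 * sigma^2))
        sum(w * yb) / sum(w)
      }, 0)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    ci_low <- apply(boot, 2, stats::quantile, 0.025)
    ci_high <- apply(boot, 2, stats::quantile, 0.975)
  } else {
    ci_low <- mean_j - 1.96 * se_j
    ci_high <- mean_j + 1.96 * se_j
  }
  out <- data.frame(quantile = p_grid, x = x_j, mean = mean_j,
                    ci_low = pmin(ci_low, mean_j),
                    ci_high = pmax(ci_high, mean_j),
                    se = se_j, n_eff = n_eff)
  structure(out, class = c("conditional_curve", "data.frame"),
            config = config, n = n)
}

#' Per-group conditional trajectory report
#'
#' For each factor and group: residualises the factor scores on age (and any
#' further covariates), then emits conditional curves against age (all
#' groups) and against time since diagnosis (diagnosed groups), plus group
#' means with 95% confidence intervals. Groups with fewer than 10 usable
#' observations are skipped with a warning.
#'
#' @param scores Data.frame of factor scores (numeric columns = factors).
#' @param covariates Row-aligned data.frame with `group`, `age` and
#'   optionally `age_at_diagnosis`.
#' @param config A [trajectory_config()].
#' @param adjust Character vector of covariate columns to residualise on
#'   (default `"age"`).
#' @param reference Group whose regression of score on the adjustment
#'   covariates anchors the residualisation, so that group traces the zero
#'   reference line and other groups' curves read as deviations from it.
#'   Defaults to `"HC"` when present, otherwise the pooled sample is used.
#' @return List with `curves_age` and `curves_tsd` (nested
#'   `factor -> group -> conditional_curve`) and `group_means` (data.frame
#'   factor, group, mean, ci_low, ci_high, n).
#' @export
group_trajectory_report <- function(scores, covariates,
                                    config = trajectory_config(),
                                    adjust = "age",
                                    reference = NULL) {
  fac_cols <- names(scores)[vapply(scores, is.numeric, TRUE)]
  fac_cols <- setdiff(fac_cols, "participant_id")
  if (nrow(scores) != nrow(covariates)) {
    stop_npdim("scores and covariates must be row-aligned")
  }
  groups <- unique(covariates$group)
  reference <- reference %||% if ("HC" %in% groups) "HC" else NA
  tsd <- if ("age_at_diagnosis" %in% names(covariates)) {
    covariates$age - covariates$age_at_diagnosis
  } else rep(NA_real_, nrow(covariates))
  curves_age <- list(); curves_tsd <- list(); gm <- list()
  for (f in fac_cols) {
    X <- stats::model.matrix(~ ., data = covariates[, adjust, drop = FALSE])
    if (!is.na(reference) && reference %in% groups) {
      ref_i <- covariates$group == reference
      beta <- qr.coef(qr(X[ref_i, , drop = FALSE]), scores[[f]][ref_i])
      if (anyNA(beta)) stop_npdim("rank-deficient adjustment design in reference group")
      y_res <- scores[[f]] - as.numeric(X %*% beta)
    } else {
      y_res <- residualize(scores[[f]], covariates[, adjust, drop = FALSE])
    }
    curves_age[[f]] <- list(); curves_tsd[[f]] <- list()
    for (g in groups) {
      i <- covariates$group == g
      if (sum(i) < 10) {
        warning("group ", g, " has fewer than 10 rows; skipped")
        next
      }
      curves_age[[f]][[g]] <- conditional_curve(covariates$age[i], y_res[i],
                                                config)
      if (any(is.finite(tsd[i]))) {
        if (sum(is.finite(tsd[i])) >= 10) {
          curves_tsd[[f]][[g]] <- conditional_curve(tsd[i], y_res[i], config)
        }
      }
      m <- mean(y_res[i]); se <- stats::sd(y_res[i]) / sqrt(sum(i))
      gm[[length(gm) + 1]] <- data.frame(factor = f, group = g, mean = m,
                                         ci_low = m - 1.96 * se,
                                         ci_high = m + 1.96 * se,
                                         n = sum(i))
    }
  }
  list(curves_age = curves_age, curves_tsd = curves_tsd,
       group_means = do.call(rbind, gm))
}
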