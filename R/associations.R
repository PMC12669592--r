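# Covariate-adjusted association surface: partial correlations with
# Bonferroni control, group/genotype linear contrasts, the executive-function
# composite and longitudinal visit-change models.

#' Partial correlation
#'
#' Residualises `x` and `y` on the covariates and correlates the residuals;
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - n_covariates - 2`. With an
#' empty covariate set this equals the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional row-aligned data.frame/matrix.
#' @return List with `r`, `t`, `df`, `p_value`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & stats::complete.cases(covariates)
    covariates <- covariates[keep, , drop = FALSE]
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= n_cov + 2) stop_npdim("need n > n_covariates + 2")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    stop_npdim("residual variance is ~0 after adjustment (collinearity)")
  }
  r <- stats::cor(rx, ry)
  df <- n - n_cov - 2
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, t = tt, df = df,
       p_value = 2 * stats::pt(-abs(tt), df), n = n)
}

#' Bonferroni adjustment
#'
#' `min(p * m, 1)` elementwise. A family size smaller than the number of
#' tests triggers a warning (misspecified family), not an error.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param m Family size (defaults to `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_npdim("p-values must lie in [0, 1]")
  if (m < 1) stop_npdim("m must be >= 1")
  if (m < length(p)) {
    warning("family size m = ", m, " is smaller than the number of tests (",
            length(p), ")")
  }
  pmin(p * m, 1)
}

#' Covariate-adjusted linear contrasts
#'
#' Least-squares fit of an outcome on group (reference-coded), covariates
#' and optionally a genotype carrier flag and its age interaction. Age is
#' mean-centred within the fitted sample before interaction terms are
#' formed, so main and interaction effects stay decorrelated. Group
#' contrasts read as reference-versus-group.
#'
#' @param data Data.frame holding all columns.
#' @param outcome Name of the outcome column.
#' @param group Optional name of the group column; its reference level is
#'   `reference`.
#' @param covariates Character vector of adjustment columns (default
#'   `c("age", "gender", "education")`).
#' @param genotype Optional name of a 0/1 carrier column.
#' @param genotype_age_interaction Include `genotype x centred age`.
#' @param reference Reference group level (default `"HC"`).
#' @return Object of class `association_table`: one row per model term with
#'   `term`, `beta`, `se`, `t`, `df`, `p_raw`; the fitted `lm` in
#'   `attr(, "fit")`.
#' @export
linear_contrasts <- function(data, outcome, group = NULL,
                             covariates = c("age", "gender", "education"),
                             genotype = NULL,
                             genotype_age_interaction = FALSE,
                             reference = "HC") {
  cols <- c(outcome, group, covariates, genotype)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop_npdim("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  if ("age" %in% names(d)) d$age <- d$age - mean(d$age)
  terms <- covariates
  if (!is.null(group)) {
    d[[group]] <- stats::relevel(factor(d[[group]]), ref = reference)
    terms <- c(group, terms)
  }
  if (!is.null(genotype)) {
    terms <- c(terms, genotype)
    if (genotype_age_interaction) {
      if (!"age" %in% names(d)) stop_npdim("age column required for the interaction")
      terms <- c(terms, paste0(genotype, ":age"))
    }
  }
  fml <- stats::reformulate(terms, response = outcome)
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop_npdim("rank-deficient design; aliased terms: ",
               paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                     collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
                    t = sm[, 3], df = fit$df.residual, p_raw = sm[, 4],
                    row.names = NULL)
  if (!is.null(genotype) && genotype_age_interaction) {
    # lm labels the interaction by variable order; expose it genotype-first
    out$term <- sub(paste0("^age:", genotype, "$"),
                    paste0(genotype, ":age"), out$term)
  }
  structure(out, class = c("association_table", "data.frame"), fit = fit)
}

#' Executive-function composite from four tasks
#'
#' One-factor extraction over z-scored task measures, with time-based tasks
#' (where larger values mean slower, worse performance) sign-reversed first
#' so higher composite = better executive function. Scores are
#' regression-method projections standardised to unit variance in the
#' fitting sample.
#'
#' @param task_table Data.frame/matrix of four task columns, complete cases
#'   only.
#' @param time_based Character vector naming the columns to sign-reverse.
#' @return Object of class `executive_composite`: `scores` (unit variance),
#'   `loadings`, `weights`; near-zero loadings trigger a warning.
#' @export
executive_composite <- function(task_table,
                                time_based = c("exec_rt", "exec_trails")) {
  m <- as.matrix(task_table)
  if (ncol(m) != 4) stop_npdim("expected exactly four task columns")
  if (anyNA(m)) stop_npdim("task table must be complete cases")
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    stop_npdim("zero-variance tasks: ", paste(colnames(m)[v == 0], collapse = ", "))
  }
  z <- scale(m)
  flip <- ifelse(colnames(m) %in% time_based, -1, 1)
  z <- sweep(z, 2, flip, "*")
  R <- correlation_matrix(z)
  ex <- extract_efa(R, 1)
  L <- ex$loadings[, 1]
  # orient so the composite runs with (reoriented) performance
  if (sum(L) < 0) L <- -L
  mean_r <- mean(abs(R[upper.tri(R)]))
  if (mean_r < 0.1) {
    warning("mean absolute inter-task correlation ",
            signif(mean_r, 2), "; tasks share little common variance")
  }
  # pseudo-inverse tolerates perfectly correlated tasks (rank-1 battery)
  w <- tryCatch(solve(R, L), error = function(e) {
    sv <- svd(R)
    pos <- sv$d > 1e-8 * sv$d[1]
    as.numeric(sv$v[, pos, drop = FALSE] %*%
                 ((t(sv$u[, pos, drop = FALSE]) %*% L) / sv$d[pos]))
  })
  s <- as.numeric(z %*% w)
  s <- s / stats::sd(s)
  structure(list(scores = s, loadings = stats::setNames(L, colnames(m)),
                 weights = stats::setNames(w, colnames(m)),
                 sign_reversed = colnames(m)[flip < 0]),
            class = "executive_composite")
}

#' Factor-by-phenotype partial-correlation grid
#'
#' One covariate-adjusted partial correlation per factor x imaging-phenotype
#' cell, Bonferroni-corrected over the whole evaluated grid (the family size
#' `m` is the number of cells actually computed, never hard-coded).
#'
#' @param scores Data.frame of factor scores (numeric columns).
#' @param imaging Row-aligned data.frame of imaging phenotypes (numeric
#'   columns; `participant_id` ignored).
#' @param covariates Row-aligned adjustment data.frame (e.g. age, gender,
#'   education, assessment centre, MRI-questionnaire interval).
#' @param alpha Significance level on the adjusted scale (default 0.05).
#' @return Object of class `association_table` with one row per cell:
#'   `factor`, `phenotype`, `r`, `t`, `df`, `p_raw`, `p_adjusted`,
#'   `significant`, plus the family size in `attr(, "m")`.
#' @export
imaging_association_grid <- function(scores, imaging, covariates,
                                     alpha = 0.05) {
  fac_cols <- names(scores)[vapply(scores, is.numeric, TRUE)]
  img_cols <- setdiff(names(imaging)[vapply(imaging, is.numeric, TRUE)],
                      "participant_id")
  rows <- list()
  skipped <- character(0)
  for (f in fac_cols) {
    for (ph in img_cols) {
      res <- tryCatch(
        partial_correlation(scores[[f]], imaging[[ph]], covariates),
        error = function(e) NULL)
      if (is.null(res)) {
        skipped <- c(skipped, paste(f, ph, sep = " x "))
        next
      }
      rows[[length(rows) + 1]] <-
        data.frame(factor = f, phenotype = ph, r = res$r, t = res$t,
                   df = res$df, p_raw = res$p_value)
    }
  }
  tab <- do.call(rbind, rows)
  m <- nrow(tab)
  tab$p_adjusted <- bonferroni(tab$p_raw, m)
  tab$significant <- tab$p_adjusted < alpha
  if (length(skipped)) {
    message("skipped cells (collinear or missing): ",
            paste(skipped, collapse = "; "))
  }
  structure(tab, class = c("association_table", "data.frame"),
            m = m, skipped = skipped)
}

#' Longitudinal visit-change model
#'
#' Regresses the change in an outcome between two visits on group, an
#' above/below-median indicator of a chosen factor (median computed within
#' the analysed sample and logged), and covariates. Rows without both visits
#' are dropped with a count.
#'
#' @param data Data.frame with the two visit columns, `group`, the factor
#'   score column and covariates.
#' @param outcome_v1,outcome_v3 Column names of the visit-1 and visit-3
#'   measurements.
#' @param factor_col Factor-score column used for the median split.
#' @param covariates Adjustment columns (default `c("age", "gender")`).
#' @param reference Reference group level.
#' @return An `association_table` (terms of the change-score model) with
#'   `attr(, "median_cut")` and `attr(, "n_dropped")`.
#' @export
visit_change_model <- function(data, outcome_v1, outcome_v3, factor_col,
                               covariates = c("age", "gender"),
                               reference = "HC") {
  need <- c(outcome_v1, outcome_v3, "group", factor_col, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop_npdim("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  cc <- stats::complete.cases(data[, need, drop = FALSE])
  n_dropped <- sum(!cc)
  d <- data[cc, , drop = FALSE]
  d$change <- d[[outcome_v3]] - d[[outcome_v1]]
  cut <- stats::median(d[[factor_col]])
  d$above_median <- as.integer(d[[factor_col]] > cut)
  tab <- linear_contrasts(d, "change", group = "group",
                          covariates = c("above_median", covariates),
                          reference = reference)
  attr(tab, "median_cut") <- cut
  attr(tab, "n_dropped") <- n_dropped
  tab
}
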