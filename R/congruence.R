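# Cross-group factor comparability: orthogonal Procrustes alignment, Tucker
# congruence, regression-method factor-score coefficients and projection.

#' Orthogonal Procrustes alignment of loading matrices
#'
#' Finds the orthogonal transformation `T` minimising
#' `|| source %*% T - target ||_F` via the singular value decomposition of
#' `t(source) %*% target`, and returns the aligned comparison loadings.
#' Unscaled and untranslated: only a rotation/reflection is applied.
#'
#' @param source Loading matrix to align (items x k).
#' @param target Reference loading matrix (same items, same k).
#' @return List with `Tmat` (orthogonal k x k) and `aligned`
#'   (`source %*% Tmat`).
#' @export
procrustes_align <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!all(dim(source) == dim(target))) {
    stop_npdim("source and target must share dimensions (same items, same k)")
  }
  sv <- svd(crossprod(source, target))
  Tmat <- sv$u %*% t(sv$v)
  aligned <- source %*% Tmat
  dimnames(aligned) <- dimnames(target)
  list(Tmat = Tmat, aligned = aligned)
}

#' Tucker congruence coefficients
#'
#' Cosine-type similarity between loading columns:
#' `phi(a, b) = sum(a*b) / sqrt(sum(a^2) * sum(b^2))`. Entry `(j, l)` of the
#' result is the congruence of column `j` of `A` with column `l` of `B`;
#' absolute values above 0.90 conventionally indicate equivalent factors.
#'
#' @param A,B Loading matrices with the same number of rows.
#' @return k_A x k_B congruence matrix.
#' @export
tucker_congruence <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop_npdim("A and B must have the same row count")
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  if (any(na == 0) || any(nb == 0)) stop_npdim("zero-norm loading column")
  phi <- crossprod(A, B) / outer(na, nb)
  dimnames(phi) <- list(colnames(A), colnames(B))
  phi
}

#' Cross-group congruence map
#'
#' Procrustes-aligns the comparison group's loadings to the reference and
#' computes the Tucker congruence matrix of the aligned solution, the
#' per-factor absolute diagonal, and the sign flips needed for interpretive
#' consistency (columns whose aligned diagonal congruence is negative).
#'
#' @param reference Reference-group pattern loadings.
#' @param comparison Comparison-group pattern loadings (same items, same k).
#' @return Object of class `congruence_map`: `rotation`, `aligned`,
#'   `congruence` (k x k), `diagonal_abs`, `sign_flips` (+-1 per factor).
#' @export
congruence_map <- function(reference, comparison) {
  pa <- procrustes_align(comparison, reference)
  phi <- tucker_congruence(pa$aligned, reference)
  d <- diag(phi)
  flips <- ifelse(d < 0, -1, 1)
  structure(list(rotation = pa$Tmat, aligned = pa$aligned,
                 congruence = phi, diagonal_abs = abs(d),
                 sign_flips = flips),
            class = "congruence_map")
}

#' @export
print.congruence_map <- function(x, ...) {
  cat("<congruence_map> |diagonal| congruence:",
      paste(sprintf("%.3f", x$diagonal_abs), collapse = ", "), "\n")
  if (any(x$sign_flips < 0)) {
    cat("  sign flips on factor(s):",
        paste(which(x$sign_flips < 0), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sign flips from a congruence map
#'
#' Returns the per-factor sign vector flipping any factor whose diagonal
#' Tucker coefficient with the reference is negative (e.g. a stress-adversity
#' factor estimated with inverted polarity in a clinical group).
#'
#' @param cmap A [congruence_map()].
#' @return Numeric vector of +-1, one per factor.
#' @export
align_signs <- function(cmap) {
  stopifnot(inherits(cmap, "congruence_map"))
  cmap$sign_flips
}

#' Regression-method factor score coefficients
#'
#' `W = R^-1 Lambda`: the inverse of the reference group's item correlation
#' matrix applied to its loadings. For an oblique solution, supplying the
#' factor correlation matrix `phi` projects through the structure matrix
#' `Lambda %*% phi` (item-factor correlations), which is the regression
#' method proper and maximises score validity; without `phi` the pattern
#' loadings are used as-is.
#'
#' @param R_ref Reference-group item correlation matrix.
#' @param loadings_ref Reference-group pattern loadings.
#' @param phi Optional factor correlation matrix of the rotated solution.
#' @param max_condition Reject `R_ref` whose condition number exceeds this.
#' @return p x k coefficient matrix `W`.
#' @export
score_coefficients <- function(R_ref, loadings_ref, phi = NULL,
                               max_condition = 1e10) {
  kap <- kappa(R_ref, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    stop_npdim("reference correlation matrix is near-singular ",
               "(condition number ", format(kap, digits = 3), ")")
  }
  L <- as.matrix(loadings_ref)
  S <- if (is.null(phi)) L else L %*% phi
  W <- solve(R_ref, S)
  dimnames(W) <- dimnames(L)
  W
}

#' Project standardised items to factor scores
#'
#' `scores = Z %*% W`, followed by the interpretive sign flips (if any).
#' Standardising the projected group against the reference group's item
#' means/SDs preserves cross-group mean differences in the scores; see
#' [factor_scores()] for the full convenience chain.
#'
#' @param z Standardised item matrix, columns aligned with the rows of `W`.
#' @param W Score coefficient matrix from [score_coefficients()].
#' @param sign_flips Optional +-1 vector per factor (default: none).
#' @param participant_id Optional identifier vector.
#' @return Object of class `factor_scores`: data.frame `scores`, plus
#'   `coefficients_used` and `sign_flips` attributes.
#' @export
project_scores <- function(z, W, sign_flips = NULL, participant_id = NULL) {
  z <- as.matrix(z)
  if (ncol(z) != nrow(W)) {
    stop_npdim("z has ", ncol(z), " columns but W has ", nrow(W), " rows")
  }
  if (!is.null(colnames(z)) && !is.null(rownames(W)) &&
      !identical(colnames(z), rownames(W))) {
    stop_npdim("z columns and W rows are not aligned")
  }
  sign_flips <- sign_flips %||% rep(1, ncol(W))
  s <- z %*% W
  s <- sweep(s, 2, sign_flips, "*")
  out <- as.data.frame(s)
  if (!is.null(participant_id)) {
    out <- data.frame(participant_id = participant_id, out,
                      check.names = FALSE)
  }
  structure(out, class = c("factor_scores", "data.frame"),
            coefficients_used = W, sign_flips = sign_flips)
}

#' Reference-anchored factor scores for every group
#'
#' The full cross-group scoring chain: fit the reference group's EFA,
#' compute regression-method coefficients from its correlation matrix and
#' loadings, then for each group standardise its items (against the
#' reference statistics by default) and project. Comparison groups also
#' receive a [congruence_map()] against the reference and the implied sign
#' flips.
#'
#' @param prep_by_group Named list of [prepare_items()] results (must include
#'   `reference`).
#' @param efa_by_group Named list of [run_efa()] fits aligned with
#'   `prep_by_group`.
#' @param reference Name of the reference group (default `"HC"`).
#' @param standardisation `"reference"` (default; reference means/SDs applied
#'   to every group) or `"own"` (each group z-scored against itself).
#' @return List per group with `scores` ([project_scores()] result),
#'   `congruence` (`NULL` for the reference) and metadata echoing the
#'   standardisation mode.
#' @export
factor_scores <- function(prep_by_group, efa_by_group, reference = "HC",
                          standardisation = c("reference", "own")) {
  standardisation <- match.arg(standardisation)
  if (!reference %in% names(prep_by_group)) {
    stop_npdim("reference group '", reference, "' not in prep_by_group")
  }
  ref_efa <- efa_by_group[[reference]]
  ref_prep <- prep_by_group[[reference]]
  W <- score_coefficients(ref_efa$R, ref_efa$loadings, phi = ref_efa$phi)
  out <- list()
  for (g in names(prep_by_group)) {
    prep <- prep_by_group[[g]]
    vars <- rownames(W)
    if (!all(vars %in% colnames(prep$z))) {
      stop_npdim("group '", g, "' lacks reference items: ",
                 paste(setdiff(vars, colnames(prep$z)), collapse = ", "))
    }
    cm <- NULL
    flips <- rep(1, ncol(W))
    if (g != reference) {
      efa_g <- efa_by_group[[g]]
      cm <- congruence_map(ref_efa$loadings, efa_g$loadings)
      flips <- align_signs(cm)
    }
    z <- if (standardisation == "reference") {
      standardize_items(prep$dataset$items[, vars, drop = FALSE],
                        reference_stats = list(
                          mean = ref_prep$stats$mean[vars],
                          sd = ref_prep$stats$sd[vars]))$z
    } else {
      prep$z[, vars, drop = FALSE]
    }
    out[[g]] <- list(
      scores = project_scores(z, W, sign_flips = flips,
                              participant_id = prep$dataset$covariates$participant_id),
      congruence = cm,
      standardisation = standardisation)
  }
  attr(out, "reference") <- reference
  attr(out, "coefficients") <- W
  out
}
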