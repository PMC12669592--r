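# Exploratory factor analysis: adequacy diagnostics, factor-count criteria,
# minimum-residual extraction and oblimin rotation.

#' Pearson correlation matrix of complete standardised items
#'
#' @param z Numeric matrix, participants x items, no missing values (filter
#'   first).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop_npdim("need at least 2 rows")
  if (anyNA(z)) stop_npdim("missing values present; apply complete-case filtering first")
  r <- stats::cor(z)
  # guard tiny asymmetries from floating point
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Compares raw correlations with anti-image partial correlations obtained
#' from the inverse correlation matrix:
#' `overall = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over off-diagonal
#' entries, with `q_ij = -S_ij / sqrt(S_ii S_jj)` and `S = R^-1`; per-item
#' analogues use the corresponding row sums. Values above 0.8 are
#' conventionally read as meritorious sampling adequacy.
#'
#' @param R Correlation matrix.
#' @return List with `overall` and `per_item`.
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  kap <- kappa(R, exact = TRUE)
  S <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(S) || !is.finite(kap) || kap > 1e12) {
    stop_npdim("correlation matrix is (near-)singular; condition number = ",
               format(kap, digits = 3))
  }
  d <- 1 / sqrt(diag(S))
  Q <- -S * outer(d, d)           # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- R0^2
  q2 <- Q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  per_item <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(per_item) <- colnames(R)
  list(overall = overall, per_item = per_item)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is distinguishable from the identity:
#' `chisq = -(n - 1 - (2p + 5)/6) * log det R`, `df = p(p-1)/2`, upper-tail
#' chi-squared p-value.
#'
#' @param R Correlation matrix of `p` items.
#' @param n Number of observations (must exceed `p`).
#' @return List with `chisq`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  p <- ncol(R)
  if (n <= p) stop_npdim("n must exceed the number of items")
  detR <- det(R)
  if (detR <= 0) stop_npdim("det(R) <= 0; correlation matrix not positive-definite")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Eigenvalues and the Kaiser factor-count criterion
#'
#' @param R Correlation matrix.
#' @return List with `eigenvalues` (sorted descending) and `kaiser_count`
#'   (number of eigenvalues strictly greater than 1); the eigenvalue series
#'   doubles as the scree plot data.
#' @export
factor_count <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  list(eigenvalues = ev, kaiser_count = sum(ev > 1))
}

# ULS objective for given uniquenesses: sum of squared trailing eigenvalues
# of R - diag(psi); its gradient in psi is -2 * sum_j>k lambda_j * v_ij^2.
uls_objective <- function(psi, R, k) {
  Rs <- R
  diag(Rs) <- 1 - psi
  e <- eigen(Rs, symmetric = TRUE)
  tail_idx <- (k + 1):ncol(R)
  lam <- e$values[tail_idx]
  f <- sum(lam^2)
  grad <- -2 * as.vector((e$vectors[, tail_idx, drop = FALSE]^2) %*% lam)
  list(f = f, grad = grad, eigen = e)
}

#' Minimum-residual (unweighted least squares) factor extraction
#'
#' Minimises the sum of squared residuals of `R - Lambda Lambda' - Psi` over
#' the uniquenesses, with loadings taken from the top-`k` eigenstructure of
#' the reduced matrix `R - diag(Psi)`. Optimisation uses `nlminb` with the
#' analytic gradient; if it fails to converge, iterated principal-axis
#' updates (squared multiple correlations as starting communalities) are
#' used as a fallback and the result flagged.
#'
#' @param R Correlation matrix.
#' @param k Number of factors (1 <= k < p).
#' @param max_iter Iteration cap for the optimiser.
#' @return List with `loadings` (p x k, unrotated), `uniquenesses`,
#'   `objective`, `rmsr_offdiag` (root-mean-square off-diagonal residual),
#'   `converged`, `method`.
#' @export
extract_efa <- function(R, k, max_iter = 1000) {
  p <- ncol(R)
  if (k < 1 || k >= p) stop_npdim("k must satisfy 1 <= k < p")
  # start at SMC-based uniquenesses; ridge fallback for singular R
  smc <- tryCatch(1 - 1 / diag(solve(R)),
                  error = function(e) 1 - 1 / diag(solve(R + diag(1e-6, p))))
  smc[!is.finite(smc)] <- 0.5
  start <- pmin(pmax(1 - smc, 0.005), 0.995)
  fit <- stats::nlminb(start,
                       objective = function(ps) uls_objective(ps, R, k)$f,
                       gradient = function(ps) uls_objective(ps, R, k)$grad,
                       lower = 0.0005, upper = 1,
                       control = list(iter.max = max_iter, eval.max = 2 * max_iter))
  converged <- fit$convergence == 0
  psi <- fit$par
  method <- "minres"
  if (!converged) {
    # principal-axis fallback: iterate communalities from successive fits
    h <- smc
    for (i in seq_len(200)) {
      Rs <- R
      diag(Rs) <- h
      e <- eigen(Rs, symmetric = TRUE)
      L <- e$vectors[, 1:k, drop = FALSE] %*%
        diag(sqrt(pmax(e$values[1:k], 0)), k)
      h_new <- pmin(rowSums(L^2), 1)
      if (max(abs(h_new - h)) < 1e-7) break
      h <- h_new
    }
    psi <- pmax(1 - h, 0.0005)
    method <- "principal_axis_fallback"
  }
  ob <- uls_objective(psi, R, k)
  e <- ob$eigen
  L <- e$vectors[, 1:k, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[1:k], 0)), k)
  rownames(L) <- colnames(R)
  res <- R - L %*% t(L)
  diag(res) <- 0
  rmsr <- sqrt(sum(res^2) / (p * (p - 1)))
  list(loadings = L, uniquenesses = stats::setNames(psi, colnames(R)),
       objective = ob$f, rmsr_offdiag = rmsr,
       converged = converged || method == "principal_axis_fallback",
       method = method)
}

#' Full exploratory factor analysis of a standardised item table
#'
#' Chains [correlation_matrix()], [kmo()], [bartlett_sphericity()],
#' [factor_count()], [extract_efa()] and [oblimin_rotate()], then orders
#' factors by explained variance and fixes signs so each column's
#' largest-magnitude loading is positive.
#'
#' @param z Standardised complete item matrix.
#' @param k Number of factors to extract.
#' @param gamma Oblimin gamma (0 = direct quartimin, the default).
#' @param restarts Random orthonormal restarts for the rotation.
#' @param n_obs Row count override (defaults to `nrow(z)`).
#' @return Object of class `efa_fit`: `loadings` (rotated pattern matrix),
#'   `phi` (factor correlations), `uniquenesses`, `eigenvalues`, `kmo`,
#'   `bartlett`, `kaiser_count`, `rotation` (transformation matrix,
#'   convergence, criterion value), `column_order`, `column_signs`,
#'   `unrotated`, `R`, `settings`.
#' @export
run_efa <- function(z, k = 4, gamma = 0, restarts = 10, n_obs = nrow(z)) {
  R <- correlation_matrix(z)
  adequacy <- kmo(R)
  bart <- bartlett_sphericity(R, n_obs)
  fc <- factor_count(R)
  ex <- extract_efa(R, k)
  rot <- oblimin_rotate(ex$loadings, gamma = gamma, restarts = restarts)
  conv <- canonicalise_solution(rot$loadings, rot$phi)
  structure(list(loadings = conv$loadings, phi = conv$phi,
                 uniquenesses = ex$uniquenesses,
                 eigenvalues = fc$eigenvalues, kaiser_count = fc$kaiser_count,
                 kmo = adequacy, bartlett = bart,
                 rotation = list(Tmat = rot$Tmat, converged = rot$converged,
                                 iterations = rot$iterations,
                                 criterion = rot$criterion,
                                 gamma = gamma, restarts = restarts),
                 column_order = conv$order, column_signs = conv$signs,
                 unrotated = ex$loadings, extraction = ex$method,
                 rmsr_offdiag = ex$rmsr_offdiag,
                 R = R, n_obs = n_obs,
                 settings = list(k = k, gamma = gamma, restarts = restarts,
                                 kaiser_normalise = FALSE)),
            class = "efa_fit")
}

# Order columns by descending sum of squared pattern loadings and make each
# column's largest-|loading| entry positive; phi is permuted/reflected to
# match. |loadings| mildly exceeding 1 are legal for oblique pattern
# coefficients; values beyond 1.1 are capped with a warning.
canonicalise_solution <- function(L, phi) {
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  signs <- vapply(seq_len(ncol(L)), function(j) {
    v <- L[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, 0)
  L <- sweep(L, 2, signs, "*")
  phi <- diag(signs, ncol(phi)) %*% phi %*% diag(signs, ncol(phi))
  # names are positional: column j is always the j-th largest factor
  colnames(L) <- paste0("F", seq_len(ncol(L)))
  dimnames(phi) <- list(colnames(L), colnames(L))
  over <- abs(L) > 1.1
  if (any(over)) {
    warning("pattern loadings beyond 1.1 capped (", sum(over), " entries)")
    L[over] <- sign(L[over]) * 1.1
  }
  list(loadings = L, phi = phi, order = ord, signs = signs)
}

#' @export
print.efa_fit <- function(x, ...) {
  k <- ncol(x$loadings)
  cat("<efa_fit> ", nrow(x$loadings), " items, ", k, " factors (",
      x$extraction, " + oblimin gamma=", x$rotation$gamma, ")\n", sep = "")
  cat(sprintf("  KMO overall = %.3f | Bartlett chisq = %.1f (df %d, p %s)\n",
              x$kmo$overall, x$bartlett$chisq, x$bartlett$df,
              format.pval(x$bartlett$p_value)))
  cat("  eigenvalues > 1:", x$kaiser_count,
      "| off-diagonal RMSR:", signif(x$rmsr_offdiag, 3), "\n")
  invisible(x)
}

#' Assign interpretive factor labels by template matching
#'
#' Matches each estimated factor to a reference loading template (by default
#' the generating simple-structure pattern) using absolute Tucker congruence,
#' greedily from the best match down, and returns the label assignment.
#' Labels are never hard-coded by column index.
#'
#' @param loadings Estimated pattern matrix (items x k), rows aligned with
#'   the template.
#' @param template Reference loading matrix with named columns.
#' @return Character vector of labels (one per estimated column) with the
#'   congruence of each match as the `congruence` attribute.
#' @export
label_factors <- function(loadings, template) {
  if (nrow(loadings) != nrow(template)) {
    stop_npdim("loadings and template must have the same items")
  }
  phi <- abs(tucker_congruence(loadings, template))
  k <- ncol(loadings)
  labels <- character(k)
  cong <- numeric(k)
  remaining_r <- seq_len(k)
  remaining_c <- seq_len(ncol(template))
  for (i in seq_len(k)) {
    sub <- phi[remaining_r, remaining_c, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    r <- remaining_r[best[1]]; cc <- remaining_c[best[2]]
    labels[r] <- colnames(template)[cc]
    cong[r] <- phi[r, cc]
    remaining_r <- setdiff(remaining_r, r)
    remaining_c <- setdiff(remaining_c, cc)
  }
  attr(labels, "congruence") <- cong
  labels
}
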