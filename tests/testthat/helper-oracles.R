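# Brute-force / closed-form oracles, deliberately independent of the package
# implementation paths they check: matrix inversion via cofactor expansion,
# explicit loops for correlation-type quantities, normal equations for
# least squares. Only usable at toy sizes (p <= ~7, n <= ~200).

# Inverse via adjugate / cofactors (O(p^2) determinants of minors).
bf_inverse <- function(M) {
  p <- nrow(M)
  if (p == 1) return(matrix(1 / M[1, 1], 1, 1))
  cof <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      cof[i, j] <- (-1)^(i + j) * det(M[-i, -j, drop = FALSE])
    }
  }
  t(cof) / det(M)
}

bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

bf_kmo <- function(R) {
  p <- ncol(R)
  S <- bf_inverse(R)
  num <- 0; den_q <- 0
  per_num <- numeric(p); per_q <- numeric(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      q <- -S[i, j] / sqrt(S[i, i] * S[j, j])
      num <- num + R[i, j]^2
      den_q <- den_q + q^2
      per_num[i] <- per_num[i] + R[i, j]^2
      per_q[i] <- per_q[i] + q^2
    }
  }
  list(overall = num / (num + den_q),
       per_item = per_num / (per_num + per_q))
}

bf_bartlett <- function(R, n) {
  p <- ncol(R)
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(det(R))
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df,
       p_value = pchisq(chisq, df, lower.tail = FALSE))
}

bf_tucker <- function(A, B) {
  ka <- ncol(A); kb <- ncol(B)
  out <- matrix(0, ka, kb)
  for (j in seq_len(ka)) {
    for (l in seq_len(kb)) {
      out[j, l] <- sum(A[, j] * B[, l]) /
        sqrt(sum(A[, j]^2) * sum(B[, l]^2))
    }
  }
  out
}

bf_score_coefficients <- function(R, L) bf_inverse(R) %*% L

# residuals of y on intercept + columns of X, via explicit normal equations
bf_residuals <- function(y, X = NULL) {
  n <- length(y)
  D <- cbind(1, X)
  beta <- bf_inverse(t(D) %*% D) %*% (t(D) %*% y)
  as.numeric(y - D %*% beta)
}

bf_partial_correlation <- function(x, y, X = NULL) {
  rx <- bf_residuals(x, X)
  ry <- bf_residuals(y, X)
  r <- bf_pearson(rx, ry)
  n_cov <- if (is.null(X)) 0 else ncol(X)
  df <- length(x) - n_cov - 2
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, t = tt, df = df, p_value = 2 * pt(-abs(tt), df))
}

# least squares with coefficient SEs via normal equations
bf_lm <- function(y, X) {
  D <- cbind(`(Intercept)` = 1, X)
  XtX_inv <- bf_inverse(t(D) %*% D)
  beta <- XtX_inv %*% (t(D) %*% y)
  res <- as.numeric(y - D %*% beta)
  df <- length(y) - ncol(D)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(XtX_inv) * sigma2)
  list(beta = as.numeric(beta), se = se, t = as.numeric(beta) / se, df = df)
}

# exhaustive enumeration of the missingness trade-off
bf_tradeoff <- function(items, grid) {
  n <- nrow(items)
  res <- data.frame(threshold = grid, n_vars = NA, complete_case_n = NA)
  for (gi in seq_along(grid)) {
    t <- grid[gi]
    keep <- c()
    for (j in seq_len(ncol(items))) {
      if (sum(!is.na(items[, j])) >= t) keep <- c(keep, j)
    }
    res$n_vars[gi] <- length(keep)
    cc <- 0
    if (length(keep) > 0) {
      for (i in seq_len(n)) {
        if (all(!is.na(items[i, keep]))) cc <- cc + 1
      }
    }
    res$complete_case_n[gi] <- cc
  }
  max_cc <- max(res$complete_case_n)
  res$info_score <- if (max_cc > 0) res$n_vars * res$complete_case_n / max_cc
                    else rep(0, nrow(res))
  # tie-breaks: max info, then more variables, then smaller threshold
  best <- order(-res$info_score, -res$n_vars, res$threshold)[1]
  list(table = res, selected = res$threshold[best])
}

# quartimin criterion value for a pattern matrix (direct double loop)
bf_quartimin <- function(L) {
  k <- ncol(L)
  f <- 0
  for (j in seq_len(k)) {
    for (l in seq_len(k)) {
      if (j != l) f <- f + sum(L[, j]^2 * L[, l]^2)
    }
  }
  f / 4
}

# small item_dataset fixture from a raw matrix
make_item_dataset <- function(items, lo = 0, hi = 4, block = "q1",
                              reverse = FALSE, group = "HC") {
  items <- as.matrix(items)
  p <- ncol(items)
  if (is.null(colnames(items))) colnames(items) <- sprintf("it%02d", 1:p)
  meta <- data.frame(item = colnames(items),
                     block = rep_len(block, p),
                     scale_min = rep_len(lo, p), scale_max = rep_len(hi, p),
                     reverse = rep_len(reverse, p))
  cov <- data.frame(participant_id = sprintf("S%04d", seq_len(nrow(items))),
                    group = rep_len(group, nrow(items)),
                    age = seq(50, 70, length.out = nrow(items)))
  item_dataset(items, meta, cov)
}

# single-group HC cohort shortcut used across tests
hc_cohort <- function(n, seed, ...) {
  generate_cohort(cohort_spec(n_per_group = c(HC = n), seed = seed, ...),
                  trajectories = default_trajectory_specs()["HC"])
}
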