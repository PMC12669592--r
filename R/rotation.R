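# Oblique rotation by gradient projection on the manifold of oblique
# rotation matrices (columns of T constrained to unit length), minimising
# the oblimin family criterion.

# Criterion value and gradient for oblimin with parameter gamma.
# gamma = 0 is direct quartimin: f = sum_i sum_{j != l} L2_ij L2_il / 4.
oblimin_criterion <- function(L, gamma = 0) {
  k <- ncol(L)
  p <- nrow(L)
  N <- matrix(1, k, k) - diag(k)
  X <- (L^2) %*% N
  if (gamma != 0) {
    X <- (diag(p) - matrix(gamma / p, p, p)) %*% X
  }
  list(f = sum(L^2 * X) / 4, Gq = L * X)
}

#' Oblimin rotation by gradient projection
#'
#' Rotates an unrotated loading matrix to oblique simple structure by
#' minimising the oblimin criterion (default `gamma = 0`, direct quartimin)
#' with a gradient-projection algorithm. Multiple random oblique starting
#' transformations are tried (plus the identity) and the solution with the
#' lowest criterion value kept; starts are drawn from a private RNG stream
#' so rotation never perturbs the caller's random state.
#'
#' @param A Unrotated loading matrix (p x k, k >= 2).
#' @param gamma Oblimin family parameter (0 = quartimin).
#' @param restarts Number of random starts in addition to the identity.
#' @param tol Convergence tolerance on the projected gradient norm.
#' @param max_iter Iteration cap per start.
#' @param start_seed Seed for the private restart stream.
#' @return List with `loadings` (rotated pattern matrix `A %*% t(solve(T))`),
#'   `phi` (`t(T) %*% T`), `Tmat`, `criterion`, `converged`, `iterations`.
#'   Non-convergence across all starts is flagged, never silent.
#' @export
oblimin_rotate <- function(A, gamma = 0, restarts = 10, tol = 1e-6,
                           max_iter = 1000, start_seed = 1L) {
  A <- as.matrix(A)
  k <- ncol(A)
  if (k < 2) stop_npdim("rotation needs k >= 2 factors")
  starts <- list(diag(k))
  if (restarts > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(start_seed)
    for (i in seq_len(restarts)) {
      M <- matrix(stats::rnorm(k * k), k, k)
      starts[[i + 1]] <- sweep(M, 2, sqrt(colSums(M^2)), "/")
    }
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }
  best <- NULL
  for (Tmat in starts) {
    res <- gpf_oblique(A, Tmat, gamma = gamma, tol = tol, max_iter = max_iter)
    if (is.null(best) || res$criterion < best$criterion) best <- res
  }
  if (!best$converged) {
    warning("oblimin rotation did not reach tolerance ", tol,
            " within ", max_iter, " iterations in any start")
  }
  colnames(best$loadings) <- paste0("F", seq_len(k))
  dimnames(best$phi) <- list(colnames(best$loadings), colnames(best$loadings))
  rownames(best$loadings) <- rownames(A)
  best
}

# One gradient-projection run from a given starting transformation.
gpf_oblique <- function(A, Tmat, gamma, tol, max_iter) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- oblimin_criterion(L, gamma)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  s <- Inf
  iter <- 0
  Tmatt <- Tmat
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (i in seq_len(30)) {
      X <- Tmat - al * Gp
      Tmatt <- sweep(X, 2, sqrt(colSums(X^2)), "/")
      Ti <- solve(Tmatt)
      L <- A %*% t(Ti)
      vg_new <- oblimin_criterion(L, gamma)
      if (vg_new$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tmatt
    f <- vg_new$f
    G <- -t(t(L) %*% vg_new$Gq %*% Ti)
  }
  list(loadings = A %*% t(solve(Tmat)), phi = t(Tmat) %*% Tmat,
       Tmat = Tmat, criterion = f, converged = s < tol, iterations = iter)
}
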