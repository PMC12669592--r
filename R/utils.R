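# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_npdim <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

# Symmetric positive-definite check via Cholesky; returns TRUE/FALSE.
is_spd <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > 1e-8) return(FALSE)
  ok <- tryCatch({
    chol(m)
    TRUE
  }, error = function(e) FALSE)
  ok
}

# Draw n samples from N(mu, Sigma) given the upper Cholesky factor of Sigma.
rmvnorm_chol <- function(n, k, chol_upper) {
  matrix(stats::rnorm(n * k), n, k) %*% chol_upper
}

# MD5 of the ASCII serialisation of an R object; stable across sessions.
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(x, connection = NULL, ascii = TRUE), tf)
  unname(tools::md5sum(tf))
}

# Kernel-weighted mean with effective-sample-size SE. Summation is centred
# on y[1], which reduces cancellation and makes constant input return the
# constant bit-exactly.
weighted_mean_se <- function(y, w) {
  sw <- sum(w)
  y0 <- y[1]
  m <- y0 + sum(w * (y - y0)) / sw
  n_eff <- sw^2 / sum(w^2)
  v <- sum(w * (y - m)^2) / sw
  se <- sqrt(v / n_eff)
  list(mean = m, se = se, n_eff = n_eff)
}

# Write a data.frame as tab-delimited text with a single header line.
#' Read or write tab-delimited tables
#'
#' Thin wrappers around [utils::read.delim()] / [utils::write.table()] fixing
#' the conventions used by all package artefacts: tab separator, one header
#' line, no quoting, no row names, `NA` for missing.
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `read_tsv_table()` returns a data.frame; `write_tsv_table()` its
#'   path, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                    check.names = FALSE)
}
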