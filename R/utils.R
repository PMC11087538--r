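## small numeric utilities shared across the package

#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Gaussian log-density via Cholesky; `what` names the matrix in errors so
## a non-PD covariance is reported against the object that caused it.
#' @noRd
dmvnorm_log <- function(x, mean, sigma, what = "covariance") {
  sigma <- as.matrix(sigma)
  R <- tryCatch(chol(sigma), error = function(e) {
    stop("matrix not positive definite: ", what, call. = FALSE)
  })
  dev <- backsolve(R, as.numeric(x) - as.numeric(mean), transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(dev^2)
}

#' Symmetrize and floor the eigenvalues of a covariance matrix
#'
#' Hard-assignment EM with small clusters can produce singular or slightly
#' asymmetric covariance estimates. Every estimated covariance is therefore
#' symmetrized as (M + t(M))/2 and its eigenvalues clipped from below at
#' `rel * trace/dim` (with a tiny absolute guard for the zero-trace
#' degenerate case, e.g. a cluster of identical trajectories).
#'
#' @param M square matrix (near-symmetric).
#' @param rel relative eigenvalue floor, as a fraction of trace/dim.
#' @param abs_min absolute lower bound on eigenvalues.
#' @return symmetric positive-definite matrix of the same dimension.
#' @export
cov_floor <- function(M, rel = 1e-6, abs_min = 1e-10) {
  M <- as.matrix(M)
  S <- (M + t(M)) / 2
  e <- eigen(S, symmetric = TRUE)
  fl <- max(rel * sum(diag(S)) / nrow(S), abs_min)
  v <- pmax(e$values, fl)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

#' @noRd
is_symmetric_tol <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

## all permutations of 1..n as a matrix (n! x n); n is small (<= 8)
#' @noRd
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- sub + (sub >= i)
    cbind(rep(i, nrow(rest)), rest)
  }))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
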