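## Joint-Gaussian moments of a length-T trajectory under one component.
## Coordinates are interleaved per visit: (z_t, x_t) for t = 1..T, so index
## block for visit t is (t-1)(d+l) + (1..d) for states, + (d+1..d+l) for
## observations. Used by the batched complete-data likelihood that powers
## the EM E-step; the per-trajectory factored recursion in loglik.R is the
## reference implementation and the two are cross-checked in the tests.

#' @noRd
joint_moments <- function(params, T) {
  d <- params$d; l <- params$l
  A <- params$A; H <- params$H
  D <- T * (d + l)
  mu <- numeric(D)
  Sig <- matrix(0, D, D)
  zi <- function(t) (t - 1L) * (d + l) + seq_len(d)
  xi <- function(t) (t - 1L) * (d + l) + d + seq_len(l)

  mz <- vector("list", T)   # E z_t
  Vz <- vector("list", T)   # Var z_t
  mz[[1L]] <- params$m
  Vz[[1L]] <- params$S
  if (T > 1L) for (t in 2:T) {
    mz[[t]] <- drop(matrix(mz[[t - 1L]], 1L) %*% A)
    Vz[[t]] <- t(A) %*% Vz[[t - 1L]] %*% A + params$Gamma
  }
  Apow <- vector("list", T)  # A^k, k = 0..T-1
  Apow[[1L]] <- diag(d)
  if (T > 1L) for (k in 2:T) Apow[[k]] <- Apow[[k - 1L]] %*% A

  for (t in seq_len(T)) {
    mu[zi(t)] <- mz[[t]]
    mu[xi(t)] <- drop(matrix(mz[[t]], 1L) %*% H)
  }
  for (s in seq_len(T)) for (t in s:T) {
    Czz <- Vz[[s]] %*% Apow[[t - s + 1L]]     # Cov(z_s, z_t), s <= t
    Sig[zi(s), zi(t)] <- Czz
    Sig[zi(t), zi(s)] <- t(Czz)
    Czx <- Czz %*% H                           # Cov(z_s, x_t)
    Sig[zi(s), xi(t)] <- Czx
    Sig[xi(t), zi(s)] <- t(Czx)
    if (s != t) {                              # Cov(x_s, z_t) = H' Cov(z_s,z_t)
      Cxz <- t(H) %*% Czz
      Sig[xi(s), zi(t)] <- Cxz
      Sig[zi(t), xi(s)] <- t(Cxz)
    }
    Cxx <- t(H) %*% Czz %*% H
    if (s == t) Cxx <- Cxx + params$Lambda
    Sig[xi(s), xi(t)] <- Cxx
    Sig[xi(t), xi(s)] <- t(Cxx)
  }
  list(mean = mu, cov = Sig)
}

## flatten a complete trajectory into the interleaved coordinate order
#' @noRd
flatten_traj <- function(traj) {
  as.numeric(t(cbind(traj$states, traj$observations)))
}

## n x n_c matrix of complete-data log-likelihoods for a complete dataset,
## vectorized over trajectories grouped by length: one Cholesky per
## (cluster, T), then a single triangular solve for the whole group.
#' @noRd
batch_complete_loglik <- function(dataset, model, groups = NULL) {
  if (is.null(groups)) groups <- length_groups(dataset)
  n <- length(dataset$trajectories)
  out <- matrix(NA_real_, n, model$n_c)
  for (g in groups) {
    Tg <- g$T
    X <- g$X    # n_g x T(d+l), rows are flattened trajectories
    for (c in seq_len(model$n_c)) {
      mom <- joint_moments(model$clusters[[c]], Tg)
      R <- tryCatch(chol(mom$cov), error = function(e)
        stop("matrix not positive definite: joint covariance of cluster ", c,
             call. = FALSE))
      Xc <- sweep(X, 2L, mom$mean, `-`)
      dev <- backsolve(R, t(Xc), transpose = TRUE)
      out[g$idx, c] <- -0.5 * ncol(X) * log(2 * pi) - sum(log(diag(R))) -
        0.5 * colSums(dev^2)
    }
  }
  out
}

## group a complete dataset by trajectory length, pre-flattening the data
#' @noRd
length_groups <- function(dataset) {
  Ts <- vapply(dataset$trajectories, `[[`, integer(1), "T")
  lapply(sort(unique(Ts)), function(Tg) {
    idx <- which(Ts == Tg)
    X <- t(vapply(dataset$trajectories[idx], flatten_traj,
                  numeric(Tg * (dataset$d + dataset$l))))
    if (length(idx) == 1L) X <- matrix(X, 1L)
    list(T = Tg, idx = idx, X = X)
  })
}
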