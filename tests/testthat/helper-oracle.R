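## Independent brute-force oracle for trajectory likelihoods.
##
## Builds the full joint Gaussian over all T(d+l) coordinates of a
## trajectory by explicit construction of the affine map from iid standard
## normal noise (no covariance recursion): with L_S = chol(S) etc. and row
## vectors,
##   z_t = m A^(t-1) + e_1 L_S A^(t-1) + sum_{s=2..t} eps_s L_G A^(t-s)
##   x_t = z_t H + f_t L_L
## so mean = deterministic part and cov = t(M) %*% M for the stacked noise
## map M. Densities are evaluated with determinant()/solve(), not Cholesky,
## keeping the oracle numerically independent of the package's code path.
## Coordinate layout matches the package: interleaved (z_t, x_t) per visit.

oracle_moments <- function(params, T) {
  d <- params$d; l <- params$l
  A <- params$A; H <- params$H
  LS <- chol(params$S); LG <- chol(params$Gamma); LL <- chol(params$Lambda)
  D <- T * (d + l)
  n_noise <- T * d + T * l
  zi <- function(t) (t - 1L) * (d + l) + seq_len(d)
  xi <- function(t) (t - 1L) * (d + l) + d + seq_len(l)
  ei <- function(s) (s - 1L) * d + seq_len(d)        # e_1, eps_2..T
  fi <- function(t) T * d + (t - 1L) * l + seq_len(l)
  Ak <- function(k) {                                 # A^k, k >= 0
    out <- diag(d)
    if (k > 0) for (i in seq_len(k)) out <- out %*% A
    out
  }
  mu <- numeric(D)
  M <- matrix(0, n_noise, D)
  for (t in seq_len(T)) {
    mu[zi(t)] <- drop(matrix(params$m, 1) %*% Ak(t - 1L))
    M[ei(1L), zi(t)] <- LS %*% Ak(t - 1L)
    if (t > 1L) for (s in 2:t)
      M[ei(s), zi(t)] <- LG %*% Ak(t - s)
    mu[xi(t)] <- drop(matrix(mu[zi(t)], 1) %*% H)
    M[, xi(t)] <- M[, zi(t)] %*% H
    M[fi(t), xi(t)] <- M[fi(t), xi(t)] + LL
  }
  list(mean = mu, cov = t(M) %*% M)
}

## log N(x; mu, Sigma) via determinant() and solve()
oracle_dmvnorm_log <- function(x, mu, Sigma) {
  k <- length(x)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  dev <- as.numeric(x - mu)
  -0.5 * k * log(2 * pi) - 0.5 * ld -
    0.5 * drop(dev %*% solve(Sigma, dev))
}

## marginal log-density of the observed cells of a trajectory
oracle_loglik <- function(traj, params) {
  mom <- oracle_moments(params, traj$T)
  obs <- as.logical(t(cbind(traj$states_mask, traj$obs_mask)))
  vals <- as.numeric(t(cbind(traj$states, traj$observations)))[obs]
  oracle_dmvnorm_log(vals, mom$mean[obs], mom$cov[obs, obs, drop = FALSE])
}

## log p(values at idx_b | values at idx_a) under the joint moments
oracle_conditional_loglik <- function(mom, idx_a, idx_b, values) {
  Saa <- mom$cov[idx_a, idx_a, drop = FALSE]
  Sba <- mom$cov[idx_b, idx_a, drop = FALSE]
  Sbb <- mom$cov[idx_b, idx_b, drop = FALSE]
  da <- values[idx_a] - mom$mean[idx_a]
  mu_b <- mom$mean[idx_b] + drop(Sba %*% solve(Saa, da))
  S_b <- Sbb - Sba %*% solve(Saa, t(Sba))
  oracle_dmvnorm_log(values[idx_b], mu_b, (S_b + t(S_b)) / 2)
}

## random well-conditioned parameter set
random_params <- function(d, l) {
  rpd <- function(k) {
    W <- matrix(rnorm(k * k, sd = 0.4), k)
    crossprod(W) + diag(k) * 0.5
  }
  mtm_cluster_params(m = rnorm(d), S = rpd(d),
                     A = matrix(rnorm(d * d, sd = 0.4 / sqrt(d)), d),
                     Gamma = rpd(d),
                     H = matrix(rnorm(d * l, sd = 0.7), d, l),
                     Lambda = rpd(l))
}

## random complete trajectory with arbitrary (not model-drawn) values
random_traj <- function(T, d, l) {
  mtm_trajectory(matrix(rnorm(T * d), T), matrix(rnorm(T * l), T))
}

## apply a random mask guaranteeing at least one observed cell
random_masked_traj <- function(T, d, l, p_miss = 0.5) {
  tr <- random_traj(T, d, l)
  sm <- matrix(runif(T * d) >= p_miss, T)
  om <- matrix(runif(T * l) >= p_miss, T)
  if (!any(sm) && !any(om)) om[1, 1] <- TRUE
  st <- tr$states; st[!sm] <- NA_real_
  ob <- tr$observations; ob[!om] <- NA_real_
  mtm_trajectory(st, ob, sm, om)
}

## trapezoidal ROC-integration oracle for AUC
trapezoid_auc <- function(index, outcome) {
  outcome <- as.logical(outcome)
  thr <- sort(unique(index), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(index[outcome] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(index[!outcome] >= t), 0), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
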