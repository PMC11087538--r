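## shared small fixtures built in code

## a fixed well-conditioned parameter set (d = 2, l = 3)
random_params_fixture <- function() {
  mtm_cluster_params(
    m = c(0.5, -0.5),
    S = matrix(c(1, 0.3, 0.3, 1), 2),
    A = matrix(c(0.9, 0.1, -0.1, 0.8), 2),
    Gamma = matrix(c(0.5, 0.1, 0.1, 0.5), 2),
    H = matrix(c(1, 0.5, -0.5, 1, 0.2, -0.2), 2, 3),
    Lambda = diag(3) * 0.4)
}

subset_small <- function(ds, idx) mtm:::subset_dataset(ds, idx)

sample_trajectory_seeded <- function(params, T, seed) {
  set.seed(seed)
  sample_trajectory(params, T)
}

## small well-separated cohort for fast end-to-end tests
small_cohort <- function(n_d = 200, n_c = 4, seed = 1, ...) {
  make_cohort(mtm_scenario(n_c = n_c, n_d = n_d, seed = seed, ...))
}

## independently coded hard-assignment Gaussian mixture with the
## state-space covariance structure, for the T = 1 equivalence check:
## joint of (z1, x1) has mean (m, m H) and covariance
## [[S, S H], [H' S, H' S H + Lambda]]; E-step by joint density, M-step by
## the closed-form estimates, no vectorization shared with the package.
oracle_hard_gmm <- function(Z, X, init_labels, n_c, max_iter = 100) {
  n <- nrow(Z); d <- ncol(Z); l <- ncol(X)
  Y <- cbind(Z, X)
  labels <- init_labels
  obj <- -Inf
  for (it in seq_len(max_iter)) {
    comp <- lapply(seq_len(n_c), function(c) {
      idx <- which(labels == c)
      Zc <- Z[idx, , drop = FALSE]; Xc <- X[idx, , drop = FALSE]
      m <- colMeans(Zc)
      S <- crossprod(sweep(Zc, 2, m)) / nrow(Zc)
      H <- solve(crossprod(Zc), crossprod(Zc, Xc))
      Lam <- crossprod(Xc - Zc %*% H) / nrow(Zc)
      mu <- c(m, drop(m %*% H))
      Sig <- rbind(cbind(S, S %*% H),
                   cbind(t(H) %*% S, t(H) %*% S %*% H + Lam))
      list(pi = nrow(Zc) / n, mu = mu, Sig = (Sig + t(Sig)) / 2)
    })
    scored <- sapply(comp, function(cp)
      apply(Y, 1, function(y) log(cp$pi) +
              oracle_dmvnorm_log(y, cp$mu, cp$Sig)))
    new_labels <- apply(scored, 1, which.max)
    new_obj <- sum(scored[cbind(seq_len(n), new_labels)])
    if (identical(new_labels, labels)) break
    labels <- new_labels
    obj <- new_obj
  }
  list(labels = labels,
       objective = sum(scored[cbind(seq_len(n), labels)]))
}
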