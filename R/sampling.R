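## Sampling from the generative process: a cluster is drawn from pi, the
## first state from N(m, S), subsequent states from the cluster dynamics and
## observations as linear read-outs. Randomness comes from R's global RNG;
## callers seed with set.seed() (the scenario generator does this for you).

#' @noRd
rmvnorm_row <- function(n, mean, sigma, what = "covariance") {
  R <- tryCatch(chol(sigma), error = function(e)
    stop("matrix not positive definite: ", what, call. = FALSE))
  E <- matrix(rnorm(n * length(mean)), n)
  sweep(E %*% R, 2L, as.numeric(mean), `+`)
}

#' Sample one trajectory from a single state-space component
#'
#' `z[1] ~ N(m, S)`, `z[t] ~ N(z[t-1] %*% A, Gamma)` for t >= 2, and
#' `x[t] ~ N(z[t] %*% H, Lambda)`; all masks fully observed. Deterministic
#' for a fixed RNG state (seed with `set.seed()`).
#'
#' @param params an [mtm_cluster_params()].
#' @param T number of visits (>= 1).
#' @param subject_id identifier for the new trajectory.
#' @return an [mtm_trajectory()].
#' @export
sample_trajectory <- function(params, T, subject_id = "s1") {
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1")
  d <- params$d; l <- params$l
  z <- matrix(NA_real_, T, d)
  z[1L, ] <- rmvnorm_row(1L, params$m, params$S, "S")
  if (T > 1L) for (t in 2:T)
    z[t, ] <- rmvnorm_row(1L, drop(z[t - 1L, , drop = FALSE] %*% params$A),
                          params$Gamma, "Gamma")
  x <- z %*% params$H +
    rmvnorm_row(T, numeric(l), params$Lambda, "Lambda")
  mtm_trajectory(z, x, subject_id = subject_id)
}

#' Sample a cohort from a mixture of state-space models
#'
#' Independently assigns each subject to a cluster drawn from the mixture
#' weights, draws a trajectory length from `length_distribution`, and
#' samples the trajectory from the assigned component. Ground-truth cluster
#' labels are returned separately and never stored on the trajectories.
#'
#' @param model an [mtm_model()].
#' @param n_d number of subjects (>= 1).
#' @param length_distribution named numeric vector mapping trajectory length
#'   `T` (names) to probability; must sum to 1.
#' @return list with `dataset` (an `mtm_dataset`) and `labels` (integer
#'   vector of true cluster indices, 1-based).
#' @export
sample_dataset <- function(model, n_d,
                           length_distribution = c("2" = 337, "3" = 194,
                                                   "4" = 40) / 571) {
  n_d <- as.integer(n_d)
  if (n_d < 1L) stop("n_d must be >= 1")
  p <- as.numeric(length_distribution)
  if (abs(sum(p) - 1) > 1e-8)
    stop("length_distribution must sum to 1")
  Ts <- as.integer(names(length_distribution))
  if (anyNA(Ts) || any(Ts < 1L))
    stop("length_distribution names must be positive integer lengths")
  labels <- sample.int(model$n_c, n_d, replace = TRUE, prob = model$pi)
  lens <- Ts[sample.int(length(Ts), n_d, replace = TRUE, prob = p)]
  trajs <- vector("list", n_d)
  for (i in seq_len(n_d))
    trajs[[i]] <- sample_trajectory(model$clusters[[labels[i]]], lens[i],
                                    subject_id = sprintf("s%04d", i))
  list(dataset = mtm_dataset(trajs, model$state_names, model$obs_names),
       labels = labels)
}
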