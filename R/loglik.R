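#' Complete-data log-likelihood of one trajectory under one cluster
#'
#' Evaluates the factored log-density of a fully observed trajectory under
#' one linear Gaussian state-space component:
#' the Gaussian log-density of `z[1]` under `(m, S)`, plus transition terms
#' `z[t] | z[t-1] ~ N(z[t-1] %*% A, Gamma)` for t = 2..T, plus emission
#' terms `x[t] | z[t] ~ N(z[t] %*% H, Lambda)` for t = 1..T.
#'
#' Requires every cell observed; use [marginal_loglik()] for trajectories
#' with missing cells (the two agree on complete data).
#'
#' @param traj an [mtm_trajectory()] with full observed-masks.
#' @param params an [mtm_cluster_params()].
#' @return scalar log-likelihood.
#' @export
complete_data_loglik <- function(traj, params) {
  check_traj_dims(traj, params)
  if (!traj_complete(traj))
    stop("trajectory has missing cells; use marginal_loglik()")
  z <- traj$states; x <- traj$observations
  ll <- dmvnorm_log(z[1L, ], params$m, params$S, "S")
  if (traj$T > 1L) {
    for (t in 2:traj$T)
      ll <- ll + dmvnorm_log(z[t, ], drop(z[t - 1L, , drop = FALSE] %*% params$A),
                             params$Gamma, "Gamma")
  }
  for (t in seq_len(traj$T))
    ll <- ll + dmvnorm_log(x[t, ], drop(z[t, , drop = FALSE] %*% params$H),
                           params$Lambda, "Lambda")
  ll
}
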