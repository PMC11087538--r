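#' Marginal log-likelihood of a partially observed trajectory
#'
#' Exact log-likelihood of the observed cells of a trajectory under one
#' state-space component, with every unobserved cell (any subset of state
#' and observation coordinates at any visit) integrated out of the joint
#' Gaussian. Implemented as a sequential prediction/update recursion: at
#' each visit the joint Gaussian of `(z_t, x_t)` given the past — mean
#' `(mu, mu %*% H)`, covariance blocks `(P, P H; H'P, H'P H + Lambda)` — is
#' restricted to the observed coordinates, the log-density of that slice
#' under its predictive marginal is accumulated, and the state belief is
#' conditioned on the slice (a blockwise Kalman update; observed states are
#' handled by the same conditioning, which is exact). On a fully observed
#' trajectory this equals [complete_data_loglik()].
#'
#' Missingness is treated as ignorable (MAR): masks select coordinates but
#' never enter the likelihood.
#'
#' @param traj an [mtm_trajectory()]; at least one cell must be observed.
#' @param params an [mtm_cluster_params()].
#' @return scalar log p(observed cells | component).
#' @export
marginal_loglik <- function(traj, params) {
  check_traj_dims(traj, params)
  if (!any(traj$states_mask) && !any(traj$obs_mask))
    stop("no observed data: trajectory is completely masked")
  d <- params$d; l <- params$l
  H <- params$H
  mu <- params$m
  P <- params$S
  ll <- 0
  for (t in seq_len(traj$T)) {
    if (t > 1L) {
      mu <- drop(matrix(mu, 1L) %*% params$A)
      P <- t(params$A) %*% P %*% params$A + params$Gamma
      P <- (P + t(P)) / 2
    }
    obs <- c(traj$states_mask[t, ], traj$obs_mask[t, ])
    if (!any(obs)) next
    w <- c(traj$states[t, ], traj$observations[t, ])[obs]
    PH <- P %*% H
    mw <- c(mu, drop(matrix(mu, 1L) %*% H))[obs]
    Sw <- rbind(cbind(P, PH), cbind(t(PH), t(H) %*% PH + params$Lambda))
    Sw <- (Sw + t(Sw)) / 2
    Soo <- Sw[obs, obs, drop = FALSE]
    ll <- ll + dmvnorm_log(w, mw, Soo,
                           sprintf("predictive covariance at visit %d", t))
    ## condition the state belief on the observed slice
    Czo <- Sw[seq_len(d), obs, drop = FALSE]
    K <- Czo %*% chol2inv(chol(Soo))
    mu <- mu + drop(K %*% (w - mw))
    P <- P - K %*% t(Czo)
    P <- (P + t(P)) / 2
  }
  ll
}

#' Per-cluster marginal log-likelihoods of one trajectory
#'
#' @param traj an [mtm_trajectory()].
#' @param model an [mtm_model()].
#' @return length-`n_c` numeric vector of `log p(observed data | c)` (no
#'   mixture weights applied).
#' @export
loglik_per_cluster <- function(traj, model) {
  vapply(model$clusters, function(p) marginal_loglik(traj, p), numeric(1))
}

## posterior over clusters from log pi + loglik, in the log domain
#' @noRd
cluster_posterior <- function(logpi_plus_ll) {
  exp(logpi_plus_ll - logsumexp(logpi_plus_ll))
}

#' Assign trajectories to clusters
#'
#' Computes, for each trajectory, the per-cluster marginal log-likelihood,
#' the posterior `pi_c * exp(loglik_c)` (normalized in the log domain), and
#' the hard label `argmax_c (log pi_c + loglik_c)` with ties broken by the
#' lowest cluster index. Works under any missingness pattern. If the model
#' carries harmonized display labels (or a `map` is supplied) the display
#' label and the cognitive health index (log-likelihood under cluster "A")
#' are attached.
#'
#' @param dataset an `mtm_dataset` (or a single `mtm_trajectory`).
#' @param model an [mtm_model()].
#' @param map optional [harmonize_labels()] result used to attach display
#'   labels without permuting the model.
#' @return an object of class `mtm_assignment`: list with `loglik`
#'   (n x n_c), `posterior` (n x n_c), `cluster` (raw 1-based indices),
#'   `label` (display labels or `NULL`), `index` (cognitive health index or
#'   `NULL`), `n_visits`, `subject_id`.
#' @export
mtm_assign <- function(dataset, model, map = NULL) {
  if (inherits(dataset, "mtm_trajectory"))
    dataset <- mtm_dataset(list(dataset))
  n <- length(dataset$trajectories)
  complete <- dataset_complete(dataset)
  ll <- if (complete) {
    batch_complete_loglik(dataset, model)
  } else {
    t(vapply(dataset$trajectories, loglik_per_cluster, numeric(model$n_c),
             model = model))
  }
  if (model$n_c == 1L) ll <- matrix(ll, n, 1L)
  scored <- sweep(ll, 2L, log(model$pi), `+`)
  cluster <- apply(scored, 1L, which.max)  # which.max: lowest index on ties
  posterior <- t(apply(scored, 1L, cluster_posterior))
  if (model$n_c == 1L) posterior <- matrix(posterior, n, 1L)
  labels <- NULL; index <- NULL
  display <- display_labels(model, map)
  if (!is.null(display)) {
    labels <- display[cluster]
    a <- which(display == "A")[1L]
    if (!is.na(a)) index <- ll[, a]
  }
  structure(list(loglik = ll, posterior = posterior, cluster = cluster,
                 label = labels, index = index,
                 n_visits = vapply(dataset$trajectories, `[[`, integer(1), "T"),
                 subject_id = subject_ids(dataset)),
            class = "mtm_assignment")
}

## display label of each raw cluster index, from a map or the model itself
#' @noRd
display_labels <- function(model, map = NULL) {
  if (!is.null(map)) {
    lab <- character(model$n_c)
    lab[map$order] <- map$labels
    return(lab)
  }
  if (!is.null(model$labels)) return(model$labels)
  NULL
}

#' @export
print.mtm_assignment <- function(x, ...) {
  cat(sprintf("<mtm_assignment> %d trajectories, %d clusters\n",
              nrow(x$loglik), ncol(x$loglik)))
  tab <- table(if (is.null(x$label)) x$cluster else x$label)
  print(tab)
  invisible(x)
}
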