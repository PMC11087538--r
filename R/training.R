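#' Configuration for hard-EM training
#'
#' @param n_c number of mixture components.
#' @param n_restarts number of random initializations; the restart with the
#'   highest final objective is kept.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative convergence tolerance on the objective
#'   `J = sum_i log pi_{c_i} + loglik(i, c_i)`.
#' @param seed base seed; restart r uses `seed + r - 1`.
#' @param floor relative eigenvalue floor applied to every estimated
#'   covariance (see [cov_floor()]).
#' @param min_size minimum cluster size during EM; defaults to `d + l + 1`
#'   trajectories (resolved against the dataset at fit time).
#' @return an object of class `mtm_fit_config`.
#' @export
mtm_fit_config <- function(n_c, n_restarts = 10L, max_iter = 200L,
                           tol = 1e-6, seed = 1L, floor = 1e-6,
                           min_size = NULL) {
  stopifnot(n_c >= 1L, n_restarts >= 1L, max_iter >= 1L, tol > 0, floor > 0)
  structure(list(n_c = as.integer(n_c), n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), floor = floor,
                 min_size = min_size),
            class = "mtm_fit_config")
}

## per-cluster sufficient statistics stacked once per dataset:
## first states, consecutive (prev, next) state pairs, and all (state, obs)
## visit pairs, each with the owning trajectory's index.
#' @noRd
stack_stats <- function(dataset) {
  trajs <- dataset$trajectories
  firsts <- matrix(as.numeric(vapply(trajs, function(tr) tr$states[1L, ],
                                     numeric(dataset$d))),
                   ncol = dataset$d, byrow = TRUE)
  pairs_prev <- list(); pairs_next <- list(); pairs_who <- list()
  vis_z <- list(); vis_x <- list(); vis_who <- list()
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    if (tr$T > 1L) {
      pairs_prev[[length(pairs_prev) + 1L]] <-
        tr$states[-tr$T, , drop = FALSE]
      pairs_next[[length(pairs_next) + 1L]] <-
        tr$states[-1L, , drop = FALSE]
      pairs_who[[length(pairs_who) + 1L]] <- rep(i, tr$T - 1L)
    }
    vis_z[[i]] <- tr$states
    vis_x[[i]] <- tr$observations
    vis_who[[i]] <- rep(i, tr$T)
  }
  list(firsts = firsts,
       pair_prev = if (length(pairs_prev)) do.call(rbind, pairs_prev) else
         matrix(0, 0L, dataset$d),
       pair_next = if (length(pairs_next)) do.call(rbind, pairs_next) else
         matrix(0, 0L, dataset$d),
       pair_who = unlist(pairs_who) %||% integer(0),
       vis_z = do.call(rbind, vis_z),
       vis_x = do.call(rbind, vis_x),
       vis_who = unlist(vis_who))
}

## least squares Y ~ X B with pseudo-inverse fallback for rank deficiency
#' @noRd
ls_solve <- function(X, Y) {
  B <- tryCatch(qr.solve(X, Y), error = function(e) NULL)
  if (is.null(B)) {
    warning("rank-deficient regression; using pseudo-inverse", call. = FALSE)
    B <- MASS::ginv(X) %*% Y
  }
  B
}

## M-step from precomputed stats (internal fast path)
#' @noRd
m_step_stats <- function(stats, labels, n_c, d, l, floor,
                         state_names, obs_names) {
  n_d <- length(labels)
  clusters <- vector("list", n_c)
  pi <- numeric(n_c)
  for (c in seq_len(n_c)) {
    members <- which(labels == c)
    pi[c] <- length(members) / n_d
    F <- stats$firsts[members, , drop = FALSE]
    m <- colMeans(F)
    S <- crossprod(sweep(F, 2L, m)) / nrow(F)       # MLE covariance
    S <- cov_floor(S, floor)
    keep_p <- stats$pair_who %in% members
    if (any(keep_p)) {
      Xp <- stats$pair_prev[keep_p, , drop = FALSE]
      Yp <- stats$pair_next[keep_p, , drop = FALSE]
      A <- ls_solve(Xp, Yp)
      Gam <- crossprod(Yp - Xp %*% A) / nrow(Xp)
    } else {
      A <- diag(d)                                   # all T = 1: dynamics
      Gam <- diag(d)                                 # unidentified, unused
    }
    Gam <- cov_floor(Gam, floor)
    keep_v <- stats$vis_who %in% members
    Zv <- stats$vis_z[keep_v, , drop = FALSE]
    Xv <- stats$vis_x[keep_v, , drop = FALSE]
    H <- ls_solve(Zv, Xv)
    Lam <- cov_floor(crossprod(Xv - Zv %*% H) / nrow(Zv), floor)
    clusters[[c]] <- mtm_cluster_params(m, S, A, Gam, H, Lam)
  }
  mtm_model(pi, clusters, state_names, obs_names)
}

#' M-step: closed-form per-cluster parameter estimates
#'
#' Given hard labels, refits each component by maximum likelihood:
#' `pi_c` = cluster share; `m_c`, `S_c` = mean/covariance of first states;
#' `A_c` = least-squares fit of `z[t] ~ z[t-1]` over within-cluster
#' consecutive pairs, `Gamma_c` its residual covariance; `H_c` =
#' least-squares fit of `x[t] ~ z[t]` over within-cluster visits,
#' `Lambda_c` its residual covariance. All covariances pass through
#' [cov_floor()]. Rank-deficient regressions fall back to the
#' pseudo-inverse with a warning; a cluster containing only single-visit
#' trajectories gets identity dynamics (which its likelihood never uses).
#'
#' @param dataset a complete `mtm_dataset`.
#' @param labels integer vector of hard assignments in `1..n_c`.
#' @param n_c number of clusters.
#' @param floor relative covariance eigenvalue floor.
#' @return an [mtm_model()].
#' @export
m_step <- function(dataset, labels, n_c = max(labels), floor = 1e-6) {
  if (!dataset_complete(dataset))
    stop("m_step requires fully observed trajectories")
  if (length(labels) != length(dataset$trajectories))
    stop("one label per trajectory required")
  if (any(tabulate(labels, n_c) == 0L))
    stop("every cluster must have at least one member")
  m_step_stats(stack_stats(dataset), as.integer(labels), as.integer(n_c),
               dataset$d, dataset$l, floor,
               dataset$state_names, dataset$obs_names)
}

#' Hard E-step: maximum a posteriori cluster labels
#'
#' `label_i = argmax_c (log pi_c + complete_data_loglik(i, c))`, ties broken
#' by the lowest cluster index.
#'
#' @param dataset a complete `mtm_dataset`.
#' @param model an [mtm_model()].
#' @return integer vector of labels in `1..n_c`.
#' @export
hard_e_step <- function(dataset, model) {
  if (!dataset_complete(dataset))
    stop("hard_e_step requires fully observed trajectories")
  ll <- batch_complete_loglik(dataset, model)
  scored <- sweep(ll, 2L, log(model$pi), `+`)
  as.integer(apply(scored, 1L, which.max))
}

## objective J(labels, model) = sum_i log pi_{c_i} + loglik(i, c_i)
#' @noRd
em_objective <- function(ll, pi, labels) {
  n <- nrow(ll)
  sum(log(pi[labels])) + sum(ll[cbind(seq_len(n), labels)])
}

## per-trajectory summary vectors used for k-means initialization and for
## refilling undersized clusters: concatenated mean state and mean obs
#' @noRd
traj_summaries <- function(dataset) {
  t(vapply(dataset$trajectories, function(tr) {
    c(colMeans(tr$states), colMeans(tr$observations))
  }, numeric(dataset$d + dataset$l)))
}

## ensure every cluster has >= min_size members by moving the trajectories
## farthest from the centroid of the most populous donor cluster
#' @noRd
refill_clusters <- function(labels, summaries, n_c, min_size) {
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 10L * n_c) return(NULL)
    sizes <- tabulate(labels, n_c)
    needy <- which(sizes < min_size)
    if (!length(needy)) return(labels)
    c0 <- needy[1L]
    donor <- which.max(sizes)
    if (sizes[donor] <= min_size) return(NULL)  # cannot refill
    members <- which(labels == donor)
    centroid <- colMeans(summaries[members, , drop = FALSE])
    dist2 <- rowSums(sweep(summaries[members, , drop = FALSE], 2L,
                           centroid)^2)
    take <- members[order(dist2, decreasing = TRUE)][
      seq_len(min_size - sizes[c0])]
    labels[take] <- c0
  }
}

## one EM run from given initial labels; returns NULL if a restart dies
#' @noRd
run_em <- function(dataset, stats, init_labels, config, min_size) {
  n_c <- config$n_c
  summaries <- traj_summaries(dataset)
  labels <- refill_clusters(init_labels, summaries, n_c, min_size)
  if (is.null(labels)) return(NULL)
  trace <- numeric(0)
  J_prev <- -Inf
  converged <- FALSE
  model <- NULL
  for (it in seq_len(config$max_iter)) {
    model <- m_step_stats(stats, labels, n_c, dataset$d, dataset$l,
                          config$floor, dataset$state_names,
                          dataset$obs_names)
    ll <- batch_complete_loglik(dataset, model)
    J <- em_objective(ll, model$pi, labels)
    trace <- c(trace, J)
    scored <- sweep(ll, 2L, log(model$pi), `+`)
    new_labels <- as.integer(apply(scored, 1L, which.max))
    new_labels <- refill_clusters(new_labels, summaries, n_c, min_size)
    if (is.null(new_labels)) return(NULL)
    if (identical(new_labels, labels) ||
        abs(J - J_prev) < config$tol * (abs(J_prev) + 1e-8)) {
      converged <- TRUE
      labels <- new_labels
      break
    }
    labels <- new_labels
    J_prev <- J
  }
  list(model = model, labels = labels, trace = trace,
       objective = trace[length(trace)], iterations = length(trace),
       converged = converged)
}

## k-means-style label seeding on trajectory summary vectors
#' @noRd
init_labels <- function(summaries, n_c, seed) {
  set.seed(seed)
  n <- nrow(summaries)
  if (n_c == 1L) return(rep(1L, n))
  km <- tryCatch(
    suppressWarnings(kmeans(summaries, centers = n_c, nstart = 1L)),
    error = function(e) NULL)
  if (!is.null(km)) return(as.integer(km$cluster))
  ## degenerate data (e.g. duplicate points): random balanced labels
  as.integer(sample(rep_len(seq_len(n_c), n)))
}

#' Fit a mixture of state-space models by hard-assignment EM
#'
#' Alternates the hard E-step (argmax cluster assignment) with the
#' closed-form M-step from each of `n_restarts` random initializations
#' (k-means seeding on per-trajectory summary vectors), until the objective
#' `J = sum_i log pi_{c_i} + loglik(i, c_i)` changes by less than `tol`
#' (relative) or labels stabilize. The restart with the highest final
#' objective is returned. Training requires fully observed states and
#' observations; incomplete trajectories are rejected with a per-subject
#' report.
#'
#' @param dataset a complete `mtm_dataset`.
#' @param config an [mtm_fit_config()].
#' @return an object of class `mtm_fit`: list with `model`, `labels` (final
#'   hard assignments), `objective`, `trace` (objective per iteration of the
#'   winning restart), `restart_objectives`, `restart_traces`, `iterations`,
#'   `converged`.
#' @export
mtm_fit <- function(dataset, config) {
  stopifnot(inherits(dataset, "mtm_dataset"),
            inherits(config, "mtm_fit_config"))
  incomplete <- !vapply(dataset$trajectories, traj_complete, logical(1))
  if (any(incomplete))
    stop("training requires complete trajectories (both biomarker states ",
         "and cognitive scores observed at every visit); incomplete ",
         "subjects: ",
         paste(subject_ids(dataset)[incomplete], collapse = ", "))
  min_size <- as.integer(config$min_size %||% (dataset$d + dataset$l + 1L))
  n_d <- length(dataset$trajectories)
  if (n_d < config$n_c * min_size)
    stop(sprintf("too few trajectories: need >= %d (= n_c x min cluster size), have %d",
                 config$n_c * min_size, n_d))
  stats <- stack_stats(dataset)
  summaries <- traj_summaries(dataset)
  runs <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    lab0 <- init_labels(summaries, config$n_c, config$seed + r - 1L)
    runs[[r]] <- run_em(dataset, stats, lab0, config, min_size)
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok))
    stop("all EM restarts failed (clusters could not be kept at minimum size)")
  if (any(!ok))
    warning(sum(!ok), " restart(s) dropped: undersized clusters could not be refilled",
            call. = FALSE)
  objs <- rep(-Inf, config$n_restarts)
  objs[ok] <- vapply(runs[ok], `[[`, numeric(1), "objective")
  best <- which.max(objs)
  run <- runs[[best]]
  structure(list(model = run$model, labels = run$labels,
                 objective = run$objective, trace = run$trace,
                 restart_objectives = objs,
                 restart_traces = lapply(runs[ok], `[[`, "trace"),
                 iterations = run$iterations, converged = run$converged,
                 config = config),
            class = "mtm_fit")
}

#' @export
print.mtm_fit <- function(x, ...) {
  cat(sprintf("<mtm_fit> n_c=%d, objective=%.3f, %d iterations, converged=%s\n",
              x$model$n_c, x$objective, x$iterations, x$converged))
  invisible(x)
}

#' Bayesian information criterion of a fitted mixture
#'
#' `BIC = k log(N) - 2 L` with `L` the full soft mixture log-likelihood
#' `sum_i log sum_c pi_c exp(loglik(i, c))` (log-sum-exp), `N` the number of
#' trajectories (the i.i.d. unit), and
#' `k = (n_c - 1) + n_c (d + d(d+1)/2 + d^2 + d(d+1)/2 + d l + l(l+1)/2)`
#' free parameters. Lower is better.
#'
#' @param dataset a complete `mtm_dataset`.
#' @param model an [mtm_model()].
#' @return scalar BIC.
#' @export
mtm_bic <- function(dataset, model) {
  ll <- batch_complete_loglik(dataset, model)
  scored <- sweep(ll, 2L, log(model$pi), `+`)
  L <- sum(apply(scored, 1L, logsumexp))
  k <- bic_param_count(model$n_c, model$d, model$l)
  k * log(length(dataset$trajectories)) - 2 * L
}

#' Free-parameter count of a mixture of state-space models
#' @param n_c,d,l mixture size and dimensions.
#' @return integer parameter count used by [mtm_bic()].
#' @export
bic_param_count <- function(n_c, d, l) {
  per <- d + d * (d + 1) / 2 + d^2 + d * (d + 1) / 2 + d * l + l * (l + 1) / 2
  (n_c - 1) + n_c * per
}

#' Choose the number of clusters by BIC
#'
#' Fits each candidate number of components (deduplicated, ascending) with
#' [mtm_fit()] and returns the BIC-minimizing candidate together with the
#' full table for elbow inspection.
#'
#' @param dataset a complete `mtm_dataset`.
#' @param candidates integer vector of candidate `n_c` values.
#' @param config an [mtm_fit_config()]; its `n_c` is overridden per
#'   candidate.
#' @return list with `n_c` (chosen), `table` (data.frame of candidate,
#'   bic, objective, converged), and `fits` (list of `mtm_fit`).
#' @export
select_n_clusters <- function(dataset, candidates, config) {
  candidates <- sort(unique(as.integer(candidates)))
  fits <- vector("list", length(candidates))
  bics <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    cfg <- config
    cfg$n_c <- candidates[i]
    fits[[i]] <- mtm_fit(dataset, cfg)
    bics[i] <- mtm_bic(dataset, fits[[i]]$model)
  }
  list(n_c = candidates[which.min(bics)],
       table = data.frame(n_c = candidates, bic = bics,
                          objective = vapply(fits, `[[`, numeric(1),
                                             "objective"),
                          converged = vapply(fits, `[[`, logical(1),
                                             "converged")),
       fits = fits)
}
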