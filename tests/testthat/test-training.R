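test_that("M-step recovers an exact linear emission from noise-free data", {
  set.seed(51)
  d <- 2; l <- 3
  H_true <- matrix(c(1, -0.5, 0.3, 0.8, -0.2, 0.6), d, l)
  trajs <- lapply(1:40, function(i) {
    T <- sample(2:4, 1)
    z <- matrix(rnorm(T * d), T)
    mtm_trajectory(z, z %*% H_true, subject_id = paste0("s", i))
  })
  ds <- mtm_dataset(trajs)
  model <- m_step(ds, rep(1L, 40), n_c = 1L)
  expect_lt(max(abs(model$clusters[[1]]$H - H_true)), 1e-6)
  ## residuals are exactly zero, so Lambda sits at its eigenvalue floor
  expect_lt(max(eigen(model$clusters[[1]]$Lambda)$values), 1e-8)
})

test_that("M-step with true labels recovers well-separated two-cluster parameters", {
  sc <- mtm_scenario(n_c = 2, n_d = 1000, separation = 5, seed = 9)
  co <- make_cohort(sc)
  model <- m_step(co$dataset, co$truth$labels, n_c = 2L)
  for (c in 1:2) {
    tt <- co$truth$model$clusters[[c]]
    ff <- model$clusters[[c]]
    expect_lt(max(abs(tt$A - ff$A)), 0.1)
    expect_lt(max(abs(tt$H - ff$H)), 0.1)
    expect_lt(max(abs(tt$S - ff$S)), 0.2)
    expect_lt(max(abs(tt$Gamma - ff$Gamma)), 0.2)
    expect_lt(max(abs(tt$Lambda - ff$Lambda)), 0.2)
  }
})

test_that("identical trajectories exercise the degenerate pseudo-inverse path with finite output", {
  z <- matrix(c(1, 1), 2, 1)
  x <- matrix(c(2, 2), 2, 1)
  trajs <- replicate(10, mtm_trajectory(z, x), simplify = FALSE)
  ds <- mtm_dataset(trajs)
  model <- suppressWarnings(m_step(ds, rep(1L, 10), n_c = 1L))
  p <- model$clusters[[1]]
  expect_true(all(vapply(p[c("m", "S", "A", "Gamma", "H", "Lambda")],
                         function(M) all(is.finite(M)), logical(1))))
  expect_lt(p$S[1, 1], 1e-8)  # floored near zero
})

test_that("hard E-step is the MAP rule with lowest-index ties", {
  co <- small_cohort(n_d = 100, n_c = 2, seed = 12)
  m1 <- m_step(co$dataset, rep(1L, 100), n_c = 1L)
  expect_true(all(hard_e_step(co$dataset, m1) == 1L))
  dup <- mtm_model(c(0.5, 0.5), list(m1$clusters[[1]], m1$clusters[[1]]))
  expect_true(all(hard_e_step(co$dataset, dup) == 1L))
})

test_that("hard E-step with the true model recovers true labels on separated data", {
  sc <- mtm_scenario(n_c = 2, n_d = 500, separation = 5, seed = 14)
  co <- make_cohort(sc)
  labels <- hard_e_step(co$dataset, co$truth$model)
  expect_gte(mean(labels == co$truth$labels), 0.99)
})

test_that("batched and factored complete-data likelihoods agree", {
  co <- small_cohort(n_d = 30, n_c = 3, seed = 15)
  model <- co$truth$model
  ll_batch <- mtm:::batch_complete_loglik(co$dataset, model)
  ll_slow <- t(vapply(co$dataset$trajectories, function(tr)
    vapply(model$clusters, function(p) complete_data_loglik(tr, p),
           numeric(1)), numeric(model$n_c)))
  expect_equal(ll_batch, ll_slow, tolerance = 1e-9)
})

test_that("EM converges on one-cluster data and the objective trace never decreases", {
  sc <- mtm_scenario(n_c = 1, n_d = 80, seed = 16)
  co <- make_cohort(sc)
  fit <- mtm_fit(co$dataset, mtm_fit_config(1L, n_restarts = 3, seed = 2))
  expect_true(fit$converged)
  ## n_c = 1: the fit is the closed-form single-model MLE
  direct <- m_step(co$dataset, rep(1L, 80), n_c = 1L)
  expect_equal(fit$objective,
               sum(mtm:::batch_complete_loglik(co$dataset, direct)),
               tolerance = 1e-8)
  for (tr in fit$restart_traces)
    expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
})

test_that("EM recovers two well-separated clusters with high ARI", {
  sc <- mtm_scenario(n_c = 2, n_d = 500, separation = 5, seed = 18)
  co <- make_cohort(sc)
  fit <- mtm_fit(co$dataset, mtm_fit_config(2L, n_restarts = 10, seed = 5))
  expect_gte(adjusted_rand(co$truth$labels, fit$labels), 0.9)
  for (tr in fit$restart_traces)
    expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
})

test_that("permuting an initialization permutes the model but not its objective", {
  co <- small_cohort(n_d = 120, n_c = 3, seed = 19)
  cfg <- mtm_fit_config(3L, n_restarts = 1, seed = 1)
  stats <- mtm:::stack_stats(co$dataset)
  lab0 <- mtm:::init_labels(mtm:::traj_summaries(co$dataset), 3L, 4L)
  perm <- c(3L, 1L, 2L)
  r1 <- mtm:::run_em(co$dataset, stats, lab0, cfg, 7L)
  r2 <- mtm:::run_em(co$dataset, stats, perm[lab0], cfg, 7L)
  expect_equal(r1$objective, r2$objective, tolerance = 1e-8)
})

test_that("training refuses incomplete trajectories, naming the subjects", {
  co <- small_cohort(n_d = 60, n_c = 2, seed = 20)
  ds <- apply_missingness(co$dataset, "mcar", mcar_rate = 0.2)
  expect_error(mtm_fit(ds, mtm_fit_config(2L, seed = 1)),
               "requires complete trajectories")
  expect_error(mtm_fit(subset_small(co$dataset, 1:5),
                       mtm_fit_config(2L, seed = 1)),
               "too few trajectories")
})

test_that("BIC parameter count matches the symbolic formula", {
  ## per cluster: d + d(d+1)/2 + d^2 + d(d+1)/2 + d*l + l(l+1)/2
  expect_equal(bic_param_count(1, 2, 4), 30)
  expect_equal(bic_param_count(4, 2, 4), 3 + 4 * 30)
})

test_that("restricting to one visit reduces hard EM to a structured Gaussian mixture", {
  sc <- mtm_scenario(n_c = 2, n_d = 150, separation = 4, seed = 23,
                     length_distribution = c("1" = 1))
  co <- make_cohort(sc)
  ds <- co$dataset
  Z <- t(vapply(ds$trajectories, function(tr) tr$states[1, ], numeric(2)))
  X <- t(vapply(ds$trajectories, function(tr) tr$observations[1, ],
                numeric(4)))
  lab0 <- mtm:::init_labels(mtm:::traj_summaries(ds), 2L, 3L)
  cfg <- mtm_fit_config(2L, n_restarts = 1, seed = 1)
  pkg <- mtm:::run_em(ds, mtm:::stack_stats(ds), lab0, cfg, 7L)
  ref <- oracle_hard_gmm(Z, X, lab0, 2L)
  expect_equal(pkg$labels, as.integer(ref$labels))
  expect_equal(pkg$objective, ref$objective, tolerance = 1e-6)
})

test_that("BIC selects the true number of clusters and the selector deduplicates", {
  sc <- mtm_scenario(n_c = 3, n_d = 240, separation = 5, seed = 24)
  co <- make_cohort(sc)
  cfg <- mtm_fit_config(1L, n_restarts = 4, seed = 3)
  sel <- select_n_clusters(co$dataset, c(2, 3, 3, 4, 2), cfg)
  expect_equal(sel$table$n_c, c(2L, 3L, 4L))
  expect_equal(sel$n_c, 3L)
  single <- select_n_clusters(co$dataset, 2L, cfg)
  expect_equal(single$n_c, 2L)
})
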