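test_that("marginalizing nothing reproduces the complete-data likelihood", {
  set.seed(8)
  for (rep in 1:20) {
    T <- sample(1:4, 1); d <- sample(1:3, 1); l <- sample(1:4, 1)
    p <- random_params(d, l)
    tr <- random_traj(T, d, l)
    expect_equal(marginal_loglik(tr, p), complete_data_loglik(tr, p),
                 tolerance = 1e-10)
  }
})

test_that("fully missing states integrate to the hand-derived joint of the observations", {
  ## d=l=1, standard parameters: (x1, x2) ~ N(0, [[2,1],[1,3]]), so the
  ## log-density at the origin is -log(2*pi) - log(5)/2
  p <- mtm_cluster_params(0, matrix(1), matrix(1), matrix(1), matrix(1),
                          matrix(1))
  tr <- mtm_trajectory(matrix(NA_real_, 2), matrix(c(0, 0), 2))
  expect_equal(marginal_loglik(tr, p), -log(2 * pi) - 0.5 * log(5),
               tolerance = 1e-10)
})

test_that("marginal likelihood matches the brute-force joint-Gaussian oracle under random masks", {
  set.seed(77)
  worst <- 0
  for (rep in 1:200) {
    T <- sample(1:4, 1); d <- sample(1:3, 1); l <- sample(1:4, 1)
    p <- random_params(d, l)
    tr <- random_masked_traj(T, d, l, p_miss = runif(1, 0.2, 0.7))
    err <- abs(marginal_loglik(tr, p) - oracle_loglik(tr, p))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-7)
})

test_that("chain rule holds: full = observed subset + conditional of the complement", {
  set.seed(13)
  for (rep in 1:50) {
    T <- sample(2:4, 1); d <- sample(1:3, 1); l <- sample(1:3, 1)
    p <- random_params(d, l)
    tr <- random_masked_traj(T, d, l, 0.5)
    full <- mtm_trajectory(tr$states, tr$observations,
                           matrix(TRUE, T, d), matrix(TRUE, T, l))
    full$states[is.na(full$states)] <- 0      # fill masked cells with
    full$observations[is.na(full$observations)] <- 0  # arbitrary values
    obs <- as.logical(t(cbind(tr$states_mask, tr$obs_mask)))
    if (all(obs)) next
    mom <- oracle_moments(p, T)
    vals <- as.numeric(t(cbind(full$states, full$observations)))
    lhs <- complete_data_loglik(full, p)
    rhs <- marginal_loglik(
      mtm_trajectory(full$states, full$observations,
                     tr$states_mask, tr$obs_mask), p) +
      oracle_conditional_loglik(mom, which(obs), which(!obs), vals)
    expect_equal(lhs, rhs, tolerance = 1e-7)
  }
})

test_that("per-cluster log-likelihood vector is consistent and symmetric", {
  p <- random_params_fixture()
  tr <- mtm_trajectory(matrix(rnorm(6), 3), matrix(rnorm(9), 3))
  m1 <- mtm_model(1, list(p))
  expect_equal(loglik_per_cluster(tr, m1),
               marginal_loglik(tr, p), tolerance = 1e-12)
  m2 <- mtm_model(c(0.5, 0.5), list(p, p))
  ll <- loglik_per_cluster(tr, m2)
  expect_equal(ll[1], ll[2], tolerance = 1e-12)
})

test_that("the generating cluster wins the likelihood comparison almost surely", {
  sc <- mtm_scenario(n_c = 2, n_d = 1, separation = 5, seed = 1)
  truth <- make_ground_truth(sc)
  model <- mtm_model(c(0.5, 0.5), truth$clusters[1:2],
                     truth$state_names, truth$obs_names)
  set.seed(31)
  wins <- vapply(1:200, function(i) {
    tr <- sample_trajectory(truth$clusters[[1]], sample(2:4, 1))
    ll <- loglik_per_cluster(tr, model)
    ll[1] > ll[2]
  }, logical(1))
  expect_gte(mean(wins), 0.99)
})

test_that("hard assignment follows log pi + loglik with lowest-index tie-breaking", {
  p <- random_params_fixture()
  tr <- sample_trajectory_seeded(p, 3, 17)
  eps <- 1e-6
  m_prior <- mtm_model(c(1 - eps, eps), list(p, p))
  asg <- mtm_assign(tr, m_prior)
  expect_equal(asg$cluster, 1L)
  m_tie <- mtm_model(c(0.5, 0.5), list(p, p))
  expect_equal(mtm_assign(tr, m_tie)$cluster, 1L)
})

test_that("posterior normalization matches the naive computation and stays finite at extreme spreads", {
  p <- random_params_fixture()
  tr <- sample_trajectory_seeded(p, 3, 18)
  p2 <- random_params(2, 3)
  m <- mtm_model(c(0.3, 0.7), list(p, p2))
  asg <- mtm_assign(tr, m)
  ll <- asg$loglik[1, ]
  naive <- m$pi * exp(ll) / sum(m$pi * exp(ll))
  expect_equal(asg$posterior[1, ], naive, tolerance = 1e-12)
  expect_equal(sum(asg$posterior[1, ]), 1, tolerance = 1e-9)
  ## spread of ~1e4 log units: log-domain arithmetic must not overflow
  tight <- mtm_cluster_params(p$m, p$S * 1e-8, p$A, p$Gamma * 1e-8, p$H,
                              p$Lambda * 1e-8)
  m_wide <- mtm_model(c(0.5, 0.5), list(tight, p))
  asg2 <- mtm_assign(tr, m_wide)
  expect_gt(abs(diff(asg2$loglik[1, ])), 1e3)
  expect_true(all(is.finite(asg2$posterior)))
  expect_equal(sum(asg2$posterior[1, ]), 1, tolerance = 1e-9)
})

test_that("empty trajectories are rejected", {
  p <- random_params_fixture()
  tr <- mtm_trajectory(matrix(NA_real_, 2, 2), matrix(NA_real_, 2, 3))
  expect_error(marginal_loglik(tr, p), "no observed data")
})
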