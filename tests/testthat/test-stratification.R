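## harmonization from constructed assignments: build a tiny model whose
## clusters separate three point masses, with diagnoses chosen to give
## known AD fractions per raw cluster
make_labeled_cohort <- function(ad_fractions, n_per = 50, seed = 1) {
  n_c <- length(ad_fractions)
  sc <- mtm_scenario(n_c = n_c, n_d = n_c * n_per, separation = 6,
                     pi = rep(1 / n_c, n_c), seed = seed,
                     diagnosis_probs = cbind(CN = 1 - ad_fractions,
                                             sMCI = 0, pMCI = 0,
                                             AD = ad_fractions))
  make_cohort(sc)
}

test_that("labels ascend with training-set AD fraction and ties keep raw order", {
  ## raw clusters get AD fractions (0.10, 0.50, 0.02): display order 3,1,2
  co <- make_labeled_cohort(c(0.10, 0.50, 0.02), n_per = 200, seed = 30)
  map <- harmonize_labels(co$truth$model, co$dataset)
  expect_equal(map$order, c(3L, 1L, 2L))
  expect_equal(map$labels, c("A", "B", "C"))
  expect_true(all(diff(map$ad_fraction[map$order]) >= 0))

  co_tie <- make_labeled_cohort(c(0, 0, 0), n_per = 30, seed = 31)
  map_tie <- harmonize_labels(co_tie$truth$model, co_tie$dataset)
  expect_equal(map_tie$order, 1:3)
})

test_that("harmonization is idempotent and the fallback ordering is configurable", {
  co <- make_labeled_cohort(c(0.3, 0.05), n_per = 100, seed = 32)
  map <- harmonize_labels(co$truth$model, co$dataset)
  harmonized <- apply_harmonization(co$truth$model, map)
  map2 <- harmonize_labels(harmonized, co$dataset)
  expect_equal(map2$order, seq_len(harmonized$n_c))

  ## strip diagnoses: fallback orders by cluster mean observation score
  ds_nodx <- mtm_dataset(lapply(co$dataset$trajectories, function(tr) {
    tr$diagnosis <- NA_character_
    tr
  }), co$dataset$state_names, co$dataset$obs_names)
  map_fb <- harmonize_labels(co$truth$model, ds_nodx)
  expect_true(map_fb$fallback_used)
  expect_error(harmonize_labels(co$truth$model, ds_nodx, fallback = "none"),
               "no diagnosis labels")
})

test_that("cross-validation predicts each subject exactly once and recovers clusters", {
  co <- small_cohort(n_d = 240, n_c = 4, seed = 33)
  cv <- suppressWarnings(
    cross_validate(co$dataset, mtm_fit_config(4L, n_restarts = 5, seed = 7),
                   k = 4L))
  expect_equal(nrow(cv$assignments), 240L)
  expect_equal(anyDuplicated(cv$assignments$subject_id), 0L)
  expect_true(all(cv$assignments$label %in% LETTERS[1:4]))
  expect_gte(adjusted_rand(co$truth$labels, cv$assignments$label), 0.85)
  expect_true(all(cv$stability >= 0 & cv$stability <= 3))
  ## well-separated data: stability mass concentrates at the top counts
  top <- sum(cv$stability >= cv$k - 3L) / length(cv$stability)
  expect_gte(top, 0.8)
  ## planted AD-enrichment: the last display label carries the highest
  ## AD fraction in (almost) every fold
  hi <- vapply(cv$fold_models, function(fm) {
    af <- fm$map$ad_fraction
    which.max(af) == fm$map$order[length(fm$map$order)]
  }, logical(1))
  expect_gte(mean(hi), 0.75)
})

test_that("the cognitive health index peaks at the healthy cluster's mean path", {
  co <- small_cohort(n_d = 200, n_c = 4, seed = 34)
  map <- harmonize_labels(co$truth$model, co$dataset)
  model <- apply_harmonization(co$truth$model, map)
  pA <- model$clusters[[1]]
  ## mean path of cluster A, fully observed
  T <- 3
  z <- matrix(NA_real_, T, 2)
  z[1, ] <- pA$m
  for (t in 2:T) z[t, ] <- drop(z[t - 1, , drop = FALSE] %*% pA$A)
  x <- z %*% pA$H
  mean_traj <- mtm_trajectory(z, x)
  shifted <- mtm_trajectory(z + 5 * sqrt(diag(pA$S)), x)
  expect_gt(cognitive_health_index(mean_traj, model),
            cognitive_health_index(shifted, model))
  ## normalized variant divides by informative visits
  expect_equal(cognitive_health_index(mean_traj, model, normalize = TRUE),
               cognitive_health_index(mean_traj, model) / T)
})

test_that("index under fully missing states matches the shared marginalization oracle", {
  p <- mtm_cluster_params(0, matrix(1), matrix(1), matrix(1), matrix(1),
                          matrix(1))
  model <- mtm_model(1, list(p), labels = "A")
  tr <- mtm_trajectory(matrix(NA_real_, 2), matrix(c(0, 0), 2))
  expect_equal(cognitive_health_index(tr, model),
               -log(2 * pi) - 0.5 * log(5), tolerance = 1e-10)
})

test_that("the index separates healthy-analog from decline-analog subjects", {
  co <- small_cohort(n_d = 400, n_c = 4, seed = 35)
  map <- harmonize_labels(co$truth$model, co$dataset)
  model <- apply_harmonization(co$truth$model, map)
  idx <- vapply(co$dataset$trajectories, cognitive_health_index,
                numeric(1), model = model, normalize = TRUE)
  ## truth cluster 1 is the healthy analog, cluster 4 the decline analog
  healthy <- idx[co$truth$labels == 1L]
  decline <- idx[co$truth$labels == 4L]
  tt <- t.test(healthy, decline, alternative = "greater")
  expect_lt(tt$p.value, 0.001)
})

test_that("cluster profiling reproduces textbook chi-square results", {
  ## 4 clusters x 4 diagnoses: df = (4-1)(4-1) = 9
  set.seed(36)
  lab <- sample(LETTERS[1:4], 400, replace = TRUE)
  dx <- sample(c("CN", "sMCI", "pMCI", "AD"), 400, replace = TRUE)
  prof <- suppressWarnings(profile_clusters(lab, dx))
  expect_equal(prof$df, 9)
  ## hand-computed 2x2: [[10,0],[0,10]] gives chi-square = 20, df = 1
  prof2 <- suppressWarnings(
    profile_clusters(rep(c("A", "B"), each = 10),
                     rep(c("CN", "AD"), each = 10)))
  expect_equal(prof2$statistic, 20, tolerance = 1e-12)
  expect_equal(prof2$df, 1)
  ## null calibration: independent labels give chi-square/df near 1
  set.seed(37)
  lab0 <- sample(LETTERS[1:4], 10000, replace = TRUE)
  dx0 <- sample(c("CN", "sMCI", "pMCI", "AD"), 10000, replace = TRUE)
  prof0 <- profile_clusters(lab0, dx0)
  expect_lt(abs(prof0$statistic / prof0$df - 1), 1.5)
  expect_error(profile_clusters(lab, dx[1:10]), "equal length")
})

test_that("agreement percentages and drift tables behave at the extremes", {
  a <- c("A", "B", "C", "D")
  expect_equal(agreement(a, a)$percent, 100)
  ag0 <- agreement(a, c("B", "C", "D", "A"))
  expect_equal(ag0$percent, 0)
  expect_equal(ag0$toward_healthier, 1L)  # D -> A
  expect_equal(ag0$less_healthy, 3L)
  expect_error(agreement(a, a, subjects_1 = 1:4, subjects_2 = 4:1),
               "subject mismatch")
})

test_that("masked assignments agree with full-data assignments above chance", {
  co <- small_cohort(n_d = 300, n_c = 4, seed = 38)
  fit <- mtm_fit(co$dataset, mtm_fit_config(4L, n_restarts = 5, seed = 8))
  map <- harmonize_labels(fit$model, co$dataset)
  full <- mtm_assign(co$dataset, fit$model, map)
  first <- mtm_assign(apply_missingness(co$dataset, "first_visit_only"),
                      fit$model, map)
  cogn <- mtm_assign(apply_missingness(co$dataset, "states_absent"),
                     fit$model, map)
  n <- 300; chance <- 0.25
  margin <- 3 * sqrt(chance * (1 - chance) / n)
  ag_first <- agreement(full$label, first$label)
  ag_cogn <- agreement(full$label, cogn$label)
  expect_gt(ag_first$percent / 100, chance + margin)
  expect_gt(ag_cogn$percent / 100, chance + margin)
  ## drift table is computed (direction is an empirical matter, not asserted)
  expect_s3_class(ag_cogn$drift, "table")
})
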