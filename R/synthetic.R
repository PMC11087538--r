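#' Scenario configuration for synthetic cohorts
#'
#' Describes a ground-truth mixture of state-space models plus the cohort
#' structure (sample size, trajectory-length distribution, missingness
#' regime, diagnosis model) from which [make_cohort()] simulates. Defaults
#' emulate a research cohort of 571 subjects with 2-4 roughly biennial
#' assessments (lengths 2/3/4 in proportions 337/194/40), 2 biomarker
#' states, 4 cognitive scores and 4 clusters.
#'
#' `separation` is the distance, in initial-state standard-deviation units
#' (`sqrt(state_noise)`), between adjacent cluster state means along the
#' severity axis. The diagnosis model draws each subject's clinical label
#' from a per-cluster categorical distribution over CN/sMCI/pMCI/AD whose
#' AD mass increases monotonically with cluster severity, so
#' "cluster explains diagnosis" is recoverable by construction but
#' imperfect, as in real cohorts.
#'
#' @param n_c,d,l number of clusters, state and observation dimensions.
#' @param n_d number of subjects.
#' @param length_distribution named probability vector over trajectory
#'   lengths.
#' @param separation adjacent-cluster mean separation in SD units.
#' @param state_noise initial-state variance (per coordinate).
#' @param trans_noise,obs_noise transition / emission noise variances.
#' @param pi mixture weights.
#' @param missingness regime applied to the sampled cohort (see
#'   [apply_missingness()]).
#' @param mcar_rate,obs_panel regime parameters.
#' @param diagnosis_probs optional n_c x 4 matrix of per-cluster
#'   probabilities over `c("CN","sMCI","pMCI","AD")`; default monotone.
#' @param seed RNG seed; same seed implies a byte-identical cohort.
#' @return an object of class `mtm_scenario`.
#' @export
mtm_scenario <- function(n_c = 4L, d = 2L, l = 4L, n_d = 571L,
                         length_distribution = c("2" = 337, "3" = 194,
                                                 "4" = 40) / 571,
                         separation = 5, state_noise = 1,
                         trans_noise = 0.25, obs_noise = 0.25,
                         pi = rep(1 / n_c, n_c),
                         missingness = "none", mcar_rate = 0.3,
                         obs_panel = NULL, diagnosis_probs = NULL,
                         seed = 1L) {
  stopifnot(n_c >= 1L, d >= 1L, l >= 1L, n_d >= 1L,
            separation >= 0, state_noise > 0, trans_noise > 0,
            obs_noise > 0, mcar_rate >= 0, mcar_rate <= 1)
  if (is.null(diagnosis_probs))
    diagnosis_probs <- default_diagnosis_probs(n_c)
  diagnosis_probs <- as.matrix(diagnosis_probs)
  if (nrow(diagnosis_probs) != n_c || ncol(diagnosis_probs) != 4L ||
      any(diagnosis_probs < 0) ||
      any(abs(rowSums(diagnosis_probs) - 1) > 1e-8))
    stop("diagnosis_probs must be n_c x 4 with rows summing to 1")
  colnames(diagnosis_probs) <- c("CN", "sMCI", "pMCI", "AD")
  structure(list(n_c = as.integer(n_c), d = as.integer(d), l = as.integer(l),
                 n_d = as.integer(n_d),
                 length_distribution = length_distribution,
                 separation = separation, state_noise = state_noise,
                 trans_noise = trans_noise, obs_noise = obs_noise,
                 pi = as.numeric(pi), missingness = missingness,
                 mcar_rate = mcar_rate, obs_panel = obs_panel,
                 diagnosis_probs = diagnosis_probs, seed = as.integer(seed)),
            class = "mtm_scenario")
}

## monotone per-cluster diagnosis distribution: AD and pMCI mass rise with
## cluster severity, the remainder splits between CN and sMCI with the CN
## share falling
#' @noRd
default_diagnosis_probs <- function(n_c) {
  if (n_c == 1L) {
    p_ad <- 0.2; p_pmci <- 0.05; cn_share <- 0.5
  } else {
    p_ad <- seq(0.02, 0.60, length.out = n_c)
    p_pmci <- seq(0.01, 0.15, length.out = n_c)
    cn_share <- seq(0.75, 0.20, length.out = n_c)
  }
  rem <- 1 - p_ad - p_pmci
  cbind(CN = rem * cn_share, sMCI = rem * (1 - cn_share),
        pMCI = p_pmci, AD = p_ad)
}

#' Deterministic ground-truth model for a scenario
#'
#' Cluster state means sit on a severity axis (direction alternating in
#' sign across coordinates, mimicking grey matter falling while amyloid
#' burden rises), with adjacent clusters `separation` SD apart and the
#' healthiest cluster farthest from the origin. Dynamics are contractive
#' (`A_c = rho_c I` plus a small cluster-alternating upper-triangular
#' coupling; spectral radius < 1), with severer clusters decaying faster
#' toward the end-stage origin. Emissions share a base read-out matrix plus
#' a cluster-specific perturbation; all noise covariances are scaled
#' identities.
#'
#' @param scenario an [mtm_scenario()].
#' @return an [mtm_model()].
#' @export
make_ground_truth <- function(scenario) {
  stopifnot(inherits(scenario, "mtm_scenario"))
  n_c <- scenario$n_c; d <- scenario$d; l <- scenario$l
  sdv <- sqrt(scenario$state_noise)
  u <- rep_len(c(1, -1), d) / sqrt(d)   # severity axis direction
  H0 <- outer(seq_len(d), seq_len(l), function(i, j)
    ifelse((j - i) %% d == 0, 0.8, 0.3))
  if (l > 1L) H0[, l] <- -H0[, l]       # one inverted-scale score
  K <- matrix(rep_len(c(1, -1), d * l), d, l)
  rho <- if (n_c == 1L) 0.9 else seq(0.98, 0.80, length.out = n_c)
  N <- matrix(0, d, d)
  if (d > 1L) N[cbind(seq_len(d - 1L), 2:d)] <- 1
  clusters <- lapply(seq_len(n_c), function(c) {
    m <- (n_c - c + 1L) * scenario$separation * sdv * u
    A <- rho[c] * diag(d) + 0.05 * (-1)^c * N
    H <- H0 + 0.05 * (c - 1L) * K
    mtm_cluster_params(m = m, S = scenario$state_noise * diag(d), A = A,
                       Gamma = scenario$trans_noise * diag(d), H = H,
                       Lambda = scenario$obs_noise * diag(l))
  })
  state_names <- if (d == 2L) c("gm_density", "amyloid") else
    paste0("state", seq_len(d))
  obs_names <- if (l == 4L) c("mem", "ef", "moca", "adas13") else
    paste0("obs", seq_len(l))
  mtm_model(scenario$pi, clusters, state_names, obs_names)
}

#' Simulate a full synthetic cohort
#'
#' Seeds the RNG from the scenario, samples the cohort from the ground
#' truth, applies the missingness regime, and draws a clinical diagnosis
#' for each subject from its true cluster's categorical distribution.
#' Ground truth (model, true cluster labels, scenario) is returned
#' separately from the dataset.
#'
#' @param scenario an [mtm_scenario()].
#' @return list with `dataset` (an `mtm_dataset`, masks applied, diagnoses
#'   attached) and `truth` (list: `model`, `labels`, `scenario`).
#' @export
make_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "mtm_scenario"))
  set.seed(scenario$seed)
  truth_model <- make_ground_truth(scenario)
  samp <- sample_dataset(truth_model, scenario$n_d,
                         scenario$length_distribution)
  dx_levels <- colnames(scenario$diagnosis_probs)
  trajs <- samp$dataset$trajectories
  for (i in seq_along(trajs)) {
    p <- scenario$diagnosis_probs[samp$labels[i], ]
    trajs[[i]]$diagnosis <- sample(dx_levels, 1L, prob = p)
  }
  ds <- mtm_dataset(trajs, samp$dataset$state_names,
                    samp$dataset$obs_names)
  ds <- apply_missingness(ds, scenario$missingness,
                          mcar_rate = scenario$mcar_rate,
                          obs_panel = scenario$obs_panel)
  list(dataset = ds,
       truth = list(model = truth_model, labels = samp$labels,
                    scenario = scenario))
}

#' Named scenario preset: research-cohort-like default
#'
#' 571 subjects, trajectory lengths 2/3/4 in proportions 337/194/40,
#' 4 clusters, d = 2 biomarker states, l = 4 cognitive scores, adjacent
#' clusters 5 SD apart.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [mtm_scenario()].
#' @return an [mtm_scenario()].
#' @export
scenario_adni_like <- function(seed = 1L, ...) {
  mtm_scenario(seed = seed, ...)
}
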