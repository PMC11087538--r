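#' Harmonize cluster labels alphabetically by training-set AD fraction
#'
#' Unsupervised mixtures are identified only up to a permutation of
#' component indices, so models trained on different folds need their
#' labels aligned before any cross-fold comparison. Clusters are assigned
#' display labels "A", "B", ... in ascending order of the fraction of their
#' assigned training subjects carrying an "AD" diagnosis (ties: ascending
#' "pMCI" fraction, then raw index). When no diagnosis labels exist the
#' configurable fallback orders clusters by the cluster mean of each
#' member's mean observation score (descending by default, so that under
#' the higher-score-is-healthier convention "A" is the healthiest-looking
#' cluster).
#'
#' @param model an [mtm_model()].
#' @param dataset the training `mtm_dataset` (diagnoses read from it).
#' @param assignment optional precomputed [mtm_assign()] result on
#'   `dataset` (saves recomputation).
#' @param fallback `"mean_observation"` or `"none"` (error when no
#'   diagnoses are present).
#' @param fallback_decreasing order of the fallback score; `TRUE` labels
#'   the highest-scoring cluster "A".
#' @return an object of class `mtm_harmonization`: list with `order` (raw
#'   cluster index receiving each successive label), `labels`,
#'   `ad_fraction`, `pmci_fraction`, `fallback_used`.
#' @export
harmonize_labels <- function(model, dataset, assignment = NULL,
                             fallback = c("mean_observation", "none"),
                             fallback_decreasing = TRUE) {
  fallback <- match.arg(fallback)
  if (is.null(assignment)) assignment <- mtm_assign(dataset, model)
  cl <- assignment$cluster
  n_c <- model$n_c
  dg <- diagnoses(dataset)
  have_dx <- any(!is.na(dg))
  ad_frac <- pmci_frac <- rep(NA_real_, n_c)
  fallback_used <- FALSE
  if (have_dx) {
    for (c in seq_len(n_c)) {
      members <- which(cl == c & !is.na(dg))
      ad_frac[c] <- if (length(members))
        mean(dg[members] == "AD") else 0
      pmci_frac[c] <- if (length(members))
        mean(dg[members] == "pMCI") else 0
    }
    ord <- order(ad_frac, pmci_frac, seq_len(n_c))
  } else if (fallback == "mean_observation") {
    fallback_used <- TRUE
    score <- vapply(seq_len(n_c), function(c) {
      members <- which(cl == c)
      if (!length(members)) return(NA_real_)
      mean(vapply(dataset$trajectories[members], function(tr)
        mean(tr$observations[tr$obs_mask]), numeric(1)))
    }, numeric(1))
    ord <- order(if (fallback_decreasing) -score else score,
                 seq_len(n_c))
  } else {
    stop("no diagnosis labels present and fallback disabled")
  }
  structure(list(order = as.integer(ord), labels = LETTERS[seq_len(n_c)],
                 ad_fraction = ad_frac, pmci_fraction = pmci_frac,
                 fallback_used = fallback_used),
            class = "mtm_harmonization")
}

#' @export
print.mtm_harmonization <- function(x, ...) {
  cat("<mtm_harmonization>\n")
  for (k in seq_along(x$order))
    cat(sprintf("  %s <- raw cluster %d (AD fraction %s)\n", x$labels[k],
                x$order[k],
                ifelse(is.na(x$ad_fraction[x$order[k]]), "n/a",
                       sprintf("%.3f", x$ad_fraction[x$order[k]]))))
  invisible(x)
}

#' Reorder a model's clusters according to a harmonization map
#'
#' Returns an equivalent model whose clusters are permuted into display
#' order and carry labels "A", "B", ...; harmonizing the result again
#' yields the identity map.
#'
#' @param model an [mtm_model()].
#' @param map an [harmonize_labels()] result.
#' @return an [mtm_model()] with `labels` set.
#' @export
apply_harmonization <- function(model, map) {
  mtm_model(model$pi[map$order], model$clusters[map$order],
            model$state_names, model$obs_names, labels = map$labels)
}

#' Cognitive health index
#'
#' The log-likelihood of a subject's available data under the harmonized
#' "A" (healthiest) cluster's state-space model, computed by exact
#' marginalization so any missingness pattern is allowed. The index is
#' defined up to an additive constant and is length-dependent (each visit
#' contributes likelihood terms); set `normalize = TRUE` to divide by the
#' number of visits with at least one observed cell. In cross-validation
#' the index must come from the fold model that held the subject out
#' ([cross_validate()] does this).
#'
#' @param traj an [mtm_trajectory()].
#' @param model an [mtm_model()] (harmonized, or accompanied by `map`).
#' @param map optional [harmonize_labels()] result.
#' @param normalize divide by the number of informative visits.
#' @return scalar index.
#' @export
cognitive_health_index <- function(traj, model, map = NULL,
                                   normalize = FALSE) {
  display <- display_labels(model, map)
  if (is.null(display))
    stop("model is not harmonized; supply a harmonization map")
  a <- which(display == "A")
  if (!length(a)) stop("no cluster carries label \"A\"")
  idx <- marginal_loglik(traj, model$clusters[[a[1L]]])
  if (normalize) {
    informative <- sum(rowSums(traj$states_mask) + rowSums(traj$obs_mask) > 0)
    idx <- idx / informative
  }
  idx
}

#' Profile clusters against clinical diagnoses
#'
#' Builds the cluster-by-diagnosis contingency table, the per-cluster
#' conditional diagnosis distributions, and the Pearson chi-square test of
#' independence (no continuity correction; `chisq.test` warns when expected
#' cell counts fall below 5). Empty rows/columns are dropped with a
#' warning.
#'
#' @param labels cluster labels (display letters or raw indices).
#' @param dx diagnosis labels, same length.
#' @return list with `table`, `proportions` (rows sum to 1), `statistic`,
#'   `df`, `p_value`.
#' @export
profile_clusters <- function(labels, dx) {
  if (length(labels) != length(dx))
    stop("labels and diagnoses must have equal length")
  keep <- !is.na(labels) & !is.na(dx)
  tab <- table(cluster = labels[keep], diagnosis = dx[keep])
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warning("empty margins collapsed", call. = FALSE)
    tab <- tab[rowSums(tab) > 0L, colSums(tab) > 0L, drop = FALSE]
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected cell counts below 5; chi-square approximation may be poor",
            call. = FALSE)
  list(table = tab, proportions = prop.table(tab, 1L),
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Agreement between two harmonized labelings of the same subjects
#'
#' Percent of subjects carrying identical display labels, plus a signed
#' drift table: for each subject the rank of the second label minus the
#' rank of the first (ranks in the sorted label alphabet), so negative
#' drift means movement toward "A" (the healthier direction under the
#' harmonization convention).
#'
#' @param labels_1,labels_2 label vectors over the same subjects, in the
#'   same order.
#' @param subjects_1,subjects_2 optional subject-id vectors; when given
#'   they must match element-wise.
#' @return list with `percent`, `n`, `drift` (table of signed rank
#'   differences), `toward_healthier`, `same`, `less_healthy` (counts).
#' @export
agreement <- function(labels_1, labels_2,
                      subjects_1 = NULL, subjects_2 = NULL) {
  if (length(labels_1) != length(labels_2))
    stop("labelings must cover the same subjects")
  if (!is.null(subjects_1) || !is.null(subjects_2)) {
    if (is.null(subjects_1) || is.null(subjects_2) ||
        !identical(as.character(subjects_1), as.character(subjects_2)))
      stop("subject mismatch between the two labelings")
  }
  l1 <- as.character(labels_1); l2 <- as.character(labels_2)
  lev <- sort(unique(c(l1, l2)))
  dr <- match(l2, lev) - match(l1, lev)
  list(percent = 100 * mean(l1 == l2), n = length(l1),
       drift = table(drift = dr),
       toward_healthier = sum(dr < 0L), same = sum(dr == 0L),
       less_healthy = sum(dr > 0L))
}

## deterministic fold split, stratified by diagnosis when present
#' @noRd
make_folds <- function(dx, k, seed) {
  set.seed(seed)
  n <- length(dx)
  fold <- integer(n)
  strata <- if (any(!is.na(dx))) dx else rep("all", n)
  strata[is.na(strata)] <- ".na"
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' K-fold cross-validation of the trajectory mixture
#'
#' Splits subjects into `k` folds (stratified by diagnosis when labels
#' exist, seed-controlled), trains on each complement, harmonizes each fold
#' model's labels by training-set AD fraction, and assigns each held-out
#' subject with the unique model that did not see it — so every subject
#' receives exactly one cross-validated label and index. A stability
#' histogram counts, for each subject, how many of the `k - 1` fold models
#' trained on it agree with its held-out label.
#'
#' @param dataset a complete `mtm_dataset`.
#' @param config an [mtm_fit_config()].
#' @param k number of folds.
#' @param fallback,fallback_decreasing passed to [harmonize_labels()].
#' @return an object of class `mtm_cv`: list with `assignments`
#'   (data.frame: subject_id, fold, cluster_raw, label, index,
#'   index_per_visit, diagnosis), `fold_models` (list of
#'   `list(model, map)`), `stability` (per-subject agreement counts),
#'   `stability_histogram`, `contingency`, `chisq`, `k`, `seed`.
#' @export
cross_validate <- function(dataset, config, k = 10L,
                           fallback = "mean_observation",
                           fallback_decreasing = TRUE) {
  n <- length(dataset$trajectories)
  min_size <- as.integer(config$min_size %||% (dataset$d + dataset$l + 1L))
  if (n < k * config$n_c * min_size / (k - 1))
    stop("dataset too small for ", k, "-fold cross-validation at this n_c")
  dx <- diagnoses(dataset)
  fold <- make_folds(dx, k, config$seed)
  fold_models <- vector("list", k)
  label <- character(n); cluster_raw <- integer(n)
  index <- numeric(n); index_pv <- numeric(n)
  for (f in seq_len(k)) {
    train <- subset_dataset(dataset, fold != f)
    fit <- mtm_fit(train, config)
    map <- harmonize_labels(fit$model, train,
                            fallback = fallback,
                            fallback_decreasing = fallback_decreasing)
    fold_models[[f]] <- list(model = fit$model, map = map)
    test_idx <- which(fold == f)
    asg <- mtm_assign(subset_dataset(dataset, test_idx), fit$model, map)
    cluster_raw[test_idx] <- asg$cluster
    label[test_idx] <- asg$label
    index[test_idx] <- asg$index
    index_pv[test_idx] <- asg$index / asg$n_visits
  }
  ## stability: score every subject under every fold model trained on it
  all_labels <- matrix(NA_character_, n, k)
  for (f in seq_len(k)) {
    asg <- mtm_assign(dataset, fold_models[[f]]$model, fold_models[[f]]$map)
    all_labels[, f] <- asg$label
  }
  stability <- vapply(seq_len(n), function(i) {
    sum(all_labels[i, -fold[i]] == label[i])
  }, integer(1))
  prof <- if (any(!is.na(dx))) profile_clusters(label, dx) else NULL
  structure(list(
    assignments = data.frame(subject_id = subject_ids(dataset),
                             fold = fold, cluster_raw = cluster_raw,
                             label = label, index = index,
                             index_per_visit = index_pv, diagnosis = dx,
                             stringsAsFactors = FALSE),
    fold_models = fold_models, stability = stability,
    stability_histogram = table(factor(stability, levels = 0:(k - 1L))),
    contingency = prof$table, chisq = prof[c("statistic", "df", "p_value")],
    k = k, seed = config$seed),
    class = "mtm_cv")
}

#' @export
print.mtm_cv <- function(x, ...) {
  cat(sprintf("<mtm_cv> %d-fold, %d subjects\n", x$k, nrow(x$assignments)))
  print(table(x$assignments$label))
  if (!is.null(x$chisq$statistic))
    cat(sprintf("  cluster x diagnosis: chi-square(%d) = %.2f, p = %.3g\n",
                x$chisq$df, x$chisq$statistic, x$chisq$p_value))
  invisible(x)
}
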