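#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same subjects:
#' 1 for identical partitions, approximately 0 for independent ones.
#'
#' @param labels_true,labels_pred label vectors of equal length (any
#'   atomic type).
#' @return scalar ARI in `[-1, 1]`.
#' @export
adjusted_rand <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("labelings must have equal length")
  tab <- table(labels_true, labels_pred)
  n <- sum(tab)
  comb2 <- function(v) sum(choose(v, 2))
  a <- comb2(rowSums(tab)); b <- comb2(colSums(tab))
  idx <- comb2(as.numeric(tab))
  expected <- a * b / choose(n, 2)
  maximum <- (a + b) / 2
  if (abs(maximum - expected) < .Machine$double.eps^0.5)
    return(if (abs(idx - expected) < .Machine$double.eps^0.5) 1 else 0)
  (idx - expected) / (maximum - expected)
}

## best injective matching of fitted clusters onto true clusters by
## assignment overlap, via exact enumeration (n_c is small)
#' @noRd
best_matching <- function(labels_true, labels_fit, k_true, k_fit) {
  tab <- matrix(0, k_true, k_fit)
  tt <- table(factor(labels_true, levels = seq_len(k_true)),
              factor(labels_fit, levels = seq_len(k_fit)))
  tab[] <- tt
  if (k_true <= k_fit) {
    perms <- all_perms(k_fit)
    best <- NULL; best_ov <- -1
    for (r in seq_len(nrow(perms))) {
      pm <- perms[r, seq_len(k_true)]
      ov <- sum(tab[cbind(seq_len(k_true), pm)])
      if (ov > best_ov) { best_ov <- ov; best <- pm }
    }
    list(true = seq_len(k_true), fitted = best, overlap = best_ov)
  } else {
    m <- best_matching(labels_fit, labels_true, k_fit, k_true)
    list(true = m$fitted, fitted = m$true, overlap = m$overlap)
  }
}

#' Match fitted clusters to truth and score parameter recovery
#'
#' Finds the overlap-maximizing injective matching between true and fitted
#' cluster indices (exact enumeration over permutations — equivalent to the
#' assignment-problem optimum at these sizes), then reports max-absolute
#' and Frobenius errors per parameter matrix for each matched pair. A
#' cluster-count mismatch is scored against the best injective matching and
#' flagged.
#'
#' @param truth,fitted [mtm_model()] objects.
#' @param labels_true,labels_fit cluster assignments of the same subjects
#'   under truth and fit (used to build the overlap table).
#' @return list with `matching` (data.frame true/fitted), `errors`
#'   (data.frame: true_cluster, matrix, max_abs, frobenius),
#'   `n_c_mismatch`.
#' @export
match_and_score_params <- function(truth, fitted, labels_true, labels_fit) {
  m <- best_matching(labels_true, labels_fit, truth$n_c, fitted$n_c)
  mats <- c("m", "S", "A", "Gamma", "H", "Lambda")
  rows <- list()
  for (i in seq_along(m$true)) {
    pt <- truth$clusters[[m$true[i]]]
    pf <- fitted$clusters[[m$fitted[i]]]
    for (nm in mats) {
      dmat <- as.matrix(pt[[nm]]) - as.matrix(pf[[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        true_cluster = m$true[i], fitted_cluster = m$fitted[i],
        matrix = nm, max_abs = max(abs(dmat)),
        frobenius = sqrt(sum(dmat^2)))
    }
  }
  list(matching = data.frame(true = m$true, fitted = m$fitted),
       errors = do.call(rbind, rows),
       n_c_mismatch = truth$n_c != fitted$n_c)
}

#' Rank-based AUC of an index against a binary outcome
#'
#' Mann-Whitney form: the probability that a randomly chosen positive
#' subject has a higher index than a randomly chosen negative one, with
#' ties averaged. Equivalent to the area under the empirical ROC curve.
#'
#' @param index numeric scores.
#' @param outcome logical (or 0/1) vector; `TRUE` is the positive class.
#' @return scalar AUC in `[0, 1]`.
#' @export
index_auc <- function(index, outcome) {
  outcome <- as.logical(outcome)
  if (length(index) != length(outcome))
    stop("index and outcome must have equal length")
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0L || n0 == 0L)
    stop("outcome must contain both classes")
  r <- rank(index)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
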