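#' Parameters of one mixture component (one state-space model)
#'
#' Row-vector convention throughout: the next-state mean is `z[t-1] %*% A`
#' and the observation mean is `z[t] %*% H`, so `A` is d x d and `H` is
#' d x l. `m`/`S` are the mean and covariance of the first biomarker
#' measurement, `A`/`Gamma` govern the biomarker dynamics, and `H`/`Lambda`
#' describe how cognitive scores read out the current biomarker state.
#'
#' @param m length-d numeric vector, initial-state mean.
#' @param S d x d symmetric positive-definite initial-state covariance.
#' @param A d x d state-transition matrix.
#' @param Gamma d x d symmetric positive-definite transition noise covariance.
#' @param H d x l emission matrix.
#' @param Lambda l x l symmetric positive-definite emission noise covariance.
#' @return an object of class `mtm_cluster_params`.
#' @export
mtm_cluster_params <- function(m, S, A, Gamma, H, Lambda) {
  m <- as.numeric(m)
  S <- as.matrix(S); A <- as.matrix(A); Gamma <- as.matrix(Gamma)
  H <- as.matrix(H); Lambda <- as.matrix(Lambda)
  d <- length(m); l <- ncol(H)
  if (!all(dim(S) == d) || !all(dim(A) == d) || !all(dim(Gamma) == d))
    stop("S, A, Gamma must all be d x d with d = length(m)")
  if (nrow(H) != d) stop("H must be d x l (row-vector convention z %*% H)")
  if (!all(dim(Lambda) == l)) stop("Lambda must be l x l with l = ncol(H)")
  for (nm in c("S", "Gamma", "Lambda")) {
    M <- get(nm)
    if (!is_symmetric_tol(M, 1e-8))
      stop(nm, " must be symmetric (tolerance 1e-8)")
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("matrix not positive definite: ", nm)
  }
  structure(list(m = m, S = S, A = A, Gamma = Gamma, H = H, Lambda = Lambda,
                 d = d, l = l),
            class = "mtm_cluster_params")
}

#' @export
print.mtm_cluster_params <- function(x, ...) {
  cat(sprintf("<mtm_cluster_params> d=%d, l=%d\n", x$d, x$l))
  invisible(x)
}

#' A fitted (or constructed) mixture of state-space models
#'
#' @param pi length-`n_c` mixture weights (non-negative, summing to 1).
#' @param clusters list of [mtm_cluster_params()] sharing dimensions (d, l).
#' @param state_names,obs_names optional feature names.
#' @param labels optional display labels (e.g. `"A".."D"`) attached after
#'   harmonization; `NULL` until then.
#' @return an object of class `mtm_model`.
#' @export
mtm_model <- function(pi, clusters, state_names = NULL, obs_names = NULL,
                      labels = NULL) {
  pi <- as.numeric(pi)
  if (length(clusters) != length(pi))
    stop("length(clusters) must equal length(pi)")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-12)
    stop("pi entries must be >= 0 and sum to 1 (tolerance 1e-12)")
  d <- clusters[[1L]]$d; l <- clusters[[1L]]$l
  ok <- vapply(clusters, function(p)
    inherits(p, "mtm_cluster_params") && p$d == d && p$l == l, logical(1))
  if (!all(ok)) stop("all clusters must be mtm_cluster_params sharing (d, l)")
  if (!is.null(labels) && length(labels) != length(pi))
    stop("labels must have one entry per cluster")
  structure(list(n_c = length(pi), pi = pi, clusters = clusters,
                 d = d, l = l,
                 state_names = as.character(state_names %||%
                                              paste0("state", seq_len(d))),
                 obs_names = as.character(obs_names %||%
                                            paste0("obs", seq_len(l))),
                 labels = labels),
            class = "mtm_model")
}

#' @export
print.mtm_model <- function(x, ...) {
  cat(sprintf("<mtm_model> %d clusters, d=%d, l=%d\n", x$n_c, x$d, x$l))
  cat("  pi:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  if (!is.null(x$labels))
    cat("  labels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' @noRd
check_traj_dims <- function(traj, params) {
  if (ncol(traj$states) != params$d || ncol(traj$observations) != params$l)
    stop(sprintf(
      "dimension mismatch: trajectory is (d=%d, l=%d), parameters are (d=%d, l=%d)",
      ncol(traj$states), ncol(traj$observations), params$d, params$l))
  invisible(TRUE)
}
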