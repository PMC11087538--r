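#' Construct a single subject trajectory
#'
#' A trajectory holds one subject's time-ordered biomarker states (T x d)
#' and cognitive observations (T x l), each with a boolean observed-mask of
#' identical shape. The mask is authoritative: the value stored in a
#' masked-out cell (conventionally `NA`) is ignored by every likelihood
#' computation. Visits are equally spaced indices t = 1..T; calendar dates
#' are not modeled.
#'
#' @param states numeric T x d matrix of biomarker values.
#' @param observations numeric T x l matrix of cognitive scores.
#' @param states_mask,obs_mask logical matrices of the same shapes; default
#'   `!is.na(.)`.
#' @param subject_id opaque identifier.
#' @param diagnosis optional categorical label (e.g. "CN", "sMCI", "pMCI",
#'   "AD"), used only for profiling and label harmonization, never inside a
#'   likelihood.
#' @return an object of class `mtm_trajectory`.
#' @export
mtm_trajectory <- function(states, observations,
                           states_mask = NULL, obs_mask = NULL,
                           subject_id = "s1", diagnosis = NA_character_) {
  states <- as.matrix(states)
  observations <- as.matrix(observations)
  if (nrow(states) != nrow(observations))
    stop("states and observations must have the same number of visits T")
  T_ <- nrow(states)
  if (T_ < 1L) stop("trajectory must have T >= 1 visits")
  if (is.null(states_mask)) states_mask <- !is.na(states)
  if (is.null(obs_mask)) obs_mask <- !is.na(observations)
  states_mask <- matrix(as.logical(states_mask), nrow(states), ncol(states))
  obs_mask <- matrix(as.logical(obs_mask),
                     nrow(observations), ncol(observations))
  if (!identical(dim(states_mask), dim(states)) ||
      !identical(dim(obs_mask), dim(observations)))
    stop("masks must have the same shape as their value matrices")
  structure(
    list(subject_id = as.character(subject_id), T = T_,
         states = states, states_mask = states_mask,
         observations = observations, obs_mask = obs_mask,
         diagnosis = as.character(diagnosis)),
    class = "mtm_trajectory")
}

#' @export
print.mtm_trajectory <- function(x, ...) {
  cat(sprintf("<mtm_trajectory> subject %s: T=%d, d=%d, l=%d, %d/%d cells observed\n",
              x$subject_id, x$T, ncol(x$states), ncol(x$observations),
              sum(x$states_mask) + sum(x$obs_mask),
              length(x$states_mask) + length(x$obs_mask)))
  invisible(x)
}

#' @noRd
traj_complete <- function(traj) all(traj$states_mask) && all(traj$obs_mask)

#' Bundle trajectories into a dataset
#'
#' @param trajectories list of [mtm_trajectory()] objects with homogeneous
#'   state dimension d and observation dimension l.
#' @param state_names,obs_names optional feature-name character vectors.
#' @return an object of class `mtm_dataset`.
#' @export
mtm_dataset <- function(trajectories, state_names = NULL, obs_names = NULL) {
  if (length(trajectories) < 1L) stop("dataset must contain at least one trajectory")
  d <- ncol(trajectories[[1L]]$states)
  l <- ncol(trajectories[[1L]]$observations)
  ok <- vapply(trajectories, function(tr)
    inherits(tr, "mtm_trajectory") &&
      ncol(tr$states) == d && ncol(tr$observations) == l, logical(1))
  if (!all(ok)) stop("all trajectories must share the same (d, l) dimensions")
  state_names <- state_names %||% paste0("state", seq_len(d))
  obs_names <- obs_names %||% paste0("obs", seq_len(l))
  if (length(state_names) != d || length(obs_names) != l)
    stop("feature-name lengths must match (d, l)")
  structure(list(trajectories = trajectories, d = d, l = l,
                 state_names = as.character(state_names),
                 obs_names = as.character(obs_names)),
            class = "mtm_dataset")
}

#' @export
length.mtm_dataset <- function(x) length(x$trajectories)

#' @export
print.mtm_dataset <- function(x, ...) {
  Ts <- vapply(x$trajectories, `[[`, integer(1), "T")
  cat(sprintf("<mtm_dataset> %d trajectories, d=%d, l=%d, T in [%d, %d]\n",
              length(x$trajectories), x$d, x$l, min(Ts), max(Ts)))
  invisible(x)
}

#' Diagnosis labels of a dataset
#' @param dataset an `mtm_dataset`.
#' @return character vector (possibly `NA`) of per-subject diagnoses.
#' @export
diagnoses <- function(dataset) {
  vapply(dataset$trajectories, `[[`, character(1), "diagnosis")
}

#' Subject identifiers of a dataset
#' @param dataset an `mtm_dataset`.
#' @return character vector of subject ids.
#' @export
subject_ids <- function(dataset) {
  vapply(dataset$trajectories, `[[`, character(1), "subject_id")
}

#' @noRd
dataset_complete <- function(dataset)
  all(vapply(dataset$trajectories, traj_complete, logical(1)))

#' @noRd
subset_dataset <- function(dataset, idx) {
  mtm_dataset(dataset$trajectories[idx], dataset$state_names, dataset$obs_names)
}

#' Truncate every trajectory to a single visit
#'
#' Keeps only the first (or last) assessment of each subject, the degenerate
#' T = 1 case under which the trajectory mixture reduces to a Gaussian
#' mixture on (z1, x1) — the "baseline-only" comparator.
#'
#' @param dataset an `mtm_dataset`.
#' @param which `"first"` or `"last"`.
#' @return an `mtm_dataset` of T = 1 trajectories.
#' @export
truncate_to_visit <- function(dataset, which = c("first", "last")) {
  which <- match.arg(which)
  trajs <- lapply(dataset$trajectories, function(tr) {
    t0 <- if (which == "first") 1L else tr$T
    mtm_trajectory(tr$states[t0, , drop = FALSE],
                   tr$observations[t0, , drop = FALSE],
                   tr$states_mask[t0, , drop = FALSE],
                   tr$obs_mask[t0, , drop = FALSE],
                   subject_id = tr$subject_id, diagnosis = tr$diagnosis)
  })
  mtm_dataset(trajs, dataset$state_names, dataset$obs_names)
}

#' Mask cells of every trajectory according to a missingness regime
#'
#' Applies one of the structured missingness patterns seen in clinical
#' cohorts: biomarkers entirely absent, a reduced cognitive panel, a single
#' (first or last) assessment, or cell-wise missingness completely at random.
#' Values are left in place; only the observed-masks change, and masked
#' cells are additionally set to `NA` so that CSV round-trips are faithful.
#'
#' @param dataset an `mtm_dataset`.
#' @param regime one of `"none"`, `"states_absent"`, `"cognitive_only_panel"`,
#'   `"first_visit_only"`, `"last_visit_only"`, `"mcar"`.
#' @param mcar_rate cell missingness probability for `"mcar"`.
#' @param obs_panel integer indices of observation coordinates retained by
#'   `"cognitive_only_panel"` (default: the single mid-panel score, mimicking
#'   a clinic that administers one screening test).
#' @return an `mtm_dataset` with updated masks.
#' @export
apply_missingness <- function(dataset,
                              regime = c("none", "states_absent",
                                         "cognitive_only_panel",
                                         "first_visit_only", "last_visit_only",
                                         "mcar"),
                              mcar_rate = 0.3, obs_panel = NULL) {
  regime <- match.arg(regime)
  if (regime == "none") return(dataset)
  l <- dataset$l
  if (is.null(obs_panel)) obs_panel <- if (l >= 3L) 3L else 1L
  trajs <- lapply(dataset$trajectories, function(tr) {
    sm <- tr$states_mask; om <- tr$obs_mask
    switch(regime,
      states_absent = { sm[] <- FALSE },
      cognitive_only_panel = {
        sm[] <- FALSE
        om[] <- FALSE; om[, obs_panel] <- TRUE
      },
      first_visit_only = {
        if (tr$T > 1L) { sm[-1L, ] <- FALSE; om[-1L, ] <- FALSE }
      },
      last_visit_only = {
        if (tr$T > 1L) { sm[-tr$T, ] <- FALSE; om[-tr$T, ] <- FALSE }
      },
      mcar = {
        sm[] <- sm & (matrix(runif(length(sm)), nrow(sm)) >= mcar_rate)
        om[] <- om & (matrix(runif(length(om)), nrow(om)) >= mcar_rate)
        if (!any(sm) && !any(om)) om[1L, 1L] <- TRUE  # keep subject usable
      })
    st <- tr$states; st[!sm] <- NA_real_
    ob <- tr$observations; ob[!om] <- NA_real_
    mtm_trajectory(st, ob, sm, om, tr$subject_id, tr$diagnosis)
  })
  mtm_dataset(trajs, dataset$state_names, dataset$obs_names)
}
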