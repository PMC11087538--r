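## Long-format CSV: one row per subject-visit, columns
## subject_id, visit (1-based, contiguous per subject), one column per
## state feature, one per observation feature, optional diagnosis.
## Empty cells denote missing values; masks are derived from them.

#' Write a trajectory dataset to long-format CSV
#'
#' @param dataset an `mtm_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(dataset, path) {
  rows <- lapply(dataset$trajectories, function(tr) {
    st <- tr$states; st[!tr$states_mask] <- NA_real_
    ob <- tr$observations; ob[!tr$obs_mask] <- NA_real_
    df <- data.frame(subject_id = tr$subject_id, visit = seq_len(tr$T),
                     stringsAsFactors = FALSE)
    df[dataset$state_names] <- as.data.frame(st)
    df[dataset$obs_names] <- as.data.frame(ob)
    df$diagnosis <- tr$diagnosis
    df
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trajectory dataset from long-format CSV
#'
#' The schema (which columns are states vs observations) must be declared.
#' Masks are derived from empty cells; non-contiguous or duplicated visits
#' and fully empty subjects are rejected with the offending subjects named.
#'
#' @param path CSV path.
#' @param state_cols,obs_cols character vectors of column names.
#' @param id_col,visit_col,diagnosis_col column-name configuration;
#'   `diagnosis_col` is optional in the file.
#' @param na_strings cell values treated as missing (default: the empty
#'   string only).
#' @return an `mtm_dataset`.
#' @export
read_trajectories <- function(path, state_cols, obs_cols,
                              id_col = "subject_id", visit_col = "visit",
                              diagnosis_col = "diagnosis",
                              na_strings = "") {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  expected <- c(id_col, visit_col, state_cols, obs_cols, diagnosis_col)
  missing_cols <- setdiff(c(id_col, visit_col, state_cols, obs_cols),
                          names(df))
  if (length(missing_cols))
    stop("columns missing from CSV: ", paste(missing_cols, collapse = ", "))
  unknown <- setdiff(names(df), expected)
  if (length(unknown))
    stop("unknown columns not in schema: ", paste(unknown, collapse = ", "))
  have_dx <- diagnosis_col %in% names(df)
  num <- function(x) {
    x[x %in% na_strings] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  ids <- df[[id_col]]
  visit <- as.integer(df[[visit_col]])
  trajs <- list()
  for (sid in unique(ids)) {
    rows <- which(ids == sid)
    v <- visit[rows]
    if (anyDuplicated(v))
      stop("duplicate (subject, visit) rows for subject ", sid)
    o <- order(v)
    rows <- rows[o]; v <- v[o]
    if (!identical(v, seq_len(length(v))))
      stop("non-contiguous visits for subject ", sid,
           " (expected 1..T, got ", paste(v, collapse = ","), ")")
    st <- vapply(state_cols, function(cc) num(df[[cc]][rows]),
                 numeric(length(rows)))
    ob <- vapply(obs_cols, function(cc) num(df[[cc]][rows]),
                 numeric(length(rows)))
    st <- matrix(st, length(rows)); ob <- matrix(ob, length(rows))
    if (all(is.na(st)) && all(is.na(ob)))
      stop("subject ", sid, " has no observed cells")
    dxv <- if (have_dx) {
      dd <- df[[diagnosis_col]][rows]
      dd <- dd[!(dd %in% na_strings) & !is.na(dd)]
      if (length(dd)) dd[length(dd)] else NA_character_
    } else NA_character_
    trajs[[length(trajs) + 1L]] <-
      mtm_trajectory(st, ob, subject_id = sid, diagnosis = dxv)
  }
  mtm_dataset(trajs, state_cols, obs_cols)
}

#' Save a model (and optional harmonization) as a versioned JSON archive
#'
#' Plain-text archive holding dimensions, feature names, mixture weights,
#' all parameter matrices at full precision, display labels, harmonization
#' and fit provenance. `read_model(write_model(m))` reproduces likelihoods
#' to better than 1e-12.
#'
#' @param model an [mtm_model()].
#' @param path output path (JSON).
#' @param map optional [harmonize_labels()] result.
#' @param provenance optional named list (seed, restarts, objective, ...).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, map = NULL, provenance = list()) {
  arch <- list(
    format = "mtm-model", version = 1L,
    d = model$d, l = model$l, n_c = model$n_c,
    state_names = model$state_names, obs_names = model$obs_names,
    pi = model$pi, labels = model$labels,
    clusters = lapply(model$clusters, function(p)
      list(m = p$m, S = p$S, A = p$A, Gamma = p$Gamma, H = p$H,
           Lambda = p$Lambda)),
    harmonization = if (!is.null(map))
      list(order = map$order, labels = map$labels,
           ad_fraction = map$ad_fraction,
           fallback_used = map$fallback_used),
    provenance = provenance)
  jsonlite::write_json(arch, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a model archive written by [write_model()]
#'
#' @param path archive path.
#' @return list with `model` ([mtm_model()]), `map` (harmonization or
#'   `NULL`), `provenance`.
#' @export
read_model <- function(path) {
  arch <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(arch$format, "mtm-model"))
    stop("not an mtm model archive: ", path)
  as_mat <- function(x, nr, nc) matrix(as.numeric(t(as.matrix(x))),
                                       nr, nc, byrow = TRUE)
  d <- arch$d; l <- arch$l
  cl_raw <- arch$clusters
  ## jsonlite may simplify the cluster list into a data.frame-like object;
  ## normalize to a plain list of parameter sets
  getp <- function(i, nm) {
    if (is.data.frame(cl_raw)) cl_raw[[nm]][[i]] else cl_raw[[i]][[nm]]
  }
  clusters <- lapply(seq_len(arch$n_c), function(i) {
    mtm_cluster_params(
      m = as.numeric(getp(i, "m")),
      S = as_mat(getp(i, "S"), d, d),
      A = as_mat(getp(i, "A"), d, d),
      Gamma = as_mat(getp(i, "Gamma"), d, d),
      H = as_mat(getp(i, "H"), d, l),
      Lambda = as_mat(getp(i, "Lambda"), l, l))
  })
  labels <- arch$labels
  if (length(labels) == 0L) labels <- NULL
  model <- mtm_model(as.numeric(arch$pi), clusters,
                     arch$state_names, arch$obs_names, labels = labels)
  map <- NULL
  if (!is.null(arch$harmonization) && length(arch$harmonization)) {
    h <- arch$harmonization
    map <- structure(list(order = as.integer(h$order),
                          labels = as.character(h$labels),
                          ad_fraction = as.numeric(h$ad_fraction),
                          pmci_fraction = rep(NA_real_, arch$n_c),
                          fallback_used = isTRUE(h$fallback_used)),
                     class = "mtm_harmonization")
  }
  list(model = model, map = map, provenance = arch$provenance)
}

#' Export a cross-validation report
#'
#' Writes the per-subject assignment table as CSV and a JSON summary
#' (stability histogram, contingency table, chi-square).
#'
#' @param cv an [cross_validate()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cv$assignments, file.path(dir, "assignments.csv"),
            row.names = FALSE, na = "")
  summ <- list(k = cv$k, seed = cv$seed,
               stability_histogram = as.list(cv$stability_histogram),
               contingency = if (!is.null(cv$contingency))
                 as.data.frame.matrix(cv$contingency),
               chisq = cv$chisq)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
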