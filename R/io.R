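# Cohort file I/O: per-subject optical-density CSVs (columns
# chNN_w695 / chNN_w830), a manifest CSV, and truth edge lists.

#' Write a cohort to disk
#'
#' Writes one CSV per subject with the dual-wavelength optical-density
#' series (rows = samples; columns = channel x wavelength, named
#' `chNN_w<λ>`), a `manifest.csv` (subject_id, group_label, fs, file),
#' and one truth edge-list CSV per subject.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "neglect_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    od <- s$optical
    wl <- od$wavelengths
    mats <- lapply(1:2, function(w) {
      m <- od$data[, , w, drop = TRUE]
      colnames(m) <- sprintf("%s_w%d", od$channel_ids, wl[w])
      m
    })
    df <- as.data.frame(do.call(cbind, mats))
    f <- file.path(dir, paste0(s$subject_id, "_od.csv"))
    utils::write.csv(df, f, row.names = FALSE)
    p <- pair_index(nrow(s$truth$adjacency))
    keep <- s$truth$adjacency[p] > 0
    utils::write.csv(data.frame(i = p[keep, 1L], j = p[keep, 2L]),
                     file.path(dir, "truth", paste0(s$subject_id, "_edges.csv")),
                     row.names = FALSE)
    data.frame(subject_id = s$subject_id, group_label = s$group_label,
               fs = od$fs, file = basename(f))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load subjects from a cohort directory
#'
#' Reads `manifest.csv` and the per-subject optical-density CSVs written
#' by [write_cohort()] (wavelength-suffixed channel columns). Channel
#' counts must agree across subjects.
#'
#' @param dir cohort directory.
#' @param wavelengths expected wavelengths (nm), used to parse column
#'   suffixes.
#' @return List of `subject_record`s (without truth networks unless edge
#'   lists are present).
#' @export
load_subjects <- function(dir, wavelengths = c(695, 830)) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stopf("no manifest.csv in %s", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  need <- c("subject_id", "group_label", "fs", "file")
  if (!all(need %in% names(manifest)))
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  n_ch_ref <- NULL
  lapply(seq_len(nrow(manifest)), function(k) {
    row <- manifest[k, ]
    df <- utils::read.csv(file.path(dir, row$file), check.names = FALSE)
    cols1 <- grep(sprintf("_w%d$", wavelengths[1L]), names(df), value = TRUE)
    cols2 <- grep(sprintf("_w%d$", wavelengths[2L]), names(df), value = TRUE)
    if (length(cols1) != length(cols2) || !length(cols1))
      stopf("subject %s: wavelength column sets do not pair up", row$subject_id)
    if (is.null(n_ch_ref)) n_ch_ref <<- length(cols1)
    if (length(cols1) != n_ch_ref)
      stopf("subject %s has %d channels; cohort has %d",
            row$subject_id, length(cols1), n_ch_ref)
    ch <- sub(sprintf("_w%d$", wavelengths[1L]), "", cols1)
    n <- nrow(df)
    od <- array(0, dim = c(n, length(cols1), 2L))
    od[, , 1L] <- as.matrix(df[cols1])
    od[, , 2L] <- as.matrix(df[cols2])
    truth_file <- file.path(dir, "truth", paste0(row$subject_id, "_edges.csv"))
    truth <- NULL
    if (file.exists(truth_file)) {
      e <- utils::read.csv(truth_file)
      adj <- matrix(0L, length(ch), length(ch))
      adj[cbind(e$i, e$j)] <- 1L
      adj[cbind(e$j, e$i)] <- 1L
      truth <- structure(list(adjacency = adj, params = NULL, seed = NA),
                         class = "truth_network")
    }
    structure(list(subject_id = row$subject_id,
                   group_label = row$group_label,
                   optical = od_series(od, fs = row$fs, channel_ids = ch,
                                       wavelengths = wavelengths),
                   truth = truth, model_sigma = NULL, seed = NA),
              class = "subject_record")
  })
}

#' Write per-subject metric curves and AUC features as CSV
#' @param curves list of metric-curve data frames named by subject id.
#' @param auc matrix subjects x AUC features.
#' @param labels group labels.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_metric_outputs <- function(curves, auc, labels, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(names(curves), function(id)
    cbind(subject_id = id, as.data.frame(curves[[id]]))))
  utils::write.csv(long, file.path(dir, "metric_curves.csv"), row.names = FALSE)
  feat <- data.frame(subject_id = names(curves), as.data.frame(auc),
                     group_label = labels)
  utils::write.csv(feat, file.path(dir, "auc_features.csv"), row.names = FALSE)
  invisible(dir)
}
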