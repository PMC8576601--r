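#' Extract the digital-biomarker vector of one participant
#'
#' Computes the full named biomarker vector (activity, sleep, circadian and
#' heart-rate families; about 122 features) from a participant's streams,
#' restricted to complete minutes of complete days. Feature names follow the
#' dotted convention `IS.st.wd`, `NHR.0406.cv`, `sleep.offset.wd.sd`, ...
#'
#' @param streams A `participant_streams`.
#' @param report Optional precomputed `completeness_report`.
#' @param families Subset of `c("activity", "sleep", "circadian",
#'   "heart_rate")` to extract.
#' @return Named numeric vector of biomarker values (NA where undefined).
#' @export
extract_biomarkers <- function(streams, report = NULL,
                               families = c("activity", "sleep", "circadian",
                                            "heart_rate")) {
  if (is.null(report)) report <- completeness_mask(streams)
  dset <- report$complete_days
  keep_min <- report$minute_complete &
    rep(seq_len(streams$days) %in% dset, each = MIN_PER_DAY)
  out <- c()
  if ("activity" %in% families) {
    out <- c(out, activity_summary(streams, report))
  }
  if ("sleep" %in% families) {
    out <- c(out, sleep_summary(sleep_episodes(streams, report)))
  }
  if ("circadian" %in% families) {
    hr_min <- col_means_na(matrix(streams$hr, nrow = HR_PER_MIN))
    out <- c(out,
             circadian_source_features(as.numeric(streams$steps), keep_min,
                                       dset, streams$start_dow, "st", "sum"),
             circadian_source_features(hr_min, keep_min, dset,
                                       streams$start_dow, "hr", "mean"))
  }
  if ("heart_rate" %in% families) {
    out <- c(out, heart_rate_summary(streams, report))
  }
  out
}

#' Cohort biomarker matrix
#'
#' Runs the QC cascade and extracts the biomarker vector for every included
#' participant.
#'
#' @param cohort A `wearable_cohort`.
#' @param qc Optional precomputed result of [qc_cohort()].
#' @param families Families passed to [extract_biomarkers()].
#' @return Tibble with `id` followed by one column per biomarker; attribute
#'   `qc` holds the QC summary.
#' @export
biomarker_matrix <- function(cohort, qc = NULL,
                             families = c("activity", "sleep", "circadian",
                                          "heart_rate")) {
  if (is.null(qc)) qc <- qc_cohort(cohort)
  keep <- which(qc$summary$included)
  rows <- lapply(keep, function(i) {
    extract_biomarkers(cohort$streams[[i]], qc$reports[[i]], families)
  })
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- tibble::add_column(out, id = qc$summary$id[keep], .before = 1)
  attr(out, "qc") <- qc$summary
  out
}
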