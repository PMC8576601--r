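#' Heart-rate-based completeness of a participant record
#'
#' Device use time is verified from the heart-rate stream, the channel most
#' sensitive to non-wear: a minute is *complete* iff at least one heart-rate
#' sample falls inside it. Activity and sleep samples outside complete minutes
#' are excluded from all downstream feature computations.
#'
#' @param streams A `participant_streams` object.
#' @return A `completeness_report`: list with `minute_complete` (logical per
#'   minute), `complete_hours` (per day, in `[0, 24]`), `complete_days`
#'   (indices of days meeting the default 20-hour rule), `included`
#'   (participant-level flag under the default 10-day rule) and
#'   retained/discarded minute counts.
#' @export
completeness_mask <- function(streams) {
  assert_that(inherits(streams, "participant_streams"),
              "streams must be a participant_streams")
  n_min <- streams$days * MIN_PER_DAY
  if (all(is.na(streams$hr))) {
    minute_complete <- rep(FALSE, n_min)
  } else {
    hr_mat <- matrix(!is.na(streams$hr), nrow = HR_PER_MIN)
    minute_complete <- colSums(hr_mat) > 0L
  }
  complete_hours <- colSums(matrix(minute_complete, nrow = MIN_PER_DAY)) / 60
  report <- structure(
    list(
      days = streams$days,
      minute_complete = minute_complete,
      complete_hours = complete_hours,
      minutes_total = n_min,
      minutes_complete = sum(minute_complete)
    ),
    class = "completeness_report"
  )
  report$complete_days <- filter_days(report)
  report$minutes_retained <- sum(minute_complete[
    rep(seq_len(streams$days) %in% report$complete_days, each = MIN_PER_DAY)])
  report$minutes_discarded <- report$minutes_complete - report$minutes_retained
  report$included <- length(report$complete_days) >= 10L
  report
}

#' Day-level inclusion rule
#'
#' A day enters the analysis iff it has at least `min_hours` hours of complete
#' recording (boundary inclusive).
#'
#' @param report A `completeness_report`.
#' @param min_hours Minimum complete hours per day (default 20).
#' @return Integer vector of included day indices.
#' @export
filter_days <- function(report, min_hours = 20) {
  which(report$complete_hours >= min_hours)
}

#' Participant-level inclusion rule
#'
#' A participant is retained iff they contribute at least `min_days` complete
#' days and at least `min_weekday_nights` weekday sleep nights.
#'
#' @param day_sets List of complete-day index vectors, one per participant.
#' @param weekday_nights Integer vector of weekday sleep-night counts.
#' @param min_days Minimum complete days (default 10).
#' @param min_weekday_nights Minimum weekday sleep nights (default 3).
#' @return Logical inclusion flags.
#' @export
filter_participants <- function(day_sets, weekday_nights = NULL,
                                min_days = 10L, min_weekday_nights = 3L) {
  ok <- vapply(day_sets, length, integer(1)) >= min_days
  if (!is.null(weekday_nights)) {
    ok <- ok & (weekday_nights >= min_weekday_nights)
  }
  ok
}

#' Tukey rule outlier flags
#'
#' Flags values more than 1.5 IQR below the first or above the third quartile.
#' Quartiles use the linear-interpolation (type 7) convention.
#'
#' @param values Numeric vector of participant-level summaries.
#' @param k IQR multiplier (default 1.5).
#' @return Logical flags (NA values are never flagged).
#' @export
tukey_outlier_flags <- function(values, k = 1.5) {
  if (sum(!is.na(values)) < 4) {
    warning("fewer than 4 values: no outlier flags assigned")
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7)
  iqr <- q[2] - q[1]
  flag <- values < q[1] - k * iqr | values > q[2] + k * iqr
  flag[is.na(flag)] <- FALSE
  flag
}

#' Cohort-level quality control
#'
#' Applies the full inclusion cascade to a cohort: per-minute completeness from
#' heart rate, the `>= min_hours` complete-day rule, the `>= min_days`
#' participant rule, the `>= 3` weekday-sleep-night rule, and Tukey outlier
#' exclusion on participant mean heart rate and mean daily steps.
#'
#' @param cohort A `wearable_cohort` (or bare list of `participant_streams`).
#' @param min_hours Day rule threshold in hours (default 20).
#' @param min_days Participant rule threshold in days (default 10).
#' @return A list with `reports` (per-participant `completeness_report`s) and
#'   `summary`, a tibble of per-participant complete-day counts, weekday sleep
#'   nights, mean HR, mean daily steps, outlier flags and the final `included`
#'   flag.
#' @export
qc_cohort <- function(cohort, min_hours = 20, min_days = 10L) {
  streams <- if (inherits(cohort, "wearable_cohort")) cohort$streams else cohort
  reports <- lapply(streams, completeness_mask)
  day_sets <- lapply(seq_along(reports), function(i) {
    filter_days(reports[[i]], min_hours)
  })

  mean_hr <- vapply(seq_along(streams), function(i) {
    s <- streams[[i]]
    keep_min <- reports[[i]]$minute_complete &
      rep(seq_len(s$days) %in% day_sets[[i]], each = MIN_PER_DAY)
    hr_min <- col_means_na(matrix(s$hr, nrow = HR_PER_MIN))
    mean_(hr_min[keep_min])
  }, numeric(1))

  mean_steps <- vapply(seq_along(streams), function(i) {
    s <- streams[[i]]
    dset <- day_sets[[i]]
    if (!length(dset)) return(NA_real_)
    keep_min <- reports[[i]]$minute_complete
    day_of_min <- rep(seq_len(s$days), each = MIN_PER_DAY)
    st <- ifelse(keep_min, s$steps, NA_real_)
    sums <- tapply(st, day_of_min, function(x) sum(x, na.rm = TRUE))
    mean(sums[as.character(dset)])
  }, numeric(1))

  wd_nights <- vapply(seq_along(streams), function(i) {
    eps <- sleep_episodes(streams[[i]], reports[[i]])
    if (!nrow(eps)) 0L else sum(eps$weekday)
  }, integer(1))

  base_ok <- filter_participants(day_sets, wd_nights, min_days)
  out_hr <- tukey_outlier_flags(ifelse(base_ok, mean_hr, NA_real_))
  out_steps <- tukey_outlier_flags(ifelse(base_ok, mean_steps, NA_real_))
  included <- base_ok & !out_hr & !out_steps

  summary <- tibble::tibble(
    id = vapply(streams, `[[`, character(1), "id"),
    complete_days = vapply(day_sets, length, integer(1)),
    weekday_sleep_nights = wd_nights,
    mean_hr = mean_hr,
    mean_daily_steps = mean_steps,
    outlier_hr = out_hr,
    outlier_steps = out_steps,
    included = included
  )
  list(reports = reports, day_sets = day_sets, summary = summary)
}

## ---------------------------------------------------------------------------
## CSV dialect: one file per stream per participant, columns timestamp,value
## (stage label for sleep); a manifest maps participant id -> file paths.
## Timestamps are local-clock "day<d> HH:MM:SS" offsets resolved against the
## configured grid, written as seconds from the start of day 1 for
## compactness and re-read positionally.

#' Write a cohort to the on-disk CSV dialect
#'
#' One CSV per stream per participant (`timestamp,value`; timestamps are
#' seconds since local midnight of day 1), a survey CSV with PHQ-9 totals and
#' covariates, and a `manifest.csv` mapping ids to file paths.
#'
#' @param cohort A `wearable_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(cohort$streams))
  for (i in seq_along(cohort$streams)) {
    s <- cohort$streams[[i]]
    paths <- c(
      steps = file.path(dir, paste0(s$id, "_steps.csv")),
      mets = file.path(dir, paste0(s$id, "_mets.csv")),
      hr = file.path(dir, paste0(s$id, "_hr.csv")),
      sleep = file.path(dir, paste0(s$id, "_sleep.csv"))
    )
    n_min <- s$days * MIN_PER_DAY
    data.table::fwrite(
      data.table::data.table(timestamp = (seq_len(n_min) - 1L) * 60L, value = s$steps),
      paths["steps"])
    data.table::fwrite(
      data.table::data.table(timestamp = (seq_len(n_min) - 1L) * 60L,
                             value = round(s$mets, 3)),
      paths["mets"])
    keep <- !is.na(s$hr)
    data.table::fwrite(
      data.table::data.table(
        timestamp = (which(keep) - 1L) * HR_INTERVAL_S, value = s$hr[keep]),
      paths["hr"])
    keep_s <- !is.na(s$sleep)
    data.table::fwrite(
      data.table::data.table(timestamp = (which(keep_s) - 1L) * 30L,
                             value = s$sleep[keep_s]),
      paths["sleep"])
    rows[[i]] <- data.table::data.table(
      id = s$id, days = s$days, start_dow = s$start_dow,
      steps = basename(paths["steps"]), mets = basename(paths["mets"]),
      hr = basename(paths["hr"]), sleep = basename(paths["sleep"]))
  }
  manifest <- data.table::rbindlist(rows)
  mpath <- file.path(dir, "manifest.csv")
  data.table::fwrite(manifest, mpath)
  data.table::fwrite(data.table::as.data.table(cohort$outcomes),
                     file.path(dir, "survey.csv"))
  invisible(mpath)
}

#' Read a cohort from the on-disk CSV dialect
#'
#' Inverse of [write_cohort_csv()].
#'
#' @param manifest_path Path to `manifest.csv`.
#' @return A `wearable_cohort` (with `config = NULL`).
#' @export
read_cohort_csv <- function(manifest_path) {
  dir <- dirname(manifest_path)
  manifest <- data.table::fread(manifest_path)
  streams <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    days <- row$days
    rd <- function(fname) data.table::fread(file.path(dir, fname))
    st <- rd(row$steps); mt <- rd(row$mets); hrf <- rd(row$hr); sl <- rd(row$sleep)
    steps <- integer(days * MIN_PER_DAY)
    steps[st$timestamp %/% 60L + 1L] <- as.integer(st$value)
    mets <- rep(NA_real_, days * MIN_PER_DAY)
    mets[mt$timestamp %/% 60L + 1L] <- mt$value
    hr <- rep(NA_real_, days * HR_PER_DAY)
    hr[hrf$timestamp %/% HR_INTERVAL_S + 1L] <- hrf$value
    sleep <- rep(NA_character_, days * SLEEP_PER_DAY)
    if (nrow(sl)) sleep[sl$timestamp %/% 30L + 1L] <- sl$value
    streams[[i]] <- structure(
      list(id = row$id, days = as.integer(days),
           start_dow = as.integer(row$start_dow),
           steps = steps, mets = mets, hr = hr, sleep = sleep,
           hr_interval = HR_INTERVAL_S,
           ledger = list(gap_minutes = NA_integer_, gap_index = integer(0),
                         bouts_planned = NA_integer_, n_episodes = NA_integer_)),
      class = "participant_streams")
  }
  names(streams) <- manifest$id
  survey_path <- file.path(dir, "survey.csv")
  outcomes <- if (file.exists(survey_path)) {
    tibble::as_tibble(data.table::fread(survey_path))
  } else NULL
  structure(list(streams = streams, outcomes = outcomes, config = NULL),
            class = "wearable_cohort")
}
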