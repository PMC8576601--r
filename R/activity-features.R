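## Physical-activity biomarkers from minute-level steps and METs over
## complete days. Intensity bands follow the CDC MET conventions: moderate
## 3.0-6.0 METs, vigorous above 6.0. "Light" is operationalized as the
## disjoint waking band (1.5, 3.0), since the prose "below 3.0" would overlap
## the sedentary definition; sedentary is any waking minute with <= 1.5 METs.

day_type_set <- function(days, day_set, day_type, start_dow) {
  wd <- is_weekday(seq_len(days), start_dow)
  keep <- switch(day_type,
                 all = rep(TRUE, days),
                 weekday = wd,
                 weekend = !wd,
                 stop("day_type must be all/weekday/weekend"))
  intersect(day_set, which(keep))
}

#' Mean daily steps
#'
#' Arithmetic mean of per-day step totals over the selected complete days.
#' Minutes excluded by the completeness mask should be NA in `steps`.
#'
#' @param steps Per-minute step counts (length a multiple of 1440; NA =
#'   excluded minute).
#' @param day_set Indices of complete days.
#' @param day_type `"all"`, `"weekday"` or `"weekend"`.
#' @param start_dow Weekday of day 1 (1 = Monday).
#' @return Mean daily steps, or NA when no day of the requested type exists.
#' @export
daily_steps <- function(steps, day_set, day_type = "all", start_dow = 1L) {
  days <- length(steps) %/% MIN_PER_DAY
  dset <- day_type_set(days, day_set, day_type, start_dow)
  if (!length(dset)) return(NA_real_)
  m <- matrix(steps, nrow = MIN_PER_DAY)
  mean(colSums(m[, dset, drop = FALSE], na.rm = TRUE))
}

#' Mean daily minutes in MET intensity bands
#'
#' Counts complete waking minutes per day with METs in (1.5, 3.0) (light),
#' `[3.0, 6.0]` (moderate) and above 6.0 (vigorous), averaged over the
#' selected days.
#'
#' @param mets Per-minute MET values (NA = excluded minute).
#' @param asleep Logical per-minute sleep flag (light band is waking only).
#' @param day_set Indices of complete days.
#' @param start_dow Weekday of day 1.
#' @param day_type Day-type restriction as in [daily_steps()].
#' @return Named vector `light`, `moderate`, `vigorous` (mean daily minutes).
#' @export
intensity_minutes <- function(mets, asleep, day_set, start_dow = 1L,
                              day_type = "all") {
  days <- length(mets) %/% MIN_PER_DAY
  dset <- day_type_set(days, day_set, day_type, start_dow)
  if (!length(dset)) {
    return(c(light = NA_real_, moderate = NA_real_, vigorous = NA_real_))
  }
  per_day <- function(flag) {
    m <- matrix(flag, nrow = MIN_PER_DAY)
    mean(colSums(m[, dset, drop = FALSE], na.rm = TRUE))
  }
  c(light = per_day(!asleep & mets > 1.5 & mets < 3.0),
    moderate = per_day(mets >= 3.0 & mets <= 6.0),
    vigorous = per_day(mets > 6.0))
}

#' Mean daily sedentary minutes
#'
#' Waking minutes with METs at or below 1.5, averaged per day over the
#' selected complete days.
#'
#' @inheritParams intensity_minutes
#' @return Mean daily sedentary minutes.
#' @export
sedentary_minutes <- function(mets, asleep, day_set, day_type = "all",
                              start_dow = 1L) {
  days <- length(mets) %/% MIN_PER_DAY
  dset <- day_type_set(days, day_set, day_type, start_dow)
  if (!length(dset)) return(NA_real_)
  m <- matrix(!asleep & mets <= 1.5, nrow = MIN_PER_DAY)
  mean(colSums(m[, dset, drop = FALSE], na.rm = TRUE))
}

# Named feature vector for the activity family.
activity_summary <- function(streams, report) {
  dset <- report$complete_days
  keep <- report$minute_complete
  steps <- ifelse(keep, as.numeric(streams$steps), NA_real_)
  mets <- ifelse(keep, streams$mets, NA_real_)
  slp_mat <- matrix(streams$sleep, nrow = 2L)
  asleep <- (!is.na(slp_mat[1, ]) & slp_mat[1, ] != "wake") |
    (!is.na(slp_mat[2, ]) & slp_mat[2, ] != "wake")
  sd0 <- streams$start_dow
  im <- intensity_minutes(mets, asleep, dset, sd0)
  c(
    steps = daily_steps(steps, dset, "all", sd0),
    steps.wd = daily_steps(steps, dset, "weekday", sd0),
    steps.we = daily_steps(steps, dset, "weekend", sd0),
    sedentary = sedentary_minutes(mets, asleep, dset, "all", sd0),
    sedentary.wd = sedentary_minutes(mets, asleep, dset, "weekday", sd0),
    sedentary.we = sedentary_minutes(mets, asleep, dset, "weekend", sd0),
    light = unname(im["light"]),
    moderate = unname(im["moderate"]),
    vigorous = unname(im["vigorous"])
  )
}
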