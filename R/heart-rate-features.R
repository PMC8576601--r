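## Physiological biomarkers from the 5-second heart-rate stream: resting,
## daytime (2-4 PM) and nighttime (12-2, 2-4, 4-6 AM) heart rate with SD/CV,
## delta heart rate, and RMSSD. Night windows belong to the night preceding
## the wake-day (they are the early-morning hours of that calendar day).
## Window statistics are computed per night/day and then averaged; a pooled
## mode over all samples is available behind a flag.

#' Resting heart rate
#'
#' Mean heart rate over calendar-aligned, non-overlapping 15-minute windows
#' whose total step count is zero. A window qualifies when all 15 minutes are
#' complete, steps sum to zero, and at least one heart-rate value is present;
#' the RHR is the mean of qualifying window means.
#'
#' @param hr_min Per-minute mean heart rate (NA = excluded minute).
#' @param steps_min Per-minute step counts (NA = excluded minute).
#' @return RHR in bpm, or NA when no window qualifies.
#' @export
resting_heart_rate <- function(hr_min, steps_min) {
  n <- (length(hr_min) %/% 15L) * 15L
  if (n < 15L) return(NA_real_)
  sm <- matrix(steps_min[seq_len(n)], nrow = 15L)
  hm <- matrix(hr_min[seq_len(n)], nrow = 15L)
  complete <- colSums(is.na(sm)) == 0L
  zero <- colSums(sm) == 0L
  has_hr <- colSums(!is.na(hm)) > 0L
  sel <- complete & zero & has_hr
  if (!any(sel)) return(NA_real_)
  mean(col_means_na(hm[, sel, drop = FALSE]))
}

#' Heart-rate statistics within a clock window
#'
#' Per-day mean and SD of the raw heart-rate samples falling in the clock
#' window `[from, to)` hours, averaged over the selected days; the CV is the
#' across-day mean of the per-day SD/mean ratios. With `pooled = TRUE` the
#' samples of all days are pooled before computing mean/SD/CV.
#'
#' @param hr Raw heart-rate sample vector on the 5-s grid (NA = missing).
#' @param day_set Day indices to use.
#' @param from,to Window bounds in hours since midnight.
#' @param pooled Pool samples across days instead of averaging per-day
#'   statistics.
#' @return Named vector `mean`, `sd`, `cv`.
#' @export
window_hr_stats <- function(hr, day_set, from, to, pooled = FALSE) {
  days <- length(hr) %/% HR_PER_DAY
  day_set <- intersect(day_set, seq_len(days))
  i0 <- as.integer(from * 3600) %/% HR_INTERVAL_S
  i1 <- as.integer(to * 3600) %/% HR_INTERVAL_S
  win <- (i0 + 1L):i1
  if (!length(day_set)) return(c(mean = NA_real_, sd = NA_real_, cv = NA_real_))
  if (pooled) {
    vals <- unlist(lapply(day_set, function(d) hr[(d - 1L) * HR_PER_DAY + win]))
    m <- mean_(vals)
    s <- sd_(vals)
    return(c(mean = m, sd = s,
             cv = if (is.na(m) || is.na(s) || m <= 0) NA_real_ else s / m))
  }
  stats_day <- vapply(day_set, hr_day_window_stats, numeric(3), hr = hr, win = win)
  c(mean = mean_(stats_day[1, ]), sd = mean_(stats_day[2, ]),
    cv = mean_(stats_day[3, ]))
}

hr_day_window_stats <- function(d, hr, win) {
  v <- hr[(d - 1L) * HR_PER_DAY + win]
  v <- v[!is.na(v)]
  if (length(v) < 2) return(c(NA_real_, NA_real_, NA_real_))
  m <- mean(v)
  s <- stats::sd(v)
  c(m, s, if (m > 0) s / m else NA_real_)
}

#' Root mean square of successive differences
#'
#' `sqrt(mean(diff(x)^2))` over the supplied series; NA gaps break
#' successiveness (differences across a gap are dropped).
#'
#' @param x Numeric series in time order.
#' @return RMSSD, or NA with fewer than 2 successive values.
#' @export
rmssd <- function(x) {
  d <- diff(x)
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  sqrt(mean(d^2))
}

#' Delta heart rate
#'
#' Difference between the overall mean heart rate and the resting heart rate.
#'
#' @param mean_hr Overall mean heart rate (bpm).
#' @param rhr Resting heart rate (bpm).
#' @return `mean_hr - rhr`, NA if either is missing.
#' @export
delta_heart_rate <- function(mean_hr, rhr) {
  if (is.na(mean_hr) || is.na(rhr)) return(NA_real_)
  mean_hr - rhr
}

# Named feature vector for the heart-rate family.
heart_rate_summary <- function(streams, report) {
  dset <- report$complete_days
  keep_min <- report$minute_complete &
    rep(seq_len(streams$days) %in% dset, each = MIN_PER_DAY)
  hr_min <- col_means_na(matrix(streams$hr, nrow = HR_PER_MIN))
  hr_min[!keep_min] <- NA_real_
  steps_min <- ifelse(keep_min, as.numeric(streams$steps), NA_real_)
  # raw samples restricted to retained minutes
  hr_raw <- streams$hr
  hr_raw[rep(!keep_min, each = HR_PER_MIN)] <- NA_real_

  mean_hr <- mean_(hr_min)
  rhr <- resting_heart_rate(hr_min, steps_min)
  dhr <- window_hr_stats(hr_raw, dset, 14, 16)
  n0002 <- window_hr_stats(hr_raw, dset, 0, 2)
  n0204 <- window_hr_stats(hr_raw, dset, 2, 4)
  n0406 <- window_hr_stats(hr_raw, dset, 4, 6)

  hourly <- bin_matrix(hr_min, rep(TRUE, length(hr_min)), dset, 60L, "mean")

  c(
    HR.mean = mean_hr,
    RHR = rhr,
    HR.delta = delta_heart_rate(mean_hr, rhr),
    DHR.mean = unname(dhr["mean"]), DHR.sd = unname(dhr["sd"]),
    DHR.cv = unname(dhr["cv"]),
    NHR.0002.mean = unname(n0002["mean"]), NHR.0002.sd = unname(n0002["sd"]),
    NHR.0002.cv = unname(n0002["cv"]),
    NHR.0204.mean = unname(n0204["mean"]), NHR.0204.sd = unname(n0204["sd"]),
    NHR.0204.cv = unname(n0204["cv"]),
    NHR.0406.mean = unname(n0406["mean"]), NHR.0406.sd = unname(n0406["sd"]),
    NHR.0406.cv = unname(n0406["cv"]),
    RMSSD.raw = rmssd(hr_raw),
    RMSSD.hourly = if (is.null(hourly)) NA_real_ else rmssd(as.vector(hourly))
  )
}
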