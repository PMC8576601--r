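## Sleep biomarkers from 30-second stage epochs.
##
## Contiguous runs of staged epochs form device sleep records; for each night
## the longest record overlapping the 8 PM - noon window is the main episode
## (naps are excluded). Episodes are assigned to the calendar day of their
## offset (the wake-day), so the weekday flag refers to the workday the night
## precedes.

# Contiguous non-NA runs of the sleep vector -> record table (epoch indices).
sleep_records <- function(sleep) {
  r <- rle(!is.na(sleep))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Select the main sleep episode of a night
#'
#' Given device sleep records (epoch-index ranges on the 30-second grid) and a
#' wake-day index, returns the longest record overlapping the window from 8 PM
#' of the previous day to noon of the wake-day, or `NULL` when no record
#' overlaps it.
#'
#' @param records Data frame with `start`/`end` epoch indices (30-s grid,
#'   epoch 1 starts at midnight of day 1).
#' @param wake_day Day index the night belongs to.
#' @return One-row data frame (`start`, `end`) or `NULL`.
#' @export
detect_main_sleep <- function(records, wake_day) {
  if (!nrow(records)) return(NULL)
  win_lo <- ((wake_day - 1) * 24 - 4) * 120   # 8 PM previous day, in epochs
  win_hi <- ((wake_day - 1) * 24 + 12) * 120  # noon of wake-day
  ov <- pmin(records$end, win_hi) - pmax(records$start - 1L, win_lo)
  cand <- which(ov > 0)
  if (!length(cand)) return(NULL)
  len <- records$end[cand] - records$start[cand] + 1L
  records[cand[which.max(len)], , drop = FALSE]
}

#' Metrics of a single sleep episode
#'
#' Time in bed (TIB) is the staged duration; total sleep time (TST) is TIB
#' minus wake time; sleep efficiency (SE) is TST/TIB; sleep-onset latency
#' (SOL) is the time to the first non-wake epoch; wake after sleep onset
#' (WASO) counts wake minutes in the middle half of the episode (positional
#' epoch indices in `[N/4, 3N/4)`, zero-based, floored).
#'
#' @param stages Character vector of 30-s stage labels
#'   (`wake`/`light`/`deep`/`rem`).
#' @return Named list with `tib`, `tst`, `se`, `sol`, `waso` (minutes, SE a
#'   proportion), or `NULL` with a warning for an all-wake episode.
#' @export
episode_metrics <- function(stages) {
  n <- length(stages)
  assert_that(n >= 4, "episode must have at least 4 epochs")
  wake <- stages == "wake"
  if (all(wake)) {
    warning("all-wake episode: sleep-onset latency undefined, episode dropped")
    return(NULL)
  }
  tib <- n * 0.5
  wake_min <- sum(wake) * 0.5
  tst <- tib - wake_min
  sol <- 0.5 * (which.min(wake) - 1L)
  idx0 <- seq_len(n) - 1L
  mid <- idx0 >= floor(n / 4) & idx0 < floor(3 * n / 4)
  waso <- 0.5 * sum(wake & mid)
  list(tib = tib, tst = tst, se = tst / tib, sol = sol, waso = waso)
}

#' Nightly sleep episodes of a participant
#'
#' Detects the main episode of every night, computes per-episode metrics and
#' timing (offset and midpoint in hours since midnight of the wake-day;
#' pre-midnight onsets yield negative midpoint components, avoiding
#' wraparound when averaging).
#'
#' @param streams A `participant_streams`.
#' @param report Optional `completeness_report`; when given, episodes whose
#'   wake-day is not a complete day are dropped.
#' @return Tibble with one row per retained night: `wake_day`, `weekday`,
#'   `onset_hour`, `offset_hour`, `midpoint_hour`, `tib`, `tst`, `se`, `sol`,
#'   `waso`.
#' @export
sleep_episodes <- function(streams, report = NULL) {
  records <- sleep_records(streams$sleep)
  rows <- list()
  keep_days <- if (is.null(report)) seq_len(streams$days) else report$complete_days
  for (wake_day in seq_len(streams$days)) {
    main <- detect_main_sleep(records, wake_day)
    if (is.null(main)) next
    # a record is consumed by the first night it is assigned to
    records <- records[!(records$start == main$start), , drop = FALSE]
    ep_wake_day <- floor((main$end - 1) / SLEEP_PER_DAY) + 1
    if (!(ep_wake_day %in% keep_days)) next
    stages <- streams$sleep[main$start:main$end]
    met <- withCallingHandlers(
      episode_metrics(stages),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (is.null(met)) next
    onset_abs <- (main$start - 1) / 120
    base <- (ep_wake_day - 1) * 24
    rows[[length(rows) + 1L]] <- c(
      wake_day = ep_wake_day,
      weekday = is_weekday(ep_wake_day, streams$start_dow),
      onset_hour = onset_abs - base,
      offset_hour = main$end / 120 - base,
      midpoint_hour = onset_abs + met$tib / 120 - base,  # tib/120 = half, in h
      tib = met$tib, tst = met$tst, se = met$se,
      sol = met$sol, waso = met$waso
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(
      wake_day = integer(0), weekday = logical(0), onset_hour = numeric(0),
      offset_hour = numeric(0), midpoint_hour = numeric(0), tib = numeric(0),
      tst = numeric(0), se = numeric(0), sol = numeric(0), waso = numeric(0)))
  }
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  out$wake_day <- as.integer(out$wake_day)
  out$weekday <- as.logical(out$weekday)
  out
}

#' Offset and midpoint timing statistics
#'
#' Mean and SD of sleep offset and midpoint (hours since midnight of the
#' wake-day) over at least three nights.
#'
#' @param episodes Episode tibble from [sleep_episodes()].
#' @param weekday_only Restrict to weekday nights.
#' @return Named list `offset_mean`, `offset_sd`, `midpoint_mean`,
#'   `midpoint_sd` (NA when fewer than 3 nights qualify).
#' @export
timing_metrics <- function(episodes, weekday_only = FALSE) {
  ep <- if (weekday_only) episodes[episodes$weekday, , drop = FALSE] else episodes
  if (nrow(ep) < 3) {
    return(list(offset_mean = NA_real_, offset_sd = NA_real_,
                midpoint_mean = NA_real_, midpoint_sd = NA_real_))
  }
  list(
    offset_mean = mean(ep$offset_hour), offset_sd = stats::sd(ep$offset_hour),
    midpoint_mean = mean(ep$midpoint_hour), midpoint_sd = stats::sd(ep$midpoint_hour)
  )
}

# Named feature vector for the sleep family: means and CVs of TIB/TST/SE/
# SOL/WASO plus offset/midpoint timing, all-days and weekday variants.
sleep_summary <- function(episodes) {
  c(sleep_variant_summary(episodes, ""),
    sleep_variant_summary(episodes[episodes$weekday, , drop = FALSE], ".wd"))
}

sleep_variant_summary <- function(ep, suffix) {
  vals <- c()
  for (v in c("tib", "tst", "se", "sol", "waso")) {
    x <- ep[[v]]
    vals[paste0("sleep.", v, suffix)] <- if (nrow(ep) >= 1) mean_(x) else NA_real_
    vals[paste0("sleep.", v, suffix, ".cv")] <- if (nrow(ep) >= 3) cv_(x) else NA_real_
  }
  tm <- timing_metrics(ep)
  vals[paste0("sleep.offset", suffix)] <- tm$offset_mean
  vals[paste0("sleep.offset", suffix, ".sd")] <- tm$offset_sd
  vals[paste0("sleep.midpoint", suffix)] <- tm$midpoint_mean
  vals[paste0("sleep.midpoint", suffix, ".sd")] <- tm$midpoint_sd
  vals
}
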