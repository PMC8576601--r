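# Hand-built participant_streams fixtures with full control over each stream.
# Defaults: full HR coverage (70 bpm), zero steps, 1.0 MET, no sleep staging.
new_streams <- function(days = 2, steps = NULL, mets = NULL, hr = NULL,
                        sleep = NULL, start_dow = 1L, id = "T1") {
  n_min <- days * 1440L
  structure(
    list(
      id = id, days = as.integer(days), start_dow = as.integer(start_dow),
      steps = if (is.null(steps)) integer(n_min) else as.integer(steps),
      mets = if (is.null(mets)) rep(1.0, n_min) else mets,
      hr = if (is.null(hr)) rep(70, n_min * 12L) else hr,
      sleep = if (is.null(sleep)) rep(NA_character_, n_min * 2L) else sleep,
      hr_interval = 5L,
      ledger = list(gap_minutes = 0L, gap_index = integer(0),
                    bouts_planned = 0L, n_episodes = 0L)
    ),
    class = "participant_streams"
  )
}

# Insert a sleep episode into a 30-s stage vector: onset/duration in hours
# from the start of the record; stages default to all "light".
with_sleep <- function(sleep_vec, onset_h, dur_h, stages = NULL) {
  start <- as.integer(round(onset_h * 120)) + 1L
  n_ep <- as.integer(round(dur_h * 120))
  if (is.null(stages)) stages <- rep("light", n_ep)
  sleep_vec[start:(start + n_ep - 1L)] <- stages
  sleep_vec
}

# Hour-of-day (0..23) for each minute of a multi-day record.
minute_hours <- function(days) rep(rep(0:23, each = 60), days)
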