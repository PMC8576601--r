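#' Configuration for a synthetic wearable cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: cohort size,
#' tracking duration, wear compliance, the test-retest correlation of the two
#' PHQ-9 assessments, and the severity-coupled effects planted into the
#' wearable streams.
#'
#' @param n_participants Number of participants (>= 2).
#' @param days_per_participant Tracking days per participant (default 14).
#' @param depressed_fraction Proportion of participants in the elevated-symptom
#'   group (default 0.15).
#' @param wear_compliance Expected proportion of minutes with the device worn
#'   (default 0.85). Non-wear is injected as contiguous blocks that remove
#'   heart-rate samples first, so the heart-rate-based completeness rule is
#'   exercised.
#' @param phq9_test_retest_r Target Pearson correlation between the two PHQ-9
#'   totals (default 0.73).
#' @param effect_sizes Named list/vector of planted effects (applied as a
#'   dose-response in latent severity); see [supported_effects()] for names
#'   and units.
#' @param start_dow Weekday of the first tracking day (1 = Monday).
#' @param seed Integer seed; the same config and seed reproduce the cohort
#'   exactly.
#' @return A `cohort_config` object (a validated list).
#' @export
cohort_config <- function(n_participants,
                          days_per_participant = 14L,
                          depressed_fraction = 0.15,
                          wear_compliance = 0.85,
                          phq9_test_retest_r = 0.73,
                          effect_sizes = list(),
                          start_dow = 1L,
                          seed = 1L) {
  assert_that(is.numeric(n_participants) && n_participants >= 2,
              "n_participants must be >= 2")
  assert_that(is.numeric(days_per_participant) && days_per_participant >= 1,
              "days_per_participant must be >= 1")
  for (p in c(depressed_fraction, wear_compliance)) {
    assert_that(is.numeric(p) && p >= 0 && p <= 1,
                "proportions must lie in [0, 1]")
  }
  assert_that(abs(phq9_test_retest_r) <= 1,
              "phq9_test_retest_r must lie in [-1, 1]")
  effect_sizes <- as.list(effect_sizes)
  unknown <- setdiff(names(effect_sizes), names(supported_effects()))
  if (length(unknown)) {
    stop("unknown effect name(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(supported_effects()), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      days_per_participant = as.integer(days_per_participant),
      depressed_fraction = depressed_fraction,
      wear_compliance = wear_compliance,
      phq9_test_retest_r = phq9_test_retest_r,
      effect_sizes = effect_sizes,
      start_dow = as.integer(start_dow),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Supported plantable effects
#'
#' Maps each plantable biomarker effect to the generator knob it turns. Inside
#' [generate_cohort()] effects follow a dose-response: each participant
#' receives the configured effect scaled by their standardized latent
#' severity, so the targeted biomarker shifts by about one cohort SD per
#' severity SD per unit effect (`sleep.midpoint` in hours per severity SD),
#' and the depressed-vs-healthy group contrast is about twice the configured
#' value under the default conditions. [plant_effects()] itself applies the
#' raw values it is given.
#'
#' * `IS.st.wd` - day-to-day jitter of the step template; negative values lower
#'   the interdaily stability of the step rhythm.
#' * `NHR.0406.cv` - scales heart-rate noise between 4 AM and 6 AM; positive
#'   values increase nighttime heart-rate variation.
#' * `peaks.st` - scales the rate of discrete activity bouts; negative values
#'   remove bouts and so lower the daily step-peak count.
#' * `sleep.midpoint` - shifts the whole sleep schedule by the stated number of
#'   hours (positive = later).
#'
#' @return Named list describing the supported effects.
#' @export
supported_effects <- function() {
  list(
    "IS.st.wd" = "day-to-day jitter of the activity template (SD units, negative lowers IS)",
    "NHR.0406.cv" = "4-6 AM heart-rate noise scale (SD units, positive raises CV)",
    "peaks.st" = "activity-bout rate scale (SD units, negative removes bouts)",
    "sleep.midpoint" = "sleep schedule shift in hours (positive = later)"
  )
}

# Calibration constants translating a +/-1 "SD unit" planted effect into the
# knob change that moves the targeted biomarker by about one cohort SD under
# the default configuration. Fixed once from a calibration run of the
# generator itself; see the methods vignette.
EFFECT_CAL <- list(
  is_jitter = 0.75,       # log-scale multiplier on day-to-day irregularity
  nhr_noise = 0.105,      # log-scale multiplier on 4-6 AM HR noise
  peak_rate = 1.10,       # log-scale multiplier on bout rate
  peak_intensity = 0.40   # log-scale multiplier on bout step rate
)

#' Baseline latent profile for one participant
#'
#' Draws the person-level parameters (activity scale, bout rate, heart-rate
#' baseline, sleep schedule, compliance) that the stream generator consumes.
#' Exposed mainly so that [plant_effects()] can be tested in isolation.
#'
#' @param seed Integer seed for the person-level draws.
#' @param wear_compliance Expected worn-minute proportion.
#' @return A `latent_profile` list.
#' @export
latent_profile <- function(seed = 1L, wear_compliance = 0.85) {
  set.seed(seed)
  prof <- list(
    activity_scale = exp(stats::rnorm(1, 0, 0.22)),
    bouts_per_day_wd = 3.8,
    bouts_per_day_we = 3.0,
    bout_hours = sort(stats::runif(6, 8.5, 21.5)),  # habitual bout start hours
    bout_time_jitter_sd = 0.35, # night-to-night jitter of bout times, h
    bout_intensity = 1.0,     # scale on bout step rate
    day_jitter_sd = 0.30,     # log-scale SD of per-hour day factors (smoothed)
    day_shift_sd = 0.30,      # SD of the daily phase shift of the template, h
    hr_rest = stats::rnorm(1, 66, 6),
    hr_day_lift = stats::rnorm(1, 15, 2),
    hr_act_gain = 0.22,       # bpm per step/min
    hr_noise_sd = 2.3,        # stationary SD of AR(1) noise, bpm
    hr_noise_phi = 0.95,
    nhr_0406_mult = 1.0,      # extra noise scale inside 4-6 AM
    sleep_onset = 23.4 + stats::rnorm(1, 0, 0.5),  # clock hours
    sleep_dur = clamp(stats::rnorm(1, 7.4, 0.45), 5.5, 9.5),
    onset_jitter_sd = 0.6,    # night-to-night, hours
    dur_jitter_sd = 0.5,
    sleep_shift = 0.0,        # planted midpoint shift, hours
    wear_compliance = wear_compliance
  )
  class(prof) <- "latent_profile"
  prof
}

#' Plant group effects into a latent profile
#'
#' Applies the configured effects (see [supported_effects()]) to a baseline
#' profile: rhythm irregularity via day-to-day template jitter, nighttime
#' heart-rate variation via the 4-6 AM noise scale, peak count via the
#' activity-bout rate, and sleep midpoint via a schedule shift. An empty
#' effect map returns the profile unchanged.
#'
#' @param profile A `latent_profile`.
#' @param effects Named list/vector of effect sizes.
#' @return The modified `latent_profile`.
#' @export
plant_effects <- function(profile, effects) {
  assert_that(inherits(profile, "latent_profile"), "profile must be a latent_profile")
  effects <- as.list(effects)
  if (!length(effects)) return(profile)
  unknown <- setdiff(names(effects), names(supported_effects()))
  if (length(unknown)) {
    stop("unknown effect name(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(supported_effects()), collapse = ", "),
         call. = FALSE)
  }
  e <- function(nm) as.numeric(effects[[nm]] %||% 0)
  # IS falls as day-to-day irregularity grows, so a negative IS effect
  # inflates the hourly jitter, the daily phase shift of the template and the
  # night-to-night jitter of habitual bout times.
  irr <- exp(-EFFECT_CAL$is_jitter * e("IS.st.wd"))
  profile$day_jitter_sd <- profile$day_jitter_sd * irr
  profile$day_shift_sd <- profile$day_shift_sd * irr
  profile$bout_time_jitter_sd <- profile$bout_time_jitter_sd * irr
  profile$nhr_0406_mult <- profile$nhr_0406_mult * exp(EFFECT_CAL$nhr_noise * e("NHR.0406.cv"))
  pk <- e("peaks.st")
  profile$bouts_per_day_wd <- profile$bouts_per_day_wd * exp(EFFECT_CAL$peak_rate * pk)
  profile$bouts_per_day_we <- profile$bouts_per_day_we * exp(EFFECT_CAL$peak_rate * pk)
  profile$bout_intensity <- profile$bout_intensity * exp(EFFECT_CAL$peak_intensity * pk)
  profile$sleep_shift <- profile$sleep_shift + e("sleep.midpoint")
  profile
}

# Smooth 24-h expected step-rate templates (steps per minute at minute
# resolution). Weekdays carry two commute-like peaks; weekends one broad,
# later peak. Scaled so that with the default bout schedule mean daily steps
# land near 10,000.
step_template <- function(weekday = TRUE) {
  m <- (seq_len(MIN_PER_DAY) - 0.5) / 60  # hour of day
  bump <- function(center, width, height) height * exp(-0.5 * ((m - center) / width)^2)
  if (weekday) {
    base <- 2.2 * (m > 7 & m < 23) +
      bump(8.3, 0.6, 16) + bump(18.2, 0.7, 14) + bump(12.8, 1.0, 5)
  } else {
    base <- 2.0 * (m > 8.5 & m < 23.5) + bump(11.5, 2.0, 10) + bump(17.5, 1.5, 7)
  }
  base
}

# One night's stage sequence: an initial wake run (sleep-onset latency), then
# semi-Markov bouts over light/deep/REM with brief wake intrusions.
gen_stage_sequence <- function(n_epochs) {
  sol_epochs <- 1L + stats::rpois(1, 14)
  mean_bout <- c(light = 40, deep = 24, rem = 20, wake = 8)   # in epochs
  probs <- c(light = 0.40, deep = 0.20, rem = 0.20, wake = 0.20)
  parts <- list(rep("wake", min(sol_epochs, n_epochs)))
  total <- length(parts[[1]])
  last <- "wake"
  while (total < n_epochs) {
    p <- probs
    p[last] <- 0
    st <- sample(names(p), 1, prob = p)
    len <- 1L + stats::rpois(1, mean_bout[[st]] - 1)
    parts[[length(parts) + 1L]] <- rep(st, len)
    total <- total + len
    last <- st
  }
  unlist(parts)[seq_len(n_epochs)]
}

# Contiguous non-wear blocks removing heart rate first: a short routine gap
# every day (charging/shower) plus occasional long device-off stretches that
# sink whole days below the completeness threshold. Returns minute indices
# (within the participant's full record) that are not worn.
gen_nonwear <- function(days, compliance) {
  if (compliance >= 1) return(integer(0))
  routine_mean <- min(70, (1 - compliance) * MIN_PER_DAY)
  mu_bad <- max(0, ((1 - compliance) * MIN_PER_DAY - routine_mean) * days / 660)
  n_bad <- stats::rpois(1, mu_bad)
  bad_days <- if (n_bad > 0) sample.int(days, min(n_bad, days)) else integer(0)
  idx <- vector("list", days)
  for (d in seq_len(days)) {
    gap_min <- round(clamp(stats::rnorm(1, routine_mean, 20), 15, 150))
    start <- sample.int(MIN_PER_DAY - gap_min, 1)
    block <- start:(start + gap_min - 1L)
    if (d %in% bad_days) {
      len <- round(stats::runif(1, 8, 14) * 60)
      s2 <- sample.int(max(1L, MIN_PER_DAY - len), 1)
      block <- c(block, s2:min(s2 + len - 1L, MIN_PER_DAY))
    }
    idx[[d]] <- unique(block) + (d - 1L) * MIN_PER_DAY
  }
  sort(unique(unlist(idx)))
}

#' Generate the wearable streams for one participant
#'
#' Builds minute-level steps and METs, 5-second heart rate (NA during non-wear
#' blocks) and 30-second sleep-stage epochs from a latent profile. The streams
#' live on regular local-clock grids starting at midnight of day 1.
#'
#' @param profile A `latent_profile` (possibly after [plant_effects()]).
#' @param days Number of tracking days.
#' @param start_dow Weekday of day 1 (1 = Monday).
#' @param seed Integer seed.
#' @param id Participant identifier.
#' @return A `participant_streams` object: list with `steps`, `mets`
#'   (length `1440 * days`), `hr` (length `17280 * days`, bpm, NA = not worn),
#'   `sleep` (length `2880 * days`, stage labels or NA), `days`, `start_dow`,
#'   `id`, and a `ledger` of injected gap/bout quantities used by tests.
#' @export
generate_participant_streams <- function(profile, days, start_dow = 1L,
                                         seed = 1L, id = "P1") {
  n_min <- days * MIN_PER_DAY
  n_slp <- days * SLEEP_PER_DAY
  n_hr <- days * HR_PER_DAY

  ## --- sleep episodes (nights 2..days; each fully inside the record) -------
  set.seed(derive_seed(seed, 1L))
  sleep <- rep(NA_character_, n_slp)
  episodes <- list()
  if (days >= 2) {
    for (night in 2:days) {
      onset_clock <- profile$sleep_onset + profile$sleep_shift +
        stats::rnorm(1, 0, profile$onset_jitter_sd)
      dur <- clamp(profile$sleep_dur + stats::rnorm(1, 0, profile$dur_jitter_sd), 4, 11)
      onset_abs <- (night - 2) * 24 + onset_clock          # hours from t=0
      ep_start <- max(1L, 1L + as.integer(round(onset_abs * 120)))
      n_ep <- as.integer(round(dur * 120))
      ep_end <- min(n_slp, ep_start + n_ep - 1L)
      if (ep_end <= ep_start) next
      sleep[ep_start:ep_end] <- gen_stage_sequence(ep_end - ep_start + 1L)
      episodes[[length(episodes) + 1L]] <-
        c(start = ep_start, end = ep_end, night = night)
    }
  }
  # minute is "asleep" if any of its two epochs is a non-wake sleep stage
  slp_mat <- matrix(sleep, nrow = 2L)
  asleep_min <- matrix(!is.na(slp_mat) & slp_mat != "wake", nrow = 2L)
  asleep_min <- asleep_min[1, ] | asleep_min[2, ]
  in_bed_min <- !is.na(slp_mat[1, ]) | !is.na(slp_mat[2, ])

  ## --- steps ----------------------------------------------------------------
  set.seed(derive_seed(seed, 2L))
  wd <- is_weekday(seq_len(days), start_dow)
  tpl_wd <- step_template(TRUE) * profile$activity_scale
  tpl_we <- step_template(FALSE) * profile$activity_scale
  mu <- numeric(n_min)
  bouts_planned <- 0L
  n_hab <- length(profile$bout_hours)
  for (d in seq_len(days)) {
    day_idx <- ((d - 1L) * MIN_PER_DAY + 1L):(d * MIN_PER_DAY)
    tpl <- if (wd[d]) tpl_wd else tpl_we
    shift_min <- as.integer(round(stats::rnorm(1, 0, profile$day_shift_sd) * 60))
    if (shift_min != 0) {
      shift_min <- shift_min %% MIN_PER_DAY
      tpl <- c(tpl[(shift_min + 1L):MIN_PER_DAY], tpl[seq_len(shift_min)])
    }
    # smooth day factor: hourly log-normal factors interpolated to minutes so
    # that irregularity does not masquerade as spikes
    jit_h <- exp(stats::rnorm(25, 0, profile$day_jitter_sd))
    jitter <- stats::approx(seq(0, MIN_PER_DAY, by = 60), jit_h,
                            xout = seq_len(MIN_PER_DAY))$y
    mu_d <- tpl * jitter
    rate <- if (wd[d]) profile$bouts_per_day_wd else profile$bouts_per_day_we
    n_bouts <- stats::rpois(1, rate)
    bouts_planned <- bouts_planned + n_bouts
    if (n_bouts > 0) {
      which_hab <- sample.int(n_hab, min(n_bouts, n_hab))
      for (b in seq_len(length(which_hab))) {
        start_h <- profile$bout_hours[which_hab[b]] +
          stats::rnorm(1, 0, profile$bout_time_jitter_sd)
        start <- clamp(as.integer(round(start_h * 60)), 420L, 1380L)
        len <- sample(15:35, 1)
        intensity <- stats::runif(1, 50, 85) * profile$bout_intensity
        sel <- start:min(start + len - 1L, MIN_PER_DAY)
        mu_d[sel] <- mu_d[sel] + intensity
      }
    }
    mu[day_idx] <- mu_d
  }
  mu[asleep_min] <- 0
  pos <- mu > 0.01
  steps <- integer(n_min)
  steps[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = 2.5)
  steps <- clamp(steps, 0L, 220L)

  ## --- METs ------------------------------------------------------------------
  set.seed(derive_seed(seed, 3L))
  mets <- 1.25 + stats::rnorm(n_min, 0, 0.18) + 0.028 * steps
  mets[asleep_min] <- 0.95 + stats::rnorm(sum(asleep_min), 0, 0.03)
  mets <- clamp(mets, 0.9, 12)

  ## --- heart rate ------------------------------------------------------------
  set.seed(derive_seed(seed, 4L))
  hod1 <- (seq_len(HR_PER_DAY) - 0.5) / (HR_PER_MIN * 60)  # hour of day, day 1
  circ <- rep((1 + cos(2 * pi * (hod1 - 15) / 24)) / 2, days)  # 0 at 3 AM
  base <- profile$hr_rest + profile$hr_day_lift * circ
  act <- profile$hr_act_gain * rep(steps, each = HR_PER_MIN)
  innov_sd <- profile$hr_noise_sd * sqrt(1 - profile$hr_noise_phi^2)
  noise <- as.numeric(stats::filter(stats::rnorm(n_hr, 0, innov_sd),
                                    profile$hr_noise_phi, method = "recursive"))
  night_win <- rep(hod1 >= 4 & hod1 < 6, days)
  noise[night_win] <- noise[night_win] * profile$nhr_0406_mult
  hr <- round(clamp(base + act + noise - 3 * rep(asleep_min, each = HR_PER_MIN), 35, 220))

  ## --- non-wear --------------------------------------------------------------
  set.seed(derive_seed(seed, 5L))
  gap_min <- gen_nonwear(days, profile$wear_compliance)
  if (length(gap_min)) {
    gap_hr <- as.vector(outer(seq_len(HR_PER_MIN), (gap_min - 1L) * HR_PER_MIN, `+`))
    hr[gap_hr] <- NA_real_
  }

  structure(
    list(
      id = id, days = as.integer(days), start_dow = as.integer(start_dow),
      steps = as.integer(steps), mets = mets, hr = hr, sleep = sleep,
      hr_interval = HR_INTERVAL_S,
      ledger = list(
        gap_minutes = length(gap_min),
        gap_index = gap_min,
        bouts_planned = bouts_planned,
        n_episodes = length(episodes)
      )
    ),
    class = "participant_streams"
  )
}

#' @export
print.participant_streams <- function(x, ...) {
  cat(sprintf("<participant_streams> %s: %d days, %d worn minutes (%.1f%%)\n",
              x$id, x$days,
              x$days * MIN_PER_DAY - x$ledger$gap_minutes,
              100 * (1 - x$ledger$gap_minutes / (x$days * MIN_PER_DAY))))
  invisible(x)
}

# PHQ-9 totals from a latent severity plus independent assessment noise.
# Severity is gamma-skewed (as observed score distributions are); the noise SD
# is the single constant calibrated so that the two totals correlate at the
# configured test-retest level under the default configuration.
phq9_noise_sd <- function(r, var_sev) {
  if (r <= 0) return(1e6)
  if (r >= 1) return(0)
  # the 1.07 factor compensates the correlation inflation caused by clipping
  # the totals at 0 (fixed once by calibration at large n)
  1.07 * sqrt(var_sev * (1 - r) / r)
}

gen_outcomes <- function(n, depressed, r_target, seed) {
  set.seed(derive_seed(seed, 7L))
  sev <- numeric(n)
  sev[!depressed] <- stats::rgamma(sum(!depressed), shape = 2.0, scale = 1.6)
  sev[depressed] <- stats::rgamma(sum(depressed), shape = 8.0, scale = 1.45)
  # variance of the severity mixture at the default depressed fraction
  var_sev <- stats::var(sev)
  sd_e <- phq9_noise_sd(r_target, var_sev)
  t1 <- clamp(round(sev + stats::rnorm(n, 0, sd_e)), 0, 27)
  t2 <- clamp(round(sev + stats::rnorm(n, 0, sd_e)), 0, 27)

  age <- clamp(round(stats::rnorm(n, 33, 8.6)), 21, 64)
  gender <- sample(c("female", "male"), n, TRUE, prob = c(0.637, 0.363))
  ethnicity <- sample(c("chinese", "indian", "malay", "other"), n, TRUE,
                      prob = c(0.790, 0.082, 0.037, 0.091))
  marital <- sample(c("single", "married"), n, TRUE, prob = c(0.61, 0.39))
  education <- sample(c("degree", "below_degree"), n, TRUE, prob = c(0.891, 0.109))
  income <- sample(c("below_4000", "above_4000"), n, TRUE, prob = c(0.577, 0.423))
  alcohol <- sample(c("yes", "no"), n, TRUE, prob = c(0.592, 0.408))
  smoking <- sample(c("nonsmoker", "smoker"), n, TRUE, prob = c(0.944, 0.056))
  health <- sample(c("excellent", "very_good", "good", "fair"), n, TRUE,
                   prob = c(0.064, 0.393, 0.464, 0.079))
  zsev <- as.numeric(scale(sev))
  loneliness <- clamp(round(37.8 + 3.5 * zsev + stats::rnorm(n, 0, 8.5)), 20, 80)
  psqi <- clamp(round(5.4 + 0.9 * zsev + stats::rnorm(n, 0, 2.3)), 0, 21)
  shi <- clamp(round(16.9 + 1.2 * zsev + stats::rnorm(n, 0, 5.3)), 0, 52)
  ess <- clamp(round(7.2 + stats::rnorm(n, 0, 4.2)), 0, 24)

  out <- tibble::tibble(
    id = sprintf("P%03d", seq_len(n)),
    depressed_group = depressed,
    phq9_t1 = as.integer(t1), phq9_t2 = as.integer(t2),
    phq9_avg = (t1 + t2) / 2,
    age = age, gender = gender, ethnicity = ethnicity, marital = marital,
    education = education, income = income, alcohol = alcohol,
    smoking = smoking, health = health,
    loneliness = loneliness, psqi = psqi, shi = shi, ess = ess
  )
  attr(out, "severity_z") <- zsev
  out
}

#' Generate a synthetic wearable cohort
#'
#' Draws a full cohort of participant streams plus outcome records under the
#' configured study conditions. Planted effects follow a dose-response in the
#' latent PHQ-9 severity shared with the outcome totals: a participant one
#' severity SD above the mean receives the configured effects at full
#' strength, the depressed subgroup (drawn from a higher severity
#' distribution) about twice that on average. The same config and seed
#' reproduce the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @return A `wearable_cohort`: list with `streams` (list of
#'   `participant_streams`), `outcomes` (tibble of PHQ-9 totals, group flags
#'   and covariates) and the originating `config`.
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  n <- config$n_participants
  set.seed(derive_seed(config$seed, 0L))
  n_dep <- round(config$depressed_fraction * n)
  depressed <- rep(FALSE, n)
  if (n_dep > 0) depressed[sample.int(n, n_dep)] <- TRUE

  outcomes <- gen_outcomes(n, depressed, config$phq9_test_retest_r, config$seed)
  # dose-response planting: each participant's effects scale with their
  # standardized latent severity (clamped), so biomarkers track the severity
  # continuum rather than jumping at the group boundary
  dose <- clamp(attr(outcomes, "severity_z"), -2.5, 2.5)

  streams <- vector("list", n)
  for (i in seq_len(n)) {
    pseed <- derive_seed(config$seed, 100L + i)
    prof <- latent_profile(seed = pseed, wear_compliance = config$wear_compliance)
    if (length(config$effect_sizes)) {
      prof <- plant_effects(prof, lapply(config$effect_sizes,
                                         function(v) v * dose[i]))
    }
    streams[[i]] <- generate_participant_streams(
      prof, config$days_per_participant, config$start_dow,
      seed = pseed, id = outcomes$id[i]
    )
  }
  names(streams) <- outcomes$id
  structure(list(streams = streams, outcomes = outcomes, config = config),
            class = "wearable_cohort")
}

#' @export
print.wearable_cohort <- function(x, ...) {
  cat(sprintf("<wearable_cohort> %d participants x %d days (%d in effect group)\n",
              length(x$streams), x$config$days_per_participant,
              sum(x$outcomes$depressed_group)))
  invisible(x)
}
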