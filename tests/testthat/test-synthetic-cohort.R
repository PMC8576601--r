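test_that("cohort configuration is validated", {
  expect_error(cohort_config(1), "n_participants")
  expect_error(cohort_config(10, depressed_fraction = 1.2), "proportions")
  expect_error(cohort_config(10, days_per_participant = 0), "days_per_participant")
  expect_error(cohort_config(10, effect_sizes = list(bogus = 1)), "unknown effect")
})

test_that("the same config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(4, days_per_participant = 7, seed = 11)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$streams, c2$streams)
  expect_identical(c1$outcomes, c2$outcomes)
  c3 <- generate_cohort(cohort_config(4, days_per_participant = 7, seed = 12))
  expect_false(identical(c1$streams, c3$streams))
})

test_that("stream invariants hold on generated participants", {
  s <- generate_participant_streams(latent_profile(seed = 5), 14, 1L, seed = 5)
  expect_true(all(s$steps >= 0))
  expect_true(all(s$mets >= 0))
  hr <- s$hr[!is.na(s$hr)]
  expect_true(all(hr > 20 & hr < 250))
  expect_true(all(s$sleep[!is.na(s$sleep)] %in% c("wake", "light", "deep", "rem")))
  expect_length(s$steps, 14 * 1440)
  expect_length(s$hr, 14 * 17280)
  expect_length(s$sleep, 14 * 2880)
})

test_that("PHQ-9 totals hit the configured test-retest correlation", {
  dep <- rep(c(TRUE, FALSE), c(75, 425))
  r <- sapply(1:3, function(s) {
    oc <- actidep:::gen_outcomes(500, sample(dep), 0.73, seed = s)
    expect_true(all(oc$phq9_t1 >= 0 & oc$phq9_t1 <= 27))
    expect_equal(oc$phq9_avg, (oc$phq9_t1 + oc$phq9_t2) / 2)
    cor(oc$phq9_t1, oc$phq9_t2)
  })
  expect_true(all(abs(r - 0.73) < 0.05))
})

test_that("an empty effect map leaves the profile unchanged", {
  prof <- latent_profile(seed = 3)
  expect_identical(plant_effects(prof, list()), prof)
  expect_error(plant_effects(prof, list(nope = 2)), "supported")
})

test_that("nighttime HR effect inflates 4-6 AM spread, all else equal", {
  prof0 <- latent_profile(seed = 8)
  prof1 <- plant_effects(latent_profile(seed = 8), list("NHR.0406.cv" = 1))
  s0 <- generate_participant_streams(prof0, 7, 1L, seed = 8)
  s1 <- generate_participant_streams(prof1, 7, 1L, seed = 8)
  hod <- rep((seq_len(17280) - 0.5) / 720, 7) %% 24
  win <- hod >= 4 & hod < 6
  expect_gt(sd(s1$hr[win], na.rm = TRUE), sd(s0$hr[win], na.rm = TRUE))
  # streams outside the perturbed component are untouched under the same seed
  expect_identical(s0$steps, s1$steps)
  expect_identical(s0$sleep, s1$sleep)
})

test_that("a +1 h sleep-midpoint effect delays recovered midpoints by about 1 h", {
  mids <- function(effect) {
    m <- sapply(1:8, function(i) {
      prof <- plant_effects(latent_profile(seed = 100 + i), effect)
      s <- generate_participant_streams(prof, 14, 1L, seed = 100 + i)
      mean(sleep_episodes(s)$midpoint_hour)
    })
    mean(m)
  }
  d <- mids(list("sleep.midpoint" = 1)) - mids(list())
  expect_gt(d, 0.8)
  expect_lt(d, 1.2)
})

test_that("injected non-wear matches the completeness mask", {
  s <- generate_participant_streams(latent_profile(seed = 17), 14, 1L, seed = 17)
  rep_ <- completeness_mask(s)
  expect_equal(rep_$minutes_total - rep_$minutes_complete, s$ledger$gap_minutes)
  expect_setequal(which(!rep_$minute_complete), s$ledger$gap_index)
})

test_that("planted IS deficit is detectable downstream at n = 200", {
  cfg <- cohort_config(200, depressed_fraction = 0.15,
                       effect_sizes = list("IS.st.wd" = -1), seed = 31)
  coh <- generate_cohort(cfg)
  fm <- biomarker_matrix(coh)
  oc <- coh$outcomes[match(fm$id, coh$outcomes$id), ]
  tt <- t.test(fm$IS.st.wd[oc$depressed_group], fm$IS.st.wd[!oc$depressed_group])
  expect_lt(tt$p.value, 0.01)
  expect_lt(diff(rev(tt$estimate)), 0)  # depressed mean lower
})
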