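test_that("completeness is driven by heart-rate coverage", {
  s <- new_streams(days = 1)                      # full 5-s coverage
  rep_ <- completeness_mask(s)
  expect_equal(rep_$complete_hours, 24)

  # one 5-hour HR gap: hours 10-15 missing
  hr <- rep(70, 17280)
  hr[(10 * 3600 / 5 + 1):(15 * 3600 / 5)] <- NA
  rep_ <- completeness_mask(new_streams(days = 1, hr = hr))
  expect_equal(rep_$complete_hours, 19)

  # a single sample in a minute is enough
  hr2 <- rep(NA_real_, 17280)
  hr2[seq(1, 17280, by = 12)] <- 70               # one sample per minute
  rep_ <- completeness_mask(new_streams(days = 1, hr = hr2))
  expect_equal(rep_$complete_hours, 24)

  # empty HR stream: zero complete days, not an error
  rep_ <- completeness_mask(new_streams(days = 1, hr = rep(NA_real_, 17280)))
  expect_equal(rep_$complete_hours, 0)
  expect_length(rep_$complete_days, 0)
})

test_that("day filter is boundary-inclusive at 20 hours", {
  gap_to_hours <- function(gap_min) {
    hr <- rep(70, 17280)
    if (gap_min > 0) hr[1:(gap_min * 12)] <- NA
    completeness_mask(new_streams(days = 1, hr = hr))
  }
  expect_equal(filter_days(gap_to_hours(240)), 1L)        # exactly 20.0 h
  expect_length(filter_days(gap_to_hours(241)), 0)        # 19.98 h
  s14 <- new_streams(days = 14)
  expect_equal(filter_days(completeness_mask(s14)), 1:14)
})

test_that("participant filter enforces day and weekday-night minimums", {
  ds <- list(1:10, 1:9, 1:12)
  expect_equal(filter_participants(ds), c(TRUE, FALSE, TRUE))
  expect_equal(filter_participants(ds, weekday_nights = c(3L, 5L, 2L)),
               c(TRUE, FALSE, FALSE))
})

test_that("Tukey outlier rule matches brute-force quartile computation", {
  x <- c(1:12, 100)
  expect_equal(which(tukey_outlier_flags(x)), 13L)
  expect_false(any(tukey_outlier_flags(rep(5, 10))))
  y <- c(rep(50, 20), -1000, 1000)
  expect_equal(which(tukey_outlier_flags(y)), c(21L, 22L))
  expect_warning(tukey_outlier_flags(c(1, 2, 3)), "fewer than 4")
  # oracle on random draws under the type-7 convention
  set.seed(1)
  for (i in 1:50) {
    v <- rnorm(sample(5:40, 1))
    q1 <- quantile(v, 0.25, type = 7)
    q3 <- quantile(v, 0.75, type = 7)
    iqr <- q3 - q1
    expect_identical(tukey_outlier_flags(v),
                     unname(v < q1 - 1.5 * iqr | v > q3 + 1.5 * iqr))
  }
})

test_that("retained plus discarded minutes equal complete minutes", {
  s <- generate_participant_streams(latent_profile(seed = 2), 14, 1L, seed = 2)
  rep_ <- completeness_mask(s)
  expect_equal(rep_$minutes_retained + rep_$minutes_discarded,
               rep_$minutes_complete)
  # filtering is idempotent
  expect_identical(filter_days(rep_), filter_days(rep_))
})

test_that("cohort QC excludes outlying participants and writes a summary", {
  coh <- generate_cohort(cohort_config(8, days_per_participant = 14, seed = 4))
  # implant an absurd heart rate in one participant
  coh$streams[[3]]$hr <- coh$streams[[3]]$hr + 90
  qc <- suppressWarnings(qc_cohort(coh))
  expect_s3_class(qc$summary, "tbl_df")
  expect_true(qc$summary$outlier_hr[3])
  expect_false(qc$summary$included[3])
  expect_equal(nrow(qc$summary), 8)
})

test_that("the CSV dialect round-trips streams and outcomes", {
  coh <- generate_cohort(cohort_config(3, days_per_participant = 3, seed = 6))
  dir <- tempfile("csvrt_")
  mpath <- write_cohort_csv(coh, dir)
  back <- read_cohort_csv(mpath)
  for (i in 1:3) {
    expect_identical(back$streams[[i]]$steps, coh$streams[[i]]$steps)
    expect_equal(back$streams[[i]]$hr, coh$streams[[i]]$hr)
    expect_identical(back$streams[[i]]$sleep, coh$streams[[i]]$sleep)
  }
  expect_equal(back$outcomes$phq9_t1, coh$outcomes$phq9_t1)
  unlink(dir, recursive = TRUE)
})
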