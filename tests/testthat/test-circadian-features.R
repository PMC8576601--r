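test_that("IS is 1 for repeated identical days and matches its formula", {
  prof <- c(rep(0, 8), rep(50, 10), rep(5, 6))
  mat <- matrix(rep(prof, 3), nrow = 24)
  expect_equal(interdaily_stability(mat), 1.0)
  expect_true(is.na(interdaily_stability(matrix(3, 24, 4))))
  set.seed(2)
  noisy <- matrix(rnorm(24 * 14), nrow = 24)
  expect_lt(interdaily_stability(noisy), 0.3)
})

test_that("IV matches the closed-form alternating-series value", {
  x <- rep(c(0, 2), 24)                            # two days of hourly 0,2,0,2...
  expect_equal(intradaily_variability(x), 4.0)
  smooth <- sin(2 * pi * (1:48) / 24)
  expect_lt(intradaily_variability(smooth), 0.2)
  # shuffling hours within days increases fragmentation
  set.seed(5)
  prof <- c(rep(1, 8), rep(40, 10), rep(4, 6)) + rnorm(24)
  series <- rep(prof, 3)
  shuffled <- as.vector(apply(matrix(series, 24), 2, sample))
  expect_gt(intradaily_variability(shuffled), intradaily_variability(series))
})

test_that("ICV averages per-hour across-day CVs", {
  mat <- matrix(rep(c(rep(100, 12), rep(10, 12)), 2), nrow = 24)
  expect_equal(interdaily_cv(mat), 0)
  mat[3, ] <- c(90, 110)
  expect_equal(interdaily_cv(mat), sd(c(90, 110)) / 100 / 24)
  # zero-mean hours are skipped with the divisor reduced
  mat2 <- mat
  mat2[5, ] <- 0
  expect_warning(v <- interdaily_cv(mat2), "skipped")
  expect_equal(v, sd(c(90, 110)) / 100 / 23)
  # monotone in the day-to-day jitter
  set.seed(3)
  prof <- c(rep(5, 8), rep(60, 16))
  icv_at <- function(s) {
    m <- sapply(1:20, function(d) prof * exp(rnorm(24, 0, s)))
    interdaily_cv(m)
  }
  expect_lt(icv_at(0.1), icv_at(0.6))
})

test_that("M10/L5 windows are circular and RA follows its formula", {
  prof <- c(rep(50, 18), rep(200, 6))              # most active block wraps? no
  mat <- matrix(rep(prof, 2), nrow = 24)
  res <- m10_l5_ra(mat)
  expect_equal(unname(res["L5"]), 50)
  expect_equal(unname(res["RA"]),
               (res[["M10"]] - res[["L5"]]) / (res[["M10"]] + res[["L5"]]))
  # constant profile: RA = 0
  expect_equal(unname(m10_l5_ra(matrix(7, 24, 3))["RA"]), 0)
  # square wave active 08:00-18:00 with zero nights: L5 = 0, RA = 1
  sq <- c(rep(0, 8), rep(100, 10), rep(0, 6))
  expect_equal(unname(m10_l5_ra(matrix(rep(sq, 2), nrow = 24))["RA"]), 1)
  # M10 = 200, L5 = 50 arithmetic
  expect_equal((200 - 50) / (200 + 50), 0.6)
  # windows must wrap midnight: nocturnal block split across the day edge
  prof2 <- c(rep(0, 3), rep(80, 18), rep(0, 3))
  l5 <- unname(m10_l5_ra(matrix(rep(prof2, 2), nrow = 24))["L5"])
  expect_equal(l5, mean(c(0, 0, 0, 0, 0)))
})

test_that("day-lag autocorrelation uses the full-sample denominator", {
  prof <- c(rep(1, 6), rep(30, 12), rep(2, 6))
  x <- rep(prof, 3)                                # N = 72, k = 24
  expect_equal(day_lag_autocorrelation(x, 24), (72 - 24) / 72)
  set.seed(7)
  noise <- rnorm(480)
  expect_lt(abs(day_lag_autocorrelation(noise, 96)), 3 / sqrt(480))
  rot12 <- c(prof[13:24], prof[1:12])              # activity moved to night
  anti <- rep(c(prof, rot12), 2)
  expect_lt(day_lag_autocorrelation(anti, 24), 0)
  expect_true(is.na(day_lag_autocorrelation(rep(2, 48), 24)))
})

test_that("peak detector matches the published z-score reference", {
  set.seed(11)
  flat <- rep(10, 96 * 2)
  expect_equal(detect_peaks(flat)$n_peaks, 0)
  spiky <- rep(10, 96 * 3) + rnorm(288, 0, 0.3)
  spike_at <- c(30, 50, 80, 30 + 96, 50 + 96, 80 + 96, 30 + 192, 50 + 192, 80 + 192)
  spiky[spike_at] <- 60
  # at a high threshold only the implanted spikes fire: 3 per day, SD 0
  counts <- daily_peak_counts(spiky, 96, threshold = 3.5)
  expect_equal(counts, c(3, 3, 3))
  det <- detect_peaks(spiky)
  ref <- bf_peak_signals(spiky, lag = 12, threshold = 2, influence = 0.1)
  expect_equal(det$signals, ref)
  # lowering the threshold never decreases the count
  thr <- c(3.5, 3, 2.5, 2, 1.5, 1)
  n_at <- sapply(thr, function(th) detect_peaks(spiky, threshold = th)$n_peaks)
  expect_true(all(diff(n_at) >= 0))
  expect_null(detect_peaks(spiky[1:10]))
})

test_that("peak signals agree with the reference on random series", {
  set.seed(21)
  for (i in 1:20) {
    y <- rpois(200, 5) + c(rep(0, 100), rep(20, 5), rep(0, 95)) * sample(0:1, 1)
    mine <- detect_peaks(y, lag = 10, threshold = 2.5, influence = 0.2)
    ref <- bf_peak_signals(y, lag = 10, threshold = 2.5, influence = 0.2)
    expect_equal(mine$signals, ref)
  }
})

test_that("the extended cosinor recovers noiseless parameters", {
  truth <- c(min = 20, amp = 180, phi = 14.5, alpha = 0.35, beta = 7)
  t <- rep(seq(0.5, 23.5, by = 1), 5)
  y <- cosinor_curve(t, as.list(truth))
  fit <- fit_extended_cosinor(t, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$min - truth["min"]) / truth["min"], 1e-3)
  expect_lt(abs(fit$amp - truth["amp"]) / truth["amp"], 1e-3)
  expect_lt(abs(fit$phi %% 24 - truth["phi"]) / truth["phi"], 1e-3)
  expect_lt(abs(fit$alpha - truth["alpha"]) / truth["alpha"], 1e-3)
  expect_lt(abs(fit$beta - truth["beta"]) / truth["beta"], 1e-3)
  expect_error(fit_extended_cosinor(t, rep(5, length(t))), "constant")
})

test_that("rhythm metrics are invariant to a common time shift", {
  set.seed(13)
  prof <- c(rep(2, 7), rep(55, 10), rep(8, 7))
  mat <- sapply(1:10, function(d) prof * exp(rnorm(24, 0, 0.2)))
  shift <- 5
  mat_s <- mat[c((shift + 1):24, 1:shift), ]
  expect_equal(interdaily_stability(mat_s), interdaily_stability(mat))
  expect_equal(interdaily_cv(mat_s), interdaily_cv(mat), tolerance = 1e-12)
  expect_equal(m10_l5_ra(mat_s)[["RA"]], m10_l5_ra(mat)[["RA"]], tolerance = 1e-12)
  # acrophase moves by the shift, modulo 24
  t <- rep(seq(0.5, 23.5), 6)
  y <- cosinor_curve(t, list(min = 5, amp = 60, phi = 15, alpha = 0.2, beta = 6))
  f1 <- fit_extended_cosinor(t, y)
  f2 <- fit_extended_cosinor((t + shift) %% 24, y)
  expect_equal((f2$acrophase - f1$acrophase) %% 24, shift, tolerance = 1e-4)
})
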