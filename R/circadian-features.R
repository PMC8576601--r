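## Circadian rhythm biomarkers from hourly (and finer) aggregated steps and
## heart-rate series: nonparametric stability/fragmentation indices, day-lag
## autocorrelation, z-score peak detection, and the extended (sigmoidally
## transformed) cosinor model.

#' Interdaily stability (IS)
#'
#' Ratio of the variance of the mean 24-hour profile to the total variance of
#' the hourly series:
#' `IS = (N * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2)`
#' with `p` points per day (24). Lies in `[0, 1]`; higher values indicate a
#' more regular rhythm.
#'
#' @param mat A `p x D` matrix of hourly values (rows = hour of day, columns =
#'   days); NAs are dropped.
#' @return IS, or NA for a constant (or empty) series.
#' @export
interdaily_stability <- function(mat) {
  x <- as.vector(mat)
  n <- sum(!is.na(x))
  xbar <- mean_(x)
  denom_total <- sum((x - xbar)^2, na.rm = TRUE)
  if (n < 2 || denom_total == 0) return(NA_real_)
  prof <- rowMeans(mat, na.rm = TRUE)
  prof <- prof[!is.nan(prof)]
  p <- length(prof)
  (n * sum((prof - xbar)^2)) / (p * denom_total)
}

#' Intradaily variability (IV)
#'
#' Mean square of successive differences of the hourly series normalized by
#' its variance:
#' `IV = (N * sum diff^2) / ((N - 1) * sum (x_i - xbar)^2)`.
#' Gaps (NA) break successiveness. Higher values indicate a more fragmented
#' rhythm.
#'
#' @param x Hourly series in time order (vector or matrix in column-day
#'   layout).
#' @return IV, or NA for a constant series or no valid successive pair.
#' @export
intradaily_variability <- function(x) {
  x <- as.vector(x)
  n <- sum(!is.na(x))
  xbar <- mean_(x)
  denom <- sum((x - xbar)^2, na.rm = TRUE)
  if (n < 2 || denom == 0) return(NA_real_)
  d <- diff(x)
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  (n * sum(d^2)) / ((n - 1) * denom)
}

#' Interdaily coefficient of variation (ICV)
#'
#' The 24-hour mean of per-hour across-day CVs:
#' `ICV = (1/p) * sum_h SD_h / mean_h`. Hours whose across-day mean is zero
#' (or with fewer than two days) are skipped with the divisor reduced.
#'
#' @param mat A `p x D` hourly matrix (rows = hour of day).
#' @return ICV, or NA when no hour qualifies.
#' @export
interdaily_cv <- function(mat) {
  cvs <- apply(mat, 1, function(h) {
    h <- h[!is.na(h)]
    if (length(h) < 2) return(NA_real_)
    m <- mean(h)
    if (m == 0) return(NA_real_)
    stats::sd(h) / m
  })
  skipped <- sum(is.na(cvs))
  if (skipped > 0 && skipped < length(cvs)) {
    warning(sprintf("%d hour(s) skipped (zero mean or too few days)", skipped))
  }
  if (all(is.na(cvs))) return(NA_real_)
  mean(cvs, na.rm = TRUE)
}

#' M10, L5 and relative amplitude (RA)
#'
#' Mean of the 10 consecutive most active and the 5 consecutive least active
#' hours of the average 24-hour profile, searched circularly;
#' `RA = (M10 - L5) / (M10 + L5)`.
#'
#' @param mat A `24 x D` hourly matrix.
#' @return Named vector `M10`, `L5`, `RA` (RA is NA when `M10 + L5 = 0`).
#' @export
m10_l5_ra <- function(mat) {
  prof <- rowMeans(mat, na.rm = TRUE)
  prof[is.nan(prof)] <- NA_real_
  if (all(is.na(prof))) return(c(M10 = NA_real_, L5 = NA_real_, RA = NA_real_))
  wrap <- c(prof, prof)
  m10 <- max(circular_window_means(wrap, 10L), na.rm = TRUE)
  l5 <- min(circular_window_means(wrap, 5L), na.rm = TRUE)
  ra <- if ((m10 + l5) == 0) NA_real_ else (m10 - l5) / (m10 + l5)
  c(M10 = m10, L5 = l5, RA = ra)
}

# Means of all 24 circular windows of width w over the doubled profile.
circular_window_means <- function(wrap, w) {
  vapply(seq_len(24), function(s) mean(wrap[s:(s + w - 1)], na.rm = TRUE),
         numeric(1))
}

#' Day-length-lag autocorrelation
#'
#' The lag-`k` autocorrelation with the full-sample denominator:
#' `AC(k) = sum_{i<=N-k} (x_i - xbar)(x_{i+k} - xbar) / sum_i (x_i - xbar)^2`,
#' where `k` is the number of aggregation intervals per day. Pairs containing
#' NA are dropped from the numerator; an alternative estimator that rescales
#' by the pair count is available via `pair_normalized = TRUE`.
#'
#' @param x Aggregated series in time order.
#' @param k Day-length lag in points.
#' @param pair_normalized Use the pair-count-normalized estimator (off by
#'   default).
#' @return AC in `[-1, 1]`, or NA for a constant series or fewer than `k + 1`
#'   points.
#' @export
day_lag_autocorrelation <- function(x, k, pair_normalized = FALSE) {
  x <- as.vector(x)
  n <- length(x)
  if (n <= k) return(NA_real_)
  xbar <- mean_(x)
  denom <- sum((x - xbar)^2, na.rm = TRUE)
  if (is.na(xbar) || denom == 0) return(NA_real_)
  a <- x[seq_len(n - k)] - xbar
  b <- x[seq_len(n - k) + k] - xbar
  prod <- a * b
  ok <- !is.na(prod)
  if (!any(ok)) return(NA_real_)
  num <- sum(prod[ok])
  if (pair_normalized) {
    n_eff <- sum(!is.na(x))
    num <- num * (n_eff / sum(ok))
  }
  num / denom
}

#' Robust z-score peak detection
#'
#' Streaming detector: a point is signaled when it deviates from the trailing
#' moving mean by more than `threshold` trailing moving SDs over the last
#' `lag` points; signaled points enter the trailing statistics with weight
#' `influence`. Contiguous upward-signaled runs count as one peak.
#'
#' @param x Aggregated series in time order (NAs are treated as the trailing
#'   filtered value and never signal).
#' @param lag Trailing window length in points (default 12).
#' @param threshold SD multiplier (default 2).
#' @param influence Weight of signaled points in the trailing statistics
#'   (default 0.1).
#' @return List with `signals` (-1/0/+1 per point) and `n_peaks` (count of
#'   upward runs), or NULL when the series is shorter than `lag + 1`.
#' @export
detect_peaks <- function(x, lag = 12L, threshold = 2.0, influence = 0.1) {
  n <- length(x)
  if (n < lag + 1) return(NULL)
  x[is.na(x)] <- 0
  signals <- integer(n)
  filt <- x
  # trailing window statistics maintained incrementally (sum and sum of
  # squares) to keep the scan linear
  s1 <- sum(filt[1:lag])
  s2 <- sum(filt[1:lag]^2)
  for (i in (lag + 1L):n) {
    avg <- s1 / lag
    varw <- (s2 - s1 * s1 / lag) / (lag - 1)
    std <- if (varw > 0) sqrt(varw) else 0
    if (std > 0 && abs(x[i] - avg) > threshold * std) {
      signals[i] <- if (x[i] > avg) 1L else -1L
      filt[i] <- influence * x[i] + (1 - influence) * filt[i - 1L]
    } else {
      filt[i] <- x[i]
    }
    drop <- filt[i - lag]
    s1 <- s1 + filt[i] - drop
    s2 <- s2 + filt[i]^2 - drop^2
  }
  up <- signals == 1L
  n_peaks <- sum(up & !c(FALSE, up[-n]))
  list(signals = signals, n_peaks = n_peaks)
}

#' Per-day peak counts for a binned series laid out day by day
#'
#' Runs [detect_peaks()] over the concatenated series and counts upward-run
#' starts within each day of `bins_per_day` points.
#'
#' @inheritParams detect_peaks
#' @param bins_per_day Number of aggregation bins per day.
#' @return Numeric vector of daily peak counts, or NULL when the series is
#'   too short.
#' @export
daily_peak_counts <- function(x, bins_per_day, lag = 12L, threshold = 2.0,
                              influence = 0.1) {
  det <- detect_peaks(x, lag, threshold, influence)
  if (is.null(det)) return(NULL)
  n_days <- length(x) %/% bins_per_day
  if (n_days < 1) return(NULL)
  up <- det$signals == 1L
  starts <- up & !c(FALSE, up[-length(up)])
  day_of <- rep(seq_len(n_days), each = bins_per_day)[seq_along(x)]
  counts <- tapply(starts, day_of, sum)
  as.numeric(counts)
}

## --- extended cosinor -------------------------------------------------------

#' Evaluate the extended cosinor curve
#'
#' Predicts the fitted curve value at time-of-day `t` for parameters
#' `min`, `amp`, `phi`, `alpha`, `beta` (see [fit_extended_cosinor()]).
#'
#' @param t Hours (any length).
#' @param par Named list/vector of the five raw parameters.
#' @return Numeric vector of curve values.
#' @export
cosinor_curve <- function(t, par) {
  c_t <- cos(2 * pi * (t - par[["phi"]]) / 24)
  par[["min"]] + par[["amp"]] * stats::plogis(par[["beta"]] * (c_t - par[["alpha"]]))
}

# Residuals of the extended cosinor for parameter vector
# p = (min, amp, phi, alpha, beta).
cosinor_resid <- function(p, t, y) {
  z <- p[5] * (cos(2 * pi * (t - p[3]) / 24) - p[4])
  y - (p[1] + p[2] / (1 + exp(-z)))
}

#' Fit the extended (sigmoidally transformed) cosinor model
#'
#' Fits `y(t) = min + amp * F(cos(2*pi*(t - phi)/24))` with
#' `F(c) = 1 / (1 + exp(-beta * (c - alpha)))` by nonlinear least squares
#' (Levenberg-Marquardt, multi-start over an acrophase grid). `alpha` is the
#' relative width of the peak and `beta` the steepness of its rise and fall.
#' The rhythm-adjusted mean (mesor) is the mean of the fitted curve over the
#' day; the amplitude reported is the curve maximum minus the mesor; the
#' acrophase is the clock time of the curve peak, wrapped to `[0, 24)`. The
#' pseudo-F statistic compares the fit against the constant model:
#' `F = ((SS0 - SSR)/(q - 1)) / (SSR/(n - q))` with `q = 5` parameters.
#'
#' @param t Time of day in hours for each observation.
#' @param y Observed values (same length as `t`); NAs dropped pairwise.
#' @param phi_grid Acrophase starting grid in hours.
#' @return A `cosinor_fit` list: `mesor`, `amplitude`, `acrophase`, `alpha`,
#'   `beta`, `pseudo_f`, raw parameters (`min`, `amp`, `phi`), `converged`.
#' @export
fit_extended_cosinor <- function(t, y, phi_grid = c(0, 6, 12, 18)) {
  ok <- !is.na(y) & !is.na(t)
  t <- t[ok]; y <- y[ok]
  n <- length(y)
  failed <- list(mesor = NA_real_, amplitude = NA_real_, acrophase = NA_real_,
                 alpha = NA_real_, beta = NA_real_, pseudo_f = NA_real_,
                 min = NA_real_, amp = NA_real_, phi = NA_real_,
                 converged = FALSE)
  class(failed) <- "cosinor_fit"
  if (n < 10 || stats::sd(y) == 0) {
    if (n >= 1 && stats::sd(y) == 0) stop("constant series: cosinor fit is degenerate")
    return(failed)
  }
  lower <- c(-Inf, 0, -Inf, -0.99, 0.05)
  upper <- c(Inf, Inf, Inf, 0.99, 60)
  rng <- diff(range(y))
  # multi-start over the acrophase grid: starts are screened by initial SSR
  # and full Levenberg-Marquardt runs launched from the best two
  starts <- lapply(phi_grid, function(phi0) c(min(y), max(rng, 1e-3), phi0, 0, 4))
  ssr0 <- vapply(starts, function(p0) sum(cosinor_resid(p0, t, y)^2), numeric(1))
  starts <- starts[order(ssr0)][1:min(2L, length(starts))]
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = cosinor_resid, t = t, y = y,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-8, ptol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) return(failed)
  p <- best$fit$par
  names(p) <- c("min", "amp", "phi", "alpha", "beta")
  grid <- seq(0, 24, by = 0.05)
  curve <- cosinor_curve(grid, as.list(p))
  mesor <- mean(curve)
  amplitude <- max(curve) - mesor
  q <- 5
  ss0 <- sum((y - mean(y))^2)
  pseudo_f <- ((ss0 - best$ssr) / (q - 1)) / (best$ssr / (n - q))
  # accept boundary-pinned fits whose SSR trace has flattened: the optimizer
  # reports maxiter when a parameter rides its bound even though the fit is done
  trace <- best$fit$rsstrace
  flat <- length(trace) >= 2 &&
    abs(diff(utils::tail(trace, 2))) <= 1e-8 * (utils::tail(trace, 1) + 1e-12)
  out <- list(
    mesor = mesor, amplitude = amplitude,
    acrophase = p[["phi"]] %% 24,
    alpha = p[["alpha"]], beta = p[["beta"]],
    pseudo_f = max(pseudo_f, 0),
    min = p[["min"]], amp = p[["amp"]], phi = p[["phi"]],
    converged = best$fit$info %in% 1:4 || flat
  )
  class(out) <- "cosinor_fit"
  out
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> mesor %.2f, amplitude %.2f, acrophase %.2f h, alpha %.2f, beta %.2f, pseudo-F %.1f (%s)\n",
    x$mesor, x$amplitude, x$acrophase, x$alpha, x$beta, x$pseudo_f,
    if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

## --- aggregation helpers and the family summary ----------------------------

# Bin a minute-level series over the selected complete days.
# agg = "sum": per-bin total inferred from the mean over available complete
# minutes (missing-aware); agg = "mean": plain mean. Returns a matrix
# bins_per_day x D in chronological day order.
bin_matrix <- function(values_min, minute_complete, day_set, bin_minutes,
                       agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  day_set <- sort(day_set)
  if (!length(day_set)) return(NULL)
  bins_per_day <- MIN_PER_DAY %/% bin_minutes
  v <- values_min
  v[!minute_complete] <- NA_real_
  sel <- as.vector(outer(seq_len(MIN_PER_DAY), (day_set - 1L) * MIN_PER_DAY, `+`))
  bm <- col_means_na(matrix(v[sel], nrow = bin_minutes))
  if (agg == "sum") bm <- bm * bin_minutes
  matrix(bm, nrow = bins_per_day)
}

# All nonparametric + cosinor + peak features for one source series.
circadian_source_features <- function(values_min, minute_complete, day_set,
                                      start_dow, source, agg,
                                      peak_lag = 12L, peak_threshold = 2.0,
                                      peak_influence = 0.1) {
  out <- c()
  for (variant in c("", ".wd")) {
    dset <- if (variant == ".wd") {
      intersect(day_set, which(is_weekday(seq_len(length(values_min) %/% MIN_PER_DAY),
                                          start_dow)))
    } else day_set
    sfx <- paste0(".", source, variant)
    enough <- length(dset) >= 2
    hourly <- if (enough) bin_matrix(values_min, minute_complete, dset, 60L, agg) else NULL
    mat30 <- if (enough) bin_matrix(values_min, minute_complete, dset, 30L, agg) else NULL
    mat15 <- if (enough) bin_matrix(values_min, minute_complete, dset, 15L, agg) else NULL
    if (is.null(hourly)) {
      nm <- c("IS", "IV", "ICV", "M10", "L5", "RA")
      out[paste0(nm, sfx)] <- NA_real_
    } else {
      suppressWarnings({
        out[paste0("IS", sfx)] <- interdaily_stability(hourly)
        out[paste0("IV", sfx)] <- intradaily_variability(hourly)
        out[paste0("ICV", sfx)] <- interdaily_cv(hourly)
      })
      mlr <- m10_l5_ra(hourly)
      out[paste0("M10", sfx)] <- mlr[["M10"]]
      out[paste0("L5", sfx)] <- mlr[["L5"]]
      out[paste0("RA", sfx)] <- mlr[["RA"]]
    }
    # day-lag autocorrelation at 15/30/60-minute aggregation
    mats <- list("15" = mat15, "30" = mat30, "60" = hourly)
    for (bm in c(15L, 30L, 60L)) {
      nm <- paste0("AC.", source, ".", bm, "m", variant)
      mat <- mats[[as.character(bm)]]
      out[nm] <- if (is.null(mat)) NA_real_ else {
        day_lag_autocorrelation(as.vector(mat), MIN_PER_DAY %/% bm)
      }
    }
    # peak detection on the 15-minute aggregation
    pk <- if (!is.null(mat15)) {
      daily_peak_counts(as.vector(mat15), 96L, peak_lag, peak_threshold,
                        peak_influence)
    } else NULL
    out[paste0("peaks", sfx)] <- if (is.null(pk)) NA_real_ else mean(pk)
    out[paste0("peaks", sfx, ".sd")] <- if (is.null(pk) || length(pk) < 2) {
      NA_real_
    } else stats::sd(pk)
    # extended cosinor on the hourly series
    fit <- if (!is.null(hourly) && sum(!is.na(hourly)) >= 48 &&
               sd_(as.vector(hourly)) > 0) {
      t_hour <- rep(seq_len(24) - 0.5, times = ncol(hourly))
      tryCatch(fit_extended_cosinor(t_hour, as.vector(hourly)),
               error = function(e) NULL)
    } else NULL
    if (is.null(fit) || !isTRUE(fit$converged)) {
      out[paste0(c("mesor", "amp", "acro", "alpha", "beta", "F"), sfx)] <- NA_real_
    } else {
      out[paste0("mesor", sfx)] <- fit$mesor
      out[paste0("amp", sfx)] <- fit$amplitude
      out[paste0("acro", sfx)] <- fit$acrophase
      out[paste0("alpha", sfx)] <- fit$alpha
      out[paste0("beta", sfx)] <- fit$beta
      out[paste0("F", sfx)] <- fit$pseudo_f
    }
  }
  out
}
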