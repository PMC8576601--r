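# Independent brute-force oracles: deliberately naive, loop-based
# evaluations of the printed formulas, sharing no code with the package.

bf_is <- function(mat) {
  x <- as.vector(mat)
  n <- length(x)
  xbar <- mean(x)
  p <- nrow(mat)
  prof <- numeric(p)
  for (h in seq_len(p)) prof[h] <- mean(mat[h, ])
  num <- 0
  for (h in seq_len(p)) num <- num + (prof[h] - xbar)^2
  den <- 0
  for (i in seq_len(n)) den <- den + (x[i] - xbar)^2
  (n * num) / (p * den)
}

bf_iv <- function(x) {
  n <- length(x)
  xbar <- mean(x)
  num <- 0
  for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
  den <- 0
  for (i in seq_len(n)) den <- den + (x[i] - xbar)^2
  (n * num) / ((n - 1) * den)
}

bf_icv <- function(mat) {
  p <- nrow(mat)
  total <- 0
  used <- 0
  for (h in seq_len(p)) {
    vals <- mat[h, ]
    m <- mean(vals)
    if (m == 0) next
    s <- sqrt(sum((vals - m)^2) / (length(vals) - 1))
    total <- total + s / m
    used <- used + 1
  }
  if (used == 0) return(NA_real_)
  total / used
}

bf_ac <- function(x, k) {
  n <- length(x)
  xbar <- mean(x)
  num <- 0
  for (i in seq_len(n - k)) num <- num + (x[i] - xbar) * (x[i + k] - xbar)
  den <- 0
  for (i in seq_len(n)) den <- den + (x[i] - xbar)^2
  num / den
}

bf_ra <- function(mat) {
  prof <- numeric(24)
  for (h in 1:24) prof[h] <- mean(mat[h, ])
  wm <- function(w) {
    best <- rep(NA_real_, 24)
    for (s in 1:24) {
      idx <- ((s - 1 + 0:(w - 1)) %% 24) + 1
      best[s] <- mean(prof[idx])
    }
    best
  }
  m10 <- max(wm(10))
  l5 <- min(wm(5))
  c(M10 = m10, L5 = l5, RA = (m10 - l5) / (m10 + l5))
}

bf_rmssd <- function(x) {
  acc <- 0
  cnt <- 0
  for (i in 2:length(x)) {
    acc <- acc + (x[i] - x[i - 1])^2
    cnt <- cnt + 1
  }
  sqrt(acc / cnt)
}

bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    i <- ord[r]
    val <- min(prev, p[i] * m / r)
    q[i] <- val
    prev <- val
  }
  q
}

bf_confusion <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  po <- (tp + tn) / total
  p_yes <- ((tp + fp) / total) * ((tp + fn) / total)
  p_no <- ((fn + tn) / total) * ((fp + tn) / total)
  pe <- p_yes + p_no
  list(accuracy = po,
       sensitivity = sdiv(tp, tp + fn),
       specificity = sdiv(tn, tn + fp),
       ppv = sdiv(tp, tp + fp),
       npv = sdiv(tn, tn + fn),
       kappa = if (pe == 1) NA_real_ else (po - pe) / (1 - pe))
}

# Published streaming z-score peak detector, transcribed naively.
bf_peak_signals <- function(y, lag, threshold, influence) {
  n <- length(y)
  signals <- integer(n)
  filteredY <- y
  avgFilter <- rep(NA_real_, n)
  stdFilter <- rep(NA_real_, n)
  avgFilter[lag] <- mean(y[1:lag])
  stdFilter[lag] <- sd(y[1:lag])
  for (i in (lag + 1):n) {
    if (stdFilter[i - 1] > 0 &&
        abs(y[i] - avgFilter[i - 1]) > threshold * stdFilter[i - 1]) {
      signals[i] <- if (y[i] > avgFilter[i - 1]) 1L else -1L
      filteredY[i] <- influence * y[i] + (1 - influence) * filteredY[i - 1]
    } else {
      signals[i] <- 0L
      filteredY[i] <- y[i]
    }
    avgFilter[i] <- mean(filteredY[(i - lag + 1):i])
    stdFilter[i] <- sd(filteredY[(i - lag + 1):i])
  }
  signals
}

expect_rel_equal <- function(actual, expected, tol = 1e-12) {
  denom <- pmax(abs(expected), 1e-300)
  expect_true(all(abs(actual - expected) / denom <= tol | actual == expected))
}
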