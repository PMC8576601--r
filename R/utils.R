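#' @keywords internal
"_PACKAGE"

# Epoch grid constants: minutes, 30-s sleep epochs and 5-s heart-rate samples
# per day. All streams are laid out on regular local-clock grids so that
# minute/hour aggregation is a reshape, not a join.
MIN_PER_DAY <- 1440L
SLEEP_PER_DAY <- 2880L
HR_INTERVAL_S <- 5L
HR_PER_MIN <- 60L %/% HR_INTERVAL_S
HR_PER_DAY <- MIN_PER_DAY * HR_PER_MIN

SLEEP_STAGES <- c("wake", "light", "deep", "rem")

# data.table is used via :: only; declare awareness so [.data.table keeps
# data.table semantics inside this package
.datatable.aware <- TRUE

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Sub-seed derivation: keeps every stochastic component of the generator on
# its own reproducible stream so that perturbing one component's parameters
# cannot shift the draws of another. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed)
  for (k in ix) s <- (s * 69069 + k * 2654435761) %% 2147483647
  as.integer(s)
}

# Mean/SD/CV with NA removal; returns NA when nothing is left.
mean_ <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
sd_ <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) NA_real_ else stats::sd(x)
}
cv_ <- function(x) {
  m <- mean_(x)
  s <- sd_(x)
  if (is.na(m) || is.na(s) || m <= 0) NA_real_ else s / m
}

# Day-of-week for day index 1..D given the weekday of day 1 (1 = Monday).
# TRUE for Monday-Friday.
is_weekday <- function(day_index, start_dow = 1L) {
  dow <- ((start_dow - 1L + day_index - 1L) %% 7L) + 1L
  dow <= 5L
}

# Column means of a matrix tolerating all-NA columns (returns NA, no warning).
col_means_na <- function(m) {
  out <- colMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}
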