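## Univariate Spearman screening with Benjamini-Hochberg correction and
## covariate-adjusted hierarchical linear regression of symptom severity on
## single biomarkers.

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values (q values).
#' @export
bh_adjust <- function(p) {
  assert_that(all(is.na(p) | (p >= 0 & p <= 1)), "p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Spearman screen of biomarkers against symptom severity
#'
#' Rank correlation (midrank ties, asymptotic two-sided p) of every biomarker
#' column against the outcome, on pairwise-complete observations, with BH
#' adjustment across the screened features. Constant features and features
#' with fewer than `min_pairs` complete pairs are excluded with a warning.
#'
#' @param features Tibble/data frame of biomarker columns (an `id` column is
#'   ignored).
#' @param outcome Numeric outcome (average PHQ-9 score), aligned with the
#'   rows of `features`.
#' @param min_pairs Minimum complete pairs per feature (default 10).
#' @return Tibble `biomarker`, `rho`, `p`, `q`, `n`, ordered as the input
#'   columns.
#' @export
spearman_screen <- function(features, outcome, min_pairs = 10L) {
  cols <- setdiff(names(features), "id")
  res <- lapply(cols, function(nm) {
    x <- features[[nm]]
    ok <- !is.na(x) & !is.na(outcome)
    n <- sum(ok)
    if (n < min_pairs || length(unique(x[ok])) < 2) {
      return(tibble::tibble(biomarker = nm, rho = NA_real_, p = NA_real_, n = n))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], outcome[ok], method = "spearman", exact = FALSE))
    tibble::tibble(biomarker = nm, rho = unname(ct$estimate),
                   p = ct$p.value, n = n)
  })
  out <- do.call(rbind, res)
  dropped <- sum(is.na(out$rho))
  if (dropped > 0) {
    warning(dropped, " feature(s) excluded (constant or too few pairs)")
  }
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  out[, c("biomarker", "rho", "p", "q", "n")]
}

# Reference levels for the categorical covariates (regression baselines).
covariate_reference_levels <- function() {
  list(gender = "female", ethnicity = "chinese", marital = "married",
       education = "below_degree", income = "below_4000",
       alcohol = "no", smoking = "smoker", health = "excellent")
}

default_covariate_blocks <- function() {
  list(
    sociodemographics = c("age", "gender", "ethnicity", "marital",
                          "education", "income"),
    lifestyle_health = c("alcohol", "smoking", "health"),
    sleep_loneliness = c("loneliness", "shi", "psqi", "ess")
  )
}

#' Hierarchical regression of severity on one biomarker
#'
#' Ordinary least squares of the outcome on the biomarker, adding covariate
#' blocks cumulatively (model 1 = biomarker only, model 2 = + block 1, ...).
#' Categorical covariates use fixed reference levels (female, Chinese,
#' married, below-degree, lower income, non-drinker, smoker, excellent
#' health). Observations are deleted listwise for the largest model.
#'
#' @param data Data frame with the outcome, biomarker and covariate columns.
#' @param outcome Name of the outcome column.
#' @param biomarker Name of the biomarker column.
#' @param blocks Named list of covariate-column blocks (default: the
#'   sociodemographic, lifestyle/health and sleep/loneliness blocks).
#' @param per_10pct Report the biomarker coefficient per 0.10 change of a
#'   unit-scale feature (multiplies the coefficient and CI by 0.10); meant
#'   for proportion-like biomarkers such as IS, AC or a CV.
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return Tibble with one row per nested model: `model`, `covariates`,
#'   `beta`, `ci_lo`, `ci_hi`, `p`, `n`.
#' @export
hierarchical_regression <- function(data, outcome, biomarker,
                                    blocks = default_covariate_blocks(),
                                    per_10pct = FALSE, conf_level = 0.95) {
  refs <- covariate_reference_levels()
  all_vars <- c(outcome, biomarker, unlist(blocks))
  missing_cols <- setdiff(all_vars, names(data))
  assert_that(!length(missing_cols),
              paste("missing columns:", paste(missing_cols, collapse = ", ")))
  d <- data[stats::complete.cases(data[, all_vars, drop = FALSE]), , drop = FALSE]
  for (v in names(refs)) {
    if (v %in% names(d)) d[[v]] <- stats::relevel(factor(d[[v]]), ref = refs[[v]])
  }
  cum <- list(character(0))
  for (b in blocks) cum[[length(cum) + 1L]] <- c(cum[[length(cum)]], b)
  scale_f <- if (per_10pct) 0.10 else 1
  rows <- lapply(seq_along(cum), function(k) {
    rhs <- paste(c(sprintf("`%s`", biomarker),
                   sprintf("`%s`", cum[[k]])), collapse = " + ")
    f <- stats::as.formula(paste(sprintf("`%s`", outcome), "~", rhs))
    mm <- stats::model.matrix(f, d)
    qrx <- qr(mm)
    if (qrx$rank < ncol(mm)) {
      bad <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
      stop("rank-deficient design; collinear columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    fit <- stats::lm(f, data = d)
    co <- summary(fit)$coefficients
    bname <- grep(biomarker, rownames(co), fixed = TRUE, value = TRUE)[1]
    ci <- stats::confint(fit, bname, level = conf_level)
    tibble::tibble(
      model = k,
      covariates = paste(cum[[k]], collapse = "+"),
      beta = co[bname, "Estimate"] * scale_f,
      ci_lo = ci[1] * scale_f, ci_hi = ci[2] * scale_f,
      p = co[bname, "Pr(>|t|)"],
      n = nrow(d))
  })
  do.call(rbind, rows)
}
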