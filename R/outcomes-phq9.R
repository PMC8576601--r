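## PHQ-9 scoring, severity cross-tabulation, depression labels under four
## cutoff rules, and contrasted subsampling.
##
## Rules (both assessments required):
##   A: total >= 10 at either assessment (the conventional screen cutoff);
##   B: total >= 8 at both assessments;
##   C: average of the two totals >= 8;
##   D: top 20% by average = depressed, bottom 20% = healthy, rest excluded
##      (quantile ties broken by participant id).

PHQ9_SEVERITY_BREAKS <- c(0, 5, 10, 15, 28)
PHQ9_SEVERITY_LABELS <- c("normal", "mild", "moderate", "moderately_severe")

#' Score the PHQ-9
#'
#' Sum of the nine items, each scored 0-3.
#'
#' @param items Numeric vector of 9 item scores.
#' @return Integer total in 0-27.
#' @export
score_phq9 <- function(items) {
  assert_that(length(items) == 9, "PHQ-9 has exactly 9 items")
  assert_that(all(items %in% 0:3), "PHQ-9 items must be integers in 0..3")
  as.integer(sum(items))
}

#' Depression labels under a cutoff rule
#'
#' Assigns `depressed` / `healthy` / `excluded` to each participant from the
#' two PHQ-9 totals under rule A, B, C or D (see the module header above).
#' Records with a missing assessment are `excluded` with a warning.
#'
#' @param t1,t2 PHQ-9 totals at the first and second assessment.
#' @param rule `"A"`, `"B"`, `"C"` or `"D"`.
#' @param id Participant ids (used to break quantile ties under rule D).
#' @return Character vector of labels.
#' @export
assign_label <- function(t1, t2, rule = c("A", "B", "C", "D"),
                         id = seq_along(t1)) {
  rule <- match.arg(rule)
  n <- length(t1)
  avg <- (t1 + t2) / 2
  miss <- is.na(t1) | is.na(t2)
  if (any(miss)) warning(sum(miss), " record(s) with a missing assessment excluded")
  lab <- rep("healthy", n)
  if (rule == "A") {
    lab[t1 >= 10 | t2 >= 10] <- "depressed"
  } else if (rule == "B") {
    lab[t1 >= 8 & t2 >= 8] <- "depressed"
  } else if (rule == "C") {
    lab[avg >= 8] <- "depressed"
  } else {
    k <- floor(0.2 * sum(!miss))
    ord <- order(avg, id)            # ascending; ties resolved by id
    ord <- ord[!miss[ord]]
    lab <- rep("excluded", n)
    lab[utils::tail(ord, k)] <- "depressed"
    lab[utils::head(ord, k)] <- "healthy"
  }
  lab[miss] <- "excluded"
  lab
}

#' Severity cross-tabulation of the two assessments
#'
#' Counts participants in the 4 x 4 grid of PHQ-9 severity categories
#' (normal 0-4, mild 5-9, moderate 10-14, moderately severe >= 15) at the
#' first by second assessment.
#'
#' @param t1,t2 PHQ-9 totals (both must be present per record).
#' @return A `severity_crosstab`: 4 x 4 integer matrix with category
#'   dimnames.
#' @export
crosstab_severity <- function(t1, t2) {
  assert_that(!anyNA(t1) && !anyNA(t2), "both totals must be present")
  cat1 <- cut(t1, PHQ9_SEVERITY_BREAKS, right = FALSE, labels = PHQ9_SEVERITY_LABELS)
  cat2 <- cut(t2, PHQ9_SEVERITY_BREAKS, right = FALSE, labels = PHQ9_SEVERITY_LABELS)
  tab <- table(t1 = cat1, t2 = cat2)
  structure(unclass(tab), class = "severity_crosstab")
}

#' Group counts from a severity cross-tabulation
#'
#' Helper queries over the 4 x 4 severity grid: the number of participants
#' with a total of >= 10 at either assessment, at both assessments, the grand
#' total, and the either-assessment prevalence in percent. Works on any
#' matrix in the severity-category layout, so printed tables can be fed in
#' directly.
#'
#' @param crosstab A `severity_crosstab` or a plain 4 x 4 count matrix
#'   (rows = first assessment).
#' @return List with `either_ge10`, `both_ge10`, `total`,
#'   `either_ge10_pct` (rounded to one decimal).
#' @export
severity_group_counts <- function(crosstab) {
  m <- unclass(crosstab)
  assert_that(all(dim(m) == c(4, 4)), "expected a 4 x 4 severity matrix")
  total <- sum(m)
  both_lt10 <- sum(m[1:2, 1:2])
  either <- total - both_lt10
  both <- sum(m[3:4, 3:4])
  list(either_ge10 = either, both_ge10 = both, total = total,
       either_ge10_pct = round(100 * either / total, 1))
}

#' @export
print.severity_crosstab <- function(x, ...) {
  m <- unclass(x)
  m <- cbind(m, total = rowSums(m))
  m <- rbind(m, total = colSums(m))
  print(m)
  invisible(x)
}

#' Contrasted subsample of depressed vs minimally symptomatic participants
#'
#' Builds the balanced subsample used for the high-contrast classification
#' models. For rules A-C the depressed group is the rule's depressed label;
#' healthy candidates are restricted to an average score in (0, 4] (zero
#' averages excluded) and randomly downsampled to match the depressed count
#' (rule A keeps two extra healthy participants, mirroring the 38 vs 40
#' shape). For rule D the groups are taken by average-score range -
#' depressed in `[7.5, 14]`, healthy in `[0.5, 1.5]` - and the larger group
#' is downsampled to the smaller.
#'
#' @param outcomes Tibble with `id`, `phq9_t1`, `phq9_t2` (and optionally
#'   `phq9_avg`).
#' @param rule Cutoff rule `"A"`-`"D"`.
#' @param seed Integer seed for the downsampling.
#' @return The subsampled rows of `outcomes` with a `label` column
#'   (`depressed`/`healthy`).
#' @export
contrasted_subsample <- function(outcomes, rule = c("A", "B", "C", "D"),
                                 seed = 1L) {
  rule <- match.arg(rule)
  avg <- outcomes$phq9_avg %||% ((outcomes$phq9_t1 + outcomes$phq9_t2) / 2)
  set.seed(derive_seed(seed, 11L))
  if (rule == "D") {
    dep_idx <- which(avg >= 7.5 & avg <= 14)
    hea_idx <- which(avg >= 0.5 & avg <= 1.5)
    k <- min(length(dep_idx), length(hea_idx))
    assert_that(k > 0, "no eligible participants for the rule-D subsample")
    if (length(dep_idx) > k) dep_idx <- sort(sample(dep_idx, k))
    if (length(hea_idx) > k) hea_idx <- sort(sample(hea_idx, k))
  } else {
    lab <- assign_label(outcomes$phq9_t1, outcomes$phq9_t2, rule, outcomes$id)
    dep_idx <- which(lab == "depressed")
    n_dep <- length(dep_idx)
    n_healthy <- if (rule == "A") n_dep + 2L else n_dep
    cand <- which(lab == "healthy" & avg > 0 & avg <= 4)
    if (length(cand) < n_healthy) {
      stop(sprintf(
        "insufficient eligible healthy participants: need %d, have %d",
        n_healthy, length(cand)), call. = FALSE)
    }
    hea_idx <- sort(sample(cand, n_healthy))
  }
  out <- outcomes[c(dep_idx, hea_idx), , drop = FALSE]
  out$label <- rep(c("depressed", "healthy"), c(length(dep_idx), length(hea_idx)))
  out
}
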