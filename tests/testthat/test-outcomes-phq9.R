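test_that("PHQ-9 scoring validates and sums items", {
  expect_equal(score_phq9(rep(0, 9)), 0L)
  expect_equal(score_phq9(rep(3, 9)), 27L)
  expect_equal(score_phq9(c(1, 1, 1, 0, 0, 0, 2, 2, 2)), 9L)
  expect_error(score_phq9(c(rep(0, 8), 4)), "0..3")
  expect_error(score_phq9(rep(1, 8)), "9 items")
})

test_that("cutoff rules assign labels as defined", {
  expect_equal(assign_label(11, 6, "A"), "depressed")
  expect_equal(assign_label(11, 6, "B"), "healthy")
  expect_equal(assign_label(8, 8, "B"), "depressed")
  expect_equal(assign_label(8, 8, "C"), "depressed")   # average exactly 8
  expect_equal(assign_label(0, 0, "A"), "healthy")
  expect_equal(assign_label(0, 0, "C"), "healthy")
  expect_warning(lab <- assign_label(c(5, NA), c(5, 3), "A"), "missing")
  expect_equal(lab[2], "excluded")
})

test_that("labels match a brute-force oracle over the full score grid", {
  grid <- expand.grid(t1 = 0:27, t2 = 0:27)
  for (rule in c("A", "B", "C")) {
    got <- assign_label(grid$t1, grid$t2, rule)
    want <- mapply(function(a, b) {
      dep <- switch(rule,
                    A = a >= 10 || b >= 10,
                    B = a >= 8 && b >= 8,
                    C = (a + b) / 2 >= 8)
      if (dep) "depressed" else "healthy"
    }, grid$t1, grid$t2)
    expect_identical(got, unname(want))
  }
})

test_that("rule D takes the top and bottom 20% with deterministic ties", {
  t1 <- c(0, 1, 2, 3, 4, 10, 11, 12, 13, 14)
  t2 <- t1
  lab <- assign_label(t1, t2, "D", id = 1:10)
  expect_equal(sum(lab == "depressed"), 2)
  expect_equal(sum(lab == "healthy"), 2)
  expect_equal(lab[c(1, 2)], c("healthy", "healthy"))
  expect_equal(lab[c(9, 10)], c("depressed", "depressed"))
  # ties broken by id: identical scores, stable result
  labt <- assign_label(rep(5, 10), rep(5, 10), "D", id = 1:10)
  expect_identical(labt, assign_label(rep(5, 10), rep(5, 10), "D", id = 1:10))
  expect_equal(which(labt == "healthy"), 1:2)
})

test_that("the severity cross-tab reproduces the published group counts", {
  # printed 4x4 distribution of the two assessments (row = first assessment)
  tab <- matrix(c(143, 14, 0, 0,
                  32, 40, 5, 0,
                  3, 20, 5, 1,
                  1, 1, 2, 0),
                nrow = 4, byrow = TRUE)
  counts <- severity_group_counts(tab)
  expect_equal(counts$either_ge10, 38)
  expect_equal(counts$both_ge10, 8)
  expect_equal(counts$total, 267)
  expect_equal(counts$either_ge10_pct, 14.2)
})

test_that("crosstab cells, margins and totals are conserved", {
  ct <- crosstab_severity(3, 12)
  expect_equal(unclass(ct)["normal", "moderate"], 1L, ignore_attr = TRUE)
  set.seed(8)
  t1 <- sample(0:27, 300, TRUE)
  t2 <- sample(0:27, 300, TRUE)
  ct2 <- crosstab_severity(t1, t2)
  expect_equal(sum(unclass(ct2)), 300)
  expect_equal(unname(rowSums(unclass(ct2))),
               unname(table(cut(t1, c(0, 5, 10, 15, 28), right = FALSE))),
               ignore_attr = TRUE)
  # and the helper agrees with direct counting
  cnt <- severity_group_counts(ct2)
  expect_equal(cnt$either_ge10, sum(t1 >= 10 | t2 >= 10))
  expect_equal(cnt$both_ge10, sum(t1 >= 10 & t2 >= 10))
})

test_that("contrasted subsamples have the published shape", {
  set.seed(1)
  n <- 260
  oc <- actidep:::gen_outcomes(n, sample(rep(c(TRUE, FALSE), c(50, 210))),
                               0.73, seed = 2)
  sub <- contrasted_subsample(oc, "A", seed = 5)
  n_dep <- sum(sub$label == "depressed")
  n_hea <- sum(sub$label == "healthy")
  expect_equal(n_hea, n_dep + 2)
  avg_h <- sub$phq9_avg[sub$label == "healthy"]
  expect_true(all(avg_h > 0 & avg_h <= 4))
  expect_identical(contrasted_subsample(oc, "A", seed = 5),
                   contrasted_subsample(oc, "A", seed = 5))
  expect_false(identical(sub, contrasted_subsample(oc, "A", seed = 6)))

  for (rule in c("B", "C")) {
    sb <- contrasted_subsample(oc, rule, seed = 5)
    expect_equal(sum(sb$label == "depressed"), sum(sb$label == "healthy"))
  }
  sd4 <- contrasted_subsample(oc, "D", seed = 5)
  expect_true(all(sd4$phq9_avg[sd4$label == "depressed"] >= 7.5 &
                    sd4$phq9_avg[sd4$label == "depressed"] <= 14))
  expect_true(all(sd4$phq9_avg[sd4$label == "healthy"] >= 0.5 &
                    sd4$phq9_avg[sd4$label == "healthy"] <= 1.5))
  expect_equal(sum(sd4$label == "depressed"), sum(sd4$label == "healthy"))
})

test_that("an exhausted healthy pool is reported as a shortfall", {
  oc <- tibble::tibble(id = 1:6, phq9_t1 = c(12, 12, 12, 0, 1, 2),
                       phq9_t2 = c(12, 12, 12, 0, 1, 2),
                       phq9_avg = (phq9_t1 + phq9_t2) / 2)
  expect_error(contrasted_subsample(oc, "A", seed = 1), "insufficient")
})
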