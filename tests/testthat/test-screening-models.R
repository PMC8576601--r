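test_that("feature selection rules partition by raw p value", {
  assoc <- tibble::tibble(biomarker = c("a", "b", "c"),
                          p = c(0.005, 0.03, 0.2))
  expect_equal(select_features(assoc, "A"), "a")
  expect_equal(select_features(assoc, "B"), c("a", "b"))
  expect_equal(select_features(assoc, "C"), "b")
  expect_equal(select_features(assoc, "A", add_demographics = TRUE),
               c("a", "age", "gender", "ethnicity", "marital"))
  expect_error(select_features(tibble::tibble(biomarker = "a", p = 0.5), "B"),
               "relax")
})

test_that("confusion metrics match hand arithmetic and flag divisions by zero", {
  m <- performance_from_confusion(8, 2, 2, 8)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$kappa, 0.6)
  expect_true(is.na(performance_from_confusion(0, 0, 3, 7)$ppv))
  perfect <- performance_from_confusion(5, 0, 0, 5)
  expect_equal(perfect$kappa, 1)
  expect_error(performance_from_confusion(0, 0, 0, 0), "all zero")
})

test_that("metrics agree with brute force on exhaustive small matrices", {
  worst <- 0
  na_mismatch <- 0
  for (tp in 0:6) for (fp in 0:6) for (fn in 0:6) for (tn in 0:6) {
    if (tp + fp + fn + tn == 0) next
    got <- performance_from_confusion(tp, fp, fn, tn)
    want <- bf_confusion(tp, fp, fn, tn)
    for (nm in names(want)) {
      if (is.na(got[[nm]]) != is.na(want[[nm]])) {
        na_mismatch <- na_mismatch + 1
      } else if (!is.na(want[[nm]])) {
        worst <- max(worst, abs(got[[nm]] - want[[nm]]))
      }
    }
  }
  expect_equal(na_mismatch, 0)
  expect_lte(worst, 1e-12)
})

test_that("AUC equals the Mann-Whitney normalization", {
  set.seed(18)
  for (i in 1:25) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    sc <- rnorm(40) + y
    wt <- suppressWarnings(wilcox.test(sc[y == 1], sc[y == 0]))
    u <- unname(wt$statistic)
    expect_equal(actidep:::auc_rank(sc, y), u / (sum(y == 1) * sum(y == 0)),
                 tolerance = 1e-12)
  }
  expect_equal(actidep:::auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
})

test_that("a separable planted signal is classified almost perfectly", {
  set.seed(19)
  n <- 120
  y <- rep(c("depressed", "healthy"), each = n / 2)
  x <- data.frame(sig = ifelse(y == "depressed", 1, 0) + rnorm(n, 0, 0.1),
                  noise1 = rnorm(n), noise2 = rnorm(n))
  fit <- cv_classify(x, y, repeats = 3, seed = 7, nrounds = 60)
  acc <- fit$performance$mean[fit$performance$metric == "accuracy"]
  expect_gte(acc, 0.95)
  expect_equal(fit$nir, 0.5)
  # the informative feature dominates the importance ranking
  expect_equal(names(fit$importance)[1], "sig")
  expect_equal(sum(fit$importance), 1, tolerance = 1e-9)
})

test_that("permuted labels collapse accuracy to the no-information rate", {
  set.seed(20)
  n <- 200
  y <- rep(c("depressed", "healthy"), each = n / 2)
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  fit <- cv_classify(x, sample(y), repeats = 3, seed = 3, nrounds = 60)
  kap <- fit$performance$mean[fit$performance$metric == "kappa"]
  acc <- fit$performance$mean[fit$performance$metric == "accuracy"]
  expect_lt(abs(kap), 0.1)
  expect_lt(abs(acc - fit$nir), 0.1)
})

test_that("cross-validation is reproducible under a fixed seed", {
  set.seed(22)
  y <- rep(c("depressed", "healthy"), 15)
  x <- data.frame(a = rnorm(30) + (y == "depressed"), b = rnorm(30))
  f1 <- cv_classify(x, y, repeats = 2, seed = 9, nrounds = 30)
  f2 <- cv_classify(x, y, repeats = 2, seed = 9, nrounds = 30)
  expect_identical(f1$performance, f2$performance)
  expect_identical(f1$per_fold, f2$per_fold)
})

test_that("regression CV separates signal from null", {
  set.seed(23)
  n <- 160
  x <- data.frame(u = runif(n), v = rnorm(n))
  fit <- cv_regress(x, 3 * x$u, repeats = 3, seed = 2, nrounds = 80)
  r2 <- fit$performance$mean[fit$performance$metric == "r2"]
  expect_gte(r2, 0.9)
  null <- cv_regress(x, rnorm(n), repeats = 3, seed = 2, nrounds = 40)
  expect_lte(null$performance$mean[null$performance$metric == "r2"], 0.05)
})
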