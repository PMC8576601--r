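## Correlation-threshold feature selection, DART gradient-boosted models of
## depression risk, repeated k-fold evaluation and confusion-matrix metrics.
## Feature selection is frozen once on the full sample and reused unchanged
## for every subsample model.

#' Select features by Spearman screen p value
#'
#' Rule `"A"`: raw p < .01; `"B"`: p < .05; `"C"`: .01 <= p < .05. Optionally
#' appends the sociodemographic predictors (age, gender, ethnic group,
#' marital status).
#'
#' @param assoc Result of [spearman_screen()].
#' @param rule Selection rule.
#' @param add_demographics Append `age`, `gender`, `ethnicity`, `marital`.
#' @return Character vector of selected feature names.
#' @export
select_features <- function(assoc, rule = c("A", "B", "C"),
                            add_demographics = FALSE) {
  rule <- match.arg(rule)
  p <- assoc$p
  sel <- switch(rule,
                A = p < 0.01,
                B = p < 0.05,
                C = p >= 0.01 & p < 0.05)
  sel[is.na(sel)] <- FALSE
  feats <- assoc$biomarker[sel]
  if (!length(feats)) {
    stop("no features pass selection rule ", rule,
         "; relax the rule or screen more biomarkers", call. = FALSE)
  }
  if (add_demographics) feats <- c(feats, "age", "gender", "ethnicity", "marital")
  feats
}

# Default DART booster settings (fixed for reproducibility, not tuned).
dart_params <- function(objective, seed) {
  list(booster = "dart", max_depth = 3, eta = 0.1, rate_drop = 0.1,
       objective = objective, nthread = 1, seed = seed)
}

# Numeric model matrix: one-hot encodes any non-numeric columns.
encode_features <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  if (all(num)) return(as.matrix(df))
  mm <- stats::model.matrix(~ . - 1, data = df)
  mm
}

# Fold assignment for one repeat; stratified keeps class proportions.
make_fold_ids <- function(y, k, stratified) {
  n <- length(y)
  ids <- integer(n)
  if (stratified && !is.null(y)) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      ids[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    ids <- sample(rep_len(seq_len(k), n))
  }
  ids
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity, specificity, PPV, NPV and Cohen's kappa from the
#' four cells. Divisions by zero yield NA ("not applicable").
#'
#' @param tp,fp,fn,tn Nonnegative integer cell counts (positive class =
#'   depressed).
#' @return Named list of metrics.
#' @export
performance_from_confusion <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  total <- tp + fp + fn + tn
  assert_that(total > 0, "confusion matrix is all zero")
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  po <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  list(
    accuracy = po,
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    kappa = if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  )
}

# AUC as the Mann-Whitney statistic with midranks.
auc_rank <- function(scores, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated DART classification of depression status
#'
#' Stratified repeated k-fold cross-validation of a gradient-boosted (DART)
#' classifier. Per holdout fold, the confusion matrix at probability 0.5 and
#' the rank-based AUC are computed; metrics are averaged over all folds. The
#' no-information rate (NIR, the majority-class prevalence) is reported
#' alongside.
#'
#' @param x Feature data frame/matrix (non-numeric columns are one-hot
#'   encoded).
#' @param labels Binary labels; `"depressed"` (or 1/TRUE) is the positive
#'   class.
#' @param folds,repeats CV geometry (defaults 4 and 25: every repeat holds
#'   out 25% of the sample).
#' @param stratified Stratify fold assignment by class (default TRUE).
#' @param seed Integer seed controlling fold assignment and booster RNG.
#' @param nrounds,params Booster rounds and parameter overrides.
#' @return List with `performance` (tibble of fold-mean and SD per metric,
#'   plus `nir`), `per_fold` (metric tibble, one row per holdout fold) and
#'   `importance` (mean relative feature importance).
#' @export
cv_classify <- function(x, labels, folds = 4L, repeats = 25L,
                        stratified = TRUE, seed = 1L, nrounds = 200L,
                        params = list()) {
  y <- as.integer(labels %in% c("depressed", "1", 1, TRUE))
  assert_that(length(unique(y)) == 2, "both classes must be present")
  xm <- encode_features(x)
  storage.mode(xm) <- "double"
  nir <- max(mean(y), 1 - mean(y))
  pars <- utils::modifyList(dart_params("binary:logistic", seed), params)
  fold_rows <- list()
  imps <- list()
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, 20L + r))
    ids <- make_fold_ids(y, folds, stratified)
    for (k in seq_len(folds)) {
      test <- ids == k
      if (length(unique(y[!test])) < 2) {
        warning("training fold with a single class: resampling")
        ids <- make_fold_ids(y, folds, stratified = TRUE)
        test <- ids == k
      }
      dtrain <- xgboost::xgb.DMatrix(xm[!test, , drop = FALSE],
                                     label = y[!test], nthread = 1)
      bst <- xgboost::xgb.train(params = pars, data = dtrain,
                                nrounds = nrounds, verbose = 0)
      prob <- stats::predict(bst, xm[test, , drop = FALSE])
      pred <- as.integer(prob > 0.5)
      yt <- y[test]
      met <- performance_from_confusion(
        tp = sum(pred == 1 & yt == 1), fp = sum(pred == 1 & yt == 0),
        fn = sum(pred == 0 & yt == 1), tn = sum(pred == 0 & yt == 0))
      met$auc <- auc_rank(prob, yt)
      fold_rows[[length(fold_rows) + 1L]] <-
        tibble::as_tibble(c(list(repeat_ = r, fold = k), met))
      imp <- tryCatch(xgboost::xgb.importance(model = bst),
                      error = function(e) NULL)
      if (!is.null(imp) && nrow(imp)) {
        imps[[length(imps) + 1L]] <- stats::setNames(imp$Gain, imp$Feature)
      }
    }
  }
  per_fold <- do.call(rbind, fold_rows)
  metric_cols <- setdiff(names(per_fold), c("repeat_", "fold"))
  performance <- tibble::tibble(
    metric = c("nir", metric_cols),
    mean = c(nir, vapply(metric_cols, function(m) mean_(per_fold[[m]]), numeric(1))),
    sd = c(NA_real_, vapply(metric_cols, function(m) sd_(per_fold[[m]]), numeric(1)))
  )
  list(performance = performance, per_fold = per_fold,
       importance = feature_importance(imps), nir = nir)
}

#' Cross-validated DART regression of symptom severity
#'
#' Repeated k-fold cross-validation of a gradient-boosted (DART) regressor;
#' holdout R-squared, Pearson correlation, RMSE and MAE are averaged over
#' folds.
#'
#' @inheritParams cv_classify
#' @param outcome Numeric outcome vector.
#' @return List with `performance`, `per_fold` and `importance` as in
#'   [cv_classify()].
#' @export
cv_regress <- function(x, outcome, folds = 4L, repeats = 25L, seed = 1L,
                       nrounds = 200L, params = list()) {
  assert_that(length(outcome) >= 2 * folds, "too few observations for the fold count")
  xm <- encode_features(x)
  storage.mode(xm) <- "double"
  pars <- utils::modifyList(dart_params("reg:squarederror", seed), params)
  fold_rows <- list()
  imps <- list()
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, 40L + r))
    ids <- sample(rep_len(seq_len(folds), length(outcome)))
    for (k in seq_len(folds)) {
      test <- ids == k
      yt <- outcome[test]
      if (stats::sd(yt) == 0) {
        warning("holdout fold with constant outcome skipped")
        next
      }
      dtrain <- xgboost::xgb.DMatrix(xm[!test, , drop = FALSE],
                                     label = outcome[!test], nthread = 1)
      bst <- xgboost::xgb.train(params = pars, data = dtrain,
                                nrounds = nrounds, verbose = 0)
      pred <- stats::predict(bst, xm[test, , drop = FALSE])
      ss_res <- sum((yt - pred)^2)
      ss_tot <- sum((yt - mean(yt))^2)
      fold_rows[[length(fold_rows) + 1L]] <- tibble::tibble(
        repeat_ = r, fold = k,
        r2 = 1 - ss_res / ss_tot,
        pearson = suppressWarnings(stats::cor(yt, pred)),
        rmse = sqrt(mean((yt - pred)^2)),
        mae = mean(abs(yt - pred)))
      imp <- tryCatch(xgboost::xgb.importance(model = bst),
                      error = function(e) NULL)
      if (!is.null(imp) && nrow(imp)) {
        imps[[length(imps) + 1L]] <- stats::setNames(imp$Gain, imp$Feature)
      }
    }
  }
  per_fold <- do.call(rbind, fold_rows)
  metric_cols <- setdiff(names(per_fold), c("repeat_", "fold"))
  performance <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean_(per_fold[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) sd_(per_fold[[m]]), numeric(1))
  )
  list(performance = performance, per_fold = per_fold,
       importance = feature_importance(imps))
}

#' Mean relative feature importance
#'
#' Averages gain-based importances across fitted ensemble members and
#' normalizes them to sum to 1.
#'
#' @param imps List of named gain vectors (one per fitted model), as
#'   collected by [cv_classify()]/[cv_regress()].
#' @return Named numeric vector, decreasing; `NULL` when nothing was fitted.
#' @export
feature_importance <- function(imps) {
  if (!length(imps)) return(NULL)
  feats <- unique(unlist(lapply(imps, names)))
  acc <- stats::setNames(numeric(length(feats)), feats)
  for (v in imps) acc[names(v)] <- acc[names(v)] + v
  acc <- acc / length(imps)
  acc <- acc / sum(acc)
  sort(acc, decreasing = TRUE)
}
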