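## End-to-end orchestration: generate (or read) streams -> QC -> biomarker
## matrix -> association screen -> screening models -> report CSVs plus a
## reproducibility manifest. The R functions themselves are the command
## surface; `run_pipeline()` is the single entry point a script would call.

#' Pipeline configuration
#'
#' @param generator A [cohort_config()] (to simulate) or a path to a cohort
#'   `manifest.csv` (to read streams from disk).
#' @param min_hours,min_days QC thresholds (defaults 20 h, 10 days).
#' @param families Biomarker families to extract.
#' @param selection_rules Feature-selection rules to run (subset of A/B/C).
#' @param cutoff_rules PHQ-9 cutoff rules to classify (subset of A/B/C/D).
#' @param contrasted Also fit the contrasted-subsample models.
#' @param whole_sample Also fit whole-sample (imbalanced) models.
#' @param folds,repeats,nrounds CV geometry and booster rounds.
#' @param seed Master seed (streams, subsampling, folds, boosters).
#' @param out_dir Output directory for reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator, min_hours = 20, min_days = 10L,
                            families = c("activity", "sleep", "circadian",
                                         "heart_rate"),
                            selection_rules = c("A", "B", "C"),
                            cutoff_rules = "A",
                            contrasted = TRUE, whole_sample = FALSE,
                            folds = 4L, repeats = 25L, nrounds = 200L,
                            seed = 1L, out_dir = tempfile("actidep_run_")) {
  structure(list(
    generator = generator, min_hours = min_hours, min_days = as.integer(min_days),
    families = families, selection_rules = selection_rules,
    cutoff_rules = cutoff_rules, contrasted = contrasted,
    whole_sample = whole_sample, folds = as.integer(folds),
    repeats = as.integer(repeats), nrounds = as.integer(nrounds),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file with the fields of [pipeline_config()]; a
#'   `generator` object is interpreted as [cohort_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(raw$generator)) {
    raw$generator <- do.call(cohort_config, raw$generator)
  }
  do.call(pipeline_config, raw)
}

#' Run the full screening pipeline
#'
#' Executes generate/ingest -> QC -> biomarker extraction -> Spearman/FDR
#' screen -> feature selection -> cross-validated screening models, writing
#' the feature matrix, association table, per-model performance tables and a
#' manifest (config, seed, versions, file hashes) to `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`cohort_summary`,
#'   `features`, `assoc`, `selected`, `models`, `paths`).
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  cohort <- if (inherits(config$generator, "cohort_config")) {
    generate_cohort(config$generator)
  } else {
    read_cohort_csv(config$generator)
  }

  qc <- qc_cohort(cohort, config$min_hours, config$min_days)
  features <- biomarker_matrix(cohort, qc, config$families)
  outcomes <- cohort$outcomes[match(features$id, cohort$outcomes$id), ]

  data.table::fwrite(data.table::as.data.table(qc$summary), out("qc_summary.csv"))
  data.table::fwrite(data.table::as.data.table(features), out("feature_matrix.csv"))

  assoc <- suppressWarnings(spearman_screen(features, outcomes$phq9_avg))
  data.table::fwrite(data.table::as.data.table(assoc), out("associations.csv"))

  selected <- lapply(stats::setNames(nm = config$selection_rules),
                     function(r) {
                       tryCatch(select_features(assoc, r),
                                error = function(e) character(0))
                     })

  models <- list()
  rows <- list()
  for (sr in config$selection_rules) {
    feats <- selected[[sr]]
    if (!length(feats)) next
    x_all <- features[, feats, drop = FALSE]
    for (cr in config$cutoff_rules) {
      if (config$whole_sample) {
        lab <- assign_label(outcomes$phq9_t1, outcomes$phq9_t2, cr, outcomes$id)
        keep <- lab != "excluded"
        if (length(unique(lab[keep])) == 2) {
          fit <- cv_classify(x_all[keep, , drop = FALSE], lab[keep],
                             folds = config$folds, repeats = config$repeats,
                             seed = config$seed, nrounds = config$nrounds)
          models[[paste0("whole_", cr, "_", sr)]] <- fit
          rows[[length(rows) + 1L]] <- perf_row(fit, "whole", cr, sr)
        }
      }
      if (config$contrasted) {
        sub <- tryCatch(
          contrasted_subsample(outcomes, cr, seed = config$seed),
          error = function(e) NULL)
        if (!is.null(sub) && length(unique(sub$label)) == 2) {
          xi <- x_all[match(sub$id, features$id), , drop = FALSE]
          fit <- cv_classify(xi, sub$label, folds = config$folds,
                             repeats = config$repeats, seed = config$seed,
                             nrounds = config$nrounds)
          models[[paste0("contrasted_", cr, "_", sr)]] <- fit
          rows[[length(rows) + 1L]] <- perf_row(fit, "contrasted", cr, sr)
        }
      }
    }
    # symptom-severity regression on the whole included sample
    reg <- cv_regress(x_all, outcomes$phq9_avg, folds = config$folds,
                      repeats = config$repeats, seed = config$seed,
                      nrounds = config$nrounds)
    models[[paste0("severity_", sr)]] <- reg
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample = "whole", cutoff = "severity", selection = sr,
      metric = reg$performance$metric, mean = reg$performance$mean,
      sd = reg$performance$sd)
  }
  perf <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(perf)) {
    data.table::fwrite(data.table::as.data.table(perf), out("performance.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("actidep")),
    seed = config$seed,
    config = config[setdiff(names(config), c("generator", "out_dir"))],
    generator = if (inherits(config$generator, "cohort_config")) {
      unclass(config$generator)
    } else as.character(config$generator),
    n_included = nrow(features),
    selected_features = selected,
    file_md5 = as.list(tools::md5sum(list.files(config$out_dir,
                                                pattern = "\\.csv$",
                                                full.names = TRUE)))
  )
  names(manifest$file_md5) <- basename(names(manifest$file_md5))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(cohort_summary = qc$summary, features = features,
                 assoc = assoc, selected = selected, models = models,
                 performance = perf, paths = config$out_dir))
}

perf_row <- function(fit, sample, cutoff, selection) {
  tibble::tibble(sample = sample, cutoff = cutoff, selection = selection,
                 metric = fit$performance$metric,
                 mean = fit$performance$mean, sd = fit$performance$sd)
}
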