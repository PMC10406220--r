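# CSV round-tripping of feature tables and the pipeline orchestrator.

#' Write and read feature tables as CSV
#'
#' One row per subject: `id`, `group`, the canonical feature columns of the
#' table's mode, and any appended clinical columns. Missing values are empty
#' cells. `read_feature_csv()` auto-detects the VOI mode from the feature
#' columns, normalizes the column order, and validates the schema.
#'
#' @param features An `icas_features` table.
#' @param path CSV path.
#' @return `write_feature_csv()`: invisibly, `path`; `read_feature_csv()`:
#'   an `icas_features` table.
#' @export
write_feature_csv <- function(features, path) {
  stopifnot(inherits(features, "icas_features"))
  df <- data.frame(id = features$id, group = as.character(features$y),
                   features$x, check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- colnames(df)
  if (anyDuplicated(cols) > 0)
    stop("duplicate column names: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  if (!all(c("id", "group") %in% cols))
    stop("feature CSV must carry 'id' and 'group' columns")
  bad_group <- setdiff(unique(df$group), c("HC", "ICAS"))
  if (length(bad_group) > 0)
    stop("unknown group labels (rows ",
         paste(which(df$group %in% bad_group), collapse = ", "), "): ",
         paste(bad_group, collapse = ", "))
  feat_cols <- setdiff(cols, c("id", "group"))
  mode <- NULL
  clinical_cols <- character(0)
  for (m in c("iwsa", "whole", "inside_only")) {
    nm <- feature_names(m)
    if (all(nm %in% feat_cols)) {
      mode <- m
      clinical_cols <- setdiff(feat_cols, nm)
      break
    }
  }
  if (is.null(mode)) {
    overlap <- vapply(c("iwsa", "whole", "inside_only"),
                      function(m) sum(feature_names(m) %in% feat_cols),
                      numeric(1))
    best <- names(which.max(overlap))
    missing_nm <- setdiff(feature_names(best), feat_cols)
    unknown <- setdiff(feat_cols, feature_names(best))
    stop("feature columns match no known VOI mode (closest: ", best,
         "); missing: ", paste(missing_nm, collapse = ", "),
         if (length(unknown) > 0)
           paste0("; unrecognized: ", paste(unknown, collapse = ", ")))
  }
  ordered <- c(feature_names(mode), clinical_cols)
  x <- as.matrix(df[, ordered, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- df$id
  out <- structure(list(x = x, y = factor(df$group, levels = c("HC", "ICAS")),
                        id = df$id, mode = mode),
                   class = "icas_features")
  if (length(clinical_cols) > 0) out$clinical_added <- clinical_cols
  out
}

#' Write a cohort (features + clinical covariates) as CSV
#'
#' @param cohort An `icas_cohort`.
#' @param path CSV path.
#' @param mode VOI definition for the feature columns.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path, mode = "iwsa") {
  stopifnot(inherits(cohort, "icas_cohort"))
  ft <- assemble_features(cohort, mode)
  df <- data.frame(id = cohort$id, group = as.character(cohort$group),
                   ft$x, cohort$clinical, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles all stage parameters. The `"paper"` profile uses the full
#' repetition counts (1000-repetition importance averaging, 100-repetition
#' evaluation, 1000-repetition misclassification profiling, 300 trees); the
#' default `"smoke"` profile scales the repetitions down for quick runs
#' while keeping the cohort and model structure identical.
#'
#' @param profile `"smoke"` or `"paper"`.
#' @param cohort Config from [cohort_config()].
#' @param n_trees,k,alpha Forest size, CV folds, significance level.
#' @param importance_repetitions,evaluation_repetitions,
#'   misclassification_repetitions,inner_repetitions Stage repetition counts
#'   (defaults set by `profile`).
#' @param seed Master seed governing every stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("smoke", "paper"),
                            cohort = cohort_config(),
                            n_trees = NULL, k = 10L, alpha = 0.05,
                            importance_repetitions = NULL,
                            evaluation_repetitions = NULL,
                            misclassification_repetitions = NULL,
                            inner_repetitions = NULL,
                            seed = 1L) {
  profile <- match.arg(profile)
  d <- if (profile == "paper") {
    list(n_trees = 300L, imp = 1000L, ev = 100L, mis = 1000L, inner = 100L)
  } else {
    list(n_trees = 100L, imp = 25L, ev = 5L, mis = 100L, inner = 5L)
  }
  structure(list(
    profile = profile, cohort = cohort,
    n_trees = if (is.null(n_trees)) d$n_trees else as.integer(n_trees),
    k = as.integer(k), alpha = alpha,
    importance_repetitions =
      if (is.null(importance_repetitions)) d$imp else as.integer(importance_repetitions),
    evaluation_repetitions =
      if (is.null(evaluation_repetitions)) d$ev else as.integer(evaluation_repetitions),
    misclassification_repetitions =
      if (is.null(misclassification_repetitions)) d$mis else as.integer(misclassification_repetitions),
    inner_repetitions =
      if (is.null(inner_repetitions)) d$inner else as.integer(inner_repetitions),
    seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (with map-level missingness), ranks feature
#' importances (repetition-averaged, then recursive elimination and
#' per-parameter deduplication), compares the three VOI definitions, runs
#' nested feature selection, and profiles misclassification probabilities
#' with the cognition subgroup comparison. All stage seeds derive from the
#' single master seed, so reruns with the same configuration are identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, per-stage CSVs and a JSON
#'   summary are written.
#' @return A list with elements `cohort`, `importance`, `rfe`, `deduped`,
#'   `voi_comparison`, `nested`, `misclassification`, `subgroups`,
#'   `subgroup_comparison`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 6L)

  cohort <- simulate_cohort(
    config = within_config(config$cohort, stage_seeds[1L]))
  cohort <- inject_missingness(cohort, seed = stage_seeds[2L])
  feats <- assemble_features(cohort, "iwsa")

  importance <- repeated_importance(
    feats, n_repetitions = config$importance_repetitions,
    n_trees = config$n_trees, seed = stage_seeds[3L])
  rfe <- recursive_feature_elimination(
    feats, n_repetitions = config$inner_repetitions,
    n_trees = config$n_trees, seed = stage_seeds[3L])
  deduped <- per_parameter_dedup(rfe)

  voi_comparison <- compare_voi_definitions(
    cohort, n_repetitions = config$evaluation_repetitions, k = config$k,
    n_trees = config$n_trees, seed = stage_seeds[4L])

  set.seed(stage_seeds[5L])
  folds <- make_folds(cohort$group, k = config$k)
  nested <- nested_feature_selection_cv(
    feats, folds = folds, inner_repetitions = config$inner_repetitions,
    n_trees = config$n_trees)

  profile <- misclassification_probability(
    feats, n_repetitions = config$misclassification_repetitions,
    n_trees = config$n_trees, seed = stage_seeds[6L])
  subgroups <- split_subgroups(profile)
  comparison <- if (length(subgroups$misclassified) > 0 &&
                    length(subgroups$correct) > 0)
    compare_subgroups(cohort, subgroups, alpha = config$alpha)
  else NULL

  summary <- list(
    profile = config$profile, seed = config$seed,
    n_icas = sum(cohort$group == "ICAS"), n_hc = sum(cohort$group == "HC"),
    missing_fraction = mean(is.na(cohort$voi)),
    top_features = head(importance$feature, 7L),
    n_rfe_survivors = nrow(rfe), n_final_features = nrow(deduped),
    voi = voi_comparison$summary,
    nested_best_size = nested$best_size,
    nested_best_auc = nested$best$auc,
    nested_best_accuracy = nested$best$accuracy,
    sensitivity = nested$best$youden$sensitivity,
    specificity = nested$best$youden$specificity,
    n_misclassified_patients = length(subgroups$misclassified))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    write.csv(importance, file.path(out_dir, "importance.csv"),
              row.names = FALSE)
    write.csv(deduped, file.path(out_dir, "final_features.csv"),
              row.names = FALSE)
    write.csv(voi_comparison$summary, file.path(out_dir, "voi_modes.csv"),
              row.names = FALSE)
    write.csv(nested$per_size, file.path(out_dir, "nested_sizes.csv"),
              row.names = FALSE)
    write.csv(profile, file.path(out_dir, "misclassification.csv"),
              row.names = FALSE)
    if (!is.null(comparison))
      write.csv(comparison, file.path(out_dir, "subgroup_comparison.csv"),
                row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = cohort, importance = importance, rfe = rfe,
       deduped = deduped, voi_comparison = voi_comparison, nested = nested,
       misclassification = profile, subgroups = subgroups,
       subgroup_comparison = comparison, summary = summary)
}

# Rebuild a cohort_config with a stage-derived seed.
within_config <- function(cc, seed) {
  cc$seed <- seed
  cc
}
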