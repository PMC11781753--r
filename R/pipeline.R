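# End-to-end pipeline stages behind the command-line interface. Each stage
# is a plain function of (inputs, seed) so runs replay exactly; stage seeds
# are derived from one top-level seed with fixed offsets, so e.g. changing
# the classifier seed never perturbs the simulated data.

stage_seed <- function(seed, stage) {
  derive_seed(seed, switch(stage, simulate = 11L, split = 23L, forest = 37L,
                           cv = 53L, abort("unknown stage")))
}

# Fig-2-style model code: classifier initial + feature-set tag + variable,
# e.g. R_CMCI_COPLen, S_OR_COPX.
model_code <- function(classifier, feature_set, variable) {
  cl <- c(ranking_forest = "R", naive_bayes = "B", logistic = "L",
          svm = "S")[[classifier]]
  fs <- if (feature_set == "cmci") "CMCI" else "OR"
  paste(cl, fs, variable, sep = "_")
}

#' Extract features from a cohort of recordings
#'
#' Builds one feature table per feature set from a list of recordings (or a
#' manifest path), optionally writing CSVs plus JSON schema sidecars.
#'
#' @param recordings A list of `cop_recording`s, or a manifest CSV path for
#'   [read_cop_manifest()].
#' @param feature_sets Character subset of `c("time_domain", "cmci")`.
#' @param variables Passed to [build_feature_table()].
#' @param out_dir If non-`NULL`, write `features_<set>.csv` (+ sidecars)
#'   there.
#' @param ... Passed to [build_feature_table()] (CMCI configuration).
#' @return Named list of feature tables.
#' @export
run_extract <- function(recordings, feature_sets = c("time_domain", "cmci"),
                        variables = c("COPX", "COPY", "COPLen", "TiltAngle"),
                        out_dir = NULL, ...) {
  if (is.character(recordings)) recordings <- read_cop_manifest(recordings)
  tables <- purrr::map(rlang::set_names(feature_sets), function(fs) {
    build_feature_table(recordings, feature_set = fs,
                        variables = variables, ...)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::iwalk(tables, function(tbl, fs) {
      write_feature_table(tbl, file.path(out_dir,
                                         sprintf("features_%s.csv", fs)))
    })
  }
  tables
}

#' Run the classification bench over feature tables
#'
#' For every condition, classifier, feature set and single variable, fits on
#' a stratified 70/30 split, evaluates on the held-out test set, and runs
#' stratified k-fold cross-validation. Models are coded in the
#' `R_CMCI_COPLen` style (classifier initial, `OR`/`CMCI`, variable).
#'
#' @param tables Named list of feature tables as produced by
#'   [run_extract()] (names are the feature sets).
#' @param classifiers Subset of `c("ranking_forest", "naive_bayes",
#'   "logistic", "svm")`.
#' @param train_fraction Split fraction, default 0.7.
#' @param k CV folds, default 10.
#' @param seed Top-level seed; split/forest/CV substreams are derived from
#'   it.
#' @param n_trees Trees for the ranking forest, default 50.
#' @param out_dir If non-`NULL`, write `results.json` and per-model ROC CSVs
#'   there.
#' @return A tibble with one row per model x condition: split and CV
#'   metrics.
#' @export
run_classify <- function(tables,
                         classifiers = c("ranking_forest", "naive_bayes",
                                         "logistic", "svm"),
                         train_fraction = 0.7, k = 10L, seed = 1L,
                         n_trees = 50L, out_dir = NULL) {
  grid <- tidyr::expand_grid(
    feature_set = names(tables),
    classifier = classifiers,
    condition = sort(unique(tables[[1]]$condition)))
  rows <- purrr::pmap(grid, function(feature_set, classifier, condition) {
    tbl <- tables[[feature_set]]
    sub <- tbl[tbl$condition == condition, , drop = FALSE]
    vars <- attr(tbl, "variables")
    purrr::map_dfr(vars, function(v) {
      cols <- grep(paste0("^(CMCI_)?", v, "(_|$)"), names(sub), value = TRUE)
      one <- sub[c("subject_id", "group", "condition", cols)]
      one <- one[stats::complete.cases(one[cols]), , drop = FALSE]
      plan <- stratified_split(one$group, train_fraction,
                               seed = stage_seed(seed, "split"))
      fit <- fit_any(one[plan$train_indices, ], classifier,
                     seed = stage_seed(seed, "forest"), n_trees = n_trees)
      ev <- evaluate_scorer(fit, one[plan$test_indices, ])
      cv <- cross_validate(one, classifier, k = k,
                           seed = stage_seed(seed, "cv"), n_trees = n_trees)
      tibble::tibble(
        model = model_code(classifier, feature_set, v),
        classifier = classifier, feature_set = feature_set,
        variable = v, condition = condition,
        split_auc = ev$auc, split_sensitivity = ev$sensitivity,
        split_specificity = ev$specificity,
        cv_mean_auc = cv$mean_auc,
        cv_mean_sensitivity = cv$mean_sensitivity,
        cv_mean_specificity = cv$mean_specificity,
        roc = list(ev$roc))
    })
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    flat <- dplyr::select(out, -"roc")
    jsonlite::write_json(flat, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    purrr::pwalk(out[c("model", "condition", "roc")],
                 function(model, condition, roc) {
                   readr::write_csv(roc, file.path(
                     out_dir, sprintf("roc_%s_%s.csv", model, condition)),
                     progress = FALSE)
                 })
  }
  out
}

#' Group-comparison stage over extracted feature tables
#'
#' @param tables Named list of feature tables.
#' @param alpha Significance level.
#' @param out_dir If non-`NULL`, write `comparisons_<set>.csv` there.
#' @return Named list of comparison tibbles.
#' @export
run_compare <- function(tables, alpha = 0.05, out_dir = NULL) {
  res <- purrr::map(tables, compare_feature_table, alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::iwalk(res, function(tbl, fs) {
      readr::write_csv(format_comparison_table(tbl),
                       file.path(out_dir,
                                 sprintf("comparisons_%s.csv", fs)),
                       progress = FALSE)
    })
  }
  res
}
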