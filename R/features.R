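#' Time-domain summary features of one series
#'
#' Mean, sample standard deviation (`n - 1` denominator), moment-based
#' skewness `m3 / m2^(3/2)` and Pearson kurtosis `m4 / m2^2` (a normal
#' sample reads ~3, not 0). Constant input yields sd 0 and `NA` skewness and
#' kurtosis.
#'
#' @param x Numeric series, length >= 4.
#' @return A one-row tibble with columns `mean`, `sd`, `skewness`,
#'   `kurtosis`.
#' @export
#' @examples
#' time_domain_features(c(1, 2, 3, 4))
time_domain_features <- function(x) {
  x <- as.double(x)
  if (length(x) < 4L) abort("`x` must have length >= 4.")
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) {
    return(tibble::tibble(mean = mean(x), sd = 0,
                          skewness = NA_real_, kurtosis = NA_real_))
  }
  tibble::tibble(mean = mean(x), sd = sd(x),
                 skewness = e1071::skewness(x, type = 1),
                 kurtosis = e1071::kurtosis(x, type = 1) + 3)
}

cop_variable_series <- function(rec, variable) {
  switch(variable,
         COPX = rec$cop_x,
         COPY = rec$cop_y,
         COPLen = cop_len(rec),
         TiltAngle = tilt_angle(cop_len(rec), attr(rec, "height")),
         abort(sprintf("unknown variable '%s'.", variable)))
}

#' Build a per-subject-per-condition feature table
#'
#' One row per recording (subject x condition). With
#' `feature_set = "time_domain"` each requested variable contributes four
#' columns `<var>_mean`, `<var>_sd`, `<var>_skewness`, `<var>_kurtosis`;
#' with `feature_set = "cmci"` each variable contributes one column
#' `CMCI_<var>` holding the Composite Multiscale Complexity Index of that
#' series. A recording whose CMCI is undefined keeps its row with an `NA`
#' cell. Rows are ordered by (condition, group, subject) and columns follow
#' the order of `variables`, so rebuilding from the same inputs is
#' bit-identical. No scaling is applied here; classifier z-scoring happens
#' at fit time on training folds only.
#'
#' @param recordings List of `cop_recording` objects.
#' @param feature_set `"time_domain"` or `"cmci"`.
#' @param variables Subset of `c("COPX", "COPY", "COPLen", "TiltAngle")`.
#' @param ... For `"cmci"`, arguments passed on to [cmci()].
#' @return A tibble with `subject_id`, `group`, `condition` and the feature
#'   columns, carrying attributes `feature_set` and `variables`.
#' @export
build_feature_table <- function(recordings,
                                feature_set = c("time_domain", "cmci"),
                                variables = c("COPX", "COPY", "COPLen",
                                              "TiltAngle"),
                                ...) {
  feature_set <- match.arg(feature_set)
  variables <- match.arg(variables, several.ok = TRUE,
                         choices = c("COPX", "COPY", "COPLen", "TiltAngle"))
  stopifnot(length(recordings) > 0,
            all(vapply(recordings, inherits, logical(1), "cop_recording")))
  rows <- purrr::map(recordings, function(rec) {
    meta <- tibble::tibble(subject_id = attr(rec, "subject_id"),
                           group = attr(rec, "group"),
                           condition = attr(rec, "condition"))
    feats <- purrr::map(variables, function(v) {
      series <- cop_variable_series(rec, v)
      if (feature_set == "time_domain") {
        f <- time_domain_features(series)
        names(f) <- paste0(v, "_", names(f))
        f
      } else {
        tibble::tibble(!!paste0("CMCI_", v) := cmci(series, ...)$cmci)
      }
    })
    dplyr::bind_cols(meta, feats)
  })
  out <- dplyr::bind_rows(rows)
  if (anyNA(out$group)) abort("every recording must carry a group label.")
  out <- dplyr::arrange(out, .data$condition, .data$group, .data$subject_id)
  attr(out, "feature_set") <- feature_set
  attr(out, "variables") <- variables
  out
}

#' Feature-table column names (excluding metadata)
#'
#' @param table A feature table from [build_feature_table()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "group", "condition"))
}

#' Write a feature table with a JSON schema sidecar
#'
#' Writes `<path>` as CSV and `<path>.json` recording the feature set,
#' variable list and column order.
#'
#' @param table A feature table.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  schema <- list(feature_set = attr(table, "feature_set"),
                 variables = attr(table, "variables"),
                 columns = names(table),
                 kurtosis_convention = "Pearson (normal = 3)")
  jsonlite::write_json(schema, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
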