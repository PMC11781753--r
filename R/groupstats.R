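#' Normality-gated two-sample comparison
#'
#' Descriptive comparison of one balance descriptor between two groups.
#' Normality of each group is assessed with the Kolmogorov-Smirnov test
#' against a normal with estimated mean and sd, using the Lilliefors
#' correction (the uncorrected KS test is anti-conservative when parameters
#' are estimated). If both groups pass at level `alpha` the groups are
#' compared with Welch's independent-samples t-test; otherwise with the
#' Mann-Whitney U test (exact when the combined sample is small and
#' untied, normal approximation with tie correction otherwise). Groups
#' smaller than 5 — below the Lilliefors minimum — are treated as
#' non-normal, which routes the comparison down the rank-based branch.
#'
#' @param a,b Numeric value vectors for the two groups, each of length >= 3.
#' @param alpha Significance level for both the normality gate and the
#'   comparison, default 0.05.
#' @param descriptor,condition Optional labels carried into the result.
#' @return A `group_comparison`: one-row tibble with group means/sds,
#'   per-group normality p-values, `test` (`"t_test"` or
#'   `"mann_whitney"`), `p_value`, `significant`, and `descriptor_auc`
#'   from [descriptor_auc()].
#' @export
#' @examples
#' set.seed(1)
#' compare_groups(rnorm(13), rnorm(12, mean = 2))
compare_groups <- function(a, b, alpha = 0.05, descriptor = NA_character_,
                           condition = NA_character_) {
  a <- as.double(a); b <- as.double(b)
  if (length(a) < 3L || length(b) < 3L) {
    abort("each group needs at least 3 values.")
  }
  norm_p <- function(x) {
    if (length(x) < 5L || pop_sd(x) == 0) return(NA_real_)
    nortest::lillie.test(x)$p.value
  }
  pa <- norm_p(a); pb <- norm_p(b)
  both_normal <- !is.na(pa) && !is.na(pb) && pa > alpha && pb > alpha
  if (both_normal) {
    test <- "t_test"
    p <- t.test(a, b)$p.value
  } else {
    test <- "mann_whitney"
    exact <- length(a) + length(b) <= 25 &&
      !any(duplicated(c(a, b)))
    p <- suppressWarnings(wilcox.test(a, b, exact = exact)$p.value)
  }
  structure(tibble::tibble(
    descriptor = descriptor, condition = condition,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b),
    normality_p_a = pa, normality_p_b = pb,
    test = test, p_value = p, significant = p < alpha,
    descriptor_auc = descriptor_auc(a, b)),
    class = c("group_comparison", class(tibble::tibble())))
}

#' Single-descriptor AUC via a one-dimensional soft-margin SVM
#'
#' Fits a linear soft-margin SVM to the pooled values of one descriptor with
#' group labels and computes the AUC of its decision scores. A linear
#' scorer in one dimension is monotone in the value, so this AUC equals the
#' rank-based (Mann-Whitney) AUC or its complement depending on
#' orientation; the larger of the two is reported. Degenerate inputs (all
#' values identical) return 0.5.
#'
#' @param a,b Numeric value vectors for the two groups, each of length >= 2.
#' @param cost Soft-margin cost, default 1.
#' @return AUC in `[0.5, 1]`.
#' @export
descriptor_auc <- function(a, b, cost = 1) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("each group needs at least 2 values.")
  }
  pooled <- c(a, b)
  y <- factor(rep(c(0, 1), c(length(a), length(b))), levels = c(0, 1))
  if (pop_sd(pooled) == 0) return(0.5)
  fit <- tryCatch(
    e1071::svm(matrix(pooled, ncol = 1), y, kernel = "linear", cost = cost,
               scale = TRUE),
    error = function(e) NULL)
  if (is.null(fit)) return(0.5)
  dv <- attr(predict(fit, matrix(pooled, ncol = 1), decision.values = TRUE),
             "decision.values")
  scores <- as.double(dv[, 1])
  if (pop_sd(scores) == 0) return(0.5)
  roc <- roc_points(scores, as.integer(y == "1"))
  auc <- trapezoid_auc(roc)
  max(auc, 1 - auc)
}

#' Compare every descriptor of a feature table between groups
#'
#' Runs [compare_groups()] per condition and feature column.
#'
#' @param table A feature table from [build_feature_table()].
#' @param alpha Significance level, default 0.05.
#' @return A tibble of group comparisons, one row per
#'   (condition, descriptor).
#' @export
compare_feature_table <- function(table, alpha = 0.05) {
  cols <- feature_columns(table)
  groups <- sort(unique(table$group))
  if (length(groups) != 2L) abort("feature table must contain exactly 2 groups.")
  combos <- tidyr::expand_grid(condition = sort(unique(table$condition)),
                               descriptor = cols)
  purrr::pmap_dfr(combos, function(condition, descriptor) {
    sub <- table[table$condition == condition, ]
    va <- sub[[descriptor]][sub$group == groups[1]]
    vb <- sub[[descriptor]][sub$group == groups[2]]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    compare_groups(va, vb, alpha = alpha, descriptor = descriptor,
                   condition = condition)
  })
}

#' Format group comparisons as a descriptor-by-group table
#'
#' Lays out comparisons in the conventional descriptor-rows by group-columns
#' form with `mean(sd)` cells and a significance asterisk on the first
#' group's cell when `p < alpha`.
#'
#' @param comparisons Tibble from [compare_feature_table()].
#' @param digits Digits for means and sds, default 2.
#' @return A tibble with `condition`, `descriptor` and one formatted column
#'   per group.
#' @export
format_comparison_table <- function(comparisons, digits = 2) {
  fmt <- function(m, s, star) {
    sprintf("%.*f(%.*g)%s", digits, m, digits, s, ifelse(star, "*", ""))
  }
  tibble::tibble(
    condition = comparisons$condition,
    descriptor = comparisons$descriptor,
    group_a = fmt(comparisons$mean_a, comparisons$sd_a,
                  comparisons$significant),
    group_b = fmt(comparisons$mean_b, comparisons$sd_b, FALSE),
    p_value = comparisons$p_value,
    auc = comparisons$descriptor_auc)
}
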