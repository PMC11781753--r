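#' Stratified train/test split
#'
#' Shuffles each class with the given seed and assigns the first
#' `round(train_fraction * class_size)` samples of each class to the
#' training set (base-R round, i.e. round-half-even), the rest to the test
#' set. The partition is disjoint and exhaustive and per-class train
#' proportions are within one sample of `train_fraction`.
#'
#' @param labels Vector of class labels (two or more classes, each with at
#'   least 2 samples).
#' @param train_fraction Fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return A list of class `split_plan` with integer vectors
#'   `train_indices`, `test_indices`, plus `train_fraction` and `seed`.
#' @export
#' @examples
#' stratified_split(rep(c("elite", "expert"), c(13, 12)), seed = 1)
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2L)) {
    abort("every class needs at least 2 samples to stratify.")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  train <- integer()
  withr::local_seed(seed)
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    n_train <- round(train_fraction * length(idx))
    if (n_train < 1L || n_train >= length(idx)) {
      abort(sprintf("class '%s' would have an empty train or test side.", cl))
    }
    train <- c(train, idx[seq_len(n_train)])
  }
  train <- sort(train)
  structure(list(train_indices = train,
                 test_indices = setdiff(seq_along(labels), train),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = TRUE),
            class = "split_plan")
}

# --- internal: design-matrix plumbing ---------------------------------------

# Feature matrix + 0/1 outcome from a feature table. Positive class is
# "expert" when present, otherwise the second level alphabetically.
table_xy <- function(table, positive = NULL) {
  cols <- feature_columns(table)
  x <- as.matrix(table[cols])
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    keep <- stats::complete.cases(x)
    x <- x[keep, , drop = FALSE]
    table <- table[keep, ]
  }
  classes <- sort(unique(table$group))
  if (is.null(positive)) {
    positive <- if ("expert" %in% classes) "expert" else classes[length(classes)]
  }
  list(x = x, y = as.integer(table$group == positive), positive = positive,
       features = cols)
}

# z-scoring statistics from training data only; zero-sd features get a
# floored sd so they scale to a constant rather than Inf.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv < 1e-9] <- 1e-9
  list(mu = mu, sd = sdv)
}
apply_scaler <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

# --- ranking forest ----------------------------------------------------------

#' Ranking forest: bagged decision trees as a ranking scorer
#'
#' An ensemble of `n_trees` CART trees (Gini impurity, grown deep:
#' `cp = 0`, `minsplit = 2`, `minbucket = 1`), each fit on a bootstrap
#' resample of the training rows using a random subset of
#' `floor(sqrt(p))` features. The score of a sample is the fraction of
#' trees voting the positive class, used as a ranking statistic for ROC
#' analysis. With `n_trees = 1` the model is a single bootstrap tree.
#'
#' @param train A feature table (see [build_feature_table()]) with both
#'   classes present.
#' @param n_trees Number of trees, default 50.
#' @param mtry Features per tree; default `max(1, floor(sqrt(p)))`.
#' @param seed Integer seed driving the bootstrap and feature sampling.
#' @param positive Positive-class label; defaults to `"expert"`.
#' @return An object of class `ranking_forest` with a `predict()` method
#'   returning scores in `[0, 1]`.
#' @export
ranking_forest <- function(train, n_trees = 50L, mtry = NULL, seed = 1L,
                           positive = NULL) {
  d <- table_xy(train, positive)
  if (length(unique(d$y)) < 2L) abort("training set has a single class.")
  p <- ncol(d$x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- min(as.integer(mtry), p)
  n <- nrow(d$x)
  df <- as.data.frame(d$x)
  names(df) <- paste0("f", seq_len(p))   # syntactic names for rpart
  df$.y <- factor(d$y, levels = c(0, 1))
  withr::local_seed(seed)
  trees <- purrr::map(seq_len(n_trees), function(i) {
    rows <- sample.int(n, n, replace = TRUE)
    feats <- sort(sample.int(p, mtry))
    boot <- df[rows, , drop = FALSE]
    if (length(unique(boot$.y)) < 2L) {
      # degenerate bootstrap: constant vote for its single class
      return(list(constant = as.double(boot$.y[1L] == "1"), feats = feats))
    }
    fml <- stats::as.formula(paste(".y ~", paste(names(df)[feats],
                                                 collapse = " + ")))
    fit <- rpart::rpart(fml, data = boot, method = "class",
                        control = rpart::rpart.control(
                          minsplit = 2, minbucket = 1, cp = 0,
                          maxcompete = 0, maxsurrogate = 0, xval = 0))
    list(fit = fit, feats = feats)
  })
  structure(list(trees = trees, features = d$features,
                 positive = d$positive, n_trees = as.integer(n_trees),
                 mtry = mtry, seed = as.integer(seed)),
            class = "ranking_forest")
}

#' @export
predict.ranking_forest <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$features])
  storage.mode(x) <- "double"
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  votes <- vapply(object$trees, function(tr) {
    if (!is.null(tr$constant)) return(rep(tr$constant, nrow(df)))
    cls <- predict(tr$fit, df, type = "class")
    as.double(cls == "1")
  }, numeric(nrow(df)))
  if (nrow(df) == 1L) votes <- matrix(votes, nrow = 1)
  rowMeans(votes)
}

#' @export
print.ranking_forest <- function(x, ...) {
  cat(sprintf("<ranking_forest> %d trees, mtry %d, %d feature(s), positive class '%s'\n",
              x$n_trees, x$mtry, length(x$features), x$positive))
  invisible(x)
}

# --- baseline classifiers ----------------------------------------------------

#' Baseline classifiers: naive Bayes, logistic regression, SVM
#'
#' Fits one of three reference scorers on a feature table, z-scoring the
#' features with training-set statistics (test data is scaled with the same
#' statistics at prediction time; never refit):
#' * `"naive_bayes"` — Gaussian naive Bayes (per-class feature
#'   means/variances via [e1071::naiveBayes()]); score is the posterior
#'   probability of the positive class. Zero class-variances are floored at
#'   1e-9 with a warning.
#' * `"logistic"` — L2-regularized logistic regression
#'   ([glmnet::glmnet()] with `alpha = 0`); score is the predicted
#'   probability.
#' * `"svm"` — soft-margin SVM with RBF kernel ([e1071::svm()], `cost = 1`,
#'   default `gamma = 1/p` on the z-scored features); score is the signed
#'   decision value oriented so larger means more positive-class.
#'
#' @param train A feature table with both classes present.
#' @param which One of `"naive_bayes"`, `"logistic"`, `"svm"`.
#' @param seed Integer seed (SVM fitting is deterministic here but the seed
#'   is stored for provenance).
#' @param lambda Ridge penalty for `"logistic"`, default 0.01.
#' @param cost SVM soft-margin cost, default 1.
#' @param positive Positive-class label; defaults to `"expert"`.
#' @return An object of class `cop_scorer` with a `predict()` method
#'   returning numeric ranking scores.
#' @export
fit_baseline <- function(train, which = c("naive_bayes", "logistic", "svm"),
                         seed = 1L, lambda = 0.01, cost = 1,
                         positive = NULL) {
  which <- match.arg(which)
  d <- table_xy(train, positive)
  if (length(unique(d$y)) < 2L) abort("training set has a single class.")
  sc <- fit_scaler(d$x)
  xs <- apply_scaler(d$x, sc)
  yf <- factor(d$y, levels = c(0, 1))
  withr::local_seed(seed)
  model <- switch(which,
    naive_bayes = {
      fit <- e1071::naiveBayes(xs, yf)
      floored <- FALSE
      fit$tables <- lapply(fit$tables, function(tab) {
        if (any(tab[, 2] < sqrt(1e-9))) {
          floored <<- TRUE
          tab[, 2] <- pmax(tab[, 2], sqrt(1e-9))
        }
        tab
      })
      if (floored) warn("zero-variance feature under naive Bayes; variance floored at 1e-9.")
      fit
    },
    logistic = {
      xin <- if (ncol(xs) == 1L) cbind(xs, 0) else xs
      # glmnet needs >= 2 columns, hence the zero pad; its small-class
      # warning is expected at fold sizes used here
      suppressWarnings(glmnet::glmnet(xin, yf, family = "binomial",
                                      alpha = 0, lambda = lambda))
    },
    svm = e1071::svm(xs, yf, kernel = "radial", cost = cost, scale = FALSE))
  structure(list(kind = which, model = model, scaler = sc,
                 features = d$features, positive = d$positive,
                 lambda = lambda, cost = cost, seed = as.integer(seed)),
            class = "cop_scorer")
}

#' @export
predict.cop_scorer <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$features])
  storage.mode(x) <- "double"
  xs <- apply_scaler(x, object$scaler)
  switch(object$kind,
    naive_bayes = {
      pr <- predict(object$model, xs, type = "raw")
      as.double(pr[, "1"])
    },
    logistic = {
      xin <- if (length(object$features) == 1L) cbind(xs, 0) else xs
      as.double(predict(object$model, xin, type = "response")[, 1])
    },
    svm = {
      dv <- attr(predict(object$model, xs, decision.values = TRUE),
                 "decision.values")
      # e1071 decision values are positive for the class named first in
      # the column label; orient so larger = positive class ("1").
      s <- as.double(dv[, 1])
      if (startsWith(colnames(dv)[1], "1")) s else -s
    })
}

#' @export
print.cop_scorer <- function(x, ...) {
  cat(sprintf("<cop_scorer> %s on %d feature(s), positive class '%s'\n",
              x$kind, length(x$features), x$positive))
  invisible(x)
}

# --- ROC / evaluation --------------------------------------------------------

# ROC curve over all score thresholds. Scores tied at a value move together,
# which yields the trapezoid = Mann-Whitney (ties = 1/2) identity.
roc_points <- function(scores, labels01) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels01[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble::tibble(threshold = c(Inf, s[last]),
                 tpr = c(0, tp[last] / sum(y)),
                 fpr = c(0, fp[last] / sum(1 - y)))
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' Evaluate a fitted scorer on a test feature table
#'
#' Computes the full ROC curve over all score thresholds, the trapezoidal
#' AUC (identical to the Mann-Whitney pairwise-ordering statistic with ties
#' counted 1/2), and sensitivity/specificity at the Youden-optimal
#' operating point (maximizing TPR - FPR; ties broken toward the lower
#' threshold).
#'
#' @param scorer A fitted `ranking_forest` or `cop_scorer` (anything with a
#'   `predict(object, newdata)` method returning numeric scores), or `NULL`
#'   if `scores` are supplied directly.
#' @param test A feature table containing both classes.
#' @param scores Optional numeric scores to evaluate directly (bypasses
#'   `scorer`); must align with `test$group`.
#' @param positive Positive-class label; defaults to `"expert"`.
#' @return An `evaluation_result`: list with `roc` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc`, `sensitivity`, `specificity`,
#'   `threshold`, `operating_rule`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' tbl <- tibble::tibble(subject_id = as.character(1:4),
#'                       group = c("elite", "elite", "expert", "expert"),
#'                       condition = "T1", f = c(0.1, 0.2, 0.8, 0.9))
#' evaluate_scorer(NULL, tbl, scores = tbl$f)$auc
evaluate_scorer <- function(scorer, test, scores = NULL, positive = NULL) {
  classes <- sort(unique(test$group))
  if (is.null(positive)) {
    positive <- if ("expert" %in% classes) "expert" else classes[length(classes)]
  }
  y <- as.integer(test$group == positive)
  if (length(unique(y)) < 2L) abort("test set must contain both classes.")
  if (is.null(scores)) scores <- predict(scorer, test)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  roc <- roc_points(scores, y)
  # midrank form of the Mann-Whitney statistic: midranks and their sums are
  # exact in floating point, so this equals pairwise counting (ties = 1/2)
  # bit-for-bit; the trapezoid area of `roc` agrees to rounding error
  n_pos <- sum(y); n_neg <- sum(1 - y)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))
  best <- best[length(best)]   # ties -> lower threshold
  structure(list(roc = roc, auc = auc,
                 sensitivity = roc$tpr[best],
                 specificity = 1 - roc$fpr[best],
                 threshold = roc$threshold[best],
                 operating_rule = "Youden J, ties to lower threshold",
                 n_pos = n_pos, n_neg = n_neg,
                 positive = positive),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> AUC %.3f, sensitivity %.3f, specificity %.3f (%d pos / %d neg)\n",
              x$auc, x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.evaluation_result <- function(x, ...) x$roc

#' @exportS3Method generics::glance
glance.evaluation_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, sensitivity = x$sensitivity,
                 specificity = x$specificity, n_pos = x$n_pos,
                 n_neg = x$n_neg)
}

#' @exportS3Method ggplot2::autoplot
autoplot.evaluation_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc))
}

# --- cross-validation --------------------------------------------------------

# Stratified k-fold assignment: shuffle within class, deal round-robin.
stratified_folds <- function(labels, k, seed) {
  counts <- table(labels)
  if (any(counts < k)) {
    abort(sprintf("smallest class has %d samples; lower k below that.",
                  min(counts)))
  }
  fold <- integer(length(labels))
  withr::local_seed(seed)
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_any <- function(train, classifier, seed, n_trees = 50L, ...) {
  if (classifier == "ranking_forest") {
    ranking_forest(train, n_trees = n_trees, seed = seed, ...)
  } else {
    fit_baseline(train, which = classifier, seed = seed, ...)
  }
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Splits a feature table into `k` stratified folds, fits the requested
#' classifier on each training portion and evaluates on the held-out fold,
#' then reports per-fold and mean AUC, sensitivity and specificity.
#'
#' @param table A feature table with both classes.
#' @param classifier One of `"ranking_forest"`, `"naive_bayes"`,
#'   `"logistic"`, `"svm"`.
#' @param k Number of folds, default 10.
#' @param seed Integer seed (drives fold assignment and per-fold model
#'   seeds).
#' @param ... Passed to the classifier constructor.
#' @return A `cv_result`: list with `folds` tibble (`fold`, `auc`,
#'   `sensitivity`, `specificity`), `mean_auc`, `mean_sensitivity`,
#'   `mean_specificity`, `classifier`, `k`, `seed`.
#' @export
cross_validate <- function(table, classifier = "ranking_forest", k = 10L,
                           seed = 1L, ...) {
  if (k < 2L) abort("`k` must be >= 2.")
  fold <- stratified_folds(table$group, k, seed)
  per_fold <- purrr::map(seq_len(k), function(f) {
    train <- table[fold != f, , drop = FALSE]
    test <- table[fold == f, , drop = FALSE]
    fit <- fit_any(train, classifier, seed = derive_seed(seed, f), ...)
    ev <- evaluate_scorer(fit, test)
    tibble::tibble(fold = f, auc = ev$auc, sensitivity = ev$sensitivity,
                   specificity = ev$specificity)
  })
  folds <- dplyr::bind_rows(per_fold)
  structure(list(folds = folds, mean_auc = mean(folds$auc),
                 mean_sensitivity = mean(folds$sensitivity),
                 mean_specificity = mean(folds$specificity),
                 classifier = classifier, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold: mean AUC %.3f, SEN %.3f, SPC %.3f\n",
              x$classifier, x$k, x$mean_auc, x$mean_sensitivity,
              x$mean_specificity))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, k = x$k, mean_auc = x$mean_auc,
                 mean_sensitivity = x$mean_sensitivity,
                 mean_specificity = x$mean_specificity)
}
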