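test_that("stratified split follows the per-class rounding rule", {
  labels <- rep(c("elite", "expert"), c(13, 12))
  plan <- stratified_split(labels, 0.7, seed = 1)
  expect_length(plan$train_indices, 17)  # round(9.1) + round(8.4) = 9 + 8
  expect_length(plan$test_indices, 8)
  expect_equal(sum(labels[plan$train_indices] == "elite"), 9)
  expect_equal(sum(labels[plan$train_indices] == "expert"), 8)
  expect_setequal(c(plan$train_indices, plan$test_indices), seq_along(labels))

  expect_error(stratified_split(labels, 1.0), "between 0 and 1")
  expect_error(stratified_split(c("a", "b", "b"), 0.7), "at least 2")

  expect_identical(stratified_split(labels, 0.7, seed = 42),
                   stratified_split(labels, 0.7, seed = 42))
  diffs <- sum(vapply(1:100, function(s) {
    !identical(stratified_split(labels, 0.7, seed = s)$train_indices,
               stratified_split(labels, 0.7, seed = s + 100)$train_indices)
  }, logical(1)))
  expect_gte(diffs, 95)
})

test_that("ranking forest separates separable data and is seed-reproducible", {
  withr::local_seed(3)
  tbl <- toy_table(runif(20, -2, -0.5), runif(20, 0.5, 2))
  rf <- ranking_forest(tbl, n_trees = 50, seed = 7)
  ev <- evaluate_scorer(rf, tbl)
  expect_equal(ev$auc, 1.0)

  rf2 <- ranking_forest(tbl, n_trees = 50, seed = 7)
  expect_identical(predict(rf, tbl), predict(rf2, tbl))
})

test_that("a single-tree forest equals one seeded bootstrap CART tree", {
  withr::local_seed(4)
  tbl <- toy_table(rnorm(15), rnorm(15, 1))
  rf1 <- ranking_forest(tbl, n_trees = 1, seed = 9)
  # replicate the internal draw: bootstrap rows then a feature subset
  df <- data.frame(f1 = tbl$f, .y = factor(as.integer(tbl$group == "expert"),
                                           levels = c(0, 1)))
  withr::local_seed(9)
  rows <- sample.int(30, 30, replace = TRUE)
  sample.int(1, 1)  # feature-subset draw
  ref <- rpart::rpart(.y ~ f1, data = df[rows, ], method = "class",
                      control = rpart::rpart.control(
                        minsplit = 2, minbucket = 1, cp = 0,
                        maxcompete = 0, maxsurrogate = 0, xval = 0))
  expect_equal(predict(rf1, tbl),
               unname(as.double(predict(ref, df, type = "class") == "1")))
})

test_that("permuted labels give chance-level forests", {
  withr::local_seed(12)
  vals <- rnorm(40)
  hits <- 0
  for (s in 1:60) {
    perm <- sample(rep(c("elite", "expert"), each = 20))
    tbl <- toy_table(vals[1:20], vals[21:40])
    tbl$group <- perm
    plan <- stratified_split(tbl$group, 0.7, seed = s)
    rf <- ranking_forest(tbl[plan$train_indices, ], n_trees = 25, seed = s)
    auc <- evaluate_scorer(rf, tbl[plan$test_indices, ])$auc
    if (auc >= 0.15 && auc <= 0.85) hits <- hits + 1
  }
  # chance-level on 12 test samples is noisy; the bulk must sit mid-range
  expect_gte(hits, 54)
})

test_that("baseline classifiers separate well-separated Gaussian classes", {
  withr::local_seed(17)
  n <- 50
  tbl <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:(2 * n)),
    group = rep(c("elite", "expert"), each = n),
    condition = "T1",
    f1 = c(rnorm(n, -2), rnorm(n, 2)),
    f2 = c(rnorm(n, -2), rnorm(n, 2)))
  plan <- stratified_split(tbl$group, 0.7, seed = 2)
  for (w in c("naive_bayes", "logistic", "svm")) {
    fit <- fit_baseline(tbl[plan$train_indices, ], w, seed = 3)
    ev <- evaluate_scorer(fit, tbl[plan$test_indices, ])
    expect_gt(ev$auc, 0.95)
  }
})

test_that("naive Bayes on one feature matches the Gaussian likelihood-ratio ordering", {
  withr::local_seed(19)
  tbl <- toy_table(rnorm(20, 0, 1), rnorm(20, 1, 2))
  fit <- fit_baseline(tbl, "naive_bayes", seed = 1)
  scores <- predict(fit, tbl)
  # closed-form: log N(x; mu1, sd1) - log N(x; mu0, sd0) on z-scored values
  sc <- fit$scaler
  z <- (tbl$f - sc$mu) / sc$sd
  z0 <- z[tbl$group == "elite"]; z1 <- z[tbl$group == "expert"]
  llr <- dnorm(z, mean(z1), sd(z1), log = TRUE) -
    dnorm(z, mean(z0), sd(z0), log = TRUE)
  expect_identical(order(scores), order(llr))
})

test_that("regularized logistic regression survives linear separability", {
  tbl <- toy_table(seq(-2, -1, length.out = 12), seq(1, 2, length.out = 12))
  fit <- fit_baseline(tbl, "logistic", seed = 1)
  expect_true(all(is.finite(as.matrix(fit$model$beta))))
  expect_equal(evaluate_scorer(fit, tbl)$auc, 1.0)
})

test_that("z-scoring statistics come from the training fold only", {
  tbl <- toy_table(c(0, 0, 0, 0, 8, 8), c(1, 1, 1, 1, 9, 9))
  train <- tbl[c(1:4, 7:10), ]  # excludes the extreme values
  fit <- fit_baseline(train, "svm", seed = 1)
  x <- as.matrix(train["f"])
  expect_equal(unname(fit$scaler$mu), mean(x))
  expect_equal(unname(fit$scaler$sd), sd(x))
  # pooled statistics would differ
  expect_false(isTRUE(all.equal(unname(fit$scaler$mu), mean(tbl$f))))
})

test_that("evaluation matches the pairwise ordering oracle and Youden reporting", {
  tbl <- toy_table(c(0.1, 0.2), c(0.8, 0.9))
  ev <- evaluate_scorer(NULL, tbl, scores = tbl$f)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)

  tie <- evaluate_scorer(NULL, toy_table(1:3, 4:6), scores = rep(0.5, 6))
  expect_equal(tie$auc, 0.5)

  withr::local_seed(23)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- sample(round(runif(n), sample(1:3, 1)))  # induce ties
    tbl <- toy_table(rep(0, sum(y == 0)), rep(0, sum(y == 1)))
    scores <- c(s[y == 0], s[y == 1])
    ev <- evaluate_scorer(NULL, tbl, scores = scores)
    expect_identical(ev$auc, pairwise_auc(scores, c(rep(0, sum(y == 0)),
                                                    rep(1, sum(y == 1)))))
    expect_true(all(diff(ev$roc$fpr) >= 0) && all(diff(ev$roc$tpr) >= 0))
    expect_equal(ev$roc$fpr[1], 0); expect_equal(ev$roc$tpr[1], 0)
    expect_equal(ev$roc$fpr[nrow(ev$roc)], 1)
    expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)
    expect_equal(ev$auc, cmcisway:::trapezoid_auc(ev$roc), tolerance = 1e-12)
  }
})

test_that("our AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(29)
  for (i in 1:10) {
    y <- c(rep(0, 15), rep(1, 15))
    s <- round(rnorm(30), 1)
    tbl <- toy_table(s[1:15], s[16:30])
    ev <- evaluate_scorer(NULL, tbl, scores = tbl$f)
    ref <- suppressMessages(pROC::auc(pROC::roc(y, s, direction = "<",
                                                quiet = TRUE)))
    expect_equal(ev$auc, as.double(ref), tolerance = 1e-12)
  }
})

test_that("cross-validation folds partition the data and aggregate sanely", {
  labels <- rep(c("elite", "expert"), c(13, 12))
  fold <- cmcisway:::stratified_folds(labels, 10, seed = 3)
  expect_setequal(unique(fold), 1:10)
  expect_equal(length(fold), 25)
  for (f in 1:10) {
    expect_true(all(c("elite", "expert") %in% labels[fold == f]))
  }
  expect_error(cmcisway:::stratified_folds(rep(c("a", "b"), c(4, 20)), 10),
               "lower k")

  # constant feature -> constant scores -> chance AUC in every fold
  tbl <- toy_table(rep(1, 6), rep(1, 6))
  cv <- cross_validate(tbl, "ranking_forest", k = 2, seed = 5, n_trees = 5)
  expect_equal(cv$mean_auc, 0.5)

  withr::local_seed(37)
  tbl2 <- toy_table(rnorm(15, -2), rnorm(15, 2))
  cv2 <- cross_validate(tbl2, "svm", k = 5, seed = 1)
  expect_gte(cv2$mean_auc, 0.95)
  expect_equal(nrow(tidy(cv2)), 5)
})

test_that("ensemble agreement with an off-the-shelf random forest on separable data", {
  skip_if_not_installed("randomForest")
  withr::local_seed(41)
  tbl <- toy_table(rnorm(25, -1.5), rnorm(25, 1.5))
  rf <- ranking_forest(tbl, n_trees = 50, seed = 2)
  ours <- evaluate_scorer(rf, tbl)$auc
  ref_fit <- randomForest::randomForest(
    x = data.frame(f = tbl$f), y = factor(tbl$group))
  ref_scores <- predict(ref_fit, data.frame(f = tbl$f), type = "prob")[, "expert"]
  ref <- evaluate_scorer(NULL, tbl, scores = as.double(ref_scores))$auc
  expect_equal(ours, ref, tolerance = 0.05)
})
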