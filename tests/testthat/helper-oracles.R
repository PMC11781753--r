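# Independent oracles and fixture builders used across the suite.

# Naive O(N^2) sample-entropy template counting: the reference against
# which the optimized counter must agree exactly.
naive_sampen_counts <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}

naive_sampen <- function(x, m = 2, r_factor = 0.2) {
  r <- r_factor * sqrt(mean((x - mean(x))^2))
  cnt <- naive_sampen_counts(x, m, r)
  -log(cnt["A"] / cnt["B"])
}

# Exhaustive pairwise Mann-Whitney ordering statistic (ties = 1/2): the
# reference AUC.
pairwise_auc <- function(scores, labels01) {
  pos <- scores[labels01 == 1]
  neg <- scores[labels01 == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# A quick valid recording from raw vectors.
make_recording <- function(x, y, sample_rate = 100, height = 68, ...) {
  t <- (seq_along(x) - 1) / sample_rate
  cop_recording(t, x, y, height = height, sample_rate = sample_rate, ...)
}

# A tiny feature table with a single numeric feature, two groups.
toy_table <- function(values_a, values_b, feature = "f") {
  n_a <- length(values_a); n_b <- length(values_b)
  tbl <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n_a + n_b)),
    group = rep(c("elite", "expert"), c(n_a, n_b)),
    condition = "T1",
    !!feature := c(values_a, values_b))
  attr(tbl, "feature_set") <- "time_domain"
  attr(tbl, "variables") <- feature
  tbl
}

interior <- function(x, frac = 0.1) {
  n <- length(x)
  k <- ceiling(frac * n)
  x[(k + 1):(n - k)]
}
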