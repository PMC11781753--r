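test_that("analytic signal of a pure tone has unit amplitude and the right frequency", {
  t <- seq(0.01, 30, by = 0.01)
  a <- analytic_signal(cos(2 * pi * 2 * t))
  amp <- interior(a$amplitude)
  expect_true(all(abs(amp - 1) < 0.01))
  fi <- interior(instantaneous_frequency(a, 100))
  expect_true(all(abs(fi - 2) < 0.02))
  expect_true(all(a$phase > -pi & a$phase <= pi))
})

test_that("amplitude and phase reconstruct the input exactly", {
  withr::local_seed(2)
  for (i in 1:10) {
    x <- emd_sift(rnorm(500))$imf
    a <- analytic_signal(x)
    expect_lt(max(abs(a$amplitude * cos(a$phase) - x)) / max(abs(x)), 1e-9)
    expect_true(all(a$amplitude >= 0))
  }
  z <- analytic_signal(numeric(64))
  expect_identical(z$amplitude, numeric(64))
  expect_identical(z$phase, numeric(64))
})

test_that("sample entropy matches the naive template-counting oracle exactly", {
  x <- rep(c(1, 2), 5)
  se <- sample_entropy(x, m = 2, r_factor = 0.2)
  ref <- naive_sampen_counts(x, 2, 0.2 * sqrt(mean((x - mean(x))^2)))
  expect_identical(c(se$A, se$B), unname(as.double(ref)))
  expect_identical(se$value, -log(ref[["A"]] / ref[["B"]]))

  withr::local_seed(7)
  for (i in 1:12) {
    n <- sample(60:250, 1)
    x <- if (i %% 2) rnorm(n) else sin(seq(0, 20, length.out = n)) + 0.3 * rnorm(n)
    se <- sample_entropy(x)
    r <- 0.2 * sqrt(mean((x - mean(x))^2))
    ref <- naive_sampen_counts(x, 2, r)
    expect_identical(se$A, as.double(ref[["A"]]))
    expect_identical(se$B, as.double(ref[["B"]]))
  }
})

test_that("sample entropy obeys the zero-variance rule and affine invariance", {
  se <- sample_entropy(rep(3, 50))
  expect_identical(se$value, 0)
  expect_true(se$degenerate)

  withr::local_seed(13)
  x <- rnorm(300)
  base <- sample_entropy(x)$value
  for (a in c(0.5, -2, 10)) {
    expect_equal(sample_entropy(a * x + 1)$value, base, tolerance = 1e-12)
  }
  expect_gte(base, 0)
})

test_that("irregular series carry higher entropy than periodic ones", {
  hits <- 0
  for (s in 1:20) {
    withr::local_seed(100 + s)
    noise <- runif(3000)
    tone <- sin(2 * pi * 1 * seq(0.01, 30, by = 0.01))
    if (sample_entropy(noise)$value > sample_entropy(tone)$value) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("amplitude entropy reflects amplitude modulation", {
  t <- seq(0.01, 30, by = 0.01)
  tone <- sin(2 * pi * 2 * t)
  a_const <- analytic_signal(tone)
  ent <- imf_entropies(a_const)
  expect_lt(ent$se_amplitude$value, 0.05)

  hits <- 0
  for (s in 1:20) {
    withr::local_seed(200 + s)
    am <- (1 + 0.5 * rnorm(length(t))) * tone
    ent_am <- imf_entropies(analytic_signal(am))
    if (ent_am$se_amplitude$value > ent$se_amplitude$value) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("total complexity is the weighted entropy sum", {
  expect_equal(total_complexity(0.3, 0.5), 0.4)
  expect_equal(total_complexity(0.3, 0.5, weights = c(1, 0)), 0.3)
  expect_equal(total_complexity(0, 0), 0)
  expect_true(is.na(total_complexity(NA_real_, 0.5)))
  expect_error(total_complexity(0.3, 0.5, weights = c(0.6, 0.6)), "summing")
})

test_that("cmci averages the retained total complexities and records provenance", {
  t <- seq(0.01, 20, by = 0.01)
  x <- sin(2 * pi * 3 * t) + sin(2 * pi * 0.4 * t) + 0.1 * rnorm(2000)
  res <- cmci(x)
  kept <- res$modes[res$modes$retained & !is.na(res$modes$total_complexity), ]
  expect_equal(res$cmci, mean(kept$total_complexity), tolerance = 1e-12)
  expect_equal(res$n_retained, length(res$imf_set$retained_indices))
  expect_identical(cmci(x)$cmci, res$cmci)  # deterministic
})

test_that("cmci is invariant under rescaling of the input", {
  withr::local_seed(31)
  for (i in 1:4) {
    t <- seq(0.01, 20, by = 0.01)
    x <- sin(2 * pi * runif(1, 1, 4) * t) + 0.3 * rnorm(2000)
    base <- cmci(x)$cmci
    for (a in c(0.5, 2, 10)) {
      expect_lt(abs(cmci(a * x)$cmci - base), 1e-6)
    }
  }
})

test_that("broadband noise raises the cmci of a structured signal", {
  t <- seq(0.01, 30, by = 0.01)
  clean <- sin(2 * pi * 1.5 * t) + sin(2 * pi * 0.3 * t)
  hits <- 0
  for (s in 1:20) {
    withr::local_seed(300 + s)
    noisy <- clean + rnorm(length(t), sd = sqrt(mean(clean^2)))  # SNR 0 dB
    if (cmci(noisy)$cmci > cmci(clean)$cmci) hits <- hits + 1
  }
  expect_gte(hits, 19)
})
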