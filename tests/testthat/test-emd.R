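brute_force_extrema <- function(x) {
  # neighborhood scan with plateau handling: an index is part of a maximal
  # plateau; the plateau is an extremum if its neighbours are both lower
  # (higher); report the floored midpoint.
  r <- rle(x)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  maxima <- integer(); minima <- integer()
  for (q in seq_along(r$values)) {
    if (q == 1L || q == length(r$values)) next
    if (r$values[q] > r$values[q - 1] && r$values[q] > r$values[q + 1]) {
      maxima <- c(maxima, floor((starts[q] + ends[q]) / 2))
    }
    if (r$values[q] < r$values[q - 1] && r$values[q] < r$values[q + 1]) {
      minima <- c(minima, floor((starts[q] + ends[q]) / 2))
    }
  }
  list(maxima = as.integer(maxima), minima = as.integer(minima))
}

test_that("find_extrema handles peaks, monotone input and plateaus", {
  expect_equal(find_extrema(c(0, 1, 0)),
               list(maxima = 2L, minima = integer()))
  expect_equal(find_extrema(1:10), list(maxima = integer(), minima = integer()))
  expect_equal(find_extrema(c(0, 1, 1, 0))$maxima, 2L)      # floor midpoint
  expect_equal(find_extrema(c(0, 1, 1, 1, 0))$maxima, 3L)
  expect_equal(find_extrema(c(1, 0, 0, 1))$minima, 2L)

  withr::local_seed(21)
  for (i in 1:25) {
    x <- round(rnorm(60), sample(0:1, 1))  # rounding creates plateaus
    expect_identical(find_extrema(x), brute_force_extrema(x))
  }
})

test_that("envelopes interpolate knots exactly and track a tone's amplitude", {
  t <- seq(0, 30, by = 0.01)[-1]
  x <- sin(2 * pi * 1 * t)
  ex <- find_extrema(x)
  up <- cmcisway:::emd_envelope(x, ex$maxima)
  expect_equal(up[ex$maxima], x[ex$maxima], tolerance = 1e-10)
  inner <- 110:2890  # away from the first/last full period
  expect_true(all(abs(up[inner] - 1) < 0.02))

  flat <- c(2, 1, 2, 1, 2, 1, 2)
  exf <- find_extrema(flat)
  expect_equal(cmcisway:::emd_envelope(flat, exf$maxima), rep(2, 7))
  expect_error(cmcisway:::emd_envelope(flat, 3L),
               class = "cmcisway_insufficient_extrema")
})

test_that("sifting leaves a pure tone nearly unchanged and rejects constants", {
  t <- seq(0, 30, by = 0.01)[-1]
  x <- sin(2 * pi * 2 * t)
  s <- emd_sift(x)
  inner <- 150:2850
  expect_lt(max(abs(s$imf[inner] - x[inner])), 0.01)
  expect_error(emd_sift(rep(1, 100)), class = "cmcisway_no_imf")
  # IMF defining property on a noisy input
  withr::local_seed(9)
  h <- emd_sift(rnorm(1000))$imf
  ex <- find_extrema(h)
  n_ext <- length(ex$maxima) + length(ex$minima)
  zc <- cmcisway:::count_zero_crossings(h)
  expect_lte(abs(zc - n_ext), 1)
})

test_that("decomposition separates well-spaced tones and is complete", {
  t <- seq(0, 30, by = 0.01)[-1]
  tone_hi <- sin(2 * pi * 5 * t); tone_lo <- sin(2 * pi * 0.5 * t)
  s <- emd(tone_hi + tone_lo)
  expect_gte(length(s$imfs), 2)
  inner <- 300:2700
  expect_gt(cor(s$imfs[[1]][inner], tone_hi[inner]), 0.95)
  expect_gt(cor(s$imfs[[2]][inner], tone_lo[inner]), 0.95)

  # monotone input: no IMFs, residual is the input
  ramp <- seq(0, 1, length.out = 100)
  sr <- emd(ramp)
  expect_length(sr$imfs, 0)
  expect_identical(sr$residual, ramp)

  withr::local_seed(33)
  for (i in 1:20) {
    x <- rnorm(400)
    s <- emd(x)
    recon <- Reduce(`+`, s$imfs, accumulate = FALSE) + s$residual
    expect_lt(max(abs(x - recon)) / max(abs(x)), 1e-9)
  }
})

test_that("decomposition is scale- and translation-equivariant", {
  withr::local_seed(44)
  x <- rnorm(500)
  s0 <- emd(x)
  for (a in c(0.5, 2, 10)) {
    sa <- emd(a * x)
    expect_length(sa$imfs, length(s0$imfs))
    for (i in seq_along(s0$imfs)) {
      expect_lt(max(abs(sa$imfs[[i]] - a * s0$imfs[[i]])) /
                  max(abs(s0$imfs[[i]])), 1e-8)
    }
  }
  sc <- emd(x + 7)
  for (i in seq_along(s0$imfs)) {
    expect_lt(max(abs(sc$imfs[[i]] - s0$imfs[[i]])) /
                max(abs(s0$imfs[[i]])), 1e-8)
  }
})

test_that("IMFs are ordered from fast to slow oscillation", {
  withr::local_seed(55)
  x <- rnorm(3000)
  s <- emd(x)
  zc_rate <- vapply(s$imfs, cmcisway:::count_zero_crossings, integer(1))
  expect_true(all(diff(zc_rate) <= 0))
})

test_that("energy truncation retains exactly the modes above threshold", {
  withr::local_seed(66)
  s <- emd(rnorm(800))
  expect_identical(truncate_imfs(s, 0)$retained_indices, seq_along(s$imfs))

  # synthetic two-mode set with energies 99 and 1
  s2 <- structure(list(source = numeric(10),
                       imfs = list(rep(sqrt(9.9), 10), rep(sqrt(0.1), 10)),
                       residual = numeric(10), sd_threshold = 0.2,
                       retained_indices = 1:2), class = "imf_set")
  expect_identical(truncate_imfs(s2, 0.05)$retained_indices, 1L)

  st <- truncate_imfs(s, 0.01)
  energy <- vapply(s$imfs, function(v) sum(v^2), numeric(1))
  frac <- energy / sum(energy)
  expect_true(all(frac[st$retained_indices] >= 0.01))
  expect_true(all(frac[-st$retained_indices] < 0.01))

  # all below threshold: fallback retains the single strongest mode,
  # or signals when the fallback is disabled
  s3 <- structure(list(source = numeric(10),
                       imfs = list(rep(1, 10), rep(1.1, 10), rep(0.9, 10)),
                       residual = numeric(10), sd_threshold = 0.2,
                       retained_indices = 1:3), class = "imf_set")
  expect_identical(truncate_imfs(s3, 0.99)$retained_indices, 2L)
  expect_error(truncate_imfs(s3, 0.99, fallback_highest = FALSE),
               class = "cmcisway_empty_retention")
})
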