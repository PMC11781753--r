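#' Discrete analytic signal of an IMF
#'
#' Computes the analytic signal by the one-sided-spectrum method: the FFT of
#' the input has its negative frequencies zeroed and positive frequencies
#' doubled (DC and, for even lengths, the Nyquist bin are kept as-is), then
#' is inverted. The modulus is the instantaneous amplitude, the argument the
#' instantaneous phase wrapped to `(-pi, pi]`; `amplitude * cos(phase)`
#' reconstructs the input.
#'
#' @param imf Numeric series, length >= 8. Intended for a zero-mean
#'   oscillatory component (an IMF).
#' @return A list of class `analytic_imf` with `amplitude` and `phase`.
#' @export
#' @examples
#' t <- seq(0.01, 30, by = 0.01)
#' a <- analytic_signal(cos(2 * pi * 2 * t))
#' range(a$amplitude[500:2500])
analytic_signal <- function(imf) {
  imf <- as.double(imf)
  n <- length(imf)
  if (n < 8L) abort("`imf` must have length >= 8.")
  if (all(imf == 0)) {
    return(structure(list(amplitude = numeric(n), phase = numeric(n)),
                     class = "analytic_imf"))
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(imf) * h, inverse = TRUE) / n
  phase <- Arg(z)
  # Arg returns [-pi, pi]; map the -pi branch onto +pi so phase is (-pi, pi].
  phase[phase == -pi] <- pi
  structure(list(amplitude = Mod(z), phase = phase), class = "analytic_imf")
}

#' Instantaneous frequency of an analytic signal
#'
#' Finite difference of the unwrapped phase, in Hz. One sample shorter than
#' the input.
#'
#' @param a An `analytic_imf`.
#' @param sample_rate Sampling rate in Hz.
#' @return Numeric vector of length `length(a$phase) - 1`.
#' @export
instantaneous_frequency <- function(a, sample_rate) {
  stopifnot(inherits(a, "analytic_imf"))
  dphi <- diff(a$phase)
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))  # unwrap increments
  dphi * sample_rate / (2 * pi)
}

#' Sample entropy
#'
#' `-log(A / B)` where `B` counts pairs of distinct length-`m` templates
#' within Chebyshev distance `r = r_factor * sd_pop(x)` of one another and
#' `A` counts the same pairs still matching when extended to length `m + 1`
#' (Richman-Moorman convention: self-matches excluded, templates taken at
#' `1..N-m` so every template has an extension, `sd_pop` the population
#' standard deviation of the series itself).
#'
#' A constant series (zero variance) is maximally regular and returns entropy
#' 0 with `degenerate = TRUE`. If no template pair matches at either length
#' the entropy is undefined (`defined = FALSE`, value `NA`).
#'
#' @param x Numeric series, length > `m + 1`.
#' @param m Embedding dimension (template length), default 2.
#' @param r_factor Tolerance as a fraction of the series' population standard
#'   deviation, default 0.2.
#' @return A list of class `sampen` with `value`, `A`, `B`, `r`, `m`,
#'   `defined`, `degenerate`.
#' @export
#' @examples
#' sample_entropy(rep(c(1, 2), 5))$value
sample_entropy <- function(x, m = 2L, r_factor = 0.2) {
  x <- as.double(x)
  n <- length(x)
  if (n <= m + 1L) abort("`x` must be longer than m + 1.")
  s <- pop_sd(x)
  # a spread at the rounding-noise scale of the values is not signal:
  # treat it as constant rather than amplifying it through r = r_factor * s
  if (s <= 1e-12 * mean(abs(x))) s <- 0
  if (s == 0) {
    # zero-variance rule: all templates match at every length for any r > 0
    nt <- n - m
    B <- nt * (nt - 1) / 2
    return(structure(list(value = 0, A = B, B = B, r = 0, m = as.integer(m),
                          defined = TRUE, degenerate = TRUE),
                     class = "sampen"))
  }
  r <- r_factor * s
  cnt <- .sampen_counts(x, as.integer(m), r)
  A <- cnt[1L]; B <- cnt[2L]
  defined <- A > 0 && B > 0
  structure(list(value = if (defined) -log(A / B) else NA_real_,
                 A = A, B = B, r = r, m = as.integer(m),
                 defined = defined, degenerate = FALSE),
            class = "sampen")
}

#' Amplitude and phase entropies of one analytic IMF
#'
#' Sample entropy of the instantaneous amplitude and of the wrapped
#' instantaneous phase, each with tolerance `r` computed from that series'
#' own population standard deviation. The wrapped phase (not the unwrapped,
#' near-monotone ramp) is what carries cycle-to-cycle irregularity; the
#' instantaneous-frequency series can be substituted via
#' `phase_series = "ifreq"`.
#'
#' @param a An `analytic_imf`.
#' @inheritParams sample_entropy
#' @param phase_series `"wrapped"` (default) or `"ifreq"` (finite-difference
#'   instantaneous frequency; requires `sample_rate`).
#' @param sample_rate Sampling rate in Hz, only used for `"ifreq"`.
#' @return A list with `se_amplitude` and `se_phase` (each a `sampen`).
#' @export
imf_entropies <- function(a, m = 2L, r_factor = 0.2,
                          phase_series = c("wrapped", "ifreq"),
                          sample_rate = NULL) {
  stopifnot(inherits(a, "analytic_imf"))
  phase_series <- match.arg(phase_series)
  ph <- if (phase_series == "wrapped") a$phase else {
    if (is.null(sample_rate)) abort("`sample_rate` needed for phase_series = \"ifreq\".")
    instantaneous_frequency(a, sample_rate)
  }
  list(se_amplitude = sample_entropy(a$amplitude, m, r_factor),
       se_phase = sample_entropy(ph, m, r_factor))
}

#' Weighted total complexity of one IMF
#'
#' `TC = w_a * SE_amplitude + w_phi * SE_phase` with non-negative weights
#' summing to 1; equal weights by default, so neither amplitude nor phase
#' irregularity is prioritized. Undefined entropies propagate to `NA`.
#'
#' @param se_amplitude,se_phase Entropy values (numbers or `sampen` objects).
#' @param weights Length-2 non-negative weights summing to 1.
#' @return A single numeric value (possibly `NA`).
#' @export
total_complexity <- function(se_amplitude, se_phase, weights = c(0.5, 0.5)) {
  if (length(weights) != 2L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-12) {
    abort("`weights` must be two non-negative values summing to 1.")
  }
  va <- if (inherits(se_amplitude, "sampen")) se_amplitude$value else se_amplitude
  vp <- if (inherits(se_phase, "sampen")) se_phase$value else se_phase
  if (is.na(va) || is.na(vp)) return(NA_real_)
  weights[1L] * va + weights[2L] * vp
}

#' Composite Multiscale Complexity Index
#'
#' Runs the full complexity pipeline on one scalar series: empirical mode
#' decomposition ([emd()]), energy-based mode truncation ([truncate_imfs()]),
#' analytic-signal amplitude/phase extraction per retained IMF
#' ([analytic_signal()]), sample entropy of each amplitude and wrapped-phase
#' series ([sample_entropy()]), the equally weighted per-IMF total
#' complexity, and finally the mean total complexity over the retained IMFs
#' — the CMCI. Higher values indicate a more irregular, less predictable
#' signal across its intrinsic oscillatory scales.
#'
#' Because the entropy tolerance tracks each series' own standard deviation
#' and the decomposition is scale-equivariant, the CMCI is invariant under
#' rescaling of the input.
#'
#' @param x Numeric series, length >= 64.
#' @inheritParams emd
#' @inheritParams truncate_imfs
#' @inheritParams sample_entropy
#' @param weights Amplitude/phase weight pair, default `c(0.5, 0.5)`.
#' @param phase_series Passed to [imf_entropies()].
#' @return A `cmci_result`: list with `cmci`, per-IMF tibble `modes`
#'   (`imf`, `retained`, `se_amplitude`, `se_phase`, `total_complexity`,
#'   `defined`), the configuration, and `n_retained`. `cmci` is `NA` with a
#'   diagnostic message when no retained IMF has a defined total complexity.
#' @export
#' @examples
#' t <- seq(0.01, 10, by = 0.01)
#' r <- cmci(sin(2 * pi * 1.3 * t) + 0.2 * sin(2 * pi * 5 * t))
#' r$cmci
cmci <- function(x, sd_threshold = 0.2, max_iter = 100L, max_imfs = 10L,
                 min_energy_fraction = 0.01, m = 2L, r_factor = 0.2,
                 weights = c(0.5, 0.5),
                 phase_series = c("wrapped", "ifreq")) {
  phase_series <- match.arg(phase_series)
  x <- as.double(x)
  if (length(x) < 64L) abort("`x` must have length >= 64.")
  s <- emd(x, sd_threshold = sd_threshold, max_iter = max_iter,
           max_imfs = max_imfs)
  s <- truncate_imfs(s, min_energy_fraction = min_energy_fraction)
  cfg <- list(sd_threshold = sd_threshold, max_iter = max_iter,
              max_imfs = max_imfs, min_energy_fraction = min_energy_fraction,
              m = as.integer(m), r_factor = r_factor, weights = weights,
              phase_series = phase_series)
  if (!length(s$imfs)) {
    return(structure(list(cmci = NA_real_, modes = empty_modes_tbl(),
                          imf_set = s, config = cfg, n_retained = 0L,
                          diagnostic = "no IMFs extracted (degenerate input)"),
                     class = "cmci_result"))
  }
  rows <- purrr::map(seq_along(s$imfs), function(i) {
    if (!i %in% s$retained_indices) {
      return(tibble::tibble(imf = i, retained = FALSE,
                            se_amplitude = NA_real_, se_phase = NA_real_,
                            total_complexity = NA_real_, defined = NA))
    }
    a <- analytic_signal(s$imfs[[i]])
    ent <- imf_entropies(a, m = m, r_factor = r_factor,
                         phase_series = phase_series)
    tc <- total_complexity(ent$se_amplitude, ent$se_phase, weights)
    tibble::tibble(imf = i, retained = TRUE,
                   se_amplitude = ent$se_amplitude$value,
                   se_phase = ent$se_phase$value,
                   total_complexity = tc, defined = !is.na(tc))
  })
  modes <- dplyr::bind_rows(rows)
  tcs <- modes$total_complexity[modes$retained & !is.na(modes$total_complexity)]
  out <- list(cmci = if (length(tcs)) mean(tcs) else NA_real_,
              modes = modes, imf_set = s, config = cfg,
              n_retained = length(s$retained_indices),
              diagnostic = if (length(tcs)) NULL else
                "all retained IMFs have undefined sample entropy")
  structure(out, class = "cmci_result")
}

empty_modes_tbl <- function() {
  tibble::tibble(imf = integer(), retained = logical(),
                 se_amplitude = double(), se_phase = double(),
                 total_complexity = double(), defined = logical())
}

#' @export
print.cmci_result <- function(x, ...) {
  cat(sprintf("<cmci_result> CMCI = %s over %d retained IMF(s) (m = %d, r = %.2f sd)\n",
              format(x$cmci, digits = 4), x$n_retained,
              x$config$m, x$config$r_factor))
  if (!is.null(x$diagnostic)) cat(" note:", x$diagnostic, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cmci_result <- function(x, ...) x$modes

#' @exportS3Method generics::glance
glance.cmci_result <- function(x, ...) {
  tibble::tibble(cmci = x$cmci, n_imfs = length(x$imf_set$imfs),
                 n_retained = x$n_retained, m = x$config$m,
                 r_factor = x$config$r_factor)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cmci_result <- function(object, ...) {
  d <- object$modes[object$modes$retained, ]
  d_long <- tidyr::pivot_longer(
    d, c("se_amplitude", "se_phase", "total_complexity"),
    names_to = "measure", values_to = "entropy")
  ggplot2::ggplot(d_long,
                  ggplot2::aes(x = factor(.data$imf), y = .data$entropy,
                               fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$cmci, linetype = 2) +
    ggplot2::labs(x = "IMF", y = "sample entropy",
                  subtitle = sprintf("CMCI = %.3f (dashed)", object$cmci))
}
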