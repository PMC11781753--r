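#' Simulation configuration for synthetic CoP cohorts
#'
#' Defines the generative conditions for synthetic stabilograms: 30-second,
#' 100 Hz two-channel center-of-pressure trajectories for two groups
#' ("elite", "expert") under four standing conditions (T1 firm/eyes open,
#' T2 firm/eyes closed, T3 foam/eyes open, T4 foam/eyes closed). Each
#' channel is a sum of a few slow sway oscillators (0.1-1.5 Hz) plus
#' `1/f^beta` (pink, beta = 1 by default) Gaussian noise, scaled so RMS sway
#' sits in a plausible posturographic range. The group contrast is injected
#' into signal *irregularity*, not sway magnitude: "expert" signals carry
#' extra broadband noise and oscillator frequency jitter in proportion to
#' `group_complexity_gap`, while condition difficulty scales sway amplitude
#' via the per-condition multipliers.
#'
#' @param n_per_group Subjects per group (each measured under all four
#'   conditions). Default 13 — with `n_expert` defaulting to one less, the
#'   13 + 12 design.
#' @param n_expert Subjects in the expert group; default `n_per_group - 1`.
#' @param duration Trial length in seconds, default 30.
#' @param sample_rate Sampling rate in Hz, default 100.
#' @param condition_amplitude Named per-condition sway-amplitude multipliers;
#'   defaults give the difficulty ordering T4 > T2 > T3 > T1.
#' @param condition_noise Named per-condition noise multipliers.
#' @param group_complexity_gap In `[0, 1]`; 0 makes the two groups'
#'   generative distributions identical.
#' @param noise_exponent Spectral slope beta of the `1/f^beta` noise.
#' @param base_rms Target RMS sway of the baseline condition, inches.
#' @param base_noise Broadband-noise amplitude relative to oscillator RMS.
#' @param seed Base seed; all per-recording randomness is derived from it by
#'   counter, so cohorts are reproducible and extensible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 13L, n_expert = n_per_group - 1L,
                       duration = 30, sample_rate = 100,
                       condition_amplitude = c(T1 = 1, T2 = 1.6,
                                               T3 = 1.3, T4 = 2.0),
                       condition_noise = c(T1 = 1, T2 = 1.2,
                                           T3 = 1.1, T4 = 1.3),
                       group_complexity_gap = 0.5,
                       noise_exponent = 1,
                       base_rms = 0.25,
                       base_noise = 0.05,
                       seed = 1L) {
  n <- duration * sample_rate
  if (abs(n - round(n)) > 1e-9) {
    abort("`duration * sample_rate` must be an integer number of samples.")
  }
  stopifnot(all(condition_amplitude > 0), all(condition_noise > 0),
            group_complexity_gap >= 0, group_complexity_gap <= 1,
            n_per_group >= 1, n_expert >= 1)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_expert = as.integer(n_expert),
                 duration = duration, sample_rate = sample_rate,
                 condition_amplitude = condition_amplitude,
                 condition_noise = condition_noise,
                 group_complexity_gap = group_complexity_gap,
                 noise_exponent = noise_exponent,
                 base_rms = base_rms, base_noise = base_noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# 1/f^beta Gaussian noise via spectral shaping of white noise, normalized
# to unit RMS. beta = 0 is white, 1 pink, 2 brown.
pink_noise <- function(n, beta = 1) {
  w <- rnorm(n)
  sp <- fft(w)
  j <- 0:(n - 1)
  freq <- pmin(j, n - j)               # two-sided frequency index
  freq[1] <- 1                         # DC kept finite (zeroed below)
  shaped <- sp / (freq^(beta / 2))
  shaped[1] <- 0                       # zero-mean by construction
  x <- Re(fft(shaped, inverse = TRUE) / n)
  x / sqrt(mean(x^2))
}

# One sway channel: 2-4 slow oscillators with 1/f-flavoured amplitudes,
# plus broadband (pink + white) noise. `irregularity` in [0, 1] adds
# broadband noise power and frequency jitter; at 0 the channel is as clean
# as the baseline model.
sway_channel <- function(n, sample_rate, amplitude_mult, noise_mult,
                         irregularity, noise_exponent, base_rms, base_noise) {
  t <- (seq_len(n) - 1) / sample_rate
  k <- sample(2:4, 1)
  f0 <- runif(k, 0.1, 1.5)
  # frequency jitter: slow random-walk modulation of each oscillator
  jitter_sd <- 0.15 * irregularity
  osc <- rowSums(vapply(seq_len(k), function(i) {
    fj <- f0[i] * (1 + jitter_sd * cumsum(rnorm(n)) / sqrt(n))
    phase <- 2 * pi * cumsum(fj) / sample_rate + runif(1, 0, 2 * pi)
    (1 / sqrt(f0[i])) * sin(phase)
  }, numeric(n)))
  osc <- osc / sqrt(mean(osc^2))
  noise_level <- base_noise * (1 + 6 * irregularity) * noise_mult
  nz <- pink_noise(n, noise_exponent) + 0.6 * irregularity * rnorm(n)
  x <- osc + noise_level * nz / sqrt(mean(nz^2))
  x <- x - mean(x)
  x * base_rms * amplitude_mult / sqrt(mean(x^2))
}

#' Generate one synthetic CoP recording
#'
#' @param group `"elite"` or `"expert"`.
#' @param condition One of `"T1"`-`"T4"`.
#' @param cfg A [sim_config()].
#' @param subject_id Identifier stored in the recording.
#' @param height Subject height in inches; drawn in 68-70 if `NULL`.
#' @param seed Seed for this recording; derived from `cfg$seed` and a hash
#'   of subject/condition if `NULL`.
#' @return A `cop_recording`.
#' @export
generate_recording <- function(group, condition, cfg,
                               subject_id = "S1", height = NULL,
                               seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(seed)) {
    counter <- sum(utf8ToInt(paste(subject_id, condition))) * 131L
    seed <- derive_seed(cfg$seed, counter)
  }
  n <- as.integer(round(cfg$duration * cfg$sample_rate))
  irregularity <- if (group == "expert") cfg$group_complexity_gap else 0
  amp <- cfg$condition_amplitude[[condition]]
  nmul <- cfg$condition_noise[[condition]]
  withr::local_seed(seed)
  if (is.null(height)) height <- runif(1, 68, 70)
  x <- sway_channel(n, cfg$sample_rate, amp, nmul, irregularity,
                    cfg$noise_exponent, cfg$base_rms, cfg$base_noise)
  y <- sway_channel(n, cfg$sample_rate, amp, nmul, irregularity,
                    cfg$noise_exponent, cfg$base_rms, cfg$base_noise)
  t <- (seq_len(n) - 1) / cfg$sample_rate
  cop_recording(t, x, y, subject_id = subject_id, group = group,
                condition = condition, height = height,
                sample_rate = cfg$sample_rate)
}

#' Generate a full synthetic cohort
#'
#' `n_per_group` elite and `n_expert` expert subjects, each recorded under
#' all four conditions. Optionally writes one CSV per recording plus a
#' manifest compatible with [read_cop_manifest()].
#'
#' @param cfg A [sim_config()].
#' @param dir If non-`NULL`, a directory to write `*.csv` recordings and
#'   `manifest.csv` into (created if needed).
#' @return A list with `recordings` (list of `cop_recording`) and
#'   `manifest` (tibble).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_per_group = 2, n_expert = 2,
#'                                      duration = 2, seed = 7))
#' nrow(cohort$manifest)
generate_cohort <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(cfg$n_per_group + cfg$n_expert)),
    group = rep(c("elite", "expert"), c(cfg$n_per_group, cfg$n_expert)))
  plan <- tidyr::expand_grid(subjects, condition = paste0("T", 1:4))
  plan$counter <- seq_len(nrow(plan))
  # one height per subject, drawn from a subject-level substream
  heights <- vapply(seq_len(nrow(subjects)), function(i) {
    withr::local_seed(derive_seed(cfg$seed, 900000L + i))
    runif(1, 68, 70)
  }, numeric(1))
  plan$height <- heights[match(plan$subject_id, subjects$subject_id)]
  recordings <- purrr::pmap(
    plan[c("subject_id", "group", "condition", "counter", "height")],
    function(subject_id, group, condition, counter, height) {
      generate_recording(group, condition, cfg, subject_id = subject_id,
                         height = height,
                         seed = derive_seed(cfg$seed, counter))
    })
  manifest <- tibble::tibble(
    file = sprintf("%s_%s.csv", plan$subject_id, plan$condition),
    subject_id = plan$subject_id, group = plan$group,
    condition = plan$condition, height = plan$height)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    purrr::walk2(recordings, manifest$file, function(rec, f) {
      write_cop_recording(rec, file.path(dir, f))
    })
    readr::write_csv(manifest, file.path(dir, "manifest.csv"),
                     progress = FALSE)
  }
  list(recordings = recordings, manifest = manifest)
}
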