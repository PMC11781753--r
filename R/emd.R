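#' Locate strict local extrema
#'
#' Finds interior local maxima and minima of a series. A plateau of equal
#' values bounded by strictly lower (higher) neighbours contributes a single
#' extremum at its midpoint index, floored on ties. Endpoints are never
#' extrema.
#'
#' @param x Numeric vector, length >= 3.
#' @return A list with integer vectors `maxima` and `minima`.
#' @export
#' @examples
#' find_extrema(c(0, 1, 0))
#' find_extrema(c(0, 1, 1, 0))  # plateau midpoint, floored
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) abort("`x` must have length >= 3.")
  # Compress runs of equal values; classify each interior run against its
  # neighbouring runs, then map back to the floored midpoint sample index.
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(list(maxima = integer(), minima = integer()))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  mid <- as.integer(floor((starts + ends) / 2))
  i <- 2:(k - 1L)
  is_max <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  is_min <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  list(maxima = mid[i][is_max], minima = mid[i][is_min])
}

# IMF defining property: zero-crossing and extrema counts differ by <= 1.
is_imf <- function(h) {
  ex <- find_extrema(h)
  abs(count_zero_crossings(h) - (length(ex$maxima) + length(ex$minima))) <= 1L
}

# Cubic-spline envelope through extrema with mirror boundary extension:
# the two extrema nearest each end are reflected about the end sample so
# the spline is anchored outside the observed range. Needs >= 2 extrema.
emd_envelope <- function(x, idx) {
  n <- length(x)
  if (length(idx) < 2L) {
    abort("envelope needs at least 2 extrema.", class = "cmcisway_insufficient_extrema")
  }
  idx <- sort(idx)
  left <- 2 - idx[c(2L, 1L)]
  right <- 2 * n - idx[c(length(idx), length(idx) - 1L)]
  kx <- c(left, idx, right)
  ky <- x[c(idx[c(2L, 1L)], idx, idx[c(length(idx), length(idx) - 1L)])]
  keep <- !duplicated(kx)
  f <- splinefun(kx[keep], ky[keep], method = "natural")
  f(seq_len(n))
}

#' One sifting pass of empirical mode decomposition
#'
#' Repeatedly subtracts the mean of the upper and lower cubic-spline
#' envelopes from the working series. Sifting stops once the normalized
#' squared change between successive iterates,
#' `sum((h_prev - h)^2) / sum(h_prev^2)` with both sides mean-centered (so
#' a constant offset cannot affect the decision), falls below
#' `sd_threshold` *and* the iterate satisfies the IMF defining property
#' (zero-crossing and extrema counts differing by at most one), or when
#' `max_iter` passes are exhausted.
#'
#' @param x Numeric series.
#' @param sd_threshold Positive stop criterion on the successive-sifting
#'   standard-deviation statistic. Default 0.2 (the classic choice).
#' @param max_iter Maximum sifting passes, default 100.
#' @return A list with `imf` (the sifted series) and `converged` (logical),
#'   or signals a condition of class `cmcisway_no_imf` when the series has
#'   too few extrema to sift (fewer than 2 maxima or 2 minima).
#' @export
emd_sift <- function(x, sd_threshold = 0.2, max_iter = 100L) {
  if (sd_threshold <= 0) abort("`sd_threshold` must be positive.")
  if (max_iter < 1L) abort("`max_iter` must be >= 1.")
  h <- x
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ex <- find_extrema(h)
    if (length(ex$maxima) < 2L || length(ex$minima) < 2L) {
      if (iter == 1L) {
        abort("series has too few extrema to sift.", class = "cmcisway_no_imf")
      }
      break
    }
    upper <- emd_envelope(h, ex$maxima)
    lower <- emd_envelope(h, ex$minima)
    h_new <- h - (upper + lower) / 2
    # mean-centered numerator and denominator: a constant offset in the
    # working series must not perturb the stop decision (value-translation
    # equivariance); for the zero-mean iterates this matches the plain
    # sum-of-squares ratio
    d <- h - h_new
    denom <- sum((h - mean(h))^2)
    sd_stat <- if (denom > 0) sum((d - mean(d))^2) / denom else 0
    h <- h_new
    if (sd_stat < sd_threshold && is_imf(h)) {
      converged <- TRUE
      break
    }
  }
  list(imf = h, converged = converged)
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (IMFs) by iterative
#' sifting: each IMF is extracted with [emd_sift()] and subtracted from the
#' running residual until the residual has too few extrema to sift (it is
#' monotone or near-monotone) or `max_imfs` is reached. The IMFs plus the
#' residual reconstruct the input exactly (bookkeeping of subtractions), and
#' are ordered from highest to lowest characteristic frequency.
#'
#' @inheritParams emd_sift
#' @param max_imfs Maximum number of IMFs to extract, default 10.
#' @return An `imf_set`: list with `source`, `imfs` (list of numeric
#'   vectors, possibly empty), `residual`, `sd_threshold`, and
#'   `retained_indices` (all indices until [truncate_imfs()] is applied).
#' @export
#' @examples
#' t <- seq(0, 30, by = 0.01)[-1]
#' x <- sin(2 * pi * 5 * t) + sin(2 * pi * 0.5 * t)
#' s <- emd(x)
#' length(s$imfs)
emd <- function(x, sd_threshold = 0.2, max_iter = 100L, max_imfs = 10L) {
  x <- as.double(x)
  if (length(x) < 16L) abort("`x` must have length >= 16.")
  imfs <- list()
  residual <- x
  for (i in seq_len(max_imfs)) {
    res <- tryCatch(emd_sift(residual, sd_threshold, max_iter),
                    cmcisway_no_imf = function(e) NULL)
    if (is.null(res)) break
    imfs[[length(imfs) + 1L]] <- res$imf
    residual <- residual - res$imf
  }
  structure(list(source = x, imfs = imfs, residual = residual,
                 sd_threshold = sd_threshold,
                 retained_indices = seq_along(imfs)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs (+residual) of a length-%d series; retained: %s\n",
              length(x$imfs), length(x$source),
              if (length(x$retained_indices)) paste(x$retained_indices, collapse = ", ") else "none"))
  invisible(x)
}

#' Discard low-energy modes
#'
#' Keeps the IMFs whose energy `sum(imf^2)` is at least `min_energy_fraction`
#' of the total IMF energy, updating `retained_indices`. The IMFs themselves,
#' the source and the residual are unchanged, so the full-set reconstruction
#' identity still holds; only the retained subset (used by [cmci()]) no
#' longer sums to the source.
#'
#' @param s An `imf_set`.
#' @param min_energy_fraction Fraction in `[0, 1)`; default 0.01.
#' @param fallback_highest If all modes fall below the threshold, retain the
#'   single highest-energy IMF instead of failing. Default `TRUE`.
#' @return The `imf_set` with updated `retained_indices`.
#' @export
truncate_imfs <- function(s, min_energy_fraction = 0.01,
                          fallback_highest = TRUE) {
  stopifnot(inherits(s, "imf_set"))
  if (min_energy_fraction < 0 || min_energy_fraction >= 1) {
    abort("`min_energy_fraction` must be in [0, 1).")
  }
  if (!length(s$imfs)) {
    s$retained_indices <- integer()
    return(s)
  }
  energy <- vapply(s$imfs, function(v) sum(v^2), numeric(1))
  total <- sum(energy)
  keep <- if (total > 0) which(energy >= min_energy_fraction * total) else integer()
  if (!length(keep)) {
    if (!fallback_highest) {
      abort("all modes fall below the energy threshold.",
            class = "cmcisway_empty_retention")
    }
    keep <- which.max(energy)
  }
  s$retained_indices <- as.integer(keep)
  s
}

#' @exportS3Method generics::tidy
tidy.imf_set <- function(x, ...) {
  n <- length(x$source)
  comp <- c(lapply(seq_along(x$imfs), function(i) {
    tibble::tibble(component = sprintf("IMF%d", i), index = seq_len(n),
                   value = x$imfs[[i]], retained = i %in% x$retained_indices)
  }), list(tibble::tibble(component = "residual", index = seq_len(n),
                          value = x$residual, retained = NA)))
  dplyr::bind_rows(comp)
}

#' @exportS3Method ggplot2::autoplot
autoplot.imf_set <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = unique(d$component))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "sample", y = NULL)
}
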