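#' Center-of-pressure recordings
#'
#' A `cop_recording` is a tibble with columns `t` (seconds), `cop_x`
#' (medial-lateral displacement, inches) and `cop_y` (anterior-posterior
#' displacement, inches), carrying subject metadata as attributes:
#' `subject_id`, `group` (`"elite"` or `"expert"`), `condition`
#' (`"T1"`–`"T4"`: firm/foam surface crossed with eyes open/closed),
#' `height` (inches) and `sample_rate` (Hz). The coordinate origin `(0, 0)`
#' is the subject's center of balance.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing and
#'   uniformly spaced.
#' @param cop_x,cop_y Numeric displacement series in inches (medial-lateral
#'   and anterior-posterior respectively), same length as `t`.
#' @param subject_id Subject identifier.
#' @param group Group label, `"elite"` or `"expert"`.
#' @param condition Standing condition, one of `"T1"`, `"T2"`, `"T3"`, `"T4"`.
#' @param height Subject height in inches (used by [tilt_angle()]).
#' @param sample_rate Sampling rate in Hz. If `NULL`, inferred from the
#'   median timestep. If declared and it disagrees with the inferred rate by
#'   more than 0.1%, a warning is raised and the declared rate wins.
#' @param center If `TRUE`, subtract the per-trial mean from each channel so
#'   the trajectory is centered on its own mean. Default `FALSE` (raw values).
#'
#' @return A `cop_recording` tibble.
#' @export
#' @examples
#' t <- seq(0, 0.02, by = 0.01)
#' rec <- cop_recording(t, c(0, 3, 0), c(0, 4, 0),
#'                      subject_id = "S1", group = "elite",
#'                      condition = "T1", height = 68)
#' cop_len(rec)
cop_recording <- function(t, cop_x, cop_y, subject_id = NA_character_,
                          group = NA_character_, condition = NA_character_,
                          height = NA_real_, sample_rate = NULL,
                          center = FALSE) {
  t <- as.double(t); cop_x <- as.double(cop_x); cop_y <- as.double(cop_y)
  n <- length(t)
  if (n < 2L || length(cop_x) != n || length(cop_y) != n) {
    abort("`t`, `cop_x` and `cop_y` must have identical length >= 2.")
  }
  bad <- which(!is.finite(t) | !is.finite(cop_x) | !is.finite(cop_y))
  if (length(bad)) {
    abort(sprintf("non-finite sample at row %d.", bad[1L]))
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    abort(sprintf("timestamps must be strictly increasing (violated at row %d).",
                  which(dt <= 0)[1L] + 1L))
  }
  if (max(dt) - min(dt) > 1e-9) {
    abort("timestamps must be uniformly spaced (to within 1e-9 s).")
  }
  inferred <- 1 / stats::median(dt)
  if (is.null(sample_rate) || is.na(sample_rate)) {
    sample_rate <- inferred
  } else {
    if (sample_rate <= 0) abort("`sample_rate` must be positive.")
    if (abs(sample_rate - inferred) / inferred > 1e-3) {
      warn(sprintf(
        "declared sample_rate %.6g Hz differs from rate inferred from timestamps (%.6g Hz); using declared.",
        sample_rate, inferred))
    }
  }
  if (!is.na(height) && height <= 0) abort("`height` must be positive.")
  if (!is.na(group) && !group %in% c("elite", "expert")) {
    abort("`group` must be \"elite\" or \"expert\".")
  }
  if (!is.na(condition) && !condition %in% paste0("T", 1:4)) {
    abort("`condition` must be one of T1, T2, T3, T4.")
  }
  if (isTRUE(center)) {
    cop_x <- cop_x - mean(cop_x)
    cop_y <- cop_y - mean(cop_y)
  }
  out <- tibble::tibble(t = t, cop_x = cop_x, cop_y = cop_y)
  structure(out,
            subject_id = as.character(subject_id),
            group = as.character(group),
            condition = as.character(condition),
            height = as.double(height),
            sample_rate = as.double(sample_rate),
            class = c("cop_recording", class(out)))
}

#' @export
print.cop_recording <- function(x, ...) {
  cat(sprintf("<cop_recording> subject %s, group %s, condition %s, %d samples @ %.6g Hz, height %.4g in\n",
              attr(x, "subject_id"), attr(x, "group"), attr(x, "condition"),
              nrow(x), attr(x, "sample_rate"), attr(x, "height")))
  NextMethod()
}

#' Read and write CoP recordings as delimited text
#'
#' `read_cop_recording()` reads one recording from a CSV or TSV file with a
#' header naming the time and displacement columns (any of `t`/`time`,
#' `x`/`cop_x`/`copx`, `y`/`cop_y`/`copy`, case-insensitive; the delimiter
#' is auto-detected among comma and tab). `write_cop_recording()` writes a
#' recording back at full precision so the round trip is exact.
#'
#' @param path File path.
#' @param subject_id,group,condition,height,sample_rate,center Metadata
#'   passed to [cop_recording()].
#' @return `read_cop_recording()` a `cop_recording`;
#'   `write_cop_recording()` the path, invisibly.
#' @export
read_cop_recording <- function(path, subject_id = NA_character_,
                               group = NA_character_,
                               condition = NA_character_,
                               height = NA_real_, sample_rate = NULL,
                               center = FALSE) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  # base parser: correctly rounded doubles, so write/read round trips are
  # bit-exact at full precision
  df <- utils::read.delim(path, sep = delim, header = TRUE,
                          colClasses = NA, check.names = FALSE)
  nm <- tolower(gsub("[^a-z]", "", tolower(names(df))))
  pick <- function(cands, what) {
    i <- which(nm %in% cands)
    if (!length(i)) abort(sprintf("no %s column found in '%s'.", what, path))
    i[1L]
  }
  it <- pick(c("t", "time"), "time")
  ix <- pick(c("x", "copx", "ml"), "x")
  iy <- pick(c("y", "copy", "ap"), "y")
  for (i in c(it, ix, iy)) {
    v <- suppressWarnings(as.double(df[[i]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      abort(sprintf("malformed or missing value in column '%s' at data row %d of '%s'.",
                    names(df)[i], bad[1L], path))
    }
    df[[i]] <- v
  }
  cop_recording(df[[it]], df[[ix]], df[[iy]],
                subject_id = subject_id, group = group, condition = condition,
                height = height, sample_rate = sample_rate, center = center)
}

#' @rdname read_cop_recording
#' @param rec A `cop_recording`.
#' @param derived If `TRUE`, append `cop_len` and `tilt_angle` columns.
#' @export
write_cop_recording <- function(rec, path, derived = FALSE) {
  stopifnot(inherits(rec, "cop_recording"))
  df <- tibble::tibble(t = rec$t, x = rec$cop_x, y = rec$cop_y)
  if (isTRUE(derived)) {
    df$cop_len <- cop_len(rec)
    df$tilt_angle <- tilt_angle(cop_len(rec), attr(rec, "height"))
  }
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(lapply(df, function(v) sprintf("%.17g", v)),
                              sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `file`, `subject_id`, `group`,
#' `condition`, `height`; file paths are resolved relative to the manifest's
#' directory. Returns the list of recordings it points to.
#'
#' @param path Manifest CSV path.
#' @param center Passed to [read_cop_recording()].
#' @return A list of `cop_recording` objects.
#' @export
read_cop_manifest <- function(path, center = FALSE) {
  man <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  need <- c("file", "subject_id", "group", "condition", "height")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) {
    abort(paste0("manifest is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dir <- dirname(path)
  purrr::pmap(man[need], function(file, subject_id, group, condition, height) {
    p <- if (file.exists(file)) file else file.path(dir, file)
    read_cop_recording(p, subject_id = subject_id, group = group,
                       condition = condition, height = height,
                       center = center)
  })
}

#' Stabilogram descriptors: CoP path radius and tilt angle
#'
#' `cop_len()` is the instantaneous radial distance of the CoP from the
#' balance origin, `sqrt(cop_x^2 + cop_y^2)` (inches). `tilt_angle()` maps
#' that radius to a body-inclination angle in degrees using 55% of the
#' subject's height as the approximate center-of-mass height:
#' `acos(cop_len / (0.55 * height))` with the argument clamped to `[-1, 1]`.
#' Under this form an upright stance (`cop_len = 0`) reads 90 degrees; the
#' complementary convention `asin(cop_len / (0.55 * height))`, which reads 0
#' degrees upright, is available with `mode = "asin"`.
#'
#' @param rec A `cop_recording`.
#' @param cop_len Numeric vector of CoP radii (inches).
#' @param height Subject height in inches; must be positive.
#' @param mode `"acos"` (default) or `"asin"`.
#' @return Numeric vector, same length as the input series.
#' @export
cop_len <- function(rec) {
  stopifnot(inherits(rec, "cop_recording"))
  sqrt(rec$cop_x^2 + rec$cop_y^2)
}

#' @rdname cop_len
#' @export
tilt_angle <- function(cop_len, height, mode = c("acos", "asin")) {
  mode <- match.arg(mode)
  if (!is.finite(height) || height <= 0) abort("`height` must be positive.")
  arg <- pmin(pmax(cop_len / (0.55 * height), -1), 1)
  rad <- if (mode == "acos") acos(arg) else asin(arg)
  rad * 180 / pi
}

#' Append derived descriptor columns to a recording
#'
#' Adds `cop_len` and `tilt_angle` columns computed with [cop_len()] and
#' [tilt_angle()].
#'
#' @inheritParams cop_len
#' @inheritParams tilt_angle
#' @return The recording with two extra columns (class preserved).
#' @export
add_cop_descriptors <- function(rec, mode = c("acos", "asin")) {
  mode <- match.arg(mode)
  len <- cop_len(rec)
  rec$cop_len <- len
  rec$tilt_angle <- tilt_angle(len, attr(rec, "height"), mode = mode)
  rec
}
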