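#' Construct a two-band RIP recording
#'
#' A \code{rip_recording} bundles the raw, uncalibrated band-displacement
#' samples from the rib-cage (RC) and abdomen (AB) inductance bands with the
#' sampling rate and optional subject metadata. It is the unit of analysis
#' for all downstream functions. Band units are arbitrary: every index the
#' package computes is a ratio or an angle, so no volume calibration is
#' required (or attempted).
#'
#' @param rc numeric vector of rib-cage band samples.
#' @param ab numeric vector of abdomen band samples; same length as
#'   \code{rc}.
#' @param fs sampling rate in Hz; must be positive and finite.
#' @param subject_id character scalar identifying the subject.
#' @param metadata optional named list of pass-through annotations, e.g.
#'   \code{weight_g}, \code{hr_bpm}, \code{spo2_pct}, \code{etco2_mmHg}.
#'   These are carried verbatim into cohort summaries, never computed.
#'
#' @return An object of class \code{rip_recording}: a list with elements
#'   \code{subject_id}, \code{fs}, \code{rc}, \code{ab}, \code{metadata}.
#'
#' @examples
#' t <- seq(0, 10, by = 0.1)
#' rec <- rip_recording(rc = sin(2 * pi * t), ab = sin(2 * pi * t),
#'                      fs = 10, subject_id = "demo")
#' rec
#' @export
rip_recording <- function(rc, ab, fs, subject_id = "unknown",
                          metadata = list()) {
  rc <- as.numeric(rc)
  ab <- as.numeric(ab)
  if (length(rc) != length(ab)) {
    wob_stop(sprintf("rc and ab must have equal length (got %d and %d)",
                     length(rc), length(ab)), "ripwob_invalid_recording")
  }
  if (length(rc) < 2L) {
    wob_stop("a recording needs at least 2 samples per channel",
             "ripwob_invalid_recording")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    wob_stop("fs must be a single finite positive number (Hz)",
             "ripwob_invalid_recording")
  }
  bad <- which(!is.finite(rc) | !is.finite(ab))
  if (length(bad)) {
    wob_stop(sprintf("non-finite sample(s) at index %s%s",
                     paste(utils::head(bad, 5L), collapse = ", "),
                     if (length(bad) > 5L) ", ..." else ""),
             "ripwob_invalid_recording")
  }
  if (!is.list(metadata)) {
    wob_stop("metadata must be a named list", "ripwob_invalid_recording")
  }
  structure(list(subject_id = as.character(subject_id)[1L],
                 fs = as.numeric(fs),
                 rc = rc, ab = ab,
                 metadata = metadata),
            class = "rip_recording")
}

#' @export
print.rip_recording <- function(x, ...) {
  cat(sprintf("<rip_recording> subject '%s': %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, length(x$rc), x$fs, length(x$rc) / x$fs))
  if (length(x$metadata)) {
    cat("  metadata:",
        paste(names(x$metadata), unlist(x$metadata), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.rip_recording <- function(x) length(x$rc)

# Validate a pair of window vectors for the per-window index formulas.
check_window <- function(rc_w, ab_w, min_n = 4L) {
  if (length(rc_w) != length(ab_w)) {
    wob_stop("window channels must have equal length",
             "ripwob_invalid_window")
  }
  if (length(rc_w) < min_n) {
    wob_stop(sprintf(
      "window of %d samples is below the minimum of %d (amplitude and phase estimates are meaningless)",
      length(rc_w), min_n), "ripwob_invalid_window")
  }
  if (anyNA(rc_w) || anyNA(ab_w) ||
      !all(is.finite(rc_w)) || !all(is.finite(ab_w))) {
    wob_stop("window contains non-finite samples", "ripwob_invalid_window")
  }
  invisible(TRUE)
}
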