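#' Averaged magnitude spectrum of a two-band recording
#'
#' Computes the FFT magnitude spectrum of each channel after mean removal
#' (rectangular window, zero-padded to the next power of two), averages the
#' two channels per bin, and restricts the result to a frequency band with
#' the DC bin excluded. This is the first stage of the respiratory-rate
#' estimator.
#'
#' @param recording a \code{\link{rip_recording}} of at least 2 seconds.
#' @param band_hz numeric length-2: the physiological search band
#'   \code{c(lo, hi)} in Hz. The default 0.3--3.0 Hz (18--180 breaths/min)
#'   excludes baseline drift below and motion harmonics above the plausible
#'   rodent breathing range.
#' @return An object of class \code{spectrum_estimate}: list with
#'   \code{freqs_hz} (ascending bin frequencies), \code{mag} (nonnegative
#'   channel-averaged magnitudes), \code{nfft}, \code{fs}, and
#'   \code{bin_width_hz}.
#' @seealso \code{\link{bpm_from_spectrum}}, \code{\link{breaths_per_minute}}
#' @export
magnitude_spectrum <- function(recording, band_hz = c(0.3, 3.0)) {
  stopifnot(inherits(recording, "rip_recording"))
  n <- length(recording$rc)
  fs <- recording$fs
  if (n < 2 * fs) {
    wob_stop("recording shorter than 2 seconds: spectrum is unreliable",
             "ripwob_insufficient_data")
  }
  lo <- band_hz[1L]; hi <- band_hz[2L]
  if (!(lo >= 0 && lo < hi && hi <= fs / 2)) {
    wob_stop("band_hz must satisfy 0 <= lo < hi <= fs/2",
             "ripwob_contract_violation")
  }
  nfft <- 2L^ceiling(log2(n))
  pad <- function(x) c(x - mean(x), numeric(nfft - n))
  mag_rc <- Mod(fft(pad(recording$rc)))
  mag_ab <- Mod(fft(pad(recording$ab)))
  k <- 0:(nfft %/% 2L)
  freqs <- k * fs / nfft
  keep <- which(freqs >= lo & freqs <= hi & k > 0L)
  if (!length(keep)) {
    wob_stop("no spectral bins inside the requested band",
             "ripwob_no_spectral_content")
  }
  structure(list(freqs_hz = freqs[keep],
                 mag = (mag_rc[keep] + mag_ab[keep]) / 2,
                 nfft = nfft, fs = fs,
                 bin_width_hz = fs / nfft),
            class = "spectrum_estimate")
}

#' Breaths per minute from a magnitude spectrum
#'
#' Implements the dominant-line weighted-average rule: take the maximum
#' in-band magnitude M, select every bin whose magnitude is within 20\% of
#' it (>= 0.8 M), and report 60 times the amplitude-weighted mean frequency
#' of the selected bins. For a single spectral line this reduces to 60
#' times the peak frequency; for a peak split across neighbouring bins the
#' weighting interpolates between them.
#'
#' A noise guard flags the estimate invalid when no line stands out: if the
#' maximum in-band magnitude is less than 3 times the median in-band
#' magnitude, the spectrum is considered line-free (e.g. pure noise) and
#' \code{valid} is \code{FALSE} rather than reporting a noise peak.
#'
#' @param spec a \code{spectrum_estimate} from
#'   \code{\link{magnitude_spectrum}}.
#' @return An object of class \code{bpm_estimate}: list with \code{bpm},
#'   \code{peak_hz}, \code{n_bins_used}, \code{bin_width_hz} and
#'   \code{valid}.
#' @export
bpm_from_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_estimate"))
  m <- spec$mag
  mx <- max(m)
  if (mx <= 0) {
    wob_stop("all in-band magnitudes are zero", "ripwob_no_spectral_content")
  }
  valid <- mx >= 3 * median(m)
  sel <- which(m >= 0.8 * mx)
  f_mean <- sum(spec$freqs_hz[sel] * m[sel]) / sum(m[sel])
  structure(list(bpm = 60 * f_mean,
                 peak_hz = spec$freqs_hz[which.max(m)],
                 n_bins_used = length(sel),
                 bin_width_hz = spec$bin_width_hz,
                 valid = valid),
            class = "bpm_estimate")
}

#' @export
print.bpm_estimate <- function(x, ...) {
  cat(sprintf("<bpm_estimate> %.2f breaths/min (peak %.3f Hz, %d bin%s, bin width %.4f Hz)%s\n",
              x$bpm, x$peak_hz, x$n_bins_used,
              if (x$n_bins_used == 1L) "" else "s", x$bin_width_hz,
              if (x$valid) "" else " [INVALID: no dominant line]"))
  invisible(x)
}

#' Respiratory rate of a recording, in breaths per minute
#'
#' Convenience pipeline: \code{\link{magnitude_spectrum}} followed by
#' \code{\link{bpm_from_spectrum}}. Operates on the whole recording; the
#' bin width (reported in the result) sets the resolution, e.g. a 210 s
#' recording at 10 Hz gives bins of 10/4096 = 0.0024 Hz, i.e. about 0.15
#' breaths/min.
#'
#' @inheritParams magnitude_spectrum
#' @return a \code{bpm_estimate}; see \code{\link{bpm_from_spectrum}}.
#' @examples
#' rec <- generate_recording(synthetic_params(seed = 1))
#' breaths_per_minute(rec)
#' @export
breaths_per_minute <- function(recording, band_hz = c(0.3, 3.0)) {
  bpm_from_spectrum(magnitude_spectrum(recording, band_hz))
}
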