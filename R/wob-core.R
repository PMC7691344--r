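#' Detrended peak-to-peak excursion of a window
#'
#' The compartment "excursion" used by \code{\link{rc_percent}} and
#' \code{\link{lbi}}: the peak-to-peak amplitude (max minus min) of the
#' window after removal of a linear trend. The trend is the line through
#' the window's first and last samples (endpoint or "bridge" detrending),
#' which makes the estimate exactly invariant under added linear baseline
#' drift while leaving periodic content untouched: a window covering whole
#' breath cycles has equal endpoints, zero estimated slope, and therefore
#' an unbiased peak-to-peak, at any phase. (A least-squares trend line is
#' deliberately not used: on windows only one or two breaths long its
#' slope correlates with the breathing waveform itself, inflating the
#' excursion by an amount that depends on the breath phase.)
#'
#' The operator is linear in the window, so the excursion of a sum of
#' channels never exceeds the sum of their excursions -- the property that
#' guarantees \code{\link{lbi}} >= 1.
#'
#' @param w numeric vector (one channel of an analysis window).
#' @return nonnegative scalar excursion in the input's units.
#' @export
excursion <- function(w) {
  n <- length(w)
  if (n < 2L) return(0)
  slope <- (w[n] - w[1L]) / (n - 1)
  r <- w - slope * (seq_len(n) - 1L)
  max(r) - min(r)
}

# Flat-window tolerance: excursions below this are treated as zero.
window_epsilon <- function(rc_w, ab_w) {
  1e-9 * max(abs(c(rc_w, ab_w)), 1)
}

#' Percent rib cage (RC\%)
#'
#' The rib cage's contribution to tidal volume, as a percent of the
#' combined RC + AB volume change:
#' \deqn{RC\% = 100 \cdot |RC| / (|RC| + |ABD|)}
#' where \eqn{|RC|} and \eqn{|ABD|} are the compartment excursions of the
#' window (detrended peak-to-peak, see \code{\link{excursion}}).
#'
#' @param rc_w,ab_w numeric vectors: the RC and AB samples of one analysis
#'   window (at least 4 samples each).
#' @return RC percent in \[0, 100\].
#' @seealso \code{\link{lbi}}, \code{\link{phase_angle}}
#' @examples
#' th <- seq(0, 2 * pi, length.out = 40)
#' rc_percent(3 * sin(th), sin(th))  # 75
#' @export
rc_percent <- function(rc_w, ab_w) {
  check_window(rc_w, ab_w)
  a_rc <- excursion(rc_w)
  a_ab <- excursion(ab_w)
  if (a_rc + a_ab < window_epsilon(rc_w, ab_w)) {
    wob_stop("flat window: both compartment excursions are below tolerance",
             "ripwob_degenerate_window")
  }
  100 * a_rc / (a_rc + a_ab)
}

#' Thoracoabdominal phase angle
#'
#' The unsigned phase angle between rib-cage and abdomen motion, the
#' standard RIP synchrony measure: 0 degrees is perfect synchrony, 180
#' degrees is paradoxical (opposed) motion. Each channel is normalised by
#' mean subtraction over the window, then
#' \deqn{\Phi = \arccos\left(\frac{\sum_n x(n) y(n)}
#'   {\sqrt{\sum_n x(n)^2 \sum_n y(n)^2}}\right)}
#' i.e. the angle whose cosine is the cosine similarity of the two
#' zero-mean windows. The arccos argument is clamped to \[-1, 1\] to absorb
#' floating-point rounding.
#'
#' The estimate is symmetric in the two channels and invariant under
#' positive rescaling of either, so it cannot tell which compartment
#' leads -- angles are reported unsigned in \[0, 180\].
#'
#' @inheritParams rc_percent
#' @return phase angle in degrees, in \[0, 180\].
#' @examples
#' x <- sin(2 * pi * (0:19) / 20)
#' phase_angle(x, x)    # 0: perfect synchrony
#' phase_angle(x, -x)   # 180: paradoxical
#' @export
phase_angle <- function(rc_w, ab_w) {
  check_window(rc_w, ab_w)
  x <- rc_w - mean(rc_w)
  y <- ab_w - mean(ab_w)
  sxx <- sum(x * x)
  syy <- sum(y * y)
  if (sxx <= 0 || syy <= 0) {
    wob_stop("zero variance in a channel: phase is undefined",
             "ripwob_degenerate_window")
  }
  r <- sum(x * y) / sqrt(sxx * syy)
  acos(min(1, max(-1, r))) * 180 / pi
}

#' Labored breathing index (LBI)
#'
#' A measure of the extra respiratory effort caused by asynchronous
#' breathing: the ratio of the maximum compartmental amplitude (the tidal
#' excursion the two compartments would produce if moving in unison) to the
#' tidal-volume proxy actually recorded (the excursion of the summed
#' signal),
#' \deqn{LBI = (A_{RC} + A_{AB}) / A_{RC+AB}}
#' with all three amplitudes estimated by the same detrended peak-to-peak
#' estimator (\code{\link{excursion}}). LBI equals 1 for perfectly
#' synchronous motion and grows with asynchrony (sub-additivity of
#' peak-to-peak guarantees LBI >= 1 up to rounding); for equal-amplitude
#' sinusoids at lag \eqn{\theta} the continuous-limit value is
#' \eqn{1/\cos(\theta/2)}.
#'
#' @inheritParams rc_percent
#' @return LBI, a dimensionless ratio >= 1.
#' @examples
#' th <- seq(0, 4 * pi, length.out = 800)
#' lbi(sin(th), sin(th))            # 1: in unison
#' lbi(sin(th), sin(th - pi / 3))   # ~1.155 = 1/cos(30 deg)
#' @export
lbi <- function(rc_w, ab_w) {
  check_window(rc_w, ab_w)
  a_rc <- excursion(rc_w)
  a_ab <- excursion(ab_w)
  num <- a_rc + a_ab
  if (num < window_epsilon(rc_w, ab_w)) {
    wob_stop("flat window: both compartment excursions are below tolerance",
             "ripwob_degenerate_window")
  }
  a_sum <- excursion(rc_w + ab_w)
  if (a_sum < 1e-6 * num) {
    wob_stop(
      "degenerate denominator: summed-signal excursion is negligible (near-total paradox)",
      "ripwob_degenerate_window")
  }
  num / a_sum
}

#' Synchrony classification thresholds
#'
#' Default thresholds for \code{\link{classify_synchrony}}: normal
#' synchronous breathing is phase angle below 30 degrees with LBI below
#' 1.05; breathing is labelled paradoxical at phase angles of 150 degrees
#' and above (exact 180-degree paradox is never observed under noise, so a
#' band rather than a point is used; configurable).
#'
#' @param phase_sync_deg synchronous iff phase below this (degrees).
#' @param lbi_sync synchronous iff LBI below this.
#' @param phase_paradox_deg paradoxical iff phase at or above this.
#' @return named list of thresholds.
#' @export
wob_thresholds <- function(phase_sync_deg = 30, lbi_sync = 1.05,
                           phase_paradox_deg = 150) {
  stopifnot(phase_sync_deg > 0, phase_sync_deg <= phase_paradox_deg,
            phase_paradox_deg <= 180, lbi_sync >= 1)
  list(phase_sync_deg = phase_sync_deg, lbi_sync = lbi_sync,
       phase_paradox_deg = phase_paradox_deg)
}

#' Classify breathing synchrony from phase angle and LBI
#'
#' Pure threshold rule on the two indices: \code{"synchronous"} when the
#' phase angle and LBI are both below their normal-range thresholds,
#' \code{"paradoxical"} when the phase angle reaches the paradox band, and
#' \code{"asynchronous"} otherwise. Vectorised over its first two
#' arguments.
#'
#' @param phase_deg phase angle(s) in degrees, in \[0, 180\].
#' @param lbi LBI value(s), >= 1 (a small numerical shortfall below 1 is
#'   tolerated).
#' @param thresholds a list from \code{\link{wob_thresholds}}.
#' @return character vector in \{"synchronous", "asynchronous",
#'   "paradoxical"\}.
#' @examples
#' classify_synchrony(8.94, 1.04)   # synchronous
#' classify_synchrony(180, 1.5)     # paradoxical
#' @export
classify_synchrony <- function(phase_deg, lbi, thresholds = wob_thresholds()) {
  if (any(!is.finite(phase_deg)) || any(phase_deg < 0) ||
      any(phase_deg > 180)) {
    wob_stop("phase_deg must lie in [0, 180]", "ripwob_contract_violation")
  }
  if (any(!is.finite(lbi)) || any(lbi < 1 - 1e-9)) {
    wob_stop("lbi must be >= 1", "ripwob_contract_violation")
  }
  out <- rep("asynchronous", length(phase_deg))
  out[phase_deg < thresholds$phase_sync_deg &
        lbi < thresholds$lbi_sync] <- "synchronous"
  out[phase_deg >= thresholds$phase_paradox_deg] <- "paradoxical"
  out
}
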