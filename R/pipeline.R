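# Sliding-window engine. Windows are right-aligned (causal): the window
# ending at sample t uses samples t-n+1 .. t, as a real-time instrument
# that only has past samples would. All three indices are computed on the
# same window, vectorised across window positions with matrix algebra;
# tests cross-check against per-window loops.

# Row-wise max/min of a matrix without apply() overhead.
row_range <- function(M) {
  mx <- M[, 1L]; mn <- M[, 1L]
  for (j in seq_len(ncol(M))[-1L]) {
    mx <- pmax(mx, M[, j]); mn <- pmin(mn, M[, j])
  }
  mx - mn
}

# Detrended peak-to-peak excursion per row of a window matrix
# (endpoint-line detrend, matching excursion()).
row_excursion <- function(W) {
  n <- ncol(W)
  slope <- (W[, n] - W[, 1L]) / (n - 1)
  R <- W - outer(slope, seq_len(n) - 1L)
  row_range(R)
}

# len-x-n window matrix: row k holds samples k .. k+n-1 of x.
window_matrix <- function(x, n, stride) {
  starts <- seq.int(1L, length(x) - n + 1L, by = stride)
  M <- matrix(0, nrow = length(starts), ncol = n)
  for (j in seq_len(n)) M[, j] <- x[starts + j - 1L]
  M
}

#' Sliding-window work-of-breathing index series
#'
#' Slides a fixed-length analysis window across a recording and emits one
#' sample of the three per-window indices -- phase angle,
#' \code{\link{lbi}} and \code{\link{rc_percent}} -- per window position.
#' With the defaults (20-sample window, stride 1) on a 10 Hz recording,
#' indices are emitted at 10 measurements per second, each window covering
#' 2 s of breathing (about two rat breaths).
#'
#' Degenerate windows (flat signal, zero variance in a channel, or a
#' vanishing summed-signal excursion under near-total paradox) are emitted
#' with \code{valid = FALSE} and \code{NA} indices rather than raising an
#' error, so a transient artefact cannot abort the analysis of a long
#' recording.
#'
#' @param recording a \code{\link{rip_recording}} with at least
#'   \code{window_n} samples.
#' @param window_n analysis window length in samples (default 20, minimum
#'   4). One consistent window length is used for all three indices.
#' @param stride samples between successive window positions (default 1).
#' @return An object of class \code{wob_series}: a data frame with one row
#'   per window position and columns \code{t_index} (0-based index of the
#'   window's last sample), \code{time_s}, \code{phase_deg}, \code{lbi},
#'   \code{rc_percent}, \code{valid}; attributes \code{window_n},
#'   \code{stride}, \code{fs} and \code{subject_id}.
#' @examples
#' rec <- generate_recording(wob_preset("healthy_synchronous", seed = 1))
#' ser <- analyze_recording(rec)
#' summary(ser$phase_deg)
#' @export
analyze_recording <- function(recording, window_n = 20L, stride = 1L) {
  stopifnot(inherits(recording, "rip_recording"))
  window_n <- as.integer(window_n)
  stride <- as.integer(stride)
  if (window_n < 4L) {
    wob_stop("window_n must be at least 4 samples",
             "ripwob_contract_violation")
  }
  if (stride < 1L) {
    wob_stop("stride must be a positive integer", "ripwob_contract_violation")
  }
  len <- length(recording$rc)
  if (len < window_n) {
    wob_stop(sprintf(
      "recording of %d samples is shorter than one %d-sample window",
      len, window_n), "ripwob_insufficient_data")
  }

  RC <- window_matrix(recording$rc, window_n, stride)
  AB <- window_matrix(recording$ab, window_n, stride)

  # phase angle: cosine similarity of mean-subtracted windows
  Xc <- RC - rowMeans(RC)
  Yc <- AB - rowMeans(AB)
  sxx <- rowSums(Xc * Xc)
  syy <- rowSums(Yc * Yc)
  phase_ok <- sxx > 0 & syy > 0
  r <- rep(NA_real_, nrow(RC))
  r[phase_ok] <- rowSums(Xc * Yc)[phase_ok] /
    sqrt(sxx[phase_ok] * syy[phase_ok])
  phase <- acos(pmin(1, pmax(-1, r))) * 180 / pi

  # excursions for LBI and RC%
  a_rc <- row_excursion(RC)
  a_ab <- row_excursion(AB)
  a_sum <- row_excursion(RC + AB)
  maxabs <- Reduce(pmax, lapply(seq_len(window_n),
                                function(j) pmax(abs(RC[, j]), abs(AB[, j]))))
  eps <- 1e-9 * pmax(maxabs, 1)
  flat <- (a_rc + a_ab) < eps
  bad_den <- a_sum < 1e-6 * (a_rc + a_ab)
  amp_ok <- !flat & !bad_den

  lbi_v <- ifelse(amp_ok, (a_rc + a_ab) / a_sum, NA_real_)
  rcp_v <- ifelse(flat, NA_real_, 100 * a_rc / (a_rc + a_ab))

  valid <- phase_ok & amp_ok
  phase[!valid] <- NA_real_
  lbi_v[!valid] <- NA_real_
  rcp_v[!valid] <- NA_real_

  t_index <- window_n - 1L + stride * (seq_len(nrow(RC)) - 1L)
  out <- data.frame(t_index = t_index,
                    time_s = t_index / recording$fs,
                    phase_deg = phase,
                    lbi = lbi_v,
                    rc_percent = rcp_v,
                    valid = valid)
  structure(out,
            window_n = window_n, stride = stride, fs = recording$fs,
            subject_id = recording$subject_id,
            class = c("wob_series", "data.frame"))
}

#' @export
print.wob_series <- function(x, ...) {
  cat(sprintf("<wob_series> subject '%s': %d windows (n=%d, stride=%d, fs=%g Hz), %.1f%% valid\n",
              attr(x, "subject_id"), nrow(x), attr(x, "window_n"),
              attr(x, "stride"), attr(x, "fs"), 100 * mean(x$valid)))
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("  ... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

as_series_list <- function(series) {
  if (inherits(series, "wob_series")) series <- list(series)
  if (!length(series) || !all(vapply(series, inherits, TRUE, "wob_series"))) {
    wob_stop("expected a wob_series or a non-empty list of them",
             "ripwob_contract_violation")
  }
  series
}

#' Cohort summary table (mean +/- SEM)
#'
#' Builds the standard physiologic and pulmonary-function summary: one row
#' per variable with cohort mean, SEM and n. Per-subject means are computed
#' first (one value per subject per variable, over that subject's valid
#' windows), then the cohort mean and SEM are taken across subjects, so a
#' long recording cannot dominate a short one. SEM is the sample SD across
#' subjects divided by sqrt(n); with a single subject it is reported as
#' \code{NA}.
#'
#' Summarised variables are the three windowed indices (\code{phase_deg},
#' \code{rc_percent}, \code{lbi}); when \code{recordings} are supplied,
#' also \code{bpm} (computed per recording by
#' \code{\link{breaths_per_minute}}) and any of the pass-through metadata
#' fields \code{weight_g}, \code{hr_bpm}, \code{spo2_pct}, \code{etco2_mmHg}.
#'
#' @param series a \code{wob_series} or list of them (one per subject).
#' @param recordings optional list of the matching
#'   \code{\link{rip_recording}} objects, used for BPM and metadata rows.
#' @param band_hz spectral search band passed to
#'   \code{\link{breaths_per_minute}}.
#' @return An object of class \code{cohort_summary}: data frame with
#'   columns \code{variable}, \code{mean}, \code{sem}, \code{n}; attribute
#'   \code{valid_fraction} gives the pooled fraction of valid windows.
#' @export
summarize_cohort <- function(series, recordings = NULL,
                             band_hz = c(0.3, 3.0)) {
  series <- as_series_list(series)
  if (!all(vapply(series, function(s) any(s$valid), TRUE))) {
    wob_stop("every series must contain at least one valid window",
             "ripwob_contract_violation")
  }
  per_rat <- function(var) {
    vapply(series, function(s) mean(s[[var]][s$valid]), numeric(1))
  }
  vals <- list()
  if (!is.null(recordings)) {
    stopifnot(length(recordings) == length(series))
    meta_vars <- c("weight_g", "hr_bpm", "spo2_pct", "etco2_mmHg")
    for (v in meta_vars) {
      x <- vapply(recordings, function(r) {
        m <- r$metadata[[v]]
        if (is.null(m)) NA_real_ else as.numeric(m)
      }, numeric(1))
      if (any(!is.na(x))) vals[[v]] <- x
    }
    vals$bpm <- vapply(recordings, function(r) {
      est <- breaths_per_minute(r, band_hz)
      if (est$valid) est$bpm else NA_real_
    }, numeric(1))
  }
  vals$phase_deg <- per_rat("phase_deg")
  vals$rc_percent <- per_rat("rc_percent")
  vals$lbi <- per_rat("lbi")

  rows <- lapply(names(vals), function(v) {
    x <- vals[[v]][!is.na(vals[[v]])]
    n <- length(x)
    data.frame(variable = v,
               mean = if (n) mean(x) else NA_real_,
               sem = if (n >= 2L) sd(x) / sqrt(n) else NA_real_,
               n = n)
  })
  out <- do.call(rbind, rows)
  total <- sum(vapply(series, nrow, 0L))
  structure(out,
            valid_fraction = sum(vapply(series, function(s) sum(s$valid),
                                        0L)) / total,
            class = c("cohort_summary", "data.frame"))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> (valid windows: %.1f%%)\n",
              100 * attr(x, "valid_fraction")))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

default_bin_width <- function(variable) {
  switch(variable, phase_deg = 2, lbi = 0.01, rc_percent = 2,
         wob_stop(sprintf("unknown variable '%s'", variable),
                  "ripwob_contract_violation"))
}

#' Pooled histogram of a work-of-breathing index
#'
#' Pools the valid samples of one index across all subjects and bins them
#' with fixed-width bins anchored at the variable's floor (so LBI bins
#' start exactly at 1.0). Bins are left-closed, right-open. Defaults: 2
#' degrees for the phase angle, 0.01 for LBI, 2 percentage points for
#' RC\%.
#'
#' @param series a \code{wob_series} or list of them.
#' @param variable one of \code{"phase_deg"}, \code{"lbi"},
#'   \code{"rc_percent"}.
#' @param bin_width bin width in the variable's units; \code{NULL} for the
#'   per-variable default.
#' @return An object of class \code{wob_histogram}: list with
#'   \code{bin_edges}, \code{counts}, \code{variable}, \code{bin_width},
#'   \code{n} and the pooled \code{values}.
#' @seealso \code{\link{pct_in_range}}
#' @export
wob_histogram <- function(series, variable = "phase_deg", bin_width = NULL) {
  series <- as_series_list(series)
  variable <- match.arg(variable, c("phase_deg", "lbi", "rc_percent"))
  if (is.null(bin_width)) bin_width <- default_bin_width(variable)
  stopifnot(is.numeric(bin_width), bin_width > 0)
  v <- unlist(lapply(series, function(s) s[[variable]][s$valid]),
              use.names = FALSE)
  if (!length(v)) {
    wob_stop("no valid samples to histogram", "ripwob_contract_violation")
  }
  lo <- floor(min(v) / bin_width) * bin_width
  n_bins <- max(1L, ceiling((max(v) - lo) / bin_width + 1e-12))
  edges <- lo + bin_width * (0:n_bins)
  # left-closed, right-open bins; top value falls in the last bin
  idx <- pmin(floor((v - lo) / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts, variable = variable,
                 bin_width = bin_width, n = length(v), values = v),
            class = "wob_histogram")
}

#' Percent of histogrammed values inside a range
#'
#' Counts with an inclusive lower and exclusive upper bound:
#' \code{lo <= x < hi}, matching the histogram's left-closed bins.
#'
#' @param hist a \code{\link{wob_histogram}}.
#' @param lo,hi range bounds in the variable's units.
#' @return percent in \[0, 100\].
#' @export
pct_in_range <- function(hist, lo, hi) {
  stopifnot(inherits(hist, "wob_histogram"), lo < hi)
  100 * mean(hist$values >= lo & hist$values < hi)
}

#' @export
print.wob_histogram <- function(x, ...) {
  cat(sprintf("<wob_histogram> %s: %d values, %d bins of width %g on [%g, %g)\n",
              x$variable, x$n, length(x$counts), x$bin_width,
              x$bin_edges[1L], x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}

#' Thoracoabdominal motion (TAM) traces for plotting
#'
#' Returns the time-aligned, per-channel mean-removed band traces of a
#' recording (or a sample range of it) for TAM plotting or export. No
#' resampling or filtering is applied; mean removal only centres each
#' channel so the two traces overlay.
#'
#' @param recording a \code{\link{rip_recording}}.
#' @param range optional integer vector of 1-based sample indices to
#'   extract (e.g. \code{201:400}); \code{NULL} for the whole recording.
#' @return data frame with columns \code{sample} (1-based index),
#'   \code{time_s}, \code{rc}, \code{ab}; zero rows for an empty range.
#' @export
tam_trace <- function(recording, range = NULL) {
  stopifnot(inherits(recording, "rip_recording"))
  idx <- if (is.null(range)) seq_along(recording$rc) else as.integer(range)
  idx <- idx[idx >= 1L & idx <= length(recording$rc)]
  rc <- recording$rc[idx]
  ab <- recording$ab[idx]
  if (length(idx)) {
    rc <- rc - mean(rc)
    ab <- ab - mean(ab)
  }
  data.frame(sample = idx, time_s = (idx - 1L) / recording$fs,
             rc = rc, ab = ab)
}
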