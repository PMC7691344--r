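# File formats. Recordings travel as plain CSV with header
# time_s,rc,ab (human-readable, diff-able); subject metadata rides in an
# optional JSON sidecar next to the CSV. Index series are CSV with
# key=value comment headers so a round trip restores the windowing
# attributes; summaries are JSON.

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read a two-band recording from CSV
#'
#' Expects a CSV with header \code{time_s,rc,ab}. The time column must be
#' strictly increasing and near-uniform: any inter-sample interval
#' deviating from the median by more than 1\% is rejected with a spacing
#' diagnostic, since the windowed indices assume a fixed rate. The
#' sampling rate is inferred as 1 / median interval unless \code{fs} is
#' supplied. If a JSON sidecar \code{<name>.json} sits next to the file,
#' its fields (\code{subject_id}, \code{weight_g}, \code{hr_bpm},
#' \code{spo2_pct}, \code{etco2_mmHg}, ...) are merged as metadata.
#'
#' @param path CSV file path.
#' @param fs optional sampling-rate override in Hz.
#' @param sidecar optional explicit sidecar path; default looks for
#'   \code{<name>.json}.
#' @return a \code{\link{rip_recording}}.
#' @export
read_recording <- function(path, fs = NULL, sidecar = NULL) {
  if (!file.exists(path)) {
    wob_stop(sprintf("file not found: %s", path), "ripwob_io_error")
  }
  df <- tryCatch(read.csv(path, comment.char = "#"),
                 error = function(e) {
                   wob_stop(sprintf("cannot parse %s: %s", path,
                                    conditionMessage(e)), "ripwob_io_error")
                 })
  need <- c("time_s", "rc", "ab")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    wob_stop(sprintf("%s: missing column(s) %s", path,
                     paste(miss, collapse = ", ")), "ripwob_io_error")
  }
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      wob_stop(sprintf("%s: non-finite value in column '%s' at data row %d",
                       path, col, bad[1L]), "ripwob_io_error")
    }
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    wob_stop(sprintf("%s: time_s not strictly increasing at data row %d",
                     path, which(dt <= 0)[1L] + 1L), "ripwob_io_error")
  }
  med <- median(dt)
  dev <- abs(dt - med)
  if (max(dev) > 0.01 * med) {
    k <- which.max(dev)
    wob_stop(sprintf(
      "%s: irregular sampling at data row %d (interval %.6g s vs median %.6g s; tolerance 1%%)",
      path, k + 1L, dt[k], med), "ripwob_io_error")
  }
  metadata <- list()
  subject_id <- tools::file_path_sans_ext(basename(path))
  sc <- if (is.null(sidecar)) sidecar_path(path) else sidecar
  if (file.exists(sc)) {
    metadata <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(metadata$subject_id)) {
      subject_id <- metadata$subject_id
      metadata$subject_id <- NULL
    }
  }
  rip_recording(rc = df$rc, ab = df$ab,
                fs = if (is.null(fs)) 1 / med else fs,
                subject_id = subject_id, metadata = as.list(metadata))
}

#' Write a recording to CSV (with optional metadata sidecar)
#'
#' Writes the \code{time_s,rc,ab} dialect that \code{\link{read_recording}}
#' reads back. Metadata, when present, goes to a JSON sidecar next to the
#' CSV.
#'
#' @param recording a \code{\link{rip_recording}}.
#' @param path destination CSV path.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "rip_recording"))
  n <- length(recording$rc)
  df <- data.frame(time_s = (0:(n - 1L)) / recording$fs,
                   rc = recording$rc, ab = recording$ab)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  md <- c(list(subject_id = recording$subject_id), recording$metadata)
  jsonlite::write_json(md, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read a work-of-breathing index series as CSV
#'
#' The CSV carries columns \code{t_index,time_s,phase_deg,lbi,rc_percent,valid}
#' preceded by \code{# key=value} comment lines holding the windowing
#' attributes, so \code{read_series} restores an object equal to the one
#' written (numeric values round-trip at 15 significant digits). An empty
#' series writes a valid header-only file.
#'
#' @param series a \code{wob_series} from \code{\link{analyze_recording}}.
#' @param path destination CSV path.
#' @return \code{path} invisibly (\code{write_series}); a
#'   \code{wob_series} (\code{read_series}).
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "wob_series"))
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("window_n", "stride", "fs", "subject_id")) {
    writeLines(sprintf("#%s=%s", key, attr(series, key)), con)
  }
  df <- as.data.frame(series)
  num <- c("time_s", "phase_deg", "lbi", "rc_percent")
  for (col in num) df[[col]] <- formatC(df[[col]], digits = 15, format = "g")
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  if (!file.exists(path)) {
    wob_stop(sprintf("file not found: %s", path), "ripwob_io_error")
  }
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  attrs <- stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  df <- read.csv(path, comment.char = "#",
                 colClasses = c(t_index = "integer", time_s = "numeric",
                                phase_deg = "numeric", lbi = "numeric",
                                rc_percent = "numeric", valid = "logical"))
  structure(df,
            window_n = as.integer(attrs$window_n),
            stride = as.integer(attrs$stride),
            fs = as.numeric(attrs$fs),
            subject_id = attrs$subject_id,
            class = c("wob_series", "data.frame"))
}

#' Write / read a cohort summary document as JSON
#'
#' The JSON document carries the mean/SEM/n summary rows, optional
#' histogram descriptions (edges, counts, percent-in-range), and the
#' fraction of valid windows. Its structure is described by the shipped
#' schema file \code{system.file("extdata", "wob-summary-schema.json",
#' package = "ripwob")}; \code{read_summary} validates the structure on
#' load.
#'
#' @param summary a \code{cohort_summary} from
#'   \code{\link{summarize_cohort}}.
#' @param path destination JSON path.
#' @param histograms optional named list of \code{\link{wob_histogram}}
#'   objects to embed (counts and edges only, not raw values).
#' @param ranges named list mapping a histogram name to the
#'   \code{c(lo, hi)} range whose percent-in-range is reported; defaults
#'   to the conventional normal ranges: phase in \[0, 30) degrees, LBI in
#'   \[1.0, 1.1).
#' @return \code{path} invisibly (\code{write_summary}); the parsed
#'   document list (\code{read_summary}).
#' @export
write_summary <- function(summary, path, histograms = NULL,
                          ranges = list(phase_deg = c(0, 30),
                                        lbi = c(1.0, 1.1))) {
  stopifnot(inherits(summary, "cohort_summary"))
  doc <- list(
    format = "ripwob_summary",
    version = 1L,
    valid_fraction = attr(summary, "valid_fraction"),
    summary = as.data.frame(summary))
  if (!is.null(histograms)) {
    doc$histograms <- lapply(histograms, function(h) {
      stopifnot(inherits(h, "wob_histogram"))
      rng <- ranges[[h$variable]]
      out <- list(variable = h$variable, bin_width = h$bin_width,
                  bin_edges = h$bin_edges, counts = h$counts, n = h$n)
      if (!is.null(rng)) {
        out$range <- rng
        out$pct_in_range <- pct_in_range(h, rng[1L], rng[2L])
      }
      out
    })
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) {
    wob_stop(sprintf("file not found: %s", path), "ripwob_io_error")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_summary_doc(doc)
  doc
}

# Structural validation of the summary JSON against the shipped schema's
# requirements (required fields, types, value ranges).
validate_summary_doc <- function(doc) {
  if (!identical(doc$format, "ripwob_summary")) {
    wob_stop("not a ripwob summary document (format field missing or wrong)",
             "ripwob_io_error")
  }
  if (is.null(doc$summary) ||
      !all(c("variable", "mean", "n") %in% names(doc$summary))) {
    wob_stop("summary table missing required columns variable/mean/n",
             "ripwob_io_error")
  }
  vf <- doc$valid_fraction
  if (!is.numeric(vf) || vf < 0 || vf > 1) {
    wob_stop("valid_fraction must be a number in [0, 1]", "ripwob_io_error")
  }
  for (h in doc$histograms) {
    if (length(h$bin_edges) != length(h$counts) + 1L ||
        is.unsorted(h$bin_edges) || any(h$counts < 0)) {
      wob_stop("malformed histogram block in summary document",
               "ripwob_io_error")
    }
  }
  invisible(TRUE)
}
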