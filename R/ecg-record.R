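#' Single-lead ECG record
#'
#' Container for a uniformly sampled single-lead ECG waveform. Sample index
#' `n` (1-based) corresponds to time `(n - 1) / fs` seconds. Optional
#' ground-truth R-apex positions are continuous times in seconds and are
#' independent of the sampling grid.
#'
#' @param samples numeric vector of amplitudes (arbitrary units).
#' @param fs sampling rate in Hz (> 0).
#' @param truth_apexes optional numeric vector of continuous-time R-apex
#'   positions in seconds, strictly increasing and within the record.
#' @param record_id label for reports.
#' @return An object of class `ecg_record` with fields `samples`, `fs`,
#'   `truth_apexes`, `record_id` and `transient_s` (edge region affected by
#'   the most recent FIR filtering step, 0 for unfiltered records).
#' @export
ecg_record <- function(samples, fs, truth_apexes = NULL, record_id = "ecg") {
  if (!is_scalar_number(fs) || fs <= 0) stop_parameter("fs must be a positive number")
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop_parameter("samples must be non-empty")
  if (!all(is.finite(samples))) stop_parameter("samples must be finite")
  dur <- length(samples) / fs
  if (!is.null(truth_apexes)) {
    truth_apexes <- as.numeric(truth_apexes)
    if (length(truth_apexes) && (any(diff(truth_apexes) <= 0) ||
        truth_apexes[1] < 0 || truth_apexes[length(truth_apexes)] > dur))
      stop_parameter("truth_apexes must be strictly increasing and within [0, duration]")
  }
  structure(list(samples = samples, fs = fs, truth_apexes = truth_apexes,
                 record_id = as.character(record_id), transient_s = 0),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s': %d samples @ %g Hz (%.2f s)%s>\n",
              x$record_id, length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$truth_apexes)) ""
              else sprintf(", %d truth apexes", length(x$truth_apexes))))
  invisible(x)
}

#' Duration of an ECG record in seconds
#' @param rec an `ecg_record`.
#' @export
ecg_duration <- function(rec) length(rec$samples) / rec$fs

#' QRS detection list
#'
#' Base QRS locations, as 1-based integer sample indices on the grid of the
#' record they refer to. Duplicates are allowed (they are merged during
#' localization); indices must be sorted.
#'
#' @param indices integer sample indices (1-based), sorted non-decreasing.
#' @param fs sampling rate in Hz of the record the indices refer to.
#' @param origin character vector, per-index provenance (e.g. `"detector"`
#'   or `"mock"`); recycled.
#' @return An object of class `qrs_detections`.
#' @export
qrs_detections <- function(indices, fs, origin = "detector") {
  if (!is_scalar_number(fs) || fs <= 0) stop_parameter("fs must be a positive number")
  indices <- as.integer(indices)
  if (any(is.na(indices))) stop_parameter("indices must be integer-valued")
  if (length(indices) && any(indices < 1L)) stop_parameter("indices must be >= 1")
  if (is.unsorted(indices)) stop_parameter("indices must be sorted")
  origin <- rep_len(as.character(origin), length(indices))
  structure(list(indices = indices, fs = fs, origin = origin),
            class = "qrs_detections")
}

#' @export
print.qrs_detections <- function(x, ...) {
  cat(sprintf("<qrs_detections: %d locations @ %g Hz (%d mock)>\n",
              length(x$indices), x$fs, sum(x$origin == "mock")))
  invisible(x)
}

#' Read an ECG waveform from a two-column CSV file
#'
#' The canonical waveform format is a two-column CSV `(time_s, amplitude)`
#' with an optional header line and decimal points (no locale-specific
#' separators). The sampling rate is inferred from the median time step;
#' the time axis must be uniform to within 1 ppm.
#'
#' @param path file path.
#' @param truth_path optional path of a one-column CSV of apex times
#'   (seconds) to attach as ground truth.
#' @param record_id label; defaults to the file name.
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(path, truth_path = NULL, record_id = NULL) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_parse(sprintf("%s: empty file", path))
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(lines[1], ",")[[1]][1])))
  first <- if (has_header) 2L else 1L
  if (length(lines) < first) stop_parse(sprintf("%s: no data rows", path))
  parts <- strsplit(lines[first:length(lines)], ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1] + first - 1L
    stop_parse(sprintf("%s: line %d: expected two columns (time_s, amplitude)", path, bad))
  }
  tm <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  am <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(tm) || anyNA(am)) {
    bad <- which(is.na(tm) | is.na(am))[1] + first - 1L
    stop_parse(sprintf("%s: line %d: non-numeric value", path, bad))
  }
  if (length(tm) < 2L) stop_sampling(sprintf("%s: need at least two samples", path))
  dt <- diff(tm)
  med <- stats::median(dt)
  if (med <= 0 || any(abs(dt - med) > 1e-6 * med + 1e-12))
    stop_sampling(sprintf("%s: non-uniform time step (beyond 1 ppm tolerance)", path))
  truth <- NULL
  if (!is.null(truth_path)) {
    tr <- utils::read.csv(truth_path)
    truth <- as.numeric(tr[[1]])
  }
  if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
  ecg_record(am, fs = 1 / med, truth_apexes = truth, record_id = record_id)
}

#' Write an ECG waveform as a two-column CSV file
#'
#' Amplitudes are written with 17 significant digits so that a
#' write/read round trip reproduces the samples bit-exactly.
#'
#' @param rec an [ecg_record()].
#' @param path output file path.
#' @param truth_path optional path for a one-column CSV of apex times.
#' @return Invisibly, `path`.
#' @export
write_ecg_csv <- function(rec, path, truth_path = NULL) {
  t <- (seq_along(rec$samples) - 1) / rec$fs
  lines <- c("time_s,amplitude",
             paste(sprintf("%.17g", t), sprintf("%.17g", rec$samples), sep = ","))
  writeLines(lines, path)
  if (!is.null(truth_path)) {
    writeLines(c("apex_time_s",
                 if (is.null(rec$truth_apexes)) character(0)
                 else sprintf("%.17g", rec$truth_apexes)), truth_path)
  }
  invisible(path)
}
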