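# Template matching: averaged-beat template, per-beat correlation scores,
# threshold-based false-positive rejection, and the two-pass
# cross-correlation (xcorr) reference localizer.

as_locations <- function(locations) {
  if (inherits(locations, "qrs_detections")) locations$indices
  else if (inherits(locations, "localized_beats")) locations$beats$n_I
  else as.numeric(locations)
}

#' Median beat length
#'
#' Median of the successive differences between sorted beat locations,
#' rounded to the nearest integer sample. This is the window length used
#' for the template and the correlation scores.
#'
#' @param locations numeric locations in samples (a vector,
#'   [qrs_detections()] or `localized_beats`).
#' @return Integer number of samples.
#' @export
median_beat_length <- function(locations) {
  loc <- as_locations(locations)
  if (length(loc) < 2L) stop_insufficient("need at least two locations")
  as.integer(round(stats::median(diff(sort(loc)))))
}

#' Build an averaged-beat template
#'
#' Pointwise mean of windows of length `B` centered on each location
#' (fractional locations are rounded to the nearest sample). Windows
#' truncated by the record edges are excluded from the average and counted.
#'
#' @param rec an [ecg_record()].
#' @param locations beat locations in samples.
#' @param B window length in samples (default [median_beat_length()]).
#' @return An object of class `ecg_template`: `template` (length `B`),
#'   `B`, `fs`, `n_beats_used`, `n_excluded`.
#' @export
build_template <- function(rec, locations, B = median_beat_length(locations)) {
  loc <- round(as_locations(locations))
  n <- length(rec$samples)
  B <- as.integer(B)
  if (B < 1L) stop_parameter("B must be >= 1")
  h <- floor(B / 2)
  starts <- loc - h
  full <- starts >= 1L & starts + B - 1L <= n
  if (!any(full)) stop_insufficient("no location has a full window inside the record")
  acc <- numeric(B)
  for (s in starts[full]) acc <- acc + rec$samples[s:(s + B - 1L)]
  structure(list(template = acc / sum(full), B = B, fs = rec$fs,
                 n_beats_used = sum(full), n_excluded = sum(!full)),
            class = "ecg_template")
}

#' @export
print.ecg_template <- function(x, ...) {
  cat(sprintf("<ecg_template: B = %d samples @ %g Hz, averaged over %d beats (%d excluded)>\n",
              x$B, x$fs, x$n_beats_used, x$n_excluded))
  invisible(x)
}

#' Score beats against the template
#'
#' Pearson correlation between the template and the window of length `B`
#' centered at each location. Windows truncated at a record edge are
#' scored on the overlapping part (the overlap length is recorded); a
#' zero-variance window gets `r = 0` and is flagged.
#'
#' @param rec an [ecg_record()] at the template's sampling rate.
#' @param locations beat locations in samples (fractional values are
#'   rounded for windowing).
#' @param tpl an `ecg_template`.
#' @return Data frame with columns `location`, `r`, `overlap`,
#'   `zero_variance`.
#' @export
score_beats <- function(rec, locations, tpl) {
  if (abs(tpl$fs - rec$fs) > 1e-9 * rec$fs)
    stop_parameter("template and record have different sampling rates")
  loc <- as_locations(locations)
  li <- round(loc)
  n <- length(rec$samples)
  h <- floor(tpl$B / 2)
  r <- numeric(length(loc)); ov <- integer(length(loc)); zv <- logical(length(loc))
  for (i in seq_along(loc)) {
    s <- li[i] - h
    a <- max(1L, s); b <- min(n, s + tpl$B - 1L)
    if (a > b) { r[i] <- 0; ov[i] <- 0L; zv[i] <- TRUE; next }
    wrec <- rec$samples[a:b]
    wtpl <- tpl$template[(a - s + 1L):(b - s + 1L)]
    ov[i] <- b - a + 1L
    if (stats::sd(wrec) == 0 || stats::sd(wtpl) == 0 || ov[i] < 2L) {
      r[i] <- 0; zv[i] <- TRUE
    } else r[i] <- stats::cor(wrec, wtpl)
  }
  data.frame(location = loc, r = r, overlap = ov, zero_variance = zv)
}

#' Reject beats scoring below a correlation threshold
#'
#' @param scored data frame from [score_beats()].
#' @param threshold correlation threshold `T` in `[-1, 1]`; beats with
#'   `r >= T` are kept, order preserved.
#' @return The kept rows of `scored`.
#' @export
reject_by_threshold <- function(scored, threshold) {
  if (!is_scalar_number(threshold) || threshold < -1 || threshold > 1)
    stop_parameter("threshold must be in [-1, 1]")
  scored[scored$r >= threshold, , drop = FALSE]
}

# Direct cross-correlation search: shift each location to the lag in
# [-radius, radius] maximizing the dot product with the template. Direct
# (non-FFT) evaluation so the instrumented op count reflects the real
# per-beat cost, which is what the complexity comparison is about.
xcorr_adjust <- function(x, loc, tpl, radius, counter) {
  B <- length(tpl)
  h <- floor(B / 2)
  n <- length(x)
  out <- loc
  for (i in seq_along(loc)) {
    s_min <- max(-radius, 1L - (loc[i] - h))
    s_max <- min(radius, n - (loc[i] - h + B - 1L))
    if (s_min > s_max) next
    shifts <- s_min:s_max
    cc <- vapply(shifts, function(s) {
      a <- loc[i] - h + s
      sum(tpl * x[a:(a + B - 1L)])
    }, numeric(1))
    counter$ops <- counter$ops + length(shifts) * B
    out[i] <- loc[i] + shifts[which.max(cc)]
  }
  out
}

#' Two-pass cross-correlation localization (reference method)
#'
#' The classical template-based localizer used as reference and for
#' ground-truth construction: build a template from the initial locations,
#' shift each location to the lag maximizing the cross-correlation with
#' the template within half a template length, rebuild the template from
#' the adjusted locations, and repeat the adjustment. Its precision is
#' bound by the sampling grid, so `upsample_to` can be used to refine the
#' grid first (the classical remedy, and the reason this method costs so
#' much more than the slope algorithm).
#'
#' @param rec a baseline-filtered [ecg_record()].
#' @param det a [qrs_detections()] (at least 2).
#' @param upsample_to optional target rate in Hz; record and locations are
#'   resampled before localization.
#' @param refine if `TRUE` (default), snap each initial location to the
#'   local signal maximum in a QRS-length window first, as detectors are
#'   expected to point at the R peak.
#' @param qrs_len_s QRS window for the refinement step.
#' @return List with `times` (localized R-peak times in seconds),
#'   `locations` (sample indices on the working grid), `fs` (working
#'   grid rate), `ops_per_beat` (instrumented multiply-accumulate count
#'   per beat) and `B` (template length used).
#' @export
xcorr_localize <- function(rec, det, upsample_to = NULL, refine = TRUE,
                           qrs_len_s = 0.08) {
  stopifnot(inherits(rec, "ecg_record"), inherits(det, "qrs_detections"))
  if (length(det$indices) < 2L) stop_insufficient("need at least two detections")
  loc <- det$indices
  if (!is.null(upsample_to) && abs(upsample_to - rec$fs) > 1e-9 * rec$fs) {
    loc <- as.integer(round((loc - 1) * upsample_to / rec$fs)) + 1L
    rec <- resample_ecg(rec, upsample_to)
    loc <- pmin(pmax(loc, 1L), length(rec$samples))
  }
  if (refine) {
    w <- max(3L, as.integer(round(qrs_len_s * rec$fs)))
    loc <- vapply(loc, function(p) find_local_max(rec, p, w), integer(1))
  }
  counter <- new.env()
  counter$ops <- 0
  B <- median_beat_length(loc)
  radius <- floor(B / 2)
  tpl <- build_template(rec, loc, B)
  loc1 <- xcorr_adjust(rec$samples, loc, tpl$template, radius, counter)
  tpl2 <- build_template(rec, loc1, B)
  loc2 <- xcorr_adjust(rec$samples, loc1, tpl2$template, radius, counter)
  list(times = (loc2 - 1) / rec$fs, locations = loc2, fs = rec$fs,
       times_pass1 = (loc1 - 1) / rec$fs,
       ops_per_beat = counter$ops / length(loc), B = B)
}

#' Ground-truth R-peak locations by upsampled cross-correlation
#'
#' Upsamples the record to 10 kHz and runs the two-pass [xcorr_localize()]
#' there, the standard recipe for constructing reference locations with a
#' time resolution of 0.1 ms.
#'
#' @inheritParams xcorr_localize
#' @return Numeric vector of apex times in seconds.
#' @export
ground_truth_locations <- function(rec, det) {
  xcorr_localize(rec, det, upsample_to = 10000)$times
}

#' Save / load a template as CSV
#'
#' One amplitude per line, preceded by a comment header carrying `fs`, `B`
#' and `n_beats_used`.
#'
#' @param tpl an `ecg_template`.
#' @param path file path.
#' @export
write_template_csv <- function(tpl, path) {
  writeLines(c(sprintf("# fs=%.10g B=%d n_beats_used=%d", tpl$fs, tpl$B, tpl$n_beats_used),
               "amplitude", sprintf("%.17g", tpl$template)), path)
  invisible(path)
}

#' @rdname write_template_csv
#' @export
read_template_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop_parse(sprintf("%s: missing template header", path))
  kv <- regmatches(lines[1], gregexpr("[A-Za-z_]+=[0-9.eE+-]+", lines[1]))[[1]]
  meta <- stats::setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  vals <- as.numeric(lines[-(1:2)])
  if (anyNA(vals) || length(vals) != meta[["B"]])
    stop_parse(sprintf("%s: malformed template body", path))
  structure(list(template = vals, B = as.integer(meta[["B"]]), fs = meta[["fs"]],
                 n_beats_used = as.integer(meta[["n_beats_used"]]), n_excluded = NA_integer_),
            class = "ecg_template")
}
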