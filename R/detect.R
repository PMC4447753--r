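# A deliberately simple base QRS detector. The package's purpose is the
# localization step, which is agnostic to the detector used; this one only
# has to put a detection within the refinement window of each QRS complex.

#' Naive QRS detection from the squared step derivative
#'
#' Squares the step derivative, smooths it with a moving average one QRS
#' length wide (a moving-window-integration stage in the Pan-Tompkins
#' tradition), and marks threshold crossings. Each above-threshold run
#' yields one detection at the run's energy maximum; detections closer than
#' the refractory period to the previous one are suppressed. The threshold
#' sits 40% of the way from the median to the 99.9th percentile of the
#' smoothed energy, which tracks the noise floor without any per-record
#' tuning.
#'
#' @param rec a baseline-filtered [ecg_record()].
#' @param cfg a [slope_config()] (provides the step and the QRS length).
#' @param refractory_s minimum spacing between detections (default 0.25 s).
#' @param threshold_frac position of the threshold between the median and
#'   the 99.9th percentile of the smoothed energy (default 0.4).
#' @return A [qrs_detections()] (possibly empty).
#' @export
naive_detect <- function(rec, cfg = slope_config(), refractory_s = 0.25,
                         threshold_frac = 0.4) {
  cs <- config_samples(cfg, rec$fs)
  n <- length(rec$samples)
  if (n <= cs$delta + cs$w) return(qrs_detections(integer(0), rec$fs))
  d <- slope_differentiate(rec, cs$delta)
  d[seq_len(cs$delta)] <- 0
  e <- d^2
  ma <- stats::filter(e, rep(1 / cs$w, cs$w), sides = 2)
  ma[is.na(ma)] <- 0
  ma <- as.numeric(ma)
  med <- stats::median(ma)
  hi <- stats::quantile(ma, 0.999, names = FALSE)
  if (hi <= med + .Machine$double.eps) return(qrs_detections(integer(0), rec$fs))
  thr <- med + threshold_frac * (hi - med)
  above <- ma > thr
  if (!any(above)) return(qrs_detections(integer(0), rec$fs))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peaks <- vapply(runs, function(j) {
    s <- starts[j]; e2 <- ends[j]
    s + which.max(ma[s:e2]) - 1L
  }, integer(1))
  refr <- as.integer(round(refractory_s * rec$fs))
  keep <- integer(0)
  last <- -Inf
  for (p in peaks) {
    if (p - last >= refr) { keep <- c(keep, p); last <- p }
  }
  qrs_detections(keep, rec$fs)
}
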