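# Detection and localization scoring: truth matching within a 40 ms
# margin, sensitivity/PPV, and the pooled trigger jitter.

#' Match detected beats to ground truth
#'
#' Greedy one-to-one nearest matching: candidate (truth, detection) pairs
#' within the margin are assigned in order of increasing absolute error.
#' Unmatched detections are false positives, unmatched truths false
#' negatives. The 40 ms default margin is half the average QRS duration,
#' the margin used in signal-averaging guidelines.
#'
#' @param truth_s sorted ground-truth apex times in seconds.
#' @param detected_s sorted detected apex times in seconds.
#' @param margin_s matching margin in seconds (default 0.040).
#' @return An object of class `match_result`: `pairs` (data frame `truth`,
#'   `detected`, `error` with `error = detected - truth`), counts `n_tp`,
#'   `n_fp`, `n_fn`, and `margin_s`.
#' @export
match_beats <- function(truth_s, detected_s, margin_s = 0.040) {
  truth_s <- as.numeric(truth_s); detected_s <- as.numeric(detected_s)
  cand_t <- integer(0); cand_d <- integer(0); cand_e <- numeric(0)
  if (length(truth_s) && length(detected_s)) {
    for (j in seq_along(detected_s)) {
      k <- findInterval(detected_s[j], truth_s)
      for (i in unique(pmin(pmax(c(k, k + 1L), 1L), length(truth_s)))) {
        err <- detected_s[j] - truth_s[i]
        if (abs(err) <= margin_s) {
          cand_t <- c(cand_t, i); cand_d <- c(cand_d, j); cand_e <- c(cand_e, err)
        }
      }
    }
  }
  used_t <- logical(length(truth_s)); used_d <- logical(length(detected_s))
  pt <- integer(0); pd <- integer(0); pe <- numeric(0)
  for (k in order(abs(cand_e))) {
    if (!used_t[cand_t[k]] && !used_d[cand_d[k]]) {
      used_t[cand_t[k]] <- TRUE; used_d[cand_d[k]] <- TRUE
      pt <- c(pt, cand_t[k]); pd <- c(pd, cand_d[k]); pe <- c(pe, cand_e[k])
    }
  }
  o <- order(pt)
  structure(list(
    pairs = data.frame(truth = truth_s[pt[o]], detected = detected_s[pd[o]],
                       error = pe[o]),
    n_tp = length(pt), n_fp = sum(!used_d), n_fn = sum(!used_t),
    margin_s = margin_s), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: TP %d, FP %d, FN %d (margin %.0f ms)>\n",
              x$n_tp, x$n_fp, x$n_fn, 1000 * x$margin_s))
  invisible(x)
}

#' Sensitivity and positive predictive value
#'
#' `sensitivity = TP / (TP + FN)`, `ppv = TP / (TP + FP)`. A ratio with a
#' zero denominator is returned as `NA` with the corresponding flag set.
#'
#' @param m a `match_result`.
#' @return List with `sensitivity`, `ppv`, `sensitivity_defined`,
#'   `ppv_defined`.
#' @export
sensitivity_ppv <- function(m) {
  sd_ <- m$n_tp + m$n_fn > 0
  pd_ <- m$n_tp + m$n_fp > 0
  list(sensitivity = if (sd_) m$n_tp / (m$n_tp + m$n_fn) else NA_real_,
       ppv = if (pd_) m$n_tp / (m$n_tp + m$n_fp) else NA_real_,
       sensitivity_defined = sd_, ppv_defined = pd_)
}

#' Pooled trigger jitter across records
#'
#' Per record, the trigger jitter is the sample standard deviation of the
#' signed localization errors of its matched beats. Across `k` records the
#' pooled jitter is the `(n_i - 1)`-weighted pooled standard deviation
#' `sqrt(sum((n_i - 1) * sigma_i^2) / sum(n_i - 1))`. Also reports the
#' mean absolute and mean signed error over all matched pairs.
#'
#' @param errors_by_record a list of numeric vectors of signed errors in
#'   seconds (one per record, names used as record ids), or a single
#'   numeric vector (one record).
#' @return An object of class `jitter_summary`: `per_record` (data frame
#'   `record_id`, `n`, `sigma`), `pooled_sigma`, `mean_abs_error`,
#'   `mean_signed_error` (all seconds).
#' @export
trigger_jitter <- function(errors_by_record) {
  if (is.numeric(errors_by_record)) errors_by_record <- list(errors_by_record)
  ids <- names(errors_by_record)
  if (is.null(ids)) ids <- as.character(seq_along(errors_by_record))
  n_i <- vapply(errors_by_record, length, integer(1))
  if (all(n_i < 2L)) stop_insufficient("need at least one record with >= 2 matched beats")
  use <- n_i >= 2L
  sig <- rep(NA_real_, length(n_i))
  sig[use] <- vapply(errors_by_record[use], stats::sd, numeric(1))
  pooled <- sqrt(sum((n_i[use] - 1) * sig[use]^2) / sum(n_i[use] - 1))
  all_err <- unlist(errors_by_record, use.names = FALSE)
  structure(list(
    per_record = data.frame(record_id = ids, n = n_i, sigma = sig),
    pooled_sigma = pooled,
    mean_abs_error = mean(abs(all_err)),
    mean_signed_error = mean(all_err)), class = "jitter_summary")
}

#' @export
print.jitter_summary <- function(x, ...) {
  cat(sprintf("<jitter_summary: pooled sigma %.3f ms, mean |error| %.3f ms over %d records>\n",
              1000 * x$pooled_sigma, 1000 * x$mean_abs_error, nrow(x$per_record)))
  invisible(x)
}
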