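# Synthetic ECG with exactly known continuous-time R apexes. The beat
# model is a sum of smooth bumps: a piecewise Gaussian R wave whose
# left/right widths set the slope asymmetry analytically, small Q and S
# dips, and optional low-frequency P and T waves. It emulates monomorphic
# sinus-rhythm morphology well enough to exercise detection, localization,
# template matching and the degradation protocol; it does not model
# arrhythmia, morphology drift, respiratory modulation or non-Gaussian
# artifacts.

#' Beat shape specification
#'
#' The R wave is a piecewise Gaussian with standard deviations
#' `sigma_L = beta_target * sigma_R` left of the apex and `sigma_R` right
#' of it, so the descending-to-ascending maximum-slope ratio is exactly
#' `beta_target`. The widths are scaled so the R wave spans `qrs_len_s`
#' at the 5% amplitude level.
#'
#' @param q_depth,r_height,s_depth amplitudes of the Q dip, R peak and S
#'   dip (positive numbers; dips are subtracted).
#' @param qrs_len_s total QRS duration in seconds (default 0.08).
#' @param beta_target descending/ascending slope-magnitude ratio, in
#'   `[0.5, 2.5]` (default 1.13, a typical median in healthy adults).
#' @param p_t_waves include P and T waves (default TRUE).
#' @return An object of class `beat_shape`.
#' @export
beat_shape <- function(q_depth = 0.08, r_height = 1, s_depth = 0.12,
                       qrs_len_s = 0.08, beta_target = 1.13, p_t_waves = TRUE) {
  if (!is_scalar_number(r_height) || r_height <= 0) stop_parameter("r_height must be > 0")
  if (!is_scalar_number(qrs_len_s) || qrs_len_s <= 0) stop_parameter("qrs_len_s must be > 0")
  if (!is_scalar_number(beta_target) || beta_target < 0.5 || beta_target > 2.5)
    stop_parameter("beta_target must be in [0.5, 2.5]")
  sigma_r <- qrs_len_s / (2.448 * (1 + beta_target))  # 2.448 sd = 5% level
  structure(list(q_depth = q_depth, r_height = r_height, s_depth = s_depth,
                 qrs_len_s = qrs_len_s, beta_target = beta_target,
                 sigma_l = beta_target * sigma_r, sigma_r = sigma_r,
                 p_t_waves = isTRUE(p_t_waves)), class = "beat_shape")
}

#' Continuous-time waveform of one beat
#'
#' Evaluates the beat model at times `t` (seconds) relative to the R apex,
#' which is at `t = 0` by construction.
#'
#' @param t numeric times in seconds.
#' @param shape a [beat_shape()].
#' @return Amplitudes at `t`.
#' @export
beat_waveform <- function(t, shape) {
  g <- function(t0, sg, amp) amp * exp(-(t - t0)^2 / (2 * sg^2))
  r <- shape$r_height * ifelse(t < 0,
        exp(-t^2 / (2 * shape$sigma_l^2)),
        exp(-t^2 / (2 * shape$sigma_r^2)))
  qs <- shape$qrs_len_s
  y <- r - g(-0.475 * qs, qs / 16, shape$q_depth * shape$r_height) -
           g( 0.475 * qs, qs / 16, shape$s_depth * shape$r_height)
  if (shape$p_t_waves)
    y <- y + g(-0.22, 0.028, 0.12 * shape$r_height) +
             g( 0.30, 0.055, 0.25 * shape$r_height)
  y
}

#' Rhythm specification
#'
#' @param duration_s record duration in seconds.
#' @param mean_hr_bpm mean heart rate in beats per minute (default 60).
#' @param rr_jitter_s standard deviation of the Gaussian perturbation of
#'   each interbeat interval in seconds (default 0.05). This is a
#'   convenience model of rhythm variability, not physiologic HRV.
#' @param fs sampling rate in Hz.
#' @param seed RNG seed for reproducibility.
#' @return An object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(duration_s, mean_hr_bpm = 60, rr_jitter_s = 0.05,
                        fs = 500, seed = 1) {
  if (!is_scalar_number(duration_s) || duration_s <= 0) stop_parameter("duration_s must be > 0")
  if (!is_scalar_number(mean_hr_bpm) || mean_hr_bpm <= 0) stop_parameter("mean_hr_bpm must be > 0")
  if (!is_scalar_number(fs) || fs <= 0) stop_parameter("fs must be > 0")
  structure(list(duration_s = duration_s, mean_hr_bpm = mean_hr_bpm,
                 rr_jitter_s = rr_jitter_s, fs = fs, seed = seed),
            class = "rhythm_spec")
}

#' Generate a synthetic ECG record with known apex times
#'
#' Draws interbeat intervals `RR_k = 60 / mean_hr_bpm + N(0,
#' rr_jitter_s^2)`, places one beat at each cumulative time and samples
#' the sum of the continuous beat waveforms on the requested grid. The
#' ground-truth apexes are the continuous beat centers, independent of the
#' sampling rate: the same seed produces the same truth at any `fs`.
#'
#' @param shape a [beat_shape()].
#' @param rhythm a [rhythm_spec()].
#' @return An [ecg_record()] with `truth_apexes` set.
#' @export
synth_ecg <- function(shape = beat_shape(), rhythm) {
  stopifnot(inherits(shape, "beat_shape"), inherits(rhythm, "rhythm_spec"))
  mean_rr <- 60 / rhythm$mean_hr_bpm
  n_max <- ceiling(rhythm$duration_s / mean_rr) + 10L
  rr <- with_seed(rhythm$seed,
                  mean_rr + stats::rnorm(n_max, 0, rhythm$rr_jitter_s))
  if (any(rr < shape$qrs_len_s))
    stop_parameter("an interbeat interval is shorter than the QRS length: beats overlap")
  apex <- 0.5 + cumsum(c(0, rr))
  apex <- apex[apex <= rhythm$duration_s - 0.5]
  n <- as.integer(round(rhythm$duration_s * rhythm$fs))
  t <- (seq_len(n) - 1) / rhythm$fs
  s <- numeric(n)
  span <- 0.55  # beat support: covers P and T tails
  for (a in apex) {
    i1 <- max(1L, as.integer(floor((a - span) * rhythm$fs)) + 1L)
    i2 <- min(n, as.integer(ceiling((a + span) * rhythm$fs)) + 1L)
    s[i1:i2] <- s[i1:i2] + beat_waveform(t[i1:i2] - a, shape)
  }
  rec <- ecg_record(s, rhythm$fs, truth_apexes = apex,
                    record_id = sprintf("synth-fs%g-seed%s", rhythm$fs, rhythm$seed))
  attr(rec, "shape") <- shape
  attr(rec, "rhythm") <- rhythm
  rec
}

#' Piecewise-linear triangular peak fixture
#'
#' A deterministic triangle whose apex is exactly representable: amplitude
#' rises at `up_slope` per sample to the apex and falls at `down_slope`
#' per sample back to zero, padded with zeros on both sides so the tangent
#' windows fit. On such a signal the tangent intersection recovers the
#' apex exactly, for any step shorter than the shorter flank.
#'
#' @param fs sampling rate in Hz (default 500).
#' @param apex_index 1-based index of the apex in the returned record; must
#'   leave room for the tangent windows (about `0.1 * fs` samples).
#' @param up_slope positive rise per sample.
#' @param down_slope negative fall per sample.
#' @param rise_len flank length in samples (default 20, preceded by zeros).
#' @param pad zero samples appended after the falling flank (default 100).
#' @return An [ecg_record()] with `truth_apexes` at the apex time.
#' @export
make_triangle_fixture <- function(fs = 500, apex_index = 121, up_slope = 2,
                                  down_slope = -1, rise_len = 20,
                                  pad = 100) {
  if (rise_len >= apex_index) stop_parameter("rise_len must fit before the apex")
  if (!(up_slope > 0 && down_slope < 0)) stop_parameter("slopes must be of opposite sign")
  amp <- up_slope * rise_len
  fall_len <- ceiling(amp / abs(down_slope))
  n <- apex_index + fall_len + pad
  i <- seq_len(n)
  s <- ifelse(i <= apex_index, pmax(0, amp + up_slope * (i - apex_index)),
              pmax(0, amp + down_slope * (i - apex_index)))
  ecg_record(s, fs, truth_apexes = (apex_index - 1) / fs, record_id = "triangle")
}
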