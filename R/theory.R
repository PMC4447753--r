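# Worst-case localization error of the tangent-intersection estimate when
# each of the four chord-defining samples is perturbed by at most +/- e.
#
# Geometry: the ascending chord runs through (n1, s1), (n2, s2) with
# n2 = n1 + delta, the descending chord through (n3, s3), (n4, s4) with
# n4 = n3 + delta, and the unperturbed tangents intersect at n_I with
# p = n_I - n2 and q = n4 - n_I. The canonical placement used here puts
# the chords symmetrically about the intersection, p = q = (L - delta)/2
# with L = n4 - n1 (the triangle fixture realizes exactly this layout).
#
# Perturbing (s1..s4) by (e1..e4), each +/- e, moves the intersection by
#
#   d = (-u p - e2 - v q + e4) / (D0 + u - v),
#   u = (e2 - e1)/delta,  v = (e4 - e3)/delta,  D0 = a_A - a_D,
#
# which is monotone in each e_i, so the maximum of |d| is attained at one
# of the 16 sign patterns. Maximizing symbolically: for positive d the
# ascending chord is always rotated flat (e1 = +e, e2 = -e), which both
# maximizes the numerator and minimizes the denominator, leaving three
# descending candidates (rotated steep, shifted up, rotated flat); the
# negative side is the mirror image with the slopes exchanged. The pure
# rotation candidate, 2 e (L - delta) / (delta (a_A - a_D)), is the
# classical worst case usually drawn for this bound (both chords pivoted
# about their midpoints); combined rotation-plus-shift patterns can exceed
# it, which is why the vertex maximum is the default model.

vertex_dplus <- function(e, a_A, a_D, p, q, delta) {
  d0 <- a_A - a_D
  r <- 2 * e / delta
  max(r * (p + q) / d0,                      # asc flat + desc steep (pure rotation)
      (r * p + 2 * e) / (d0 - r),            # asc flat + desc shifted up
      (r * (p - q) + 2 * e) / (d0 - 2 * r))  # asc flat + desc flat
}

#' Worst-case tangent-intersection error under bounded perturbation
#'
#' Closed-form maximum of the intersection displacement when each of the
#' four chord-defining samples may move by at most `±e`. `model =
#' "vertex"` (default) is the exact maximum over all 16 sign assignments;
#' `model = "rotation"` restricts the perturbation to pure chord
#' rotations (the configuration classically drawn as the worst case),
#' giving `2 e (L - delta) / (delta * (a_A - a_D))`.
#'
#' The bound shrinks as the step `delta` and chord span `L` grow, which is
#' why the step should be as large as the slope duration allows.
#'
#' Units are agnostic: with slopes per sample and `delta`, `L` in samples
#' the result is in samples; with per-second slopes and seconds it is in
#' seconds.
#'
#' @param e maximum per-sample perturbation (`E/2` for a noise component
#'   of peak-to-peak amplitude `E`).
#' @param a_A ascending tangent slope (> 0).
#' @param a_D descending tangent slope (< 0).
#' @param delta differentiation step (> 0).
#' @param L span `n4 - n1` between the outermost chord samples
#'   (`>= 2 * delta`).
#' @param model `"vertex"` or `"rotation"`.
#' @return Maximum localization error (same time unit as `delta`).
#' @export
worst_case_error <- function(e, a_A, a_D, delta, L, model = c("vertex", "rotation")) {
  model <- match.arg(model)
  if (!is_scalar_number(e) || e < 0) stop_parameter("e must be >= 0")
  if (!is_scalar_number(delta) || delta <= 0) stop_parameter("delta must be > 0")
  if (!is_scalar_number(L) || L < 2 * delta) stop_parameter("L must be >= 2 * delta")
  if (!(is_scalar_number(a_A) && is_scalar_number(a_D) && a_A > 0 && a_D < 0))
    stop_parameter("need a_A > 0 > a_D")
  if (e > 0 && 2 * e / delta >= min(a_A, -a_D))
    stop_parameter("perturbation too large: a perturbed tangent loses its sign")
  if (e == 0) return(0)
  if (model == "rotation") return(2 * e * (L - delta) / (delta * (a_A - a_D)))
  p <- (L - delta) / 2
  max(vertex_dplus(e, a_A, a_D, p, p, delta),
      vertex_dplus(e, -a_D, -a_A, p, p, delta))
}

#' Brute-force perturbation maximum (validation oracle)
#'
#' Enumerates all 16 sign assignments of `±e` on the four chord samples,
#' refits both chords through the perturbed points and recomputes the
#' intersection numerically via [intersect_tangents()]. Exists to certify
#' [worst_case_error()]; the two must agree to floating precision.
#'
#' @inheritParams worst_case_error
#' @return Maximum `|n_I' - n_I|` over the 16 assignments.
#' @export
worst_case_error_enum <- function(e, a_A, a_D, delta, L) {
  if (!is_scalar_number(L) || L < 2 * delta) stop_parameter("L must be >= 2 * delta")
  p <- (L - delta) / 2
  # canonical geometry: intersection at 0, chords on the tangent lines
  nx <- c(-p - delta, -p, p - delta, p)
  sx <- c(a_A * nx[1], a_A * nx[2], a_D * nx[3], a_D * nx[4])
  chord <- function(x1, y1, x2, y2) {
    a <- (y2 - y1) / (x2 - x1)
    list(a = a, b = y1 - a * x1)
  }
  worst <- 0
  for (mask in 0:15) {
    sg <- 2 * ((mask %/% c(1L, 2L, 4L, 8L)) %% 2L) - 1
    y <- sx + sg * e
    ca <- chord(nx[1], y[1], nx[2], y[2])
    cd <- chord(nx[3], y[3], nx[4], y[4])
    tp <- structure(list(a_A = ca$a, b_A = ca$b, a_D = cd$a, b_D = cd$b),
                    class = "tangent_pair")
    worst <- max(worst, abs(intersect_tangents(tp)))
  }
  worst
}

#' Trigger-jitter bound for Gaussian-noise-contaminated ECG
#'
#' Evaluates the worst-case localization error for a canonical QRS complex
#' whose ascending slope is `S = A / (Q/2)` (signal amplitude over half
#' the QRS duration) and whose descending slope is `-beta * S`, with the
#' per-sample perturbation tied to the noise level, `e = noise_sigma_rel *
#' A`. With the default 10% relative noise (a typical EMG noise level),
#' `beta = 1.13`, `Q = 80` ms, step 20 ms and chord span equal to `Q`,
#' this bounds the trigger jitter achievable by the tangent method; the
#' result is in seconds and independent of the sampling rate.
#'
#' @param noise_sigma_rel noise standard deviation as a fraction of the
#'   signal amplitude (default 0.10).
#' @param beta descending/ascending slope-magnitude ratio (default 1.13).
#' @param Q_s QRS duration in seconds (default 0.08).
#' @param delta_s differentiation step in seconds (default 0.02).
#' @param L_s chord span in seconds (default `Q_s`, the largest span whose
#'   end samples are still part of the QRS).
#' @param model passed to [worst_case_error()]; the classical form of this
#'   bound is the `"rotation"` case (default).
#' @return Bound on the trigger jitter in seconds.
#' @export
jitter_bound <- function(noise_sigma_rel = 0.10, beta = 1.13, Q_s = 0.08,
                         delta_s = 0.02, L_s = Q_s, model = "rotation") {
  if (!is_scalar_number(noise_sigma_rel) || noise_sigma_rel < 0)
    stop_parameter("noise_sigma_rel must be >= 0")
  if (noise_sigma_rel == 0) return(0)
  S <- 1 / (Q_s / 2)                      # slope for unit amplitude, per second
  worst_case_error(e = noise_sigma_rel, a_A = S, a_D = -beta * S,
                   delta = delta_s, L = L_s, model = model)
}
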