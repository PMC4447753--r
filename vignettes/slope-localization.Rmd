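---
title: "Precise QRS localization by tangent intersection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precise QRS localization by tangent intersection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slopeqrs)
```

## The problem

QRS detectors are good at finding heartbeats and bad at saying exactly
*when* they happened. For heart-rate-variability analysis, detection of
small transient heart-rate changes, and signal averaging of QRS complexes,
the fiducial point of each beat must be located with millisecond precision
— signal-averaging guidelines ask for a trigger jitter (the standard
deviation of the localization error across beats) below 1 ms. Grid-bound
estimators cannot do better than the sample period unless the record is
upsampled, which is exactly the step that low-power and real-time
applications cannot afford.

`slopeqrs` implements a post-processing localizer that takes *any*
detector's approximate beat locations and refines each to a sub-sample
apex estimate from just a handful of samples per beat.

## The slope algorithm

For a filtered signal $s$ and step $\Delta$ the step derivative is
$s'_\Delta(n) = s(n) - s(n-\Delta)$, the rise of a chord spanning
$\Delta$ samples. For each detection:

1. refine the detection to the local maximum $\hat p$ of $s$ in a window
   one expected QRS length $W$ wide;
2. find the maximum of $s'_\Delta$ in the $W$ samples up to $\hat p$ and
   its minimum in the $W + \Delta$ samples after it — the steepest
   ascending and descending chords of the R wave;
3. form the two chord lines $y_A = a_A n + b_A$, $y_D = a_D n + b_D$ and
   intersect them:
   $$n_I = \frac{b_D - b_A}{a_A - a_D}.$$

$n_I$ is in general not an integer: the apex estimate has sub-sample
precision, which is why the achievable jitter is set by the signal's
bandwidth and noise, not by the sampling grid. Because the chords span
$\Delta$ samples, spike artifacts shorter than $\Delta$ do not become the
selected extrema, and because a clipped R wave keeps the lower parts of
its flanks, the intersection also survives amplitude clipping — the two
failure modes that break simple local-maximum or single-sample-derivative
refinement.

### Parameters

* `delta_s` (default **0.02 s**): the differentiation step. The error
  bound below shrinks as $\Delta$ grows, so the step should be as long as
  possible — but no longer than a slope, or the chord leaves the flank.
  A QRS complex lasts about 0.08 s, each slope about 0.04 s; half a slope
  (20 ms) keeps a full chord on the flank even when clipping shortens it.
  On clean signals a larger step lowers the jitter further; a smaller one
  raises it.
* `qrs_len_s` (default **0.08 s**): the expected QRS duration $W$, which
  sizes the refinement and extremum-search windows.

Both are seconds and convert to at least one sample at any supported rate;
at 100 Hz the step is 2 samples and the method still resolves fractions of
the 10 ms sample period (the pooled jitter at 20 dB SNR stays below 1 ms,
see the acceptance figures).

### Numerical conventions

* Backward difference. The derivative convention keeps the ascending
  chord strictly left of the apex, so the two chords bracket it.
* Ties in the extremum searches go to the earliest index — deterministic,
  and symmetric with the backward difference on plateaus.
* Search windows: ascending extremum in $(\hat p - W,\ \hat p]$,
  descending in $(\hat p,\ \hat p + W + \Delta]$; the trailing window is
  one step longer because the backward difference reports a flank at its
  lower end.
* Degenerate beats (no positive derivative before the peak, none negative
  after it, parallel chords, or an intersection outside the chord span)
  are reported in a rejects table with a reason, never guessed at;
  downstream metrics count them as not localized.
* Merging. Detections whose refined peaks coincide are one beat. In
  addition, beats whose intersections fall within **one sample** of each
  other are merged: the tangent windows of two nearby detections capture
  the same pair of flanks, and two intersections inside one grid cell are
  indistinguishable estimates of the same apex. Without this rule a mock
  false positive 40–80 ms from a true beat survives as a duplicate that
  scores as well as the real beat under template matching and can never
  be rejected by a correlation threshold. One sample is the grid
  resolution, not a tunable threshold.
* Indices are 1-based (R convention) and sample $n$ corresponds to time
  $(n-1)/f_s$; all file interfaces carry times in seconds.

## Filtering and resampling

Baseline wander is removed with a linear-phase FIR high-pass built from a
Kaiser window of 1.016 s, cutoff 0.8 Hz, 30 dB side-lobe attenuation. The
filter length is forced odd so the group delay is an integer and can be
compensated exactly; the high-pass is the spectral inversion of a
unity-DC-gain low-pass, so DC is removed exactly rather than to within the
stopband ripple. The Kaiser shape parameter comes from the standard
attenuation relation (the design only states the attenuation; the
transition bandwidth is whatever the 1.016 s length implies — about
1.5 Hz — and is deliberately not re-tuned). One filter length at each edge
is a transient; records carry that span in `transient_s` and the region is
flagged, not deleted.

Resampling uses Kaiser-windowed sinc (band-limited) interpolation; when
downsampling, an anti-alias low-pass at $0.8 \cdot (f_{s,\mathrm{new}}/2)$
is applied first. Ground-truth apex times ride along unchanged — truth is
a property of the continuous signal, not of any grid.

## Template matching and the xcorr reference

The averaged-beat template is the pointwise mean of windows one median
interbeat interval long, centered on each location ("around the location"
is read as centered, matching the symmetric correlation search).
Correlation is Pearson's $r$ — scale- and offset-invariant, so electrode
gain does not matter. Rejecting locations with $r$ below a threshold
trades a tiny amount of sensitivity for a large gain in positive
predictive value; sweeping the threshold traces that curve. Both scoring
paths are provided: `post_none` scores detections at their original
indices, `post_slope` at the localized positions. Localization helps
twice: nearby false positives merge into the true beat, and the windows of
true beats align with the template so their scores concentrate near 1.

The two-pass cross-correlation localizer (`xcorr_localize`) is the
classical template-based reference: align each beat to the template within
half a template length (cross-correlation evaluated directly, shift by
shift, so its instrumented cost is the real per-beat cost), rebuild the
template from the adjusted locations, align again. Its precision is bound
by the grid, hence the `upsample_to` option; at 10 kHz it is the standard
recipe for constructing reference locations (`ground_truth_locations`).
Note one honest caveat established by the tests: with noisy records the
template itself carries noise, which shifts *all* aligned locations by a
common random offset that shrinks only as $1/\sqrt{n_\mathrm{beats}}$;
the beat-to-beat spread stays an order of magnitude smaller. On real
recordings, where no continuous-time truth exists, only the relative
component matters.

## Degradation harness

* **Clipping**: with $p_m$ the median and $p_M$ the 99.9th percentile of
  the amplitude, the threshold for clipping factor $cf$ is
  $ct = p_m + cf\,(p_M - p_m)$, an interpolation between the median and
  the practical signal ceiling; $cf = 1$ alters at most 0.1% of samples.
  Clipping is symmetric about the median by default, with a one-sided
  `saturate` mode for pure saturation artifacts. The linear interpolation
  percentile (R type 7) is used for determinism across implementations.
  Clipping by *factor* is deliberately not idempotent once more than 0.1%
  of samples clip (the percentile moves); re-applying the returned
  realized `clip_spec` is.
* **Noise**: zero-mean white Gaussian noise with variance
  $\overline{s^2} / 10^{\mathrm{SNR}/10}$, treating the noise already in
  the signal as negligible; seeded and bit-reproducible.
* **Mock false positives**: `round(f_i/100 · N)` uniform random indices
  appended and re-sorted, provenance kept. Mocks may land near true
  beats on purpose — handling those is the localization stage's job.

## Metrics

Detections match ground truth one-to-one within 40 ms (half a QRS
duration, the margin used by the signal-averaging guidelines), greedily by
increasing absolute error — deterministic, standard in beat-scoring
practice, and equivalent to optimal assignment for well-separated beats.
The signed error convention is detected − truth (positive = late). Across
records, the pooled trigger jitter is the $(n_i - 1)$-weighted pooled
standard deviation
$$\sigma_\mathrm{pooled} = \sqrt{\frac{\sum_i (n_i - 1)\,\sigma_i^2}
{\sum_i (n_i - 1)}},$$
the standard pooled estimator. Both mean absolute and mean signed errors
are reported; the absolute one is the headline localization-error figure.

## Worst-case error theory

Perturb each of the four chord-defining samples by at most $\pm e$. The
intersection displacement is monotone in each perturbation, so the
maximum is attained at one of the 16 sign patterns; maximizing
symbolically leaves three candidate configurations per direction
(`worst_case_error(model = "vertex")`), and the result is certified in
the tests against a brute-force oracle that refits the chords
numerically for all 16 patterns — the oracle, not the formula, is the
source of truth. The classically drawn worst case — both chords pivoted
about their midpoints — is available as `model = "rotation"`:
$$e'_I = \frac{2e\,(L - \Delta)}{\Delta\,(a_A - a_D)},$$
with $L$ the span between the outermost chord samples. On the canonical
triangle chords ($a_A = 2$, $a_D = -1$, $\Delta = 10$, $L = 30$, $e = 2$)
rotation gives $8/3$ while the full vertex maximum is $40/13$: a rotation
*plus* a uniform shift of the opposite chord moves the intersection
further, which is easy to miss when reasoning from the usual figure. Both
forms shrink as $\Delta$ grows at fixed $L$ (the design rationale for the
20 ms step); the rotation form depends only on $(L-\Delta)/\Delta$, so
scaling $\Delta$ and $L$ together leaves it unchanged.

`jitter_bound()` evaluates the rotation form for a canonical beat with
ascending slope $S = A/(Q/2)$, descending slope $-\beta S$, chord span
$L = Q$ and $e$ tied to a Gaussian noise level of 10% of the amplitude
(a typical EMG noise figure), with $\beta = 1.13$, $Q = 0.08$ s,
$\Delta = 0.02$ s by default — about 11.3 ms, an upper bound that the
simulated jitter under the same noise stays far below (the bound takes
every sample at its worst simultaneously).

## The synthetic generator

Every quantitative claim in the package is exercised on synthetic ECG
with exactly known continuous-time apexes. One beat is a sum of smooth
bumps: a piecewise Gaussian R wave with left/right standard deviations
$\sigma_L = \beta_t \sigma_R$ — so the descending/ascending
maximum-slope ratio is exactly the target $\beta_t$ — scaled so the R
wave spans the QRS duration at the 5% level; small Q and S dips; and P
and T waves (amplitudes 0.12 and 0.25 of the R height at −0.22 s and
+0.30 s, typical of lead II morphology). Defaults: QRS 0.08 s,
$\beta_t = 1.13$ (a representative median slope ratio in healthy
adults; measured ratios on generated records come out within 10% of the
target), heart rate 60 bpm with independent Gaussian RR perturbations of
0.05 s. The truth apex is the R-bump center; the neighboring bumps move
the true maximum by nanoseconds at these defaults, far below every
tolerance used.

What the generator does *not* model: arrhythmia and morphology change
(the template matcher assumes monomorphic beats by design), respiratory
modulation, physiologic HRV structure, powerline interference, and
non-Gaussian motion artifacts. Passing tests therefore demonstrate the
algorithmic properties — exactness on idealized peaks, rate invariance,
noise and clipping robustness, false-positive rejection — under a clean
monomorphic model, not clinical performance on pathological recordings.

A piecewise-linear triangle fixture (`make_triangle_fixture`) provides
the worked example for all tangent arithmetic: on any sampled triangle
the chords lie exactly on the flanks, so the intersection recovers the
apex to floating precision, for any asymmetry, any rate, and any apex —
on-grid or between samples.

## Problem sizes

The test suite runs every end-to-end property on 30–120 s records
(60–120 beats) at 100–1000 Hz, sizes at which every stochastic assertion
is already stable across seeds. `scripts/acceptance.R` recomputes the
headline figures at the full protocol scale — 10-minute records
(≈600 beats per rate, three rates for the pooled jitter) — and writes
them as JSON; see the README for how to run it.

## Known limitations

* Single-lead only; no multi-lead fusion or vectorcardiographic alignment.
* The naive detector included is deliberately simple plumbing so the
  localizer can be exercised end-to-end; it is not a competitive QRS
  detector and the localizer is meant to run behind any production
  detector.
* WFDB files are not read directly; waveforms come and go as two-column
  CSV (time, amplitude), the canonical interchange format here.
* Under combined severe clipping and 10 dB noise the mean absolute error
  on synthetic records slightly exceeds 2 ms (≈2.4 ms); the sub-2 ms
  regime is the moderate grid in which at most one artifact is severe.
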