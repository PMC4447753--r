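# slopeqrs

Precise, sampling-rate-independent R-peak localization for single-lead
ECG, as a post-processing step behind any QRS detector.

## Why

Detecting heartbeats is easy; timing them precisely is not. Heart-rate
-variability analysis, detection of small transient heart-rate changes,
and signal averaging for high-resolution QRS morphology all need the
R-wave fiducial point with millisecond precision — signal-averaging
guidelines ask for a trigger jitter (standard deviation of the
localization error) below 1 ms. Template/cross-correlation localizers
reach that only on upsampled high-resolution recordings and cost
*O*(*n*²) per beat; threshold and local-maximum methods break under
noise and amplitude clipping, both routine in ambulatory and sleep
recordings.

## The method

The ECG is differentiated with a step Δ rather than sample-to-sample:
`s'_Δ(n) = s(n) − s(n−Δ)`, the rise of a chord Δ samples wide. Around
each detector output, the refined peak `p̂` is the local signal maximum
in one QRS length `W`; the maximum of `s'_Δ` in the `W` samples before
`p̂` and its minimum in the `W + Δ` samples after give the steepest
ascending and descending chords `y_A = a_A n + b_A`, `y_D = a_D n + b_D`,
and the apex estimate is their intersection

    n_I = (b_D − b_A) / (a_A − a_D)

— in general not an integer, so the precision is set by the signal's
bandwidth and noise rather than by the sampling grid. With Δ ≈ half a
slope (20 ms), short spike artifacts never become the selected extrema
and a clipped R wave still presents full chords on its remaining flanks.
The per-beat cost is *O*(W + Δ).

The package also provides: the companion template matcher
(averaged-beat template, Pearson scores, threshold rejection of false
positives), the classical two-pass cross-correlation localizer as the
reference method and ground-truth constructor (at 10 kHz), a degradation
harness (amplitude clipping by factor, Gaussian noise at a target SNR,
mock false-positive injection), matching/jitter/sensitivity/PPV metrics,
a synthetic ECG generator with exactly known continuous-time apexes, and
the closed-form worst-case localization-error bound certified against a
brute-force oracle.

## Worked example

```r
library(slopeqrs)

rec   <- synth_ecg(beat_shape(beta_target = 1.13),
                   rhythm_spec(duration_s = 60, mean_hr_bpm = 60,
                               fs = 250, seed = 1))
noisy <- add_noise(rec, snr_db = 20, seed = 2)
pl    <- localize_pipeline(noisy)     # baseline filter -> detect -> localize
pl$localized
#> <localized_beats: 59 beats, 0 rejects>
head(pl$localized$beats[, c("source_index", "n_I", "t_I", "a_A", "a_D", "beta")], 3)
#>   source_index      n_I       t_I       a_A        a_D     beta
#> 1          128 125.8204 0.4992817 0.1303923 -0.1394781 1.069681
#> 2          370 368.3112 1.4692447 0.1203336 -0.1405543 1.168039
#> 3          622 620.3356 2.4773422 0.1346153 -0.1463040 1.086831

m <- match_beats(rec$truth_apexes, pl$localized$beats$t_I)
m
#> <match_result: TP 59, FP 0, FN 0 (margin 40 ms)>
trigger_jitter(m$pairs$error)
#> <jitter_summary: pooled sigma 0.557 ms, mean |error| 0.515 ms over 1 records>
```

Every beat of a 250 Hz record (4 ms sample period) is localized with a
fractional-sample apex (`n_I`), a jitter of 0.56 ms and a mean absolute
error of 0.51 ms against the generator's continuous-time truth — an
order of magnitude below the grid. `beta` is the per-beat
descending/ascending slope-magnitude ratio; `a_A`, `a_D` are the fitted
tangent slopes (amplitude per sample). The worst-case theory gives the
matching upper bound:

```r
jitter_bound()        # canonical beat, 10% Gaussian noise, 20 ms step
#> [1] 0.01126761      # seconds, ~11.3 ms: every sample at its worst at once
```

A command-line front end wrapping the same functions (subcommands
`simulate`, `localize`, `xcorr`, `degrade`, `evaluate`, `bound`) is
installed at `inst/cli/slopeqrs.R`; waveforms travel as two-column CSV
`(time_s, amplitude)`.

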