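Package: slopeqrs
Title: Sub-Sample QRS Localization by Tangent Intersection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Post-processing of single-lead ECG QRS detections for precise,
    sampling-rate-independent R-peak localization. Implements the low-complexity
    slope algorithm (step differentiation, tangent fitting to the R-wave slopes
    and tangent intersection with sub-sample precision), template-matching
    false-positive rejection, a two-pass cross-correlation reference localizer,
    a controlled degradation harness (amplitude clipping, additive Gaussian
    noise, mock false positives), trigger-jitter and localization-error
    metrics, a synthetic ECG generator with exactly known apex times, and the
    closed-form worst-case localization-error bound with its brute-force
    validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
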