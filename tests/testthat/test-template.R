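test_that("median beat length follows its definition", {
  expect_equal(median_beat_length(c(0, 500, 1000, 1600)), 500L)
  expect_equal(median_beat_length(c(0, 400)), 400L)
  expect_error_class(median_beat_length(100), "slopeqrs_insufficient_data_error")
})

# helper: record of identical Gaussian beats at known sample locations
beat_train <- function(locs, fs = 500, n = 6000, width = 0.01, amp = 1) {
  t <- (seq_len(n) - 1) / fs
  s <- numeric(n)
  for (l in locs) s <- s + amp * exp(-(t - (l - 1) / fs)^2 / (2 * width^2))
  ecg_record(s, fs)
}

test_that("template averaging reproduces identical beats and cancels noise", {
  locs <- c(1000, 2000, 3000, 4000, 5000)
  rec <- beat_train(locs)
  tpl <- build_template(rec, locs, B = 400)
  expect_equal(tpl$n_beats_used, 5)
  one <- rec$samples[(1000 - 200):(1000 + 199)]
  expect_equal(tpl$template, one, tolerance = 1e-12)

  # one beat the negation of the other
  rec2 <- rec
  rec2$samples <- rec$samples * rep(c(1, -1), c(1500, 4500))
  tpl2 <- build_template(rec2, c(1000, 2000), B = 400)
  expect_lt(max(abs(tpl2$template)), 1e-9)

  # windows truncated at the record edge are excluded and counted
  tpl3 <- build_template(rec, c(100, locs), B = 400)
  expect_equal(tpl3$n_beats_used, 5)
  expect_equal(tpl3$n_excluded, 1)
  expect_error_class(build_template(rec, 100, B = 400),
                     "slopeqrs_insufficient_data_error")

  # residual template noise variance shrinks like 1/n_beats_used
  resid_var <- function(n_beats, seed) {
    locs <- seq(1000, by = 1000, length.out = n_beats)
    rec <- beat_train(locs, n = 1000 * (n_beats + 1))
    noisy <- add_noise(rec, 10, seed = seed)
    clean <- build_template(rec, locs, B = 400)$template
    mean((build_template(noisy, locs, B = 400)$template - clean)^2)
  }
  v4 <- mean(vapply(1:12, function(s) resid_var(4, s), numeric(1)))
  v16 <- mean(vapply(1:12, function(s) resid_var(16, s + 100), numeric(1)))
  expect_equal(v4 / v16, 4, tolerance = 0.35)
})

test_that("beat scoring is a Pearson correlation with edge handling", {
  locs <- c(1000, 2000, 3000)
  rec <- beat_train(locs)
  tpl <- build_template(rec, locs, B = 400)
  sc <- score_beats(rec, 2000, tpl)
  expect_equal(sc$r, 1, tolerance = 1e-9)

  neg <- rec; neg$samples <- -neg$samples
  expect_equal(score_beats(neg, 2000, tpl)$r, -1, tolerance = 1e-9)

  # affine amplitude transform leaves scores unchanged
  aff <- rec; aff$samples <- 3.2 * rec$samples - 7
  expect_equal(score_beats(aff, locs, tpl)$r, score_beats(rec, locs, tpl)$r,
               tolerance = 1e-9)

  # constant window -> r = 0, flagged
  flat <- ecg_record(c(numeric(3000), rec$samples[1:3000]), 500)
  sc0 <- score_beats(flat, 1000, tpl)
  expect_equal(sc0$r, 0)
  expect_true(sc0$zero_variance)

  # edge-truncated window scored on the overlap
  sce <- score_beats(rec, 100, tpl)
  expect_lt(sce$overlap, 400)

  # independent noise scores near zero on average
  rs <- vapply(1:100, function(s) {
    noise <- ecg_record(with_seed_test(s, stats::rnorm(400)), 500)
    score_beats(noise, 200, tpl)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("threshold rejection keeps order and is monotone in T", {
  sc <- data.frame(location = 1:3, r = c(0.99, 0.2, 0.95))
  kept <- reject_by_threshold(sc, 0.9)
  expect_equal(kept$location, c(1, 3))
  expect_equal(nrow(reject_by_threshold(sc, -1)), 3)
  expect_error_class(reject_by_threshold(sc, 1.1), "slopeqrs_parameter_error")

  set.seed(3)
  sc2 <- data.frame(location = 1:50, r = runif(50, -1, 1))
  counts <- vapply(seq(-1, 1, by = 0.1),
                   function(T) nrow(reject_by_threshold(sc2, T)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("xcorr localization undoes a constant offset and refines with passes", {
  locs <- seq(1000, 8000, by = 1000)
  rec <- beat_train(locs, n = 9000)
  det <- qrs_detections(locs + 7L, 500)     # all detections late by 7 samples
  xc <- xcorr_localize(rec, det)
  expect_equal(xc$locations, as.integer(locs))

  # with upsampling the grid is 0.1 original samples
  xcu <- xcorr_localize(rec, qrs_detections(locs, 500), upsample_to = 5000)
  expect_equal(xcu$fs, 5000)
  expect_lt(max(abs(xcu$times - (locs - 1) / 500)), 0.1 / 500 + 1e-9)

  expect_error_class(xcorr_localize(rec, qrs_detections(1000L, 500)),
                     "slopeqrs_insufficient_data_error")
})

test_that("slope and xcorr agree on clean synthetic records", {
  rec <- synth_record(20, fs = 500, seed = 31)
  filt <- remove_baseline(rec)
  det <- naive_detect(filt)
  lb <- slope_localize(filt, det)
  xc <- xcorr_localize(filt, det)
  m <- match_beats(lb$beats$t_I, xc$times, margin_s = 0.05)
  expect_equal(m$n_tp, nrow(lb$beats))
  expect_lt(max(abs(m$pairs$error)), 1 / 500 + 1e-9)

  # the second pass never increases the mean error on clean records
  e1 <- match_beats(rec$truth_apexes, xc$times_pass1)$pairs$error
  e2 <- match_beats(rec$truth_apexes, xc$times)$pairs$error
  expect_lte(mean(abs(e2)), mean(abs(e1)) + 1e-12)
})

test_that("upsampled xcorr ground truth tracks the generator truth", {
  rec <- synth_record(12, fs = 500, seed = 5)
  filt <- remove_baseline(rec)
  det <- naive_detect(filt)
  gt <- ground_truth_locations(filt, det)
  m <- match_beats(rec$truth_apexes, gt)
  expect_equal(m$n_tp, length(rec$truth_apexes))
  # noiseless: absolute accuracy well under a quarter millisecond
  expect_lt(max(abs(m$pairs$error)), 0.25e-3)

  # at 20 dB the beat-to-beat spread stays small even though template
  # noise shifts the whole record by a common offset
  noisy <- add_noise(rec, 20, seed = 51)
  filtn <- remove_baseline(noisy)
  gtn <- ground_truth_locations(filtn, naive_detect(filtn))
  en <- match_beats(rec$truth_apexes, gtn)$pairs$error
  expect_lt(stats::sd(en), 0.5e-3)
})

test_that("templates survive a CSV round trip", {
  locs <- c(1000, 2000, 3000)
  rec <- beat_train(locs)
  tpl <- build_template(rec, locs, B = 256)
  p <- withr::local_tempfile(fileext = ".csv")
  write_template_csv(tpl, p)
  back <- read_template_csv(p)
  expect_equal(back$template, tpl$template)
  expect_equal(back$B, tpl$B)
  expect_equal(back$fs, tpl$fs)
})
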