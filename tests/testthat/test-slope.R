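# The canonical triangle has its apex at sample 121 with flanks +2 and -1
# per sample; with delta = 10 samples and W = 40 the derivative plateaus
# put the ascending chord on (101, 111) and the descending chord on
# (121, 131), so all tangent quantities below follow directly from the
# fixture definition.

test_that("step differentiation matches its definition", {
  expect_error_class(slope_differentiate(1:50, 0), "slopeqrs_parameter_error")

  d <- slope_differentiate(rep(3, 100), 10)
  expect_true(all(is.na(d[1:10])))
  expect_true(all(d[-(1:10)] == 0))

  d <- slope_differentiate(2 * (0:99), 10)
  expect_true(all(d[-(1:10)] == 20))

  tri <- tri_fixture()
  d <- slope_differentiate(tri, 10)
  # sample 126 sits 5 past the apex: s(126) - s(116) = 35 - 30
  expect_equal(d[126], 5)
  expect_equal(d[111], 20)   # full ascending chord
  expect_equal(d[131], -10)  # full descending chord
})

test_that("local-max refinement clips windows and breaks ties early", {
  tri <- tri_fixture()
  expect_equal(find_local_max(tri, 116, 40), 121L)
  expect_equal(find_local_max(tri, 3, 40), 1L)   # truncated at the start
  plateau <- ecg_record(c(0, 1, 5, 5, 1, 0), 100)
  expect_equal(find_local_max(plateau, 3, 6), 3L)
  expect_error_class(find_local_max(tri, 1000, 10), "slopeqrs_boundary_error")
})

test_that("tangent fitting recovers the chords of the triangle", {
  tri <- tri_fixture()
  tp <- fit_tangents(tri, 121)
  expect_equal(tp$n1, 101); expect_equal(tp$n2, 111)
  expect_equal(tp$n3, 121); expect_equal(tp$n4, 131)
  expect_equal(tp$a_A, 2);  expect_equal(tp$b_A, 20 - 2 * 111)
  expect_equal(tp$a_D, -1); expect_equal(tp$b_D, 30 + 131)
  expect_equal(tp$L, 30)
  expect_equal(intersect_tangents(tp), 121)

  sym <- make_triangle_fixture(fs = 500, apex_index = 121, up_slope = 1.5,
                               down_slope = -1.5, rise_len = 30)
  tps <- fit_tangents(sym, 121)
  expect_equal(tps$a_A, -tps$a_D)
  expect_equal(intersect_tangents(tps), 121)

  ramp <- ecg_record(seq_len(400), 500)
  expect_error_class(fit_tangents(ramp, 200), "slopeqrs_degenerate_error")
  expect_error_class(fit_tangents(tri, 30), "slopeqrs_boundary_error")

  tp$a_D <- tp$a_A
  expect_error_class(intersect_tangents(tp), "slopeqrs_degenerate_error")
})

test_that("tangent intersection is exact on piecewise-linear peaks", {
  # grid-aligned apexes, random asymmetries and rates
  set.seed(42)
  for (i in 1:25) {
    fs <- sample(c(250, 500, 1000), 1)
    up <- runif(1, 0.3, 5)
    dn <- -runif(1, 0.3, 5)
    rise <- sample(15:60, 1)
    apex <- 150L
    tri <- make_triangle_fixture(fs, apex, up, dn, rise_len = rise, pad = 150)
    lb <- slope_localize(tri, qrs_detections(apex, fs))
    expect_equal(nrow(lb$beats), 1)
    expect_lt(abs(lb$beats$n_I - apex), 1e-9)
  }

  # off-grid apex: sample a continuous triangle whose apex falls between
  # samples; the chords still lie on the flank lines, so the intersection
  # is the continuous apex
  for (apex_frac in c(150.3, 150.5, 149.82)) {
    i <- seq_len(400)
    up <- 2; dn <- -1.3; amp <- 55
    s <- pmax(0, pmin(amp + up * (i - apex_frac), amp + dn * (i - apex_frac)))
    tri <- ecg_record(s, 500)
    lb <- slope_localize(tri, qrs_detections(150L, 500))
    expect_lt(abs(lb$beats$n_I - apex_frac), 1e-9)
  }
})

test_that("clipping the top of a peak does not move the intersection", {
  # QRS-sized triangle (flanks ~12 samples after clipping, still >= delta)
  tri <- make_triangle_fixture(500, 150, 2, -2, rise_len = 20, pad = 150)
  clipped <- tri
  clipped$samples <- pmin(clipped$samples, 0.6 * 40)  # top 40% flattened
  lb <- slope_localize(clipped, qrs_detections(150L, 500))
  expect_lt(abs(lb$beats$n_I - 150), 1e-9)
})

test_that("localize merges coincident beats and reports rejects", {
  tri <- tri_fixture()
  lb <- slope_localize(tri, qrs_detections(c(116L, 121L), 500))
  expect_equal(nrow(lb$beats), 1)            # merged at the refined peak
  expect_equal(lb$beats$n_merged, 2L)
  expect_equal(lb$beats$beta, 0.5)           # |a_D| / a_A = 1/2

  empty <- slope_localize(tri, qrs_detections(integer(0), 500))
  expect_equal(nrow(empty$beats), 0)

  # a detection in the zero pad has no usable slopes -> reported reject
  lb2 <- slope_localize(tri, qrs_detections(c(121L, 200L), 500))
  expect_equal(nrow(lb2$beats), 1)
  expect_equal(nrow(lb2$rejects), 1)
  expect_match(lb2$rejects$reason, "derivative|intersection")
})

test_that("localization error stays below one sample on clean synthetic ECG", {
  rec <- synth_record(30, fs = 500, seed = 21)
  pl <- localize_pipeline(rec)
  m <- match_beats(rec$truth_apexes, pl$localized$beats$t_I)
  expect_equal(m$n_tp, length(rec$truth_apexes))
  expect_lt(stats::median(abs(m$pairs$error)), 1 / 500)
})

test_that("localized output CSV carries beats and reject reasons", {
  tri <- tri_fixture()
  lb <- slope_localize(tri, qrs_detections(c(121L, 200L), 500))
  p <- withr::local_tempfile(fileext = ".csv")
  write_localized_csv(lb, p)
  out <- utils::read.csv(p)
  expect_equal(nrow(out), 2)
  expect_equal(out$status[1], "ok")
  expect_equal(out$n_I_samples[1], 121)
  expect_true(is.na(out$n_I_samples[2]))
})

test_that("naive detection finds beats and honors the refractory period", {
  flat <- ecg_record(numeric(5000), 500)
  expect_length(naive_detect(flat)$indices, 0)

  rec <- synth_record(12, fs = 500, seed = 8)
  noisy <- add_noise(rec, 20, seed = 80)
  det <- naive_detect(remove_baseline(noisy))
  expect_equal(length(det$indices), length(rec$truth_apexes))
  offs <- vapply((det$indices - 1) / 500,
                 function(td) min(abs(rec$truth_apexes - td)), numeric(1))
  expect_lt(max(offs), 0.040)

  # two peaks 0.1 s apart: the second falls inside the refractory period
  t <- (0:2499) / 500
  two <- ecg_record(exp(-(t - 2)^2 / (2 * 0.01^2)) +
                    exp(-(t - 2.1)^2 / (2 * 0.01^2)), 500)
  expect_length(naive_detect(two)$indices, 1)
})
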