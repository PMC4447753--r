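# Shared fixtures. Records are generated in code (no stored data) and
# cached across test files, keyed by their parameters.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Canonical triangle: rise +2/sample for 20 samples, fall -1/sample, apex
# amplitude 40. Zero-padded so the default tangent windows fit; apex at
# sample 121 (1-based).
tri_fixture <- function() make_triangle_fixture(fs = 500, apex_index = 121,
                                                up_slope = 2, down_slope = -1,
                                                rise_len = 20, pad = 100)

# Synthetic test records (clean; degrade in the test that needs it).
synth_record <- function(duration_s = 60, fs = 500, seed = 1,
                         beta = 1.13, rr_jitter = 0.05) {
  key <- sprintf("synth_%g_%g_%d_%g_%g", duration_s, fs, seed, beta, rr_jitter)
  cached(key, synth_ecg(beat_shape(beta_target = beta),
                        rhythm_spec(duration_s, 60, rr_jitter, fs = fs, seed = seed)))
}

# Fit a straight line exponent on log-log data.
loglog_slope <- function(x, y) unname(stats::coef(stats::lm(log(y) ~ log(x)))[2])

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}

# run expr under a local seed without disturbing the global stream
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
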