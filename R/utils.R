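# Internal helpers shared across modules.

# Classed errors so callers can distinguish user errors from degenerate-signal
# conditions (which localize() turns into reject rows rather than failures).
stop_classed <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "slopeqrs_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_parameter    <- function(msg) stop_classed("slopeqrs_parameter_error", msg)
stop_parse        <- function(msg) stop_classed("slopeqrs_parse_error", msg)
stop_sampling     <- function(msg) stop_classed("slopeqrs_sampling_error", msg)
stop_length       <- function(msg) stop_classed("slopeqrs_length_error", msg)
stop_boundary     <- function(msg) stop_classed("slopeqrs_boundary_error", msg)
stop_degenerate   <- function(msg) stop_classed("slopeqrs_degenerate_error", msg)
stop_insufficient <- function(msg) stop_classed("slopeqrs_insufficient_data_error", msg)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. `seed = NULL` leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# normalized sinc
sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Kaiser shape parameter for a given stopband attenuation (dB), standard
# empirical design relation.
kaiser_beta <- function(atten_db) {
  if (atten_db > 50) 0.1102 * (atten_db - 8.7)
  else if (atten_db >= 21) 0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  else 0
}

# Kaiser window value at normalized positions u in [-1, 1].
kaiser_val <- function(u, beta) {
  u <- pmin(pmax(u, -1), 1)
  besselI(beta * sqrt(pmax(0, 1 - u^2)), 0) / besselI(beta, 0)
}
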