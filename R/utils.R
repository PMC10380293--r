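# Internal helpers: classed conditions, seeded evaluation, small numerics.

# Signal a classed error so callers (and tests) can distinguish failure modes
# without string matching. `class` is the specific condition class, e.g.
# "fretstab_invalid_input".
fs_stop <- function(message, class) {
  stop(structure(
    class = c(class, "fretstab_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stop_invalid    <- function(msg) fs_stop(msg, "fretstab_invalid_input")
stop_degenerate <- function(msg) fs_stop(msg, "fretstab_degenerate_data")
stop_fit        <- function(msg) fs_stop(msg, "fretstab_fit_failure")
stop_missing_control <- function(msg) fs_stop(msg, "fretstab_missing_control")
stop_insufficient <- function(msg) fs_stop(msg, "fretstab_insufficient_data")
stop_domain     <- function(msg) fs_stop(msg, "fretstab_domain_error")
stop_estimation <- function(msg) fs_stop(msg, "fretstab_estimation_failure")
stop_schema     <- function(msg) fs_stop(msg, "fretstab_schema_error")

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All stochastic entry points route through this so that a
# seed argument never leaks into (or depends on) the global RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

# log(mean(exp(x))) without overflow.
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# Linear interpolation of the abscissa where `y` first crosses `target`,
# scanning in the given order. Returns NA when there is no crossing.
interp_crossing <- function(x, y, target) {
  for (i in seq_len(length(x) - 1L)) {
    y0 <- y[i]; y1 <- y[i + 1L]
    if ((y0 - target) * (y1 - target) <= 0 && y0 != y1) {
      return(x[i] + (target - y0) * (x[i + 1L] - x[i]) / (y1 - y0))
    }
  }
  NA_real_
}

# Savitzky-Golay style first derivative: local quadratic fit over a sliding
# window of odd length `w` on a (possibly non-uniform) grid. Endpoints reuse
# the nearest full window. Returns dy/dx at every x.
local_quadratic_derivative <- function(x, y, w) {
  n <- length(x)
  stopifnot(w %% 2L == 1L, w >= 5L, w < n)
  h <- (w - 1L) %/% 2L
  d <- numeric(n)
  for (i in seq_len(n)) {
    c0 <- min(max(i, h + 1L), n - h)
    idx <- (c0 - h):(c0 + h)
    xs <- x[idx] - x[i]
    fit <- stats::lm.fit(cbind(1, xs, xs^2), y[idx])
    d[i] <- fit$coefficients[2L]
  }
  d
}
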