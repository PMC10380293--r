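# Chemical (urea) denaturation: logistic midpoint fits of intrinsic
# tryptophan fluorescence, including biphasic three-state profiles handled
# by two-segment fitting.

#' Denaturation curve container
#'
#' @param urea Denaturant concentrations (M), nonnegative ascending.
#' @param intensity Fluorescence values aligned with `urea` (normalised or
#'   raw; see `normalize` in [fit_cm()]).
#' @param sample_id,replicate Labels.
#' @return Object of class `denaturation_curve`.
#' @export
denaturation_curve <- function(urea, intensity, sample_id = "sample",
                               replicate = 1L) {
  if (length(urea) != length(intensity))
    stop_invalid("urea and intensity must align")
  if (any(urea < 0)) stop_invalid("urea concentrations must be >= 0")
  if (any(diff(urea) < 0)) stop_invalid("urea concentrations must be ascending")
  if (any(!is.finite(intensity))) stop_invalid("intensities must be finite")
  structure(
    list(sample_id = sample_id, replicate = as.integer(replicate),
         urea = as.numeric(urea), intensity = as.numeric(intensity)),
    class = "denaturation_curve"
  )
}

#' Logistic denaturation model
#'
#' `y = a2 + (a1 - a2) / (1 + (x/x0)^p)`: `a1` is the initial (native)
#' value, `a2` the final (denatured) value, `x0` the midpoint (`C_m`) and
#' `p` the power. At `x = 0` the model returns `a1` exactly (the `p > 0`
#' limit), avoiding the `0^p` singularity.
#'
#' @param x Denaturant concentrations, M.
#' @param a1,a2 Initial and final values.
#' @param x0 Midpoint, M (> 0).
#' @param p Power.
#' @return Model values, same length as `x`.
#' @export
logistic_denaturation_model <- function(x, a1, a2, x0, p) {
  if (x0 <= 0) stop_domain("x0 must be > 0")
  y <- numeric(length(x))
  zero <- x == 0
  y[zero] <- a1
  y[!zero] <- a2 + (a1 - a2) / (1 + (x[!zero] / x0)^p)
  y
}

#' Denaturation midpoint (Cm) fit
#'
#' Four-parameter nonlinear least squares of
#' [logistic_denaturation_model()] against a denaturation curve; the fitted
#' midpoint `x0` is the denaturation midpoint `C_m` and its standard error
#' is the standard error of the fit.
#'
#' @param curve A [denaturation_curve()] with >= 6 points bracketing the
#'   transition (both plateaus represented).
#' @param normalize Min-max rescale intensities before fitting (default
#'   TRUE, matching normalised-fluorescence workups); the midpoint and
#'   power are invariant under this affine transform.
#' @return Object of class `logistic_fit`: `a1`, `a2`, `x0` (= `cm`), `p`,
#'   per-parameter standard errors, `residual_norm`, `n_points`, `$fit`.
#' @export
fit_cm <- function(curve, normalize = TRUE) {
  stopifnot(inherits(curve, "denaturation_curve"))
  x <- curve$urea; y <- curve$intensity
  if (length(x) < 6) stop_invalid("need >= 6 points to fit Cm")
  if (stats::sd(y) < 1e-12 * max(abs(y), 1))
    stop_degenerate("denaturation curve is constant")
  if (normalize) {
    rng <- range(y)
    y <- (y - rng[1L]) / (rng[2L] - rng[1L])
  }
  a1_0 <- mean(y[seq_len(max(1L, floor(length(y) * 0.15)))])
  a2_0 <- mean(y[seq.int(ceiling(length(y) * 0.85), length(y))])
  x0_0 <- interp_crossing(x, y, (a1_0 + a2_0) / 2)
  if (!is.finite(x0_0) || x0_0 <= 0) x0_0 <- stats::median(x[x > 0])
  fit <- lm_nls(function(par) logistic_denaturation_model(x, par[1L],
                                                          par[2L], par[3L],
                                                          par[4L]),
                start = c(a1_0, a2_0, x0_0, 5), y = y,
                lower = c(-Inf, -Inf, 1e-6, -200),
                upper = c(Inf, Inf, max(x) * 10, 200))
  structure(
    list(sample_id = curve$sample_id,
         a1 = fit$par[1L],
         a2 = fit$par[2L],
         x0 = fit$par[3L],
         p = fit$par[4L],
         cm = fit$par[3L],
         a1_stderr = fit$stderr[1L],
         a2_stderr = fit$stderr[2L],
         x0_stderr = fit$stderr[3L],
         p_stderr = fit$stderr[4L],
         residual_norm = sqrt(fit$ssr),
         n_points = length(x),
         fit = fit),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Denaturation fit (%s): Cm = %.4g +/- %.3g M, p = %.3g, plateaus %.3g -> %.3g (n = %d)\n",
              x$sample_id, x$cm, x$x0_stderr, x$p, x$a1, x$a2, x$n_points))
  invisible(x)
}

#' Three-state (biphasic) denaturation fit
#'
#' Splits a biphasic denaturation profile at `split_point` and fits
#' [fit_cm()] to each segment, yielding the two midpoints `C_m1 < C_m2`.
#' With `split_point = NULL` the split is chosen automatically: the urea
#' concentration at which the smoothed |dy/dx| is minimal between the two
#' steepest-descent regions of the curve.
#'
#' @param curve A [denaturation_curve()].
#' @param split_point Split concentration (M) inside the x-range, or NULL
#'   for automatic selection.
#' @param normalize Passed to the per-segment [fit_cm()] calls.
#' @return Object of class `three_state_result`: `split_point`, `first`,
#'   `second` (both `logistic_fit`), `cm1`, `cm2`.
#' @export
fit_three_state <- function(curve, split_point = NULL, normalize = TRUE) {
  stopifnot(inherits(curve, "denaturation_curve"))
  x <- curve$urea; y <- curve$intensity
  if (!is.null(split_point)) {
    if (split_point <= min(x) || split_point >= max(x))
      stop_invalid("split_point lies outside the denaturant range")
  } else {
    w <- min(7L, (length(x) - 1L) %/% 2L * 2L - 1L)
    if (w < 5L) stop_insufficient("too few points for automatic splitting")
    d <- local_quadratic_derivative(x, y, w)
    # Two steepest-descent regions = two most negative, well-separated
    # derivative minima; split where |dy/dx| is minimal between them.
    n <- length(d)
    mins <- which(d[-c(1L, n)] < d[-c(n - 1L, n)] &
                    d[-c(1L, n)] <= d[-c(1L, 2L)]) + 1L
    mins <- mins[order(d[mins])]
    if (length(mins) < 2)
      stop_insufficient("could not locate two transitions for auto split")
    i1 <- mins[1L]
    i2 <- mins[which(abs(x[mins] - x[i1]) > 0.15 * diff(range(x)))[1L]]
    if (is.na(i2))
      stop_insufficient("could not locate two separated transitions")
    lo <- min(i1, i2); hi <- max(i1, i2)
    mid <- lo:hi
    split_point <- x[mid][which.min(abs(d[mid]))]
  }
  left <- x <= split_point
  if (sum(left) < 6 || sum(!left) < 6)
    stop_insufficient(sprintf(
      "segments at split %.3g M have %d and %d points; >= 6 each required",
      split_point, sum(left), sum(!left)))
  first <- fit_cm(denaturation_curve(x[left], y[left],
                                     paste0(curve$sample_id, ":seg1"),
                                     curve$replicate),
                  normalize = normalize)
  second <- fit_cm(denaturation_curve(x[!left], y[!left],
                                      paste0(curve$sample_id, ":seg2"),
                                      curve$replicate),
                   normalize = normalize)
  cms <- sort(c(first$cm, second$cm))
  structure(
    list(split_point = split_point, first = first, second = second,
         cm1 = cms[1L], cm2 = cms[2L], sample_id = curve$sample_id),
    class = "three_state_result"
  )
}

#' @export
print.three_state_result <- function(x, ...) {
  cat(sprintf("Three-state denaturation (%s): split at %.3g M\n",
              x$sample_id, x$split_point))
  cat(sprintf("  Cm1 = %.4g +/- %.3g M, Cm2 = %.4g +/- %.3g M\n",
              x$first$cm, x$first$x0_stderr, x$second$cm, x$second$x0_stderr))
  invisible(x)
}
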