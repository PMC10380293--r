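#' Titration series container
#'
#' Bundles a constant donor concentration with the acceptor-concentration
#' grid and the per-well crosstalk-corrected sensitized emission. Replicate
#' wells appear as repeated acceptor concentrations; the fit uses all
#' individual points.
#'
#' @param donor_conc Constant total donor concentration `a`, uM (> 0).
#' @param acceptor_conc Acceptor total concentrations, uM, one per SE value.
#' @param se Sensitized emission values (RFU), aligned with `acceptor_conc`.
#' @param sample_id Optional label.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(donor_conc, acceptor_conc, se,
                             sample_id = "sample") {
  if (donor_conc <= 0) stop_invalid("donor concentration must be > 0")
  if (length(acceptor_conc) != length(se))
    stop_invalid("acceptor_conc and se must have the same length")
  if (any(acceptor_conc < 0))
    stop_invalid("acceptor concentrations must be >= 0")
  if (length(unique(acceptor_conc)) < 2)
    stop_invalid("acceptor concentrations must not all be equal")
  structure(
    list(sample_id = sample_id, donor_conc = donor_conc,
         acceptor_conc = as.numeric(acceptor_conc), se = as.numeric(se)),
    class = "titration_series"
  )
}

#' Build a titration series from corrected well table
#'
#' @param se_table Output of [sensitized_emission()].
#' @param donor_conc Donor concentration, uM; defaults to the unique
#'   `donor_conc_uM` in the table.
#' @return A `titration_series`.
#' @export
as_titration_series <- function(se_table, donor_conc = NULL) {
  if (is.null(donor_conc)) {
    donor_conc <- unique(se_table$donor_conc_uM)
    if (length(donor_conc) != 1)
      stop_invalid("donor concentration is not constant; pass `donor_conc`")
  }
  titration_series(donor_conc, se_table$acceptor_conc_uM, se_table$se,
                   sample_id = se_table$sample_id[1L])
}

#' Fit the dissociation constant from a titration series
#'
#' Nonlinear least squares of the quadratic ligand-depletion isotherm
#' ([emfret_model()]) against sensitized emission, estimating `kd` and
#' `em_fret_max`. Initial values are data-driven: `kd0` is the acceptor
#' concentration at half-maximal SE (linear interpolation) and
#' `em_fret_max0` the maximal SE. All replicate points enter individually
#' (unweighted); the fit is deterministic given identical input.
#'
#' @param series A [titration_series()].
#' @param tol Convergence tolerance on relative parameter change.
#' @param max_iter Maximum number of iterations.
#' @return Object of class `binding_fit`: `kd`, `em_fret_max`, `kd_stderr`,
#'   `em_fret_max_stderr`, `residual_norm`, `n_points`, `donor_conc`,
#'   `sample_id`, plus the underlying `nls` fit in `$fit`.
#' @export
fit_kd <- function(series, tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(series, "titration_series"))
  X <- series$acceptor_conc
  y <- series$se
  a <- series$donor_conc
  if (length(unique(X)) < 5)
    stop_invalid("need >= 5 distinct acceptor concentrations to fit kd")
  if (min(X) > 0.05 * max(X))
    stop_invalid("titration lacks a near-zero acceptor concentration")
  if (all(y == 0)) stop_degenerate("all sensitized-emission values are zero")
  if (max(y) <= 0)
    stop_degenerate("sensitized emission never rises above zero")

  # Data-driven start: half-max crossing of the per-concentration means.
  ord <- order(X)
  mx <- tapply(y[ord], X[ord], mean)
  xs <- as.numeric(names(mx))
  ymax <- max(mx)
  kd0 <- interp_crossing(xs, as.numeric(mx), ymax / 2)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(X[X > 0])
  start <- list(kd = kd0, em_fret_max = ymax)

  fit <- lm_nls(function(p) emfret_model(X, a, p[1L], p[2L]),
                start = c(start$kd, start$em_fret_max), y = y,
                lower = c(1e-9, 1e-9), tol = tol, max_iter = max_iter)
  structure(
    list(kd = fit$par[1L],
         em_fret_max = fit$par[2L],
         kd_stderr = fit$stderr[1L],
         em_fret_max_stderr = fit$stderr[2L],
         residual_norm = sqrt(fit$ssr),
         n_points = length(y),
         donor_conc = a,
         sample_id = series$sample_id,
         fit = fit),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit (%s): Kd = %.4g +/- %.3g uM, EmFRETmax = %.4g +/- %.3g RFU (n = %d, a = %g uM)\n",
              x$sample_id, x$kd, x$kd_stderr, x$em_fret_max,
              x$em_fret_max_stderr, x$n_points, x$donor_conc))
  invisible(x)
}

#' Incubation-time series of dissociation constants
#'
#' Fits [fit_kd()] independently at each incubation time and reports the
#' ratio `kd(t)/kd(t_first)` as a protein-stability indicator: a titrant
#' losing functional concentration during incubation shows a rising
#' apparent Kd, while a stable protein keeps the ratio near one.
#'
#' @param series_by_time Named list of [titration_series()]; names are
#'   incubation times in minutes, coercible to numeric, strictly increasing.
#' @return Object of class `time_series_kd`: `times` (min), `fits`
#'   (list of `binding_fit`), `kd` (numeric), `kd_ratio` (kd(t)/kd(first)).
#' @export
kd_time_course <- function(series_by_time) {
  times <- suppressWarnings(as.numeric(names(series_by_time)))
  if (length(series_by_time) < 2)
    stop_invalid("need >= 2 incubation time points")
  if (any(is.na(times)))
    stop_invalid("list names must be numeric incubation times (minutes)")
  if (any(diff(times) <= 0))
    stop_invalid("incubation times must be strictly increasing")
  fits <- vector("list", length(times))
  for (i in seq_along(times)) {
    fits[[i]] <- tryCatch(
      fit_kd(series_by_time[[i]]),
      fretstab_error = function(e) {
        fs_stop(sprintf("fit at incubation time %g min failed: %s",
                        times[i], conditionMessage(e)),
                class(e)[1L])
      }
    )
  }
  kd <- vapply(fits, function(f) f$kd, numeric(1))
  structure(
    list(times = times, fits = fits, kd = kd, kd_ratio = kd / kd[1L]),
    class = "time_series_kd"
  )
}

#' @export
print.time_series_kd <- function(x, ...) {
  cat("Incubation-time Kd series:\n")
  for (i in seq_along(x$times)) {
    cat(sprintf("  t = %4g min: Kd = %.4g uM (ratio to first: %.3g)\n",
                x$times[i], x$kd[i], x$kd_ratio[i]))
  }
  invisible(x)
}
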