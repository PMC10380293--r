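# Differential scanning fluorimetry: melt-curve normalisation, Tm detection
# from the smoothed first derivative, fraction-folded construction and
# van't Hoff extraction of unfolding thermodynamics.

#' Melt curve container
#'
#' @param temperature Temperatures in Kelvin, strictly increasing, >= 20
#'   points. Use `celsius = TRUE` if supplying degrees Celsius.
#' @param intensity Dye fluorescence (RFU), aligned with `temperature`.
#' @param sample_id,replicate Labels.
#' @param celsius Interpret `temperature` as degrees Celsius.
#' @return Object of class `melt_curve` with temperatures stored in Kelvin.
#' @export
melt_curve <- function(temperature, intensity, sample_id = "sample",
                       replicate = 1L, celsius = FALSE) {
  if (celsius) temperature <- celsius_to_kelvin(temperature)
  if (length(temperature) != length(intensity))
    stop_invalid("temperature and intensity must align")
  if (length(temperature) < 20)
    stop_invalid("melt curve needs >= 20 points")
  if (any(diff(temperature) <= 0))
    stop_invalid("temperatures must be strictly increasing")
  if (any(!is.finite(intensity)))
    stop_invalid("intensities must be finite")
  structure(
    list(sample_id = sample_id, replicate = as.integer(replicate),
         temperature = as.numeric(temperature),
         intensity = as.numeric(intensity)),
    class = "melt_curve"
  )
}

# Truncate at the global fluorescence maximum. SYPRO-type dye signal decays
# beyond the peak as aggregates sequester the dye; the post-peak region
# violates the two-state model and is dropped before Eqs. of state are
# applied.
truncate_at_peak <- function(curve) {
  i <- which.max(curve$intensity)
  melt_curve(curve$temperature[seq_len(i)], curve$intensity[seq_len(i)],
             curve$sample_id, curve$replicate)
}

#' Min-max normalise a melt curve
#'
#' Rescales intensities to \[0, 1\]; idempotent and invariant under affine
#' intensity transforms.
#'
#' @param curve A [melt_curve()].
#' @return A `melt_curve` with intensities in \[0, 1\].
#' @export
normalize_melt <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  f_min <- min(curve$intensity); f_max <- max(curve$intensity)
  if (f_max - f_min <= 0 ||
      (f_max - f_min) < 1e-12 * max(abs(f_max), 1))
    stop_degenerate("melt curve is constant; cannot normalise")
  melt_curve(curve$temperature, (curve$intensity - f_min) / (f_max - f_min),
             curve$sample_id, curve$replicate)
}

#' Melting temperatures from the smoothed derivative
#'
#' Smooths dF/dT with a local quadratic (Savitzky-Golay style) filter and
#' returns the temperatures of local maxima exceeding a prominence
#' threshold, in ascending order. Only the pre-peak region (up to the
#' global fluorescence maximum) is searched, since the post-peak dye-signal
#' decay is an aggregation artifact, not unfolding.
#'
#' @param curve A [melt_curve()].
#' @param smoothing_window Odd window length (points) for the derivative
#'   filter; default 11 (5.5 K at a 0.5 K grid).
#' @param prominence Minimum peak height above the derivative minimum, as a
#'   fraction of the derivative range (default 0.05).
#' @return Numeric vector of melting temperatures (K); empty if no
#'   transition is resolved.
#' @export
find_tm <- function(curve, smoothing_window = 11L, prominence = 0.05) {
  stopifnot(inherits(curve, "melt_curve"))
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window %% 2L == 0L || smoothing_window < 5L ||
      smoothing_window >= length(curve$temperature))
    stop_invalid("smoothing_window must be odd, >= 5 and < curve length")
  pre <- truncate_at_peak(curve)
  if (length(pre$temperature) <= smoothing_window) return(numeric(0))
  d <- local_quadratic_derivative(pre$temperature, pre$intensity,
                                  smoothing_window)
  rng <- diff(range(d))
  # A transition-free curve has an essentially constant derivative; the
  # tiny numerical ripple must not be mistaken for peaks.
  if (rng <= 0 || rng <= 0.05 * max(abs(d))) return(numeric(0))
  floor_level <- min(d) + prominence * rng
  n <- length(d)
  peaks <- which(d[-c(1L, n)] > d[-c(n - 1L, n)] &
                   d[-c(1L, n)] >= d[-c(1L, 2L)]) + 1L
  peaks <- peaks[d[peaks] > floor_level & d[peaks] > 0]
  if (length(peaks) == 0) return(numeric(0))
  # Merge plateau duplicates closer than the smoothing window.
  tm <- pre$temperature[peaks]
  keep <- c(TRUE, diff(tm) > diff(range(pre$temperature)) *
              smoothing_window / n / 2)
  sort(tm[keep])
}

#' Fraction of folded protein along a melt curve
#'
#' `P_f = 1 - (F - F_min) / (F_max - F_min)` with the extrema taken over the
#' pre-peak region only (the curve is truncated at its global maximum before
#' the two-state construction is applied).
#'
#' @param curve A [melt_curve()].
#' @return Data frame `temperature` (K), `p_folded`.
#' @export
fraction_folded <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  pre <- truncate_at_peak(curve)
  f_min <- min(pre$intensity); f_max <- max(pre$intensity)
  if (f_max - f_min <= 0) stop_degenerate("melt curve is constant")
  data.frame(temperature = pre$temperature,
             p_folded = 1 - (pre$intensity - f_min) / (f_max - f_min))
}

#' van't Hoff analysis of a melt curve
#'
#' Builds the unfolding equilibrium constant `K_u = P_u / P_f` from the
#' fraction folded, then regresses `ln K_u` on `1/T` over the points whose
#' unfolded fraction lies inside `window` (default the early unfolding limb,
#' 10-50% unfolded). With `ln K_u = -dH/(R T) + dS/R`, the slope gives
#' `dH = -R * slope` and the intercept `dS = R * intercept`;
#' `dG(t_ref) = dH - t_ref * dS`.
#'
#' For biphasic (three-state) curves the fit is restricted to the final,
#' major transition: when [find_tm()] resolves more than one melting point,
#' the curve is truncated at the derivative valley between the last two
#' transitions before the two-state construction. An explicit `t_range`
#' overrides this.
#'
#' @param curve A [melt_curve()].
#' @param window Length-2 numeric: admissible unfolded-fraction interval
#'   (default `c(0.10, 0.50)`).
#' @param t_ref Reference temperature (K) at which `dG` is reported;
#'   default 298.15 K.
#' @param t_range Optional length-2 temperature interval (K) restricting
#'   the analysis (per-transition fits).
#' @param smoothing_window Passed to [find_tm()].
#' @return Object of class `stability_fit`: `f_min`, `f_max`, `tm_list`
#'   (K), `delta_h` (kcal/mol), `delta_s` (kcal/(mol K)), `delta_g_ref`
#'   (kcal/mol), `t_ref`, `window`, `r_squared`, `n_window`, `sample_id`.
#' @export
vant_hoff_fit <- function(curve, window = c(0.10, 0.50), t_ref = 298.15,
                          t_range = NULL, smoothing_window = 11L) {
  stopifnot(inherits(curve, "melt_curve"))
  if (length(window) != 2 || window[1L] <= 0 || window[2L] >= 1 ||
      window[1L] >= window[2L])
    stop_invalid("window must be an increasing fraction interval inside (0, 1)")
  tm_list <- find_tm(curve, smoothing_window = smoothing_window)
  work <- curve
  if (!is.null(t_range)) {
    keep <- curve$temperature >= t_range[1L] & curve$temperature <= t_range[2L]
    if (sum(keep) < 20) stop_insufficient("t_range leaves < 20 points")
    work <- melt_curve(curve$temperature[keep], curve$intensity[keep],
                       curve$sample_id, curve$replicate)
  } else if (length(tm_list) >= 2) {
    # Final-transition restriction: cut at the derivative valley between
    # the last two transitions.
    pre <- truncate_at_peak(curve)
    d <- local_quadratic_derivative(pre$temperature, pre$intensity,
                                    as.integer(smoothing_window))
    between <- pre$temperature > tm_list[length(tm_list) - 1L] &
      pre$temperature < tm_list[length(tm_list)]
    if (any(between)) {
      valley <- pre$temperature[between][which.min(d[between])]
      keep <- curve$temperature >= valley
      if (sum(keep) >= 20)
        work <- melt_curve(curve$temperature[keep], curve$intensity[keep],
                           curve$sample_id, curve$replicate)
    }
  }
  pre <- truncate_at_peak(work)
  f_min <- min(pre$intensity); f_max <- max(pre$intensity)
  ff <- fraction_folded(work)
  p_u <- 1 - ff$p_folded
  inside <- p_u >= window[1L] & p_u <= window[2L] &
    ff$p_folded > 0 & p_u > 0
  if (sum(inside) < 5)
    stop_insufficient(sprintf(
      "only %d point(s) with unfolded fraction in [%g, %g]; >= 5 required",
      sum(inside), window[1L], window[2L]))
  ln_ku <- log(p_u[inside] / ff$p_folded[inside])
  inv_t <- 1 / ff$temperature[inside]
  ols <- stats::lm(ln_ku ~ inv_t)
  slope <- unname(stats::coef(ols)[2L])
  intercept <- unname(stats::coef(ols)[1L])
  delta_h <- -R_KCAL * slope
  delta_s <- R_KCAL * intercept
  structure(
    list(f_min = f_min, f_max = f_max, tm_list = tm_list,
         delta_h = delta_h, delta_s = delta_s,
         delta_g_ref = delta_h - t_ref * delta_s,
         t_ref = t_ref, window = window,
         r_squared = summary(ols)$r.squared,
         n_window = sum(inside),
         sample_id = curve$sample_id),
    class = "stability_fit"
  )
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf("van't Hoff stability fit (%s):\n", x$sample_id))
  if (length(x$tm_list) > 0)
    cat("  Tm:", paste(sprintf("%.2f K (%.2f C)", x$tm_list,
                               kelvin_to_celsius(x$tm_list)),
                       collapse = ", "), "\n")
  cat(sprintf("  dH = %.3f kcal/mol, dS = %.5f kcal/(mol K)\n",
              x$delta_h, x$delta_s))
  cat(sprintf("  dG(%.2f K) = %.3f kcal/mol  (R^2 = %.5f, n = %d in window [%g, %g])\n",
              x$t_ref, x$delta_g_ref, x$r_squared, x$n_window,
              x$window[1L], x$window[2L]))
  invisible(x)
}

#' Stability difference between a reference protein and a variant
#'
#' `ddG = dG_ref - dG_variant`; positive values mean the variant is
#' destabilised relative to the reference.
#'
#' @param g_ref,g_variant Unfolding free energies, kcal/mol, at a common
#'   reference temperature.
#' @return ddG in kcal/mol.
#' @examples
#' delta_delta_g(6.54, 4.89)  # 1.65
#' @export
delta_delta_g <- function(g_ref, g_variant) {
  if (!is.finite(g_ref) || !is.finite(g_variant))
    stop_invalid("free energies must be finite")
  g_ref - g_variant
}
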