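# Inhibitor dose-response analysis: 4PL IC50 fits, Cheng-Prusoff Ki and the
# dual-criterion single-concentration screen.

#' Competition dose-response series
#'
#' @param inhibitor_conc Inhibitor concentrations, uM (>= 0).
#' @param relative_binding Normalised binding signal (uninhibited == 1),
#'   aligned with `inhibitor_conc`.
#' @param inhibitor_id Label.
#' @param donor_conc,acceptor_conc Assay concentrations, uM (metadata).
#' @return Object of class `competition_series`.
#' @export
competition_series <- function(inhibitor_conc, relative_binding,
                               inhibitor_id = "inhibitor",
                               donor_conc = NA_real_,
                               acceptor_conc = NA_real_) {
  if (length(inhibitor_conc) != length(relative_binding))
    stop_invalid("inhibitor_conc and relative_binding must align")
  if (any(inhibitor_conc < 0))
    stop_invalid("inhibitor concentrations must be >= 0")
  if (any(!is.finite(relative_binding)))
    stop_invalid("relative binding values must be finite")
  structure(
    list(inhibitor_id = inhibitor_id,
         inhibitor_conc = as.numeric(inhibitor_conc),
         relative_binding = as.numeric(relative_binding),
         donor_conc = donor_conc, acceptor_conc = acceptor_conc),
    class = "competition_series"
  )
}

# 4PL response in log10-concentration space.
fourpl <- function(x, top, bottom, hill, log_ic50) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(x) - log_ic50)))
}

#' Four-parameter logistic IC50 fit
#'
#' Fits `y = bottom + (top - bottom) / (1 + 10^(hill (log10 x - log10 IC50)))`
#' ("log(inhibitor) vs response, variable slope") by nonlinear least squares.
#' Zero-concentration points cannot enter a log-space likelihood; they are
#' excluded from the fit and should be used upstream to anchor the
#' normalisation of `relative_binding`.
#'
#' @param series A [competition_series()]. Needs >= 5 distinct nonzero
#'   concentrations spanning at least two decades.
#' @return Object of class `ic50_fit`: `ic50`, `hill_slope`, `top`,
#'   `bottom`, per-parameter standard errors, `residual_norm`, `n_points`,
#'   and the `nls` object in `$fit`. The IC50 standard error is delta-method
#'   propagated from the fitted log10(IC50).
#' @export
fit_ic50 <- function(series) {
  stopifnot(inherits(series, "competition_series"))
  keep <- series$inhibitor_conc > 0
  x <- series$inhibitor_conc[keep]
  y <- series$relative_binding[keep]
  if (length(unique(x)) < 5)
    stop_invalid("need >= 5 distinct nonzero inhibitor concentrations")
  if (log10(max(x) / min(x)) < 2)
    stop_invalid("inhibitor concentrations must span >= 2 log-units")
  if (stats::sd(y) < 1e-12 * max(abs(y), 1))
    stop_degenerate("response is flat; no dose dependence to fit")

  ord <- order(x)
  top0 <- max(y); bottom0 <- min(y)
  mid0 <- interp_crossing(x[ord], y[ord], (top0 + bottom0) / 2)
  if (!is.finite(mid0) || mid0 <= 0) mid0 <- exp(mean(log(range(x))))
  fit <- lm_nls(function(p) fourpl(x, p[1L], p[2L], p[3L], p[4L]),
                start = c(top0, bottom0, 1, log10(mid0)), y = y,
                lower = c(-Inf, -Inf, -50, log10(min(x)) - 3),
                upper = c(Inf, Inf, 50, log10(max(x)) + 3))
  ic50 <- 10^fit$par[4L]
  structure(
    list(inhibitor_id = series$inhibitor_id,
         ic50 = ic50,
         hill_slope = fit$par[3L],
         top = fit$par[1L],
         bottom = fit$par[2L],
         ic50_stderr = log(10) * ic50 * fit$stderr[4L],
         hill_stderr = fit$stderr[3L],
         top_stderr = fit$stderr[1L],
         bottom_stderr = fit$stderr[2L],
         residual_norm = sqrt(fit$ssr),
         n_points = length(y),
         fit = fit),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 fit (%s): IC50 = %.4g +/- %.3g uM, hill = %.3g, top = %.3g, bottom = %.3g (n = %d)\n",
              x$inhibitor_id, x$ic50, x$ic50_stderr, x$hill_slope, x$top,
              x$bottom, x$n_points))
  invisible(x)
}

#' Predict the fitted 4PL response
#'
#' @param object An `ic50_fit`.
#' @param x Inhibitor concentrations, uM (> 0).
#' @param ... Unused.
#' @return Predicted relative binding.
#' @export
predict.ic50_fit <- function(object, x, ...) {
  fourpl(x, object$top, object$bottom, object$hill_slope,
         log10(object$ic50))
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' For pure competition with a labelled partner present at concentration `L`
#' and binding with dissociation constant `kd`,
#' `Ki = IC50 / (1 + L / kd)`.
#'
#' @param ic50 Fitted half-maximal inhibitory concentration, uM (> 0).
#' @param labeled_conc Concentration `L` of the labelled competing species,
#'   uM (>= 0).
#' @param kd Dissociation constant of the labelled pair, uM (> 0).
#' @return Object of class `ki_result`: `ki`, plus the inputs for audit.
#' @examples
#' cheng_prusoff(1.24, 1, 0.4308)$ki  # ~0.37 uM
#' @export
cheng_prusoff <- function(ic50, labeled_conc, kd) {
  if (!is.finite(ic50) || ic50 <= 0) stop_domain("ic50 must be > 0")
  if (!is.finite(labeled_conc) || labeled_conc < 0)
    stop_domain("labeled_conc must be >= 0")
  if (!is.finite(kd) || kd <= 0) stop_domain("kd must be > 0")
  structure(
    list(ki = ic50 / (1 + labeled_conc / kd),
         ic50 = ic50, labeled_conc = labeled_conc, kd = kd),
    class = "ki_result"
  )
}

#' @export
print.ki_result <- function(x, ...) {
  cat(sprintf("Ki = %.4g uM  (IC50 = %.4g uM, L = %g uM, Kd = %.4g uM)\n",
              x$ki, x$ic50, x$labeled_conc, x$kd))
  invisible(x)
}

#' Dual-criterion single-concentration inhibitor screen
#'
#' Evaluates compounds tested at one concentration against matched
#' uninhibited control wells. Two orthogonal binding readouts must both
#' respond for a hit call: the sensitized emission must drop
#' (`se_reduction = 1 - SE_compound / SE_control`) *and* the donor emission
#' must recover from FRET quenching
#' (`donor_dequench = DD_compound / DD_control - 1`). Requiring both rejects
#' optical artifacts (e.g. compounds that absorb or quench all channels,
#' which lower SE without restoring donor emission).
#'
#' @param readings Long-format plate readings containing control wells
#'   (`sample_id == control_id`, zero inhibitor) and one or more compounds
#'   (`sample_id` = compound label, inhibitor at the screening
#'   concentration).
#' @param crosstalk A `crosstalk_model`.
#' @param thresholds Length-2 numeric: minimum fractional `se_reduction`
#'   and `donor_dequench` for a hit (default 0.2 and 0.2).
#' @param control_id `sample_id` of the uninhibited control wells.
#' @return Data frame of class `screen_result`: one row per compound with
#'   `compound_id`, `se_reduction`, `donor_dequench`, `is_hit`.
#' @export
screen_compounds <- function(readings, crosstalk,
                             thresholds = c(se = 0.2, dd = 0.2),
                             control_id = "control") {
  ww <- sensitized_emission(readings, crosstalk)
  ctrl <- ww[ww$sample_id == control_id, ]
  if (nrow(ctrl) == 0)
    stop_missing_control(paste0("no uninhibited control wells (sample_id == '",
                                control_id, "')"))
  se_ctrl <- mean(ctrl$se)
  dd_ctrl <- mean(ctrl$DD)
  if (se_ctrl <= 0 || dd_ctrl <= 0)
    stop_degenerate("control wells have nonpositive SE or DD")
  compounds <- setdiff(unique(ww$sample_id), control_id)
  rows <- lapply(compounds, function(id) {
    w <- ww[ww$sample_id == id, ]
    se_red <- 1 - mean(w$se) / se_ctrl
    dq <- mean(w$DD) / dd_ctrl - 1
    data.frame(compound_id = id, se_reduction = se_red, donor_dequench = dq,
               is_hit = se_red > thresholds[[1L]] && dq > thresholds[[2L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screen_result", class(out))
  out
}
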