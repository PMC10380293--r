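# Three-channel sensitized-emission crosstalk correction.
#
# Plate readings are long-format data frames with one row per
# (well, channel): columns sample_id, well, replicate, donor_conc_uM,
# acceptor_conc_uM, inhibitor_conc_uM, channel (DD | AA | DA), intensity.
# DD = donor excitation / donor emission, AA = acceptor excitation /
# acceptor emission, DA = donor excitation / acceptor emission (the raw
# FRET channel, contaminated by donor bleed-through and direct acceptor
# excitation).

PLATE_COLUMNS <- c("sample_id", "well", "replicate", "donor_conc_uM",
                   "acceptor_conc_uM", "inhibitor_conc_uM", "channel",
                   "intensity")
CHANNELS <- c("DD", "AA", "DA")

# Validate the plate dialect; returns the data frame invisibly.
validate_plate <- function(readings) {
  missing_cols <- setdiff(PLATE_COLUMNS, names(readings))
  if (length(missing_cols) > 0)
    stop_schema(paste0("plate table is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  bad <- setdiff(unique(readings$channel), CHANNELS)
  if (length(bad) > 0)
    stop_invalid(paste0("unknown channel value(s): ",
                        paste(bad, collapse = ", ")))
  if (any(!is.finite(readings$intensity)))
    stop_invalid("non-finite intensity values in plate table")
  num <- c("donor_conc_uM", "acceptor_conc_uM", "inhibitor_conc_uM")
  for (col in num) {
    if (any(readings[[col]] < 0))
      stop_invalid(paste0("negative concentrations in column ", col))
  }
  invisible(readings)
}

# Pivot a long plate table to one row per well with DD/AA/DA columns.
# Errors (naming the well) if any well lacks a channel.
wells_wide <- function(readings, require = CHANNELS) {
  validate_plate(readings)
  key <- interaction(readings$sample_id, readings$well, readings$replicate,
                     drop = TRUE)
  pieces <- split(readings, key)
  out <- lapply(pieces, function(p) {
    row <- p[1L, setdiff(PLATE_COLUMNS, c("channel", "intensity"))]
    for (ch in CHANNELS) {
      v <- p$intensity[p$channel == ch]
      if (ch %in% require && length(v) == 0)
        stop_invalid(paste0("well ", p$well[1L], " (sample ", p$sample_id[1L],
                            ", replicate ", p$replicate[1L],
                            ") lacks channel ", ch))
      row[[ch]] <- if (length(v) > 0) mean(v) else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Crosstalk coefficients from single-fluorophore control wells
#'
#' Builds a crosstalk model for the three-channel sensitized-emission method
#' from donor-only and acceptor-only control wells: `delta` is the donor
#' bleed-through into the FRET channel (mean DA/DD over donor-only wells)
#' and `alpha` is the direct acceptor excitation (mean DA/AA over
#' acceptor-only wells).
#'
#' @param donor_only_readings,acceptor_only_readings Long-format plate
#'   readings (see [read_plate_csv()]) for wells containing only the donor
#'   (DD and DA channels needed) or only the acceptor (AA and DA needed).
#' @return An object of class `crosstalk_model`: list with elements `delta`,
#'   `alpha`, `n_donor_wells`, `n_acceptor_wells`.
#' @export
estimate_crosstalk <- function(donor_only_readings, acceptor_only_readings) {
  if (is.null(donor_only_readings) || nrow(donor_only_readings) == 0)
    stop_invalid("donor-only control readings are empty")
  if (is.null(acceptor_only_readings) || nrow(acceptor_only_readings) == 0)
    stop_invalid("acceptor-only control readings are empty")
  dw <- wells_wide(donor_only_readings, require = c("DD", "DA"))
  aw <- wells_wide(acceptor_only_readings, require = c("AA", "DA"))
  if (any(dw$DD <= 0))
    stop_degenerate(paste0("donor-only well(s) with DD <= 0: ",
                           paste(dw$well[dw$DD <= 0], collapse = ", ")))
  if (any(aw$AA <= 0))
    stop_degenerate(paste0("acceptor-only well(s) with AA <= 0: ",
                           paste(aw$well[aw$AA <= 0], collapse = ", ")))
  delta <- mean(dw$DA / dw$DD)
  alpha <- mean(aw$DA / aw$AA)
  if (!is.finite(delta) || !is.finite(alpha))
    stop_degenerate("crosstalk coefficients are not finite")
  structure(
    list(delta = delta, alpha = alpha,
         n_donor_wells = nrow(dw), n_acceptor_wells = nrow(aw)),
    class = "crosstalk_model"
  )
}

#' @export
print.crosstalk_model <- function(x, ...) {
  cat("Crosstalk model (three-channel sensitized emission)\n")
  cat(sprintf("  delta (donor bleed-through DA/DD): %.6g  [%d wells]\n",
              x$delta, x$n_donor_wells))
  cat(sprintf("  alpha (acceptor direct excitation DA/AA): %.6g  [%d wells]\n",
              x$alpha, x$n_acceptor_wells))
  invisible(x)
}

#' Crosstalk-corrected sensitized emission per well
#'
#' Removes donor bleed-through and direct acceptor excitation from the raw
#' FRET channel: `SE = DA - alpha * AA - delta * DD`. When a non-binding
#' control series is supplied (the empirical correction with a
#' non-interacting donor), the control SE at the matching acceptor
#' concentration is additionally subtracted. Negative values are retained:
#' clipping at zero would bias downstream fits near baseline.
#'
#' @param sample_readings Long-format plate readings; every well must carry
#'   all three channels.
#' @param crosstalk A `crosstalk_model` from [estimate_crosstalk()], or a
#'   list with `delta` and `alpha`.
#' @param control_se Optional data frame `acceptor_conc_uM`, `se`: the
#'   sensitized emission of a non-binding control at each acceptor
#'   concentration (e.g. free donor fluorophore + acceptor fusion).
#' @return Data frame with one row per well: `sample_id`, `well`,
#'   `replicate`, `donor_conc_uM`, `acceptor_conc_uM`, `inhibitor_conc_uM`,
#'   `DD`, `AA`, `DA`, `se`.
#' @export
sensitized_emission <- function(sample_readings, crosstalk,
                                control_se = NULL) {
  ww <- wells_wide(sample_readings)
  se <- ww$DA - crosstalk$alpha * ww$AA - crosstalk$delta * ww$DD
  if (!is.null(control_se)) {
    idx <- vapply(ww$acceptor_conc_uM, function(x) {
      hit <- which(abs(control_se$acceptor_conc_uM - x) <=
                     1e-8 * max(x, 1e-12))
      if (length(hit) == 0) NA_integer_ else hit[1L]
    }, integer(1))
    if (any(is.na(idx)))
      stop_missing_control(paste0(
        "no non-binding control SE at acceptor concentration(s): ",
        paste(unique(ww$acceptor_conc_uM[is.na(idx)]), collapse = ", ")))
    se <- se - control_se$se[idx]
  }
  ww$se <- se
  ww
}
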