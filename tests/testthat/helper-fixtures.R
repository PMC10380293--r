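# Shared fixture builders. Everything is generated in code; no data files.

# Full pipeline from a simulated plate to a corrected titration series:
# crosstalk from the single-fluorophore controls, SE correction, optional
# non-binding-control subtraction.
plate_to_series <- function(plate, subtract_control = FALSE) {
  xt <- estimate_crosstalk(plate[plate$sample_id == "donor_only", ],
                           plate[plate$sample_id == "acceptor_only", ])
  ctrl_se <- NULL
  if (subtract_control) {
    nb <- sensitized_emission(plate[plate$sample_id == "nonbinding_control", ],
                              xt)
    ctrl_se <- stats::aggregate(se ~ acceptor_conc_uM, nb, mean)
  }
  se <- sensitized_emission(plate[plate$sample_id == "sample", ], xt,
                            control_se = ctrl_se)
  as_titration_series(se)
}

# Noiseless titration series straight from the isotherm (no plate layer),
# with replicated points; optionally multiplicative noise on the SE values.
make_series <- function(kd = 0.4308, a = 1, em_max = 1000,
                        X = c(0, 3.09 / 2^(9:0)), replicates = 3,
                        noise_cv = 0, seed = NULL) {
  Xr <- rep(X, replicates)
  y <- emfret_model(Xr, a, kd, em_max)
  if (noise_cv > 0) {
    stopifnot(!is.null(seed))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    y <- y * (1 + noise_cv * stats::rnorm(length(y)))
  }
  titration_series(a, Xr, y)
}

# Dose-response pipeline: simulated competition plate -> normalised series.
competition_pipeline <- function(cfg, ki,
                                 doses = c(0, 10^seq(-2, 2.5,
                                                     length.out = 13))) {
  plate <- simulate_competition_plate(cfg, ki = ki, doses = doses)
  xt <- list(delta = cfg$delta, alpha = cfg$alpha)
  se <- sensitized_emission(plate, xt)
  anchor <- mean(se$se[se$inhibitor_conc_uM == 0])
  competition_series(se$inhibitor_conc_uM, se$se / anchor)
}
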