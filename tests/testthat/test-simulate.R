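# Generator contracts: determinism, adjointness with the analyzers, and
# configuration validation.

test_that("every generator is a deterministic function of (config, seed)", {
  cfg <- fret_sim_config(noise_cv = 0.02, seed = 99)
  expect_identical(simulate_titration_plate(cfg),
                   simulate_titration_plate(cfg))
  expect_identical(simulate_competition_plate(cfg, ki = 2),
                   simulate_competition_plate(cfg, ki = 2))
  mcfg <- melt_sim_config(noise_cv = 0.01, seed = 3)
  expect_identical(simulate_melt_curve(mcfg), simulate_melt_curve(mcfg))
  expect_identical(simulate_urea_curve(noise_cv = 0.02, seed = 4),
                   simulate_urea_curve(noise_cv = 0.02, seed = 4))
  wcfg <- work_sim_config(seed = 5)
  expect_identical(simulate_work_values(wcfg), simulate_work_values(wcfg))
  # Different seeds give different noise realisations.
  cfg2 <- fret_sim_config(noise_cv = 0.02, seed = 100)
  expect_false(identical(simulate_titration_plate(cfg),
                         simulate_titration_plate(cfg2)))
})

test_that("generators refuse stochastic output without a seed", {
  expect_error(fret_sim_config(noise_cv = 0.02),
               class = "fretstab_invalid_input")
  expect_error(melt_sim_config(noise_cv = 0.02),
               class = "fretstab_invalid_input")
  expect_error(simulate_urea_curve(noise_cv = 0.02),
               class = "fretstab_invalid_input")
  expect_error(work_sim_config(seed = NULL),
               class = "fretstab_invalid_input")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- .Random.seed
  invisible(simulate_titration_plate(fret_sim_config(noise_cv = 0.02,
                                                     seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("no FRET means zero corrected SE at every concentration", {
  cfg <- fret_sim_config(e_app = 0)
  plate <- simulate_titration_plate(cfg)
  se <- sensitized_emission(plate[plate$sample_id == "sample", ],
                            list(delta = cfg$delta, alpha = cfg$alpha))
  expect_equal(se$se, rep(0, nrow(se)), tolerance = 1e-9)
})

test_that("titration generator and fit_kd are adjoint at the design point", {
  plate <- simulate_titration_plate(fret_sim_config())
  f <- fit_kd(plate_to_series(plate, subtract_control = TRUE))
  expect_lt(abs(f$kd - 0.4308) / 0.4308, 1e-3)
  expect_lt(abs(f$em_fret_max - 1000) / 1000, 1e-3)
})

test_that("melt generator fixed points", {
  # Put Tm = dH/dS exactly on a grid point (50 C): the intensity there is
  # exactly midway between the flat baselines, i.e. P_u(Tm) = 0.5.
  cfg <- melt_sim_config(delta_h = 100, delta_s = 100 / 323.15)
  cv <- simulate_melt_curve(cfg)
  expect_equal(cv$intensity[cv$temperature == 323.15], (200 + 1800) / 2,
               tolerance = 1e-12)
  # Flat baselines, no noise: normalized curve equals P_u up to the
  # (tiny) residual unfolded fraction at the grid edges.
  pu_true <- {
    t <- cv$temperature
    ku <- exp(-(100 - t * cfg$delta_s) / (R_KCAL * t))
    ku / (1 + ku)
  }
  expect_lt(max(abs(normalize_melt(cv)$intensity - pu_true)), 1e-3)
})

test_that("aggregation decay produces a peaked curve that is truncated", {
  cfg <- melt_sim_config(delta_h = 100, delta_s = 0.3096,
                         aggregation_rate = 0.05)
  cv <- simulate_melt_curve(cfg)
  peak <- which.max(cv$intensity)
  expect_lt(peak, length(cv$intensity))         # signal decays post-peak
  f <- vant_hoff_fit(cv)
  expect_lt(abs(f$delta_h - 100) / 100, 0.01)   # analysis unaffected
})

test_that("competition generator: inactive compounds give flat response", {
  cfg <- fret_sim_config()
  plate <- simulate_competition_plate(cfg, ki = 1e9)
  se <- sensitized_emission(plate, list(delta = cfg$delta,
                                        alpha = cfg$alpha))
  expect_lt(diff(range(se$se)) / mean(se$se), 1e-6)
})

test_that("urea generator fixed points", {
  cv <- simulate_urea_curve(a1 = 0.9, a2 = 0.1, x0 = 3, p = 8,
                            urea = c(0, 1, 2, 3, 4, 6, 8))
  expect_identical(cv$intensity[cv$urea == 0], 0.9)
  expect_equal(cv$intensity[cv$urea == 3], 0.5, tolerance = 1e-12)
})

test_that("work generator matches its stated Gaussian construction", {
  cfg <- work_sim_config(true_dg = 1.0, sigma = 0.5, n_per_direction = 5e4,
                         temperature = 300, seed = 21)
  ws <- simulate_work_values(cfg)
  shift <- 0.5^2 / (2 * R_KCAL * 300)
  expect_equal(mean(ws$forward), 1.0 + shift, tolerance = 0.01)
  expect_equal(mean(ws$reverse), -1.0 + shift, tolerance = 0.01)
  expect_equal(sd(ws$forward), 0.5, tolerance = 0.01)
  # sigma -> 0 limit: all works equal +/- dG.
  tiny <- simulate_work_values(work_sim_config(true_dg = 2, sigma = 1e-12,
                                               seed = 3,
                                               n_per_direction = 10))
  expect_equal(tiny$forward, rep(2, 10), tolerance = 1e-9)
  expect_equal(tiny$reverse, rep(-2, 10), tolerance = 1e-9)
})
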