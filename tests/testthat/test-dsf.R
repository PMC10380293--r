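# DSF melt-curve analysis.

test_that("normalization is idempotent and affine-invariant", {
  cv <- simulate_melt_curve(melt_sim_config())
  n1 <- normalize_melt(cv)
  expect_equal(range(n1$intensity), c(0, 1))
  expect_equal(normalize_melt(n1)$intensity, n1$intensity)
  affine <- melt_curve(cv$temperature, 3.7 * cv$intensity + 55)
  expect_equal(normalize_melt(affine)$intensity, n1$intensity,
               tolerance = 1e-12)
  flat <- melt_curve(cv$temperature, rep(5, length(cv$temperature)))
  expect_error(normalize_melt(flat), class = "fretstab_degenerate_data")
})

test_that("fraction_folded hits the three fixed points", {
  # Simple V-free synthetic curve: linear ramp.
  temps <- seq(300, 330, by = 1)
  f <- seq(100, 700, by = 20)
  pf <- fraction_folded(melt_curve(temps, f))
  expect_equal(pf$p_folded[1], 1)                      # F = F_min
  expect_equal(pf$p_folded[length(f)], 0)              # F = F_max
  expect_equal(pf$p_folded[f == 400], 0.5)             # midpoint
})

test_that("find_tm recovers single and double transitions", {
  # Two-state, Tm = dH/dS = 323.0 K; grid resolution is 0.5 K.
  cv <- simulate_melt_curve(melt_sim_config(delta_h = 100,
                                            delta_s = 0.3096))
  tm <- find_tm(cv)
  expect_length(tm, 1)
  expect_lt(abs(tm - 100 / 0.3096), 0.3)
  # Three-state with sharp transitions at 322.25 K and 327.69 K.
  cv3 <- simulate_melt_curve(melt_sim_config(delta_h = 250,
                                             delta_s = 250 / 322.25),
                             n_states = 3)
  tm3 <- find_tm(cv3)
  expect_length(tm3, 2)
  expect_lt(abs(tm3[1] - 322.25), 0.5)
  expect_lt(abs(tm3[2] - 327.69), 0.5)
  # Monotone (transition-free) curve yields an empty list.
  lin <- melt_curve(seq(303, 368, 0.5),
                    seq_along(seq(303, 368, 0.5)) * 2 + 100)
  expect_length(find_tm(lin), 0)
  expect_error(find_tm(cv, smoothing_window = 4),
               class = "fretstab_invalid_input")
})

test_that("van't Hoff round trip over the generator parameter range", {
  # Combinations chosen so that < 0.5% of the protein is unfolded at the
  # 30 C start of the grid: the fraction-folded construction assumes the
  # observed minimum fluorescence is the folded baseline, which fails for
  # low-dH, low-Tm proteins (see the methods vignette).
  for (ps in list(c(100, 0.3096), c(50, 50 / 340), c(150, 150 / 315))) {
    dh <- ps[1]; ds <- ps[2]
    cv <- simulate_melt_curve(melt_sim_config(delta_h = dh, delta_s = ds))
    f <- vant_hoff_fit(cv)
    expect_lt(abs(f$delta_h - dh) / dh, 0.01)
    expect_lt(abs(f$delta_s - ds) / ds, 0.01)
    expect_gt(f$r_squared, 0.9999)       # ln Ku exactly linear in 1/T
    # Tm from the derivative agrees with dH/dS.
    expect_lt(abs(find_tm(cv) - dh / ds), 0.5)
    # dG vanishes on the fitted line at T = Tm.
    expect_lt(abs(f$delta_h - (dh / ds) * f$delta_s), 0.02 * dh)
  }
})

test_that("published-order example: dG(298.15 K) of the reference curve", {
  cv <- simulate_melt_curve(melt_sim_config(delta_h = 100,
                                            delta_s = 0.3096))
  f <- vant_hoff_fit(cv, t_ref = 298.15)
  expect_lt(abs(f$delta_g_ref - (100 - 298.15 * 0.3096)) / 7.693, 0.01)
  # dG decreases strictly with reference temperature (dS > 0).
  g <- sapply(c(290, 300, 310, 320), function(tr)
    vant_hoff_fit(cv, t_ref = tr)$delta_g_ref)
  expect_true(all(diff(g) < 0))
})

test_that("van't Hoff results are invariant to affine intensity and T-shift", {
  cfg <- melt_sim_config(delta_h = 100, delta_s = 0.3096)
  cv <- simulate_melt_curve(cfg)
  f0 <- vant_hoff_fit(cv)
  aff <- melt_curve(cv$temperature, 12 * cv$intensity + 300)
  fa <- vant_hoff_fit(aff)
  expect_equal(fa$delta_h, f0$delta_h, tolerance = 1e-9)
  expect_equal(fa$delta_s, f0$delta_s, tolerance = 1e-9)
  # Same thermodynamics measured on a shifted grid: identical estimates,
  # since the fit depends only on (T, P_u) pairs.
  cfg_shift <- melt_sim_config(delta_h = 100, delta_s = 0.3096,
                               temp_celsius = seq(35, 100, by = 0.5))
  fs <- vant_hoff_fit(simulate_melt_curve(cfg_shift))
  expect_lt(abs(fs$delta_h - f0$delta_h) / f0$delta_h, 0.01)
})

test_that("window occupancy is enforced", {
  cv <- simulate_melt_curve(melt_sim_config(delta_h = 100,
                                            delta_s = 0.3096))
  err <- tryCatch(vant_hoff_fit(cv, window = c(0.001, 0.002)),
                  error = function(e) e)
  expect_s3_class(err, "fretstab_insufficient_data")
  expect_match(conditionMessage(err), "point")
  expect_error(vant_hoff_fit(cv, window = c(0.5, 0.1)),
               class = "fretstab_invalid_input")
})

test_that("delta_delta_g sign convention and antisymmetry", {
  expect_equal(delta_delta_g(6.54, 4.89), 1.65)
  expect_identical(delta_delta_g(3.14, 3.14), 0)
  expect_equal(delta_delta_g(2, 7), -delta_delta_g(7, 2))
  expect_error(delta_delta_g(Inf, 1), class = "fretstab_invalid_input")
})
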