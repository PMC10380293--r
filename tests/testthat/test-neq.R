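# Nonequilibrium free-energy estimators and cycle bookkeeping.

rt300 <- R_KCAL * 300

test_that("jarzynski limits: deterministic and single-sample work", {
  expect_equal(jarzynski(rep(2.5, 6), n_boot = 0)$delta_g, 2.5,
               tolerance = 1e-12)
  expect_equal(jarzynski(1.7, n_boot = 0)$delta_g, 1.7)
  # Reverse direction reports the A -> B frame.
  expect_equal(jarzynski(rep(-2.5, 6), direction = "reverse",
                         n_boot = 0)$delta_g, 2.5, tolerance = 1e-12)
  expect_error(jarzynski(numeric(0)), class = "fretstab_invalid_input")
})

test_that("jarzynski matches the Gaussian closed form", {
  # W ~ N(mu, sigma^2): dG = mu - sigma^2 / (2RT).
  set.seed(31)
  sigma <- sqrt(2 * rt300)
  w <- rnorm(1e5, 2.0, sigma)
  est <- jarzynski(w, 300, "forward", seed = 1)
  expect_lt(abs(est$delta_g - 1.0), 3 * est$uncertainty)
})

test_that("CGI: symmetric, asymmetric and degenerate cases", {
  set.seed(5)
  wf <- rnorm(4000, 3, 0.6)
  wr <- -wf + 2   # exactly equal variances by construction
  est <- crooks_gaussian_intersection(work_set(wf, wr), n_boot = 50,
                                      seed = 9)
  # Equal variances: (mean(Wf) - mean(Wr)) / 2.
  expect_equal(est$delta_g, (mean(wf) - mean(wr)) / 2, tolerance = 1e-9)
  # Identical forward and negated-reverse samples: the common mean.
  ws_id <- work_set(wf, -wf)
  expect_equal(crooks_gaussian_intersection(ws_id, n_boot = 0)$delta_g,
               mean(wf), tolerance = 1e-9)
  # Unequal variances: cross-check against a density-equality root found
  # numerically (independent of the quadratic formula).
  wf2 <- rnorm(4000, 3, 1); wr2n <- rnorm(4000, 1, 0.5)
  est2 <- crooks_gaussian_intersection(work_set(wf2, -wr2n), n_boot = 0)
  froot <- stats::uniroot(function(x)
    dnorm(x, mean(wf2), sd(wf2)) - dnorm(x, mean(wr2n), sd(wr2n)),
    lower = mean(wr2n), upper = mean(wf2))$root
  expect_equal(est2$delta_g, froot, tolerance = 1e-6)
  expect_error(crooks_gaussian_intersection(work_set(1, c(1, 2))),
               class = "fretstab_invalid_input")
})

test_that("BAR: trivial symmetry, antisymmetry and non-overlap error", {
  expect_equal(bar(work_set(c(2, 2), c(-2, -2)))$delta_g, 2,
               tolerance = 1e-8)
  set.seed(6)
  ws <- simulate_work_values(work_sim_config(true_dg = 1, sigma = 0.5,
                                             n_per_direction = 2000,
                                             seed = 8))
  b <- bar(ws)
  swapped <- bar(work_set(ws$reverse, ws$forward, ws$temperature))
  expect_equal(swapped$delta_g, -b$delta_g, tolerance = 1e-7)
  # Permutation invariance.
  set.seed(2)
  b_perm <- bar(work_set(sample(ws$forward), sample(ws$reverse),
                         ws$temperature))
  expect_equal(b_perm$delta_g, b$delta_g, tolerance = 1e-10)
  # Hopelessly separated distributions.
  far <- work_set(rnorm(50, 1000, 0.1), rnorm(50, 1000, 0.1))
  expect_error(bar(far), class = "fretstab_estimation_failure")
})

test_that("estimators agree on Crooks-consistent work sets", {
  ws <- simulate_work_values(work_sim_config(true_dg = 1.0, sigma = 0.5,
                                             n_per_direction = 10000,
                                             seed = 11))
  b <- bar(ws)
  cg <- crooks_gaussian_intersection(ws, seed = 3)
  jf <- jarzynski(ws$forward, 300, "forward", seed = 4)
  jr <- jarzynski(ws$reverse, 300, "reverse", seed = 5)
  for (est in list(b, cg, jf, jr))
    expect_lt(abs(est$delta_g - 1.0), 3 * max(est$uncertainty, 1e-6))
  expect_lt(abs(b$delta_g - cg$delta_g),
            2 * sqrt(b$uncertainty^2 + cg$uncertainty^2))
})

test_that("BAR is at least as efficient as Jarzynski on average", {
  errs <- sapply(1:50, function(s) {
    ws <- simulate_work_values(work_sim_config(true_dg = 1.0, sigma = 1.0,
                                               n_per_direction = 200,
                                               seed = s))
    c(bar = abs(bar(ws)$delta_g - 1.0),
      jar = abs(jarzynski(ws$forward, n_boot = 0)$delta_g - 1.0))
  })
  expect_lt(mean(errs["bar", ]), mean(errs["jar", ]))
})

test_that("generated work sets satisfy the Crooks identity empirically", {
  ws <- simulate_work_values(work_sim_config(true_dg = 1.0, sigma = 0.5,
                                             n_per_direction = 20000,
                                             seed = 13))
  # ln[Pf(W)/Pr(-W)] should be linear in W with slope 1/RT and cross zero
  # at W = dG. Estimate both densities on a common grid.
  grid <- seq(0.2, 1.8, by = 0.1)
  lf <- approxfun(stats::density(ws$forward, from = 0, to = 2.5, n = 512))
  lr <- approxfun(stats::density(-ws$reverse, from = 0, to = 2.5, n = 512))
  lr_vals <- log(lf(grid) / lr(grid))
  fit <- stats::lm(lr_vals ~ grid)
  expect_equal(unname(coef(fit)[2]), 1 / rt300, tolerance = 0.1)
  expect_equal(-unname(coef(fit)[1] / coef(fit)[2]), 1.0, tolerance = 0.1)
})

test_that("ddg_from_legs combines and validates legs", {
  leg1 <- fretstab:::new_fe_estimate(-3.0, "bar", 0.2, 100L, 100L, 300)
  leg2 <- fretstab:::new_fe_estimate(-0.61, "bar", 0.3, 100L, 100L, 300)
  d <- ddg_from_legs(leg1, leg2, "folding")
  expect_equal(d$ddg, 2.39)
  expect_equal(d$uncertainty, sqrt(0.2^2 + 0.3^2))
  expect_equal(ddg_from_legs(leg1, leg1)$ddg, 0)
  expect_equal(ddg_from_legs(leg2, leg1)$ddg, -d$ddg)
  # Replica-level uncertainty overrides quadrature.
  dr <- ddg_from_legs(leg1, leg2, replica_ddgs = c(2.2, 2.4, 2.6))
  expect_equal(dr$uncertainty, sd(c(2.2, 2.4, 2.6)))
  leg_hot <- fretstab:::new_fe_estimate(-0.61, "bar", 0.3, 100L, 100L, 310)
  expect_error(ddg_from_legs(leg1, leg_hot),
               class = "fretstab_invalid_input")
})

test_that("cycle closure sums signed edges and validates the path", {
  edges <- data.frame(from = c("C", "S", "A"), to = c("S", "A", "C"),
                      ddg = c(2.39, -1.0, -1.39))
  cc <- cycle_closure(edges)
  expect_equal(cc$closure, 0)
  expect_false(cc$flagged)
  # Reversing an edge's orientation flips its sign in the sum.
  rev_edges <- edges
  rev_edges[2, ] <- list("A", "S", 1.0)
  expect_equal(cycle_closure(rev_edges)$closure, 0)
  # Open paths are rejected with the break named.
  open_edges <- data.frame(from = c("C", "S"), to = c("S", "A"),
                           ddg = c(1, 1))
  expect_error(cycle_closure(open_edges), class = "fretstab_invalid_input")
  broken <- data.frame(from = c("C", "X"), to = c("S", "A"), ddg = c(1, 1))
  err <- tryCatch(cycle_closure(broken), error = function(e) e)
  expect_match(conditionMessage(err), "edge 2")
})

test_that("closure of three estimated edges is within combined error", {
  # True edge values sum to zero: C->S 2.39, S->A -1.0, A->C -1.39.
  truth <- c(2.39, -1.0, -1.39)
  est <- lapply(seq_along(truth), function(i) {
    ws <- simulate_work_values(work_sim_config(true_dg = truth[i],
                                               sigma = 0.5,
                                               n_per_direction = 5000,
                                               seed = 100 + i))
    bar(ws)
  })
  edges <- data.frame(from = c("C", "S", "A"), to = c("S", "A", "C"),
                      ddg = sapply(est, `[[`, "delta_g"),
                      uncertainty = sapply(est, `[[`, "uncertainty"))
  cc <- cycle_closure(edges)
  expect_lt(abs(cc$closure), 3 * cc$uncertainty)
})
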