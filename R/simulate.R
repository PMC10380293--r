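# Synthetic-data generators. Each generator is a deterministic function of
# (config, seed) and emits exactly the containers / CSV dialects the
# analysis modules consume, with the statistical structure the analysis
# assumes. Defaults reproduce the assay's stated design: 1 uM donor,
# acceptor titrated 0-3.09 uM, Kd 0.4308 uM; melt curves 30-95 C in 0.5 C
# steps; Crooks-consistent Gaussian work distributions.

#' FRET titration simulation configuration
#'
#' @param kd Dissociation constant, uM.
#' @param em_fret_max Sensitized emission at saturation, RFU.
#' @param donor_conc Constant donor concentration `a`, uM.
#' @param acceptor_grid Acceptor concentrations, uM. Default: 0 plus a
#'   two-fold dilution series from 3.09 uM (the assay's titration span).
#' @param delta,alpha Crosstalk coefficients (donor bleed-through,
#'   acceptor direct excitation).
#' @param donor_brightness,acceptor_brightness RFU per uM in the DD / AA
#'   channels.
#' @param e_app Apparent FRET efficiency: fractional donor quenching at
#'   full binding.
#' @param noise_cv Multiplicative Gaussian noise CV on every intensity.
#' @param noise_floor Additive Gaussian noise SD, RFU.
#' @param functional_decay_rate First-order loss rate of functional
#'   acceptor, per hour (0 = stable protein).
#' @param replicates Technical replicates per concentration.
#' @param seed Seed; mandatory when `noise_cv > 0` or `noise_floor > 0`.
#' @return Object of class `fret_sim_config`.
#' @export
fret_sim_config <- function(kd = 0.4308, em_fret_max = 1000,
                            donor_conc = 1,
                            acceptor_grid = c(0, 3.09 / 2^(9:0)),
                            delta = 0.12, alpha = 0.30,
                            donor_brightness = 2000,
                            acceptor_brightness = 1500,
                            e_app = 0.4,
                            noise_cv = 0, noise_floor = 0,
                            functional_decay_rate = 0,
                            replicates = 3L, seed = NULL) {
  if (kd <= 0 || donor_conc <= 0) stop_invalid("kd and donor_conc must be > 0")
  if (delta < 0 || delta >= 1 || alpha < 0 || alpha >= 1)
    stop_invalid("crosstalk coefficients must lie in [0, 1)")
  if (e_app < 0 || e_app > 1) stop_invalid("e_app must lie in [0, 1]")
  if (noise_cv < 0 || noise_floor < 0) stop_invalid("noise must be >= 0")
  if ((noise_cv > 0 || noise_floor > 0) && is.null(seed))
    stop_invalid("a seed is mandatory for stochastic output")
  structure(
    list(kd = kd, em_fret_max = em_fret_max, donor_conc = donor_conc,
         acceptor_grid = acceptor_grid, delta = delta, alpha = alpha,
         donor_brightness = donor_brightness,
         acceptor_brightness = acceptor_brightness, e_app = e_app,
         noise_cv = noise_cv, noise_floor = noise_floor,
         functional_decay_rate = functional_decay_rate,
         replicates = as.integer(replicates), seed = seed),
    class = "fret_sim_config"
  )
}

# One plate row per channel.
plate_rows <- function(sample_id, well, replicate, donor, acceptor,
                       inhibitor, dd, aa, da) {
  data.frame(
    sample_id = sample_id, well = well, replicate = replicate,
    donor_conc_uM = donor, acceptor_conc_uM = acceptor,
    inhibitor_conc_uM = inhibitor,
    channel = c("DD", "AA", "DA"), intensity = c(dd, aa, da),
    stringsAsFactors = FALSE
  )
}

apply_noise <- function(x, cv, floor) {
  if (cv == 0 && floor == 0) return(x)
  x * (1 + cv * stats::rnorm(length(x))) + stats::rnorm(length(x), 0, floor)
}

# Raw channel model for one well. The FRET term is e_app * G * a * f_bound
# with the emission gain G fixed so that the crosstalk-corrected SE at full
# binding equals em_fret_max; with zero transfer efficiency there is no
# sensitized emission at all.
channel_intensities <- function(cfg, X_total, f_bound) {
  dd <- cfg$donor_brightness * cfg$donor_conc * (1 - cfg$e_app * f_bound)
  aa <- cfg$acceptor_brightness * X_total
  fret <- if (cfg$e_app > 0) cfg$em_fret_max * f_bound else 0
  da <- fret + cfg$alpha * aa + cfg$delta * dd
  c(dd = dd, aa = aa, da = da)
}

#' Simulate a three-channel FRET titration plate
#'
#' Generates sample wells across the acceptor grid plus donor-only,
#' acceptor-only and non-binding control wells, with spectral crosstalk and
#' optional noise. The bound fraction comes from the exact mass-action
#' equilibrium ([simulate_binding_equilibrium()]). When
#' `functional_decay_rate > 0`, the functional acceptor concentration decays
#' exponentially with incubation time while total (fluorescent) acceptor is
#' unchanged, mimicking a titrant that denatures during incubation.
#'
#' @param config A [fret_sim_config()].
#' @param incubation_time_min Incubation time in minutes (default 60).
#' @return Long-format plate data frame (see [read_plate_csv()]) with
#'   sample wells (`sample_id = "sample"`), `"donor_only"`,
#'   `"acceptor_only"` and `"nonbinding_control"` wells.
#' @export
simulate_titration_plate <- function(config, incubation_time_min = 60) {
  stopifnot(inherits(config, "fret_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    decay <- exp(-cfg$functional_decay_rate * incubation_time_min / 60)
    rows <- list()
    wi <- 0L
    for (rep in seq_len(cfg$replicates)) {
      for (X in cfg$acceptor_grid) {
        wi <- wi + 1L
        fb <- simulate_binding_equilibrium(cfg$donor_conc, X * decay,
                                           cfg$kd) / cfg$donor_conc
        ch <- channel_intensities(cfg, X, fb)
        rows[[length(rows) + 1L]] <- plate_rows(
          "sample", sprintf("S%03d", wi), rep, cfg$donor_conc, X, 0,
          ch["dd"], ch["aa"], ch["da"])
        # Non-binding control: same fluorophores, no interaction.
        ch0 <- channel_intensities(cfg, X, 0)
        rows[[length(rows) + 1L]] <- plate_rows(
          "nonbinding_control", sprintf("N%03d", wi), rep, cfg$donor_conc,
          X, 0, ch0["dd"], ch0["aa"], ch0["da"])
      }
      # Donor-only control (no acceptor at all).
      dd <- cfg$donor_brightness * cfg$donor_conc
      rows[[length(rows) + 1L]] <- plate_rows(
        "donor_only", sprintf("D%03d", rep), rep, cfg$donor_conc, 0, 0,
        dd, 0, cfg$delta * dd)
    }
    # Acceptor-only controls across the nonzero grid.
    for (X in setdiff(cfg$acceptor_grid, 0)) {
      wi <- wi + 1L
      aa <- cfg$acceptor_brightness * X
      rows[[length(rows) + 1L]] <- plate_rows(
        "acceptor_only", sprintf("A%03d", wi), 1L, 0, X, 0,
        0, aa, cfg$alpha * aa)
    }
    out <- do.call(rbind, rows)
    out$intensity <- apply_noise(out$intensity, cfg$noise_cv,
                                 cfg$noise_floor)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a competitive-inhibition dose-response plate
#'
#' Fixed donor and acceptor concentrations; the competitor binds the donor
#' at the same site with dissociation constant `ki` (pure competition, the
#' Cheng-Prusoff assumption). The bound fraction at each dose comes from
#' the coupled mass-action solver. Artifact modes generate instructive
#' failure cases for the dual-criterion hit rule: `"quencher"` scales all
#' channels down with dose without displacing the complex.
#'
#' @param config A [fret_sim_config()]; `acceptor_grid` is ignored.
#' @param ki Competitor dissociation constant, uM.
#' @param doses Inhibitor concentrations, uM (include 0 for normalisation
#'   anchors).
#' @param acceptor_conc Fixed acceptor concentration, uM (default 1).
#' @param compound_id `sample_id` for the generated wells.
#' @param artifact `"none"` or `"quencher"`.
#' @return Long-format plate data frame.
#' @export
simulate_competition_plate <- function(config, ki,
                                       doses = c(0, 10^seq(-2, 2,
                                                           length.out = 12)),
                                       acceptor_conc = 1,
                                       compound_id = "compound",
                                       artifact = c("none", "quencher")) {
  stopifnot(inherits(config, "fret_sim_config"))
  artifact <- match.arg(artifact)
  cfg <- config
  with_seed(cfg$seed, {
    rows <- list()
    wi <- 0L
    for (rep in seq_len(cfg$replicates)) {
      for (dose in doses) {
        wi <- wi + 1L
        fb <- if (artifact == "quencher") {
          simulate_binding_equilibrium(cfg$donor_conc, acceptor_conc,
                                       cfg$kd) / cfg$donor_conc
        } else {
          simulate_binding_equilibrium(cfg$donor_conc, acceptor_conc,
                                       cfg$kd, competitor_conc = dose,
                                       competitor_ki = ki) / cfg$donor_conc
        }
        ch <- channel_intensities(cfg, acceptor_conc, fb)
        if (artifact == "quencher") ch <- ch / (1 + dose / ki)
        rows[[length(rows) + 1L]] <- plate_rows(
          compound_id, sprintf("C%03d", wi), rep, cfg$donor_conc,
          acceptor_conc, dose, ch["dd"], ch["aa"], ch["da"])
      }
    }
    out <- do.call(rbind, rows)
    out$intensity <- apply_noise(out$intensity, cfg$noise_cv,
                                 cfg$noise_floor)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a single-concentration screening plate
#'
#' Control wells (no inhibitor) plus one block of wells per compound at the
#' screening concentration. Compound behaviour is set per row of
#' `compounds`: a true competitive inhibitor (`artifact = "none"`, potency
#' `ki`), or a channel `"quencher"` artifact that lowers every intensity
#' without displacing the complex.
#'
#' @param config A [fret_sim_config()].
#' @param compounds Data frame with columns `id`, `ki`, `artifact`.
#' @param screen_conc Screening concentration, uM (default 50).
#' @param acceptor_conc Fixed acceptor concentration, uM (default 1).
#' @return Long-format plate data frame with `sample_id = "control"` wells
#'   and one `sample_id` per compound.
#' @export
simulate_screen_plate <- function(config, compounds, screen_conc = 50,
                                  acceptor_conc = 1) {
  stopifnot(inherits(config, "fret_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    rows <- list()
    fb0 <- simulate_binding_equilibrium(cfg$donor_conc, acceptor_conc,
                                        cfg$kd) / cfg$donor_conc
    for (rep in seq_len(cfg$replicates)) {
      ch <- channel_intensities(cfg, acceptor_conc, fb0)
      rows[[length(rows) + 1L]] <- plate_rows(
        "control", sprintf("K%03d", rep), rep, cfg$donor_conc,
        acceptor_conc, 0, ch["dd"], ch["aa"], ch["da"])
      for (i in seq_len(nrow(compounds))) {
        art <- compounds$artifact[i]
        fb <- if (art == "quencher") fb0 else {
          simulate_binding_equilibrium(cfg$donor_conc, acceptor_conc,
                                       cfg$kd, competitor_conc = screen_conc,
                                       competitor_ki = compounds$ki[i]) /
            cfg$donor_conc
        }
        ch <- channel_intensities(cfg, acceptor_conc, fb)
        if (art == "quencher") ch <- ch / (1 + screen_conc / compounds$ki[i])
        rows[[length(rows) + 1L]] <- plate_rows(
          compounds$id[i], sprintf("W%03d_%d", i, rep), rep,
          cfg$donor_conc, acceptor_conc, screen_conc,
          ch["dd"], ch["aa"], ch["da"])
      }
    }
    out <- do.call(rbind, rows)
    out$intensity <- apply_noise(out$intensity, cfg$noise_cv,
                                 cfg$noise_floor)
    rownames(out) <- NULL
    out
  })
}

#' Melt-curve simulation configuration
#'
#' Two-state thermodynamics: `K_u(T) = exp(-(dH - T dS)/(R T))`,
#' `P_u = K_u / (1 + K_u)`, `Tm = dH / dS`. A three-state curve adds a
#' second sequential transition (`delta_h2`, `delta_s2`) with an
#' intermediate fluorescence level. Defaults give a single transition at
#' 323.0 K with dH = 100 kcal/mol on a 30-95 C, 0.5 C grid.
#'
#' @param delta_h,delta_s Unfolding enthalpy (kcal/mol) and entropy
#'   (kcal/(mol K)) of the (first) transition.
#' @param delta_h2,delta_s2 Optional second transition (used when
#'   `n_states = 3` in [simulate_melt_curve()]). Defaults place sharp
#'   transitions at 322.25 K and 327.69 K.
#' @param baseline_n,baseline_u Native / unfolded fluorescence baselines as
#'   `c(intercept, slope_per_K)`, RFU.
#' @param intermediate_level Fluorescence of the intermediate state as a
#'   fraction of the native-to-unfolded step.
#' @param aggregation_rate Post-peak exponential signal decay per K
#'   (0 = none), emulating dye loss on aggregation.
#' @param temp_celsius Temperature grid, degrees C.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Seed; mandatory when `noise_cv > 0`.
#' @return Object of class `melt_sim_config`.
#' @export
melt_sim_config <- function(delta_h = 100, delta_s = 100 / 323,
                            delta_h2 = 250, delta_s2 = 250 / 327.69,
                            baseline_n = c(200, 0),
                            baseline_u = c(1800, 0),
                            intermediate_level = 0.5,
                            aggregation_rate = 0,
                            temp_celsius = seq(30, 95, by = 0.5),
                            noise_cv = 0, seed = NULL) {
  if (delta_h <= 0 || delta_s <= 0)
    stop_invalid("delta_h and delta_s must be > 0")
  tm <- delta_h / delta_s
  tk <- celsius_to_kelvin(temp_celsius)
  if (tm < min(tk) || tm > max(tk))
    stop_invalid(sprintf("Tm = %.1f K lies outside the temperature grid", tm))
  if (noise_cv > 0 && is.null(seed))
    stop_invalid("a seed is mandatory for stochastic output")
  structure(
    list(delta_h = delta_h, delta_s = delta_s, delta_h2 = delta_h2,
         delta_s2 = delta_s2, baseline_n = baseline_n,
         baseline_u = baseline_u, intermediate_level = intermediate_level,
         aggregation_rate = aggregation_rate, temp_celsius = temp_celsius,
         noise_cv = noise_cv, seed = seed),
    class = "melt_sim_config"
  )
}

#' Simulate a DSF melt curve
#'
#' @param config A [melt_sim_config()].
#' @param n_states 2 for a single unfolding transition, 3 for a sequential
#'   native -> intermediate -> unfolded profile.
#' @param sample_id,replicate Labels.
#' @return A [melt_curve()].
#' @export
simulate_melt_curve <- function(config, n_states = 2L, sample_id = "sim",
                                replicate = 1L) {
  stopifnot(inherits(config, "melt_sim_config"), n_states %in% c(2L, 3L))
  cfg <- config
  with_seed(cfg$seed, {
    tk <- celsius_to_kelvin(cfg$temp_celsius)
    bn <- cfg$baseline_n[1L] + cfg$baseline_n[2L] * (tk - min(tk))
    bu <- cfg$baseline_u[1L] + cfg$baseline_u[2L] * (tk - min(tk))
    ku1 <- exp(-(cfg$delta_h - tk * cfg$delta_s) / (R_KCAL * tk))
    if (n_states == 2L) {
      pu <- ku1 / (1 + ku1)
      f <- (1 - pu) * bn + pu * bu
    } else {
      # Sequential N <-> I <-> U; populations from the two equilibrium
      # constants, intermediate fluorescence between the baselines.
      ku2 <- exp(-(cfg$delta_h2 - tk * cfg$delta_s2) / (R_KCAL * tk))
      pn <- 1 / (1 + ku1 + ku1 * ku2)
      pi_ <- ku1 * pn
      pu <- ku1 * ku2 * pn
      bi <- bn + cfg$intermediate_level * (bu - bn)
      f <- pn * bn + pi_ * bi + pu * bu
    }
    if (cfg$aggregation_rate > 0) {
      # Dye signal decays once unfolding is essentially complete and
      # aggregates start sequestering the dye.
      done <- which(pu >= 0.99)
      onset <- if (length(done) > 0) tk[done[1L]] else max(tk)
      f <- f * exp(-cfg$aggregation_rate * pmax(0, tk - onset))
    }
    if (cfg$noise_cv > 0) f <- f * (1 + cfg$noise_cv * stats::rnorm(length(f)))
    melt_curve(tk, f, sample_id, replicate)
  })
}

#' Simulate a chemical-denaturation curve
#'
#' Single or double logistic decay of normalised fluorescence with urea
#' concentration. Defaults reproduce a two-state profile with midpoint
#' 3.32 M, or a biphasic profile with midpoints 1.56 M and 3.95 M when
#' `n_transitions = 2`.
#'
#' @param a1,a2 Initial and final plateau values.
#' @param x0 Midpoint(s), M: length `n_transitions`.
#' @param p Power(s): length 1 or `n_transitions`.
#' @param n_transitions 1 or 2.
#' @param mid Intermediate plateau value for biphasic curves (default
#'   halfway between `a1` and `a2`).
#' @param urea Concentration grid, M.
#' @param noise_cv Multiplicative noise CV; `seed` mandatory when > 0.
#' @param seed Seed.
#' @param sample_id,replicate Labels.
#' @return A [denaturation_curve()].
#' @export
simulate_urea_curve <- function(a1 = 1, a2 = 0, x0 = NULL, p = 10,
                                n_transitions = 1L, mid = (a1 + a2) / 2,
                                urea = seq(0, 8, by = 0.25),
                                noise_cv = 0, seed = NULL,
                                sample_id = "sim", replicate = 1L) {
  stopifnot(n_transitions %in% c(1L, 2L))
  if (is.null(x0)) x0 <- if (n_transitions == 1L) 3.32 else c(1.56, 3.95)
  if (length(x0) != n_transitions)
    stop_invalid("x0 must have one midpoint per transition")
  p <- rep_len(p, n_transitions)
  if (noise_cv > 0 && is.null(seed))
    stop_invalid("a seed is mandatory for stochastic output")
  with_seed(seed, {
    y <- if (n_transitions == 1L) {
      logistic_denaturation_model(urea, a1, a2, x0[1L], p[1L])
    } else {
      logistic_denaturation_model(urea, a1, mid, x0[1L], p[1L]) +
        logistic_denaturation_model(urea, 0, a2 - mid, x0[2L], p[2L])
    }
    if (noise_cv > 0) y <- y * (1 + noise_cv * stats::rnorm(length(y)))
    denaturation_curve(urea, y, sample_id, replicate)
  })
}

#' Work-distribution simulation configuration
#'
#' @param true_dg Target free-energy difference, kcal/mol.
#' @param sigma Work standard deviation, kcal/mol.
#' @param n_per_direction Samples per direction.
#' @param temperature Temperature, K.
#' @param seed Seed (mandatory).
#' @return Object of class `work_sim_config`.
#' @export
work_sim_config <- function(true_dg = 1.0, sigma = 0.5,
                            n_per_direction = 10000L, temperature = 300,
                            seed = NULL) {
  if (sigma <= 0) stop_invalid("sigma must be > 0")
  if (is.null(seed)) stop_invalid("a seed is mandatory for stochastic output")
  structure(
    list(true_dg = true_dg, sigma = sigma,
         n_per_direction = as.integer(n_per_direction),
         temperature = temperature, seed = seed),
    class = "work_sim_config"
  )
}

#' Simulate Crooks-consistent Gaussian work distributions
#'
#' Draws `Wf ~ N(dG + sigma^2 / (2 RT), sigma^2)` and
#' `Wr ~ N(-dG + sigma^2 / (2 RT), sigma^2)`; with equal variances this
#' pair satisfies the Crooks fluctuation theorem
#' `ln[Pf(W) / Pr(-W)] = (W - dG)/RT` exactly.
#'
#' @param config A [work_sim_config()].
#' @param edge_label Label for the generated edge.
#' @return A [work_set()].
#' @export
simulate_work_values <- function(config, edge_label = "sim") {
  stopifnot(inherits(config, "work_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    rt <- R_KCAL * cfg$temperature
    shift <- cfg$sigma^2 / (2 * rt)
    wf <- stats::rnorm(cfg$n_per_direction, cfg$true_dg + shift, cfg$sigma)
    wr <- stats::rnorm(cfg$n_per_direction, -cfg$true_dg + shift, cfg$sigma)
    work_set(wf, wr, cfg$temperature, edge_label)
  })
}
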