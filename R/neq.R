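# Free-energy estimation from nonequilibrium work distributions.
#
# Sign conventions: all stored work values are work performed ON the system
# in the stated transition direction. Forward works drive A -> B; reverse
# works drive B -> A and are kept in their own frame, so the Crooks
# comparison uses -Wr. All estimates are reported in the A -> B frame.

#' Work set for one alchemical edge
#'
#' @param forward Forward (A to B) work values, kcal/mol.
#' @param reverse Reverse (B to A) work values, kcal/mol, in the reverse
#'   direction's own frame.
#' @param temperature Temperature, K (default 300).
#' @param edge_label Label for the transformation edge.
#' @return Object of class `work_set`.
#' @export
work_set <- function(forward, reverse = numeric(0), temperature = 300,
                     edge_label = "edge") {
  if (temperature <= 0) stop_invalid("temperature must be > 0")
  if (any(!is.finite(c(forward, reverse))))
    stop_invalid("work values must be finite")
  structure(
    list(edge_label = edge_label, forward = as.numeric(forward),
         reverse = as.numeric(reverse), temperature = temperature),
    class = "work_set"
  )
}

new_fe_estimate <- function(delta_g, method, uncertainty, n_forward,
                            n_reverse, temperature) {
  structure(
    list(delta_g = delta_g, method = method,
         uncertainty = uncertainty, n_forward = n_forward,
         n_reverse = n_reverse, temperature = temperature),
    class = "fe_estimate"
  )
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("dG = %.4f +/- %.4f kcal/mol  [%s, nF = %d, nR = %d, T = %g K]\n",
              x$delta_g, x$uncertainty, x$method, x$n_forward, x$n_reverse,
              x$temperature))
  invisible(x)
}

# Exponential-average core: -RT log< exp(-W/RT) >, computed via log-sum-exp.
jarzynski_core <- function(work, rt) -rt * log_mean_exp(-work / rt)

#' Jarzynski free-energy estimate from one work direction
#'
#' `dG = -RT ln< exp(-W/RT) >` over forward works; for reverse works the
#' same average estimates the B-to-A free energy, so the A-to-B estimate is
#' its negation. The exponential average is evaluated with a log-sum-exp
#' formulation and is dominated by rare low-work tails, making this the
#' noisiest of the estimators here.
#'
#' @param work Work values, kcal/mol, all in `direction`'s frame.
#' @param temperature Temperature, K.
#' @param direction `"forward"` or `"reverse"`.
#' @param n_boot Bootstrap resamples for the uncertainty (default 200).
#' @param seed Seed for the bootstrap (the estimate itself is
#'   deterministic).
#' @return A `fe_estimate` (method `jarzynski_forward` or
#'   `jarzynski_reverse`), reported in the A-to-B frame.
#' @export
jarzynski <- function(work, temperature = 300,
                      direction = c("forward", "reverse"),
                      n_boot = 200L, seed = NULL) {
  direction <- match.arg(direction)
  if (length(work) == 0) stop_invalid("work list is empty")
  if (temperature <= 0) stop_invalid("temperature must be > 0")
  rt <- R_KCAL * temperature
  sgn <- if (direction == "forward") 1 else -1
  dg <- sgn * jarzynski_core(work, rt)
  unc <- 0
  if (length(work) > 1 && n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        jarzynski_core(sample(work, replace = TRUE), rt)
      }, numeric(1))
    })
    unc <- stats::sd(boots)
  }
  new_fe_estimate(dg, paste0("jarzynski_", direction), unc,
                  n_forward = if (direction == "forward") length(work) else 0L,
                  n_reverse = if (direction == "reverse") length(work) else 0L,
                  temperature = temperature)
}

# Intersection of N(mf, sf^2) and N(mr, sr^2) densities; root between the
# means where possible.
gaussian_intersection <- function(mf, sf, mr, sr) {
  if (abs(sf - sr) <= 1e-6 * max(sf, sr)) return((mf + mr) / 2)
  a <- 1 / sf^2 - 1 / sr^2
  b <- -2 * mf / sf^2 + 2 * mr / sr^2
  c <- mf^2 / sf^2 - mr^2 / sr^2 + 2 * log(sf / sr)
  disc <- b^2 - 4 * a * c
  if (disc < 0)
    stop_estimation(sprintf(
      "forward N(%.4g, %.4g^2) and reverse N(%.4g, %.4g^2) densities do not intersect",
      mf, sf, mr, sr))
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  inside <- roots >= min(mf, mr) & roots <= max(mf, mr)
  if (any(inside)) roots[inside][1L] else roots[which.min(abs(roots - (mf + mr) / 2))]
}

#' Crooks-Gaussian-intersection free-energy estimate
#'
#' Fits Gaussians to the forward work distribution and to the negated
#' reverse work distribution; by the Crooks fluctuation theorem the two
#' densities cross at `W = dG`. In the equal-variance case this reduces to
#' `(mean(Wf) - mean(Wr)) / 2`.
#'
#' @param workset A [work_set()] with >= 2 samples in each direction.
#' @param n_boot Bootstrap resamples for the uncertainty.
#' @param seed Bootstrap seed.
#' @return A `fe_estimate` (method `cgi`).
#' @export
crooks_gaussian_intersection <- function(workset, n_boot = 200L,
                                         seed = NULL) {
  stopifnot(inherits(workset, "work_set"))
  wf <- workset$forward
  wr_neg <- -workset$reverse
  if (length(wf) < 2 || length(wr_neg) < 2)
    stop_invalid("CGI needs >= 2 work samples in each direction")
  point <- function(f, r) {
    gaussian_intersection(mean(f), max(stats::sd(f), .Machine$double.eps),
                          mean(r), max(stats::sd(r), .Machine$double.eps))
  }
  dg <- point(wf, wr_neg)
  unc <- 0
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        tryCatch(point(sample(wf, replace = TRUE),
                       sample(wr_neg, replace = TRUE)),
                 fretstab_error = function(e) NA_real_)
      }, numeric(1))
    })
    unc <- stats::sd(boots, na.rm = TRUE)
  }
  new_fe_estimate(dg, "cgi", unc, length(wf), length(wr_neg),
                  workset$temperature)
}

#' Bennett-acceptance-ratio free-energy estimate
#'
#' Solves the BAR self-consistency equation
#' \deqn{\sum_i f(\beta(M + W_{f,i} - \Delta G)) =
#'       \sum_j f(\beta(-M + W_{r,j} + \Delta G))}
#' with `f` the logistic function and `M = RT ln(n_f / n_r)`, by bracketed
#' root finding to an absolute tolerance of 1e-8 kcal/mol. The reported
#' uncertainty is the asymptotic maximum-likelihood variance estimate.
#'
#' @param workset A [work_set()] with >= 2 samples in each direction.
#' @return A `fe_estimate` (method `bar`).
#' @export
bar <- function(workset) {
  stopifnot(inherits(workset, "work_set"))
  wf <- workset$forward
  wr <- workset$reverse
  if (length(wf) < 2 || length(wr) < 2)
    stop_invalid("BAR needs >= 2 work samples in each direction")
  rt <- R_KCAL * workset$temperature
  beta <- 1 / rt
  nf <- length(wf); nr <- length(wr)
  m <- rt * log(nf / nr)
  fermi <- function(t) 1 / (1 + exp(t))
  g <- function(dg) {
    sum(fermi(beta * (m + wf - dg))) - sum(fermi(beta * (-m + wr + dg)))
  }
  span <- max(abs(c(wf, -wr))) + abs(m) + 50 * rt
  if (g(-span) * g(span) > 0)
    stop_estimation(paste0(
      "forward and reverse work distributions do not overlap; ",
      "BAR is unsolvable - collect more sampling"))
  dg <- stats::uniroot(g, lower = -span, upper = span, tol = 1e-10)$root
  # Asymptotic ML variance (Bennett 1976 / Shirts et al. 2003).
  ff <- fermi(beta * (m + wf - dg))
  fr <- fermi(beta * (-m + wr + dg))
  if (mean(ff) < 1e-12 || mean(fr) < 1e-12)
    stop_estimation(paste0(
      "forward and reverse work distributions barely overlap at the ",
      "solution; the BAR estimate is unreliable - collect more sampling"))
  var_b <- rt^2 * (mean(ff^2) / (nf * mean(ff)^2) +
                     mean(fr^2) / (nr * mean(fr)^2) - 1 / nf - 1 / nr)
  new_fe_estimate(dg, "bar", sqrt(max(var_b, 0)), nf, nr,
                  workset$temperature)
}

#' Relative free-energy difference from two thermodynamic-cycle legs
#'
#' For an alchemical mutation, the vertical legs of the thermodynamic cycle
#' are the mutation free energies in a reference environment (leg 1: the
#' unfolded-state tripeptide, or free receptor) and in the environment of
#' interest (leg 2: the folded protein, or the complex);
#' `ddG = dG_2 - dG_1`.
#'
#' @param leg1,leg2 `fe_estimate` objects at the same temperature.
#' @param kind `"folding"` or `"affinity"` (bookkeeping label).
#' @param replica_ddgs Optional numeric vector of per-replica ddG
#'   estimates; when supplied, the uncertainty is their standard deviation
#'   instead of the per-leg quadrature.
#' @return Object of class `ddg_result`: `ddg`, `uncertainty`, `kind`,
#'   `leg1`, `leg2`.
#' @export
ddg_from_legs <- function(leg1, leg2, kind = c("folding", "affinity"),
                          replica_ddgs = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(leg1, "fe_estimate"), inherits(leg2, "fe_estimate"))
  if (!isTRUE(all.equal(leg1$temperature, leg2$temperature)))
    stop_invalid(sprintf("leg temperatures differ: %g K vs %g K",
                         leg1$temperature, leg2$temperature))
  unc <- if (!is.null(replica_ddgs)) {
    stats::sd(replica_ddgs)
  } else {
    sqrt(leg1$uncertainty^2 + leg2$uncertainty^2)
  }
  structure(
    list(ddg = leg2$delta_g - leg1$delta_g, uncertainty = unc, kind = kind,
         leg1 = leg1, leg2 = leg2),
    class = "ddg_result"
  )
}

#' @export
print.ddg_result <- function(x, ...) {
  cat(sprintf("ddG_%s = %.3f +/- %.3f kcal/mol\n", x$kind, x$ddg,
              x$uncertainty))
  invisible(x)
}

#' Thermodynamic cycle closure
#'
#' Sums signed ddG values around a closed path of states. Edges may be
#' listed in either orientation; an edge traversed against its stated
#' direction contributes with flipped sign. For converged, consistent
#' estimates the closure is zero within statistical error; the result is
#' flagged when `|closure|` exceeds `tolerance`.
#'
#' @param edges Data frame with columns `from`, `to`, `ddg` and optionally
#'   `uncertainty` (kcal/mol), describing a closed path.
#' @param tolerance Flagging threshold on `|closure|`, kcal/mol
#'   (default 0.5).
#' @return Object of class `cycle_closure`: `closure` (kcal/mol),
#'   `uncertainty` (quadrature over edges, 0 if none supplied), `flagged`,
#'   `tolerance`, `path`.
#' @export
cycle_closure <- function(edges, tolerance = 0.5) {
  need <- c("from", "to", "ddg")
  if (!all(need %in% names(edges)))
    stop_invalid("edges must have columns from, to, ddg")
  if (nrow(edges) < 2) stop_invalid("a cycle needs >= 2 edges")
  state <- edges$from[1L]
  start <- state
  total <- 0
  path <- state
  for (i in seq_len(nrow(edges))) {
    if (edges$from[i] == state) {
      total <- total + edges$ddg[i]
      state <- edges$to[i]
    } else if (edges$to[i] == state) {
      total <- total - edges$ddg[i]
      state <- edges$from[i]
    } else {
      stop_invalid(sprintf(
        "path breaks at edge %d (%s -> %s): current state is '%s'",
        i, edges$from[i], edges$to[i], state))
    }
    path <- c(path, state)
  }
  if (state != start)
    stop_invalid(sprintf("path is not closed: ends at '%s', started at '%s'",
                         state, start))
  unc <- if ("uncertainty" %in% names(edges)) {
    sqrt(sum(edges$uncertainty^2))
  } else 0
  structure(
    list(closure = total, uncertainty = unc,
         flagged = abs(total) > tolerance, tolerance = tolerance,
         path = path),
    class = "cycle_closure"
  )
}

#' @export
print.cycle_closure <- function(x, ...) {
  cat(sprintf("Cycle %s: closure = %.4f kcal/mol (tolerance %.2f)%s\n",
              paste(x$path, collapse = " -> "), x$closure, x$tolerance,
              if (x$flagged) "  ** exceeds tolerance **" else ""))
  invisible(x)
}
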