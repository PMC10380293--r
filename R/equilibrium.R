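#' Exact mass-action binding equilibrium, optionally with a competitor
#'
#' Solves the 1:1 equilibrium `D + A <-> DA` (dissociation constant `kd`) for
#' the bound complex concentration, given total concentrations `a` (donor,
#' the fixed partner) and `X` (acceptor, the titrated partner). With a
#' competitor `I` that binds the donor at the same site (`D + I <-> DI`,
#' dissociation constant `ki`), the coupled mass balances are solved by
#' bracketed root finding on the free donor concentration.
#'
#' This routine is the independent mass-action oracle behind both the
#' binding isotherm ([emfret_model()] must agree with it to ~1e-10) and the
#' competition generator; it deliberately takes the direct quadratic /
#' root-finding route rather than the rearranged fitting formula.
#'
#' @param a Total donor concentration, uM (> 0).
#' @param X Total acceptor concentration(s), uM (>= 0). Vectorised.
#' @param kd Donor-acceptor dissociation constant, uM (> 0).
#' @param competitor_conc Total competitor concentration, uM (default 0).
#' @param competitor_ki Competitor dissociation constant, uM; required when
#'   `competitor_conc > 0`.
#' @param tol Absolute tolerance on free-donor concentration for the
#'   competitive root find (uM).
#' @return Bound complex concentration(s) `[DA]` in uM, `<= min(a, X)`
#'   elementwise.
#' @examples
#' simulate_binding_equilibrium(1, 1, 1) / 1  # (3 - sqrt(5))/2
#' @export
simulate_binding_equilibrium <- function(a, X, kd,
                                         competitor_conc = 0,
                                         competitor_ki = NULL,
                                         tol = 1e-10) {
  if (a <= 0) stop_domain("total donor concentration `a` must be > 0")
  if (kd <= 0) stop_domain("`kd` must be > 0")
  if (any(X < 0)) stop_domain("acceptor concentrations must be >= 0")
  if (competitor_conc < 0) stop_domain("competitor concentration must be >= 0")
  if (competitor_conc > 0) {
    if (is.null(competitor_ki) || competitor_ki <= 0)
      stop_domain("`competitor_ki` must be > 0 when a competitor is present")
    return(vapply(X, function(x) {
      if (x == 0) return(0)
      # Mass balance on total donor as a function of free donor d:
      #   a = d + d x /(kd + d) + d I/(ki + d); monotone increasing in d.
      f <- function(d) {
        d + d * x / (kd + d) + d * competitor_conc / (competitor_ki + d) - a
      }
      d <- stats::uniroot(f, lower = 0, upper = a, tol = tol)$root
      d * x / (kd + d)
    }, numeric(1)))
  }
  # No competitor: stable closed-form quadratic root for [DA].
  s <- a + X + kd
  2 * a * X / (s + sqrt(s * s - 4 * a * X))
}
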