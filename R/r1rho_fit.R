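#' Mono-exponential decay fit with Monte Carlo errors
#'
#' Least-squares fit of `I0 * exp(-R * t)` to intensity-versus-delay data.
#' The uncertainty of R is the standard deviation of the rate over
#' `n_monte_carlo` refits in which Gaussian noise at the residual scale is
#' added to the fitted curve.
#'
#' @param intensities Positive intensities.
#' @param delays Relaxation delays (s), same length, >= 3 values.
#' @param n_monte_carlo Number of noise resamples (0 skips the error
#'   estimate).
#' @return List with `rate` (s^-1), `i0`, `error` (NA when skipped),
#'   `residual_sd` and logical `decaying` (FALSE flags a non-positive
#'   fitted rate).
#' @export
fit_decay <- function(intensities, delays, n_monte_carlo = 500) {
  stopifnot(length(intensities) == length(delays), length(delays) >= 3)
  if (any(intensities <= 0))
    stop("fit_decay: intensities must be > 0 for a mono-exponential fit")
  ls_fit <- function(y) {
    # log-linear solution, exact for noiseless data, then refined on the
    # natural scale
    cf <- stats::lm.fit(cbind(1, delays), log(y))$coefficients
    start <- list(i0 = exp(cf[[1]]), r = -cf[[2]])
    pred0 <- start$i0 * exp(-start$r * delays)
    if (max(abs(y - pred0)) <= 1e-10 * max(abs(y)))
      return(unlist(start))  # already exact (noiseless data)
    fit <- tryCatch(
      stats::nls(y ~ i0 * exp(-r * delays), start = start,
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) unlist(start) else stats::coef(fit)
  }
  cf <- ls_fit(intensities)
  i0 <- cf[[1]]; rate <- cf[[2]]
  pred <- i0 * exp(-rate * delays)
  rsd <- stats::sd(intensities - pred)
  if (!is.finite(rsd)) rsd <- 0
  err <- NA_real_
  if (n_monte_carlo > 0 && rsd > 0) {
    draws <- vapply(seq_len(n_monte_carlo), function(i) {
      y <- pred + stats::rnorm(length(pred), sd = rsd)
      y[y <= 0] <- .Machine$double.eps
      ls_fit(y)[[2]]
    }, numeric(1))
    err <- stats::sd(draws)
  }
  decaying <- rate > 0
  if (!decaying)
    warning("fit_decay: fitted rate is not positive")
  list(rate = rate, i0 = i0, error = err, residual_sd = rsd,
       decaying = decaying)
}

#' Off-resonance dispersion profile
#'
#' Applies the `(R2 + Rex) = (R1rho - R1 cos^2 theta) / sin^2 theta`
#' transform to each measured condition and returns it against the
#' rotating-frame offset `Omega_eff / 2pi` in Hz. On-axis conditions
#' (`sin theta = 0`) are excluded with a warning.
#'
#' @param conditions List of [spinlock_condition()] objects.
#' @param r1rho_values Measured R1rho per condition (s^-1).
#' @param r1 Longitudinal relaxation rate (s^-1).
#' @return Data frame with columns `offset_hz`, `power_hz`, `theta`,
#'   `r2_plus_rex`.
#' @export
dispersion_profile <- function(conditions, r1rho_values, r1) {
  stopifnot(length(conditions) == length(r1rho_values))
  rows <- lapply(seq_along(conditions), function(i) {
    sl <- conditions[[i]]
    if (abs(sin(sl$theta)) < 1e-6) {
      warning("dispersion_profile: skipping on-axis condition at offset ",
              sl$offset_hz, " Hz")
      return(NULL)
    }
    data.frame(offset_hz = sl$offset_hz, power_hz = sl$power_hz,
               theta = sl$theta,
               r2_plus_rex = r2eff_transform(r1rho_values[i], r1, sl$theta))
  })
  do.call(rbind, rows)
}

#' Two-state Bloch-McConnell fit of R1rho dispersion data
#'
#' Minimizes the error-weighted squared difference between measured R1rho
#' values and values simulated with [r1rho_value()] over the spin-lock
#' grid. Parameter uncertainties come from Monte Carlo resampling of the
#' R1rho values within their errors followed by refitting.
#'
#' @param conditions List of [spinlock_condition()] objects.
#' @param r1rho_values,r1rho_errors Measured rates and their errors
#'   (s^-1).
#' @param start_grid,bounds As in [fit_two_state()].
#' @param n_refine Number of multistart refinements.
#' @param n_monte_carlo Monte Carlo iterations for parameter errors
#'   (0 skips them).
#' @return A list of class `r1rho_fit` with `pars`, `errors`, `chisq`,
#'   `r_chi2`, `fitted`, `n`, `k`.
#' @export
fit_r1rho_bm <- function(conditions, r1rho_values, r1rho_errors,
                         start_grid = default_start_grid(),
                         bounds = default_bounds(),
                         n_refine = 3, n_monte_carlo = 0) {
  stopifnot(length(conditions) == length(r1rho_values),
            length(r1rho_values) == length(r1rho_errors),
            all(r1rho_errors > 0))
  bl <- bounds$lower; bu <- bounds$upper
  sim <- function(par) {
    model <- two_state_model(par[["p_es"]], par[["k_ex"]],
                             par[["delta_omega_ppm"]],
                             r1_gs = par[["r1"]], r2_gs = par[["r2"]])
    vapply(conditions, function(sl) r1rho_value(model, sl)$r1rho,
           numeric(1))
  }
  fit_once <- function(y, starts) {
    run <- function(p0) {
      nm <- names(p0)
      minpack.lm::nls.lm(
        par = p0,
        fn = function(p) { names(p) <- nm; (y - sim(p)) / r1rho_errors },
        lower = bl[nm], upper = bu[nm],
        control = minpack.lm::nls.lm.control(maxiter = 150))
    }
    obj0 <- vapply(starts, function(p)
      sum(((y - sim(p)) / r1rho_errors)^2), numeric(1))
    keep <- order(obj0)[seq_len(min(n_refine, length(starts)))]
    fits <- lapply(starts[keep], run)
    fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]
  }
  r2_seed <- max(bl[["r2"]], min(min(r1rho_values), bu[["r2"]]))
  starts <- lapply(seq_len(nrow(start_grid)), function(i)
    c(p_es = start_grid$p_es[i], k_ex = start_grid$k_ex[i],
      delta_omega_ppm = start_grid$delta_omega_ppm[i],
      r1 = 2, r2 = r2_seed))
  best <- fit_once(r1rho_values, starts)
  par <- best$par
  errors <- rep(NA_real_, length(par)); names(errors) <- names(par)
  if (n_monte_carlo > 0) {
    draws <- vapply(seq_len(n_monte_carlo), function(i) {
      y <- r1rho_values + stats::rnorm(length(r1rho_values),
                                       sd = r1rho_errors)
      fit_once(y, list(par))$par
    }, numeric(length(par)))
    errors <- apply(draws, 1, stats::sd)
    names(errors) <- names(par)
  }
  fitted <- sim(par)
  n <- length(r1rho_values); k <- length(par)
  chisq <- best$deviance
  structure(list(pars = par, errors = errors, chisq = chisq,
                 r_chi2 = chisq / (n - k), fitted = fitted,
                 n = n, k = k, converged = best$info %in% 1:4),
            class = "r1rho_fit")
}

#' @export
print.r1rho_fit <- function(x, ...) {
  cat("Bloch-McConnell R1rho fit\n")
  cat(sprintf("  pES = %.4g %%  kex = %.5g s-1  dw = %.3f ppm\n",
              100 * x$pars[["p_es"]], x$pars[["k_ex"]],
              x$pars[["delta_omega_ppm"]]))
  cat(sprintf("  R1 = %.3f  R2 = %.3f s-1   rchi2 = %.4g (N = %d)\n",
              x$pars[["r1"]], x$pars[["r2"]], x$r_chi2, x$n))
  invisible(x)
}
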