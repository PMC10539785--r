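#' Bloch-McConnell generator matrix
#'
#' Builds the 6x6 evolution matrix for two-state exchange under continuous
#' RF irradiation, acting on the magnetization vector
#' `(Mx, My, Mz)_GS + (Mx, My, Mz)_ES`. It combines rotation about the
#' effective field (angular offset and `omega1 = 2*pi*b1`), relaxation
#' (R1, R2) and two-site exchange (`k1`, `k-1`). No thermal-recovery source
#' term is included: during the short irradiation delays used here
#' (TEX <= 100 ms << 1/R1) magnetization relaxes toward zero.
#'
#' @param model A [two_state_model()].
#' @param rf An [rf_condition()].
#' @return A 6x6 numeric matrix (units s^-1 / rad s^-1).
#' @export
build_bm_generator <- function(model, rf) {
  stopifnot(inherits(model, "two_state_model"), inherits(rf, "rf_condition"))
  omega1 <- 2 * pi * rf$b1_hz
  # Omega = omegaRF - omegaObs, so the GS angular offset from the carrier
  # is -2*pi*offset_hz; the ES sits dw_rad further away
  omega_gs <- -2 * pi * rf$offset_hz
  dw_rad <- 2 * pi * ppm_to_hz(model$delta_omega_ppm, rf$spectrometer_mhz)
  bm_generator_cpp(model$p_es, model$k_ex, dw_rad,
                   model$r1_gs, model$r1_es, model$r2_gs, model$r2_es,
                   omega1, omega_gs)
}

#' Propagate magnetization under constant irradiation
#'
#' Applies the matrix exponential of the generator times `t_ex` to an
#' initial magnetization vector. Exact for piecewise-constant RF.
#'
#' @inheritParams build_bm_generator
#' @param m0 Numeric vector of length 6,
#'   `(Mx, My, Mz)_GS` followed by `(Mx, My, Mz)_ES`.
#' @return The magnetization after `rf$t_ex` seconds.
#' @export
bm_propagate <- function(model, rf, m0) {
  stopifnot(length(m0) == 6, all(is.finite(m0)))
  L <- build_bm_generator(model, rf)
  as.numeric(bm_propagate_cpp(L, rf$t_ex, as.numeric(m0)))
}

#' Equilibrium longitudinal magnetization
#'
#' @param model A [two_state_model()].
#' @return Length-6 vector with `Mz_GS = 1 - p_es`, `Mz_ES = p_es`.
#' @export
equilibrium_magnetization <- function(model) {
  c(0, 0, 1 - model$p_es, 0, 0, model$p_es)
}

#' Gaussian quadrature nodes for B1 inhomogeneity averaging
#'
#' The B1 distribution is modelled as a Gaussian centred on the nominal
#' amplitude with fractional FWHM `fwhm`, discretized on `n_points` evenly
#' spaced nodes spanning +/- `span` standard deviations with weights
#' proportional to the Gaussian density (renormalized). The default is
#' deliberately dense: near resonance the magnetization nutates coherently
#' at the effective field, and the continuous B1 distribution dephases
#' those oscillations completely by the end of a 100 ms irradiation. A
#' trapezoidal rule reproduces that dephasing only while the aliasing
#' revival time `1 / node spacing` exceeds the irradiation delay, which
#' for B1 up to 1 kHz, 10 % FWHM and TEX = 100 ms requires node spacings
#' below about 8 Hz - hence 33 nodes over +/- 3 sigma.
#'
#' @param b1_hz Nominal RF amplitude (Hz).
#' @param fwhm Fractional FWHM of the B1 distribution.
#' @param n_points Number of nodes (>= 1); `NULL` selects the count from
#'   the aliasing-revival rule for the given `t_ex`.
#' @param span Half-range in standard deviations.
#' @param t_ex Irradiation delay (s) entering the adaptive node-count
#'   rule.
#' @return List with numeric vectors `b1` (Hz, floored at 0) and `w`
#'   (weights summing to 1).
#' @export
b1_quadrature <- function(b1_hz, fwhm, n_points = NULL, span = 3,
                          t_ex = 0.1) {
  if (is.null(n_points)) {
    # node spacing below 1/(t_ex + 4.3/(2 pi sigma)) keeps the first
    # trapezoidal aliasing revival beyond the irradiation delay
    sigma <- fwhm / (2 * sqrt(2 * log(2))) * b1_hz
    n_points <- if (sigma <= 0) 1L else
      max(5L, as.integer(ceiling(2 * span * sigma * t_ex + 4.2)) + 1L)
  }
  stopifnot(n_points >= 1)
  if (fwhm <= 0 || n_points == 1 || b1_hz == 0)
    return(list(b1 = b1_hz, w = 1))
  sigma <- fwhm / (2 * sqrt(2 * log(2))) * b1_hz
  nodes <- seq(-span, span, length.out = n_points) * sigma + b1_hz
  w <- stats::dnorm(nodes, mean = b1_hz, sd = sigma)
  list(b1 = pmax(nodes, 0), w = w / sum(w))
}

#' CEST intensity for one irradiation condition
#'
#' Starting from equilibrium longitudinal magnetization, propagates through
#' the irradiation delay and returns the summed Mz of both states divided
#' by its value at `t_ex = 0` (which is 1). When
#' `rf$inhomogeneity_fwhm > 0` the intensity is averaged over the Gaussian
#' B1 distribution via [b1_quadrature()].
#'
#' @inheritParams build_bm_generator
#' @param n_b1 Number of quadrature nodes for inhomogeneity averaging.
#' @return Normalized intensity (dimensionless).
#' @export
cest_intensity <- function(model, rf, n_b1 = NULL) {
  q <- b1_quadrature(rf$b1_hz, rf$inhomogeneity_fwhm, n_b1, t_ex = rf$t_ex)
  dw_rad <- 2 * pi * ppm_to_hz(model$delta_omega_ppm, rf$spectrometer_mhz)
  omega_gs <- -2 * pi * rf$offset_hz
  vals <- cest_intensity_batch_cpp(
    model$p_es, model$k_ex, dw_rad,
    model$r1_gs, model$r1_es, model$r2_gs, model$r2_es, rf$t_ex,
    2 * pi * q$b1, rep(omega_gs, length(q$b1)))
  sum(q$w * as.numeric(vals))
}

#' CEST profile over a grid of powers and offsets
#'
#' Vectorized forward model: one intensity per row of
#' `(b1_hz, offset_hz)`, each averaged over B1 inhomogeneity.
#'
#' @inheritParams cest_intensity
#' @param b1_hz,offset_hz Equal-length numeric vectors defining the grid.
#' @param t_ex Irradiation delay (s).
#' @param spectrometer_mhz Larmor frequency (MHz).
#' @param inhomogeneity_fwhm Fractional FWHM of the B1 distribution.
#' @return Numeric vector of normalized intensities.
#' @export
cest_profile_model <- function(model, b1_hz, offset_hz, t_ex,
                               spectrometer_mhz = 600,
                               inhomogeneity_fwhm = 0, n_b1 = NULL) {
  stopifnot(length(b1_hz) == length(offset_hz))
  dw_rad <- 2 * pi * ppm_to_hz(model$delta_omega_ppm, spectrometer_mhz)
  out <- numeric(length(b1_hz))
  # group by power so each group shares one quadrature rule; all
  # (node, offset) pairs of a power go through one batched call
  for (b1 in unique(b1_hz)) {
    idx <- which(b1_hz == b1)
    q <- b1_quadrature(b1, inhomogeneity_fwhm, n_b1, t_ex = t_ex)
    og <- -2 * pi * offset_hz[idx]
    nn <- length(q$b1)
    vals <- cest_intensity_batch_cpp(
      model$p_es, model$k_ex, dw_rad,
      model$r1_gs, model$r1_es, model$r2_gs, model$r2_es, t_ex,
      rep(2 * pi * q$b1, each = length(idx)), rep(og, nn))
    out[idx] <- as.numeric(matrix(vals, ncol = nn) %*% q$w)
  }
  out
}

#' R1rho for one spin-lock condition
#'
#' Simulates the decay of magnetization prepared along the chosen effective
#' field, projects it back onto that axis at each delay, and fits a
#' mono-exponential to the projected intensities. Initial magnetization is
#' aligned along the ground-state effective field in slow exchange
#' (`kex / |dw_rad| < 1`) and along the population-averaged effective field
#' otherwise.
#'
#' @param model A [two_state_model()].
#' @param sl A [spinlock_condition()].
#' @return List with `r1rho` (s^-1), `theta` (radians) and the simulated
#'   `intensities` at `sl$delays`.
#' @export
r1rho_value <- function(model, sl) {
  stopifnot(inherits(model, "two_state_model"),
            inherits(sl, "spinlock_condition"))
  sim <- r1rho_simulate(model, sl)
  delays <- sl$delays
  if (length(delays) < 3)
    stop("r1rho_value: need >= 3 delays")
  fit <- fit_decay(sim$intensities, delays, n_monte_carlo = 0)
  if (!is.finite(fit$rate))
    stop("r1rho_value: signal does not decay mono-exponentially")
  list(r1rho = fit$rate, theta = sim$theta, intensities = sim$intensities)
}

# Simulate projected magnetization under a spin lock. Internally the
# carrier offset is negated to reuse the CEST convention.
r1rho_simulate <- function(model, sl) {
  omega1 <- 2 * pi * sl$power_hz
  dw_rad <- 2 * pi * ppm_to_hz(model$delta_omega_ppm, sl$spectrometer_mhz)
  omega_gs <- 2 * pi * sl$offset_hz  # Omega_eff = omegaObs - omegaRF
  fast <- model$k_ex / max(abs(dw_rad), .Machine$double.eps) >= 1
  omega_align <- if (fast) omega_gs + model$p_es * dw_rad else omega_gs
  theta <- atan2(omega1, omega_align)
  u <- c(sin(theta), 0, cos(theta))
  m0 <- c(u * (1 - model$p_es), u * model$p_es)
  rf <- rf_condition(sl$power_hz, -sl$offset_hz, t_ex = 0,
                     spectrometer_mhz = sl$spectrometer_mhz)
  L <- build_bm_generator(model, rf)
  inten <- vapply(sl$delays, function(t) {
    m <- as.numeric(bm_propagate_cpp(L, t, m0))
    sum(u * m[1:3]) + sum(u * m[4:6])
  }, numeric(1))
  list(intensities = inten, theta = theta, m0 = m0)
}

#' Transform R1rho to an exchange-broadened transverse rate
#'
#' Removes the longitudinal contribution from a measured R1rho:
#' `(R2 + Rex) = (R1rho - R1 * cos^2(theta)) / sin^2(theta)`.
#'
#' @param r1rho Measured rotating-frame relaxation rate (s^-1).
#' @param r1 Longitudinal relaxation rate (s^-1).
#' @param theta Tilt angle of the effective field (radians), in `(0, pi)`
#'   excluding the poles.
#' @return `R2 + Rex` in s^-1.
#' @export
r2eff_transform <- function(r1rho, r1, theta) {
  s2 <- sin(theta)^2
  if (any(s2 < 1e-12))
    stop("r2eff_transform: undefined for theta = 0 or pi (sin(theta) = 0)")
  (r1rho - r1 * cos(theta)^2) / s2
}

#' Laguerre closed-form approximation to R1rho
#'
#' Second-order approximation for two-site exchange outside the slow-exchange
#' limit (Miloushev & Palmer 2005). Used as an independent reference for the
#' numerical simulation in its regime of validity; not used in fitting.
#'
#' @param model A [two_state_model()].
#' @param sl A [spinlock_condition()].
#' @return Approximate R1rho (s^-1).
#' @export
r1rho_laguerre <- function(model, sl) {
  pG <- 1 - model$p_es
  pE <- model$p_es
  dw <- 2 * pi * ppm_to_hz(model$delta_omega_ppm, sl$spectrometer_mhz)
  kex <- model$k_ex
  w1 <- 2 * pi * sl$power_hz
  oG <- 2 * pi * sl$offset_hz
  oE <- oG + dw
  obar <- pG * oG + pE * oE
  weG2 <- oG^2 + w1^2
  weE2 <- oE^2 + w1^2
  we2 <- obar^2 + w1^2
  theta <- atan2(w1, obar)
  s2 <- sin(theta)^2
  num <- s2 * pG * pE * dw^2 * kex
  den <- weG2 * weE2 / we2 + kex^2 -
    s2 * pG * pE * dw^2 *
      (1 + 2 * kex^2 * (pG * weG2 + pE * weE2) / (weG2 * weE2 + we2 * kex^2))
  rex <- num / den
  model$r1_gs * cos(theta)^2 + model$r2_gs * s2 + rex
}
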