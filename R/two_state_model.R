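#' Two-state exchange model
#'
#' Defines a ground-state (GS) / excited-state (ES) conformational exchange,
#' e.g. a Watson-Crick ground state exchanging with a transient Hoogsteen
#' base pair. The forward and backward rate constants follow from the
#' excited-state population and the total exchange rate:
#' \eqn{k_1 = p_{ES} k_{ex}}, \eqn{k_{-1} = (1 - p_{ES}) k_{ex}}, so that
#' \eqn{k_1 + k_{-1} = k_{ex}} exactly and detailed balance
#' \eqn{p_{GS} k_1 = p_{ES} k_{-1}} holds.
#'
#' @param p_es Excited-state population as a fraction in `[0, 0.5)`.
#' @param k_ex Total exchange rate `k1 + k-1` (s^-1), >= 0.
#' @param delta_omega_ppm ES minus GS chemical-shift difference (ppm);
#'   upfield-shifted Hoogsteen imino protons give negative values.
#' @param r1_gs,r1_es Longitudinal relaxation rates (s^-1).
#' @param r2_gs,r2_es Transverse relaxation rates (s^-1). `r1_es`/`r2_es`
#'   default to the GS values, the tying used during fitting where the ES
#'   rates are not identifiable.
#' @return An object of class `two_state_model`.
#' @export
two_state_model <- function(p_es, k_ex, delta_omega_ppm,
                            r1_gs, r2_gs,
                            r1_es = r1_gs, r2_es = r2_gs) {
  vals <- c(p_es = p_es, k_ex = k_ex, delta_omega_ppm = delta_omega_ppm,
            r1_gs = r1_gs, r2_gs = r2_gs, r1_es = r1_es, r2_es = r2_es)
  if (any(!is.finite(vals)))
    stop("two_state_model: all parameters must be finite numbers")
  if (p_es < 0 || p_es >= 0.5)
    stop("two_state_model: p_es must lie in [0, 0.5)")
  if (k_ex < 0) stop("two_state_model: k_ex must be >= 0")
  if (any(c(r1_gs, r2_gs, r1_es, r2_es) < 0))
    stop("two_state_model: relaxation rates must be >= 0")
  structure(list(p_es = p_es, k_ex = k_ex,
                 delta_omega_ppm = delta_omega_ppm,
                 r1_gs = r1_gs, r2_gs = r2_gs,
                 r1_es = r1_es, r2_es = r2_es),
            class = "two_state_model")
}

#' @export
print.two_state_model <- function(x, ...) {
  k <- split_rates(x$p_es, x$k_ex)
  cat("Two-state exchange model\n")
  cat(sprintf("  pES = %.4g %%   kex = %.6g s-1  (k1 = %.4g, k-1 = %.4g s-1)\n",
              100 * x$p_es, x$k_ex, k[["k1"]], k[["k_minus1"]]))
  cat(sprintf("  dw(ES-GS) = %.4g ppm\n", x$delta_omega_ppm))
  cat(sprintf("  R1 = %.4g / %.4g s-1   R2 = %.4g / %.4g s-1  (GS/ES)\n",
              x$r1_gs, x$r1_es, x$r2_gs, x$r2_es))
  invisible(x)
}

#' Split an exchange rate into forward and backward rate constants
#'
#' @param p_es Excited-state population (fraction).
#' @param k_ex Total exchange rate (s^-1).
#' @return Named numeric vector `c(k1 = p_es * k_ex, k_minus1 = (1 - p_es) * k_ex)`.
#' @export
split_rates <- function(p_es, k_ex) {
  c(k1 = p_es * k_ex, k_minus1 = (1 - p_es) * k_ex)
}

#' One CEST irradiation condition
#'
#' @param b1_hz RF amplitude (Hz), >= 0.
#' @param offset_hz Offset of the RF carrier from the observed resonance,
#'   `Omega = omegaRF - omegaObs`, in Hz.
#' @param t_ex Irradiation (relaxation) delay in seconds, >= 0.
#' @param spectrometer_mhz 1H Larmor frequency in MHz (ppm-to-Hz factor).
#' @param inhomogeneity_fwhm Fractional full width at half maximum of the
#'   Gaussian B1 distribution (0 = perfectly homogeneous field).
#' @return An object of class `rf_condition`.
#' @export
rf_condition <- function(b1_hz, offset_hz, t_ex,
                         spectrometer_mhz = 600,
                         inhomogeneity_fwhm = 0) {
  vals <- c(b1_hz, offset_hz, t_ex, spectrometer_mhz, inhomogeneity_fwhm)
  if (any(!is.finite(vals)))
    stop("rf_condition: all parameters must be finite")
  if (b1_hz < 0 || t_ex < 0 || spectrometer_mhz <= 0 || inhomogeneity_fwhm < 0)
    stop("rf_condition: b1_hz, t_ex, inhomogeneity_fwhm >= 0 and spectrometer_mhz > 0 required")
  structure(list(b1_hz = b1_hz, offset_hz = offset_hz, t_ex = t_ex,
                 spectrometer_mhz = spectrometer_mhz,
                 inhomogeneity_fwhm = inhomogeneity_fwhm),
            class = "rf_condition")
}

#' One off-resonance spin-lock condition
#'
#' The offset follows the rotating-frame convention used for R1rho,
#' `Omega_eff = omegaObs - omegaRF` (opposite in sign to the CEST offset);
#' conversions happen internally.
#'
#' @param power_hz Spin-lock amplitude (Hz), > 0.
#' @param offset_hz `omegaObs - omegaRF` in Hz.
#' @param delays Relaxation delays (s) at which intensities are sampled.
#' @param spectrometer_mhz Larmor frequency (MHz) of the observed nucleus.
#' @return An object of class `spinlock_condition` with the tilt angle
#'   `theta = atan2(power, offset)` (radians) precomputed.
#' @export
spinlock_condition <- function(power_hz, offset_hz,
                               delays = seq(0, 0.055, length.out = 7),
                               spectrometer_mhz = 600) {
  if (!is.finite(power_hz) || !is.finite(offset_hz) || power_hz <= 0)
    stop("spinlock_condition: power_hz must be finite and > 0")
  if (any(delays < 0)) stop("spinlock_condition: delays must be >= 0")
  theta <- atan2(power_hz, offset_hz)
  structure(list(power_hz = power_hz, offset_hz = offset_hz,
                 delays = sort(unique(delays)), theta = theta,
                 spectrometer_mhz = spectrometer_mhz),
            class = "spinlock_condition")
}

ppm_to_hz <- function(ppm, spectrometer_mhz) ppm * spectrometer_mhz
hz_to_ppm <- function(hz, spectrometer_mhz) hz / spectrometer_mhz
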