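#' Physical constants used in the van 't Hoff analysis
#'
#' Boltzmann and Planck constants in SI units, the gas constant in
#' kcal mol^-1 K^-1 (energies are reported in kcal/mol), and the
#' transmission coefficient, taken as unity.
#' @keywords internal
thermo_constants <- function() {
  list(kB = 1.380649e-23,          # J K-1
       h = 6.62607015e-34,         # J s
       R = 1.98720425e-3,          # kcal mol-1 K-1
       kappa = 1)
}

#' Harmonic-mean temperature
#'
#' `Thm = n / sum(1/Ti)`; the reference temperature at which activation
#' free energies are reported, chosen to decorrelate the fitted enthalpy
#' and free energy.
#'
#' @param temperatures Temperatures in kelvin (> 0).
#' @return Thm in kelvin.
#' @export
harmonic_mean_temperature <- function(temperatures) {
  if (length(temperatures) == 0)
    stop("harmonic_mean_temperature: empty temperature list")
  if (any(temperatures <= 0))
    stop("harmonic_mean_temperature: temperatures must be > 0 K")
  length(temperatures) / sum(1 / temperatures)
}

# ln(k/T) predicted by transition-state theory with the enthalpy/free
# energy parameterized at the reference temperature t_ref
vant_hoff_log_rate <- function(dG_ref, dH, temperature, t_ref) {
  const <- thermo_constants()
  log(const$kB * const$kappa / const$h) -
    dG_ref / (const$R * t_ref) -
    (dH / const$R) * (1 / temperature - 1 / t_ref)
}

#' Rate series container for van 't Hoff analysis
#'
#' @param temperatures Kelvin.
#' @param k1,k_minus1 Forward and backward rate constants (s^-1).
#' @param k1_err,k_minus1_err Optional standard errors (s^-1).
#' @return A `rate_series` data frame.
#' @export
rate_series <- function(temperatures, k1, k_minus1,
                        k1_err = NULL, k_minus1_err = NULL) {
  n <- length(temperatures)
  stopifnot(length(k1) == n, length(k_minus1) == n)
  if (any(temperatures <= 0)) stop("rate_series: temperatures must be > 0 K")
  if (any(c(k1, k_minus1) <= 0)) stop("rate_series: rates must be > 0")
  out <- data.frame(temperature_K = temperatures, k1 = k1,
                    k_minus1 = k_minus1,
                    k1_err = if (is.null(k1_err)) NA_real_ else k1_err,
                    k_minus1_err = if (is.null(k_minus1_err)) NA_real_
                                   else k_minus1_err)
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Van 't Hoff fit of forward and backward rate constants
#'
#' Fits `ln(ki/T) = ln(kB kappa / h) - dG(Thm)/(R Thm)
#' - (dH/R) (1/T - 1/Thm)` separately for the forward (i = 1) and
#' backward (i = -1) directions. The model is linear in the two unknowns,
#' so the fit is an (optionally weighted) linear regression; weights are
#' `1 / sigma^2` on the log-rate scale with `sigma = k_err / k` by
#' first-order propagation. Entropies follow from the identity
#' `T dS = dH - dG` at `Thm`, and equilibrium thermodynamics from the
#' difference of the two activation directions.
#'
#' @param series A [rate_series()].
#' @param weighted Use rate errors as weights when available.
#' @return A `thermo_result` with per-direction activation parameters
#'   (kcal/mol), their standard errors, the pooled coefficient of
#'   determination on the rate scale, `t_hm`, and equilibrium `dG0`,
#'   `dH0`, `tds0`.
#' @export
fit_van_t_hoff <- function(series, weighted = TRUE) {
  stopifnot(inherits(series, "rate_series"))
  tk <- series$temperature_K
  if (length(unique(tk)) < 3)
    stop("fit_van_t_hoff: need >= 3 distinct temperatures")
  const <- thermo_constants()
  t_hm <- harmonic_mean_temperature(tk)
  x <- 1 / tk - 1 / t_hm

  fit_dir <- function(k, k_err) {
    y <- log(k / tk)
    w <- if (weighted && all(is.finite(k_err)) && all(k_err > 0))
      (k / k_err)^2 else rep(1, length(k))
    fit <- stats::lm(y ~ x, weights = w)
    cf <- stats::coef(fit)
    vc <- stats::vcov(fit)
    dG <- (log(const$kB * const$kappa / const$h) - cf[[1]]) * const$R * t_hm
    dH <- -cf[[2]] * const$R
    dG_err <- sqrt(vc[1, 1]) * const$R * t_hm
    dH_err <- sqrt(vc[2, 2]) * const$R
    k_fit <- tk * exp(stats::fitted(fit))
    list(dG = dG, dH = dH, tds = dH - dG,
         dG_err = dG_err, dH_err = dH_err,
         # tds = a*R*Thm - b*R - ln(kB/h)*R*Thm with (a, b) = coefficients
         tds_err = sqrt(max(vc[1, 1] * (const$R * t_hm)^2 +
                              vc[2, 2] * const$R^2 -
                              2 * vc[1, 2] * const$R^2 * t_hm, 0)),
         k_fit = k_fit)
  }

  fwd <- fit_dir(series$k1, series$k1_err)
  bwd <- fit_dir(series$k_minus1, series$k_minus1_err)

  k_exp <- c(series$k1, series$k_minus1)
  k_fit <- c(fwd$k_fit, bwd$k_fit)
  ss_res <- sum((k_fit - k_exp)^2)
  ss_tot <- sum((k_exp - mean(k_exp))^2)

  structure(list(t_hm = t_hm,
                 forward = fwd[c("dG", "dH", "tds", "dG_err", "dH_err",
                                 "tds_err")],
                 backward = bwd[c("dG", "dH", "tds", "dG_err", "dH_err",
                                  "tds_err")],
                 dG0 = fwd$dG - bwd$dG, dH0 = fwd$dH - bwd$dH,
                 tds0 = (fwd$dH - fwd$dG) - (bwd$dH - bwd$dG),
                 r_squared = 1 - ss_res / ss_tot,
                 k1_fit = fwd$k_fit, k_minus1_fit = bwd$k_fit),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Van 't Hoff analysis (Thm = %.2f K, R2 = %.5f)\n",
              x$t_hm, x$r_squared))
  fmt <- function(d, lab)
    cat(sprintf("  %s: dG = %.3f +/- %.3f, dH = %.3f +/- %.3f, -TdS = %.3f kcal/mol\n",
                lab, d$dG, d$dG_err, d$dH, d$dH_err, -d$tds))
  fmt(x$forward, "GS -> ES ")
  fmt(x$backward, "ES -> GS ")
  cat(sprintf("  equilibrium: dG0 = %.3f, dH0 = %.3f, -TdS0 = %.3f kcal/mol\n",
              x$dG0, x$dH0, -x$tds0))
  invisible(x)
}
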