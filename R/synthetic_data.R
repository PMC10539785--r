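#' Simulation specification for synthetic CEST datasets
#'
#' Captures the acquisition envelope of an imino 1H CEST measurement:
#' RF powers, an offset grid about the observed resonance, the irradiation
#' delay, spectrometer frequency, homoscedastic Gaussian intensity noise
#' per power, zero-delay reference replicates, and the fractional B1
#' inhomogeneity. The defaults mirror a typical 600 MHz acquisition:
#' offsets -6 to +6 ppm in 0.1 ppm steps, powers {250, 500, 1000} Hz,
#' TEX = 100 ms, 0.5 % noise and triplicate references.
#'
#' @param model A [two_state_model()] (ground truth).
#' @param powers RF amplitudes (Hz).
#' @param offset_ppm Offset grid (ppm) about the observed resonance.
#' @param t_ex Irradiation delay (s).
#' @param spectrometer_mhz Larmor frequency (MHz).
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   reference intensity.
#' @param n_zero_delay_replicates Reference scans per power.
#' @param inhomogeneity_fwhm Fractional B1 FWHM used in the forward model.
#' @param seed Integer seed; fixes the dataset bit-for-bit.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(model,
                            powers = c(250, 500, 1000),
                            offset_ppm = seq(-6, 6, by = 0.1),
                            t_ex = 0.1,
                            spectrometer_mhz = 600,
                            noise_sd = 0.005,
                            n_zero_delay_replicates = 3,
                            inhomogeneity_fwhm = 0.1,
                            seed = 1L) {
  stopifnot(inherits(model, "two_state_model"), noise_sd >= 0,
            n_zero_delay_replicates >= 1)
  structure(list(model = model, powers = powers, offset_ppm = offset_ppm,
                 t_ex = t_ex, spectrometer_mhz = spectrometer_mhz,
                 noise_sd = noise_sd,
                 n_zero_delay_replicates = n_zero_delay_replicates,
                 inhomogeneity_fwhm = inhomogeneity_fwhm,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a raw (pre-normalization) synthetic CEST intensity table
#'
#' For each (power, offset) the raw intensity is
#' `scale * I_model + N(0, noise_sd * scale)` where `I_model` is the
#' inhomogeneity-averaged Bloch-McConnell intensity, plus
#' `n_zero_delay_replicates` reference scans per power at `t_ex = 0`
#' carrying the same noise. Deterministic under the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @param scale Arbitrary raw-intensity scale (peak height units).
#' @param resonance_id Label carried into the table.
#' @return Data frame with columns `resonance_id`, `b1_hz`, `offset_hz`,
#'   `t_ex_s`, `replicate`, `intensity`.
#' @export
generate_cest_dataset <- function(spec, scale = 1e5, resonance_id = "sim") {
  stopifnot(inherits(spec, "simulation_spec"))
  withr_seed(spec$seed, {
    offs_hz <- ppm_to_hz(spec$offset_ppm, spec$spectrometer_mhz)
    grid <- expand.grid(b1_hz = spec$powers, offset_hz = offs_hz)
    ideal <- cest_profile_model(spec$model, grid$b1_hz, grid$offset_hz,
                                spec$t_ex,
                                spectrometer_mhz = spec$spectrometer_mhz,
                                inhomogeneity_fwhm = spec$inhomogeneity_fwhm)
    meas <- data.frame(resonance_id = resonance_id,
                       b1_hz = grid$b1_hz, offset_hz = grid$offset_hz,
                       t_ex_s = spec$t_ex, replicate = 1L,
                       intensity = scale * ideal +
                         stats::rnorm(nrow(grid), 0, spec$noise_sd * scale))
    refs <- expand.grid(b1_hz = spec$powers,
                        replicate = seq_len(spec$n_zero_delay_replicates))
    refs <- data.frame(resonance_id = resonance_id, b1_hz = refs$b1_hz,
                       offset_hz = 0, t_ex_s = 0,
                       replicate = refs$replicate,
                       intensity = scale +
                         stats::rnorm(nrow(refs), 0, spec$noise_sd * scale))
    rbind(refs, meas)
  })
}

#' Generate a synthetic off-resonance R1rho decay table
#'
#' Decay curves are generated from [r1rho_value()] with multiplicative
#' Gaussian noise. The default delay grid keeps the maximal spin-lock
#' duration under 60 ms, long enough for roughly 70 % intensity loss at
#' typical rates.
#'
#' @param model A [two_state_model()] (ground truth).
#' @param conditions List of [spinlock_condition()] objects.
#' @param noise_sd Fractional intensity noise.
#' @param seed Integer seed.
#' @return Data frame with columns `power_hz`, `offset_hz`, `delay_s`,
#'   `intensity`, plus the true rate per condition in attribute
#'   `true_r1rho`.
#' @export
generate_r1rho_dataset <- function(model, conditions, noise_sd = 0.01,
                                   seed = 1L) {
  withr_seed(seed, {
    truth <- numeric(length(conditions))
    rows <- lapply(seq_along(conditions), function(i) {
      sl <- conditions[[i]]
      rv <- r1rho_value(model, sl)
      truth[i] <<- rv$r1rho
      ideal <- rv$intensities / rv$intensities[1]
      data.frame(power_hz = sl$power_hz, offset_hz = sl$offset_hz,
                 delay_s = sl$delays,
                 intensity = ideal * (1 + stats::rnorm(length(ideal), 0,
                                                       noise_sd)))
    })
    out <- do.call(rbind, rows)
    attr(out, "true_r1rho") <- truth
    out
  })
}

#' Generate a rate series from activation thermodynamics
#'
#' Forward and backward rate constants are computed from transition-state
#' theory with the stated activation free energies (at the harmonic-mean
#' temperature of the grid) and enthalpies, with optional log-normal
#' multiplicative noise.
#'
#' @param dG_fwd,dH_fwd,dG_bwd,dH_bwd Activation free energies at `Thm`
#'   and enthalpies, kcal/mol.
#' @param temperatures Kelvin (>= 3 values for a fit).
#' @param noise Fractional (log-normal) rate noise.
#' @param seed Integer seed.
#' @return A [rate_series()]; errors set to `noise * k` when noise > 0.
#' @export
generate_rate_series <- function(dG_fwd, dH_fwd, dG_bwd, dH_bwd,
                                 temperatures, noise = 0, seed = 1L) {
  t_hm <- harmonic_mean_temperature(temperatures)
  k1 <- temperatures *
    exp(vant_hoff_log_rate(dG_fwd, dH_fwd, temperatures, t_hm))
  km1 <- temperatures *
    exp(vant_hoff_log_rate(dG_bwd, dH_bwd, temperatures, t_hm))
  if (noise > 0) {
    withr_seed(seed, {
      k1n <- k1 * exp(stats::rnorm(length(k1), 0, noise))
      km1n <- km1 * exp(stats::rnorm(length(km1), 0, noise))
      rate_series(temperatures, k1n, km1n,
                  k1_err = noise * k1n, k_minus1_err = noise * km1n)
    })
  } else {
    rate_series(temperatures, k1, km1)
  }
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
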