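#' Normalize raw CEST intensities by zero-delay triplicates
#'
#' Each raw intensity is divided by the mean of the zero-delay reference
#' scans recorded at the same RF power; the per-power uncertainty is the
#' standard deviation of those references propagated onto the normalized
#' scale, and is shared by all offsets of that power.
#'
#' @param raw Data frame with columns `b1_hz`, `offset_hz`, `t_ex_s`,
#'   `replicate`, `intensity` (a `resonance_id` column is carried through
#'   if present). Rows with `t_ex_s == 0` are the reference scans.
#' @param spectrometer_mhz Larmor frequency (MHz), stored on the profile.
#' @param sigma_floor Substitute uncertainty when the reference scans have
#'   zero spread (noiseless synthetic data); applied with a warning.
#' @return A `cest_profile`: data frame with columns `b1_hz`, `offset_hz`,
#'   `intensity`, `sigma` and attributes `t_ex`, `spectrometer_mhz`,
#'   `resonance_id`.
#' @export
normalize_profile <- function(raw, spectrometer_mhz = 600,
                              sigma_floor = 1e-4) {
  need <- c("b1_hz", "offset_hz", "t_ex_s", "intensity")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("normalize_profile: missing columns: ", paste(miss, collapse = ", "))
  t_ex <- unique(raw$t_ex_s[raw$t_ex_s > 0])
  if (length(t_ex) != 1)
    stop("normalize_profile: expected exactly one non-zero relaxation delay, got ",
         length(t_ex))
  res_id <- if ("resonance_id" %in% names(raw)) unique(raw$resonance_id)[1] else NA
  pieces <- lapply(unique(raw$b1_hz), function(b1) {
    ref <- raw$intensity[raw$b1_hz == b1 & raw$t_ex_s == 0]
    if (length(ref) < 1)
      stop("normalize_profile: no zero-delay reference scans for power ",
           b1, " Hz")
    m <- mean(ref)
    s <- if (length(ref) > 1) stats::sd(ref) else 0
    sig <- s / abs(m)
    if (!is.finite(sig) || sig <= 0) {
      warning("normalize_profile: zero reference spread at ", b1,
              " Hz; using floor uncertainty ", sigma_floor)
      sig <- sigma_floor
    }
    sub <- raw[raw$b1_hz == b1 & raw$t_ex_s > 0, , drop = FALSE]
    data.frame(b1_hz = sub$b1_hz, offset_hz = sub$offset_hz,
               intensity = sub$intensity / m, sigma = sig)
  })
  out <- do.call(rbind, pieces)
  structure(out, t_ex = t_ex, spectrometer_mhz = spectrometer_mhz,
            resonance_id = res_id,
            class = c("cest_profile", "data.frame"))
}

#' Restrict a CEST profile to an offset window
#'
#' Points with `|offset| > window_ppm` are discarded; the window guards
#' against cross-relaxation (NOE) artifacts far from the main dip.
#'
#' @param profile A `cest_profile`.
#' @param window_ppm Half-width of the retained window (ppm).
#' @return The restricted profile (same class and attributes).
#' @export
restrict_offsets <- function(profile, window_ppm) {
  mhz <- attr(profile, "spectrometer_mhz")
  keep <- abs(profile$offset_hz) <= ppm_to_hz(window_ppm, mhz) + 1e-9
  if (!any(keep))
    stop("restrict_offsets: no points remain inside +/-", window_ppm, " ppm")
  out <- profile[keep, , drop = FALSE]
  attributes(out)[c("t_ex", "spectrometer_mhz", "resonance_id")] <-
    attributes(profile)[c("t_ex", "spectrometer_mhz", "resonance_id")]
  class(out) <- class(profile)
  out
}

default_start_grid <- function() {
  expand.grid(p_es = c(5e-4, 2e-3, 1e-2),
              k_ex = c(500, 3000, 20000),
              delta_omega_ppm = c(-1, -2))
}

# The delta-omega window is the physically meaningful range for an imino
# proton moving into a Hoogsteen (or related upfield-shifted) excited
# state, with margin around the expected -1 to -2 ppm. Constraining it is
# what keeps the fast-exchange ridge (p_es, dw, kex trading off at
# kex/|dw_rad| >> 1) from wandering to unphysical shift differences.
# The kex floor of 200 s^-1 marks the validity limit of the experiment
# itself: slower exchange is dominated by NOE cross-relaxation artifacts
# and lies below the identifiability floor of high-power irradiation,
# where profiles become invariant along constant p_es * kex.
default_bounds <- function() {
  list(lower = c(p_es = 1e-5, k_ex = 200, delta_omega_ppm = -3,
                 r1 = 0.1, r2 = 1),
       upper = c(p_es = 0.3, k_ex = 1e6, delta_omega_ppm = -0.2,
                 r1 = 10, r2 = 100))
}

profile_residuals <- function(par, profile, t_ex, mhz, fwhm, with_exchange) {
  model <- if (with_exchange) {
    two_state_model(par[["p_es"]], par[["k_ex"]], par[["delta_omega_ppm"]],
                    r1_gs = par[["r1"]], r2_gs = par[["r2"]])
  } else {
    two_state_model(0, 0, 0, r1_gs = par[["r1"]], r2_gs = par[["r2"]])
  }
  fit <- cest_profile_model(model, profile$b1_hz, profile$offset_hz, t_ex,
                            spectrometer_mhz = mhz,
                            inhomogeneity_fwhm = fwhm)
  (profile$intensity - fit) / profile$sigma
}

#' Joint two-state Bloch-McConnell fit of a CEST profile
#'
#' Minimizes the uncertainty-weighted sum of squared residuals over all RF
#' powers jointly, via Levenberg-Marquardt. With exchange the free
#' parameters are `pES`, `kex`, `dw` (ppm), `R1`, `R2` (K = 5), with the
#' excited-state relaxation rates tied to the ground state; without
#' exchange `pES = kex = dw = 0` are frozen and only `R1`, `R2` float
#' (K = 2). The exchange fit is multistarted from a grid of initial
#' guesses; the objective is evaluated at every start and full
#' optimizations are run from the most promising ones.
#'
#' @param profile A `cest_profile` (see [normalize_profile()]).
#' @param with_exchange Logical; fit with or without chemical exchange.
#' @param inhomogeneity_fwhm Fractional FWHM of the B1 distribution used in
#'   the forward model.
#' @param start_grid Data frame of starting values (`p_es`, `k_ex`,
#'   `delta_omega_ppm`); `R1`/`R2` are seeded from the no-exchange fit.
#' @param bounds List with named `lower`/`upper` vectors.
#' @param n_refine Number of grid starts refined by full optimization.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return A `fit_result` with elements `model`, `pars`, `errors`, `rss`
#'   (unweighted), `chisq` (weighted), `n`, `k`, `r_chi2`, `aic`, `bic`,
#'   `fitted`, `with_exchange`, `at_bound`, `converged`.
#' @export
fit_two_state <- function(profile, with_exchange = TRUE,
                          inhomogeneity_fwhm = 0.1,
                          start_grid = default_start_grid(),
                          bounds = default_bounds(),
                          n_refine = 4, maxiter = 200) {
  stopifnot(inherits(profile, "cest_profile"))
  t_ex <- attr(profile, "t_ex")
  mhz <- attr(profile, "spectrometer_mhz")
  bl <- bounds$lower; bu <- bounds$upper

  resid_fn <- function(par, ex) {
    profile_residuals(par, profile, t_ex, mhz, inhomogeneity_fwhm, ex)
  }

  run_lm <- function(par0, ex) {
    nm <- names(par0)
    minpack.lm::nls.lm(
      par = par0, fn = function(p) { names(p) <- nm; resid_fn(p, ex) },
      lower = bl[nm], upper = bu[nm],
      control = minpack.lm::nls.lm.control(maxiter = maxiter))
  }

  # no-exchange fit always runs: it is the null model and seeds R1/R2
  far <- profile$intensity[rank(-abs(profile$offset_hz)) <= 5]
  r1_init <- min(max(-log(max(mean(far), 0.05)) / t_ex, 0.2), 8)
  noex_starts <- lapply(c(5, 20, 50), function(r2)
    c(r1 = r1_init, r2 = r2))
  noex_fits <- lapply(noex_starts, run_lm, ex = FALSE)
  noex <- noex_fits[[which.min(vapply(noex_fits, function(f) f$deviance,
                                      numeric(1)))]]
  if (!with_exchange)
    return(build_fit_result(noex, profile, t_ex, mhz, inhomogeneity_fwhm,
                            FALSE, bl, bu))

  r1_seed <- min(max(noex$par[["r1"]], bl[["r1"]]), bu[["r1"]])
  r2_seed <- min(max(noex$par[["r2"]], bl[["r2"]]), bu[["r2"]])
  starts <- lapply(seq_len(nrow(start_grid)), function(i)
    c(p_es = start_grid$p_es[i], k_ex = start_grid$k_ex[i],
      delta_omega_ppm = start_grid$delta_omega_ppm[i],
      r1 = r1_seed, r2 = r2_seed))
  obj0 <- vapply(starts, function(p) sum(resid_fn(p, TRUE)^2), numeric(1))
  keep <- order(obj0)[seq_len(min(n_refine, length(starts)))]
  fits <- lapply(starts[keep], run_lm, ex = TRUE)
  ok <- vapply(fits, function(f) is.finite(f$deviance), logical(1))
  if (!any(ok))
    stop("fit_two_state: optimizer failed to converge from every start")
  best <- fits[ok][[which.min(vapply(fits[ok], function(f) f$deviance,
                                     numeric(1)))]]
  build_fit_result(best, profile, t_ex, mhz, inhomogeneity_fwhm, TRUE,
                   bl, bu)
}

build_fit_result <- function(lmfit, profile, t_ex, mhz, fwhm,
                             with_exchange, bl, bu) {
  par <- lmfit$par
  nm <- names(par)
  model <- if (with_exchange) {
    two_state_model(par[["p_es"]], par[["k_ex"]], par[["delta_omega_ppm"]],
                    r1_gs = par[["r1"]], r2_gs = par[["r2"]])
  } else {
    two_state_model(0, 0, 0, r1_gs = par[["r1"]], r2_gs = par[["r2"]])
  }
  fitted <- cest_profile_model(model, profile$b1_hz, profile$offset_hz,
                               t_ex, spectrometer_mhz = mhz,
                               inhomogeneity_fwhm = fwhm)
  n <- nrow(profile)
  k <- if (with_exchange) 5L else 2L
  rss_val <- rss(fitted, profile$intensity)
  chisq <- sum(((profile$intensity - fitted) / profile$sigma)^2)
  errors <- rep(NA_real_, length(par))
  names(errors) <- nm
  cov <- tryCatch(solve(lmfit$hessian), error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov)
    errors[d > 0] <- sqrt(d[d > 0])
  }
  tol <- 1e-8
  at_bound <- any(par <= bl[nm] * (1 + tol) + tol |
                    par >= bu[nm] * (1 - tol) - tol)
  if (at_bound && with_exchange)
    warning("fit_two_state: a parameter sits at its bound")
  structure(list(model = model, pars = par, errors = errors,
                 rss = rss_val, chisq = chisq, n = n, k = k,
                 r_chi2 = chisq / (n - k),
                 aic = aic(rss_val, n, k), bic = bic(rss_val, n, k),
                 fitted = fitted, with_exchange = with_exchange,
                 at_bound = at_bound,
                 converged = lmfit$info %in% 1:4,
                 inhomogeneity_fwhm = fwhm),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Bloch-McConnell CEST fit (%s exchange)\n",
              if (x$with_exchange) "with" else "without"))
  if (x$with_exchange)
    cat(sprintf("  pES = %.4g %%  kex = %.5g s-1  dw = %.3f ppm\n",
                100 * x$pars[["p_es"]], x$pars[["k_ex"]],
                x$pars[["delta_omega_ppm"]]))
  cat(sprintf("  R1 = %.3f s-1  R2 = %.3f s-1\n",
              x$pars[["r1"]], x$pars[["r2"]]))
  cat(sprintf("  N = %d  K = %d  RSS = %.4g  rchi2 = %.4g  AIC = %.2f  BIC = %.2f\n",
              x$n, x$k, x$rss, x$r_chi2, x$aic, x$bic))
  invisible(x)
}

#' Reduced chi-square degeneracy scan
#'
#' Fixes one exchange parameter on a log-spaced grid spanning
#' `[best / fold, best * fold]` about its fitted value, refits the
#' remaining parameters from the best-fit solution, and reports the
#' reduced chi-square along the grid. A flat scan signals an
#' unidentifiable parameter; a sharp rise at 3-fold displacement shows
#' the exchange parameters are well determined by the data.
#'
#' @param profile The fitted `cest_profile`.
#' @param fit The unconstrained `fit_result` (with exchange).
#' @param param One of `"k_ex"`, `"delta_omega_ppm"`, `"p_es"`.
#' @param fold Grid half-range factor (> 1).
#' @param n_grid Number of grid points.
#' @param bounds As in [fit_two_state()].
#' @return Data frame with columns `value`, `r_chi2`, `converged`.
#' @export
degeneracy_scan <- function(profile, fit,
                            param = c("k_ex", "delta_omega_ppm", "p_es"),
                            fold = 3, n_grid = 11,
                            bounds = default_bounds()) {
  param <- match.arg(param)
  stopifnot(fold > 1, inherits(fit, "fit_result"), fit$with_exchange)
  t_ex <- attr(profile, "t_ex")
  mhz <- attr(profile, "spectrometer_mhz")
  fwhm <- fit$inhomogeneity_fwhm
  best <- fit$pars[[param]]
  sgn <- sign(best)
  if (sgn == 0) sgn <- 1
  grid <- sgn * exp(seq(log(abs(best) / fold), log(abs(best) * fold),
                        length.out = n_grid))
  free <- setdiff(names(fit$pars), param)
  bl <- bounds$lower; bu <- bounds$upper
  rows <- lapply(grid, function(v) {
    fn <- function(p) {
      names(p) <- free
      full <- c(p, v)
      names(full) <- c(free, param)
      profile_residuals(full, profile, t_ex, mhz, fwhm, TRUE)
    }
    p0 <- pmin(pmax(fit$pars[free], bl[free]), bu[free])
    lmfit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = fn, lower = bl[free],
                         upper = bu[free],
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(lmfit))
      return(data.frame(value = v, r_chi2 = NA_real_, converged = FALSE))
    data.frame(value = v,
               r_chi2 = lmfit$deviance / (nrow(profile) - length(free)),
               converged = lmfit$info %in% 1:4)
  })
  do.call(rbind, rows)
}

#' Calibrate fractional B1 inhomogeneity from a nutation curve
#'
#' Fourier transforms a uniformly sampled on-resonance nutation signal,
#' locates the nutation peak, fits a Gaussian to the magnitude profile
#' around it, and returns the full width at half maximum as a fraction of
#' the nominal RF amplitude.
#'
#' @param intensity Nutation signal sampled at `times`.
#' @param times Uniform sampling times (s).
#' @param nominal_b1 Nominal RF amplitude (Hz).
#' @return List with `fwhm_fraction`, `peak_hz`, `fwhm_hz`.
#' @export
calibrate_inhomogeneity <- function(intensity, times, nominal_b1) {
  n <- length(intensity)
  stopifnot(n == length(times), n >= 8)
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("calibrate_inhomogeneity: sampling must be uniform")
  dt <- dt[1]
  pad <- 4L * stats::nextn(n, 2)
  sig <- c(intensity - mean(intensity), rep(0, pad - n))
  mag <- Mod(stats::fft(sig))[seq_len(pad %/% 2)]
  freq <- (seq_len(pad %/% 2) - 1) / (pad * dt)
  pos <- freq > 0
  if (max(mag[pos]) <= 10 * stats::median(mag[pos]) ||
      max(mag[pos]) < 1e-12)
    stop("calibrate_inhomogeneity: no detectable nutation peak")
  ipk <- which(pos)[which.max(mag[pos])]
  f0 <- freq[ipk]
  half <- mag[ipk] / 2
  win <- which(freq > 0.5 * f0 & freq < 1.5 * f0 & mag > 0.05 * mag[ipk])
  win <- win[abs(win - ipk) < length(freq)]
  df <- data.frame(f = freq[win], m = mag[win])
  s0 <- sqrt(sum(df$m * (df$f - f0)^2) / sum(df$m))
  gfit <- tryCatch(
    stats::nls(m ~ A * exp(-(f - mu)^2 / (2 * s^2)), data = df,
               start = list(A = mag[ipk], mu = f0, s = max(s0, 1 / (n * dt))),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(gfit))
    stop("calibrate_inhomogeneity: Gaussian fit of the nutation peak failed")
  cf <- stats::coef(gfit)
  fwhm_hz <- 2 * sqrt(2 * log(2)) * abs(cf[["s"]])
  list(fwhm_fraction = fwhm_hz / nominal_b1, peak_hz = cf[["mu"]],
       fwhm_hz = fwhm_hz)
}
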