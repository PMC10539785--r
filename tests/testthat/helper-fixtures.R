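# Shared fixtures: all synthetic, built in code.

# reference Hoogsteen-regime model (G6-like): pES 0.3 %, kex 3000 s-1
hg_model <- function(p_es = 0.003, k_ex = 3000, dw = -1.5,
                     r1 = 2, r2 = 20) {
  two_state_model(p_es, k_ex, dw, r1_gs = r1, r2_gs = r2)
}

no_exchange_model <- function(r1 = 2, r2 = 20) {
  two_state_model(0, 0, 0, r1_gs = r1, r2_gs = r2)
}

# small acquisition for unit tests: one/two powers, coarse offsets
small_spec <- function(model, seed = 1, noise_sd = 0.005,
                       powers = c(500, 1000),
                       offset_ppm = seq(-6, 6, by = 0.25), ...) {
  simulation_spec(model, powers = powers, offset_ppm = offset_ppm,
                  noise_sd = noise_sd, seed = seed, ...)
}

make_profile <- function(spec, window = 6) {
  raw <- generate_cest_dataset(spec)
  restrict_offsets(suppressWarnings(normalize_profile(
    raw, spectrometer_mhz = spec$spectrometer_mhz)), window)
}

# independent brute-force propagation oracle: adaptive ODE integration of
# dM/dt = L M at tight tolerance (deSolve), never the matrix exponential
ode_propagate <- function(L, t, m0, tol = 1e-12) {
  sol <- deSolve::ode(y = m0, times = c(0, t),
                      func = function(tt, y, p) list(as.numeric(L %*% y)),
                      atol = tol, rtol = tol, maxsteps = 1e6)
  as.numeric(sol[2, -1])
}

random_model <- function() {
  two_state_model(stats::runif(1, 1e-4, 5e-3),
                  stats::runif(1, 500, 25000),
                  stats::runif(1, -2, -1),
                  r1_gs = stats::runif(1, 1, 4),
                  r2_gs = stats::runif(1, 10, 40))
}
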