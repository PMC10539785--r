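test_that("normalization divides by the triplicate mean and propagates its sd", {
  raw <- data.frame(
    b1_hz = 500, offset_hz = c(0, 0, 0, 300, -300),
    t_ex_s = c(0, 0, 0, 0.1, 0.1), replicate = c(1:3, 1, 1),
    intensity = c(98, 100, 102, 80, 50))
  prof <- normalize_profile(raw)
  expect_s3_class(prof, "cest_profile")
  expect_equal(prof$intensity, c(0.80, 0.50))
  expect_equal(prof$sigma, rep(2 / 100, 2))
  expect_equal(attr(prof, "t_ex"), 0.1)

  # scale invariance: multiplying a power's raw intensities is a no-op
  raw2 <- raw
  raw2$intensity <- raw2$intensity * 37.5
  prof2 <- normalize_profile(raw2)
  expect_equal(prof2$intensity, prof$intensity)
  expect_equal(prof2$sigma, prof$sigma)
})

test_that("zero reference spread triggers the floor uncertainty with a warning", {
  raw <- data.frame(b1_hz = 500, offset_hz = c(0, 0, 0, 100),
                    t_ex_s = c(0, 0, 0, 0.1), replicate = c(1:3, 1),
                    intensity = c(100, 100, 100, 50))
  expect_warning(prof <- normalize_profile(raw), "floor")
  expect_equal(prof$intensity, 0.5)
  expect_equal(prof$sigma, 1e-4)
})

test_that("missing zero-delay references are a hard error", {
  raw <- data.frame(b1_hz = c(500, 1000), offset_hz = c(100, 100),
                    t_ex_s = 0.1, replicate = 1, intensity = c(50, 60))
  expect_error(normalize_profile(raw), "zero-delay")
})

test_that("recovered uncertainty tracks the generating noise level", {
  m <- hg_model()
  sigmas <- unlist(lapply(1:12, function(s) {
    spec <- small_spec(m, seed = 400 + s, noise_sd = 0.005,
                       offset_ppm = seq(-2, 2, by = 1))
    prof <- normalize_profile(generate_cest_dataset(spec))
    unique(prof$sigma)
  }))
  # triplicate sd is chi-distributed around the truth; the mean over many
  # powers should land near 0.005
  expect_gt(mean(sigmas), 0.005 * 0.5)
  expect_lt(mean(sigmas), 0.005 * 1.5)
})

test_that("offset windows retain the expected counts", {
  raw <- data.frame(
    b1_hz = 500,
    offset_hz = c(rep(0, 3), seq(-8, 8, by = 1) * 600),
    t_ex_s = c(rep(0, 3), rep(0.1, 17)), replicate = c(1:3, rep(1, 17)),
    intensity = c(100, 101, 99, rep(50, 17)))
  prof <- normalize_profile(raw)
  expect_equal(nrow(restrict_offsets(prof, 6)), 13)
  expect_equal(nrow(restrict_offsets(prof, 3)), 7)
  expect_equal(nrow(restrict_offsets(prof, 100)), nrow(prof))
  raw2 <- raw[raw$offset_hz != 0 | raw$t_ex_s == 0, ]
  raw2$offset_hz[raw2$t_ex_s == 0] <- 0
  prof2 <- normalize_profile(raw2)
  expect_error(restrict_offsets(prof2, 1e-4), "no points")
})

test_that("noiseless profiles are recovered to optimizer tolerance", {
  m <- hg_model()
  spec <- small_spec(m, noise_sd = 0, powers = 500,
                     offset_ppm = seq(-4, 4, by = 0.25))
  prof <- make_profile(spec)
  fit <- suppressWarnings(fit_two_state(prof, TRUE, n_refine = 2))
  expect_lt(abs(fit$pars[["p_es"]] - 0.003) / 0.003, 1e-3)
  expect_lt(abs(fit$pars[["k_ex"]] - 3000) / 3000, 1e-3)
  expect_lt(abs(fit$pars[["delta_omega_ppm"]] + 1.5) / 1.5, 1e-3)
  expect_lt(abs(fit$pars[["r1"]] - 2) / 2, 1e-3)
  expect_lt(abs(fit$pars[["r2"]] - 20) / 20, 1e-3)
})

test_that("exchange fit beats the nested no-exchange fit on exchange data", {
  m <- hg_model()
  prof <- make_profile(small_spec(m, seed = 21))
  fex <- fit_two_state(prof, TRUE, n_refine = 2)
  fno <- fit_two_state(prof, FALSE)
  expect_lt(fex$rss, fno$rss)
  expect_equal(fex$k, 5L)
  expect_equal(fno$k, 2L)
  expect_equal(fno$pars[["r1"]], 2, tolerance = 0.25)
  # frozen exchange parameters in the null fit
  expect_identical(fno$model$p_es, 0)
  expect_identical(fno$model$k_ex, 0)
})

test_that("parameter recovery within 3-fold across the exchange regime", {
  set.seed(99)
  n <- 12
  pes_t <- exp(runif(n, log(5e-4), log(5e-3)))
  kex_t <- exp(runif(n, log(500), log(25000)))
  ok <- logical(n)
  dws <- numeric(n)
  for (i in seq_len(n)) {
    m <- two_state_model(pes_t[i], kex_t[i], runif(1, -2, -1),
                         r1_gs = 2, r2_gs = 20)
    # full acquisition grid: the 0.1 ppm offset sampling carries the
    # dip-width information that separates pES from kex in slow exchange
    prof <- make_profile(small_spec(m, seed = 600 + i,
                                    powers = c(250, 500, 1000),
                                    offset_ppm = seq(-6, 6, by = 0.1)))
    fit <- suppressWarnings(fit_two_state(prof, TRUE, n_refine = 3))
    rp <- fit$pars[["p_es"]] / pes_t[i]
    rk <- fit$pars[["k_ex"]] / kex_t[i]
    ok[i] <- rp > 1 / 3 && rp < 3 && rk > 1 / 3 && rk < 3
    dws[i] <- fit$pars[["delta_omega_ppm"]]
  }
  expect_gte(mean(ok), 0.95)
  # fitted shift differences stay in the Hoogsteen range
  expect_true(all(dws > -2.5 & dws < -0.5))
})

test_that("degeneracy scan is minimal at the optimum and flat when unidentifiable", {
  m <- hg_model()
  prof <- make_profile(small_spec(m, seed = 31, powers = 500))
  fit <- fit_two_state(prof, TRUE, n_refine = 2)
  scan <- degeneracy_scan(prof, fit, "k_ex", fold = 3, n_grid = 5)
  mid <- scan$r_chi2[3]
  expect_true(all(scan$r_chi2 >= mid - 1e-6))
  expect_gt(max(scan$r_chi2[c(1, 5)]), mid * 1.5)

  # null data: pES is unidentifiable, the scan stays flat
  prof0 <- make_profile(small_spec(no_exchange_model(), seed = 32,
                                   powers = 500,
                                   offset_ppm = seq(-4, 4, by = 0.5)))
  fit0 <- suppressWarnings(fit_two_state(prof0, TRUE, n_refine = 2))
  scan0 <- degeneracy_scan(prof0, fit0, "p_es", fold = 3, n_grid = 5)
  expect_lt(max(scan0$r_chi2) / min(scan0$r_chi2), 1.2)
})

test_that("nutation calibration round-trips a known inhomogeneity width", {
  b1 <- 1000
  fwhm_true <- 0.10
  sigma <- fwhm_true / (2 * sqrt(2 * log(2))) * b1
  tt <- seq(0, 0.4, by = 1e-4)
  nodes <- seq(-3, 3, length.out = 61) * sigma + b1
  w <- dnorm(nodes, b1, sigma); w <- w / sum(w)
  sig <- as.numeric(cos(2 * pi * outer(tt, nodes)) %*% w)
  cal <- calibrate_inhomogeneity(sig, tt, b1)
  expect_equal(cal$peak_hz, b1, tolerance = 0.01)
  expect_equal(cal$fwhm_fraction, fwhm_true, tolerance = 0.2)

  # pure cosine: peak at b1, width at the resolution floor
  cal2 <- calibrate_inhomogeneity(cos(2 * pi * b1 * tt), tt, b1)
  expect_equal(cal2$peak_hz, b1, tolerance = 0.01)
  expect_lt(cal2$fwhm_fraction, 0.02)

  expect_error(calibrate_inhomogeneity(rep(0, 500), seq(0, 0.05, length.out = 500), b1),
               "no detectable")
})
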