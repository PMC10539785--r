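test_that("decoupled limits of the generator behave like free precession", {
  m <- two_state_model(0, 0, 0, r1_gs = 1.5, r2_gs = 25)
  rf <- rf_condition(0, 0, 0.1)
  L <- build_bm_generator(m, rf)
  # block-diagonal: no exchange coupling anywhere
  expect_equal(L[1:3, 4:6], matrix(0, 3, 3))
  expect_equal(L[4:6, 1:3], matrix(0, 3, 3))
  # Mz decays at exactly R1
  expect_equal(L[3, 3], -1.5)
  expect_equal(L[6, 6], -1.5)

  # p_es = 0 with k_ex > 0: k1 = 0, GS block identical to no-exchange
  m2 <- two_state_model(0, 5000, -1.5, r1_gs = 1.5, r2_gs = 25)
  L2 <- build_bm_generator(m2, rf_condition(500, 300, 0.1))
  L0 <- build_bm_generator(two_state_model(0, 0, -1.5, r1_gs = 1.5,
                                           r2_gs = 25),
                           rf_condition(500, 300, 0.1))
  expect_equal(L2[1:3, 1:3] + diag(0, 3), L0[1:3, 1:3])
  expect_equal(L2[4:6, 1:3], matrix(0, 3, 3))
})

test_that("exchange terms conserve summed magnetization componentwise", {
  m <- two_state_model(0.01, 8000, -1.5, r1_gs = 0, r2_gs = 0)
  rf <- rf_condition(300, 450, 0.1)
  # isolate the exchange contribution by subtracting the k_ex = 0 matrix
  L <- build_bm_generator(m, rf)
  L0 <- build_bm_generator(two_state_model(0, 0, -1.5, r1_gs = 0,
                                           r2_gs = 0), rf)
  Lex <- L - L0
  expect_equal(colSums(Lex), rep(0, 6), tolerance = 1e-12)
  k <- split_rates(m$p_es, m$k_ex)
  expect_equal(Lex[4, 1], k[["k1"]])
  expect_equal(Lex[1, 4], k[["k_minus1"]])
  # summed Mz is conserved without relaxation and rf off resonance... with
  # rf off entirely, d(MzGS + MzES)/dt = 0
  Lfree <- build_bm_generator(m, rf_condition(0, 450, 0.1))
  expect_equal(sum(Lfree[c(3, 6), 3]), 0, tolerance = 1e-12)
  expect_equal(sum(Lfree[c(3, 6), 6]), 0, tolerance = 1e-12)
})

test_that("detailed balance holds for constructed models", {
  for (pes in c(5e-4, 0.003, 0.01)) {
    m <- two_state_model(pes, 3000, -1.5, r1_gs = 2, r2_gs = 20)
    k <- split_rates(m$p_es, m$k_ex)
    expect_equal((1 - pes) * k[["k1"]], pes * k[["k_minus1"]])
    expect_identical(k[["k1"]] + k[["k_minus1"]], m$k_ex)
  }
})

test_that("propagation at t = 0 is the identity and pure nutation is cosine", {
  m <- hg_model()
  rf0 <- rf_condition(500, 200, 0)
  v <- c(0.1, -0.3, 0.7, 0.05, 0, 0.01)
  expect_identical(bm_propagate(m, rf0, v), v)

  free <- two_state_model(0, 0, 0, r1_gs = 0, r2_gs = 0)
  t <- 0.0021
  rf <- rf_condition(430, 0, t)
  out <- bm_propagate(free, rf, c(0, 0, 1, 0, 0, 0))
  expect_equal(out[3], cos(2 * pi * 430 * t), tolerance = 1e-9)
})

test_that("propagator matches brute-force ODE integration", {
  set.seed(7)
  worst <- 0
  for (i in 1:12) {
    m <- random_model()
    rf <- rf_condition(runif(1, 50, 1000), runif(1, -2000, 2000),
                       t_ex = 0.01)
    L <- build_bm_generator(m, rf)
    m0 <- equilibrium_magnetization(m)
    ref <- ode_propagate(L, rf$t_ex, m0)
    got <- bm_propagate(m, rf, m0)
    worst <- max(worst, max(abs(got - ref)) / max(abs(ref)))
  }
  expect_lt(worst, 1e-6)
})

test_that("reference scenario propagation agrees with the ODE oracle", {
  m <- hg_model()  # pES 0.3 %, kex 3000, dw -1.5 ppm, R1 2, R2 20
  rf <- rf_condition(500, -600, 0.1)
  L <- build_bm_generator(m, rf)
  m0 <- equilibrium_magnetization(m)
  ref <- ode_propagate(L, rf$t_ex, m0)
  got <- bm_propagate(m, rf, m0)
  expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-6)
})

test_that("magnetization norm is non-increasing with relaxation on", {
  set.seed(11)
  for (i in 1:8) {
    m <- random_model()
    rf <- rf_condition(runif(1, 0, 800), runif(1, -1500, 1500),
                       t_ex = runif(1, 0.01, 0.2))
    m0 <- equilibrium_magnetization(m)
    expect_lte(sqrt(sum(bm_propagate(m, rf, m0)^2)), sqrt(sum(m0^2)) + 1e-12)
  }
})

test_that("cest_intensity limits: t_ex = 0, free decay, symmetry", {
  m <- hg_model()
  expect_identical(cest_intensity(m, rf_condition(500, 300, 0)), 1)

  dec <- two_state_model(0, 0, 0, r1_gs = 2.5, r2_gs = 30)
  i <- cest_intensity(dec, rf_condition(0, 700, 0.12))
  expect_equal(i, exp(-2.5 * 0.12), tolerance = 1e-10)

  noex <- no_exchange_model()
  for (off in c(150, 600, 1800)) {
    ip <- cest_intensity(noex, rf_condition(500, off, 0.1))
    im <- cest_intensity(noex, rf_condition(500, -off, 0.1))
    expect_equal(ip, im, tolerance = 1e-10)
  }
})

test_that("exchange with negative dw skews the profile toward negative offsets", {
  m <- hg_model()
  offs <- c(-1.5, 1.5) * 600
  lo <- cest_intensity(m, rf_condition(250, offs[1], 0.1))
  hi <- cest_intensity(m, rf_condition(250, offs[2], 0.1))
  expect_lt(lo, hi)  # deeper dip at the ES position
})

test_that("inhomogeneity averaging reduces to nominal B1 and is bracketed", {
  m <- hg_model()
  rf0 <- rf_condition(500, -900, 0.1, inhomogeneity_fwhm = 0)
  rf <- rf_condition(500, -900, 0.1, inhomogeneity_fwhm = 0.1)
  expect_identical(cest_intensity(m, rf0), cest_intensity(m, rf0, n_b1 = 1))
  q <- b1_quadrature(500, 0.1, t_ex = 0.1)
  vals <- vapply(q$b1, function(b)
    cest_intensity(m, rf_condition(b, -900, 0.1)), numeric(1))
  avg <- cest_intensity(m, rf)
  expect_gte(avg, min(vals) - 1e-12)
  expect_lte(avg, max(vals) + 1e-12)
})

test_that("coarse quadrature matches Monte Carlo averaging where coherence is mild", {
  # gentle b1*t product so a 5-point rule resolves the distribution
  m <- hg_model()
  rf <- rf_condition(100, -300, 0.02, inhomogeneity_fwhm = 0.1)
  q5 <- cest_intensity(m, rf, n_b1 = 5)
  set.seed(3)
  sigma <- 0.1 / (2 * sqrt(2 * log(2))) * 100
  b1s <- rnorm(10000, 100, sigma)
  mc <- mean(vapply(b1s, function(b)
    cest_intensity(m, rf_condition(b, -300, 0.02)), numeric(1)))
  expect_equal(q5, mc, tolerance = 1e-3)
})

test_that("dense quadrature reproduces the continuous average at full power", {
  m <- hg_model()
  for (off in c(0, -900)) {
    auto <- cest_profile_model(m, 1000, off, 0.1, inhomogeneity_fwhm = 0.1)
    dense <- cest_profile_model(m, 1000, off, 0.1, inhomogeneity_fwhm = 0.1,
                                n_b1 = 201)
    expect_equal(auto, dense, tolerance = 1e-3)
  }
})

test_that("r1rho limits reproduce closed forms", {
  noex <- no_exchange_model(r1 = 2, r2 = 20)
  on <- r1rho_value(noex, spinlock_condition(1000, 0))
  expect_equal(on$r1rho, 20, tolerance = 1e-8)

  off <- r1rho_value(noex, spinlock_condition(1000, 800))
  th <- off$theta
  expect_equal(off$r1rho, 2 * cos(th)^2 + 20 * sin(th)^2, tolerance = 1e-3)
})

test_that("fast-exchange r1rho agrees with the Laguerre approximation", {
  # kex / |dw_rad| > 3: approximation regime
  m <- two_state_model(0.01, 20000, -1.5, r1_gs = 2, r2_gs = 20)
  for (off in c(-900, -300, 400)) {
    sl <- spinlock_condition(800, off)
    sim <- r1rho_value(m, sl)$r1rho
    lag <- r1rho_laguerre(m, sl)
    expect_lt(abs(sim - lag) / lag, 0.05)
  }
})

test_that("r2eff transform identities", {
  expect_equal(r2eff_transform(25, 2, pi / 2), 25)
  expect_equal(r2eff_transform(15, 2, pi / 4), 28)
  for (th in c(0.3, 1, 2.2)) {
    r1rho <- 2 * cos(th)^2 + 17 * sin(th)^2
    expect_equal(r2eff_transform(r1rho, 2, th), 17, tolerance = 1e-12)
  }
  expect_error(r2eff_transform(10, 2, 0), "undefined")
})

test_that("invalid model and rf inputs are rejected", {
  expect_error(two_state_model(0.6, 100, -1, r1_gs = 2, r2_gs = 20), "p_es")
  expect_error(two_state_model(NA, 100, -1, r1_gs = 2, r2_gs = 20), "finite")
  expect_error(two_state_model(0.01, 100, -1, r1_gs = -2, r2_gs = 20),
               "relaxation")
  expect_error(rf_condition(-5, 0, 0.1), "b1_hz")
})
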