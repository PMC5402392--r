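test_that("lineshapes match closed forms and adaptive quadrature", {
  # Lorentzian at resonance is T2/pi
  expect_equal(lineshape(0, 0.022, "lorentzian"), 0.022 / pi)
  # super-Lorentzian is even in the offset
  expect_identical(lineshape(4500, 1e-5), lineshape(-4500, 1e-5))
  # fixed-grid quadrature agrees with an adaptive oracle
  for (d in c(2000, 4500, 9000))
    expect_equal(lineshape(d, 1e-5), oracle_superlorentzian(d, 1e-5),
                 tolerance = 1e-4)
  # quadrature convergence: doubling nodes changes g negligibly
  expect_equal(lineshape(4500, 1e-5, nodes = 1024),
               lineshape(4500, 1e-5, nodes = 512), tolerance = 1e-6)
  # on-resonance domain guard
  expect_error(lineshape(500, 1e-5), "1000 Hz")
})

test_that("pulse RMS amplitude matches waveform quadrature", {
  # rectangular: constant amplitude theta / tm
  expect_equal(omega1_rms_from_pulse(mt_pulse("rectangular", 0.01, 900, 4500)),
               5 * pi / 0.01)
  expect_equal(omega1_rms_from_pulse(mt_pulse("gaussian", 0.01, 0, 4500)), 0)
  # gaussian: independent fine-grid quadrature on the same truncated waveform
  tm <- 0.01
  t <- seq(0, tm, length.out = 16384)
  w <- exp(-(t - tm / 2)^2 / (2 * (tm / 6)^2))
  w <- w * (900 * pi / 180) / pracma::trapz(t, w)
  expect_equal(omega1_rms_from_pulse(mt_pulse("gaussian", tm, 900, 4500)),
               sqrt(pracma::trapz(t, w^2) / tm), tolerance = 1e-5)
})

test_that("saturation rates follow the lineshape formulas", {
  z <- saturation_rates(0, 4500, 0.05, 1e-5)
  expect_equal(z$W_F, 0)
  expect_equal(z$W_B, 0)
  a <- saturation_rates(500, 4500, 0.05, 1e-5)
  b <- saturation_rates(1000, 4500, 0.05, 1e-5)
  expect_equal(b$W_F / a$W_F, 4)     # quadratic in omega1
  expect_equal(b$W_B / a$W_B, 4)
  # direct-formula oracle
  expect_equal(a$W_F, pi * 500^2 * (0.05 / pi) / (1 + (2 * pi * 4500 * 0.05)^2),
               tolerance = 1e-10)
  expect_equal(a$W_B, pi * 500^2 * oracle_superlorentzian(4500, 1e-5),
               tolerance = 1e-6)
})

test_that("Ernst signal behaves at limits and matches direct evaluation", {
  expect_equal(spgr_signal(1, 0.5, 0, 0.016), 0)
  # full recovery limit: S -> pd sin(alpha)
  expect_equal(spgr_signal(2, 100, 30, 1),     # tr * r1 = 100
               2 * sin(30 * pi / 180), tolerance = 1e-10)
  expect_equal(spgr_signal(1, 0.5, 16, 0.016),
               oracle_ernst(1, 0.5, 16, 0.016))
})

test_that("observed-R1 inversion reproduces the slow eigenvalue", {
  expect_equal(r1f_from_observed(0.7, 0, 19, 1), 0.7)
  expect_equal(r1f_from_observed(0.7, 0.13, 0, 1), 0.7)
  for (r1o in c(0.4, 0.55, 0.9)) for (f in c(0.05, 0.13, 0.3)) {
    R1F <- r1f_from_observed(r1o, f, 19, 1)
    kF <- 19 * f; kB <- 19 * (1 - f)
    A <- matrix(c(-(R1F + kF), kB, kF, -(1 + kB)), 2, byrow = TRUE)
    expect_equal(-max(eigen(A)$values), r1o, tolerance = 1e-10)
  }
  expect_error(r1f_from_observed(25, 0.13, 19, 1), "inconsistent")
})

test_that("two-pool steady state reduces, iterates and orders correctly", {
  pr0 <- spgr_protocol(0.022, 9)        # no saturation pulse
  p0 <- two_pool_params(0, 0.55, 1, 0.04, 1e-5, 19, PD = 2)
  # single-pool reduction at f = 0, zero power
  expect_equal(mt_spgr_steady_state(p0, pr0), oracle_ernst(2, 0.55, 9, 0.022),
               tolerance = 1e-10)
  pr <- mt_proto()
  w1 <- omega1_rms_from_pulse(pr$mt_pulse)
  cons <- single_point_constraints()
  # closed-form fixed point equals 2000-TR brute-force iteration
  for (f in c(0.05, 0.15)) for (r1o in c(0.5, 1.0)) {
    R1F <- r1f_from_observed(r1o, f, cons$R, cons$R1B)
    p <- two_pool_params(f, R1F, cons$R1B, cons$T2F_R1F / R1F, cons$T2B,
                         cons$R)
    expect_equal(mt_spgr_steady_state(p, pr, b0_offset = 50, b1_scale = 0.9),
                 oracle_mt_ss_iter(f, R1F, cons$R1B, cons$T2F_R1F / R1F,
                                   cons$T2B, cons$R, 1, pr$TR, pr$flip,
                                   pr$mt_pulse$duration, pr$mt_pulse$offset,
                                   w1, 50, 0.9),
                 tolerance = 1e-6)
  }
  # saturation suppresses signal; PD scales it linearly; monotone in f
  p <- two_pool_params(0.13, 0.48, 1, 0.045, 1e-5, 19)
  s_on <- mt_spgr_steady_state(p, pr)
  s_off <- mt_spgr_steady_state(p, pr0)
  expect_lt(s_on, s_off)
  p2 <- two_pool_params(0.13, 0.48, 1, 0.045, 1e-5, 19, PD = 3)
  expect_equal(mt_spgr_steady_state(p2, pr), 3 * s_on)
  sig <- vapply(seq(0, 0.4, by = 0.02), function(f) {
    R1F <- r1f_from_observed(0.55, f, cons$R, cons$R1B)
    mt_spgr_steady_state(two_pool_params(f, R1F, cons$R1B,
                                         cons$T2F_R1F / R1F, cons$T2B,
                                         cons$R), pr)
  }, numeric(1))
  expect_true(all(diff(sig) < 0))
  expect_true(all(sig >= 0))
})

test_that("parameter containers enforce their invariants", {
  expect_error(two_pool_params(0.6, 0.5, 1, 0.04, 1e-5, 19))
  expect_error(mt_pulse("gaussian", 0.01, 900, 500), "1000 Hz")
  expect_error(spgr_protocol(0.005, 9,
                             mt_pulse = mt_pulse("gaussian", 0.01, 900, 4500)),
               "exceed")
})
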