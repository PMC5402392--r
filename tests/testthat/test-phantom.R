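test_that("phantom labels partition the grid and carry exact truth", {
  ph <- make_phantom(phantom_spec())
  expect_equal(length(ph$labels), prod(phantom_spec()$dim))
  expect_equal(sum(table(ph$labels)), length(ph$labels))
  st <- ph$structures
  # jitter off: structure-mean f equals the reference value exactly
  cc <- st$label[st$name == "corpus_callosum"]
  expect_equal(unique(ph$f[ph$labels == cc]), 0.1315)
  expect_equal(mean(ph$f[ph$labels == cc]), 0.1315)
  for (i in seq_len(nrow(st)))
    expect_gt(sum(ph$labels == st$label[i]), 0)
  # cuprizone phantom carries the demyelinated means
  phz <- make_phantom(phantom_spec(group = "cuprizone"))
  expect_equal(unique(phz$f[phz$labels == cc]), 0.0965)
  expect_identical(phz$labels, ph$labels)
})

test_that("within-structure jitter is seeded and label-stable", {
  p1 <- make_phantom(phantom_spec(jitter_sd = 0.3, seed = 11))
  p2 <- make_phantom(phantom_spec(jitter_sd = 0.3, seed = 12))
  p1b <- make_phantom(phantom_spec(jitter_sd = 0.3, seed = 11))
  expect_identical(p1$labels, p2$labels)
  expect_false(identical(p1$f, p2$f))
  expect_identical(p1$f, p1b$f)
})

test_that("noiseless simulation equals the forward models voxelwise", {
  ph <- small_phantom()
  acq <- simulate_acquisition(ph, sigma = 0)
  cons <- single_point_constraints()
  pr <- acq$protocols
  idx <- which(ph$labels == 1)[c(1, 5)]      # corpus callosum voxels
  for (i in idx) {
    f <- ph$f[i]; r1 <- ph$r1_obs[i]
    R1F <- r1f_from_observed(r1, f, cons$R, cons$R1B)
    p <- two_pool_params(f, R1F, cons$R1B, cons$T2F_R1F / R1F, cons$T2B,
                         cons$R, PD = ph$pd[i])
    expect_equal(acq$mt_w[i],
                 mt_spgr_steady_state(p, pr$mt, ph$b0[i], ph$b1[i]),
                 tolerance = 1e-12)
    expect_equal(acq$t1_w[i],
                 spgr_signal(ph$pd[i], r1, pr$t1w$flip * ph$b1[i], pr$t1w$TR),
                 tolerance = 1e-12)
  }
})

test_that("background magnitude noise is Rician and seeds reproduce", {
  ph <- make_phantom(phantom_spec(dim = c(64, 64, 12)))
  sig <- 5e-4
  a1 <- simulate_acquisition(ph, sigma = sig, seed = 99)
  a2 <- simulate_acquisition(ph, sigma = sig, seed = 99)
  expect_identical(a1$mt_w, a2$mt_w)
  expect_identical(a1$b0_phase1, a2$b0_phase1)
  bg <- ph$labels == 0
  expect_gt(sum(bg), 1e4)
  # zero-signal Rician mean is sigma * sqrt(pi/2)
  expect_equal(mean(a1$pd_w[bg]), sig * sqrt(pi / 2), tolerance = 0.02)
})

test_that("LFB rendering encodes optical density in the red channel", {
  cal <- lfb_calibration()
  # MPF at the calibration intercept: OD 0, red channel = background
  sl <- matrix(cal$intercept, 4, 4)
  sec <- render_lfb_sections(sl, cal, I_B = 245)
  expect_true(all(sec[[1]][, , 1] == 245))
  # reference white-matter MPF renders the expected OD
  od <- (13.15 - 5.941) / 0.135
  sl2 <- matrix(13.15, 6, 6)
  sec2 <- render_lfb_sections(sl2, cal, I_B = 245)
  red <- sec2[[1]][1, 1, 1]
  expect_lt(abs(100 * (1 - red / 245) - od), 100 * 0.5 / 245)
  expect_error(render_lfb_sections(sl2, cal, I_B = 0), "I_B")
})

test_that("section averaging recovers the rendered OD under noise", {
  cal <- lfb_calibration()
  sl <- matrix(13.15, 24, 24)
  secs <- render_lfb_sections(sl, cal, I_B = 245, noise_sd = 2,
                              n_sections = 3, seed = 5)
  od_true <- (13.15 - cal$intercept) / cal$slope
  od_est <- mean(vapply(secs, function(s) 100 * (1 - mean(s[, , 1]) / 245),
                        numeric(1)))
  expect_lt(abs(od_est - od_true), 0.01 * od_true)
})

test_that("cohort and rescan simulators are seeded and in range", {
  raw <- simulate_cohort(n_per_group = 3, seed = 21)
  raw2 <- simulate_cohort(n_per_group = 3, seed = 21)
  expect_identical(raw, raw2)
  expect_setequal(unique(raw$group), c("control", "cuprizone"))
  expect_equal(length(unique(raw$animal_id)), 6)
  od <- raw$value[raw$measure == "lfb_od_percent"]
  expect_true(all(od >= 0 & od <= 100))
  rs <- simulate_rescan(5, 0.02, seed = 3)
  expect_equal(nrow(rs), 5 * 6)
  expect_true(all(rs$scan1 > 0))
})
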