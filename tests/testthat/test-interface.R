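test_that("NIfTI volume round trip preserves data and anisotropic geometry", {
  v <- array(rnorm(24 * 20 * 6), c(24, 20, 6))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f, voxel = c(0.1, 0.1, 0.5))
  back <- read_volume(f)
  # float32 storage: exact at single precision
  expect_equal(back, v, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(attr(back, "voxel")[1:3], c(0.1, 0.1, 0.5), tolerance = 1e-6)
  expect_error(check_same_grid(v, array(0, c(10, 10, 2))), "mismatch")
  expect_true(check_same_grid(v, v))
})

test_that("PNG section round trip preserves 8-bit channels", {
  img <- array(sample(0:255, 12 * 10 * 3, replace = TRUE), c(12, 10, 3))
  f <- tempfile(fileext = ".png")
  write_section_png(img, f)
  expect_equal(read_section_png(f), img, ignore_attr = TRUE)
})

test_that("configuration round-trips through YAML", {
  cfg <- default_config()
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(cfg2, cfg)
  # protocol and constraints rebuild into valid objects
  pr <- mpfkit:::.protocols_from_config(cfg2)
  expect_s3_class(pr$mt, "spgr_protocol")
  expect_equal(pr$mt$mt_pulse$offset, 4500)
  expect_equal(mpfkit:::.constraints_from_config(cfg2)$T2B, 1e-5)
})

test_that("CLI dispatch validates usage and runs stages deterministically", {
  expect_equal(cli_dispatch(character()), 2L)
  expect_equal(cli_dispatch("frobnicate"), 2L)
  expect_equal(cli_dispatch(c("simulate", "--seed")), 2L)

  cfg <- default_config()
  cfg$phantom$dim <- c(32L, 32L, 8L)
  cfgf <- tempfile(fileext = ".yaml")
  write_config(cfg, cfgf)
  d1 <- file.path(tempdir(), "cli_run1")
  expect_equal(cli_dispatch(c("simulate", "--seed", "3", "--config", cfgf,
                              "--out", d1)), 0L)
  expect_true(file.exists(file.path(d1, "mt_w.nii.gz")))
  expect_true(file.exists(file.path(d1, "ground_truth.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # reconstruct from the simulated volumes
  outmap <- file.path(d1, "mpf.nii.gz")
  expect_equal(cli_dispatch(c("reconstruct",
                              "--mt", file.path(d1, "mt_w.nii.gz"),
                              "--t1w", file.path(d1, "t1_w.nii.gz"),
                              "--pdw", file.path(d1, "pd_w.nii.gz"),
                              "--config", cfgf, "--outfile", outmap)), 0L)
  mpf <- read_volume(outmap)
  expect_equal(dim(mpf), c(32L, 32L, 8L))
  # analyze a cohort table
  raw <- simulate_cohort(7, seed = 5)
  tbl <- aggregate_measurements(raw, collapse = "structure")
  tf <- file.path(d1, "tbl.csv")
  utils::write.csv(tbl, tf, row.names = FALSE)
  expect_equal(cli_dispatch(c("analyze", "--table", tf, "--out", d1)), 0L)
  expect_true(file.exists(file.path(d1, "report.json")))
  # determinism: same seed gives byte-identical table outputs
  d2 <- file.path(tempdir(), "cli_run2")
  expect_equal(cli_dispatch(c("simulate", "--seed", "3", "--config", cfgf,
                              "--out", d2)), 0L)
  expect_identical(readBin(file.path(d1, "ground_truth.csv"), "raw", 1e6),
                   readBin(file.path(d2, "ground_truth.csv"), "raw", 1e6))
  expect_identical(unname(tools::md5sum(file.path(d1, "mt_w.nii.gz"))),
                   unname(tools::md5sum(file.path(d2, "mt_w.nii.gz"))))
  # stage failure surfaces as exit 1
  expect_equal(suppressWarnings(suppressMessages(
    cli_dispatch(c("analyze", "--table", "/nonexistent.csv")))), 1L)
})

test_that("repeatability stage writes per-structure agreement metrics", {
  d <- file.path(tempdir(), "cli_rep")
  expect_equal(cli_dispatch(c("repeatability", "--seed", "11", "--out", d)),
               0L)
  rep <- jsonlite::read_json(file.path(d, "repeatability.json"),
                             simplifyVector = TRUE)
  expect_equal(length(rep), 6)
  expect_true(all(vapply(rep, function(s) s$within_subject_cov < 10,
                         logical(1))))
})
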