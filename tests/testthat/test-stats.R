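test_that("Cohen's d follows the pooled-SD definition", {
  x <- c(10, 11, 12, 13)
  expect_equal(cohens_d(x, x)$d, 0)
  y <- c(8, 9, 10, 11)
  expect_equal(cohens_d(x, y)$d, -cohens_d(y, x)$d)
  # df-weighted pooling equals the average-variance form at equal n
  d <- cohens_d_from_summary(13.15, 0.73, 7, 9.65, 0.95, 7)
  expect_equal(d$d, 3.5 / sqrt((0.73^2 + 0.95^2) / 2))
  expect_true(d$ci[1] <= d$d && d$d <= d$ci[2])
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("regression results carry exact fits and consistent intervals", {
  x <- c(1, 2, 3, 4, 5)
  r <- suppressWarnings(pearson_regression(x, 2 * x))  # perfect fit
  expect_equal(r$r, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  r2 <- suppressWarnings(pearson_regression(x, -x + 10))
  expect_equal(r2$r, -1)
  expect_error(pearson_regression(rep(1, 5), x), "constant")
  set.seed(8)
  r3 <- pearson_regression(x, 2 * x + rnorm(5, 0, 0.3))
  expect_equal(r3$r2, r3$r^2, tolerance = 5e-4)
  expect_true(r3$slope_ci[1] <= r3$slope && r3$slope <= r3$slope_ci[2])
  expect_true(r3$intercept_ci[1] <= r3$intercept &&
                r3$intercept <= r3$intercept_ci[2])
})

test_that("Fisher r-to-z comparison matches its closed form", {
  eq <- fisher_compare_correlations(0.8, 20, 0.8, 30)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  far <- fisher_compare_correlations(0.9, 50, -0.9, 50)
  expect_lt(far$p, 1e-6)
  expect_error(fisher_compare_correlations(0.5, 3, 0.5, 10), "exceed")
  # direct formula check
  fc <- fisher_compare_correlations(0.962, 6, 0.932, 6)
  z <- (atanh(0.962) - atanh(0.932)) / sqrt(1 / 3 + 1 / 3)
  expect_equal(fc$z, z)
})

test_that("ANCOVA separates slope and intercept differences", {
  set.seed(4)
  x <- runif(400, 0, 10)
  g <- rep(c("a", "b"), each = 200)
  # duplicated group: group terms are exactly zero, p = 1
  y0 <- 1 + 0.1 * x[1:200] + rnorm(200, 0, 0.2)
  ident <- ancova_compare_lines(c(x[1:200], x[1:200]), c(y0, y0), g)
  expect_gte(ident$p_slope_diff, 0.99)
  expect_gte(ident$p_intercept_diff, 0.99)
  y <- ifelse(g == "a", 1 + 0.10 * x, 1 + 0.20 * x) + rnorm(400, 0, 0.05)
  diff <- ancova_compare_lines(x, y, g)
  expect_lt(diff$p_slope_diff, 0.001)
})

test_that("factorial ANOVA reduces to the two-sample t-test", {
  set.seed(5)
  v <- rnorm(20)
  g <- rep(c("x", "y"), each = 10)
  res <- factorial_anova(v, data.frame(grp = g))
  tt <- t.test(v[g == "x"], v[g == "y"], var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)
})

test_that("factorial ANOVA detects an injected treatment effect", {
  set.seed(6)
  cells <- expand.grid(treatment = c("ctl", "cpz"), rostral = c("r", "c"),
                       medial = c("m", "l"))
  fac <- cells[rep(seq_len(nrow(cells)), each = 7), ]
  hits <- vapply(1:50, function(i) {
    v <- rnorm(nrow(fac)) + 2 * (fac$treatment == "cpz")
    res <- factorial_anova(v, fac)
    res$p[res$term == "treatment"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("Wilks' lambda reduces to ANOVA and separates groups", {
  set.seed(7)
  g <- rep(c("a", "b"), each = 10)
  y <- rnorm(20)
  m1 <- manova_wilks(g, cbind(y))
  a <- anova(lm(y ~ g))
  expect_equal(m1$F, a[1, "F value"])
  expect_equal(m1$p, a[1, "Pr(>F)"])
  # zero between-group variance: lambda = 1
  ymat <- matrix(rnorm(60), 10, 6)
  m2 <- manova_wilks(rep(c("a", "b"), each = 10), rbind(ymat, ymat))
  expect_equal(m2$lambda, 1, tolerance = 1e-10)
  # well-separated six-variate groups
  sep <- rbind(matrix(rnorm(42), 7, 6), matrix(rnorm(42, mean = 5), 7, 6))
  m3 <- manova_wilks(rep(c("a", "b"), each = 7), sep)
  expect_lt(m3$lambda, 0.1)
  expect_lt(m3$p, 0.001)
  expect_true(m3$lambda > 0 && m3$lambda <= 1)
})

test_that("Bland-Altman agreement metrics follow their definitions", {
  m <- c(10, 11, 12, 13, 14)
  ba0 <- bland_altman(m, m)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$within_subject_cov, 0)
  expect_equal(ba0$loa, c(0, 0))
  # per-subject CoV: SD of the pair over the pair mean
  ba <- bland_altman(c(10.0, 10, 10), c(10.2, 10, 10))
  expect_equal(ba$cov_per_subject[1], 100 * (0.2 / sqrt(2)) / 10.1,
               tolerance = 1e-9)
  # symmetric limits of agreement around the bias
  set.seed(9)
  b2 <- bland_altman(rnorm(10, 10), rnorm(10, 10))
  expect_equal(mean(b2$loa), b2$bias)
  expect_true(b2$p_bias >= 0 && b2$p_bias <= 1)
  expect_true(b2$levene_p >= 0 && b2$levene_p <= 1)
})

test_that("Shapiro-Wilk wrapper guards and rejects non-normal data", {
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3")
  set.seed(10)
  rej <- vapply(1:200, function(i) shapiro_wilk(rexp(100))$p < 0.01,
                logical(1))
  expect_gt(mean(rej), 0.95)
  norm_rej <- vapply(1:200, function(i) shapiro_wilk(rnorm(50))$p < 0.05,
                     logical(1))
  expect_lt(mean(norm_rej), 0.1)
})

test_that("group comparison report flags demyelination in all structures", {
  raw <- simulate_cohort(n_per_group = 7, seed = 41)
  tbl <- aggregate_measurements(raw, collapse = "structure")
  rep_mpf <- compare_groups(tbl[tbl$measure == "mpf_percent", ])
  expect_equal(nrow(rep_mpf$structures), 6)
  expect_lt(rep_mpf$manova$p, 0.05)
  # the corpus callosum carries a very large effect (d ~ 4): always detected;
  # smaller-effect structures (thalamus d ~ 1.3) are underpowered at n = 7,
  # so only a majority is required of any single cohort draw
  cc <- rep_mpf$structures[rep_mpf$structures$structure == "corpus_callosum", ]
  expect_lt(cc$p, 0.001)
  expect_gt(cc$d, 2)
  expect_gte(sum(rep_mpf$structures$p < 0.05), 3)
  expect_gt(cc$mean_1, cc$mean_2)     # group 1 is "control"
})

test_that("structure-mean MRI and histology stay strongly correlated", {
  ok <- vapply(1:10, function(s) {
    raw <- simulate_cohort(n_per_group = 7, seed = 600 + s)
    tbl <- aggregate_measurements(raw, collapse = "structure")
    rep <- analyze_roi_table(tbl)
    rep$correlation$pooled_structures$r > 0.9
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
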