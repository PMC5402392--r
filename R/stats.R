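# Statistical procedures of the MRI-histology validation analysis: group
# comparison with effect sizes, correlation/regression with group-equality
# tests, factorial ANOVA, and scan-rescan repeatability.

#' Cohen's d between two samples
#'
#' Mean difference divided by the pooled (df-weighted) standard deviation;
#' with equal group sizes the denominator reduces to
#' `sqrt((s1^2 + s2^2)/2)`.  The 95% CI uses the large-sample standard error
#' of d.
#'
#' @param x1,x2 Numeric samples (each n >= 2).
#' @return List with `d`, `ci` (length 2), `n1`, `n2`.
#' @export
cohens_d <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  stopifnot(n1 >= 2, n2 >= 2)
  cohens_d_from_summary(mean(x1), stats::sd(x1), n1,
                        mean(x2), stats::sd(x2), n2)
}

#' Cohen's d from group summaries
#'
#' @param m1,s1,n1 Mean, SD and size of the first group.
#' @param m2,s2,n2 Mean, SD and size of the second group.
#' @return List with `d`, `ci`, `n1`, `n2`.
#' @export
cohens_d_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp <= 0) stop("pooled standard deviation is zero")
  d <- (m1 - m2) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  list(d = d, ci = d + c(-1, 1) * stats::qnorm(0.975) * se, n1 = n1, n2 = n2)
}

#' Pearson correlation and linear regression of y on x
#'
#' Ordinary least squares with the associated Pearson correlation: r, r^2,
#' two-sided p from `t = r sqrt((n-2)/(1-r^2))`, and slope/intercept
#' estimates with t-based 95% confidence intervals and p-values.
#'
#' @param x,y Numeric vectors (n >= 3; `x` non-constant).
#' @return List of class `regression_result`: `r`, `r2`, `n`, `p`, `slope`,
#'   `slope_ci`, `slope_p`, `intercept`, `intercept_ci`, `intercept_p`.
#' @export
pearson_regression <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  if (stats::sd(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  structure(list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2, n = n,
                 p = ct$p.value,
                 slope = sm["x", "Estimate"], slope_ci = unname(ci["x", ]),
                 slope_p = sm["x", "Pr(>|t|)"],
                 intercept = sm["(Intercept)", "Estimate"],
                 intercept_ci = unname(ci["(Intercept)", ]),
                 intercept_p = sm["(Intercept)", "Pr(>|t|)"]),
            class = "regression_result")
}

#' Compare two independent correlation coefficients
#'
#' Fisher r-to-z transformation: `z = (atanh r1 - atanh r2) /
#' sqrt(1/(n1-3) + 1/(n2-3))`, two-sided normal p-value.
#'
#' @param r1,n1 First correlation and its sample size (n > 3).
#' @param r2,n2 Second correlation and its sample size.
#' @return List with `z` and `p`.
#' @export
fisher_compare_correlations <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1)
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' ANCOVA comparison of two regression lines
#'
#' Tests slope equality via the group-by-covariate interaction in
#' `y ~ group * x`; the intercept (group-effect) test comes from the
#' homogeneous-slopes model `y ~ group + x`.
#'
#' @param x Covariate.
#' @param y Response.
#' @param group Two-level factor (each level n >= 3).
#' @return List with `p_slope_diff` and `p_intercept_diff`.
#' @export
ancova_compare_lines <- function(x, y, group) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2, all(table(group) >= 3))
  full <- stats::lm(y ~ group * x)
  if (any(is.na(stats::coef(full)))) stop("singular ANCOVA design")
  p_slope <- stats::anova(stats::lm(y ~ group + x), full)[2, "Pr(>F)"]
  add <- stats::lm(y ~ x + group)
  p_int <- summary(add)$coefficients[3, "Pr(>|t|)"]
  list(p_slope_diff = p_slope, p_intercept_diff = p_int)
}

#' Factorial fixed-effects ANOVA with main effects and pairwise interactions
#'
#' Fits a fixed-effects linear model with sum-to-zero (effect) coding and
#' reports Type III F-tests for the requested terms.  The default term set
#' for a three-factor design is all main effects plus all pairwise
#' interactions, without the three-way term.
#'
#' @param values Response vector.
#' @param factors Data frame of factors (one column per factor).
#' @param terms Character vector of model terms (e.g. `"treatment"`,
#'   `"treatment:region"`); default main effects + pairwise interactions.
#' @return Data frame with columns `term`, `df`, `F`, `p`.
#' @export
factorial_anova <- function(values, factors, terms = NULL) {
  stopifnot(is.data.frame(factors), nrow(factors) == length(values))
  factors[] <- lapply(factors, factor)
  if (any(vapply(factors, nlevels, 1L) < 2))
    stop("each factor needs at least 2 levels")
  nm <- names(factors)
  if (is.null(terms)) {
    terms <- nm
    if (length(nm) > 1)
      terms <- c(terms, utils::combn(nm, 2, paste, collapse = ":"))
  }
  dat <- cbind(.y = values, factors)
  fml <- stats::reformulate(terms, response = ".y")
  ctr <- stats::setNames(rep(list("contr.sum"), length(nm)), nm)
  fit <- stats::lm(fml, data = dat, contrasts = ctr)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("aliased model terms: ", paste(bad, collapse = ", "))
  }
  a3 <- car::Anova(fit, type = 3)
  keep <- setdiff(rownames(a3), c("(Intercept)", "Residuals"))
  data.frame(term = keep, df = a3[keep, "Df"], F = a3[keep, "F value"],
             p = a3[keep, "Pr(>F)"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' One-way MANOVA with Wilks' lambda
#'
#' Wilks' Lambda `det(W)/det(W + B)` with Rao's F approximation, via
#' [stats::manova()].
#'
#' @param group Grouping factor.
#' @param response_matrix Numeric matrix, one column per response variable.
#' @return List with `lambda`, `F`, `df` (numerator, denominator), `p`.
#' @export
manova_wilks <- function(group, response_matrix) {
  group <- factor(group)
  Y <- as.matrix(response_matrix)
  stopifnot(nrow(Y) == length(group),
            nrow(Y) > ncol(Y) + nlevels(group))
  if (ncol(Y) == 1) {
    a <- stats::anova(stats::lm(Y[, 1] ~ group))
    ss <- a[["Sum Sq"]]
    return(list(lambda = ss[2] / sum(ss), F = a[1, "F value"],
                df = c(a[1, "Df"], a[2, "Df"]), p = a[1, "Pr(>F)"]))
  }
  fit <- stats::manova(Y ~ group)
  sw <- summary(fit, test = "Wilks")$stats
  list(lambda = sw["group", "Wilks"], F = sw["group", "approx F"],
       df = unname(sw["group", c("num Df", "den Df")]),
       p = sw["group", "Pr(>F)"])
}

#' Bland-Altman repeatability analysis of paired measurements
#'
#' Bias (mean difference) with limits of agreement `bias +/- 1.96 SD`, a
#' one-sample t-test of the bias against zero, within-subject coefficients
#' of variation (per-pair SD over pair mean, in percent, aggregated as the
#' arithmetic mean or RMS over subjects), and Levene's test of equal
#' variances between the two measurement sets.
#'
#' @param m1,m2 Paired measurements (n >= 3).
#' @param cov_aggregate `"mean"` (default) or `"rms"` aggregation of the
#'   per-subject CoV.
#' @return List of class `repeatability_result`: `bias`, `loa` (lower,
#'   upper), `p_bias`, `within_subject_cov` (percent), `cov_per_subject`,
#'   `levene_p`, `n`.
#' @export
bland_altman <- function(m1, m2, cov_aggregate = c("mean", "rms")) {
  cov_aggregate <- match.arg(cov_aggregate)
  n <- length(m1)
  stopifnot(n >= 3, length(m2) == n)
  d <- m1 - m2
  bias <- mean(d)
  sdd <- stats::sd(d)
  pm <- (m1 + m2) / 2
  keep <- pm != 0
  if (any(!keep)) warning(sum(!keep), " subject(s) with zero pair mean excluded from CoV")
  cov_i <- 100 * abs(d[keep]) / sqrt(2) / pm[keep]   # SD of a pair = |d|/sqrt(2)
  wcov <- if (cov_aggregate == "mean") mean(cov_i) else sqrt(mean(cov_i^2))
  p_bias <- if (sdd > 0) stats::t.test(d)$p.value else 1
  lev <- car::leveneTest(c(m1, m2), factor(rep(c("m1", "m2"), c(n, n))),
                         center = mean)
  structure(list(bias = bias, loa = bias + c(-1.96, 1.96) * sdd,
                 p_bias = p_bias, within_subject_cov = wcov,
                 cov_per_subject = cov_i,
                 levene_p = lev[1, "Pr(>F)"], n = n),
            class = "repeatability_result")
}

#' Shapiro-Wilk normality test
#'
#' Thin guard around [stats::shapiro.test()].
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000) stop("n must be in [3, 5000]")
  if (stats::sd(x) == 0) stop("constant input")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Group comparison report across structures
#'
#' MANOVA across structures followed by per-structure two-sample t-tests and
#' Cohen's d, for one measure of an aggregated ROI table (per-animal
#' structure means).
#'
#' @param tbl Aggregated table (see [aggregate_measurements()] with
#'   `collapse = "structure"`) containing one `measure`.
#' @return List with `manova` (see [manova_wilks()]) and a per-structure
#'   data frame `structures` (`mean_1`, `sd_1`, `mean_2`, `sd_2`, `t`, `p`,
#'   `d`, `d_lo`, `d_hi`); group 1 is the first factor level.
#' @export
compare_groups <- function(tbl) {
  stopifnot(length(unique(tbl$measure)) == 1)
  wide <- stats::reshape(tbl[c("animal_id", "group", "structure", "value")],
                         idvar = c("animal_id", "group"),
                         timevar = "structure", direction = "wide")
  g <- factor(wide$group)
  Y <- as.matrix(wide[, -(1:2)])
  man <- manova_wilks(g, Y)
  lv <- levels(g)
  per <- lapply(colnames(Y), function(cn) {
    x1 <- Y[g == lv[1], cn]; x2 <- Y[g == lv[2], cn]
    tt <- stats::t.test(x1, x2, var.equal = TRUE)
    dd <- cohens_d(x1, x2)
    data.frame(structure = sub("^value\\.", "", cn),
               mean_1 = mean(x1), sd_1 = stats::sd(x1),
               mean_2 = mean(x2), sd_2 = stats::sd(x2),
               t = unname(tt$statistic), p = tt$p.value,
               d = dd$d, d_lo = dd$ci[1], d_hi = dd$ci[2],
               stringsAsFactors = FALSE)
  })
  list(manova = man, structures = do.call(rbind, per), groups = lv)
}
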