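test_that("variance components: perfect repeatability and degenerate input", {
  rec <- test_retest_records(1:6, c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  vc <- variance_components_oneway(rec)
  expect_equal(vc$sigma_w2, 0)
  expect_gt(vc$sigma_b2, 0)
  # subjects missing a visit are excluded with a warning; < 3 complete errors
  rec2 <- test_retest_records(1:4, c(1, 2, 3, NA), c(1.1, 2.1, 3.1, 4))
  expect_warning(variance_components_oneway(rec2), "excluded")
  expect_error(
    suppressWarnings(variance_components_oneway(
      test_retest_records(1:3, c(1, 2, NA), c(1, 2, 3)))),
    "fewer than 3")
})

test_that("null subject effect is truncated to zero between-subject variance", {
  set.seed(21)
  zeros <- replicate(200, {
    v1 <- rnorm(10); v2 <- rnorm(10)  # no subject effect at all
    variance_components_oneway(test_retest_records(1:10, v1, v2))$sigma_b2
  })
  expect_gt(mean(zeros == 0), 0.3)   # truncation engages often under the null
  expect_lt(mean(zeros), 0.2)        # and the component stays near zero
})

test_that("variance components recover the generating truth by Monte Carlo", {
  sb2 <- 2.1e-4; sw2 <- 2.4e-5
  set.seed(22)
  n <- 1000
  subj <- rnorm(n, 0.039, sqrt(sb2))
  v1 <- subj + rnorm(n, 0, sqrt(sw2))
  v2 <- subj + rnorm(n, 0, sqrt(sw2))
  vc <- variance_components_oneway(test_retest_records(1:n, v1, v2))
  expect_lt(abs(vc$sigma_b2 - sb2) / sb2, 0.10)
  expect_lt(abs(vc$sigma_w2 - sw2) / sw2, 0.10)
})

test_that("ICC from components reproduces the published whole-joint values", {
  expect_equal(round(icc_from_components(2.1e-4, 2.4e-5), 2), 0.90)
  expect_equal(round(icc_from_components(4.2, 2.4), 2), 0.64)
  expect_equal(icc_from_components(0.37, 0), 1)
  expect_error(icc_from_components(0, 0), "undefined")
  expect_error(icc_from_components(-1, 1), ">= 0")
  # monotone increasing in the between-subject component
  iccs <- vapply(c(1, 2, 4, 8), icc_from_components, numeric(1),
                 sigma_w2 = 1)
  expect_true(all(diff(iccs) > 0))
})

test_that("within-subject SD follows the two-replicate ANOVA algebra", {
  # sqrt of the within-subject variance
  set.seed(23)
  subj <- rnorm(40, 10, 1)
  rec <- test_retest_records(1:40, subj, subj)
  expect_equal(within_subject_sd(rec), 0)
  # constant paired difference d gives wSD = |d| / sqrt(2)
  d <- 0.6
  rec2 <- test_retest_records(1:40, subj, subj + d)
  expect_equal(within_subject_sd(rec2), d / sqrt(2), tolerance = 1e-10)
  expect_equal(sqrt(1.3e-5), 0.0036, tolerance = 0.002)
})

test_that("within-subject CV is scale invariant and consistent by Monte Carlo", {
  set.seed(24)
  v1 <- runif(30, 5, 15)
  v2 <- 1.1 * v1
  rec_a <- test_retest_records(1:30, v1, v2)
  rec_b <- test_retest_records(1:30, 100 * v1, 100 * v2)
  expect_equal(within_subject_cv(rec_a), within_subject_cv(rec_b),
               tolerance = 1e-10)
  expect_equal(within_subject_cv(test_retest_records(1:30, v1, v1)), 0)
  expect_error(within_subject_cv(test_retest_records(1:5, -(1:5), 1:5)),
               "positive")
  # lognormal with true CV 10%: RMS pair estimate lands within 1.5 points
  sdlog <- sqrt(log(1 + 0.1^2))
  n <- 500
  subj <- rlnorm(n, log(10), 0.3)
  v1 <- subj * rlnorm(n, -sdlog^2 / 2, sdlog)
  v2 <- subj * rlnorm(n, -sdlog^2 / 2, sdlog)
  wcv <- within_subject_cv(test_retest_records(1:n, v1, v2))
  expect_lt(abs(wcv - 10), 1.5)
})

test_that("variability scale selection reacts to magnitude correlation", {
  # |difference| proportional to the mean: relative scale
  m <- seq(1, 20, length.out = 20)
  d <- 0.1 * m
  rec <- test_retest_records(1:20, m - d / 2, m + d / 2)
  expect_identical(as.character(select_variability_scale(rec)), "relative")
  # constant differences: absolute
  rec2 <- test_retest_records(1:20, m, m + 0.5)
  expect_identical(as.character(select_variability_scale(rec2)), "absolute")
  expect_error(select_variability_scale(
    test_retest_records(1:4, 1:4, 2:5)), "5")
})

test_that("SDD is 2.77 times the within-subject variability on either scale", {
  expect_equal(sqrt(2) * 1.96, 2.7719, tolerance = 1e-4)
  sdd <- smallest_detectable_difference(sqrt(1.3e-5))
  expect_equal(round(as.numeric(sdd), 3), 0.010)
  sdd_rel <- smallest_detectable_difference(8.5, "relative")
  expect_lt(abs(as.numeric(sdd_rel) - 23.5), 0.1)
  expect_equal(as.numeric(smallest_detectable_difference(0)), 0)
  # ratio is the fixed repeatability constant
  w <- c(0.004, 1.54, 24.8)
  r <- vapply(w, function(x)
    as.numeric(smallest_detectable_difference(x)) / x, numeric(1))
  expect_equal(r, rep(sqrt(2) * 1.96, 3))
})

test_that("RMSCV matches hand arithmetic and is scale invariant", {
  expect_equal(rmscv(9, 11), 10 * sqrt(2), tolerance = 1e-10)
  expect_equal(rmscv(c(10, 20), c(10, 20)), 0)
  set.seed(25)
  x <- runif(20, 5, 15); y <- x * runif(20, 0.9, 1.1)
  expect_equal(rmscv(3 * x, 3 * y), rmscv(x, y), tolerance = 1e-10)
  expect_error(rmscv(c(1, -2), c(1, 2)), "positive")
})

test_that("concordance correlation penalises location shift", {
  set.seed(26)
  x <- rnorm(100)
  expect_equal(lin_ccc(x, x), 1)
  xc <- x - mean(x)
  expect_equal(lin_ccc(xc, -xc), -1)
  c0 <- 2; s2 <- mean((x - mean(x))^2)
  expect_equal(lin_ccc(x, x + c0), 2 * s2 / (2 * s2 + c0^2),
               tolerance = 1e-10)
  # CCC never exceeds |Pearson r|
  y <- 2 * x + 1 + rnorm(100, 0, 0.5)
  expect_lte(abs(lin_ccc(x, y)), abs(cor(x, y)) + 1e-12)
  expect_error(lin_ccc(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("standardised mean difference uses the pooled SD", {
  set.seed(27)
  a <- rnorm(50, 5, 1); b <- rnorm(50, 5, 1)
  expect_lt(abs(standardized_mean_difference(a, a)$smd), 1e-12)
  g1 <- c(0, 1, 2); g2 <- c(-1, 0, 1)  # unit means difference, unit SDs
  sm <- standardized_mean_difference(g1, g2)
  expect_equal(sm$smd, 1, tolerance = 1e-12)
  expect_error(standardized_mean_difference(rep(1, 3), rep(1, 3)), "zero")
  expect_error(standardized_mean_difference(1, c(1, 2)), ">= 2")
})

test_that("responsiveness counts strict SDD exceedances on both scales", {
  s <- 0.013
  expect_equal(responsiveness_count(c(0.001, -0.002, 0.005), s), 0)
  expect_equal(responsiveness_count(c(2 * s, -2 * s, 0.5 * s), s), 2)
  # relative scale expresses changes as percent of baseline
  base <- c(10, 10, 10)
  chg <- c(3, -1, 0.5)
  expect_equal(responsiveness_count(chg, 25, scale = "relative",
                                    baseline = base), 1)
  expect_error(responsiveness_count(1, -1), ">= 0")
})

test_that("the repeatability panel assembles coherently", {
  set.seed(28)
  n <- 16
  subj <- rnorm(n, 0.039, sqrt(2.1e-4))
  v1 <- subj + rnorm(n, 0, sqrt(2.4e-5))
  v2 <- subj + rnorm(n, 0, sqrt(2.4e-5))
  rm <- repeatability_metrics(test_retest_records(1:n, v1, v2),
                              oa_mean = 0.039)
  expect_s3_class(rm, "repeatability_metrics")
  expect_equal(rm$icc, icc_from_components(rm$sigma_b2, rm$sigma_w2))
  expect_gte(rm$icc_lower, 0); expect_lte(rm$icc_upper, 1)
  expect_lte(rm$icc_lower, rm$icc); expect_gte(rm$icc_upper, rm$icc)
  expect_equal(rm$sdd, sqrt(2) * 1.96 * rm$wsd_or_wcv)
  out <- capture.output(print(rm))
  expect_true(any(grepl("ICC", out)))
})
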