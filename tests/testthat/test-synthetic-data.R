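test_that("phantom generation is deterministic and respects its spec", {
  ps <- phantom_spec(grid_shape = c(16, 16, 4), voxel_size = c(2.5, 2.5, 4))
  p1 <- generate_phantom(ps, seed = 5)
  p2 <- generate_phantom(ps, seed = 5)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$ktrans, p2$ktrans)
  expect_identical(p1$enhancing, p2$enhancing)
  # all 7 synovial labels present
  expect_true(all(1:7 %in% unique(as.vector(p1$roi))))
  # enhancing voxels have positive transfer; non-enhancing synovium has none
  expect_true(all(p1$ktrans[p1$enhancing] > 0))
  off <- p1$roi > 0 & !p1$enhancing
  expect_true(all(p1$ktrans[off] == 0))
  expect_true(all(p1$vp[off] == 0))
})

test_that("degenerate enhancing fractions and constant fields behave", {
  ps0 <- phantom_spec(grid_shape = c(16, 16, 4), enhancing_fraction = 0)
  p0 <- generate_phantom(ps0, seed = 1)
  expect_true(all(p0$ktrans[p0$roi > 0] == 0))

  # a single custom region with uniform ktrans yields a constant field
  tt <- default_tissue_table()
  tt$ktrans[tt$label == 3] <- 0.05
  ps1 <- phantom_spec(
    grid_shape = c(16, 16, 4), tissue_table = tt, enhancing_fraction = 1,
    regions = list(list(label = 3L, centre = c(8, 8, 2.5),
                        semi_axes = c(4, 4, 1.4))))
  p1 <- generate_phantom(ps1, seed = 1)
  expect_gt(sum(p1$labels == 3L), 0)
  expect_true(all(p1$ktrans[p1$labels == 3L] == 0.05))
})

test_that("overlapping custom regions raise an error naming the labels", {
  ps <- phantom_spec(
    grid_shape = c(16, 16, 4),
    regions = list(
      list(label = 1L, centre = c(8, 8, 2), semi_axes = c(3, 3, 1)),
      list(label = 2L, centre = c(9, 8, 2), semi_axes = c(3, 3, 1))))
  expect_error(generate_phantom(ps, seed = 1), "overlapping.*1, 2")
})

test_that("noiseless non-enhancing phantoms give flat dynamic signals", {
  acq <- small_acq()
  ph <- small_phantom(enhancing_fraction = 0)
  st <- generate_subject_images(ph, acq, seed = 2)
  dyn <- matrix(st$dynamic, ncol = acq$n_phases)
  expect_lt(max(apply(dyn, 1, function(x) diff(range(x)))), 1e-9)
  expect_error(generate_subject_images(ph, acq, haematocrit = 1.2),
               "haematocrit")
})

test_that("the imaging chain recovers ground-truth concentration noiselessly", {
  acq <- small_acq()
  ph <- small_phantom(seed = 3, enhancing_fraction = 1)
  st <- generate_subject_images(ph, acq, seed = 4)
  idx <- which(st$roi > 0)[1:20]
  dyn <- matrix(st$dynamic, ncol = acq$n_phases)
  rec <- signal_to_concentration(dyn[idx, , drop = FALSE],
                                 acq$baseline_frames, t10 = ph$t10[idx],
                                 r1 = st$r1, tr = acq$tr,
                                 flip_angle = acq$dynamic_flip_angle)
  for (j in seq_along(idx)) {
    v <- idx[j]
    truth <- extended_tofts_forward(st$truth$ktrans[v], st$truth$ve[v],
                                    st$truth$vp[v], st$cp, st$t_min)
    expect_equal(rec$concentration[j, ], truth, tolerance = 1e-6)
  }
})

test_that("rician noise at zero signal averages to the noise floor", {
  # background voxels with zero magnitude: E|noise| = sigma * sqrt(pi/2)
  tt <- default_tissue_table()
  tt$m0[tt$label == 0] <- 0
  sigma <- 5
  acq <- small_acq(noise_sd = sigma, noise_model = "rician")
  ph <- generate_phantom(
    phantom_spec(grid_shape = c(16, 16, 4), tissue_table = tt), seed = 6)
  st <- generate_subject_images(ph, acq, seed = 7)
  vals <- st$pre[ph$labels == 0L]
  expect_equal(mean(vals), sigma * sqrt(pi / 2), tolerance = 0.05)
})

test_that("cohort truth generation is seeded, calibrated and structured", {
  cs <- cohort_spec(n_oa = 4, n_hv = 2, within_subject_sd = 0, seed = 11)
  m1 <- simulate_biomarker_truth(cs)
  m2 <- simulate_biomarker_truth(cs)
  expect_identical(m1, m2)
  # zero within-subject noise: baseline and month1 true levels coincide
  b <- m1[m1$visit == "baseline", ]
  r <- m1[m1$visit == "month1", ]
  expect_equal(b$true_value, r$true_value)
  expect_error(cohort_spec(n_oa = 0, n_hv = 0), "empty")

  # empirical variance components converge to the specification; averaging
  # replicate n = 500 cohorts separates estimator bias from draw noise
  est <- sapply(1:10, function(s) {
    m <- simulate_biomarker_truth(cohort_spec(n_oa = 500, n_hv = 0,
                                              seed = 100 + s))
    v1 <- m$true_value[m$visit == "baseline"]
    v2 <- m$true_value[m$visit == "month1"]
    vc <- variance_components_oneway(
      test_retest_records(m$subject_id[m$visit == "baseline"], v1, v2))
    c(vc$sigma_b2, vc$sigma_w2)
  })
  expect_lt(abs(mean(est[1, ]) - 2.1e-4) / 2.1e-4, 0.10)
  expect_lt(abs(mean(est[2, ]) - 2.4e-5) / 2.4e-5, 0.10)
})

test_that("ICC estimates distribute around the variance-ratio truth", {
  sb2 <- 2.1e-4; sw2 <- 2.4e-5
  icc_true <- sb2 / (sb2 + sw2)
  set.seed(13)
  iccs <- replicate(50, {
    n <- 100
    subj <- rnorm(n, 0.039, sqrt(sb2))
    v1 <- subj + rnorm(n, 0, sqrt(sw2))
    v2 <- subj + rnorm(n, 0, sqrt(sw2))
    icc_oneway(test_retest_records(1:n, v1, v2))$icc
  })
  expect_lt(abs(mean(iccs) - icc_true), 0.02)
  expect_gt(min(iccs), icc_true - 0.1)
})

test_that("generated subject images are calibrated to the drawn true level", {
  cs <- cohort_spec(n_oa = 1, n_hv = 1, visits = "baseline",
                    within_subject_sd = 0, seed = 14)
  ph <- small_phantom(c(32, 32, 8), seed = 14)
  acq <- small_acq(c(32, 32, 8))
  syn <- generate_cohort(cs, ph, acq, images = TRUE)
  for (i in seq_len(nrow(syn$metadata))) {
    st <- syn$studies[[i]]
    an <- analyze_study(st)
    wj <- an$biomarkers
    measured <- wj$value[wj$region == "whole_joint" &
                           wj$biomarker == "ktrans" &
                           wj$method == "semiauto"]
    expect_lt(abs(measured - syn$metadata$true_value[i]) /
                syn$metadata$true_value[i], 0.02)
  }
  # same seed gives an identical metadata table
  syn2 <- generate_cohort(cs, ph, acq, images = FALSE)
  expect_identical(syn$metadata, syn2$metadata)
})
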