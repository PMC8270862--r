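test_that("shuffle subtraction of an identical pair is identically zero", {
  set.seed(1)
  img <- array(runif(16 * 16 * 4, 0, 100), c(16, 16, 4))
  out <- shuffle_subtract(img, img)
  expect_equal(max(abs(out)), 0)
})

test_that("shuffle subtraction absorbs a one-voxel in-plane shift", {
  set.seed(2)
  pre <- array(runif(20 * 20 * 3, 0, 100), c(20, 20, 3))
  post <- pre
  post[2:20, , ] <- pre[1:19, , ]  # shift by one voxel along x
  out <- shuffle_subtract(pre, post)
  interior <- out[2:19, 2:19, ]
  expect_equal(max(abs(interior)), 0)
  # while simple subtraction is visibly nonzero there
  simple <- (post - pre)[2:19, 2:19, ]
  expect_gt(max(abs(simple)), 1)
})

test_that("shuffle output matches the brute-force oracle on the printed 5x5 pair", {
  pre <- matrix(c(12, 7, 30, 22, 5,
                  18, 25, 9, 14, 28,
                  3, 16, 21, 8, 19,
                  27, 11, 6, 24, 13,
                  10, 29, 17, 2, 26), 5, 5, byrow = TRUE)
  post <- matrix(c(14, 9, 28, 25, 6,
                   20, 23, 12, 13, 30,
                   5, 18, 19, 10, 17,
                   25, 13, 8, 22, 15,
                   12, 27, 19, 4, 24), 5, 5, byrow = TRUE)
  # expected values computed by exhaustive neighbourhood search (independent
  # implementation), frozen
  expected <- matrix(c(2, 0, -2, 3, 1,
                       2, -2, -2, -1, 2,
                       2, 0, -2, 1, -2,
                       -2, 2, 0, 1, 2,
                       1, 0, 2, 2, 0), 5, 5, byrow = TRUE)
  out <- shuffle_subtract(pre, post)
  expect_equal(array(expected, c(5, 5, 1)), unclass(out),
               ignore_attr = TRUE)
})

test_that("shuffle difference never exceeds simple subtraction in magnitude", {
  set.seed(3)
  for (rep in 1:5) {
    pre <- array(rnorm(12 * 12 * 4, 100, 20), c(12, 12, 4))
    post <- array(rnorm(12 * 12 * 4, 110, 20), c(12, 12, 4))
    for (nb in c("inplane", "3d")) {
      out <- shuffle_subtract(pre, post, nb)
      expect_true(all(abs(out) <= abs(post - pre) + 1e-12))
    }
  }
  # exactly zero wherever post equals any pre neighbour
  pre <- array(1:27, c(3, 3, 3))
  post <- array(0, c(3, 3, 3)); post[2, 2, 2] <- pre[1, 2, 2]
  out <- shuffle_subtract(pre, post)
  expect_equal(out[2, 2, 2], 0)
  expect_error(shuffle_subtract(array(0, c(4, 4, 2)), array(0, c(4, 4, 3))),
               "dimensions differ")
})

test_that("Otsu threshold separates a two-level sample and scales with it", {
  s <- c(0, 0, 0, 10, 10, 10)
  thr <- otsu_threshold(s)
  expect_gt(thr, 0); expect_lt(thr, 10)
  expect_equal(otsu_threshold(3 * s), 3 * thr, tolerance = 1e-10)
  expect_error(otsu_threshold(rep(5, 10)), "constant")
})

test_that("Otsu equals the brute-force between-class-variance maximiser", {
  set.seed(4)
  for (rep in 1:5) {
    x <- c(rnorm(300, 10, 2), rnorm(150, 30, 3))
    thr <- otsu_threshold(x)
    brute <- otsu_brute(x)
    bin_width <- diff(range(x)) / 256
    expect_lt(abs(thr - brute), bin_width + 1e-12)
    # both split the sample between the two modes
    expect_gt(thr, 14); expect_lt(thr, 26)
  }
})

test_that("VEP mask is the enhancing-ROI intersection with correct volumes", {
  dm <- c(16, 16, 4)
  roi <- array(0L, dm); roi[4:8, 4:8, 2] <- 1L; roi[10:14, 10:14, 3] <- 2L
  diffv <- array(rnorm(prod(dm), 0, 0.01), dm)
  blob <- array(FALSE, dm); blob[5:6, 5:6, 2] <- TRUE
  diffv[blob] <- 50
  vep <- build_vep_mask(diffv, roi, voxel_size = c(2, 2, 5))
  expect_true(all(vep$mask[blob]))
  expect_equal(sum(vep$mask), sum(blob))
  # volumes: voxel count x voxel volume, additive to whole joint
  v <- vep$volumes
  expect_equal(v$volume_ml, v$voxels * 2 * 2 * 5 / 1000)
  expect_equal(v$volume_ml[v$region == "whole_joint"],
               sum(v$volume_ml[v$region != "whole_joint"]))
  # region 2 holds no enhancement
  expect_equal(v$voxels[v$label %in% 2], 0)
  expect_error(build_vep_mask(diffv, array(0L, dm), c(2, 2, 5)), "empty")
})

test_that("enhancement volume is monotone non-increasing in the threshold", {
  set.seed(6)
  dm <- c(16, 16, 4)
  roi <- array(1L, dm)
  diffv <- array(rnorm(prod(dm), 0, 1), dm)
  vep <- build_vep_mask(diffv, roi, c(1, 1, 1))
  higher <- sum(diffv > vep$threshold + 0.5 & roi > 0)
  expect_lte(higher, sum(vep$mask))
})

test_that("phantom VEP volume matches the designed enhancing fraction", {
  acq <- small_acq(c(32, 32, 8))
  ph <- small_phantom(c(32, 32, 8), seed = 9, enhancing_fraction = 0.5)
  st <- generate_subject_images(ph, acq, seed = 10)
  sh <- shuffle_subtract(st$pre, st$post)
  vep <- build_vep_mask(sh, st$roi, acq$voxel_size)
  syn_vol <- sum(st$roi > 0) * prod(acq$voxel_size) / 1000
  wj <- vep$volumes$volume_ml[vep$volumes$region == "whole_joint"]
  expect_lt(abs(wj - 0.5 * syn_vol) / (0.5 * syn_vol), 0.05)
})

test_that("median biomarker extraction respects masks, regions and missingness", {
  dm <- c(8, 8, 2)
  roi <- array(0L, dm); roi[1:4, , 1] <- 1L; roi[5:8, , 1] <- 2L
  ktrans <- array(0, dm)
  ktrans[roi == 1L] <- 0.039
  ktrans[roi == 2L] <- 0.100
  pk <- list(ktrans = ktrans)
  # manual arm: medians over the full regions
  bm <- extract_median_biomarkers(pk, roi, method = "manual",
                                  biomarkers = "ktrans")
  expect_equal(bm$value[bm$label %in% 1], 0.039)
  expect_equal(bm$value[bm$label %in% 2], 0.100)
  # whole-joint median of equal-count symmetric regions lies between them
  wj <- bm$value[bm$region == "whole_joint"]
  expect_gte(wj, 0.039); expect_lte(wj, 0.100)

  # VEP arm: region 2 disjoint from the mask reads missing, not zero
  mask <- roi == 1L
  vep <- structure(list(mask = mask, threshold = 0,
                        volumes = NULL, voxel_size = c(1, 1, 1)),
                   class = "vep_result")
  bm2 <- extract_median_biomarkers(pk, roi, vep, method = "vep",
                                   biomarkers = "ktrans")
  expect_equal(bm2$value[bm2$label %in% 1], 0.039)
  expect_true(is.na(bm2$value[bm2$label %in% 2]))
  expect_equal(bm2$n_voxels[bm2$label %in% 2], 0)
})

test_that("per-region medians recover phantom ground truth noiselessly", {
  acq <- small_acq(c(32, 32, 8))
  ph <- small_phantom(c(32, 32, 8), seed = 12, enhancing_fraction = 0.5)
  st <- generate_subject_images(ph, acq, seed = 13)
  an <- analyze_study(st)
  tt <- default_tissue_table()
  bm <- an$biomarkers
  for (l in 1:7) {
    # the VEP arm should read each region's enhancing-tissue Ktrans
    truth <- tt$ktrans[tt$label == l]
    got <- bm$value[bm$label %in% l & bm$biomarker == "ktrans" &
                      bm$method == "semiauto"]
    expect_equal(got, truth, tolerance = 0.01)
    # the manual arm mixes enhancing and zero-transfer voxels, so it can
    # only read lower than (or equal to) the enhancing-tissue value
    man <- bm$value[bm$label %in% l & bm$biomarker == "ktrans" &
                      bm$method == "manual"]
    expect_lte(man, got)
  }
})
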