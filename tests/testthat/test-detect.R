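test_that("environmental samples respect neighborhood geometry", {
  d <- c(8L, 8L, 3L)
  set.seed(1)
  dat <- array(rnorm(prod(d)), d)
  full <- array(TRUE, d)
  env <- environmental_samples(dat, full)
  # interior voxel of a fully-brain slice: all 9 in-plane values
  i_interior <- which(env$center_index[, 1] == 4 & env$center_index[, 2] == 4 &
                      env$center_index[, 3] == 2)
  expect_equal(env$n[i_interior], 9)
  # grid-corner voxel: 2x2 in-plane neighborhood
  i_corner <- which(env$center_index[, 1] == 1 & env$center_index[, 2] == 1 &
                    env$center_index[, 3] == 1)
  expect_equal(env$n[i_corner], 4)
  # self value always belongs to the sample
  expect_equal(env$values[, 1], env$self_value)
  # neighborhoods are restricted to the mask: isolated voxel is a singleton
  lone <- array(FALSE, d); lone[5, 5, 2] <- TRUE
  env1 <- environmental_samples(dat, lone)
  expect_equal(env1$n, 1)
  expect_equal(env1$mean_env, dat[5, 5, 2])
})

test_that("constant image has mean_env equal to self everywhere", {
  d <- c(6L, 6L, 2L)
  env <- environmental_samples(array(3, d), array(TRUE, d))
  expect_equal(env$mean_env, env$self_value)
})

test_that("relative volume is an exact integer ratio with contract checks", {
  brain <- box_brain()
  empty <- array(FALSE, dim(brain))
  expect_equal(relative_volume(empty, brain), 0)
  expect_equal(relative_volume(brain, brain), 1)
  m <- array(FALSE, dim(brain)); m[which(brain)[1:50]] <- TRUE
  expect_equal(relative_volume(m, brain), 0.05)
  expect_error(relative_volume(empty, empty), class = "bbbmap_data_error")
  outside <- array(FALSE, dim(brain)); outside[1, 1, 1] <- TRUE
  expect_error(relative_volume(outside, brain), class = "bbbmap_data_error")
})

test_that("a reference far above the brain suppresses all detections", {
  ph <- generate_phantom(small_phantom_params(seed = 31, lesion_contrast = 4))
  dat <- ph$scans$t2w$data
  # the muscle shell, shifted far above every brain intensity, as reference:
  # the self/mean conditions then fail for every brain voxel
  ref <- ph$truth$muscle_mask
  dat[ref] <- dat[ref] + 1000
  m <- detect_t2w_hyperintensity(dat, ph$truth$brain_mask, ref)
  expect_equal(m$relative_volume, 0)
})

test_that("identical pre and post scans yield zero BBBD volume", {
  ph <- generate_phantom(small_phantom_params(seed = 32))
  m <- detect_bbbd(ph$scans$t1_pre, ph$scans$t1_pre, ph$truth$brain_mask,
                   ph$truth$muscle_mask, assume_registered = TRUE)
  expect_equal(m$relative_volume, 0)
})

test_that("detection maps are deterministic and nested in alpha", {
  ph <- generate_phantom(small_phantom_params(seed = 33))
  args <- list(ph$scans$t2w, ph$truth$brain_mask, ph$truth$contralateral_mask)
  m1 <- do.call(detect_t2w_hyperintensity, c(args, alpha = 0.01))
  m2 <- do.call(detect_t2w_hyperintensity, c(args, alpha = 0.01))
  expect_identical(m1$map, m2$map)
  # nesting: stricter alpha selects a subset
  m_strict <- do.call(detect_t2w_hyperintensity, c(args, alpha = 0.001))
  m_loose <- do.call(detect_t2w_hyperintensity, c(args, alpha = 0.05))
  expect_false(any(m_strict$map & !m1$map))
  expect_false(any(m1$map & !m_loose$map))
})

test_that("maps are invariant to positive intensity rescaling", {
  ph <- generate_phantom(small_phantom_params(seed = 34))
  tr <- ph$truth
  m1 <- detect_t2w_hyperintensity(ph$scans$t2w, tr$brain_mask,
                                  tr$contralateral_mask)
  m2 <- detect_t2w_hyperintensity(ph$scans$t2w$data * 7.3, tr$brain_mask,
                                  tr$contralateral_mask)
  expect_identical(m1$map, m2$map)
  b1 <- detect_bbbd(ph$scans$t1_pre, ph$scans$t1_post, tr$brain_mask,
                    tr$muscle_mask)
  b2 <- detect_bbbd(ph$scans$t1_pre$data * 7.3,
                    shift_volume(ph$scans$t1_post$data * 7.3, c(0, 0, 0)),
                    tr$brain_mask, tr$muscle_mask, assume_registered = TRUE)
  expect_identical(b1$map, b2$map)
})

test_that("detectors recover phantom lesions on the study-size grid", {
  ph <- generate_phantom(phantom_params(seed = 35))
  tr <- ph$truth
  m <- detect_t2w_hyperintensity(ph$scans$t2w, tr$brain_mask,
                                 tr$contralateral_mask)
  expect_lt(abs(m$relative_volume - tr$true_t2w_fraction) /
              tr$true_t2w_fraction, 0.2)
  expect_gte(dice_coefficient(m$map, tr$lesion_mask), 0.8)
  b <- detect_bbbd(ph$scans$t1_pre, ph$scans$t1_post, tr$brain_mask,
                   tr$muscle_mask)
  expect_lt(abs(b$relative_volume - tr$true_bbbd_fraction) /
              tr$true_bbbd_fraction, 0.25)
  expect_gte(dice_coefficient(b$map, tr$leakage_mask), 0.75)
})

test_that("unregistered post-contrast input is refused without an override", {
  ph <- generate_phantom(small_phantom_params(seed = 36,
                                              inter_scan_shift = c(1, 0, 0)))
  expect_error(detect_bbbd(ph$scans$t1_pre, ph$scans$t1_post,
                           ph$truth$brain_mask, ph$truth$muscle_mask),
               class = "bbbmap_data_error")
  m <- detect_bbbd(ph$scans$t1_pre, ph$scans$t1_post, ph$truth$brain_mask,
                   ph$truth$muscle_mask, assume_registered = TRUE)
  expect_s3_class(m, "detection_map")
})

test_that("quantized intensities fall back to exact tie handling", {
  # coarsely rounded intensities create heavy ties in every neighborhood
  ph <- generate_phantom(small_phantom_params(seed = 37, lesion_contrast = 6))
  dat <- round(ph$scans$t2w$data)
  tr <- ph$truth
  m <- detect_t2w_hyperintensity(dat, tr$brain_mask, tr$contralateral_mask,
                                 alpha = 0.01)
  # the lesion is still found despite quantization
  expect_gt(dice_coefficient(m$map, tr$lesion_mask), 0.6)
  pre <- round(ph$scans$t1_pre$data)
  post <- round(ph$scans$t1_post$data)
  b <- detect_bbbd(pre, post, tr$brain_mask, tr$muscle_mask,
                   assume_registered = TRUE, alpha = 0.01)
  expect_gt(dice_coefficient(b$map, tr$leakage_mask), 0.6)
})

test_that("seeded reference subsampling is reproducible", {
  ph <- generate_phantom(small_phantom_params(seed = 38))
  tr <- ph$truth
  m1 <- detect_t2w_hyperintensity(ph$scans$t2w, tr$brain_mask,
                                  tr$contralateral_mask,
                                  ref_subsample = 500, ref_seed = 7)
  m2 <- detect_t2w_hyperintensity(ph$scans$t2w, tr$brain_mask,
                                  tr$contralateral_mask,
                                  ref_subsample = 500, ref_seed = 7)
  expect_identical(m1$map, m2$map)
  expect_equal(m1$n_reference, 500)
  expect_error(detect_t2w_hyperintensity(ph$scans$t2w, tr$brain_mask,
                                         tr$contralateral_mask,
                                         ref_subsample = 500),
               class = "bbbmap_config_error")
})
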