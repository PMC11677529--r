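test_that("phantom generation is bit-reproducible and seed-consistent", {
  p <- small_phantom_params(seed = 5)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$scans$t2w$data, b$scans$t2w$data)
  expect_identical(a$scans$t1_post$data, b$scans$t1_post$data)
  expect_identical(a$truth$lesion_mask, b$truth$lesion_mask)

  # different seed: identical geometry, different noise realization
  c2 <- generate_phantom(small_phantom_params(seed = 6))
  expect_identical(a$truth$lesion_mask, c2$truth$lesion_mask)
  expect_identical(a$truth$brain_mask, c2$truth$brain_mask)
  expect_false(identical(a$scans$t2w$data, c2$scans$t2w$data))
})

test_that("true fractions are exact mask ratios near their targets", {
  ph <- generate_phantom(small_phantom_params(seed = 1, lesion_fraction = 0.1))
  tr <- ph$truth
  n_brain <- sum(tr$brain_mask)
  expect_identical(tr$true_t2w_fraction, sum(tr$lesion_mask) / n_brain)
  expect_identical(tr$true_bbbd_fraction, sum(tr$leakage_mask) / n_brain)
  # within one voxel-quantization step of the requested fraction
  expect_lte(abs(tr$true_t2w_fraction - 0.1), 1 / n_brain)
  # masks live inside the brain; lesion and leakage disjoint by default
  expect_false(any(tr$lesion_mask & !tr$brain_mask))
  expect_false(any(tr$leakage_mask & !tr$brain_mask))
  expect_false(any(tr$lesion_mask & tr$leakage_mask))
})

test_that("zero-effect phantom yields statistically matched scans", {
  ph <- generate_phantom(small_phantom_params(
    seed = 2, lesion_fraction = 0, lesion_contrast = 0, leakage_fraction = 0,
    enhancement_contrast = 0, muscle_enhancement = 0,
    t1_brain_contrast = 5, t1_muscle_contrast = 2.5))
  expect_equal(ph$truth$true_t2w_fraction, 0)
  expect_equal(ph$truth$true_bbbd_fraction, 0)
  br <- ph$truth$brain_mask
  m <- vapply(list(ph$scans$t2w, ph$scans$t1_pre, ph$scans$t1_post),
              function(v) mean(v$data[br]), numeric(1))
  s <- vapply(list(ph$scans$t2w, ph$scans$t1_pre, ph$scans$t1_post),
              function(v) sd(v$data[br]), numeric(1))
  expect_lt(max(m) - min(m), 4 / sqrt(sum(br)))   # brain means agree
  expect_lt(max(abs(s - 1)), 0.05)                 # unit noise SD
})

test_that("realized lesion contrast matches the requested effect size", {
  ph <- generate_phantom(small_phantom_params(seed = 3, lesion_fraction = 0.1,
                                              lesion_contrast = 4))
  tr <- ph$truth
  inside <- ph$scans$t2w$data[tr$lesion_mask]
  outside <- ph$scans$t2w$data[tr$brain_mask & !tr$lesion_mask]
  emp <- (mean(inside) - mean(outside)) / tr$params$noise_sd
  tol <- 3 * sqrt(1 / length(inside) + 1 / length(outside))
  expect_lt(abs(emp - 4), tol)
})

test_that("rician background follows Rayleigh moments", {
  ph <- generate_phantom(small_phantom_params(seed = 4, noise_model = "rician"))
  bg <- !ph$truth$brain_mask & !ph$truth$muscle_mask
  x <- ph$scans$t2w$data[bg]           # zero signal, channel SD 1
  n <- length(x)
  expect_lt(abs(mean(x) - sqrt(pi / 2)), 4 / sqrt(n))
  expect_lt(abs(sd(x) - sqrt(2 - pi / 2)), 4 / sqrt(n))
  expect_true(all(x >= 0))
})

test_that("contralateral mirror splits a symmetric brain in half", {
  brain <- box_brain()                  # 1000 voxels, 500 per hemisphere
  right_ref <- mirror_reference_mask(brain, "right")
  left_ref <- mirror_reference_mask(brain, "left")
  expect_equal(sum(right_ref), 500)
  expect_equal(sum(left_ref), 500)
  expect_false(any(right_ref & left_ref))
  expect_identical(right_ref | left_ref, brain)
  # phantom contralateral mask excludes the lesion hemisphere entirely
  ph <- generate_phantom(small_phantom_params(seed = 1))
  xs <- slice.index(ph$truth$contralateral_mask, 1)
  expect_true(all(xs[ph$truth$contralateral_mask] < (dim(xs)[1] + 1) / 2))
  expect_false(any(ph$truth$contralateral_mask & ph$truth$lesion_mask))
})

test_that("invalid or infeasible parameters are rejected", {
  expect_error(phantom_params(lesion_fraction = 1.2),
               class = "bbbmap_parameter_error")
  expect_error(phantom_params(noise_sd = -1),
               class = "bbbmap_parameter_error")
  expect_error(phantom_params(lesion_contrast = -2),
               class = "bbbmap_parameter_error")
  # lesion occupies all brain voxels: no room left for disjoint leakage
  expect_error(
    generate_phantom(small_phantom_params(lesion_fraction = 1,
                                          leakage_fraction = 0.1)),
    class = "bbbmap_infeasible_geometry")
  # but overlap is allowed when requested explicitly
  ph <- generate_phantom(small_phantom_params(lesion_fraction = 1,
                                              leakage_fraction = 0.1,
                                              allow_overlap = TRUE))
  expect_gt(sum(ph$truth$leakage_mask & ph$truth$lesion_mask), 0)
  expect_error(mirror_reference_mask(array(FALSE, c(4, 4, 4))),
               class = "bbbmap_data_error")
})

test_that("inter-scan shift is recorded and moves only the post scan", {
  ph <- generate_phantom(small_phantom_params(seed = 9,
                                              inter_scan_shift = c(2, 0, 0)))
  expect_equal(ph$truth$applied_shift, c(2, 0, 0))
  expect_false(isTRUE(ph$scans$t1_post$registered))
  # leakage signal center of mass moved by ~2 voxels along axis 1
  ph0 <- generate_phantom(small_phantom_params(seed = 9))
  expect_true(isTRUE(ph0$scans$t1_post$registered))
  diff1 <- ph$scans$t1_post$data - ph$scans$t1_pre$data
  diff0 <- ph0$scans$t1_post$data - ph0$scans$t1_pre$data
  com <- function(w) {
    w <- pmax(w, 0)
    sum(slice.index(w, 1) * w) / sum(w)
  }
  expect_equal(com(diff1) - com(diff0), 2, tolerance = 0.5)
})
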