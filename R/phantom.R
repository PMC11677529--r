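# Synthetic phantom: a brain-shaped ellipsoid on a dark background with a
# peripheral muscle shell, a T2w hyper-intense lesion, a post-contrast
# enhancing leakage region, additive gaussian or Rician noise, and an
# optional inter-scan translation of the post-contrast scan.  All contrasts
# are parameterized in units of the noise SD so detection power is
# controlled directly; absolute intensity units are arbitrary.

#' Phantom generation parameters
#'
#' Defaults describe the standing study conditions used by the package's
#' simulation suites: a 96x96x18 grid at 0.2x0.2x1 mm (a rodent-brain-like
#' field of view), a brain ellipsoid filling 30% of the grid, brain tissue
#' 5 noise-SD above background, and unit noise SD.
#'
#' @param grid_shape Integer triple of voxel counts.
#' @param voxel_spacing mm per axis.
#' @param brain_fraction Fraction of grid voxels inside the brain ellipsoid.
#' @param lesion_fraction Target fraction of brain voxels in the T2w lesion.
#' @param lesion_contrast Lesion mean shift on T2w, in noise-SD units.
#' @param leakage_fraction Fraction of brain voxels that enhance post-contrast.
#' @param enhancement_contrast Post-minus-pre mean shift inside the leakage
#'   region, noise-SD units.
#' @param muscle_enhancement Global post-contrast shift of the muscle shell,
#'   noise-SD units.
#' @param noise_sd Additive noise SD in intensity units.
#' @param noise_model `"gaussian"` or `"rician"` (magnitude of a complex
#'   gaussian channel pair, the physical MRI magnitude-noise model).
#' @param inter_scan_shift Voxel-unit translation (may be fractional) applied
#'   to the post-contrast scan before its noise draw.
#' @param seed Integer RNG seed; identical seed and parameters give
#'   bit-identical output.
#' @param tissue_contrast T2w brain-over-background contrast (noise-SD units).
#' @param muscle_t2_contrast T2w muscle-over-background contrast.
#' @param t1_brain_contrast,t1_muscle_contrast T1w baselines for brain and
#'   muscle; muscle sits slightly above parenchyma so the muscle reference is
#'   conservative for systemic enhancement.
#' @param allow_overlap Permit the lesion and leakage regions to overlap; by
#'   default leakage voxels are drawn from non-lesion brain voxels, which
#'   resolves the geometry deterministically.
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(96L, 96L, 18L),
                           voxel_spacing = c(0.2, 0.2, 1),
                           brain_fraction = 0.3,
                           lesion_fraction = 0.1,
                           lesion_contrast = 4,
                           leakage_fraction = 0.08,
                           enhancement_contrast = 4,
                           muscle_enhancement = 1,
                           noise_sd = 1,
                           noise_model = c("gaussian", "rician"),
                           inter_scan_shift = c(0, 0, 0),
                           seed = 1L,
                           tissue_contrast = 5,
                           muscle_t2_contrast = 2.5,
                           t1_brain_contrast = 5,
                           t1_muscle_contrast = 6,
                           allow_overlap = FALSE) {
  noise_model <- match.arg(noise_model)
  p <- list(grid_shape = as.integer(grid_shape),
            voxel_spacing = as.numeric(voxel_spacing),
            brain_fraction = brain_fraction,
            lesion_fraction = lesion_fraction,
            lesion_contrast = lesion_contrast,
            leakage_fraction = leakage_fraction,
            enhancement_contrast = enhancement_contrast,
            muscle_enhancement = muscle_enhancement,
            noise_sd = noise_sd, noise_model = noise_model,
            inter_scan_shift = as.numeric(inter_scan_shift),
            seed = as.integer(seed),
            tissue_contrast = tissue_contrast,
            muscle_t2_contrast = muscle_t2_contrast,
            t1_brain_contrast = t1_brain_contrast,
            t1_muscle_contrast = t1_muscle_contrast,
            allow_overlap = isTRUE(allow_overlap))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  bbb_assert(length(p$grid_shape) == 3L && all(p$grid_shape >= 8L),
             "bbbmap_parameter_error", "grid_shape must be a triple >= 8")
  for (f in c("brain_fraction", "lesion_fraction", "leakage_fraction")) {
    bbb_assert(p[[f]] >= 0 && p[[f]] <= 1, "bbbmap_parameter_error",
               "%s must be in [0, 1] (got %g)", f, p[[f]])
  }
  bbb_assert(p$brain_fraction > 0, "bbbmap_parameter_error",
             "brain_fraction must be positive")
  for (f in c("lesion_contrast", "enhancement_contrast", "noise_sd")) {
    bbb_assert(p[[f]] >= 0, "bbbmap_parameter_error",
               "%s must be >= 0", f)
  }
  bbb_assert(length(p$inter_scan_shift) == 3L, "bbbmap_parameter_error",
             "inter_scan_shift must be a triple")
  invisible(TRUE)
}

# Normalized ellipsoid radius^2 grid for the brain: rho <= 1 inside.
phantom_geometry <- function(p) {
  d <- p$grid_shape
  f <- (6 * p$brain_fraction / pi)^(1 / 3)   # (pi/6) f^3 = brain_fraction
  semi <- f * d / 2
  cen <- (d + 1) / 2
  ix <- (seq_len(d[1]) - cen[1]) / semi[1]
  iy <- (seq_len(d[2]) - cen[2]) / semi[2]
  iz <- (seq_len(d[3]) - cen[3]) / semi[3]
  rho2 <- outer(outer(ix^2, iy^2, `+`), iz^2, `+`)
  brain <- rho2 <= 1
  bbb_assert(any(brain), "bbbmap_infeasible_geometry",
             "grid too small to host the requested brain fraction")
  muscle <- rho2 > 1.15^2 & rho2 <= 1.45^2
  list(brain = brain, muscle = muscle, semi = semi, center = cen)
}

# k nearest brain voxels (physical mm distance, deterministic tie-break by
# voxel index) to a center given in voxel coordinates.
nearest_region <- function(candidate_idx, dims, spacing, center_vox, k) {
  bbb_assert(k <= length(candidate_idx), "bbbmap_infeasible_geometry",
             "requested region of %d voxels but only %d candidates", k,
             length(candidate_idx))
  if (k == 0L) return(integer(0))
  coord <- arrayInd(candidate_idx, dims)
  dmm2 <- ((coord[, 1] - center_vox[1]) * spacing[1])^2 +
          ((coord[, 2] - center_vox[2]) * spacing[2])^2 +
          ((coord[, 3] - center_vox[3]) * spacing[3])^2
  ord <- order(dmm2, coord[, 1], coord[, 2], coord[, 3])
  candidate_idx[ord[seq_len(k)]]
}

add_noise <- function(clean, sd, model) {
  if (sd == 0) return(clean)
  if (model == "gaussian") {
    clean + array(stats::rnorm(length(clean), sd = sd), dim = dim(clean))
  } else {
    # Rician: magnitude of (signal + n1) + i n2 with gaussian channel noise
    n1 <- array(stats::rnorm(length(clean), sd = sd), dim = dim(clean))
    n2 <- array(stats::rnorm(length(clean), sd = sd), dim = dim(clean))
    sqrt((clean + n1)^2 + n2^2)
  }
}

#' Generate a synthetic subject scan set with ground truth
#'
#' Builds the T2w / pre-contrast T1w / post-contrast T1w triplet the
#' detector expects: the lesion is hyper-intense on T2w only; the leakage
#' region enhances on the post-contrast T1w only; the muscle shell receives
#' an optional global post-contrast shift; the post-contrast scan is then
#' translated by `inter_scan_shift` (linear interpolation, background fill)
#' and each scan gets an independent noise draw. Region geometry is fully
#' deterministic in the parameters; only the noise depends on the seed.
#'
#' @param params A [phantom_params()] object.
#' @return A list with `scans` (a `subject_scan_set`: `t2w`, `t1_pre`,
#'   `t1_post`, plus `brain_mask`, `contralateral_mask`, `muscle_mask`) and
#'   `truth` (a `phantom_truth`: `brain_mask`, `lesion_mask`, `leakage_mask`,
#'   `muscle_mask`, `contralateral_mask`, exact `true_t2w_fraction` and
#'   `true_bbbd_fraction`, `applied_shift`, `params`).
#' @export
generate_phantom <- function(params) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  p <- params
  d <- p$grid_shape
  g <- phantom_geometry(p)
  brain <- g$brain; muscle <- g$muscle
  n_brain <- sum(brain)
  brain_idx <- which(brain)

  # lesion and leakage: k-nearest-voxel "spheres" in the right hemisphere
  # (axis 1 upper half), separated along axis 2
  k_les <- as.integer(round(p$lesion_fraction * n_brain))
  k_leak <- as.integer(round(p$leakage_fraction * n_brain))
  les_center <- c(g$center[1] + g$semi[1] / 2, g$center[2] - g$semi[2] / 3,
                  g$center[3])
  leak_center <- c(g$center[1] + g$semi[1] / 2, g$center[2] + g$semi[2] / 3,
                   g$center[3])
  lesion_idx <- nearest_region(brain_idx, d, p$voxel_spacing, les_center, k_les)
  leak_candidates <- if (p$allow_overlap) brain_idx else setdiff(brain_idx, lesion_idx)
  leak_idx <- nearest_region(leak_candidates, d, p$voxel_spacing, leak_center,
                             k_leak)
  lesion <- array(FALSE, d); lesion[lesion_idx] <- TRUE
  leak <- array(FALSE, d); leak[leak_idx] <- TRUE
  contra <- mirror_reference_mask(brain, lesion_side = "right")

  s <- p$noise_sd
  t2_clean <- (p$tissue_contrast * brain + p$muscle_t2_contrast * muscle +
               p$lesion_contrast * lesion) * s
  t1_clean <- (p$t1_brain_contrast * brain + p$t1_muscle_contrast * muscle) * s
  t1_post_clean <- t1_clean + (p$enhancement_contrast * leak +
                               p$muscle_enhancement * muscle) * s
  if (any(p$inter_scan_shift != 0)) {
    t1_post_clean <- shift_volume(t1_post_clean, p$inter_scan_shift, fill = 0)
  }

  set.seed(p$seed)
  t2 <- add_noise(t2_clean, s, p$noise_model)
  t1p <- add_noise(t1_clean, s, p$noise_model)
  t1q <- add_noise(t1_post_clean, s, p$noise_model)

  sp <- p$voxel_spacing
  sid <- sprintf("phantom-s%d", p$seed)
  scans <- structure(list(
    t2w = volume_image(t2, sp, "T2w", sid),
    t1_pre = volume_image(t1p, sp, "T1w_pre", sid),
    t1_post = volume_image(t1q, sp, "T1w_post", sid,
                           registered = all(p$inter_scan_shift == 0)),
    brain_mask = brain, contralateral_mask = contra, muscle_mask = muscle
  ), class = "subject_scan_set")
  truth <- structure(list(
    brain_mask = brain, lesion_mask = lesion, leakage_mask = leak,
    muscle_mask = muscle, contralateral_mask = contra,
    true_t2w_fraction = k_les / n_brain,
    true_bbbd_fraction = k_leak / n_brain,
    applied_shift = p$inter_scan_shift, params = p
  ), class = "phantom_truth")
  list(scans = scans, truth = truth)
}

#' Contralateral reference mask by mid-sagittal mirroring
#'
#' Returns the brain voxels on the hemisphere opposite `lesion_side`. The
#' mid-sagittal plane is the central grid plane along axis 1 (left-right);
#' for an even extent the grid splits exactly in half, for an odd extent the
#' central plane itself belongs to neither hemisphere.
#'
#' @param brain_mask Binary 3-D brain mask.
#' @param lesion_side `"right"` (upper half of axis 1) or `"left"`.
#' @return Logical array of reference voxels.
#' @export
mirror_reference_mask <- function(brain_mask, lesion_side = c("right", "left")) {
  lesion_side <- match.arg(lesion_side)
  m <- as_mask(brain_mask, what = "brain_mask")
  bbb_assert(any(m), "bbbmap_data_error", "brain mask is empty")
  nx <- dim(m)[1]
  xs <- slice.index(m, 1)
  half <- (nx + 1) / 2
  ref <- if (lesion_side == "right") m & xs < half else m & xs > half
  bbb_assert(any(ref), "bbbmap_degenerate_reference_error",
             "contralateral reference mask is empty")
  ref
}
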