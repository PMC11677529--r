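# Per-voxel environmental-histogram rank classification.
#
# For every brain voxel the "environmental sample" is the set of intensities
# of the in-plane 3x3 neighborhood restricted to the brain mask (1-9 values;
# border voxels use truncated neighborhoods -- padding would invent data).
# T2w hyper-intensity: environmental sample ranks above a contralateral
# reference sample (one-sided Mann-Whitney at alpha) AND the voxel's own
# value and environmental mean both exceed the reference mean.  BBBD: the
# post-contrast environmental sample ranks above the pre-contrast sample at
# the same location AND the post self value exceeds the pre self value AND
# the post environmental mean exceeds the mean temporal-muscle reference
# signal (taken from the post-contrast scan, so systemic uptake is
# controlled for).

# In-plane 3x3 offsets (axis-1 / axis-2), self first.
ENV_OFFSETS <- cbind(dx = c(0, -1, 0, 1, -1, 1, -1, 0, 1),
                     dy = c(0, -1, -1, -1, 0, 0, 1, 1, 1))

# n_brain x 9 matrix of neighborhood intensities (NA where the neighbor is
# outside the grid or the mask), for the voxels in brain_idx.
env_value_matrix <- function(dat, mask, brain_idx) {
  d <- dim(dat)
  dat_masked <- dat
  dat_masked[!mask] <- NA_real_
  out <- matrix(NA_real_, nrow = length(brain_idx), ncol = nrow(ENV_OFFSETS))
  for (j in seq_len(nrow(ENV_OFFSETS))) {
    off <- c(ENV_OFFSETS[j, 1], ENV_OFFSETS[j, 2], 0)
    # shift_volume_int(x, -off) places dat[x + off] at x
    out[, j] <- shift_volume_int(dat_masked, -off)[brain_idx]
  }
  out
}

#' Environmental samples of brain voxels
#'
#' Returns, for each brain voxel, the intensities of its in-plane 3x3
#' neighborhood intersected with the brain mask, its environmental mean and
#' its own value. Isolated voxels yield singleton samples.
#'
#' @param volume `volume_image` or 3-D array.
#' @param brain_mask Binary mask on the same grid.
#' @return A list of class `environmental_samples`: `center_index` (matrix
#'   of voxel triples), `values` (n x 9 matrix, NA-padded, self in column
#'   1), `n` (sample sizes), `mean_env`, `self_value`.
#' @export
environmental_samples <- function(volume, brain_mask) {
  dat <- vol_data(volume)
  mask <- as_mask(brain_mask, dim(dat), "brain_mask")
  brain_idx <- which(mask)
  vals <- env_value_matrix(dat, mask, brain_idx)
  structure(list(center_index = arrayInd(brain_idx, dim(dat)),
                 linear_index = brain_idx,
                 values = vals,
                 n = rowSums(!is.na(vals)),
                 mean_env = rowMeans(vals, na.rm = TRUE),
                 self_value = dat[brain_idx]),
            class = "environmental_samples")
}

new_detection_map <- function(map, brain_mask, kind, alpha, n_reference,
                              reference_mean) {
  rv <- sum(map) / sum(brain_mask)
  structure(list(map = map, relative_volume = rv, kind = kind, alpha = alpha,
                 n_reference = n_reference, reference_mean = reference_mean),
            class = "detection_map")
}

#' @export
print.detection_map <- function(x, ...) {
  cat(sprintf("<detection_map> %s: %d voxels, relative volume %.4f (%.2f%%), alpha %g\n",
              x$kind, sum(x$map), x$relative_volume,
              100 * x$relative_volume, x$alpha))
  invisible(x)
}

#' Relative volume of a detection map
#'
#' The number of positive voxels divided by the number of brain voxels, as
#' an exact integer ratio.
#'
#' @param map Binary map (or `detection_map`), a subset of `brain_mask`.
#' @param brain_mask Binary brain mask.
#' @return Fraction in `[0, 1]`.
#' @export
relative_volume <- function(map, brain_mask) {
  if (inherits(map, "detection_map")) map <- map$map
  m <- as_mask(map, what = "map")
  b <- as_mask(brain_mask, dim(m), "brain_mask")
  bbb_assert(sum(b) > 0, "bbbmap_data_error", "brain mask is empty")
  bbb_assert(!any(m & !b), "bbbmap_data_error",
             "map contains voxels outside the brain mask")
  sum(m) / sum(b)
}

# One-sided normal-approximation p values (env > reference) for all voxels
# at once against a single fixed reference sample.  The tie-corrected
# variance is computed exactly in vectorized form: an env value matching a
# reference tie group of size r enlarges that group to r + 1, changing
# sum(t^3 - t) by 3r^2 + 3r.  Rows whose env sample contains internal
# duplicates (exact equality of intensities, rare for continuous data) fall
# back to the scalar test.
env_vs_reference_p <- function(env, ref_values) {
  sr <- sort(ref_values)
  nb <- length(sr)
  v <- env$values
  cnt_le <- matrix(findInterval(v, sr), nrow = nrow(v))
  cnt_lt <- matrix(findInterval(v, sr, left.open = TRUE), nrow = nrow(v))
  eq <- cnt_le - cnt_lt
  u2 <- rowSums(2 * cnt_lt + eq, na.rm = TRUE)   # doubled U
  n_a <- env$n
  # internal env duplicates (pairwise check, vectorized over voxels)
  internal_dup <- logical(nrow(v))
  k <- ncol(v)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      dup <- v[, i] == v[, j]
      dup[is.na(dup)] <- FALSE
      internal_dup <- internal_dup | dup
    }
  }

  n <- n_a + nb
  t_comb <- tie_term(sr) + rowSums(3 * eq^2 + 3 * eq, na.rm = TRUE)
  var2 <- 4 * (n_a * nb / 12) * ((n + 1) - t_comb / (n * (n - 1)))
  z <- (u2 - n_a * nb - 1) / sqrt(var2)          # continuity-corrected, 2U scale
  p <- stats::pnorm(z, lower.tail = FALSE)

  if (any(internal_dup)) {
    for (i in which(internal_dup)) {
      sa <- v[i, ]; sa <- sa[!is.na(sa)]
      p[i] <- mwu_test(sa, ref_values, alternative = "a_greater",
                       method = "normal_approx")$p_one_sided
    }
  }
  p
}

#' Detect T2w hyper-intense voxels
#'
#' A brain voxel is hyper-intense when (a) its environmental sample ranks
#' above the reference sample by a one-sided Mann-Whitney test at `alpha`,
#' (b) its own value exceeds the reference mean, and (c) its environmental
#' mean exceeds the reference mean. The reference is by default the
#' contralateral hemisphere; means are always computed on the full
#' reference, the rank test optionally on a seeded subsample.
#'
#' @param t2w `volume_image` or array.
#' @param brain_mask,reference_mask Binary masks on the same grid; the
#'   reference must be nonempty (and should exclude the suspected-lesion
#'   hemisphere -- caller's responsibility).
#' @param alpha Voxel-level significance level (no multiplicity correction;
#'   the mean conditions suppress chance positives).
#' @param ref_subsample Optional integer: subsample the reference to this
#'   size for the rank test (seeded by `ref_seed`).
#' @param ref_seed Seed for the reference subsample.
#' @param min_reference Floor below which a warning is logged.
#' @return A `detection_map` with `kind = "t2w_hyper"`.
#' @export
detect_t2w_hyperintensity <- function(t2w, brain_mask, reference_mask,
                                      alpha = 0.001, ref_subsample = NULL,
                                      ref_seed = NULL, min_reference = 50) {
  bbb_assert(alpha > 0 && alpha < 1, "bbbmap_config_error",
             "alpha must be in (0, 1)")
  dat <- vol_data(t2w)
  mask <- as_mask(brain_mask, dim(dat), "brain_mask")
  ref <- as_mask(reference_mask, dim(dat), "reference_mask")
  bbb_assert(any(ref), "bbbmap_data_error", "reference mask is empty")
  ref_values <- dat[ref]
  if (length(ref_values) < min_reference) {
    bbb_log("lesion_detect", "detect_t2w_hyperintensity",
            sprintf("reference has only %d voxels", length(ref_values)),
            level = "warn")
  }
  ref_mean <- mean(ref_values)
  test_ref <- ref_values
  if (!is.null(ref_subsample) && ref_subsample < length(ref_values)) {
    bbb_assert(!is.null(ref_seed), "bbbmap_config_error",
               "reference subsampling requires ref_seed")
    set.seed(ref_seed)
    test_ref <- sample(ref_values, ref_subsample)
    bbb_log("lesion_detect", "detect_t2w_hyperintensity",
            sprintf("reference subsampled to %d (seed %d)", ref_subsample,
                    ref_seed))
  }

  env <- environmental_samples(dat, mask)
  p <- env_vs_reference_p(env, test_ref)
  pos <- p <= alpha & env$self_value > ref_mean & env$mean_env > ref_mean
  map <- array(FALSE, dim(dat))
  map[env$linear_index[pos]] <- TRUE
  new_detection_map(map, mask, "t2w_hyper", alpha, length(test_ref), ref_mean)
}

#' Detect blood-brain-barrier-dysfunction voxels
#'
#' A brain voxel is BBBD-positive when (a) its post-contrast environmental
#' sample ranks above the pre-contrast environmental sample at the same
#' location (one-sided Mann-Whitney at `alpha`, exact null distribution),
#' (b) its post-contrast value exceeds its pre-contrast value, and (c) its
#' post-contrast environmental mean exceeds the mean temporal-muscle
#' reference signal from the post-contrast scan.
#'
#' @param t1_pre,t1_post_registered `volume_image`s on the same grid; the
#'   post volume must carry `registered = TRUE` (set by [register_rigid()]
#'   or by the phantom when no shift was applied) unless `assume_registered`.
#' @param brain_mask,muscle_mask Binary masks; muscle must be nonempty.
#' @param alpha Voxel-level significance level.
#' @param assume_registered Skip the registration-metadata check.
#' @return A `detection_map` with `kind = "bbbd"`.
#' @export
detect_bbbd <- function(t1_pre, t1_post_registered, brain_mask, muscle_mask,
                        alpha = 0.001, assume_registered = FALSE) {
  bbb_assert(alpha > 0 && alpha < 1, "bbbmap_config_error",
             "alpha must be in (0, 1)")
  if (inherits(t1_post_registered, "volume_image") && !assume_registered) {
    bbb_assert(isTRUE(t1_post_registered$registered), "bbbmap_data_error",
               paste("post-contrast volume is not marked registered;",
                     "run register_rigid() or set assume_registered = TRUE"))
  }
  pre <- vol_data(t1_pre); post <- vol_data(t1_post_registered)
  bbb_assert(identical(dim(pre), dim(post)), "bbbmap_alignment_error",
             "pre and post grids differ")
  mask <- as_mask(brain_mask, dim(pre), "brain_mask")
  muscle <- as_mask(muscle_mask, dim(pre), "muscle_mask")
  bbb_assert(any(muscle), "bbbmap_data_error", "muscle mask is empty")
  muscle_mean <- mean(post[muscle])

  env_pre <- environmental_samples(pre, mask)
  env_post <- environmental_samples(post, mask)
  vp <- env_pre$values; vq <- env_post$values
  nv <- nrow(vp); k <- ncol(vp)
  u2 <- numeric(nv)
  any_eq <- logical(nv)
  for (i in seq_len(k)) {
    qi <- vq[, i]
    for (j in seq_len(k)) {
      pj <- vp[, j]
      gt <- qi > pj
      eqm <- qi == pj
      gt[is.na(gt)] <- FALSE
      eqm[is.na(eqm)] <- FALSE
      u2 <- u2 + 2 * gt + eqm
      any_eq <- any_eq | eqm
    }
  }
  n_a <- env_post$n; n_b <- env_pre$n

  # exact one-sided p (post > pre) from cached tie-free null tables
  p <- rep(NA_real_, nv)
  clean <- !any_eq
  if (any(clean)) {
    combos <- unique(paste(n_a[clean], n_b[clean], sep = "."))
    for (nn in combos) {
      sz <- as.integer(strsplit(nn, ".", fixed = TRUE)[[1]])
      rows <- clean & n_a == sz[1] & n_b == sz[2]
      tab <- mwu_exact_tail_table(sz[1], sz[2])
      p[rows] <- tab$p_ge[u2[rows] + 1L]
    }
  }
  if (any(any_eq)) {
    for (i in which(any_eq)) {
      sa <- vq[i, ]; sa <- sa[!is.na(sa)]
      sb <- vp[i, ]; sb <- sb[!is.na(sb)]
      p[i] <- mwu_test(sa, sb, alternative = "a_greater",
                       method = "exact")$p_one_sided
    }
  }

  pos <- p <= alpha &
    env_post$self_value > env_pre$self_value &
    env_post$mean_env > muscle_mean
  map <- array(FALSE, dim(pre))
  map[env_post$linear_index[pos]] <- TRUE
  new_detection_map(map, mask, "bbbd", alpha, sum(muscle), muscle_mean)
}
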