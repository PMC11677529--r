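# Histogram-based brain segmentation: intensity bands are estimated from a
# brain seed region (central block) and a peripheral seed region (border
# shell); brain voxels are those inside the brain band and outside the
# peripheral band, cleaned up by largest-connected-component selection and
# hole filling.

# 6-connected component labeling by vectorized breadth-first search on a
# zero-padded grid (padding removes wrap-around at faces).
label_components <- function(mask) {
  d <- dim(mask)
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  offs <- c(-1L, 1L, -dp[1], dp[1], -dp[1] * dp[2], dp[1] * dp[2])
  labels <- array(0L, dp)
  todo <- which(pad)
  lab <- 0L
  while (length(todo) > 0) {
    lab <- lab + 1L
    frontier <- todo[1L]
    labels[frontier] <- lab
    while (length(frontier) > 0) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[pad[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      frontier <- nb
    }
    todo <- todo[labels[todo] == 0L]
  }
  labels[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# Keep the largest component; report how many were discarded.
largest_component <- function(mask) {
  labels <- label_components(mask)
  n <- max(labels)
  if (n <= 1L) return(list(mask = mask, removed = 0L))
  sizes <- tabulate(labels[labels > 0L], nbins = n)
  keep <- which.max(sizes)
  list(mask = labels == keep, removed = n - 1L)
}

# Fill interior cavities: background components not reachable from the grid
# border become foreground.
fill_holes <- function(mask) {
  d <- dim(mask)
  dp <- d + 2L
  pad <- array(TRUE, dp)                  # padding belongs to the outside
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- !mask
  offs <- c(-1L, 1L, -dp[1], dp[1], -dp[1] * dp[2], dp[1] * dp[2])
  outside <- array(FALSE, dp)
  # the padding shell is 6-connected, so one corner seeds the whole outside
  frontier <- 1L
  outside[frontier] <- TRUE
  while (length(frontier) > 0) {
    nb <- unique(as.vector(outer(frontier, offs, `+`)))
    nb <- nb[nb >= 1L & nb <= length(pad)]
    nb <- nb[pad[nb] & !outside[nb]]
    outside[nb] <- TRUE
    frontier <- nb
  }
  inner <- outside[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  mask | (!mask & !inner)
}

default_seed_regions <- function(d) {
  brain_seed <- array(FALSE, d)
  half <- pmax(1L, d %/% 8L)              # central block of ~1/4 extent
  cen <- (d + 1L) %/% 2L
  brain_seed[(cen[1] - half[1]):(cen[1] + half[1]),
             (cen[2] - half[2]):(cen[2] + half[2]),
             (cen[3] - half[3]):(cen[3] + half[3])] <- TRUE
  periph_seed <- array(TRUE, d)
  periph_seed[3:(d[1] - 2), 3:(d[2] - 2), ] <- FALSE
  list(brain = brain_seed, peripheral = periph_seed)
}

#' Segment the brain from a T2w volume by signal histograms
#'
#' Estimates an accepted intensity band from a brain seed region (by default
#' the central block of the grid) and a rejected band from a peripheral seed
#' region (the border shell); a voxel is brain when its intensity falls
#' inside the brain band and outside the peripheral band. The raw mask is
#' cleaned up by keeping the largest 6-connected component and filling
#' interior holes. When the two bands cannot be separated (flat or unimodal
#' images), a `bbbmap_segmentation_failure` error is raised rather than an
#' empty mask being returned.
#'
#' @param t2w A `volume_image` (or 3-D array).
#' @param seed_regions Optional list with logical arrays `brain` and
#'   `peripheral`; automatic seeding is used when absent.
#' @param band_percentiles Two probabilities defining both bands (default
#'   `c(0.025, 0.975)`).
#' @param min_mask_fraction Smallest credible brain-to-grid volume ratio;
#'   below it segmentation is declared failed.
#' @return A list of class `segmentation_result`: `brain_mask` (cleaned),
#'   `band_mask` (pre-cleanup voxels satisfying the band criterion),
#'   `brain_range`, `peripheral_range`, `n_components_removed`,
#'   `n_holes_filled`.
#' @export
segment_brain <- function(t2w, seed_regions = NULL,
                          band_percentiles = c(0.025, 0.975),
                          min_mask_fraction = 0.01) {
  dat <- vol_data(t2w)
  bbb_assert(all(is.finite(dat)), "bbbmap_data_error",
             "segment_brain: non-finite voxels")
  d <- dim(dat)
  if (is.null(seed_regions)) seed_regions <- default_seed_regions(d)
  bseed <- as_mask(seed_regions$brain, d, "brain seed")
  pseed <- as_mask(seed_regions$peripheral, d, "peripheral seed")

  brange <- unname(stats::quantile(dat[bseed], band_percentiles, type = 7))
  prange <- unname(stats::quantile(dat[pseed], band_percentiles, type = 7))
  if (brange[1] >= prange[1] && brange[2] <= prange[2]) {
    bbb_stop("bbbmap_segmentation_failure",
             "brain band [%g, %g] indistinguishable from peripheral band [%g, %g]",
             brange[1], brange[2], prange[1], prange[2])
  }
  in_brain <- dat >= brange[1] & dat <= brange[2]
  in_periph <- dat >= prange[1] & dat <= prange[2]
  band_mask <- in_brain & !in_periph
  if (sum(band_mask) < min_mask_fraction * length(dat)) {
    bbb_stop("bbbmap_segmentation_failure",
             "band criterion selects only %d voxels (%.2f%% of grid)",
             sum(band_mask), 100 * sum(band_mask) / length(dat))
  }
  lc <- largest_component(band_mask)
  filled <- fill_holes(lc$mask)
  bbb_log("preprocess", "segment_brain",
          sprintf("brain voxels %d, components removed %d, holes filled %d",
                  sum(filled), lc$removed, sum(filled) - sum(lc$mask)))
  structure(list(brain_mask = filled, band_mask = band_mask,
                 brain_range = brange, peripheral_range = prange,
                 n_components_removed = lc$removed,
                 n_holes_filled = sum(filled) - sum(lc$mask)),
            class = "segmentation_result")
}
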