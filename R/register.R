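# Rigid registration by normalized cross-correlation: exhaustive integer
# translation search in a window, optional per-axis subvoxel refinement by
# 1-D optimization of the interpolated NCC, optional small in-plane rotation
# grid.  Deterministic throughout.

# Translate an array by an integer voxel offset: out(x) = in(x - n).
shift_volume_int <- function(arr, n, fill = NA_real_) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    lo <- max(1, 1 + n[k]); hi <- min(d[k], d[k] + n[k])
    if (lo > hi) return(out)
    dst[[k]] <- lo:hi
    src[[k]] <- (lo - n[k]):(hi - n[k])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Translate a volume by a (possibly fractional) voxel offset
#'
#' Separable linear interpolation: each axis is shifted by its integer part
#' and then linearly blended for the fractional remainder, which is exact
#' trilinear interpolation for a pure translation. Voxels shifted in from
#' outside the grid take `fill`.
#'
#' @param arr 3-D array (or `volume_image` data).
#' @param shift Numeric triple in voxel units; `out(x) = in(x - shift)`.
#' @param fill Value for voxels with no source (default `NA`).
#' @return Shifted array of the same shape.
#' @export
shift_volume <- function(arr, shift, fill = NA_real_) {
  arr <- vol_data(arr)
  bbb_assert(length(shift) == 3L && all(is.finite(shift)),
             "bbbmap_parameter_error", "shift must be a finite triple")
  for (k in 1:3) {
    s <- shift[k]
    if (s == 0) next
    n <- floor(s); f <- s - n
    off <- c(0, 0, 0)
    off[k] <- n
    lo <- shift_volume_int(arr, off, fill = fill)
    if (f == 0) { arr <- lo; next }
    off[k] <- n + 1
    hi <- shift_volume_int(arr, off, fill = fill)
    arr <- (1 - f) * lo + f * hi
  }
  arr
}

# NCC over the jointly finite voxels of two equally shaped arrays.
ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok)) return(-Inf)
  x <- a[ok]; y <- b[ok]
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  mean((x - mean(x)) * (y - mean(y))) * length(x) / (length(x) - 1) / (sx * sy)
}

# Bilinear in-plane rotation of every slice about the volume center
# (degrees, right-handed about axis 3).  Used only in "rigid" mode.
rotate_volume_z <- function(arr, theta_deg, fill = NA_real_) {
  if (theta_deg == 0) return(arr)
  d <- dim(arr)
  th <- theta_deg * pi / 180
  cen <- (d[1:2] + 1) / 2
  xg <- matrix(seq_len(d[1]) - cen[1], d[1], d[2])
  yg <- matrix(seq_len(d[2]) - cen[2], d[1], d[2], byrow = TRUE)
  # inverse mapping: source coords of each target voxel
  xs <- cos(th) * xg + sin(th) * yg + cen[1]
  ys <- -sin(th) * xg + cos(th) * yg + cen[2]
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 1 & x0 + 1 <= d[1] & y0 >= 1 & y0 + 1 <= d[2]
  out <- array(fill, d)
  for (z in seq_len(d[3])) {
    sl <- arr[, , z]
    v <- rep(fill, length(sl))
    xo <- x0[ok]; yo <- y0[ok]
    v[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * sl[cbind(xo, yo)] +
      fx[ok] * (1 - fy[ok]) * sl[cbind(xo + 1L, yo)] +
      (1 - fx[ok]) * fy[ok] * sl[cbind(xo, yo + 1L)] +
      fx[ok] * fy[ok] * sl[cbind(xo + 1L, yo + 1L)]
    out[, , z] <- v
  }
  out
}

best_integer_shift <- function(mv, fx, window) {
  grid <- expand.grid(x = -window[1]:window[1], y = -window[2]:window[2],
                      z = -window[3]:window[3])
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    t <- as.numeric(grid[i, ])
    ncc(shift_volume_int(mv, -t), fx)
  }, numeric(1))
  i <- which.max(scores)
  list(t = as.numeric(grid[i, ]), score = scores[i],
       on_boundary = any(abs(as.numeric(grid[i, ])) == window & window > 0))
}

#' Rigid registration of one volume onto another
#'
#' Finds the translation (and, in `"rigid"` mode, additionally a small
#' in-plane rotation) maximizing normalized cross-correlation, by exhaustive
#' integer-shift search in a window followed by per-axis subvoxel refinement
#' of the interpolated NCC. The returned translation is the displacement of
#' the moving content relative to the fixed grid; the resampled volume has
#' that displacement undone.
#'
#' @param moving,fixed `volume_image`s (or arrays) on the same grid.
#' @param mode `"translation"` (default) or `"rigid"` (adds an in-plane
#'   rotation grid search).
#' @param window Integer triple: half-width of the integer search window per
#'   axis.
#' @param subvoxel Refine each translation axis to subvoxel precision.
#' @param angle_grid Degrees searched in `"rigid"` mode.
#' @return A list with `transform` (fields `translation`, `rotation`
#'   (degrees about each axis), `score`, `on_boundary`) and `resampled`, the
#'   moving volume resampled onto the fixed grid (background-filled,
#'   `registered = TRUE`).
#' @export
register_rigid <- function(moving, fixed, mode = c("translation", "rigid"),
                           window = c(5L, 5L, 2L), subvoxel = TRUE,
                           angle_grid = seq(-2, 2, by = 0.5)) {
  mode <- match.arg(mode)
  mv <- vol_data(moving); fx <- vol_data(fixed)
  bbb_assert(identical(dim(mv), dim(fx)), "bbbmap_alignment_error",
             "register_rigid: moving and fixed grids differ")
  window <- as.integer(window)

  theta <- 0
  mv_rot <- mv
  if (mode == "rigid") {
    cand <- vapply(angle_grid, function(a) {
      r <- rotate_volume_z(mv, -a)
      best_integer_shift(r, fx, window)$score
    }, numeric(1))
    theta <- angle_grid[which.max(cand)]
    mv_rot <- rotate_volume_z(mv, -theta)
  }

  best <- best_integer_shift(mv_rot, fx, window)
  t_hat <- best$t
  if (best$on_boundary) {
    bbb_log("preprocess", "register_rigid",
            sprintf("optimum on search-window boundary at (%s); widen window",
                    paste(t_hat, collapse = ",")), level = "warn")
  }

  if (subvoxel) {
    # Per-axis parabolic interpolation of the NCC profile through the three
    # integer samples around the optimum.  Fitting integer-shift scores
    # avoids the bias of optimizing interpolation-resampled NCC directly
    # (resampling smooths noise and inflates correlation off-integer).
    t_int <- t_hat
    for (k in 1:3) {
      if (window[k] == 0) next
      cm <- vapply(-1:1, function(dd) {
        t <- t_int; t[k] <- t[k] + dd
        ncc(shift_volume_int(mv_rot, -t), fx)
      }, numeric(1))
      den <- cm[1] - 2 * cm[2] + cm[3]
      if (is.finite(den) && den < 0) {
        delta <- 0.5 * (cm[1] - cm[3]) / den
        t_hat[k] <- t_int[k] + min(0.5, max(-0.5, delta))
      }
    }
    best$score <- ncc(shift_volume(mv_rot, -t_hat), fx)
  }

  res <- shift_volume(mv_rot, -t_hat, fill = 0)
  resampled <- if (inherits(moving, "volume_image")) {
    volume_image(res, moving$spacing, moving$modality, moving$subject_id,
                 moving$day, registered = TRUE)
  } else res
  list(transform = list(translation = t_hat, rotation = c(0, 0, theta),
                        score = best$score, on_boundary = best$on_boundary),
       resampled = resampled)
}
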