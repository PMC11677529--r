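#' Construct a volume image
#'
#' The single in-memory representation used throughout the pipeline: a 3-D
#' grid of finite intensities with voxel spacing (mm per axis) and a modality
#' role. Axis convention is fixed package-wide: axis 1 is left-right (the
#' mid-sagittal plane is the central plane along this axis), axis 2
#' anterior-posterior, axis 3 the slice (through-plane) direction. The 3x3
#' "environmental" neighborhood of the detector lives in the axis-1/axis-2
#' plane.
#'
#' @param data 3-D numeric array of finite values.
#' @param spacing Numeric triple, mm per axis.
#' @param modality One of `"T2w"`, `"T1w_pre"`, `"T1w_post"`, or `"mask"`.
#' @param subject_id,day Optional labels carried through to result tables.
#' @param registered Logical; `TRUE` marks a volume that has been resampled
#'   onto its within-session reference grid (set by [register_rigid()]).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), modality = "T2w",
                         subject_id = "subj", day = NA, registered = FALSE) {
  bbb_assert(is.array(data) && length(dim(data)) == 3L, "bbbmap_data_error",
             "volume_image: data must be a 3-D array")
  bbb_assert(all(is.finite(data)), "bbbmap_data_error",
             "volume_image: non-finite voxel values")
  bbb_assert(length(spacing) == 3L && all(spacing > 0), "bbbmap_data_error",
             "volume_image: spacing must be a positive triple")
  modality <- match.arg(modality, c("T2w", "T1w_pre", "T1w_post", "mask"))
  structure(list(data = data, spacing = as.numeric(spacing),
                 modality = modality, subject_id = subject_id, day = day,
                 registered = isTRUE(registered)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s  %s  grid %s  spacing %s mm%s\n",
              x$subject_id, x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              if (x$registered) "  [registered]" else ""))
  invisible(x)
}

# Coerce to a plain array (accepts volume_image or array).
vol_data <- function(x) {
  if (inherits(x, "volume_image")) x$data else x
}

# Validate a binary mask argument: logical or strictly {0,1} values, same
# shape as the reference grid.  Returns a logical array.
as_mask <- function(mask, dim_ref = NULL, what = "mask") {
  m <- vol_data(mask)
  bbb_assert(is.array(m) && length(dim(m)) == 3L, "bbbmap_data_error",
             "%s must be a 3-D array", what)
  if (!is.null(dim_ref)) {
    bbb_assert(identical(dim(m), as.integer(dim_ref)), "bbbmap_alignment_error",
               "%s shape (%s) does not match volume shape (%s)", what,
               paste(dim(m), collapse = "x"), paste(dim_ref, collapse = "x"))
  }
  if (!is.logical(m)) {
    u <- unique(as.vector(m))
    bbb_assert(all(u %in% c(0, 1)), "bbbmap_data_error",
               "%s contains values other than {0,1}; refusing to threshold",
               what)
    m <- array(m == 1, dim = dim(m))
  }
  m
}
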