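# NIfTI volume/mask I/O (RNifti), scan-set loading with role mapping, and
# YAML configuration reading.  One internal representation (volume_image /
# logical mask arrays) for all downstream modules; masks on disk are uint8
# {0,1} and any other value is an error, never thresholded.

#' Write a volume to NIfTI
#'
#' @param vol A `volume_image` (or 3-D array with `spacing`).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing when `vol` is a bare array.
#' @param datatype Storage datatype (`"double"` for scans, `"uint8"` for
#'   masks).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing = NULL, datatype = "double") {
  dat <- vol_data(vol)
  if (is.logical(dat)) dat <- array(as.integer(dat), dim(dat))
  sp <- spacing %||% (if (inherits(vol, "volume_image")) vol$spacing else c(1, 1, 1))
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' Volumes are checked for finiteness on load; masks additionally for strict
#' {0,1} coding.
#'
#' @param path NIfTI file.
#' @param modality `"T2w"`, `"T1w_pre"`, `"T1w_post"` or `"mask"`.
#' @param subject_id,day Labels attached to the result.
#' @return A `volume_image` (for scans) or a logical array (for masks).
#' @export
read_volume <- function(path, modality = "T2w", subject_id = "subj", day = NA) {
  bbb_assert(file.exists(path), "bbbmap_data_error", "no such file: %s", path)
  img <- RNifti::readNifti(path)
  dat <- array(as.vector(as.array(img)), dim = dim(img))  # strip image attrs
  bbb_assert(length(dim(dat)) == 3L, "bbbmap_data_error",
             "%s: expected a 3-D volume, got %d-D", path, length(dim(dat)))
  bbb_assert(all(is.finite(dat)), "bbbmap_data_error",
             "%s: non-finite voxels after load", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (modality == "mask") return(as_mask(array(dat, dim(dat)), what = path))
  volume_image(dat, sp, modality, subject_id, day)
}

#' Load a subject scan set from files
#'
#' @param paths Named character vector/list of file paths.
#' @param roles Named character vector mapping each name in `paths` to one
#'   of `t2w`, `t1_pre`, `t1_post`, `brain_mask`, `contralateral_mask`,
#'   `muscle_mask`. Defaults to using the names of `paths` directly.
#' @param subject_id,day Labels for the loaded volumes.
#' @return A `subject_scan_set`; all present volumes are shape- and
#'   spacing-checked against each other.
#' @export
load_scan_set <- function(paths, roles = NULL, subject_id = "subj", day = NA) {
  paths <- unlist(paths)
  roles <- roles %||% stats::setNames(names(paths), names(paths))
  slots <- c("t2w", "t1_pre", "t1_post", "brain_mask", "contralateral_mask",
             "muscle_mask")
  bad <- setdiff(unname(roles), slots)
  bbb_assert(length(bad) == 0, "bbbmap_config_error",
             "unknown scan-set role(s): %s", paste(bad, collapse = ", "))
  modal <- c(t2w = "T2w", t1_pre = "T1w_pre", t1_post = "T1w_post")
  out <- stats::setNames(vector("list", length(slots)), slots)
  for (nm in names(paths)) {
    role <- roles[[nm]]
    out[[role]] <- if (role %in% names(modal)) {
      read_volume(paths[[nm]], modal[[role]], subject_id, day)
    } else {
      read_volume(paths[[nm]], "mask")
    }
  }
  dims <- lapply(Filter(Negate(is.null), out), function(v) dim(vol_data(v)))
  bbb_assert(length(unique(dims)) == 1, "bbbmap_alignment_error",
             "scan-set volumes differ in grid shape")
  structure(out, class = "subject_scan_set")
}

#' Write a detection map as a uint8 NIfTI overlay
#'
#' @param map A `detection_map` or binary array, same shape as
#'   `reference_volume`.
#' @param reference_volume `volume_image` providing the grid and spacing.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detection_map <- function(map, reference_volume, path) {
  m <- if (inherits(map, "detection_map")) map$map else map
  ref <- vol_data(reference_volume)
  bbb_assert(identical(dim(m), dim(ref)), "bbbmap_alignment_error",
             "map shape does not match reference volume")
  write_volume(array(as.integer(as.logical(m)), dim(m)), path,
               spacing = if (inherits(reference_volume, "volume_image"))
                 reference_volume$spacing else c(1, 1, 1),
               datatype = "uint8")
}

#' Read a detection map written by [write_detection_map()]
#'
#' @param path NIfTI file.
#' @return Logical array.
#' @export
read_detection_map <- function(path) {
  read_volume(path, modality = "mask")
}

#' Write a phantom scan set, truth masks and parameters to a directory
#'
#' Scans as float NIfTI, masks as uint8 NIfTI, truth summary as JSON,
#' parameters as YAML.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- phantom$scans; tr <- phantom$truth
  write_volume(s$t2w, file.path(dir, "t2w.nii.gz"))
  write_volume(s$t1_pre, file.path(dir, "t1_pre.nii.gz"))
  write_volume(s$t1_post, file.path(dir, "t1_post.nii.gz"))
  sp <- s$t2w$spacing
  for (nm in c("brain_mask", "lesion_mask", "leakage_mask", "muscle_mask",
               "contralateral_mask")) {
    write_volume(tr[[nm]], file.path(dir, paste0(nm, ".nii.gz")),
                 spacing = sp, datatype = "uint8")
  }
  jsonlite::write_json(
    list(true_t2w_fraction = tr$true_t2w_fraction,
         true_bbbd_fraction = tr$true_bbbd_fraction,
         applied_shift = tr$applied_shift),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  pars <- unclass(tr$params)
  yaml::write_yaml(pars, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Load a phantom directory as a scan set
#'
#' Round-trips the output of [write_phantom()].
#'
#' @param dir Directory written by [write_phantom()].
#' @param subject_id,day Labels.
#' @return A `subject_scan_set` (contralateral/muscle masks included).
#' @export
load_phantom_scan_set <- function(dir, subject_id = "subj", day = NA) {
  paths <- c(t2w = file.path(dir, "t2w.nii.gz"),
             t1_pre = file.path(dir, "t1_pre.nii.gz"),
             t1_post = file.path(dir, "t1_post.nii.gz"),
             brain_mask = file.path(dir, "brain_mask.nii.gz"),
             contralateral_mask = file.path(dir, "contralateral_mask.nii.gz"),
             muscle_mask = file.path(dir, "muscle_mask.nii.gz"))
  load_scan_set(paths, subject_id = subject_id, day = day)
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  bbb_assert(file.exists(path), "bbbmap_config_error", "no such config: %s",
             path)
  yaml::read_yaml(path)
}
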