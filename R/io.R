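# NIfTI-1 and TSV input/output.  Images travel as NIfTI via RNifti; frame
# timing, label tables and read-out tables are TSV with a one-line header.

timing_sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), "_frames.tsv")
}

labels_sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), "_labels.tsv")
}

#' Write a dynamic image as NIfTI plus a frame-timing sidecar
#'
#' The image is written as 4-D NIfTI-1; the schedule goes to a TSV sidecar
#' (`<stem>_frames.tsv`, columns `frame_start_min`, `frame_end_min`).
#'
#' @param img A [dynamic_image()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_dynamic_image <- function(img, path) {
  stopifnot(inherits(img, "dynamic_image"))
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- c(rep(img$voxel_mm, 3), 1)
  RNifti::writeNifti(nii, path)
  utils::write.table(
    data.frame(frame_start_min = img$schedule$starts,
               frame_end_min = img$schedule$ends),
    timing_sidecar_path(path),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dynamic image written by [write_dynamic_image()]
#'
#' @param path Path to a 4-D NIfTI file with a `<stem>_frames.tsv` sidecar.
#' @return A [dynamic_image()]; the round trip preserves voxel values and
#'   timing exactly.
#' @export
read_dynamic_image <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- array(as.numeric(nii), dim = dim(nii))
  if (length(dim(arr)) == 3L) arr <- array(arr, dim = c(dim(arr), 1L))
  timing <- utils::read.table(timing_sidecar_path(path), header = TRUE,
                              sep = "\t")
  if (nrow(timing) != dim(arr)[4]) {
    stop(sprintf(
      "timing table has %d rows but image has %d frames", nrow(timing),
      dim(arr)[4]))
  }
  sched <- frame_schedule(timing$frame_start_min, timing$frame_end_min)
  voxel_mm <- RNifti::pixdim(nii)[1]
  dynamic_image(arr, voxel_mm = voxel_mm, schedule = sched)
}

#' Write an atlas label image plus its label table
#' @param atlas An [atlas_labels()] object.
#' @param path Output path ending in `.nii` or `.nii.gz`; the label table
#'   goes to `<stem>_labels.tsv`.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas_labels"))
  nii <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(nii) <- rep(atlas$voxel_mm, 3)
  RNifti::writeNifti(nii, path, datatype = "int16")
  utils::write.table(atlas$table, labels_sidecar_path(path),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an atlas written by [write_atlas()]
#' @param path Path to the label NIfTI.
#' @return An [atlas_labels()] object.
#' @export
read_atlas <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- array(as.integer(nii), dim = dim(nii))
  tab <- utils::read.table(labels_sidecar_path(path), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  atlas_labels(arr, tab, voxel_mm = RNifti::pixdim(nii)[1])
}

#' Write a 3-D parametric map (DVR map, z map) as NIfTI
#' @param map 3-D numeric array; `NA` marks invalid voxels.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, voxel_mm, path) {
  nii <- RNifti::asNifti(map)
  RNifti::pixdim(nii) <- rep(voxel_mm, 3)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a 3-D parametric map
#' @param path Path to a 3-D NIfTI file.
#' @return Numeric 3-D array.
#' @export
read_map <- function(path) {
  nii <- RNifti::readNifti(path)
  array(as.numeric(nii), dim = dim(nii))
}

#' Write / read a table as tab-separated values
#'
#' TSV with a one-line header, no quoting, no row names.
#'
#' @param x A `data.frame`.
#' @param path File path.
#' @return `path` (write) or a `data.frame` (read).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a YAML pipeline configuration
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Cluster volume from voxel count
#'
#' @param n_voxels Non-negative voxel count.
#' @param voxel_size_mm Positive isotropic voxel edge length in mm.
#' @return Volume in mm^3: `n_voxels * voxel_size_mm^3`.  Twenty voxels on
#'   the 2 mm analysis grid give 160 mm^3.
#' @export
cluster_volume_mm3 <- function(n_voxels, voxel_size_mm) {
  if (any(n_voxels < 0)) stop("'n_voxels' must be non-negative")
  if (any(voxel_size_mm <= 0)) stop("'voxel_size_mm' must be positive")
  n_voxels * voxel_size_mm^3
}
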