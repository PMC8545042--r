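#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule holds the start and end time (minutes post injection) of
#' every frame of a dynamic scan.  Frames must be contiguous and strictly
#' increasing: `ends[i] == starts[i + 1]` and `ends[i] > starts[i]`.
#'
#' @param starts Numeric vector of frame start times in minutes.
#' @param ends Numeric vector of frame end times in minutes.
#' @return An object of class `frame_schedule`.
#' @seealso [default_frame_schedule()] for the 23-frame 0-60 min schedule.
#' @export
frame_schedule <- function(starts, ends) {
  starts <- as.numeric(starts)
  ends <- as.numeric(ends)
  if (length(starts) == 0L) stop("frame schedule must contain at least one frame")
  if (length(starts) != length(ends)) {
    stop("'starts' and 'ends' must have the same length")
  }
  if (any(!is.finite(starts)) || any(!is.finite(ends))) {
    stop("frame times must be finite")
  }
  if (any(ends <= starts)) stop("every frame must have end > start")
  n <- length(starts)
  if (n > 1L && any(abs(ends[-n] - starts[-1L]) > 1e-9)) {
    stop("frames must be contiguous: ends[i] must equal starts[i + 1]")
  }
  structure(list(starts = starts, ends = ends), class = "frame_schedule")
}

#' Default 0-60 min dynamic frame schedule
#'
#' Six frames of 30 s, four of 60 s, four of 120 s and nine of 300 s:
#' 23 frames spanning 0-60 minutes post injection.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  durations <- c(rep(0.5, 6), rep(1, 4), rep(2, 4), rep(5, 9))
  ends <- cumsum(durations)
  frame_schedule(starts = c(0, ends[-length(ends)]), ends = ends)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule: %d frames, %.3g-%.3g min>\n",
              n_frames(x), x$starts[1], x$ends[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule A [frame_schedule()].
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  length(schedule$starts)
}

#' Frame midpoints
#'
#' @param schedule A [frame_schedule()].
#' @return Numeric vector `(starts + ends) / 2`, minutes.
#' @export
midpoints <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  (schedule$starts + schedule$ends) / 2
}

#' Frame durations
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of durations in minutes.
#' @export
frame_durations <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$ends - schedule$starts
}

#' Time-activity curve
#'
#' One decay-corrected activity concentration value (kBq/ml) per frame of a
#' schedule.  A fine-grid version of the same curve (as produced by the
#' simulator) may ride along as the `fine` attribute, a list with elements
#' `time` and `values`; model fitting uses it when present instead of
#' interpolating the frame values.
#'
#' @param schedule A [frame_schedule()].
#' @param values Numeric vector, one non-negative finite value per frame.
#' @param label Optional region identifier.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, label = NA_character_) {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != n_frames(schedule)) {
    stop(sprintf("expected %d values (one per frame), got %d",
                 n_frames(schedule), length(values)))
  }
  if (any(!is.finite(values))) stop("TAC values must be finite")
  if (any(values < -1e-9)) stop("TAC values must be non-negative")
  structure(list(schedule = schedule, values = pmax(values, 0),
                 label = as.character(label)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac '%s': %d frames, peak %.3g kBq/ml>\n",
              x$label, n_frames(x$schedule), max(x$values)))
  invisible(x)
}

same_schedule <- function(a, b, tol = 1e-9) {
  n_frames(a) == n_frames(b) &&
    all(abs(a$starts - b$starts) < tol) &&
    all(abs(a$ends - b$ends) < tol)
}

#' 4-D dynamic image
#'
#' A voxel grid with one 3-D volume per frame, plus its frame schedule.
#'
#' @param data 4-D numeric array, last dimension indexing frames.
#' @param voxel_mm Isotropic voxel size in mm (strictly positive).
#' @param schedule A [frame_schedule()]; frame count must match `dim(data)[4]`.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, voxel_mm, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(dim(data)) != 4L) stop("'data' must be a 4-D array")
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1L || voxel_mm <= 0) {
    stop("'voxel_mm' must be a single positive number")
  }
  if (dim(data)[4] != n_frames(schedule)) {
    stop(sprintf("image has %d volumes but schedule has %d frames",
                 dim(data)[4], n_frames(schedule)))
  }
  structure(list(data = data, voxel_mm = voxel_mm, schedule = schedule),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image: %dx%dx%d voxels @ %g mm, %d frames>\n",
              d[1], d[2], d[3], x$voxel_mm, d[4]))
  invisible(x)
}

#' Atlas label image
#'
#' Integer label volume plus a table mapping labels to region names.  The
#' reference region (used to extract the reference time-activity curve) is
#' marked in the table and must be disjoint from all target regions.
#'
#' @param labels 3-D integer array; 0 is background.
#' @param table `data.frame` with columns `label` (integer), `region`
#'   (character), `class` (`"cortical"`, `"subcortical"` or `"reference"`).
#' @param voxel_mm Isotropic voxel size in mm.
#' @return An object of class `atlas_labels`.
#' @export
atlas_labels <- function(labels, table, voxel_mm = 2) {
  if (length(dim(labels)) != 3L) stop("'labels' must be a 3-D array")
  stopifnot(is.data.frame(table),
            all(c("label", "region", "class") %in% names(table)))
  if (voxel_mm <= 0) stop("'voxel_mm' must be positive")
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, table$label)
  if (length(missing) > 0L) {
    stop("labels present in image but absent from table: ",
         paste(missing, collapse = ", "))
  }
  ref <- table$label[table$class == "reference"]
  if (length(ref) != 1L) stop("exactly one reference region is required")
  structure(list(labels = labels, table = table, voxel_mm = voxel_mm),
            class = "atlas_labels")
}

#' @export
print.atlas_labels <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<atlas_labels: %dx%dx%d @ %g mm, %d regions>\n",
              d[1], d[2], d[3], x$voxel_mm, nrow(x$table)))
  invisible(x)
}

#' Region names of the atlas target regions
#' @param atlas An [atlas_labels()] object.
#' @param classes Region classes to include.
#' @return Character vector of region names.
#' @export
target_regions <- function(atlas, classes = c("cortical", "subcortical")) {
  atlas$table$region[atlas$table$class %in% classes]
}

atlas_label_of <- function(atlas, region) {
  i <- match(region, atlas$table$region)
  if (is.na(i)) stop("unknown atlas region: ", region)
  atlas$table$label[i]
}

#' Mean time-activity curve over a voxel mask
#'
#' @param img A [dynamic_image()].
#' @param mask Logical 3-D array (same grid) or integer vector of voxel
#'   indices into the 3-D grid.
#' @param label Region identifier stored on the returned curve.
#' @return A [tac()]: the spatial mean per frame.
#' @export
mask_tac <- function(img, mask, label = NA_character_) {
  stopifnot(inherits(img, "dynamic_image"))
  d <- dim(img$data)
  if (is.logical(mask)) {
    if (!identical(dim(mask), d[1:3])) stop("mask grid does not match image")
    idx <- which(mask)
  } else {
    idx <- as.integer(mask)
  }
  if (length(idx) == 0L) stop("empty voxel mask")
  nvox <- prod(d[1:3])
  mat <- matrix(img$data, nrow = nvox, ncol = d[4])
  tac(img$schedule, colMeans(mat[idx, , drop = FALSE]), label = label)
}
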