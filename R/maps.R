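# Normative healthy-control DVR maps, patient z-score maps, and extraction
# of tracer-positive clusters within atlas target regions.

#' Voxelwise normative maps from healthy-control DVR maps
#'
#' @param dvr_maps List of >= 2 3-D DVR arrays on one grid (`NA` marks
#'   invalid voxels, which are ignored voxelwise).
#' @param sd_denominator `"sample"` (n - 1, default) or `"population"` (n).
#' @return A list of class `normative_maps`: `mean` and `sd` 3-D arrays
#'   (`NA` where fewer than two controls contribute) and `n_controls`.
#' @export
build_normative <- function(dvr_maps, sd_denominator = c("sample",
                                                         "population")) {
  sd_denominator <- match.arg(sd_denominator)
  if (length(dvr_maps) < 2L) stop("need at least 2 control maps")
  d <- dim(dvr_maps[[1]])
  if (any(!vapply(dvr_maps, function(m) identical(dim(m), d), logical(1)))) {
    stop("control maps must share one grid")
  }
  M <- vapply(dvr_maps, as.numeric, numeric(prod(d)))
  n_ok <- rowSums(!is.na(M))
  mu <- rowMeans(M, na.rm = TRUE)
  ss <- rowSums((M - mu)^2, na.rm = TRUE)
  denom <- if (sd_denominator == "sample") pmax(n_ok - 1, 1) else n_ok
  sdv <- sqrt(ss / denom)
  bad <- n_ok < 2L
  mu[bad] <- NA_real_
  sdv[bad] <- NA_real_
  structure(list(mean = array(mu, d), sd = array(sdv, d),
                 n_controls = length(dvr_maps)),
            class = "normative_maps")
}

#' Patient z-score map
#'
#' `z = (patient DVR - control mean DVR) / control DVR SD`, voxelwise.
#' Voxels with zero or missing control SD carry `NA`.
#'
#' @param patient_dvr 3-D DVR array.
#' @param norm A [build_normative()] result on the same grid.
#' @return 3-D z-score array.
#' @export
zscore_map <- function(patient_dvr, norm) {
  stopifnot(inherits(norm, "normative_maps"))
  if (!identical(dim(patient_dvr), dim(norm$mean))) {
    stop("patient map grid does not match the normative maps")
  }
  z <- (patient_dvr - norm$mean) / norm$sd
  z[!is.finite(z) | norm$sd == 0] <- NA_real_
  z
}

neighbour_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6" = g[rowSums(abs(g)) == 1, , drop = FALSE],
         "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26"))
}

# connected components of a voxel index set; returns a list of integer
# vectors of linear indices (breadth-first search over coordinate-checked
# neighbours, so components never wrap across grid edges)
label_components <- function(idx, dim3, connectivity = 26) {
  if (length(idx) == 0L) return(list())
  offs <- neighbour_offsets(connectivity)
  in_mask <- logical(prod(dim3))
  in_mask[idx] <- TRUE
  visited <- logical(prod(dim3))
  comps <- list()
  for (seed in idx) {
    if (visited[seed]) next
    comp <- integer(0)
    wave <- seed
    visited[seed] <- TRUE
    while (length(wave) > 0L) {
      comp <- c(comp, wave)
      co <- arrayInd(wave, dim3)
      n <- nrow(co)
      k <- nrow(offs)
      nb <- co[rep(seq_len(n), each = k), , drop = FALSE] +
        offs[rep(seq_len(k), n), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
        nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
        nb[, 3] >= 1 & nb[, 3] <= dim3[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * dim3[1] +
                      (nb[, 3] - 1L) * dim3[1] * dim3[2])
      lin <- lin[in_mask[lin] & !visited[lin]]
      visited[lin] <- TRUE
      wave <- lin
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Extract tracer-positive clusters from a z-score map
#'
#' Within each atlas target region independently, voxels with `z >=
#' threshold` are binarised, connected components are labelled
#' (26-neighbour by default) and components whose voxel count strictly
#' exceeds `min_voxels` are kept ("exceeding 20 voxels" read as > 20).
#' Clusters from different regions never merge, even when adjacent.
#'
#' @param z 3-D z-score array.
#' @param atlas An [atlas_labels()] object on the same grid.
#' @param threshold z threshold (default 2.5 SD).
#' @param min_voxels Strict lower bound on cluster voxel count (default 20;
#'   a 20-voxel component is rejected).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param regions Region names to search; default all cortical and
#'   subcortical target regions.  Unknown names are an error.
#' @param subject Optional subject id recorded on each cluster.
#' @return A list of `cluster` objects (fields `region`, `class`, `side`,
#'   `voxels`, `n_voxels`, `volume_mm3`, `peak_z`, `subject`), ordered by
#'   region then size descending.
#' @export
extract_clusters <- function(z, atlas, threshold = 2.5, min_voxels = 20,
                             connectivity = 26, regions = NULL,
                             subject = NA_character_) {
  stopifnot(inherits(atlas, "atlas_labels"))
  if (!identical(dim(z), dim(atlas$labels))) {
    stop("z map grid does not match the atlas")
  }
  if (is.null(regions)) regions <- target_regions(atlas)
  dim3 <- dim(z)
  out <- list()
  for (region in regions) {
    lab <- atlas_label_of(atlas, region)
    cls <- atlas$table$class[atlas$table$label == lab]
    idx <- which(atlas$labels == lab & !is.na(z) & z >= threshold)
    comps <- label_components(idx, dim3, connectivity)
    comps <- comps[vapply(comps, length, integer(1)) > min_voxels]
    if (length(comps) == 0L) next
    comps <- comps[order(vapply(comps, length, integer(1)),
                         decreasing = TRUE)]
    for (voxels in comps) {
      out[[length(out) + 1L]] <- structure(
        list(region = region, class = cls,
             side = if (grepl("_l$", region)) "L" else
               if (grepl("_r$", region)) "R" else NA_character_,
             voxels = voxels, n_voxels = length(voxels),
             volume_mm3 = cluster_volume_mm3(length(voxels),
                                             atlas$voxel_mm),
             peak_z = max(z[voxels]), subject = subject),
        class = "cluster")
    }
  }
  out
}

#' Summarise a cluster list as a data frame
#' @param clusters List of clusters from [extract_clusters()].
#' @return `data.frame`, one row per cluster (voxel lists dropped).
#' @export
clusters_table <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(subject = character(), region = character(),
                      class = character(), side = character(),
                      n_voxels = integer(), volume_mm3 = numeric(),
                      peak_z = numeric()))
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(subject = cl$subject, region = cl$region, class = cl$class,
               side = cl$side, n_voxels = cl$n_voxels,
               volume_mm3 = cl$volume_mm3, peak_z = cl$peak_z,
               stringsAsFactors = FALSE)
  }))
}

#' Dice overlap between two voxel index sets
#' @param a,b Integer voxel index vectors.
#' @return `2 |a & b| / (|a| + |b|)`.
#' @export
dice_overlap <- function(a, b) {
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
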