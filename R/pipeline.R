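# End-to-end cohort pipeline: subject-level parametric mapping, normative
# maps from the control group, z-score cluster extraction, cluster
# read-outs and the discrimination report.  Subjects are processed one at
# a time so a full 50-subject cohort never holds more than one dynamic
# image in memory.

reference_mask <- function(atlas) {
  lab <- atlas$table$label[atlas$table$class == "reference"]
  which(atlas$labels == lab)
}

#' Region-level binding read-outs from whole atlas regions
#'
#' The healthy-control read-out mode: kinetics, SUVR and slopes computed
#' from whole atlas target regions rather than clusters.
#'
#' @param img A [dynamic_image()].
#' @param atlas An [atlas_labels()] object.
#' @param ref Reference [tac()]; default the mean over the atlas reference
#'   region.
#' @param consts [global_kinetic_constants()]; default estimated from
#'   first-pass SRTM fits of the target regions.
#' @param subject Subject id recorded on the rows.
#' @return Read-out `data.frame`, one row per target region.
#' @export
region_readouts <- function(img, atlas, ref = NULL, consts = NULL,
                            subject = NA_character_) {
  if (is.null(ref)) ref <- mask_tac(img, reference_mask(atlas),
                                    label = "reference")
  regions <- target_regions(atlas)
  if (is.null(consts)) {
    fits <- lapply(regions, function(r) {
      fit_srtm(mask_tac(img, atlas$labels == atlas_label_of(atlas, r)), ref)
    })
    consts <- estimate_k2prime(fits)
  }
  rows <- lapply(regions, function(r) {
    lab <- atlas_label_of(atlas, r)
    cls <- atlas$table$class[atlas$table$label == lab]
    fake <- structure(list(region = r, class = cls,
                           side = if (grepl("_l$", r)) "L" else "R",
                           voxels = which(atlas$labels == lab),
                           n_voxels = sum(atlas$labels == lab),
                           volume_mm3 = cluster_volume_mm3(
                             sum(atlas$labels == lab), atlas$voxel_mm),
                           peak_z = NA_real_, subject = subject),
                      class = "cluster")
    cluster_readouts(img, fake, ref, consts)
  })
  do.call(rbind, rows)
}

#' Subject-level parametric mapping
#'
#' Measures the reference curve from the image, fixes the subject's
#' k2prime from first-pass SRTM fits of all atlas target regions, and
#' computes the voxelwise MRTM2 DVR map over the tissue mask.
#'
#' @param img A [dynamic_image()].
#' @param atlas An [atlas_labels()] object.
#' @param tstar Equilibration time for the multilinear fits, minutes.
#' @return A list with `dvr` (3-D array), `consts`, `ref` and
#'   `region_fits` (first-pass SRTM fits, named by region).
#' @export
subject_dvr_map <- function(img, atlas, tstar = 0) {
  ref <- mask_tac(img, reference_mask(atlas), label = "reference")
  regions <- target_regions(atlas)
  fits <- lapply(regions, function(r) {
    fit_srtm(mask_tac(img, atlas$labels == atlas_label_of(atlas, r),
                      label = r), ref)
  })
  names(fits) <- regions
  consts <- estimate_k2prime(fits, tstar = tstar)
  dvr <- dvr_map(img, reference_mask(atlas), consts,
                 mask = atlas$labels > 0)
  list(dvr = dvr, consts = consts, ref = ref, region_fits = fits)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates the cohort subject by subject (controls first), builds the
#' normative DVR maps from the controls, then for every patient computes
#' the z-score map, extracts tracer-positive clusters, evaluates all
#' cluster read-outs and records lesion recovery (Dice overlap of each
#' painted lesion with the best matching extracted cluster in its region).
#'
#' @param spec A [cohort_spec()].
#' @param atlas An [atlas_labels()] phantom.
#' @param seed Master seed.
#' @param threshold z threshold for cluster extraction.
#' @param min_voxels Strict voxel-count bound for clusters.
#' @param tstar Equilibration time, minutes.
#' @param hc_readouts Also compute whole-region read-outs for controls.
#' @return A list of class `cohort_results`: `readouts` (cluster read-out
#'   table with `group` column), `clusters` (summary table), `recovery`
#'   (per painted lesion), `hc_readouts`, `norm` (normative maps),
#'   `manifest`, `truth` (per-lesion ground truth table).
#' @export
run_cohort_pipeline <- function(spec, atlas = phantom_atlas(), seed = 1,
                                threshold = 2.5, min_voxels = 20,
                                tstar = 0, hc_readouts = TRUE) {
  manifest <- cohort_manifest(spec, seed)
  manifest <- manifest[order(manifest$group != "HC"), , drop = FALSE]
  hc_rows <- manifest[manifest$group == "HC", , drop = FALSE]
  pt_rows <- manifest[manifest$group != "HC", , drop = FALSE]
  if (nrow(hc_rows) < 2L) stop("the cohort needs at least 2 controls")

  hc_maps <- vector("list", nrow(hc_rows))
  hc_tab <- list()
  for (i in seq_len(nrow(hc_rows))) {
    sub <- simulate_subject(atlas, spec, "HC", seed = hc_rows$seed[i])
    m <- subject_dvr_map(sub$image, atlas, tstar = tstar)
    hc_maps[[i]] <- m$dvr
    if (hc_readouts) {
      hc_tab[[i]] <- region_readouts(sub$image, atlas, ref = m$ref,
                                     consts = m$consts,
                                     subject = hc_rows$subject[i])
    }
  }
  norm <- build_normative(hc_maps)

  readouts <- list()
  cl_tabs <- list()
  recovery <- list()
  truth_tabs <- list()
  for (i in seq_len(nrow(pt_rows))) {
    id <- pt_rows$subject[i]
    sub <- simulate_subject(atlas, spec, pt_rows$group[i],
                            seed = pt_rows$seed[i])
    m <- subject_dvr_map(sub$image, atlas, tstar = tstar)
    z <- zscore_map(m$dvr, norm)
    clusters <- extract_clusters(z, atlas, threshold = threshold,
                                 min_voxels = min_voxels, subject = id)
    if (length(clusters) > 0L) {
      tab <- readout_table(sub$image, clusters, m$ref, m$consts)
      tab$group <- pt_rows$group[i]
      readouts[[id]] <- tab
      cl_tabs[[id]] <- clusters_table(clusters)
    }
    if (nrow(sub$lesions) > 0L) {
      rec <- sub$lesions
      rec$subject <- id
      rec$group <- pt_rows$group[i]
      rec$frac_supra <- vapply(seq_len(nrow(rec)), function(k) {
        zl <- z[sub$lesion_voxels[[k]]]
        mean(!is.na(zl) & zl >= threshold)
      }, numeric(1))
      rec$dice <- vapply(seq_len(nrow(rec)), function(k) {
        same <- clusters[vapply(clusters, function(cl)
          cl$region == rec$region[k], logical(1))]
        if (length(same) == 0L) return(0)
        max(vapply(same, function(cl)
          dice_overlap(sub$lesion_voxels[[k]], cl$voxels), numeric(1)))
      }, numeric(1))
      recovery[[id]] <- rec
      truth_tabs[[id]] <- rec
    }
  }
  rbind_or_empty <- function(lst) {
    if (length(lst) == 0L) data.frame() else do.call(rbind, lst)
  }
  structure(list(readouts = rbind_or_empty(readouts),
                 clusters = rbind_or_empty(cl_tabs),
                 recovery = rbind_or_empty(recovery),
                 hc_readouts = rbind_or_empty(hc_tab),
                 norm = norm, manifest = manifest,
                 spec = spec, threshold = threshold,
                 min_voxels = min_voxels),
            class = "cohort_results")
}

#' Discrimination report for a cohort pipeline result
#'
#' Cortical clusters only enter the ROC/PCA analysis (the subcortical
#' binding profile does not separate the groups); the statistical unit is
#' the cluster.
#'
#' @param results A [run_cohort_pipeline()] result.
#' @param classes Cluster classes to include (default `"cortical"`).
#' @param ... Passed to [discrimination_report()].
#' @return A [discrimination_report()].
#' @export
cohort_discrimination <- function(results, classes = "cortical", ...) {
  stopifnot(inherits(results, "cohort_results"))
  tab <- results$readouts
  tab <- tab[tab$class %in% classes, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no clusters in the requested classes")
  discrimination_report(tab, tab$group, ...)
}
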