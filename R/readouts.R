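# Per-cluster binding read-outs: kinetic parameters from all three models,
# SUVR over the 30-60 min window, and the post-perfusion slope family.

#' Mean TAC over a cluster's voxels
#' @param img A [dynamic_image()].
#' @param cluster A cluster from [extract_clusters()].
#' @return A [tac()] (spatial mean per frame).
#' @export
cluster_tac <- function(img, cluster) {
  stopifnot(inherits(cluster, "cluster"))
  if (cluster$n_voxels == 0L) stop("empty cluster")
  mask_tac(img, cluster$voxels, label = cluster$region)
}

#' Late-window standardised uptake value ratio (SUVR 30-60 min)
#'
#' Duration-weighted mean of the target over frames fully inside the
#' 30-60 min window (frame start >= 30 and end <= 60), divided by the same
#' for the reference.
#'
#' @param target,ref Target and reference [tac()] on one schedule.
#' @return Unitless SUVR.
#' @export
suvr_30_60 <- function(target, ref) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  if (!same_schedule(target$schedule, ref$schedule)) {
    stop("target and reference must share one frame schedule")
  }
  s <- target$schedule
  sel <- s$starts >= 30 - 1e-9 & s$ends <= 60 + 1e-9
  if (!any(sel)) stop("schedule has no frames inside the 30-60 min window")
  w <- frame_durations(s)[sel]
  sum(w * target$values[sel]) / sum(w * ref$values[sel])
}

#' Frame-by-frame SUVR curve
#' @param target,ref Target and reference [tac()] on one schedule.
#' @return Numeric vector, elementwise `target / ref` per frame.
#' @export
suvr_curve <- function(target, ref) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  if (!same_schedule(target$schedule, ref$schedule)) {
    stop("target and reference must share one frame schedule")
  }
  if (any(ref$values == 0)) stop("reference TAC has zero-valued frames")
  target$values / ref$values
}

#' Post-perfusion SUVR slope family
#'
#' Ordinary least-squares slope of SUVR against frame midpoint over every
#' interval `[i, end]` minutes; frame membership is by midpoint.  The
#' default starts follow the post-perfusion phase: 9, 11, 13, 15, 20, 25,
#' 30, 35, 40, 45 min, all ending at 60 min.
#'
#' @param suvr Per-frame SUVR values (see [suvr_curve()]).
#' @param schedule The [frame_schedule()] the values live on.
#' @param starts Interval start times, minutes.
#' @param end Interval end, minutes (default 60).
#' @return Named numeric vector of slopes (1/min), names `slope_<i>_<end>`;
#'   intervals with fewer than 3 frames are `NA`.
#' @export
slope_family <- function(suvr, schedule,
                         starts = c(9, 11, 13, 15, 20, 25, 30, 35, 40, 45),
                         end = 60) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(suvr) != n_frames(schedule)) {
    stop("'suvr' must hold one value per frame")
  }
  mids <- midpoints(schedule)
  out <- vapply(starts, function(i) {
    sel <- mids >= i - 1e-9 & mids <= end + 1e-9
    if (sum(sel) < 3L) return(NA_real_)
    unname(stats::coef(stats::lm(suvr[sel] ~ mids[sel]))[2])
  }, numeric(1))
  names(out) <- sprintf("slope_%g_%g", starts, end)
  out
}

#' All binding read-outs for one cluster
#'
#' Fits SRTM, SRTM2 and MRTM2 to the cluster TAC, and computes SUVR 30-60
#' and the slope family from the frame-domain SUVR curve.
#'
#' @param img A [dynamic_image()].
#' @param cluster A cluster from [extract_clusters()].
#' @param ref Reference [tac()].
#' @param consts [global_kinetic_constants()] shared across SRTM2 / MRTM2.
#' @param slope_starts Interval starts for [slope_family()].
#' @return One-row `data.frame` with model parameters, validity flags,
#'   `SUVR_30_60` and one column per slope interval.
#' @export
cluster_readouts <- function(img, cluster, ref, consts,
                             slope_starts = c(9, 11, 13, 15, 20, 25, 30,
                                              35, 40, 45)) {
  target <- cluster_tac(img, cluster)
  srtm <- fit_srtm(target, ref)
  srtm2 <- fit_srtm2(target, ref, consts)
  mrtm2 <- fit_mrtm2(target, ref, consts)
  suvr <- suvr_curve(target, ref)
  slopes <- slope_family(suvr, target$schedule, starts = slope_starts)
  row <- data.frame(
    subject = cluster$subject, region = cluster$region,
    class = cluster$class, side = cluster$side,
    n_voxels = cluster$n_voxels, volume_mm3 = cluster$volume_mm3,
    R1_srtm = srtm$R1, k2_srtm = srtm$k2, k2a_srtm = srtm$k2a,
    R1_srtm2 = srtm2$R1, k2a_srtm2 = srtm2$k2a,
    DVR_mrtm2 = mrtm2$DVR,
    valid_srtm = srtm$within_limits, valid_srtm2 = srtm2$within_limits,
    valid_mrtm2 = mrtm2$within_limits,
    SUVR_30_60 = suvr_30_60(target, ref),
    stringsAsFactors = FALSE)
  cbind(row, as.data.frame(as.list(slopes)))
}

#' Read-out table for a set of clusters
#'
#' One row per (subject, cluster), deterministic ordering (subject, region,
#' descending size).  An empty cluster list yields a header-only table.
#'
#' @param img A [dynamic_image()] (single subject) or a list of subject
#'   images named by subject id when clusters span subjects.
#' @param clusters List of clusters.
#' @param ref Reference [tac()] or named list of per-subject reference
#'   curves.
#' @param consts [global_kinetic_constants()] or named list per subject.
#' @param ... Passed to [cluster_readouts()].
#' @return `data.frame` of read-out rows.
#' @export
readout_table <- function(img, clusters, ref, consts, ...) {
  pick <- function(x, subject) {
    if (is.list(x) && is.null(class(x)) || (is.list(x) &&
        !inherits(x, c("dynamic_image", "tac",
                       "global_kinetic_constants")))) {
      x[[subject]]
    } else {
      x
    }
  }
  rows <- lapply(clusters, function(cl) {
    cluster_readouts(pick(img, cl$subject), cl, pick(ref, cl$subject),
                     pick(consts, cl$subject), ...)
  })
  if (length(rows) == 0L) {
    empty <- data.frame(subject = character(), region = character(),
                        class = character(), side = character(),
                        n_voxels = integer(), volume_mm3 = numeric(),
                        R1_srtm = numeric(), k2_srtm = numeric(),
                        k2a_srtm = numeric(), R1_srtm2 = numeric(),
                        k2a_srtm2 = numeric(), DVR_mrtm2 = numeric(),
                        valid_srtm = logical(), valid_srtm2 = logical(),
                        valid_mrtm2 = logical(), SUVR_30_60 = numeric())
    return(empty)
  }
  tab <- do.call(rbind, rows)
  tab[order(tab$subject, tab$region, -tab$n_voxels), , drop = FALSE]
}
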