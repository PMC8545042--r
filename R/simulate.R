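# Synthetic dynamic-PET generator: forward one-tissue reference-tissue
# kinetics on a fine time grid, frame averaging, frame-count noise, lesion
# phantoms and whole cohorts with known ground truth.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) > 0L && tries < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1L
  }
  pmin(pmax(x, lower), upper)
}

#' Ground-truth kinetic parameters of one tissue element
#'
#' One-tissue reference-tissue parameterisation: delivery ratio `R1`
#' (target K1 over reference K1'), target efflux `k2` (1/min) and binding
#' potential `BPND`.  Derived: apparent efflux `k2a = k2 / (1 + BPND)` and
#' distribution volume ratio `DVR = BPND + 1`.
#'
#' @param R1 Positive delivery ratio.
#' @param k2 Positive efflux rate, 1/min.
#' @param BPND Non-negative binding potential.
#' @return A list of class `kinetic_truth` with fields `R1`, `k2`, `BPND`,
#'   `k2a`, `DVR`.
#' @export
kinetic_truth <- function(R1, k2, BPND) {
  if (R1 <= 0) stop("'R1' must be positive")
  if (k2 <= 0) stop("'k2' must be positive")
  if (BPND < 0) stop("'BPND' must be non-negative (k2a cannot exceed k2)")
  structure(list(R1 = R1, k2 = k2, BPND = BPND,
                 k2a = k2 / (1 + BPND), DVR = BPND + 1),
            class = "kinetic_truth")
}

#' Feng-type arterial input function
#'
#' Four-exponential bolus shape
#' `Cp(t) = (A1 t - A2 - A3) exp(-l1 t) + A2 exp(-l2 t) + A3 exp(-l3 t)`,
#' clipped at zero.  Amplitudes are in kBq/ml, decay constants in 1/min.
#'
#' @param A1,A2,A3 Amplitudes (kBq/ml/min for `A1`, kBq/ml otherwise).
#' @param l1,l2,l3 Decay constants, 1/min.
#' @return A function of time (minutes) returning plasma activity.
#' @export
feng_input <- function(A1 = 800, A2 = 25, A3 = 8,
                       l1 = 4.1, l2 = 0.2, l3 = 0.02) {
  function(t) {
    pmax((A1 * t - A2 - A3) * exp(-l1 * t) + A2 * exp(-l2 * t) +
           A3 * exp(-l3 * t), 0)
  }
}

# conv(f, exp(-k t)) on a uniform grid by a trapezoidal recursive update;
# O(n) and exact up to O(dt^3) per step.  stats::filter runs the recursion
# in C.
exp_conv <- function(f, dt, k) {
  n <- length(f)
  if (n < 2L) return(numeric(n))
  a <- exp(-k * dt)
  g <- dt / 2 * (f[-1L] + a * f[-n])
  c(0, as.numeric(stats::filter(g, a, method = "recursive")))
}

# mean of a fine-grid curve over each frame, by trapezoid within the frame
# window (frame boundaries are snapped to the nearest grid node)
frame_average <- function(time, values, schedule) {
  dt <- time[2] - time[1]
  ct <- c(0, cumsum((values[-1L] + values[-length(values)]) / 2 * dt))
  at <- function(tq) {
    i <- pmin(pmax(round(tq / dt), 0) + 1, length(ct))
    ct[i]
  }
  (at(schedule$ends) - at(schedule$starts)) / frame_durations(schedule)
}

fine_grid <- function(schedule, fine_dt) {
  seq(0, schedule$ends[n_frames(schedule)], by = fine_dt)
}

attach_fine <- function(x, time, values) {
  attr(x, "fine") <- list(time = time, values = values)
  x
}

#' Fine-grid curve attached to a TAC, if any
#' @param x A [tac()].
#' @return A list with `time` and `values`, or `NULL`.
#' @export
tac_fine <- function(x) attr(x, "fine")

#' Simulate the reference-tissue time-activity curve
#'
#' Solves the one-tissue reference kinetics
#' `dC_R/dt = K1' Cp(t) - k2' C_R(t)` on a fine grid and returns the
#' frame-averaged curve (each frame value is the time average of `C_R` over
#' the frame window, not a point sample).  The fine-grid solution rides
#' along as the `fine` attribute for downstream forward modelling.
#'
#' @param schedule A [frame_schedule()].
#' @param K1prime Reference delivery, ml/min/ml (non-negative; 0 gives an
#'   all-zero curve).
#' @param k2prime Reference efflux, 1/min (strictly positive).
#' @param input Plasma input function of time in minutes; default
#'   [feng_input()].
#' @param fine_dt Fine-grid step, minutes.
#' @return A [tac()] labelled `"reference"`.
#' @export
simulate_reference_tac <- function(schedule, K1prime = 0.1, k2prime = 0.12,
                                   input = feng_input(), fine_dt = 0.005) {
  if (k2prime <= 0) stop("'k2prime' must be strictly positive")
  if (K1prime < 0) stop("'K1prime' must be non-negative")
  t <- fine_grid(schedule, fine_dt)
  cr <- K1prime * exp_conv(input(t), fine_dt, k2prime)
  out <- tac(schedule, frame_average(t, cr, schedule), label = "reference")
  attach_fine(out, t, cr)
}

#' Forward-simulate a target TAC under the SRTM operational equation
#'
#' `C_T(t) = R1 C_R(t) + (k2 - R1 k2a) (C_R (x) exp(-k2a t))(t)` where
#' `(x)` is convolution; with `R1 = 1`, `BPND = 0` the target equals the
#' reference exactly.  The reference must carry a fine-grid curve (see
#' [simulate_reference_tac()]); the returned target carries one too.
#'
#' @param ref Reference [tac()] with a `fine` attribute.
#' @param truth A [kinetic_truth()].
#' @param label Region label for the result.
#' @return A frame-averaged target [tac()].
#' @export
simulate_target_tac <- function(ref, truth, label = "target") {
  stopifnot(inherits(ref, "tac"), inherits(truth, "kinetic_truth"))
  fine <- tac_fine(ref)
  if (is.null(fine)) stop("'ref' must carry a fine-grid curve")
  if (truth$k2a > truth$k2 + 1e-12) stop("k2a cannot exceed k2 (BPND < 0)")
  dt <- fine$time[2] - fine$time[1]
  ct <- truth$R1 * fine$values +
    (truth$k2 - truth$R1 * truth$k2a) * exp_conv(fine$values, dt, truth$k2a)
  out <- tac(ref$schedule, frame_average(fine$time, ct, ref$schedule),
             label = label)
  attach_fine(out, fine$time, ct)
}

#' Add frame-count noise to a TAC
#'
#' Independent Gaussian noise per frame with standard deviation
#' `scale * sqrt(max(value, eps) / duration)`: variance proportional to
#' activity and inversely proportional to frame length, the usual count-
#' statistics heuristic for reconstructed PET frames.
#'
#' @param x A [tac()].
#' @param scale Non-negative noise scale; 0 returns the input unchanged.
#' @param seed Optional integer seed for reproducibility.
#' @param eps Activity floor inside the square root.
#' @return A [tac()] (fine-grid attribute dropped; noise is a frame-domain
#'   property).  Values are clipped at zero.
#' @export
add_tac_noise <- function(x, scale, seed = NULL, eps = 0.01) {
  stopifnot(inherits(x, "tac"))
  if (scale < 0) stop("'scale' must be non-negative")
  if (scale == 0) return(x)
  sds <- scale * sqrt(pmax(x$values, eps) / frame_durations(x$schedule))
  noisy <- with_seed(seed, x$values + stats::rnorm(length(sds), 0, sds))
  tac(x$schedule, pmax(noisy, 0), label = x$label)
}

#' Synthetic atlas phantom
#'
#' A 40 x 48 x 40 voxel grid at 2 mm isotropic holding eight cortical
#' target regions (frontal / parietal / temporal / occipital, left and
#' right), four subcortical targets (putamen and globus pallidus, left and
#' right) and a cerebellar reference block, with background 0.
#'
#' @param dim Grid dimensions.
#' @param voxel_mm Isotropic voxel size, mm.
#' @return An [atlas_labels()] object.
#' @export
phantom_atlas <- function(dim = c(40L, 48L, 40L), voxel_mm = 2) {
  lab <- array(0L, dim = dim)
  set_block <- function(lab, xs, ys, zs, value, only_bg = TRUE) {
    block <- lab[xs, ys, zs]
    if (only_bg) block[block == 0L] <- value else block[] <- value
    lab[xs, ys, zs] <- block
    lab
  }
  # subcortical nuclei and cerebellar reference first, then cortical
  # octants fill the remaining space so regions never overlap
  lab <- set_block(lab, 7:16, 19:26, 17:24, 9L)    # putamen L
  lab <- set_block(lab, 25:34, 19:26, 17:24, 10L)  # putamen R
  lab <- set_block(lab, 9:14, 28:33, 17:24, 11L)   # pallidus L
  lab <- set_block(lab, 27:32, 28:33, 17:24, 12L)  # pallidus R
  lab <- set_block(lab, 13:28, 9:24, 2:7, 13L)     # cerebellum (reference)
  octant <- function(lab, xs, ys, zs, value) set_block(lab, xs, ys, zs, value)
  xl <- 3:20; xr <- 21:38; ya <- 25:46; yp <- 3:24; zs <- 28:39; zi <- 12:27
  lab <- octant(lab, xl, ya, zs, 1L)  # frontal L
  lab <- octant(lab, xr, ya, zs, 2L)  # frontal R
  lab <- octant(lab, xl, yp, zs, 3L)  # parietal L
  lab <- octant(lab, xr, yp, zs, 4L)  # parietal R
  lab <- octant(lab, xl, ya, zi, 5L)  # temporal L
  lab <- octant(lab, xr, ya, zi, 6L)  # temporal R
  lab <- octant(lab, xl, yp, zi, 7L)  # occipital L
  lab <- octant(lab, xr, yp, zi, 8L)  # occipital R
  table <- data.frame(
    label = 1:13,
    region = c("frontal_l", "frontal_r", "parietal_l", "parietal_r",
               "temporal_l", "temporal_r", "occipital_l", "occipital_r",
               "putamen_l", "putamen_r", "pallidus_l", "pallidus_r",
               "cerebellum"),
    class = c(rep("cortical", 8), rep("subcortical", 4), "reference"),
    stringsAsFactors = FALSE)
  atlas_labels(lab, table, voxel_mm = voxel_mm)
}

group_param_defaults <- function() {
  # group x region-class distributions of delivery (R1) and binding (DVR),
  # emulating the printed cluster read-out distributions of the clinical
  # cohorts (cortical and subcortical, per diagnostic group); efflux k2 is
  # derived from R1 and the subject's reference efflux (one-tissue volume
  # equality, up to a mild lognormal jitter), never drawn independently
  data.frame(
    group  = rep(c("HC", "3/4R", "4R"), each = 2),
    class  = rep(c("cortical", "subcortical"), 3),
    r1_mean  = c(0.87, 0.77, 0.83, 1.02, 0.92, 0.96),
    r1_sd    = c(0.11, 0.10, 0.10, 0.15, 0.21, 0.14),
    dvr_mean = c(NA,   NA,   1.38, 1.22, 1.13, 1.32),
    dvr_sd   = c(NA,   NA,   0.18, 0.17, 0.10, 0.09),
    stringsAsFactors = FALSE)
}

lesion_rule_defaults <- function() {
  # lesion presence probability per target region and lesion size as a
  # fraction of the host region's voxel count
  data.frame(
    group = rep(c("3/4R", "4R"), each = 2),
    class = rep(c("cortical", "subcortical"), 2),
    p_lesion = c(1.00, 0.35, 0.72, 0.77),
    frac_min = c(0.40, 0.15, 0.02, 0.15),
    frac_max = c(0.80, 0.60, 0.20, 0.60),
    stringsAsFactors = FALSE)
}

#' Generative specification of a synthetic cohort
#'
#' Holds the per-group / per-region-class distributions of the kinetic
#' parameters, the lesion seeding rules, the reference-tissue kinetics, the
#' noise level and the group sizes.  Defaults emulate the published
#' cluster read-out distributions of 3/4R-tauopathy, 4R-tauopathy and
#' healthy-control cohorts (11 HC / 10 3/4R / 29 4R subjects).
#'
#' @param n_per_group Named integer vector of subjects per group.
#' @param params `data.frame` of kinetic distributions per group and region
#'   class (columns `group, class, r1_mean, r1_sd, dvr_mean, dvr_sd`).
#' @param lesion_rules `data.frame` of lesion presence probability and size
#'   fraction range per group and class.
#' @param hc_bp_sd SD of the half-normal healthy-tissue binding potential.
#' @param K1prime,k2prime Reference-tissue kinetics (ml/min/ml, 1/min).
#' @param k2prime_jitter_sd Between-subject SD of the reference efflux.
#' @param vol_ratio_sdlog SD of the log nondisplaceable-volume ratio
#'   between target and reference: each tissue element's efflux is
#'   `k2 = R1 k2prime exp(N(0, vol_ratio_sdlog))`, so targets stay close
#'   to one-tissue-consistent with the reference (exact at 0).
#' @param noise_scale Frame-noise scale passed to [add_tac_noise()].
#' @param lesion_dvr_margin Safety margin (DVR units) added above the
#'   healthy 2.5-SD threshold when truncating lesion DVR draws, so painted
#'   lesions are supra-threshold by construction even under fit noise.
#' @param fine_dt Fine simulation grid step, minutes.
#' @param schedule Frame schedule; default [default_frame_schedule()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c("HC" = 11, "3/4R" = 10, "4R" = 29),
                        params = group_param_defaults(),
                        lesion_rules = lesion_rule_defaults(),
                        hc_bp_sd = 0.02,
                        K1prime = 0.1, k2prime = 0.12,
                        k2prime_jitter_sd = 0.006,
                        vol_ratio_sdlog = 0.10,
                        noise_scale = 0.05,
                        lesion_dvr_margin = 0.06,
                        fine_dt = 0.005,
                        schedule = default_frame_schedule()) {
  stopifnot(all(n_per_group >= 1), all(params$r1_sd >= 0),
            all(params$dvr_sd >= 0, na.rm = TRUE))
  if (any(params$r1_mean <= 0.3 | params$r1_mean >= 1.5) ||
      any(params$dvr_mean <= 1 | params$dvr_mean >= 3, na.rm = TRUE)) {
    stop("group means outside physiological bounds (R1 in (0.3,1.5), ",
         "DVR in (1,3))")
  }
  structure(list(n_per_group = n_per_group, params = params,
                 lesion_rules = lesion_rules, hc_bp_sd = hc_bp_sd,
                 K1prime = K1prime, k2prime = k2prime,
                 k2prime_jitter_sd = k2prime_jitter_sd,
                 vol_ratio_sdlog = vol_ratio_sdlog,
                 noise_scale = noise_scale,
                 lesion_dvr_margin = lesion_dvr_margin,
                 fine_dt = fine_dt, schedule = schedule),
            class = "cohort_spec")
}

# healthy-tissue truth: DVR = 1 + |N(0, sd)| (near-zero specific binding;
# a one-tissue forward model cannot produce DVR < 1)
hc_dvr_moments <- function(sd) {
  list(mean = 1 + sd * sqrt(2 / pi), sd = sd * sqrt(1 - 2 / pi))
}

#' Healthy-control DVR threshold implied by a cohort spec
#'
#' The 2.5-SD supra-threshold level of the generator's healthy-tissue DVR
#' distribution; lesion DVR draws are truncated at this value plus the
#' spec's safety margin.
#'
#' @param spec A [cohort_spec()].
#' @return Numeric threshold (DVR units).
#' @export
lesion_dvr_floor <- function(spec) {
  m <- hc_dvr_moments(spec$hc_bp_sd)
  m$mean + 2.5 * m$sd + spec$lesion_dvr_margin
}

draw_truth <- function(spec, group, class, k2prime_subject,
                       lesion = FALSE) {
  p <- spec$params
  row <- p[p$group == group & p$class == class, ]
  if (nrow(row) == 0L) row <- p[p$group == "HC" & p$class == class, ]
  R1 <- rnorm_trunc(1, row$r1_mean, row$r1_sd, 0.3, 1.5)
  if (lesion) {
    dvr <- rnorm_trunc(1, row$dvr_mean, row$dvr_sd, lesion_dvr_floor(spec), 3)
  } else {
    dvr <- 1 + abs(stats::rnorm(1, 0, spec$hc_bp_sd))
  }
  k2 <- R1 * k2prime_subject *
    exp(stats::rnorm(1, 0, spec$vol_ratio_sdlog))
  k2 <- min(max(k2, 0.011), 0.59)
  kinetic_truth(R1 = R1, k2 = k2, BPND = dvr - 1)
}

# grow a contiguous blob of `size` voxels inside `region_idx` by random
# face-connected accretion from a random seed voxel
grow_lesion <- function(region_idx, size, dim3) {
  if (size > length(region_idx)) {
    stop(sprintf("lesion size %d exceeds region size %d", size,
                 length(region_idx)))
  }
  in_region <- logical(prod(dim3))
  in_region[region_idx] <- TRUE
  in_blob <- logical(prod(dim3))
  nx <- dim3[1]; nxy <- dim3[1] * dim3[2]
  offsets <- c(-1L, 1L, -nx, nx, -nxy, nxy)
  seed_vox <- region_idx[sample.int(length(region_idx), 1L)]
  blob <- integer(size)
  blob[1L] <- seed_vox
  in_blob[seed_vox] <- TRUE
  frontier <- seed_vox + offsets
  frontier <- frontier[frontier >= 1L & frontier <= prod(dim3) &
                         in_region[frontier]]
  n_in <- 1L
  while (n_in < size) {
    if (length(frontier) == 0L) {
      # region exhausted around the blob (non-convex region); restart the
      # frontier from the current surface
      surf <- rep(blob[seq_len(n_in)], each = 6L) + offsets
      surf <- surf[surf >= 1L & surf <= prod(dim3)]
      frontier <- surf[in_region[surf] & !in_blob[surf]]
      if (length(frontier) == 0L) stop("region cannot host a contiguous lesion of this size")
    }
    pick <- sample.int(length(frontier), 1L)
    v <- frontier[pick]
    frontier <- frontier[-pick]
    if (in_blob[v]) next
    n_in <- n_in + 1L
    blob[n_in] <- v
    in_blob[v] <- TRUE
    nb <- v + offsets
    nb <- nb[nb >= 1L & nb <= prod(dim3)]
    nb <- nb[in_region[nb] & !in_blob[nb]]
    frontier <- c(frontier, nb)
  }
  blob
}

#' Simulate one phantom subject
#'
#' Draws per-lesion kinetic truths from the group's distributions, paints
#' contiguous lesion blobs into the group's designated regions, fills
#' non-lesion tissue with healthy-level kinetics and the reference region
#' with the reference curve, then adds frame-count noise voxelwise.
#'
#' @param atlas An [atlas_labels()] phantom.
#' @param spec A [cohort_spec()].
#' @param group `"HC"`, `"3/4R"` or `"4R"`.
#' @param seed Integer seed; the subject is fully reproducible.
#' @return A list with elements `image` ([dynamic_image()]), `truth` (list
#'   of 3-D arrays `R1`, `k2a`, `DVR`, `NA` outside tissue), `lesion_mask`
#'   (logical 3-D array), `lesions` (data.frame of per-lesion truths),
#'   `ref_tac` (noise-free reference [tac()]), `k2prime_true`, `group`.
#' @export
simulate_subject <- function(atlas, spec, group, seed = NULL) {
  stopifnot(inherits(atlas, "atlas_labels"), inherits(spec, "cohort_spec"))
  with_seed(seed, {
    dim3 <- dim(atlas$labels)
    sched <- spec$schedule
    nf <- n_frames(sched)
    k2p <- rnorm_trunc(1, spec$k2prime, spec$k2prime_jitter_sd, 0.02, 0.5)
    ref <- simulate_reference_tac(sched, K1prime = spec$K1prime,
                                  k2prime = k2p, fine_dt = spec$fine_dt)
    truth <- list(R1 = array(NA_real_, dim3), k2a = array(NA_real_, dim3),
                  DVR = array(NA_real_, dim3))
    lesion_mask <- array(FALSE, dim3)
    img <- array(0, dim = c(dim3, nf))
    nvox <- prod(dim3)
    flat <- matrix(img, nrow = nvox, ncol = nf)
    paint <- function(idx, truth_obj, curve) {
      flat[idx, ] <<- matrix(curve$values, nrow = length(idx), ncol = nf,
                             byrow = TRUE)
      truth$R1[idx] <<- truth_obj$R1
      truth$k2a[idx] <<- truth_obj$k2a
      truth$DVR[idx] <<- truth_obj$DVR
    }
    lesions <- list()
    lesion_voxels <- list()
    rules <- spec$lesion_rules
    for (i in seq_len(nrow(atlas$table))) {
      region <- atlas$table$region[i]
      cls <- atlas$table$class[i]
      idx <- which(atlas$labels == atlas$table$label[i])
      if (cls == "reference") {
        flat[idx, ] <- matrix(ref$values, nrow = length(idx), ncol = nf,
                              byrow = TRUE)
        truth$R1[idx] <- 1; truth$k2a[idx] <- k2p; truth$DVR[idx] <- 1
        next
      }
      tissue <- draw_truth(spec, "HC", cls, k2p)
      paint(idx, tissue, simulate_target_tac(ref, tissue, label = region))
      rule <- rules[rules$group == group & rules$class == cls, ]
      if (nrow(rule) == 1L && stats::runif(1) < rule$p_lesion) {
        frac <- stats::runif(1, rule$frac_min, rule$frac_max)
        size <- max(2L, round(frac * length(idx)))
        blob <- grow_lesion(idx, size, dim3)
        ltruth <- draw_truth(spec, group, cls, k2p, lesion = TRUE)
        paint(blob, ltruth, simulate_target_tac(ref, ltruth, label = region))
        lesion_mask[blob] <- TRUE
        lesions[[length(lesions) + 1L]] <- data.frame(
          region = region, class = cls, n_voxels = length(blob),
          R1 = ltruth$R1, k2 = ltruth$k2, k2a = ltruth$k2a, DVR = ltruth$DVR)
        lesion_voxels[[length(lesion_voxels) + 1L]] <- sort(blob)
      }
    }
    if (spec$noise_scale > 0) {
      sds <- spec$noise_scale *
        sqrt(pmax(flat, 0.01) / rep(frame_durations(sched), each = nvox))
      flat <- pmax(flat + stats::rnorm(length(flat), 0, as.numeric(sds)), 0)
    }
    list(image = dynamic_image(array(flat, dim = c(dim3, nf)),
                               voxel_mm = atlas$voxel_mm, schedule = sched),
         truth = truth, lesion_mask = lesion_mask,
         lesions = if (length(lesions)) do.call(rbind, lesions) else
           data.frame(region = character(), class = character(),
                      n_voxels = integer(), R1 = numeric(), k2 = numeric(),
                      k2a = numeric(), DVR = numeric()),
         lesion_voxels = lesion_voxels,
         ref_tac = ref, k2prime_true = k2p, group = group)
  })
}

#' Deterministic per-subject seeds and group labels of a cohort
#' @param spec A [cohort_spec()].
#' @param seed Cohort master seed.
#' @return `data.frame` with columns `subject`, `group`, `seed`.
#' @export
cohort_manifest <- function(spec, seed = 1) {
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  ids <- unlist(lapply(seq_along(spec$n_per_group), function(i) {
    sprintf("%s%02d", gsub("[^0-9A-Za-z]", "", names(spec$n_per_group)[i]),
            seq_len(spec$n_per_group[i]))
  }))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      length(groups)))
  data.frame(subject = ids, group = groups, seed = seeds,
             stringsAsFactors = FALSE)
}

#' Simulate a whole cohort
#'
#' Default sizes are 11 healthy controls, 10 3/4R-like and 29 4R-like
#' subjects (50 dynamic datasets).  Deterministic under `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param atlas An [atlas_labels()] phantom; default [phantom_atlas()].
#' @param seed Master seed.
#' @return A list of subjects as returned by [simulate_subject()], with a
#'   `subject` id element added; names are the subject ids.
#' @export
simulate_cohort <- function(spec, atlas = phantom_atlas(), seed = 1) {
  manifest <- cohort_manifest(spec, seed)
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    s <- simulate_subject(atlas, spec, manifest$group[i],
                          seed = manifest$seed[i])
    s$subject <- manifest$subject[i]
    out[[i]] <- s
  }
  names(out) <- manifest$subject
  out
}
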