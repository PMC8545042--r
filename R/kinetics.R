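# Reference-tissue model solvers.  SRTM and SRTM2 are fitted by a
# basis-function search over the apparent efflux k2a (linear least squares
# per basis, bounded 1-D refinement of the grid optimum); MRTM2 is a
# two-parameter multilinear regression.  All fits are weighted by frame
# duration (longer frames carry lower variance under count statistics).

#' Admissible-range check for fitted kinetic parameters
#'
#' A fit is within limits when k2a lies in [0.006, 0.6]/min and DVR in the
#' open interval (0, 5); fits reaching these limits are flagged for
#' exclusion from read-out statistics.
#'
#' @param k2a Apparent efflux, 1/min.
#' @param DVR Distribution volume ratio.
#' @return Logical.
#' @export
kinetic_limits_ok <- function(k2a, DVR) {
  is.finite(k2a) & is.finite(DVR) &
    k2a >= 0.006 & k2a <= 0.6 & DVR > 0 & DVR < 5
}

#' Construct a kinetic fit record
#'
#' @param model `"SRTM"`, `"SRTM2"` or `"MRTM2"`.
#' @param R1 Delivery ratio.
#' @param k2 Target efflux, 1/min.
#' @param k2a Apparent efflux, 1/min.
#' @param BPND Binding potential; `DVR` is always `BPND + 1`.
#' @param fit_residual Weighted sum of squared residuals.
#' @param at_boundary `TRUE` when the k2a search ended on the edge of its
#'   admissible grid (the fit is then also marked out of limits).
#' @return A list of class `kinetic_fit` with a `within_limits` flag.
#' @export
kinetic_fit <- function(model, R1, k2, k2a, BPND, fit_residual = NA_real_,
                        at_boundary = FALSE) {
  DVR <- BPND + 1
  structure(list(model = model, R1 = R1, k2 = k2, k2a = k2a, BPND = BPND,
                 DVR = DVR,
                 within_limits = kinetic_limits_ok(k2a, DVR) && !at_boundary,
                 at_boundary = at_boundary, fit_residual = fit_residual),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<%s fit: R1=%.3f k2=%.4f k2a=%.4f DVR=%.3f%s>\n", x$model, x$R1,
    x$k2, x$k2a, x$DVR, if (x$within_limits) "" else " [out of limits]"))
  invisible(x)
}

#' Global kinetic constants shared across SRTM2 / MRTM2 fits
#'
#' @param k2prime Reference-tissue efflux, 1/min (positive).
#' @param tstar Equilibration time in minutes; frames with midpoint >=
#'   `tstar` enter the multilinear fit.  Default 0 (all frames), adequate
#'   for data that are one-tissue-consistent from injection.
#' @return A list of class `global_kinetic_constants`.
#' @export
global_kinetic_constants <- function(k2prime, tstar = 0) {
  if (!is.finite(k2prime) || k2prime <= 0) stop("'k2prime' must be positive")
  if (tstar < 0 || tstar > 60) stop("'tstar' must lie in [0, 60] minutes")
  structure(list(k2prime = k2prime, tstar = tstar),
            class = "global_kinetic_constants")
}

# fine-grid reference curve: the simulator's fine curve when present,
# otherwise linear interpolation of the frame values at midpoints anchored
# at (0, 0), held constant beyond the last midpoint
ref_fine_curve <- function(ref, fine_dt = 0.01) {
  fine <- tac_fine(ref)
  if (!is.null(fine)) return(fine)
  t <- fine_grid(ref$schedule, fine_dt)
  v <- stats::approx(c(0, midpoints(ref$schedule)), c(0, ref$values),
                     xout = t, rule = 2)$y
  list(time = t, values = v)
}

# frame-averaged convolution basis conv(C_R, exp(-k2a t)) for each k2a
srtm_basis <- function(ref, k2a_values, fine_dt = 0.01) {
  fine <- ref_fine_curve(ref, fine_dt)
  dt <- fine$time[2] - fine$time[1]
  vapply(k2a_values, function(k) {
    frame_average(fine$time, exp_conv(fine$values, dt, k), ref$schedule)
  }, numeric(n_frames(ref$schedule)))
}

default_k2a_grid <- function(n = 100) exp(seq(log(0.006), log(0.6),
                                              length.out = n))

check_fit_inputs <- function(target, ref) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  if (!same_schedule(target$schedule, ref$schedule)) {
    stop("target and reference must share one frame schedule")
  }
  if (all(ref$values == 0)) stop("reference TAC is identically zero")
  if (all(target$values == 0)) stop("target TAC is identically zero")
}

wls_2col <- function(X, y, w) {
  sw <- sqrt(w)
  fit <- stats::lm.fit(X * sw, y * sw)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2),
       rank = fit$rank)
}

#' Fit the simplified reference tissue model (SRTM)
#'
#' Basis-function implementation: for each candidate k2a on a log-spaced
#' grid spanning the admissible range [0.006, 0.6]/min, the model
#' `C_T = theta1 C_R + theta2 conv(C_R, exp(-k2a t))` is solved by weighted
#' linear least squares; the grid optimum is refined by bounded 1-D
#' minimisation.  Then `R1 = theta1`, `k2 = theta2 + R1 k2a`,
#' `BPND = k2 / k2a - 1`.
#'
#' @param target,ref Target and reference [tac()] on the same schedule.
#' @param k2a_grid Candidate k2a values; default 100 log-spaced points on
#'   [0.006, 0.6]/min.
#' @param weights Frame weights; default frame durations.
#' @param fine_dt Grid step for the internal convolution, minutes.
#' @return A [kinetic_fit()]; a grid-edge optimum is flagged via
#'   `at_boundary` rather than silently accepted.
#' @export
fit_srtm <- function(target, ref, k2a_grid = default_k2a_grid(),
                     weights = NULL, fine_dt = 0.01) {
  check_fit_inputs(target, ref)
  w <- if (is.null(weights)) frame_durations(target$schedule) else weights
  fine <- ref_fine_curve(ref, fine_dt)
  dt <- fine$time[2] - fine$time[1]
  y <- target$values
  basis <- srtm_basis(ref, k2a_grid, fine_dt)
  rss <- vapply(seq_along(k2a_grid), function(i) {
    wls_2col(cbind(ref$values, basis[, i]), y, w)$rss
  }, numeric(1))
  i <- which.min(rss)
  lo <- k2a_grid[max(i - 1L, 1L)]
  hi <- k2a_grid[min(i + 1L, length(k2a_grid))]
  objective <- function(k) {
    b <- frame_average(fine$time, exp_conv(fine$values, dt, k),
                       target$schedule)
    wls_2col(cbind(ref$values, b), y, w)$rss
  }
  opt <- stats::optimize(objective, lower = lo, upper = hi, tol = 1e-7)
  k2a <- opt$minimum
  b <- frame_average(fine$time, exp_conv(fine$values, dt, k2a),
                     target$schedule)
  sol <- wls_2col(cbind(ref$values, b), y, w)
  R1 <- sol$coef[1]
  k2 <- sol$coef[2] + R1 * k2a
  at_boundary <- i == 1L || i == length(k2a_grid)
  kinetic_fit("SRTM", R1 = unname(R1), k2 = unname(k2), k2a = k2a,
              BPND = unname(k2 / k2a - 1), fit_residual = sol$rss,
              at_boundary = at_boundary)
}

#' Fit SRTM2 (SRTM with the reference efflux fixed)
#'
#' Two-parameter variant: `k2 = R1 k2prime` is substituted into the SRTM
#' operational equation, leaving `R1` (linear) and `k2a` (1-D search):
#' `C_T = R1 [C_R + (k2prime - k2a) conv(C_R, exp(-k2a t))]`.
#'
#' @inheritParams fit_srtm
#' @param consts A [global_kinetic_constants()] carrying the fixed k2prime.
#' @return A [kinetic_fit()].
#' @export
fit_srtm2 <- function(target, ref, consts, k2a_grid = default_k2a_grid(),
                      weights = NULL, fine_dt = 0.01) {
  check_fit_inputs(target, ref)
  stopifnot(inherits(consts, "global_kinetic_constants"))
  w <- if (is.null(weights)) frame_durations(target$schedule) else weights
  fine <- ref_fine_curve(ref, fine_dt)
  dt <- fine$time[2] - fine$time[1]
  y <- target$values
  k2p <- consts$k2prime
  basis <- srtm_basis(ref, k2a_grid, fine_dt)
  one_fit <- function(b, k2a) {
    x <- ref$values + (k2p - k2a) * b
    R1 <- sum(w * x * y) / sum(w * x * x)
    list(R1 = R1, rss = sum(w * (y - R1 * x)^2))
  }
  rss <- vapply(seq_along(k2a_grid), function(i) {
    one_fit(basis[, i], k2a_grid[i])$rss
  }, numeric(1))
  i <- which.min(rss)
  lo <- k2a_grid[max(i - 1L, 1L)]
  hi <- k2a_grid[min(i + 1L, length(k2a_grid))]
  objective <- function(k) {
    b <- frame_average(fine$time, exp_conv(fine$values, dt, k),
                       target$schedule)
    one_fit(b, k)$rss
  }
  opt <- stats::optimize(objective, lower = lo, upper = hi, tol = 1e-7)
  k2a <- opt$minimum
  b <- frame_average(fine$time, exp_conv(fine$values, dt, k2a),
                     target$schedule)
  sol <- one_fit(b, k2a)
  R1 <- sol$R1
  kinetic_fit("SRTM2", R1 = R1, k2 = R1 * k2p, k2a = k2a,
              BPND = R1 * k2p / k2a - 1, fit_residual = sol$rss,
              at_boundary = i == 1L || i == length(k2a_grid))
}

# cumulative integral of a frame-averaged curve evaluated at frame
# midpoints.  A frame average times its duration is the exact integral
# over that frame, so the integral to midpoint k is the sum over complete
# earlier frames plus half of frame k; this is markedly more accurate than
# a trapezoid through midpoint samples for peaked early kinetics.  Works
# columnwise on a matrix (frames x voxels).
cum_trapz_frames <- function(values, durations) {
  if (is.matrix(values)) {
    full <- values * durations
    apply(full, 2, cumsum) - full / 2
  } else {
    full <- values * durations
    cumsum(full) - full / 2
  }
}

#' Fit the multilinear reference tissue model 2 (MRTM2)
#'
#' Two-parameter multilinear regression over frames with midpoint >=
#' `tstar`:
#' `C_T(T) = g1 [int_0^T C_R + C_R(T)/k2prime] + g2 int_0^T C_T`,
#' with `DVR = -g1/g2`.  For one-tissue-consistent data this identity is
#' exact at all times with the true k2prime, with `g1 = DVR k2a` and
#' `g2 = -k2a`.  Cumulative integrals use exact frame sums (frame average
#' times duration) plus half of the current frame, anchored at t = 0.  A
#' non-negative `g2` is non-physical and marks the fit out of limits.
#'
#' @inheritParams fit_srtm2
#' @return A [kinetic_fit()]; only `DVR`/`BPND` are contractually exact,
#'   `R1 = g1/k2prime`, `k2 = g1` and `k2a = -g2` follow the one-tissue
#'   identity.
#' @export
fit_mrtm2 <- function(target, ref, consts, weights = NULL) {
  check_fit_inputs(target, ref)
  stopifnot(inherits(consts, "global_kinetic_constants"))
  mids <- midpoints(target$schedule)
  sel <- mids >= consts$tstar
  if (sum(sel) < 3L) stop("need at least 3 frames with midpoint >= tstar")
  dur <- frame_durations(target$schedule)
  w <- if (is.null(weights)) dur else weights
  int_t <- cum_trapz_frames(target$values, dur)
  int_r <- cum_trapz_frames(ref$values, dur)
  X <- cbind(int_r + ref$values / consts$k2prime, int_t)[sel, , drop = FALSE]
  y <- target$values[sel]
  sol <- wls_2col(X, y, w[sel])
  if (sol$rank < 2L || any(is.na(sol$coef))) {
    stop("singular MRTM2 design matrix")
  }
  g1 <- unname(sol$coef[1]); g2 <- unname(sol$coef[2])
  DVR <- -g1 / g2
  fit <- kinetic_fit("MRTM2", R1 = g1 / consts$k2prime, k2 = g1, k2a = -g2,
                     BPND = DVR - 1, fit_residual = sol$rss)
  if (g2 >= 0) fit$within_limits <- FALSE
  fit
}

#' Fix the reference efflux from first-pass SRTM fits
#'
#' `k2prime` is the median of `k2 / R1` over the valid (within-limits)
#' first-pass SRTM fits of a subject's target regions or clusters; `tstar`
#' comes from configuration.
#'
#' @param fits List of [kinetic_fit()] objects.
#' @param tstar Equilibration time, minutes (default 0).
#' @return A [global_kinetic_constants()].
#' @export
estimate_k2prime <- function(fits, tstar = 0) {
  if (length(fits) == 0L) stop("no fits supplied")
  ok <- vapply(fits, function(f) isTRUE(f$within_limits), logical(1))
  if (!any(ok)) stop("no valid fits to estimate k2prime from")
  vals <- vapply(fits[ok], function(f) f$k2 / f$R1, numeric(1))
  global_kinetic_constants(stats::median(vals), tstar = tstar)
}

#' Voxelwise MRTM2 DVR parametric map
#'
#' The reference curve is the spatial mean over the reference mask per
#' frame; MRTM2 is then solved voxel by voxel (closed-form 2 x 2 weighted
#' normal equations, fully vectorised).  Voxels whose fit is out of limits
#' (non-negative `g2`, DVR outside (0, 5), singular design) carry the
#' missing-value sentinel `NA`.
#'
#' @param img A [dynamic_image()].
#' @param ref_mask Logical 3-D array or voxel index vector: the reference
#'   region (non-empty).
#' @param consts A [global_kinetic_constants()].
#' @param mask Optional logical 3-D array or voxel indices restricting the
#'   computation (e.g. a brain mask); default all voxels.
#' @return 3-D numeric array of DVR, `NA` where invalid or outside `mask`.
#' @export
dvr_map <- function(img, ref_mask, consts, mask = NULL) {
  stopifnot(inherits(img, "dynamic_image"),
            inherits(consts, "global_kinetic_constants"))
  d <- dim(img$data)
  nvox <- prod(d[1:3])
  ref <- mask_tac(img, ref_mask, label = "reference")
  idx <- if (is.null(mask)) seq_len(nvox) else if (is.logical(mask))
    which(mask) else as.integer(mask)
  if (length(idx) == 0L) stop("empty analysis mask")
  mids <- midpoints(img$schedule)
  sel <- which(mids >= consts$tstar)
  if (length(sel) < 3L) stop("need at least 3 frames with midpoint >= tstar")
  dur <- frame_durations(img$schedule)
  w <- dur[sel]
  Y <- t(matrix(img$data, nrow = nvox, ncol = d[4])[idx, , drop = FALSE])
  int_y <- cum_trapz_frames(Y, dur)[sel, , drop = FALSE]
  Y <- Y[sel, , drop = FALSE]
  x1 <- (cum_trapz_frames(ref$values, dur) +
           ref$values / consts$k2prime)[sel]
  a11 <- sum(w * x1 * x1)
  a12 <- colSums(w * x1 * int_y)
  a22 <- colSums(w * int_y * int_y)
  b1 <- colSums(w * x1 * Y)
  b2 <- colSums(w * int_y * Y)
  det <- a11 * a22 - a12^2
  scale_det <- a11 * a22
  ok <- is.finite(det) & scale_det > 0 & abs(det) > 1e-12 * scale_det
  g1 <- (a22 * b1 - a12 * b2) / det
  g2 <- (a11 * b2 - a12 * b1) / det
  dvr <- -g1 / g2
  ok <- ok & is.finite(dvr) & g2 < 0 & dvr > 0 & dvr < 5
  out <- array(NA_real_, d[1:3])
  out[idx[ok]] <- dvr[ok]
  out
}
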