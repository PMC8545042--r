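test_that("fitting the reference against itself gives the null fit", {
  ref <- strip_fine(fixture_ref())
  f <- fit_srtm(ref, ref)
  expect_equal(f$R1, 1, tolerance = 1e-3)
  expect_equal(f$DVR, 1, tolerance = 1e-3)
  f2 <- fit_srtm2(ref, ref, global_kinetic_constants(0.12))
  expect_equal(f2$R1, 1, tolerance = 1e-3)
  expect_equal(f2$DVR, 1, tolerance = 1e-3)
  m <- fit_mrtm2(ref, ref, global_kinetic_constants(0.12))
  expect_equal(m$DVR, 1, tolerance = 1e-3)
})

test_that("SRTM recovers noise-free forward truths within 1 percent", {
  ref <- fixture_ref()
  tr <- kinetic_truth(0.83, 0.05 * 1.4, 0.4)  # cortical 3/4R-like
  out <- simulate_target_tac(ref, tr)
  f <- fit_srtm(out, ref)
  expect_lt(abs(f$R1 - tr$R1) / tr$R1, 0.01)
  expect_lt(abs(f$k2a - tr$k2a) / tr$k2a, 0.01)
  expect_lt(abs(f$DVR - tr$DVR) / tr$DVR, 0.01)
  expect_true(f$within_limits)
  expect_false(f$at_boundary)
})

test_that("fit records flag out-of-limit parameters", {
  f <- kinetic_fit("SRTM", R1 = 0.9, k2 = 0.01, k2a = 0.005, BPND = 1)
  expect_false(f$within_limits)  # k2a below the 0.006/min floor
  f <- kinetic_fit("MRTM2", R1 = 0.9, k2 = 0.4, k2a = 0.08, BPND = 4.2)
  expect_false(f$within_limits)  # DVR 5.2 above the ceiling
  f <- kinetic_fit("SRTM", R1 = 0.9, k2 = 0.09, k2a = 0.06, BPND = 0.5)
  expect_true(f$within_limits)
  expect_equal(f$DVR, f$BPND + 1)
  f <- kinetic_fit("SRTM", R1 = 0.9, k2 = 0.09, k2a = 0.06, BPND = 0.5,
                   at_boundary = TRUE)
  expect_false(f$within_limits)  # reaching the search limit excludes
})

test_that("degenerate targets are rejected with informative errors", {
  s <- default_frame_schedule()
  ref <- strip_fine(fixture_ref())
  zero <- tac(s, rep(0, 23))
  expect_error(fit_srtm(zero, ref), "identically zero")
  expect_error(fit_srtm(ref, zero), "identically zero")
  other <- tac(frame_schedule(0:22, 1:23), rep(1, 23))
  expect_error(fit_srtm(other, ref), "schedule")
})

test_that("k2prime is the median k2/R1 of valid first-pass fits", {
  one <- kinetic_fit("SRTM", R1 = 0.9, k2 = 0.09, k2a = 0.05, BPND = 0.8)
  expect_equal(estimate_k2prime(list(one))$k2prime, 0.1)
  expect_error(estimate_k2prime(list()), "no fits")
  bad <- kinetic_fit("SRTM", R1 = 0.9, k2 = 0.003, k2a = 0.003, BPND = 0)
  expect_error(estimate_k2prime(list(bad)), "no valid fits")
  # simulated subject with common true k2prime
  ref <- fixture_ref(0.06)
  set.seed(13)
  fits <- lapply(1:8, function(i) {
    r1 <- runif(1, 0.7, 1.1)
    tr <- kinetic_truth(r1, r1 * 0.06, runif(1, 0.1, 0.6))
    fit_srtm(add_tac_noise(simulate_target_tac(ref, tr), 0.02,
                           seed = 100 + i), ref)
  })
  expect_lt(abs(estimate_k2prime(fits)$k2prime - 0.06) / 0.06, 0.02)
})

test_that("SRTM2 tracks SRTM delivery on noise-free curves", {
  ref <- fixture_ref()
  co <- global_kinetic_constants(0.12)
  for (p in list(c(0.83, 1.38), c(0.92, 1.13))) {
    tr <- kinetic_truth(p[1], p[1] * 0.12, p[2] - 1)
    out <- simulate_target_tac(ref, tr)
    f1 <- fit_srtm(out, ref)
    f2 <- fit_srtm2(out, ref, co)
    expect_lt(abs(f2$R1 - f1$R1) / f1$R1, 0.02)
    expect_lt(abs(f2$DVR - p[2]) / p[2], 0.01)
  }
})

test_that("mis-specified k2prime biases SRTM2/MRTM2 DVR only mildly", {
  # regression snapshot of the sensitivity: +50 percent k2prime error
  # must not move DVR by more than a few percent for mid-range kinetics
  ref <- fixture_ref()
  tr <- kinetic_truth(0.83, 0.83 * 0.12, 0.38)
  out <- simulate_target_tac(ref, tr)
  m_wrong <- fit_mrtm2(out, ref, global_kinetic_constants(0.18))
  bias <- abs(m_wrong$DVR - tr$DVR) / tr$DVR
  expect_gt(bias, 0)      # the bias exists and is documented
  expect_lt(bias, 0.05)   # but stays in the few-percent range
})

test_that("MRTM2 recovers DVR within 0.5 percent with correct k2prime", {
  ref <- fixture_ref()
  co <- global_kinetic_constants(0.12)
  for (p in list(c(0.7, 1.25), c(0.9, 1.4), c(1.1, 1.8))) {
    tr <- kinetic_truth(p[1], p[1] * 0.12, p[2] - 1)
    out <- simulate_target_tac(ref, tr)
    m <- fit_mrtm2(out, ref, co)
    expect_lt(abs(m$DVR - p[2]) / p[2], 0.005)
    expect_true(m$within_limits)
  }
})

test_that("MRTM2 needs at least three frames past tstar", {
  ref <- strip_fine(fixture_ref())
  expect_error(fit_mrtm2(ref, ref, global_kinetic_constants(0.12,
                                                            tstar = 59)),
               "at least 3 frames")
})

test_that("fitted DVR is monotone in true binding, noise-free", {
  ref <- fixture_ref()
  dvrs <- seq(1.05, 1.9, by = 0.1)
  fitted <- vapply(dvrs, function(d) {
    tr <- kinetic_truth(0.85, 0.85 * 0.12, d - 1)
    fit_srtm(simulate_target_tac(ref, tr), ref)$DVR
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("a uniform phantom maps to DVR 1 everywhere valid", {
  s <- default_frame_schedule()
  ref <- fixture_ref()
  arr <- array(rep(ref$values, each = 6 * 6 * 6), c(6, 6, 6, 23))
  img <- dynamic_image(arr, 2, s)
  ref_mask <- array(FALSE, c(6, 6, 6)); ref_mask[1:2, 1:2, 1:2] <- TRUE
  map <- dvr_map(img, ref_mask, global_kinetic_constants(0.12))
  expect_true(all(abs(map[!is.na(map)] - 1) < 1e-3))
  expect_gt(sum(!is.na(map)), 0)
  expect_error(dvr_map(img, array(FALSE, c(6, 6, 6)),
                       global_kinetic_constants(0.12)), "empty")
})

test_that("voxelwise DVR recovers the phantom truth at noise scale 0.05", {
  at <- phantom_atlas()
  spec <- small_cohort_spec()
  sub <- simulate_subject(at, spec, "3/4R", seed = 42)
  m <- subject_dvr_map(sub$image, at)
  err <- abs(m$dvr - sub$truth$DVR)
  expect_lt(median(err[!is.na(err)]), 0.05)
  lesion_dvr <- m$dvr[sub$lesion_mask & !is.na(m$dvr)]
  cort <- at$labels %in% 1:8 & !sub$lesion_mask
  tissue_dvr <- m$dvr[cort & !is.na(m$dvr)]
  expect_gt(median(lesion_dvr), median(tissue_dvr))
})
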