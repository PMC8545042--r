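test_that("two-sample t handles identity, separation and the closed form", {
  x <- c(1, 2, 3)
  r <- two_sample_t(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  tiny <- c(1, 2, 3) / 1000  # tiny variance, large shift
  sep <- two_sample_t(tiny, tiny + 10)
  expect_lt(sep$p, 1e-6)
  # pooled-t closed form by hand: a = {1,2,3,4}, b = {3,5,7}
  a <- c(1, 2, 3, 4); b <- c(3, 5, 7)
  sp2 <- (3 * var(a) + 2 * var(b)) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  r <- two_sample_t(a, b, variant = "student")
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 5)
  expect_error(two_sample_t(1, c(1, 2)), ">= 2")
})

test_that("empirical AUC equals brute-force pair counting", {
  expect_equal(auc_empirical(1:4, c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(auc_empirical(c(1, 3, 2, 4),
                             c(FALSE, FALSE, TRUE, TRUE))$auc, 0.75)
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- round(rnorm(n), 1)  # ties on purpose
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    got <- auc_empirical(scores, labels)
    want <- brute_force_auc(scores, labels)
    expect_equal(got$auc_raw, want, tolerance = 1e-12)
    expect_gte(got$auc, 0.5)
    expect_equal(got$auc, if (want < 0.5) 1 - want else want)
  }
  expect_error(auc_empirical(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(5)
  scores <- rnorm(150)
  labels <- runif(150) < 0.5 - 0.3 * (scores < 0)
  got <- auc_empirical(scores, labels)$auc_raw
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("random scores give chance-level AUC at large n", {
  set.seed(7)
  got <- auc_empirical(rnorm(4000), runif(4000) < 0.5)
  expect_lt(abs(got$auc_raw - 0.5), 0.03)
})

test_that("KMO and Bartlett match textbook-formula recomputation", {
  set.seed(12)
  n <- 100
  base <- rnorm(n)
  x <- cbind(v1 = base + rnorm(n, 0, 0.6),
             v2 = base + rnorm(n, 0, 0.6),
             v3 = rnorm(n),
             v4 = base - rnorm(n, 0, 0.9),
             v5 = rnorm(n))
  expect_equal(kmo_measure(x), oracle_kmo(x), tolerance = 1e-8)
  b <- bartlett_sphericity(x)
  expect_equal(b$statistic, oracle_bartlett_stat(x), tolerance = 1e-8)
  expect_equal(b$df, 10)
  expect_lt(b$p, 0.05)
})

test_that("PCA retains the correlated block and preserves structure", {
  set.seed(9)
  n <- 200
  f <- rnorm(n)
  tab <- data.frame(a = f + rnorm(n, 0, 0.1), b = f + rnorm(n, 0, 0.1),
                    c = rnorm(n), d = rnorm(n), e = f + rnorm(n, 0, 0.4))
  res <- pca_readouts(tab, c("a", "b", "c", "d", "e"), r_min = 0)
  expect_gt(res$eigenvalues[1], 2 - 0.1)  # the {a,b,e} block dominates
  expect_equal(sum(res$eigenvalues), 5, tolerance = 1e-10)
  # unrotated loadings have orthogonal columns
  LtL <- t(res$loadings) %*% res$loadings
  expect_equal(LtL[upper.tri(LtL)], rep(0, sum(upper.tri(LtL))),
               tolerance = 1e-8)
  # rotation preserves communalities
  expect_equal(rowSums(res$loadings^2), rowSums(res$rotated_loadings^2),
               tolerance = 1e-10)
  # full loadings reconstruct the correlation matrix
  R <- cor(scale(tab))
  expect_equal(res$loadings_full %*% t(res$loadings_full), R,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the correlation filter discards isolated variables", {
  set.seed(10)
  n <- 300
  f <- rnorm(n)
  tab <- data.frame(a = f + rnorm(n, 0, 0.2), b = f + rnorm(n, 0, 0.2),
                    c = f + rnorm(n, 0, 0.3), lone = rnorm(n))
  res <- pca_readouts(tab, names(tab), labels = NULL)
  expect_equal(res$discarded, "lone")
  expect_setequal(res$variables, c("a", "b", "c"))
  tab2 <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                     d = rnorm(n))
  expect_error(pca_readouts(tab2, names(tab2)), "fewer than 3")
})

test_that("t-test power follows the noncentral t and Monte-Carlo", {
  expect_equal(power_two_sample_t(6, 0.05, 1, 0.2, 1, 0.2), 0.05,
               tolerance = 1e-10)  # d = 0 gives alpha
  pw <- power_two_sample_t(6, 0.05, 1.17, 0.20, 0.89, 0.07)
  expect_gt(pw, 0.8)
  # cross-check against the stats recommended-package implementation
  ref <- stats::power.t.test(n = 6, delta = 1.17 - 0.89,
                             sd = sqrt((0.2^2 + 0.07^2) / 2),
                             sig.level = 0.05)$power
  expect_equal(pw, ref, tolerance = 1e-6)
  ns <- c(3, 6, 12, 24, 48)
  pws <- vapply(ns, function(n) {
    power_two_sample_t(n, 0.05, 1.17, 0.20, 0.89, 0.07)
  }, numeric(1))
  expect_true(all(diff(pws) > 0))
  mc <- mc_power_two_sample_t(6, 0.05, 1.17, 0.20, 0.89, 0.07,
                              nsim = 50000, seed = 2)
  expect_lt(abs(pw - mc), 0.01)
  expect_error(power_two_sample_t(1, 0.05, 1, 1, 0, 1), ">= 2")
})

test_that("discrimination reports assemble stats and PCA per read-out", {
  set.seed(14)
  n <- 60
  grp <- rep(c("3/4R", "4R"), each = n / 2)
  sig <- ifelse(grp == "3/4R", 1.4, 1.1)
  tab <- data.frame(
    DVR_mrtm2 = sig + rnorm(n, 0, 0.1),
    SUVR_30_60 = sig * 1.2 + rnorm(n, 0, 0.15),
    R1_srtm = ifelse(grp == "3/4R", 0.83, 0.92) + rnorm(n, 0, 0.15),
    k2a_srtm = ifelse(grp == "3/4R", 0.07, 0.10) + rnorm(n, 0, 0.03),
    slope_9_60 = ifelse(grp == "3/4R", 0.016, 0.006) + rnorm(n, 0, 0.008))
  rep1 <- discrimination_report(tab, grp)
  expect_s3_class(rep1, "discrimination_report")
  expect_true(all(rep1$stats$auc >= 0.5 & rep1$stats$auc <= 1))
  expect_equal(nrow(rep1$stats), 5L)
  expect_length(rep1$pca_variables, 5L)
  rep2 <- discrimination_report(tab, grp)
  expect_identical(rep1$stats, rep2$stats)
  expect_error(discrimination_report(tab, rep("4R", n)), "two groups")
})
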