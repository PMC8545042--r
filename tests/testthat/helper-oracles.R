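# Independent oracles used to freeze expected values: an ODE integrator for
# the compartment kinetics, brute-force pair counting for the AUC, partial
# correlations by residual regression for the KMO, and Monte-Carlo
# rejection rates for the t-test power.

# reference-tissue ODE solved with deSolve (independent of the package's
# recursive-convolution path), frame-averaged by dense sampling
ode_reference_tac <- function(schedule, K1prime = 0.1, k2prime = 0.12,
                              input = feng_input(), dt = 0.002) {
  t <- seq(0, schedule$ends[n_frames(schedule)], by = dt)
  out <- deSolve::lsoda(
    y = c(CR = 0), times = t,
    func = function(t, y, p) list(K1prime * input(t) - k2prime * y[1]),
    parms = NULL, rtol = 1e-10, atol = 1e-10)
  values <- out[, "CR"]
  avg <- vapply(seq_len(n_frames(schedule)), function(i) {
    sel <- t >= schedule$starts[i] & t <= schedule$ends[i]
    mean(values[sel])
  }, numeric(1))
  list(frames = avg, time = t, values = values)
}

# target one-tissue ODE for one-tissue-consistent truths (k2 = R1 k2prime)
ode_target_tac <- function(schedule, truth, K1prime = 0.1, k2prime = 0.12,
                           input = feng_input(), dt = 0.002) {
  t <- seq(0, schedule$ends[n_frames(schedule)], by = dt)
  K1 <- truth$R1 * K1prime
  out <- deSolve::lsoda(
    y = c(CT = 0), times = t,
    func = function(t, y, p) list(K1 * input(t) - truth$k2a * y[1]),
    parms = NULL, rtol = 1e-10, atol = 1e-10)
  values <- out[, "CT"]
  avg <- vapply(seq_len(n_frames(schedule)), function(i) {
    sel <- t >= schedule$starts[i] & t <= schedule$ends[i]
    mean(values[sel])
  }, numeric(1))
  list(frames = avg, time = t, values = values)
}

# empirical AUC by exhaustive pair counting (ties count one half)
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# KMO from partial correlations computed by residualised regression,
# avoiding the package's inverse-correlation-matrix route
oracle_kmo <- function(x) {
  p <- ncol(x)
  R <- cor(x)
  part <- matrix(NA_real_, p, p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    others <- setdiff(seq_len(p), c(i, j))
    ri <- stats::residuals(stats::lm(x[, i] ~ x[, others]))
    rj <- stats::residuals(stats::lm(x[, j] ~ x[, others]))
    part[i, j] <- cor(ri, rj)
  }
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(part[off]^2, na.rm = TRUE))
}

oracle_bartlett_stat <- function(x) {
  n <- nrow(x); p <- ncol(x)
  -(n - 1 - (2 * p + 5) / 6) * log(det(cor(x)))
}

# Monte-Carlo two-sample pooled-t rejection rate (vectorised over
# simulated experiments)
mc_power_two_sample_t <- function(n, alpha, mean1, sd1, mean2, sd2,
                                  nsim = 50000, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n * nsim, mean1, sd1), nrow = n)
  b <- matrix(rnorm(n * nsim, mean2, sd2), nrow = n)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums((a - rep(ma, each = n))^2) / (n - 1)
  vb <- colSums((b - rep(mb, each = n))^2) / (n - 1)
  sp <- sqrt(((n - 1) * va + (n - 1) * vb) / (2 * n - 2))
  tstat <- (ma - mb) / (sp * sqrt(2 / n))
  mean(abs(tstat) > qt(1 - alpha / 2, 2 * n - 2))
}
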