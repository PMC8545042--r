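# Group-level statistics: two-sample comparisons, ROC/AUC, principal
# component analysis with KMO / Bartlett gating and varimax rotation, and
# the two-sample t-test power computation.

#' Two-sample t-test between read-out groups
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return A list with `t`, `p` (two-sided), `df`, `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`.  When both groups are constant with equal means the
#'   degenerate convention `t = 0, p = 1` applies.
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  base <- list(mean_a = mean(a), mean_b = mean(b),
               sd_a = stats::sd(a), sd_b = stats::sd(b))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(c(list(t = 0, p = 1,
                    df = length(a) + length(b) - 2), base))
    }
    return(c(list(t = Inf * sign(mean(a) - mean(b)), p = 0,
                  df = length(a) + length(b) - 2), base))
  }
  tt <- stats::t.test(a, b, var.equal = variant == "student")
  c(list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter)), base)
}

#' Empirical ROC area under the curve
#'
#' Rank (Mann-Whitney) formulation with ties counted one half; oriented so
#' the reported AUC is >= 0.5, with the applied orientation returned.
#'
#' @param scores Numeric read-out values.
#' @param labels Binary labels (logical, or a factor/vector with exactly
#'   two levels; the second sorted level is the positive class).
#' @return A list with `auc`, `flipped` (`TRUE` when higher scores mark the
#'   negative class) and `auc_raw` (positive-class orientation before
#'   flipping).
#' @export
auc_empirical <- function(scores, labels) {
  if (is.logical(labels)) pos <- labels
  else {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2L) stop("labels must contain exactly two classes")
    pos <- as.character(labels) == lv[2]
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ok <- is.finite(scores)
  scores <- scores[ok]; pos <- pos[ok]
  r <- rank(scores)
  auc_raw <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  flipped <- auc_raw < 0.5
  list(auc = if (flipped) 1 - auc_raw else auc_raw, flipped = flipped,
       auc_raw = auc_raw)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO from zero-order and anti-image partial correlations:
#' `sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal elements, where `q`
#' are the partial correlations from the inverse correlation matrix.
#'
#' @param x Numeric data matrix (observations x variables).
#' @return KMO value in [0, 1].
#' @export
kmo_measure <- function(x) {
  R <- stats::cor(x)
  A <- solve(R)
  q <- -A / sqrt(outer(diag(A), diag(A)))
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Statistic `-(n - 1 - (2p + 5)/6) ln|R|` against chi-squared with
#' `p(p-1)/2` degrees of freedom.
#'
#' @param x Numeric data matrix (observations x variables).
#' @return List with `statistic`, `df`, `p`.
#' @export
bartlett_sphericity <- function(x) {
  n <- nrow(x); p <- ncol(x)
  R <- stats::cor(x)
  stat <- -(n - 1 - (2 * p + 5) / 6) * determinant(R, logarithm = TRUE)$modulus
  stat <- as.numeric(stat)
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Principal component analysis of binding read-outs
#'
#' The SPSS-style recipe: (1) z-standardise the variables; (2) discard any
#' variable whose maximum absolute correlation with the others falls below
#' `r_min`; (3) compute KMO and Bartlett's sphericity on the survivors;
#' (4) eigendecompose the correlation matrix and retain components with
#' eigenvalue > 1; (5) varimax-rotate the retained loadings; (6) compute
#' component scores by the regression method and an oriented AUC per
#' component against `labels`.
#'
#' @param readouts `data.frame` holding the read-out columns.
#' @param variables Column names to analyse (complete cases only).
#' @param labels Binary group labels aligned with `readouts` rows, or
#'   `NULL` to skip per-component AUCs.
#' @param r_min Correlation filter threshold (default 0.3).
#' @return A list with `variables` (survivors), `discarded`, `kmo`,
#'   `bartlett`, `eigenvalues` (all), `n_retained`, `loadings` (unrotated,
#'   retained), `rotated_loadings`, `scores`, `component_auc`.
#' @export
pca_readouts <- function(readouts, variables, labels = NULL, r_min = 0.3) {
  X <- as.matrix(readouts[, variables, drop = FALSE])
  keep_rows <- stats::complete.cases(X)
  X <- X[keep_rows, , drop = FALSE]
  if (!is.null(labels)) labels <- labels[keep_rows]
  R0 <- stats::cor(X)
  max_r <- apply(abs(R0) - diag(ncol(R0)), 2, max)
  discarded <- variables[max_r < r_min]
  survivors <- setdiff(variables, discarded)
  if (length(survivors) < 3L) {
    stop("fewer than 3 variables survive the correlation filter; ",
         "discarded: ", paste(discarded, collapse = ", "))
  }
  X <- scale(X[, survivors, drop = FALSE])
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  n_ret <- sum(ev > 1)
  n_ret <- max(n_ret, 1L)
  L <- eig$vectors[, seq_len(n_ret), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_ret)]), n_ret)
  rownames(L) <- survivors
  rot <- if (n_ret > 1L) {
    vm <- stats::varimax(L, normalize = TRUE)
    Lr <- unclass(vm$loadings)
    attr(Lr, "rotmat") <- vm$rotmat
    Lr
  } else L
  scores <- X %*% solve(R) %*% rot
  colnames(scores) <- paste0("PC", seq_len(n_ret))
  comp_auc <- if (!is.null(labels)) {
    lapply(seq_len(n_ret), function(j) auc_empirical(scores[, j], labels))
  } else NULL
  L_full <- eig$vectors %*% diag(sqrt(ev), length(ev))
  rownames(L_full) <- survivors
  list(variables = survivors, discarded = discarded,
       kmo = kmo_measure(X), bartlett = bartlett_sphericity(X),
       eigenvalues = ev, n_retained = n_ret, loadings_full = L_full,
       var_explained = sum(ev[seq_len(n_ret)]) / length(survivors),
       loadings = L, rotated_loadings = rot, scores = scores,
       component_auc = comp_auc)
}

#' Power of the two-sided two-sample t-test
#'
#' Noncentral-t computation with effect size
#' `d = (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)`, noncentrality
#' `d sqrt(n/2)` and `2n - 2` degrees of freedom.
#'
#' @param n Subjects per group (>= 2).
#' @param alpha Two-sided significance level.
#' @param mean1,sd1,mean2,sd2 Group means and SDs in read-out units.
#' @return Power in [0, 1].
#' @export
power_two_sample_t <- function(n, alpha = 0.05, mean1, sd1, mean2, sd2) {
  if (n < 2) stop("'n' must be >= 2 per group")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (sd1 <= 0 || sd2 <= 0) stop("group SDs must be positive")
  d <- (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
  ncp <- d * sqrt(n / 2)
  df <- 2 * n - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}

#' Group discrimination report over cluster read-outs
#'
#' Per read-out: group means and SDs, two-sample t statistics and an
#' oriented AUC.  The principal component block follows the five-parameter
#' recipe: the R1, efflux and slope variables with the highest AUC plus
#' DVR and SUVR 30-60.  Intended for cortical clusters (pass them only).
#'
#' @param readouts Read-out table from [readout_table()].
#' @param labels Two-level group label per row.
#' @param variables Read-out columns to compare; default all kinetic,
#'   binding and slope columns present.
#' @param t_variant Passed to [two_sample_t()].
#' @param valid_only Drop rows whose MRTM2/SRTM fits are out of limits
#'   before statistics (default TRUE).
#' @return A list of class `discrimination_report`: `stats` (per-read-out
#'   `data.frame`), `pca` (see [pca_readouts()]), `n_per_group`,
#'   `excluded_fraction`.
#' @export
discrimination_report <- function(readouts, labels,
                                  variables = NULL,
                                  t_variant = "student",
                                  valid_only = TRUE) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) {
    stop("labels must contain exactly two groups")
  }
  if (nrow(readouts) != length(labels)) {
    stop("one label per read-out row is required")
  }
  n_all <- nrow(readouts)
  if (valid_only && all(c("valid_srtm", "valid_mrtm2") %in%
                        names(readouts))) {
    ok <- readouts$valid_srtm & readouts$valid_srtm2 & readouts$valid_mrtm2
    readouts <- readouts[ok, , drop = FALSE]
    labels <- labels[ok]
  }
  if (is.null(variables)) {
    candidates <- c("R1_srtm", "R1_srtm2", "k2_srtm", "k2a_srtm",
                    "k2a_srtm2", "DVR_mrtm2", "SUVR_30_60",
                    grep("^slope_", names(readouts), value = TRUE))
    variables <- intersect(candidates, names(readouts))
  }
  lv <- sort(unique(labels))
  rows <- lapply(variables, function(v) {
    x <- readouts[[v]]
    a <- x[labels == lv[1]]; b <- x[labels == lv[2]]
    tt <- two_sample_t(a[is.finite(a)], b[is.finite(b)],
                       variant = t_variant)
    roc <- auc_empirical(x, labels)
    data.frame(readout = v, mean_1 = tt$mean_a, sd_1 = tt$sd_a,
               mean_2 = tt$mean_b, sd_2 = tt$sd_b, t = tt$t, df = tt$df,
               p = tt$p, auc = roc$auc, auc_flipped = roc$flipped,
               stringsAsFactors = FALSE)
  })
  stats_tab <- do.call(rbind, rows)
  best <- function(cands) {
    cands <- intersect(cands, stats_tab$readout)
    if (length(cands) == 0L) return(character(0))
    cands[which.max(stats_tab$auc[match(cands, stats_tab$readout)])]
  }
  five <- unique(c(best(c("R1_srtm", "R1_srtm2")),
                   best(c("k2_srtm", "k2a_srtm", "k2a_srtm2")),
                   "DVR_mrtm2", "SUVR_30_60",
                   best(grep("^slope_", stats_tab$readout, value = TRUE))))
  pca <- tryCatch(pca_readouts(readouts, five, labels = labels),
                  error = function(e) {
                    structure(list(message = conditionMessage(e)),
                              class = "pca_skipped")
                  })
  structure(list(stats = stats_tab, pca = pca, groups = lv,
                 n_per_group = table(labels),
                 pca_variables = five,
                 excluded_fraction = 1 - nrow(readouts) / n_all),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("<discrimination_report: %s vs %s (%d vs %d clusters)>\n",
              x$groups[1], x$groups[2], x$n_per_group[1],
              x$n_per_group[2]))
  print(x$stats[, c("readout", "mean_1", "mean_2", "p", "auc")],
        digits = 3)
  invisible(x)
}
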