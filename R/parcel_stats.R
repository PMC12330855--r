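## Parcel-level aggregation and the statistical battery: per-area medians,
## Pearson correlations with two-tailed bootstrap tests, correlation
## differences, paired t-test, variance-ratio comparison, and Bonferroni
## correction. Bootstrap p-values are bit-reproducible given (seed, n_boot).

#' Per-area median of a vertex metric
#'
#' Medians are used (not means) because a handful of vertices clipping a
#' macrovessel would otherwise dominate an area's value. With several
#' subjects, per-subject medians are taken first and then averaged across
#' subjects.
#'
#' @param metric per-vertex values, or a list of per-subject vectors.
#' @param labels per-vertex area labels (character or factor).
#' @param exclude area labels to drop (e.g. areas with unreliable surface
#'   estimation).
#' @return data.frame `area`, `value`, `n_vertices`; empty areas are
#'   flagged with `NA` and a warning.
#' @export
parcel_median <- function(metric, labels, exclude = character(0)) {
  subjects <- if (is.list(metric)) metric else list(metric)
  labels <- as.character(labels)
  for (s in subjects) {
    if (length(s) != length(labels)) stopf("metric and labels lengths differ")
  }
  areas <- setdiff(sort(unique(labels)), exclude)
  per_subject <- vapply(subjects, function(s) {
    vapply(areas, function(a) {
      v <- s[labels == a]
      v <- v[is.finite(v)]
      if (length(v) == 0) NA_real_ else stats::median(v)
    }, numeric(1))
  }, numeric(length(areas)))
  value <- rowMeans(matrix(per_subject, length(areas)))
  if (anyNA(value)) warnf("%d areas have no finite vertices", sum(is.na(value)))
  data.frame(area = areas,
             value = value,
             n_vertices = vapply(areas, function(a) sum(labels == a), 0L),
             row.names = NULL)
}

boot_r <- function(x, y, n_boot) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  xb <- matrix(x[idx], n_boot, n)
  yb <- matrix(y[idx], n_boot, n)
  mx <- rowMeans(xb); my <- rowMeans(yb)
  sx <- rowMeans(xb^2) - mx^2; sy <- rowMeans(yb^2) - my^2
  cxy <- rowMeans(xb * yb) - mx * my
  den <- sqrt(sx * sy)
  r <- ifelse(den > 0, cxy / den, NA_real_)
  r
}

#' Pearson correlation with two-tailed bootstrap test
#'
#' Resamples pairs with replacement; the two-tailed p-value is
#' `2 * min(P(r* <= 0), P(r* >= 0))` over the bootstrap distribution,
#' clipped to `[2/n_boot, 1]` (the percentile form; a studentized variant
#' is out of scope).
#'
#' @param x,y paired vectors, n >= 5.
#' @param n_boot bootstrap resamples (>= 1000).
#' @param seed integer seed (reproducible bit-for-bit).
#' @return a `correlation_result`: `r`, `p_boot`, `n`, `n_boot`;
#'   zero-variance input yields `undefined = TRUE`.
#' @export
pearson_bootstrap <- function(x, y, n_boot = 10000L, seed = 1L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5L) stopf("need at least 5 pairs, got %d", n)
  if (n_boot < 1000L) stopf("n_boot must be >= 1000")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, p_boot = NA_real_, n = n,
                          n_boot = n_boot, undefined = TRUE),
                     class = "correlation_result"))
  }
  r <- pearson_r(x, y)
  rb <- local_seed(seed, boot_r(x, y, n_boot))
  rb <- rb[!is.na(rb)]
  p <- 2 * min(mean(rb <= 0), mean(rb >= 0))
  p <- min(max(p, 2 / n_boot), 1)
  structure(list(r = r, p_boot = p, n = n, n_boot = n_boot,
                 undefined = FALSE), class = "correlation_result")
}

#' Bootstrap test for a difference between two correlations
#'
#' Independently resamples the two paired datasets, forms the bootstrap
#' distribution of `delta = r_A* - r_B*`, and returns the two-tailed
#' p-value for `delta = 0`.
#'
#' @param xA,yA,xB,yB paired vectors for the two datasets.
#' @param n_boot,seed as in [pearson_bootstrap()].
#' @return list: `r_A`, `r_B`, `delta`, `p`, `n_boot`.
#' @export
compare_correlations <- function(xA, yA, xB, yB, n_boot = 10000L, seed = 1L) {
  if (stats::sd(xA) == 0 || stats::sd(yA) == 0 ||
      stats::sd(xB) == 0 || stats::sd(yB) == 0) {
    stopf("zero-variance input")
  }
  if (n_boot < 1000L) stopf("n_boot must be >= 1000")
  seeds <- derive_seeds(seed, 2L)
  ra <- local_seed(seeds[1], boot_r(xA, yA, n_boot))
  rb <- local_seed(seeds[2], boot_r(xB, yB, n_boot))
  dl <- ra - rb
  dl <- dl[!is.na(dl)]
  p <- 2 * min(mean(dl <= 0), mean(dl >= 0))
  p <- min(max(p, 2 / n_boot), 1)
  list(r_A = pearson_r(xA, yA), r_B = pearson_r(xB, yB),
       delta = pearson_r(xA, yA) - pearson_r(xB, yB), p = p, n_boot = n_boot)
}

#' Bonferroni correction
#'
#' `p_corrected = min(1, m * p)`, monotone in the number of comparisons m.
#'
#' @param p p-value(s).
#' @param m number of comparisons (default: `length(p)`).
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, m * p)

#' Paired t-test and variance-ratio comparison of two tissue compartments
#'
#' Standard paired t statistic (`df = n - 1`; on 88 paired areas the test
#' reports df 87) plus the variance ratio `F = var(gm) / var(swm)` with a
#' two-tailed p (df `n-1`, `n-1`), and descriptive SD and IQR per group.
#'
#' @param gm,swm paired vectors (e.g. per-area Delta-R2* in a gray-matter
#'   layer and the superficial white matter).
#' @return list: `t`, `df`, `p_t`, `F`, `df1`, `df2`, `p_F`, and
#'   `descriptives` (sd, iqr per group).
#' @export
paired_t_and_variance <- function(gm, swm) {
  if (length(gm) != length(swm)) stopf("paired vectors must have equal length")
  n <- length(gm)
  if (n < 2L) stopf("need at least 2 pairs")
  dd <- gm - swm
  sd_d <- stats::sd(dd)
  t <- if (sd_d == 0) 0 else mean(dd) / (sd_d / sqrt(n))
  p_t <- 2 * stats::pt(-abs(t), n - 1)
  v1 <- stats::var(gm); v2 <- stats::var(swm)
  if (v2 == 0) stopf("zero variance in swm group")
  F <- v1 / v2
  pf1 <- stats::pf(F, n - 1, n - 1)
  p_F <- 2 * min(pf1, 1 - pf1)
  list(t = t, df = n - 1L, p_t = p_t,
       F = F, df1 = n - 1L, df2 = n - 1L, p_F = p_F,
       descriptives = data.frame(
         group = c("gm", "swm"),
         sd = c(stats::sd(gm), stats::sd(swm)),
         iqr = c(stats::IQR(gm), stats::IQR(swm))))
}
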