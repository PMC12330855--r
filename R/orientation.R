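## B0 orientation bias: gradient-echo Delta-R2* depends on the angle between
## tubular structure (vessels) and the static field, modelled empirically as
## a cos^2(theta) term. Estimation reads vessel alignment off the
## Delta-R2* ~ cos^2(theta_normal,B0) regression; correction residualizes
## the fitted term out while preserving the mean.

#' Squared cosine of the angle between two directions
#'
#' `cos^2(theta) = (v . b0)^2` after defensive renormalization; axis sign is
#' irrelevant, as for a physical cylinder axis.
#'
#' @param v n x 3 matrix (or length-3 vector) of directions.
#' @param b0 unit 3-vector of the static field.
#' @return values in `[0, 1]`.
#' @export
cos2_angle <- function(v, b0) {
  v <- matrix(as.numeric(v), ncol = 3)
  nv <- sqrt(rowSums(v^2))
  if (any(nv == 0)) stopf("zero direction vector")
  b0 <- unit_vector(as.numeric(b0))
  pmin(1, ((v / nv) %*% b0)[, 1]^2)
}

#' Fit the orientation-bias slope
#'
#' Ordinary least squares `delta = intercept + slope * cos2` with the
#' Pearson correlation and its two-sided t-test p-value. Sign convention
#' (documented, not asserted as physics): a negative slope against
#' cos^2(theta_normal,B0) is read as vessels predominantly perpendicular to
#' the cortical surface (radial), a positive slope as parallel (tangential).
#'
#' @param delta per-location Delta-R2* (1/s).
#' @param cos2 per-location cos^2(theta), same length, at least 10 pairs.
#' @return a `bias_fit`: `slope`, `intercept`, `pearson_r`, `p_value`, `n`,
#'   `undefined` (TRUE when cos2 has zero variance).
#' @export
fit_orientation_bias <- function(delta, cos2) {
  keep <- is.finite(delta) & is.finite(cos2)
  delta <- delta[keep]; cos2 <- cos2[keep]
  n <- length(delta)
  if (n < 10L) stopf("need at least 10 paired samples, got %d", n)
  if (stats::var(cos2) == 0) {
    return(structure(list(slope = NA_real_, intercept = mean(delta),
                          pearson_r = NA_real_, p_value = NA_real_,
                          n = n, undefined = TRUE), class = "bias_fit"))
  }
  slope <- stats::cov(delta, cos2) / stats::var(cos2)
  intercept <- mean(delta) - slope * mean(cos2)
  r <- pearson_r(delta, cos2)
  p <- if (is.na(r) || abs(r) >= 1) {
    if (is.na(r)) NA_real_ else 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  structure(list(slope = slope, intercept = intercept, pearson_r = r,
                 p_value = p, n = n, undefined = FALSE), class = "bias_fit")
}

#' Remove the orientation-bias component from a metric
#'
#' `corrected = metric - slope * (cos2 - mean(cos2))` with the slope from
#' [fit_orientation_bias()]; the global mean is preserved exactly and the
#' corrected metric is uncorrelated with cos^2(theta) (OLS orthogonality).
#' When the fit is undefined (no cos2 variance) the input is returned
#' unchanged with attribute `undefined = TRUE`. The residualization is
#' global and linear; in laminar use it is applied per layer.
#'
#' @param metric per-vertex values.
#' @param cos2 per-vertex cos^2(theta), same length.
#' @return corrected metric (same length), attribute `fit` holding the
#'   `bias_fit`.
#' @export
correct_orientation_bias <- function(metric, cos2) {
  if (length(metric) != length(cos2)) stopf("metric and cos2 lengths differ")
  fit <- fit_orientation_bias(metric, cos2)
  if (isTRUE(fit$undefined)) {
    attr(metric, "fit") <- fit
    attr(metric, "undefined") <- TRUE
    return(metric)
  }
  keep <- is.finite(metric) & is.finite(cos2)
  out <- metric
  out[keep] <- metric[keep] - fit$slope * (cos2[keep] - mean(cos2[keep]))
  attr(out, "fit") <- fit
  out
}
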