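## Voxel-wise mono-exponential R2* fitting from multi-echo gradient-echo
## magnitude data, and Delta-R2* (post minus pre contrast) mapping.
## TE is millisecond at every interface (protocol convention) and converted
## to seconds internally, so R2* and Delta-R2* are always 1/s.

#' Multi-echo gradient-echo series
#'
#' @param echoes list of 3-D arrays (or [vm_volume]s), one per echo, equal
#'   shapes.
#' @param te_ms echo times in ms, strictly increasing, all > 0; at least 3
#'   echoes.
#' @param voxel_size_mm voxel spacing carried to derived maps.
#' @return a `multi_echo_series`.
#' @export
multi_echo_series <- function(echoes, te_ms, voxel_size_mm = 1) {
  echoes <- lapply(echoes, function(e) if (inherits(e, "vm_volume")) e$data else e)
  if (length(echoes) < 3L) stopf("need at least 3 echoes, got %d", length(echoes))
  if (length(te_ms) != length(echoes)) stopf("te_ms length must match echo count")
  if (any(te_ms <= 0) || any(diff(te_ms) <= 0)) {
    stopf("te_ms must be positive and strictly increasing")
  }
  shp <- dim(echoes[[1]])
  ok <- vapply(echoes, function(e) identical(dim(e), shp), logical(1))
  if (!all(ok)) stopf("all echo volumes must share one shape")
  structure(list(echoes = echoes, te_ms = as.numeric(te_ms),
                 voxel_size_mm = voxel_size_mm),
            class = "multi_echo_series")
}

#' Fit voxel-wise R2*
#'
#' Mono-exponential model `S(TE) = S0 exp(-R2* TE)`. `"loglinear"` is
#' ordinary least squares on the log signal; `"nls"` is vectorized
#' Levenberg-Marquardt nonlinear least squares initialized from the
#' log-linear solution (lower bias at low SNR because log-transformed noise
#' is skewed at late echoes).
#'
#' Voxels with fewer than 3 positive-signal echoes are flagged invalid
#' rather than raising an error.
#'
#' @param series a [multi_echo_series()].
#' @param method `"loglinear"` (default) or `"nls"`.
#' @param mask optional logical array restricting the fit.
#' @return an `r2star_map`: `r2star` (1/s), `s0`, `fit_quality` (R^2 of the
#'   fit), `valid` (logical array); all [vm_volume]s on the series grid.
#' @export
fit_r2star <- function(series, method = c("loglinear", "nls"), mask = NULL) {
  stopifnot(inherits(series, "multi_echo_series"))
  method <- match.arg(method)
  d <- dim(series$echoes[[1]])
  nvox <- prod(d)
  ne <- length(series$echoes)
  te <- series$te_ms / 1000                      # seconds
  S <- matrix(0, nvox, ne)
  for (e in seq_len(ne)) S[, e] <- as.numeric(series$echoes[[e]])
  in_mask <- if (is.null(mask)) rep(TRUE, nvox) else as.logical(mask)

  w <- (S > 0) & in_mask                         # usable (voxel, echo) cells
  nvalid <- rowSums(w)
  valid <- nvalid >= 3L
  y <- log(pmax(S, .Machine$double.xmin))
  y[!w] <- 0
  X <- matrix(te, nvox, ne, byrow = TRUE)
  X[!w] <- 0
  n <- nvalid
  sx <- rowSums(X); sy <- rowSums(y)
  sxx <- rowSums(X^2); sxy <- rowSums(X * y)
  denom <- n * sxx - sx^2
  slope <- ifelse(valid & denom > 0, (n * sxy - sx * sy) / denom, NA_real_)
  icept <- ifelse(valid, (sy - slope * sx) / n, NA_real_)
  r2star <- -slope
  s0 <- exp(icept)
  ## R^2 of the log-linear fit
  ybar <- sy / pmax(n, 1)
  sst <- rowSums((y - ybar)^2 * w)
  fit <- icept + slope * X
  sse <- rowSums((y - fit)^2 * w)
  q <- ifelse(valid & sst > 0, 1 - sse / sst, NA_real_)

  if (method == "nls") {
    fitv <- which(valid)
    if (length(fitv)) {
      res <- lm_expfit(S[fitv, , drop = FALSE], te, w[fitv, , drop = FALSE],
                       s0[fitv], r2star[fitv])
      s0[fitv] <- res$s0
      r2star[fitv] <- res$r2star
      ## R^2 on the signal scale for the nonlinear fit
      pred <- res$s0 * exp(-outer(res$r2star, te))
      ww <- w[fitv, , drop = FALSE]
      ss <- S[fitv, , drop = FALSE]
      mbar <- rowSums(ss * ww) / rowSums(ww)
      q[fitv] <- 1 - rowSums((ss - pred)^2 * ww) /
        pmax(rowSums((ss - mbar)^2 * ww), .Machine$double.eps)
    }
  }
  r2star[!valid] <- NA_real_; s0[!valid] <- NA_real_; q[!valid] <- NA_real_
  vx <- series$voxel_size_mm
  structure(list(
    r2star = vm_volume(array(r2star, d), vx),
    s0 = vm_volume(array(s0, d), vx),
    fit_quality = vm_volume(array(q, d), vx),
    valid = array(valid, d),
    method = method, te_ms = series$te_ms), class = "r2star_map")
}

## vectorized Levenberg-Marquardt for S0*exp(-R2* te) across voxels
lm_expfit <- function(S, te, w, s0, r2star, max_iter = 60L, tol = 1e-12) {
  lambda <- rep(1e-3, nrow(S))
  rss <- function(s0, r2) {
    pred <- s0 * exp(-outer(r2, te))
    rowSums((S - pred)^2 * w)
  }
  cur <- rss(s0, r2star)
  for (it in seq_len(max_iter)) {
    E <- exp(-outer(r2star, te))                # nvox x ne
    pred <- s0 * E
    R <- (S - pred) * w
    J1 <- E * w                                 # d pred / d s0
    J2 <- -s0 * outer(rep(1, length(s0)), te) * E * w  # d pred / d r2*
    a11 <- rowSums(J1 * J1); a12 <- rowSums(J1 * J2); a22 <- rowSums(J2 * J2)
    g1 <- rowSums(J1 * R); g2 <- rowSums(J2 * R)
    d11 <- a11 * (1 + lambda); d22 <- a22 * (1 + lambda)
    det <- d11 * d22 - a12^2
    det[det == 0] <- .Machine$double.eps
    ds0 <- (d22 * g1 - a12 * g2) / det
    dr2 <- (d11 * g2 - a12 * g1) / det
    new_s0 <- s0 + ds0; new_r2 <- r2star + dr2
    new <- rss(new_s0, new_r2)
    better <- is.finite(new) & new <= cur
    s0[better] <- new_s0[better]; r2star[better] <- new_r2[better]
    lambda <- ifelse(better, lambda * 0.5, lambda * 4)
    moved <- abs(cur - new) > tol * (cur + tol)
    cur[better] <- new[better]
    if (!any(better & moved)) break
  }
  list(s0 = s0, r2star = r2star)
}

#' Delta-R2* map (post minus pre contrast)
#'
#' Voxel-wise `R2*_post - R2*_pre`: the susceptibility contrast agent raises
#' blood R2* in proportion to local vascular volume, so this difference is
#' an indirect vascular-volume measure. Negative values are retained (not
#' clipped); downstream medians are robust to them.
#'
#' @param post,pre `r2star_map`s on identical grids.
#' @return a `delta_r2star_map` with `delta` ([vm_volume], 1/s) and `valid`.
#' @export
delta_r2star <- function(post, pre) {
  stopifnot(inherits(post, "r2star_map"), inherits(pre, "r2star_map"))
  if (!identical(dim(post$r2star$data), dim(pre$r2star$data))) {
    stopf("post and pre maps have different shapes")
  }
  valid <- post$valid & pre$valid
  delta <- post$r2star$data - pre$r2star$data
  delta[!valid] <- NA_real_
  structure(list(delta = vm_volume(delta, post$r2star$voxel_size_mm),
                 valid = valid), class = "delta_r2star_map")
}
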