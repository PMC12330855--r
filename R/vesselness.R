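## Multi-scale Hessian-based Frangi vesselness. Gaussian second derivatives
## are computed by separable convolution with reflect padding (reproducible
## edge behavior), gamma-normalized by sigma^2 so responses are comparable
## across scales; eigenvalue geometry scores tubes against plates and blobs.

#' Frangi filter parameters
#'
#' @param sigmas_mm Gaussian scales (mm), all > 0.
#' @param alpha plate-vs-line sensitivity (> 0).
#' @param beta blob sensitivity (> 0).
#' @param gamma structureness cutoff; `NULL` (default) auto-sets half the
#'   maximum Hessian Frobenius norm per scale, the common convention.
#' @param polarity `"dark_tubes"` (vessels darker than background, the
#'   post-contrast appearance) or `"bright_tubes"`.
#' @export
frangi_params <- function(sigmas_mm = c(0.25, 0.5, 1),
                          alpha = 0.5, beta = 0.5, gamma = NULL,
                          polarity = c("dark_tubes", "bright_tubes")) {
  polarity <- match.arg(polarity)
  if (length(sigmas_mm) == 0) stopf("empty sigma list")
  if (any(sigmas_mm <= 0)) stopf("sigmas must be > 0")
  if (alpha <= 0 || beta <= 0) stopf("alpha and beta must be > 0")
  structure(list(sigmas_mm = as.numeric(sigmas_mm), alpha = alpha,
                 beta = beta, gamma = gamma, polarity = polarity),
            class = "frangi_params")
}

## 1-D convolution along one axis with reflect padding, via a dense
## kernel matrix (volumes here are small enough that this is the fast path)
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  h <- (length(kernel) - 1L) %/% 2L
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  a <- aperm(arr, perm)
  da <- dim(a)
  n <- da[1]
  idx <- c(rev(seq_len(min(h, n))), seq_len(n), n + 1 - rev(seq_len(min(h, n))))
  if (h > n) stopf("kernel wider than volume axis")
  m <- matrix(a, n, prod(da[2:3]))
  padded <- m[idx, , drop = FALSE]
  K <- matrix(0, n, n + 2L * h)
  for (k in seq_along(kernel)) {
    K[cbind(seq_len(n), seq_len(n) + k - 1L)] <- kernel[length(kernel) - k + 1L]
  }
  out <- K %*% padded
  aperm(array(out, da), order(perm))
}

gaussian_kernels <- function(sigma_vox) {
  h <- max(2L, ceiling(4 * sigma_vox))
  x <- seq(-h, h)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  s <- sum(g)
  g0 <- g / s
  g1 <- (-x / sigma_vox^2) * g / s
  g2 <- ((x^2 - sigma_vox^2) / sigma_vox^4) * g / s
  ## truncation leaves a small DC component in g2; remove it so constant
  ## volumes map exactly to zero (g1 is odd, hence already zero-sum)
  g2 <- g2 - sum(g2) * g0
  list(g0 = g0, g1 = g1, g2 = g2)
}

#' Gaussian-scale Hessian eigenvalues of a volume
#'
#' Second derivatives at scale `sigma_mm` (gamma-normalized: multiplied by
#' sigma^2 in voxel units), eigenvalues sorted by magnitude
#' `|lambda1| <= |lambda2| <= |lambda3|`.
#'
#' @param vol a [vm_volume] with isotropic voxels.
#' @param sigma_mm Gaussian scale in mm.
#' @return list of three eigenvalue arrays `l1`, `l2`, `l3`.
#' @export
hessian_eigenvalues <- function(vol, sigma_mm) {
  stopifnot(inherits(vol, "vm_volume"))
  sv <- sigma_mm / vol$voxel_size_mm
  if (sv < 0.5) warnf("sigma %.3g mm is below half a voxel; response unreliable", sigma_mm)
  kk <- gaussian_kernels(sv)
  a <- vol$data
  ax0 <- conv_axis(a, kk$g0, 1); ax1 <- conv_axis(a, kk$g1, 1)
  ax2 <- conv_axis(a, kk$g2, 1)
  b00 <- conv_axis(ax0, kk$g0, 2); b01 <- conv_axis(ax0, kk$g1, 2)
  b02 <- conv_axis(ax0, kk$g2, 2)
  b10 <- conv_axis(ax1, kk$g0, 2); b11 <- conv_axis(ax1, kk$g1, 2)
  b20 <- conv_axis(ax2, kk$g0, 2)
  s2 <- sv^2
  hxx <- conv_axis(b20, kk$g0, 3) * s2
  hyy <- conv_axis(b02, kk$g0, 3) * s2
  hzz <- conv_axis(b00, kk$g2, 3) * s2
  hxy <- conv_axis(b11, kk$g0, 3) * s2
  hxz <- conv_axis(b10, kk$g1, 3) * s2
  hyz <- conv_axis(b01, kk$g1, 3) * s2
  eig_sym3(hxx, hyy, hzz, hxy, hxz, hyz)
}

## analytic eigenvalues of symmetric 3x3 fields (trigonometric method),
## returned sorted by absolute value
eig_sym3 <- function(a11, a22, a33, a12, a13, a23) {
  d <- dim(a11)
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  tiny <- p <= .Machine$double.eps * (abs(q) + 1)
  ps <- ifelse(tiny, 1, p)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
          b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[tiny] <- q[tiny]; e2[tiny] <- q[tiny]; e3[tiny] <- q[tiny]
  ## sort triple by |.| with a 3-element sorting network
  lo <- e1; mid <- e2; hi <- e3
  swp <- abs(lo) > abs(mid)
  tmp <- lo[swp]; lo[swp] <- mid[swp]; mid[swp] <- tmp
  swp <- abs(mid) > abs(hi)
  tmp <- mid[swp]; mid[swp] <- hi[swp]; hi[swp] <- tmp
  swp <- abs(lo) > abs(mid)
  tmp <- lo[swp]; lo[swp] <- mid[swp]; mid[swp] <- tmp
  list(l1 = array(lo, d), l2 = array(mid, d), l3 = array(hi, d))
}

#' Multi-scale Frangi vesselness filter
#'
#' At each scale, `V = (1 - exp(-R_A^2 / 2 alpha^2)) * exp(-R_B^2 / 2 beta^2)
#' * (1 - exp(-S^2 / 2 gamma^2))` with `R_A = |l2|/|l3|` (plate vs line),
#' `R_B = |l1|/sqrt(|l2 l3|)` (blob), `S` the Hessian Frobenius norm
#' (structureness), zeroed where the tube-polarity condition fails; the
#' final response is the maximum over scales.
#'
#' @param vol a [vm_volume].
#' @param params a [frangi_params()].
#' @return a `vesselness_map`: `response` in `[0, 1]`, `best_scale` (mm, the
#'   argmax scale, NA where response is 0), and the parameters used
#'   (including the per-scale auto gamma) in `$meta`.
#' @export
frangi <- function(vol, params = frangi_params()) {
  stopifnot(inherits(vol, "vm_volume"), inherits(params, "frangi_params"))
  work <- vol
  if (params$polarity == "dark_tubes") {
    work <- vm_volume(-vol$data, vol$voxel_size_mm, vol$origin_mm)
  }
  d <- dim(vol$data)
  resp <- array(0, d)
  best <- array(NA_real_, d)
  gammas <- numeric(length(params$sigmas_mm))
  for (si in seq_along(params$sigmas_mm)) {
    sg <- params$sigmas_mm[si]
    ev <- hessian_eigenvalues(work, sg)
    l1 <- ev$l1; l2 <- ev$l2; l3 <- ev$l3
    S <- sqrt(l1^2 + l2^2 + l3^2)
    ## featureless volume at this scale: nothing to normalize against
    if (max(S) <= 1e-10 * (max(abs(work$data)) + 1)) {
      gammas[si] <- NA_real_
      next
    }
    g <- if (is.null(params$gamma)) max(S) / 2 else params$gamma
    if (g <= 0) g <- .Machine$double.eps
    gammas[si] <- g
    a3 <- pmax(abs(l3), .Machine$double.xmin)
    a23 <- pmax(abs(l2 * l3), .Machine$double.xmin)
    RA <- abs(l2) / a3
    RB <- abs(l1) / sqrt(a23)
    V <- (1 - exp(-RA^2 / (2 * params$alpha^2))) *
         exp(-RB^2 / (2 * params$beta^2)) *
         (1 - exp(-S^2 / (2 * g^2)))
    ## bright-tube condition on the (possibly negated) working volume
    V[l2 > 0 | l3 > 0] <- 0
    upd <- V > resp
    resp[upd] <- V[upd]
    best[upd] <- sg
  }
  structure(list(response = vm_volume(resp, vol$voxel_size_mm, vol$origin_mm),
                 best_scale = vm_volume(best, vol$voxel_size_mm, vol$origin_mm),
                 meta = list(params = params, gamma_used = gammas)),
            class = "vesselness_map")
}

#' Average echoes of a series (TE-averaging pre-step)
#'
#' Equal-weight mean across echoes; improves SNR before vesselness
#' filtering of post-contrast data.
#' @param series a [multi_echo_series()].
#' @return a [vm_volume].
#' @export
average_echoes <- function(series) {
  stopifnot(inherits(series, "multi_echo_series"))
  vm_volume(Reduce(`+`, series$echoes) / length(series$echoes),
            series$voxel_size_mm)
}

#' Vessel-mask statistics
#'
#' Thresholds the vesselness response within a region of interest and
#' reports absolute vessel volume and the fraction of ROI voxels flagged.
#'
#' @param vmap a [frangi()] result.
#' @param threshold response threshold in `(0, 1]`.
#' @param roi_mask logical array; must select at least one voxel.
#' @param voxel_volume_mm3 voxel volume; default from the map's spacing.
#' @return list `vessel_volume_mm3`, `fraction_of_roi`, `n_vessel_voxels`,
#'   `mask`.
#' @export
vessel_mask_stats <- function(vmap, threshold, roi_mask,
                              voxel_volume_mm3 = NULL) {
  stopifnot(inherits(vmap, "vesselness_map"))
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  roi_mask <- as.logical(roi_mask)
  if (!any(roi_mask)) stopf("empty ROI")
  if (is.null(voxel_volume_mm3)) {
    voxel_volume_mm3 <- vmap$response$voxel_size_mm^3
  }
  mask <- (vmap$response$data >= threshold) & array(roi_mask, dim(vmap$response$data))
  nv <- sum(mask)
  list(vessel_volume_mm3 = nv * voxel_volume_mm3,
       fraction_of_roi = nv / sum(roi_mask),
       n_vessel_voxels = nv, mask = mask)
}
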