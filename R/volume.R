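## 3-D scalar volumes in a shared scanner-mm frame.
## world mm = origin + (index - 1) * voxel_size  (isotropic spacing, axis-
## aligned; the phantom and all synthetic data live in this simple frame).

#' Create a 3-D scalar volume
#'
#' Minimal axis-aligned volume container used throughout the pipeline:
#' a numeric 3-D array plus an isotropic voxel size (mm) and the world
#' coordinate of the centre of voxel (1,1,1).
#'
#' @param data numeric 3-D array.
#' @param voxel_size_mm isotropic voxel spacing in mm (> 0).
#' @param origin_mm world coordinate (mm) of the first voxel centre.
#' @return an object of class `vm_volume`.
#' @export
vm_volume <- function(data, voxel_size_mm = 1, origin_mm = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stopf("volume data must be a 3-D array")
  if (!is_number(voxel_size_mm) || voxel_size_mm <= 0) {
    stopf("voxel_size_mm must be a positive scalar")
  }
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "vm_volume")
}

#' @export
print.vm_volume <- function(x, ...) {
  cat(sprintf("<vm_volume %s, voxel %.3g mm, range [%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = "x"), x$voxel_size_mm,
              min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.vm_volume <- function(x) dim(x$data)

world_to_index <- function(vol, xyz) {
  ## continuous (fractional) 1-based voxel index
  sweep(xyz, 2, vol$origin_mm) / vol$voxel_size_mm + 1
}

index_to_world <- function(vol, ijk) {
  sweep((ijk - 1) * vol$voxel_size_mm, 2, vol$origin_mm, `+`)
}

## world-mm voxel-centre coordinate grids (vectors per axis)
voxel_centers <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(a) vol$origin_mm[a] + (seq_len(d[a]) - 1) * vol$voxel_size_mm)
}

#' Sample a volume at world-mm points
#'
#' Trilinear interpolation; points outside the grid fall back to the nearest
#' voxel and are flagged.
#'
#' @param vol a [vm_volume].
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @param method `"trilinear"` or `"nearest"`.
#' @return numeric vector of length n with attribute `"oob"` (logical vector,
#'   TRUE where the nearest-voxel fallback was used).
#' @export
sample_volume <- function(vol, xyz, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  idx <- world_to_index(vol, xyz)
  d <- dim(vol$data)
  oob <- idx[, 1] < 1 | idx[, 1] > d[1] |
         idx[, 2] < 1 | idx[, 2] > d[2] |
         idx[, 3] < 1 | idx[, 3] > d[3]
  clamp <- function(v, hi) pmin(pmax(v, 1), hi)
  if (method == "nearest") {
    i <- clamp(round(idx[, 1]), d[1])
    j <- clamp(round(idx[, 2]), d[2])
    k <- clamp(round(idx[, 3]), d[3])
    out <- vol$data[cbind(i, j, k)]
  } else {
    x <- clamp(idx[, 1], d[1]); y <- clamp(idx[, 2], d[2]); z <- clamp(idx[, 3], d[3])
    i0 <- clamp(floor(x), d[1] - 1L); j0 <- clamp(floor(y), d[2] - 1L)
    k0 <- clamp(floor(z), d[3] - 1L)
    if (any(d < 2L)) {  # degenerate axis: nearest
      return(sample_volume(vol, xyz, method = "nearest"))
    }
    fx <- x - i0; fy <- y - j0; fz <- z - k0
    g <- function(di, dj, dk) vol$data[cbind(i0 + di, j0 + dj, k0 + dk)]
    out <- g(0,0,0) * (1-fx)*(1-fy)*(1-fz) + g(1,0,0) * fx*(1-fy)*(1-fz) +
           g(0,1,0) * (1-fx)*fy*(1-fz)     + g(0,0,1) * (1-fx)*(1-fy)*fz +
           g(1,1,0) * fx*fy*(1-fz)         + g(1,0,1) * fx*(1-fy)*fz +
           g(0,1,1) * (1-fx)*fy*fz         + g(1,1,1) * fx*fy*fz
  }
  attr(out, "oob") <- oob
  out
}
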