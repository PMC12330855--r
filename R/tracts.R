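## Along-tract profiling: bundle cleaning by positional outlier rejection,
## equidistant node resampling, per-node median metric extraction, and
## relative-distance assignment from the white-matter surface (0%) to the
## midsagittal plane (100%).

#' Resample a streamline to equidistant nodes
#'
#' Arc-length parameterization with nodes at arc fractions `i/(n-1)`;
#' endpoints are preserved exactly.
#'
#' @param s n x 3 matrix of ordered points (mm).
#' @param n_nodes number of output nodes (default 20).
#' @return `n_nodes` x 3 matrix.
#' @export
resample_equidistant <- function(s, n_nodes = 20L) {
  s <- matrix(as.numeric(s), ncol = 3)
  if (nrow(s) < 2L) stopf("streamline needs at least 2 points")
  seg <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (total <= 0) stopf("zero-length streamline cannot be resampled")
  target <- seq(0, total, length.out = n_nodes)
  out <- vapply(1:3, function(a) stats::approx(arc, s[, a], xout = target,
                                               ties = "ordered")$y,
                numeric(n_nodes))
  matrix(out, n_nodes, 3)
}

streamline_length <- function(s) {
  sum(sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))
}

#' Clean a bundle by positional outlier rejection
#'
#' All streamlines are resampled to a common node count; a streamline's
#' deviation score is its node-averaged normalized Euclidean distance to the
#' per-node mean position (node scale = per-node positional SD, averaged
#' over coordinates). Streamlines scoring above `sd_threshold` are removed,
#' and the pass is iterated once on the survivors. This is a scalar
#' simplification of the per-node Gaussian outlier model of automated
#' fiber-tract quantification.
#'
#' @param streamlines list of n x 3 matrices (>= 2).
#' @param sd_threshold removal threshold in SD units (default 3).
#' @param n_nodes resampling resolution used for scoring.
#' @return the retained streamlines, with attributes `removed` (indices
#'   into the input) and `valid` (FALSE when everything was removed or
#'   fewer than 6 streamlines survive, the bundle-retention rule).
#' @export
clean_bundle <- function(streamlines, sd_threshold = 3, n_nodes = 20L) {
  if (length(streamlines) < 2L) stopf("need at least 2 streamlines")
  rs <- lapply(streamlines, resample_equidistant, n_nodes = n_nodes)
  keep <- seq_along(rs)
  for (pass in 1:2) {
    P <- array(unlist(rs[keep]), c(n_nodes, 3, length(keep)))
    mu <- apply(P, c(1, 2), mean)
    sdn <- apply(P, c(1, 2), stats::sd)          # node x coord SD
    scale <- rowMeans(sdn)                       # per-node scalar scale
    dist <- sqrt(apply((P - array(mu, dim(P)))^2, c(1, 3), sum))  # node x sl
    norm <- sweep(dist, 1, ifelse(scale > 0, scale, Inf), `/`)
    norm[dist == 0] <- 0
    score <- colMeans(norm)
    bad <- score > sd_threshold
    if (!any(bad)) break
    keep <- keep[!bad]
    if (length(keep) == 0) break
  }
  removed <- setdiff(seq_along(rs), keep)
  out <- streamlines[keep]
  attr(out, "removed") <- removed
  attr(out, "valid") <- length(keep) > 5L
  out
}

#' Extract a tract profile from scalar volumes
#'
#' Resamples each streamline to `n_nodes` equidistant nodes, samples each
#' volume by trilinear interpolation at every node (nearest-voxel fallback
#' outside the grid, flagged), and takes the median across streamlines at
#' each node — the median is robust to the occasional streamline clipping a
#' macrovessel.
#'
#' @param streamlines list of n x 3 matrices (a cleaned bundle).
#' @param scalar_volumes named list of [vm_volume]s on a shared frame.
#' @param n_nodes nodes per profile (default 20).
#' @return a data.frame with `node` and one median column per metric, plus
#'   attributes `path_length_mm` (median streamline length) and `n_oob`
#'   (nodes that used the out-of-bounds fallback).
#' @export
extract_profile <- function(streamlines, scalar_volumes, n_nodes = 20L) {
  if (length(streamlines) == 0) stopf("empty bundle")
  rs <- lapply(streamlines, resample_equidistant, n_nodes = n_nodes)
  out <- data.frame(node = seq_len(n_nodes))
  n_oob <- 0L
  for (m in names(scalar_volumes)) {
    vals <- vapply(rs, function(p) {
      v <- sample_volume(scalar_volumes[[m]], p)
      n_oob <<- n_oob + sum(attr(v, "oob"))
      as.numeric(v)
    }, numeric(n_nodes))
    out[[m]] <- apply(matrix(vals, n_nodes), 1, stats::median)
  }
  attr(out, "path_length_mm") <- stats::median(vapply(streamlines,
                                                      streamline_length,
                                                      numeric(1)))
  attr(out, "n_oob") <- n_oob
  out
}

#' Node-wise median profile of a synthetic bundle's stored metrics
#'
#' The generator attaches per-node metric values directly to streamlines;
#' this collapses them to the bundle profile (median across streamlines per
#' node), the same statistic [extract_profile()] computes from volumes.
#'
#' @param bundle one element of a [make_bundles()] `bundle_set`.
#' @return data.frame: `node`, `relative_distance`, one column per metric.
#' @export
profile_from_bundle <- function(bundle) {
  met <- bundle$metrics
  out <- data.frame(node = seq_len(dim(met)[2]),
                    relative_distance = bundle$relative_distance)
  for (m in dimnames(met)[[3]]) {
    out[[m]] <- apply(met[, , m, drop = FALSE], 2, stats::median)
  }
  out
}

#' Relative distance of profile nodes (% surface to midline)
#'
#' Per streamline (ordered cortical end first), 0% at the first node and
#' 100% where the streamline crosses the midsagittal plane; intermediate
#' nodes by normalized arc length. Streamlines that never cross the plane
#' are excluded from the calibration and flagged. Bundle-level node
#' distances are the median over streamlines.
#'
#' @param streamlines list of n x 3 matrices with a common node count.
#' @param midsagittal_x x-coordinate (mm) of the midline plane.
#' @return list: `per_node` (median % per node), `per_streamline` (matrix),
#'   `excluded` (indices of non-crossing streamlines).
#' @export
relative_distance <- function(streamlines, midsagittal_x = 0) {
  n_nodes <- nrow(streamlines[[1]])
  per <- matrix(NA_real_, length(streamlines), n_nodes)
  excluded <- integer(0)
  for (i in seq_along(streamlines)) {
    p <- streamlines[[i]]
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    arc <- c(0, cumsum(seg))
    side <- sign(p[, 1] - midsagittal_x)
    cross <- which(side[-1] * side[-length(side)] <= 0 & side[-length(side)] != 0)
    if (length(cross) == 0) {
      if (side[length(side)] == 0) {
        arc_cross <- arc[length(arc)]
      } else {
        excluded <- c(excluded, i)
        next
      }
    } else {
      j <- cross[1]
      f <- (midsagittal_x - p[j, 1]) / (p[j + 1, 1] - p[j, 1])
      arc_cross <- arc[j] + f * (arc[j + 1] - arc[j])
    }
    if (arc_cross <= 0) { excluded <- c(excluded, i); next }
    per[i, ] <- 100 * arc / arc_cross
  }
  per_node <- apply(per, 2, stats::median, na.rm = TRUE)
  list(per_node = per_node, per_streamline = per, excluded = excluded)
}
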