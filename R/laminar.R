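## Equivolumetric cortical layers, the superficial white-matter offset
## surface, ribbon-constrained volume-to-surface sampling, and per-vertex
## surface gradients. White and pial meshes must be in vertex correspondence
## (same count and topology), as surface pipelines produce.

#' Equivolumetric layers between white and pial surfaces
#'
#' Per vertex, the boundary at cumulative (white-to-pial) volume fraction
#' `alpha` sits at relative depth
#' `r(alpha) = (-A_w + sqrt(alpha A_p^2 + (1-alpha) A_w^2)) / (A_p - A_w)`
#' using the local white (`A_w`) and pial (`A_p`) vertex areas, with the
#' equidistant limit `r = alpha` when the areas match. This places each of
#' the `n_layers` slabs so it encloses equal tissue volume per cortical
#' column, compensating for curvature. Layers are named `EL1a ... EL6b`
#' ordered pial to white (12 layers), echoing anatomical laminae.
#'
#' @param white,pial corresponding [surface_mesh()]es (white below pial).
#' @param n_layers number of layers (default 12).
#' @return a `layer_stack`: `fractions` (vertex x (n_layers+1) boundary
#'   depth fractions, 0 = white, 1 = pial, monotone increasing),
#'   `boundary_surfaces` (list of interpolated meshes, white to pial),
#'   `layer_names` (pial to white), `layer_bounds` (per layer, the two
#'   boundary columns), and `n_fallback` (vertices that fell back to
#'   equidistant spacing because of non-positive areas).
#' @export
equivolumetric_layers <- function(white, pial, n_layers = 12L) {
  stopifnot(inherits(white, "vm_mesh"), inherits(pial, "vm_mesh"))
  nv <- nrow(white$vertices)
  if (nrow(pial$vertices) != nv || !identical(white$faces, pial$faces)) {
    stopf("white and pial meshes must be in vertex correspondence")
  }
  aw <- white$areas; ap <- pial$areas
  bad <- !(aw > 0 & ap > 0)
  if (any(bad)) {
    warnf("%d vertices with non-positive area fall back to equidistant spacing",
          sum(bad))
  }
  alphas <- seq(0, 1, length.out = n_layers + 1L)
  fr <- matrix(0, nv, n_layers + 1L)
  near_equal <- abs(ap - aw) <= 1e-12 * pmax(aw, ap)
  for (i in seq_along(alphas)) {
    a <- alphas[i]
    r <- (-aw + sqrt(a * ap^2 + (1 - a) * aw^2)) / (ap - aw)
    r[near_equal | bad] <- a
    fr[, i] <- r
  }
  boundary_surfaces <- lapply(seq_len(n_layers + 1L), function(i) {
    v <- white$vertices + fr[, i] * (pial$vertices - white$vertices)
    surface_mesh(v, white$faces)
  })
  half <- n_layers %/% 2L
  layer_names <- if (n_layers == 12L) {
    paste0("EL", rep(1:6, each = 2), rep(c("a", "b"), 6))
  } else {
    sprintf("L%02d", seq_len(n_layers))
  }
  ## layer k in pial->white order spans boundary columns
  ## (n_layers+1-k, n_layers+2-k) in white->pial fraction indexing
  layer_bounds <- cbind(lower = (n_layers + 1L) - seq_len(n_layers),
                        upper = (n_layers + 2L) - seq_len(n_layers))
  rownames(layer_bounds) <- layer_names
  structure(list(fractions = fr, boundary_surfaces = boundary_surfaces,
                 layer_names = layer_names, layer_bounds = layer_bounds,
                 n_fallback = sum(bad)), class = "layer_stack")
}

#' Mid-depth surface of one named layer
#'
#' @param stack a [equivolumetric_layers()] result.
#' @param white,pial the generating meshes.
#' @param layer layer name (e.g. `"EL4a"`).
#' @export
layer_midsurface <- function(stack, white, pial, layer) {
  k <- match(layer, stack$layer_names)
  if (is.na(k)) stopf("unknown layer '%s'", layer)
  b <- stack$layer_bounds[k, ]
  frmid <- (stack$fractions[, b[1]] + stack$fractions[, b[2]]) / 2
  surface_mesh(white$vertices + frmid * (pial$vertices - white$vertices),
               white$faces)
}

#' Superficial white-matter offset surface
#'
#' Displaces the white surface inward (against the pial-ward normal) by a
#' fixed distance; 0.32 mm places the sampling sheet in the superficial
#' white matter just beneath the gray/white boundary. Self-intersections are
#' not repaired, but flipped faces are detected and reported in the
#' `n_flipped` attribute.
#'
#' @param white a [surface_mesh()] with pial-ward normals.
#' @param distance_mm inward displacement (default 0.32).
#' @return the displaced `vm_mesh` with attribute `n_flipped`.
#' @export
offset_surface <- function(white, distance_mm = 0.32) {
  stopifnot(inherits(white, "vm_mesh"))
  v <- white$vertices - distance_mm * white$normals
  out <- surface_mesh(v, white$faces, normals = white$normals)
  fg0 <- face_geometry(white$vertices, white$faces)
  fg1 <- face_geometry(v, white$faces)
  flipped <- rowSums(fg0$normal * fg1$normal) < 0 & fg1$area > 0
  attr(out, "n_flipped") <- sum(flipped)
  out
}

#' Ribbon-constrained volume-to-surface sampling
#'
#' Per vertex, averages voxel values whose centres fall inside the wedge
#' between the corresponding inner and outer surface patches, weighting each
#' voxel by its fractional wedge occupancy estimated from 2^3 sub-voxel
#' corner points. The wedge is modelled as the capsule around the
#' inner-to-outer vertex segment with radius `sqrt(vertex area / pi)`.
#' Vertices with empty wedges (including degenerate inner = outer columns)
#' get the nearest-voxel value and are flagged.
#'
#' @param vol a [vm_volume] in the surfaces' coordinate frame.
#' @param inner,outer corresponding [surface_mesh()]es.
#' @return numeric per-vertex values with attribute `fallback` (logical).
#' @export
ribbon_sample <- function(vol, inner, outer) {
  stopifnot(inherits(vol, "vm_volume"))
  nv <- nrow(inner$vertices)
  if (nrow(outer$vertices) != nv) stopf("surfaces must correspond")
  d <- dim(vol$data)
  vx <- vol$voxel_size_mm
  cgrid <- voxel_centers(vol)
  radius <- sqrt(pmax(inner$areas, .Machine$double.eps) / pi)
  out <- numeric(nv)
  fallback <- logical(nv)
  corners <- as.matrix(expand.grid(c(-0.25, 0.25), c(-0.25, 0.25),
                                   c(-0.25, 0.25))) * vx
  for (i in seq_len(nv)) {
    p0 <- inner$vertices[i, ]; p1 <- outer$vertices[i, ]
    axis <- p1 - p0
    len2 <- sum(axis^2)
    rr <- radius[i]
    if (len2 < (1e-6 * vx)^2) {              # degenerate wedge
      out[i] <- sample_volume(vol, rbind((p0 + p1) / 2), "nearest")[1]
      fallback[i] <- TRUE
      next
    }
    lo <- pmin(p0, p1) - rr - vx; hi <- pmax(p0, p1) + rr + vx
    ir <- lapply(1:3, function(a) {
      which(cgrid[[a]] >= lo[a] & cgrid[[a]] <= hi[a])
    })
    if (any(lengths(ir) == 0)) {
      out[i] <- sample_volume(vol, rbind((p0 + p1) / 2), "nearest")[1]
      fallback[i] <- TRUE
      next
    }
    cand <- as.matrix(expand.grid(ir[[1]], ir[[2]], ir[[3]]))
    centers <- cbind(cgrid[[1]][cand[, 1]], cgrid[[2]][cand[, 2]],
                     cgrid[[3]][cand[, 3]])
    occ <- numeric(nrow(cand))
    for (j in seq_len(nrow(corners))) {
      q <- sweep(centers, 2, corners[j, ], `+`)
      rel <- sweep(q, 2, p0)
      t <- (rel %*% axis)[, 1] / len2
      perp2 <- rowSums(rel^2) - t^2 * len2
      occ <- occ + (t >= 0 & t <= 1 & perp2 <= rr^2)
    }
    w <- occ / nrow(corners)
    if (sum(w) == 0) {
      out[i] <- sample_volume(vol, rbind((p0 + p1) / 2), "nearest")[1]
      fallback[i] <- TRUE
    } else {
      out[i] <- sum(w * vol$data[cand]) / sum(w)
    }
  }
  attr(out, "fallback") <- fallback
  out
}

#' Surface gradient magnitude of a per-vertex metric
#'
#' Gradient of the per-triangle linear interpolant (which lies in the
#' triangle plane), area-weighted onto vertices; returns the magnitude of
#' the averaged tangential gradient vector. High-gradient "circular" rings
#' mark vessels piercing a layer; elongated "rod-like" ridges mark vessels
#' running along it.
#'
#' @param metric numeric per-vertex values.
#' @param mesh a [surface_mesh()].
#' @return per-vertex gradient magnitude (metric units per mm).
#' @export
surface_gradient <- function(metric, mesh) {
  stopifnot(inherits(mesh, "vm_mesh"))
  if (length(metric) != nrow(mesh$vertices)) {
    stopf("metric must be defined on all vertices")
  }
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  f1 <- metric[f[, 1]]; f2 <- metric[f[, 2]]; f3 <- metric[f[, 3]]
  fg <- face_geometry(v, f)
  N <- fg$normal; A <- fg$area
  cross3 <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  ## gradient of the linear interpolant on each face
  g <- ((f2 - f1) * cross3(N, p1 - p3) + (f3 - f1) * cross3(N, p2 - p1)) /
    pmax(2 * A, .Machine$double.eps)
  nv <- nrow(v)
  acc <- matrix(0, nv, 3)
  wsum <- numeric(nv)
  for (c3 in 1:3) {
    acc[, 1] <- acc[, 1] + rowsum_full(g[, 1] * A, f[, c3], nv)
    acc[, 2] <- acc[, 2] + rowsum_full(g[, 2] * A, f[, c3], nv)
    acc[, 3] <- acc[, 3] + rowsum_full(g[, 3] * A, f[, c3], nv)
    wsum <- wsum + rowsum_full(A, f[, c3], nv)
  }
  wsum[wsum == 0] <- 1
  sqrt(rowSums((acc / wsum)^2))
}
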