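## Triangle surface meshes with per-vertex outward normals and areas.
## White and pial surfaces produced by laminar pipelines share vertex count
## and topology (vertex correspondence); the layering code relies on that.

#' Create a triangle surface mesh
#'
#' @param vertices n x 3 matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param normals optional n x 3 matrix of per-vertex outward unit normals;
#'   computed by area-weighted face-normal averaging when omitted.
#' @return an object of class `vm_mesh` with fields `vertices`, `faces`,
#'   `normals` and `areas` (one third of incident triangle area per vertex).
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (max(faces) > nrow(vertices) || min(faces) < 1L) {
    stopf("face indices out of range")
  }
  fn <- face_geometry(vertices, faces)
  areas <- numeric(nrow(vertices))
  third <- rep(fn$area / 3, 3L)
  idx <- as.vector(faces)
  areas <- as.numeric(rowsum(third, idx, reorder = TRUE))
  ## rowsum drops vertices absent from any face; re-expand
  full <- numeric(nrow(vertices))
  full[sort(unique(idx))] <- areas
  areas <- full
  if (is.null(normals)) {
    acc <- matrix(0, nrow(vertices), 3)
    for (c3 in 1:3) {
      w <- fn$normal * fn$area
      acc[, 1] <- acc[, 1] + as.numeric(rowsum_full(w[, 1], faces[, c3], nrow(vertices)))
      acc[, 2] <- acc[, 2] + as.numeric(rowsum_full(w[, 2], faces[, c3], nrow(vertices)))
      acc[, 3] <- acc[, 3] + as.numeric(rowsum_full(w[, 3], faces[, c3], nrow(vertices)))
    }
    nrm <- sqrt(rowSums(acc^2))
    nrm[nrm == 0] <- 1
    normals <- acc / nrm
  } else {
    normals <- matrix(as.numeric(normals), ncol = 3)
    nrm <- sqrt(rowSums(normals^2))
    nrm[nrm == 0] <- 1
    normals <- normals / nrm
  }
  structure(list(vertices = vertices, faces = faces,
                 normals = normals, areas = areas),
            class = "vm_mesh")
}

rowsum_full <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group, reorder = TRUE)
  out[as.integer(rownames(s))] <- s
  out
}

face_geometry <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  area <- nrm / 2
  nz <- nrm > 0
  unitn <- cr
  unitn[nz, ] <- cr[nz, ] / nrm[nz]
  list(normal = unitn, area = area)
}

#' @export
print.vm_mesh <- function(x, ...) {
  cat(sprintf("<vm_mesh %d vertices, %d faces, total area %.4g mm^2>\n",
              nrow(x$vertices), nrow(x$faces), sum(face_geometry(x$vertices, x$faces)$area)))
  invisible(x)
}

## Regular grid sheet z = f(x) (constant in y), triangulated, normals
## analytic from df/dx and oriented towards +z (pial-ward for our phantoms).
sheet_mesh <- function(xs, ys, fz, dfz = NULL) {
  nx <- length(xs); ny <- length(ys)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  verts <- cbind(xs[g$ix], ys[g$iy], fz(xs[g$ix]))
  vid <- matrix(seq_len(nx * ny), nx, ny)
  f1 <- cbind(as.vector(vid[-nx, -ny]), as.vector(vid[-1, -ny]), as.vector(vid[-1, -1]))
  f2 <- cbind(as.vector(vid[-nx, -ny]), as.vector(vid[-1, -1]), as.vector(vid[-nx, -1]))
  faces <- rbind(f1, f2)
  normals <- NULL
  if (!is.null(dfz)) {
    d <- dfz(verts[, 1])
    normals <- cbind(-d, 0, 1) / sqrt(1 + d^2)
  }
  surface_mesh(verts, faces, normals)
}

#' Subdivide a mesh by edge midpoint splitting
#'
#' Each triangle is split into four; shared edges get a single midpoint
#' vertex. Stands in for the high-density mesh upsampling used when surface
#' spacing must undersample vessel spacing.
#'
#' @param mesh a [surface_mesh()].
#' @param times number of subdivision rounds.
#' @return a finer `vm_mesh`.
#' @export
mesh_subdivide <- function(mesh, times = 1L) {
  for (t in seq_len(times)) {
    v <- mesh$vertices; f <- mesh$faces
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uk <- unique(key)
    eid <- match(key, uk) + nrow(v)
    first <- !duplicated(key)
    mids <- (v[edges[first, 1], , drop = FALSE] + v[edges[first, 2], , drop = FALSE]) / 2
    ## eid rows: 1..m = edge(1,2), m+1..2m = edge(2,3), 2m+1..3m = edge(3,1)
    m <- nrow(f)
    e12 <- eid[seq_len(m)]; e23 <- eid[m + seq_len(m)]; e31 <- eid[2 * m + seq_len(m)]
    nf <- rbind(cbind(f[, 1], e12, e31),
                cbind(e12, f[, 2], e23),
                cbind(e31, e23, f[, 3]),
                cbind(e12, e23, e31))
    ## unique() keeps first-appearance order, so mids rows already align to uk
    mesh <- surface_mesh(rbind(v, mids), nf)
  }
  mesh
}
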