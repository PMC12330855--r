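test_that("flat slab gives the exact equidistant limit with the EL names", {
  white <- flat_sheet(6, spacing = 1, z0 = 0)
  pial <- flat_sheet(6, spacing = 1, z0 = 2)
  st <- equivolumetric_layers(white, pial)
  expect_equal(length(st$layer_names), 12L)
  expect_identical(st$layer_names,
                   c("EL1a", "EL1b", "EL2a", "EL2b", "EL3a", "EL3b",
                     "EL4a", "EL4b", "EL5a", "EL5b", "EL6a", "EL6b"))
  for (i in 0:12) {
    expect_equal(st$fractions[, i + 1], rep(i / 12, nrow(white$vertices)),
                 tolerance = 1e-12)
  }
  ## boundary surfaces interpolate linearly in z
  expect_equal(st$boundary_surfaces[[7]]$vertices[, 3],
               rep(1, nrow(white$vertices)))
  ## EL1a sits just beneath the pial surface, EL6b just above white
  expect_identical(unname(st$layer_bounds["EL1a", ]), c(12L, 13L))
  expect_identical(unname(st$layer_bounds["EL6b", ]), c(1L, 2L))
})

test_that("wedge columns get equal per-slab volumes (numeric prism oracle)", {
  ## vertex with A_p = 2 A_w; the equivolume rule assumes the column
  ## cross-section interpolates linearly white->pial
  aw <- 1; ap <- 2
  alphas <- seq(0, 1, length.out = 13)
  r <- (-aw + sqrt(alphas * ap^2 + (1 - alphas) * aw^2)) / (ap - aw)
  ## oracle: numeric integration of A(r) = aw + (ap - aw) r
  area_f <- function(x) aw + (ap - aw) * x
  vols <- vapply(seq_len(12), function(i) {
    stats::integrate(area_f, r[i], r[i + 1], rel.tol = 1e-10)$value
  }, numeric(1))
  expect_lt(max(abs(vols / mean(vols) - 1)), 0.01)
  ## spot-check the closed form against the package on a real mesh pair:
  ## pial = white scaled so every pial vertex area is ~2x the white one
  white <- flat_sheet(7, spacing = 1, z0 = 0)
  pial_v <- cbind(white$vertices[, 1] * sqrt(2), white$vertices[, 2] * sqrt(2),
                  2)
  pial <- surface_mesh(pial_v, white$faces)
  st <- equivolumetric_layers(white, pial)
  interior <- which(white$areas > 0.9 * max(white$areas))  # away from rim
  awi <- white$areas[interior]; api <- pial$areas[interior]
  a <- 0.5
  expected <- (-awi + sqrt(a * api^2 + (1 - a) * awi^2)) / (api - awi)
  expect_equal(st$fractions[interior, 7], expected, tolerance = 1e-12)
  ## monotone 0 -> 1
  expect_true(all(diff(t(st$fractions)) > -1e-12))
  expect_equal(st$fractions[, 1], rep(0, nrow(white$vertices)))
  expect_equal(st$fractions[, 13], rep(1, nrow(white$vertices)))
})

test_that("equivolume fractions are invariant under uniform rescaling", {
  ph <- cached_phantom()
  st1 <- equivolumetric_layers(ph$white_surface, ph$pial_surface)
  w2 <- surface_mesh(ph$white_surface$vertices * 3.7, ph$white_surface$faces)
  p2 <- surface_mesh(ph$pial_surface$vertices * 3.7, ph$pial_surface$faces)
  st2 <- equivolumetric_layers(w2, p2)
  expect_equal(st1$fractions, st2$fractions, tolerance = 1e-9)
})

test_that("slab volumes sum to the column volume within 1%", {
  ph <- cached_phantom()
  st <- equivolumetric_layers(ph$white_surface, ph$pial_surface)
  w <- ph$white_surface; p <- ph$pial_surface
  thick <- sqrt(rowSums((p$vertices - w$vertices)^2))
  ## per-vertex column volume model: integral of the linearly interpolated
  ## area times thickness; slab volume from the fraction increments
  aw <- w$areas; ap <- p$areas
  interior <- aw > 0 & ap > 0
  col_vol <- thick * (aw + ap) / 2
  slab_sum <- numeric(length(thick))
  for (i in seq_len(12)) {
    r0 <- st$fractions[, i]; r1 <- st$fractions[, i + 1]
    area_int <- function(r) aw * r + (ap - aw) * r^2 / 2
    slab_sum <- slab_sum + thick * (area_int(r1) - area_int(r0))
  }
  expect_lt(max(abs(slab_sum[interior] / col_vol[interior] - 1)), 0.01)
})

test_that("offset surface displaces along the inward normal", {
  white <- flat_sheet(5, spacing = 1, z0 = 1)
  expect_equal(offset_surface(white, 0)$vertices, white$vertices)
  off <- offset_surface(white, 0.32)
  expect_equal(off$vertices[, 3], rep(1 - 0.32, nrow(white$vertices)))
  expect_equal(attr(off, "n_flipped"), 0L)
})

test_that("phantom offset surface lies inside white matter", {
  ph <- cached_phantom()
  off <- offset_surface(ph$white_surface, 0.32)
  lab <- sample_volume(ph$tissue_labels, off$vertices, "nearest")
  ## >99% of vertices inside the SWM shell or deep WM (never gray matter)
  expect_gt(mean(lab %in% c(2, 3)), 0.99)
})

test_that("ribbon sampling reproduces constants and linear ramps", {
  vol_c <- vm_volume(array(3.5, c(12, 12, 12)), 0.5)
  inner <- flat_sheet(6, spacing = 0.9, z0 = 1.2)
  outer <- flat_sheet(6, spacing = 0.9, z0 = 3.8)
  expect_equal(as.numeric(ribbon_sample(vol_c, inner, outer)),
               rep(3.5, nrow(inner$vertices)), tolerance = 1e-12)
  ## linear-in-z volume between flat surfaces -> mid-wedge value
  zs <- (seq_len(12) - 1) * 0.5
  vol_l <- vm_volume(array(rep(zs, each = 144), c(12, 12, 12)), 0.5)
  got <- as.numeric(ribbon_sample(vol_l, inner, outer))
  expect_true(all(abs(got - 2.5) <= 0.5))          # within one voxel
  expect_lt(abs(mean(got) - 2.5), 0.1)
  ## degenerate wedge falls back to nearest voxel with a flag
  res <- ribbon_sample(vol_l, inner, inner)
  expect_true(all(attr(res, "fallback")))
  expect_true(all(abs(as.numeric(res) - 1.2) <= 0.3))
})

test_that("phantom layers reproduce the imposed GM/SWM vascular contrast", {
  ph <- cached_phantom()
  st <- equivolumetric_layers(ph$white_surface, ph$pial_surface)
  el4a <- layer_midsurface(st, ph$white_surface, ph$pial_surface, "EL4a")
  swm <- offset_surface(ph$white_surface, 0.32)
  half <- ph$spec$voxel_size_mm
  sample_on <- function(mesh) {
    inner <- surface_mesh(mesh$vertices - half * mesh$normals, mesh$faces,
                          mesh$normals)
    outer <- surface_mesh(mesh$vertices + half * mesh$normals, mesh$faces,
                          mesh$normals)
    as.numeric(ribbon_sample(ph$true_delta_r2star, inner, outer))
  }
  v_gm <- sample_on(el4a)
  v_swm <- sample_on(swm)
  ## imposed ordering, read directly off the truth volume at the same
  ## depths: ribbon sampling must preserve it
  truth <- ph$true_delta_r2star$data
  imposed_gm <- mean(truth[ph$tissue_labels$data == 1L])
  imposed_swm <- mean(truth[ph$tissue_labels$data == 2L])
  expect_equal(sign(mean(v_gm) - mean(v_swm)), sign(imposed_gm - imposed_swm))
  expect_gt(mean(v_gm), 0)
  expect_gt(mean(v_swm), 0)
})

test_that("surface gradients: constants are flat, linear ramps have slope 1", {
  mesh <- flat_sheet(8, spacing = 0.7)
  expect_equal(surface_gradient(rep(2, nrow(mesh$vertices)), mesh),
               rep(0, nrow(mesh$vertices)), tolerance = 1e-12)
  g <- surface_gradient(mesh$vertices[, 1], mesh)
  expect_equal(g, rep(1, nrow(mesh$vertices)), tolerance = 1e-9)
  expect_error(surface_gradient(1:3, mesh), "all vertices")
})

test_that("SWM-surface gradients ridge along tangential vessel paths", {
  ph <- cached_phantom()
  swm <- offset_surface(ph$white_surface, ph$spec$swm_thickness_mm / 2)
  half <- ph$spec$voxel_size_mm
  inner <- surface_mesh(swm$vertices - half * swm$normals, swm$faces, swm$normals)
  outer <- surface_mesh(swm$vertices + half * swm$normals, swm$faces, swm$normals)
  mean_post <- average_echoes(ph$post_echoes)
  vals <- as.numeric(ribbon_sample(mean_post, inner, outer))
  g <- surface_gradient(vals, swm)
  ## ground-truth trace: vertices within a dilated radius of any tangential
  ## vessel voxel
  vo <- ph$vessel_orientations
  tang <- vo$index[vo$class == "tangential", , drop = FALSE]
  tang_mm <- (tang - 1) * ph$spec$voxel_size_mm
  near <- vapply(seq_len(nrow(swm$vertices)), function(i) {
    min(sqrt(colSums((t(tang_mm) - swm$vertices[i, ])^2)))
  }, numeric(1)) < (ph$spec$vessel_radius_mm + 2 * ph$spec$voxel_size_mm)
  ## threshold the gradient at the trace's size; require overlap (IoU)
  thr <- stats::quantile(g, 1 - mean(near))
  hot <- g >= thr
  iou <- sum(hot & near) / sum(hot | near)
  expect_gt(iou, 0.3)
})
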