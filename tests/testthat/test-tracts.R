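straight_line <- function(from, to, n = 20L) {
  tt <- seq(0, 1, length.out = n)
  outer(1 - tt, from) + outer(tt, to)
}

test_that("equidistant resampling preserves endpoints and spacing", {
  s <- straight_line(c(0, 0, 0), c(19, 0, 0), 5L)
  r <- resample_equidistant(s, 20L)
  expect_equal(nrow(r), 20L)
  expect_equal(r[1, ], c(0, 0, 0))
  expect_equal(r[20, ], c(19, 0, 0))
  spacing <- sqrt(rowSums(diff(r)^2))
  expect_equal(spacing, rep(1, 19), tolerance = 1e-12)
  expect_error(resample_equidistant(matrix(1, 1, 3)), "at least 2")
  expect_error(resample_equidistant(rbind(c(1, 1, 1), c(1, 1, 1))), "zero-length")
})

test_that("semicircle node spacing matches the dense resampling oracle", {
  r <- 7
  th <- seq(0, pi, length.out = 10000)               # dense polyline oracle
  semi <- cbind(r * cos(th), r * sin(th), 0)
  out <- resample_equidistant(semi, 20L)
  spacing <- sqrt(rowSums(diff(out)^2))
  ## chord of an arc of length pi*r/19
  arc <- pi * r / 19
  chord <- 2 * r * sin(arc / (2 * r))
  expect_true(all(abs(spacing - chord) / chord < 1e-3))
})

test_that("cleaning keeps identical streamlines and removes planted outliers", {
  base <- straight_line(c(0, 0, 0), c(50, 10, 5))
  ident <- replicate(8, base, simplify = FALSE)
  out <- clean_bundle(ident)
  expect_length(attr(out, "removed"), 0L)
  expect_true(attr(out, "valid"))
  ## 20 coherent + 2 planted at 10x the positional SD
  sdn <- 0.1
  bs <- make_bundles(bundle_spec(n_bundles = 6L, streamlines_per_bundle = 22L,
                                 geometry_jitter_sd = sdn,
                                 outlier_fraction = 2 / 22,
                                 outlier_displacement_sd = 10 * sdn,
                                 seed = 17L))
  for (b in bs$bundles) {
    cleaned <- clean_bundle(b$streamlines, sd_threshold = 3)
    expect_identical(attr(cleaned, "removed"), b$outlier_idx)
  }
})

test_that("cleaning is invariant to order and rigid motion", {
  bs <- make_bundles(bundle_spec(n_bundles = 1L, streamlines_per_bundle = 22L,
                                 geometry_jitter_sd = 0.5,
                                 outlier_fraction = 2 / 22,
                                 outlier_displacement_sd = 5, seed = 23L))
  sl <- bs$bundles[[1]]$streamlines
  removed <- attr(clean_bundle(sl), "removed")
  ## permutation of streamline order
  perm <- rev(seq_along(sl))
  removed_perm <- attr(clean_bundle(sl[perm]), "removed")
  expect_setequal(perm[removed_perm], removed)
  ## global rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- lapply(sl, function(p) sweep(p %*% t(R), 2, c(5, -3, 11), `+`))
  expect_identical(attr(clean_bundle(moved), "removed"), removed)
})

test_that("all-outlier bundles are flagged invalid", {
  base <- straight_line(c(0, 0, 0), c(10, 0, 0))
  sl <- list(base, sweep(base, 2, c(0, 100, 0), `+`),
             sweep(base, 2, c(0, -100, 0), `+`), sweep(base, 2, c(0, 0, 90), `+`))
  out <- clean_bundle(sl)
  expect_false(attr(out, "valid"))
})

test_that("profiles reproduce constants, curves and use the median", {
  vol_c <- vm_volume(array(4.2, c(10, 10, 10)), 2)
  sl <- lapply(1:7, function(i) straight_line(c(1, 1, 1), c(17, 15, 13)))
  prof <- extract_profile(sl, list(m = vol_c))
  expect_equal(prof$m, rep(4.2, 20), tolerance = 1e-12)
  ## linear-in-x volume: trilinear sampling is exact for linear fields
  vx <- 2
  xs <- (seq_len(10) - 1) * vx
  vol_l <- vm_volume(array(rep(xs, times = 100), c(10, 10, 10)), vx)
  sl2 <- list(straight_line(c(2, 4, 4), c(16, 12, 12)))
  prof2 <- extract_profile(sl2, list(x = vol_l))
  nodes <- resample_equidistant(sl2[[1]], 20L)
  expect_equal(prof2$x, nodes[, 1], tolerance = 1e-10)
  ## median across streamlines: one aberrant streamline cannot move it
  bs <- make_bundles(bundle_spec(n_bundles = 1L, streamlines_per_bundle = 11L,
                                 node_noise_sd = c(dr2 = 0, ndi = 0, odi = 0),
                                 seed = 3L))
  b <- bs$bundles[[1]]
  met <- b$metrics
  met[1, , "dr2"] <- met[1, , "dr2"] + 1000
  prof3 <- profile_from_bundle(list(metrics = met,
                                    relative_distance = b$relative_distance))
  truth <- default_depth_models()$dr2
  expect_equal(prof3$dr2,
               truth[["A"]] * exp(-truth[["b"]] * b$relative_distance) + truth[["c"]],
               tolerance = 1e-10)
  ## duplicating every streamline leaves the median profile unchanged
  met2 <- met[rep(seq_len(11), each = 2), , ]
  prof4 <- profile_from_bundle(list(metrics = met2,
                                    relative_distance = b$relative_distance))
  expect_equal(prof4$dr2, prof3$dr2, tolerance = 1e-12)
})

test_that("out-of-volume nodes fall back to nearest voxel with a flag", {
  vol <- vm_volume(array(1:8, c(2, 2, 2)), 1)
  sl <- list(straight_line(c(-5, 0, 0), c(6, 1, 1)))
  prof <- extract_profile(sl, list(v = vol))
  expect_gt(attr(prof, "n_oob"), 0)
  expect_true(all(is.finite(prof$v)))
})

test_that("relative distance is 0% at the cortex and 100% at the midline", {
  s <- straight_line(c(19, 0, 0), c(0, 0, 0), 20L)
  rd <- relative_distance(list(s), midsagittal_x = 0)
  expect_equal(rd$per_node, 100 * (0:19) / 19, tolerance = 1e-10)
  ## curved streamline: proportional to arc length (dense oracle)
  th <- seq(0, 0.55 * pi, length.out = 5000)
  curved <- cbind(10 * cos(th), 10 * sin(th), 0)   # x: 10 -> past 0
  nodes <- resample_equidistant(curved, 20L)
  rd2 <- relative_distance(list(nodes), midsagittal_x = 0)
  ## circle oracle: equal chords subtend equal arcs, so node i sits at arc
  ## (i/19) * R * 0.55 pi while the plane crossing is at arc R * pi/2
  expected <- 100 * (0:19) / 19 * (0.55 * pi) / (pi / 2)
  expect_equal(rd2$per_node, expected, tolerance = 1e-3)
  ## streamline never crossing the plane is excluded and flagged
  far <- straight_line(c(30, 0, 0), c(10, 0, 0), 20L)
  rd3 <- relative_distance(list(s, far), midsagittal_x = 0)
  expect_identical(rd3$excluded, 2L)
  expect_true(all(is.na(rd3$per_streamline[2, ])))
  expect_equal(rd3$per_node, 100 * (0:19) / 19, tolerance = 1e-10)
})
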