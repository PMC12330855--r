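## analytic shapes on a 1 mm grid
make_vol <- function(f, n = 41L, vx = 1) {
  ax <- (seq_len(n) - 1) * vx
  ctr <- ax[(n + 1) / 2]
  g <- expand.grid(x = ax, y = ax, z = ax)
  vm_volume(array(f(g$x - ctr, g$y - ctr, g$z - ctr), c(n, n, n)), vx)
}

test_that("constant volumes have zero eigenvalues and zero response", {
  vol <- vm_volume(array(7, c(16, 16, 16)), 1)
  ev <- hessian_eigenvalues(vol, 2)
  expect_lt(max(abs(ev$l1), abs(ev$l2), abs(ev$l3)), 1e-10)
  vmap <- frangi(vol, frangi_params(sigmas_mm = c(1, 2)))
  expect_equal(max(vmap$response$data), 0)
})

test_that("a ridge along z has a near-zero axial eigenvalue on its axis", {
  ## value varies only in (x, y): translational symmetry along z
  vol <- make_vol(function(x, y, z) exp(-(x^2 + y^2) / 8))
  ev <- hessian_eigenvalues(vol, 2)
  ctr <- 21
  ## on-axis Hessian is diag(hxx, hyy, ~0); smallest |eigenvalue| ~ 0
  expect_lt(abs(ev$l1[ctr, ctr, ctr]), 1e-8)
  expect_lt(ev$l3[ctr, ctr, ctr], 0)           # bright ridge: negative
})

test_that("Gaussian-cylinder eigenvalues match the closed form within 2%", {
  ## I = exp(-(x^2+y^2)/(2 w^2)); Gaussian smoothing at sigma gives
  ## amplitude w^2/(w^2+s^2) and on-axis second derivative -amp/(w^2+s^2);
  ## gamma normalization multiplies by s^2 (symbolic oracle)
  w <- 3; s <- 2
  vol <- make_vol(function(x, y, z) exp(-(x^2 + y^2) / (2 * w^2)))
  ev <- hessian_eigenvalues(vol, s)
  ctr <- 21
  expected <- -s^2 * w^2 / (w^2 + s^2)^2
  expect_equal(ev$l2[ctr, ctr, ctr], expected, tolerance = 0.02)
  expect_equal(ev$l3[ctr, ctr, ctr], expected, tolerance = 0.02)
  expect_lt(abs(ev$l1[ctr, ctr, ctr]), 1e-6)
})

test_that("a dark cylinder is detected and its best scale matches a scan", {
  r <- 2
  vol <- make_vol(function(x, y, z) ifelse(x^2 + y^2 <= r^2, 0, 100), n = 41L)
  sig <- c(1, 2, 3, 4)
  vmap <- frangi(vol, frangi_params(sigmas_mm = sig, polarity = "dark_tubes"))
  ctr <- 21
  axis_resp <- vmap$response$data[ctr, ctr, 5:37]
  bg <- vmap$response$data[3:10, 3:10, 3:10]
  expect_gt(min(axis_resp), 10 * (stats::median(bg) + 1e-12))
  ## oracle: exhaustive per-scale scan of the on-axis response
  per_scale <- vapply(sig, function(s) {
    m <- frangi(vol, frangi_params(sigmas_mm = s, polarity = "dark_tubes"))
    m$response$data[ctr, ctr, ctr]
  }, numeric(1))
  expect_equal(vmap$best_scale$data[ctr, ctr, ctr], sig[which.max(per_scale)])
  expect_equal(vmap$response$data[ctr, ctr, ctr], max(per_scale))
  ## response lives in [0, 1]
  expect_true(all(vmap$response$data >= 0 & vmap$response$data <= 1))
})

test_that("a sphere is suppressed relative to a cylinder at matched scale", {
  r <- 2
  cyl <- make_vol(function(x, y, z) ifelse(x^2 + y^2 <= r^2, 0, 100), n = 33L)
  sph <- make_vol(function(x, y, z) ifelse(x^2 + y^2 + z^2 <= r^2, 0, 100), n = 33L)
  ctr <- 17
  p <- frangi_params(sigmas_mm = 2, polarity = "dark_tubes", gamma = 50)
  resp_c <- frangi(cyl, p)$response$data[ctr, ctr, ctr]
  resp_s <- frangi(sph, p)$response$data[ctr, ctr, ctr]
  expect_gt(resp_c, resp_s)
})

test_that("response is offset-invariant and flips with polarity", {
  vol <- make_vol(function(x, y, z) ifelse(x^2 + y^2 <= 4, 0, 100), n = 25L)
  p <- frangi_params(sigmas_mm = c(1.5, 2.5), gamma = 50)
  a <- frangi(vol, p)$response$data
  b <- frangi(vm_volume(vol$data + 55, vol$voxel_size_mm), p)$response$data
  expect_equal(a, b, tolerance = 1e-6)
  neg <- vm_volume(-vol$data, vol$voxel_size_mm)
  c_ <- frangi(neg, frangi_params(sigmas_mm = c(1.5, 2.5), gamma = 50,
                                  polarity = "bright_tubes"))$response$data
  expect_equal(a, c_, tolerance = 1e-12)
})

test_that("mask statistics behave and are monotone in the threshold", {
  vol <- make_vol(function(x, y, z) ifelse(x^2 + y^2 <= 4, 0, 100), n = 25L)
  vmap <- frangi(vol, frangi_params(sigmas_mm = c(1.5, 2.5)))
  roi <- array(TRUE, dim(vol$data))
  s1 <- vessel_mask_stats(vmap, 0.2, roi)
  s2 <- vessel_mask_stats(vmap, 0.5, roi)
  s3 <- vessel_mask_stats(vmap, 0.9, roi)
  expect_true(s1$vessel_volume_mm3 >= s2$vessel_volume_mm3)
  expect_true(s2$vessel_volume_mm3 >= s3$vessel_volume_mm3)
  expect_equal(s1$fraction_of_roi, s1$n_vessel_voxels / sum(roi))
  ## threshold 1.0 against a strictly-sub-1 response: empty mask
  expect_lt(max(vmap$response$data), 1)
  s4 <- vessel_mask_stats(vmap, 1.0, roi)
  expect_equal(s4$vessel_volume_mm3, 0)
  expect_equal(s4$fraction_of_roi, 0)
  expect_error(vessel_mask_stats(vmap, 0.5, array(FALSE, dim(vol$data))),
               "empty ROI")
  expect_error(vessel_mask_stats(vmap, 0, roi), "threshold")
})

test_that("phantom vessel volume is recovered within 25% at the Youden threshold", {
  ## resolvable-vessel regime: radius 0.35 mm (~1.5 voxels); sub-voxel
  ## cylinders cannot be quantified volumetrically by any Hessian filter
  ph <- make_cortical_phantom(test_phantom_spec(vessel_radius_mm = 0.35,
                                                vessel_density_gm = 0.3,
                                                vessel_density_swm = 0.1,
                                                seed = 13L))
  mean_post <- average_echoes(ph$post_echoes)
  vx <- ph$spec$voxel_size_mm
  vmap <- frangi(mean_post, frangi_params(sigmas_mm = c(0.25, 0.35, 0.5)))
  roi <- ph$tissue_labels$data > 0
  truth <- ph$vessel_mask$data & roi
  ## Youden threshold against ground truth (oracle: generator mask)
  ths <- c(seq(0.005, 0.1, by = 0.005), seq(0.15, 0.95, by = 0.05))
  youden <- vapply(ths, function(t) {
    m <- vmap$response$data >= t & roi
    tpr <- sum(m & truth) / sum(truth)
    fpr <- sum(m & !truth & roi) / sum(!truth & roi)
    tpr - fpr
  }, numeric(1))
  thr <- ths[which.max(youden)]
  got <- vessel_mask_stats(vmap, thr, roi)
  true_vol <- sum(truth) * vx^3
  expect_lt(abs(got$vessel_volume_mm3 - true_vol) / true_vol, 0.25)
})

test_that("parameter validation and small-sigma warning fire", {
  expect_error(frangi_params(sigmas_mm = numeric(0)), "empty")
  expect_error(frangi_params(alpha = 0), "alpha")
  vol <- vm_volume(array(rnorm(8^3), c(8, 8, 8)), 1)
  expect_warning(hessian_eigenvalues(vol, 0.3), "half a voxel")
})
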