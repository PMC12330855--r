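test_that("noise-free bundles carry the exact model curves at the nodes", {
  sp <- bundle_spec(n_bundles = 2L, streamlines_per_bundle = 5L,
                    node_noise_sd = c(dr2 = 0, ndi = 0, odi = 0), seed = 3L)
  bs <- make_bundles(sp)
  d <- bs$bundles[[1]]$relative_distance
  for (m in c("dr2", "ndi", "odi")) {
    truth <- sp$depth_models[[m]][["A"]] * exp(-sp$depth_models[[m]][["b"]] * d) +
      sp$depth_models[[m]][["c"]]
    for (s in 1:5) {
      expect_equal(unname(bs$bundles[[1]]$metrics[s, , m]), truth,
                   tolerance = 1e-12)
    }
  }
  ## group-level Delta-R2* model value at the white surface: 11.64 + 19.13
  expect_equal(unname(bs$bundles[[1]]$metrics[1, 1, "dr2"]), 30.77,
               tolerance = 1e-10)
})

test_that("streamlines run from the cortex to the midsagittal plane", {
  bs <- make_bundles(bundle_spec(n_bundles = 3L, streamlines_per_bundle = 8L,
                                 geometry_jitter_sd = 0, seed = 5L))
  for (b in bs$bundles) {
    for (s in b$streamlines) {
      expect_gt(s[1, 1], 30)                    # cortical end, lateral
      expect_lt(s[nrow(s), 1], 0)               # crosses the midline plane
    }
  }
})

test_that("planted outliers are displaced by the stated deterministic norm", {
  sd_noise <- 0.4
  sp <- bundle_spec(n_bundles = 4L, streamlines_per_bundle = 22L,
                    geometry_jitter_sd = sd_noise,
                    outlier_fraction = 2 / 22, outlier_displacement_sd = 10 * sd_noise,
                    seed = 11L)
  bs <- make_bundles(sp)
  for (b in bs$bundles) {
    expect_length(b$outlier_idx, 2L)
  }
  ## check the offset magnitude on a jitter-free rebuild
  sp0 <- bundle_spec(n_bundles = 1L, streamlines_per_bundle = 10L,
                     geometry_jitter_sd = 0, outlier_fraction = 0.2,
                     outlier_displacement_sd = 4, seed = 2L)
  b0 <- make_bundles(sp0)$bundles[[1]]
  inl <- setdiff(seq_along(b0$streamlines), b0$outlier_idx)[1]
  for (o in b0$outlier_idx) {
    offset <- b0$streamlines[[o]] - b0$streamlines[[inl]]
    norms <- sqrt(rowSums(offset^2))
    expect_equal(norms, rep(sqrt(3) * 4, length(norms)), tolerance = 1e-9)
  }
})

test_that("per-node sample means converge to the model curve (LLN)", {
  sp <- bundle_spec(n_bundles = 1L, streamlines_per_bundle = 4000L,
                    node_noise_sd = c(dr2 = 0.5, ndi = 0.02, odi = 0.02),
                    outlier_fraction = 0, seed = 21L)
  bs <- make_bundles(sp)
  d <- bs$bundles[[1]]$relative_distance
  n <- sp$streamlines_per_bundle
  for (m in c("dr2", "ndi", "odi")) {
    truth <- sp$depth_models[[m]][["A"]] *
      exp(-sp$depth_models[[m]][["b"]] * d) + sp$depth_models[[m]][["c"]]
    means <- colMeans(bs$bundles[[1]]$metrics[, , m])
    se <- sp$node_noise_sd[[m]] / sqrt(n)
    ## per-node 3 SE across 63 node-metric cells would false-alarm ~16% of
    ## the time; use a familywise 4 SE bound plus an aggregate mean-bias
    ## check at 1 SE, which is more sensitive to systematic error
    expect_true(all(abs(means - truth) < 4 * se + 1e-12))
    expect_lt(abs(mean(means - truth)), se + 1e-12)
  }
})

test_that("identity-correlation parcel tables have near-zero cross-correlations", {
  eye <- diag(4)
  dimnames(eye) <- dimnames(default_parcel_correlations())
  sp <- parcel_table_spec(n_areas = 100000L, target_correlations = eye,
                          seed = 9L)
  pt <- make_parcel_table(sp)
  mets <- colnames(sp$target_correlations)
  cm <- stats::cor(as.matrix(pt[, mets]))
  expect_true(all(abs(cm[upper.tri(cm)]) < 0.01))
})

test_that("target correlation is recovered within the Fisher-z bound", {
  ## 1000 replicates at n = 103; oracle: Fisher z transform of r is
  ## approximately N(atanh(rho) + rho/(2(n-1)), 1/(n-3))
  n_rep <- 1000L
  rho <- 0.50
  zs <- vapply(seq_len(n_rep), function(i) {
    pt <- make_parcel_table(parcel_table_spec(seed = 1000L + i))
    atanh(stats::cor(pt$dr2_swm, pt$receptor))
  }, numeric(1))
  n <- 103
  se_mean <- (1 / sqrt(n - 3)) / sqrt(n_rep)
  bias <- rho / (2 * (n - 1))
  expect_lt(abs(mean(zs) - (atanh(rho) + bias)), 3 * se_mean + 0.003)
  ## single-sample r also lands inside the 95% Fisher interval on average
  expect_lt(abs(tanh(mean(zs)) - rho), tanh(1.96 / sqrt(n - 3)))
})

test_that("parcel spec validation enforces a proper correlation matrix", {
  R <- default_parcel_correlations()
  R[1, 2] <- 0.9                                # asymmetric
  expect_error(parcel_table_spec(target_correlations = R), "symmetric")
  R2 <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(parcel_table_spec(target_correlations = R2), "semidefinite")
  expect_equal(parcel_table_spec()$n_areas, 103L)
  expect_equal(nrow(make_parcel_table(parcel_table_spec(seed = 1L))), 103L)
})
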