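## Synthetic commissural-style bundles and parcel tables with known ground
## truth. Bundle node metrics follow the exponential depth-model family
## y(d) = A*exp(-b*d) + c in the positive-amplitude display convention,
## with d the relative distance (%) from the white-matter surface (0) to the
## midline (100). Defaults are the group-level models for Delta-R2*, NDI and
## ODI along commissural bundles.

#' Default group-level depth models
#'
#' Display-form triples (amplitude A, rate b per percent, offset c) of
#' `y(d) = A exp(-b d) + c`: Delta-R2* and ODI decay with depth, NDI grows
#' (negative amplitude).
#' @export
default_depth_models <- function() {
  list(dr2 = c(A = 11.64, b = 0.05, c = 19.13),
       ndi = c(A = -0.32, b = 0.01, c = 0.87),
       odi = c(A = 0.30, b = 0.02, c = 0.07))
}

eval_depth_model <- function(par, d) par[["A"]] * exp(-par[["b"]] * d) + par[["c"]]

#' Synthetic bundle specification
#'
#' @param n_bundles number of commissural bundles.
#' @param streamlines_per_bundle streamlines in each bundle.
#' @param nodes_per_streamline nodes per streamline (>= 2).
#' @param depth_models named list of display-form `(A, b, c)` triples for
#'   `dr2`, `ndi`, `odi`; see [default_depth_models()].
#' @param node_noise_sd named per-metric Gaussian noise sd on node values.
#' @param geometry_jitter_sd positional sd (mm) of within-bundle streamline
#'   scatter (independent per node).
#' @param outlier_fraction fraction of streamlines displaced as outliers.
#' @param outlier_displacement_sd displacement scale (mm): each outlier is
#'   offset by a random direction with fixed magnitude
#'   `sqrt(3) * outlier_displacement_sd` (the RMS norm of an isotropic
#'   Gaussian with that sd), so a "10 x SD" plant is deterministic in size.
#' @param seed integer seed.
#' @return a `bundle_spec` list.
#' @export
bundle_spec <- function(n_bundles = 10L,
                        streamlines_per_bundle = 30L,
                        nodes_per_streamline = 21L,
                        depth_models = default_depth_models(),
                        node_noise_sd = c(dr2 = 0.5, ndi = 0.02, odi = 0.02),
                        geometry_jitter_sd = 0.5,
                        outlier_fraction = 0,
                        outlier_displacement_sd = 5,
                        seed = 1L) {
  if (nodes_per_streamline < 2L) stopf("nodes_per_streamline must be >= 2")
  if (any(node_noise_sd < 0)) stopf("node noise sd must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stopf("outlier_fraction must be in [0, 1)")
  }
  structure(list(n_bundles = as.integer(n_bundles),
                 streamlines_per_bundle = as.integer(streamlines_per_bundle),
                 nodes_per_streamline = as.integer(nodes_per_streamline),
                 depth_models = depth_models,
                 node_noise_sd = node_noise_sd,
                 geometry_jitter_sd = geometry_jitter_sd,
                 outlier_fraction = outlier_fraction,
                 outlier_displacement_sd = outlier_displacement_sd,
                 seed = as.integer(seed)), class = "bundle_spec")
}

#' Generate synthetic commissural bundles
#'
#' Each streamline is a smooth 3-D polyline from a cortical endpoint to the
#' midsagittal plane (x = 0); per-node metrics are the depth models
#' evaluated at the node's relative distance plus Gaussian noise; a stated
#' fraction of streamlines are rigidly displaced outliers whose indices are
#' recorded for cleaning tests.
#'
#' @param spec a [bundle_spec()].
#' @return a `bundle_set`: list of bundles, each with `name`, `streamlines`
#'   (list of n x 3 matrices, cortical end first), `metrics` (streamline x
#'   node x metric array), `relative_distance` (per node, %), and
#'   `outlier_idx`; plus the generating spec and truth parameters.
#' @export
make_bundles <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  n_nodes <- spec$nodes_per_streamline
  dists <- seq(0, 100, length.out = n_nodes)
  metrics <- names(spec$depth_models)
  seeds <- derive_seeds(spec$seed, spec$n_bundles)
  bundles <- vector("list", spec$n_bundles)
  for (b in seq_len(spec$n_bundles)) {
    bundles[[b]] <- local_seed(seeds[b], {
      ## bundle trunk: cortical endpoint in lateral white matter, curving
      ## to the midline; quadratic Bezier control point bends the path
      p0 <- c(40, stats::runif(1, -30, 30), stats::runif(1, -10, 30))
      ## overshoot the midsagittal plane slightly so every streamline
      ## robustly crosses it even after node jitter
      p2 <- c(-0.8, p0[2] * 0.3, stats::runif(1, -5, 10))
      p1 <- c(20, p0[2] * 0.7, p2[3] + stats::runif(1, 5, 15))
      tt <- seq(0, 1, length.out = n_nodes)
      trunk <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) +
               outer(tt^2, p2)
      ## unit tangents of the trunk (central differences) for transverse
      ## jitter: noise along the trunk would perturb each streamline's arc
      ## length coherently and reappear after equidistant resampling as a
      ## whole-streamline shift
      tang <- rbind(trunk[2, ] - trunk[1, ],
                    (trunk[-(1:2), , drop = FALSE] -
                       trunk[seq_len(n_nodes - 2L), , drop = FALSE]) / 2,
                    trunk[n_nodes, ] - trunk[n_nodes - 1L, ])
      tang <- tang / sqrt(rowSums(tang^2))
      n_sl <- spec$streamlines_per_bundle
      n_out <- round(spec$outlier_fraction * n_sl)
      out_idx <- if (n_out > 0) sort(sample.int(n_sl, n_out)) else integer(0)
      sl <- vector("list", n_sl)
      met <- array(NA_real_, c(n_sl, n_nodes, length(metrics)),
                   dimnames = list(NULL, NULL, metrics))
      for (s in seq_len(n_sl)) {
        ## scatter is independent node-level noise projected onto the plane
        ## transverse to the trunk: correlated (whole-streamline or
        ## along-trunk) components would defeat the node-averaged outlier
        ## score that separates planted outliers from coherent streamlines
        eps <- matrix(stats::rnorm(n_nodes * 3, 0, spec$geometry_jitter_sd),
                      n_nodes, 3)
        eps <- eps - rowSums(eps * tang) * tang
        pts <- trunk + eps
        if (s %in% out_idx) {
          u <- unit_vector(stats::rnorm(3))
          pts <- sweep(pts, 2, u * sqrt(3) * spec$outlier_displacement_sd, `+`)
        }
        sl[[s]] <- pts
        for (m in metrics) {
          y <- eval_depth_model(spec$depth_models[[m]], dists)
          sdm <- spec$node_noise_sd[[m]]
          if (sdm > 0) y <- y + stats::rnorm(n_nodes, 0, sdm)
          if (m %in% c("ndi", "odi")) y <- pmin(pmax(y, 0), 1)
          met[s, , m] <- y
        }
      }
      list(name = sprintf("bundle%02d", b), streamlines = sl, metrics = met,
           relative_distance = dists, outlier_idx = out_idx)
    })
  }
  structure(list(bundles = bundles, spec = spec,
                 truth = spec$depth_models), class = "bundle_set")
}

#' Parcel-table specification
#'
#' @param n_areas number of retained cortical areas (103 matches a
#'   Julich-style parcellation after exclusions; 87 per hemisphere matches
#'   an M132-style layout).
#' @param target_correlations symmetric positive-semidefinite correlation
#'   matrix over the metrics (unit diagonal).
#' @param means,sds named per-metric location and scale.
#' @param seed integer seed.
#' @export
parcel_table_spec <- function(n_areas = 103L,
                              target_correlations = default_parcel_correlations(),
                              means = c(dr2_swm = 25, neuron = 100,
                                        receptor = 1000, myelin = 1.5),
                              sds = c(dr2_swm = 5, neuron = 30,
                                      receptor = 200, myelin = 0.3),
                              seed = 1L) {
  R <- as.matrix(target_correlations)
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-8)) {
    stopf("target_correlations must be symmetric with unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stopf("target_correlations is not positive semidefinite")
  structure(list(n_areas = as.integer(n_areas), target_correlations = R,
                 means = means, sds = sds, seed = as.integer(seed)),
            class = "parcel_table_spec")
}

#' Default cross-metric correlation targets
#'
#' Off-diagonal structure patterned on reported parcel-level relationships:
#' superficial-WM Delta-R2* correlates moderately with overlying receptor
#' density (r = 0.50), weakly with myelin (r ~ 0.32, R^2 ~ 0.10) and
#' negligibly with neuron density (r ~ 0.10, R^2 ~ 0.01).
#' @export
default_parcel_correlations <- function() {
  m <- c("dr2_swm", "neuron", "receptor", "myelin")
  R <- diag(4)
  dimnames(R) <- list(m, m)
  R["dr2_swm", "neuron"] <- R["neuron", "dr2_swm"] <- 0.10
  R["dr2_swm", "receptor"] <- R["receptor", "dr2_swm"] <- 0.50
  R["dr2_swm", "myelin"] <- R["myelin", "dr2_swm"] <- 0.32
  R["neuron", "receptor"] <- R["receptor", "neuron"] <- 0.30
  R["neuron", "myelin"] <- R["myelin", "neuron"] <- 0.20
  R["receptor", "myelin"] <- R["myelin", "receptor"] <- 0.30
  R
}

#' Generate a synthetic parcel table
#'
#' Draws `n_areas` joint samples from a Gaussian copula with the target
#' correlation matrix (Gaussian marginals, so a multivariate normal), then
#' rescales each metric to its stated mean and sd.
#'
#' @param spec a [parcel_table_spec()].
#' @return a data.frame: `area`, `hemisphere`, one column per metric.
#' @export
make_parcel_table <- function(spec) {
  stopifnot(inherits(spec, "parcel_table_spec"))
  R <- spec$target_correlations
  p <- ncol(R)
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  Z <- local_seed(spec$seed, matrix(stats::rnorm(spec$n_areas * p),
                                    spec$n_areas, p)) %*% t(L)
  mets <- colnames(R)
  out <- data.frame(area = sprintf("area%03d", seq_len(spec$n_areas)),
                    hemisphere = "L", stringsAsFactors = FALSE)
  for (j in seq_along(mets)) {
    out[[mets[j]]] <- spec$means[[mets[j]]] + spec$sds[[mets[j]]] * Z[, j]
  }
  attr(out, "spec") <- spec
  out
}
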