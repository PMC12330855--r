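## Shared fixtures. Phantoms are expensive, so one noise-free phantom is
## built lazily and shared across test files (same R process under
## test_dir). All generators are seeded; nothing touches the global RNG.

.fixture_env <- new.env(parent = emptyenv())

test_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(40L, 40L, 40L), wavelength_mm = 8,
         amplitude_mm = 1.5, noise_sd = 0, seed = 7L),
    list(...))
  do.call(phantom_spec, args)
}

cached_phantom <- function() {
  if (is.null(.fixture_env$phantom)) {
    .fixture_env$phantom <- make_cortical_phantom(test_phantom_spec())
  }
  .fixture_env$phantom
}

## dense-microvasculature regime: statistical power for orientation-bias
## fits needs many vessels per surface (no vesselness filtering involved)
cached_dense_phantom <- function() {
  if (is.null(.fixture_env$dense_phantom)) {
    .fixture_env$dense_phantom <- make_cortical_phantom(
      test_phantom_spec(vessel_density_gm = 3, vessel_density_swm = 0.6))
  }
  .fixture_env$dense_phantom
}

## flat horizontal sheet meshes at height z0 over an n x n grid
flat_sheet <- function(n = 8L, spacing = 1, z0 = 0) {
  xs <- (seq_len(n) - 1) * spacing
  vasculomap:::sheet_mesh(xs, xs, function(x) rep(z0, length(x)),
                          function(x) rep(0, length(x)))
}

## analytic surface normal of the phantom's white sheet at given x
phantom_normal_at <- function(spec, x) {
  d <- spec$amplitude_mm * 2 * pi / spec$wavelength_mm *
    cos(2 * pi * x / spec$wavelength_mm)
  cbind(-d, 0, 1) / sqrt(1 + d^2)
}

## all permutations of 1..n (small n), one per row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}
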