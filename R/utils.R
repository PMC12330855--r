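#' @keywords internal
"_PACKAGE"

## RNG hygiene: every stochastic entry point takes an integer seed and runs
## under an isolated RNG state, so library calls never disturb (or depend on)
## the caller's .Random.seed.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

## spawn a stream of sub-seeds from one master seed (keeps them < 2^31)
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

unit_vector <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stopf("zero vector cannot be normalized")
  v / nv
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Pearson r without the cor() NA ceremony; returns NA for zero variance
pearson_r <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  mean((x - mean(x)) * (y - mean(y))) / (sx * sy) * length(x) / (length(x) - 1L)
}
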