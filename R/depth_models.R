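## Exponential depth models along white-matter bundles and alternatives
## (linear, quadratic, logistic), compared by small-sample information
## criteria. Internal parameterization keeps the y = -a*exp(-b*d) + c
## convention (d = relative distance in %, so rates print per percent); the
## reporting layer uses the positive-amplitude display form
## y = A*exp(-b*d) + c with A = -a, matching how fitted curves are usually
## printed for decaying metrics.

depth_fit <- function(family, params, d, y, fitted, k, flagged = NULL) {
  rss <- sum((y - fitted)^2)
  n <- length(y)
  kp <- k + 1L                                  # + noise variance
  ll_term <- n * log(max(rss, .Machine$double.xmin) / n)
  aic <- ll_term + 2 * kp
  bic <- ll_term + kp * log(n)
  aicc <- if (n - kp - 1 > 0) aic + 2 * kp * (kp + 1) / (n - kp - 1) else NA_real_
  sst <- sum((y - mean(y))^2)
  structure(list(family = family, params = params, rss = rss, n = n, k = k,
                 aic = aic, aicc = aicc, bic = bic,
                 r_squared = if (sst > 0) 1 - rss / sst else NA_real_,
                 fitted = fitted, d = d, y = y, flagged = flagged),
            class = "depth_fit")
}

## linear LS of y on [exp(-b d), 1]; returns coef, offset, rss
varpro_exp <- function(b, d, y) {
  e <- exp(-b * d)
  X <- cbind(e, 1)
  xtx <- crossprod(X)
  if (rcond_2x2(xtx) < 1e-13) {
    ## basis collinear (b ~ 0 or huge): offset-only fit
    return(list(coef = 0, offset = mean(y), rss = sum((y - mean(y))^2),
                degenerate = TRUE))
  }
  beta <- solve(xtx, crossprod(X, y))
  r <- y - X %*% beta
  list(coef = beta[1], offset = beta[2], rss = sum(r^2), degenerate = FALSE)
}

rcond_2x2 <- function(m) {
  e <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(e) <= 0) 0 else max(min(e), 0) / max(e)
}

#' Fit the exponential depth model
#'
#' Nonlinear least squares for `y = -a exp(-b d) + c` by variable
#' projection: for each candidate rate `b` the amplitude and offset are the
#' exact linear solution, and the profiled RSS is minimized over `b > 0`
#' (multi-start grid including 0.005, 0.01, 0.02, 0.05, 0.1 per %, then
#' golden-section refinement). The amplitude sign is free, so both decaying
#' and growing profiles are representable.
#'
#' @param d relative distances in % (0--100), at least 4 points.
#' @param y metric values at the nodes.
#' @return a `depth_fit` with `params = c(a, b, c)` (internal convention)
#'   and `display = c(A, b, c)` with `A = -a` (positive for decay);
#'   `flagged = "unidentifiable_rate"` when the data are constant.
#' @export
fit_exponential <- function(d, y) {
  if (length(d) < 4L) stopf("need at least 4 points")
  if (any(d < 0 | d > 100)) stopf("relative distance must be within [0, 100]")
  if (stats::var(y) == 0) {
    fit <- depth_fit("exponential", c(a = 0, b = NA_real_, c = y[1]),
                     d, y, rep(y[1], length(y)), k = 3L,
                     flagged = "unidentifiable_rate")
    fit$display <- c(A = 0, b = NA_real_, c = y[1])
    return(fit)
  }
  grid <- sort(unique(c(0.005, 0.01, 0.02, 0.05, 0.1,
                        10^seq(-4, 0, length.out = 25))))
  rsss <- vapply(grid, function(b) varpro_exp(b, d, y)$rss, numeric(1))
  i <- which.min(rsss)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(b) varpro_exp(b, d, y)$rss,
                         lower = lo, upper = hi, tol = 1e-12)
  b <- opt$minimum
  sol <- varpro_exp(b, d, y)
  flagged <- if (sol$degenerate) "unidentifiable_rate" else NULL
  a <- -sol$coef
  cc <- sol$offset
  fitted <- -a * exp(-b * d) + cc
  fit <- depth_fit("exponential", c(a = a, b = b, c = cc), d, y, fitted,
                   k = 3L, flagged = flagged)
  fit$display <- c(A = -a, b = b, c = cc)
  fit
}

#' Fit the alternative depth-model families
#'
#' Linear and quadratic by closed-form least squares; logistic
#' `y = L / (1 + exp(-r (d - d0)))` (3 free parameters, no separate offset —
#' the family is compared at equal complexity with the exponential) by
#' variable projection over `(d0, r)` with Nelder-Mead multi-start and BFGS
#' polish.
#'
#' @param d,y as in [fit_exponential()].
#' @param families subset of `c("linear", "quadratic", "logistic")`.
#' @return named list of `depth_fit`s.
#' @export
fit_alternatives <- function(d, y, families = c("linear", "quadratic", "logistic")) {
  out <- list()
  if ("linear" %in% families) {
    X <- cbind(1, d)
    beta <- solve(crossprod(X), crossprod(X, y))
    out$linear <- depth_fit("linear", c(intercept = beta[1], slope = beta[2]),
                            d, y, as.numeric(X %*% beta), k = 2L)
  }
  if ("quadratic" %in% families) {
    X <- cbind(1, d, d^2)
    beta <- solve(crossprod(X), crossprod(X, y))
    out$quadratic <- depth_fit("quadratic",
                               c(intercept = beta[1], slope = beta[2],
                                 quad = beta[3]),
                               d, y, as.numeric(X %*% beta), k = 3L)
  }
  if ("logistic" %in% families) {
    prof <- function(p) {                        # p = (d0, r)
      phi <- 1 / (1 + exp(-p[2] * (d - p[1])))
      den <- sum(phi^2)
      if (den < 1e-300) return(list(rss = sum((y - mean(y))^2), L = 0, phi = phi))
      L <- sum(phi * y) / den
      list(rss = sum((y - L * phi)^2), L = L, phi = phi)
    }
    obj <- function(p) prof(p)$rss
    starts <- expand.grid(d0 = c(25, 50, 75), r = c(-0.1, -0.02, 0.02, 0.1))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- stats::optim(as.numeric(starts[s, ]), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
      o <- stats::optim(o$par, obj, method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 500))
      if (is.null(best) || o$value < best$value) best <- o
    }
    pr <- prof(best$par)
    fitted <- pr$L / (1 + exp(-best$par[2] * (d - best$par[1])))
    out$logistic <- depth_fit("logistic",
                              c(asymptote = pr$L, midpoint = best$par[1],
                                rate = best$par[2]),
                              d, y, fitted, k = 3L)
  }
  out
}

#' Compare fitted depth models by AICc and BIC
#'
#' Gaussian-likelihood criteria with the noise variance counted as a free
#' parameter: `AIC = n ln(RSS/n) + 2 k'`, `BIC = n ln(RSS/n) + k' ln n`,
#' `AICc = AIC + 2 k'(k'+1)/(n-k'-1)`, `k' = k + 1`. Winners minimize each
#' criterion; exact ties are reported.
#'
#' @param fits named list of `depth_fit`s on identical data.
#' @return a `model_comparison`: `table` (family, k, rss, aic, aicc, bic),
#'   `winner_aicc`, `winner_bic`, `delta_aicc`, `delta_bic`, `ties`.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2L) stopf("need at least two fits to compare")
  n0 <- fits[[1]]$n
  y0 <- fits[[1]]$y
  for (f in fits) {
    if (f$n != n0 || !isTRUE(all.equal(f$y, y0))) {
      stopf("all fits must be on identical data")
    }
  }
  tab <- data.frame(family = vapply(fits, `[[`, "", "family"),
                    k = vapply(fits, `[[`, 0L, "k"),
                    rss = vapply(fits, `[[`, 0, "rss"),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    aicc = vapply(fits, `[[`, 0, "aicc"),
                    bic = vapply(fits, `[[`, 0, "bic"),
                    row.names = NULL)
  if (any(is.na(tab$aicc))) {
    warnf("AICc undefined for some fits (n <= k'+1)")
  }
  win <- function(v) {
    i <- which(v == min(v, na.rm = TRUE))
    tab$family[i]
  }
  wa <- win(tab$aicc); wb <- win(tab$bic)
  structure(list(table = tab,
                 winner_aicc = wa[1], winner_bic = wb[1],
                 delta_aicc = tab$aicc - min(tab$aicc, na.rm = TRUE),
                 delta_bic = tab$bic - min(tab$bic, na.rm = TRUE),
                 ties = list(aicc = wa, bic = wb)),
            class = "model_comparison")
}
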