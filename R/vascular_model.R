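## Forward stepwise nonlinear regression predicting node-wise Delta-R2*
## from NDI and ODI (linear terms) and relative distance (exponential term
## A*exp(-r*d), no separate offset — the model intercept plays that role),
## selected by BIC and validated by leave-one-bundle-out cross-validation.
## Observations are (bundle, node) pairs; no autocorrelation correction.

#' Assemble a predictor set
#'
#' @param bundle bundle identifier per observation.
#' @param ndi,odi,relative_distance,dr2 numeric vectors per observation
#'   (relative distance in %, response Delta-R2* in 1/s).
#' @return a complete-cases data.frame of class `predictor_set`.
#' @export
predictor_set <- function(bundle, ndi, odi, relative_distance, dr2) {
  df <- data.frame(bundle = as.character(bundle), ndi = ndi, odi = odi,
                   relative_distance = relative_distance, dr2 = dr2,
                   stringsAsFactors = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  class(df) <- c("predictor_set", "data.frame")
  df
}

## fit one model form; terms is a character subset of
## c("ndi", "odi", "exp_distance"); intercept always included
fit_term_model <- function(data, terms) {
  y <- data$dr2
  n <- length(y)
  lin <- intersect(terms, c("ndi", "odi"))
  X0 <- cbind(intercept = rep(1, n))
  for (t in lin) X0 <- cbind(X0, data[[t]])
  colnames(X0) <- c("intercept", lin)
  has_exp <- "exp_distance" %in% terms
  solve_lin <- function(X) {
    xtx <- crossprod(X)
    beta <- tryCatch(solve(xtx, crossprod(X, y)), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    list(beta = as.numeric(beta), rss = sum((y - X %*% beta)^2))
  }
  if (!has_exp) {
    sol <- solve_lin(X0)
    if (is.null(sol)) return(NULL)
    beta <- stats::setNames(sol$beta, colnames(X0))
    k <- ncol(X0)
    pred_fun <- function(nd) {
      out <- rep(beta[["intercept"]], nrow(nd))
      for (t in lin) out <- out + beta[[t]] * nd[[t]]
      out
    }
    rss <- sol$rss
    rate <- NULL
  } else {
    d <- data$relative_distance
    rss_of <- function(r) {
      s <- solve_lin(cbind(X0, exp_distance = exp(-r * d)))
      if (is.null(s)) Inf else s$rss
    }
    grid <- c(0.005, 0.01, 0.02, 0.05, 0.1, 10^seq(-4, 0, length.out = 17))
    grid <- sort(unique(grid))
    rsss <- vapply(grid, rss_of, numeric(1))
    i <- which.min(rsss)
    opt <- stats::optimize(rss_of, lower = grid[max(1, i - 1)],
                           upper = grid[min(length(grid), i + 1)], tol = 1e-10)
    rate <- opt$minimum
    sol <- solve_lin(cbind(X0, exp_distance = exp(-rate * d)))
    if (is.null(sol)) return(NULL)
    beta <- stats::setNames(sol$beta, c(colnames(X0), "exp_distance"))
    k <- ncol(X0) + 2L                           # amplitude + rate
    pred_fun <- function(nd) {
      out <- rep(beta[["intercept"]], nrow(nd))
      for (t in lin) out <- out + beta[[t]] * nd[[t]]
      out + beta[["exp_distance"]] * exp(-rate * nd$relative_distance)
    }
    rss <- sol$rss
  }
  kp <- k + 1L                                   # + noise variance
  list(terms = terms, coefficients = beta, rate = rate, rss = rss, n = n,
       k = k, bic = n * log(max(rss, .Machine$double.xmin) / n) + kp * log(n),
       predict = pred_fun)
}

#' Forward stepwise model selection by BIC
#'
#' Starts from the intercept-only model; at each step every unused
#' candidate (`ndi`, `odi`, `exp_distance`, tried in that order — ties go
#' to the earlier candidate) is added and the full model refit by nonlinear
#' least squares (the exponential rate is re-optimized at every step); the
#' candidate with the largest BIC decrease is kept, and selection stops
#' when no candidate decreases BIC.
#'
#' @param data a [predictor_set()] with at least 20 observations.
#' @return a `stepwise_result`: `selected_terms`, `coefficients` (the
#'   `exp_distance` coefficient is the amplitude; its rate is in `rate`),
#'   `bic_path` (BIC after each accepted step, starting at intercept-only),
#'   `r`, `r_squared`, and the final `fit`.
#' @export
forward_stepwise <- function(data) {
  stopifnot(inherits(data, "predictor_set"))
  if (nrow(data) < 20L) stopf("need at least 20 observations")
  candidates <- c("ndi", "odi", "exp_distance")
  current <- fit_term_model(data, character(0))
  path <- current$bic
  repeat {
    remaining <- setdiff(candidates, current$terms)
    if (length(remaining) == 0) break
    trials <- list()
    for (t in remaining) {
      f <- tryCatch(fit_term_model(data, c(current$terms, t)),
                    error = function(e) NULL)
      if (is.null(f)) {
        warnf("candidate '%s' failed to converge at this step; skipped", t)
        next
      }
      trials[[t]] <- f
    }
    if (length(trials) == 0) break
    bics <- vapply(trials, `[[`, 0, "bic")
    best <- names(trials)[which.min(bics)]       # which.min keeps first = candidate order
    if (bics[[best]] >= current$bic) break
    current <- trials[[best]]
    path <- c(path, current$bic)
  }
  pred <- current$predict(data)
  r <- pearson_r(data$dr2, pred)
  structure(list(selected_terms = c("intercept", current$terms),
                 coefficients = current$coefficients, rate = current$rate,
                 bic_path = path, r = r,
                 r_squared = if (is.na(r)) NA_real_ else r^2,
                 fit = current), class = "stepwise_result")
}

#' Leave-one-bundle-out cross-validation
#'
#' For each bundle, the selected model *form* is refit (all free parameters,
#' including the exponential rate) on the remaining bundles and used to
#' predict the held-out nodes; accuracy is the pooled Pearson r over all
#' held-out (observed, predicted) pairs.
#'
#' @param data a [predictor_set()] with at least 2 bundles.
#' @param model a `stepwise_result` (its `selected_terms` define the form).
#' @return a `cv_result`: `pooled_r`, `pooled_r_squared`, `per_bundle`
#'   (data.frame bundle, n, r), `predictions` (data.frame with observed and
#'   predicted), `dropped_folds`.
#' @export
loobcv <- function(data, model) {
  stopifnot(inherits(data, "predictor_set"), inherits(model, "stepwise_result"))
  bundles <- unique(data$bundle)
  if (length(bundles) < 2L) stopf("need at least 2 bundles for cross-validation")
  terms <- setdiff(model$selected_terms, "intercept")
  preds <- obs <- numeric(0)
  fold_of <- character(0)
  dropped <- character(0)
  for (b in bundles) {
    train <- data[data$bundle != b, , drop = FALSE]
    test <- data[data$bundle == b, , drop = FALSE]
    f <- tryCatch(fit_term_model(train, terms), error = function(e) NULL)
    if (is.null(f)) { dropped <- c(dropped, b); next }
    p <- f$predict(test)
    preds <- c(preds, p); obs <- c(obs, test$dr2)
    fold_of <- c(fold_of, rep(b, nrow(test)))
  }
  if (length(dropped)) warnf("folds dropped: %s", paste(dropped, collapse = ", "))
  per <- do.call(rbind, lapply(unique(fold_of), function(b) {
    i <- fold_of == b
    data.frame(bundle = b, n = sum(i), r = pearson_r(obs[i], preds[i]))
  }))
  r <- pearson_r(obs, preds)
  structure(list(pooled_r = r,
                 pooled_r_squared = if (is.na(r)) NA_real_ else r^2,
                 per_bundle = per,
                 predictions = data.frame(bundle = fold_of, observed = obs,
                                          predicted = preds),
                 dropped_folds = dropped), class = "cv_result")
}
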