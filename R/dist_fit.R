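## Fitting candidate probability distributions to exposure inputs and
## selecting the best by AIC.  Parametric maximum-likelihood fits go
## through fitdistrplus; the uniform family has the closed-form MLE
## (sample min, max) and is handled directly.  The "empirical" family
## stores the data vector and resamples it, which is how
## questionnaire-derived exposure frequency is modelled by default.

DIST_FAMILIES <- c("lognormal", "gamma", "weibull", "normal", "uniform",
                   "empirical")
## tie-break preference when AICs are (numerically) equal
FAMILY_PREFERENCE <- c("lognormal", "gamma", "weibull", "normal",
                       "uniform")

FAMILY_DISTNAME <- c(lognormal = "lnorm", gamma = "gamma",
                     weibull = "weibull", normal = "norm")

#' Fit one distribution family to data
#'
#' Maximum-likelihood fit of a single candidate family, recording the
#' parameter vector, AIC, and the Kolmogorov-Smirnov statistic as a
#' goodness-of-fit diagnostic.  Parameter order per family:
#' lognormal `(meanlog, sdlog)`; gamma `(shape, rate)`; weibull
#' `(shape, scale)`; normal `(mean, sd)`; uniform `(min, max)`;
#' empirical stores the data itself (no parameters).
#'
#' @param data Numeric data vector; positive values required for
#'   lognormal/gamma/weibull, at least 5 points for any parametric
#'   family.
#' @param family One of `"lognormal"`, `"gamma"`, `"weibull"`,
#'   `"normal"`, `"uniform"`, `"empirical"`.
#' @param variable_name Label carried through to summaries.
#' @return A `fitted_dist` object: list with `variable_name`, `family`,
#'   `params`, `aic`, `ks_stat`, `support`, and (empirical only) `data`.
#' @seealso [select_best()], [sample_dist()], [quantile_dist()]
#' @export
fit_dist <- function(data, family, variable_name = "x") {
  family <- match.arg(family, DIST_FAMILIES)
  stopifnot(is.numeric(data), length(data) >= 1)
  data <- data[!is.na(data)]

  if (family == "empirical") {
    return(new_fitted_dist(variable_name, "empirical", numeric(0),
                           aic = NA_real_, ks = NA_real_,
                           support = range(data), data = data))
  }

  if (length(data) < 5)
    stop("parametric fit requires at least 5 observations")
  if (stats::sd(data) == 0)
    stop("degenerate (zero-variance) data: use the empirical family")
  if (family %in% c("lognormal", "gamma", "weibull") && any(data <= 0))
    stop(family, " family requires strictly positive data")

  if (family == "uniform") {
    params <- c(min = min(data), max = max(data))
    n <- length(data)
    loglik <- -n * log(params[["max"]] - params[["min"]])
    aic <- 2 * 2 - 2 * loglik
    ks <- ks_statistic(data, stats::punif, params[["min"]],
                       params[["max"]])
    return(new_fitted_dist(variable_name, "uniform", params, aic, ks,
                           support = unname(params)))
  }

  dn <- FAMILY_DISTNAME[[family]]
  fit <- fitdistrplus::fitdist(data, dn, method = "mle")
  params <- fit$estimate
  pfun <- get(paste0("p", dn), mode = "function")
  ks <- ks_statistic(data, pfun, params[[1]], params[[2]])
  support <- switch(family,
                    lognormal = , gamma = , weibull = c(0, Inf),
                    normal = c(-Inf, Inf))
  new_fitted_dist(variable_name, family, params, fit$aic, ks, support)
}

new_fitted_dist <- function(variable_name, family, params, aic, ks,
                            support, data = NULL) {
  structure(list(variable_name = variable_name, family = family,
                 params = params, aic = aic, ks_stat = ks,
                 support = support, data = data),
            class = "fitted_dist")
}

#' Treat a constant as a (degenerate) fitted distribution
#'
#' Convenience for simulation configs where an input is fixed rather
#' than stochastic: all quantiles and draws equal `value`.
#'
#' @param value The constant.
#' @param variable_name Label.
#' @return A `fitted_dist` of family `"fixed"`.
#' @export
fixed_value <- function(value, variable_name = "x") {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  structure(list(variable_name = variable_name, family = "fixed",
                 params = c(value = value), aic = NA_real_,
                 ks_stat = NA_real_, support = c(value, value),
                 data = NULL),
            class = "fitted_dist")
}

ks_statistic <- function(data, pfun, ...) {
  suppressWarnings(
    unname(stats::ks.test(data, function(q) pfun(q, ...))$statistic))
}

#' @export
print.fitted_dist <- function(x, ...) {
  p <- if (length(x$params))
    paste(sprintf("%s = %.4g", names(x$params), x$params),
          collapse = ", ") else sprintf("n = %d", length(x$data))
  cat(sprintf("<fitted_dist> %s ~ %s(%s)", x$variable_name, x$family, p))
  if (!is.na(x$aic)) cat(sprintf("  AIC = %.2f", x$aic))
  cat("\n")
  invisible(x)
}

#' Select the minimum-AIC family among candidates
#'
#' Fits each candidate family and keeps the one with the smallest AIC.
#' Exact AIC ties are broken by a fixed preference order (lognormal,
#' gamma, weibull, normal, uniform).  If every candidate fails to fit,
#' the data are kept as an empirical distribution, with a warning.
#'
#' @inheritParams fit_dist
#' @param candidates Character vector of at least two families.
#' @param verbose Report the per-family AIC table via `message()`.
#' @return The winning `fitted_dist`, with the full comparison table in
#'   attribute `"aic_table"`.
#' @export
select_best <- function(data, candidates = FAMILY_PREFERENCE,
                        variable_name = "x", verbose = FALSE) {
  candidates <- match.arg(candidates, DIST_FAMILIES, several.ok = TRUE)
  if (length(candidates) < 2)
    stop("need at least two candidate families")
  fits <- lapply(candidates, function(fam)
    tryCatch(fit_dist(data, fam, variable_name), error = function(e) e))
  ok <- !vapply(fits, inherits, TRUE, what = "error")
  if (!any(ok)) {
    warning("all candidate fits failed; falling back to empirical")
    return(fit_dist(data, "empirical", variable_name))
  }
  fits <- fits[ok]
  aics <- vapply(fits, function(f) f$aic, 1)
  tab <- data.frame(family = vapply(fits, function(f) f$family, ""),
                    aic = aics,
                    ks_stat = vapply(fits, function(f) f$ks_stat, 1),
                    stringsAsFactors = FALSE)
  if (verbose)
    message(paste(utils::capture.output(print(tab)), collapse = "\n"))
  best_aic <- min(aics)
  ## tie tolerance: identical log-likelihood up to rounding noise
  tied <- which(aics <= best_aic + 1e-9)
  if (length(tied) > 1) {
    pref <- order(match(tab$family[tied], FAMILY_PREFERENCE))
    winner <- tied[pref[1]]
  } else winner <- tied
  structure(fits[[winner]], aic_table = tab)
}

#' Draw from a fitted distribution
#'
#' Inverse-CDF sampling: uniforms from the current RNG state (or a
#' caller-provided seed) pushed through [quantile_dist()], so every
#' family -- including empirical, which resamples the observed values --
#' shares one sampling path and fixed seeds reproduce exactly.
#'
#' @param dist A `fitted_dist`.
#' @param n Number of draws.
#' @param seed Optional integer seed set locally for this call.
#' @return Numeric vector of length `n`, inside the family's support.
#' @export
sample_dist <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "fitted_dist"), n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  quantile_dist(dist, stats::runif(n))
}

#' Quantile function of a fitted distribution
#'
#' @param dist A `fitted_dist`.
#' @param p Probabilities in `[0, 1]`.
#' @return Quantiles; for the empirical family the type-1 (inverse-ECDF)
#'   quantile, which only ever returns observed values.
#' @export
quantile_dist <- function(dist, p) {
  stopifnot(inherits(dist, "fitted_dist"))
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  pr <- dist$params
  switch(dist$family,
    fixed = rep(pr[["value"]], length(p)),
    lognormal = stats::qlnorm(p, pr[["meanlog"]], pr[["sdlog"]]),
    gamma = stats::qgamma(p, pr[["shape"]], pr[["rate"]]),
    weibull = stats::qweibull(p, pr[["shape"]], pr[["scale"]]),
    normal = stats::qnorm(p, pr[["mean"]], pr[["sd"]]),
    uniform = stats::qunif(p, pr[["min"]], pr[["max"]]),
    empirical = unname(stats::quantile(dist$data, p, type = 1)),
    stop("unknown family: ", dist$family))
}

#' Mean of a fitted distribution
#'
#' Closed-form mean per family (data mean for empirical); used for
#' closed-form cross-checks of Monte Carlo output.
#'
#' @param dist A `fitted_dist`.
#' @return The distribution mean.
#' @export
mean_dist <- function(dist) {
  pr <- dist$params
  switch(dist$family,
    fixed = pr[["value"]],
    lognormal = exp(pr[["meanlog"]] + pr[["sdlog"]]^2 / 2),
    gamma = pr[["shape"]] / pr[["rate"]],
    weibull = pr[["scale"]] * gamma(1 + 1 / pr[["shape"]]),
    normal = pr[["mean"]],
    uniform = (pr[["min"]] + pr[["max"]]) / 2,
    empirical = mean(dist$data),
    stop("unknown family: ", dist$family))
}
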