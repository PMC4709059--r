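#' Parametric distribution specifications for uncertain model inputs
#'
#' Every uncertain input of the asthma cost-effectiveness model carries a
#' `dist_spec()`: a parametric family with two parameters, used by the
#' probabilistic sensitivity analysis to draw concrete values. Supported
#' families are `"lognormal"` (log-scale mean and log-scale SD), `"beta"`
#' (shape1, shape2), `"gamma"` (shape, rate), `"normal"` (mean, SD) and
#' `"fixed"` (degenerate at the point estimate; `param2` is ignored).
#'
#' @param family One of `"lognormal"`, `"beta"`, `"gamma"`, `"normal"`,
#'   `"fixed"`.
#' @param param1,param2 Numeric distribution parameters; see Details.
#' @return A one-row tibble with columns `family`, `param1`, `param2`.
#' @examples
#' dist_spec("lognormal", 0.29, 0.10)
#' dist_spec("fixed", 14900)
#' @export
dist_spec <- function(family, param1, param2 = NA_real_) {
  family <- match.arg(family, dist_families())
  validate_dist(family, param1, param2)
  tibble::tibble(family = family, param1 = param1, param2 = param2)
}

dist_families <- function() c("lognormal", "beta", "gamma", "normal", "fixed")

validate_dist <- function(family, param1, param2, what = family) {
  if (!is.numeric(param1) || (family != "fixed" && !is.numeric(param2))) {
    stop("distribution parameters must be numeric for ", what, call. = FALSE)
  }
  ok <- switch(family,
    lognormal = is.finite(param1) && is.finite(param2) && param2 >= 0,
    beta      = param1 > 0 && param2 > 0,
    gamma     = param1 > 0 && param2 > 0,
    normal    = is.finite(param1) && param2 >= 0,
    fixed     = is.finite(param1)
  )
  if (!ok) {
    stop("invalid parameters for ", family, " distribution (", what, "): (",
         param1, ", ", param2, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Draw from a distribution specification
#'
#' @param family,param1,param2 As in [dist_spec()] (scalars).
#' @param n Number of draws.
#' @return Numeric vector of length `n`. `"fixed"` and zero-spread
#'   specifications return the point value unchanged.
#' @export
dist_sample <- function(family, param1, param2, n = 1) {
  family <- match.arg(family, dist_families())
  switch(family,
    lognormal = if (param2 == 0) rep(exp(param1), n) else stats::rlnorm(n, param1, param2),
    beta      = stats::rbeta(n, param1, param2),
    gamma     = stats::rgamma(n, shape = param1, rate = param2),
    normal    = if (param2 == 0) rep(param1, n) else stats::rnorm(n, param1, param2),
    fixed     = rep(param1, n)
  )
}

#' Analytic mean and median of a distribution specification
#'
#' Used to audit a parameter table: the analytic centre of each assigned
#' distribution should sit close to its point estimate.
#'
#' @inheritParams dist_sample
#' @return A scalar.
#' @export
dist_mean <- function(family, param1, param2) {
  switch(match.arg(family, dist_families()),
    lognormal = exp(param1 + param2^2 / 2),
    beta      = param1 / (param1 + param2),
    gamma     = param1 / param2,
    normal    = param1,
    fixed     = param1
  )
}

#' @rdname dist_mean
#' @export
dist_median <- function(family, param1, param2) {
  switch(match.arg(family, dist_families()),
    lognormal = exp(param1),
    beta      = stats::qbeta(0.5, param1, param2),
    gamma     = stats::qgamma(0.5, shape = param1, rate = param2),
    normal    = param1,
    fixed     = param1
  )
}

#' @rdname dist_mean
#' @param p Probability for the quantile.
#' @export
dist_quantile <- function(family, param1, param2, p) {
  switch(match.arg(family, dist_families()),
    lognormal = stats::qlnorm(p, param1, param2),
    beta      = stats::qbeta(p, param1, param2),
    gamma     = stats::qgamma(p, shape = param1, rate = param2),
    normal    = stats::qnorm(p, param1, param2),
    fixed     = rep(param1, length(p))
  )
}
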