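#' Meta-analysis of trial-level log relative rates
#'
#' The relative-rate inputs of the model derive from pooled trial evidence.
#' Three poolers operate on trial tables (columns `trial`, `log_rr`,
#' `se_log_rr`, each SE strictly positive):
#'
#' * `pool_fixed()` — inverse-variance fixed-effect pooling, weights
#'   `1/se^2`, pooled SE `sqrt(1/sum(w))`.
#' * `pool_random()` — DerSimonian–Laird random effects: the between-study
#'   variance is the moment estimator
#'   `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#'   fixed-effect weights `w`, then trials are re-weighted by
#'   `1/(se^2 + tau2)`. Needs at least two trials.
#' * `pool_external_tau()` — random-effects pooling with a between-study
#'   variance borrowed from an external, larger meta-analysis (the device
#'   used to widen the thermoplasty intervals when only a few trials exist):
#'   weights `1/(se^2 + tau2_external)`. With `reweight_point = FALSE` the
#'   fixed-effect point estimate is kept and only the interval reflects the
#'   borrowed heterogeneity.
#'
#' All results are reported on the relative-rate scale with normal-theory
#' 95% intervals computed on the log scale.
#'
#' @param trials A tibble of trial effects (see [simulate_trial_set()]).
#' @param tau2_external Nonnegative externally estimated between-study
#'   variance (log scale).
#' @param reweight_point Whether the borrowed variance also re-weights the
#'   point estimate (default) or only widens the interval.
#' @return A one-row tibble: `method`, `k`, `mu` (pooled log RR), `se_mu`,
#'   `tau2`, `rr`, `cri_low`, `cri_high`, `q` (Cochran's Q, where computed).
#' @name meta_pooling
NULL

check_trials <- function(trials, min_k = 1) {
  if (is.null(trials) || nrow(trials) == 0) stop("empty trial list", call. = FALSE)
  if (nrow(trials) < min_k) {
    stop("need at least ", min_k, " trials", call. = FALSE)
  }
  if (any(!is.finite(trials$log_rr)) || any(!is.finite(trials$se_log_rr)) ||
      any(trials$se_log_rr <= 0)) {
    stop("trial standard errors must be positive and finite", call. = FALSE)
  }
  invisible(trials)
}

pool_result <- function(method, k, mu, se_mu, tau2, q = NA_real_) {
  tibble::tibble(method = method, k = k, mu = mu, se_mu = se_mu, tau2 = tau2,
                 rr = exp(mu),
                 cri_low = exp(mu - 1.959964 * se_mu),
                 cri_high = exp(mu + 1.959964 * se_mu),
                 q = q)
}

#' @rdname meta_pooling
#' @export
pool_fixed <- function(trials) {
  check_trials(trials, 1)
  w <- 1 / trials$se_log_rr^2
  mu <- sum(w * trials$log_rr) / sum(w)
  pool_result("fixed", nrow(trials), mu, sqrt(1 / sum(w)), 0)
}

#' @rdname meta_pooling
#' @export
pool_random <- function(trials) {
  check_trials(trials, 2)
  w <- 1 / trials$se_log_rr^2
  mu_fe <- sum(w * trials$log_rr) / sum(w)
  q <- sum(w * (trials$log_rr - mu_fe)^2)
  k <- nrow(trials)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (trials$se_log_rr^2 + tau2)
  mu <- sum(wr * trials$log_rr) / sum(wr)
  pool_result("random", k, mu, sqrt(1 / sum(wr)), tau2, q)
}

#' @rdname meta_pooling
#' @export
pool_external_tau <- function(trials, tau2_external, reweight_point = TRUE) {
  check_trials(trials, 1)
  if (!is.numeric(tau2_external) || length(tau2_external) != 1 ||
      is.na(tau2_external) || tau2_external < 0) {
    stop("tau2_external must be nonnegative", call. = FALSE)
  }
  wr <- 1 / (trials$se_log_rr^2 + tau2_external)
  mu <- if (reweight_point) {
    sum(wr * trials$log_rr) / sum(wr)
  } else {
    w <- 1 / trials$se_log_rr^2
    sum(w * trials$log_rr) / sum(w)
  }
  pool_result("random-external-tau", nrow(trials), mu, sqrt(1 / sum(wr)),
              tau2_external)
}

#' Read / write trial-effect tables as CSV
#'
#' @param path CSV path with columns `trial`, `log_rr`, `se_log_rr` (an
#'   optional `event_type` column is carried through).
#' @return `read_trials_csv()`: a validated trial tibble.
#' @export
read_trials_csv <- function(path) {
  tr <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("trial", "log_rr", "se_log_rr")
  if (!all(need %in% names(tr))) {
    stop("trial CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  check_trials(tr)
}

#' @rdname read_trials_csv
#' @param pooled A pooled-effect tibble (any pooler's output, possibly
#'   row-bound).
#' @export
write_pooled_csv <- function(pooled, path) {
  utils::write.csv(pooled, path, row.names = FALSE)
  invisible(path)
}
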