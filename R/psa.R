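#' Probabilistic sensitivity analysis
#'
#' Runs the Monte Carlo PSA: `n_iter` joint parameter draws (one draw per
#' iteration, shared by all strategies so that between-strategy comparisons
#' are correlated), then the cohort model per strategy per draw. The cohort
#' engine is vectorized over draws, so the published 10,000-iteration
#' analysis runs in seconds.
#'
#' @param ps A `cea_parameters` object.
#' @param settings A [model_settings()] object.
#' @param n_iter Number of Monte Carlo iterations (published analysis:
#'   10,000).
#' @param seed Integer seed; the full run is bit-reproducible given the seed.
#' @param strategies Strategies to run.
#' @return An object of class `cea_psa`: list with `samples` (tibble
#'   `iteration`, `strategy`, `cost`, `qalys`, event counts, `prop_dead`),
#'   `draws` (the sampled parameter table), `settings`, `n_iter`, `seed`.
#'   Has `tidy()` (credible-interval summary) and `glance()` methods, and an
#'   `autoplot()` showing the cost-effectiveness plane.
#' @export
run_psa <- function(ps, settings = model_settings(), n_iter = 10000,
                    seed = NULL, strategies = cea_strategies()) {
  stopifnot(n_iter >= 1)
  draws <- sample_parameters(ps, n = n_iter, seed = seed)
  samples <- purrr::map_dfr(strategies, function(s) {
    out <- run_cohort(draws, s, settings, ps$life_table)
    dplyr::mutate(out, iteration = dplyr::row_number(), .before = 1)
  })
  structure(list(samples = samples, draws = draws, settings = settings,
                 n_iter = as.integer(n_iter), seed = seed),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat("<cea_psa> ", x$n_iter, " iterations x ",
      dplyr::n_distinct(x$samples$strategy), " strategies",
      if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"), "\n", sep = "")
  print(summarize_psa(x$samples))
  invisible(x)
}

#' Summarize PSA samples with means and 95% credible intervals
#'
#' Empirical means and 2.5th/97.5th percentiles (linear-interpolation
#' quantiles) per outcome per strategy.
#'
#' @param samples A PSA sample table (`iteration`, `strategy`, outcome
#'   columns), or a `cea_psa` object.
#' @return A tibble `strategy`, `outcome`, `mean`, `cri_low`, `cri_high`.
#' @export
summarize_psa <- function(samples) {
  if (inherits(samples, "cea_psa")) samples <- samples$samples
  if (nrow(samples) == 0) stop("empty sample table", call. = FALSE)
  if (dplyr::n_distinct(samples$iteration) < 2) {
    stop("summary needs at least 2 iterations", call. = FALSE)
  }
  samples %>%
    select(-"iteration") %>%
    tidyr::pivot_longer(-"strategy", names_to = "outcome") %>%
    group_by(.data$strategy, .data$outcome) %>%
    summarise(mean = mean(.data$value),
              cri_low = stats::quantile(.data$value, 0.025, names = FALSE),
              cri_high = stats::quantile(.data$value, 0.975, names = FALSE),
              .groups = "drop")
}

#' @exportS3Method generics::tidy
tidy.cea_psa <- function(x, ...) summarize_psa(x$samples)

#' @exportS3Method generics::glance
glance.cea_psa <- function(x, ...) {
  key_wtp <- c(5e4, 1e5)
  cc <- ceac(x$samples, key_wtp)
  ev <- evpi(x$samples, key_wtp)
  tibble::tibble(
    n_iter = x$n_iter,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed),
    horizon_weeks = x$settings$horizon_weeks,
    prob_bt_wtp50k = cc$probability[cc$wtp == 5e4 & cc$strategy == "bt"],
    prob_bt_wtp100k = cc$probability[cc$wtp == 1e5 & cc$strategy == "bt"],
    evpi_wtp50k = ev$evpi[ev$wtp == 5e4],
    evpi_wtp100k = ev$evpi[ev$wtp == 1e5])
}

#' Export PSA iteration-level samples as CSV
#'
#' @param psa A `cea_psa` object or sample table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_psa_csv <- function(psa, path) {
  samples <- if (inherits(psa, "cea_psa")) psa$samples else psa
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
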