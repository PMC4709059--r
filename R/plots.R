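#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_hline geom_vline
#'   labs facet_wrap autoplot scale_y_continuous geom_linerange
#'   coord_flip theme_minimal
NULL

#' Plot the cost-effectiveness plane from PSA samples
#'
#' Per-iteration cost and QALY increments of each non-reference strategy
#' against the reference.
#'
#' @param psa A `cea_psa` object or PSA sample table.
#' @param reference Reference strategy.
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, reference = "standard", alpha = 0.2) {
  samples <- if (inherits(psa, "cea_psa")) psa$samples else psa
  pts <- ce_plane(samples, reference) %>%
    filter(.data$strategy != reference)
  ggplot(pts, aes(x = .data$delta_qalys, y = .data$delta_cost)) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    geom_vline(xintercept = 0, linewidth = 0.3) +
    geom_point(alpha = alpha, size = 0.5) +
    facet_wrap(~strategy, scales = "free") +
    labs(x = sprintf("Incremental QALYs vs %s", reference),
         y = sprintf("Incremental cost vs %s ($)", reference)) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cea_psa <- function(object, ...) plot_ce_plane(object, ...)

#' Plot cost-effectiveness acceptability curves
#'
#' @param psa A `cea_psa` object, PSA sample table, or a precomputed
#'   [ceac()] tibble.
#' @param wtp_grid Grid used when `psa` is not already a CEAC table.
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa, wtp_grid = NULL) {
  curves <- if (is.data.frame(psa) && all(c("wtp", "probability") %in% names(psa))) {
    psa
  } else {
    samples <- if (inherits(psa, "cea_psa")) psa$samples else psa
    grid <- wtp_grid %||% (if (inherits(psa, "cea_psa")) psa$settings$wtp_grid
                           else seq(0, 2e5, 5000))
    ceac(samples, grid)
  }
  ggplot(curves, aes(x = .data$wtp, y = .data$probability,
                     colour = .data$strategy)) +
    geom_line() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Willingness to pay ($/QALY)",
         y = "Probability cost-effective", colour = "Strategy") +
    theme_minimal()
}

#' Plot the expected value of perfect information curve
#'
#' @inheritParams plot_ceac
#' @return A ggplot object.
#' @export
plot_evpi <- function(psa, wtp_grid = NULL) {
  curve <- if (is.data.frame(psa) && all(c("wtp", "evpi") %in% names(psa))) {
    psa
  } else {
    samples <- if (inherits(psa, "cea_psa")) psa$samples else psa
    grid <- wtp_grid %||% (if (inherits(psa, "cea_psa")) psa$settings$wtp_grid
                           else seq(0, 2e5, 5000))
    evpi(samples, grid)
  }
  ggplot(curve, aes(x = .data$wtp, y = .data$evpi)) +
    geom_line() +
    labs(x = "Willingness to pay ($/QALY)",
         y = "EVPI ($ per individual)") +
    theme_minimal()
}

#' Tornado plot of one-way sensitivity results
#'
#' @param tornado Output of [one_way_tornado()].
#' @param icer Which ICER column to display.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, icer = "icer_bt_vs_standard") {
  ranges <- tornado %>%
    group_by(.data$label) %>%
    summarise(lo = min(.data[[icer]], na.rm = TRUE),
              hi = max(.data[[icer]], na.rm = TRUE), .groups = "drop") %>%
    mutate(label = stats::reorder(.data$label, .data$hi - .data$lo))
  ggplot(ranges, aes(x = .data$label, ymin = .data$lo, ymax = .data$hi)) +
    geom_linerange(linewidth = 3) +
    coord_flip() +
    labs(x = NULL, y = "ICER ($/QALY)") +
    theme_minimal()
}

#' Plot ICERs as a function of the thermoplasty cost
#'
#' @param sweep Output of [bt_cost_sweep()].
#' @return A ggplot object.
#' @export
plot_bt_cost_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, -"bt_cost", names_to = "comparison",
                              values_to = "icer")
  ggplot(long, aes(x = .data$bt_cost, y = .data$icer)) +
    geom_line() +
    facet_wrap(~comparison, scales = "free_y") +
    labs(x = "Thermoplasty upfront cost ($)", y = "ICER ($/QALY)") +
    theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
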