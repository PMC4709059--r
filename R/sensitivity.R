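# Point-estimate runs with one parameter overridden: shared helper for the
# deterministic sensitivity analyses.
base_icers <- function(ps, settings) {
  bc <- run_base_case(ps, settings)
  glance(bc)
}

#' Default one-way sensitivity scenarios
#'
#' Cost parameters are varied by +/-25% around their point estimates;
#' utility differences use the published alternative ranges (0 to 0.06 for
#' thermoplasty, 0.03 to 0.05 for omalizumab); baseline exacerbation rates
#' vary by +/-25%; relative rates use their 95% credible-interval bounds.
#'
#' @param ps A `cea_parameters` object.
#' @return A scenario tibble (`label`, `name`, `low`, `high`).
#' @export
default_tornado_scenarios <- function(ps) {
  p <- ps$params
  rows <- purrr::pmap(p, function(name, group, label, value, family, param1,
                                  param2) {
    if (group == "cost") {
      tibble::tibble(label = label, name = name,
                     low = value * 0.75, high = value * 1.25)
    } else if (group == "rate") {
      tibble::tibble(label = label, name = name,
                     low = value * 0.75, high = value * 1.25)
    } else if (group == "rr") {
      tibble::tibble(label = label, name = name,
                     low = dist_quantile(family, param1, param2, 0.025),
                     high = dist_quantile(family, param1, param2, 0.975))
    } else if (name == "utility_delta_bt") {
      tibble::tibble(label = label, name = name, low = 0, high = 0.06)
    } else if (name == "utility_delta_omalizumab") {
      tibble::tibble(label = label, name = name, low = 0.03, high = 0.05)
    } else {
      NULL
    }
  })
  bind_rows(rows)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the point-estimate model with each scenario parameter set to its
#' low and high bound, reporting the pairwise ICERs of thermoplasty versus
#' standard therapy and omalizumab versus thermoplasty at each bound. The
#' output is sorted by the width of the thermoplasty-versus-standard ICER
#' range, the conventional tornado ordering.
#'
#' @param ps A `cea_parameters` object.
#' @param scenarios A scenario tibble (`label`, `name`, `low`, `high`);
#'   defaults to [default_tornado_scenarios()].
#' @param settings A [model_settings()] object.
#' @return A tibble with one row per scenario and bound: `label`, `name`,
#'   `bound`, `value`, `icer_bt_vs_standard`, `icer_omalizumab_vs_bt`.
#' @export
one_way_tornado <- function(ps, scenarios = default_tornado_scenarios(ps),
                            settings = model_settings()) {
  stopifnot(all(c("label", "name", "low", "high") %in% names(scenarios)))
  unknown <- setdiff(scenarios$name, ps$params$name)
  if (length(unknown)) {
    stop("unknown parameter path(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(scenarios$low > scenarios$high, na.rm = TRUE)) {
    stop("scenario low bound exceeds high bound", call. = FALSE)
  }
  rows <- purrr::pmap_dfr(scenarios, function(label, name, low, high, ...) {
    purrr::map_dfr(c(low = low, high = high), function(v) {
      g <- base_icers(set_parameter_value(ps, name, v), settings)
      tibble::tibble(label = label, name = name, value = v,
                     icer_bt_vs_standard = g$icer_bt_vs_standard,
                     icer_omalizumab_vs_bt = g$icer_omalizumab_vs_bt)
    }, .id = "bound")
  })
  widths <- rows %>%
    group_by(.data$name) %>%
    summarise(width = abs(diff(range(.data$icer_bt_vs_standard))),
              .groups = "drop")
  rows %>%
    left_join(widths, by = "name") %>%
    arrange(dplyr::desc(.data$width)) %>%
    select(-"width")
}

#' ICERs as a function of the thermoplasty upfront cost
#'
#' Sweeps the one-time thermoplasty cost over a grid, recomputing the
#' point-estimate ICERs of thermoplasty versus standard therapy (strictly
#' increasing in the cost) and omalizumab versus thermoplasty (strictly
#' decreasing).
#'
#' @param ps A `cea_parameters` object.
#' @param cost_grid Nonnegative cost grid (default $8,000-$30,000, the
#'   published sweep range).
#' @param settings A [model_settings()] object.
#' @return A tibble `bt_cost`, `icer_bt_vs_standard`,
#'   `icer_omalizumab_vs_bt`.
#' @export
bt_cost_sweep <- function(ps, cost_grid = seq(8000, 30000, by = 1000),
                          settings = model_settings()) {
  stopifnot(all(cost_grid >= 0))
  purrr::map_dfr(cost_grid, function(cost) {
    g <- base_icers(set_parameter_value(ps, "cost_bt_upfront", cost), settings)
    tibble::tibble(bt_cost = cost,
                   icer_bt_vs_standard = g$icer_bt_vs_standard,
                   icer_omalizumab_vs_bt = g$icer_omalizumab_vs_bt)
  })
}

#' Threshold thermoplasty cost at a willingness-to-pay
#'
#' Bisection search for the upfront thermoplasty cost at which the ICER of
#' thermoplasty versus standard therapy equals the willingness-to-pay, to a
#' tolerance of $100/QALY on the ICER.
#'
#' @param ps A `cea_parameters` object.
#' @param wtp Positive willingness-to-pay ($/QALY).
#' @param settings A [model_settings()] object.
#' @param bracket Cost bracket to search (the ICER must straddle `wtp`
#'   across it).
#' @param tol ICER tolerance ($/QALY).
#' @return The threshold cost (scalar).
#' @export
threshold_cost <- function(ps, wtp, settings = model_settings(),
                           bracket = c(0, 1e5), tol = 100) {
  stopifnot(wtp > 0, length(bracket) == 2, bracket[1] < bracket[2])
  icer_at <- function(cost) {
    ps_c <- set_parameter_value(ps, "cost_bt_upfront", cost)
    draw <- point_estimates(ps_c)
    std <- run_cohort(draw, "standard", settings, ps_c$life_table)
    bt <- run_cohort(draw, "bt", settings, ps_c$life_table)
    cmp <- compute_icer(std, bt)
    # dominance maps to a signed extreme so the bisection bracket stays valid
    if (cmp$label == "dominant") -Inf
    else if (cmp$label %in% c("dominated", "undefined")) Inf
    else cmp$icer
  }
  f_lo <- icer_at(bracket[1]) - wtp
  f_hi <- icer_at(bracket[2]) - wtp
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0) {
    stop("ICER does not cross the willingness-to-pay over the bracket",
         call. = FALSE)
  }
  lo <- bracket[1]; hi <- bracket[2]
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    f_mid <- icer_at(mid) - wtp
    if (abs(f_mid) <= tol) return(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Scenario analyses over horizons and effect waning
#'
#' Point-estimate outcomes and pairwise ICERs under alternative horizons and
#' thermoplasty effect-waning assumptions: the 5-year base case, 10 years
#' with and without exponential waning after year 5, 5 years with waning
#' after year 1, and a lifetime horizon (to the life-table terminal age)
#' with waning after year 5. The waning half-life defaults to the one
#' configured in [waning_exponential()] (52 weeks).
#'
#' @param ps A `cea_parameters` object.
#' @param settings Base [model_settings()]; horizon and waning are overridden
#'   per scenario.
#' @param half_life_weeks Half-life for the waning scenarios.
#' @return An object of class `cea_scenarios`: list with `outcomes`
#'   (scenario x strategy) and `icers` (scenario-level [glance()] rows);
#'   `tidy()` returns the ICER table.
#' @export
scenario_horizons <- function(ps, settings = model_settings(),
                              half_life_weeks = 52) {
  lifetime_weeks <- (max(ps$life_table$age) - settings$baseline_age_years) * 52
  scen <- tibble::tibble(
    scenario = c("5y constant", "10y constant", "10y waning after 5y",
                 "5y waning after 1y", "lifetime waning after 5y"),
    horizon = c(260, 520, 520, 260, lifetime_weeks),
    onset = c(NA, NA, 260, 52, 260))
  runs <- purrr::pmap(scen, function(scenario, horizon, onset) {
    s <- model_settings(
      horizon_weeks = horizon,
      annual_discount_rate = settings$annual_discount_rate,
      baseline_age_years = settings$baseline_age_years,
      waning = if (is.na(onset)) waning_none()
               else waning_exponential(onset, half_life_weeks),
      wtp_grid = settings$wtp_grid)
    bc <- run_base_case(ps, s)
    list(outcomes = dplyr::mutate(bc$outcomes, scenario = scenario, .before = 1),
         icers = dplyr::mutate(glance(bc), scenario = scenario, .before = 1))
  })
  structure(list(outcomes = purrr::map_dfr(runs, "outcomes"),
                 icers = purrr::map_dfr(runs, "icers")),
            class = "cea_scenarios")
}

#' @exportS3Method generics::tidy
tidy.cea_scenarios <- function(x, ...) x$icers

#' @export
print.cea_scenarios <- function(x, ...) {
  print(x$icers)
  invisible(x)
}
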