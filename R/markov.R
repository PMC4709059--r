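# State indexing used throughout the engine.
cea_states <- function() c("free", "ocs", "ed", "hosp", "dead")

#' Built-in treatment strategies
#'
#' The three comparators: standard therapy (reference: all relative rates 1,
#' no upfront cost, no utility difference), bronchial thermoplasty (one-time
#' upfront cost on top of continued standard drug therapy, reduced
#' exacerbation rates, exacerbation-free utility gain, effect subject to
#' waning when configured) and omalizumab (annual add-on drug cost on top of
#' standard therapy, reduced rates, utility gain).
#'
#' @return Character vector of strategy names.
#' @export
cea_strategies <- function() c("standard", "bt", "omalizumab")

# Resolve a strategy's inputs from a (possibly multi-row) parameter draw.
strategy_inputs <- function(draw, strategy) {
  strategy <- match.arg(strategy, cea_strategies())
  one <- function(x) rep(x, length.out = nrow(draw))
  switch(strategy,
    standard = list(
      name = "standard", upfront = one(0),
      drug_annual = draw$cost_drug_standard,
      rr_ocs = one(1), rr_ed = one(1), rr_hosp = one(1),
      delta = one(0)),
    bt = list(
      name = "bt", upfront = draw$cost_bt_upfront,
      drug_annual = draw$cost_drug_standard,
      rr_ocs = draw$rr_bt_ocs, rr_ed = draw$rr_bt_ed, rr_hosp = draw$rr_bt_hosp,
      delta = draw$utility_delta_bt),
    omalizumab = list(
      name = "omalizumab", upfront = one(0),
      drug_annual = draw$cost_drug_standard + draw$cost_drug_omalizumab,
      rr_ocs = draw$rr_omalizumab_ocs, rr_ed = draw$rr_omalizumab_ed,
      rr_hosp = draw$rr_omalizumab_hosp,
      delta = draw$utility_delta_omalizumab)
  )
}

#' Effective relative rate under treatment-effect waning
#'
#' With no waning the relative rate is constant. With exponential waning, for
#' weeks strictly after the onset the log relative rate decays geometrically
#' toward zero (the relative rate drifts back to 1):
#' `log rr_t = log(rr) * 2^(-(t - onset) / half_life)`.
#'
#' @param rr Positive relative rate.
#' @param week Model week (0-based).
#' @param waning A configuration from [waning_none()] or
#'   [waning_exponential()].
#' @return The effective relative rate at `week`.
#' @export
waning_relative_rate <- function(rr, week, waning = waning_none()) {
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("rr must be positive", call. = FALSE)
  }
  rr^waning_exponent(week, waning)
}

# Scalar exponent on log(rr) at a given week; 1 = full effect.
waning_exponent <- function(week, waning) {
  if (identical(waning$type, "none") || week <= waning$onset_week) return(1)
  if (waning$half_life_weeks == 0) return(0)
  2^(-(week - waning$onset_week) / waning$half_life_weeks)
}

# Weekly transition components for one strategy at one week, vectorized over
# draws. Competing risks within the cycle: independent weekly hazards for the
# three exacerbation types plus background death are summed to a total hazard
# H; the total event probability 1 - exp(-H) is allocated proportionally to
# each cause's hazard. Exacerbation states last one cycle and exit to
# exacerbation-free unless death intervenes (background mortality for the OCS
# and ED levels; hospitalization additionally carries the 30-day death risk).
transition_components <- function(draw, strategy, week, settings,
                                  life_table = default_life_table()) {
  si <- if (is.list(strategy) && !is.null(strategy$name)) strategy
        else strategy_inputs(draw, strategy)
  waning <- settings$waning
  wanes <- !identical(waning$type, "none") && si$name %in% waning$strategies
  wexp <- if (wanes) waning_exponent(week, waning) else 1

  age <- settings$baseline_age_years + week / 52
  p_bg <- background_mortality_weekly(age, life_table)
  qx_eff <- pmin(1 - (1 - p_bg)^52, 1 - 1e-12)
  h_bg <- -log(1 - qx_eff) / 52

  h_ocs <- si$rr_ocs^wexp * draw$rate_ocs / 52
  h_ed <- si$rr_ed^wexp * draw$rate_ed / 52
  h_hosp <- si$rr_hosp^wexp * draw$rate_hosp / 52
  H <- h_ocs + h_ed + h_hosp + h_bg
  share <- ifelse(H > 0, (1 - exp(-H)) / H, 0)

  p_hosp_dead <- 1 - (1 - draw$death_risk_hosp) * (1 - p_bg)
  comps <- list(
    p_free_ocs = h_ocs * share,
    p_free_ed = h_ed * share,
    p_free_hosp = h_hosp * share,
    p_free_dead = h_bg * share,
    p_exac_dead = rep(p_bg, length.out = nrow(draw)),
    p_hosp_dead = p_hosp_dead
  )
  bad <- purrr::some(comps, function(p) any(!is.finite(p) | p < 0 | p > 1))
  if (bad) stop("transition probability outside [0, 1]", call. = FALSE)
  comps
}

#' Build the weekly transition matrix for one strategy
#'
#' Assembles the full 5x5 row-stochastic matrix over the states
#' exacerbation-free, OCS exacerbation, ED exacerbation, hospitalization and
#' death, for a single parameter draw at a given week. Death is absorbing.
#'
#' @param draw A one-row parameter draw ([point_estimates()] or one row of
#'   [sample_parameters()]).
#' @param strategy Strategy name (see [cea_strategies()]).
#' @param week Model week (0-based).
#' @param settings A [model_settings()] object.
#' @param life_table Background-mortality life table.
#' @return A 5x5 matrix with dimnames over the model states.
#' @export
build_transition_matrix <- function(draw, strategy, week, settings = model_settings(),
                                    life_table = default_life_table()) {
  stopifnot(nrow(draw) == 1)
  cp <- transition_components(draw, strategy, week, settings, life_table)
  st <- cea_states()
  m <- matrix(0, 5, 5, dimnames = list(st, st))
  m["free", ] <- c(1 - (cp$p_free_ocs + cp$p_free_ed + cp$p_free_hosp + cp$p_free_dead),
                   cp$p_free_ocs, cp$p_free_ed, cp$p_free_hosp, cp$p_free_dead)
  m["ocs", c("free", "dead")] <- c(1 - cp$p_exac_dead, cp$p_exac_dead)
  m["ed", c("free", "dead")] <- c(1 - cp$p_exac_dead, cp$p_exac_dead)
  m["hosp", c("free", "dead")] <- c(1 - cp$p_hosp_dead, cp$p_hosp_dead)
  m["dead", "dead"] <- 1
  if (any(m < 0 | m > 1) || any(abs(rowSums(m) - 1) > 1e-12)) {
    stop("internal consistency error: transition matrix not row-stochastic",
         call. = FALSE)
  }
  m
}

# Strategy-specific annual state utilities, clamped so that no exacerbation
# state can exceed the strategy's exacerbation-free utility.
strategy_utilities <- function(draw, si) {
  u_free <- pmin(pmax(draw$utility_free + si$delta, 0), 1)
  list(free = u_free,
       ocs = pmin(draw$utility_ocs, u_free),
       ed = pmin(draw$utility_ed, u_free),
       hosp = pmin(draw$utility_hosp, u_free))
}

#' Run the weekly-cycle cohort model for one strategy
#'
#' Propagates a cohort (starting fully in the exacerbation-free state)
#' through the five-state weekly-cycle Markov model, accruing discounted
#' costs and QALYs and undiscounted expected event counts. Vectorized over
#' parameter draws: `draw` may have any number of rows (e.g. a full PSA
#' sample), and one outcome row is returned per draw.
#'
#' Per cycle the cohort accrues utility `occupancy * annual utility / 52` and
#' drug cost `occupancy_alive * annual drug cost / 52`, both discounted by
#' `(1 + r)^(-week/52)`; each incident entry into an exacerbation state adds
#' that event's unit cost (discounted at the week of entry). Any upfront
#' treatment cost is charged once at week 0 undiscounted.
#'
#' @param draw Parameter draw(s): a wide tibble from [point_estimates()] or
#'   [sample_parameters()].
#' @param strategy Strategy name (see [cea_strategies()]).
#' @param settings A [model_settings()] object.
#' @param life_table Background-mortality life table.
#' @param trace If `TRUE` (single-draw runs only), attach the full weekly
#'   cohort trace as attribute `"trace"`: state occupancies, incident events
#'   and accrued discounted cost/QALYs per week.
#' @return A tibble with one row per draw: `strategy`, `cost`, `qalys`,
#'   `n_ocs`, `n_ed`, `n_hosp`, `total_exacerbations`, `prop_dead`.
#' @export
run_cohort <- function(draw, strategy, settings = model_settings(),
                       life_table = default_life_table(), trace = FALSE) {
  strategy <- match.arg(strategy, cea_strategies())
  n <- nrow(draw)
  T <- settings$horizon_weeks
  if (trace && n != 1) stop("trace requires a single draw", call. = FALSE)
  si <- strategy_inputs(draw, strategy)
  u <- strategy_utilities(draw, si)
  disc <- (1 + settings$annual_discount_rate)^(-(seq_len(max(T, 1)) - 1) / 52)

  v <- matrix(0, n, 5)
  v[, 1] <- 1
  cost <- si$upfront + numeric(n)
  qalys <- numeric(n)
  n_ocs <- n_ed <- n_hosp <- numeric(n)
  tr <- if (trace) vector("list", T) else NULL

  for (w in seq_len(T) - 1L) {
    cp <- transition_components(draw, si, w, settings, life_table)
    d <- disc[w + 1]
    alive <- 1 - v[, 5]
    qalys <- qalys + (v[, 1] * u$free + v[, 2] * u$ocs + v[, 3] * u$ed +
                        v[, 4] * u$hosp) / 52 * d
    cost <- cost + si$drug_annual / 52 * alive * d
    inc_ocs <- v[, 1] * cp$p_free_ocs
    inc_ed <- v[, 1] * cp$p_free_ed
    inc_hosp <- v[, 1] * cp$p_free_hosp
    cost <- cost + (inc_ocs * draw$cost_event_ocs + inc_ed * draw$cost_event_ed +
                      inc_hosp * draw$cost_event_hosp) * d
    n_ocs <- n_ocs + inc_ocs
    n_ed <- n_ed + inc_ed
    n_hosp <- n_hosp + inc_hosp
    dead <- v[, 5] + v[, 1] * cp$p_free_dead +
      (v[, 2] + v[, 3]) * cp$p_exac_dead + v[, 4] * cp$p_hosp_dead
    free <- v[, 1] * (1 - cp$p_free_ocs - cp$p_free_ed - cp$p_free_hosp -
                        cp$p_free_dead) +
      (v[, 2] + v[, 3]) * (1 - cp$p_exac_dead) + v[, 4] * (1 - cp$p_hosp_dead)
    v <- cbind(free, inc_ocs, inc_ed, inc_hosp, dead, deparse.level = 0)
    if (trace) {
      tr[[w + 1]] <- tibble::tibble(
        week = w + 1L, free = v[, 1], ocs = v[, 2], ed = v[, 3],
        hosp = v[, 4], dead = v[, 5],
        inc_ocs = inc_ocs, inc_ed = inc_ed, inc_hosp = inc_hosp,
        cum_cost = cost, cum_qalys = qalys)
    }
  }

  out <- tibble::tibble(
    strategy = strategy, cost = cost, qalys = qalys,
    n_ocs = n_ocs, n_ed = n_ed, n_hosp = n_hosp,
    total_exacerbations = n_ocs + n_ed + n_hosp,
    prop_dead = v[, 5])
  if (trace) {
    attr(out, "trace") <- dplyr::bind_rows(
      tibble::tibble(week = 0L, free = 1, ocs = 0, ed = 0, hosp = 0, dead = 0,
                     inc_ocs = 0, inc_ed = 0, inc_hosp = 0,
                     cum_cost = si$upfront, cum_qalys = 0),
      tr)
  }
  out
}

#' Run the base-case (point-estimate) analysis for all strategies
#'
#' Runs [run_cohort()] with the point estimates for each requested strategy
#' and attaches the full incremental analysis.
#'
#' @param ps A `cea_parameters` object.
#' @param settings A [model_settings()] object.
#' @param strategies Strategies to run.
#' @return An object of class `cea_base_case`: list with `outcomes` (one row
#'   per strategy) and `comparisons` (pairwise incremental results). Has
#'   [tidy()][generics::tidy] and [glance()][generics::glance] methods.
#' @export
run_base_case <- function(ps, settings = model_settings(),
                          strategies = cea_strategies()) {
  draw <- point_estimates(ps)
  outcomes <- purrr::map_dfr(strategies, function(s) {
    run_cohort(draw, s, settings, ps$life_table)
  })
  inc <- incremental_analysis(outcomes)
  structure(list(outcomes = outcomes, comparisons = inc$comparisons,
                 frontier = inc$outcomes, settings = settings),
            class = "cea_base_case")
}

#' @export
print.cea_base_case <- function(x, ...) {
  cat("<cea_base_case> horizon", x$settings$horizon_weeks, "weeks\n")
  print(x$outcomes)
  print(x$comparisons)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cea_base_case <- function(x, ...) x$outcomes

#' @exportS3Method generics::glance
glance.cea_base_case <- function(x, ...) {
  cmp <- x$comparisons
  pick <- function(ref, comp) {
    i <- which(cmp$reference == ref & cmp$comparator == comp)
    if (length(i)) cmp$icer[i[1]] else NA_real_
  }
  tibble::tibble(
    horizon_weeks = x$settings$horizon_weeks,
    icer_bt_vs_standard = pick("standard", "bt"),
    icer_omalizumab_vs_bt = pick("bt", "omalizumab"),
    icer_omalizumab_vs_standard = pick("standard", "omalizumab"))
}

#' Export a cohort trace as CSV
#'
#' @param outcome Result of `run_cohort(..., trace = TRUE)`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace_csv <- function(outcome, path) {
  tr <- attr(outcome, "trace")
  if (is.null(tr)) stop("no trace attached; rerun with trace = TRUE", call. = FALSE)
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
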