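#' Individual-level microsimulation (validation oracle for the cohort engine)
#'
#' Simulates `n_individuals` weekly trajectories from exactly the same
#' transition-probability sequence the cohort engine uses, accruing the same
#' discounted costs, discounted QALYs and event counts per individual. The
#' sample means estimate the cohort-model outcomes; Monte Carlo standard
#' errors are reported so agreement can be judged on the SE scale.
#'
#' @param draw A one-row parameter draw.
#' @param strategy Strategy name (see [cea_strategies()]).
#' @param settings A [model_settings()] object.
#' @param n_individuals Number of simulated individuals.
#' @param seed Optional integer seed (reproducible when supplied).
#' @param life_table Background-mortality life table.
#' @return A one-row tibble of mean outcomes (`cost`, `qalys`, `n_ocs`,
#'   `n_ed`, `n_hosp`, `total_exacerbations`, `prop_dead`) with matching
#'   standard-error columns (`se_cost`, `se_qalys`, ...).
#' @export
microsimulate <- function(draw, strategy, settings = model_settings(),
                          n_individuals = 1e4, seed = NULL,
                          life_table = default_life_table()) {
  stopifnot(nrow(draw) == 1, n_individuals >= 1)
  strategy <- match.arg(strategy, cea_strategies())
  if (!is.null(seed)) set.seed(seed)
  si <- strategy_inputs(draw, strategy)
  u <- strategy_utilities(draw, si)
  u_by_state <- c(u$free, u$ocs, u$ed, u$hosp, 0)
  ecost_by_state <- c(0, draw$cost_event_ocs, draw$cost_event_ed,
                      draw$cost_event_hosp, 0)
  T <- settings$horizon_weeks
  N <- as.integer(n_individuals)
  disc <- (1 + settings$annual_discount_rate)^(-(seq_len(max(T, 1)) - 1) / 52)

  state <- rep(1L, N)   # 1 free, 2 ocs, 3 ed, 4 hosp, 5 dead
  cost <- rep(si$upfront, N)
  qalys <- numeric(N)
  events <- matrix(0, N, 3)

  for (w in seq_len(T) - 1L) {
    cp <- transition_components(draw, si, w, settings, life_table)
    d <- disc[w + 1]
    alive <- state != 5L
    qalys <- qalys + u_by_state[state] / 52 * d
    cost <- cost + si$drug_annual / 52 * d * alive
    r <- stats::runif(N)
    new <- state
    free <- state == 1L
    if (any(free)) {
      th <- cumsum(c(cp$p_free_ocs, cp$p_free_ed, cp$p_free_hosp, cp$p_free_dead))
      rf <- r[free]
      dest <- rep(1L, sum(free))
      dest[rf < th[4]] <- 5L
      dest[rf < th[3]] <- 4L
      dest[rf < th[2]] <- 3L
      dest[rf < th[1]] <- 2L
      new[free] <- dest
      entered <- dest %in% 2:4
      if (any(entered)) {
        idx <- which(free)[entered]
        dst <- dest[entered]
        cost[idx] <- cost[idx] + ecost_by_state[dst] * d
        events[cbind(idx, dst - 1L)] <- events[cbind(idx, dst - 1L)] + 1
      }
    }
    exac <- state %in% 2:3
    new[exac] <- ifelse(r[exac] < cp$p_exac_dead, 5L, 1L)
    hosp <- state == 4L
    new[hosp] <- ifelse(r[hosp] < cp$p_hosp_dead, 5L, 1L)
    state <- new
  }

  per <- tibble::tibble(cost = cost, qalys = qalys,
                        n_ocs = events[, 1], n_ed = events[, 2],
                        n_hosp = events[, 3],
                        total_exacerbations = rowSums(events),
                        prop_dead = as.numeric(state == 5L))
  means <- dplyr::summarise(per, across(dplyr::everything(), mean))
  ses <- dplyr::summarise(per, across(dplyr::everything(),
                                      ~ stats::sd(.x) / sqrt(N)))
  names(ses) <- paste0("se_", names(ses))
  dplyr::bind_cols(tibble::tibble(strategy = strategy, n_individuals = N),
                   means, ses)
}
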