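#' Incremental cost-effectiveness ratio between two strategies
#'
#' Computes the cost and QALY increments of `comparator` over `reference` and
#' classifies the comparison: a ratio is reported when the comparator is both
#' costlier and more effective (northeast quadrant) or both cheaper and less
#' effective (southwest quadrant, flagged via `quadrant`); otherwise the
#' comparator is labelled `"dominant"` (cheaper, at least as effective) or
#' `"dominated"`. Identical outcomes yield an `"undefined"` label, never a
#' division by zero.
#'
#' @param reference,comparator One-row outcome tibbles (columns `strategy`,
#'   `cost`, `qalys`), e.g. rows of [run_cohort()] output.
#' @return A one-row tibble: `reference`, `comparator`, `delta_cost`,
#'   `delta_qalys`, `icer`, `label`, `quadrant`.
#' @export
compute_icer <- function(reference, comparator) {
  dc <- comparator$cost - reference$cost
  dq <- comparator$qalys - reference$qalys
  if (dq == 0 && dc == 0) {
    label <- "undefined"; icer <- NA_real_; quad <- NA_character_
  } else if (dq >= 0 && dc <= 0) {
    label <- "dominant"; icer <- NA_real_; quad <- "southeast"
  } else if (dq <= 0 && dc >= 0) {
    label <- "dominated"; icer <- NA_real_; quad <- "northwest"
  } else {
    label <- "icer"; icer <- dc / dq
    quad <- if (dq > 0) "northeast" else "southwest"
  }
  tibble::tibble(reference = reference$strategy,
                 comparator = comparator$strategy,
                 delta_cost = dc, delta_qalys = dq,
                 icer = icer, label = label, quadrant = quad)
}

#' Net monetary benefit
#'
#' `NMB = wtp * QALYs - cost`; the strategy with the highest NMB at a given
#' willingness-to-pay is the optimal choice at that threshold.
#'
#' @param outcome An outcome tibble with columns `cost` and `qalys` (any
#'   number of rows).
#' @param wtp Willingness to pay ($/QALY), nonnegative scalar.
#' @return Numeric vector of net monetary benefits.
#' @export
net_monetary_benefit <- function(outcome, wtp) {
  stopifnot(wtp >= 0)
  wtp * outcome$qalys - outcome$cost
}

# samples -> iteration x strategy NMB matrix at one wtp
nmb_matrix <- function(samples, wtp) {
  wide_q <- tidyr::pivot_wider(samples[, c("iteration", "strategy", "qalys")],
                               names_from = "strategy", values_from = "qalys")
  wide_c <- tidyr::pivot_wider(samples[, c("iteration", "strategy", "cost")],
                               names_from = "strategy", values_from = "cost")
  q <- as.matrix(wide_q[, -1])
  cc <- as.matrix(wide_c[, -1])
  if (anyNA(q) || anyNA(cc)) {
    stop("every strategy must be present in every iteration", call. = FALSE)
  }
  wtp * q - cc
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability that each strategy is
#' optimal: the fraction of PSA iterations in which its net monetary benefit
#' is the maximum among all strategies (exact ties split equally), so the
#' probabilities sum to 1 across strategies at every threshold.
#'
#' @param samples A PSA sample table (columns `iteration`, `strategy`,
#'   `cost`, `qalys`), e.g. the `samples` element of [run_psa()].
#' @param wtp_grid Vector of willingness-to-pay values ($/QALY).
#' @return A tibble `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(samples, wtp_grid) {
  if (nrow(samples) == 0) stop("empty sample table", call. = FALSE)
  purrr::map_dfr(wtp_grid, function(wtp) {
    nmb <- nmb_matrix(samples, wtp)
    best <- nmb == apply(nmb, 1, max)
    share <- best / rowSums(best)
    tibble::tibble(wtp = wtp, strategy = colnames(nmb),
                   probability = unname(colMeans(share)))
  })
}

#' Expected value of perfect information
#'
#' Per-individual EVPI at each willingness-to-pay: the mean (over PSA
#' iterations) of the best attainable NMB under perfect information minus the
#' best expected NMB under current information,
#' `EVPI(wtp) = E[max_s NMB_s] - max_s E[NMB_s]`. Nonnegative by
#' construction, and exactly zero when all parameter distributions are
#' degenerate.
#'
#' @inheritParams ceac
#' @return A tibble `wtp`, `evpi` ($ per individual).
#' @export
evpi <- function(samples, wtp_grid) {
  if (nrow(samples) == 0) stop("empty sample table", call. = FALSE)
  if (dplyr::n_distinct(samples$iteration) < 2) {
    stop("EVPI needs at least 2 iterations", call. = FALSE)
  }
  purrr::map_dfr(wtp_grid, function(wtp) {
    nmb <- nmb_matrix(samples, wtp)
    tibble::tibble(wtp = wtp,
                   evpi = mean(apply(nmb, 1, max)) - max(colMeans(nmb)))
  })
}

#' Incremental analysis across all strategies
#'
#' Orders strategies by cost (ties broken by QALYs, descending), flags simple
#' and extended dominance on the cost-effectiveness frontier, and reports
#' pairwise ICERs both between cost-adjacent strategies and of every strategy
#' against the cheapest. Dominated strategies are flagged but still reported
#' pairwise.
#'
#' @param outcomes A tibble with one row per strategy (columns `strategy`,
#'   `cost`, `qalys`).
#' @return A list with `outcomes` (sorted, with `dominated` and
#'   `extended_dominated` flags) and `comparisons` (pairwise
#'   [compute_icer()] rows with a `comparison` type column).
#' @export
incremental_analysis <- function(outcomes) {
  if (nrow(outcomes) < 1) stop("no strategies", call. = FALSE)
  if (anyDuplicated(outcomes$strategy)) {
    stop("duplicate strategy names", call. = FALSE)
  }
  sorted <- dplyr::arrange(outcomes, .data$cost, dplyr::desc(.data$qalys))
  n <- nrow(sorted)
  dominated <- purrr::map_lgl(seq_len(n), function(i) {
    any(sorted$cost <= sorted$cost[i] & sorted$qalys >= sorted$qalys[i] &
          seq_len(n) != i &
          (sorted$cost < sorted$cost[i] | sorted$qalys > sorted$qalys[i]))
  })
  # extended dominance: on the non-dominated set, ICERs must increase with cost
  ext <- rep(FALSE, n)
  repeat {
    keep <- which(!dominated & !ext)
    if (length(keep) < 3) break
    icers <- diff(sorted$cost[keep]) / diff(sorted$qalys[keep])
    drop <- which(diff(icers) < 0)
    if (!length(drop)) break
    ext[keep[drop[1] + 1]] <- TRUE
  }
  sorted$dominated <- dominated
  sorted$extended_dominated <- ext
  comparisons <- NULL
  if (n >= 2) {
    adj <- purrr::map_dfr(2:n, function(i) {
      dplyr::mutate(compute_icer(sorted[i - 1, ], sorted[i, ]),
                    comparison = "adjacent")
    })
    vs_cheapest <- purrr::map_dfr(2:n, function(i) {
      dplyr::mutate(compute_icer(sorted[1, ], sorted[i, ]),
                    comparison = "vs_cheapest")
    })
    comparisons <- dplyr::distinct(
      dplyr::bind_rows(adj, vs_cheapest),
      .data$reference, .data$comparator, .keep_all = TRUE)
  } else {
    comparisons <- tibble::tibble(reference = character(), comparator = character(),
                                  delta_cost = numeric(), delta_qalys = numeric(),
                                  icer = numeric(), label = character(),
                                  quadrant = character(), comparison = character())
  }
  list(outcomes = sorted, comparisons = comparisons)
}

#' Cost-effectiveness plane points
#'
#' Per-iteration cost and QALY increments of every strategy against a
#' reference strategy, for plotting or CSV export.
#'
#' @inheritParams ceac
#' @param reference Reference strategy name.
#' @return A tibble `iteration`, `strategy`, `delta_cost`, `delta_qalys`.
#' @export
ce_plane <- function(samples, reference = "standard") {
  if (!reference %in% samples$strategy) {
    stop("unknown reference strategy: ", reference, call. = FALSE)
  }
  ref <- samples %>%
    filter(.data$strategy == reference) %>%
    select("iteration", ref_cost = "cost", ref_qalys = "qalys")
  samples %>%
    left_join(ref, by = "iteration") %>%
    mutate(delta_cost = .data$cost - .data$ref_cost,
           delta_qalys = .data$qalys - .data$ref_qalys) %>%
    select("iteration", "strategy", "delta_cost", "delta_qalys")
}
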