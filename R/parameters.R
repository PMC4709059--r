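#' @importFrom dplyr %>% mutate filter select arrange group_by ungroup summarise
#'   across left_join bind_rows bind_cols rename n
#' @importFrom rlang .data
NULL

# Canonical parameter inventory. `group` drives validation: rates/costs must be
# nonnegative, utilities and risks must lie in [0, 1] (utility deltas may be
# negative in a draw but not at the point estimate below 0 check is skipped).
parameter_inventory <- function() {
  tibble::tribble(
    ~name,                       ~group,          ~label,
    "rate_ocs",                  "rate",          "Annual rate of exacerbations requiring oral corticosteroids, standard therapy",
    "rate_ed",                   "rate",          "Annual rate of exacerbations requiring an emergency department visit, standard therapy",
    "rate_hosp",                 "rate",          "Annual rate of exacerbations requiring hospitalization, standard therapy",
    "rr_bt_ocs",                 "rr",            "Relative rate of OCS exacerbations, bronchial thermoplasty vs standard",
    "rr_bt_ed",                  "rr",            "Relative rate of ED exacerbations, bronchial thermoplasty vs standard",
    "rr_bt_hosp",                "rr",            "Relative rate of hospitalizations, bronchial thermoplasty vs standard",
    "rr_omalizumab_ocs",         "rr",            "Relative rate of OCS exacerbations, omalizumab vs standard",
    "rr_omalizumab_ed",          "rr",            "Relative rate of ED exacerbations, omalizumab vs standard",
    "rr_omalizumab_hosp",        "rr",            "Relative rate of hospitalizations, omalizumab vs standard",
    "death_risk_hosp",           "risk",          "30-day risk of death given an asthma hospitalization",
    "cost_event_ocs",            "cost",          "Unit cost of an OCS-treated exacerbation (2013 US$)",
    "cost_event_ed",             "cost",          "Unit cost of an ED-treated exacerbation (2013 US$)",
    "cost_event_hosp",           "cost",          "Unit cost of a hospitalized exacerbation (2013 US$)",
    "cost_drug_standard",        "cost",          "Annual cost of standard therapy (2013 US$/person-year)",
    "cost_drug_omalizumab",      "cost",          "Annual add-on cost of omalizumab (2013 US$/person-year)",
    "cost_bt_upfront",           "cost",          "One-time cost of bronchial thermoplasty (2013 US$)",
    "utility_free",              "utility",       "Utility of the exacerbation-free state, standard therapy",
    "utility_delta_bt",          "utility_delta", "Exacerbation-free utility difference, bronchial thermoplasty vs standard",
    "utility_delta_omalizumab",  "utility_delta", "Exacerbation-free utility difference, omalizumab vs standard",
    "utility_ocs",               "utility",       "Utility while in the OCS exacerbation state",
    "utility_ed",                "utility",       "Utility while in the ED exacerbation state",
    "utility_hosp",              "utility",       "Utility while in the hospitalization exacerbation state"
  )
}

#' Construct a validated parameter set
#'
#' A parameter set couples the tabular uncertain inputs of the model (annual
#' exacerbation rates under standard therapy, per-treatment relative rates,
#' event and treatment costs, health-state utilities, and the hospitalization
#' death risk — each a point estimate plus a distribution specification) with
#' a background-mortality life table.
#'
#' @param params A tibble with columns `name`, `value`, `family`, `param1`,
#'   `param2` (one row per parameter in the canonical inventory; see
#'   [default_parameters()] for the bundled set).
#' @param life_table A life table as produced by [default_life_table()]:
#'   columns `age`, `qx`.
#' @return An object of class `cea_parameters`.
#' @seealso [load_parameters()], [default_parameters()], [sample_parameters()]
#' @export
cea_parameters <- function(params, life_table = default_life_table()) {
  inv <- parameter_inventory()
  params <- tibble::as_tibble(params)
  required <- c("name", "value", "family", "param1", "param2")
  missing_cols <- setdiff(required, names(params))
  if (length(missing_cols)) {
    stop("parameter table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(params$name, inv$name)
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(inv$name, params$name)
  if (length(absent)) {
    stop("missing parameter(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(params$name)) {
    stop("duplicated parameter(s): ",
         paste(unique(params$name[duplicated(params$name)]), collapse = ", "),
         call. = FALSE)
  }
  params <- inv %>%
    left_join(params %>% select("name", "value", "family", "param1", "param2"),
              by = "name")
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    validate_dist(row$family, row$param1, row$param2, what = row$name)
    v <- row$value
    path <- paste0("parameters/", row$name)
    if (!is.finite(v)) stop("non-finite value at ", path, call. = FALSE)
    if (row$group %in% c("rate", "rr", "cost") && v < 0) {
      stop("negative value at ", path, " (must be >= 0)", call. = FALSE)
    }
    if (row$group %in% c("utility", "risk") && (v < 0 || v > 1)) {
      stop("value at ", path, " must lie in [0, 1]", call. = FALSE)
    }
  }
  validate_life_table(life_table)
  structure(list(params = params, life_table = tibble::as_tibble(life_table)),
            class = "cea_parameters")
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("<cea_parameters> ", nrow(x$params), " parameters; life table ages ",
      min(x$life_table$age), "-", max(x$life_table$age), "\n", sep = "")
  print(x$params, n = nrow(x$params))
  invisible(x)
}

json_dist_fields <- function() {
  list(lognormal = c("meanlog", "sdlog"), beta = c("shape1", "shape2"),
       gamma = c("shape", "rate"), normal = c("mean", "sd"),
       fixed = character(0))
}

#' Load a parameter set from a structured-text (JSON) file
#'
#' The on-disk format is a self-describing JSON document: a `parameters` array
#' whose entries carry a `name`, a point `value` and a `dist` object with an
#' explicit `family` and named (never positional) parameters, e.g.
#' `{"family": "lognormal", "meanlog": 0.29, "sdlog": 0.10}`. Unknown top-level
#' keys, unknown parameter names and missing parameters are all rejected, and
#' every invariant of [cea_parameters()] is checked.
#'
#' @param path Path to the JSON parameter file. The set distributed with the
#'   package is at `system.file("extdata", "asthma_parameters.json",
#'   package = "btcea")`.
#' @param life_table Background-mortality life table; defaults to the bundled
#'   synthetic table ([default_life_table()]).
#' @return A `cea_parameters` object.
#' @export
load_parameters <- function(path, life_table = default_life_table()) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  allowed <- c("format", "currency_year", "description", "parameters")
  extra <- setdiff(names(doc), allowed)
  if (length(extra)) {
    stop("unknown top-level key(s) in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (is.null(doc$parameters)) stop("no 'parameters' array in ", path, call. = FALSE)
  fields <- json_dist_fields()
  rows <- purrr::map(doc$parameters, function(p) {
    for (k in c("name", "value", "dist")) {
      if (is.null(p[[k]])) {
        stop("parameter entry missing '", k, "' field", call. = FALSE)
      }
    }
    fam <- p$dist$family
    if (is.null(fam) || !fam %in% dist_families()) {
      stop("unsupported distribution family for ", p$name, ": ",
           if (is.null(fam)) "<absent>" else fam, call. = FALSE)
    }
    want <- fields[[fam]]
    got <- setdiff(names(p$dist), "family")
    if (!setequal(got, want)) {
      stop("distribution for ", p$name, " must have fields {",
           paste(want, collapse = ", "), "}, got {",
           paste(got, collapse = ", "), "}", call. = FALSE)
    }
    tibble::tibble(
      name = p$name, value = as.numeric(p$value), family = fam,
      param1 = if (length(want) >= 1) as.numeric(p$dist[[want[1]]]) else as.numeric(p$value),
      param2 = if (length(want) >= 2) as.numeric(p$dist[[want[2]]]) else NA_real_
    )
  })
  cea_parameters(bind_rows(rows), life_table = life_table)
}

#' Write a parameter set to its JSON interchange format
#'
#' Round-trips through [load_parameters()] without loss.
#'
#' @param ps A `cea_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  stopifnot(inherits(ps, "cea_parameters"))
  fields <- json_dist_fields()
  entries <- purrr::pmap(ps$params, function(name, group, label, value, family,
                                             param1, param2) {
    dist <- c(list(family = family),
              stats::setNames(as.list(c(param1, param2)[seq_along(fields[[family]])]),
                              fields[[family]]))
    list(name = name, label = label, value = value, dist = dist)
  })
  doc <- list(format = "btcea-parameters", currency_year = 2013,
              parameters = entries)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export the loaded parameter table as CSV for audit
#'
#' @param ps A `cea_parameters` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_parameters_csv <- function(ps, path) {
  stopifnot(inherits(ps, "cea_parameters"))
  utils::write.csv(ps$params, path, row.names = FALSE)
  invisible(path)
}

#' Point-estimate parameter draw
#'
#' Returns the "value" column of the parameter table as a one-row wide tibble
#' (one column per parameter), the format consumed by [run_cohort()]. No
#' sampling takes place; repeated calls are identical.
#'
#' @param ps A `cea_parameters` object.
#' @return A one-row tibble with one numeric column per parameter.
#' @export
point_estimates <- function(ps) {
  stopifnot(inherits(ps, "cea_parameters"))
  tibble::as_tibble(as.list(stats::setNames(ps$params$value, ps$params$name)))
}

#' Sample concrete parameter draws for probabilistic analysis
#'
#' Draws `n` joint realizations of the uncertain parameters, each parameter
#' independently from its assigned distribution ("fixed" entries are returned
#' unchanged). One row of the result is one joint draw, shared across
#' strategies within a PSA iteration.
#'
#' @param ps A `cea_parameters` object.
#' @param n Number of joint draws.
#' @param seed Optional integer; when given, the draw is reproducible
#'   (bit-identical across calls with the same seed).
#' @return An `n`-row tibble, one column per parameter.
#' @export
sample_parameters <- function(ps, n = 1, seed = NULL) {
  stopifnot(inherits(ps, "cea_parameters"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cols <- purrr::pmap(ps$params, function(name, group, label, value, family,
                                          param1, param2) {
    dist_sample(family, param1, param2, n)
  })
  tibble::as_tibble(stats::setNames(cols, ps$params$name))
}

#' Widen or shrink every distribution spread by a common factor
#'
#' Multiplies each distribution's spread by `scale` while preserving its
#' centre: log-scale SDs and normal SDs are multiplied directly; beta and
#' gamma shapes are divided by `scale^2` (keeping the mean, scaling the SD
#' approximately linearly). `scale = 0` collapses every distribution to its
#' point value, making a PSA reproduce the point-estimate run exactly.
#'
#' @param ps A `cea_parameters` object.
#' @param scale Nonnegative spread multiplier.
#' @return A new `cea_parameters` object.
#' @export
perturb_parameters <- function(ps, scale) {
  stopifnot(inherits(ps, "cea_parameters"))
  if (!is.numeric(scale) || length(scale) != 1 || is.na(scale) || scale < 0) {
    stop("scale must be a nonnegative number", call. = FALSE)
  }
  p <- ps$params
  if (scale == 0) {
    p$family <- "fixed"
    p$param1 <- p$value
    p$param2 <- NA_real_
  } else {
    for (i in seq_len(nrow(p))) {
      fam <- p$family[i]
      if (fam %in% c("lognormal", "normal")) {
        p$param2[i] <- p$param2[i] * scale
      } else if (fam %in% c("beta", "gamma")) {
        p$param1[i] <- p$param1[i] / scale^2
        p$param2[i] <- p$param2[i] / scale^2
      }
    }
  }
  cea_parameters(p, life_table = ps$life_table)
}

#' Set a parameter's point value (deterministic sensitivity analyses)
#'
#' Returns a copy of `ps` with the named parameter's point estimate replaced.
#' The distribution is left untouched; deterministic analyses use
#' [point_estimates()] and so see only the value.
#'
#' @param ps A `cea_parameters` object.
#' @param name Canonical parameter name.
#' @param value New point value.
#' @return A new `cea_parameters` object.
#' @export
set_parameter_value <- function(ps, name, value) {
  stopifnot(inherits(ps, "cea_parameters"))
  if (!name %in% ps$params$name) {
    stop("unknown parameter path: ", name, call. = FALSE)
  }
  p <- ps$params
  p$value[p$name == name] <- value
  cea_parameters(p, life_table = ps$life_table)
}

#' Convert an annual event rate to a weekly transition probability
#'
#' Uses the exponential-waiting-time conversion `1 - exp(-rate / 52)`.
#'
#' @param annual_rate Nonnegative annual event rate (events/person-year).
#' @return Weekly probability in `[0, 1)`.
#' @examples
#' rate_to_weekly_probability(1.35)
#' @export
rate_to_weekly_probability <- function(annual_rate) {
  if (any(!is.finite(annual_rate)) || any(annual_rate < 0)) {
    stop("annual_rate must be nonnegative", call. = FALSE)
  }
  1 - exp(-annual_rate / 52)
}

#' Apply a treatment relative rate to a baseline annual rate
#'
#' @param baseline_rate Nonnegative annual rate under standard therapy.
#' @param rr Nonnegative relative rate (treatment vs standard).
#' @return Treated annual rate `baseline_rate * rr`.
#' @export
apply_relative_rate <- function(baseline_rate, rr) {
  if (any(!is.finite(baseline_rate)) || any(baseline_rate < 0)) {
    stop("baseline_rate must be nonnegative", call. = FALSE)
  }
  if (any(!is.finite(rr)) || any(rr < 0)) {
    stop("rr must be nonnegative", call. = FALSE)
  }
  baseline_rate * rr
}

#' Model run settings
#'
#' @param horizon_weeks Time horizon in weekly cycles (base case 260 = 5
#'   years).
#' @param annual_discount_rate Annual discount rate applied to both costs and
#'   QALYs (base case 0.03).
#' @param baseline_age_years Cohort age at entry (base case 40).
#' @param waning Treatment-effect waning configuration: [waning_none()] or
#'   [waning_exponential()].
#' @param wtp_grid Willingness-to-pay grid ($/QALY) for acceptability curves
#'   and value-of-information analyses.
#' @return A list of class `cea_settings`.
#' @export
model_settings <- function(horizon_weeks = 260,
                           annual_discount_rate = 0.03,
                           baseline_age_years = 40,
                           waning = waning_none(),
                           wtp_grid = seq(0, 2e5, by = 5000)) {
  stopifnot(horizon_weeks >= 0, horizon_weeks == round(horizon_weeks),
            annual_discount_rate >= 0, baseline_age_years >= 0,
            all(wtp_grid >= 0))
  if (identical(waning$type, "exponential") && waning$onset_week > horizon_weeks) {
    stop("waning onset must lie within the horizon", call. = FALSE)
  }
  structure(list(horizon_weeks = as.integer(horizon_weeks),
                 cycle_length_weeks = 1L,
                 annual_discount_rate = annual_discount_rate,
                 baseline_age_years = baseline_age_years,
                 waning = waning,
                 wtp_grid = wtp_grid),
            class = "cea_settings")
}

#' Treatment-effect waning configurations
#'
#' With `waning_none()` relative rates are constant over the horizon. With
#' `waning_exponential()`, for every week `t` strictly after `onset_week` the
#' log relative rate decays geometrically toward 0 (i.e. the relative rate
#' drifts back to 1): `log rr_t = log(rr) * 2^(-(t - onset)/half_life)`.
#'
#' @param onset_week Week after which the decay starts (e.g. 260 for "after
#'   the fifth year").
#' @param half_life_weeks Half-life of the log relative rate, in weeks
#'   (default 52: one year).
#' @param strategies Names of strategies whose effects wane (default the
#'   thermoplasty arm, whose long-term efficacy is the uncertain one).
#' @return A waning configuration list.
#' @export
waning_exponential <- function(onset_week, half_life_weeks = 52,
                               strategies = "bt") {
  stopifnot(onset_week >= 0, half_life_weeks >= 0)
  list(type = "exponential", onset_week = onset_week,
       half_life_weeks = half_life_weeks, strategies = strategies)
}

#' @rdname waning_exponential
#' @export
waning_none <- function() list(type = "none")
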