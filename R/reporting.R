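#' Display rounding conventions for monetary results
#'
#' Model cost outputs are displayed to the nearest $1,000; ICERs to the
#' nearest $100 below $1 million and to three significant figures above.
#' Rounding applies only at the report layer — stored CSV/JSON values keep
#' full precision.
#'
#' @param x Numeric vector of dollar amounts.
#' @return Rounded numeric vector.
#' @export
round_cost_display <- function(x) round(x / 1000) * 1000

#' @rdname round_cost_display
#' @export
round_icer_display <- function(x) {
  ifelse(is.na(x), NA_real_,
         ifelse(abs(x) < 1e6, round(x / 100) * 100, signif(x, 3)))
}

run_manifest <- function(command, config, seed, outputs) {
  list(command = command,
       config = if (is.null(config)) NA else normalizePath(config, mustWork = FALSE),
       config_md5 = if (is.null(config)) NA else unname(tools::md5sum(config)),
       seed = if (is.null(seed)) NA else seed,
       package_version = as.character(utils::packageVersion("btcea")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = as.list(outputs))
}

write_manifest <- function(manifest, dir) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

load_config <- function(config, life_table = NULL) {
  lt <- if (is.null(life_table)) default_life_table()
        else tibble::as_tibble(utils::read.csv(life_table))
  if (is.null(config)) default_parameters(life_table = lt)
  else load_parameters(config, life_table = lt)
}

#' Base-case report
#'
#' Runs the point-estimate model for all strategies and writes the outcome
#' table, the pairwise incremental analysis, a display-rounded JSON summary
#' and a run manifest into `out_dir`. Outputs are deterministic: reruns are
#' byte-identical apart from the manifest timestamp.
#'
#' @param config Path to a JSON parameter file, or `NULL` for the bundled
#'   published set.
#' @param out_dir Output directory (created if needed).
#' @param settings A [model_settings()] object.
#' @param life_table Optional path to a life-table CSV.
#' @return The `cea_base_case` object, invisibly.
#' @export
report_base_case <- function(config = NULL, out_dir = ".",
                             settings = model_settings(), life_table = NULL) {
  ps <- load_config(config, life_table)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bc <- run_base_case(ps, settings)
  paths <- c(outcomes = file.path(out_dir, "base_case_outcomes.csv"),
             icers = file.path(out_dir, "base_case_icers.csv"),
             report = file.path(out_dir, "base_case_report.json"))
  utils::write.csv(bc$outcomes, paths[["outcomes"]], row.names = FALSE)
  utils::write.csv(bc$comparisons, paths[["icers"]], row.names = FALSE)
  display <- list(
    outcomes = purrr::pmap(bc$outcomes, function(strategy, cost, qalys, n_ocs,
                                                 n_ed, n_hosp,
                                                 total_exacerbations,
                                                 prop_dead) {
      list(strategy = strategy, cost = round_cost_display(cost),
           qalys = round(qalys, 2),
           total_exacerbations = round(total_exacerbations, 2),
           prop_dead = round(prop_dead, 3))
    }),
    icers = purrr::pmap(bc$comparisons, function(reference, comparator, icer,
                                                 label, ...) {
      list(comparator = comparator, reference = reference, label = label,
           icer = round_icer_display(icer))
    }))
  jsonlite::write_json(display, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_manifest(run_manifest("base-case", config, NULL, paths), out_dir)
  invisible(bc)
}

#' Probabilistic sensitivity analysis report
#'
#' Runs the full PSA and writes iteration-level samples, the
#' cost-effectiveness plane, acceptability curves, the EVPI curve, the
#' credible-interval summary and a manifest.
#'
#' @inheritParams report_base_case
#' @param n_iter Number of iterations (default 10,000).
#' @param seed Integer seed recorded in the manifest.
#' @return The `cea_psa` object, invisibly.
#' @export
report_psa <- function(config = NULL, out_dir = ".", n_iter = 10000,
                       seed = 1, settings = model_settings(),
                       life_table = NULL) {
  ps <- load_config(config, life_table)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  psa <- run_psa(ps, settings, n_iter = n_iter, seed = seed)
  paths <- c(samples = file.path(out_dir, "psa_samples.csv"),
             ce_plane = file.path(out_dir, "ce_plane.csv"),
             ceac = file.path(out_dir, "ceac.csv"),
             evpi = file.path(out_dir, "evpi.csv"),
             summary = file.path(out_dir, "psa_summary.csv"))
  export_psa_csv(psa, paths[["samples"]])
  utils::write.csv(ce_plane(psa$samples, "standard"), paths[["ce_plane"]],
                   row.names = FALSE)
  utils::write.csv(ceac(psa$samples, settings$wtp_grid), paths[["ceac"]],
                   row.names = FALSE)
  utils::write.csv(evpi(psa$samples, settings$wtp_grid), paths[["evpi"]],
                   row.names = FALSE)
  utils::write.csv(summarize_psa(psa$samples), paths[["summary"]],
                   row.names = FALSE)
  write_manifest(c(run_manifest("psa", config, seed, paths),
                   list(n_iter = n_iter)), out_dir)
  invisible(psa)
}

#' Deterministic sensitivity analysis report
#'
#' Runs the tornado analysis (from a scenario file or the defaults), the
#' thermoplasty cost sweep and the threshold-cost search at $50,000 and
#' $100,000 per QALY, writing each as CSV plus a manifest. An empty scenario
#' file triggers a warning and the sweep/threshold analyses run alone.
#'
#' @inheritParams report_base_case
#' @param scenario_file Optional CSV with columns `label`, `name`, `low`,
#'   `high`; `NULL` uses [default_tornado_scenarios()].
#' @param wtp_thresholds Willingness-to-pay values for the threshold-cost
#'   search.
#' @return A list with `tornado`, `sweep`, `thresholds`, invisibly.
#' @export
report_dsa <- function(config = NULL, out_dir = ".", scenario_file = NULL,
                       settings = model_settings(),
                       wtp_thresholds = c(5e4, 1e5), life_table = NULL) {
  ps <- load_config(config, life_table)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scenarios <- if (is.null(scenario_file)) {
    default_tornado_scenarios(ps)
  } else {
    tibble::as_tibble(utils::read.csv(scenario_file))
  }
  tornado <- NULL
  if (nrow(scenarios) == 0) {
    warning("empty scenario file: running sweep and thresholds only",
            call. = FALSE)
  } else {
    tornado <- one_way_tornado(ps, scenarios, settings)
  }
  sweep <- bt_cost_sweep(ps, settings = settings)
  thresholds <- tibble::tibble(
    wtp = wtp_thresholds,
    bt_cost = purrr::map_dbl(wtp_thresholds,
                             ~ threshold_cost(ps, .x, settings)))
  paths <- c(sweep = file.path(out_dir, "bt_cost_sweep.csv"),
             thresholds = file.path(out_dir, "threshold_costs.csv"))
  if (!is.null(tornado)) {
    paths <- c(tornado = file.path(out_dir, "tornado.csv"), paths)
    utils::write.csv(tornado, paths[["tornado"]], row.names = FALSE)
  }
  utils::write.csv(sweep, paths[["sweep"]], row.names = FALSE)
  utils::write.csv(thresholds, paths[["thresholds"]], row.names = FALSE)
  write_manifest(run_manifest("dsa", config, NULL, paths), out_dir)
  invisible(list(tornado = tornado, sweep = sweep, thresholds = thresholds))
}
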