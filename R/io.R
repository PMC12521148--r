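#' Read a YAML run configuration
#'
#' A run configuration ties the pipeline together for scripted use: which
#' parameter table to load (packaged study tables by default), the cost
#' basis, the comparator pairs, the WTP threshold, and the PSA and
#' synthetic-cohort settings. Every field has a default, so an empty file is
#' a valid configuration reproducing the packaged analysis.
#'
#' Recognised fields:
#' \preformatted{
#' parameters: path to a strategy CSV (default: packaged table)
#' cost_basis: ics | medication
#' comparisons: [{ref: A1, alt: A2}, ...]
#' wtp: 287100
#' psa: {n_iterations: 1000, seed: 42, cv_fallback: 0.3,
#'       wtp_grid: {from: 0, to: 600000, by: 10000},
#'       pair: {ref: A, alt: B}}
#' cohort: {n_patients: null, seed: 7}
#' }
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- list(
    parameters = raw$parameters,
    cost_basis = raw$cost_basis %||% "ics",
    comparisons = raw$comparisons %||%
      list(list(ref = "A1", alt = "A2"), list(ref = "B1", alt = "B2"),
           list(ref = "A", alt = "B")),
    wtp = raw$wtp %||% 287100,
    psa = utils::modifyList(
      list(n_iterations = 1000, seed = 42, cv_fallback = 0.3,
           wtp_grid = list(from = 0, to = 600000, by = 10000),
           pair = list(ref = "A", alt = "B")),
      raw$psa %||% list()),
    cohort = utils::modifyList(list(n_patients = NULL, seed = 7),
                               raw$cohort %||% list())
  )
  cfg$cost_basis <- match.arg(cfg$cost_basis, c("ics", "medication"))
  structure(cfg, class = "run_config")
}

config_params <- function(config) {
  if (is.null(config$parameters)) {
    asthma_strategies(config$cost_basis)
  } else {
    read_strategy_table(config$parameters, cost_basis = config$cost_basis)
  }
}

config_pairs <- function(comparisons) {
  tibble::tibble(
    ref = vapply(comparisons, function(p) p$ref, character(1)),
    alt = vapply(comparisons, function(p) p$alt, character(1))
  )
}

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

#' Run the cost-utility evaluation from a configuration
#'
#' Loads the parameter table, evaluates every strategy and every configured
#' comparison, and writes `cua_results.csv` (tidy long table) and
#' `cua_results.json` to the output directory.
#'
#' @param config A [read_run_config()] object (or `NULL` for defaults).
#' @param out_dir Output directory.
#' @return The `cua_table`, invisibly.
#' @export
run_evaluate <- function(config = read_run_config(), out_dir = ".") {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  ensure_dir(out_dir)
  tab <- cua_table(config_params(config), config_pairs(config$comparisons),
                   wtp = config$wtp)
  readr::write_csv(generics::tidy(tab), file.path(out_dir, "cua_results.csv"))
  jsonlite::write_json(
    list(strategies = tab$strategies, comparisons = tab$comparisons,
         wtp = tab$wtp, cost_basis = tab$cost_basis),
    file.path(out_dir, "cua_results.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(tab)
}

#' Run the cost-effectiveness analysis from a configuration
#'
#' Builds the C/E and ICER table from the packaged per-strategy mean costs
#' and effectiveness rates on the configured cost basis and writes
#' `cea_results.csv`.
#'
#' @inheritParams run_evaluate
#' @return The `cea_table`, invisibly.
#' @export
run_cea <- function(config = read_run_config(), out_dir = ".") {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  ensure_dir(out_dir)
  tab <- cea_table(asthma_mean_costs(config$cost_basis),
                   asthma_effectiveness(),
                   comparisons = config_pairs(config$comparisons))
  readr::write_csv(tibble::as_tibble(tab),
                   file.path(out_dir, "cea_results.csv"))
  invisible(tab)
}

#' Run the probabilistic sensitivity analysis from a configuration
#'
#' Builds the PSA priors for the configured pair (Gamma cost priors from the
#' packaged cost moments, Dirichlet probability priors from the packaged
#' visit counts), runs the Monte Carlo propagation, and writes the draws
#' (`psa_draws.csv`), the acceptability curve (`ceac.csv`) and the two
#' figures (`ce_plane.png`, `ceac.png`).
#'
#' @inheritParams run_evaluate
#' @return The `psa_result`, invisibly.
#' @export
run_psa_workflow <- function(config = read_run_config(), out_dir = ".") {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  ensure_dir(out_dir)
  pair <- config$psa$pair
  ref <- asthma_psa_spec(pair$ref, config$cost_basis,
                         cv = config$psa$cv_fallback)
  alt <- asthma_psa_spec(pair$alt, config$cost_basis,
                         cv = config$psa$cv_fallback)
  psa <- run_psa(ref, alt, n = config$psa$n_iterations,
                 seed = config$psa$seed, wtp = config$wtp)
  grid <- config$psa$wtp_grid
  curve <- ceac(psa, wtp_grid = seq(grid$from, grid$to, by = grid$by))
  readr::write_csv(psa$draws, file.path(out_dir, "psa_draws.csv"))
  readr::write_csv(curve, file.path(out_dir, "ceac.csv"))
  ggplot2::ggsave(file.path(out_dir, "ce_plane.png"), autoplot(psa),
                  width = 6, height = 5, dpi = 150)
  ggplot2::ggsave(file.path(out_dir, "ceac.png"),
                  autoplot(curve, wtp = psa$wtp),
                  width = 6, height = 4, dpi = 150)
  invisible(psa)
}

#' Generate and aggregate a synthetic cohort from a configuration
#'
#' Generates the study-calibrated synthetic cohort (optionally scaled to a
#' different number of patients per subgroup), writes the patient- and
#' visit-level CSVs, aggregates the cohort back into model parameters and
#' writes the recovered strategy tables.
#'
#' @inheritParams run_evaluate
#' @return The `cohort_summary`, invisibly.
#' @export
run_simulate <- function(config = read_run_config(), out_dir = ".") {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  ensure_dir(out_dir)
  n <- config$cohort$n_patients
  cfg <- asthma_cohort_config(n_patients = if (is.null(n)) NULL else
    unlist(n), seed = config$cohort$seed)
  cohort <- generate_cohort(cfg)
  write_cohort_csv(cohort, out_dir)
  summ <- aggregate_cohort(cohort)
  readr::write_csv(tibble::as_tibble(summ$strategies_ics),
                   file.path(out_dir, "recovered_strategies_ics.csv"))
  readr::write_csv(tibble::as_tibble(summ$strategies_medication),
                   file.path(out_dir, "recovered_strategies_medication.csv"))
  readr::write_csv(summ$effectiveness,
                   file.path(out_dir, "recovered_effectiveness.csv"))
  invisible(summ)
}

#' Study-calibrated PSA prior for one strategy
#'
#' Convenience wrapper around [psa_spec()] that wires in the packaged study
#' aggregates: the strategy's Table of decision-tree parameters on the given
#' cost basis, Gamma cost priors with the printed per-state cost sds for
#' that basis, and a Dirichlet probability prior with the printed visit
#' counts as concentration.
#'
#' @param label Strategy (one of A1, A2, A, B1, B2, B).
#' @param cost_basis `"ics"` or `"medication"`.
#' @param ... Passed on to [psa_spec()].
#' @return A `psa_spec`.
#' @export
#' @examples
#' asthma_psa_spec("A", "ics")
asthma_psa_spec <- function(label, cost_basis = c("ics", "medication"), ...) {
  cost_basis <- match.arg(cost_basis)
  params <- asthma_strategies(cost_basis)
  sds <- dplyr::filter(asthma_cost_moments(),
                       .data$category == cost_basis,
                       .data$strategy == label)
  counts <- dplyr::filter(asthma_visit_counts(), .data$strategy == label)
  psa_spec(params, label,
           cost_sd = sds[c("state", "sd")],
           prob_counts = counts, ...)
}
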