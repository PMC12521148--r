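#' Packaged study aggregates for the pediatric asthma cohort
#'
#' The package ships the printed group-level aggregates of the 59-child
#' retrospective cohort behind its worked examples: a single-inhaler arm A
#' (A1 = salmeterol-fluticasone, A2 = budesonide-formoterol) and a
#' multiple-inhaler arm B (B1 = dual combinations, B2 = triple combination),
#' plus the pooled columns `A` and `B`. These accessors read the plain-text
#' tables under `inst/extdata/` and return tidy tibbles ready for the model
#' functions.
#'
#' * `asthma_strategies()` -- the decision-tree parameter table (per-state
#'   cost, probability, utility) for one cost basis, as a
#'   [strategy_params()] object.
#' * `asthma_visit_counts()` -- per-strategy visit counts by health state,
#'   the raw input behind the branch probabilities.
#' * `asthma_effectiveness()` -- per-strategy counts of patients whose
#'   longest symptom-free duration reached 3/6/12/24 months, with the
#'   corresponding percentage rates.
#' * `asthma_mean_costs()` -- per-strategy average cost on both cost bases
#'   (ICS-only and total medication), the numerators of the C/E ratios.
#' * `asthma_cost_moments()` -- per (strategy, state, cost category) mean and
#'   sd, used as Gamma priors in the PSA and by the cohort generator.
#' * `asthma_visit_moments()` -- per-strategy visit-count and follow-up
#'   moments used by the cohort generator.
#'
#' @param cost_basis `"ics"` or `"medication"`.
#' @return A tibble (see the individual descriptions).
#' @name asthma_data
NULL

qt_extdata <- function(file) {
  path <- system.file("extdata", file, package = "qalytree")
  if (!nzchar(path)) stop("packaged data file not found: ", file, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname asthma_data
#' @export
asthma_strategies <- function(cost_basis = c("ics", "medication")) {
  cost_basis <- match.arg(cost_basis)
  read_strategy_table(
    system.file("extdata", paste0("strategies_", cost_basis, ".csv"),
                package = "qalytree"),
    cost_basis = cost_basis
  )
}

#' @rdname asthma_data
#' @export
asthma_visit_counts <- function() {
  qt_extdata("visit_counts.csv")
}

#' @rdname asthma_data
#' @export
asthma_effectiveness <- function() {
  x <- qt_extdata("effectiveness_counts.csv")
  dplyr::mutate(x, rate_percent = 100 * .data$n_achieving / .data$n_patients)
}

#' @rdname asthma_data
#' @export
asthma_mean_costs <- function(cost_basis = NULL) {
  x <- qt_extdata("mean_costs.csv")
  if (!is.null(cost_basis)) {
    cost_basis <- match.arg(cost_basis, c("ics", "medication"))
    x <- dplyr::filter(x, .data$cost_basis == !!cost_basis)
  }
  x
}

#' @rdname asthma_data
#' @export
asthma_cost_moments <- function() {
  qt_extdata("cost_moments.csv")
}

#' @rdname asthma_data
#' @export
asthma_visit_moments <- function() {
  qt_extdata("visit_moments.csv")
}
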