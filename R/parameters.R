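#' The three health states of the decision tree
#'
#' Every parameter vector in the model is indexed by the same three mutually
#' exclusive health states a visit can fall into: an acute exacerbation
#' requiring hospitalization, an acute exacerbation managed in outpatient
#' care, and a symptom-free (maintenance) visit. The ordering returned here
#' is fixed and used for all state-indexed tables in the package.
#'
#' @return Character vector of the three state labels, in canonical order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("hospitalization", "outpatient_exacerbation", "symptom_free")
}

#' Build a utility model for the decision tree
#'
#' Health-state utilities are derived from a base annual utility for a
#' well-controlled (symptom-free) year, per-state annual decrements for the
#' exacerbation states, and a fixed simulation horizon. The default values
#' are the literature-derived weights used for pediatric asthma: base utility
#' 0.867/year, decrement -0.1 for an exacerbation managed as an outpatient,
#' -0.22 for an exacerbation requiring hospitalization, over an 18-year
#' horizon. A discount-rate field is reserved; the default (and the model the
#' defaults reproduce) applies no discounting.
#'
#' @param base_utility Annual utility of the symptom-free state, in `[0, 1]`.
#' @param decrements Named numeric vector of annual utility decrements
#'   (<= 0), one per health state; the symptom-free decrement must be 0.
#' @param horizon_years Simulation horizon in years (> 0).
#' @param discount_rate Annual discount rate (>= 0). Reserved; default 0.
#' @return An object of class `utility_model`.
#' @export
#' @examples
#' utility_model()
#' state_utilities(utility_model())
utility_model <- function(base_utility = 0.867,
                          decrements = c(hospitalization = -0.22,
                                         outpatient_exacerbation = -0.1,
                                         symptom_free = 0),
                          horizon_years = 18,
                          discount_rate = 0) {
  states <- health_states()
  if (!is.numeric(base_utility) || length(base_utility) != 1L ||
      base_utility < 0 || base_utility > 1) {
    stop("`base_utility` must be a single value in [0, 1]", call. = FALSE)
  }
  if (is.null(names(decrements)) || !setequal(names(decrements), states)) {
    stop("`decrements` must be named with the three health states",
         call. = FALSE)
  }
  decrements <- decrements[states]
  if (any(decrements > 0)) {
    stop("utility decrements must be <= 0", call. = FALSE)
  }
  annual <- base_utility + decrements
  if (any(annual < -1) || any(annual > 1)) {
    stop("annual state utility (base + decrement) must lie in [-1, 1]",
         call. = FALSE)
  }
  if (!is.numeric(horizon_years) || length(horizon_years) != 1L ||
      horizon_years <= 0) {
    stop("`horizon_years` must be a single positive number", call. = FALSE)
  }
  if (discount_rate < 0) {
    stop("`discount_rate` must be >= 0", call. = FALSE)
  }
  structure(
    list(base_utility = base_utility,
         decrements = decrements,
         horizon_years = horizon_years,
         discount_rate = discount_rate),
    class = "utility_model"
  )
}

#' @export
print.utility_model <- function(x, ...) {
  cat("<utility_model>\n")
  cat("  base utility:", x$base_utility, "/year; horizon:",
      x$horizon_years, "years; discount rate:", x$discount_rate, "\n")
  print(state_utilities(x))
  invisible(x)
}

# Horizon multiplier: plain years at rate 0, otherwise the annuity factor.
horizon_factor <- function(horizon_years, discount_rate) {
  if (discount_rate == 0) {
    horizon_years
  } else {
    (1 - (1 + discount_rate)^(-horizon_years)) / discount_rate
  }
}

#' Derive per-state QALY utilities from a utility model
#'
#' Each state's lifetime utility is `(base_utility + decrement) * horizon`
#' (with the annuity factor replacing the bare horizon when a non-zero
#' discount rate is set). With the default model this gives 15.6060 QALYs for
#' the symptom-free state, 13.8060 for outpatient exacerbations and 11.6460
#' for hospitalization.
#'
#' @param model A [utility_model()].
#' @return A tibble with columns `state` and `utility_qaly`.
#' @export
#' @examples
#' state_utilities(utility_model())
state_utilities <- function(model) {
  stopifnot(inherits(model, "utility_model"))
  u <- (model$base_utility + model$decrements) *
    horizon_factor(model$horizon_years, model$discount_rate)
  if (any(u < 0)) {
    stop("utility below zero: decrements are inconsistent with the base utility",
         call. = FALSE)
  }
  tibble::tibble(state = health_states(), utility_qaly = unname(u))
}

#' Derive state probabilities as visit shares
#'
#' The probability attached to each branch of the decision tree is the share
#' of all recorded visits that fall in that health state:
#' `p_i = visits_i / sum(visits)`, computed per strategy.
#'
#' @param counts A data frame with columns `state`, `visits` and optionally
#'   `strategy` (shares are computed within strategy), or a named numeric
#'   vector of visit counts over the three health states.
#' @return A tibble with columns (`strategy`,) `state`, `visits`,
#'   `probability`; probabilities sum to 1 within each strategy.
#' @export
#' @examples
#' visit_share_probabilities(c(hospitalization = 8,
#'                             outpatient_exacerbation = 8,
#'                             symptom_free = 30))
visit_share_probabilities <- function(counts) {
  if (is.numeric(counts)) {
    counts <- tibble::tibble(state = names(counts), visits = unname(counts))
  }
  stopifnot(is.data.frame(counts),
            all(c("state", "visits") %in% names(counts)))
  if (any(counts$visits < 0)) {
    stop("visit counts must be non-negative", call. = FALSE)
  }
  grouped <- if ("strategy" %in% names(counts)) {
    dplyr::group_by(counts, .data$strategy)
  } else {
    counts
  }
  out <- dplyr::mutate(grouped, total = sum(.data$visits))
  out <- dplyr::ungroup(out)
  if (any(out$total == 0)) {
    stop("empty cohort: all visit counts are zero", call. = FALSE)
  }
  out <- dplyr::mutate(out, probability = .data$visits / .data$total)
  dplyr::select(out, -"total")
}

#' Validate a strategy parameter table
#'
#' A strategy parameter table holds, for one or more strategies, the
#' per-state branch cost (CNY), branch probability and branch utility (QALYs)
#' of the decision tree -- one row per (strategy, state). Probabilities must
#' sum to 1 within each strategy; `prob_tol` defaults to the slack needed by
#' tables printed at 4 decimals (5e-4) and can be tightened to machine
#' tolerance for freshly derived shares.
#'
#' @param x A data frame with columns `strategy`, `state`, `cost_cny`,
#'   `probability`, `utility_qaly`.
#' @param cost_basis Which costs the table carries: `"ics"` (inhaled
#'   corticosteroid costs only) or `"medication"` (total medication costs).
#' @param prob_tol Allowed deviation of each strategy's probability sum
#'   from 1.
#' @return The validated table as a `strategy_params` tibble (rows ordered by
#'   strategy and canonical state order), with the cost basis recorded as an
#'   attribute.
#' @export
strategy_params <- function(x, cost_basis = c("ics", "medication"),
                            prob_tol = 5e-4) {
  cost_basis <- match.arg(cost_basis)
  needed <- c("strategy", "state", "cost_cny", "probability", "utility_qaly")
  if (!is.data.frame(x) || !all(needed %in% names(x))) {
    stop("strategy table must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)[needed]
  states <- health_states()
  bad_state <- setdiff(unique(x$state), states)
  if (length(bad_state)) {
    stop("unknown health state(s): ", paste(bad_state, collapse = ", "),
         call. = FALSE)
  }
  per <- dplyr::summarise(
    dplyr::group_by(x, .data$strategy),
    n_states = dplyr::n_distinct(.data$state),
    n_rows = dplyr::n(),
    prob_sum = sum(.data$probability),
    .groups = "drop"
  )
  if (any(per$n_states != 3L) || any(per$n_rows != 3L)) {
    bad <- per$strategy[per$n_states != 3L | per$n_rows != 3L]
    stop("incomplete strategy: ", paste(bad, collapse = ", "),
         " must have exactly one row per health state", call. = FALSE)
  }
  if (any(abs(per$prob_sum - 1) > prob_tol)) {
    bad <- per$strategy[abs(per$prob_sum - 1) > prob_tol]
    stop("probability normalization: probabilities for ",
         paste(bad, collapse = ", "), " do not sum to 1 (tolerance ",
         format(prob_tol), ")", call. = FALSE)
  }
  if (any(x$probability < 0 | x$probability > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(x$cost_cny < 0)) {
    stop("state costs must be >= 0", call. = FALSE)
  }
  if (any(x$utility_qaly < 0)) {
    stop("state utilities must be >= 0", call. = FALSE)
  }
  x <- dplyr::arrange(x,
                      factor(.data$strategy, levels = unique(x$strategy)),
                      factor(.data$state, levels = states))
  structure(x, class = c("strategy_params", class(tibble::tibble())),
            cost_basis = cost_basis)
}

#' @rdname strategy_params
#' @param path File to read from or write to (CSV with the `strategy_params`
#'   columns).
#' @export
read_strategy_table <- function(path, cost_basis = c("ics", "medication"),
                                prob_tol = 5e-4) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  strategy_params(x, cost_basis = cost_basis, prob_tol = prob_tol)
}

#' @rdname strategy_params
#' @export
write_strategy_table <- function(x, path) {
  stopifnot(inherits(x, "strategy_params"))
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Cost basis of a strategy table or result
#'
#' @param x A `strategy_params`, `strategy_result` or `psa_result` object.
#' @return `"ics"` or `"medication"`.
#' @export
cost_basis <- function(x) {
  basis <- attr(x, "cost_basis", exact = TRUE)
  if (is.null(basis) && is.list(x)) basis <- x$cost_basis
  basis
}

#' Willingness-to-pay threshold
#'
#' The maximum acceptable incremental cost per QALY gained. The default is
#' the threshold used throughout the package's worked examples:
#' 287,100 CNY/QALY, three times China's 2024 per-capita GDP (95,700 CNY).
#'
#' @param value Threshold in CNY per QALY (> 0).
#' @param basis Free-text provenance of the value.
#' @return An object of class `wtp_threshold` (a single number with a `basis`
#'   attribute).
#' @export
#' @examples
#' wtp_threshold()
wtp_threshold <- function(value = 287100,
                          basis = "3x China's 2024 per-capita GDP (95,700 CNY)") {
  if (!is.numeric(value) || length(value) != 1L || value <= 0) {
    stop("WTP threshold must be a single positive number", call. = FALSE)
  }
  structure(value, basis = basis, class = "wtp_threshold")
}

#' @export
print.wtp_threshold <- function(x, ...) {
  cat("<wtp_threshold> ", format(unclass(x), big.mark = ","),
      " CNY/QALY (", attr(x, "basis"), ")\n", sep = "")
  invisible(x)
}

as_wtp <- function(wtp) {
  if (inherits(wtp, "wtp_threshold")) as.numeric(wtp) else {
    stopifnot(is.numeric(wtp), length(wtp) == 1L, wtp > 0)
    as.numeric(wtp)
  }
}
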