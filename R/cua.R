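#' Expected cost and utility of each strategy under the decision tree
#'
#' The decision tree has a single chance node per strategy with the three
#' health-state branches; the strategy's expected cost and expected utility
#' are the probability-weighted sums `E[C] = sum(p_i * c_i)` and
#' `E[U] = sum(p_i * u_i)` over the states.
#'
#' @param params A [strategy_params()] table (any number of strategies).
#' @return A `strategy_result` tibble with columns `strategy`,
#'   `expected_cost` (CNY), `expected_utility` (QALYs), carrying the cost
#'   basis of the input.
#' @export
#' @examples
#' evaluate_strategy(asthma_strategies("ics"))
evaluate_strategy <- function(params) {
  stopifnot(inherits(params, "strategy_params"))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(params), .data$strategy),
    expected_cost = sum(.data$probability * .data$cost_cny),
    expected_utility = sum(.data$probability * .data$utility_qaly),
    .groups = "drop"
  )
  out <- out[match(unique(params$strategy), out$strategy), ]
  structure(out, class = c("strategy_result", class(tibble::tibble())),
            cost_basis = cost_basis(params))
}

result_row <- function(results, label) {
  row <- dplyr::filter(tibble::as_tibble(results), .data$strategy == label)
  if (nrow(row) != 1L) {
    stop("unknown strategy label: ", label, call. = FALSE)
  }
  row
}

check_same_basis <- function(a, b) {
  ba <- cost_basis(a); bb <- cost_basis(b)
  if (!is.null(ba) && !is.null(bb) && !identical(ba, bb)) {
    stop("cost basis mismatch: cannot compare '", ba, "' with '", bb, "'",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Incremental cost-utility ratio between two strategies
#'
#' `ICUR = (E[C]_alt - E[C]_ref) / (E[U]_alt - E[U]_ref)`, in CNY per QALY,
#' together with the dominance quadrant and -- when a willingness-to-pay
#' threshold is supplied -- a cost-effectiveness verdict: for a tradeoff pair
#' the alternative is cost-effective iff `ICUR < wtp` (equivalently, iff its
#' net monetary benefit at `wtp` is higher); a dominating alternative is
#' always cost-effective and a dominated one never is.
#'
#' @param results A `strategy_result` table (from [evaluate_strategy()]), or
#'   the reference result when `alt` is a second `strategy_result`.
#' @param ref,alt Strategy labels in `results`. Alternatively pass two
#'   one-row `strategy_result` objects as `results` and `ref`.
#' @param wtp Optional [wtp_threshold()] (or a positive number, CNY/QALY).
#' @return A one-row tibble: `reference`, `strategy`, `delta_cost`,
#'   `delta_utility`, `icur`, `dominance`, and `cost_effective` when `wtp`
#'   is given.
#' @export
#' @examples
#' res <- evaluate_strategy(asthma_strategies("ics"))
#' icur(res, ref = "A", alt = "B", wtp = wtp_threshold())
icur <- function(results, ref, alt, wtp = NULL) {
  if (inherits(ref, "strategy_result")) {
    check_same_basis(results, ref)
    r <- tibble::as_tibble(results)
    a <- tibble::as_tibble(ref)
    stopifnot(nrow(r) == 1L, nrow(a) == 1L)
  } else {
    r <- result_row(results, ref)
    a <- result_row(results, alt)
  }
  dc <- a$expected_cost - r$expected_cost
  du <- a$expected_utility - r$expected_utility
  out <- tibble::tibble(
    reference = r$strategy,
    strategy = a$strategy,
    delta_cost = dc,
    delta_utility = du,
    icur = ifelse(du != 0, dc / du, NA_real_),
    dominance = classify_dominance(dc, du)
  )
  if (!is.null(wtp)) {
    lambda <- as_wtp(wtp)
    out$cost_effective <- dplyr::case_when(
      out$dominance == "alt_dominates" ~ TRUE,
      out$dominance == "ref_dominates" ~ FALSE,
      out$dominance == "equivalent" ~ NA,
      TRUE ~ out$icur < lambda
    )
  }
  out
}

#' Net monetary benefit
#'
#' `NMB = wtp * E[U] - E[C]`: the strategy's utility converted to money at
#' the willingness-to-pay threshold, net of its cost. At a given threshold
#' the strategy with the higher NMB is preferred; for a pair with a positive
#' utility difference, `NMB(alt) > NMB(ref)` exactly when `ICUR < wtp`.
#'
#' @param results A `strategy_result` table.
#' @param wtp A [wtp_threshold()] or positive number (CNY/QALY).
#' @return The input with an `nmb` column (CNY) appended.
#' @export
#' @examples
#' nmb(evaluate_strategy(asthma_strategies("ics")), wtp_threshold())
nmb <- function(results, wtp) {
  stopifnot(is.data.frame(results),
            all(c("expected_cost", "expected_utility") %in% names(results)))
  lambda <- as_wtp(wtp)
  dplyr::mutate(tibble::as_tibble(results),
                nmb = lambda * .data$expected_utility - .data$expected_cost)
}

#' Full cost-utility report
#'
#' Evaluates every strategy in the parameter table and every requested
#' comparison, producing the standard cost-utility layout: per-strategy
#' expected cost, expected utility and NMB, and per-pair incremental cost,
#' incremental utility, ICUR, dominance and WTP verdict.
#'
#' @param params A [strategy_params()] table.
#' @param comparisons A data frame with columns `ref` and `alt`, or a list of
#'   length-2 character vectors `c(ref, alt)`. The convention in the worked
#'   examples is alt = the more intensive (higher-cost) regimen.
#' @param wtp A [wtp_threshold()] or positive number.
#' @return A `cua_table` object: a list with elements `strategies` (results
#'   with NMB), `comparisons` (ICUR rows), `wtp` and `cost_basis`. Use
#'   [generics::tidy()] for a long tibble and [generics::glance()] for a
#'   one-row summary.
#' @export
#' @examples
#' cua_table(asthma_strategies("ics"),
#'           comparisons = list(c("A1", "A2"), c("B1", "B2"), c("A", "B")))
cua_table <- function(params, comparisons, wtp = wtp_threshold()) {
  results <- evaluate_strategy(params)
  if (is.list(comparisons) && !is.data.frame(comparisons)) {
    comparisons <- tibble::tibble(
      ref = vapply(comparisons, `[`, character(1), 1L),
      alt = vapply(comparisons, `[`, character(1), 2L)
    )
  }
  stopifnot(all(c("ref", "alt") %in% names(comparisons)))
  cmp <- purrr::pmap(comparisons, function(ref, alt, ...) {
    icur(results, ref = ref, alt = alt, wtp = wtp)
  })
  structure(
    list(strategies = nmb(results, wtp),
         comparisons = dplyr::bind_rows(cmp),
         wtp = as_wtp(wtp),
         cost_basis = cost_basis(results)),
    class = "cua_table"
  )
}

#' @export
print.cua_table <- function(x, ...) {
  cat("<cua_table> cost basis:", x$cost_basis,
      "| WTP:", format(x$wtp, big.mark = ","), "CNY/QALY\n")
  strat <- dplyr::mutate(x$strategies,
                         expected_cost = round(.data$expected_cost, 2),
                         expected_utility = round(.data$expected_utility, 4),
                         nmb = round(.data$nmb, 2))
  print(strat)
  if (nrow(x$comparisons)) {
    cmp <- dplyr::mutate(x$comparisons,
                         delta_cost = round(.data$delta_cost, 2),
                         delta_utility = round(.data$delta_utility, 4),
                         icur = round(.data$icur, 2))
    print(cmp)
  }
  invisible(x)
}

#' Tidy a cost-utility report
#'
#' @param x A `cua_table`.
#' @param ... Unused.
#' @return A long tibble with one row per strategy quantity and per
#'   comparison quantity (`section`, `strategy`, `reference`, `quantity`,
#'   `value`).
#' @export
tidy.cua_table <- function(x, ...) {
  strat <- tidyr::pivot_longer(
    x$strategies,
    cols = c("expected_cost", "expected_utility", "nmb"),
    names_to = "quantity", values_to = "value"
  )
  strat <- dplyr::mutate(strat, section = "strategy",
                         reference = NA_character_)
  cmp <- x$comparisons
  out <- strat[c("section", "strategy", "reference", "quantity", "value")]
  if (nrow(cmp)) {
    cmp_long <- tidyr::pivot_longer(
      dplyr::mutate(cmp,
                    cost_effective = as.numeric(.data$cost_effective)),
      cols = c("delta_cost", "delta_utility", "icur", "cost_effective"),
      names_to = "quantity", values_to = "value"
    )
    cmp_long <- dplyr::mutate(cmp_long, section = "comparison")
    out <- dplyr::bind_rows(
      out, cmp_long[c("section", "strategy", "reference", "quantity", "value")]
    )
  }
  out
}

#' Glance at a cost-utility report
#'
#' @param x A `cua_table`.
#' @param ... Unused.
#' @return A one-row tibble: number of strategies and comparisons, cost
#'   basis, WTP, and the NMB-optimal strategy at that WTP.
#' @export
glance.cua_table <- function(x, ...) {
  best <- x$strategies$strategy[which.max(x$strategies$nmb)]
  tibble::tibble(
    n_strategies = nrow(x$strategies),
    n_comparisons = nrow(x$comparisons),
    cost_basis = x$cost_basis,
    wtp = x$wtp,
    best_nmb_strategy = best
  )
}
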