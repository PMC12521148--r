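#' Effectiveness rates from longest symptom-free durations
#'
#' Treatment effectiveness is summarised as the percentage of patients whose
#' longest continuous symptom-free period reached each threshold:
#' `rate_k = 100 * #\{duration >= t_k\} / n`. Rates are necessarily
#' non-increasing in the threshold.
#'
#' @param data A data frame with a `duration_months` column (one row per
#'   patient) and optionally a `strategy` column (rates computed per
#'   strategy), or a bare numeric vector of durations.
#' @param thresholds Strictly increasing thresholds in months.
#' @return A tibble with columns (`strategy`,) `threshold_months`,
#'   `n_patients`, `n_achieving`, `rate_percent`.
#' @export
#' @examples
#' effectiveness_rates(c(0, 2, 4, 7, 13, 30))
effectiveness_rates <- function(data, thresholds = c(3, 6, 12, 24)) {
  if (is.numeric(data)) {
    data <- tibble::tibble(duration_months = data)
  }
  stopifnot(is.data.frame(data), "duration_months" %in% names(data))
  if (nrow(data) == 0L) stop("empty cohort", call. = FALSE)
  if (any(data$duration_months < 0)) {
    stop("durations must be >= 0", call. = FALSE)
  }
  if (length(thresholds) == 0L || any(diff(thresholds) <= 0)) {
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  }
  grouped <- if ("strategy" %in% names(data)) {
    dplyr::group_by(data, .data$strategy)
  } else {
    data
  }
  out <- dplyr::reframe(
    grouped,
    threshold_months = thresholds,
    n_patients = dplyr::n(),
    n_achieving = vapply(thresholds,
                         function(t) sum(.data$duration_months >= t),
                         integer(1))
  )
  dplyr::mutate(out, rate_percent = 100 * .data$n_achieving / .data$n_patients)
}

#' Cost-effectiveness ratio
#'
#' `C/E = cost / effect`, with the effect expressed as the printed percentage
#' of patients achieving a symptom-free threshold (so the unit is CNY per
#' percentage point of effectiveness).
#'
#' @param cost Cost in CNY (vectorised).
#' @param effect_percent Effectiveness in percent, must be > 0.
#' @return The ratio(s), CNY per percentage point.
#' @export
#' @examples
#' cost_effectiveness_ratio(3824.02, 75)
cost_effectiveness_ratio <- function(cost, effect_percent) {
  if (any(effect_percent <= 0)) {
    stop("undefined ratio: effect must be > 0", call. = FALSE)
  }
  cost / effect_percent
}

#' Dominance classification of an incremental comparison
#'
#' Classifies the (delta cost, delta effect) quadrant of an alternative
#' against a reference: `alt_dominates` when the alternative is no more
#' costly and no less effective (with at least one strict inequality),
#' `ref_dominates` in the mirror case, `equivalent` when both deltas are
#' zero, and `tradeoff` otherwise (more costly and more effective, or cheaper
#' and less effective -- the only quadrants where the incremental ratio is
#' interpreted against a willingness-to-pay threshold).
#'
#' @param delta_cost,delta_effect Incremental cost and effect
#'   (alt - ref), vectorised.
#' @return Character vector with levels `alt_dominates`, `ref_dominates`,
#'   `tradeoff`, `equivalent`.
#' @export
classify_dominance <- function(delta_cost, delta_effect) {
  dplyr::case_when(
    delta_cost == 0 & delta_effect == 0 ~ "equivalent",
    delta_cost <= 0 & delta_effect >= 0 ~ "alt_dominates",
    delta_cost >= 0 & delta_effect <= 0 ~ "ref_dominates",
    TRUE ~ "tradeoff"
  )
}

#' Incremental cost-effectiveness ratio
#'
#' `ICER = (cost_alt - cost_ref) / (effect_alt - effect_ref)`. When the
#' effect difference is zero the ratio is undefined (`NA`) but the dominance
#' quadrant is still classified. A bare negative ICER is ambiguous -- it
#' arises both when the alternative is dominated (costlier, less effective)
#' and when it dominates (cheaper, more effective) -- so the ratio is always
#' reported together with its dominance label.
#'
#' @param ref_cost,ref_effect Cost and effect of the reference strategy.
#' @param alt_cost,alt_effect Cost and effect of the alternative.
#' @return A tibble with columns `delta_cost`, `delta_effect`, `icer`,
#'   `dominance`. Vectorised over all four inputs.
#' @export
#' @examples
#' icer(3339.63, 50, 3824.02, 75)
icer <- function(ref_cost, ref_effect, alt_cost, alt_effect) {
  stopifnot(is.finite(ref_cost), is.finite(ref_effect),
            is.finite(alt_cost), is.finite(alt_effect))
  dc <- alt_cost - ref_cost
  de <- alt_effect - ref_effect
  tibble::tibble(
    delta_cost = dc,
    delta_effect = de,
    icer = ifelse(de != 0, dc / de, NA_real_),
    dominance = classify_dominance(dc, de)
  )
}

#' Cost-effectiveness table over strategies and thresholds
#'
#' Assembles the full CEA report: a `C/E` block with one ratio per strategy
#' and effectiveness threshold, and an `ICER` block with one incremental
#' ratio per requested comparison and threshold. By default each comparison
#' pair is oriented so that the lower-cost strategy is the reference (the
#' convention used throughout the worked examples); pass
#' `orient_by_cost = FALSE` to keep the pairs as given.
#'
#' @param costs A data frame with columns `strategy` and `mean_cost` (CNY).
#' @param effectiveness A data frame with columns `strategy`,
#'   `threshold_months`, `rate_percent` (see [effectiveness_rates()]).
#' @param comparisons Optional data frame with columns `ref` and `alt`
#'   naming strategy pairs, or a list of length-2 character vectors.
#' @param orient_by_cost Re-orient each pair so the cheaper strategy is the
#'   reference.
#' @return A `cea_table` tibble with columns `section` (`"ce"` or `"icer"`),
#'   `strategy`, `reference`, `threshold_months`, `cost`, `effect_percent`,
#'   `value`, `dominance`. For `"ce"` rows `reference` is `NA` and `value` is
#'   the C/E ratio; for `"icer"` rows `cost` and `effect_percent` hold the
#'   deltas and `value` the ICER (`NA` where the effect delta is zero).
#' @export
#' @examples
#' cea_table(asthma_mean_costs("medication"), asthma_effectiveness(),
#'           comparisons = list(c("A", "B")))
cea_table <- function(costs, effectiveness, comparisons = NULL,
                      orient_by_cost = TRUE) {
  stopifnot(is.data.frame(costs),
            all(c("strategy", "mean_cost") %in% names(costs)),
            is.data.frame(effectiveness),
            all(c("strategy", "threshold_months", "rate_percent") %in%
                  names(effectiveness)))
  if (anyDuplicated(costs$strategy)) {
    stop("strategy labels must be unique", call. = FALSE)
  }
  eff <- dplyr::select(effectiveness, "strategy", "threshold_months",
                       "rate_percent")
  ce <- dplyr::inner_join(costs, eff, by = "strategy")
  ce <- dplyr::mutate(
    ce,
    section = "ce",
    reference = NA_character_,
    value = cost_effectiveness_ratio(.data$mean_cost, .data$rate_percent),
    dominance = NA_character_
  )
  ce <- dplyr::select(ce, "section", "strategy", "reference",
                      "threshold_months", cost = "mean_cost",
                      effect_percent = "rate_percent", "value", "dominance")

  rows <- list(ce)
  if (!is.null(comparisons)) {
    if (is.list(comparisons) && !is.data.frame(comparisons)) {
      comparisons <- tibble::tibble(
        ref = vapply(comparisons, `[`, character(1), 1L),
        alt = vapply(comparisons, `[`, character(1), 2L)
      )
    }
    stopifnot(all(c("ref", "alt") %in% names(comparisons)))
    unknown <- setdiff(c(comparisons$ref, comparisons$alt), costs$strategy)
    if (length(unknown)) {
      stop("unknown strategy label(s) in comparisons: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    lookup_cost <- stats::setNames(costs$mean_cost, costs$strategy)
    icer_rows <- purrr::pmap(comparisons, function(ref, alt, ...) {
      if (orient_by_cost && lookup_cost[[ref]] > lookup_cost[[alt]]) {
        tmp <- ref; ref <- alt; alt <- tmp
      }
      e_ref <- dplyr::filter(eff, .data$strategy == ref)
      e_alt <- dplyr::filter(eff, .data$strategy == alt)
      joined <- dplyr::inner_join(e_ref, e_alt, by = "threshold_months",
                                  suffix = c("_ref", "_alt"))
      cmp <- icer(lookup_cost[[ref]], joined$rate_percent_ref,
                  lookup_cost[[alt]], joined$rate_percent_alt)
      tibble::tibble(
        section = "icer",
        strategy = alt,
        reference = ref,
        threshold_months = joined$threshold_months,
        cost = cmp$delta_cost,
        effect_percent = cmp$delta_effect,
        value = cmp$icer,
        dominance = cmp$dominance
      )
    })
    rows <- c(rows, icer_rows)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cea_table", class(out))
  out
}

#' @export
print.cea_table <- function(x, ...) {
  cat("<cea_table> C/E in CNY per percentage point\n")
  ce <- dplyr::filter(x, .data$section == "ce")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(ce, value = round(.data$value, 2)),
    id_cols = "strategy", names_from = "threshold_months",
    names_prefix = "C/E_", values_from = "value"
  )
  print(wide)
  ic <- dplyr::filter(x, .data$section == "icer")
  if (nrow(ic)) {
    cat("ICER (alt vs reference):\n")
    wide_i <- tidyr::pivot_wider(
      dplyr::mutate(ic, value = round(.data$value, 2),
                    pair = paste(.data$strategy, "vs", .data$reference)),
      id_cols = "pair", names_from = "threshold_months",
      names_prefix = "dC/dE_", values_from = "value"
    )
    print(wide_i)
  }
  invisible(x)
}

#' Write a CEA or CUA report to CSV
#'
#' @param x A `cea_table` or `cua_table`.
#' @param path Output file.
#' @export
write_report_csv <- function(x, path) {
  if (inherits(x, "cua_table")) x <- generics::tidy(x)
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
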