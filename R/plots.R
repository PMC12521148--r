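#' Cost-effectiveness plane plot
#'
#' Scatter of the PSA's incremental draws on the cost-effectiveness plane
#' (incremental QALYs on the x axis, incremental cost on the y axis), with
#' the normal-theory confidence ellipse and the willingness-to-pay line
#' `cost = wtp * utility` (draws below the line are cost-effective at that
#' threshold).
#'
#' @param object A `psa_result`.
#' @param level Confidence level for the ellipse.
#' @param wtp WTP threshold drawn as a line; defaults to the one recorded in
#'   the result. `NULL` suppresses the line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psa_result <- function(object, level = 0.95, wtp = object$wtp, ...) {
  summ <- ce_plane_summary(object, level = level)
  p <- ggplot2::ggplot(object$draws,
                       ggplot2::aes(x = .data$delta_utility,
                                    y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "#2c7fb8")
  if (nrow(summ$ellipse) > 1L) {
    p <- p + ggplot2::geom_path(
      data = summ$ellipse,
      ggplot2::aes(x = .data$delta_utility, y = .data$delta_cost),
      colour = "#d95f02", linewidth = 0.7)
  }
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = as_wtp(wtp), intercept = 0,
                                  linetype = "dashed", colour = "grey40")
  }
  p +
    ggplot2::labs(
      x = "Incremental utility (QALYs)",
      y = "Incremental cost (CNY)",
      title = paste0(object$labels[["alt"]], " vs ", object$labels[["ref"]],
                     " (", object$cost_basis, " costs)"),
      subtitle = paste0(object$n, " Monte Carlo iterations; ",
                        round(100 * level), "% confidence ellipse")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.psa_result
#' @export
plot_ce_plane <- function(object, level = 0.95, wtp = object$wtp) {
  autoplot.psa_result(object, level = level, wtp = wtp)
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param object A `ceac` tibble (from [ceac()]).
#' @param wtp Optional WTP threshold to mark with a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ceac <- function(object, wtp = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp,
                                            y = .data$prob_cost_effective)) +
    ggplot2::geom_line(colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::ylim(0, 1)
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_vline(xintercept = as_wtp(wtp),
                                 linetype = "dashed", colour = "grey40")
  }
  p +
    ggplot2::labs(x = "Willingness to pay (CNY/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ceac
#' @export
plot_ceac <- function(object, wtp = NULL) {
  if (inherits(object, "psa_result")) object <- ceac(object)
  autoplot.ceac(object, wtp = wtp)
}

#' Effectiveness-rate bar plot
#'
#' @param object An effectiveness table (see [effectiveness_rates()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_effectiveness <- function(object, ...) {
  stopifnot(all(c("threshold_months", "rate_percent") %in% names(object)))
  mapping <- if ("strategy" %in% names(object)) {
    ggplot2::aes(x = factor(.data$threshold_months), y = .data$rate_percent,
                 fill = .data$strategy)
  } else {
    ggplot2::aes(x = factor(.data$threshold_months), y = .data$rate_percent)
  }
  ggplot2::ggplot(object, mapping) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Symptom-free duration threshold (months)",
                  y = "Patients achieving threshold (%)") +
    ggplot2::theme_minimal()
}
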