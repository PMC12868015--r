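# ggplot2 autoplot() methods for every result type.

#' Plot methods for model results
#'
#' `autoplot()` methods: a `strategy_result` draws the state-occupancy
#' trace; a `psa_result` the incremental cost-effectiveness plane (or the
#' acceptability curve with `type = "ceac"`); an `owsa_result` the one-way
#' NMB curves; a `twsa_result` the two-way preference map; a
#' `tornado_result` the ranked influence bars.
#'
#' @param object A result object.
#' @param type For `psa_result`: `"plane"` (default) or `"ceac"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-cryocea
NULL

#' @rdname autoplot-cryocea
#' @method autoplot strategy_result
#' @export
autoplot.strategy_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                               fill = .data$state)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      title = paste0("Cohort trace: ", object$strategy, " (",
                     object$scenario_name, ")"),
      x = "Cycle (year)", y = "Cohort fraction", fill = "State") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-cryocea
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, type = c("plane", "ceac"), ...) {
  type <- match.arg(type)
  if (identical(type, "ceac")) {
    return(
      ggplot2::ggplot(object$ceac,
                      ggplot2::aes(x = .data$wtp, y = .data$p_bca)) +
        ggplot2::geom_line() +
        ggplot2::geom_point() +
        ggplot2::scale_y_continuous(limits = c(0, 1)) +
        ggplot2::labs(title = paste0("Acceptability curve: ",
                                     object$scenario_name),
                      x = "Willingness-to-pay ($/QALY)",
                      y = "P(cryoablation preferred)") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost,
                               colour = .data$preferred)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = object$wtp, intercept = 0,
                         linetype = 3) +
    ggplot2::labs(
      title = paste0("Cost-effectiveness plane: ", object$scenario_name),
      x = "Incremental QALYs (BCA - BCS)",
      y = "Incremental cost ($, BCA - BCS)", colour = "Preferred") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-cryocea
#' @method autoplot owsa_result
#' @export
autoplot.owsa_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("nmb_bca", "nmb_bcs"),
                              names_to = "strategy", values_to = "nmb",
                              names_prefix = "nmb_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$nmb,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = paste0("One-way sweep: ", object$param[1]),
                  x = object$param[1], y = "Net monetary benefit ($)",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-cryocea
#' @method autoplot twsa_result
#' @export
autoplot.twsa_result <- function(object, ...) {
  params <- attr(object, "params")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value_a, y = .data$value_b,
                                       fill = .data$preferred)) +
    ggplot2::geom_tile() +
    ggplot2::labs(title = "Two-way preference map", x = params[1],
                  y = params[2], fill = "Preferred") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-cryocea
#' @method autoplot tornado_result
#' @export
autoplot.tornado_result <- function(object, ...) {
  base <- attr(object, "base_nmb_diff")
  df <- dplyr::mutate(object,
                      param = factor(.data$param, levels = rev(.data$param)))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$nmb_diff_low, xend = .data$nmb_diff_high,
                   y = .data$param, yend = .data$param),
      linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(title = "Tornado diagram",
                  x = "NMB difference, BCA - BCS ($)", y = NULL) +
    ggplot2::theme_minimal()
}
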