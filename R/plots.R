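#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-site F-IBI totals coloured by grade
#'
#' @param object A [score_sites()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fibir_scorecard
#' @export
autoplot.fibir_scorecard <- function(object, ...) {
  tot <- object$totals
  p95 <- 0.95 * object$expected_total
  ggplot2::ggplot(tot, ggplot2::aes(x = .data$site, y = .data$total,
                                    fill = .data$grade)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = p95, linetype = "dashed") +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = 1, drop = FALSE) +
    ggplot2::labs(x = "site", y = "F-IBI total score",
                  title = sprintf("F-IBI totals (expected = %d, P95 = %.2f)",
                                  object$expected_total, p95)) +
    ggplot2::theme_minimal()
}

#' Plot both importance measures of a driver model
#'
#' @param object A [fit_driver_model()] result.
#' @param ... Unused.
#' @return A ggplot (dot plot, one panel per importance measure).
#' @method autoplot fibir_driver
#' @export
autoplot.fibir_driver <- function(object, ...) {
  long <- tidyr::pivot_longer(object$importance,
                              cols = c("inc_mse_pct", "inc_node_purity"),
                              names_to = "measure", values_to = "importance")
  long$measure <- factor(long$measure, levels = c("inc_mse_pct", "inc_node_purity"),
                         labels = c("%IncMSE", "IncNodePurity"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$importance,
                                     y = stats::reorder(.data$covariate, .data$importance))) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::labs(x = "importance", y = NULL,
                  title = sprintf("Drivers of %s (%.1f%% variance explained, OOB)",
                                  object$response, object$pct_var_oob)) +
    ggplot2::theme_minimal()
}

#' Plot the gap-statistic curve
#'
#' @param object An [optimal_k()] result.
#' @param ... Unused.
#' @return A ggplot with the selected k marked.
#' @method autoplot fibir_gap
#' @export
autoplot.fibir_gap <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$SE_sim,
                                          ymax = .data$gap + .data$SE_sim)) +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "number of groups k", y = "gap statistic",
                  title = sprintf("Gap curve (selected k = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot per-segment connectivity over time
#'
#' @param object A [trci()] result.
#' @param ... Unused.
#' @return A ggplot: per-year static RCI lines with the TRCI average.
#' @method autoplot fibir_trci
#' @export
autoplot.fibir_trci <- function(object, ...) {
  ggplot2::ggplot(object$by_year,
                  ggplot2::aes(x = .data$year, y = .data$rci,
                               colour = .data$segment)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(data = object$trci,
                        ggplot2::aes(yintercept = .data$trci,
                                     colour = .data$segment),
                        linetype = "dotted") +
    ggplot2::labs(x = "year", y = "static RCI (dotted: time-weighted TRCI)",
                  title = "River connectivity under accumulating barriers") +
    ggplot2::theme_minimal()
}
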