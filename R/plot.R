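# ggplot2 displays for interval tables, simulation runs and sweeps.

#' Forest plot of an interval table
#'
#' @param ci_table a [gs_ci()] result.
#' @param reference vertical reference line (default 0, the null).
#' @return a ggplot object.
#' @export
plot_ci <- function(ci_table, reference = 0) {
  d <- dplyr::filter(ci_table, !is.na(.data$lower))
  d$method <- factor(d$method, levels = rev(ci_methods()))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$method)) +
    ggplot2::geom_vline(xintercept = reference, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper), height = 0.25) +
    ggplot2::geom_point(ggplot2::aes(x = .data$point_estimate),
                        na.rm = TRUE, size = 2) +
    ggplot2::labs(x = "treatment difference", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_ci autoplot method for simulation runs: interval limits
#'   of the first few replicates by method.
#' @param object a `gs_sim` or `gs_sweep` object.
#' @param n_show replicates to display.
#' @param ... unused.
#' @export
autoplot.gs_sim <- function(object, n_show = 5, ...) {
  truth <- object$scenario$p_treatment - object$scenario$p_control
  d <- dplyr::filter(object$intervals, .data$rep <= n_show, !.data$failed)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$rep))) +
    ggplot2::geom_hline(yintercept = truth, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), width = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$method)) +
    ggplot2::labs(x = "simulation replicate", y = "treatment difference") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_ci autoplot method for sweeps: coverage and mean width
#'   against the true treatment response rate, facetted by conditioning,
#'   with +/- 1.96 Monte-Carlo standard error ribbons on coverage.
#' @param level nominal coverage drawn as a reference line.
#' @export
autoplot.gs_sweep <- function(object, level = 0.95, ...) {
  d <- tidyr::pivot_longer(
    dplyr::mutate(object,
                  coverage_lo = .data$coverage - 1.96 * .data$mcse_coverage,
                  coverage_hi = .data$coverage + 1.96 * .data$mcse_coverage),
    cols = c("coverage", "mean_width"),
    names_to = "metric", values_to = "value"
  )
  ref <- tibble(metric = "coverage", value = level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p_treatment, y = .data$value,
                                  colour = .data$method)) +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_ribbon(
      data = ~ dplyr::filter(.x, .data$metric == "coverage"),
      ggplot2::aes(ymin = .data$coverage_lo, ymax = .data$coverage_hi,
                   fill = .data$method), alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(ggplot2::vars(.data$metric),
                        ggplot2::vars(.data$conditioning),
                        scales = "free_y") +
    ggplot2::labs(x = "true treatment response rate", y = NULL) +
    ggplot2::theme_minimal()
}
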