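#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a phenotype trajectory
#'
#' One line per phenotype fraction over time, with protocol events marked.
#'
#' @param object A `platelet_trajectory` from [simulate_phenotypes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.platelet_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                              names_to = "phenotype", values_to = "fraction")
  long$phenotype <- factor(long$phenotype,
                           levels = c("n_rest", "n_sph", "n_gp",
                                      "n_agg", "n_exh", "n_inh"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$fraction,
                                          colour = .data$phenotype)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "time (s)", y = "fraction of population (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  protocol <- attr(object, "protocol")
  if (!is.null(protocol) && nrow(protocol$events) > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = protocol$events$t,
                                 linetype = "dotted", colour = "grey50")
  }
  p
}

#' Plot an instrument-like trace
#'
#' @param object A `platelet_trace` from [observables()] or
#'   [generate_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.platelet_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                              names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$intensity,
                                     colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::labs(x = "time (s)", y = "light-scatter intensity (AU)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Hill fit over its data
#'
#' Points are the fitted dataset; the curve is the fitted law on a log-dose
#' grid.
#'
#' @param object A `hill_fit` from [fit_hill()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  ds <- object$data
  pos <- ds$dose[ds$dose > 0]
  grid <- 10^seq(log10(min(pos)) - 0.3, log10(max(pos)) + 0.3, length.out = 200)
  curve <- tibble::tibble(dose = grid, response = eval_hill(object$params, grid))
  ggplot2::ggplot(ds, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0("dose (", object$params$unit, ")"),
                  y = "response") +
    ggplot2::theme_minimal()
}
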