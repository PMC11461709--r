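#' Plot posterior marginals of an SMC-ABC fit
#'
#' Weighted KDE of each parameter's marginal, overlaid across SMC
#' iterations (early iterations dark, late iterations bright), in the
#' style customary for visualising the tolerance schedule's convergence.
#'
#' @param object An `"abc_fit"` object.
#' @param true_values Optional named vector of data-generating parameters
#'   to mark with dashed vertical lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abc_fit <- function(object, true_values = NULL, ...) {
  snaps <- if (length(object$history)) object$history else
    list(dplyr::mutate(object$particles[c(object$prior$name, "weight")],
                       iteration = object$n_iterations))
  dens <- purrr::map_dfr(snaps, function(s) {
    purrr::map_dfr(object$prior$name, function(p) {
      k <- weighted_kde(s[[p]], s$weight, n_grid = 256)
      tibble(parameter = p, iteration = s$iteration[1],
             x = k$x, density = k$density)
    })
  })
  g <- ggplot2::ggplot(dens, ggplot2::aes(.data$x, .data$density,
                                          colour = .data$iteration,
                                          group = .data$iteration)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c(option = "inferno") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density", colour = "iteration")
  if (!is.null(true_values)) {
    tv <- tibble(parameter = names(true_values), value = unname(true_values))
    g <- g + ggplot2::geom_vline(data = tv,
                                 ggplot2::aes(xintercept = .data$value),
                                 linetype = "dashed")
  }
  g
}

#' Plot Sobol indices with confidence intervals
#'
#' @param object A `"sobol_result"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sobol_result <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$parameter, .data$estimate,
                                     fill = .data$index)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$ci_half_width,
                   ymax = .data$estimate + .data$ci_half_width),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2,
      colour = "grey40"
    ) +
    ggplot2::facet_wrap(~output) +
    ggplot2::labs(y = "sensitivity index", x = NULL, fill = NULL)
}

#' Plot a posterior predictive check
#'
#' Observed (histogram) versus posterior-simulated (density) QoI
#' marginals.
#'
#' @param object A `"predictive_check"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.predictive_check <- function(object, ...) {
  sim <- tidyr::pivot_longer(attr(object, "sim_qois"),
                             dplyr::everything(),
                             names_to = "qoi", values_to = "value")
  dat <- tidyr::pivot_longer(attr(object, "data_qois"),
                             dplyr::everything(),
                             names_to = "qoi", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_density(data = sim, colour = "darkgreen") +
    ggplot2::facet_wrap(~qoi, scales = "free") +
    ggplot2::labs(x = NULL, y = "density")
}

#' Plot a neuron morphology projection
#'
#' 2-D projection of the agent cylinders; the soma is drawn as a circle.
#'
#' @param tree A `neuron_tree`.
#' @param plane `"xz"`, `"xy"` or `"yz"`.
#' @return A ggplot object.
#' @export
plot_neuron <- function(tree, plane = c("xz", "xy", "yz")) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  neur <- tree[tree$kind == "neurite", ]
  df <- tibble(
    x = neur[[paste0("start_", ax[1])]], y = neur[[paste0("start_", ax[2])]],
    xend = neur[[paste0("end_", ax[1])]], yend = neur[[paste0("end_", ax[2])]],
    type = factor(neur$type, c(3, 4), c("basal", "apical"))
  )
  soma <- soma_row_of(tree)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(.data$x, .data$y, xend = .data$xend,
                                       yend = .data$yend,
                                       colour = .data$type),
                          linewidth = 0.3) +
    ggplot2::annotate("point",
                      x = soma[[paste0("end_", ax[1])]],
                      y = soma[[paste0("end_", ax[2])]],
                      size = 3, colour = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = ax[1], y = ax[2], colour = NULL)
}
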