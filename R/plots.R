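# ggplot2 visualisations for the main result types. autoplot methods return
# plain ggplot objects so they compose with the usual grammar.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_hline geom_vline scale_fill_gradient2 labs theme_minimal
NULL

#' Raster plot of spike data
#'
#' @param object A [as_spike_data()] tibble.
#' @param max_neurons Thin the raster to at most this many neurons.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spike_data <- function(object, max_neurons = 200, ...) {
  ids <- sort(unique(object$neuron))
  if (length(ids) > max_neurons) {
    ids <- ids[seq(1, length(ids), length.out = max_neurons)]
    object <- object[object$neuron %in% ids, ]
  }
  ggplot(object, aes(x = .data$time, y = .data$neuron)) +
    geom_point(shape = ".", alpha = 0.6) +
    labs(x = "time (ms)", y = "neuron") +
    theme_minimal()
}

#' Summary plot of a simulation: raster, population rate, control current
#'
#' @param object A `dfc_sim`.
#' @param bin Rate bin (ms).
#' @param ... Passed to [autoplot.spike_data()].
#' @return A ggplot (patchwork stack when the patchwork package is
#'   installed, otherwise the rate panel alone annotated with the control
#'   onset).
#' @export
autoplot.dfc_sim <- function(object, bin = 1, ...) {
  rate <- population_rate(object, bin = bin)
  p_rate <- ggplot(rate, aes(x = .data$time, y = .data$rate)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (ms)", y = "rate (sp/s)") +
    theme_minimal()
  ctrl <- object$diagnostics$controller
  if (!is.null(ctrl)) {
    p_rate <- p_rate + geom_vline(xintercept = ctrl$onset,
                                  linetype = "dashed", colour = "red")
  }
  if (requireNamespace("patchwork", quietly = TRUE)) {
    p_raster <- autoplot(object$spikes, ...)
    if (!is.null(ctrl)) {
      p_raster <- p_raster + geom_vline(xintercept = ctrl$onset,
                                        linetype = "dashed",
                                        colour = "red")
    }
    patchwork::wrap_plots(p_raster, p_rate, ncol = 1, heights = c(2, 1))
  } else {
    p_rate
  }
}

#' Stability landscape heat map
#'
#' Cells show the rightmost eigenvalue real part over the (gain, delay)
#' grid; negative (blue) cells are stable control domains.
#'
#' @param object A `dfc_landscape`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dfc_landscape <- function(object, ...) {
  ggplot(object, aes(x = .data$d_eff, y = .data$K,
                     fill = .data$re_max)) +
    geom_tile() +
    scale_fill_gradient2(low = "#08306b", mid = "white", high = "#a50f15",
                         midpoint = 0, name = "Re λ (1/s)") +
    labs(x = "effective control delay (ms)", y = "gain K (mV)") +
    theme_minimal()
}

#' Eigenvalue spectrum plot
#'
#' @param object A `dfc_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dfc_spectrum <- function(object, ...) {
  ggplot(object$roots, aes(x = .data$re, y = .data$im)) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    geom_point() +
    labs(x = "Re λ (1/s)", y = "Im λ (rad/s)") +
    theme_minimal()
}

#' Plot the K-scan of a gain optimisation
#'
#' @param opt Result of [optimal_gain()].
#' @return A ggplot of the rightmost eigenvalue versus gain with the
#'   optimum marked.
#' @export
plot_gain_scan <- function(opt) {
  ggplot(opt$scan, aes(x = .data$K, y = .data$re_max)) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    geom_line() +
    geom_point(data = tibble(K = opt$K_opt, re_max = opt$B_cr),
               colour = "red", size = 2) +
    labs(x = "gain K (mV)", y = "rightmost Re λ (1/s)") +
    theme_minimal()
}
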