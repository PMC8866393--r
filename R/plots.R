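#' Spike raster plot
#'
#' @param sim a `bg_sim`.
#' @param populations populations to facet.
#' @return a ggplot.
#' @export
plot_raster <- function(sim, populations = c("STN", "GPi")) {
  df <- purrr::map_dfr(populations, function(pop)
    dplyr::mutate(raster(sim, pop), population = pop))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$neuron)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::facet_wrap(~population, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "neuron index") +
    ggplot2::theme_minimal()
}

#' Order-parameter time series plot
#'
#' @param macro a `bg_macro` (or `bg_run`).
#' @return a ggplot of r(t) and l(t).
#' @export
plot_macro_series <- function(macro) {
  if (inherits(macro, "bg_run")) macro <- macro$macro
  df <- tidyr::pivot_longer(macro$series, c("r", "l"),
                            names_to = "observable")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~observable, ncol = 1, labeller = ggplot2::labeller(
      observable = c(r = "synchronisation index r",
                     l = "mean synaptic activity l"))) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Log-log spectrum plot with slope fit
#'
#' @param macro a `bg_macro` (or `bg_run`).
#' @return a ggplot.
#' @export
plot_spectrum <- function(macro) {
  if (inherits(macro, "bg_run")) macro <- macro$macro
  sp <- dplyr::filter(macro$spectrum, .data$frequency >= 1,
                      .data$frequency <= 200, .data$power > 0)
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = macro$peaks, colour = "red", size = 1.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power",
                  subtitle = sprintf("log-log slope %.2f", macro$slope)) +
    ggplot2::theme_minimal()
}

#' DBS frequency-sweep plot
#'
#' @param sweep a [frequency_sweep()] table.
#' @param what column to plot against frequency.
#' @return a ggplot.
#' @export
plot_sweep <- function(sweep, what = c("R", "E_r", "E_l")) {
  what <- match.arg(what)
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$f, y = .data[[what]])) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "DBS frequency (Hz)", y = what) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bg_macro <- function(object, ...) plot_macro_series(object)

#' @export
autoplot.bg_sim <- function(object, ...) plot_raster(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
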