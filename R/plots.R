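# ggplot2 views of the three result shapes: angular histograms of phase
# samples, controller traces (tempo and phase against time), and
# per-participant resultant lengths of a cohort report.

#' Angular histogram of a phase sample
#'
#' @param angles_deg Angles in degrees, or a tibble with a `phi_display`
#'   column (e.g. from [phase_series()]).
#' @param bin_width_deg Bin width, a divisor of 360 (default 20).
#' @param polar Draw as a rose diagram (default TRUE); FALSE gives a linear
#'   histogram over `(-180, 180]`.
#' @return A ggplot.
#' @export
plot_phase_histogram <- function(angles_deg, bin_width_deg = 20, polar = TRUE) {
  if (is.data.frame(angles_deg)) angles_deg <- angles_deg$phi_display
  h <- angular_histogram(angles_deg, bin_width_deg)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid_deg, y = .data$count)) +
    ggplot2::geom_col(width = bin_width_deg, fill = "steelblue",
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, by = 60),
                                limits = c(-180, 180)) +
    ggplot2::labs(x = "relative phase (degrees)", y = "steps") +
    ggplot2::theme_minimal()
  if (polar) p <- p + ggplot2::coord_polar(start = pi)
  p
}

#' Controller trace: tempo and relative phase against time
#'
#' The familiar two-panel view of a trial: the music tempo modifier (with
#' song changes) above, the per-step relative phase below, with the
#' synchronisation band marked.
#'
#' @param trace A trace tibble from [run_controller()] or [run_trial()].
#' @param band_deg Band half-width drawn on the phase panel (default 30).
#' @return A ggplot (facetted).
#' @export
plot_trace <- function(trace, band_deg = 30) {
  long <- dplyr::bind_rows(
    tibble::tibble(time_s = trace$time_s, value = trace$final_modifier,
                   panel = "tempo modifier"),
    tibble::tibble(time_s = trace$time_s, value = trace$phi_display,
                   panel = "relative phase (deg)")
  )
  guides <- tibble::tibble(
    panel = rep("relative phase (deg)", 3),
    y = c(-band_deg, 0, band_deg)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_hline(data = guides, ggplot2::aes(yintercept = .data$y),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = "grey60") +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-participant resultant lengths of a cohort report
#'
#' @param object A `cohort_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_report
#' @export
autoplot.cohort_report <- function(object, ...) {
  ggplot2::ggplot(object$per_participant,
                  ggplot2::aes(x = .data$condition, y = .data$R)) +
    ggplot2::geom_jitter(width = 0.1, height = 0,
                         ggplot2::aes(colour = .data$synchronised)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.35,
                          linewidth = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "resultant vector length R per participant",
                  x = NULL, colour = "Rayleigh p < alpha") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
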