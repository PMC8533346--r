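#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an amplitude distribution
#'
#' @param object an [amplitude_distribution()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nm_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$prop)) +
    ggplot2::geom_col(width = attr(object, "bin"), fill = "grey55") +
    ggplot2::labs(x = "amplitude", y = "proportion of events") +
    ggplot2::theme_minimal()
}

#' Plot an Up/Down threshold fit
#'
#' Shows the binned distribution, its smoothed version, and the detected
#' modes and threshold (when bimodal).
#'
#' @param object an [updown_threshold()] result.
#' @param ... unused.
#' @export
autoplot.nm_threshold <- function(object, ...) {
  d <- object$distribution
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$prop), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "firebrick") +
    ggplot2::labs(x = "LFP (mV)", y = "proportion") +
    ggplot2::theme_minimal()
  if (object$bimodal)
    p <- p + ggplot2::geom_vline(xintercept = object$threshold,
                                 linetype = "dashed")
  p
}

#' Plot an averaged power spectrum
#'
#' @param object an [lfp_spectrum()] result.
#' @param max_freq upper frequency limit, Hz.
#' @param ... unused.
#' @export
autoplot.nm_spectrum <- function(object, max_freq = 50, ...) {
  d <- dplyr::filter(tidy(object), .data$freq > 0, .data$freq <= max_freq)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD (dB)") +
    ggplot2::theme_minimal()
}

#' Plot a cluster test
#'
#' The t-series with the critical band and the significant clusters
#' marked.
#'
#' @param object an [cluster_test()] result.
#' @param dt sampling interval, seconds (defaults to the test's).
#' @param alpha significance level for highlighting.
#' @param ... unused.
#' @export
autoplot.nm_cluster_test <- function(object, dt = object$dt, alpha = 0.01,
                                     ...) {
  d <- tibble::tibble(time = (seq_along(object$tseries$t) - 1) * dt,
                      t = object$tseries$t)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$t)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$critical,
                        linetype = "dashed", colour = "goldenrod") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from stimulus onset (s)", y = "t-value") +
    ggplot2::theme_minimal()
  sig <- dplyr::filter(object$clusters, .data$p < alpha)
  if (nrow(sig))
    p <- p + ggplot2::geom_segment(
      data = sig,
      ggplot2::aes(x = .data$start_s,
                   xend = .data$start_s + .data$length_ms / 1000,
                   y = 0, yend = 0),
      colour = "red", linewidth = 2, inherit.aes = FALSE)
  p
}

#' Plot a propagation sweep
#'
#' First-cluster area and length against the inter-/intra conductance
#' ratio, one line per AMPAergic conductance. Grid points without a
#' significant cluster are drawn at zero as open squares.
#'
#' @param object an [propagation_sweep()] result.
#' @param ... unused.
#' @export
autoplot.nm_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::mutate(object,
                  area_s = ifelse(.data$found, .data$area_s, 0),
                  length_ms = ifelse(.data$found, .data$length_ms, 0)),
    c("area_s", "length_ms"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$value,
                                  colour = factor(.data$g_ampa),
                                  shape = .data$found)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 15, `FALSE` = 0),
                                guide = "none") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(beta), y = NULL,
                  colour = expression(bar(g)[AMPA])) +
    ggplot2::theme_minimal()
}

#' Plot a single simulated trial
#'
#' LFP, firing rate and membrane potential of the pyramidal population.
#'
#' @param trace an [run_trial()] result.
#' @param column column index.
#' @return A ggplot.
#' @export
plot_trace <- function(trace, column = 1L) {
  m <- trace$signals[[column]]
  d <- tibble::tibble(time = trace$time,
                      `LFP (mV)` = m[, "lfp_p"],
                      `rate (Hz)` = m[, "rate_p"] * 1000,
                      `Vp (mV)` = m[, "v_p"])
  d <- tidyr::pivot_longer(d, -"time")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~name, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
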