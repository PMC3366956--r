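#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_col
#'   geom_point scale_fill_viridis_c labs theme_minimal facet_wrap
NULL

#' Plot a firing-rate map
#'
#' @param object A [rate_map()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.rate_map <- function(object, ...) {
  d <- as_tibble(object)
  if (object$dims == 2L) {
    ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$rate)) +
      geom_raster() +
      scale_fill_viridis_c(na.value = "grey90") +
      labs(x = "x (cm)", y = "y (cm)", fill = "Hz") +
      theme_minimal()
  } else {
    ggplot(d, aes(x = .data$pos, y = .data$rate)) +
      geom_line(na.rm = TRUE) +
      labs(x = "linear position (cm)", y = "rate (Hz)") +
      theme_minimal()
  }
}

#' Plot a time-frequency map
#'
#' @param object A `tf_map` from [morlet_tf()] or [mean_swr_tf()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.tf_map <- function(object, ...) {
  d2 <- tibble(time = rep(object$times, each = length(object$frequencies)),
               frequency = rep(object$frequencies, times = length(object$times)),
               magnitude = as.vector(object$magnitude))
  ggplot(d2, aes(x = .data$time, y = .data$frequency,
                 fill = .data$magnitude)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "time (s)", y = "frequency (Hz)") +
    theme_minimal()
}

#' Phase histogram of spikes
#'
#' @param phases Degrees.
#' @param bins Number of bins (default 12).
#' @return A ggplot.
#' @export
plot_phase_histogram <- function(phases, bins = 12) {
  edges <- seq(0, 360, length.out = bins + 1)
  idx <- findInterval(phases %% 360, edges, rightmost.closed = TRUE)
  d <- tibble(phase = (edges[-(bins + 1)] + edges[-1]) / 2,
              count = as.numeric(table(factor(idx, levels = seq_len(bins)))))
  ggplot(d, aes(x = .data$phase, y = .data$count)) +
    geom_col(width = 360 / bins * 0.9) +
    labs(x = "phase (deg)", y = "spikes") +
    theme_minimal()
}

#' Plot a phase-precession fit
#'
#' Spike theta phase against relative position in the field (phases doubled
#' vertically for continuity, as is conventional), with the fitted line.
#'
#' @param object A `precession_fit`.
#' @param phases,positions The data the fit was computed from.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.precession_fit <- function(object, phases, positions, ...) {
  d <- tibble(position = rep(positions, 2),
              phase = c(phases %% 360, phases %% 360 + 360))
  xs <- seq(0, 1, length.out = 100)
  line <- tibble(position = xs,
                 phase = (object$offset + object$slope_deg * xs) %% 360)
  ggplot(d, aes(x = .data$position, y = .data$phase)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_line(data = line, colour = "red") +
    labs(x = "relative position in field", y = "theta phase (deg)",
         subtitle = sprintf("slope %.2f cycles/field, r = %.2f, p = %.3g",
                            object$slope, object$r, object$p)) +
    theme_minimal()
}

#' Plot a spatio-temporal field map
#'
#' @param object A `spatiotemporal_map`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.spatiotemporal_map <- function(object, ...) {
  d <- tibble(position = rep(object$pos_mid, times = length(object$phase_mid)),
              phase = rep(object$phase_mid, each = length(object$pos_mid)),
              rate = as.vector(object$rate))
  ggplot(d, aes(x = .data$position, y = .data$phase, fill = .data$rate)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "relative position in field", y = "theta phase (deg)") +
    theme_minimal()
}
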