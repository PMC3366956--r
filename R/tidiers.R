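#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a precession fit
#'
#' @param x A `precession_fit`.
#' @param ... Ignored.
#' @return One-row tibble: `slope`, `slope_deg`, `offset`, `r`, `p`.
#' @export
tidy.precession_fit <- function(x, ...) {
  tibble(slope = x$slope, slope_deg = x$slope_deg, offset = x$offset,
         r = x$r, p = x$p)
}

#' Fit summary of a precession fit
#'
#' @param x A `precession_fit`.
#' @param ... Ignored.
#' @return One-row tibble: `n`, `resultant`, `degenerate`.
#' @export
glance.precession_fit <- function(x, ...) {
  tibble(n = x$n, resultant = x$resultant, degenerate = x$degenerate)
}

#' Tidy a spikes-per-SWR distribution
#'
#' @param x A `swr_spike_distribution`.
#' @param ... Ignored.
#' @return Tibble `k`, `probability`.
#' @export
tidy.swr_spike_distribution <- function(x, ...) x$probabilities

#' Summary of a spikes-per-SWR distribution
#'
#' @param x A `swr_spike_distribution`.
#' @param ... Ignored.
#' @return One-row tibble: `n_epochs`, `mean_rate`.
#' @export
glance.swr_spike_distribution <- function(x, ...) {
  tibble(n_epochs = x$n_epochs, mean_rate = x$mean_rate)
}
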