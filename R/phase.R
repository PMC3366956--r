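#' Oscillation phase of spikes
#'
#' Linearly interpolates the phase series at each spike time. Spikes falling
#' outside valid phase segments are dropped; the number dropped is attached
#' as attribute `n_dropped`.
#'
#' @param spike_times Seconds.
#' @param phase_series A `phase_series` tibble.
#' @return Numeric vector of phases (deg in \[0,360)), attribute
#'   `n_dropped`.
#' @export
phases_of_spikes <- function(spike_times, phase_series) {
  phase <- spike_phase_or_na(spike_times, phase_series)
  out <- phase[!is.na(phase)]
  attr(out, "n_dropped") <- sum(is.na(phase))
  out
}

count_complete_cycles <- function(phase_series) {
  # a complete cycle = one wrap-around (360 -> 0) inside a valid segment
  v <- phase_series$valid & !is.na(phase_series$phase)
  if (!any(v)) return(0L)
  r <- rle(v)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  total <- 0L
  for (k in which(r$values)) {
    seg <- phase_series$phase[starts[k]:ends[k]]
    total <- total + sum(diff(seg) < -180)
  }
  total
}

#' Firing probability by oscillation phase
#'
#' Spike count per phase bin divided by the number of complete valid cycles:
#' the probability of observing a spike in that phase bin on any one cycle.
#'
#' @param spike_phases Degrees (e.g. from [phases_of_spikes()]).
#' @param phase_series The `phase_series` the phases came from (supplies the
#'   cycle count).
#' @param bins Number of phase bins (default 12).
#' @return Tibble: `phase_lo`, `phase_hi`, `phase_mid`, `count`,
#'   `probability`.
#' @export
firing_probability_by_phase <- function(spike_phases, phase_series,
                                        bins = 12) {
  n_cycles <- count_complete_cycles(phase_series)
  if (n_cycles == 0) abort("no complete valid cycles")
  edges <- seq(0, 360, length.out = bins + 1)
  idx <- findInterval(spike_phases %% 360, edges, rightmost.closed = TRUE)
  cnt <- as.numeric(table(factor(idx, levels = seq_len(bins))))
  tibble(phase_lo = edges[-(bins + 1)], phase_hi = edges[-1],
         phase_mid = (edges[-(bins + 1)] + edges[-1]) / 2,
         count = cnt, probability = cnt / n_cycles)
}

#' Intrinsic burst theta frequency from the spike-time autocorrelation
#'
#' Autocorrelation histogram of in-epoch spikes over lags up to 200 ms in
#' 2 ms bins, smoothed with a 3-bin boxcar; the lag of the histogram maximum
#' within 70-180 ms is the theta-burst period, returned with its frequency
#' 1000/period.
#'
#' @param spike_times Seconds.
#' @param theta_epochs Start/end tibble; spikes are restricted to it.
#' @param lag_range Search range in ms (default c(70, 180)).
#' @param bin Bin width in ms (default 2).
#' @param max_lag Histogram extent in ms (default 200).
#' @param min_spikes Below this count the result is flagged low-confidence.
#' @return One-row tibble: `peak_lag_ms`, `frequency_hz`, `n_spikes`,
#'   `low_confidence`.
#' @export
burst_theta_frequency <- function(spike_times, theta_epochs,
                                  lag_range = c(70, 180), bin = 2,
                                  max_lag = 200, min_spikes = 50) {
  st <- restrict(spike_times, theta_epochs)
  lags <- pairwise_lags(st, max_lag / 1000) * 1000
  if (length(lags) == 0)
    return(tibble(peak_lag_ms = NA_real_, frequency_hz = NA_real_,
                  n_spikes = length(st), low_confidence = TRUE))
  edges <- seq(0, max_lag, by = bin)
  h <- graphics::hist(lags, breaks = edges, plot = FALSE)
  counts <- boxcar_smooth(h$counts, 3L)
  mids <- h$mids
  inr <- mids >= lag_range[1] & mids <= lag_range[2]
  if (!any(inr) || all(counts[inr] == 0))
    return(tibble(peak_lag_ms = NA_real_, frequency_hz = NA_real_,
                  n_spikes = length(st), low_confidence = TRUE))
  tstar <- mids[inr][which.max(counts[inr])]
  tibble(peak_lag_ms = tstar, frequency_hz = 1000 / tstar,
         n_spikes = length(st),
         low_confidence = length(st) < min_spikes)
}

#' Distribution of spikes fired per SWR
#'
#' `p(k)` is the fraction of SWR epochs in which the unit fired exactly k
#' spikes (k above `k_max` pooled into the last class), plus the mean
#' within-SWR firing rate.
#'
#' @param spike_times Seconds.
#' @param epochs SWR start/end tibble.
#' @param k_max Largest spike count reported individually (default 5).
#' @return List of class `swr_spike_distribution`: tibble `probabilities`
#'   (`k`, `probability`; last row is `>k_max`), `mean_rate` (Hz),
#'   `n_epochs`.
#' @export
swr_spike_distribution <- function(spike_times, epochs, k_max = 5) {
  if (nrow(epochs) == 0) abort("need at least one epoch")
  counts <- map_int(seq_len(nrow(epochs)), function(i)
    sum(spike_times >= epochs$start[i] & spike_times < epochs$end[i]))
  ks <- 0:k_max
  p <- map_dbl(ks, ~ mean(counts == .x))
  p_over <- mean(counts > k_max)
  probs <- tibble(k = c(as.character(ks), paste0(">", k_max)),
                  probability = c(p, p_over))
  total_dur <- sum(epochs$end - epochs$start)
  structure(list(probabilities = probs,
                 mean_rate = sum(counts) / total_dur,
                 n_epochs = nrow(epochs)),
            class = "swr_spike_distribution")
}

#' Peri-SWR firing-rate histogram
#'
#' Spike counts in bins relative to each epoch's peak-power time, averaged
#' over epochs and divided by the bin width, in Hz.
#'
#' @param spike_times Seconds.
#' @param peak_times Peak-power times of the SWR epochs.
#' @param half_width Seconds either side of the peak (default 0.25).
#' @param bin Bin width in seconds (default 0.01).
#' @return Tibble: `time` (bin center, s relative to peak), `rate` (Hz).
#' @export
swr_rate_histogram <- function(spike_times, peak_times, half_width = 0.25,
                               bin = 0.01) {
  if (length(peak_times) == 0) abort("need at least one epoch")
  edges <- seq(-half_width, half_width, by = bin)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  acc <- numeric(length(mids))
  for (pt in peak_times) {
    rel <- spike_times - pt
    rel <- rel[rel >= -half_width & rel < half_width]
    if (length(rel) > 0) {
      idx <- findInterval(rel, edges)
      idx <- idx[idx >= 1 & idx <= length(mids)]
      acc <- acc + tabulate(idx, nbins = length(mids))
    }
  }
  tibble(time = mids, rate = acc / (length(peak_times) * bin))
}
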