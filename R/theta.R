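#' Detect theta epochs from the theta/delta power ratio
#'
#' The signal is band-passed at theta (6-10 Hz) and delta (2-4 Hz); RMS power
#' of each is computed over non-overlapping windows (500 ms) and contiguous
#' windows with a theta/delta ratio above the threshold (2) are merged into
#' theta epochs.
#'
#' @param x Numeric signal or `lfp_signal`.
#' @param sample_rate Hz (ignored for `lfp_signal`).
#' @param cfg An [osc_config()].
#' @param t0 Time of the first sample (s).
#' @return Tibble with `start`, `end` columns.
#' @export
detect_theta_epochs <- function(x, sample_rate = NULL, cfg = osc_config(),
                                t0 = 0) {
  if (inherits(x, "lfp_signal")) { sample_rate <- x$sample_rate; x <- x$samples }
  wn <- round(cfg$theta_ratio_window * sample_rate)
  if (length(x) < wn) abort("signal shorter than one ratio window")
  th <- bandpass(x, cfg$theta_band, sample_rate, cfg$filter_order)
  de <- bandpass(x, cfg$delta_band, sample_rate, cfg$filter_order)
  nwin <- length(x) %/% wn
  idx <- rep(seq_len(nwin), each = wn)
  rms_th <- sqrt(tapply(th[seq_len(nwin * wn)]^2, idx, mean))
  rms_de <- sqrt(tapply(de[seq_len(nwin * wn)]^2, idx, mean))
  ratio <- as.numeric(rms_th / rms_de)
  is_theta <- ratio > cfg$theta_ratio_threshold
  if (!any(is_theta)) return(tibble(start = numeric(0), end = numeric(0)))
  r <- rle(is_theta)
  re <- cumsum(r$lengths); rs <- re - r$lengths + 1
  keep <- which(r$values)
  tibble(start = t0 + (rs[keep] - 1) * wn / sample_rate,
         end = t0 + re[keep] * wn / sample_rate)
}

interpolated_phase <- function(crossings, times) {
  # unwrapped phase: 360 * (index-1) at each descending crossing, linear
  # in between; NA outside [first, last] crossing
  ph <- rep(NA_real_, length(times))
  if (length(crossings) < 2) return(ph)
  k <- approx(crossings, (seq_along(crossings) - 1) * 360, xout = times,
              rule = 1)$y
  k %% 360
}

#' Theta phase series from the 5-14 Hz filtered trace
#'
#' Inside each theta epoch, the positive-to-negative zero-crossings of the
#' 5-14 Hz filtered raw signal are assigned phase 0 deg and phase advances
#' linearly to 360 deg across each cycle. Samples outside epochs, or inside
#' epochs with fewer than two crossings, are invalid.
#'
#' @param x Raw signal or `lfp_signal`.
#' @param theta_epochs Tibble with `start`/`end` from
#'   [detect_theta_epochs()].
#' @param sample_rate Hz (ignored for `lfp_signal`).
#' @param cfg An [osc_config()].
#' @param t0 Time of the first sample (s).
#' @return Tibble of class `phase_series`: `time`, `phase` (deg in
#'   \[0, 360)), `valid`.
#' @export
theta_phase_series <- function(x, theta_epochs, sample_rate = NULL,
                               cfg = osc_config(), t0 = 0) {
  if (inherits(x, "lfp_signal")) { sample_rate <- x$sample_rate; x <- x$samples }
  filt <- bandpass(x, cfg$phase_filter_band, sample_rate, cfg$filter_order)
  phase_series_from_filtered(filt, theta_epochs, sample_rate, t0)
}

#' Ripple phase series within SWR epochs
#'
#' Same interpolation scheme as [theta_phase_series()] but between the ripple
#' cycle crossings of the ripple-band filtered trace, valid only inside SWR
#' epochs.
#'
#' @param filtered Ripple-band filtered trace.
#' @param epochs SWR epoch tibble (`start`, `end`).
#' @param sample_rate Hz.
#' @param t0 Time of the first sample (s).
#' @return A `phase_series` tibble.
#' @export
ripple_phase_series <- function(filtered, epochs, sample_rate, t0 = 0) {
  phase_series_from_filtered(filtered, epochs, sample_rate, t0)
}

phase_series_from_filtered <- function(filt, epochs, sample_rate, t0) {
  n <- length(filt)
  times <- t0 + (seq_len(n) - 1) / sample_rate
  phase <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (k in seq_len(nrow(epochs))) {
    s <- epochs$start[k]; e <- epochs$end[k]
    sel <- which(times >= s & times < e)
    if (length(sel) < 2) next
    cyc <- descending_zero_crossings(filt[sel], sample_rate,
                                     t0 = times[sel[1]])
    if (length(cyc) < 2) next                 # too few crossings: invalid
    ph <- interpolated_phase(cyc, times[sel])
    ok <- !is.na(ph)
    phase[sel[ok]] <- ph[ok]
    valid[sel[ok]] <- TRUE
  }
  out <- tibble(time = times, phase = phase, valid = valid)
  class(out) <- c("phase_series", class(out))
  out
}

#' Theta-band multitaper spectra split by running speed
#'
#' Cuts the theta epochs into ratio-window-sized segments, assigns each to a
#' speed bin by the mean running speed over the segment, and returns one
#' multitaper spectrum per bin together with its theta-band peak.
#'
#' @param x Raw signal or `lfp_signal`.
#' @param theta_epochs Start/end tibble.
#' @param speed Tibble `time`/`speed` from [compute_speed()].
#' @param sample_rate Hz (ignored for `lfp_signal`).
#' @param cfg An [osc_config()]; `speed_bins` gives lower bin edges (cm/s),
#'   last bin open-ended.
#' @param t0 Time of the first sample (s).
#' @return Tibble: `speed_bin` (label), `n_segments`, `peak_frequency`,
#'   `peak_power`, list-column `spectrum`.
#' @export
theta_spectra_by_speed <- function(x, theta_epochs, speed, sample_rate = NULL,
                                   cfg = osc_config(), t0 = 0) {
  if (inherits(x, "lfp_signal")) { sample_rate <- x$sample_rate; x <- x$samples }
  wn <- round(cfg$theta_ratio_window * sample_rate)
  edges <- c(cfg$speed_bins, Inf)
  labels <- paste0("[", edges[-length(edges)], ",",
                   ifelse(is.finite(edges[-1]), edges[-1], "Inf"), ")")
  segs <- vector("list", length(labels))
  for (k in seq_len(nrow(theta_epochs))) {
    s <- theta_epochs$start[k]
    i0 <- round((s - t0) * sample_rate) + 1
    nseg <- floor((theta_epochs$end[k] - s) * sample_rate / wn)
    for (j in seq_len(nseg)) {
      a <- i0 + (j - 1) * wn; b <- a + wn - 1
      if (b > length(x)) next
      ts <- t0 + (a - 1) / sample_rate; te <- t0 + b / sample_rate
      sp <- speed$speed[speed$time >= ts & speed$time < te]
      if (length(sp) == 0 || all(is.na(sp))) next
      bin <- findInterval(mean(sp, na.rm = TRUE), edges)
      if (bin < 1 || bin > length(labels)) next
      segs[[bin]] <- c(segs[[bin]], list(x[a:b]))
    }
  }
  rows <- lapply(seq_along(labels), function(b) {
    if (length(segs[[b]]) == 0)
      return(tibble(speed_bin = labels[b], n_segments = 0L,
                    peak_frequency = NA_real_, peak_power = NA_real_,
                    spectrum = list(NULL)))
    spec <- multitaper_psd(segs[[b]], sample_rate, nfft = 4L * wn)
    inb <- spec$frequency >= cfg$theta_band[1] &
      spec$frequency <= cfg$theta_band[2]
    i <- which.max(spec$power[inb])
    tibble(speed_bin = labels[b], n_segments = length(segs[[b]]),
           peak_frequency = spec$frequency[inb][i],
           peak_power = spec$power[inb][i], spectrum = list(spec))
  })
  bind_rows(rows)
}
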