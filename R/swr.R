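#' Detect sharp wave/ripple epochs from ripple-band power
#'
#' A window whose ripple-band RMS power exceeds `swr_enter_sd` SD above the
#' mean seeds an epoch, which extends in both directions up to the last
#' window still at or above `swr_exit_sd` SD above the mean. Candidate
#' epochs whose seed windows coincide (within one window) with a
#' `ref_reject_sd` SD excursion on the reference channel are discarded as
#' muscle artifacts. Overlapping or nearly touching epochs are merged and
#' sub-duration detections dropped.
#'
#' Because ripples occur principally during immobility, the mean/SD baseline
#' is best computed over rest-trial windows: pass them as `baseline_epochs`.
#' With `baseline_epochs = NULL` all windows form the baseline. The baseline
#' must describe the noise floor, not the events being detected, so windows
#' beyond `baseline_clip_sd` SD are iteratively excluded before the final
#' mean/SD are fixed (the events themselves otherwise inflate the SD and
#' depress sensitivity).
#'
#' @param power A `power_series` from [windowed_rms()] on the detection
#'   channel.
#' @param ref_power Optional `power_series` of the reference channel (same
#'   windowing).
#' @param cfg An [osc_config()].
#' @param baseline_epochs Optional start/end tibble over which the mean and
#'   SD of the power are estimated.
#' @param baseline_clip_sd Clip threshold for the iterative baseline
#'   (default 5; `Inf` disables clipping).
#' @return Tibble with columns `start`, `end` (seconds), one row per epoch.
#' @export
detect_swr <- function(power, ref_power = NULL, cfg = osc_config(),
                       baseline_epochs = NULL, baseline_clip_sd = 5) {
  stats_of <- function(p) {
    r <- p$rms
    if (!is.null(baseline_epochs)) {
      keep <- in_epochs(p$time, baseline_epochs)
      if (!any(keep)) abort("no power windows inside baseline epochs")
      r <- r[keep]
    }
    if (is.finite(baseline_clip_sd)) {
      for (i in 1:5) {
        m <- mean(r); ss <- sd(r)
        if (!is.finite(ss) || ss <= 0) break
        keep <- r < m + baseline_clip_sd * ss
        if (all(keep)) break
        r <- r[keep]
      }
    }
    c(mean(r), sd(r))
  }
  ms <- stats_of(power)
  mu <- ms[1]; sdv <- ms[2]
  empty <- tibble(start = numeric(0), end = numeric(0))
  if (!is.finite(sdv) || sdv <= 0) return(empty)

  z <- (power$rms - mu) / sdv
  seed <- z > cfg$swr_enter_sd
  if (!any(seed)) return(empty)
  above <- z >= cfg$swr_exit_sd

  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  keep_run <- r$values & map_lgl(seq_along(r$values), function(k)
    r$values[k] && any(seed[run_start[k]:run_end[k]]))
  idx <- which(keep_run)
  if (length(idx) == 0) return(empty)

  half <- cfg$rms_window / 2
  start <- power$time[run_start[idx]] - half
  end <- power$time[run_end[idx]] + half

  if (!is.null(ref_power)) {
    msr <- stats_of(ref_power)
    if (is.finite(msr[2]) && msr[2] > 0) {
      zr <- (ref_power$rms - msr[1]) / msr[2]
      hot <- which(zr > cfg$ref_reject_sd)
      if (length(hot) > 0) {
        bad <- map_lgl(idx, function(k) {
          sw <- which(seed[run_start[k]:run_end[k]]) + run_start[k] - 1L
          any(outer(sw, hot, function(a, b) abs(a - b) <= 1L))
        })
        start <- start[!bad]; end <- end[!bad]
      }
    }
  }
  if (length(start) == 0) return(empty)

  # merge epochs separated by less than merge_gap
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms_start <- start[1]; ms_end <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] - ms_end <= cfg$merge_gap) {
      ms_end <- max(ms_end, end[i])
    } else {
      out_s <- c(out_s, ms_start); out_e <- c(out_e, ms_end)
      ms_start <- start[i]; ms_end <- end[i]
    }
  }
  out_s <- c(out_s, ms_start); out_e <- c(out_e, ms_end)

  keep <- (out_e - out_s) >= cfg$min_swr_duration
  tibble(start = out_s[keep], end = out_e[keep])
}

descending_zero_crossings <- function(x, sample_rate, t0 = 0) {
  n <- length(x)
  if (n < 2) return(numeric(0))
  i <- which(x[-n] > 0 & x[-1] <= 0)
  if (length(i) == 0) return(numeric(0))
  frac <- x[i] / (x[i] - x[i + 1])
  t0 + (i - 1 + frac) / sample_rate
}

#' Characterize detected ripple epochs
#'
#' For each epoch: the peak-power time (center of the maximal RMS window),
#' the individual ripple cycles (positive-to-negative zero-crossings of the
#' band-passed trace), the ripple amplitude (half the peak-to-trough swing of
#' the band-passed trace within one cycle of the power peak), and the peak
#' frequency of the epoch's multitaper spectrum inside the ripple band.
#'
#' @param epochs Tibble with `start`/`end` from [detect_swr()].
#' @param filtered Ripple-band filtered trace (full session).
#' @param raw Raw trace (same sampling), used for the spectrum.
#' @param sample_rate Hz.
#' @param cfg An [osc_config()].
#' @param t0 Time of the first sample (s).
#' @return Tibble: `start`, `end`, `duration`, `peak_power_time`,
#'   `peak_frequency`, `amplitude`, `n_cycles`, `flagged`, and list-column
#'   `cycles` of crossing times. Epochs without a zero-crossing are flagged
#'   with undefined amplitude/frequency.
#' @export
characterize_swr <- function(epochs, filtered, raw, sample_rate,
                             cfg = osc_config(), t0 = 0) {
  band <- cfg$ripple_band
  res <- lapply(seq_len(nrow(epochs)), function(k) {
    s <- epochs$start[k]; e <- epochs$end[k]
    i0 <- max(1L, floor((s - t0) * sample_rate) + 1L)
    i1 <- min(length(filtered), ceiling((e - t0) * sample_rate) + 1L)
    seg_f <- filtered[i0:i1]
    seg_r <- raw[i0:i1]
    seg_t0 <- t0 + (i0 - 1) / sample_rate

    pw <- windowed_rms(seg_f, sample_rate, window = cfg$rms_window,
                       step = cfg$rms_step, t0 = seg_t0)
    peak_t <- pw$time[which.max(pw$rms)]

    cyc <- descending_zero_crossings(seg_f, sample_rate, t0 = seg_t0)
    if (length(cyc) == 0) {
      return(list(peak_power_time = peak_t, peak_frequency = NA_real_,
                  amplitude = NA_real_, cycles = numeric(0), flagged = TRUE))
    }
    period <- if (length(cyc) >= 2) median(diff(cyc)) else 2 / sum(band)
    j0 <- max(1L, floor((peak_t - period - seg_t0) * sample_rate) + 1L)
    j1 <- min(length(seg_f), ceiling((peak_t + period - seg_t0) * sample_rate) + 1L)
    amp <- (max(seg_f[j0:j1]) - min(seg_f[j0:j1])) / 2

    # single Slepian taper: epoch segments are 50-100 ms, so the taper
    # half-bandwidth (NW/T) must stay ~10-20 Hz to resolve the carrier
    spec <- multitaper_psd(list(seg_f), sample_rate, nw = 1, k = 1,
                           nfft = max(2048L, length(seg_f)))
    inb <- spec$frequency >= band[1] & spec$frequency <= band[2]
    pf <- spec$frequency[inb][which.max(spec$power[inb])]
    list(peak_power_time = peak_t, peak_frequency = pf, amplitude = amp,
         cycles = cyc, flagged = FALSE)
  })
  tibble(
    start = epochs$start, end = epochs$end,
    duration = epochs$end - epochs$start,
    peak_power_time = map_dbl(res, "peak_power_time"),
    peak_frequency = map_dbl(res, "peak_frequency"),
    amplitude = map_dbl(res, "amplitude"),
    n_cycles = map_int(res, ~ length(.x$cycles)),
    flagged = map_lgl(res, "flagged"),
    cycles = map(res, "cycles"))
}
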