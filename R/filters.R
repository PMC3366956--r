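#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (filtfilt), giving zero group delay — mandatory here because oscillation
#' phase is defined by the zero-crossings of the filtered trace.
#'
#' @param x Numeric vector or an [lfp_signal()].
#' @param band Hz pair `c(low, high)`; `high` must be below Nyquist.
#' @param sample_rate Hz; ignored (taken from the object) when `x` is an
#'   `lfp_signal`.
#' @param order Butterworth prototype order (default 4).
#' @return Filtered numeric vector, same length as the input.
#' @export
bandpass <- function(x, band, sample_rate = NULL, order = 4) {
  if (inherits(x, "lfp_signal")) {
    sample_rate <- x$sample_rate
    x <- x$samples
  }
  if (is.null(sample_rate)) abort("`sample_rate` required for a bare vector")
  nyq <- sample_rate / 2
  if (band[2] >= nyq)
    abort(sprintf("band upper edge %g Hz must be below Nyquist (%g Hz)",
                  band[2], nyq))
  if (band[1] <= 0 || band[1] >= band[2]) abort("need 0 < low < high")
  # very narrow normalized bands push poles outside the unit circle at high
  # order; step the order down until the realization is stable
  ord <- order
  repeat {
    bf <- signal::butter(ord, band / nyq, type = "pass")
    if (max(Mod(polyroot(rev(bf$a)))) < 1 - 1e-7 || ord == 1) break
    ord <- ord - 1
  }
  as.numeric(signal::filtfilt(bf, x))
}

#' Windowed RMS power of a filtered signal
#'
#' RMS over windows of `window` seconds whose centers step by `step` seconds:
#' window k covers `[t_k - window/2, t_k + window/2)`. Returns the per-window
#' RMS together with its mean and SD over all windows (the detection
#' thresholds are expressed in these SD units).
#'
#' @param x Numeric vector (typically a band-passed trace).
#' @param sample_rate Hz.
#' @param window,step Seconds; `window >= step`.
#' @param t0 Time of the first sample (s), default 0.
#' @return A tibble of class `power_series` with columns `time` (window
#'   center) and `rms`; attributes `mean`, `sd`, `window`, `step`.
#' @export
windowed_rms <- function(x, sample_rate, window = 0.020, step = 0.010,
                         t0 = 0) {
  wn <- max(1L, round(window * sample_rate))
  sn <- max(1L, round(step * sample_rate))
  n <- length(x)
  if (n < wn) abort("signal shorter than one window")
  starts <- seq(1L, n - wn + 1L, by = sn)
  cs <- c(0, cumsum(x^2))
  ms <- (cs[starts + wn] - cs[starts]) / wn
  rms <- sqrt(ms)
  centers <- t0 + (starts - 1 + wn / 2) / sample_rate
  out <- tibble(time = centers, rms = rms)
  attr(out, "mean") <- mean(rms)
  attr(out, "sd") <- sd(rms)
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("power_series", class(out))
  out
}
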