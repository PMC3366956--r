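#' Morlet wavelet time-frequency map
#'
#' Convolves the signal with complex Morlet wavelets whose Gaussian temporal
#' SD equals one period of the target frequency (SD = 1/f). Each wavelet is
#' normalized to unit total energy so that magnitudes are directly comparable
#' across frequencies. The map holds the absolute value of the convolution.
#'
#' @param x Numeric signal.
#' @param sample_rate Hz.
#' @param frequencies Increasing Hz vector; all below Nyquist.
#' @param t0 Time of the first sample (s).
#' @return List of class `tf_map`: `times`, `frequencies`,
#'   `magnitude` (frequency x time matrix).
#' @export
morlet_tf <- function(x, sample_rate, frequencies, t0 = 0) {
  if (length(frequencies) == 0) abort("empty frequency list")
  if (is.unsorted(frequencies, strictly = TRUE))
    abort("frequencies must be strictly increasing")
  if (max(frequencies) >= sample_rate / 2)
    abort("max frequency must be below Nyquist")
  n <- length(x)
  dt <- 1 / sample_rate
  # pad so circular FFT convolution is linear for the widest wavelet
  max_half <- ceiling(4 / min(frequencies) * sample_rate)
  nfft <- stats::nextn(n + 2 * max_half, 2)
  X <- fft(c(x, rep(0, nfft - n)))
  mag <- matrix(0, nrow = length(frequencies), ncol = n)
  for (k in seq_along(frequencies)) {
    f <- frequencies[k]
    sdt <- 1 / f
    half <- ceiling(4 * sdt * sample_rate)
    tt <- (-half:half) * dt
    w <- exp(-tt^2 / (2 * sdt^2)) * exp(2i * pi * f * tt)
    w <- w / sqrt(sum(Mod(w)^2) * dt)        # unit total energy
    W <- fft(c(w, rep(0, nfft - length(w))))
    conv <- fft(X * W, inverse = TRUE) / nfft
    # center of the wavelet sits at index half+1 of the kernel
    mag[k, ] <- Mod(conv[(half + 1):(half + n)]) * dt
  }
  structure(list(times = t0 + (seq_len(n) - 1) * dt,
                 frequencies = frequencies, magnitude = mag),
            class = "tf_map")
}

#' Ripple-triggered mean time-frequency map
#'
#' Computes a Morlet map per SWR epoch in a window of `half_width` seconds
#' around its peak-power time and averages the maps elementwise; epochs whose
#' window exceeds the signal extent are skipped with a warning.
#'
#' @param x Raw signal.
#' @param sample_rate Hz.
#' @param epochs Characterized epochs (need `peak_power_time`).
#' @param half_width Seconds around the peak (default 0.125).
#' @param frequencies Hz vector (default 90-300 Hz in 2 Hz steps).
#' @param t0 Time of the first sample (s).
#' @return A `tf_map` with times relative to the epoch peak.
#' @export
mean_swr_tf <- function(x, sample_rate, epochs, half_width = 0.125,
                        frequencies = seq(90, 300, by = 2), t0 = 0) {
  if (nrow(epochs) == 0) abort("need at least one epoch")
  hw <- round(half_width * sample_rate)
  acc <- NULL; used <- 0
  for (k in seq_len(nrow(epochs))) {
    c0 <- round((epochs$peak_power_time[k] - t0) * sample_rate) + 1
    i0 <- c0 - hw; i1 <- c0 + hw
    if (i0 < 1 || i1 > length(x)) {
      warn(sprintf("epoch %d window exceeds signal extent; skipped", k))
      next
    }
    m <- morlet_tf(x[i0:i1], sample_rate, frequencies)$magnitude
    acc <- if (is.null(acc)) m else acc + m
    used <- used + 1
  }
  if (used == 0) abort("no epoch fits inside the signal")
  structure(list(times = (-hw:hw) / sample_rate, frequencies = frequencies,
                 magnitude = acc / used, n_epochs = used),
            class = "tf_map")
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem; tapers are
#' orthonormal and ordered by decreasing spectral concentration.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 3).
#' @param k Number of tapers (default 5).
#' @return n x k matrix, columns orthonormal.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  if (k > n) abort("more tapers than samples")
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  # sign convention: positive mean for symmetric tapers, positive first lobe
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) > 1e-8) { if (s < 0) v[, j] <- -v[, j] }
    else if (v[2, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' Multitaper power spectral density
#'
#' DPSS-tapered (time-bandwidth `nw`, `k` tapers) periodograms averaged over
#' tapers and segments. Shorter segments are zero-padded to the longest (or
#' to `nfft`). The two-sided PSD integrates to the signal variance
#' (Parseval); returned one-sided.
#'
#' @param segments List of numeric vectors.
#' @param sample_rate Hz.
#' @param nw Time-bandwidth product (default 3).
#' @param k Number of tapers (default 5).
#' @param nfft FFT length; default the longest segment.
#' @return Tibble with columns `frequency` (Hz) and `power` (units^2/Hz).
#' @export
multitaper_psd <- function(segments, sample_rate, nw = 3, k = 5,
                           nfft = NULL) {
  if (length(segments) == 0) abort("empty segment list")
  nmax <- max(lengths(segments))
  if (is.null(nfft)) nfft <- nmax
  nfft <- max(nfft, nmax)
  acc <- NULL
  tap_cache <- list()
  for (seg in segments) {
    n <- length(seg)
    key <- as.character(n)
    if (is.null(tap_cache[[key]])) tap_cache[[key]] <- dpss_tapers(n, nw, k)
    v <- tap_cache[[key]]
    ps <- 0
    for (j in seq_len(k)) {
      tx <- c(seg * v[, j], rep(0, nfft - n))
      ps <- ps + Mod(fft(tx))^2
    }
    ps <- ps / (k * sample_rate)          # two-sided PSD per segment
    acc <- if (is.null(acc)) ps else acc + ps
  }
  psd2 <- acc / length(segments)
  nf <- floor(nfft / 2) + 1
  freq <- (0:(nf - 1)) * sample_rate / nfft
  onesided <- psd2[1:nf]
  if (nfft %% 2 == 0) {
    onesided[2:(nf - 1)] <- onesided[2:(nf - 1)] + rev(psd2[(nf + 1):nfft])
  } else {
    onesided[2:nf] <- onesided[2:nf] + rev(psd2[(nf + 1):nfft])
  }
  tibble(frequency = freq, power = onesided)
}
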