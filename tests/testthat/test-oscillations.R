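fs <- 1000

test_that("bandpass is unity-gain in band, strongly attenuating out of band", {
  tt <- seq(0, 5, by = 1 / fs)
  mid <- seq(round(length(tt) / 4), round(3 * length(tt) / 4))
  y150 <- bandpass(sin(2 * pi * 150 * tt), c(125, 250), fs)
  expect_lt(abs(max(abs(y150[mid])) - 1), 0.01)
  y50 <- bandpass(sin(2 * pi * 50 * tt), c(125, 250), fs)
  expect_lt(max(abs(y50[mid])), 10^(-40 / 20))     # >= 40 dB down
  expect_error(bandpass(rnorm(100), c(100, 600), fs), "Nyquist")
})

test_that("bandpass is zero-phase: impulse response is symmetric", {
  x <- rep(0, 2001); x[1001] <- 1
  y <- bandpass(x, c(125, 250), fs)
  expect_equal(y[1001 + 1:500], y[1001 - 1:500], tolerance = 1e-8)
})

test_that("windowed_rms matches constants, sines and a loop oracle", {
  p <- windowed_rms(rep(3, 1000), fs, 0.02, 0.01)
  expect_true(all(abs(p$rms - 3) < 1e-12))
  expect_equal(attr(p, "sd"), 0)

  tt <- seq(0, 2, by = 1 / fs)
  p2 <- windowed_rms(5 * sin(2 * pi * 200 * tt), fs, 0.2, 0.1)
  expect_true(all(abs(p2$rms - 5 / sqrt(2)) < 0.05))

  set.seed(5)
  for (i in 1:100) {
    x <- rnorm(sample(200:400, 1))
    p3 <- windowed_rms(x, fs, 0.02, 0.01)
    expect_equal(p3$rms, oracle_windowed_rms(x, fs, 0.02, 0.01),
                 tolerance = 1e-12)
  }
  expect_error(windowed_rms(rnorm(10), fs, 0.02, 0.01), "shorter")
})

test_that("detect_swr finds an injected burst and matches a window oracle", {
  set.seed(8)
  tt <- seq(0, 10, by = 1 / fs)
  noise <- bandpass(rnorm(length(tt)), c(125, 250), fs)
  burst <- 10 * sd(noise) * exp(-(tt - 5)^2 / (2 * 0.0125^2)) *
    sin(2 * pi * 150 * tt)
  x <- noise + burst
  cfg <- osc_config()
  pw <- windowed_rms(x, fs, cfg$rms_window, cfg$rms_step)
  ep <- detect_swr(pw, cfg = cfg, baseline_clip_sd = Inf)
  expect_equal(nrow(ep), 1)
  expect_true(ep$start[1] < 5 && ep$end[1] > 5)

  # independent oracle: plain threshold walk over the window series
  z <- (pw$rms - mean(pw$rms)) / sd(pw$rms)
  seeds <- which(z > cfg$swr_enter_sd)
  expect_true(length(seeds) > 0)
  lo <- min(seeds); hi <- max(seeds)
  while (lo > 1 && z[lo - 1] >= cfg$swr_exit_sd) lo <- lo - 1
  while (hi < length(z) && z[hi + 1] >= cfg$swr_exit_sd) hi <- hi + 1
  expect_equal(ep$start[1], pw$time[lo] - cfg$rms_window / 2)
  expect_equal(ep$end[1], pw$time[hi] + cfg$rms_window / 2)
})

test_that("detect_swr is scale-invariant, silent on flat power, and merges", {
  set.seed(9)
  tt <- seq(0, 10, by = 1 / fs)
  x <- bandpass(rnorm(length(tt)), c(125, 250), fs) +
    10 * exp(-(tt - 5)^2 / (2 * 0.0125^2)) * sin(2 * pi * 150 * tt)
  cfg <- osc_config()
  e1 <- detect_swr(windowed_rms(x, fs, cfg$rms_window, cfg$rms_step), cfg = cfg)
  e2 <- detect_swr(windowed_rms(7.3 * x, fs, cfg$rms_window, cfg$rms_step),
                   cfg = cfg)
  expect_equal(e1, e2)

  flat <- windowed_rms(rep(2, 5000), fs, 0.02, 0.01)
  expect_equal(nrow(detect_swr(flat, cfg = cfg)), 0)

  if (nrow(e1) > 1) expect_true(all(e1$start[-1] >= e1$end[-nrow(e1)]))
  expect_true(all(e1$end - e1$start >= cfg$min_swr_duration))
})

test_that("reference-channel coincidence vetoes candidate epochs", {
  set.seed(10)
  tt <- seq(0, 10, by = 1 / fs)
  burst <- 12 * exp(-(tt - 5)^2 / (2 * 0.0125^2)) * sin(2 * pi * 160 * tt)
  x <- bandpass(rnorm(length(tt)), c(125, 250), fs) + burst
  ref <- bandpass(rnorm(length(tt)), c(125, 250), fs) + burst
  cfg <- osc_config()
  pw <- windowed_rms(x, fs, cfg$rms_window, cfg$rms_step)
  rpw <- windowed_rms(ref, fs, cfg$rms_window, cfg$rms_step)
  expect_gt(nrow(detect_swr(pw, cfg = cfg)), 0)
  expect_equal(nrow(detect_swr(pw, rpw, cfg)), 0)
})

test_that("characterize_swr recovers tone frequency, cycles and amplitude", {
  tt <- seq(0, 2, by = 1 / fs)
  env <- exp(-(tt - 1)^2 / (2 * 0.02^2))
  x <- 3 * env * sin(2 * pi * 160 * tt)
  cfg <- osc_config()
  filt <- bandpass(x, cfg$ripple_band, fs)
  ep <- tibble::tibble(start = 0.94, end = 1.06)
  ch <- characterize_swr(ep, filt, x, fs, cfg)
  expect_lt(abs(ch$peak_frequency - 160), 5)
  expect_lt(abs(median(diff(ch$cycles[[1]])) - 1 / 160), 2e-4)
  expect_true(ch$peak_power_time > ep$start && ch$peak_power_time < ep$end)
  expect_false(ch$flagged)

  # half peak-to-trough of an unmodulated amplitude-3 tone is 3
  x2 <- 3 * sin(2 * pi * 160 * tt)
  ch2 <- characterize_swr(ep, bandpass(x2, cfg$ripple_band, fs), x2, fs, cfg)
  expect_lt(abs(ch2$amplitude - 3), 0.1)
})

test_that("theta epochs follow the theta/delta ratio rule", {
  tt <- seq(0, 20, by = 1 / fs)
  cfg <- osc_config()
  ep8 <- detect_theta_epochs(sin(2 * pi * 8 * tt), fs, cfg)
  expect_equal(nrow(ep8), 1)
  expect_gte(sum(ep8$end - ep8$start), 19.5)
  ep3 <- detect_theta_epochs(sin(2 * pi * 3 * tt), fs, cfg)
  expect_equal(nrow(ep3), 0)

  # amplitude sweep: onset where the per-window oracle says so
  amp <- seq(0.2, 4, length.out = 40)           # one 0.5 s window each
  x <- unlist(lapply(amp, function(a) {
    t2 <- seq(0, 0.499, by = 1 / fs)
    a * sin(2 * pi * 8 * t2) + sin(2 * pi * 3 * t2)
  }))
  epm <- detect_theta_epochs(x, fs, cfg)
  th <- bandpass(x, cfg$theta_band, fs)
  de <- bandpass(x, cfg$delta_band, fs)
  wn <- 500
  nwin <- length(x) %/% wn
  idx <- rep(seq_len(nwin), each = wn)
  ratio <- as.numeric(sqrt(tapply(th[1:(nwin * wn)]^2, idx, mean)) /
                        sqrt(tapply(de[1:(nwin * wn)]^2, idx, mean)))
  is_theta_oracle <- ratio > cfg$theta_ratio_threshold
  covered <- rep(FALSE, nwin)
  for (k in seq_len(nrow(epm))) {
    covered[(round(epm$start[k] * 2) + 1):round(epm$end[k] * 2)] <- TRUE
  }
  expect_equal(covered, is_theta_oracle)
})

test_that("theta phase advances linearly with 0 deg at descending crossings", {
  tt <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 8 * tt)
  ps <- theta_phase_series(x, tibble::tibble(start = 0, end = 10), fs)
  # analytic phase: descending zero-crossing of sin at t = (k + 1/2) / 8
  an <- ((tt - 1 / 16) * 8 * 360) %% 360
  core <- ps$valid & tt > 1 & tt < 9
  err <- abs(((ps$phase[core] - an[core] + 180) %% 360) - 180)
  expect_lt(max(err), 2)
  # half the samples on each half-cycle
  expect_lt(abs(mean(ps$phase[ps$valid] < 180) - 0.5), 0.02)
  # phase rate approximately 2880 deg/s
  d <- diff(ps$phase[which(core)[1:200]]) %% 360
  expect_lt(abs(median(d) * fs - 2880), 30)
})

test_that("ripple phase places spikes at crossings and midpoints correctly", {
  tt <- seq(0, 1, by = 1 / fs)
  x <- sin(2 * pi * 160 * tt)
  ep <- tibble::tibble(start = 0.1, end = 0.9)
  ps <- ripple_phase_series(x, ep, fs)
  # spike exactly at a crossing well inside the epoch: phase 0
  crossings <- which(diff(sign(x)) < 0)
  crossings <- crossings[crossings > 0.2 * fs & crossings < 0.8 * fs]
  i0 <- crossings[10]
  ct <- tt[i0] + (x[i0] / (x[i0] - x[i0 + 1])) / fs
  ph0 <- phases_of_spikes(ct, ps)
  expect_lt(min(ph0 %% 360, 360 - ph0 %% 360), 1.5)
  # 3.125 ms after a crossing at 160 Hz: half a cycle = 180 deg
  ph180 <- phases_of_spikes(ct + 0.003125, ps)
  expect_lt(abs(ph180 - 180), 1.5)
})

test_that("phases of Poisson spikes inside a tone burst pass Rayleigh", {
  # uniform firing against the carrier: Rayleigh should NOT reject
  set.seed(11)
  tt <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 160 * tt)
  ps <- ripple_phase_series(x, tibble::tibble(start = 0, end = 60), fs)
  rejections <- vapply(1:50, function(i) {
    st <- sort(runif(200, 1, 59))
    circ_stats(phases_of_spikes(st, ps))$rayleigh_p < 0.01
  }, logical(1))
  expect_lte(mean(rejections), 0.02)
})
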