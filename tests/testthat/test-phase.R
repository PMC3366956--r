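fs <- 1000

# shared fixture: clean 8 Hz phase series over 60 s
theta_fixture <- function(dur = 60) {
  tt <- seq(0, dur, by = 1 / fs)
  x <- sin(2 * pi * 8 * tt)
  theta_phase_series(x, tibble::tibble(start = 0, end = dur), fs)
}

test_that("spike phases interpolate linearly between phase samples", {
  ps <- theta_fixture(10)
  v <- which(ps$valid)
  # a spike exactly on a sample carries that sample's phase
  i <- v[5000]
  expect_equal(phases_of_spikes(ps$time[i], ps)[1], ps$phase[i],
               tolerance = 1e-9)
  # halfway between neighbouring samples: midpoint phase (same cycle)
  j <- v[which(diff(ps$phase[v]) > 0)[6000]]
  tmid <- (ps$time[j] + ps$time[j + 1]) / 2
  expect_equal(phases_of_spikes(tmid, ps)[1],
               (ps$phase[j] + ps$phase[j + 1]) / 2, tolerance = 1e-6)
  # spikes outside valid segments are dropped and counted
  ph <- phases_of_spikes(c(5, 1e4), ps)
  expect_equal(length(ph), 1)
  expect_equal(attr(ph, "n_dropped"), 1L)
})

test_that("firing probability by phase is per complete cycle", {
  ps <- theta_fixture(10)           # ~80 cycles
  n_cyc <- hippocode:::count_complete_cycles(ps)
  expect_gt(n_cyc, 70)

  # one spike at 100 deg on every cycle
  cross <- ps$time[which(diff(ps$phase) < -180) + 1]
  st <- cross[-length(cross)] + (100 / 360) / 8
  fp <- firing_probability_by_phase(phases_of_spikes(st, ps), ps)
  hot <- fp$phase_lo <= 100 & fp$phase_hi > 100
  expect_lt(abs(fp$probability[hot] - length(st) / n_cyc), 0.06)
  expect_true(all(fp$probability[!hot] == 0))

  # concentrated phases: all mass in one bin
  fp2 <- firing_probability_by_phase(rep(75, 50), ps)
  expect_equal(sum(fp2$count), 50)
  expect_equal(fp2$count[fp2$phase_lo == 60], 50)
})

test_that("uniform spiking is flat across phase bins within 3 SE", {
  set.seed(31)
  ps <- theta_fixture(60)
  st <- sort(runif(3000, 1, 59))
  ph <- phases_of_spikes(st, ps)
  fp <- firing_probability_by_phase(ph, ps)
  expected <- length(ph) / 12
  se <- sqrt(expected)
  expect_true(all(abs(fp$count - expected) < 3.5 * se))
})

test_that("burst theta frequency reads the autocorrelation peak", {
  ep <- tibble::tibble(start = 0, end = 100)
  st8 <- seq(0, 100, by = 0.125)
  b8 <- burst_theta_frequency(st8, ep)
  expect_equal(b8$peak_lag_ms, 125, tolerance = 2)
  expect_equal(b8$frequency_hz, 8, tolerance = 0.15)

  st10 <- seq(0, 100, by = 0.100)
  expect_equal(burst_theta_frequency(st10, ep)$frequency_hz, 10,
               tolerance = 0.2)

  # jittered 8 Hz bursting train: peak within 3 bins of 125 ms
  set.seed(32)
  bursts <- seq(0, 100, by = 0.125) + rnorm(801, 0, 0.004)
  st <- sort(unlist(lapply(bursts, function(b) b + c(0, 0.006))))
  bj <- burst_theta_frequency(st, ep)
  expect_lt(abs(bj$peak_lag_ms - 125), 6.1)
  expect_false(bj$low_confidence)
})

test_that("spikes-per-SWR distribution sums to one and matches Poisson", {
  ep <- tibble::tibble(start = seq(0, 99, by = 1),
                       end = seq(0, 99, by = 1) + 0.08)
  d0 <- swr_spike_distribution(numeric(0), ep)
  expect_equal(d0$probabilities$probability[1], 1)
  expect_equal(sum(d0$probabilities$probability), 1)

  # exactly 2 spikes per epoch
  st2 <- sort(c(ep$start + 0.01, ep$start + 0.02))
  d2 <- swr_spike_distribution(st2, ep)
  expect_equal(d2$probabilities$probability[d2$probabilities$k == "2"], 1)
  expect_equal(d2$mean_rate, 2 / 0.08, tolerance = 1e-9)

  # Poisson firing at 25 Hz in 80 ms epochs: lambda*d = 2
  set.seed(33)
  epp <- tibble::tibble(start = seq(0, 4999, by = 1),
                        end = seq(0, 4999, by = 1) + 0.08)
  stp <- sort(runif(round(25 * 5000), 0, 5000))
  dp <- swr_spike_distribution(stp, epp)
  lam <- 25 * 0.08
  for (k in 0:5) {
    pk <- dp$probabilities$probability[dp$probabilities$k == as.character(k)]
    se <- sqrt(stats::dpois(k, lam) * (1 - stats::dpois(k, lam)) / 5000)
    expect_lt(abs(pk - stats::dpois(k, lam)), 4 * se + 1e-4)
  }
  expect_equal(sum(dp$probabilities$probability), 1, tolerance = 1e-12)
})

test_that("peri-SWR rate histogram is flat for Poisson, peaked for locked", {
  peaks <- seq(10, 990, by = 10)
  h0 <- swr_rate_histogram(numeric(0), peaks)
  expect_true(all(h0$rate == 0))

  hp <- swr_rate_histogram(peaks + 0.001, peaks, half_width = 0.1,
                           bin = 0.01)
  expect_equal(which.max(hp$rate), which(hp$time > 0)[1])
  expect_equal(sum(hp$rate > 0), 1)

  set.seed(34)
  st <- sort(runif(20000, 0, 1000))
  hf <- swr_rate_histogram(st, peaks, half_width = 0.25, bin = 0.05)
  expect_true(all(abs(hf$rate - 20) / (sqrt(20 / (0.05 * 99))) < 4))
})

test_that("precession fit recovers noiseless slopes of both signs", {
  set.seed(35)
  x <- runif(200)
  f_neg <- precession_fit((360 * (1 - x)) %% 360, x)
  expect_equal(f_neg$slope, -1, tolerance = 0.01)
  expect_equal(f_neg$r, -1, tolerance = 0.01)
  expect_lte(f_neg$p, 0.001)

  f_pos <- precession_fit((360 * x) %% 360, x)
  expect_equal(f_pos$slope, 1, tolerance = 0.01)
  expect_equal(f_pos$r, 1, tolerance = 0.01)

  # degenerate: constant phases
  f_deg <- precession_fit(rep(123, 20), runif(20))
  expect_true(f_deg$degenerate)
  expect_equal(f_deg$r, 0)
  expect_equal(f_deg$p, 1)

  expect_error(precession_fit(runif(5, 0, 360), runif(5)), "at least 10")
})

test_that("permutation p is roughly uniform when phase ignores position", {
  set.seed(36)
  ps_vals <- vapply(1:60, function(i)
    precession_fit(runif(80, 0, 360), runif(80), n_perm = 200)$p,
    numeric(1))
  expect_gt(mean(ps_vals > 0.05), 0.85)
  expect_lt(abs(mean(ps_vals) - 0.5), 0.12)
})

test_that("tidy/glance/autoplot methods work on fits and maps", {
  set.seed(37)
  x <- runif(80)
  f <- precession_fit((360 * (1 - x) + rnorm(80, 0, 30)) %% 360, x,
                      n_perm = 100)
  td <- generics::tidy(f)
  expect_named(td, c("slope", "slope_deg", "offset", "r", "p"))
  gl <- generics::glance(f)
  expect_named(gl, c("n", "resultant", "degenerate"))
  p <- ggplot2::autoplot(f, phases = (360 * (1 - x)) %% 360, positions = x)
  expect_s3_class(p, "ggplot")

  m <- make_map(matrix(rexp(100), 10, 10))
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
  expect_s3_class(plot_phase_histogram(runif(100, 0, 360)), "ggplot")
})

test_that("segment phase rates expose the preferred-phase shift of precession", {
  set.seed(38)
  ps <- theta_fixture(120)
  # traversal position: sweep the field repeatedly at constant speed
  tt <- ps$time
  pos <- 100 * ((tt / 4) %% 1)            # 0..100 every 4 s
  pos_at <- stats::approxfun(tt, pos, rule = 2)
  # phase-coded spikes: preferred phase 300 deg at entry -> 60 deg at exit
  cyc <- tt[which(diff(ps$phase) < -180) + 1]
  spikes <- c()
  for (ct in cyc) {
    p0 <- pos_at(ct)
    mu <- (300 - 240 * (p0 / 100)) %% 360
    if (runif(1) < 0.8)
      spikes <- c(spikes, ct + (mu / 360) / 8 + rnorm(1, 0, 0.004))
  }
  spikes <- sort(spikes[spikes > 0 & spikes < 120])
  seg <- field_segment_phase_rates(spikes, pos_at(spikes), 0, 100, ps,
                                   pos_at)
  pref <- vapply(1:4, function(s) {
    d <- seg[seg$segment == s, ]
    hippocode:::circ_mean_deg(rep(d$phase_mid, round(d$count)))
  }, numeric(1))
  # preferred phase decreases monotonically across segments (mod 360)
  dd <- diff(pref) %% 360
  expect_true(all(dd > 180))

  # spikes confined to segment 2 leave the others empty
  s2 <- spikes[pos_at(spikes) >= 25 & pos_at(spikes) < 50]
  seg2 <- field_segment_phase_rates(s2, pos_at(s2), 0, 100, ps, pos_at)
  expect_true(all(seg2$count[seg2$segment != 2] == 0))
})

test_that("spatiotemporal maps separate precessing from locked cells", {
  set.seed(39)
  ps <- theta_fixture(120)
  tt <- ps$time
  pos <- 100 * ((tt / 4) %% 1)
  pos_at <- stats::approxfun(tt, pos, rule = 2)
  cyc <- tt[which(diff(ps$phase) < -180) + 1]
  mk_spikes <- function(mu_of_x) {
    s <- c()
    for (ct in cyc) {
      x0 <- pos_at(ct) / 100
      s <- c(s, ct + (mu_of_x(x0) / 360) / 8)
    }
    sort(s[s > 0 & s < 120])
  }
  prec <- mk_spikes(function(x) (360 * (1 - x)) %% 360)
  lock <- mk_spikes(function(x) 90)

  mp <- spatiotemporal_map(prec, pos_at(prec), 0, 100, ps, pos_at)
  ml <- spatiotemporal_map(lock, pos_at(lock), 0, 100, ps, pos_at)
  # locked cell: max-rate phase equal in every position bin
  peak_phase_l <- ml$phase_mid[apply(ml$rate, 1, which.max)]
  expect_true(all(abs(peak_phase_l - 90) <= 30))
  # precessing cell: peak phase decreases with position
  peak_phase_p <- mp$phase_mid[apply(mp$rate, 1, which.max)]
  expect_lt(stats::cor(mp$pos_mid[3:18], peak_phase_p[3:18]), -0.8)

  m0 <- spatiotemporal_map(numeric(0), numeric(0), 0, 100, ps, pos_at)
  expect_true(all(m0$rate == 0))
})
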