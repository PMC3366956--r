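#' Generate a synthetic trajectory
#'
#' Open field: smoothed random walk (Ornstein-Uhlenbeck velocity, mean speed
#' about 12 cm/s) with reflecting walls in the 70 x 70 cm arena, sampled at
#' 25 Hz. Zigzag: end-to-end runs along the maze skeleton with pauses at the
#' ends. Rest: near-stationary jitter.
#'
#' @param environment One of `"open_field"`, `"zigzag"`, `"rest"`.
#' @param duration Seconds.
#' @param seed Integer RNG seed.
#' @param t0 Start time (s).
#' @param sample_rate Tracker rate, Hz (default 25).
#' @param geometry Zigzag geometry (default [zigzag_geometry()]).
#' @return A [position_track()].
#' @export
gen_trajectory <- function(environment = c("open_field", "zigzag", "rest"),
                           duration, seed = 1, t0 = 0, sample_rate = 25,
                           geometry = zigzag_geometry()) {
  environment <- match.arg(environment)
  if (duration <= 0) abort("duration must be positive")
  set.seed(seed)
  dt <- 1 / sample_rate
  n <- round(duration * sample_rate)
  times <- t0 + (seq_len(n) - 1) * dt

  if (environment == "rest") {
    # immobile animal: sub-cm tracker jitter around a resting spot
    x <- 12 + cumsum(rnorm(n, 0, 0.01))
    y <- 12 + cumsum(rnorm(n, 0, 0.01))
    return(position_track(times, x, y))
  }

  if (environment == "open_field") {
    lim <- c(0, 70)
    tau <- 0.7                         # velocity correlation time (s)
    sigma_v <- 12 / sqrt(pi / 2)       # mean |v| of a Rayleigh ~ 12 cm/s
    a <- exp(-dt / tau)
    sn <- sigma_v * sqrt(1 - a^2)
    vx <- numeric(n); vy <- numeric(n)
    x <- numeric(n); y <- numeric(n)
    x[1] <- 35; y[1] <- 35
    vx[1] <- rnorm(1, 0, sigma_v); vy[1] <- rnorm(1, 0, sigma_v)
    ex <- rnorm(n, 0, sn); ey <- rnorm(n, 0, sn)
    for (i in 2:n) {
      vx[i] <- a * vx[i - 1] + ex[i]
      vy[i] <- a * vy[i - 1] + ey[i]
      x[i] <- x[i - 1] + vx[i] * dt
      y[i] <- y[i - 1] + vy[i] * dt
      if (x[i] < lim[1]) { x[i] <- 2 * lim[1] - x[i]; vx[i] <- -vx[i] }
      if (x[i] > lim[2]) { x[i] <- 2 * lim[2] - x[i]; vx[i] <- -vx[i] }
      if (y[i] < lim[1]) { y[i] <- 2 * lim[1] - y[i]; vy[i] <- -vy[i] }
      if (y[i] > lim[2]) { y[i] <- 2 * lim[2] - y[i]; vy[i] <- -vy[i] }
    }
    return(position_track(times, x, y))
  }

  # zigzag: run end-to-end at ~15 cm/s with 2-4 s pauses at the ends
  L <- geometry$total_length
  pos <- numeric(n)
  i <- 1; at <- 0; dir <- 1
  while (i <= n) {
    pause <- round(runif(1, 2, 4) * sample_rate)
    for (j in seq_len(min(pause, n - i + 1))) {
      pos[i] <- at + rnorm(1, 0, 0.3); i <- i + 1
      if (i > n) break
    }
    if (i > n) break
    v <- runif(1, 12, 18)
    while (i <= n) {
      at <- at + dir * v * dt * exp(rnorm(1, 0, 0.1))
      if (at >= L) { at <- L; pos[i] <- at; i <- i + 1; dir <- -1; break }
      if (at <= 0) { at <- 0; pos[i] <- at; i <- i + 1; dir <- 1; break }
      pos[i] <- at; i <- i + 1
    }
  }
  pos <- pmin(pmax(pos, 0), L)
  sk <- approx(geometry$arc, seq_along(geometry$arc), xout = pos)$y
  xi <- floor(sk); frac <- sk - xi
  xi <- pmin(pmax(xi, 1), length(geometry$sx) - 1)
  x <- geometry$sx[xi] * (1 - frac) + geometry$sx[xi + 1] * frac
  y <- geometry$sy[xi] * (1 - frac) + geometry$sy[xi + 1] * frac
  position_track(times, x, y)
}

#' Generate a synthetic LFP channel with ground truth
#'
#' 1/f ("pink") background noise plus a 6-10 Hz theta rhythm whose amplitude
#' is gated on running speed above 3 cm/s, plus ripple bursts (Gaussian
#' envelope, SD 10 ms; carrier drawn in 130-180 Hz) injected at Poisson
#' times during immobility at `ripple_rate` events/s. Ripple amplitude is
#' `ripple_snr` times the ripple-band SD of the background. An optional
#' reference channel holds its own background and shared artifacts but no
#' ripples.
#'
#' @param speed Tibble from [compute_speed()] (or with `time`/`speed`).
#' @param duration Seconds; defaults to the speed extent.
#' @param seed Integer.
#' @param sample_rate LFP rate, Hz (default 1000).
#' @param t0 Start time (s).
#' @param theta_amp Theta amplitude relative to background SD (default 1.5).
#' @param theta_freq Hz (default 8).
#' @param ripple_rate Events/s during immobility (default 0.3).
#' @param ripple_snr Burst amplitude as a multiple of the ripple-band
#'   background SD (default 8).
#' @param ripple_env_sd Burst envelope SD, s (default 0.010).
#' @param carrier_range Hz pair for the per-event carrier (default
#'   c(130, 180)).
#' @param amp_jitter Log-normal SD of per-event amplitude variability
#'   (default 0: every burst at exactly `ripple_snr` times the band SD).
#' @param with_reference Also return a reference channel (default TRUE).
#' @param n_artifacts Broadband artifacts shared with the reference
#'   channel (default 0).
#' @return List: `lfp` (an [lfp_signal()]), `reference` (or NULL), and
#'   `truth` tibble of injected ripples (`time`, `frequency`, `amplitude`,
#'   `duration`).
#' @export
gen_lfp <- function(speed, duration = NULL, seed = 1, sample_rate = 1000,
                    t0 = 0, theta_amp = 1.5, theta_freq = 8,
                    ripple_rate = 0.3, ripple_snr = 8,
                    ripple_env_sd = 0.010, carrier_range = c(130, 180),
                    amp_jitter = 0, with_reference = TRUE,
                    n_artifacts = 0) {
  set.seed(seed)
  if (is.null(duration))
    duration <- max(speed$time) - min(speed$time) + 1 / 25
  n <- round(duration * sample_rate)
  tt <- t0 + (seq_len(n) - 1) / sample_rate

  bg <- pink_noise(n)
  bg <- bg / sd(bg)
  rip_sd <- sd(bandpass(bg, c(125, 250), sample_rate))

  # speed-gated theta envelope (smoothed binary gate)
  sp <- approx(speed$time, speed$speed, xout = tt, rule = 2)$y
  gate <- as.numeric(!is.na(sp) & sp > 3)
  gate <- boxcar_smooth(gate, round(0.5 * sample_rate))
  inst_f <- theta_freq + 0.5 * sin(2 * pi * 0.05 * (tt - t0))
  phase <- 2 * pi * cumsum(inst_f) / sample_rate
  theta <- theta_amp * gate * sin(phase)

  # Poisson ripple times during immobility
  still <- !is.na(sp) & sp < 3
  x <- bg + theta
  truth <- list()
  margin <- 4 * ripple_env_sd
  cand <- tt[still & tt > t0 + margin & tt < t0 + duration - margin]
  if (length(cand) > 0 && ripple_rate > 0) {
    n_ev <- rpois(1, ripple_rate * length(cand) / sample_rate)
    ev_t <- sort(sample(cand, min(n_ev, length(cand))))
    # enforce a refractory gap so events stay resolvable
    if (length(ev_t) > 1) ev_t <- ev_t[c(TRUE, diff(ev_t) > 0.25)]
    for (et in ev_t) {
      f <- runif(1, carrier_range[1], carrier_range[2])
      amp <- ripple_snr * rip_sd *
        (if (amp_jitter > 0) exp(rnorm(1, 0, amp_jitter)) else 1)
      idx <- which(abs(tt - et) <= margin)
      env <- exp(-(tt[idx] - et)^2 / (2 * ripple_env_sd^2))
      x[idx] <- x[idx] + amp * env * cos(2 * pi * f * (tt[idx] - et))
      truth[[length(truth) + 1]] <-
        tibble(time = et, frequency = f, amplitude = amp,
               duration = 6 * ripple_env_sd)
    }
  }
  truth <- if (length(truth)) bind_rows(truth) else
    tibble(time = numeric(0), frequency = numeric(0),
           amplitude = numeric(0), duration = numeric(0))

  ref <- NULL
  if (with_reference) {
    rbg <- pink_noise(n)
    rbg <- rbg / sd(rbg)
    if (n_artifacts > 0) {
      at <- runif(n_artifacts, t0 + 0.1, t0 + duration - 0.1)
      for (a in at) {
        idx <- which(abs(tt - a) <= 0.015)
        burst <- 10 * exp(-(tt[idx] - a)^2 / (2 * 0.005^2)) *
          sin(2 * pi * 180 * (tt[idx] - a))
        x[idx] <- x[idx] + burst
        rbg[idx] <- rbg[idx] + burst
      }
    }
    ref <- lfp_signal("ref", rbg, sample_rate,
                      in_pyramidal_layer = FALSE, is_reference = TRUE)
  }
  list(lfp = lfp_signal("ca1", x, sample_rate), reference = ref,
       truth = truth)
}

pink_noise <- function(n) {
  # 1/f amplitude shaping in the frequency domain
  nf <- n %/% 2
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(ph[nf]), imaginary = 0)
    if (nf > 1) full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  Re(fft(full, inverse = TRUE)) / n
}

#' Generate a synthetic place cell spike train
#'
#' Inhomogeneous Poisson process by exact thinning. The rate is a Gaussian
#' spatial envelope (peak `peak_rate` at `center`, SD `sd`) multiplied by a
#' von Mises theta modulation (concentration `kappa`, normalized to unit
#' mean) whose preferred phase shifts linearly across the field according to
#' `precession_slope` (cycles per field, negative = precession), and by
#' `swr_gain` inside SWR epochs.
#'
#' @param track_pos Tibble `time` + either `x`,`y` (2D) or `pos` (1D).
#' @param phase_series Theta `phase_series` (NULL for no theta coupling).
#' @param center Field center: length-2 (2D) or scalar (1D).
#' @param sd Field SD, cm.
#' @param peak_rate Hz.
#' @param kappa Theta coupling concentration (0 = none).
#' @param preferred_phase Degrees at the field center (default 180).
#' @param precession_slope Cycles/field (default 0); the field spans
#'   `center +- field_half_span`.
#' @param field_half_span cm; the span over which precession runs
#'   (default 2 sd).
#' @param swr_gain Rate multiplier inside `swr_epochs` (default 1).
#' @param swr_epochs Optional start/end tibble.
#' @param baseline_rate Hz added everywhere (default 0).
#' @param seed Integer.
#' @return Sorted spike-time vector (seconds).
#' @export
gen_place_cell <- function(track_pos, phase_series = NULL, center, sd = 6,
                           peak_rate = 10, kappa = 0, preferred_phase = 180,
                           precession_slope = 0, field_half_span = NULL,
                           swr_gain = 1, swr_epochs = NULL,
                           baseline_rate = 0, seed = 1) {
  set.seed(seed)
  if (peak_rate <= 0 && baseline_rate <= 0) return(numeric(0))
  if (is.null(field_half_span)) field_half_span <- 2 * sd
  t0 <- min(track_pos$time); t1 <- max(track_pos$time)
  one_d <- "pos" %in% names(track_pos)
  # emit spikes only where the track has coverage: interpolating across
  # gaps between epochs would fabricate positions (and spikes) there
  gap <- which(diff(track_pos$time) > 1)
  coverage <- tibble(
    start = track_pos$time[c(1, gap + 1)],
    end = c(track_pos$time[gap], t1) + 1e-9)

  pos_fun <- if (one_d) {
    f <- approxfun_safe(track_pos$time, track_pos$pos)
    function(t) f(t)
  } else {
    fx <- approxfun_safe(track_pos$time, track_pos$x)
    fy <- approxfun_safe(track_pos$time, track_pos$y)
    function(t) cbind(fx(t), fy(t))
  }
  ph_fun <- if (!is.null(phase_series)) {
    function(t) spike_phase_or_na(t, phase_series)
  } else NULL

  rate_at <- function(t) {
    p <- pos_fun(t)
    d2 <- if (one_d) (p - center)^2 else
      (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2
    lam <- baseline_rate + peak_rate * exp(-d2 / (2 * sd^2))
    lam[is.na(lam)] <- baseline_rate
    if (!is.null(ph_fun) && kappa > 0) {
      th <- ph_fun(t)
      relx <- if (one_d) (p - center) / (2 * field_half_span) + 0.5 else {
        # 2D: project on x for the precession axis
        (p[, 1] - center[1]) / (2 * field_half_span) + 0.5
      }
      mu <- preferred_phase + 360 * precession_slope *
        (pmin(pmax(relx, 0), 1) - 0.5)
      mod <- exp(kappa * cos((th - mu) * pi / 180)) /
        besselI(kappa, 0)
      mod[is.na(th)] <- 1
      lam <- lam * mod
    }
    if (!is.null(swr_epochs) && swr_gain != 1 && nrow(swr_epochs) > 0) {
      lam <- lam * ifelse(in_epochs(t, swr_epochs), swr_gain, 1)
    }
    lam[!in_epochs(t, coverage)] <- 0
    lam
  }

  lam_max <- (baseline_rate + peak_rate) *
    (if (kappa > 0) exp(kappa) / besselI(kappa, 0) else 1) *
    max(1, swr_gain)
  # exact thinning
  cand <- t0 + cumsum(rexp(ceiling((t1 - t0) * lam_max * 1.1) + 100,
                           rate = lam_max))
  while (length(cand) > 0 && cand[length(cand)] < t1) {
    extra <- cand[length(cand)] +
      cumsum(rexp(ceiling((t1 - cand[length(cand)]) * lam_max) + 100,
                  rate = lam_max))
    cand <- c(cand, extra)
  }
  cand <- cand[cand <= t1]
  if (length(cand) == 0) return(numeric(0))
  keep <- runif(length(cand)) < rate_at(cand) / lam_max
  sort(cand[keep])
}

approxfun_safe <- function(x, y) {
  f <- stats::approxfun(x, y, rule = 2)
  function(t) f(t)
}

#' Generate a synthetic interneuron spike train
#'
#' Poisson baseline (15-40 Hz) modulated by a von Mises theta coupling and,
#' inside SWR epochs, by a ripple-phase von Mises coupling; exact thinning.
#'
#' @param duration Seconds (spikes on `[t0, t0 + duration]`).
#' @param t0 Start time (default 0).
#' @param baseline_rate Hz (default 25).
#' @param theta_phase A theta `phase_series` or NULL.
#' @param theta_kappa,theta_pref Theta coupling (default 0.5, 90 deg).
#' @param ripple_phase A ripple `phase_series` or NULL.
#' @param ripple_kappa,ripple_pref Ripple coupling (default 1, 150 deg).
#' @param swr_gain Rate multiplier inside SWR epochs (default 2).
#' @param swr_epochs Start/end tibble or NULL.
#' @param seed Integer.
#' @return Sorted spike times.
#' @export
gen_interneuron <- function(duration, t0 = 0, baseline_rate = 25,
                            theta_phase = NULL, theta_kappa = 0.5,
                            theta_pref = 90, ripple_phase = NULL,
                            ripple_kappa = 1, ripple_pref = 150,
                            swr_gain = 2, swr_epochs = NULL, seed = 1) {
  set.seed(seed)
  rate_at <- function(t) {
    lam <- rep(baseline_rate, length(t))
    if (!is.null(theta_phase) && theta_kappa > 0) {
      th <- spike_phase_or_na(t, theta_phase)
      mod <- exp(theta_kappa * cos((th - theta_pref) * pi / 180)) /
        besselI(theta_kappa, 0)
      mod[is.na(th)] <- 1
      lam <- lam * mod
    }
    if (!is.null(swr_epochs) && nrow(swr_epochs) > 0) {
      gain <- rep(1, length(t))
      inr <- in_epochs(t, swr_epochs)
      gain[inr] <- swr_gain
      if (!is.null(ripple_phase) && ripple_kappa > 0) {
        rp <- spike_phase_or_na(t, ripple_phase)
        rmod <- exp(ripple_kappa * cos((rp - ripple_pref) * pi / 180)) /
          besselI(ripple_kappa, 0)
        ok <- inr & !is.na(rp)
        gain[ok] <- gain[ok] * rmod[ok]
      }
      lam <- lam * gain
    }
    lam
  }
  lam_max <- baseline_rate *
    (if (theta_kappa > 0) exp(theta_kappa) / besselI(theta_kappa, 0) else 1) *
    max(1, swr_gain) *
    (if (ripple_kappa > 0) exp(ripple_kappa) / besselI(ripple_kappa, 0) else 1)
  cand <- t0 + cumsum(rexp(ceiling(duration * lam_max * 1.2) + 100,
                           rate = lam_max))
  cand <- cand[cand <= t0 + duration]
  if (length(cand) == 0) return(numeric(0))
  keep <- runif(length(cand)) < rate_at(cand) / lam_max
  sort(cand[keep])
}

#' Synthetic pyramidal/interneuron waveforms
#'
#' Pyramidal: wide biphasic spike (about 0.35 ms at 25% amplitude);
#' interneuron: narrow (about 0.15 ms). Shapes are generator parameters
#' mimicking the typical extracellular cluster separation, not measurements.
#'
#' @param class `"pyramidal"` or `"interneuron"`.
#' @param waveform_rate Hz (default 24000).
#' @param jitter Relative width jitter (default 0.05).
#' @return List `waveform`, `rate`.
#' @export
gen_waveform <- function(class = c("pyramidal", "interneuron"),
                         waveform_rate = 24000, jitter = 0.05) {
  class <- match.arg(class)
  w_ms <- if (class == "pyramidal") 0.35 else 0.15
  w_ms <- w_ms * exp(rnorm(1, 0, jitter))
  # |exp(-t^2/2s^2)| crosses 0.25 at +-s sqrt(2 ln 4): width 2 s sqrt(2 ln 4)
  s_ms <- w_ms / (2 * sqrt(2 * log(4)))
  tt <- seq(-1.5, 1.5, by = 1000 / waveform_rate)
  main <- -exp(-tt^2 / (2 * s_ms^2))
  after <- 0.3 * exp(-(tt - 3 * s_ms)^2 / (2 * (2 * s_ms)^2))
  list(waveform = main + after, rate = waveform_rate)
}

#' Generate a synthetic unit feature population
#'
#' Draws physiological feature vectors (log10 firing rate, autocorrelation
#' first moment, spike duration) for a pyramidal and an interneuron cluster:
#' pyramidal cells slow-firing with wide spikes and short-lag-heavy
#' autocorrelations, interneurons fast-firing with narrow spikes. The
#' template cluster is tight (it mimics a selected, homogeneous
#' subpopulation of spatially selective cells), which puts the interneuron
#' cluster around 100 Mahalanobis units away — far beyond the 40 threshold,
#' as in real CA1 populations.
#'
#' @param n_pyramidal,n_interneuron Counts (defaults 40 and 10).
#' @param seed Integer.
#' @param pyr_mean,pyr_sd,int_mean,int_sd Cluster means/SDs as
#'   `c(log10 rate, moment ms, duration ms)`.
#' @return Tibble: `unit_id`, `rate_feature`, `ac_first_moment`,
#'   `spike_duration`, `class`.
#' @export
gen_unit_population <- function(n_pyramidal = 40, n_interneuron = 10,
                                seed = 1,
                                pyr_mean = c(0.10, 7, 0.35),
                                pyr_sd = c(0.0225, 0.095, 0.00345),
                                int_mean = c(1.40, 12.5, 0.15),
                                int_sd = c(0.06, 0.3, 0.010)) {
  set.seed(seed)
  n <- n_pyramidal + n_interneuron
  draw <- function(k, mu, s)
    cbind(rnorm(k, mu[1], s[1]), rnorm(k, mu[2], s[2]), rnorm(k, mu[3], s[3]))
  pyr <- draw(n_pyramidal, pyr_mean, pyr_sd)
  int <- draw(n_interneuron, int_mean, int_sd)
  tibble(unit_id = sprintf("u%03d", seq_len(n)),
         rate_feature = c(pyr[, 1], int[, 1]),
         ac_first_moment = c(pyr[, 2], int[, 2]),
         spike_duration = c(pyr[, 3], int[, 3]),
         class = c(rep("pyramidal", n_pyramidal),
                   rep("interneuron", n_interneuron)))
}

#' Generate a complete synthetic recording session
#'
#' Builds the standard nine-trial protocol (rest trials alternating with
#' open-field and zigzag foraging in an ABAB order), a CA1 LFP channel with
#' injected theta and ripples plus a reference channel, and a unit
#' population: place cells with Gaussian fields, theta coupling and optional
#' precession, and interneurons with high tonic rates and theta/ripple
#' coupling. The returned ground truth records every injected parameter.
#'
#' @param seed Integer; the session is a pure function of its arguments.
#' @param trial_duration Seconds per trial (default 1200; scale down for
#'   quick runs).
#' @param n_place_cells,n_interneurons Population sizes (defaults 8 and 3).
#' @param ripple_rate,ripple_snr Passed to [gen_lfp()].
#' @param precession_slope Cycles/field for the place cells (default -1).
#' @param place_kappa Theta coupling of place cells (default 1).
#' @param lfp_rate LFP sample rate (default 1000).
#' @return List: `session` (a [recording_session()]) and `truth` (list with
#'   `ripples`, `units`, `seed`).
#' @export
gen_session <- function(seed = 1, trial_duration = 1200,
                        n_place_cells = 8, n_interneurons = 3,
                        ripple_rate = 0.3, ripple_snr = 8,
                        precession_slope = -1, place_kappa = 1,
                        lfp_rate = 1000) {
  set.seed(seed)
  labels <- c("rest", "open_field", "rest", "zigzag", "rest",
              "open_field", "rest", "zigzag", "rest")
  starts <- (seq_along(labels) - 1) * trial_duration
  trials <- trial_epochs(labels, starts, starts + trial_duration)
  geom <- zigzag_geometry()

  tracks <- lapply(seq_along(labels), function(i)
    gen_trajectory(labels[i], trial_duration, seed = seed * 1000 + i,
                   t0 = starts[i], geometry = geom))
  track <- position_track(
    unlist(lapply(tracks, function(t) t$time)),
    unlist(lapply(tracks, function(t) t$x)),
    unlist(lapply(tracks, function(t) t$y)))
  speed <- compute_speed(track)

  lfp_out <- gen_lfp(speed, duration = max(trials$end), seed = seed + 7,
                     sample_rate = lfp_rate, ripple_rate = ripple_rate,
                     ripple_snr = ripple_snr)
  cfg <- osc_config()
  filt <- bandpass(lfp_out$lfp, cfg$ripple_band, order = cfg$filter_order)
  swr_ep <- tibble(start = lfp_out$truth$time - 0.03,
                   end = lfp_out$truth$time + 0.03)
  theta_ep <- detect_theta_epochs(lfp_out$lfp, cfg = cfg)
  theta_ph <- theta_phase_series(lfp_out$lfp, theta_ep, cfg = cfg)
  ripple_ph <- ripple_phase_series(filt, swr_ep, lfp_rate)

  linear <- linearize_zigzag(track, geom)
  ep_of <- function(lab) tibble(start = trials$start[trials$label == lab],
                                end = trials$end[trials$label == lab])
  zz <- ep_of("zigzag")
  of <- ep_of("open_field")

  units <- list()
  unit_truth <- list()
  for (k in seq_len(n_place_cells)) {
    s2 <- seed * 100 + k
    set.seed(s2)
    ctr2 <- runif(2, 15, 55)
    ctr1 <- runif(1, 40, geom$total_length - 40)
    pref <- runif(1, 0, 360)
    # open-field component
    tr_of <- restrict(tibble(time = track$time, x = track$x, y = track$y),
                      of)
    st_of <- gen_place_cell(tr_of, theta_ph, center = ctr2, sd = 6,
                            peak_rate = 10, kappa = place_kappa,
                            preferred_phase = pref, seed = s2 + 1)
    # zigzag component on the linearized coordinate (northbound field)
    tr_zz <- tibble(time = linear$time, pos = linear$pos)
    tr_zz <- restrict(tr_zz, zz)
    tr_zz <- tr_zz[!is.na(tr_zz$pos), , drop = FALSE]
    st_zz <- gen_place_cell(tr_zz, theta_ph, center = ctr1, sd = 8,
                            peak_rate = 10, kappa = place_kappa,
                            preferred_phase = pref,
                            precession_slope = precession_slope,
                            seed = s2 + 2)
    # sparse SWR participation during rest
    rest_ep <- ep_of("rest")
    st_swr <- gen_place_cell(
      tibble(time = track$time, x = track$x, y = track$y),
      NULL, center = c(-100, -100), sd = 6, peak_rate = 0.0,
      baseline_rate = 0.2, swr_gain = 20, swr_epochs = swr_ep,
      seed = s2 + 3)
    st_swr <- restrict(st_swr, rest_ep)
    st <- sort(unique(c(st_of, st_zz, st_swr)))
    wf <- gen_waveform("pyramidal")
    units[[length(units) + 1]] <-
      spike_unit(sprintf("pc%02d", k), sprintf("tt%d", (k %% 4) + 1),
                 st, wf$waveform, wf$rate)
    unit_truth[[length(unit_truth) + 1]] <- tibble(
      unit_id = sprintf("pc%02d", k), class = "pyramidal",
      center_x = ctr2[1], center_y = ctr2[2], center_lin = ctr1,
      peak_rate = 10, field_sd = 6, kappa = place_kappa,
      preferred_phase = pref, precession_slope = precession_slope)
  }
  for (k in seq_len(n_interneurons)) {
    s2 <- seed * 100 + 50 + k
    set.seed(s2)
    base <- runif(1, 15, 40)
    st <- gen_interneuron(max(trials$end), baseline_rate = base,
                          theta_phase = theta_ph, theta_kappa = 0.5,
                          ripple_phase = ripple_ph, swr_epochs = swr_ep,
                          seed = s2 + 1)
    wf <- gen_waveform("interneuron")
    units[[length(units) + 1]] <-
      spike_unit(sprintf("in%02d", k), sprintf("tt%d", (k %% 4) + 1),
                 st, wf$waveform, wf$rate)
    unit_truth[[length(unit_truth) + 1]] <- tibble(
      unit_id = sprintf("in%02d", k), class = "interneuron",
      center_x = NA_real_, center_y = NA_real_, center_lin = NA_real_,
      peak_rate = base, field_sd = NA_real_, kappa = 0.5,
      preferred_phase = 90, precession_slope = 0)
  }

  session <- recording_session(
    sprintf("synth-%d", seed),
    lfp = c(list(lfp_out$lfp),
            if (!is.null(lfp_out$reference)) list(lfp_out$reference)),
    units = units, track = track, trials = trials)
  list(session = session,
       truth = list(ripples = lfp_out$truth,
                    units = bind_rows(unit_truth), seed = seed))
}
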