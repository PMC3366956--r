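#' Circular-linear correlation fit of theta phase precession
#'
#' Fits `theta ~ 360 * a * x + theta0` (x the relative position within the
#' field, in \[0,1]; a in cycles per field) by maximizing the mean resultant
#' length of `theta - 360 a x` over a bounded slope range (grid search then
#' local refinement). The signed correlation r is the circular-circular
#' correlation magnitude between the observed and fitted phases, signed like
#' the slope; its p-value comes from permuting positions against phases,
#' using the maximal resultant over the slope grid as the test statistic.
#'
#' @param spike_phases Degrees.
#' @param positions Relative in-field positions in \[0,1], same length.
#' @param slope_range Cycles/field search bound (default c(-2, 2)).
#' @param n_perm Permutations for the p-value (default 1000).
#' @param min_spikes Minimum spikes (default 10).
#' @return Object of class `precession_fit`: list with `slope`
#'   (cycles/field), `slope_deg` (deg/field), `offset` (deg), `r`, `p`, `n`,
#'   `resultant`, `degenerate`.
#' @export
precession_fit <- function(spike_phases, positions, slope_range = c(-2, 2),
                           n_perm = 1000, min_spikes = 10) {
  n <- length(spike_phases)
  if (n != length(positions)) abort("phases and positions differ in length")
  if (n < min_spikes) abort(sprintf("need at least %d spikes", min_spikes))
  th <- (spike_phases %% 360) * pi / 180
  x <- positions

  if (sd(th) < 1e-12 || sd(x) < 1e-12) {
    return(structure(list(slope = 0, slope_deg = 0,
                          offset = circ_mean_deg(spike_phases), r = 0, p = 1,
                          n = n, resultant = 1, degenerate = TRUE),
                     class = "precession_fit"))
  }

  # resultant of theta - 2 pi a x over the slope grid, vectorized as a
  # complex matrix product; the same grid supplies the permutation null
  a_grid <- seq(slope_range[1], slope_range[2], by = 0.01)
  basis <- exp(-1i * 2 * pi * outer(x, a_grid))     # n x n_a
  e_obs <- exp(1i * th)
  R_of <- Mod(crossprod(basis, e_obs)) / n
  a0 <- a_grid[which.max(R_of)]

  resfun <- function(a) Mod(sum(exp(1i * (th - 2 * pi * a * x)))) / n
  lo <- max(slope_range[1], a0 - 0.01)
  hi <- min(slope_range[2], a0 + 0.01)
  opt <- optimize(resfun, c(lo, hi), maximum = TRUE, tol = 1e-5)
  a_hat <- opt$maximum
  Rmax <- opt$objective
  offset <- (atan2(sum(sin(th - 2 * pi * a_hat * x)),
                   sum(cos(th - 2 * pi * a_hat * x))) * 180 / pi) %% 360

  fitted <- (2 * pi * a_hat * x) %% (2 * pi)
  r <- sign(a_hat) * abs(circ_circ_cor(th, fitted))
  if (abs(a_hat) < 1e-9) r <- 0

  stat_obs <- max(R_of)
  perm_mat <- vapply(seq_len(n_perm), function(k) sample.int(n), integer(n))
  E <- matrix(e_obs[perm_mat], nrow = n)
  R_perm <- Mod(crossprod(basis, E)) / n            # n_a x n_perm
  stat_perm <- apply(R_perm, 2, max)
  p <- (1 + sum(stat_perm >= stat_obs)) / (n_perm + 1)

  structure(list(slope = a_hat, slope_deg = 360 * a_hat, offset = offset,
                 r = r, p = p, n = n, resultant = Rmax, degenerate = FALSE),
            class = "precession_fit")
}

circ_circ_cor <- function(a, b) {
  # pairwise Fisher-Lee circular-circular correlation (radians in). The
  # pairwise form needs no circular mean, so it stays stable when the
  # phases span the full cycle (where sample circular means are arbitrary).
  sa <- sin(outer(a, a, "-")); sb <- sin(outer(b, b, "-"))
  num <- sum(sa * sb)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(0)
  num / den
}

#' @export
print.precession_fit <- function(x, ...) {
  cat(sprintf(
    "<precession_fit> slope %.3f cycles/field (%.0f deg), r = %.3f, p = %.4g, n = %d%s\n",
    x$slope, x$slope_deg, x$r, x$p, x$n,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Oscillation phase at given times, NA outside valid segments
#'
#' Like [phases_of_spikes()] but length-stable: returns one phase per input
#' time, `NA` where the time falls outside a valid phase segment, so the
#' result stays aligned with per-spike covariates (position, trial, ...).
#'
#' @param spike_times Seconds.
#' @param phase_series A `phase_series`.
#' @return Numeric vector, same length as `spike_times`.
#' @export
spike_phase_or_na <- function(spike_times, phase_series) {
  ps <- phase_series
  phase <- rep(NA_real_, length(spike_times))
  v <- ps$valid & !is.na(ps$phase)
  if (!any(v) || length(spike_times) == 0) return(phase)
  r <- rle(v)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i1 - i0 < 1) next
    sel <- which(spike_times >= ps$time[i0] & spike_times <= ps$time[i1])
    if (length(sel) == 0) next
    seg_ph <- ps$phase[i0:i1]
    wraps <- cumsum(c(0, diff(seg_ph) < -180))
    unwrapped <- seg_ph + 360 * wraps
    phase[sel] <- approx(ps$time[i0:i1], unwrapped,
                         xout = spike_times[sel])$y %% 360
  }
  phase
}

#' Firing rate by theta phase in field segments
#'
#' Divides a place field into `n_segments` equal-length segments, assigns
#' each spike to the segment occupied when it fired, and returns a firing
#' rate per (segment, phase bin): the per-cycle spike probability of
#' [firing_probability_by_phase()] divided by the time one phase bin
#' occupies in a mean cycle, giving Hz.
#'
#' @param spike_times Seconds.
#' @param spike_pos Animal position at each spike (units of the field
#'   boundaries).
#' @param field_start,field_end Field boundaries.
#' @param phase_series A `phase_series`.
#' @param pos_at_time Function mapping times to positions (segment
#'   occupancy), e.g. an [stats::approxfun()] over the linearized track.
#' @param n_segments Number of segments (default 4).
#' @param bins Phase bins (default 12).
#' @return Tibble: `segment`, `phase_mid`, `count`, `rate` (Hz).
#' @export
field_segment_phase_rates <- function(spike_times, spike_pos, field_start,
                                      field_end, phase_series, pos_at_time,
                                      n_segments = 4, bins = 12) {
  seg_edges <- seq(field_start, field_end, length.out = n_segments + 1)
  ph_edges <- seq(0, 360, length.out = bins + 1)
  v <- phase_series$valid & !is.na(phase_series$phase)
  dt <- median(diff(phase_series$time))
  n_cycles <- count_complete_cycles(phase_series)
  if (n_cycles == 0) abort("no complete valid cycles")
  mean_cycle <- sum(v) * dt / n_cycles
  bin_time <- mean_cycle / bins
  vt <- phase_series$time[v]
  vpos <- pos_at_time(vt)

  ph <- spike_phase_or_na(spike_times, phase_series)
  rows <- vector("list", n_segments)
  for (s in seq_len(n_segments)) {
    hi_edge <- if (s == n_segments) field_end + 1e-9 else seg_edges[s + 1]
    occ_time <- sum(!is.na(vpos) & vpos >= seg_edges[s] & vpos < hi_edge) * dt
    n_cycles_seg <- occ_time / mean_cycle
    sel <- !is.na(ph) & !is.na(spike_pos) &
      spike_pos >= seg_edges[s] & spike_pos < hi_edge
    idx <- findInterval(ph[sel] %% 360, ph_edges, rightmost.closed = TRUE)
    cnt <- as.numeric(table(factor(idx, levels = seq_len(bins))))
    rate <- if (n_cycles_seg > 0) cnt / (n_cycles_seg * bin_time)
      else rep(NA_real_, bins)
    rows[[s]] <- tibble(segment = s,
                        phase_mid = (ph_edges[-(bins + 1)] + ph_edges[-1]) / 2,
                        count = cnt, rate = rate)
  }
  bind_rows(rows)
}

#' Spatio-temporal (position x phase) firing map of a field
#'
#' 2D histogram of spikes over relative field position (0-1) and theta
#' phase, normalized by the occupancy time per position bin and smoothed
#' with a small Gaussian (SD one bin). A precessing cell concentrates its
#' mass along a descending diagonal; a phase-locked, non-precessing cell
#' shows a horizontal band at its preferred phase.
#'
#' @param spike_times,spike_pos Spikes and their positions.
#' @param field_start,field_end Field boundaries.
#' @param phase_series A `phase_series`.
#' @param pos_at_time Function mapping times to positions.
#' @param pos_bins,phase_bins Grid size (defaults 20 and 12).
#' @return List of class `spatiotemporal_map`: `pos_mid` (relative),
#'   `phase_mid` (deg), `rate` (pos x phase matrix).
#' @export
spatiotemporal_map <- function(spike_times, spike_pos, field_start,
                               field_end, phase_series, pos_at_time,
                               pos_bins = 20, phase_bins = 12) {
  span <- field_end - field_start
  ph <- spike_phase_or_na(spike_times, phase_series)
  rel <- (spike_pos - field_start) / span
  sel <- !is.na(ph) & !is.na(rel) & rel >= 0 & rel <= 1
  pe <- seq(0, 1, length.out = pos_bins + 1)
  fe <- seq(0, 360, length.out = phase_bins + 1)
  cnt <- matrix(0, pos_bins, phase_bins)
  if (any(sel)) {
    ip <- findInterval(pmin(rel[sel], 1 - 1e-12), pe,
                       rightmost.closed = TRUE)
    jf <- findInterval(ph[sel] %% 360, fe, rightmost.closed = TRUE)
    for (j in seq_along(ip)) cnt[ip[j], jf[j]] <- cnt[ip[j], jf[j]] + 1
  }
  v <- phase_series$valid & !is.na(phase_series$phase)
  dt <- median(diff(phase_series$time))
  vt <- phase_series$time[v]
  vp <- (pos_at_time(vt) - field_start) / span
  inf <- !is.na(vp) & vp >= 0 & vp <= 1
  occ <- as.numeric(table(factor(
    findInterval(pmin(vp[inf], 1 - 1e-12), pe, rightmost.closed = TRUE),
    levels = seq_len(pos_bins)))) * dt
  rate <- sweep(cnt, 1, pmax(occ, 1e-12), "/")
  rate[occ < dt, ] <- 0
  k <- gauss_kernel_1d(1)
  sm <- apply(rate, 2, conv1_fast, k = k)
  sm <- t(apply(t(sm), 2, conv1_fast, k = k))
  structure(list(pos_mid = (pe[-1] + pe[-length(pe)]) / 2,
                 phase_mid = (fe[-1] + fe[-length(fe)]) / 2,
                 rate = sm),
            class = "spatiotemporal_map")
}
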