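#' Arena description
#'
#' @param xlim,ylim Extent in cm (2D); for a 1D (linearized) arena give
#'   `xlim` only and `ylim = NULL`.
#' @param bin_size Bin side in cm (default 2).
#' @return List of class `arena`.
#' @export
arena <- function(xlim, ylim = NULL, bin_size = 2) {
  structure(list(xlim = xlim, ylim = ylim, bin_size = bin_size,
                 dims = if (is.null(ylim)) 1L else 2L),
            class = "arena")
}

#' Standard 70 x 70 cm open field
#' @param bin_size Bin side in cm (default 2).
#' @return An [arena()].
#' @export
open_field_arena <- function(bin_size = 2) {
  arena(c(0, 70), c(0, 70), bin_size)
}

arena_edges <- function(a) {
  ex <- seq(a$xlim[1], a$xlim[2], by = a$bin_size)
  if (abs(ex[length(ex)] - a$xlim[2]) > 1e-9) ex <- c(ex, a$xlim[2])
  if (a$dims == 1L) return(list(x = ex))
  ey <- seq(a$ylim[1], a$ylim[2], by = a$bin_size)
  if (abs(ey[length(ey)] - a$ylim[2]) > 1e-9) ey <- c(ey, a$ylim[2])
  list(x = ex, y = ey)
}

gauss_kernel_1d <- function(sd_bins, trunc = 3) {
  half <- max(1L, ceiling(trunc * sd_bins))
  k <- exp(-((-half:half)^2) / (2 * sd_bins^2))
  k / sum(k)
}

conv1 <- function(v, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- length(v)
  vp <- c(rep(0, half), v, rep(0, half))
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sum(vp[i:(i + 2 * half)] * rev(k))
  out
}

conv1_fast <- function(v, k) {
  # symmetric kernel: plain correlation via filter
  half <- (length(k) - 1L) %/% 2L
  vp <- c(rep(0, half), v, rep(0, half))
  as.numeric(stats::filter(vp, k, method = "convolution", sides = 2))[
    (half + 1):(half + length(v))]
}

smooth_mass <- function(m, mask, sd_bins, trunc = 3) {
  # mass-conserving Gaussian smoothing: each source bin's kernel is
  # renormalized over the in-arena support, so no mass leaks at edges
  k <- gauss_kernel_1d(sd_bins, trunc)
  if (is.matrix(m)) {
    sm2 <- function(z) {
      z1 <- apply(z, 2, conv1_fast, k = k)
      t(apply(t(z1), 2, conv1_fast, k = k))
    }
    w <- sm2(mask * 1)
    src <- m
    src[mask] <- m[mask] / w[mask]
    src[!mask] <- 0
    out <- sm2(src)
    out[!mask] <- NA_real_
    out
  } else {
    w <- conv1_fast(mask * 1, k)
    src <- m
    src[mask] <- m[mask] / w[mask]
    src[!mask] <- 0
    out <- conv1_fast(src, k)
    out[!mask] <- NA_real_
    out
  }
}

bin_index <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(edges) - 1] <- NA_integer_
  i
}

#' Occupancy map
#'
#' Time spent per 2 x 2 cm bin from track samples with running speed above
#' `min_speed`, smoothed with a Gaussian kernel (SD 3 cm, truncated at 3 SD,
#' renormalized at arena edges so total time is conserved).
#'
#' @param track A [position_track()] (or a tibble with `time`, `x`, `y`,
#'   `valid`; for a 1D arena a `pos` column replaces `x`/`y`).
#' @param speed Tibble from [compute_speed()] aligned to the track samples.
#' @param arena An [arena()].
#' @param min_speed cm/s (default 3); use `-Inf` to keep all samples.
#' @param kernel_sd Smoothing SD in cm (default 3).
#' @return List of class `occupancy_map`: `occupancy` (smoothed, s), `raw`
#'   (unsmoothed, s), `mask`, `edges`, `dims`, `total_time`.
#' @export
occupancy_map <- function(track, speed, arena, min_speed = 3, kernel_sd = 3) {
  keep <- track$valid & !is.na(speed$speed) & speed$speed > min_speed
  if (!any(keep)) abort("no samples above min_speed")
  dt <- median(diff(track$time))
  edges <- arena_edges(arena)
  sd_bins <- kernel_sd / arena$bin_size
  if (arena$dims == 2L) {
    ix <- bin_index(track$x[keep], edges$x)
    iy <- bin_index(track$y[keep], edges$y)
    ok <- !is.na(ix) & !is.na(iy)
    raw <- matrix(0, nrow = length(edges$x) - 1, ncol = length(edges$y) - 1)
    tb <- table(factor(ix[ok], levels = seq_len(nrow(raw))),
                factor(iy[ok], levels = seq_len(ncol(raw))))
    raw <- matrix(as.numeric(tb), nrow(raw), ncol(raw)) * dt
    mask <- matrix(TRUE, nrow(raw), ncol(raw))
  } else {
    pos <- if ("pos" %in% names(track)) track$pos else track$x
    ix <- bin_index(pos[keep], edges$x)
    ok <- !is.na(ix)
    raw <- as.numeric(table(factor(ix[ok],
                                   levels = seq_len(length(edges$x) - 1)))) * dt
    mask <- rep(TRUE, length(raw))
  }
  sm <- smooth_mass(raw, mask, sd_bins)
  structure(list(occupancy = sm, raw = raw, mask = mask, edges = edges,
                 dims = arena$dims, total_time = sum(raw),
                 kernel_sd = kernel_sd, bin_size = arena$bin_size),
            class = "occupancy_map")
}

#' Firing-rate map
#'
#' Spikes are assigned to the nearest-in-time track sample (speed-gated like
#' the occupancy); the smoothed spike-count map is divided by the smoothed
#' occupancy (identical kernel). Bins with raw occupancy below
#' `min_occupancy` seconds are unvisited and carry no rate.
#'
#' @param spike_times Seconds.
#' @param track,speed,arena,min_speed,kernel_sd As [occupancy_map()].
#' @param min_occupancy Seconds (default 0.05).
#' @param direction Optional direction tag for 1D maps.
#' @return List of class `rate_map`: `rate`, `occupancy`, `raw_occupancy`,
#'   `visited`, `edges`, `dims`, `n_spikes`, `direction`.
#' @export
rate_map <- function(spike_times, track, speed, arena, min_speed = 3,
                     kernel_sd = 3, min_occupancy = 0.05, direction = NA) {
  occ <- occupancy_map(track, speed, arena, min_speed, kernel_sd)
  keep <- track$valid & !is.na(speed$speed) & speed$speed > min_speed
  # nearest track sample per spike, then apply the same speed gate
  si <- findInterval(spike_times, track$time)
  si[si < 1] <- 1L
  upper <- si < nrow(track)
  d0 <- abs(spike_times - track$time[si])
  d1 <- abs(ifelse(upper, track$time[si + upper], Inf) - spike_times)
  si <- ifelse(upper & d1 < d0, si + 1L, si)
  si <- si[keep[si]]
  edges <- occ$edges
  sd_bins <- kernel_sd / arena$bin_size
  if (arena$dims == 2L) {
    ix <- bin_index(track$x[si], edges$x)
    iy <- bin_index(track$y[si], edges$y)
    ok <- !is.na(ix) & !is.na(iy)
    cnt <- matrix(as.numeric(table(
      factor(ix[ok], levels = seq_len(nrow(occ$raw))),
      factor(iy[ok], levels = seq_len(ncol(occ$raw))))),
      nrow(occ$raw), ncol(occ$raw))
  } else {
    pos <- if ("pos" %in% names(track)) track$pos else track$x
    ix <- bin_index(pos[si], edges$x)
    ok <- !is.na(ix)
    cnt <- as.numeric(table(factor(ix[ok],
                                   levels = seq_along(occ$raw))))
  }
  sm_cnt <- smooth_mass(cnt, occ$mask, sd_bins)
  visited <- occ$raw >= min_occupancy
  rate <- sm_cnt / occ$occupancy
  rate[!visited] <- NA_real_
  structure(list(rate = rate, occupancy = occ$occupancy,
                 raw_occupancy = occ$raw, visited = visited, edges = edges,
                 dims = arena$dims, n_spikes = length(si),
                 bin_size = arena$bin_size, direction = direction),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %dD, %s bins (%d visited), %d spikes, peak %.2f Hz\n",
              x$dims, paste(dim(as.matrix(x$rate)), collapse = "x"),
              sum(x$visited), x$n_spikes,
              suppressWarnings(max(x$rate[x$visited], na.rm = TRUE))))
  invisible(x)
}

#' @export
as_tibble.rate_map <- function(x, ...) {
  map <- x
  ex <- map$edges$x
  cx <- (ex[-1] + ex[-length(ex)]) / 2
  if (map$dims == 2L) {
    ey <- map$edges$y
    cy <- (ey[-1] + ey[-length(ey)]) / 2
    g <- expand.grid(cx = cx, cy = cy)
    tibble(x = g$cx, y = g$cy, rate = as.vector(map$rate),
           occupancy = as.vector(map$occupancy),
           visited = as.vector(map$visited))
  } else {
    tibble(pos = cx, rate = as.numeric(map$rate),
           occupancy = as.numeric(map$occupancy),
           visited = as.logical(map$visited))
  }
}

rate_weights <- function(map) {
  ok <- map$visited & !is.na(map$rate)
  p <- map$occupancy[ok] / sum(map$occupancy[ok])
  list(p = p, lambda = map$rate[ok])
}

#' Skaggs spatial information score
#'
#' `sum_i p_i (lambda_i/lambda) log2(lambda_i/lambda)` in bits/spike over
#' visited bins, with `p_i` the occupancy probability and `lambda` the
#' occupancy-weighted mean rate. Zero-rate bins contribute zero.
#'
#' @param map A [rate_map()].
#' @return Bits per spike (non-negative).
#' @export
spatial_information <- function(map) {
  w <- rate_weights(map)
  lam <- sum(w$p * w$lambda)
  if (lam <= 0) abort("mean rate is zero")
  rel <- w$lambda / lam
  pos <- rel > 0
  sum(w$p[pos] * rel[pos] * log2(rel[pos]))
}

#' Firing sparsity
#'
#' `(sum p_i lambda_i)^2 / sum p_i lambda_i^2`, in (0, 1]; 1 means spatially
#' uniform firing, small values mean firing confined to few bins.
#'
#' @param map A [rate_map()].
#' @return Sparsity in (0, 1].
#' @export
sparsity <- function(map) {
  w <- rate_weights(map)
  lam <- sum(w$p * w$lambda)
  if (lam <= 0) abort("mean rate is zero")
  lam^2 / sum(w$p * w$lambda^2)
}

#' Across-trial rate-map stability
#'
#' Pearson correlation between the rates of the two maps over bins visited
#' in both; undefined (NA) with fewer than `min_bins` common bins.
#'
#' @param map1,map2 Two [rate_map()]s with identical binning.
#' @param min_bins Minimum common visited bins (default 10).
#' @return Pearson r, or NA.
#' @export
map_stability <- function(map1, map2, min_bins = 10) {
  if (!identical(dim(as.matrix(map1$rate)), dim(as.matrix(map2$rate))))
    abort("maps must share binning")
  both <- map1$visited & map2$visited & !is.na(map1$rate) & !is.na(map2$rate)
  if (sum(both) < min_bins) return(NA_real_)
  cor(map1$rate[both], map2$rate[both])
}
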