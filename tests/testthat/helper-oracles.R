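# Independent brute-force oracles used to check the vectorized
# implementations on random small instances.

oracle_restrict <- function(times, epochs) {
  keep <- vapply(times, function(t) {
    any(t >= epochs$start & t < epochs$end)
  }, logical(1))
  times[keep]
}

oracle_windowed_rms <- function(x, fs, window, step) {
  wn <- round(window * fs); sn <- round(step * fs)
  starts <- seq(1, length(x) - wn + 1, by = sn)
  vapply(starts, function(s) sqrt(mean(x[s:(s + wn - 1)]^2)), numeric(1))
}

oracle_ac_first_moment <- function(st, window_ms, bin_ms) {
  lags <- c()
  for (i in seq_along(st)) for (j in seq_along(st)) {
    d <- (st[j] - st[i]) * 1000
    if (d > 0 && d <= window_ms) lags <- c(lags, d)
  }
  edges <- seq(0, window_ms, by = bin_ms)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  cnt <- vapply(seq_along(mids), function(k)
    sum(lags > edges[k] & lags <= edges[k + 1]), numeric(1))
  sum(cnt * mids) / sum(cnt)
}

oracle_rank_sum_exhaustive <- function(x, y) {
  # exact null distribution of the rank-sum of x by enumeration (no ties)
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  all_w <- apply(utils::combn(N, n1), 2, function(id) sum(r[id]))
  mean_w <- mean(all_w)
  p <- mean(abs(all_w - mean_w) >= abs(W - mean_w))
  list(W = W, p = p)
}

oracle_watson_u2 <- function(a, b) {
  # direct formula on the pooled empirical distributions
  x <- sort((a %% 360) / 360); y <- sort((b %% 360) / 360)
  n <- length(x); m <- length(y); N <- n + m
  pooled <- sort(c(x, y))
  dk <- vapply(pooled, function(v)
    mean(x <= v) - mean(y <= v), numeric(1))
  (n * m / N^2) * (sum(dk^2) - sum(dk)^2 / N)
}

oracle_pearson <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

oracle_flood_fields_2d <- function(rate, peak_thr = 5, frac = 0.2,
                                   min_bins = 10) {
  # independent implementation: repeated BFS over a queue
  r <- rate
  assigned <- matrix(FALSE, nrow(r), ncol(r))
  sizes <- c()
  repeat {
    cand <- r; cand[assigned] <- NA
    if (all(is.na(cand)) || max(cand, na.rm = TRUE) <= peak_thr) break
    pk <- which(cand == max(cand, na.rm = TRUE), arr.ind = TRUE)[1, ]
    thr <- frac * cand[pk[1], pk[2]]
    q <- list(pk); mem <- matrix(FALSE, nrow(r), ncol(r))
    while (length(q) > 0) {
      p <- q[[1]]; q <- q[-1]
      i <- p[1]; j <- p[2]
      if (i < 1 || j < 1 || i > nrow(r) || j > ncol(r)) next
      if (mem[i, j] || assigned[i, j]) next
      if (is.na(r[i, j]) || r[i, j] < thr) next
      mem[i, j] <- TRUE
      q <- c(q, list(c(i - 1, j)), list(c(i + 1, j)),
             list(c(i, j - 1)), list(c(i, j + 1)))
    }
    assigned[mem] <- TRUE
    if (sum(mem) >= min_bins) sizes <- c(sizes, sum(mem))
  }
  sizes
}

# minimal rate-map object for analytic identity checks (no smoothing)
make_map <- function(rate, occupancy = NULL) {
  rate <- as.matrix(rate)
  if (is.null(occupancy)) occupancy <- matrix(1, nrow(rate), ncol(rate))
  structure(list(rate = rate, occupancy = as.matrix(occupancy),
                 raw_occupancy = as.matrix(occupancy),
                 visited = matrix(TRUE, nrow(rate), ncol(rate)),
                 edges = list(x = 0:nrow(rate) * 2, y = 0:ncol(rate) * 2),
                 dims = 2L, n_spikes = NA_integer_, bin_size = 2,
                 direction = NA),
            class = "rate_map")
}

triangle_wave <- function(t, period) {
  # unit-amplitude triangle: constant |slope|, uniform dwell density
  ph <- (t / period) %% 1
  4 * abs(ph - 0.5) - 1
}

triangle01 <- function(t, period) (triangle_wave(t, period) + 1) / 2

# flat speed table covering [0, dur] at 25 Hz (for generator calls)
flat_speed <- function(dur, v = 0.5) {
  tibble::tibble(time = seq(0, dur, by = 0.04), speed = v,
                 valid = TRUE)
}
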