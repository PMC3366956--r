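#' Restrict times or records to a set of epochs
#'
#' Keeps only entries whose time lies in a half-open interval `[start, end)`
#' of the epoch table. Half-open intervals prevent double counting at the
#' joint of adjacent epochs.
#'
#' @param x Numeric vector of times, or a data frame with a `time` column.
#' @param epochs Data frame with `start` and `end` columns, sorted and
#'   non-overlapping (an empty table yields an empty result).
#' @return Same kind as `x`, restricted.
#' @export
restrict <- function(x, epochs) UseMethod("restrict")

check_epochs <- function(epochs) {
  if (nrow(epochs) == 0) return(invisible(epochs))
  if (is.unsorted(epochs$start))
    abort("epochs must be sorted by start")
  if (nrow(epochs) > 1 && any(epochs$start[-1] < epochs$end[-nrow(epochs)]))
    abort("epochs must be non-overlapping")
  invisible(epochs)
}

in_epochs <- function(times, epochs) {
  check_epochs(epochs)
  if (nrow(epochs) == 0 || length(times) == 0)
    return(rep(FALSE, length(times)))
  # locate the epoch whose start is the last one <= t, then test its end
  idx <- findInterval(times, epochs$start)
  ok <- idx >= 1
  ok[ok] <- times[ok] < epochs$end[idx[ok]]
  ok
}

#' @export
restrict.numeric <- function(x, epochs) x[in_epochs(x, epochs)]

#' @export
restrict.data.frame <- function(x, epochs) {
  if (!"time" %in% names(x)) abort("data frame must have a `time` column")
  x[in_epochs(x$time, epochs), , drop = FALSE]
}

#' Instantaneous running speed from a position track
#'
#' Coordinates are boxcar-smoothed over `smoothing_window` to suppress tracker
#' jitter, then differentiated by central differences. Tracking dropouts up to
#' `max_gap` seconds are linearly interpolated first; longer gaps stay invalid
#' and propagate to the speed samples that touch them.
#'
#' @param track A [position_track()].
#' @param smoothing_window Boxcar width in seconds (default 0.2).
#' @param max_gap Longest dropout (s) bridged by interpolation (default 0.4).
#' @return Tibble with columns `time`, `speed` (cm/s), `valid`.
#' @export
compute_speed <- function(track, smoothing_window = 0.2, max_gap = 0.4) {
  if (sum(track$valid) < 2) abort("need at least 2 valid track samples")
  t <- track$time
  filled <- interpolate_dropouts(track, max_gap)
  x <- filled$x; y <- filled$y; valid <- filled$valid

  dt <- median(diff(t))
  w <- max(1L, round(smoothing_window / dt))
  if (w %% 2 == 0) w <- w + 1L
  xs <- boxcar_smooth(x, w)
  ys <- boxcar_smooth(y, w)

  n <- length(t)
  speed <- rep(NA_real_, n)
  if (n >= 3) {
    i <- 2:(n - 1)
    speed[i] <- sqrt((xs[i + 1] - xs[i - 1])^2 + (ys[i + 1] - ys[i - 1])^2) /
      (t[i + 1] - t[i - 1])
  }
  speed[1] <- speed[2]; speed[n] <- speed[n - 1]
  # a speed sample uses neighbours; invalidate where any contributor invalid
  ok <- valid
  okn <- ok & c(ok[-1], FALSE) & c(FALSE, ok[-n])
  speed[!okn] <- NA_real_
  tibble(time = t, speed = speed, valid = okn)
}

interpolate_dropouts <- function(track, max_gap) {
  t <- track$time; x <- track$x; y <- track$y; valid <- track$valid
  if (all(valid)) return(list(x = x, y = y, valid = valid))
  r <- rle(valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1 || i1 == length(t)) next          # edge gap: cannot bridge
    gap <- t[i1 + 1] - t[i0 - 1]
    if (gap > max_gap) next
    idx <- i0:i1
    x[idx] <- approx(c(t[i0 - 1], t[i1 + 1]), c(x[i0 - 1], x[i1 + 1]),
                     xout = t[idx])$y
    y[idx] <- approx(c(t[i0 - 1], t[i1 + 1]), c(y[i0 - 1], y[i1 + 1]),
                     xout = t[idx])$y
    valid[idx] <- TRUE
  }
  list(x = x, y = y, valid = valid)
}

boxcar_smooth <- function(x, w) {
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1L        # symmetric window only
  half <- (w - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  cs <- cumsum(xp)
  (cs[(w):(n + w - 1)] - c(0, cs[1:(n - 1)])) / w
}
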