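#' Zigzag maze geometry
#'
#' Five adjacent 7 cm wide, 65 cm long alleys; the walls separating alleys
#' are 58 cm long, leaving a 7 cm turning gap at alternating ends. The
#' skeleton is the chain of alley centerlines joined by half-turns of radius
#' 3.5 cm (half the alley width); its arc length runs from the south end of
#' alley 1 to the north end of alley 5.
#'
#' @param n_alleys Number of alleys (default 5).
#' @param alley_length,alley_width,wall_length cm.
#' @return List of class `zigzag_geometry` with a densely sampled skeleton
#'   (`sx`, `sy`, `arc`) and `total_length`.
#' @export
zigzag_geometry <- function(n_alleys = 5, alley_length = 65, alley_width = 7,
                            wall_length = 58) {
  r <- alley_width / 2
  y_lo <- alley_length - wall_length    # straight part spans [y_lo, y_hi]...
  # centerline of alley i at x = (i - 1/2) * width; turns alternate N/S
  ds <- 0.1
  xs <- list(); ys <- list()
  for (i in seq_len(n_alleys)) {
    xc <- (i - 0.5) * alley_width
    going_up <- i %% 2 == 1
    y0 <- if (i == 1) 0 else r
    y1 <- if (i == n_alleys) alley_length else alley_length - r
    yy <- seq(y0, y1, by = ds)
    if (!going_up) yy <- rev(yy)
    xs[[length(xs) + 1]] <- rep(xc, length(yy))
    ys[[length(ys) + 1]] <- yy
    if (i < n_alleys) {
      # half-turn to the next alley at the open (gap) end
      at_top <- going_up
      cy <- if (at_top) alley_length - r else r
      cx <- xc + r
      th <- seq(0, pi, length.out = ceiling(pi * r / ds))
      if (at_top) {
        xs[[length(xs) + 1]] <- cx - r * cos(th)
        ys[[length(ys) + 1]] <- cy + r * sin(th)
      } else {
        xs[[length(xs) + 1]] <- cx - r * cos(th)
        ys[[length(ys) + 1]] <- cy - r * sin(th)
      }
    }
  }
  sx <- unlist(xs); sy <- unlist(ys)
  seglen <- sqrt(diff(sx)^2 + diff(sy)^2)
  keep <- c(TRUE, seglen > 1e-9)       # drop duplicate joint points
  sx <- sx[keep]; sy <- sy[keep]
  arc <- c(0, cumsum(sqrt(diff(sx)^2 + diff(sy)^2)))
  structure(list(sx = sx, sy = sy, arc = arc,
                 total_length = arc[length(arc)],
                 n_alleys = n_alleys, alley_length = alley_length,
                 alley_width = alley_width, wall_length = wall_length),
            class = "zigzag_geometry")
}

#' Linearize zigzag-maze positions
#'
#' Projects each track sample onto the nearest point of the maze skeleton
#' and returns its arc-length coordinate (cm from the south end of alley 1),
#' plus a run direction per sample: runs are split at visits to the two maze
#' ends, northbound running from the 0 end towards the far end.
#'
#' @param track A [position_track()].
#' @param geometry A [zigzag_geometry()].
#' @param tolerance Max distance (cm) from the skeleton beyond the alley
#'   half-width before a sample is invalidated (default 5).
#' @param end_zone Arc length (cm) from either maze end that counts as a
#'   visit to that end (default 10).
#' @return Tibble: `time`, `pos` (cm), `direction`
#'   (northbound/southbound/NA), `valid`.
#' @export
linearize_zigzag <- function(track, geometry, tolerance = 5, end_zone = 10) {
  n <- nrow(track)
  pos <- rep(NA_real_, n)
  ok <- track$valid
  max_d <- geometry$alley_width / 2 + tolerance
  idx <- which(ok)
  # nearest skeleton point, chunked to bound memory
  chunk <- 2000L
  for (c0 in seq(1, length(idx), by = chunk)) {
    ii <- idx[c0:min(c0 + chunk - 1, length(idx))]
    dx <- outer(track$x[ii], geometry$sx, "-")
    dy <- outer(track$y[ii], geometry$sy, "-")
    d2 <- dx * dx + dy * dy
    j <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(d2[cbind(seq_along(ii), j)])
    good <- dmin <= max_d
    pos[ii[good]] <- geometry$arc[j[good]]
  }
  valid <- !is.na(pos)

  # run segmentation from end-zone visits
  L <- geometry$total_length
  zone <- rep(NA_integer_, n)
  zone[valid & pos <= end_zone] <- 0L
  zone[valid & pos >= L - end_zone] <- 1L
  direction <- rep(NA_character_, n)
  zi <- which(!is.na(zone))
  if (length(zi) >= 2) {
    # compress consecutive same-zone samples into visits
    keep <- c(TRUE, diff(zone[zi]) != 0)
    vi <- zi[keep]; vz <- zone[vi]
    # the visit extends until the last in-zone sample before the zone flips
    last_in_zone <- c(vi[-1], zi[length(zi)])
    for (k in seq_len(length(vi) - 1)) {
      if (vz[k] == vz[k + 1]) next
      seg0 <- max(which(zone[seq_len(vi[k + 1])] == vz[k]))
      seg <- seg0:vi[k + 1]
      direction[seg] <- if (vz[k] == 0L) "northbound" else "southbound"
    }
  }
  direction[!valid] <- NA_character_
  tibble(time = track$time, pos = pos, direction = direction, valid = valid)
}

#' Directional 1D rate map on the linearized zigzag maze
#'
#' Builds a linear firing-rate profile (2 cm bins, 3 cm kernel SD, same
#' procedure as the 2D maps) from the samples of one run direction.
#'
#' @param spike_times Seconds.
#' @param linear Tibble from [linearize_zigzag()].
#' @param speed Tibble from [compute_speed()] on the same clock.
#' @param geometry A [zigzag_geometry()].
#' @param direction `"northbound"` or `"southbound"`.
#' @param ... Passed to [rate_map()] (`min_speed`, `kernel_sd`, ...).
#' @return A 1D [rate_map()] tagged with the direction.
#' @export
linear_rate_map <- function(spike_times, linear, speed, geometry,
                            direction = c("northbound", "southbound"), ...) {
  direction <- match.arg(direction)
  keep <- linear$valid & !is.na(linear$direction) &
    linear$direction == direction
  tr <- tibble(time = linear$time, x = linear$pos,
               y = 0, valid = keep)
  a <- arena(c(0, geometry$total_length), NULL, bin_size = 2)
  rate_map(spike_times, tr, speed, a, direction = direction, ...)
}
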