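#' Detect 2D place fields
#'
#' Iteratively: take the highest unassigned bin with rate above
#' `peak_threshold` (5 Hz), flood-fill its 4-connected neighbourhood over
#' bins at or above `extent_frac` (20%) of that peak, accept the component if
#' it has at least `min_bins` (10) bins, mark its bins assigned, repeat until
#' no qualifying peak remains.
#'
#' @param map A 2D [rate_map()].
#' @param peak_threshold Hz (default 5).
#' @param extent_frac Fraction of field peak (default 0.2).
#' @param min_bins Minimum bins per field (default 10).
#' @return Tibble: `field_id`, `peak_rate`, `n_bins`, `size` (cm^2),
#'   `centroid_x`, `centroid_y`, list-column `bins` (matrix row/col indices).
#' @export
detect_fields_2d <- function(map, peak_threshold = 5, extent_frac = 0.2,
                             min_bins = 10) {
  r <- map$rate
  r[!map$visited] <- NA_real_
  assigned <- matrix(FALSE, nrow(r), ncol(r))
  area <- map$bin_size^2
  ex <- map$edges$x; ey <- map$edges$y
  cx <- (ex[-1] + ex[-length(ex)]) / 2
  cy <- (ey[-1] + ey[-length(ey)]) / 2
  fields <- list()
  repeat {
    cand <- r
    cand[assigned] <- NA_real_
    if (all(is.na(cand)) || max(cand, na.rm = TRUE) <= peak_threshold) break
    peak_idx <- which(cand == max(cand, na.rm = TRUE), arr.ind = TRUE)[1, ]
    peak <- cand[peak_idx[1], peak_idx[2]]
    member <- flood_fill_2d(r, assigned, peak_idx, extent_frac * peak)
    assigned[member] <- TRUE
    if (sum(member) >= min_bins) {
      idx <- which(member, arr.ind = TRUE)
      w <- r[member]
      fields[[length(fields) + 1]] <- tibble(
        peak_rate = peak, n_bins = sum(member), size = sum(member) * area,
        centroid_x = sum(cx[idx[, 1]] * w) / sum(w),
        centroid_y = sum(cy[idx[, 2]] * w) / sum(w),
        bins = list(idx))
    }
  }
  out <- bind_rows(fields)
  if (nrow(out) == 0)
    return(tibble(field_id = integer(0), peak_rate = numeric(0),
                  n_bins = integer(0), size = numeric(0),
                  centroid_x = numeric(0), centroid_y = numeric(0),
                  bins = list()))
  out$field_id <- seq_len(nrow(out))
  out[, c("field_id", "peak_rate", "n_bins", "size",
          "centroid_x", "centroid_y", "bins")]
}

flood_fill_2d <- function(r, assigned, start, thr) {
  nr <- nrow(r); nc <- ncol(r)
  member <- matrix(FALSE, nr, nc)
  ok <- !is.na(r) & r >= thr & !assigned
  stack <- matrix(start, ncol = 2)
  while (nrow(stack) > 0) {
    i <- stack[nrow(stack), 1]; j <- stack[nrow(stack), 2]
    stack <- stack[-nrow(stack), , drop = FALSE]
    if (i < 1 || i > nr || j < 1 || j > nc) next
    if (member[i, j] || !ok[i, j]) next
    member[i, j] <- TRUE
    stack <- rbind(stack, c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
  }
  member
}

#' Detect 1D place fields on a linear rate profile
#'
#' Iteratively: take the highest unassigned bin above `peak_threshold` and
#' extend in both directions until the rate drops below `extent_frac` of that
#' peak. No minimum-length criterion is applied on the line.
#'
#' @param map A 1D [rate_map()].
#' @param peak_threshold Hz (default 5).
#' @param extent_frac Fraction of field peak (default 0.2).
#' @return Tibble: `field_id`, `peak_rate`, `n_bins`, `size` (cm), `start`,
#'   `end` (cm, outer bin edges), `peak_pos`, `direction`, list-column `bins`.
#' @export
detect_fields_1d <- function(map, peak_threshold = 5, extent_frac = 0.2) {
  r <- as.numeric(map$rate)
  r[!map$visited] <- NA_real_
  n <- length(r)
  assigned <- rep(FALSE, n)
  edges <- map$edges$x
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  fields <- list()
  repeat {
    cand <- r
    cand[assigned] <- NA_real_
    if (all(is.na(cand)) || max(cand, na.rm = TRUE) <= peak_threshold) break
    ip <- which.max(cand)
    peak <- cand[ip]
    thr <- extent_frac * peak
    lo <- ip
    while (lo > 1 && !is.na(r[lo - 1]) && !assigned[lo - 1] &&
           r[lo - 1] >= thr) lo <- lo - 1
    hi <- ip
    while (hi < n && !is.na(r[hi + 1]) && !assigned[hi + 1] &&
           r[hi + 1] >= thr) hi <- hi + 1
    assigned[lo:hi] <- TRUE
    fields[[length(fields) + 1]] <- tibble(
      peak_rate = peak, n_bins = hi - lo + 1L,
      size = edges[hi + 1] - edges[lo],
      start = edges[lo], end = edges[hi + 1], peak_pos = centers[ip],
      direction = map$direction, bins = list(lo:hi))
  }
  out <- bind_rows(fields)
  if (nrow(out) == 0)
    return(tibble(field_id = integer(0), peak_rate = numeric(0),
                  n_bins = integer(0), size = numeric(0), start = numeric(0),
                  end = numeric(0), peak_pos = numeric(0),
                  direction = character(0), bins = list()))
  out$field_id <- seq_len(nrow(out))
  out[, c("field_id", "peak_rate", "n_bins", "size", "start", "end",
          "peak_pos", "direction", "bins")]
}
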