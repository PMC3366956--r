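#' Spike duration at 25% of maximum amplitude
#'
#' Width (ms) of the interval around the waveform's global extremum where the
#' absolute waveform stays at or above 25% of its maximum absolute amplitude,
#' with linear interpolation at the two threshold crossings.
#'
#' @param waveform Numeric vector with a unique global extremum.
#' @param waveform_rate Hz.
#' @param threshold_frac Fraction of the peak (default 0.25).
#' @return Duration in ms.
#' @export
spike_duration_at_25pct <- function(waveform, waveform_rate,
                                    threshold_frac = 0.25) {
  a <- abs(waveform)
  peak <- max(a)
  if (peak <= 0) abort("flat waveform: no extremum")
  thr <- threshold_frac * peak
  ip <- which.max(a)
  n <- length(a)
  # walk left from the peak to the first sample below threshold
  left <- ip
  while (left > 1 && a[left - 1] >= thr) left <- left - 1
  tl <- if (left == 1) left else {
    left - (a[left] - thr) / (a[left] - a[left - 1])
  }
  right <- ip
  while (right < n && a[right + 1] >= thr) right <- right + 1
  tr <- if (right == n) right else {
    right + (a[right] - thr) / (a[right] - a[right + 1])
  }
  (tr - tl) / waveform_rate * 1000
}

#' First moment of the spike-time autocorrelation
#'
#' Histogram of all positive pairwise lags up to `window` ms (bin width
#' `bin` ms); returns the count-weighted mean lag (ms). Short-latency-heavy
#' trains (bursty pyramidal cells) give small moments; tonic interneurons
#' approach the uniform-lag expectation of `window/2`.
#'
#' @param spike_times Seconds, sorted.
#' @param window Max lag in ms (default 25).
#' @param bin Bin width in ms (default 0.5).
#' @return First moment in ms.
#' @export
autocorr_first_moment <- function(spike_times, window = 25, bin = 0.5) {
  lags <- pairwise_lags(spike_times, window / 1000) * 1000
  if (length(lags) == 0) abort("no lags within window")
  edges <- seq(0, window, by = bin)
  h <- graphics::hist(lags, breaks = edges, plot = FALSE)
  sum(h$counts * h$mids) / sum(h$counts)
}

# all positive lags <= window (s) between spike pairs; O(n * mean pairs)
pairwise_lags <- function(spike_times, window) {
  n <- length(spike_times)
  if (n < 2) return(numeric(0))
  out <- vector("list", n - 1)
  j <- 1
  for (i in seq_len(n - 1)) {
    k <- i + 1
    # spikes are sorted; advance until outside the window
    while (k <= n && spike_times[k] - spike_times[i] <= window) k <- k + 1
    if (k > i + 1) out[[i]] <- spike_times[(i + 1):(k - 1)] - spike_times[i]
  }
  unlist(out) %||% numeric(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Physiological feature vector of a unit
#'
#' Mean firing rate over the whole session, autocorrelation first moment and
#' spike duration at 25% amplitude — the three axes on which pyramidal cells
#' and interneurons separate. Rate is carried as log10(Hz) for the template
#' space (cluster separation is multiplicative in rate).
#'
#' @param unit A [spike_unit()].
#' @param session_duration Seconds of recording.
#' @param ac_window,ac_bin Autocorrelation window/bin, ms.
#' @param log_rate Use log10 rate in the feature vector (default TRUE).
#' @return One-row tibble: `unit_id`, `mean_rate`, `rate_feature`,
#'   `ac_first_moment`, `spike_duration`.
#' @export
unit_features <- function(unit, session_duration, ac_window = 25,
                          ac_bin = 0.5, log_rate = TRUE) {
  rate <- length(unit$spike_times) / session_duration
  tibble(
    unit_id = unit$unit_id,
    mean_rate = rate,
    rate_feature = if (log_rate) log10(rate) else rate,
    ac_first_moment = autocorr_first_moment(unit$spike_times, ac_window, ac_bin),
    spike_duration = spike_duration_at_25pct(unit$waveform, unit$waveform_rate))
}

feature_matrix <- function(features) {
  m <- as.matrix(features[, c("rate_feature", "ac_first_moment",
                              "spike_duration")])
  rownames(m) <- features$unit_id
  m
}

#' Build the pyramidal-cell template
#'
#' Mean and sample covariance of the three physiological features over the
#' reference units (spatially selective cells with information score > 0.5
#' during open-field exploration). A near-singular covariance is regularized
#' by adding 1e-6 x trace/3 to the diagonal.
#'
#' @param features Tibble from [unit_features()], one row per reference unit
#'   (at least 4).
#' @return List of class `pyramidal_template`: `mean`, `cov`.
#' @export
build_template <- function(features) {
  m <- feature_matrix(features)
  if (nrow(m) < 4) abort("need at least 4 reference units")
  mu <- colMeans(m)
  S <- stats::cov(m)
  if (rcond_sym(S) < 1e-10) {
    S <- S + diag(3) * (1e-6 * sum(diag(S)) / 3)
    if (rcond_sym(S) < 1e-12)
      S <- S + diag(3) * 1e-12                 # fully degenerate input
  }
  structure(list(mean = mu, cov = S), class = "pyramidal_template")
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Mahalanobis distance of units from the pyramidal template
#'
#' @param features Tibble from [unit_features()] (any number of rows).
#' @param template A `pyramidal_template`.
#' @return Numeric vector of distances (not squared).
#' @export
template_distance <- function(features, template) {
  m <- feature_matrix(features)
  d <- sweep(m, 2, template$mean)
  sol <- solve(template$cov, t(d))
  sqrt(colSums(t(d) * sol))
}

#' Classify units from their template distance
#'
#' Distance below 20 is a pyramidal cell, above 40 an interneuron; the band
#' in between (boundaries included) is left unclassified and excluded from
#' further analysis.
#'
#' @param distance Non-negative numeric vector.
#' @param pyramidal_max,interneuron_min Thresholds (defaults 20 and 40).
#' @return Factor with levels pyramidal/unclassified/interneuron.
#' @export
classify_units <- function(distance, pyramidal_max = 20,
                           interneuron_min = 40) {
  if (any(distance < 0)) abort("distance must be non-negative")
  lab <- ifelse(distance < pyramidal_max, "pyramidal",
                ifelse(distance > interneuron_min, "interneuron",
                       "unclassified"))
  factor(lab, levels = c("pyramidal", "unclassified", "interneuron"))
}

#' Isolation distance of a cluster
#'
#' With n cluster spikes, the Mahalanobis distance (from the cluster's own
#' mean and covariance in the per-tetrode feature space) within which as many
#' noise spikes as cluster spikes are contained: the n-th smallest noise
#' distance. The squared variant is selectable.
#'
#' @param cluster_features Numeric matrix (n spikes x features).
#' @param noise_features Matrix of non-cluster spikes on the same tetrode.
#' @param squared Return squared distance (default FALSE).
#' @return Scalar; `Inf` with a warning when fewer noise than cluster spikes.
#' @export
isolation_distance <- function(cluster_features, noise_features,
                               squared = FALSE) {
  cluster_features <- as.matrix(cluster_features)
  noise_features <- as.matrix(noise_features)
  n <- nrow(cluster_features)
  if (nrow(noise_features) < n) {
    warn("fewer noise spikes than cluster spikes: isolation distance undefined")
    return(Inf)
  }
  mu <- colMeans(cluster_features)
  S <- stats::cov(cluster_features)
  d2 <- stats::mahalanobis(noise_features, mu, S)
  nth <- sort(d2, partial = n)[n]
  if (squared) nth else sqrt(nth)
}
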