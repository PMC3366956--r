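#' Construct an LFP channel
#'
#' A regularly sampled local field potential trace from one tetrode channel.
#' Analysis operates on channels flagged as lying in the CA1 pyramidal cell
#' layer; a channel outside the layer may be flagged as the reference used to
#' reject muscle artifacts during ripple detection.
#'
#' @param channel_id Character scalar.
#' @param samples Numeric vector of voltages (arbitrary units).
#' @param sample_rate Sampling rate in Hz.
#' @param in_pyramidal_layer Logical; analyze this channel for ripples/theta?
#' @param is_reference Logical; artifact-rejection reference channel?
#' @return An object of class `lfp_signal`.
#' @export
lfp_signal <- function(channel_id, samples, sample_rate,
                       in_pyramidal_layer = TRUE, is_reference = FALSE) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    abort("`sample_rate` must be a positive scalar")
  if (length(samples) == 0) abort("`samples` must be non-empty")
  structure(
    list(channel_id = as.character(channel_id),
         samples = as.numeric(samples),
         sample_rate = as.numeric(sample_rate),
         in_pyramidal_layer = isTRUE(in_pyramidal_layer),
         is_reference = isTRUE(is_reference)),
    class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("<lfp_signal> %s: %d samples @ %g Hz (%.1f s)%s%s\n",
              x$channel_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (x$in_pyramidal_layer) ", pyramidal layer" else "",
              if (x$is_reference) ", reference" else ""))
  invisible(x)
}

#' Times of the samples of an LFP channel
#' @param lfp An `lfp_signal`.
#' @return Numeric vector of sample times in seconds from session start.
#' @export
lfp_times <- function(lfp) {
  (seq_along(lfp$samples) - 1) / lfp$sample_rate
}

#' Construct a single unit (putative neuron)
#'
#' Spike times are in seconds from session start and must be strictly sorted.
#' The mean waveform is used for spike-duration measurement; per-spike cluster
#' features (principal components) are optional and only needed for the
#' isolation-distance cluster quality metric.
#'
#' @param unit_id,tetrode_id Character scalars.
#' @param spike_times Strictly increasing numeric vector, seconds.
#' @param waveform Numeric vector, mean spike waveform.
#' @param waveform_rate Waveform sampling rate, Hz.
#' @param cluster_features Optional numeric matrix (spikes x features).
#' @return An object of class `spike_unit`.
#' @export
spike_unit <- function(unit_id, tetrode_id, spike_times, waveform,
                       waveform_rate, cluster_features = NULL) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE))
    abort(sprintf("spike_times of unit %s must be strictly increasing", unit_id))
  if (!is.null(cluster_features)) cluster_features <- as.matrix(cluster_features)
  structure(
    list(unit_id = as.character(unit_id),
         tetrode_id = as.character(tetrode_id),
         spike_times = spike_times,
         waveform = as.numeric(waveform),
         waveform_rate = as.numeric(waveform_rate),
         cluster_features = cluster_features),
    class = "spike_unit")
}

#' @export
print.spike_unit <- function(x, ...) {
  cat(sprintf("<spike_unit> %s (tetrode %s): %d spikes\n",
              x$unit_id, x$tetrode_id, length(x$spike_times)))
  invisible(x)
}

#' Construct a position track
#'
#' Head position from video tracking at a nominal 25 Hz. Samples where the
#' tracker lost the animal carry `valid = FALSE`; their coordinates are
#' ignored by all downstream computations.
#'
#' @param times Strictly increasing numeric vector, seconds.
#' @param x,y Coordinates in cm.
#' @param valid Logical vector; defaults to all valid.
#' @return A tibble of class `position_track` with columns
#'   `time`, `x`, `y`, `valid`.
#' @export
position_track <- function(times, x, y, valid = NULL) {
  times <- as.numeric(times)
  if (length(times) != length(x) || length(times) != length(y))
    abort("times, x and y must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    abort("track times must be strictly increasing")
  if (is.null(valid)) valid <- rep(TRUE, length(times))
  out <- tibble(time = times, x = as.numeric(x), y = as.numeric(y),
                valid = as.logical(valid))
  class(out) <- c("position_track", class(out))
  out
}

#' Trial epoch table
#'
#' @param label Character vector, each one of `"rest"`, `"open_field"`,
#'   `"zigzag"`.
#' @param start,end Numeric vectors, seconds.
#' @return A tibble with columns `label`, `start`, `end`.
#' @export
trial_epochs <- function(label, start, end) {
  lab <- as.character(label)
  bad <- setdiff(unique(lab), c("rest", "open_field", "zigzag"))
  if (length(bad) > 0)
    abort(sprintf("unknown trial label(s): %s", paste(bad, collapse = ", ")))
  out <- tibble(label = lab, start = as.numeric(start), end = as.numeric(end))
  if (any(out$end <= out$start)) abort("trial end must exceed start")
  out <- arrange(out, .data$start)
  if (nrow(out) > 1 && any(out$start[-1] < out$end[-nrow(out)]))
    abort("trial epochs must be non-overlapping")
  out
}

#' Assemble a recording session
#'
#' Binds the LFP channels, curated units, position track and trial table of
#' one recording session and checks the structural invariants (ordered,
#' non-overlapping trials; spikes and tracking inside the trial span; at most
#' one reference channel).
#'
#' @param session_id Character scalar.
#' @param lfp List of [lfp_signal()] objects.
#' @param units List of [spike_unit()] objects.
#' @param track A [position_track()].
#' @param trials A [trial_epochs()] tibble.
#' @param validate Check invariants (default TRUE).
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(session_id, lfp, units, track, trials,
                              validate = TRUE) {
  s <- structure(
    list(session_id = as.character(session_id),
         lfp = lfp, units = units, track = track, trials = trials),
    class = "recording_session")
  if (validate) validate_session(s)
  s
}

#' Validate the invariants of a recording session
#'
#' @param session A `recording_session`.
#' @param pad Tolerance (s) allowed outside the union of trial epochs.
#' @return The session, invisibly; aborts with the violated invariant.
#' @export
validate_session <- function(session, pad = 1) {
  tr <- session$trials
  if (nrow(tr) > 1 && any(tr$start[-1] < tr$end[-nrow(tr)]))
    abort("invariant violated: trials must be time-ordered and non-overlapping")
  if (sum(map_lgl(session$lfp, "is_reference")) > 1)
    abort("invariant violated: at most one reference channel per session")
  lo <- min(tr$start) - pad; hi <- max(tr$end) + pad
  for (u in session$units) {
    if (is.unsorted(u$spike_times, strictly = TRUE))
      abort(sprintf("invariant violated: spike_times of %s not strictly sorted",
                    u$unit_id))
    if (length(u$spike_times) > 0 &&
        (min(u$spike_times) < lo || max(u$spike_times) > hi))
      abort(sprintf("invariant violated: spikes of %s outside trial span",
                    u$unit_id))
  }
  tk <- session$track
  if (nrow(tk) > 0 && (min(tk$time) < lo || max(tk$time) > hi))
    abort("invariant violated: track samples outside trial span")
  invisible(session)
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %s\n", x$session_id))
  cat(sprintf("  %d LFP channel(s), %d unit(s), %d track samples, %d trial(s)\n",
              length(x$lfp), length(x$units), nrow(x$track), nrow(x$trials)))
  invisible(x)
}

#' Trial epochs of one label as a start/end tibble
#'
#' @param session A `recording_session`.
#' @param label Trial label to select, or NULL for all trials.
#' @return Tibble with columns `start`, `end`.
#' @export
session_epochs <- function(session, label = NULL) {
  tr <- session$trials
  if (!is.null(label)) tr <- tr[tr$label %in% label, , drop = FALSE]
  tibble(start = tr$start, end = tr$end)
}
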