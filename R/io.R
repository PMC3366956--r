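#' Write a recording session to a fixture directory
#'
#' Layout: `session.yaml` (ids, rates, trial table), one `lfp_<channel>.bin`
#' per channel (little-endian float32), `units.csv`, per-unit
#' `spikes_<unit>.csv` and `waveform_<unit>.csv`, and `track.csv`. All CSVs
#' carry a single header line.
#'
#' @param session A `recording_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    session_id = session$session_id,
    lfp = lapply(session$lfp, function(l)
      list(channel_id = l$channel_id, sample_rate = l$sample_rate,
           in_pyramidal_layer = l$in_pyramidal_layer,
           is_reference = l$is_reference)),
    trials = lapply(seq_len(nrow(session$trials)), function(i)
      list(label = session$trials$label[i],
           start = session$trials$start[i], end = session$trials$end[i])),
    units = lapply(session$units, function(u)
      list(unit_id = u$unit_id, tetrode_id = u$tetrode_id,
           waveform_rate = u$waveform_rate)))
  yaml::write_yaml(meta, file.path(path, "session.yaml"), precision = 15)

  for (l in session$lfp) {
    con <- file(file.path(path, paste0("lfp_", l$channel_id, ".bin")), "wb")
    writeBin(as.numeric(l$samples), con, size = 4, endian = "little")
    close(con)
  }

  readr::write_csv(
    tibble(unit_id = map_chr(session$units, "unit_id"),
           tetrode_id = map_chr(session$units, "tetrode_id")),
    file.path(path, "units.csv"))
  for (u in session$units) {
    readr::write_csv(tibble(time = u$spike_times),
                     file.path(path, paste0("spikes_", u$unit_id, ".csv")))
    readr::write_csv(tibble(voltage = u$waveform),
                     file.path(path, paste0("waveform_", u$unit_id, ".csv")))
    if (!is.null(u$cluster_features)) {
      cf <- as.data.frame(u$cluster_features)
      names(cf) <- paste0("pc", seq_along(cf))
      readr::write_csv(cf,
                       file.path(path, paste0("features_", u$unit_id, ".csv")))
    }
  }
  readr::write_csv(session$track, file.path(path, "track.csv"))
  invisible(path)
}

#' Read a recording session from a fixture directory
#'
#' Inverse of [write_session()]. Missing optional parts (cluster features)
#' yield empty fields; a missing required file is a validation error naming
#' the missing part.
#'
#' @param path Session directory.
#' @param validate Check session invariants after loading (default TRUE).
#' @return A `recording_session`.
#' @export
read_session <- function(path, validate = TRUE) {
  yml <- file.path(path, "session.yaml")
  if (!file.exists(yml)) abort(sprintf("missing session.yaml in %s", path))
  meta <- yaml::read_yaml(yml)

  lfp <- lapply(meta$lfp, function(m) {
    f <- file.path(path, paste0("lfp_", m$channel_id, ".bin"))
    if (!file.exists(f)) abort(sprintf("missing LFP file %s", f))
    n <- file.info(f)$size / 4
    con <- file(f, "rb")
    samples <- readBin(con, what = "numeric", n = n, size = 4,
                       endian = "little")
    close(con)
    lfp_signal(m$channel_id, samples, m$sample_rate,
               in_pyramidal_layer = m$in_pyramidal_layer,
               is_reference = m$is_reference)
  })

  tf <- file.path(path, "track.csv")
  if (!file.exists(tf)) abort("validation error: missing track (track.csv)")
  tk <- readr::read_csv(tf, show_col_types = FALSE)
  track <- position_track(tk$time, tk$x, tk$y, tk$valid)

  trials <- trial_epochs(
    label = map_chr(meta$trials, "label"),
    start = map_dbl(meta$trials, "start"),
    end = map_dbl(meta$trials, "end"))

  wf_rates <- stats::setNames(map_dbl(meta$units, "waveform_rate"),
                              map_chr(meta$units, "unit_id"))
  uf <- file.path(path, "units.csv")
  if (!file.exists(uf)) abort("validation error: missing units.csv")
  ut <- readr::read_csv(uf, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  units <- lapply(seq_len(nrow(ut)), function(i) {
    uid <- ut$unit_id[i]
    st <- readr::read_csv(file.path(path, paste0("spikes_", uid, ".csv")),
                          show_col_types = FALSE)$time
    wv <- readr::read_csv(file.path(path, paste0("waveform_", uid, ".csv")),
                          show_col_types = FALSE)$voltage
    ff <- file.path(path, paste0("features_", uid, ".csv"))
    cf <- if (file.exists(ff))
      as.matrix(readr::read_csv(ff, show_col_types = FALSE)) else NULL
    spike_unit(uid, ut$tetrode_id[i], st, wv, wf_rates[[uid]],
               cluster_features = cf)
  })

  recording_session(meta$session_id, lfp, units, track, trials,
                    validate = validate)
}
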