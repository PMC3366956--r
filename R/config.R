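#' Oscillation analysis configuration
#'
#' Defaults follow standard CA1 practice: ripples are 125-250 Hz transients
#' detected from band-passed power (RMS in 20 ms windows stepped by 10 ms)
#' exceeding 7 SD above the mean, with epoch edges at 2.5 SD; candidate
#' events coincident with a 7 SD excursion on the reference channel are
#' rejected as muscle artifacts. Theta epochs are 500 ms windows with a
#' theta(6-10 Hz)/delta(2-4 Hz) power ratio above 2; theta phase is taken
#' from the 5-14 Hz filtered trace with 0 deg at each positive-to-negative
#' zero-crossing.
#'
#' @param ripple_band,theta_band,delta_band,phase_filter_band Hz pairs.
#' @param rms_window,rms_step Ripple power windowing, seconds.
#' @param swr_enter_sd,swr_exit_sd,ref_reject_sd Detection thresholds in SD
#'   units above the mean.
#' @param min_swr_duration Shortest accepted event, seconds.
#' @param merge_gap Events closer than this are merged, seconds.
#' @param theta_ratio_window Theta/delta window, seconds.
#' @param theta_ratio_threshold Ratio above which a window is theta.
#' @param filter_order Butterworth prototype order (applied forward-backward).
#' @param speed_bins Lower edges (cm/s) of the speed bins used for
#'   speed-resolved theta spectra; last bin is open-ended.
#' @return A list of class `osc_config`.
#' @export
osc_config <- function(ripple_band = c(125, 250),
                       rms_window = 0.020, rms_step = 0.010,
                       swr_enter_sd = 7, swr_exit_sd = 2.5,
                       ref_reject_sd = 7,
                       min_swr_duration = 0.020, merge_gap = 0.010,
                       theta_band = c(6, 10), delta_band = c(2, 4),
                       theta_ratio_window = 0.5, theta_ratio_threshold = 2,
                       phase_filter_band = c(5, 14),
                       filter_order = 4,
                       speed_bins = c(3, 8, 13, 18, 23)) {
  stopifnot(ripple_band[1] < ripple_band[2], theta_band[1] < theta_band[2],
            delta_band[1] < delta_band[2],
            phase_filter_band[1] < phase_filter_band[2],
            swr_enter_sd > swr_exit_sd, swr_enter_sd > 0, swr_exit_sd > 0,
            rms_window >= rms_step, rms_step > 0)
  structure(list(
    ripple_band = ripple_band, rms_window = rms_window, rms_step = rms_step,
    swr_enter_sd = swr_enter_sd, swr_exit_sd = swr_exit_sd,
    ref_reject_sd = ref_reject_sd, min_swr_duration = min_swr_duration,
    merge_gap = merge_gap, theta_band = theta_band, delta_band = delta_band,
    theta_ratio_window = theta_ratio_window,
    theta_ratio_threshold = theta_ratio_threshold,
    phase_filter_band = phase_filter_band, filter_order = filter_order,
    speed_bins = speed_bins), class = "osc_config")
}
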