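#' Wilcoxon rank-sum test (normal approximation, tie-corrected)
#'
#' Two-sided rank-sum test from the normal-approximation formula with tie
#' correction — the default comparison for linear unit- and session-level
#' metrics between groups.
#'
#' @param x,y Numeric samples.
#' @return One-row tibble: `statistic` (rank-sum W of `x`), `z`, `p`,
#'   `median_x`, `median_y`, `n_x`, `n_y`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 1 || n2 < 1) abort("both samples must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
  p <- 2 * pnorm(-abs(z))
  tibble(statistic = W, z = z, p = min(p, 1),
         median_x = median(x), median_y = median(y),
         n_x = n1, n_y = n2)
}

#' Compare a metric between two groups
#'
#' Linear metrics use the tie-corrected rank-sum normal approximation;
#' circular metrics (phases) use Watson's two-sample U^2. The unit of
#' analysis can be the cell (row) or the mouse/session (averaging rows per
#' `id_col` first) to mirror the convention that LFP-level metrics are
#' compared per animal and unit metrics per cell.
#'
#' @param a,b Data frames holding the metric.
#' @param metric Column name.
#' @param unit `"cell"` (rows as-is) or `"mouse"` (average per `id_col`).
#' @param id_col Grouping column for `unit = "mouse"` (default
#'   `"session_id"`).
#' @param circular Is the metric a phase in degrees? (default FALSE).
#' @return One-row tibble from [rank_sum_test()] or [watson_two_sample()],
#'   plus `metric` and `unit`.
#' @export
compare_groups <- function(a, b, metric, unit = c("cell", "mouse"),
                           id_col = "session_id", circular = FALSE) {
  unit <- match.arg(unit)
  pull_metric <- function(d) {
    v <- d[[metric]]
    if (is.null(v)) abort(sprintf("metric `%s` not found", metric))
    if (unit == "mouse") {
      g <- d[[id_col]]
      if (is.null(g)) abort(sprintf("id column `%s` not found", id_col))
      if (circular) {
        as.numeric(tapply(v, g, circ_mean_deg))
      } else {
        as.numeric(tapply(v, g, mean, na.rm = TRUE))
      }
    } else v
  }
  va <- pull_metric(a); vb <- pull_metric(b)
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) < 3 || length(vb) < 3)
    abort("need at least 3 observations per group")
  res <- if (circular) watson_two_sample(va, vb) else rank_sum_test(va, vb)
  res$metric <- metric
  res$unit <- unit
  res
}

#' Run the full per-session analysis
#'
#' Executes the stages in order — oscillations (SWR detection and
#' characterization, theta epochs, theta/ripple phase series), units
#' (features, pyramidal template from spatially selective open-field cells,
#' classification), spatial (open-field rate maps, information, sparsity,
#' fields; zigzag linearization and 1D maps) and phase (theta/ripple locking
#' per unit, spikes-per-SWR, precession per 1D field) — and returns all
#' products as tibbles. A stage that fails is reported and its dependents
#' skipped. Deterministic given the session and config.
#'
#' @param session A `recording_session`.
#' @param cfg An [osc_config()].
#' @param out_dir Optional directory: write every product as CSV.
#' @param min_spikes_selectivity Spikes needed in a trial before a cell
#'   enters the selectivity analysis (default 300).
#' @param info_threshold Information score above which a control cell seeds
#'   the pyramidal template (default 0.5).
#' @param perm_seed Seed for the precession permutation test (default 1).
#' @return List of class `session_results` with tibbles: `swr`,
#'   `theta_epochs`, `unit_features`, `classification`, `selectivity`,
#'   `theta_phase`, `ripple_phase`, `swr_participation`, `precession`,
#'   `errors`.
#' @export
run_session <- function(session, cfg = osc_config(), out_dir = NULL,
                        min_spikes_selectivity = 300, info_threshold = 0.5,
                        perm_seed = 1) {
  res <- list()
  errors <- character(0)
  session_duration <- max(session$trials$end) - min(session$trials$start)
  speed <- compute_speed(session$track)

  ## --- oscillations -------------------------------------------------------
  ca1 <- purrr::detect(session$lfp, ~ .x$in_pyramidal_layer)
  ref <- purrr::detect(session$lfp, ~ .x$is_reference)
  swr <- theta_ep <- theta_ph <- ripple_ph <- NULL
  if (is.null(ca1)) {
    errors <- c(errors, "oscillations: no pyramidal-layer channel")
  } else {
    fs <- ca1$sample_rate
    filt <- bandpass(ca1, cfg$ripple_band, order = cfg$filter_order)
    pw <- windowed_rms(filt, fs, cfg$rms_window, cfg$rms_step)
    rest <- session_epochs(session, "rest")
    base_ep <- if (nrow(rest) > 0) rest else NULL
    ref_pw <- if (!is.null(ref))
      windowed_rms(bandpass(ref, cfg$ripple_band, order = cfg$filter_order),
                   fs, cfg$rms_window, cfg$rms_step) else NULL
    ep <- detect_swr(pw, ref_pw, cfg, baseline_epochs = base_ep)
    swr <- characterize_swr(ep, filt, ca1$samples, fs, cfg)
    theta_ep <- detect_theta_epochs(ca1, cfg = cfg)
    theta_ph <- theta_phase_series(ca1, theta_ep, cfg = cfg)
    ripple_ph <- ripple_phase_series(filt, ep, fs)
  }
  res$swr <- swr %||% tibble()
  res$theta_epochs <- theta_ep %||% tibble()

  ## --- unit features ------------------------------------------------------
  feats <- purrr::map_dfr(session$units, function(u) {
    tryCatch(unit_features(u, session_duration),
             error = function(e) tibble(unit_id = u$unit_id,
                                        mean_rate = NA_real_,
                                        rate_feature = NA_real_,
                                        ac_first_moment = NA_real_,
                                        spike_duration = NA_real_))
  })
  res$unit_features <- feats

  ## --- spatial: open-field maps, selectivity ------------------------------
  of_trials <- session$trials[session$trials$label == "open_field", ]
  sel_rows <- list()
  maps_by_unit_trial <- list()
  if (nrow(of_trials) > 0) {
    ar <- open_field_arena()
    for (ti in seq_len(nrow(of_trials))) {
      ep1 <- tibble(start = of_trials$start[ti], end = of_trials$end[ti])
      tr1 <- restrict(session$track, ep1)
      sp1 <- restrict(speed, ep1)
      for (u in session$units) {
        st <- restrict(u$spike_times, ep1)
        row <- tibble(unit_id = u$unit_id, trial = ti,
                      n_spikes = length(st), info = NA_real_,
                      sparsity = NA_real_, n_fields = NA_integer_,
                      peak_rate = NA_real_, field_size = NA_real_)
        ok <- tryCatch({
          m <- rate_map(st, tr1, sp1, ar)
          maps_by_unit_trial[[paste(u$unit_id, ti)]] <- m
          if (length(st) >= min_spikes_selectivity) {
            f <- detect_fields_2d(m)
            row$info <- spatial_information(m)
            row$sparsity <- sparsity(m)
            row$n_fields <- nrow(f)
            row$peak_rate <- if (nrow(f) > 0) max(f$peak_rate) else
              suppressWarnings(max(m$rate[m$visited], na.rm = TRUE))
            row$field_size <- if (nrow(f) > 0) mean(f$size) else NA_real_
          }
          TRUE
        }, error = function(e) FALSE)
        if (!ok) errors <- c(errors,
                             sprintf("spatial: unit %s trial %d", u$unit_id, ti))
        sel_rows[[length(sel_rows) + 1]] <- row
      }
    }
  }
  res$selectivity <- bind_rows(sel_rows)

  ## --- units: template + classification ----------------------------------
  cls <- NULL
  if (nrow(feats) > 0 && nrow(res$selectivity) > 0) {
    best_info <- res$selectivity |>
      group_by(.data$unit_id) |>
      summarise(info = suppressWarnings(max(.data$info, na.rm = TRUE)))
    ref_ids <- best_info$unit_id[is.finite(best_info$info) &
                                   best_info$info > info_threshold]
    ref_feats <- feats[feats$unit_id %in% ref_ids &
                         complete.cases(feats), , drop = FALSE]
    if (nrow(ref_feats) >= 4) {
      tmpl <- build_template(ref_feats)
      usable <- complete.cases(feats)
      d <- rep(NA_real_, nrow(feats))
      d[usable] <- template_distance(feats[usable, , drop = FALSE], tmpl)
      lab <- rep(NA_character_, nrow(feats))
      lab[usable] <- as.character(classify_units(d[usable]))
      cls <- tibble(unit_id = feats$unit_id, distance = d, label = lab)
    } else {
      errors <- c(errors, "units: fewer than 4 template reference units")
    }
  }
  res$classification <- cls %||%
    tibble(unit_id = character(0), distance = numeric(0),
           label = character(0))

  ## --- phase: locking, SWR participation, precession ----------------------
  th_rows <- rp_rows <- sw_rows <- list()
  if (!is.null(theta_ph)) {
    for (u in session$units) {
      ph <- phases_of_spikes(u$spike_times, theta_ph)
      if (length(ph) >= 1) {
        cs <- circ_stats(ph)
        cs$unit_id <- u$unit_id
        th_rows[[length(th_rows) + 1]] <- cs
      }
      if (!is.null(ripple_ph)) {
        rp <- phases_of_spikes(u$spike_times, ripple_ph)
        if (length(rp) >= 1) {
          cs <- circ_stats(rp)
          cs$unit_id <- u$unit_id
          rp_rows[[length(rp_rows) + 1]] <- cs
        }
      }
      if (!is.null(swr) && nrow(swr) > 0) {
        sd_ <- swr_spike_distribution(u$spike_times,
                                      swr[, c("start", "end")])
        sw_rows[[length(sw_rows) + 1]] <-
          tibble(unit_id = u$unit_id, mean_swr_rate = sd_$mean_rate,
                 p0 = sd_$probabilities$probability[1])
      }
    }
  }
  res$theta_phase <- bind_rows(th_rows)
  res$ripple_phase <- bind_rows(rp_rows)
  res$swr_participation <- bind_rows(sw_rows)

  ## --- precession on zigzag 1D fields -------------------------------------
  prec_rows <- list()
  zz <- session_epochs(session, "zigzag")
  if (nrow(zz) > 0 && !is.null(theta_ph)) {
    geom <- zigzag_geometry()
    linear <- linearize_zigzag(session$track, geom)
    lin_zz <- restrict(linear, zz)
    sp_zz <- restrict(speed, zz)
    pos_fun <- stats::approxfun(linear$time[linear$valid],
                                linear$pos[linear$valid], rule = 2)
    set.seed(perm_seed)
    for (u in session$units) {
      st <- restrict(u$spike_times, zz)
      if (length(st) < 10) next
      for (dirn in c("northbound", "southbound")) {
        m <- tryCatch(
          linear_rate_map(st, lin_zz, sp_zz, geom, direction = dirn),
          error = function(e) NULL)
        if (is.null(m)) next
        flds <- detect_fields_1d(m)
        if (nrow(flds) == 0) next
        for (fi in seq_len(nrow(flds))) {
          fs_ <- flds$start[fi]; fe_ <- flds$end[fi]
          spos <- pos_fun(st)
          sph <- spike_phase_or_na(st, theta_ph)
          sdir <- linear$direction[
            pmax(1, findInterval(st, linear$time))]
          infield <- !is.na(spos) & !is.na(sph) & spos >= fs_ &
            spos <= fe_ & !is.na(sdir) & sdir == dirn
          if (sum(infield) < 10) next
          relpos <- (spos[infield] - fs_) / (fe_ - fs_)
          if (dirn == "southbound") relpos <- 1 - relpos
          fit <- precession_fit(sph[infield], relpos)
          prec_rows[[length(prec_rows) + 1]] <- tibble(
            unit_id = u$unit_id, direction = dirn,
            field_id = flds$field_id[fi], field_start = fs_,
            field_end = fe_, n_spikes = fit$n, slope = fit$slope,
            r = fit$r, p = fit$p)
        }
      }
    }
  }
  res$precession <- bind_rows(prec_rows)
  res$errors <- tibble(error = errors)

  out <- structure(res, class = "session_results")
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (!is.data.frame(x) || nrow(x) == 0 && ncol(x) == 0) next
    drop <- map_lgl(x, is.list)
    readr::write_csv(x[, !drop, drop = FALSE],
                     file.path(out_dir, paste0(nm, ".csv")))
  }
  invisible(out_dir)
}

#' @export
print.session_results <- function(x, ...) {
  cat("<session_results>\n")
  for (nm in names(x)) {
    if (is.data.frame(x[[nm]]))
      cat(sprintf("  $%s: %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
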