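# Displacement/slippage kinematics, event segmentation and the descriptive
# summaries of tracking behavior.

#' Motion-aligned displacement and slippage series for one trial
#'
#' Computes the two visual-stabilization measures on the trial's sample
#' clock: displacement `(gaze_x - target_x) * sign(direction)` (deg,
#' positive = gaze ahead of the target in the motion direction) and
#' slippage `(gaze_v - target_v) * sign(direction)` (deg/s, positive =
#' gaze faster than the target). During occlusion the target is the
#' extrapolated ramp: the invisible target keeps moving. Samples with
#' invalid gaze (or undefined velocity) are `NA`.
#'
#' @param samples One trial's sample tibble: `t`, `gaze_x`, `target_x`,
#'   `target_v` (or a `schedule` to derive the target from), optionally
#'   `valid`, `phase`, `in_saccade`.
#' @param schedule One-row schedule for the trial (provides direction,
#'   phase boundaries, and the exact target ramp).
#' @param gaze_v Gaze velocity vector (deg/s); estimated with
#'   [estimate_velocity()] if omitted. Pass `samples$gaze_v` to use the
#'   generator's noiseless model velocity.
#' @param anchor Zero point of `t_rel`: `"launch"` or `"occlusion"`.
#' @return Tibble with `t`, `t_rel`, `displacement`, `slippage`, `phase`,
#'   `in_saccade`, `valid`.
#' @export
stabilization_series <- function(samples, schedule, gaze_v = NULL,
                                 anchor = c("launch", "occlusion")) {
  anchor <- match.arg(anchor)
  dir <- schedule$direction
  t <- samples$t
  target_x <- col_or(samples, "target_x", target_position_at(schedule, t))
  target_v <- col_or(samples, "target_v",
    ifelse(t < schedule$t_launch, 0, schedule$target_velocity))
  if (is.null(gaze_v)) gaze_v <- estimate_velocity(samples)
  if (length(gaze_v) != length(t))
    stop_input("gaze_v length (%d) does not match the sample clock (%d)",
               length(gaze_v), length(t))
  valid <- col_or(samples, "valid", rep(TRUE, length(t)))

  disp <- (samples$gaze_x - target_x) * dir
  slip <- (gaze_v - target_v) * dir
  disp[!valid] <- NA_real_
  slip[!valid] <- NA_real_

  phase <- col_or(samples, "phase") %||% {
    p <- rep("reappearance", length(t))
    p[t < schedule$t_launch] <- "prelaunch"
    p[t >= schedule$t_launch & t < schedule$t_occlusion_onset] <- "visible"
    if (isTRUE(schedule$occluded))
      p[t >= schedule$t_occlusion_onset & t < schedule$t_reappear] <-
        "occluded"
    p
  }
  t0 <- if (anchor == "launch") schedule$t_launch else
    schedule$t_occlusion_onset
  tibble::tibble(
    t = t, t_rel = t - t0, displacement = disp, slippage = slip,
    phase = phase,
    in_saccade = col_or(samples, "in_saccade", rep(NA, length(t))),
    valid = valid)
}

#' Per-trial features at target reappearance
#'
#' Absolute displacement `d` and absolute slippage `s` evaluated at the
#' sample nearest reappearance onset (not averaged over the brief probe
#' window). If no valid sample lies within 25 ms of reappearance the
#' features are marked missing with a reason, and the trial is later
#' excluded from the likelihood.
#'
#' @param series A [stabilization_series()] tibble.
#' @param schedule The trial's schedule row.
#' @param outcome 0/1 discrimination outcome (may be `NA`).
#' @return One-row tibble: `participant_id`, `trial_id`, `d`, `s`,
#'   `outcome`, `occlusion_duration`, `missing`, `missing_reason`.
#' @export
features_at_reappearance <- function(series, schedule, outcome = NA) {
  if (max(series$t) < schedule$t_reappear - 1e-9)
    stop_input("series ends at %.3f s, before reappearance at %.3f s",
               max(series$t), schedule$t_reappear)
  dt_re <- abs(series$t - schedule$t_reappear)
  ok <- series$valid & !is.na(series$displacement) & !is.na(series$slippage)
  cand <- which(ok & dt_re <= 0.025)
  if (length(cand) == 0) {
    return(tibble::tibble(
      participant_id = schedule$participant_id,
      trial_id = schedule$trial_id,
      d = NA_real_, s = NA_real_, outcome = outcome,
      occlusion_duration = schedule$occlusion_duration,
      missing = TRUE,
      missing_reason = "no valid sample within 25 ms of reappearance"))
  }
  i <- cand[which.min(dt_re[cand])]
  tibble::tibble(
    participant_id = schedule$participant_id,
    trial_id = schedule$trial_id,
    d = abs(series$displacement[i]),
    s = abs(series$slippage[i]),
    outcome = outcome,
    occlusion_duration = schedule$occlusion_duration,
    missing = FALSE, missing_reason = NA_character_)
}

#' Segment a gaze trace into saccades and pursuit/fixation
#'
#' A velocity-threshold stand-in for a full event classifier: contiguous
#' runs with absolute gaze velocity above `velocity_threshold` for at least
#' `min_duration` are saccades, everything else is pursuit-or-fixation.
#' Externally produced event tables can be passed through unchanged via
#' `events`.
#'
#' @param samples Trial sample tibble (`t`, plus velocity source).
#' @param schedule Trial schedule row (for landing displacement against the
#'   extrapolated target and for phase labels).
#' @param gaze_v Gaze velocity; defaults to `samples$gaze_v`, else
#'   estimated.
#' @param velocity_threshold Saccade speed threshold, deg/s (default 60).
#' @param min_duration Minimum saccade duration, s (default 0.015).
#' @param events Optional pre-computed event tibble; returned as-is.
#' @return Tibble of events: `kind`, `t_start`, `t_end`,
#'   `landing_displacement` (deg, motion-aligned, `NA` for non-saccades),
#'   `phase` (phase at event end).
#' @export
segment_events <- function(samples, schedule, gaze_v = NULL,
                           velocity_threshold = 60, min_duration = 0.015,
                           events = NULL) {
  if (!is.null(events)) return(events)
  if (is.null(gaze_v)) gaze_v <- col_or(samples, "gaze_v") %||% estimate_velocity(samples)
  t <- samples$t
  n <- length(t)
  fast <- !is.na(gaze_v) & abs(gaze_v) > velocity_threshold
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  is_sac <- r$values & (t[ends] - t[starts]) >= min_duration - 1e-9
  # the speed threshold clips the low-velocity tails of the saccade
  # waveform: extend each saccade run by one sample on both sides so the
  # boundaries approach the true onset/offset and the landing is measured
  # with the eye settled; neighbouring events shrink accordingly
  for (k in which(is_sac)) {
    if (starts[k] > 1) {
      starts[k] <- starts[k] - 1L
      if (k > 1) ends[k - 1] <- min(ends[k - 1], starts[k] - 1L)
    }
    if (ends[k] < n) {
      ends[k] <- ends[k] + 1L
      if (k < length(starts)) starts[k + 1] <- starts[k + 1] + 1L
    }
  }
  keep <- starts <= ends & starts <= n
  rows <- list()
  dir <- schedule$direction
  for (k in which(keep)) {
    i0 <- starts[k]; i1 <- min(ends[k], n)
    land <- if (is_sac[k])
      (samples$gaze_x[i1] - target_position_at(schedule, t[i1])) * dir
    else NA_real_
    ph <- if ("phase" %in% names(samples)) samples$phase[i1] else NA_character_
    rows[[length(rows) + 1L]] <- tibble::tibble(
      kind = if (is_sac[k]) "saccade" else "pursuit_or_fixation",
      t_start = t[i0], t_end = t[i1],
      landing_displacement = land, phase = ph)
  }
  dplyr::bind_rows(rows)
}

#' Build an event table from per-sample saccade labels
#'
#' When per-sample saccade labels exist (the generator's `in_saccade`
#' column, or labels imported from an external classifier), events can be
#' built directly instead of re-detected: contiguous labelled runs become
#' saccades, with the landing measured at the first sample after the run
#' (eye settled). This avoids the detectability bias of the
#' velocity-threshold segmenter, which misses small, short saccades at
#' typical eye-tracker sampling rates.
#'
#' @param samples Trial sample tibble with `t`, `gaze_x`, `in_saccade` and
#'   optionally `phase`.
#' @param schedule The trial's schedule row.
#' @return Event tibble in the [segment_events()] format.
#' @export
events_from_labels <- function(samples, schedule) {
  lab <- col_or(samples, "in_saccade")
  if (is.null(lab))
    stop_input("samples have no in_saccade labels")
  t <- samples$t
  n <- length(t)
  r <- rle(isTRUE_vec(lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rows <- list()
  dir <- schedule$direction
  for (k in seq_along(r$values)) {
    i1 <- if (r$values[k]) min(ends[k] + 1L, n) else ends[k]
    land <- if (r$values[k])
      (samples$gaze_x[i1] - target_position_at(schedule, t[i1])) * dir
    else NA_real_
    ph <- if ("phase" %in% names(samples)) samples$phase[i1] else NA_character_
    rows[[k]] <- tibble::tibble(
      kind = if (r$values[k]) "saccade" else "pursuit_or_fixation",
      t_start = t[starts[k]], t_end = t[i1],
      landing_displacement = land, phase = ph)
  }
  dplyr::bind_rows(rows)
}

#' Saccade landing-displacement summary
#'
#' Per-participant median landing displacement for a phase, plus the
#' cross-participant mean with a percentile-bootstrap CI. If both phases
#' are present, the paired visible-vs-occluded difference of medians is
#' attached.
#'
#' @param events Event tibble with `participant_id`, `kind`, `phase`,
#'   `landing_displacement`.
#' @param phase Phase to summarise (`"occluded"` or `"visible"`).
#' @param n_resamples Bootstrap resamples (default 5000).
#' @return List: `per_participant` (tibble of medians), `summary`
#'   (bootstrap mean/CI), and `paired_difference` when computable.
#' @export
landing_displacement_summary <- function(events, phase = "occluded",
                                         n_resamples = 5000) {
  sac <- events[events$kind == "saccade", , drop = FALSE]
  med_by <- function(ph) {
    sub <- sac[sac$phase == ph, , drop = FALSE]
    dplyr::summarise(dplyr::group_by(sub, .data$participant_id),
                     median_landing = median(.data$landing_displacement),
                     n_saccades = dplyr::n(), .groups = "drop")
  }
  per <- med_by(phase)
  if (nrow(per) == 0)
    stop_input("no saccades in phase '%s'", phase)
  dropped <- setdiff(unique(sac$participant_id), per$participant_id)
  if (length(dropped) > 0)
    warning(sprintf("participants without '%s' saccades omitted: %s",
                    phase, paste(dropped, collapse = ", ")))
  res <- list(per_participant = per,
              summary = bootstrap_ci(per$median_landing, n_resamples))
  other <- setdiff(c("visible", "occluded"), phase)
  per2 <- med_by(other)
  common <- intersect(per$participant_id, per2$participant_id)
  if (length(common) >= 2) {
    a <- per$median_landing[match(common, per$participant_id)]
    b <- per2$median_landing[match(common, per2$participant_id)]
    diffs <- if (phase == "occluded") a - b else b - a
    res$paired_difference <- bootstrap_ci(diffs, n_resamples)
  }
  res
}

#' Smooth-pursuit decay summary during occlusion
#'
#' For each participant: the median absolute gaze speed `t_probe` seconds
#' into occlusion (one value per qualifying trial, i.e. occlusions lasting
#' at least `t_probe`) divided by the median speed in the first 100 ms of
#' occlusion, both over pursuit/fixation samples only (saccade samples are
#' excluded for this pursuit-specific summary). Cross-participant mean
#' with bootstrap CI.
#'
#' @param samples Long sample tibble (`participant_id`, `trial_id`, `t`,
#'   `gaze_v`, `in_saccade`).
#' @param trials Schedule tibble (needs `t_occlusion_onset`,
#'   `occlusion_duration`, `occluded`).
#' @param t_probe Probe time into occlusion, s (default 0.6).
#' @param n_resamples Bootstrap resamples.
#' @return List: `per_participant` (ratios), `summary` (mean/CI).
#' @export
pursuit_decay_summary <- function(samples, trials, t_probe = 0.6,
                                  n_resamples = 5000) {
  qual <- trials[trials$occluded & trials$occlusion_duration >= t_probe, ,
                 drop = FALSE]
  if (nrow(qual) == 0)
    stop_input("no occlusions lasting at least %g s", t_probe)
  ratios <- list()
  for (pid in unique(qual$participant_id)) {
    tq <- qual[qual$participant_id == pid, , drop = FALSE]
    probe_speed <- rep(NA_real_, nrow(tq))
    onset_speeds <- list()
    for (k in seq_len(nrow(tq))) {
      tr <- tq[k, ]
      sub <- samples[samples$participant_id == pid &
                       samples$trial_id == tr$trial_id, , drop = FALSE]
      pursuit <- !isTRUE_vec(sub$in_saccade)
      rel <- sub$t - tr$t_occlusion_onset
      onset_idx <- which(rel >= 0 & rel < 0.1 & pursuit)
      onset_speeds[[k]] <- abs(sub$gaze_v[onset_idx])
      cand <- which(pursuit & abs(rel - t_probe) <= 0.5 / 120)
      if (length(cand) > 0)
        probe_speed[k] <- abs(sub$gaze_v[cand[which.min(
          abs(rel[cand] - t_probe))]])
    }
    onset_med <- median(unlist(onset_speeds), na.rm = TRUE)
    probe_med <- median(probe_speed, na.rm = TRUE)
    if (is.finite(onset_med) && onset_med > 0 && is.finite(probe_med))
      ratios[[as.character(pid)]] <- probe_med / onset_med
  }
  if (length(ratios) == 0)
    stop_input("pursuit decay summary undefined: no qualifying data")
  per <- tibble::tibble(participant_id = names(ratios),
                        speed_ratio = unname(unlist(ratios)))
  list(per_participant = per,
       summary = if (nrow(per) >= 2)
         bootstrap_ci(per$speed_ratio, n_resamples)
       else tibble::tibble(mean = per$speed_ratio, lower = NA_real_,
                           upper = NA_real_, n = 1,
                           n_resamples = n_resamples))
}

# Treat NA as FALSE elementwise (for optional logical columns).
isTRUE_vec <- function(x) !is.na(x) & x

#' Centred rolling mean
#'
#' Moving average over a time window, excluding undefined samples from each
#' average; edges use the available partial window.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param window Window length in seconds (default 0.1).
#' @param sample_rate Sampling rate, Hz.
#' @return Smoothed numeric vector of the same length.
#' @export
rolling_mean <- function(x, window = 0.1, sample_rate = 120) {
  w <- max(1, round(window * sample_rate))
  zoo::rollapply(x, width = w, FUN = function(z) {
    z <- z[!is.na(z)]
    if (length(z) == 0) NA_real_ else mean(z)
  }, partial = TRUE, align = "center")
}

#' Pursuit gain series
#'
#' Pointwise gaze velocity divided by target velocity; undefined (NA)
#' wherever the target is stationary (pre-launch) or gaze velocity is
#' undefined.
#'
#' @param gaze_v Gaze velocity, deg/s.
#' @param target_v Target velocity, deg/s.
#' @return Numeric gain vector.
#' @export
gain_series <- function(gaze_v, target_v) {
  out <- gaze_v / target_v
  out[target_v == 0] <- NA_real_
  out
}

#' Trial features for a whole simulated cohort
#'
#' Convenience wrapper running [stabilization_series()] and
#' [features_at_reappearance()] over every trial of a
#' [simulate_experiment()] result (or equivalently structured data).
#'
#' @param samples Long sample tibble.
#' @param trials Schedule tibble with an `outcome` column.
#' @param use_model_velocity If `TRUE` use the generator's `gaze_v` column;
#'   otherwise estimate velocity from the (noisy) `gaze_x`.
#' @return Feature tibble, one row per trial.
#' @export
cohort_features <- function(samples, trials, use_model_velocity = FALSE) {
  rows <- vector("list", nrow(trials))
  key <- paste(samples$participant_id, samples$trial_id)
  idx <- split(seq_len(nrow(samples)), key)
  for (k in seq_len(nrow(trials))) {
    tr <- trials[k, ]
    sub <- samples[idx[[paste(tr$participant_id, tr$trial_id)]], ,
                   drop = FALSE]
    gv <- if (use_model_velocity) sub$gaze_v else estimate_velocity(sub)
    st <- stabilization_series(sub, tr, gaze_v = gv)
    rows[[k]] <- features_at_reappearance(st, tr, outcome = tr$outcome)
  }
  dplyr::bind_rows(rows)
}
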