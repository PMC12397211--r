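# The derived tracking-quality metric evaluated continuously over
# occlusion.

#' Tracking quality over one trial's occlusion
#'
#' Evaluates `Q(t) = F(|displacement(t)|, |slippage(t)|)` pointwise over
#' the occluded samples of a trial, using fitted (or supplied) participant
#' parameters. Saccadic samples are included: drops in quality during
#' saccades (via their large instantaneous slippage) are part of the
#' metric. Chance level and lapse rate do not enter `Q` by construction.
#'
#' @param stabilization A [stabilization_series()] tibble (anchor either
#'   way; `t_rel` is re-anchored to occlusion onset in the output when an
#'   occluded phase exists).
#' @param params Fitted [model_params()] for the participant. Missing
#'   parameters are an error directing to [fit_participant()].
#' @param phases Phases to evaluate (default `"occluded"`).
#' @return Tibble with `t_rel` (s since occlusion onset), `Q`, `phase`,
#'   `in_saccade`.
#' @export
quality_series <- function(stabilization, params, phases = "occluded") {
  if (missing(params) || is.null(params))
    stop_input(paste0("no model parameters supplied: fit them with ",
                      "fit_participant() (or pass known parameters)"))
  stopifnot(inherits(params, "occlu_params"))
  sub <- stabilization[stabilization$phase %in% phases, , drop = FALSE]
  if (nrow(sub) == 0)
    return(tibble::tibble(t_rel = numeric(0), Q = numeric(0),
                          phase = character(0), in_saccade = logical(0)))
  t0 <- min(sub$t_rel)
  tibble::tibble(
    t_rel = sub$t_rel - t0,
    Q = tracking_quality(abs(sub$displacement), abs(sub$slippage), params),
    phase = sub$phase,
    in_saccade = sub$in_saccade)
}

#' Aggregate quality curves across trials and participants
#'
#' Builds the time-resolved tracking-quality curves: per time point since
#' occlusion onset, the participant-wise mean `Q` over the trials still
#' occluded at that time (occlusion durations vary, so the denominator
#' shrinks), smoothed with a centred rolling mean; plus a parallel curve
#' computed with cohort-mean parameters over all trials. Curves are
#' truncated where fewer than `min_trials` trials remain.
#'
#' @param samples Long sample tibble from [simulate_experiment()] (or
#'   preprocessed data with the same columns).
#' @param trials Schedule tibble.
#' @param fits Per-participant parameter tibble (e.g. the full-model rows
#'   of [fit_cohort()]): columns `participant_id`, `beta_d`, `beta_s`,
#'   `lapse`.
#' @param params_mean Cohort-mean [model_params()]; computed from `fits`
#'   if omitted.
#' @param window Rolling-mean window, s (default 0.1). Use `0` (or one
#'   sample) for unsmoothed means.
#' @param min_trials Truncation threshold on the surviving-trial count.
#' @param use_model_velocity Velocity source, as in [cohort_features()].
#' @param phases Phase selector passed to [quality_series()].
#' @return Tibble of curves: `curve_id` (participant or `"mean_params"`),
#'   `t_rel`, `Q_mean`, `n_trials`.
#' @export
aggregate_quality <- function(samples, trials, fits, params_mean = NULL,
                              window = 0.1, min_trials = 5,
                              use_model_velocity = FALSE,
                              phases = "occluded") {
  occ <- trials[trials$occluded, , drop = FALSE]
  if (nrow(occ) == 0) stop_input("no occlusion trials to aggregate")
  if (is.null(params_mean))
    params_mean <- model_params(mean(fits$beta_d), mean(fits$beta_s),
                                mean(fits$lapse))
  sample_rate <- 1 / median(diff(samples$t[samples$participant_id ==
                                             occ$participant_id[1] &
                                             samples$trial_id ==
                                             occ$trial_id[1]]))
  key <- paste(samples$participant_id, samples$trial_id)
  idx <- split(seq_len(nrow(samples)), key)

  per_trial <- vector("list", nrow(occ))
  for (k in seq_len(nrow(occ))) {
    tr <- occ[k, ]
    sub <- samples[idx[[paste(tr$participant_id, tr$trial_id)]], ,
                   drop = FALSE]
    gv <- if (use_model_velocity) sub$gaze_v else estimate_velocity(sub)
    st <- stabilization_series(sub, tr, gaze_v = gv, anchor = "occlusion")
    prow <- fits[fits$participant_id == tr$participant_id, , drop = FALSE]
    if (nrow(prow) == 0)
      stop_input("no fitted parameters for participant %s: run fit_cohort()",
                 as.character(tr$participant_id))
    pp <- model_params(prow$beta_d[1], prow$beta_s[1], prow$lapse[1])
    qs <- quality_series(st, pp, phases = phases)
    qm <- quality_series(st, params_mean, phases = phases)
    if (nrow(qs) == 0) next
    per_trial[[k]] <- tibble::tibble(
      participant_id = tr$participant_id,
      bin = round(qs$t_rel * sample_rate),
      Q = qs$Q, Q_meanpar = qm$Q)
  }
  long <- dplyr::bind_rows(per_trial)
  if (nrow(long) == 0) stop_input("no occluded samples found")

  smooth_curve <- function(df, col) {
    agg <- dplyr::summarise(dplyr::group_by(df, .data$bin),
                            Q_mean = mean(.data[[col]], na.rm = TRUE),
                            n_trials = sum(!is.na(.data[[col]])),
                            .groups = "drop")
    agg <- agg[order(agg$bin), ]
    agg <- agg[agg$n_trials >= min_trials, , drop = FALSE]
    if (nrow(agg) > 0 && window > 0)
      agg$Q_mean <- rolling_mean(agg$Q_mean, window, sample_rate)
    agg
  }

  curves <- list()
  for (pid in unique(long$participant_id)) {
    agg <- smooth_curve(long[long$participant_id == pid, , drop = FALSE],
                        "Q")
    if (nrow(agg) == 0) next
    curves[[length(curves) + 1L]] <- tibble::tibble(
      curve_id = as.character(pid), t_rel = agg$bin / sample_rate,
      Q_mean = agg$Q_mean, n_trials = agg$n_trials)
  }
  aggm <- smooth_curve(long, "Q_meanpar")
  curves[[length(curves) + 1L]] <- tibble::tibble(
    curve_id = "mean_params", t_rel = aggm$bin / sample_rate,
    Q_mean = aggm$Q_mean, n_trials = aggm$n_trials)
  dplyr::bind_rows(curves)
}
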