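# End-to-end configuration-driven pipeline with machine-readable outputs.

fmt_num <- function(x) {
  if (is.numeric(x)) signif(x, 9) else x
}

write_csv9 <- function(df, path) {
  df <- as.data.frame(lapply(df, fmt_num))
  write.csv(df, path, row.names = FALSE)
  path
}

#' Write / read the gaze sample CSV format
#'
#' One row per sample: `participant_id`, `trial_id`, `t` (s), `target_x`
#' (deg), `target_visible` (0/1), `gaze_x` (deg), `confidence` (0-1).
#' The reader shim also accepts minimal tables with `t`, `confidence` and
#' either `gaze_deg` or `gaze_px` (converted via [px_to_deg()] when
#' `units = "px"`).
#'
#' @param samples Long sample tibble.
#' @param path File path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_gaze_csv <- function(samples, path) {
  keep <- intersect(c("participant_id", "trial_id", "t", "target_x",
                      "target_visible", "gaze_x", "confidence"),
                    names(samples))
  df <- samples[, keep]
  df$target_visible <- as.integer(df$target_visible)
  invisible(write_csv9(df, path))
}

#' @rdname write_gaze_csv
#' @param units `"deg"` or `"px"` for the minimal-format gaze column.
#' @param screen_width_px,fov_deg Mapping constants for `units = "px"`.
#' @export
read_gaze_csv <- function(path, units = c("deg", "px"),
                          screen_width_px = 1920, fov_deg = 80) {
  units <- match.arg(units)
  df <- tibble::as_tibble(read.csv(path))
  if (!"gaze_x" %in% names(df)) {
    if ("gaze_deg" %in% names(df)) df$gaze_x <- df$gaze_deg
    else if ("gaze_px" %in% names(df))
      df$gaze_x <- px_to_deg(df$gaze_px, screen_width_px, fov_deg)
    else stop_input("no gaze_x / gaze_deg / gaze_px column in %s", path)
  } else if (units == "px") {
    df$gaze_x <- px_to_deg(df$gaze_x, screen_width_px, fov_deg)
  }
  if (!all(c("t", "confidence") %in% names(df)))
    stop_input("gaze CSV needs at least t and confidence columns")
  if ("target_visible" %in% names(df))
    df$target_visible <- df$target_visible > 0
  df
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys mirror the arguments of [experiment_config()],
#' [gaze_model_params()] and [model_params()] under the top-level keys
#' `experiment`, `gaze` and `outcome` (all optional; defaults fill in the
#' rest).
#'
#' @param path Path to a YAML config file.
#' @return List with elements `config`, `gaze_params`, `outcome_params`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("experiment", "gaze", "outcome"))
  if (length(bad) > 0)
    stop_input("unknown top-level config key(s): %s",
               paste(bad, collapse = ", "))
  exp_args <- raw$experiment %||% list()
  if (!is.null(exp_args$blocks))
    exp_args$blocks <- as.data.frame(do.call(rbind.data.frame,
                                             exp_args$blocks))
  check_keys <- function(args, fn, label) {
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad) > 0)
      stop_input("unknown %s config key(s): %s", label,
                 paste(bad, collapse = ", "))
  }
  check_keys(exp_args, experiment_config, "experiment")
  check_keys(raw$gaze %||% list(), gaze_model_params, "gaze")
  check_keys(raw$outcome %||% list(), model_params, "outcome")
  list(config = do.call(experiment_config, exp_args),
       gaze_params = do.call(gaze_model_params, raw$gaze %||% list()),
       outcome_params = do.call(model_params, raw$outcome %||% list()))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess -> features -> fit -> compare -> quality
#' in order, writes every stage's output as CSV into `out_dir`, and
#' returns a run manifest (config snapshot, seed, record counts, file
#' checksums, per-stage wall times). Re-running with the same config and
#' seed reproduces byte-identical outputs.
#'
#' @param config An [experiment_config()], or a path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master-seed override.
#' @param gaze_params,outcome_params Generator parameter objects (ignored
#'   when `config` is a YAML path providing them).
#' @param success_floor Participants with overall success rate below this
#'   are excluded from fitting (default 0.5).
#' @param confidence_threshold,max_gap Preprocessing settings.
#' @param variants Model variants to fit (default all seven).
#' @param verbose Log stage boundaries and exclusions at INFO level.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL,
                         gaze_params = gaze_model_params(),
                         outcome_params = model_params(),
                         success_floor = 0.5,
                         confidence_threshold = 0.8, max_gap = 0.1,
                         variants = "all", verbose = TRUE) {
  if (is.character(config)) {
    cc <- read_run_config(config)
    config <- cc$config
    gaze_params <- cc$gaze_params
    outcome_params <- cc$outcome_params
  }
  if (!is.null(seed)) {
    args <- unclass(config)
    args$occlusion_sampler <- NULL
    args$trials_total <- NULL
    args$seed <- as.integer(seed)
    config <- do.call(experiment_config, args)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage_times <- c()
  files <- c()
  tic <- function() proc.time()[["elapsed"]]
  exclusions <- list()

  # --- simulate -----------------------------------------------------------
  t0 <- tic()
  say("INFO [simulate] %d participants x %d trials, seed %d",
      config$n_participants, config$trials_total, config$seed)
  sim <- simulate_experiment(config, gaze_params, outcome_params)
  files["samples"] <- write_gaze_csv(sim$samples,
                                     file.path(out_dir, "gaze_samples.csv"))
  files["trials"] <- write_csv9(sim$trials,
                                file.path(out_dir, "trials.csv"))
  stage_times["simulate"] <- tic() - t0

  # --- preprocess + features ---------------------------------------------
  t0 <- tic()
  say("INFO [preprocess/features] confidence >= %g, gaps <= %g s",
      confidence_threshold, max_gap)
  key <- paste(sim$samples$participant_id, sim$samples$trial_id)
  idx <- split(seq_len(nrow(sim$samples)), key)
  feats <- vector("list", nrow(sim$trials))
  n_low_conf <- 0L
  for (k in seq_len(nrow(sim$trials))) {
    tr <- sim$trials[k, ]
    sub <- sim$samples[idx[[paste(tr$participant_id, tr$trial_id)]], ,
                       drop = FALSE]
    sub <- filter_confidence(sub, confidence_threshold)
    n_low_conf <- n_low_conf + attr(sub, "n_removed")
    sub <- interpolate_gaps(sub, max_gap)
    gv <- estimate_velocity(sub)
    st <- stabilization_series(sub, tr, gaze_v = gv)
    feats[[k]] <- features_at_reappearance(st, tr, outcome = tr$outcome)
  }
  features <- dplyr::bind_rows(feats)
  miss <- features[features$missing, , drop = FALSE]
  if (nrow(miss) > 0) {
    say("INFO [features] %d trial(s) excluded: missing features", nrow(miss))
    for (k in seq_len(nrow(miss)))
      exclusions[[length(exclusions) + 1L]] <- tibble::tibble(
        stage = "features", participant_id = miss$participant_id[k],
        trial_id = miss$trial_id[k], reason = miss$missing_reason[k])
  }
  files["features"] <- write_csv9(
    dplyr::rename(features[, c("participant_id", "trial_id", "d", "s",
                               "outcome", "occlusion_duration")],
                  d_deg = "d", s_deg_per_s = "s",
                  occlusion_s = "occlusion_duration"),
    file.path(out_dir, "trial_features.csv"))
  stage_times["features"] <- tic() - t0

  # --- fit + compare ------------------------------------------------------
  t0 <- tic()
  fit_feats <- features[!features$missing &
                          features$occlusion_duration > 0, , drop = FALSE]
  rates <- tapply(fit_feats$outcome, fit_feats$participant_id, mean)
  low <- names(rates)[rates < success_floor]
  if (length(low) > 0) {
    say("INFO [fit] excluding %d participant(s) below %g success: %s",
        length(low), success_floor, paste(low, collapse = ", "))
    for (p in low)
      exclusions[[length(exclusions) + 1L]] <- tibble::tibble(
        stage = "fit", participant_id = as.integer(p), trial_id = NA_integer_,
        reason = sprintf("overall success rate %.2f below floor %.2f",
                         rates[[p]], success_floor))
    fit_feats <- fit_feats[!fit_feats$participant_id %in% as.integer(low), ,
                           drop = FALSE]
  }
  say("INFO [fit] fitting %s variants for %d participants",
      if (identical(variants, "all")) "all 7" else length(variants),
      length(unique(fit_feats$participant_id)))
  fits <- fit_cohort(fit_feats, variants = variants)
  files["fits"] <- write_csv9(fits, file.path(out_dir, "fits.csv"))
  comparison <- compare_models(fits)
  files["comparison"] <- write_csv9(comparison,
                                    file.path(out_dir, "comparison.csv"))
  stage_times["fit"] <- tic() - t0

  # --- descriptive summaries + binned accuracy ---------------------------
  t0 <- tic()
  full_fits <- fits[fits$variant == "full", , drop = FALSE]
  params_mean <- model_params(mean(full_fits$beta_d),
                              mean(full_fits$beta_s),
                              mean(full_fits$lapse))
  binned <- binned_accuracy(fit_feats, params_mean = params_mean)
  files["binned"] <- write_csv9(binned,
                                file.path(out_dir, "binned_accuracy.csv"))
  summaries <- tibble::tibble(
    statistic = c("success_rate_occlusion", "beta_d_mean", "beta_s_mean",
                  "lapse_mean"),
    value = c(mean(fit_feats$outcome), params_mean$beta_d,
              params_mean$beta_s, params_mean$lapse))
  files["summaries"] <- write_csv9(summaries,
                                   file.path(out_dir, "summaries.csv"))
  stage_times["summaries"] <- tic() - t0

  # --- quality curves -----------------------------------------------------
  t0 <- tic()
  say("INFO [quality] aggregating occlusion quality curves")
  curves <- aggregate_quality(sim$samples, sim$trials, full_fits,
                              params_mean = params_mean)
  files["quality"] <- write_csv9(curves,
                                 file.path(out_dir, "quality_curves.csv"))
  stage_times["quality"] <- tic() - t0

  excl_df <- if (length(exclusions) > 0) dplyr::bind_rows(exclusions)
  else tibble::tibble(stage = character(0), participant_id = integer(0),
                      trial_id = integer(0), reason = character(0))
  files["exclusions"] <- write_csv9(excl_df,
                                    file.path(out_dir, "exclusions.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("occlutrack")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(unclass(config)),
                                     "occlusion_sampler")],
    gaze_params = unclass(gaze_params),
    outcome_params = unclass(outcome_params),
    n_participants = config$n_participants,
    n_trials = nrow(sim$trials),
    n_samples = nrow(sim$samples),
    n_low_confidence_samples = n_low_conf,
    n_excluded = nrow(excl_df),
    stage_seconds = as.list(stage_times),
    files = as.list(files),
    md5 = as.list(setNames(unname(tools::md5sum(unname(files))),
                           names(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("INFO [done] outputs in %s", out_dir)
  invisible(manifest)
}
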