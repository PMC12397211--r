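# Shared fixtures, built lazily and cached for the session so expensive
# simulations run once across test files.

.fixture_env <- new.env(parent = emptyenv())

# The default study-scale cohort: 9 participants x 120 trials with all
# generator defaults (the conditions the analysis targets).
default_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- experiment_config(seed = 1)
    .fixture_env$cohort <- list(
      config = cfg,
      sim = simulate_experiment(cfg))
  }
  .fixture_env$cohort
}

# Full-model fits on the default cohort's occlusion trials (generator-true
# features).
default_fits <- function() {
  if (is.null(.fixture_env$fits)) {
    co <- default_cohort()
    occ <- co$sim$trials[co$sim$trials$occluded, ]
    .fixture_env$fits <- fit_cohort(occ, variants = "full")
  }
  .fixture_env$fits
}

# A single deterministic pursuit-only trial: noise, saccades, drift and
# participant variability all off; occlusion grid-aligned.
deterministic_trace <- function(target_velocity = 30, visible_duration = 0.5,
                                occlusion_duration = 0.7, gain = 0.95,
                                decay = TRUE) {
  cfg <- experiment_config(seed = 1)
  gp <- gaze_model_params(
    pursuit_gain_visible = gain,
    pursuit_decay_rate = if (decay) -log(0.62) / 0.6 else 0,
    saccades_enabled = FALSE, noise_enabled = FALSE,
    position_noise_sd = 0, low_confidence_rate = 0,
    occlusion_drift_sd = 0, anticipatory_drift_speed = 0)
  sch <- trial_schedule(direction = 1, target_velocity = target_velocity,
                        visible_duration = visible_duration,
                        occlusion_duration = occlusion_duration)
  list(schedule = sch, config = cfg, gaze_params = gp,
       trace = simulate_gaze(sch, cfg, gp, seed = 5))
}

# Random trial-feature tables for likelihood tests.
random_features <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    d = abs(rnorm(n, 2, 2)),
    s = abs(rnorm(n, 10, 10)),
    outcome = rbinom(n, 1, 0.7))
}
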