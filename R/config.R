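#' Experiment configuration
#'
#' Defines the design of the occluded-tracking experiment that the
#' synthetic-data generator emulates: a target launched from roughly 27 deg
#' eccentricity runs at a constant, trial-randomized velocity (uniform
#' 22.5-45 deg/s), is visible for a randomized 0.2-1 s, occluded for a
#' randomized duration (median 0.53 s, mean 0.58 s, at most 1.9 s), and
#' reappears for a 0.05 s discrimination probe. 120 trials split into four
#' blocks: one training block without occlusion and three occlusion blocks.
#'
#' @param n_participants Cohort size (default 9, the number of analyzed
#'   participants the design targets).
#' @param blocks Data frame with columns `n_trials` and `occluded` (one row
#'   per block). Default: 4 blocks of 30 trials, the first without
#'   occlusion.
#' @param sample_rate Gaze sampling rate, Hz.
#' @param velocity_range Target speed interval, deg/s.
#' @param visible_motion_range Visible-motion duration interval, s.
#' @param occlusion_max Maximum occlusion duration, s.
#' @param occlusion_median_target,occlusion_mean_target Calibration targets
#'   for the occlusion-duration sampler, s.
#' @param reappearance_duration Probe duration, s.
#' @param prelaunch_duration Stationary period before launch, s.
#' @param start_eccentricity Unsigned launch eccentricity, deg.
#' @param seed Master seed for all generator randomness.
#' @return An `experiment_config` list with a calibrated
#'   `occlusion_sampler` attached.
#' @export
experiment_config <- function(n_participants = 9,
                              blocks = NULL,
                              sample_rate = 120,
                              velocity_range = c(22.5, 45.0),
                              visible_motion_range = c(0.2, 1.0),
                              occlusion_max = 1.9,
                              occlusion_median_target = 0.53,
                              occlusion_mean_target = 0.58,
                              reappearance_duration = 0.05,
                              prelaunch_duration = 1.0,
                              start_eccentricity = 27,
                              seed = 1L) {
  if (is.null(blocks))
    blocks <- data.frame(n_trials = rep(30L, 4),
                         occluded = c(FALSE, TRUE, TRUE, TRUE))
  if (!all(c("n_trials", "occluded") %in% names(blocks)))
    stop_input("blocks must have columns n_trials and occluded")
  if (any(blocks$n_trials < 1))
    stop_input("every block needs at least one trial")
  if (!(velocity_range[1] > 0 && velocity_range[1] <= velocity_range[2]))
    stop_input("velocity_range must be a positive ordered interval")
  if (!(visible_motion_range[1] > 0 &&
          visible_motion_range[1] <= visible_motion_range[2]))
    stop_input("visible_motion_range must be a positive ordered interval")
  if (!(occlusion_median_target < occlusion_mean_target &&
          occlusion_mean_target < occlusion_max))
    stop_input("need occlusion median (%g) < mean (%g) < max (%g)",
               occlusion_median_target, occlusion_mean_target, occlusion_max)
  # Feasibility of the midpoint rule: the slowest trial must be able to stay
  # on the launch side for at least the minimum visible duration.
  if (velocity_range[1] * visible_motion_range[1] >= start_eccentricity)
    stop_input(paste0(
      "infeasible config: minimum visible duration x minimum speed (%g deg) ",
      "reaches the midpoint from %g deg eccentricity"),
      velocity_range[1] * visible_motion_range[1], start_eccentricity)

  cfg <- list(
    n_participants = as.integer(n_participants),
    blocks = blocks,
    trials_total = sum(blocks$n_trials),
    sample_rate = sample_rate,
    velocity_range = velocity_range,
    visible_motion_range = visible_motion_range,
    occlusion_max = occlusion_max,
    occlusion_median_target = occlusion_median_target,
    occlusion_mean_target = occlusion_mean_target,
    reappearance_duration = reappearance_duration,
    prelaunch_duration = prelaunch_duration,
    start_eccentricity = start_eccentricity,
    seed = as.integer(seed))
  cfg$occlusion_sampler <- calibrate_occlusion_sampler(
    occlusion_median_target, occlusion_mean_target, occlusion_max)
  structure(cfg, class = "experiment_config")
}

#' Gaze-behavior parameters of the synthetic generator
#'
#' Controls the simulated oculomotor behavior: smooth pursuit gain while the
#' target is visible, exponential pursuit decay during occlusion (default
#' rate calibrated so pursuit speed 600 ms into occlusion is 62% of its
#' occlusion-onset value: `-log(0.62)/0.6`), displacement-triggered
#' saccades whose landing point is drawn relative to the (possibly
#' extrapolated) target -- around +1.5 deg ahead during occlusion, around
#' -0.26 deg when visible -- pre-launch anticipatory drift with return
#' saccades, measurement noise, and confidence dropouts.
#'
#' @param pursuit_gain_visible Pursuit velocity gain on the visible target,
#'   in (0, 1.2].
#' @param pursuit_decay_rate Exponential decay rate of occluded pursuit
#'   speed, 1/s.
#' @param saccade_trigger_threshold Absolute predicted displacement (deg)
#'   that triggers a corrective saccade.
#' @param landing_displacement_occluded,landing_displacement_visible
#'   `c(mean, sd)` of the normal law of saccade landing displacement (deg,
#'   motion-aligned: positive = ahead of the target) per phase.
#' @param saccade_latency Sensorimotor delay between the displacement
#'   threshold being crossed and saccade onset, s (default 0.2, a typical
#'   saccadic reaction time). Displacement keeps growing during this delay,
#'   so corrective saccades overshoot the trigger threshold as real ones
#'   do.
#' @param saccade_refractory Minimum interval between the end of one
#'   saccade and the next trigger evaluation, s.
#' @param launch_latency Pursuit onset latency after target launch, s.
#' @param anticipatory_drift_speed Pre-launch drift speed toward the coming
#'   motion direction, deg/s.
#' @param anticipatory_drift_amplitude Drift excursion (deg) at which a
#'   return saccade is made back to the stationary target.
#' @param occlusion_drift_sd During occlusion the participant's internal
#'   estimate of the invisible target's position drifts away from the true
#'   ramp at a per-trial rate drawn from Normal(0, `occlusion_drift_sd`)
#'   deg/s. Saccade triggering and landing operate on the estimated
#'   target, so true displacement degrades with occluded time even though
#'   corrective saccades keep firing -- the mechanism behind the decaying
#'   tracking-quality curve. Set to 0 for a perfectly informed
#'   extrapolator.
#' @param participant_gain_sd,participant_decay_sd,participant_threshold_sd
#'   Between-participant variability: each simulated participant gets a
#'   pursuit gain drawn from Normal(`pursuit_gain_visible`, gain_sd)
#'   (truncated to (0, 1.2]), a decay rate scaled by a lognormal factor
#'   with log-sd `decay_sd`, and a trigger threshold from
#'   Normal(`saccade_trigger_threshold`, threshold_sd) truncated below at
#'   1 deg. Set to 0 for a homogeneous cohort.
#' @param position_noise_sd Gaussian measurement noise on gaze position,
#'   deg.
#' @param low_confidence_rate i.i.d. per-sample probability of a
#'   low-confidence (< 0.8) sample.
#' @param saccades_enabled,noise_enabled Switches used by tests to isolate
#'   the deterministic pursuit kinematics.
#' @return A `gaze_model_params` list.
#' @export
gaze_model_params <- function(pursuit_gain_visible = 0.95,
                              pursuit_decay_rate = -log(0.62) / 0.6,
                              saccade_trigger_threshold = 2.0,
                              landing_displacement_occluded = c(1.5, 1.0),
                              landing_displacement_visible = c(-0.26, 0.7),
                              saccade_latency = 0.2,
                              saccade_refractory = 0.15,
                              launch_latency = 0.12,
                              anticipatory_drift_speed = 2.0,
                              anticipatory_drift_amplitude = 1.0,
                              occlusion_drift_sd = 3.0,
                              participant_gain_sd = 0.05,
                              participant_decay_sd = 0.2,
                              participant_threshold_sd = 0.5,
                              position_noise_sd = 0.15,
                              low_confidence_rate = 0.01,
                              saccades_enabled = TRUE,
                              noise_enabled = TRUE) {
  if (!(pursuit_gain_visible > 0 && pursuit_gain_visible <= 1.2))
    stop_input("pursuit_gain_visible must be in (0, 1.2]")
  if (pursuit_decay_rate < 0) stop_input("pursuit_decay_rate must be >= 0")
  if (position_noise_sd < 0) stop_input("position_noise_sd must be >= 0")
  structure(list(
    pursuit_gain_visible = pursuit_gain_visible,
    pursuit_decay_rate = pursuit_decay_rate,
    saccade_trigger_threshold = saccade_trigger_threshold,
    landing_displacement_occluded = landing_displacement_occluded,
    landing_displacement_visible = landing_displacement_visible,
    saccade_latency = saccade_latency,
    saccade_refractory = saccade_refractory,
    launch_latency = launch_latency,
    anticipatory_drift_speed = anticipatory_drift_speed,
    anticipatory_drift_amplitude = anticipatory_drift_amplitude,
    occlusion_drift_sd = occlusion_drift_sd,
    participant_gain_sd = participant_gain_sd,
    participant_decay_sd = participant_decay_sd,
    participant_threshold_sd = participant_threshold_sd,
    position_noise_sd = position_noise_sd,
    low_confidence_rate = low_confidence_rate,
    saccades_enabled = saccades_enabled,
    noise_enabled = noise_enabled),
    class = "gaze_model_params")
}

#' Construct a single trial schedule
#'
#' Low-level constructor for the deterministic kinematic plan of one trial.
#' Mostly useful for tests and worked examples; [sample_schedule()] draws
#' whole sessions.
#'
#' @param trial_id,participant_id Identifiers.
#' @param direction +1 (rightward motion) or -1 (leftward).
#' @param target_velocity Signed target velocity, deg/s (sign must match
#'   `direction`).
#' @param start_position Signed launch position, deg; defaults to the
#'   eccentricity opposite to the motion direction.
#' @param t_launch Launch time on the trial clock, s.
#' @param visible_duration Visible-motion duration, s.
#' @param occlusion_duration Occlusion duration, s (0 for non-occluded
#'   trials).
#' @param reappearance_duration Probe duration, s.
#' @param occluded Logical; FALSE for training-block trials.
#' @param block Block index.
#' @return One-row tibble with the schedule fields, including the derived
#'   `t_occlusion_onset` and `t_reappear = t_occlusion_onset +
#'   occlusion_duration`.
#' @export
trial_schedule <- function(trial_id = 1L, participant_id = 1L,
                           direction = 1, target_velocity = 30,
                           start_position = NULL, t_launch = 1.0,
                           visible_duration = 0.5,
                           occlusion_duration = 0.5,
                           reappearance_duration = 0.05,
                           occluded = occlusion_duration > 0,
                           block = 1L) {
  stopifnot(direction %in% c(-1, 1))
  if (sign(target_velocity) != direction)
    stop_input("target_velocity sign must match direction")
  if (is.null(start_position)) start_position <- -direction * 27
  t_occ <- t_launch + visible_duration
  tibble::tibble(
    participant_id = participant_id, trial_id = trial_id, block = block,
    direction = direction, start_position = start_position,
    target_velocity = target_velocity, t_launch = t_launch,
    visible_duration = visible_duration,
    t_occlusion_onset = t_occ,
    occlusion_duration = occlusion_duration,
    t_reappear = t_occ + occlusion_duration,
    reappearance_duration = reappearance_duration,
    occluded = occluded)
}
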