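# Synthetic occluded-tracking experiment generator.
#
# The generator is event-driven on top of closed-form pursuit kinematics:
# the smooth (pursuit) trajectory is integrated analytically per phase, and
# a short loop inserts displacement-triggered minimum-jerk saccades, each of
# which re-anchors the smooth trajectory at its landing point. This keeps a
# 120 Hz trial to a handful of vectorized operations.

# Target position at arbitrary times for one schedule row (the ramp keeps
# moving during occlusion; the "invisible" target is the extrapolated ramp).
target_position_at <- function(schedule, t) {
  ifelse(t < schedule$t_launch,
         schedule$start_position,
         schedule$start_position +
           schedule$target_velocity * (t - schedule$t_launch))
}

#' Draw the trial schedules of one participant's session
#'
#' Samples the full deterministic kinematic plan of every trial: alternating
#' motion direction, signed target velocity with magnitude uniform on the
#' configured range, visible-motion duration uniform on its range, and
#' occlusion durations from the calibrated truncated-lognormal sampler
#' (zero in non-occluded blocks). The pair (speed, visible duration) is
#' rejection-sampled (up to 1000 attempts, then clipped) so the target
#' never reaches the screen's horizontal midpoint before disappearing.
#'
#' @param config An [experiment_config()].
#' @param participant_id Participant identifier (also keys the random
#'   substream).
#' @param seed Optional integer overriding the substream derived from
#'   `config$seed`.
#' @return Tibble of `config$trials_total` schedules (see
#'   [trial_schedule()] for the columns).
#' @export
sample_schedule <- function(config, participant_id = 1L, seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(seed %||% seed_stream(config$seed, 101L, participant_id))
  ecc <- config$start_eccentricity
  vr <- config$velocity_range
  mr <- config$visible_motion_range

  n <- config$trials_total
  block_id <- rep(seq_len(nrow(config$blocks)), config$blocks$n_trials)
  block_occluded <- config$blocks$occluded[block_id]
  dir0 <- sample(c(-1, 1), 1)
  direction <- dir0 * (-1)^(seq_len(n) - 1)

  # Speeds are drawn once (their marginal stays exactly uniform); the
  # visible duration is rejection-resampled given the speed so the target
  # never reaches the midpoint, with a final clip as a fallback.
  speed <- numeric(n)
  t_vis <- numeric(n)
  for (i in seq_len(n)) {
    sp <- runif(1, vr[1], vr[2])
    ok <- FALSE
    for (attempt in seq_len(1000)) {
      tv <- runif(1, mr[1], mr[2])
      if (sp * tv < ecc) { ok <- TRUE; break }
    }
    if (!ok) tv <- 0.999 * ecc / sp   # clip: stop just short of the midpoint
    speed[i] <- sp
    t_vis[i] <- tv
  }
  occ <- ifelse(block_occluded,
                sample_occlusion_durations(n, config$occlusion_sampler), 0)

  t_occ <- config$prelaunch_duration + t_vis
  tibble::tibble(
    participant_id = participant_id,
    trial_id = seq_len(n),
    block = block_id,
    direction = direction,
    start_position = -direction * ecc,
    target_velocity = direction * speed,
    t_launch = config$prelaunch_duration,
    visible_duration = t_vis,
    t_occlusion_onset = t_occ,
    occlusion_duration = occ,
    t_reappear = t_occ + occ,
    reappearance_duration = config$reappearance_duration,
    occluded = block_occluded)
}

# Smooth-pursuit velocity profile (signed, deg/s) at sample times, before
# any saccades: zero until pursuit onset, gain-scaled target velocity while
# visible, exponential decay from the occlusion-onset value while occluded,
# re-acquired gain pursuit after reappearance.
.pursuit_velocity <- function(t, schedule, gp) {
  v <- schedule$target_velocity
  onset <- schedule$t_launch + gp$launch_latency
  vis_v <- gp$pursuit_gain_visible * v
  out <- numeric(length(t))
  out[t >= onset] <- vis_v
  if (schedule$occluded && schedule$occlusion_duration > 0) {
    occ <- t >= schedule$t_occlusion_onset & t < schedule$t_reappear
    out[occ] <- vis_v *
      exp(-gp$pursuit_decay_rate * (t[occ] - schedule$t_occlusion_onset))
  }
  out
}

# Analytic integral of .pursuit_velocity from the launch position.
.pursuit_position <- function(t, schedule, gp) {
  v <- schedule$target_velocity
  onset <- schedule$t_launch + gp$launch_latency
  vis_v <- gp$pursuit_gain_visible * v
  r <- gp$pursuit_decay_rate
  t_occ <- schedule$t_occlusion_onset
  t_re <- schedule$t_reappear

  pos <- rep(schedule$start_position, length(t))
  vis <- t >= onset & (!schedule$occluded | t < t_occ)
  pos[vis] <- schedule$start_position + vis_v * (t[vis] - onset)
  if (schedule$occluded && schedule$occlusion_duration > 0) {
    p_occ0 <- schedule$start_position + vis_v * (t_occ - onset)
    occ <- t >= t_occ & t < t_re
    if (r > 0) {
      pos[occ] <- p_occ0 + vis_v / r * (1 - exp(-r * (t[occ] - t_occ)))
      p_re <- p_occ0 + vis_v / r * (1 - exp(-r * (t_re - t_occ)))
    } else {
      pos[occ] <- p_occ0 + vis_v * (t[occ] - t_occ)
      p_re <- p_occ0 + vis_v * (t_re - t_occ)
    }
    re <- t >= t_re
    pos[re] <- p_re + vis_v * (t[re] - t_re)
  }
  pos
}

#' Simulate the gaze trace of one trial
#'
#' Produces a gaze/target trace sampled at the configured rate from trial
#' start through 200 ms after target reappearance. The smooth component
#' follows the pursuit profile (anticipatory drift with return saccades
#' before launch, a launch latency, gain-scaled pursuit while visible,
#' exponentially decaying pursuit during occlusion). Whenever the absolute
#' motion-aligned displacement exceeds the trigger threshold, a
#' minimum-jerk saccade (duration 20 ms + 2 ms/deg) is inserted whose
#' landing displacement relative to the (possibly extrapolated) target is
#' drawn from the phase-specific landing law. Gaussian position noise and
#' i.i.d. low-confidence samples are added last.
#'
#' @param schedule One-row schedule tibble ([trial_schedule()] or a row of
#'   [sample_schedule()]).
#' @param config An [experiment_config()] (supplies the sample rate).
#' @param gaze_params A [gaze_model_params()].
#' @param seed Optional integer seed for this trial's substream.
#' @return Tibble with columns `t`, `target_x`, `target_v`,
#'   `target_visible`, `gaze_x` (noisy observed position, deg), `gaze_smooth`
#'   (noiseless model position), `gaze_v` (true model velocity, deg/s),
#'   `confidence`, `in_saccade`, `phase`; attributes `d_true`/`s_true` hold
#'   the model's absolute displacement and slippage at the sample nearest
#'   reappearance.
#' @export
simulate_gaze <- function(schedule, config, gaze_params = gaze_model_params(),
                          seed = NULL) {
  gp <- gaze_params
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sample_rate
  dt <- 1 / fs
  t_end <- schedule$t_reappear + 0.2
  t <- seq(0, t_end, by = dt)
  n <- length(t)
  dir <- schedule$direction

  target_x <- target_position_at(schedule, t)
  target_v <- ifelse(t < schedule$t_launch, 0, schedule$target_velocity)
  target_visible <- t < schedule$t_occlusion_onset |
    (t >= schedule$t_reappear &
       t < schedule$t_reappear + schedule$reappearance_duration)

  # --- pre-launch anticipatory drift with return saccades -----------------
  offset <- numeric(n)        # gaze offset from the smooth pursuit position
  gv <- .pursuit_velocity(t, schedule, gp)
  pre <- which(t < schedule$t_launch)
  if (length(pre) > 0 && gp$anticipatory_drift_speed > 0) {
    amp <- gp$anticipatory_drift_amplitude
    drift_t <- amp / gp$anticipatory_drift_speed
    ret_dur <- saccade_duration(amp)
    cycle <- drift_t + ret_dur
    tau <- t[pre] %% cycle
    drifting <- tau < drift_t
    offset[pre] <- ifelse(
      drifting,
      dir * gp$anticipatory_drift_speed * tau,
      dir * amp * (1 - minjerk((tau - drift_t) / ret_dur)))
    gv[pre] <- ifelse(
      drifting,
      dir * gp$anticipatory_drift_speed,
      -dir * amp * minjerk_deriv((tau - drift_t) / ret_dur) / ret_dur)
  }

  # --- smooth trajectory + event-driven saccades --------------------------
  base <- .pursuit_position(t, schedule, gp)
  i_launch <- which(t >= schedule$t_launch)[1]
  c_off <- if (i_launch > 1) offset[i_launch - 1] else 0
  gaze <- base
  gaze[t >= schedule$t_launch] <- base[t >= schedule$t_launch] + c_off
  gaze[t < schedule$t_launch] <- schedule$start_position +
    offset[t < schedule$t_launch]
  in_saccade <- rep(FALSE, n)

  # Internal estimate of the occluded target: true ramp plus a per-trial
  # linear drift while the target is invisible. Saccade triggering and
  # aiming use this estimate; displacement/slippage are always measured
  # against the true ramp.
  drift_rate <- if (isTRUE(schedule$occluded) && gp$occlusion_drift_sd > 0)
    rnorm(1, 0, gp$occlusion_drift_sd) else 0
  est_bias_at <- function(tq) {
    occluded_now <- tq >= schedule$t_occlusion_onset & tq < schedule$t_reappear
    dir * drift_rate * (tq - schedule$t_occlusion_onset) * occluded_now
  }
  est_bias <- est_bias_at(t)

  if (gp$saccades_enabled) {
    i0 <- which(t >= schedule$t_launch)[1]
    iter <- 0L
    while (!is.na(i0) && i0 <= n && iter < 100L) {
      iter <- iter + 1L
      disp <- (gaze[i0:n] - target_x[i0:n] - est_bias[i0:n]) * dir
      j <- which(abs(disp) >= gp$saccade_trigger_threshold)[1]
      if (is.na(j)) break
      # threshold crossed at sample i; the saccade launches only after the
      # sensorimotor latency, during which displacement keeps evolving
      i_trig <- i0 + j - 1L
      i <- which(t >= t[i_trig] + gp$saccade_latency)[1]
      if (is.na(i)) break
      ti <- t[i]
      law <- if (target_visible[i]) gp$landing_displacement_visible
             else gp$landing_displacement_occluded
      L <- rnorm(1, law[1], law[2])
      amp0 <- (target_position_at(schedule, ti) + est_bias_at(ti) +
                 dir * L) - gaze[i]
      dur <- saccade_duration(amp0)
      t_land <- ti + dur
      landing_pos <- target_position_at(schedule, t_land) +
        est_bias_at(t_land) + dir * L
      delta <- landing_pos - gaze[i]

      sac <- which(t > ti & t < t_land)
      if (length(sac) > 0) {
        tau <- (t[sac] - ti) / dur
        gaze[sac] <- gaze[i] + delta * minjerk(tau)
        gv[sac] <- delta * minjerk_deriv(tau) / dur
        in_saccade[sac] <- TRUE
      }
      after <- which(t >= t_land)
      if (length(after) > 0) {
        # re-anchor: smooth pursuit resumes from the landing point
        base_at_land <- .pursuit_position(t_land, schedule, gp)
        gaze[after] <- base[after] + (landing_pos - base_at_land)
      }
      i0 <- which(t >= t_land + gp$saccade_refractory)[1]
    }
  }

  phase <- rep("reappearance", n)
  phase[t < schedule$t_launch] <- "prelaunch"
  phase[t >= schedule$t_launch & t < schedule$t_occlusion_onset] <- "visible"
  if (schedule$occluded)
    phase[t >= schedule$t_occlusion_onset & t < schedule$t_reappear] <-
      "occluded"

  gaze_obs <- gaze
  if (gp$noise_enabled && gp$position_noise_sd > 0)
    gaze_obs <- gaze + rnorm(n, 0, gp$position_noise_sd)
  low <- runif(n) < gp$low_confidence_rate
  confidence <- ifelse(low, runif(n, 0, 0.79), runif(n, 0.85, 1.0))

  ir <- which.min(abs(t - schedule$t_reappear))
  d_true <- abs((gaze[ir] - target_x[ir]) * dir)
  s_true <- abs((gv[ir] - target_v[ir]) * dir)

  out <- tibble::tibble(
    t = t, target_x = target_x, target_v = target_v,
    target_visible = target_visible,
    gaze_x = gaze_obs, gaze_smooth = gaze, gaze_v = gv,
    confidence = confidence, in_saccade = in_saccade, phase = phase)
  attr(out, "d_true") <- d_true
  attr(out, "s_true") <- s_true
  out
}

#' Draw a discrimination outcome from the accuracy model
#'
#' Bernoulli outcome with success probability `predict_accuracy(d, s)`.
#' The generating probability is returned alongside the outcome so tests
#' can introspect the generative process.
#'
#' @param d,s Absolute displacement (deg) and slippage (deg/s); vectors.
#' @param true_params [model_params()] used as the generating truth.
#' @param seed Optional seed.
#' @return Tibble with columns `p_success` and `outcome` (0/1).
#' @export
simulate_outcome <- function(d, s, true_params = model_params(),
                             seed = NULL) {
  if (any(d < 0) || any(s < 0))
    stop_input("d and s must be non-negative absolute values")
  if (!is.null(seed)) set.seed(seed)
  p <- predict_accuracy(d, s, true_params)
  tibble::tibble(p_success = p, outcome = rbinom(length(p), 1, p))
}

# Draw one participant's individual gaze parameters around the cohort
# defaults (between-participant variability in pursuit behavior).
.participant_gaze_params <- function(gp, seed) {
  set.seed(seed)
  out <- gp
  if (gp$participant_gain_sd > 0) {
    g <- rnorm(1, gp$pursuit_gain_visible, gp$participant_gain_sd)
    out$pursuit_gain_visible <- min(max(g, 0.5), 1.2)
  }
  if (gp$participant_decay_sd > 0)
    out$pursuit_decay_rate <- gp$pursuit_decay_rate *
      exp(rnorm(1, 0, gp$participant_decay_sd))
  if (gp$participant_threshold_sd > 0)
    out$saccade_trigger_threshold <- max(
      rnorm(1, gp$saccade_trigger_threshold, gp$participant_threshold_sd), 1)
  out
}

#' Simulate a full cohort
#'
#' Runs [sample_schedule()], [simulate_gaze()] and [simulate_outcome()] for
#' every participant and trial, using counter-based random substreams so
#' any trial is reproducible in isolation from the master seed.
#'
#' @param config An [experiment_config()].
#' @param gaze_params A [gaze_model_params()].
#' @param outcome_params Generating [model_params()].
#' @param return_samples If `FALSE`, gaze traces are discarded after the
#'   per-trial features are recorded (fast path for parameter-recovery
#'   studies).
#' @return List with `trials` (schedules plus `d`, `s`, `p_success`,
#'   `outcome`) and `samples` (long gaze/target trace tibble, or `NULL`).
#' @export
simulate_experiment <- function(config,
                                gaze_params = gaze_model_params(),
                                outcome_params = model_params(),
                                return_samples = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  all_trials <- vector("list", config$n_participants)
  all_samples <- if (return_samples)
    vector("list", config$n_participants * config$trials_total)
  si <- 0L
  for (pid in seq_len(config$n_participants)) {
    sched <- sample_schedule(config, pid)
    gp_pid <- .participant_gaze_params(
      gaze_params, seed_stream(config$seed, 404L, pid))
    d <- numeric(nrow(sched)); s <- numeric(nrow(sched))
    for (k in seq_len(nrow(sched))) {
      trace <- simulate_gaze(sched[k, ], config, gp_pid,
                             seed = seed_stream(config$seed, 202L, pid, k))
      d[k] <- attr(trace, "d_true")
      s[k] <- attr(trace, "s_true")
      if (return_samples) {
        si <- si + 1L
        trace$participant_id <- pid
        trace$trial_id <- sched$trial_id[k]
        all_samples[[si]] <- trace
      }
    }
    out <- simulate_outcome(d, s, outcome_params,
                            seed = seed_stream(config$seed, 303L, pid))
    sched$d <- d
    sched$s <- s
    sched$p_success <- out$p_success
    sched$outcome <- out$outcome
    all_trials[[pid]] <- sched
  }
  list(trials = dplyr::bind_rows(all_trials),
       samples = if (return_samples) dplyr::bind_rows(all_samples) else NULL)
}
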