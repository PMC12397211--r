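# Displacement/slippage series, reappearance features, event segmentation,
# descriptive summaries.

fs <- 120

# Hand-built trial: target at 30 deg/s rightward, launch at t = 1, gaze
# supplied explicitly along with its true velocity.
manual_trial <- function(gaze_fun, gaze_v_fun, visible_duration = 0.5,
                         occlusion_duration = 0.5, direction = 1,
                         velocity = 30) {
  sch <- trial_schedule(direction = direction,
                        target_velocity = direction * velocity,
                        visible_duration = visible_duration,
                        occlusion_duration = occlusion_duration)
  t <- seq(0, sch$t_reappear + 0.2, by = 1 / fs)
  target <- ifelse(t < sch$t_launch, sch$start_position,
                   sch$start_position + sch$target_velocity *
                     (t - sch$t_launch))
  samples <- tibble::tibble(
    t = t, gaze_x = gaze_fun(t, target), target_x = target,
    target_v = ifelse(t < sch$t_launch, 0, sch$target_velocity))
  list(schedule = sch, samples = samples,
       gaze_v = gaze_v_fun(t, samples$target_v))
}

test_that("perfect tracking gives zero displacement and slippage", {
  m <- manual_trial(function(t, target) target,
                    function(t, tv) tv)
  st <- stabilization_series(m$samples, m$schedule, gaze_v = m$gaze_v)
  expect_true(all(abs(st$displacement) < 1e-12))
  expect_true(all(abs(st$slippage) < 1e-12))
  f <- features_at_reappearance(st, m$schedule, outcome = 1)
  expect_equal(f$d, 0)
  expect_equal(f$s, 0)
  expect_false(f$missing)
})

test_that("a constant lead in motion direction is positive displacement", {
  m <- manual_trial(function(t, target) target + 2,
                    function(t, tv) tv)
  st <- stabilization_series(m$samples, m$schedule, gaze_v = m$gaze_v)
  expect_true(all(abs(st$displacement - 2) < 1e-12))
  expect_true(all(abs(st$slippage) < 1e-12))
})

test_that("sign convention mirrors with trial direction", {
  # rightward trial, gaze 1 deg left of target (behind) -> displacement -1
  mr <- manual_trial(function(t, target) target - 1, function(t, tv) tv,
                     direction = 1)
  # leftward trial, gaze 1 deg left of target (ahead)  -> displacement +1
  ml <- manual_trial(function(t, target) target - 1, function(t, tv) tv,
                     direction = -1)
  sr <- stabilization_series(mr$samples, mr$schedule, gaze_v = mr$gaze_v)
  sl <- stabilization_series(ml$samples, ml$schedule, gaze_v = ml$gaze_v)
  expect_true(all(abs(sr$displacement + 1) < 1e-12))
  expect_true(all(abs(sl$displacement - 1) < 1e-12))
})

test_that("a fully mirrored trial leaves d and s unchanged", {
  fx <- deterministic_trace()
  st <- stabilization_series(fx$trace, fx$schedule, gaze_v = fx$trace$gaze_v)
  f <- features_at_reappearance(st, fx$schedule, 1)
  # mirror: negate positions, velocities and direction
  sch2 <- fx$schedule
  sch2$direction <- -1
  sch2$start_position <- -sch2$start_position
  sch2$target_velocity <- -sch2$target_velocity
  tr2 <- fx$trace
  tr2$gaze_x <- -tr2$gaze_x
  tr2$gaze_smooth <- -tr2$gaze_smooth
  tr2$target_x <- -tr2$target_x
  tr2$target_v <- -tr2$target_v
  st2 <- stabilization_series(tr2, sch2, gaze_v = -fx$trace$gaze_v)
  expect_equal(st2$displacement, st$displacement)
  expect_equal(st2$slippage, st$slippage)
  f2 <- features_at_reappearance(st2, sch2, 1)
  expect_equal(f2$d, f$d)
  expect_equal(f2$s, f$s)
})

test_that("frozen gaze through occlusion gives the closed-form features", {
  # gaze freezes at occlusion onset; target at 30 deg/s, 0.5 s occlusion
  m <- manual_trial(
    function(t, target) {
      sch_occ <- 1.5   # t_launch 1 + visible 0.5
      frozen <- target[which.min(abs(t - sch_occ))]
      ifelse(t < sch_occ, target, frozen)
    },
    function(t, tv) ifelse(t < 1.5, tv, 0),
    visible_duration = 0.5, occlusion_duration = 0.5)
  st <- stabilization_series(m$samples, m$schedule, gaze_v = m$gaze_v)
  f <- features_at_reappearance(st, m$schedule, outcome = 0)
  expect_equal(f$d, 15, tolerance = 1e-9)   # 30 deg/s * 0.5 s
  expect_equal(f$s, 30, tolerance = 1e-9)
})

test_that("features take absolute values and respect the 25 ms rule", {
  m <- manual_trial(function(t, target) target - 3, function(t, tv) tv)
  st <- stabilization_series(m$samples, m$schedule, gaze_v = m$gaze_v)
  f <- features_at_reappearance(st, m$schedule, 1)
  expect_equal(f$d, 3)
  # invalidate everything near reappearance -> missing feature
  st2 <- st
  st2$valid[abs(st2$t - m$schedule$t_reappear) <= 0.03] <- FALSE
  st2$displacement[!st2$valid] <- NA
  f2 <- features_at_reappearance(st2, m$schedule, 1)
  expect_true(f2$missing)
  expect_match(f2$missing_reason, "25 ms")
})

test_that("features reproduce the generator's recorded (d, s)", {
  cfg <- experiment_config(seed = 4)
  gp <- gaze_model_params(noise_enabled = FALSE, low_confidence_rate = 0)
  for (s in 1:5) {
    sch <- trial_schedule(direction = (-1)^s,
                          target_velocity = (-1)^s * (25 + 3 * s),
                          visible_duration = 0.4 + 0.05 * s,
                          occlusion_duration = 0.45 + 0.1 * s)
    tr <- simulate_gaze(sch, cfg, gp, seed = 600 + s)
    st <- stabilization_series(tr, sch, gaze_v = tr$gaze_v)
    f <- features_at_reappearance(st, sch, 1)
    expect_equal(f$d, attr(tr, "d_true"), tolerance = 1e-9)
    expect_equal(f$s, attr(tr, "s_true"), tolerance = 1e-9)
  }
})

test_that("segmentation finds an injected minimum-jerk step and only it", {
  sch <- trial_schedule(direction = 1, target_velocity = 30,
                        visible_duration = 0.5, occlusion_duration = 0.5)
  t <- seq(0, 2.2, by = 1 / fs)
  # constant-velocity pursuit at 30 deg/s: no saccades at threshold 60
  g0 <- tibble::tibble(t = t, gaze_x = 30 * t)
  ev0 <- segment_events(g0, sch, gaze_v = rep(30, length(t)))
  expect_equal(sum(ev0$kind == "saccade"), 0)

  # one 4-deg, 40 ms minimum-jerk step starting at t = 1
  amp <- 4; dur <- 0.04; t0 <- 1
  tau <- pmin(pmax((t - t0) / dur, 0), 1)
  pos <- amp * tau^3 * (10 - 15 * tau + 6 * tau^2)
  vel <- amp * (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / dur
  vel[t < t0 | t > t0 + dur] <- 0
  g1 <- tibble::tibble(t = t, gaze_x = pos)
  ev1 <- segment_events(g1, sch, gaze_v = vel)
  sacc <- ev1[ev1$kind == "saccade", ]
  expect_equal(nrow(sacc), 1)
  expect_lt(abs((sacc$t_end - sacc$t_start) - dur), 1 / fs + 1e-9)

  # externally supplied labels bypass detection unchanged
  ext <- tibble::tibble(kind = "saccade", t_start = 0.1, t_end = 0.2,
                        landing_displacement = 1.2, phase = "visible")
  expect_identical(segment_events(g1, sch, events = ext), ext)
})

test_that("label-built events recover the exact landing displacement", {
  cfg <- experiment_config(seed = 1)
  gp <- gaze_model_params(noise_enabled = FALSE, low_confidence_rate = 0,
                          occlusion_drift_sd = 0,
                          landing_displacement_occluded = c(1.5, 0),
                          landing_displacement_visible = c(-0.26, 0))
  sch <- trial_schedule(direction = 1, target_velocity = 35,
                        visible_duration = 0.9, occlusion_duration = 1.5)
  tr <- simulate_gaze(sch, cfg, gp, seed = 2)
  ev <- events_from_labels(tr, sch)
  occ <- ev[ev$kind == "saccade" & ev$phase == "occluded", ]
  expect_gt(nrow(occ), 0)
  # landing = drawn L plus at most one sample of pursuit drift
  expect_true(all(abs(occ$landing_displacement - 1.5) < 35 / fs))
})

test_that("landing summaries aggregate medians and bootstrap the mean", {
  ev <- tibble::tibble(
    participant_id = rep(1:2, each = 4),
    kind = "saccade", phase = "occluded",
    landing_displacement = c(rep(1, 4), rep(2, 4)),
    t_start = 0, t_end = 0.02)
  s <- landing_displacement_summary(ev, "occluded", n_resamples = 200)
  expect_equal(s$per_participant$median_landing, c(1, 2))
  expect_equal(s$summary$mean, 1.5)

  ev_const <- ev
  ev_const$landing_displacement <- 0.7
  s2 <- landing_displacement_summary(ev_const, "occluded", n_resamples = 200)
  expect_equal(unlist(s2$summary[, c("mean", "lower", "upper")]),
               c(mean = 0.7, lower = 0.7, upper = 0.7))
})

test_that("pursuit decay ratio matches the window-median oracle", {
  # one participant, 6 identical occluded trials with pure exponential
  # decay and no saccades
  rate <- -log(0.62) / 0.6
  make <- function(rate) {
    trials <- list(); samples <- list()
    for (k in 1:6) {
      sch <- trial_schedule(trial_id = k, direction = 1,
                            target_velocity = 30, visible_duration = 0.5,
                            occlusion_duration = 0.8)
      cfg <- experiment_config(seed = 1)
      gp <- gaze_model_params(pursuit_decay_rate = rate,
                              saccades_enabled = FALSE,
                              noise_enabled = FALSE,
                              occlusion_drift_sd = 0,
                              low_confidence_rate = 0)
      tr <- simulate_gaze(sch, cfg, gp, seed = k)
      tr$participant_id <- 1; tr$trial_id <- k
      trials[[k]] <- sch; samples[[k]] <- tr
    }
    trials <- dplyr::bind_rows(trials)
    trials$participant_id <- 1
    list(trials = trials, samples = dplyr::bind_rows(samples))
  }
  dat <- make(rate)
  res <- pursuit_decay_summary(dat$samples, dat$trials, n_resamples = 100)
  # oracle: onset reference is the median over the 12 onset-window samples
  # exp(-rate * k/120), k = 0..11; probe is the sample at exactly 0.6 s
  onset_med <- median(exp(-rate * (0:11) / 120))
  oracle <- exp(-rate * 0.6) / onset_med
  expect_equal(res$per_participant$speed_ratio[1], oracle,
               tolerance = 1e-6)
  expect_lt(abs(res$per_participant$speed_ratio[1] - 0.62), 0.03)

  # zero decay: ratio exactly 1
  dat0 <- make(0)
  res0 <- pursuit_decay_summary(dat0$samples, dat0$trials, n_resamples = 100)
  expect_equal(res0$per_participant$speed_ratio[1], 1, tolerance = 1e-9)

  # doubled rate: the same oracle squares the per-sample decay
  dat2 <- make(2 * rate)
  res2 <- pursuit_decay_summary(dat2$samples, dat2$trials, n_resamples = 100)
  oracle2 <- exp(-2 * rate * 0.6) / median(exp(-2 * rate * (0:11) / 120))
  expect_equal(res2$per_participant$speed_ratio[1], oracle2,
               tolerance = 1e-6)
})

test_that("rolling mean has the convolution arithmetic of its window", {
  x <- rep(3.5, 100)
  expect_equal(rolling_mean(x), x)
  # unit impulse with a 12-sample window: a plateau of 12 samples at 1/12
  imp <- rep(0, 100); imp[50] <- 1
  sm <- rolling_mean(imp, window = 0.1, sample_rate = 120)
  expect_equal(sum(abs(sm - 1 / 12) < 1e-12), 12)
  expect_equal(sum(sm > 1e-12), 12)
  # linear ramp unchanged away from edges (odd window: symmetric average)
  ramp <- seq(0, 1, length.out = 100)
  smr <- rolling_mean(ramp, window = 11 / 120, sample_rate = 120)
  expect_equal(smr[20:80], ramp[20:80], tolerance = 1e-12)
  # an even window averages over a half-sample-shifted centre
  smr12 <- rolling_mean(ramp, window = 0.1, sample_rate = 120)
  shift <- (ramp[2] - ramp[1]) / 2
  expect_equal(smr12[20:80], ramp[20:80] + shift, tolerance = 1e-12)
})

test_that("gain is the velocity ratio, undefined pre-launch", {
  gv <- c(0, 0, 15, 30, 30)
  tv <- c(0, 0, 30, 30, 30)
  g <- gain_series(gv, tv)
  expect_true(all(is.na(g[1:2])))
  expect_equal(g[3:5], c(0.5, 1, 1))
})
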