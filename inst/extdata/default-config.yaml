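# Complete annotated default configuration for occlutrack.
# Every key is optional; omitted keys take the package defaults shown here.
# Load with read_run_config(), or pass to run_pipeline() / the CLI.

experiment:
  n_participants: 9          # cohort size
  sample_rate: 120           # Hz
  velocity_range: [22.5, 45.0]       # target speed, deg/s (uniform)
  visible_motion_range: [0.2, 1.0]   # visible-motion duration, s (uniform)
  occlusion_max: 1.9         # truncation of the occlusion-duration law, s
  occlusion_median_target: 0.53      # calibration targets of the
  occlusion_mean_target: 0.58        #   truncated-lognormal sampler, s
  reappearance_duration: 0.05        # probe duration, s
  prelaunch_duration: 1.0    # stationary period before launch, s
  start_eccentricity: 27     # unsigned launch eccentricity, deg
  seed: 1                    # master seed for all generator randomness
  blocks:                    # one entry per block, in order
    - {n_trials: 30, occluded: false}   # training block
    - {n_trials: 30, occluded: true}
    - {n_trials: 30, occluded: true}
    - {n_trials: 30, occluded: true}

gaze:
  pursuit_gain_visible: 0.95 # pursuit velocity gain on the visible target
  # decay rate of occluded pursuit speed, 1/s; the default -ln(0.62)/0.6
  # makes speed at 600 ms of occlusion 62% of its onset value
  pursuit_decay_rate: 0.7965
  saccade_trigger_threshold: 2.0     # predicted |displacement| trigger, deg
  landing_displacement_occluded: [1.5, 1.0]    # N(mean, sd), deg
  landing_displacement_visible: [-0.26, 0.7]   # N(mean, sd), deg
  saccade_latency: 0.2       # trigger-to-saccade sensorimotor delay, s
  saccade_refractory: 0.15   # minimum inter-saccade interval, s
  launch_latency: 0.12       # pursuit onset latency after launch, s
  anticipatory_drift_speed: 2.0      # pre-launch drift, deg/s
  anticipatory_drift_amplitude: 1.0  # drift excursion before return, deg
  occlusion_drift_sd: 3.0    # sd of per-trial target-estimate drift, deg/s
  participant_gain_sd: 0.05  # between-participant pursuit-gain sd
  participant_decay_sd: 0.2  # lognormal log-sd on the decay rate
  participant_threshold_sd: 0.5      # sd of the trigger threshold, deg
  position_noise_sd: 0.15    # gaze measurement noise, deg
  low_confidence_rate: 0.01  # per-sample probability of confidence < 0.8

outcome:                     # generating truth of the accuracy model
  beta_d: 0.18               # displacement sensitivity, 1/deg
  beta_s: 0.01               # slippage sensitivity, s/deg
  lapse: 0.03                # lapse probability
  chance: 0.25               # 4AFC guessing floor (fixed)
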