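# occlutrack

Task-anchored tracking quality for occluded visual tracking.

When an observer tracks a moving target that temporarily disappears, how
good is their tracking? `occlutrack` answers this the way the task itself
does: by linking gaze–target error at the moment the target reappears to
success in a brief four-alternative forced-choice discrimination probe,
and then turning the fitted psychometric model into a 0–1 tracking-quality
score that can be evaluated continuously through the occlusion. It is
aimed at researchers in visual psychophysics and oculomotor control who
want a performance-anchored alternative to de-saccaded pursuit gain.

## The model

Each trial contributes a binary outcome and two features measured at
target reappearance: absolute gaze–target displacement *d* (deg) and
absolute slippage *s* (deg/s). Accuracy is modelled as

    A(d, s) = γ + (1 − γ)(1 − λ) · F(d, s)
    F(d, s) = exp(−(β_d·d)²) · exp(−(β_s·s)²)

with γ = 0.25 the 4AFC chance level (fixed), λ a per-participant lapse
rate, and β_d, β_s per-participant sensitivities estimated by maximum
likelihood under box constraints (deterministic dense-grid global search +
L-BFGS-B refinement). Reduced models pinning subsets of {β_d, β_s, λ} at
zero form an AIC comparison ladder summed across participants. The
tracking-quality metric is F itself — chance and lapse dropped — evaluated
pointwise on the displacement/slippage series during occlusion.

The package also ships a synthetic-data generator that emulates the
underlying ramp-with-occlusion experiment (pursuit with exponential decay
during occlusion, latency-delayed catch-up and jump-ahead saccades,
prediction drift for the invisible target, confidence dropouts,
between-participant variability), so the entire pipeline is testable with
no recorded data.

## Worked example

```r
library(occlutrack)

cfg <- experiment_config(seed = 1)        # 9 participants x 120 trials
sim <- simulate_experiment(cfg)           # schedules, gaze traces, outcomes

occ <- sim$trials[sim$trials$occluded, ]
mean(occ$outcome)
#> [1] 0.8061728

fits <- fit_cohort(occ, variants = "all") # 7-variant ladder per participant
as.data.frame(compare_models(fits)[, c("variant", "log_likelihood", "aic", "rank")])
#>                variant log_likelihood       aic rank
#> 1                 full      -310.4254  674.8508    1
#> 2        remove_lambda      -326.8833  689.7667    2
#> 3        remove_beta_s      -346.4233  728.8465    3
#> 4        remove_beta_d      -359.9123  755.8245    4
#> 5 remove_beta_d_beta_s      -396.8520  811.7039    5
#> 6 remove_beta_s_lambda      -396.8698  811.7395    6
#> 7 remove_beta_d_lambda      -530.1423 1078.2846    7

full <- fits[fits$variant == "full", ]
round(colMeans(full[, c("beta_d", "beta_s", "lapse")]), 3)
#> beta_d beta_s  lapse
#>  0.159  0.014  0.043

curves <- aggregate_quality(sim$samples, sim$trials, full,
                            use_model_velocity = TRUE)
m <- curves[curves$curve_id == "mean_params", ]
round(c(onset = m$Q_mean[1],
        at_600ms = m$Q_mean[which.min(abs(m$t_rel - 0.6))]), 2)
#>    onset at_600ms
#>     0.89     0.78
```

Interpretation: the simulated cohort succeeds on about 81% of occlusion
trials against a 25% guessing floor; displacement dominates the fit
(removing β_d costs far more likelihood than removing β_s); and cohort
tracking quality starts near 0.9 at occlusion onset, decaying to about
0.78 by 600 ms as the prediction of the hidden target degrades. Exact
numbers vary with the master seed; rerunning the chunk reproduces them
bit-for-bit.

An end-to-end run writing every stage's CSV plus a JSON manifest:

```r
run_pipeline(experiment_config(seed = 1), out_dir = "out")
```

or from a shell, `Rscript inst/cli/occlutrack.R run-all --out out --seed 1`
(a YAML config can override any experiment/gaze/outcome parameter; see
`?read_run_config`).

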