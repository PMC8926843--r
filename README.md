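# acttime

Simulation and analysis of **when-to-act decisions** in the
reward-accumulation "dots" task, for researchers studying the timing of
self-initiated actions (behavioral neuroscience, pharmacology, macaque
fMRI).

In the task, a frame fills with up to 25 dots and the subject chooses when
to respond; the reward probability at response follows a fixed sigmoid in
the dot count,

    p(d) = 1 / (1 + exp(-k (d - d0))),   d0 = 12, k = 0.5,

so the *action time* (`actTime`, the dot count at response) trades reward
probability against session time. The package provides the complete
analysis chain around that variable:

* **Task and behavior simulation** — exact-quota schedules for balanced
  and biased (46/33/21%) offer distributions, blocked ITIs, and a
  proportional-hazards response agent with 23 contextual and history
  covariates, missed trials, and drug-intervention shifts, all with known
  ground truth.
* **Discrete-time Cox model of action timing** — Breslow-tie partial
  likelihood with a Newton–Raphson fitter and Breslow baseline cumulative
  hazard `Λ0(t)`; per-trial survival curves `S_x(t) = exp(-Λ0(t) e^{βx})`
  and the **deterministic actTime**, the expectation
  `Σ_{t=1..25} S_x(t)` of the fitted survival curve — the component of
  action time explained by the immediate and recent-past context.
* **Behavioral mixed models** — the standard model set (environment,
  intervention and dose models with by-subject slopes and by-session
  intercepts), ML estimation via `lme4` with type-II Wald chi-square
  tests via `car`.
* **ROI BOLD time-course pipeline** — 2.5 SD volume censoring,
  normalization and 0.1 s upsampling, 8 s epoching, per-timestep OLS
  models including PPI regressors, and **leave-one-out group-peak**
  significance testing (per-session or per-animal pooling).
* **Pipeline runner** — a YAML-configured, seed-reproducible driver with
  a CLI wrapper (`inst/scripts/acttime-pipeline.R`).

## Worked example

Simulate one biased-design session, fit the hazard model, and compute a
trial's deterministic actTime:

```r
library(acttime)

cfg <- task_config("biased")
round(reward_probability(c(5, 12, 15, 20), cfg), 3)
#> [1] 0.029 0.500 0.818 0.982

sch <- make_schedule(cfg, n_blocks = 3, seed = 42)        # 90 trials
par <- agent_params(coefficients = c(magRew = 0.3, ITI = -0.2),
                    miss_prob = 0.05)
ses <- simulate_agent(sch, par, cfg, seed = 42)
# 90 trials, mean actTime 14.3 dots, 7 missed

dsn <- build_cox_design(ses)        # 80 rows x 23 covariates
fit <- fit_cox(dsn)
round(fit$coef[c("magRew", "dotSpd", "ITI", "rewOut_lag1")], 3)
#>      magRew      dotSpd         ITI rewOut_lag1
#>       0.379       0.279      -0.373       0.071

deterministic_acttime(fit, dsn$X[1, ])
#> [1] 16.26      # expected dots for this trial's context (observed: 15)
```

The reward probability is 50% at the sigmoid midpoint (dot 12) and 82% at
dot 15; the positive `magRew` weight means larger offers hasten the
response (higher hazard), and the negative `ITI` weight means long
intervals slow it. The deterministic actTime is each trial's expected
action time under the fitted hazard given its context — the quantity the
downstream behavioral and BOLD analyses use.

End-to-end, from a config file:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "acttime"))
```

writes trial tables, per-session hazard coefficients, deterministic
actTimes, mixed-model Wald tables, ROI beta time courses and
leave-one-out peak tests, each stamped with the seed and config hash.

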