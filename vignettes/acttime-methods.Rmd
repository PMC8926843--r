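---
title: "Modelling when-to-act decisions: simulation, survival analysis and ROI time-course inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling when-to-act decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acttime)
```

# The problem

In the dots task, a frame gradually fills with up to 25 dots and the
subject (a macaque, in the studies this package supports) chooses *when*
to respond. The probability of reward at response follows a fixed sigmoid
in the number of dots on screen,

$$p(d) = \frac{1}{1 + e^{-k (d - d_0)}}, \qquad d_0 = 12,\; k = 0.5,$$

so waiting buys reward probability at an opportunity cost in session time.
The *action time* (`actTime`) — the dot count at response — is the
time-to-event variable of interest. Reward magnitude (1–3 drops), dot
speed (100/200/300 ms per dot) and the inter-trial interval (3/5/7 s in
30-trial blocks) vary trial to trial; the *environment* is the offer
distribution of a session, either balanced (equal thirds) or biased
toward good offers (46/33/21%).

The package implements the full analysis chain for such experiments —
task simulation with known ground truth, a discrete-time proportional-
hazards model of action timing, behavioral mixed-effects models, and an
ROI BOLD time-course pipeline — so that every estimator can be validated
by parameter recovery before it touches real data.

# The generative simulator

`make_schedule()` draws contextual factors with *exact* per-block quotas:
the smallest block over which the design proportions are integer counts
(3 trials for the balanced design, 100 for the biased 46/33/21 design),
shuffled within block. This makes proportions assertable by counting
rather than only in expectation; the task's own "pseudo-randomized order"
is unspecified, and exact quotas are the testable choice. ITIs are
constant within 30-trial blocks, with block levels a shuffled balanced
multiset.

`simulate_agent()` realizes behavior through a discrete-time hazard: at
dot $t$ the response fires with probability
$h_0(t)\, e^{\beta^\top (x - x_{\mathrm{ref}})}$, clipped to $[0,1]$,
where $x$ is the same 23-covariate vector the fitting model uses (current
reward magnitude, dot-speed level, ITI; the realized reward outcome and
action time of the past ten trials). Centering at a fixed reference
$x_{\mathrm{ref}}$ keeps the exponential moderate on raw covariate
scales; hazard-model estimates are invariant to that shift. The default
baseline hazard rises logistically with the dot count,
$h_0(t) = 0.25\,\mathrm{logit}^{-1}(0.6 (t - 12))$, mirroring the growing
urgency as the reward sigmoid saturates. It produces action times of
about $14.6 \pm 4.1$ dots with ~2% of trials reaching the end of the
window, matching the reported range of observed behavior (14–15 ± 3–4
dots). Two properties drove this choice, made once: a flat hazard leaves
a large no-response tail that must be force-responded at the final dot
(an end-pile not seen in real data), and a baseline peaking above ~0.25
lets $h_0 e^{\beta^\top x}$ clip at 1 for plausible coefficient sizes,
breaking proportionality. Misses are modelled as an unconditional
probability per trial (`miss_prob`) under which the hazard process is
suppressed entirely.

Drug interventions are additive log-hazard shifts (a main term and an
ITI-proportional term) switched on in treatment sessions and scaled down
during dose build-up, mirroring the structure of the behavioral
intervention models.

`simulate_bold()` provides the forward model for the ROI pipeline: each
channel receives, at every responded trial's response time, a
double-gamma hemodynamic response scaled by
$\sum_r \mathrm{effect}_r \cdot z(\mathrm{covariate}_r)$, sampled at
TR = 2.28 s, plus Gaussian noise. The kernel's time-to-peak defaults to
3.0 s — faster than the human canonical 5 s, as appropriate for macaque
hemodynamics — and is configurable. Psychophysiological coupling is
injected as $g \cdot z(\psi_i) \cdot s(t)$ between a seed channel $s$ and
a target within a window after each event, so that seed–target coupling
scales with the trial's psychological variable $\psi$.

What the simulator does *not* emulate: spatial structure (volumes,
registration, smoothing), physiological noise spectra (noise is white),
temporal filtering, and any vision or motor process. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated model, not robustness to real-scanner artifacts.

# The hazard model of action time and the deterministic actTime

Action timing is modelled with a Cox proportional-hazards model on the
integer dot grid,
$$\lambda(t \mid x) = \lambda_0(t)\, e^{\beta^\top x},$$
with the 23 covariates above, fitted per testing session
(`build_cox_design()`, `fit_cox()`). Missed trials are right-censored at
the final dot; missed *predecessors* enter later histories as reward 0
and action time 25 (configurable); the first ten trials of a session are
excluded rather than padded. Events are heavily tied by construction, so
the partial likelihood uses Breslow tie handling — the default of the
common implementations — maximized by Newton–Raphson with step-halving
(gradient max-norm tolerance $10^{-8}$, 50 iterations; a step is accepted
if it does not decrease the likelihood beyond the floating-point noise of
the summed log-likelihood, without which Newton stalls short of strict
tolerances on a few thousand rows). The baseline cumulative hazard is the
Breslow estimator
$\hat\Lambda_0(t) = \sum_{t_j \le t} d_j / \sum_{i \in R_j}
e^{\hat\beta^\top x_i}$, held flat beyond the last observed event time,
where the hazard is unidentified. The test suite requires agreement with
an established survival implementation to $10^{-4}$ relative on random
instances; in practice agreement is at machine precision.

Each trial's **deterministic actTime** is the expectation of its fitted
survival curve $\hat S_x(t) = \exp(-\hat\Lambda_0(t) e^{\hat\beta^\top
x})$, truncated at the dot window:
$$\widehat{\mathbb{E}}[\mathrm{actTime}] \;=\;
\sum_{t=1}^{25} \hat S_x(t),$$
the integral over $(0, 25]$ of the left-continuous survival step
function. This form reproduces the truncated-geometric sum
$\sum_t (1-h)^t$ under a constant discrete hazard, returns 25 under full
survival, and is strictly decreasing in the risk score
$\hat\beta^\top x$. It is verified against a brute-force expectation over
the enumerated fitted distribution to $10^{-10}$.

Two numerical caveats are documented deliberately. First, the Breslow
survival curve $e^{-\hat\Lambda}$ differs from the discrete product-limit
form $(1-h)^t$ by $O(h^2 t)$; at $h = 0.05$ this bounds the expectation
gap by about 0.2 dots, which the constant-hazard tests account for.
Second, *unconditionally* missed trials censored at the window end are
informative censoring — under the generative miss mechanism the censored
trial never ran its hazard process, so it violates the at-risk
assumption. At a 5% miss rate this attenuates every coefficient by
roughly a quarter, identically in this implementation and in the
reference survival package. The parameter-recovery suite therefore runs
its round trip without misses; sign recovery, which is robust to the
attenuation, is verified at a realistic 5% miss rate. Fits with fewer
than 30 events are flagged rather than dropped.

# Behavioral mixed-effects models

`model_spec()` encodes the standard model set: the observed action time
on environment/context and their interactions (GLM1.1), its medium-offer
restriction without the constant factors (GLM1.2), the intervention
variants (GLM3.1–3.3), and the pooled two-experiment model with the
experiment-by-intervention interaction (GRAND). All models carry
by-subject random intercepts and slopes mirroring the fixed terms and —
except GLM3.3, where dose varies only between sessions — a by-session
random intercept. Estimation is maximum likelihood via `lme4`, the tool
the analyses are defined with, and inference is per-term Wald chi-square
(type II) via `car::Anova`; this module owns the design construction
(numeric codes for the labels, within-session lagging of the previous
trial's realized reward and action time, centering before interactions —
switchable) and the singular-fit fallback ladder (correlated slopes →
uncorrelated slopes → intercepts only, recorded in the result). ITI
enters in seconds by default, with a level-index switch.

Calibration was checked by simulation at the suite's sizes: with 4
subjects × 10 sessions × 40 trials and intercept-only variance, the Wald
test of a null intervention effect rejects at 5.6% over 500 replicates.
With very few grouping units the Wald chi-square reference is known to be
permissive; the suite's 40 sessions keep it adequate.

# The ROI time-course pipeline

Volumes are censored when any artifact metric exceeds its median + 2.5 SD
(the threshold that keeps censoring under ~10% in practice); series are
voxel-averaged, z-scored over uncensored volumes (a constant series maps
to zeros), linearly interpolated to a 0.1 s grid bridging censored
volumes, and epoched in 8 s windows — $[0, 8]$ s from trial onset or
$[-4, +4]$ s around the response. At each timepoint an OLS model is fit
across responded trials (GLM2.1–2.4), with per-trial regressors z-scored
within session. PPI regressors mean-center the seed (per timestep) and
the psychological variable before forming their product, the standard
construction. The per-timestep OLS is verified against the normal
equations to $10^{-10}$.

Linear upsampling from the TR grid is not innocuous for narrow kernels:
sampling a 3 s-peak HRF at TR = 2.28 s and interpolating attenuates the
recoverable peak to ~0.81 of the injected amplitude (phase-averaged). The
round-trip suite computes this expected attenuation from the kernel alone
and requires recovery of injected effects at the known kernel peak within
two standard errors — recovery is unbiased once the injection and the
regression share the same z-scoring set of trials.

## Leave-one-out group-peak inference

Significance of a beta time course across units (scanning sessions, or
animals when medium-offer trials are pooled within subject) is assessed
by a leave-one-out procedure: for each unit, the group mean course over
the *other* units is computed, its positive-or-negative peak located as
the extremum of the absolute mean (earliest timepoint on ties), and the
held-out unit's beta read off at that time; a two-tailed one-sample
t-test is applied to the held-out betas, with Cohen's d. Degenerate
(zero-spread) inputs are flagged.

The procedure makes each held-out value *individually* unbiased under the
null — the peak is selected without that unit's data — and the suite
verifies this unbiasedness by simulation. It is important to be precise
about what it does **not** buy: under an exchangeable null with
independent noise (45 units × 81 timepoints), the units' selection sets
overlap almost completely, so all units are evaluated at nearly the same
data-driven peak; the held-out betas are then positively correlated
through co-selection, and the one-sample t-test — which assumes
independence — rejects a true null far above nominal rate (about 50% in
simulation, versus about 95% for naive within-dataset peak picking).
When a genuine effect determines the peak location the selection is
signal-driven, the co-selection correlation vanishes, and the test
behaves well — the regime the round-trip suite exercises. Users should
treat the procedure as an unbiased effect-size reader at the group peak
with well-calibrated inference only in the presence of a real peak, and
prefer it to naive peak picking in all cases.

# The pipeline runner

`run_pipeline()` executes simulate → cox → behavior → roi → report from a
validated YAML configuration, with one master seed driving every
stochastic stage; each output CSV carries the seed and a hash of the
configuration, and identical configurations reproduce outputs bit for
bit. A thin command-line wrapper (`inst/scripts/acttime-pipeline.R`)
exposes `--config`, `--seed`, `--out`, `--stages` and `--log-level`.

# Problem sizes used by the test suite

The recovery and calibration suites run at sizes chosen to give stable
Monte-Carlo estimates while keeping a full check quick on a laptop:
oracle equivalence on 20 random instances (n = 50–200); sign recovery on
100 sessions of ~300 trials; 1000 null datasets for the peak-test
calibration; 60 simulated scanning sessions for the BOLD round trip; 500
null and 100 effect replicates for the mixed-model suite. Each block
states its sizes inline.

# Known limitations

* The hazard model is fitted per session; sessions with few events are
  flagged, not pooled or shrunk.
* No within-trial time-varying covariates, frailty terms, or Efron tie
  handling.
* The BOLD forward model is a single-channel amplitude model; it does not
  simulate voxelwise data, physiological noise, or filtering, and the ROI
  pipeline performs no whole-brain inference.
* Under the censor-at-window convention, unconditional misses attenuate
  hazard coefficients (informative censoring); interpret coefficient
  magnitudes accordingly when miss rates are non-negligible.
* The leave-one-out peak t-test is anticonservative under a pure null
  with independent unit noise, as discussed above.
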