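#' Covariate layout of the action-time hazard model
#'
#' The hazard model of action time uses 23 covariates: the three contextual
#' factors of the current trial (reward magnitude in drops, dot-speed level
#' index with 1 = fastest, ITI in seconds) followed by the realized reward
#' outcome on each of the past `history_depth` trials and the observed
#' action time on each of the past `history_depth` trials.
#'
#' @param history_depth Number of past trials entering the model.
#' @return Character vector of covariate names, length `3 + 2 * history_depth`.
#' @export
cox_covariate_names <- function(history_depth = 10L) {
  c("magRew", "dotSpd", "ITI",
    paste0("rewOut_lag", seq_len(history_depth)),
    paste0("actTime_lag", seq_len(history_depth)))
}

#' Parameters of the proportional-hazards response agent
#'
#' The simulated animal decides when to respond through a discrete-time
#' hazard: at each dot `t` of a trial it responds with probability
#' `h0(t) * exp(beta . (x - ref))`, clipped to `[0, 1]`, where `x` holds
#' the 23 covariates of [cox_covariate_names()] built from the trial's
#' context and the realized history, and `ref` is a fixed reference point
#' (centering keeps the exponential moderate on the raw covariate scales;
#' hazard-model coefficient estimates are invariant to this shift). If no
#' hazard event fires by the last dot the agent responds at the last dot;
#' independently, with probability `miss_prob` a trial is missed outright
#' (no response, censored observation).
#'
#' `log_shift_main` and `log_shift_iti` are additive log-hazard shifts used
#' to emulate a pharmacological intervention: the effective log hazard
#' gains `log_shift_main + log_shift_iti * (ITI - ref["ITI"])`. They default
#' to zero; [simulate_experiment()] switches them on for treatment sessions.
#'
#' @param baseline_hazard Per-dot baseline hazard vector (length
#'   `max_dots`), each element in `[0, 1]`. The default rises
#'   logistically with the dot count (`0.25 * plogis(0.6 * (t - 12))`),
#'   mirroring the growing urgency as the reward probability saturates;
#'   it yields action times of about 14.6 +/- 4.1 dots with ~2% of
#'   trials reaching the end of the window, matching typical observed
#'   behavior (14-15 +/- 3-4 dots).
#' @param coefficients Named log-hazard-ratio vector over
#'   [cox_covariate_names()]; unnamed entries default to zero. A partial
#'   named vector is merged onto zeros.
#' @param miss_prob Probability of a missed (non-responded) trial.
#' @param history_depth Number of past trials in the covariate vector.
#' @param reference Named reference values for centering; defaults are
#'   typical values (reward 2 drops, speed level 2, ITI 5 s, past reward
#'   1 drop, past action time 12 dots).
#' @param log_shift_main,log_shift_iti Intervention log-hazard shifts.
#' @param max_dots Trial length in dots (must match the task config).
#' @return An object of class `"agent_params"`.
#' @export
agent_params <- function(baseline_hazard = NULL,
                         coefficients = NULL,
                         miss_prob = 0.05,
                         history_depth = 10L,
                         reference = NULL,
                         log_shift_main = 0,
                         log_shift_iti = 0,
                         max_dots = 25L) {
  nm <- cox_covariate_names(history_depth)
  if (is.list(coefficients)) coefficients <- unlist(coefficients)
  if (is.list(baseline_hazard)) baseline_hazard <- unlist(baseline_hazard)
  if (is.null(baseline_hazard)) {
    baseline_hazard <- 0.25 * stats::plogis(0.6 * (seq_len(max_dots) - 12))
  }
  if (length(baseline_hazard) != max_dots) {
    stop("baseline_hazard must have length max_dots (", max_dots, ")")
  }
  if (any(baseline_hazard < 0 | baseline_hazard > 1)) {
    stop("baseline hazards must lie in [0, 1]")
  }
  beta <- stats::setNames(numeric(length(nm)), nm)
  if (!is.null(coefficients)) {
    if (is.null(names(coefficients)) && length(coefficients) == length(nm)) {
      beta[] <- coefficients
    } else {
      bad <- setdiff(names(coefficients), nm)
      if (length(bad)) stop("unknown coefficient name(s): ",
                            paste(bad, collapse = ", "))
      beta[names(coefficients)] <- coefficients
    }
  }
  ref <- stats::setNames(numeric(length(nm)), nm)
  ref["magRew"] <- 2; ref["dotSpd"] <- 2; ref["ITI"] <- 5
  ref[grep("^rewOut_", nm)] <- 1
  ref[grep("^actTime_", nm)] <- 12
  if (!is.null(reference)) ref[names(reference)] <- reference
  structure(list(
    baseline_hazard = baseline_hazard,
    coefficients = beta,
    miss_prob = miss_prob,
    history_depth = as.integer(history_depth),
    reference = ref,
    log_shift_main = log_shift_main,
    log_shift_iti = log_shift_iti,
    max_dots = as.integer(max_dots)
  ), class = "agent_params")
}

# covariate vector for trial i given context and realized history;
# missing history (start of session) sits at the reference point
agent_covariates <- function(i, schedule, rew_hist, act_hist, params,
                             speed_levels) {
  x <- params$reference
  x["magRew"] <- schedule$reward_mag[i]
  x["dotSpd"] <- match(schedule$dot_speed_ms[i], speed_levels)
  x["ITI"] <- schedule$iti_s[i]
  for (k in seq_len(params$history_depth)) {
    j <- i - k
    if (j >= 1) {
      x[paste0("rewOut_lag", k)] <- rew_hist[j]
      x[paste0("actTime_lag", k)] <- act_hist[j]
    }
  }
  x
}

#' Simulate a behavioral session from a schedule
#'
#' Runs the proportional-hazards agent over a context schedule from
#' [make_schedule()]. Per trial, the per-dot response hazard is
#' `h0(t) * exp(beta . (x - ref))` clipped to `[0, 1]`; the action time is
#' the first dot at which a Bernoulli event fires (or the last dot if none
#' fires); the reward outcome is `reward_mag` drops with probability
#' [reward_probability()] at the action time, else 0. With probability
#' `miss_prob` a trial is missed: no response, reward 0, and the full dot
#' window elapses. History covariates use the realized past, with missed
#' predecessors contributing reward 0 and action time `max_dots`.
#'
#' Onset, response and outcome times are accumulated in seconds (dot `d`
#' appears `d * dot_speed / 1000` s after onset; outcome follows the
#' response by the action-outcome delay; the next trial starts after the
#' outcome display plus the ITI). Trials whose onset falls at or beyond
#' `config$session_duration_s` are dropped, as the task ends on the clock.
#'
#' @param schedule Context schedule from [make_schedule()].
#' @param params [agent_params()].
#' @param config [task_config()].
#' @param seed Optional integer seed.
#' @param session_id,subject_id,intervention,dose_phase,experiment Labels
#'   stamped onto every trial row.
#' @return A `data.frame` of completed trial records (one row per trial)
#'   with columns `session_id, subject_id, trial_index, design,
#'   intervention, dose_phase, experiment, reward_mag, dot_speed_ms, iti_s,
#'   responded, act_time_dots, reward_outcome, onset_s, response_s,
#'   outcome_s`.
#' @export
simulate_agent <- function(schedule, params, config, seed = NULL,
                           session_id = "s01", subject_id = "m1",
                           intervention = "control",
                           dose_phase = "maintenance",
                           experiment = "none") {
  stopifnot(nrow(schedule) >= 1, inherits(params, "agent_params"),
            inherits(config, "task_config"))
  if (length(params$coefficients) != 2L * params$history_depth + 3L) {
    stop("coefficient vector does not match the covariate layout")
  }
  if (params$max_dots != config$max_dots) {
    stop("agent max_dots must match the task config")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(schedule)
  responded <- logical(n)
  act <- rep(NA_integer_, n)
  rew <- integer(n)
  onset <- response <- outcome <- rep(NA_real_, n)
  rew_hist <- numeric(n)           # realized rewardOutcome (0 if missed)
  act_hist <- numeric(n)           # realized actTime (max_dots if missed)
  t_now <- 0
  kept <- 0L
  for (i in seq_len(n)) {
    if (t_now >= config$session_duration_s) break
    kept <- i
    onset[i] <- t_now
    spd <- schedule$dot_speed_ms[i] / 1000
    x <- agent_covariates(i, schedule, rew_hist, act_hist, params,
                          sort(config$dot_speeds_ms))
    eta <- sum(params$coefficients * (x - params$reference)) +
      params$log_shift_main +
      params$log_shift_iti * (x["ITI"] - params$reference["ITI"])
    if (stats::runif(1) < params$miss_prob) {
      responded[i] <- FALSE
      rew_hist[i] <- 0
      act_hist[i] <- config$max_dots
      t_now <- onset[i] + config$max_dots * spd + 0.3 +
        config$action_outcome_delay_s + schedule$iti_s[i]
    } else {
      haz <- pmin(pmax(params$baseline_hazard * exp(eta), 0), 1)
      u <- stats::runif(config$max_dots)
      hit <- which(u < haz)
      a <- if (length(hit)) hit[1] else config$max_dots
      responded[i] <- TRUE
      act[i] <- a
      rewarded <- stats::runif(1) < reward_probability(a, config)
      rew[i] <- if (rewarded) schedule$reward_mag[i] else 0L
      response[i] <- onset[i] + a * spd
      outcome[i] <- response[i] + config$action_outcome_delay_s
      rew_hist[i] <- rew[i]
      act_hist[i] <- a
      t_now <- outcome[i] + config$outcome_display_s + schedule$iti_s[i]
    }
  }
  idx <- seq_len(kept)
  data.frame(
    session_id = session_id, subject_id = subject_id,
    trial_index = schedule$trial_index[idx],
    design = schedule$design[idx],
    intervention = intervention, dose_phase = dose_phase,
    experiment = experiment,
    reward_mag = schedule$reward_mag[idx],
    dot_speed_ms = schedule$dot_speed_ms[idx],
    iti_s = schedule$iti_s[idx],
    responded = responded[idx],
    act_time_dots = act[idx],
    reward_outcome = rew[idx],
    onset_s = onset[idx], response_s = response[idx],
    outcome_s = outcome[idx],
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-subject, multi-session experiment
#'
#' Convenience wrapper that simulates a cohort performing the task over
#' several sessions, optionally under a within-subject crossover drug
#' intervention. Treatment sessions receive additive log-hazard shifts
#' (`drug_effect$main` plus `drug_effect$iti` per second of ITI away from
#' its reference), scaled by `dose_mult` for build-up-phase sessions,
#' mirroring a main drug effect and a drug-by-ITI interaction on the
#' response hazard.
#'
#' @param n_subjects Number of subjects.
#' @param sessions_per_subject Sessions per subject.
#' @param n_blocks ITI blocks per session.
#' @param config [task_config()].
#' @param params Base [agent_params()] (shared across subjects).
#' @param drug_effect List with `main` and `iti` log-hazard shifts applied
#'   in treatment sessions; `NULL` for no intervention (all control).
#' @param experiment Experiment label (e.g. `"citalopram"`,
#'   `"rivastigmine"`, `"none"`).
#' @param buildup_frac Fraction of sessions (rounded down) labelled
#'   `"build-up"`; the remainder are `"maintenance"`.
#' @param dose_mult Multiplier on the drug shifts during build-up.
#' @param seed Integer seed; per-session seeds are derived from it.
#' @return Combined trial `data.frame` across all subjects and sessions.
#' @export
simulate_experiment <- function(n_subjects = 4, sessions_per_subject = 10,
                                n_blocks = 3, config = task_config(),
                                params = agent_params(),
                                drug_effect = NULL,
                                experiment = "none",
                                buildup_frac = 0, dose_mult = 0.5,
                                seed = 1) {
  set.seed(seed)
  out <- vector("list", n_subjects * sessions_per_subject)
  k <- 0L
  n_build <- floor(buildup_frac * sessions_per_subject)
  for (s in seq_len(n_subjects)) {
    # within-subject crossover: alternate treatment/control sessions
    intv <- rep(c("treatment", "control"), length.out = sessions_per_subject)
    if (is.null(drug_effect)) intv <- rep("control", sessions_per_subject)
    for (j in seq_len(sessions_per_subject)) {
      phase <- if (j <= n_build) "build-up" else "maintenance"
      p <- params
      if (!is.null(drug_effect) && intv[j] == "treatment") {
        mult <- if (phase == "build-up") dose_mult else 1
        p$log_shift_main <- params$log_shift_main + mult * drug_effect$main
        p$log_shift_iti <- params$log_shift_iti + mult * drug_effect$iti
      }
      sched <- make_schedule(config, n_blocks)
      k <- k + 1L
      out[[k]] <- simulate_agent(
        sched, p, config,
        session_id = sprintf("m%d_s%02d", s, j),
        subject_id = sprintf("m%d", s),
        intervention = intv[j], dose_phase = phase,
        experiment = experiment
      )
    }
  }
  do.call(rbind, out)
}

#' Simulate per-volume artifact metrics with planted outliers
#'
#' Generates the per-volume quality metrics used by [censor_volumes()]:
#' baseline Gaussian noise with a known fraction of volumes displaced far
#' above the median, so the censoring rule has a ground truth to recover.
#'
#' @param n_volumes Number of volumes.
#' @param n_metrics Number of metric columns.
#' @param outlier_frac Fraction of volumes planted as outliers.
#' @param outlier_size Displacement of outliers, in SD units.
#' @param seed Optional seed.
#' @return A `data.frame` of metrics with attribute `"outliers"` holding
#'   the planted volume indices.
#' @export
simulate_artifact_metrics <- function(n_volumes, n_metrics = 3,
                                      outlier_frac = 0.06,
                                      outlier_size = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(n_volumes * n_metrics), n_volumes, n_metrics)
  n_out <- round(outlier_frac * n_volumes)
  bad <- sort(sample(n_volumes, n_out))
  m[bad, ] <- m[bad, ] + outlier_size
  out <- as.data.frame(m)
  names(out) <- paste0("metric", seq_len(n_metrics))
  attr(out, "outliers") <- bad
  out
}
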