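# Shared fixtures, built in code.

# A simulated session with given hazard coefficients and size.
sim_session <- function(n_blocks = 2, coefficients = NULL, seed = 1,
                        design = "balanced", miss_prob = 0,
                        baseline = NULL, session_id = "s01",
                        subject_id = "m1", duration = Inf, ...) {
  cfg <- task_config(design, session_duration_s = duration)
  sch <- make_schedule(cfg, n_blocks, seed = seed)
  if (length(baseline) == 1) baseline <- rep(baseline, cfg$max_dots)
  par <- agent_params(baseline_hazard = baseline,
                      coefficients = coefficients, miss_prob = miss_prob,
                      ...)
  simulate_agent(sch, par, cfg, seed = seed + 1000,
                 session_id = session_id, subject_id = subject_id)
}

# A synthetic trial table with a response generated directly from a mixed
# model (for inference-calibration suites): by-subject and by-session
# intercepts plus Gaussian noise, optional fixed effects on the coded
# intervention (0/1) and ITI (seconds).
sim_lmem_trials <- function(n_subjects = 4, sessions_per_subject = 10,
                            trials_per_session = 40,
                            b_intervention = 0, b_iti = 0,
                            b_interaction = 0,
                            sd_subject = 1, sd_session = 0.5,
                            sd_noise = 3, seed = 1) {
  set.seed(seed)
  out <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) {
    u <- rnorm(1, sd = sd_subject)
    intv <- rep(c("treatment", "control"),
                length.out = sessions_per_subject)
    for (j in seq_len(sessions_per_subject)) {
      v <- rnorm(1, sd = sd_session)
      iti <- sample(c(3, 5, 7), trials_per_session, replace = TRUE)
      iv <- as.numeric(intv[j] == "treatment")
      y <- 14 + u + v + b_intervention * iv + b_iti * iti +
        b_interaction * iv * iti + rnorm(trials_per_session, sd = sd_noise)
      k <- k + 1L
      out[[k]] <- data.frame(
        session_id = sprintf("m%d_s%02d", s, j),
        subject_id = sprintf("m%d", s),
        trial_index = seq_len(trials_per_session),
        design = "balanced", intervention = intv[j],
        dose_phase = "maintenance", experiment = "none",
        reward_mag = sample(1:3, trials_per_session, replace = TRUE),
        dot_speed_ms = sample(c(100L, 200L, 300L), trials_per_session,
                              replace = TRUE),
        iti_s = iti, responded = TRUE,
        act_time_dots = y,
        det_act_time_dots = y,
        reward_outcome = sample(0:3, trials_per_session, replace = TRUE),
        onset_s = seq_len(trials_per_session) * 20,
        response_s = seq_len(trials_per_session) * 20 + 2,
        outcome_s = seq_len(trials_per_session) * 20 + 6,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Expected peak of the HRF kernel after TR sampling and linear
# interpolation to the fine grid, averaged over uniform event phase.
# Independent forward-model oracle for the BOLD round trip: uses only the
# kernel and stats::approx, not the fitting pipeline.
interp_kernel_course <- function(tr = 2.28, dt = 0.1, peak_s = 3,
                                 window = c(-4, 4), n_phase = 57) {
  rel <- seq(window[1], window[2], by = dt)
  phases <- seq(0, tr, length.out = n_phase + 1)[-(n_phase + 1)]
  course <- rowMeans(vapply(phases, function(ph) {
    grid <- seq(-ceiling(8 / tr) * tr + ph, 20, by = tr)
    approx(grid, hrf_double_gamma(grid, peak_s), xout = rel, rule = 2)$y
  }, numeric(length(rel))))
  list(times = rel, course = course, peak = max(abs(course)))
}
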