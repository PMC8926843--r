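test_that("model matrices follow the published model structure", {
  trials <- rbind(
    simulate_experiment(2, 2, 2, task_config("balanced"), seed = 1),
    within(simulate_experiment(2, 2, 2, task_config("biased"), seed = 2), {
      session_id <- paste0(session_id, "b")
    })
  )
  mm <- build_model_matrix(trials, model_spec("GLM1.1"))
  expect_length(mm$fixed_cols, 11)
  expect_equal(mm$fixed_cols[1:6],
               c("env", "magRew", "dotSpd", "ITI", "rewOut_lag1",
                 "actTime_lag1"))
  expect_true(all(grepl("_x_env$", mm$fixed_cols[7:11])))
  expect_equal(mm$response, "act_time_dots")

  mm2 <- build_model_matrix(trials, model_spec("GLM1.2"))
  expect_false(any(c("magRew", "dotSpd") %in% mm2$fixed_cols))
  expect_length(mm2$fixed_cols, 7)
  # the medium-offer subset keeps only medium reward at medium speed
  expect_lt(nrow(mm2$data), nrow(mm$data))

  # first trial of each session is dropped (no lagged covariates);
  # missed trials are dropped from the observed-actTime response
  n_sessions <- length(unique(trials$session_id))
  n_resp <- sum(trials$responded)
  first_resp <- sum(vapply(split(trials, trials$session_id),
                           function(s) s$responded[1], logical(1)))
  expect_equal(nrow(mm$data), n_resp - first_resp)

  expect_error(build_model_matrix(trials[, -match("reward_mag",
                                                  names(trials))],
                                  model_spec("GLM1.1")), "reward_mag")
  expect_error(build_model_matrix(trials, model_spec("GLM3.2")),
               "det_act_time_dots")
})

test_that("model matrices are reproducible bit for bit", {
  trials <- simulate_experiment(2, 2, 2, seed = 3,
                                drug_effect = list(main = 0.3, iti = 0))
  a <- build_model_matrix(trials, model_spec("GLM3.1"))
  b <- build_model_matrix(trials, model_spec("GLM3.1"))
  expect_identical(a$data, b$data)
})

test_that("the grand model pools experiments with their interaction", {
  spec <- model_spec("GRAND")
  expect_true("experiment" %in% spec$fixed)
  expect_true("experiment:intervention" %in% spec$fixed)
  tr <- rbind(
    simulate_experiment(2, 4, 2, seed = 4,
                        drug_effect = list(main = 0.3, iti = 0),
                        experiment = "citalopram"),
    within(simulate_experiment(2, 4, 2, seed = 5,
                               drug_effect = list(main = -0.3, iti = 0),
                               experiment = "rivastigmine"), {
      session_id <- paste0(session_id, "r")
    })
  )
  mm <- build_model_matrix(tr, spec)
  expect_true(all(c("experiment", "experiment_x_intervention") %in%
                    mm$fixed_cols))
})

test_that("zero group variance reduces the mixed fit to OLS", {
  tr <- sim_lmem_trials(n_subjects = 3, sessions_per_subject = 4,
                        trials_per_session = 50, b_intervention = 0.5,
                        sd_subject = 0, sd_session = 0, sd_noise = 1,
                        seed = 6)
  spec <- model_spec("GLM3.2")
  mm <- build_model_matrix(tr, spec)
  fit <- fit_lmem(mm)
  ols <- lm(det_act_time_dots ~ intervention, data = mm$data)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-6)
  expect_true(fit$singular)  # variance components collapse to zero
})

test_that("an injected intervention effect is detected with its sign", {
  tr <- sim_lmem_trials(b_intervention = -0.8, sd_noise = 2, seed = 7)
  fit <- fit_lmem(build_model_matrix(tr, model_spec("GLM3.2")))
  est <- fit$coefficients$estimate[fit$coefficients$term == "intervention"]
  expect_lt(est, 0)
  expect_lt(fit$wald$p[fit$wald$term == "intervention"], 0.05)
  expect_equal(unname(fit$n_groups["subjects"]), 4L)
})

test_that("wald table covers every fixed term with valid p-values", {
  tr <- sim_lmem_trials(b_interaction = 0.2, seed = 8)
  spec <- list(name = "custom", response = "act_time_dots",
               fixed = c("intervention", "ITI", "intervention:ITI"),
               subset = NULL, session_intercept = TRUE)
  fit <- fit_lmem(build_model_matrix(tr, spec))
  expect_setequal(fit$wald$term,
                  c("intervention", "ITI", "intervention_x_ITI"))
  expect_true(all(fit$wald$df >= 1))
  expect_true(all(fit$wald$p >= 0 & fit$wald$p <= 1))
})

test_that("missed-trial proportions are counted per condition", {
  tr <- data.frame(
    design = rep(c("balanced", "biased"), each = 100),
    responded = c(rep(c(TRUE, FALSE), c(90, 10)),
                  rep(c(TRUE, FALSE), c(80, 20))))
  out <- miss_rate_summary(tr, "design")
  expect_equal(out$table$prop_missed, c(0.10, 0.20))
  expect_true(is.finite(out$chisq))
  all_resp <- data.frame(design = tr$design, responded = TRUE)
  out2 <- miss_rate_summary(all_resp, "design")
  expect_true(all(out2$table$prop_missed == 0))
})
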