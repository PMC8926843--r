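# random small survival instance with discrete tied times
rand_cox_instance <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- runif(p, -0.5, 0.5)
  h <- pmin(0.08 * exp(drop(X %*% beta)), 1)
  time <- integer(n); status <- integer(n)
  for (i in seq_len(n)) {
    hit <- which(runif(25) < h[i])
    if (length(hit)) { time[i] <- hit[1]; status[i] <- 1L }
    else { time[i] <- 25L; status[i] <- rbinom(1, 1, 0.5) }
  }
  list(X = X, time = time, status = status, beta = beta)
}

test_that("design matrix has 23 covariates and the stated row geometry", {
  ses <- sim_session(n_blocks = 2, seed = 10)   # 60 trials, all responded
  dsn <- build_cox_design(ses)
  expect_equal(dim(dsn$X), c(50L, 23L))
  expect_equal(colnames(dsn$X), cox_covariate_names(10))
  expect_true(all(dsn$status == 1))
  expect_warning(build_cox_design(ses[1:10, ]), "no design rows")
})

test_that("missed trials are censored at the dot window", {
  ses <- sim_session(n_blocks = 2, seed = 11)
  ses$responded[15] <- FALSE
  ses$act_time_dots[15] <- NA
  ses$reward_outcome[15] <- 0L
  dsn <- build_cox_design(ses)
  row15 <- which(dsn$trial_index == 15)
  expect_equal(dsn$status[row15], 0L)
  expect_equal(dsn$time[row15], 25L)
  # the missed trial enters later histories as reward 0, actTime 25
  row16 <- which(dsn$trial_index == 16)
  expect_equal(unname(dsn$X[row16, "rewOut_lag1"]), 0)
  expect_equal(unname(dsn$X[row16, "actTime_lag1"]), 25)
  row20 <- which(dsn$trial_index == 20)
  expect_equal(unname(dsn$X[row20, "actTime_lag5"]), 25)
})

test_that("coefficients, errors and baseline match the survival oracle", {
  skip_if_not_installed("survival")
  for (r in 1:20) {
    inst <- rand_cox_instance(n = sample(50:200, 1), p = sample(3:6, 1),
                              seed = 100 + r)
    fit <- fit_cox(inst$X, time = inst$time, status = inst$status,
                   min_events = 1)
    ref <- survival::coxph(survival::Surv(inst$time, inst$status) ~ inst$X,
                           ties = "breslow")
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-4)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-4)
    bh <- survival::basehaz(ref, centered = FALSE)
    bh <- bh[match(fit$baseline$time, bh$time), ]
    expect_equal(fit$baseline$cumhaz, bh$hazard, tolerance = 1e-4)
  }
})

test_that("a true hazard ratio of 2 is recovered within its 95% CI", {
  set.seed(21)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  h <- 0.06 * 2^x
  time <- integer(n); status <- integer(n)
  for (i in seq_len(n)) {
    hit <- which(runif(25) < h[i])
    if (length(hit)) { time[i] <- hit[1]; status[i] <- 1L }
    else { time[i] <- 25L; status[i] <- 0L }
  }
  X <- cbind(group = x, noise = rnorm(n))
  fit <- fit_cox(X, time = time, status = status, min_events = 1)
  expect_lt(abs(fit$coef["group"] - log(2)), 1.96 * fit$se["group"])
})

test_that("non-identifiable designs are rejected by name", {
  inst <- rand_cox_instance(60, 3, seed = 31)
  X <- inst$X; X[, 2] <- 1.5
  expect_error(fit_cox(X, time = inst$time, status = inst$status),
               "x2")
  expect_error(fit_cox(matrix(0, 60, 2), time = inst$time,
                       status = inst$status), "not identifiable")
})

test_that("partial likelihood never decreases across Newton iterations", {
  ses <- sim_session(n_blocks = 4, seed = 32, miss_prob = 0.1,
                     coefficients = c(magRew = 0.3, ITI = -0.2))
  fit <- suppressWarnings(fit_cox(build_cox_design(ses)))
  expect_true(fit$converged)
  expect_gte(fit$loglik[2], fit$loglik[1])
})

test_that("cumulative hazard scales as exp(beta . x)", {
  inst <- rand_cox_instance(120, 3, seed = 41)
  fit <- fit_cox(inst$X, time = inst$time, status = inst$status,
                 min_events = 1)
  L0 <- cumulative_hazard(fit, rep(0, 3))
  expect_equal(L0(0), 0)
  expect_equal(L0(fit$baseline$time), fit$baseline$cumhaz)
  # beta . x = log 2 doubles the curve pointwise
  x2 <- c(log(2) / fit$coef[1], 0, 0)
  L2 <- cumulative_hazard(fit, x2)
  expect_equal(L2(1:25), 2 * L0(1:25))
  # held-out covariates: direct re-summation over risk sets
  xh <- c(0.3, -0.2, 0.1)
  w <- exp(drop(inst$X %*% fit$coef))
  brute <- sapply(1:25, function(t) {
    ev <- fit$baseline$time[fit$baseline$time <= t]
    sum(sapply(ev, function(tj) {
      sum(inst$time == tj & inst$status == 1) / sum(w[inst$time >= tj])
    }))
  }) * exp(sum(fit$coef * xh))
  Lh <- cumulative_hazard(fit, xh)
  expect_equal(Lh(1:25), brute, tolerance = 1e-12)
  expect_error(cumulative_hazard(fit, rep(0, 5)), "length")
})

test_that("survival curves are proper and match the constant-hazard form", {
  inst <- rand_cox_instance(120, 3, seed = 42)
  fit <- fit_cox(inst$X, time = inst$time, status = inst$status,
                 min_events = 1)
  s <- survival_curve(fit, c(0.2, 0.1, -0.3))
  expect_equal(s$survival[s$time == 0], 1)
  expect_true(all(diff(s$survival) <= 1e-12))
  expect_true(all(s$survival >= 0 & s$survival <= 1))

  # discrete constant hazard h: fitted S(t) ~ (1-h)^t. The Breslow curve
  # is exp(-h t), which differs from the product-limit form by at most
  # t h^2/2 * S(t) (< 0.02 at h = 0.1); allow that plus estimator noise.
  set.seed(43)
  h <- 0.1; n <- 5000
  time <- pmin(rgeom(n, h) + 1, 25)
  status <- as.integer(time < 25 | runif(n) < h)
  X <- cbind(z = rnorm(n))
  fitc <- fit_cox(X, time = time, status = status, min_events = 1)
  sc <- survival_curve(fitc, 0)
  expect_lt(max(abs(sc$survival[match(1:25, sc$time)] - (1 - h)^(1:25))),
            0.03)
})

test_that("deterministic action time is the survival-curve expectation", {
  # full survival over the window -> maximal expected action time
  s1 <- structure(data.frame(time = 0:25, survival = 1),
                  class = c("survival_curve", "data.frame"))
  expect_equal(deterministic_acttime(s1), 25)

  inst <- rand_cox_instance(150, 3, seed = 44)
  fit <- fit_cox(inst$X, time = inst$time, status = inst$status,
                 min_events = 1)
  # brute force: enumerate the fitted discrete distribution and take the
  # expectation, with survival re-summed from raw risk sets
  w <- exp(drop(inst$X %*% fit$coef))
  for (r in 1:5) {
    set.seed(50 + r)
    xh <- rnorm(3, sd = 0.3)
    S <- sapply(1:26, function(t) {
      ev <- fit$baseline$time[fit$baseline$time <= min(t, 25)]
      L0 <- sum(sapply(ev, function(tj) {
        sum(inst$time == tj & inst$status == 1) / sum(w[inst$time >= tj])
      }))
      exp(-L0 * exp(sum(fit$coef * xh)))
    })
    mass <- S[1:24] - S[2:25]          # event mass attributed to dot t
    brute <- sum((1:24) * mass) + 25 * S[25]
    expect_equal(deterministic_acttime(fit, xh), brute, tolerance = 1e-10)
  }

  # monotone decreasing in the risk score
  risk <- function(x) sum(fit$coef * x)
  xa <- c(0.5, 0, 0); xb <- c(-0.5, 0, 0)
  if (risk(xa) < risk(xb)) { tmp <- xa; xa <- xb; xb <- tmp }
  expect_lt(deterministic_acttime(fit, xa), deterministic_acttime(fit, xb))
})

test_that("constant-hazard expectation matches the truncated-geometric sum", {
  set.seed(45)
  h <- 0.05; n <- 5000
  time <- pmin(rgeom(n, h) + 1, 25)
  status <- as.integer(time < 25)
  X <- cbind(z = rnorm(n))
  fit <- fit_cox(X, time = time, status = status, min_events = 1)
  # Breslow discretization bound: sum_t t h^2/2 e^{-ht} ~ 0.19 at h=.05
  expect_lt(abs(deterministic_acttime(fit, 0) - sum((1 - h)^(1:25))), 0.3)
})

test_that("pooled sessions recover the generative coefficients", {
  # round trip under the model's own assumptions: misses are disabled
  # because unconditionally missed trials censored at the window end are
  # informative censoring, which attenuates any proportional-hazards fit
  beta_true <- c(magRew = 0.3, ITI = -0.25, rewOut_lag1 = 0.25)
  designs <- lapply(1:40, function(s) {
    build_cox_design(sim_session(n_blocks = 3, seed = 600 + s,
                                 coefficients = beta_true,
                                 miss_prob = 0,
                                 session_id = sprintf("s%02d", s)))
  })
  X <- do.call(rbind, lapply(designs, `[[`, "X"))
  fit <- fit_cox(X, time = unlist(lapply(designs, `[[`, "time")),
                 status = unlist(lapply(designs, `[[`, "status")))
  err <- abs(fit$coef[names(beta_true)] - beta_true) / abs(beta_true)
  expect_lt(mean(err), 0.15)
})

test_that("per-session deterministic action times are tabulated", {
  trials <- rbind(sim_session(2, seed = 71, session_id = "a"),
                  sim_session(2, seed = 72, session_id = "b"))
  det <- suppressWarnings(det_acttime_table(trials))
  expect_setequal(unique(det$session_id), c("a", "b"))
  expect_equal(nrow(det), 100)  # 50 complete-history rows per session
  expect_true(all(det$det_act_time_dots > 0 & det$det_act_time_dots <= 25))
})
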