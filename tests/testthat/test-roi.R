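make_series <- function(values, dt = 0.1, tr = 2.28) {
  structure(list(values = values, time_s = (seq_along(values) - 1) * dt,
                 dt = dt, tr = tr, roi_label = "toy"),
            class = "roi_series")
}

test_that("volume censoring follows the median + 2.5 SD rule", {
  expect_equal(sum(censor_volumes(data.frame(m = rep(1, 50)))), 0)
  set.seed(1)
  m <- data.frame(m = rnorm(200))
  m$m[37] <- median(m$m) + 10 * sd(m$m)
  expect_true(censor_volumes(m)[37])
  met <- simulate_artifact_metrics(1000, outlier_frac = 0.06, seed = 2)
  mask <- censor_volumes(met)
  expect_setequal(which(mask), attr(met, "outliers"))
  expect_equal(attr(mask, "censored_fraction"), 0.06)
  expect_error(censor_volumes(data.frame()[1:5, , drop = FALSE]),
               "at least one metric")
})

test_that("preprocessing averages voxels, normalizes and upsamples", {
  expect_warning(out <- preprocess_roi(rep(3, 40)), "constant")
  expect_true(all(out$values == 0))
  # voxel averaging happens before normalization
  a <- sin(seq_len(40)); b <- cos(seq_len(40))
  two <- preprocess_roi(cbind(a, b), upsample_dt = 2.28)
  avg <- preprocess_roi((a + b) / 2, upsample_dt = 2.28)
  expect_equal(two$values, avg$values)
  expect_error(preprocess_roi(rnorm(10), censored_mask = rep(TRUE, 10)),
               "all volumes censored")
})

test_that("linear upsampling meets the interpolation-error bound", {
  tr <- 2.28; f <- 1 / 60
  tt <- (0:199) * tr
  x <- sin(2 * pi * f * tt)
  out <- preprocess_roi(x, tr = tr, upsample_dt = 0.1, normalize = FALSE)
  truth <- sin(2 * pi * f * out$time_s)
  bound <- (2 * pi * f)^2 * tr^2 / 8    # max |f''| h^2 / 8
  expect_lt(max(abs(out$values - truth)), bound * 1.0001)
})

test_that("epoching yields the stated window geometry", {
  ser <- make_series(rnorm(1000))
  ep <- epoch_series(ser, event_times = c(10, 30, 50), window = c(0, 8))
  expect_equal(dim(ep$data), c(3L, 81L))
  expect_equal(ep$times[1], 0)
  expect_equal(ep$times[81], 8)
  # an isolated unit impulse reappears at lag zero
  v <- rep(0, 1000); v[301] <- 1        # t = 30.0
  epi <- epoch_series(make_series(v), 30, window = c(0, 8))
  expect_equal(epi$data[1, ], c(1, rep(0, 80)))
  expect_warning(epoch_series(ser, c(50, 98), window = c(0, 8)), "dropped")
  expect_error(epoch_series(ser, 1e5, window = c(0, 8)), "no events")
})

test_that("epochs align to simulated responses within one fine-grid step", {
  ses <- sim_session(n_blocks = 2, seed = 21)
  bc <- bold_config(noise_sd = 0, channels = list(R = list(event = 1)))
  ch <- simulate_bold(ses, bc)
  roi <- preprocess_roi(ch$R, tr = 2.28, normalize = FALSE)
  ep <- suppressWarnings(
    epoch_series(roi, ses$response_s[ses$responded], window = c(0, 8)))
  # mean epoch peaks at the HRF peak as smeared by TR interpolation
  k <- interp_kernel_course(window = c(0, 8))
  peak_obs <- ep$times[which.max(colMeans(ep$data))]
  peak_exp <- k$times[which.max(k$course)]
  expect_lt(abs(peak_obs - peak_exp), 0.5)
})

test_that("per-timestep OLS reproduces exact identities", {
  set.seed(31)
  n <- 40; nt <- 21
  obs <- rnorm(n); tim <- seq_len(n)
  design <- data.frame(obs_act = obs, time = tim)
  z <- function(x) (x - mean(x)) / sd(x)
  # BOLD equal to a regressor: unit beta on it, zero on the rest
  Y <- matrix(z(obs), n, nt)
  ep <- structure(list(data = Y, times = seq_len(nt), events = seq_len(n),
                       kept = seq_len(n), lock_event = "response"),
                  class = "epoch_matrix")
  fit <- fit_timestep_glm(ep, design, "GLM2.1")
  expect_equal(unname(fit$beta["obs_act", ]), rep(1, nt), tolerance = 1e-12)
  expect_equal(unname(fit$beta["time", ]), rep(0, nt), tolerance = 1e-12)
  expect_equal(unname(fit$beta["intercept", ]), rep(0, nt),
               tolerance = 1e-12)
  # known mixture of two orthonormal-ized regressors
  a <- z(rnorm(n)); b <- z(residuals(lm(rnorm(n) ~ a)))
  Y2 <- outer(0.7 * a + 0.3 * b, rep(1, nt))
  ep$data <- Y2
  fit2 <- fit_timestep_glm(ep, data.frame(obs_act = a, time = b), "GLM2.1")
  expect_equal(unname(fit2$beta["obs_act", 1]), 0.7, tolerance = 1e-10)
  expect_equal(unname(fit2$beta["time", 1]), 0.3, tolerance = 1e-10)
})

test_that("per-timestep OLS equals the brute-force normal equations", {
  set.seed(32)
  n <- 60; nt <- 15
  design <- data.frame(det_act = rnorm(n), obs_act = rnorm(n),
                       time = rnorm(n))
  Y <- matrix(rnorm(n * nt), n, nt)
  ep <- structure(list(data = Y, times = seq_len(nt), events = seq_len(n),
                       kept = seq_len(n), lock_event = "response"),
                  class = "epoch_matrix")
  fit <- fit_timestep_glm(ep, design, "GLM2.2")
  z <- function(x) (x - mean(x)) / sd(x)
  X <- cbind(1, z(design$det_act), z(design$obs_act), z(design$time))
  for (j in c(1, 7, 15)) {
    brute <- solve(crossprod(X), crossprod(X, Y[, j]))
    expect_lt(max(abs(fit$beta[, j] - brute)), 1e-10)
  }
  # rank deficiency is reported with the aliased column
  design$det_act <- design$obs_act
  expect_error(fit_timestep_glm(ep, design, "GLM2.2"), "aliased")
})

test_that("PPI design demands aligned rows and a varying moderator", {
  ser <- make_series(rnorm(2000))
  ep <- epoch_series(ser, c(20, 60, 100, 140), window = c(0, 8))
  expect_error(build_ppi_design(ep, psych = 1:3), "misaligned")
  expect_error(build_ppi_design(ep, psych = rep(2, 4)), "collinear")
  d <- build_ppi_design(ep, psych = c(1, 2, 3, 4))
  expect_equal(mean(d$psych_centered), 0)
  expect_equal(dim(d$seed), dim(ep$data))
})

test_that("leave-one-out peak mechanics match a hand computation", {
  b <- rbind(c(0.1, 0.9, 0.2),
             c(0.2, 0.8, 0.1),
             c(0.0, 0.7, 0.3),
             c(0.3, 1.0, 0.0))
  r <- loo_peak_test(b, times = c(-1, 0, 1))
  # every leave-one-out mean peaks at the middle timepoint
  expect_equal(r$peak_times, rep(0, 4))
  expect_equal(r$held_out_betas, b[, 2])
  expect_equal(r$peak_time, 0)
  tt <- t.test(b[, 2])
  expect_equal(r$t_stat, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)
  expect_error(loo_peak_test(b[1:2, ]), "at least 3")
  # identical courses: degenerate spread is flagged
  expect_warning(rd <- loo_peak_test(matrix(0.4, 5, 7)), "zero spread")
  expect_true(rd$degenerate)
})

test_that("ties in the group mean resolve to the earliest timepoint", {
  b <- rbind(c(0.5, 0.5, 0.1),
             c(0.5, 0.5, 0.1),
             c(0.5, 0.5, 0.1),
             c(0.5, 0.5, 0.2))
  r <- suppressWarnings(loo_peak_test(b, times = c(1, 2, 3)))
  expect_true(all(r$peak_times == 1))
})

test_that("paired contrast compares held-out betas across conditions", {
  set.seed(41)
  ba <- matrix(rnorm(10 * 9, mean = 2.5), 10, 9)
  bb <- matrix(rnorm(10 * 9, mean = 0.0), 10, 9)
  r <- loo_peak_compare(ba, bb)
  expect_lt(r$p, 0.01)
  rw <- loo_peak_compare(ba, bb, method = "wilcoxon")
  expect_lt(rw$p, 0.01)
})
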