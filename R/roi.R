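#' Censor volumes from artifact metrics
#'
#' A volume is censored when any quality metric exceeds the metric's
#' median plus `k` standard deviations (the threshold is chosen to keep
#' the censored fraction below about 10% in practice). Metrics with zero
#' spread censor nothing.
#'
#' @param metrics `data.frame` or matrix of per-volume artifact metrics
#'   (at least one column).
#' @param k SD multiplier above the median.
#' @return Logical censor mask (TRUE = censored) with attribute
#'   `"censored_fraction"`.
#' @export
censor_volumes <- function(metrics, k = 2.5) {
  metrics <- as.matrix(metrics)
  if (ncol(metrics) < 1) stop("at least one metric column is required")
  mask <- rep(FALSE, nrow(metrics))
  for (j in seq_len(ncol(metrics))) {
    s <- stats::sd(metrics[, j])
    if (is.na(s) || s == 0) next
    mask <- mask | (metrics[, j] > stats::median(metrics[, j]) + k * s)
  }
  frac <- mean(mask)
  if (frac > 0.10) {
    warning(sprintf("censored fraction %.1f%% exceeds the 10%% budget",
                    100 * frac))
  }
  attr(mask, "censored_fraction") <- frac
  mask
}

#' Preprocess an ROI series: average, normalize, upsample
#'
#' Multi-voxel input is averaged across voxels, the series is z-scored
#' over uncensored volumes (a constant series normalizes to all zeros,
#' with a warning), and linearly interpolated from the TR grid to a fine
#' grid of step `upsample_dt`, bridging censored volumes.
#'
#' @param x Numeric vector (one channel at the TR grid) or matrix with
#'   volumes in rows and voxels in columns.
#' @param censored_mask Optional logical mask from [censor_volumes()].
#' @param tr Repetition time, seconds.
#' @param upsample_dt Fine-grid step, seconds.
#' @param roi_label Name carried on the result.
#' @param normalize Z-score over uncensored volumes (the standard
#'   preprocessing). Set `FALSE` to keep the raw signal scale, e.g. when
#'   validating recovery of injected effect sizes in their own units.
#' @return An object of class `"roi_series"`: list with `values`,
#'   `time_s`, `dt`, `tr`, `roi_label`.
#' @export
preprocess_roi <- function(x, censored_mask = NULL, tr = 2.28,
                           upsample_dt = 0.1, roi_label = "roi",
                           normalize = TRUE) {
  v <- if (is.matrix(x)) rowMeans(x) else as.numeric(x)
  n <- length(v)
  if (is.null(censored_mask)) censored_mask <- rep(FALSE, n)
  stopifnot(length(censored_mask) == n)
  keep <- !censored_mask
  if (!any(keep)) stop("all volumes censored")
  if (normalize) {
    z <- zscore(v[keep], warn = FALSE)
    if (stats::sd(v[keep]) == 0) {
      warning("constant series z-scored to all zeros")
    }
  } else {
    z <- v[keep]
  }
  tcoarse <- (seq_len(n) - 1) * tr
  tfine <- seq(0, tcoarse[n], by = upsample_dt)
  vals <- stats::approx(tcoarse[keep], z, xout = tfine, rule = 2)$y
  structure(list(values = vals, time_s = tfine, dt = upsample_dt, tr = tr,
                 roi_label = roi_label), class = "roi_series")
}

#' Epoch an ROI series around events
#'
#' Cuts the upsampled series into trial epochs on a window relative to
#' each lock event (trial onset for decision-locked analyses, response
#' time for response-locked analyses). Events whose window extends beyond
#' the series span are dropped with a warning. The window always spans
#' 8 s in the standard analyses (`c(0, 8)` onset-locked, `c(-4, 4)`
#' response-locked).
#'
#' @param series An `"roi_series"` from [preprocess_roi()].
#' @param event_times Event times in seconds (responded trials only).
#' @param window Length-2 window in seconds relative to the event.
#' @param lock_event Label (`"onset"` or `"response"`).
#' @return An object of class `"epoch_matrix"`: `data` (trials x
#'   timepoints), `times` (relative grid), `events` (kept event times),
#'   `kept` (indices into `event_times`), `lock_event`.
#' @export
epoch_series <- function(series, event_times, window = c(0, 8),
                         lock_event = "response") {
  stopifnot(inherits(series, "roi_series"), length(window) == 2)
  rel <- seq(window[1], window[2], by = series$dt)
  span <- range(series$time_s)
  ok <- event_times + window[1] >= span[1] - 1e-9 &
    event_times + window[2] <= span[2] + 1e-9
  if (!any(ok)) stop("no events with a complete window inside the series")
  if (any(!ok)) {
    warning(sum(!ok), " event(s) dropped: window extends beyond the series")
  }
  ev <- event_times[ok]
  idx_of <- function(t) round(t / series$dt) + 1
  data <- t(vapply(ev, function(e) series$values[idx_of(e + rel)],
                   numeric(length(rel))))
  structure(list(data = data, times = rel, events = ev, kept = which(ok),
                 lock_event = lock_event), class = "epoch_matrix")
}

roi_models <- list(
  GLM2.1 = c("obs_act", "time"),
  GLM2.2 = c("det_act", "obs_act", "time"),
  GLM2.3 = c("env", "obs_act", "env_x_obs_act", "time"),
  GLM2.4 = c("seed", "obs_act", "ppi", "time")
)

# z-score columns of a per-trial design, flagging rank deficiency
build_static_design <- function(design, cols) {
  missing_cols <- setdiff(cols, names(design))
  if (length(missing_cols)) {
    stop("design lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  Xz <- vapply(cols, function(cn) zscore(design[[cn]], warn = FALSE),
               numeric(nrow(design)))
  X <- cbind(intercept = 1, Xz)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  X
}

#' Fit per-timestep OLS GLMs to epoched BOLD
#'
#' At each timepoint of the epoch window, regresses the across-trial BOLD
#' values on the model's regressors by ordinary least squares, yielding
#' one beta time course per regressor. Per-trial regressors are z-scored
#' across trials before fitting. Models: `GLM2.1` (observed action time +
#' session-time confound), `GLM2.2` (adds the deterministic action time),
#' `GLM2.3` (environment, observed action time and their interaction, on
#' medium-offer trials), `GLM2.4` (PPI: seed BOLD, psychological variable
#' and their interaction; pass a [build_ppi_design()] as `design`).
#'
#' @param epochs An `"epoch_matrix"`.
#' @param design Per-trial regressor table with rows matching epoch rows:
#'   a `data.frame` with columns `obs_act`, `time` and, as needed,
#'   `det_act`, `env`; or a `"ppi_design"` for `GLM2.4`.
#' @param model Model label in `names(roi_models)`, or a character vector
#'   of design column names for a custom model.
#' @return An object of class `"timestep_glm"`: `beta` (regressors x
#'   timepoints, intercept included), `times`, `regressor_names`, `model`.
#' @export
fit_timestep_glm <- function(epochs, design, model = "GLM2.1") {
  stopifnot(inherits(epochs, "epoch_matrix"))
  Y <- epochs$data
  cols <- if (length(model) == 1 && model %in% names(roi_models)) {
    roi_models[[model]]
  } else {
    model
  }
  if (inherits(design, "ppi_design")) {
    if (nrow(design$seed) != nrow(Y)) {
      stop("PPI design rows do not match epoch rows")
    }
    nt <- length(epochs$times)
    p <- 5L
    beta <- matrix(NA_real_, p, nt,
                   dimnames = list(c("intercept", "seed", "obs_act",
                                     "ppi", "time"), NULL))
    psych_z <- zscore(design$psych, warn = FALSE)
    time_z <- zscore(design$time, warn = FALSE)
    for (j in seq_len(nt)) {
      sc <- design$seed[, j] - mean(design$seed[, j])
      ppi <- sc * design$psych_centered
      X <- cbind(1, zscore(sc, warn = FALSE), psych_z,
                 zscore(ppi, warn = FALSE), time_z)
      beta[, j] <- qr.coef(qr(X), Y[, j])
    }
    model <- "GLM2.4"
  } else {
    if (is.data.frame(design) && nrow(design) != nrow(Y)) {
      stop("design rows do not match epoch rows")
    }
    if (identical(model, "GLM2.3") && is.null(design$env_x_obs_act)) {
      ec <- design$env - mean(design$env)
      ac <- design$obs_act - mean(design$obs_act)
      design$env_x_obs_act <- ec * ac
    }
    X <- build_static_design(design, cols)
    beta <- qr.coef(qr(X), Y)
    rownames(beta) <- colnames(X)
    if (length(model) > 1) model <- "custom"
  }
  structure(list(beta = beta, times = epochs$times,
                 regressor_names = rownames(beta), model = model),
            class = "timestep_glm")
}

#' Build PPI regressors from seed epochs and a psychological variable
#'
#' Constructs the regressor set of the psychophysiological-interaction
#' model: the seed region's epoched BOLD, the psychological variable, and
#' their interaction, plus the session-time confound. Seed (per timestep)
#' and psychological variable are mean-centered before forming the
#' product, the standard construction that keeps the interaction
#' interpretable as coupling modulation. A constant psychological variable
#' makes the interaction collinear with the seed and is rejected.
#'
#' @param seed_epochs `"epoch_matrix"` of the seed region, row-aligned
#'   with the target epochs.
#' @param psych Per-trial psychological variable (e.g. observed action
#'   time), one value per epoch row.
#' @param time Per-trial session-time confound (trial onsets); defaults to
#'   the epoch events.
#' @return An object of class `"ppi_design"`.
#' @export
build_ppi_design <- function(seed_epochs, psych, time = NULL) {
  stopifnot(inherits(seed_epochs, "epoch_matrix"))
  if (length(psych) != nrow(seed_epochs$data)) {
    stop("psych must have one value per epoch row (misaligned rows)")
  }
  if (stats::sd(psych) == 0) {
    stop("psychological variable is constant: PPI column would be ",
         "collinear with the seed")
  }
  if (is.null(time)) time <- seed_epochs$events
  structure(list(seed = seed_epochs$data,
                 psych = psych,
                 psych_centered = psych - mean(psych),
                 time = time,
                 times = seed_epochs$times), class = "ppi_design")
}

#' Leave-one-out test on the group peak of beta time courses
#'
#' For each unit (scanning session, or animal for pooled analyses), the
#' group mean beta course is computed over all *other* units and its
#' (positive or negative) peak located as the extremum of the absolute
#' mean within the full epoch window (earliest timepoint on ties); the
#' held-out unit's beta at that timepoint is recorded. Because each peak
#' is selected independently of the unit evaluated there, the resulting
#' betas are free of temporal selection bias and a two-tailed one-sample
#' t-test applies.
#'
#' @param betas Units x timepoints matrix of beta courses for one
#'   regressor (at least 3 units).
#' @param times Optional timepoint grid (seconds) for reporting.
#' @param mu Null value of the mean held-out beta.
#' @return An object of class `"loo_peak"`: `held_out_betas`,
#'   `peak_times` (per unit), `peak_time` (full-group peak, for
#'   reporting), `t_stat`, `df`, `p`, `cohens_d`, `degenerate` (TRUE when
#'   the held-out betas have zero spread), `n_units`.
#' @export
loo_peak_test <- function(betas, times = NULL, mu = 0) {
  betas <- as.matrix(betas)
  n <- nrow(betas)
  if (n < 3) stop("at least 3 units are required")
  if (is.null(times)) times <- seq_len(ncol(betas))
  tot <- colSums(betas)
  held <- numeric(n)
  pk <- integer(n)
  for (i in seq_len(n)) {
    m <- (tot - betas[i, ]) / (n - 1)
    pk[i] <- which.max(abs(m))           # earliest on ties
    held[i] <- betas[i, pk[i]]
  }
  grp_pk <- which.max(abs(colMeans(betas)))
  s <- stats::sd(held)
  degenerate <- s == 0
  if (degenerate) {
    tt <- list(statistic = c(t = Inf * sign(mean(held) - mu)),
               parameter = c(df = n - 1), p.value = 0)
    d <- Inf * sign(mean(held) - mu)
    warning("held-out betas have zero spread; test degenerate")
  } else {
    tt <- stats::t.test(held, mu = mu)
    d <- (mean(held) - mu) / s
  }
  structure(list(held_out_betas = held,
                 peak_times = times[pk],
                 peak_time = times[grp_pk],
                 t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = d,
                 degenerate = degenerate, n_units = n),
            class = "loo_peak")
}

#' @export
print.loo_peak <- function(x, ...) {
  cat("Leave-one-out group-peak test (", x$n_units, " units)\n", sep = "")
  cat(sprintf("  group peak at %s; mean held-out beta = %.4f\n",
              format(x$peak_time), mean(x$held_out_betas)))
  cat(sprintf("  t(%d) = %.3f, p = %.4g, d = %.3f\n",
              x$df, x$t_stat, x$p, x$cohens_d))
  invisible(x)
}

#' Naive within-dataset peak test (biased; for contrast only)
#'
#' Picks the peak of the full group-mean course and t-tests all units'
#' betas at that same timepoint. This is the temporally circular procedure
#' that the leave-one-out test exists to avoid; it is provided so the
#' selection-bias inflation can be demonstrated by simulation.
#'
#' @inheritParams loo_peak_test
#' @return List with `peak_time`, `t_stat`, `df`, `p`.
#' @export
naive_peak_test <- function(betas, times = NULL, mu = 0) {
  betas <- as.matrix(betas)
  if (is.null(times)) times <- seq_len(ncol(betas))
  pk <- which.max(abs(colMeans(betas)))
  tt <- stats::t.test(betas[, pk], mu = mu)
  list(peak_time = times[pk], t_stat = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Paired contrast between two sets of held-out peak betas
#'
#' Runs the leave-one-out peak extraction separately for two regressors or
#' conditions measured on the same units, then compares the held-out betas
#' with a paired t-test or a Wilcoxon signed-rank test.
#'
#' @param betas_a,betas_b Units x timepoints beta matrices (same units).
#' @param times Optional timepoint grid.
#' @param method `"paired_t"` or `"wilcoxon"`.
#' @return List with the two `"loo_peak"` results and the comparison
#'   statistic (`statistic`, `p`).
#' @export
loo_peak_compare <- function(betas_a, betas_b, times = NULL,
                             method = c("paired_t", "wilcoxon")) {
  method <- match.arg(method)
  a <- loo_peak_test(betas_a, times)
  b <- loo_peak_test(betas_b, times)
  if (method == "paired_t") {
    tt <- stats::t.test(a$held_out_betas, b$held_out_betas, paired = TRUE)
  } else {
    tt <- stats::wilcox.test(a$held_out_betas, b$held_out_betas,
                             paired = TRUE, exact = FALSE)
  }
  list(a = a, b = b, method = method,
       statistic = unname(tt$statistic), p = tt$p.value)
}
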