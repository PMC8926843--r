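#' Build the discrete-time Cox design for a session
#'
#' Turns an ordered session of trial records into the 23-covariate design
#' of the action-time hazard model: the current trial's reward magnitude
#' (drops), dot-speed level index (1 = fastest) and ITI (seconds), followed
#' by the realized reward outcome and observed action time on each of the
#' past `history_depth` trials. Only trials with a complete history of
#' `history_depth` predecessors contribute rows; the leading trials of the
#' session are excluded (no padding). The event time is the observed action
#' time in dots; missed trials are right-censored at `max_dots` (the trial
#' ran its full dot window without a response). Missed predecessors enter
#' the history as reward 0 and action time `max_dots`.
#'
#' @param session Trial `data.frame` (one session, ordered by
#'   `trial_index`) in the schema written by [simulate_agent()].
#' @param history_depth Number of past trials in the covariate vector.
#' @param max_dots Dot window length (censoring time).
#' @param speed_levels Dot-speed levels in ms, fastest first, used to code
#'   the level index.
#' @param missing_history Named list giving the history values imputed for
#'   a missed predecessor: `reward` (default 0) and `acttime` (default
#'   `max_dots`).
#' @return An object of class `"cox_design"`: list with covariate matrix
#'   `X` (rows x 23), integer `time`, `status` (1 = responded, 0 =
#'   censored), and the originating `session_id` / `trial_index`. Zero rows
#'   (with a warning) if the session is shorter than `history_depth + 1`.
#' @export
build_cox_design <- function(session, history_depth = 10L, max_dots = 25L,
                             speed_levels = c(100L, 200L, 300L),
                             missing_history = list(reward = 0,
                                                    acttime = max_dots)) {
  stopifnot(is.data.frame(session))
  if (is.unsorted(session$trial_index)) {
    session <- session[order(session$trial_index), ]
  }
  nm <- cox_covariate_names(history_depth)
  n <- nrow(session)
  idx <- if (n > history_depth) seq.int(history_depth + 1L, n) else integer(0)
  if (!length(idx)) {
    warning("session shorter than history_depth + 1; no design rows")
  }
  # realized per-trial history values
  rew_hist <- ifelse(session$responded, session$reward_outcome,
                     missing_history$reward)
  act_hist <- ifelse(session$responded, session$act_time_dots,
                     missing_history$acttime)
  X <- matrix(0, length(idx), length(nm), dimnames = list(NULL, nm))
  if (length(idx)) {
    X[, "magRew"] <- session$reward_mag[idx]
    X[, "dotSpd"] <- match(session$dot_speed_ms[idx], speed_levels)
    X[, "ITI"] <- session$iti_s[idx]
    for (k in seq_len(history_depth)) {
      X[, paste0("rewOut_lag", k)] <- rew_hist[idx - k]
      X[, paste0("actTime_lag", k)] <- act_hist[idx - k]
    }
  }
  time <- ifelse(session$responded[idx], session$act_time_dots[idx],
                 as.integer(max_dots))
  structure(list(
    X = X,
    time = as.integer(time),
    status = as.integer(session$responded[idx]),
    session_id = session$session_id[idx],
    trial_index = session$trial_index[idx],
    max_dots = as.integer(max_dots)
  ), class = "cox_design")
}

# Breslow partial log-likelihood, gradient and Hessian on sorted data.
# Event times are the integer dot grid, so ties are heavy; risk-set sums
# are accumulated per distinct event time.
cox_pl_parts <- function(X, time, status, beta, hessian = TRUE) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ev_times <- sort(unique(time[status == 1]))
  p <- ncol(X)
  ll <- 0
  grad <- numeric(p)
  H <- if (hessian) matrix(0, p, p) else NULL
  for (tj in ev_times) {
    at_risk <- time >= tj
    dead <- time == tj & status == 1
    dj <- sum(dead)
    S0 <- sum(w[at_risk])
    Xr <- X[at_risk, , drop = FALSE]
    wr <- w[at_risk]
    S1 <- drop(crossprod(Xr, wr))
    ll <- ll + sum(eta[dead]) - dj * log(S0)
    grad <- grad + colSums(X[dead, , drop = FALSE]) - dj * S1 / S0
    if (hessian) {
      S2 <- crossprod(Xr, Xr * wr)
      m1 <- S1 / S0
      H <- H - dj * (S2 / S0 - tcrossprod(m1))
    }
  }
  list(loglik = ll, grad = grad, hessian = H)
}

#' Fit the discrete-time Cox proportional-hazards model of action time
#'
#' Maximizes the Cox partial likelihood with Breslow handling of tied
#' event times (ties are intrinsic here: events live on the integer dot
#' grid) by Newton-Raphson with step-halving, and estimates the baseline
#' cumulative hazard by the Breslow estimator
#' `Lambda0(t) = sum_(event times tj <= t) d_j / sum_(at risk) exp(beta . x)`.
#'
#' @param design A `"cox_design"` from [build_cox_design()], or a covariate
#'   matrix (then `time` and `status` must be given).
#' @param time,status Event times and status (1 = event, 0 = censored),
#'   ignored when `design` is a `"cox_design"`.
#' @param tol Convergence tolerance on the max-norm of the score.
#' @param max_iter Maximum Newton iterations.
#' @param standardize Z-score covariates before fitting (coefficients and
#'   baseline are transformed back to the raw scale).
#' @param min_events Fits with fewer uncensored events than this are
#'   flagged (`low_events = TRUE`) with a warning; they are returned, not
#'   dropped.
#' @return An object of class `"cox_acttime_fit"`: coefficients `coef`,
#'   standard errors `se`, variance matrix `var`, `baseline` data frame
#'   (`time`, `n_event`, `increment`, `cumhaz`), `loglik` (initial, final),
#'   counts, `converged`, `iter`.
#' @export
fit_cox <- function(design, time = NULL, status = NULL,
                    tol = 1e-8, max_iter = 50L, standardize = FALSE,
                    min_events = 30L) {
  if (inherits(design, "cox_design")) {
    X <- design$X; time <- design$time; status <- design$status
    max_dots <- design$max_dots
  } else {
    X <- as.matrix(design)
    if (is.null(time) || is.null(status)) {
      stop("time and status are required when design is a matrix")
    }
    max_dots <- max(time)
  }
  stopifnot(nrow(X) == length(time), length(time) == length(status))
  if (sum(status) < 1) stop("at least one uncensored event is required")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant covariate(s), not identifiable: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  ctr <- colMeans(X)
  scl <- if (standardize) sds else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2, ctr), 2, scl, "/")  # centered for stability
  p <- ncol(Xc)
  beta <- numeric(p)
  parts <- cox_pl_parts(Xc, time, status, beta)
  ll0 <- parts$loglik
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(parts$grad)) < tol) { converged <- TRUE; break }
    step <- solve(parts$hessian, -parts$grad)
    ll_old <- parts$loglik
    fac <- 1
    # accept any step that does not decrease the likelihood beyond
    # floating-point noise in the summed log-likelihood
    noise <- 1e-10 * (abs(ll_old) + 1)
    repeat {
      cand <- beta + fac * step
      new_parts <- cox_pl_parts(Xc, time, status, cand)
      if (new_parts$loglik >= ll_old - noise || fac < 1e-10) break
      fac <- fac / 2
    }
    beta <- beta + fac * step
    parts <- new_parts
  }
  if (!converged && max(abs(parts$grad)) < tol) converged <- TRUE
  if (!converged) warning("Newton-Raphson did not converge in ", max_iter,
                          " iterations")
  beta_raw <- beta / scl
  names(beta_raw) <- colnames(X)
  V <- solve(-parts$hessian)
  V_raw <- diag(1 / scl, p) %*% V %*% diag(1 / scl, p)
  dimnames(V_raw) <- list(colnames(X), colnames(X))
  # Breslow baseline on the raw (uncentered) scale: risk weights exp(b.x)
  w <- exp(drop(X %*% beta_raw))
  ev_times <- sort(unique(time[status == 1]))
  d <- vapply(ev_times, function(tj) sum(time == tj & status == 1), 0)
  S0 <- vapply(ev_times, function(tj) sum(w[time >= tj]), 0)
  baseline <- data.frame(time = ev_times, n_event = d,
                         increment = d / S0, cumhaz = cumsum(d / S0))
  n_events <- sum(status)
  fit <- structure(list(
    coef = beta_raw,
    se = sqrt(diag(V_raw)),
    var = V_raw,
    baseline = baseline,
    loglik = c(ll0, parts$loglik),
    n = nrow(X), n_events = n_events, n_censored = sum(status == 0),
    converged = converged, iter = iter,
    low_events = n_events < min_events,
    max_dots = max_dots
  ), class = "cox_acttime_fit")
  if (fit$low_events) {
    warning("only ", n_events, " events (< ", min_events,
            "); estimates may be unstable")
  }
  fit
}

#' @export
print.cox_acttime_fit <- function(x, ...) {
  cat("Discrete-time Cox model of action time\n")
  cat("  n =", x$n, "(", x$n_events, "events,", x$n_censored, "censored )\n")
  cat("  partial log-likelihood:", format(x$loglik[2]),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(data.frame(coef = x$coef, `exp(coef)` = exp(x$coef), se = x$se,
                   z = x$coef / x$se, check.names = FALSE))
  invisible(x)
}

#' Cumulative hazard for a covariate vector
#'
#' Under proportional hazards the cumulative hazard for covariates `x` is
#' `Lambda_x(t) = Lambda0(t) * exp(beta . x)` with `Lambda0` the Breslow
#' baseline; the returned step function is right-continuous, zero at 0,
#' nondecreasing, and flat beyond the last observed event time (the
#' baseline hazard is unidentified beyond the data).
#'
#' @param fit A `"cox_acttime_fit"`.
#' @param x Covariate vector on the raw scale (length = number of model
#'   covariates).
#' @return A [stats::stepfun()] evaluating `Lambda_x(t)`.
#' @export
cumulative_hazard <- function(fit, x) {
  stopifnot(inherits(fit, "cox_acttime_fit"))
  if (length(x) != length(fit$coef)) {
    stop("x must have length ", length(fit$coef))
  }
  lp <- sum(fit$coef * x)
  stats::stepfun(fit$baseline$time, c(0, fit$baseline$cumhaz * exp(lp)),
                 right = FALSE)
}

#' Fitted survival curve for a covariate vector
#'
#' `S_x(t) = exp(-Lambda_x(t))`: the probability that the action has not
#' yet occurred by dot `t`. Evaluated on the requested time grid (the unit
#' dot grid by default); starts at 1 and is nonincreasing.
#'
#' @param fit A `"cox_acttime_fit"`.
#' @param x Covariate vector on the raw scale.
#' @param times Evaluation grid (default `0:max_dots`).
#' @return An object of class `"survival_curve"`: data frame with columns
#'   `time` and `survival`.
#' @export
survival_curve <- function(fit, x, times = 0:fit$max_dots) {
  Lx <- cumulative_hazard(fit, x)
  out <- data.frame(time = times, survival = exp(-Lx(times)))
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Deterministic action time: expectation of the fitted survival curve
#'
#' The deterministic component of a trial's action time is the expected
#' action time implied by the fitted hazard model and the trial's
#' covariates: the integral of the survival curve, truncated at the dot
#' window. On the unit dot grid this is `sum_(t = 1..max_dots) S_x(t)`,
#' the integral of the left-continuous survival step function over
#' `(0, max_dots]`. It lies in `(0, max_dots]` and is strictly decreasing
#' in the risk score `beta . x`.
#'
#' @param object A `"cox_acttime_fit"` (with `x` supplied) or a
#'   `"survival_curve"` evaluated on the unit dot grid.
#' @param ... Method arguments.
#' @return Expected action time in dots (scalar).
#' @export
deterministic_acttime <- function(object, ...) {
  UseMethod("deterministic_acttime")
}

#' @rdname deterministic_acttime
#' @param x Covariate vector on the raw scale.
#' @param max_dots Truncation point of the expectation integral.
#' @export
deterministic_acttime.cox_acttime_fit <- function(object, x,
                                                  max_dots = object$max_dots,
                                                  ...) {
  Lx <- cumulative_hazard(object, x)
  sum(exp(-Lx(seq_len(max_dots))))
}

#' @rdname deterministic_acttime
#' @export
deterministic_acttime.survival_curve <- function(object, max_dots = NULL,
                                                 ...) {
  if (is.null(max_dots)) max_dots <- max(object$time)
  s <- object$survival[match(seq_len(max_dots), object$time)]
  if (anyNA(s)) stop("survival curve must cover the unit dot grid 1..",
                     max_dots)
  sum(s)
}

#' Per-trial deterministic action time for a trial table
#'
#' Fits the hazard model separately within each session (as the analysis
#' is defined per testing session) and evaluates the deterministic action
#' time of every design row, responded or censored, from its own covariate
#' vector.
#'
#' @param trials Trial table covering one or more sessions.
#' @param history_depth,max_dots,speed_levels Passed to
#'   [build_cox_design()].
#' @param ... Passed to [fit_cox()].
#' @return `data.frame` with columns `session_id`, `trial_index`,
#'   `det_act_time_dots`.
#' @export
det_acttime_table <- function(trials, history_depth = 10L, max_dots = 25L,
                              speed_levels = c(100L, 200L, 300L), ...) {
  out <- lapply(split(trials, trials$session_id), function(ses) {
    dsn <- build_cox_design(ses, history_depth, max_dots, speed_levels)
    if (!length(dsn$time)) return(NULL)
    fit <- fit_cox(dsn, ...)
    det <- apply(dsn$X, 1, function(x) deterministic_acttime(fit, x))
    data.frame(session_id = dsn$session_id, trial_index = dsn$trial_index,
               det_act_time_dots = det, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
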