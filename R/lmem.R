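#' Built-in behavioral model specifications
#'
#' The standard linear mixed-effects models of action time. `GLM1.1`
#' regresses the observed action time on the environment (balanced vs
#' biased design), the three contextual factors, the previous trial's
#' reward outcome and action time, and the interaction of each with the
#' environment. `GLM1.2` is its medium-offer restriction (reward magnitude
#' and dot speed are constant there, so they are dropped). `GLM3.1`
#' replaces the environment with the drug intervention (treatment vs
#' control). `GLM3.2` regresses the deterministic action time on the
#' intervention alone. `GLM3.3` adds the dose phase (build-up vs
#' maintenance) and its interaction, without the by-session intercept
#' (dose does not vary within session). `GRAND` augments `GLM3.1` with
#' the experiment label and the experiment-by-intervention interaction,
#' pooling both pharmacology datasets.
#'
#' All models carry a by-subject random intercept, by-subject random
#' slopes mirroring the fixed terms, and (except `GLM3.3`) a by-session
#' random intercept.
#'
#' @param name Model label.
#' @return A list describing the model: `name`, `response`, `fixed`
#'   (ordered term labels; `a:b` denotes an interaction), `subset`
#'   (`NULL` or `"medium_offer"`), `session_intercept`.
#' @export
model_spec <- function(name = c("GLM1.1", "GLM1.2", "GLM3.1", "GLM3.2",
                                "GLM3.3", "GRAND")) {
  name <- match.arg(name)
  base_ctx <- c("magRew", "dotSpd", "ITI", "rewOut_lag1", "actTime_lag1")
  spec <- switch(name,
    "GLM1.1" = list(
      response = "act_time_dots",
      fixed = c("env", base_ctx, paste0(base_ctx, ":env")),
      subset = NULL, session_intercept = TRUE),
    "GLM1.2" = list(
      response = "act_time_dots",
      fixed = c("env", "ITI", "rewOut_lag1", "actTime_lag1",
                "env:ITI", "env:rewOut_lag1", "env:actTime_lag1"),
      subset = "medium_offer", session_intercept = TRUE),
    "GLM3.1" = list(
      response = "act_time_dots",
      fixed = c("intervention", base_ctx, paste0(base_ctx, ":intervention")),
      subset = NULL, session_intercept = TRUE),
    "GLM3.2" = list(
      response = "det_act_time_dots",
      fixed = "intervention",
      subset = NULL, session_intercept = TRUE),
    "GLM3.3" = list(
      response = "act_time_dots",
      fixed = c("intervention", "dose", "intervention:dose"),
      subset = NULL, session_intercept = FALSE),
    "GRAND" = list(
      response = "act_time_dots",
      fixed = c("intervention", base_ctx,
                paste0(base_ctx, ":intervention"),
                "experiment", "experiment:intervention"),
      subset = NULL, session_intercept = TRUE)
  )
  c(list(name = name), spec)
}

# formula-safe column name for an interaction term
term_col <- function(term) gsub(":", "_x_", term, fixed = TRUE)

#' Build the model frame for a behavioral mixed model
#'
#' Derives the regressors from a trial table: numeric codes for the design
#' labels (`env` 0 = balanced / 1 = biased; `intervention` 0 = control /
#' 1 = treatment; `dose` 0 = build-up / 1 = maintenance; `experiment` 0/1
#' over its sorted labels), `dotSpd` as the speed level index (1 =
#' fastest), `ITI` in seconds (or the level index with
#' `iti_as_seconds = FALSE`), and the previous trial's realized reward
#' outcome and action time shifted within session (missed predecessors
#' contribute reward 0 and action time `max_dots`). Continuous main
#' effects are mean-centered (switchable) before interaction columns are
#' formed as elementwise products. Rows without a lagged predecessor
#' (first trial of each session), without a response (when the observed
#' action time is the response), or without a deterministic action time
#' (when that is the response) are dropped.
#'
#' @param trials Trial table; must contain `det_act_time_dots` (see
#'   [det_acttime_table()]) when the spec's response is the deterministic
#'   action time.
#' @param spec A [model_spec()].
#' @param center Mean-center predictors before forming interactions.
#' @param iti_as_seconds Code ITI in seconds (default) or as level index.
#' @param max_dots Imputed action time for missed predecessors.
#' @param speed_levels Dot-speed levels in ms, fastest first.
#' @return List with `data` (model frame: response, fixed-effect columns,
#'   `subject_id`, `session_id`), `response`, `fixed_cols` (ordered),
#'   `spec`.
#' @export
build_model_matrix <- function(trials, spec, center = TRUE,
                               iti_as_seconds = TRUE, max_dots = 25,
                               speed_levels = c(100L, 200L, 300L)) {
  need <- c("session_id", "subject_id", "trial_index", "responded",
            "reward_mag", "dot_speed_ms", "iti_s", "act_time_dots",
            "reward_outcome")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  trials <- trials[order(trials$session_id, trials$trial_index), ]
  code01 <- function(x, one) as.numeric(x == one)
  d <- data.frame(
    subject_id = trials$subject_id,
    session_id = trials$session_id,
    magRew = as.numeric(trials$reward_mag),
    dotSpd = as.numeric(match(trials$dot_speed_ms, speed_levels)),
    ITI = if (iti_as_seconds) trials$iti_s else
      as.numeric(match(trials$iti_s, sort(unique(trials$iti_s)))),
    stringsAsFactors = FALSE
  )
  if ("design" %in% names(trials)) d$env <- code01(trials$design, "biased")
  if ("intervention" %in% names(trials)) {
    d$intervention <- code01(trials$intervention, "treatment")
  }
  if ("dose_phase" %in% names(trials)) {
    d$dose <- code01(trials$dose_phase, "maintenance")
  }
  if ("experiment" %in% names(trials)) {
    lv <- sort(unique(trials$experiment))
    d$experiment <- as.numeric(match(trials$experiment, lv) - 1)
  }
  # realized previous-trial regressors, shifted within session
  rew_real <- ifelse(trials$responded, trials$reward_outcome, 0)
  act_real <- ifelse(trials$responded, trials$act_time_dots, max_dots)
  lag1 <- function(x) unlist(lapply(split(x, trials$session_id),
                                    function(v) c(NA, v[-length(v)])),
                             use.names = FALSE)
  # split() reorders by factor level; session-sorted input keeps alignment
  d$rewOut_lag1 <- lag1(rew_real)
  d$actTime_lag1 <- lag1(act_real)
  d$act_time_dots <- ifelse(trials$responded, trials$act_time_dots, NA)
  if ("det_act_time_dots" %in% names(trials)) {
    d$det_act_time_dots <- trials$det_act_time_dots
  } else if (spec$response == "det_act_time_dots") {
    stop("spec response is the deterministic action time but the trial ",
         "table has no det_act_time_dots column")
  }
  if (identical(spec$subset, "medium_offer")) {
    keep <- trials$reward_mag == 2 & trials$dot_speed_ms == speed_levels[2]
    if (!any(keep)) stop("empty subset: no medium-offer trials")
    d <- d[keep, ]
  }
  mains <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  d <- d[stats::complete.cases(d[, c(spec$response, mains)]), ]
  if (!nrow(d)) stop("no usable rows after filtering")
  if (center) {
    for (m in mains) d[[m]] <- d[[m]] - mean(d[[m]])
  }
  for (term in spec$fixed[grepl(":", spec$fixed)]) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    d[[term_col(term)]] <- d[[parts[1]]] * d[[parts[2]]]
  }
  list(data = d, response = spec$response,
       fixed_cols = term_col(spec$fixed), spec = spec)
}

#' Fit a behavioral linear mixed-effects model
#'
#' Fits the mixed model by maximum likelihood (not REML) with the spec's
#' random structure -- by-subject random intercept and slopes mirroring
#' the fixed terms, plus a by-session random intercept unless the spec
#' excludes it -- and computes per-term type-II Wald chi-square tests.
#' Singular fits fall back progressively (uncorrelated slopes, then
#' intercepts only), recording the reduction.
#'
#' @param mm Output of [build_model_matrix()].
#' @param random_slopes Include by-subject random slopes (disable for
#'   degenerate designs or speed).
#' @return An object of class `"lmem_fit"`: `coefficients` (estimate,
#'   se), `wald` (chisq, df, p per term), `model` (the lme4 fit),
#'   `random_structure`, `converged`, `singular`, `n_obs`, `n_groups`.
#' @export
fit_lmem <- function(mm, random_slopes = TRUE) {
  d <- mm$data
  fx <- mm$fixed_cols
  slopes <- if (random_slopes) paste(fx, collapse = " + ") else "1"
  forms <- c(
    sprintf("(1 + %s | subject_id)", slopes),
    sprintf("(1 + %s || subject_id)", slopes),
    "(1 | subject_id)"
  )
  if (!random_slopes) forms <- forms[3]
  ses <- if (mm$spec$session_intercept) " + (1 | session_id)" else ""
  fit <- NULL
  used <- NA_character_
  converged <- FALSE
  for (rf in forms) {
    f <- stats::as.formula(paste(
      mm$response, "~", paste(fx, collapse = " + "), "+", rf, ses))
    ok <- TRUE
    fit_try <- withCallingHandlers(
      tryCatch(suppressMessages(lme4::lmer(f, data = d, REML = FALSE)),
               error = function(e) NULL),
      warning = function(w) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (is.null(fit_try)) next
    used <- rf
    fit <- fit_try
    if (ok && !lme4::isSingular(fit_try)) { converged <- TRUE; break }
  }
  if (is.null(fit)) stop("mixed model could not be fit under any fallback")
  singular <- lme4::isSingular(fit)
  wald <- as.data.frame(car::Anova(fit, type = 2, test.statistic = "Chisq"))
  names(wald) <- c("chisq", "df", "p")
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(list(
    coefficients = data.frame(term = names(cf), estimate = unname(cf),
                              se = unname(se), stringsAsFactors = FALSE),
    wald = cbind(term = rownames(wald), wald),
    model = fit,
    random_structure = paste0(used, ses),
    converged = converged, singular = singular,
    n_obs = nrow(d),
    n_groups = c(subjects = length(unique(d$subject_id)),
                 sessions = length(unique(d$session_id)))
  ), class = "lmem_fit")
}

#' @export
print.lmem_fit <- function(x, ...) {
  cat("Linear mixed-effects fit (ML): ", x$n_obs, " obs, ",
      x$n_groups["subjects"], " subjects, ", x$n_groups["sessions"],
      " sessions\n", sep = "")
  cat("  random structure:", x$random_structure,
      if (x$singular) "[singular]" else "", "\n")
  tab <- merge(x$coefficients,
               stats::setNames(x$wald, c("term", "chisq", "df", "p")),
               by = "term", all.x = TRUE, sort = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Missed-trial rates by condition
#'
#' Proportion of non-responded trials per condition, with a chi-square
#' test of homogeneity on the responded/missed counts (used e.g. to check
#' that an intervention or environment effect is not explained by
#' disengagement).
#'
#' @param trials Trial table with a `responded` flag.
#' @param by Name of the grouping column (e.g. `"design"`,
#'   `"intervention"`).
#' @return List with `table` (per-condition n, missed, proportion),
#'   `chisq`, `df`, `p`.
#' @export
miss_rate_summary <- function(trials, by = "design") {
  if (!"responded" %in% names(trials)) stop("responded flag is required")
  g <- trials[[by]]
  tab <- do.call(rbind, lapply(split(trials$responded, g), function(r) {
    data.frame(n = length(r), missed = sum(!r), prop_missed = mean(!r))
  }))
  tab <- cbind(condition = rownames(tab), tab)
  rownames(tab) <- NULL
  counts <- cbind(missed = tab$missed, responded = tab$n - tab$missed)
  if (nrow(counts) > 1 && all(rowSums(counts) > 0) && sum(tab$missed) > 0) {
    ct <- suppressWarnings(stats::chisq.test(counts))
    list(table = tab, chisq = unname(ct$statistic),
         df = unname(ct$parameter), p = ct$p.value)
  } else {
    list(table = tab, chisq = NA_real_, df = NA_integer_, p = NA_real_)
  }
}
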