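pipeline_stages <- c("simulate", "cox", "behavior", "roi", "report")

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (usually parsed from a YAML file)
#' with blocks: `seed`, `output_dir`, `stages` (subset of
#' `simulate, cox, behavior, roi, report` in dependency order), `task`
#' (task configuration arguments plus `n_blocks`), `agent` (agent
#' parameter arguments), `experiment` (cohort layout for
#' [simulate_experiment()]), `bold` ([bold_config()] arguments; optional
#' unless the roi stage runs), `models` (behavioral model names), and
#' `roi` (`channel`, `glm`, `window`, `upsample_dt`, `seed_channel` for
#' the PPI model). Violations are reported with the offending block and
#' field.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated configuration list, invisibly classed
#'   `"run_config"`, with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  stages <- config$stages %||% pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) {
    stop("config field 'stages': unknown stage(s) ",
         paste(bad, collapse = ", "))
  }
  if ("simulate" %in% stages) {
    if (is.null(config$task)) stop("stage 'simulate' requires block 'task'")
    if (is.null(config$agent)) stop("stage 'simulate' requires block 'agent'")
  }
  if ("roi" %in% stages && is.null(config$bold)) {
    stop("stage 'roi' requires block 'bold'")
  }
  for (m in config$models %||% character(0)) {
    if (!m %in% c("GLM1.1", "GLM1.2", "GLM3.1", "GLM3.2", "GLM3.3",
                  "GRAND")) {
      stop("config field 'models': unknown model ", m)
    }
  }
  config$stages <- stages
  config$seed <- config$seed %||% 1L
  config$output_dir <- config$output_dir %||% "acttime-out"
  class(config) <- c("run_config", "list")
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cfg_call <- function(fun, args, allowed) {
  do.call(fun, args[intersect(names(args), allowed)])
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the selected stages in dependency order: `simulate` (trial
#' tables and ROI BOLD channels), `cox` (per-session hazard-model
#' coefficients and deterministic action times), `behavior` (mixed-model
#' coefficient and Wald tables), `roi` (per-session beta time courses and
#' leave-one-out peak tests), `report` (plain-text run manifest). Every
#' output CSV carries the master seed and a hash of the configuration in
#' its header; rerunning with an identical configuration and seed
#' reproduces the outputs bit for bit.
#'
#' @param config Configuration list or YAML path (see
#'   [validate_config()]).
#' @param seed Override for the configured master seed.
#' @param output_dir Override for the configured output directory.
#' @param stages Override for the configured stage list.
#' @param log_level `"info"` (progress messages) or `"quiet"`.
#' @return Invisibly, a list with the in-memory results of each stage and
#'   the paths written.
#' @export
run_pipeline <- function(config, seed = NULL, output_dir = NULL,
                         stages = NULL, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  say <- function(...) if (log_level == "info") message(...)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(output_dir)) config$output_dir <- output_dir
  if (!is.null(stages)) config$stages <- stages
  config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- fnv1a(yaml::as.yaml(unclass(config)))
  meta <- list(package = "acttime", seed = config$seed, config_hash = chash)
  res <- list(config = config, paths = character(0))
  add_path <- function(p) res$paths <<- c(res$paths, p)

  set.seed(config$seed)
  cfg <- cfg_call(task_config, config$task %||% list(),
                  names(formals(task_config)))
  params <- cfg_call(agent_params, config$agent %||% list(),
                     names(formals(agent_params)))

  if ("simulate" %in% config$stages) {
    say("stage simulate")
    ex <- config$experiment %||% list()
    trials <- simulate_experiment(
      n_subjects = ex$n_subjects %||% 2,
      sessions_per_subject = ex$sessions_per_subject %||% 2,
      n_blocks = config$task$n_blocks %||% 3,
      config = cfg, params = params,
      drug_effect = ex$drug_effect,
      experiment = ex$experiment %||% "none",
      buildup_frac = ex$buildup_frac %||% 0,
      seed = config$seed
    )
    res$trials <- trials
    p <- file.path(out_dir, "trials.csv")
    write_trials(trials, p, meta)
    add_path(p)
    if (!is.null(config$bold)) {
      bcfg <- cfg_call(bold_config, config$bold, names(formals(bold_config)))
      res$bold <- list()
      for (sid in unique(trials$session_id)) {
        ses <- trials[trials$session_id == sid, ]
        # deterministic covariates for injection come from the realized
        # context; the det_act channel needs the cox stage, so effects
        # here reference simulated columns only
        ch <- simulate_bold(ses, bcfg)
        res$bold[[sid]] <- ch
        p <- file.path(out_dir, sprintf("bold_%s.csv", sid))
        write_roi_channels(ch, p, meta)
        add_path(p)
      }
    }
  }

  trials <- res$trials %||% {
    p <- file.path(out_dir, "trials.csv")
    if (!file.exists(p)) stop("stage input missing: ", p,
                              " (run the simulate stage first)")
    read_trials(p)
  }

  if ("cox" %in% config$stages) {
    say("stage cox")
    coefs <- do.call(rbind, lapply(split(trials, trials$session_id),
      function(ses) {
        dsn <- build_cox_design(ses)
        if (!length(dsn$time)) return(NULL)
        fit <- suppressWarnings(fit_cox(dsn))
        data.frame(session_id = ses$session_id[1],
                   term = names(fit$coef), estimate = unname(fit$coef),
                   se = unname(fit$se), n_events = fit$n_events,
                   converged = fit$converged, stringsAsFactors = FALSE)
      }))
    rownames(coefs) <- NULL
    res$cox_coefficients <- coefs
    p <- file.path(out_dir, "cox_coefficients.csv")
    write_csv_header(coefs, p, meta)
    add_path(p)
    det <- suppressWarnings(det_acttime_table(trials))
    res$det_acttime <- det
    p <- file.path(out_dir, "det_acttime.csv")
    write_csv_header(det, p, meta)
    add_path(p)
  }

  if ("behavior" %in% config$stages) {
    say("stage behavior")
    det <- res$det_acttime %||% {
      p <- file.path(out_dir, "det_acttime.csv")
      if (file.exists(p)) read_csv_header(p) else NULL
    }
    tr <- trials
    if (!is.null(det)) {
      tr <- merge(tr, det, by = c("session_id", "trial_index"),
                  all.x = TRUE, sort = FALSE)
    }
    res$behavior <- list()
    for (m in config$models %||% "GLM3.2") {
      spec <- model_spec(m)
      fit <- tryCatch({
        mm <- build_model_matrix(tr, spec)
        fit_lmem(mm)
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        say("  model ", m, " skipped: ", conditionMessage(fit))
        next
      }
      res$behavior[[m]] <- fit
      tab <- merge(fit$coefficients,
                   stats::setNames(fit$wald, c("term", "chisq", "df", "p")),
                   by = "term", all = TRUE, sort = FALSE)
      p <- file.path(out_dir, sprintf("behavior_%s.csv", m))
      write_csv_header(tab, p, meta)
      add_path(p)
    }
  }

  if ("roi" %in% config$stages) {
    say("stage roi")
    rcfg <- config$roi %||% list()
    channel <- rcfg$channel %||% "BF"
    glm <- rcfg$glm %||% "GLM2.1"
    window <- rcfg$window %||% c(-4, 4)
    dt <- rcfg$upsample_dt %||% 0.1
    det <- res$det_acttime %||% {
      p <- file.path(out_dir, "det_acttime.csv")
      if (file.exists(p)) read_csv_header(p) else NULL
    }
    betas <- list()
    for (sid in unique(trials$session_id)) {
      ses <- trials[trials$session_id == sid, ]
      ch <- if (!is.null(res$bold[[sid]])) res$bold[[sid]] else {
        p <- file.path(out_dir, sprintf("bold_%s.csv", sid))
        if (!file.exists(p)) stop("stage input missing: ", p)
        read_roi_channels(p)
      }
      tr_attr <- attr(ch, "tr") %||% diff(ch$time_s[1:2])
      roi <- preprocess_roi(ch[[channel]], tr = tr_attr, upsample_dt = dt,
                            roi_label = channel)
      resp <- ses[ses$responded, ]
      ep <- tryCatch(
        suppressWarnings(epoch_series(roi, resp$response_s, window)),
        error = function(e) NULL)
      if (is.null(ep)) next
      dsn <- data.frame(obs_act = resp$act_time_dots[ep$kept],
                        time = resp$onset_s[ep$kept])
      if (!is.null(det)) {
        dd <- det[det$session_id == sid, ]
        dsn$det_act <- dd$det_act_time_dots[
          match(resp$trial_index[ep$kept], dd$trial_index)]
      }
      use_glm <- glm
      if (use_glm == "GLM2.2" && (is.null(dsn$det_act) || anyNA(dsn$det_act))) {
        keep <- !is.na(dsn$det_act %||% rep(NA, nrow(dsn)))
        if (!any(keep)) use_glm <- "GLM2.1"
        else {
          ep$data <- ep$data[keep, , drop = FALSE]
          dsn <- dsn[keep, , drop = FALSE]
        }
      }
      fit <- tryCatch(fit_timestep_glm(ep, dsn, use_glm),
                      error = function(e) NULL)
      if (is.null(fit)) next
      betas[[sid]] <- fit
    }
    res$roi_fits <- betas
    if (length(betas)) {
      reg_names <- setdiff(rownames(betas[[1]]$beta), "intercept")
      times <- betas[[1]]$times
      long <- do.call(rbind, lapply(names(betas), function(sid) {
        b <- betas[[sid]]$beta
        data.frame(session_id = sid,
                   regressor = rep(rownames(b), each = ncol(b)),
                   time_s = rep(times, times = nrow(b)),
                   beta = as.vector(t(b)), stringsAsFactors = FALSE)
      }))
      p <- file.path(out_dir, "roi_betas.csv")
      write_csv_header(long, p, meta)
      add_path(p)
      if (length(betas) >= 3) {
        loo <- do.call(rbind, lapply(reg_names, function(rg) {
          B <- t(vapply(betas, function(f) f$beta[rg, ],
                        numeric(length(times))))
          r <- loo_peak_test(B, times)
          data.frame(regressor = rg, peak_time_s = r$peak_time,
                     mean_beta = mean(r$held_out_betas),
                     t_stat = r$t_stat, df = r$df, p = r$p,
                     cohens_d = r$cohens_d, n_units = r$n_units,
                     stringsAsFactors = FALSE)
        }))
        res$roi_loo <- loo
        p <- file.path(out_dir, "roi_loo.csv")
        write_csv_header(loo, p, meta)
        add_path(p)
      }
    }
  }

  if ("report" %in% config$stages) {
    say("stage report")
    p <- file.path(out_dir, "run_manifest.txt")
    lines <- c(
      "acttime pipeline run manifest",
      sprintf("seed: %s", config$seed),
      sprintf("config_hash: %s", chash),
      sprintf("stages: %s", paste(config$stages, collapse = ", ")),
      "outputs:",
      sprintf("  %s (%s)", basename(res$paths),
              vapply(res$paths, function(f) fnv1a(readLines(f, warn = FALSE)),
                     character(1)))
    )
    writeLines(lines, p)
    add_path(p)
  }
  say("done: ", length(res$paths), " output file(s) in ", out_dir)
  invisible(res)
}
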