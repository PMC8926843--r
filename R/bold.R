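#' Double-gamma hemodynamic response function
#'
#' Canonical difference-of-gammas HRF kernel with a configurable
#' time-to-peak. The default peak of 3.0 s is faster than the 5 s human
#' canonical kernel, reflecting the faster hemodynamics of the macaque
#' brain; the positive lobe is a gamma density with shape 6 and the
#' undershoot a gamma with shape 16 at `undershoot_ratio` amplitude, both
#' sharing the scale implied by `time_to_peak`. The kernel is normalized
#' to unit peak amplitude.
#'
#' @param t Time(s) in seconds (`t < 0` gives 0).
#' @param time_to_peak Mode of the positive lobe, seconds.
#' @param undershoot_ratio Relative amplitude of the undershoot lobe.
#' @return Kernel values, same length as `t`.
#' @export
hrf_double_gamma <- function(t, time_to_peak = 3.0, undershoot_ratio = 1 / 6) {
  b <- time_to_peak / 5                # gamma(shape 6) mode = 5 * scale
  h <- function(u) {
    stats::dgamma(u, shape = 6, scale = b) -
      undershoot_ratio * stats::dgamma(u, shape = 16, scale = b)
  }
  peak <- h(time_to_peak)
  out <- ifelse(t < 0, 0, h(pmax(t, 0)) / peak)
  out
}

#' BOLD simulation configuration
#'
#' Describes the forward model for event-locked ROI BOLD channels: each
#' channel is a sum over trial events of `effect_size * z(covariate)`
#' scaled copies of the HRF shifted to the event time, sampled at the TR,
#' plus Gaussian noise. Channels may additionally receive a
#' psychophysiological coupling: the target channel gains
#' `strength * z(psych_i) * seed_signal(t)` within a window after each
#' event, so its coupling to the seed channel scales with the trial's
#' psychological variable.
#'
#' @param tr Repetition time in seconds.
#' @param hrf_peak_s HRF time-to-peak, seconds.
#' @param noise_sd Gaussian noise SD added per volume (signal units).
#' @param channels Named list; each element is a list of
#'   `regressor = effect_size` entries. Regressor names refer to columns of
#'   the per-trial covariate table (or `"event"` for a unit response per
#'   trial). A channel may include a `couple` element:
#'   `list(seed = <channel>, psych = <regressor>, strength = g,
#'   window_s = 8)`.
#' @param session_length_volumes Number of volumes; `NULL` derives it from
#'   the session's span.
#' @return An object of class `"bold_config"`.
#' @export
bold_config <- function(tr = 2.28, hrf_peak_s = 3.0, noise_sd = 0.5,
                        channels = list(
                          BF = list(event = 1, det_act = 0.5),
                          ACC = list(event = 1, obs_act = 0.5),
                          DRN = list(event = 1, iti = 0.5)
                        ),
                        session_length_volumes = NULL) {
  stopifnot(tr > 0, noise_sd >= 0)
  structure(list(tr = tr, hrf_peak_s = hrf_peak_s, noise_sd = noise_sd,
                 channels = channels,
                 session_length_volumes = session_length_volumes),
            class = "bold_config")
}

# z-score that maps a constant vector to zeros (with a warning)
zscore <- function(x, warn = TRUE) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) {
    if (warn) warning("constant series z-scored to all zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Simulate event-locked ROI BOLD channels
#'
#' Forward model for the ROI analyses: for every responded trial, each
#' channel receives an HRF response at the response time with amplitude
#' `sum_r effect_r * z(covariate_r)` (z-scoring across responded trials),
#' then channels with a `couple` entry gain the seed-coupling term, and
#' finally Gaussian noise is added at the TR grid.
#'
#' @param session Trial table from [simulate_agent()] (one session).
#' @param config A [bold_config()].
#' @param covariates Optional per-trial covariate table aligned with
#'   `session` rows; columns referenced by channel effects. Columns
#'   `obs_act` (observed action time), `iti`, `reward_mag` and `time`
#'   (trial onset, a slow drift proxy) are derived from the session
#'   automatically; others (e.g. `det_act`) must be supplied here.
#' @param seed Optional integer seed.
#' @return A `data.frame` with `volume_index`, `time_s` and one column per
#'   channel, with attributes `"events"` (response times of responded
#'   trials), `"trials"` (their row indices in `session`) and `"tr"`.
#' @export
simulate_bold <- function(session, config = bold_config(),
                          covariates = NULL, seed = NULL) {
  stopifnot(inherits(config, "bold_config"))
  if (!is.null(seed)) set.seed(seed)
  resp <- which(session$responded)
  if (!length(resp)) stop("no responded trials: nothing to lock events to")
  events <- session$response_s[resp]
  covs <- data.frame(
    event = rep(1, length(resp)),
    obs_act = session$act_time_dots[resp],
    iti = session$iti_s[resp],
    reward_mag = session$reward_mag[resp],
    time = session$onset_s[resp]
  )
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == nrow(session))
    for (nmc in names(covariates)) covs[[nmc]] <- covariates[[nmc]][resp]
  }
  n_vol <- config$session_length_volumes
  if (is.null(n_vol)) {
    n_vol <- ceiling((max(events) + 20) / config$tr)
  }
  tgrid <- (seq_len(n_vol) - 1) * config$tr
  if (any(events > max(tgrid))) stop("event times exceed the session span")
  clean <- matrix(0, n_vol, length(config$channels),
                  dimnames = list(NULL, names(config$channels)))
  amp_of <- function(effects) {
    amp <- rep(0, length(resp))
    for (r in names(effects)) {
      if (r == "couple") next
      if (is.null(covs[[r]])) stop("unknown regressor in channel effects: ", r)
      v <- if (r == "event") covs[[r]] else zscore(covs[[r]], warn = FALSE)
      amp <- amp + effects[[r]] * v
    }
    amp
  }
  for (ch in names(config$channels)) {
    amp <- amp_of(config$channels[[ch]])
    sig <- rep(0, n_vol)
    for (i in seq_along(events)) {
      sig <- sig + amp[i] * hrf_double_gamma(tgrid - events[i],
                                             config$hrf_peak_s)
    }
    clean[, ch] <- sig
  }
  # psychophysiological coupling: target gains strength * z(psych) * seed
  out <- clean
  for (ch in names(config$channels)) {
    cp <- config$channels[[ch]]$couple
    if (is.null(cp)) next
    if (!cp$seed %in% colnames(clean)) stop("unknown coupling seed: ", cp$seed)
    win <- if (is.null(cp$window_s)) 8 else cp$window_s
    psych <- zscore(covs[[cp$psych]], warn = FALSE)
    add <- rep(0, n_vol)
    for (i in seq_along(events)) {
      in_win <- tgrid >= events[i] & tgrid <= events[i] + win
      add[in_win] <- add[in_win] + cp$strength * psych[i] * clean[in_win, cp$seed]
    }
    out[, ch] <- out[, ch] + add
  }
  if (config$noise_sd > 0) {
    out <- out + matrix(stats::rnorm(length(out), sd = config$noise_sd),
                        nrow(out), ncol(out))
  }
  res <- data.frame(volume_index = seq_len(n_vol), time_s = tgrid)
  for (ch in colnames(out)) res[[ch]] <- out[, ch]
  attr(res, "events") <- events
  attr(res, "trials") <- resp
  attr(res, "tr") <- config$tr
  res
}
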