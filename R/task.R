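#' Task configuration for the dots task
#'
#' Builds the configuration object describing one session of the dots task:
#' a frame fills with up to `max_dots` dots; the probability of reward at
#' response follows a sigmoid in the number of dots on screen, with its
#' midpoint at `midpoint_dots` (50% chance) and steepness `steepness`.
#' Reward magnitude (1-3 juice drops, signalled by colour) and dot speed
#' (100/200/300 ms per dot) vary trial to trial; the inter-trial interval
#' is constant within blocks of `block_length` trials and drawn from
#' `iti_levels_s`.
#'
#' Two offer distributions are supported. In the `"balanced"` design the
#' three levels of each factor are equally frequent. In the `"biased"`
#' design good offers are over-represented: 46% large / 33% medium / 21%
#' small reward magnitude, and 46% fast / 33% medium / 21% slow dot speed.
#' By default the 46/33/21 split is the marginal proportion of each factor
#' and the two factors are drawn independently; set `couple_factors = TRUE`
#' to yoke reward magnitude and dot speed into joint good/medium/bad offers
#' (so that e.g. "medium offer" trials are exactly 33% of trials rather
#' than 33% x 33%).
#'
#' @param design `"balanced"` or `"biased"` offer distribution.
#' @param midpoint_dots Sigmoid midpoint (dot count at 50% reward chance).
#' @param steepness Sigmoid steepness (per dot).
#' @param max_dots Maximum number of dots per trial.
#' @param reward_levels Reward magnitudes in juice drops, small to large.
#' @param dot_speeds_ms Inter-dot intervals in ms, fast to slow.
#' @param iti_levels_s Inter-trial interval levels in seconds.
#' @param block_length Trials per ITI block.
#' @param session_duration_s Session length in seconds (task stops here
#'   regardless of trial count).
#' @param action_outcome_delay_s Delay between response and outcome, seconds.
#' @param outcome_display_s Outcome marker duration, seconds.
#' @param design_proportions Optional named list with elements `reward` and
#'   `speed`, each a probability vector over the factor levels (small to
#'   large reward; fast to slow speed). Defaults follow `design`.
#' @param couple_factors Logical; yoke reward and speed into joint offers.
#' @return An object of class `"task_config"`.
#' @examples
#' cfg <- task_config("biased")
#' reward_probability(12, cfg)
#' @export
task_config <- function(design = c("balanced", "biased"),
                        midpoint_dots = 12,
                        steepness = 0.5,
                        max_dots = 25,
                        reward_levels = c(1L, 2L, 3L),
                        dot_speeds_ms = c(100L, 200L, 300L),
                        iti_levels_s = c(3, 5, 7),
                        block_length = 30L,
                        session_duration_s = 2400,
                        action_outcome_delay_s = 4,
                        outcome_display_s = 2,
                        design_proportions = NULL,
                        couple_factors = FALSE) {
  design <- match.arg(design)
  if (is.null(design_proportions)) {
    design_proportions <- if (design == "balanced") {
      list(reward = rep(1 / 3, 3), speed = rep(1 / 3, 3))
    } else {
      # good offers over-represented: large reward and fast dots at 46%
      list(reward = c(0.21, 0.33, 0.46), speed = c(0.46, 0.33, 0.21))
    }
  }
  stopifnot(
    length(design_proportions$reward) == length(reward_levels),
    length(design_proportions$speed) == length(dot_speeds_ms)
  )
  for (p in design_proportions) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop("design proportions must be nonnegative and sum to 1")
    }
  }
  cfg <- list(
    design = design,
    midpoint_dots = midpoint_dots,
    steepness = steepness,
    max_dots = as.integer(max_dots),
    reward_levels = as.integer(reward_levels),
    dot_speeds_ms = as.integer(dot_speeds_ms),
    iti_levels_s = iti_levels_s,
    block_length = as.integer(block_length),
    session_duration_s = session_duration_s,
    action_outcome_delay_s = action_outcome_delay_s,
    outcome_display_s = outcome_display_s,
    design_proportions = design_proportions,
    couple_factors = isTRUE(couple_factors)
  )
  class(cfg) <- "task_config"
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("Dots task configuration (", x$design, " design)\n", sep = "")
  cat("  sigmoid: midpoint dot ", x$midpoint_dots, ", steepness ",
      x$steepness, ", max ", x$max_dots, " dots\n", sep = "")
  cat("  reward levels (drops): ", paste(x$reward_levels, collapse = ", "),
      "  proportions: ", paste(format(x$design_proportions$reward), collapse = ", "),
      "\n", sep = "")
  cat("  dot speeds (ms): ", paste(x$dot_speeds_ms, collapse = ", "),
      "  proportions: ", paste(format(x$design_proportions$speed), collapse = ", "),
      "\n", sep = "")
  cat("  ITI levels (s): ", paste(x$iti_levels_s, collapse = ", "),
      " in blocks of ", x$block_length, " trials\n", sep = "")
  invisible(x)
}

#' Reward probability of the task sigmoid
#'
#' Probability of reward if the response is made with `d` dots on screen:
#' `1 / (1 + exp(-k (d - d0)))` with midpoint `d0` and steepness `k` taken
#' from the task configuration. Strictly increasing in `d` for `k > 0`, and
#' exactly 0.5 at the midpoint.
#'
#' @param d Dot count(s) at response, in `1..max_dots`.
#' @param config A [task_config()] object.
#' @return Probability vector, same length as `d`.
#' @examples
#' reward_probability(c(12, 15), task_config())
#' @export
reward_probability <- function(d, config = task_config()) {
  if (any(d < 1 | d > config$max_dots)) {
    stop("d must lie in [1, ", config$max_dots, "]")
  }
  1 / (1 + exp(-config$steepness * (d - config$midpoint_dots)))
}

# Smallest block size (<= limit) over which all proportions are exact
# integer counts: 3 for the balanced design, 100 for the biased 46/33/21.
quota_block_size <- function(props, limit = 1000L) {
  for (m in seq_len(limit)) {
    if (all(abs(m * props - round(m * props)) < 1e-9)) return(m)
  }
  stop("design proportions are not representable as integer per-block ",
       "counts for any block size up to ", limit)
}

# Exact-quota pseudo-randomized level sequence: levels appear with exact
# counts m * props within every complete quota block, shuffled within block.
quota_sequence <- function(levels, props, n) {
  m <- quota_block_size(props)
  counts <- round(m * props)
  block <- rep(levels, times = counts)
  out <- unlist(lapply(seq_len(ceiling(n / m)), function(i) sample(block)))
  out[seq_len(n)]
}

#' Generate a pseudo-randomized trial schedule
#'
#' Draws the contextual factors for `n_blocks` ITI blocks of
#' `config$block_length` trials each. Reward magnitude and dot speed follow
#' the design proportions with exact per-quota-block counts (quota block =
#' smallest size at which the proportions are integer counts: 3 trials for
#' the balanced design, 100 for the biased 46/33/21 design), shuffled
#' within quota block. The ITI is constant within each ITI block and the
#' block levels are a shuffled balanced multiset of the configured levels.
#'
#' The returned schedule carries context only (no times, no behavior);
#' [simulate_agent()] realizes behavior and applies the session-duration
#' cap once onsets are known.
#'
#' @param config A [task_config()].
#' @param n_blocks Number of ITI blocks (`>= 1`).
#' @param seed Optional integer seed.
#' @return A `data.frame` with one row per trial: `trial_index`,
#'   `block`, `reward_mag`, `dot_speed_ms`, `iti_s`, `design`.
#' @export
make_schedule <- function(config, n_blocks, seed = NULL) {
  stopifnot(inherits(config, "task_config"), n_blocks >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_blocks * config$block_length
  if (config$couple_factors) {
    # joint good/medium/bad offers: level index shared by both factors
    idx <- quota_sequence(seq_along(config$reward_levels),
                          config$design_proportions$reward, n)
    reward <- config$reward_levels[idx]
    # good offer = large reward + fast dots: reverse index into speeds
    speed <- config$dot_speeds_ms[length(config$dot_speeds_ms) + 1L - idx]
  } else {
    reward <- quota_sequence(config$reward_levels,
                             config$design_proportions$reward, n)
    speed <- quota_sequence(config$dot_speeds_ms,
                            config$design_proportions$speed, n)
  }
  iti_blocks <- sample(rep(config$iti_levels_s, length.out = n_blocks))
  data.frame(
    trial_index = seq_len(n),
    block = rep(seq_len(n_blocks), each = config$block_length),
    reward_mag = reward,
    dot_speed_ms = speed,
    iti_s = rep(iti_blocks, each = config$block_length),
    design = config$design,
    stringsAsFactors = FALSE
  )
}

#' Identify medium-offer trials
#'
#' Medium-offer trials (medium reward magnitude and medium dot speed) are
#' the comparison set between the balanced and biased environments: they
#' occur with the same frequency in both designs but their relative value
#' differs.
#'
#' @param trials Trial table with `reward_mag` and `dot_speed_ms` columns.
#' @param config A [task_config()] (provides the level sets).
#' @return Logical vector marking medium-offer trials.
#' @export
is_medium_offer <- function(trials, config = task_config()) {
  mid_rew <- config$reward_levels[ceiling(length(config$reward_levels) / 2)]
  mid_spd <- config$dot_speeds_ms[ceiling(length(config$dot_speeds_ms) / 2)]
  trials$reward_mag == mid_rew & trials$dot_speed_ms == mid_spd
}
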