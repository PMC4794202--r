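#' Two-step task configuration
#'
#' Bundles the fixed structure of the sequential two-step Markov decision
#' task: the number of main-task trials, the probability of the common
#' first-stage transition, the dynamics of the stage-2 reward-probability
#' random walks, and the session schedule (breaks, practice block).
#'
#' The default configuration reproduces the standard session layout:
#' 201 main trials with breaks after trials 67 and 134 (1-based), a 50-trial
#' practice block, a fixed 70/30 transition structure, and four stage-2
#' reward probabilities drifting as Gaussian random walks reflected at
#' 0.25 and 0.75.
#'
#' @param n_trials Number of main-task trials (positive integer).
#' @param common_prob Probability of the common transition, in (0.5, 1).
#' @param walk_sd Standard deviation of the Gaussian random-walk step, in
#'   probability units. The task literature does not pin this value down;
#'   0.025 is the conventional choice for this task class.
#' @param walk_lo,walk_hi Reflecting boundaries of the walk, `0 < walk_lo <
#'   walk_hi < 1`.
#' @param reward_magnitude Payoff per rewarded trial, in currency units
#'   (bookkeeping only; the model sees rewards coded 1/0).
#' @param break_after 1-based trial indices after which breaks occur; strictly
#'   increasing, all `< n_trials`. Breaks are schedule markers only: neither
#'   the environment nor the agent changes behaviour at a break.
#' @param n_practice Number of practice trials (simulated with an independent
#'   reward schedule and excluded from likelihoods).
#' @param rng_seed Optional integer seed stored with the config.
#'
#' @return An object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config()
#' cfg$common_prob
#' @export
task_config <- function(n_trials = 201L,
                        common_prob = 0.7,
                        walk_sd = 0.025,
                        walk_lo = 0.25,
                        walk_hi = 0.75,
                        reward_magnitude = 0.2,
                        break_after = c(67L, 134L),
                        n_practice = 50L,
                        rng_seed = NULL) {
  cfg <- structure(
    list(
      n_trials = as.integer(n_trials),
      common_prob = common_prob,
      walk_sd = walk_sd,
      walk_lo = walk_lo,
      walk_hi = walk_hi,
      reward_magnitude = reward_magnitude,
      break_after = as.integer(break_after),
      n_practice = as.integer(n_practice),
      rng_seed = rng_seed
    ),
    class = "task_config"
  )
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (length(cfg$n_trials) != 1L || is.na(cfg$n_trials) || cfg$n_trials < 1L)
    stop("invalid task_config: n_trials must be a positive integer", call. = FALSE)
  if (!(cfg$common_prob > 0.5 && cfg$common_prob < 1))
    stop("invalid task_config: common_prob must lie in (0.5, 1)", call. = FALSE)
  if (cfg$walk_sd < 0)
    stop("invalid task_config: walk_sd must be non-negative", call. = FALSE)
  if (!(cfg$walk_lo > 0 && cfg$walk_lo < cfg$walk_hi && cfg$walk_hi < 1))
    stop("invalid task_config: need 0 < walk_lo < walk_hi < 1", call. = FALSE)
  if (length(cfg$break_after) > 0) {
    if (any(diff(cfg$break_after) <= 0))
      stop("invalid task_config: break_after must be strictly increasing", call. = FALSE)
    if (any(cfg$break_after >= cfg$n_trials) || any(cfg$break_after < 1L))
      stop("invalid task_config: break_after indices must lie in [1, n_trials)", call. = FALSE)
  }
  if (cfg$n_practice < 0L)
    stop("invalid task_config: n_practice must be non-negative", call. = FALSE)
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Two-step task configuration\n")
  cat(sprintf("  trials: %d (+%d practice), breaks after: %s\n",
              x$n_trials, x$n_practice,
              if (length(x$break_after)) paste(x$break_after, collapse = ", ") else "none"))
  cat(sprintf("  common transition: %.2f, walk: sd %.3f reflected at [%.2f, %.2f]\n",
              x$common_prob, x$walk_sd, x$walk_lo, x$walk_hi))
  invisible(x)
}

#' Reflect values into an interval
#'
#' Mirror reflection at both boundaries, applied repeatedly so that
#' excursions beyond either bound (even past both) end up inside
#' `[lo, hi]`. This is the "reflecting boundaries" rule of the reward
#' random walks, as opposed to clipping.
#'
#' @param x Numeric vector.
#' @param lo,hi Boundaries, `lo < hi`.
#' @return Numeric vector with all values in `[lo, hi]`.
#' @keywords internal
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  # fold onto [0, 2*width) then mirror the upper half; exact for any overshoot
  y <- (x - lo) %% (2 * width)
  y <- ifelse(y > width, 2 * width - y, y)
  y + lo
}

#' Generate stage-2 reward-probability schedules
#'
#' Simulates four independent Gaussian random walks (one per stage-2 action:
#' two states times two actions) with reflecting boundaries, giving each
#' stage-2 arm a slowly drifting reward probability. Initial values are drawn
#' uniformly within the boundaries.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param n_trials Optional override of `config$n_trials` (e.g. for the
#'   practice block).
#'
#' @return A `reward_schedule`: a 4 x `n_trials` numeric matrix of reward
#'   probabilities, rows ordered (state 0 action 0, state 0 action 1,
#'   state 1 action 0, state 1 action 1), with attributes `walk_lo`,
#'   `walk_hi`.
#' @examples
#' sched <- build_reward_schedule(task_config(), seed = 1)
#' range(sched)
#' @export
build_reward_schedule <- function(config, seed, n_trials = config$n_trials) {
  validate_task_config(config)
  stopifnot(length(seed) == 1L, is.finite(seed))
  n_trials <- as.integer(n_trials)
  probs <- with_seed(seed, {
    m <- matrix(NA_real_, nrow = 4L, ncol = n_trials)
    init <- stats::runif(4L, config$walk_lo, config$walk_hi)
    steps <- matrix(stats::rnorm(4L * max(n_trials - 1L, 0L), 0, config$walk_sd),
                    nrow = 4L)
    for (arm in 1:4) {
      x <- init[arm]
      m[arm, 1L] <- x
      if (n_trials > 1L) {
        for (t in 2:n_trials) {
          x <- reflect_into(x + steps[arm, t - 1L], config$walk_lo, config$walk_hi)
          m[arm, t] <- x
        }
      }
    }
    m
  })
  structure(probs,
            walk_lo = config$walk_lo, walk_hi = config$walk_hi,
            class = c("reward_schedule", "matrix", "array"))
}

#' First-stage transition matrix
#'
#' The fixed mapping from first-stage actions to second-stage states:
#' action 0 leads commonly to state 0, action 1 commonly to state 1, each
#' with probability `common_prob`; the other state is the rare outcome.
#'
#' @param config A [task_config()].
#' @return A 2 x 2 matrix, `P[a + 1, s + 1] = P(state s | action a)`.
#' @export
transition_matrix <- function(config) {
  p <- config$common_prob
  matrix(c(p, 1 - p,
           1 - p, p), nrow = 2L, byrow = TRUE,
         dimnames = list(action = c("a0", "a1"), state = c("s0", "s1")))
}

#' Sample a first-stage transition
#'
#' @param stage1_action First-stage action, 0 or 1.
#' @param config A [task_config()].
#' @return Second-stage state index (0 or 1): the action's commonly
#'   associated state with probability `common_prob`, else the other state.
#' @export
sample_transition <- function(stage1_action, config) {
  if (!stage1_action %in% c(0L, 1L))
    stop("stage1_action must be 0 or 1", call. = FALSE)
  common_state <- as.integer(stage1_action)
  if (stats::runif(1L) < config$common_prob) common_state else 1L - common_state
}

#' Sample a stage-2 reward
#'
#' Bernoulli draw with the scheduled reward probability of the chosen arm
#' at the given trial; rewards are coded 1 (win) / 0 (no win).
#'
#' @param stage2_state,stage2_action Indices in \{0, 1\}.
#' @param trial 1-based trial index.
#' @param schedule A [build_reward_schedule()] matrix.
#' @return Reward, 0 or 1.
#' @export
sample_reward <- function(stage2_state, stage2_action, trial, schedule) {
  if (trial < 1L || trial > ncol(schedule))
    stop("trial index out of range for the reward schedule", call. = FALSE)
  p <- schedule[schedule_row(stage2_state, stage2_action), trial]
  as.integer(stats::runif(1L) < p)
}

# row of the 4 x T schedule for (state, action), both 0/1
schedule_row <- function(state, action) 2L * as.integer(state) + as.integer(action) + 1L

#' Block label for a trial
#'
#' Maps a 1-based trial index to its block (1 to `length(break_after) + 1`)
#' given the break positions.
#' @param trial Integer vector of 1-based trial indices.
#' @param config A [task_config()].
#' @return Integer block labels.
#' @export
trial_block <- function(trial, config) {
  findInterval(trial, c(config$break_after + 0.5)) + 1L
}
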