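#' Seven-parameter hybrid agent parameter set
#'
#' The dual-control model has seven free parameters: stage-1 and stage-2
#' learning rates `alpha1`, `alpha2` in (0, 1); the eligibility parameter
#' `lam` in (0, 1), which scales how strongly stage-2 reward prediction
#' errors also update stage-1 model-free values; the stage-2 inverse
#' temperature `beta2 >= 0`; non-negative weights `beta_hb` (model-free,
#' habitual) and `beta_gd` (model-based, goal-directed) that both weight
#' their system's stage-1 values and act as that system's inverse
#' temperature; and an unbounded stage-1 perseveration parameter `p`
#' (positive = stickiness, negative = switching).
#'
#' @param alpha1,alpha2 Learning rates in (0, 1).
#' @param lam Eligibility parameter in (0, 1).
#' @param beta2 Stage-2 inverse temperature, `>= 0`.
#' @param beta_hb Model-free (habitual) weight, `>= 0`.
#' @param beta_gd Model-based (goal-directed) weight, `>= 0`.
#' @param p Stage-1 perseveration, any real.
#' @return A named numeric vector of class `param_set`.
#' @examples
#' param_set(alpha1 = 0.5, alpha2 = 0.6, lam = 0.8,
#'           beta2 = 3, beta_hb = 2, beta_gd = 3, p = 0.5)
#' @export
param_set <- function(alpha1, alpha2, lam, beta2, beta_hb, beta_gd, p) {
  x <- c(alpha1 = alpha1, alpha2 = alpha2, lam = lam,
         beta2 = beta2, beta_hb = beta_hb, beta_gd = beta_gd, p = p)
  validate_param_set(x)
  structure(x, class = "param_set")
}

#' Names of the seven free parameters, in canonical order
#' @return Character vector of length 7.
#' @export
param_names <- function() {
  c("alpha1", "alpha2", "lam", "beta2", "beta_hb", "beta_gd", "p")
}

validate_param_set <- function(x) {
  if (length(x) != 7L || !identical(names(x), param_names()))
    stop("a param_set must hold exactly the seven named parameters", call. = FALSE)
  if (any(!is.finite(x)))
    stop("parameters must be finite", call. = FALSE)
  for (nm in c("alpha1", "alpha2", "lam"))
    if (x[[nm]] <= 0 || x[[nm]] >= 1)
      stop(sprintf("%s must lie strictly in (0, 1)", nm), call. = FALSE)
  for (nm in c("beta2", "beta_hb", "beta_gd"))
    if (x[[nm]] < 0)
      stop(sprintf("%s must be non-negative", nm), call. = FALSE)
  invisible(x)
}

#' @export
print.param_set <- function(x, ...) {
  cat("Hybrid agent parameters:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Relative goal-directed weight
#'
#' Derived index `omega = beta_gd / (beta_gd + beta_hb)` in `[0, 1]`,
#' summarising the balance between the two systems. It is a reporting
#' convenience, not a free parameter of the model.
#'
#' @param params A [param_set()] (or anything with `beta_gd`, `beta_hb`).
#' @return Numeric in `[0, 1]`; `NaN` when both weights are 0.
#' @export
relative_weight <- function(params) {
  unname(params[["beta_gd"]] / (params[["beta_gd"]] + params[["beta_hb"]]))
}

#' Model-based stage-1 values by Bellman evaluation
#'
#' Computes the goal-directed value of each first-stage action by weighting
#' the best attainable stage-2 value in each second-stage state by the true,
#' fixed transition probabilities: `Q_MB(a) = sum_s P(s | a) max_a' q2(s, a')`.
#' The transition structure is taken as known and fixed; only the stage-2
#' values are learned.
#'
#' @param q2 2 x 2 matrix of stage-2 action values (rows = states).
#' @param trans 2 x 2 transition matrix from [transition_matrix()].
#' @return Numeric vector of 2 stage-1 model-based values.
#' @examples
#' q2 <- rbind(c(1, 0), c(0, 0))
#' model_based_values(q2, transition_matrix(task_config()))  # 0.7, 0.3
#' @export
model_based_values <- function(q2, trans) {
  stopifnot(is.matrix(q2), all(dim(q2) == c(2L, 2L)),
            is.matrix(trans), all(dim(trans) == c(2L, 2L)))
  state_max <- apply(q2, 1L, max)
  as.numeric(trans %*% state_max)
}

# numerically stable softmax over a vector of utilities
softmax <- function(u) {
  z <- u - max(u)
  e <- exp(z)
  e / sum(e)
}

#' First-stage choice probabilities
#'
#' Combines the two systems' stage-1 values and a perseveration bonus in a
#' single softmax: `P(a) propto exp(beta_hb * q_mf1(a) + beta_gd * q_mb1(a)
#' + p * rep(a))`, where `rep(a) = 1` iff `a` repeats the previous stage-1
#' choice. The system weights double as inverse temperatures; there is no
#' separate stage-1 temperature.
#'
#' @param q_mf1 Length-2 model-free stage-1 values.
#' @param q_mb1 Length-2 model-based stage-1 values.
#' @param prev_choice1 Previous stage-1 action (0/1) or `NA` at session start.
#' @param params A [param_set()].
#' @return Length-2 probability vector (sums to 1, strictly positive).
#' @export
stage1_choice_probs <- function(q_mf1, q_mb1, prev_choice1, params) {
  rep_ind <- c(0, 0)
  if (!is.na(prev_choice1)) rep_ind[as.integer(prev_choice1) + 1L] <- 1
  u <- params[["beta_hb"]] * q_mf1 + params[["beta_gd"]] * q_mb1 +
    params[["p"]] * rep_ind
  softmax(u)
}

#' Second-stage choice probabilities
#'
#' Softmax over the chosen second-stage state's two action values with
#' inverse temperature `beta2`.
#'
#' @param q2_row Length-2 value pair of the current stage-2 state.
#' @param beta2 Inverse temperature, `>= 0`.
#' @return Length-2 probability vector.
#' @export
stage2_choice_probs <- function(q2_row, beta2) {
  softmax(beta2 * q2_row)
}

#' Initialise agent learning state
#'
#' All Q-values start at `q_init` (default 0.5, the midpoint of the \{0, 1\}
#' outcome range) and no previous choice is recorded.
#'
#' @param q_init Initial Q-value.
#' @return List with `q_mf1` (2 stage-1 model-free values), `q2` (2 x 2
#'   stage-2 values), `prev_choice1` (`NA`).
#' @export
agent_state <- function(q_init = 0.5) {
  list(q_mf1 = rep(q_init, 2L),
       q2 = matrix(q_init, 2L, 2L),
       prev_choice1 = NA_integer_)
}

#' SARSA(lambda) temporal-difference update for one trial
#'
#' Applies the model-free learning rule after a completed trial. With
#' first-stage choice `c1`, second-stage state `s2`, choice `c2` and reward
#' `r`:
#' \deqn{\delta_1 = q_2(s_2, c_2) - q_{mf1}(c_1), \quad
#'       q_{mf1}(c_1) \mathrel{+}= \alpha_1 \delta_1}
#' \deqn{\delta_2 = r - q_2(s_2, c_2), \quad
#'       q_2(s_2, c_2) \mathrel{+}= \alpha_2 \delta_2, \quad
#'       q_{mf1}(c_1) \mathrel{+}= \alpha_1 \lambda \delta_2}
#' Unchosen values are untouched; `prev_choice1` is set to `c1`. The stage-2
#' prediction error uses the pre-update `q2(s2, c2)`.
#'
#' @param state An [agent_state()].
#' @param choice1,state2,choice2 Trial outcome indices in \{0, 1\}.
#' @param reward Reward in \{0, 1\}.
#' @param params A [param_set()].
#' @return The updated state.
#' @export
td_update <- function(state, choice1, state2, choice2, reward, params) {
  i1 <- as.integer(choice1) + 1L
  is2 <- as.integer(state2) + 1L
  i2 <- as.integer(choice2) + 1L
  q2_sa <- state$q2[is2, i2]
  delta1 <- q2_sa - state$q_mf1[i1]
  state$q_mf1[i1] <- state$q_mf1[i1] + params[["alpha1"]] * delta1
  delta2 <- reward - q2_sa
  state$q2[is2, i2] <- q2_sa + params[["alpha2"]] * delta2
  state$q_mf1[i1] <- state$q_mf1[i1] + params[["alpha1"]] * params[["lam"]] * delta2
  state$prev_choice1 <- as.integer(choice1)
  state
}

#' Simulate one session of the two-step task
#'
#' Plays `n_trials` trials of the task with a hybrid agent: on each trial the
#' agent chooses at stage 1 (softmax over combined model-free, model-based
#' and perseveration utilities), transitions per the fixed 70/30 structure,
#' chooses at stage 2 (softmax under `beta2`), collects a Bernoulli reward
#' from the schedule, and runs the SARSA(lambda) update.
#'
#' @param params A [param_set()].
#' @param config A [task_config()].
#' @param schedule A [build_reward_schedule()]; defaults to a fresh schedule
#'   drawn from `seed`.
#' @param seed Integer seed; the session is deterministic given the seed.
#' @param subject_id,condition Metadata stamped into the trial log.
#' @param q_init Initial Q-value (default 0.5).
#' @return A `data.frame` trial log with columns `subject_id`, `condition`,
#'   `trial` (1-based), `choice1`, `state2`, `choice2` (all 0/1), `reward`
#'   (0/1) and `block`.
#' @examples
#' pars <- param_set(0.5, 0.6, 0.8, 3, 2, 3, 0.5)
#' log1 <- simulate_session(pars, task_config(), seed = 1)
#' head(log1)
#' @export
simulate_session <- function(params, config, schedule = NULL, seed,
                             subject_id = "s01", condition = "music",
                             q_init = 0.5) {
  validate_param_set(params)
  validate_task_config(config)
  if (is.null(schedule))
    schedule <- build_reward_schedule(config, seed = derive_seed(seed, "schedule"))
  stopifnot(ncol(schedule) >= config$n_trials)
  trans <- transition_matrix(config)
  with_seed(seed, {
    st <- agent_state(q_init)
    n <- config$n_trials
    choice1 <- state2 <- choice2 <- reward <- integer(n)
    for (t in seq_len(n)) {
      q_mb1 <- model_based_values(st$q2, trans)
      p1 <- stage1_choice_probs(st$q_mf1, q_mb1, st$prev_choice1, params)
      c1 <- as.integer(stats::runif(1L) < p1[2L])
      s2 <- sample_transition(c1, config)
      p2 <- stage2_choice_probs(st$q2[s2 + 1L, ], params[["beta2"]])
      c2 <- as.integer(stats::runif(1L) < p2[2L])
      r <- sample_reward(s2, c2, t, schedule)
      st <- td_update(st, c1, s2, c2, r, params)
      choice1[t] <- c1; state2[t] <- s2; choice2[t] <- c2; reward[t] <- r
    }
    data.frame(subject_id = subject_id, condition = condition,
               trial = seq_len(n), choice1 = choice1, state2 = state2,
               choice2 = choice2, reward = reward,
               block = trial_block(seq_len(n), config),
               stringsAsFactors = FALSE)
  })
}

#' Session negative log-likelihood of the hybrid model
#'
#' Evaluates `-sum_t [log P(choice1_t) + log P(choice2_t)]` for an ordered
#' session, updating the agent state trial by trial exactly as
#' [td_update()] does. Trials flagged missing (any of `choice1`, `state2`,
#' `choice2`, `reward` is `NA`) are skipped from both the likelihood and the
#' learning update. The hot loop runs in compiled code; a plain-R reference
#' evaluator with identical semantics is exercised in the test suite.
#'
#' @param data A session trial log as returned by [simulate_session()]
#'   (only `choice1`, `state2`, `choice2`, `reward` are used; rows must be
#'   in trial order).
#' @param params A [param_set()].
#' @param common_prob Common-transition probability assumed known by the
#'   model-based system (default 0.7).
#' @param q_init Initial Q-value (default 0.5).
#' @return Non-negative finite scalar.
#' @examples
#' pars <- param_set(0.5, 0.6, 0.8, 3, 2, 3, 0.5)
#' dat <- simulate_session(pars, task_config(), seed = 1)
#' session_neg_log_likelihood(dat, pars)
#' @export
session_neg_log_likelihood <- function(data, params, common_prob = 0.7,
                                       q_init = 0.5) {
  validate_param_set(params)
  required <- c("choice1", "state2", "choice2", "reward")
  if (!all(required %in% names(data)))
    stop("session data must contain columns choice1, state2, choice2, reward",
         call. = FALSE)
  if (nrow(data) == 0L) return(0)
  bad <- function(v) !is.na(v) & !(v %in% c(0, 1))
  if (any(bad(data$choice1) | bad(data$state2) | bad(data$choice2) | bad(data$reward)))
    stop("trial fields must be coded 0/1 (NA marks a missing trial)", call. = FALSE)
  nll_session_cpp(as.integer(data$choice1), as.integer(data$state2),
                  as.integer(data$choice2), as.numeric(data$reward),
                  as.numeric(params), common_prob, q_init)
}
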