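# Independent brute-force oracles, coded separately from the package paths
# they check.

# Trial-by-trial session negative log-likelihood of the hybrid model,
# written directly from the model definition with plain probability
# arithmetic (no log-sum-exp, no shared code with the package evaluator).
oracle_session_nll <- function(data, params, common_prob = 0.7, q_init = 0.5,
                               verbose = FALSE) {
  a1 <- params[["alpha1"]]; a2 <- params[["alpha2"]]; lam <- params[["lam"]]
  b2 <- params[["beta2"]]; bhb <- params[["beta_hb"]]; bgd <- params[["beta_gd"]]
  pstick <- params[["p"]]
  trans <- rbind(c(common_prob, 1 - common_prob),
                 c(1 - common_prob, common_prob))
  qmf1 <- rep(q_init, 2)
  q2 <- matrix(q_init, 2, 2)
  prev <- NA
  nll <- 0
  for (t in seq_len(nrow(data))) {
    c1 <- data$choice1[t]; s2 <- data$state2[t]
    c2 <- data$choice2[t]; r <- data$reward[t]
    if (anyNA(c(c1, s2, c2, r))) next
    qmb <- as.numeric(trans %*% apply(q2, 1, max))
    util <- bhb * qmf1 + bgd * qmb
    if (!is.na(prev)) util[prev + 1] <- util[prev + 1] + pstick
    p1 <- exp(util) / sum(exp(util))
    p2 <- exp(b2 * q2[s2 + 1, ]) / sum(exp(b2 * q2[s2 + 1, ]))
    if (verbose)
      cat(sprintf("t=%d P(c1)=%.6f P(c2)=%.6f\n", t, p1[c1 + 1], p2[c2 + 1]))
    nll <- nll - log(p1[c1 + 1]) - log(p2[c2 + 1])
    # learning
    qmf1[c1 + 1] <- qmf1[c1 + 1] + a1 * (q2[s2 + 1, c2 + 1] - qmf1[c1 + 1])
    d2 <- r - q2[s2 + 1, c2 + 1]
    q2[s2 + 1, c2 + 1] <- q2[s2 + 1, c2 + 1] + a2 * d2
    qmf1[c1 + 1] <- qmf1[c1 + 1] + a1 * lam * d2
    prev <- c1
  }
  nll
}

# a small hand-built session as a data.frame
fixture_session <- function(choice1, state2, choice2, reward,
                            subject_id = "fix", condition = "music") {
  data.frame(subject_id = subject_id, condition = condition,
             trial = seq_along(choice1), choice1 = choice1, state2 = state2,
             choice2 = choice2, reward = reward,
             block = 1L, stringsAsFactors = FALSE)
}

# a library of hand-built fixture sessions exercising different
# choice/transition/reward patterns
fixture_sessions <- function() {
  list(
    three_trials = fixture_session(c(0, 1, 0), c(0, 1, 1), c(1, 0, 1),
                                   c(1, 0, 1)),
    all_same = fixture_session(rep(0, 6), rep(0, 6), rep(0, 6), rep(1, 6)),
    alternating = fixture_session(rep(c(0, 1), 4), rep(c(1, 0), 4),
                                  rep(c(0, 1), 4), rep(c(0, 1), 4)),
    rare_heavy = fixture_session(c(0, 0, 1, 1, 0), c(1, 1, 0, 0, 1),
                                 c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 0)),
    no_reward = fixture_session(c(1, 0, 1, 0, 1, 1, 0), c(1, 0, 0, 1, 1, 0, 0),
                                c(0, 0, 1, 1, 0, 1, 0), rep(0, 7)),
    with_missing = {
      s <- fixture_session(c(0, 1, NA, 1, 0), c(0, 1, NA, 0, 1),
                           c(1, 0, NA, 0, 1), c(1, 0, NA, 1, 0))
      s
    }
  )
}

# parameter sets spanning the plausible range
fixture_params <- function() {
  list(
    mid = param_set(0.5, 0.5, 0.5, 1, 1, 1, 0),
    typical = param_set(0.6, 0.67, 0.79, 3.13, 2.42, 3.33, 0.76),
    mf_only = param_set(0.4, 0.7, 0.9, 2, 4, 1e-8, 0.2),
    mb_only = param_set(0.4, 0.7, 0.3, 2, 1e-8, 4, -0.3),
    sticky = param_set(0.2, 0.3, 0.6, 5, 0.5, 0.5, 3)
  )
}

# random valid parameter set on the natural scale
random_params <- function() {
  param_set(alpha1 = runif(1, 0.01, 0.99), alpha2 = runif(1, 0.01, 0.99),
            lam = runif(1, 0.01, 0.99), beta2 = exp(rnorm(1, 1, 0.8)),
            beta_hb = exp(rnorm(1, 0.5, 0.8)), beta_gd = exp(rnorm(1, 0.7, 0.8)),
            p = rnorm(1, 0.5, 0.5))
}
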