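test_that("the scale transformations are exact bijections", {
  expect_equal(unname(to_unbounded(param_set(0.5, 0.5, 0.5, 1, 1, 1, 0))),
               rep(0, 7))
  set.seed(2)
  max_err <- 0
  for (rep in 1:1000) {
    pars <- random_params()
    back <- to_natural(to_unbounded(pars))
    max_err <- max(max_err, max(abs(back - pars)))
  }
  expect_lt(max_err, 1e-12)
  # unbounded -> natural -> unbounded likewise
  u <- c(-1.2, 0.3, 2, -0.5, 1.1, 0.7, -2)
  expect_equal(unname(to_unbounded(to_natural(u))), u, tolerance = 1e-12)
  expect_error(to_unbounded(param_set(0.5, 0.5, 0.5, 0, 1, 1, 0)), "positive")
})

test_that("the prior validates and penalises as a quadratic on the unbounded scale", {
  expect_error(map_prior(sd = 0), "SD")
  prior <- map_prior()
  ses <- fixture_sessions()$three_trials
  u <- to_unbounded(fixture_params()$typical)
  # at the prior mean the penalty vanishes
  expect_equal(neg_log_posterior(ses, rep(0, 7), prior),
               session_neg_log_likelihood(ses, to_natural(rep(0, 7))))
  # hand-computed quadratic penalty on a fixture session
  expect_equal(neg_log_posterior(ses, u, prior),
               oracle_session_nll(ses, to_natural(u)) +
                 sum(u^2) / (2 * 100^2), tolerance = 1e-10)
  # a near-flat prior reduces to the plain likelihood
  flat <- map_prior(sd = 1e12)
  expect_equal(neg_log_posterior(ses, u, flat),
               session_neg_log_likelihood(ses, to_natural(u)),
               tolerance = 1e-8)
})

test_that("MAP fitting is deterministic and improves on its start points", {
  pars <- fixture_params()$typical
  dat <- simulate_session(pars, task_config(), seed = 77)
  f1 <- fit_map(dat, n_restarts = 6, seed = 4)
  f2 <- fit_map(dat, n_restarts = 6, seed = 4)
  expect_identical(f1, f2)
  expect_true(f1$converged)
  expect_equal(unname(f1$map_natural), unname(to_natural(f1$map_unbounded)))
  # objective at the optimum beats the all-zero start and the truth
  expect_lt(f1$neg_log_posterior, neg_log_posterior(dat, rep(0, 7)))
  expect_lte(f1$neg_log_posterior, neg_log_posterior(dat, to_unbounded(pars)))
})

test_that("MAP estimates approach the truth for long identifiable sessions", {
  pars <- fixture_params()$typical
  cfg <- task_config(n_trials = 2000, break_after = integer(0))
  dat <- simulate_session(pars, cfg, seed = 5)
  fit <- fit_map(dat, n_restarts = 6, seed = 1)
  expect_lt(max(abs(fit$map_unbounded - to_unbounded(pars))), 0.35)
  # and the broad-prior MAP is essentially the MLE there
  mle_like <- fit_map(dat, prior = map_prior(sd = 1e6), n_restarts = 6, seed = 1)
  expect_lt(max(abs(mle_like$map_unbounded - fit$map_unbounded)), 0.05)
})

test_that("degenerate one-key sessions still yield a finite regularised fit", {
  cfg <- task_config(n_trials = 80, break_after = integer(0))
  sched <- build_reward_schedule(cfg, seed = 1)
  set.seed(3)
  dat <- data.frame(subject_id = "deg", condition = "music", trial = 1:80,
                    choice1 = 0L,
                    state2 = rbinom(80, 1, 0.3),
                    choice2 = 0L,
                    reward = rbinom(80, 1, 0.5),
                    block = 1L)
  fit <- fit_map(dat, n_restarts = 4, seed = 2)
  expect_true(all(is.finite(fit$map_unbounded)))
  expect_true(is.finite(fit$neg_log_posterior))
})

test_that("fit_cohort returns one labelled row per session on both scales", {
  cc <- cohort_config(n_subjects = 3)
  records <- draw_cohort(cc, seed = 1)
  sim <- generate_cohort_sessions(records, task_config(n_trials = 40, break_after = integer(0)), seed = 2)
  fits <- fit_cohort(sim$trials, n_restarts = 2, seed = 3)
  expect_equal(nrow(fits), 6L)
  expect_setequal(fits$condition, c("music", "gaming"))
  expect_true(all(param_names() %in% names(fits)))
  expect_equal(fits$beta_gd, exp(fits$u_beta_gd), tolerance = 1e-12)
  expect_equal(fits$alpha1, plogis(fits$u_alpha1), tolerance = 1e-12)
})

test_that("one EM step recentres the prior on the population of fits", {
  # all subjects share the same true parameters; with long sessions the EM
  # prior mean should land near the common unbounded truth
  pars <- fixture_params()$typical
  u_true <- to_unbounded(pars)
  cfg <- task_config(n_trials = 600, break_after = integer(0))
  logs <- do.call(rbind, lapply(1:6, function(i) {
    simulate_session(pars, cfg, seed = 100 + i,
                     subject_id = sprintf("s%02d", i),
                     condition = if (i %% 2) "music" else "gaming")
  }))
  fits <- fit_cohort(logs, n_restarts = 3, seed = 5, hessian = TRUE)
  em <- suppressWarnings(em_prior_step(fits, logs, n_restarts = 3, seed = 6))
  expect_s3_class(em$prior, "map_prior")
  expect_lt(max(abs(em$prior$mean - u_true)), 1.1)
  expect_lt(mean(abs(em$prior$mean - u_true)), 0.5)
  # EM shrinkage must preserve the subject ordering of the well-identified
  # goal-directed weight
  expect_equal(order(em$fits$u_beta_gd), order(fits$u_beta_gd))
  expect_error(em_prior_step(fits[0, ], logs), "at least two")
})
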