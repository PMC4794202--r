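# build a balanced two-condition cohort table directly (no model fitting):
# per-subject intercepts plus condition effects and noise
make_table <- function(n = 20, cond_effect = 0, interaction = 0,
                       sigma_b = 1, sigma_e = 0.5, seed = 1) {
  set.seed(seed)
  subj <- sprintf("s%02d", 1:n)
  wm <- rnorm(n, 7.4, 1.8)
  z <- as.numeric(scale(wm))
  b0 <- rnorm(n, 0.7, sigma_b)
  rows <- lapply(1:n, function(i) {
    y_m <- b0[i] + rnorm(1, 0, sigma_e)
    y_g <- b0[i] + cond_effect + interaction * z[i] + rnorm(1, 0, sigma_e)
    data.frame(subject_id = subj[i], condition = c("music", "gaming"),
               u_beta_gd = c(y_m, y_g), wm_score = wm[i], z_wm = z[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("the condition coefficient equals the paired-difference oracle", {
  tab <- make_table(n = 24, cond_effect = -0.4, seed = 11)
  res <- fit_condition_model(tab, "u_beta_gd", tails = "two.sided")
  g <- tab$u_beta_gd[tab$condition == "gaming"]
  m <- tab$u_beta_gd[tab$condition == "music"]
  pt_res <- paired_t(g, m)
  expect_equal(res$estimate, mean(g - m), tolerance = 1e-6)
  expect_equal(res$estimate, pt_res$estimate, tolerance = 1e-6)
  expect_equal(res$se, pt_res$se, tolerance = 1e-4)
  expect_equal(res$df, 23)  # within-subject stratum: 48 - 24 - 1
  expect_equal(res$t, pt_res$t, tolerance = 1e-3)
})

test_that("paired_t agrees with the textbook formula and stats::t.test", {
  set.seed(21)
  a <- rnorm(15); b <- rnorm(15)
  mine <- paired_t(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter))
  one <- paired_t(a, b, tails = "less")
  ref1 <- stats::t.test(a, b, paired = TRUE, alternative = "less")
  expect_equal(one$p, ref1$p.value, tolerance = 1e-12)
  # degenerate cases
  same <- paired_t(1:5, 1:5)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- paired_t(1:5 + 1, 1:5)
  expect_equal(shifted$p, 0)
  expect_error(paired_t(1:4, 1:3), "equal length")
  expect_error(paired_t(1:2, 1:2), "at least 3")
})

test_that("one-tailed interaction tests hold their nominal size under the null", {
  n_reps <- 400
  rejections <- 0L
  for (r in 1:n_reps) {
    tab <- make_table(n = 16, cond_effect = 0, interaction = 0, seed = 5000 + r)
    mod <- fit_moderation_model(tab, "u_beta_gd", moderator = "wm_score",
                                tails_interaction = "greater")
    p <- mod$p[mod$term == "condition_code:z_mod"]
    rejections <- rejections + (p < 0.05)
  }
  rate <- rejections / n_reps
  # binomial 99% band around 0.05 at 400 replicates
  expect_gt(rate, 0.05 - 2.58 * sqrt(0.05 * 0.95 / n_reps))
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_reps))
})

test_that("moderation inference is invariant to the moderator's raw scale", {
  tab <- make_table(n = 20, cond_effect = -0.3, interaction = 0.4, seed = 31)
  tab$wm_doubled <- tab$wm_score * 2
  m1 <- fit_moderation_model(tab, "u_beta_gd", moderator = "wm_score")
  m2 <- fit_moderation_model(tab, "u_beta_gd", moderator = "wm_doubled")
  expect_equal(m1$estimate, m2$estimate, tolerance = 1e-8)
  expect_equal(m1$p, m2$p, tolerance = 1e-8)
})

test_that("simple effects at +/-1 SD satisfy the interaction identity", {
  for (seed in c(3, 17, 23)) {
    tab <- make_table(n = 18, cond_effect = -0.4, interaction = 0.3,
                      seed = seed)
    mod <- fit_moderation_model(tab, "u_beta_gd")
    int_b <- mod$estimate[mod$term == "condition_code:z_mod"]
    simp <- simple_effects(tab, "u_beta_gd")
    expect_equal(simp$estimate[2] - simp$estimate[1], 2 * int_b,
                 tolerance = 1e-6)
  }
  # zero-interaction generator: simple effects approximately equal
  tab0 <- make_table(n = 200, cond_effect = -0.4, interaction = 0,
                     sigma_e = 0.2, seed = 41)
  simp0 <- simple_effects(tab0, "u_beta_gd")
  expect_lt(abs(simp0$estimate[2] - simp0$estimate[1]), 0.15)
})

test_that("an injected low-WM deficit shows in the simple-effect pattern", {
  tab <- make_table(n = 120, cond_effect = -0.3, interaction = 0.3,
                    sigma_e = 0.3, seed = 53)
  simp <- simple_effects(tab, "u_beta_gd", tails = "less")
  # negative and larger in magnitude at -1 SD than at +1 SD
  expect_lt(simp$estimate[1], 0)
  expect_lt(simp$estimate[1], simp$estimate[2])
  expect_lt(abs(simp$estimate[2]), abs(simp$estimate[1]))
})

test_that("covariates enter z-scored and collinearity is reported", {
  tab <- make_table(n = 20, cond_effect = -0.3, interaction = 0.4, seed = 61)
  set.seed(62)
  per_subj <- unique(tab[, c("subject_id", "wm_score")])
  tab$dsst <- rnorm(nrow(per_subj), 87, 10)[match(tab$subject_id, per_subj$subject_id)]
  withcov <- fit_moderation_model(tab, "u_beta_gd", covariates = "dsst")
  expect_true("z_dsst" %in% withcov$term)
  tab$dsst_copy <- tab$dsst
  expect_error(
    fit_moderation_model(tab, "u_beta_gd",
                         covariates = c("dsst", "dsst_copy")),
    "degenerate|collinear")
})

test_that("degenerate designs and small samples are refused", {
  tab <- make_table(n = 10, seed = 71)
  tab$condition <- "music"
  expect_error(fit_condition_model(tab, "u_beta_gd"), "two conditions")
  tab2 <- make_table(n = 2, seed = 72)
  expect_error(fit_condition_model(tab2, "u_beta_gd"), "3 subjects")
  expect_error(fit_condition_model(make_table(4), "nope"), "not found")
})

test_that("Bonferroni correction is exact, capped and family-aware", {
  expect_equal(bonferroni(0.03, m = 6), 0.18)
  expect_equal(bonferroni(0.5, m = 6), 1)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroni(0.04, m = 1), 0.04)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
  expect_error(bonferroni(1.2, m = 2), "0, 1")
})

test_that("stay probabilities separate model-free from model-based signatures", {
  cfg <- task_config(n_trials = 2500, break_after = integer(0))
  mf <- fixture_params()$mf_only
  mb <- fixture_params()$mb_only
  mf_log <- simulate_session(mf, cfg, seed = 81)
  mb_log <- simulate_session(mb, cfg, seed = 82)
  st_mf <- stay_probability_table(mf_log)
  st_mb <- stay_probability_table(mb_log)
  # model-free: reward main effect, negligible reward x transition interaction
  mf_reward_effect <- mean(st_mf["rewarded", ]) - mean(st_mf["unrewarded", ])
  mf_interaction <- (st_mf["rewarded", "common"] - st_mf["rewarded", "rare"]) -
    (st_mf["unrewarded", "common"] - st_mf["unrewarded", "rare"])
  expect_gt(mf_reward_effect, 0.05)
  # model-based: the reward effect reverses with transition type
  mb_interaction <- (st_mb["rewarded", "common"] - st_mb["rewarded", "rare"]) -
    (st_mb["unrewarded", "common"] - st_mb["unrewarded", "rare"])
  expect_gt(mb_interaction, 0.1)
  expect_gt(mb_interaction, mf_interaction + 0.05)
  # an indifferent agent stays at chance everywhere
  flat <- param_set(0.5, 0.5, 0.5, 1e-9, 1e-9, 1e-9, 0)
  st_flat <- stay_probability_table(simulate_session(flat, cfg, seed = 83))
  expect_true(all(abs(st_flat - 0.5) < 0.06))
  expect_error(stay_probability_table(mf_log[1, ]), "2 trials")
})
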