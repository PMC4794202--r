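#' Run the full simulate-fit-test pipeline
#'
#' Orchestrates a complete synthetic study: draw a cohort, simulate every
#' session, fit the hybrid model to each session by MAP, optionally apply
#' the one-step empirical-Bayes (EM) prior update, and run the group-level
#' analyses (overall condition effect on the goal-directed weight, the
#' condition-by-working-memory moderation model with simple effects at
#' +/- 1 SD, and Bonferroni-corrected exploratory condition tests on the
#' other six parameters). All stage seeds derive deterministically from the
#' master seed, so two runs with the same configuration and seed produce
#' identical files.
#'
#' @param task A [task_config()].
#' @param cohort A [cohort_config()].
#' @param prior A [map_prior()].
#' @param n_restarts Optimisation restarts per session fit.
#' @param em Also run the one-step EM prior update and report both fits
#'   (default `FALSE`).
#' @param seed Master seed.
#' @param out_dir Optional output directory (created if missing); when
#'   given, writes `trials.csv`, `covariates.csv`, `parameters.csv`
#'   (and `parameters_em.csv` with `em = TRUE`), `tests.csv` and
#'   `summary.csv`.
#' @return List with `trials`, `covariates`, `fits`, `tests` (all group
#'   test results with Bonferroni-adjusted exploratory p-values),
#'   `summary` (mean and quartiles of each natural-scale MAP parameter),
#'   `stay_probability`, and with `em = TRUE` also `em_prior`, `em_fits`,
#'   `em_tests` and `em_concordance` (side-by-side focal p-values under
#'   both priors).
#' @examples
#' \donttest{
#' res <- run_full_pipeline(
#'   task = task_config(n_trials = 60),
#'   cohort = cohort_config(n_subjects = 8),
#'   n_restarts = 2, seed = 1)
#' res$summary
#' }
#' @export
run_full_pipeline <- function(task = task_config(),
                              cohort = cohort_config(),
                              prior = map_prior(),
                              n_restarts = 6L,
                              em = FALSE,
                              seed = 1L,
                              out_dir = NULL) {
  validate_task_config(task)
  validate_cohort_config(cohort)
  records <- draw_cohort(cohort, seed = derive_seed(seed, "cohort"))
  sim <- generate_cohort_sessions(records, task,
                                  seed = derive_seed(seed, "sessions"),
                                  conditions = cohort$conditions)
  fits <- fit_cohort(sim$trials, prior = prior, n_restarts = n_restarts,
                     seed = derive_seed(seed, "fits"), hessian = em,
                     common_prob = task$common_prob)
  tab <- merge(fits, sim$covariates, by = "subject_id")
  tests <- group_analysis(tab, reference = cohort$conditions[1L])
  summary_tab <- parameter_summary(fits)
  out <- list(trials = sim$trials, covariates = sim$covariates, fits = fits,
              tests = tests, summary = summary_tab,
              stay_probability = stay_probability_table(sim$trials,
                                                        task$common_prob))
  if (em) {
    emres <- em_prior_step(fits, sim$trials, n_restarts = n_restarts,
                           seed = derive_seed(seed, "em"),
                           common_prob = task$common_prob)
    em_tab <- merge(emres$fits, sim$covariates, by = "subject_id")
    out$em_prior <- emres$prior
    out$em_fits <- emres$fits
    out$em_tests <- group_analysis(em_tab, reference = cohort$conditions[1L])
    focal <- c("beta_gd: condition", "beta_gd: interaction")
    out$em_concordance <- data.frame(
      test = focal,
      p_broad = out$tests$p[match(focal, out$tests$test)],
      p_em = out$em_tests$p[match(focal, out$em_tests$test)],
      stringsAsFactors = FALSE)
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    write_trial_log(sim$trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(sim$covariates, file.path(out_dir, "covariates.csv"),
                     row.names = FALSE, quote = FALSE)
    write_parameter_table(fits, file.path(out_dir, "parameters.csv"))
    utils::write.csv(tests, file.path(out_dir, "tests.csv"), row.names = FALSE)
    utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (em)
      write_parameter_table(out$em_fits, file.path(out_dir, "parameters_em.csv"))
  }
  out
}

# the pre-registered analysis set: overall condition effect on the
# goal-directed weight (one-tailed, gaming < music), the working-memory
# moderation model with simple effects at +/-1 SD, and two-tailed
# exploratory condition tests on the remaining six parameters with
# Bonferroni correction over the six-test family
group_analysis <- function(tab, reference = "music") {
  focal <- "u_beta_gd"
  cond <- fit_condition_model(tab, focal, tails = "less", reference = reference)
  cond$test <- "beta_gd: condition"
  mod <- fit_moderation_model(tab, focal, moderator = "z_wm",
                              tails_condition = "less",
                              tails_interaction = "greater",
                              reference = reference)
  mod$test <- paste0("beta_gd: ", c(condition_code = "condition @ mean wm",
                                    z_mod = "wm slope",
                                    `condition_code:z_mod` = "interaction")[mod$term])
  simp <- simple_effects(tab, focal, moderator = "z_wm", tails = "less",
                         reference = reference)
  simp$test <- paste0("beta_gd: simple ", simp$term)
  others <- setdiff(paste0("u_", param_names()), focal)
  expl <- do.call(rbind, lapply(others, function(par) {
    r <- fit_condition_model(tab, par, tails = "two.sided",
                             reference = reference)
    r$test <- paste0(sub("^u_", "", par), ": condition (exploratory)")
    r
  }))
  res <- rbind(cond, mod, simp, expl)
  res$p_adjusted <- NA_real_
  is_expl <- grepl("exploratory", res$test)
  res$p_adjusted[is_expl] <- bonferroni(res$p[is_expl], m = 6L)
  rownames(res) <- NULL
  res[, c("test", "term", "estimate", "se", "df", "t", "p", "p_adjusted",
          "tails", "formula")]
}

# mean / 25% / 75% of each natural-scale MAP parameter across sessions
parameter_summary <- function(fits) {
  do.call(rbind, lapply(param_names(), function(par) {
    v <- fits[[par]]
    data.frame(parameter = par, mean = mean(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)))
  }))
}

#' Parameter- and effect-recovery experiment
#'
#' Repeats the generate-fit-analyse chain over replicate cohorts and
#' summarises how well the method recovers what was injected: per
#' parameter, the Pearson correlation between true and recovered unbounded
#' values (pooled over replicates), bias and RMSE; per focal hypothesis,
#' the one-tailed rejection rate at `alpha` (the type-I error rate under a
#' null generator, power under an effect generator) and the mean simple
#' effects at +/- 1 SD of working memory.
#'
#' @param task A [task_config()].
#' @param cohort A [cohort_config()] (set both effect fields to 0 for a
#'   null-calibration run).
#' @param n_replicates Number of replicate cohorts (`>= 1`).
#' @param n_restarts Optimisation restarts per session fit.
#' @param alpha Nominal one-tailed level for the rejection-rate summaries.
#' @param seed Master seed; each replicate derives its own seeds.
#' @inheritParams run_full_pipeline
#' @return List with `recovery` (per-parameter correlation/bias/RMSE),
#'   `rejection_rates` (interaction, overall condition, and simple-effect
#'   tests), `mean_effects` (mean estimates of the focal coefficients) and
#'   `n_replicates`. With `n_replicates = 1` the rate columns are the 0/1
#'   outcome of the single replicate.
#' @export
run_recovery <- function(task = task_config(),
                         cohort = cohort_config(),
                         n_replicates = 1L,
                         n_restarts = 6L,
                         prior = map_prior(),
                         alpha = 0.05,
                         seed = 1L) {
  stopifnot(n_replicates >= 1L)
  ucols <- paste0("u_", param_names())
  true_all <- rec_all <- NULL
  focal <- data.frame()
  for (r in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, "replicate", r)
    records <- draw_cohort(cohort, seed = derive_seed(rep_seed, "cohort"))
    sim <- generate_cohort_sessions(records, task,
                                    seed = derive_seed(rep_seed, "sessions"),
                                    conditions = cohort$conditions)
    fits <- fit_cohort(sim$trials, prior = prior, n_restarts = n_restarts,
                       seed = derive_seed(rep_seed, "fits"),
                       common_prob = task$common_prob)
    truth <- cohort_true_params(records, conditions = cohort$conditions)
    merged <- merge(truth, fits, by = c("subject_id", "condition"),
                    suffixes = c("_true", "_fit"))
    true_all <- rbind(true_all, merged[, paste0(ucols, "_true")])
    rec_all <- rbind(rec_all, merged[, paste0(ucols, "_fit")])
    tab <- merge(fits, records[, c("subject_id", "wm_score", "z_wm")],
                 by = "subject_id")
    mod <- fit_moderation_model(tab, "u_beta_gd", moderator = "z_wm",
                                tails_condition = "less",
                                tails_interaction = "greater",
                                reference = cohort$conditions[1L])
    cond <- fit_condition_model(tab, "u_beta_gd", tails = "less",
                                reference = cohort$conditions[1L])
    simp <- simple_effects(tab, "u_beta_gd", moderator = "z_wm",
                           tails = "less", reference = cohort$conditions[1L])
    focal <- rbind(focal, data.frame(
      replicate = r,
      interaction_b = mod$estimate[mod$term == "condition_code:z_mod"],
      interaction_p = mod$p[mod$term == "condition_code:z_mod"],
      condition_b = cond$estimate, condition_p = cond$p,
      simple_low_b = simp$estimate[1L], simple_low_p = simp$p[1L],
      simple_high_b = simp$estimate[2L], simple_high_p = simp$p[2L]))
  }
  recovery <- do.call(rbind, lapply(seq_along(ucols), function(i) {
    tv <- true_all[[i]]; rv <- rec_all[[i]]
    data.frame(parameter = param_names()[i],
               correlation = stats::cor(tv, rv),
               bias = mean(rv - tv),
               rmse = sqrt(mean((rv - tv)^2)))
  }))
  list(
    recovery = recovery,
    rejection_rates = data.frame(
      test = c("interaction", "condition", "simple at -1 SD", "simple at +1 SD"),
      rate = c(mean(focal$interaction_p < alpha),
               mean(focal$condition_p < alpha),
               mean(focal$simple_low_p < alpha),
               mean(focal$simple_high_p < alpha))),
    mean_effects = data.frame(
      coefficient = c("interaction", "condition", "simple at -1 SD",
                      "simple at +1 SD"),
      mean_b = c(mean(focal$interaction_b), mean(focal$condition_b),
                 mean(focal$simple_low_b), mean(focal$simple_high_b))),
    replicates = focal,
    n_replicates = n_replicates)
}
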