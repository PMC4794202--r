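#' Synthetic-cohort configuration
#'
#' Describes a simulated within-subject study: each subject performs the
#' two-step task once per break condition (music, gaming), carries a
#' working-memory covariate emulating a backwards Digit Span score, and has
#' subject-level true parameters drawn on the unbounded scale around
#' population means. The gaming condition can shift the unbounded
#' goal-directed weight by a main effect plus an interaction with the
#' z-scored working-memory score, which is the effect structure the
#' group-level moderation analysis is designed to detect.
#'
#' Population defaults are chosen so that the natural-scale medians of the
#' generated parameters fall inside the interquartile ranges typically
#' reported for this task (e.g. median `beta_gd` about 2.1 against reported
#' quartiles 0.84–5.19). The default effect sizes mirror the qualitative
#' pattern of interest: a modest overall gaming-related reduction of the
#' unbounded goal-directed weight (-0.17) plus a positive interaction with
#' working memory (+0.24), so the deficit concentrates in low-WM subjects
#' (simple effect -0.41 at one SD below the mean, roughly zero at one SD
#' above).
#'
#' @param n_subjects Number of subjects (default 33).
#' @param conditions Two condition labels; the second is the one receiving
#'   the effect shifts (default `c("music", "gaming")`).
#' @param wm_mean,wm_sd Mean and SD of the working-memory covariate
#'   (defaults 7.39 and 1.78, i.e. an SEM of about 0.31 at n = 33).
#' @param pop_mean,pop_sd Length-7 population means and between-subject SDs
#'   of the unbounded parameters (order: alpha1, alpha2, lam, beta2,
#'   beta_hb, beta_gd, p).
#' @param effect_beta_gd_condition Main shift of unbounded `beta_gd` in the
#'   second condition.
#' @param effect_beta_gd_interaction Shift of unbounded `beta_gd` in the
#'   second condition per unit of z-scored working memory.
#' @param counterbalance Alternate condition order across subjects
#'   (default `TRUE`).
#' @param round_wm Round the working-memory score to integers, as a real
#'   Digit Span score would be (default `FALSE`, keeping the covariate
#'   continuous).
#' @param rng_seed Default seed used by [draw_cohort()] when none is given.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 33L,
                          conditions = c("music", "gaming"),
                          wm_mean = 7.39, wm_sd = 1.78,
                          pop_mean = c(alpha1 = 0.4, alpha2 = 0.7, lam = 1.3,
                                       beta2 = 1.1, beta_hb = 0.6,
                                       beta_gd = 0.75, p = 0.75),
                          pop_sd = c(alpha1 = 1.0, alpha2 = 0.8, lam = 1.0,
                                     beta2 = 0.5, beta_hb = 0.8,
                                     beta_gd = 0.9, p = 0.5),
                          effect_beta_gd_condition = -0.17,
                          effect_beta_gd_interaction = 0.24,
                          counterbalance = TRUE,
                          round_wm = FALSE,
                          rng_seed = 1L) {
  pop_mean <- rep_len(as.numeric(pop_mean), 7L)
  pop_sd <- rep_len(as.numeric(pop_sd), 7L)
  names(pop_mean) <- names(pop_sd) <- param_names()
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects), conditions = conditions,
         wm_mean = wm_mean, wm_sd = wm_sd,
         pop_mean = pop_mean, pop_sd = pop_sd,
         effect_beta_gd_condition = effect_beta_gd_condition,
         effect_beta_gd_interaction = effect_beta_gd_interaction,
         counterbalance = isTRUE(counterbalance),
         round_wm = isTRUE(round_wm),
         rng_seed = as.integer(rng_seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_subjects < 2L)
    stop("invalid cohort_config: n_subjects must be >= 2", call. = FALSE)
  if (length(cfg$conditions) != 2L || anyDuplicated(cfg$conditions))
    stop("invalid cohort_config: exactly two distinct conditions required",
         call. = FALSE)
  if (cfg$wm_sd < 0 || any(cfg$pop_sd < 0))
    stop("invalid cohort_config: SDs must be non-negative", call. = FALSE)
  invisible(cfg)
}

#' Draw a synthetic cohort of subjects
#'
#' For each subject: a working-memory score `wm ~ Normal(wm_mean, wm_sd)`;
#' subject-level unbounded parameters `Normal(pop_mean, pop_sd)` shared
#' across conditions; and, in the second (gaming) condition only, unbounded
#' `beta_gd` shifted by `effect_beta_gd_condition +
#' effect_beta_gd_interaction * z_wm`, where `z_wm` is the within-cohort
#' z-score of the working-memory score. Condition order alternates across
#' subjects when counterbalancing is on.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (default `config$rng_seed`).
#' @return A `data.frame` with one row per subject: `subject_id`,
#'   `wm_score`, `z_wm`, `condition_order`, and list-columns `params_music`
#'   / `params_gaming` holding each condition's true unbounded parameter
#'   vector (names follow `conditions`).
#' @examples
#' cohort <- draw_cohort(cohort_config(n_subjects = 4), seed = 1)
#' cohort$subject_id
#' @export
draw_cohort <- function(config, seed = config$rng_seed) {
  validate_cohort_config(config)
  n <- config$n_subjects
  with_seed(seed, {
    wm <- stats::rnorm(n, config$wm_mean, config$wm_sd)
    if (config$round_wm) wm <- round(wm)
    z_wm <- as.numeric(scale(wm))
    base <- t(vapply(seq_len(n),
                     function(i) stats::rnorm(7L, config$pop_mean, config$pop_sd),
                     numeric(7L)))
    colnames(base) <- param_names()
    shift <- config$effect_beta_gd_condition +
      config$effect_beta_gd_interaction * z_wm
    first <- if (config$counterbalance) {
      config$conditions[(seq_len(n) - 1L) %% 2L + 1L]
    } else rep(config$conditions[1L], n)
    p1 <- lapply(seq_len(n), function(i) base[i, ])
    p2 <- lapply(seq_len(n), function(i) {
      u <- base[i, ]
      u[["beta_gd"]] <- u[["beta_gd"]] + shift[i]
      u
    })
    out <- data.frame(
      subject_id = sprintf("s%02d", seq_len(n)),
      wm_score = wm, z_wm = z_wm,
      condition_order = vapply(first, function(f)
        paste(c(f, setdiff(config$conditions, f)), collapse = ","), ""),
      stringsAsFactors = FALSE)
    out[[paste0("params_", config$conditions[1L])]] <- I(p1)
    out[[paste0("params_", config$conditions[2L])]] <- I(p2)
    out
  })
}

#' Simulate every session of a cohort
#'
#' Generates one two-step session per subject and condition with
#' [simulate_session()], each with a fresh reward schedule, and returns the
#' two tables the downstream analysis consumes.
#'
#' @param records Cohort table from [draw_cohort()].
#' @param config A [task_config()].
#' @param seed Master seed; per-session seeds are derived from it.
#' @param conditions The two condition labels, in the order used by
#'   [draw_cohort()].
#' @return List with `trials` (long trial log: all sessions stacked) and
#'   `covariates` (`subject_id`, `wm_score`, `z_wm`, `condition_order`).
#' @export
generate_cohort_sessions <- function(records, config = task_config(),
                                     seed = 1L,
                                     conditions = c("music", "gaming")) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  logs <- vector("list", nrow(records) * 2L)
  k <- 0L
  for (i in seq_len(nrow(records))) {
    for (j in seq_along(conditions)) {
      cond <- conditions[j]
      u <- records[[paste0("params_", cond)]][[i]]
      pars <- to_natural(u)
      sched <- build_reward_schedule(
        config, seed = derive_seed(seed, paste0("schedule_", cond), i))
      k <- k + 1L
      logs[[k]] <- simulate_session(
        pars, config, schedule = sched,
        seed = derive_seed(seed, paste0("session_", cond), i),
        subject_id = records$subject_id[i], condition = cond)
    }
  }
  trials <- do.call(rbind, logs)
  rownames(trials) <- NULL
  covariates <- records[, c("subject_id", "wm_score", "z_wm", "condition_order")]
  list(trials = trials, covariates = covariates)
}

#' True unbounded parameters of a cohort in long format
#'
#' Convenience reshaping of [draw_cohort()] output into one row per
#' subject-condition with `u_`-prefixed columns, directly comparable to
#' [fit_cohort()] output.
#'
#' @inheritParams generate_cohort_sessions
#' @return A `data.frame` with `subject_id`, `condition`, `z_wm` and the
#'   seven `u_` columns.
#' @export
cohort_true_params <- function(records, conditions = c("music", "gaming")) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    do.call(rbind, lapply(conditions, function(cond) {
      u <- records[[paste0("params_", cond)]][[i]]
      out <- data.frame(subject_id = records$subject_id[i], condition = cond,
                        z_wm = records$z_wm[i], t(as.numeric(u)),
                        stringsAsFactors = FALSE)
      names(out)[4:10] <- paste0("u_", param_names())
      out
    }))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
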