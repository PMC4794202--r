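#' @importFrom lme4 lmer lmerControl
NULL

# one test's worth of inference, as a tidy one-row data.frame
test_result <- function(term, estimate, se, df, t, p, tails, formula = NA_character_) {
  data.frame(term = term, estimate = estimate, se = se, df = df, t = t,
             p = p, tails = tails, formula = formula,
             stringsAsFactors = FALSE)
}

tail_p <- function(t, df, tails) {
  switch(tails,
         two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
         less = stats::pt(t, df),
         greater = stats::pt(t, df, lower.tail = FALSE),
         stop("tails must be 'two.sided', 'less' or 'greater'", call. = FALSE))
}

# containment-style denominator df for a random-intercept model:
# a fixed-effect column that varies within subjects is tested against the
# within-subject stratum (N - g - #within columns), a column constant
# within every subject against the between-subject stratum
# (g - #between columns - 1)
containment_df <- function(X, subject) {
  cols <- colnames(X)
  non_int <- setdiff(cols, "(Intercept)")
  varies_within <- vapply(non_int, function(cn) {
    any(tapply(X[, cn], subject, function(v) length(unique(v)) > 1L))
  }, logical(1L))
  n_within <- sum(varies_within)
  n_between <- sum(!varies_within)
  g <- length(unique(subject))
  df <- stats::setNames(numeric(length(cols)), cols)
  df["(Intercept)"] <- g - n_between - 1L
  df[non_int] <- ifelse(varies_within,
                        nrow(X) - g - n_within,
                        g - n_between - 1L)
  df
}

# fit parameter ~ <rhs> + (1 | subject_id) and extract per-term inference
fit_mixed <- function(table, parameter, rhs, tails_by_term,
                      df_method = c("containment", "satterthwaite")) {
  df_method <- match.arg(df_method)
  if (!parameter %in% names(table))
    stop(sprintf("parameter column '%s' not found", parameter), call. = FALSE)
  if (length(unique(table$subject_id)) < 3L)
    stop("group inference needs at least 3 subjects", call. = FALSE)
  fml <- stats::as.formula(
    sprintf("%s ~ %s + (1 | subject_id)", parameter, rhs))
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = table)
  d <- svd(X, nu = 0, nv = 0)$d
  kappa_x <- d[1] / max(d[length(d)], .Machine$double.eps)
  if (qr(X)$rank < ncol(X))
    stop(sprintf(
      "degenerate or collinear fixed-effect design (rank %d < %d columns, condition number %.3g)",
      qr(X)$rank, ncol(X), kappa_x), call. = FALSE)
  if (is.finite(kappa_x) && kappa_x > 1e6)
    warning(sprintf("near-collinear predictors (condition number %.3g)", kappa_x))
  ctrl <- lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
  fit <- suppressMessages(lmerTest::lmer(fml, data = table, control = ctrl))
  smry <- summary(fit, ddf = "Satterthwaite")$coefficients
  est <- smry[, "Estimate"]
  se <- smry[, "Std. Error"]
  ddf <- if (df_method == "containment") {
    containment_df(X, table$subject_id)[rownames(smry)]
  } else smry[, "df"]
  tval <- est / se
  rows <- lapply(rownames(smry), function(term) {
    tails <- tails_by_term[[term]]
    if (is.null(tails)) tails <- "two.sided"
    test_result(term, est[[term]], se[[term]], ddf[[term]], tval[[term]],
                tail_p(tval[[term]], ddf[[term]], tails), tails,
                formula = deparse(fml))
  })
  do.call(rbind, rows)
}

# condition as a 0/1 numeric with the stated reference level first
code_condition <- function(table, reference = "music") {
  conds <- unique(table$condition)
  if (length(conds) != 2L)
    stop("exactly two conditions are required", call. = FALSE)
  if (!reference %in% conds) reference <- sort(conds)[1L]
  other <- setdiff(conds, reference)
  table$condition_code <- as.numeric(table$condition == other)
  attr(table, "condition_labels") <- c(reference, other)
  table
}

#' Condition effect on a fitted parameter (mixed model)
#'
#' Regresses a per-session parameter estimate on break condition with
#' random subject intercepts: `parameter ~ condition + (1 | subject)`.
#' The condition predictor is coded 0 for the reference condition (music)
#' and 1 for the other (gaming), so a negative coefficient means a
#' gaming-related reduction. With exactly two observations per subject the
#' condition coefficient equals the paired mean difference.
#'
#' @param table Long cohort table: columns `subject_id`, `condition` and the
#'   parameter of interest (typically a `u_`-prefixed unbounded MAP column
#'   from [fit_cohort()]), two rows per subject.
#' @param parameter Name of the column to analyse.
#' @param tails `"two.sided"`, `"less"` (directed: gaming < music) or
#'   `"greater"`, applied to the condition coefficient.
#' @param reference Reference condition (coded 0; default `"music"`).
#' @param df_method Denominator degrees of freedom: `"containment"`
#'   (default; within-subject terms are tested in the within-subject
#'   stratum) or `"satterthwaite"`.
#' @return One-row `data.frame` with `term`, `estimate`, `se`, `df`, `t`,
#'   `p`, `tails`, `formula`.
#' @export
fit_condition_model <- function(table, parameter, tails = "two.sided",
                                reference = "music",
                                df_method = c("containment", "satterthwaite")) {
  table <- code_condition(table, reference)
  if (length(unique(table$condition_code)) < 2L)
    stop("degenerate design: condition does not vary", call. = FALSE)
  res <- fit_mixed(table, parameter, "condition_code",
                   tails_by_term = list(condition_code = tails),
                   df_method = match.arg(df_method))
  res[res$term == "condition_code", , drop = FALSE]
}

#' Condition-by-moderator moderation model
#'
#' Fits `parameter ~ condition * z(moderator) + covariates +
#' (1 | subject)` and returns the inference for the condition main effect
#' (at the moderator mean), the condition-by-moderator interaction, and any
#' covariates. The moderator is z-scored across subjects before entering
#' the model, so its coefficients are standardised; covariates are likewise
#' z-scored.
#'
#' @inheritParams fit_condition_model
#' @param moderator Name of the (between-subject) moderator column, e.g. a
#'   working-memory score.
#' @param covariates Optional character vector of covariate columns (e.g.
#'   processing-speed and verbal-knowledge scores), z-scored and added as
#'   fixed effects.
#' @param tails_condition,tails_interaction Tail specification for the two
#'   focal tests (directed hypotheses: `"less"` for a gaming-related
#'   deficit, `"greater"` for a positive working-memory interaction).
#' @return A `data.frame` of test results, one row per fixed-effect term
#'   (condition, moderator, interaction, covariates).
#' @export
fit_moderation_model <- function(table, parameter, moderator = "z_wm",
                                 covariates = NULL,
                                 tails_condition = "two.sided",
                                 tails_interaction = "two.sided",
                                 reference = "music",
                                 df_method = c("containment", "satterthwaite")) {
  table <- code_condition(table, reference)
  table$z_mod <- z_by_subject(table, moderator)
  rhs_terms <- c("condition_code * z_mod")
  for (cv in covariates) {
    zc <- paste0("z_", cv)
    table[[zc]] <- z_by_subject(table, cv)
    rhs_terms <- c(rhs_terms, zc)
  }
  tails <- list(condition_code = tails_condition,
                `condition_code:z_mod` = tails_interaction)
  res <- fit_mixed(table, parameter, paste(rhs_terms, collapse = " + "),
                   tails_by_term = tails, df_method = match.arg(df_method))
  res[res$term != "(Intercept)", , drop = FALSE]
}

# z-score a column across subjects (between-subject variables appear twice
# per subject; standardise over the per-subject unique values)
z_by_subject <- function(table, column) {
  if (!column %in% names(table))
    stop(sprintf("column '%s' not found", column), call. = FALSE)
  per_subj <- tapply(table[[column]], table$subject_id, function(v) v[1L])
  m <- mean(per_subj)
  s <- stats::sd(per_subj)
  if (!is.finite(s) || s == 0)
    stop(sprintf("column '%s' has no between-subject variance", column),
         call. = FALSE)
  (table[[column]] - m) / s
}

#' Simple condition effects at +/- 1 SD of the moderator
#'
#' Re-centers the z-scored moderator at `at_sd` standard deviations above
#' the mean and refits the moderation model, so the condition coefficient
#' becomes the simple effect of condition for subjects at that moderator
#' level. By construction `simple(+1) - simple(-1) = 2 * interaction`.
#'
#' @inheritParams fit_moderation_model
#' @param at_sd Numeric vector of moderator levels in SD units (default
#'   `c(-1, 1)`).
#' @param tails Tail specification applied to each simple effect.
#' @return A `data.frame` with one row per level of `at_sd`; the `term`
#'   column records the level (e.g. `"condition at z = -1"`).
#' @export
simple_effects <- function(table, parameter, moderator = "z_wm",
                           covariates = NULL, at_sd = c(-1, 1),
                           tails = "two.sided", reference = "music",
                           df_method = c("containment", "satterthwaite")) {
  df_method <- match.arg(df_method)
  table <- code_condition(table, reference)
  table$z_mod0 <- z_by_subject(table, moderator)
  rhs_extra <- character(0)
  for (cv in covariates) {
    zc <- paste0("z_", cv)
    table[[zc]] <- z_by_subject(table, cv)
    rhs_extra <- c(rhs_extra, zc)
  }
  rows <- lapply(at_sd, function(a) {
    table$z_mod <- table$z_mod0 - a
    rhs <- paste(c("condition_code * z_mod", rhs_extra), collapse = " + ")
    res <- fit_mixed(table, parameter, rhs,
                     tails_by_term = list(condition_code = tails),
                     df_method = df_method)
    res <- res[res$term == "condition_code", , drop = FALSE]
    res$term <- sprintf("condition at z = %+g", a)
    res
  })
  do.call(rbind, rows)
}

#' Bonferroni correction
#'
#' `min(1, m * p)` for each p-value, with `m` the number of tests in the
#' family (which may exceed the number of p-values passed).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param m Family size; must be at least `length(p)`.
#' @return Adjusted p-values, same length as `p`.
#' @examples
#' bonferroni(0.03, m = 6)  # 0.18
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p))
    stop("family size m cannot be smaller than the number of tests", call. = FALSE)
  pmin(1, m * p)
}

#' Paired t-test
#'
#' Classic paired t-test computed from the difference scores, used for
#' rating-scale comparisons and as the algebraic reference for the
#' balanced two-observation mixed model. A zero-variance difference vector
#' is handled explicitly: the statistic is `0` (p = 1) when all differences
#' are zero and signed infinity (p = 0 one-/two-tailed) otherwise.
#'
#' @param a,b Numeric vectors of equal length `>= 3` (pairs).
#' @param tails `"two.sided"`, `"less"` or `"greater"` (direction of
#'   `a - b`).
#' @return One-row `data.frame` as in [fit_condition_model()].
#' @export
paired_t <- function(a, b, tails = "two.sided") {
  if (length(a) != length(b))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- tail_p(t, df, tails)
    return(test_result("paired difference", m, 0, df, t, p, tails))
  }
  se <- s / sqrt(n)
  t <- m / se
  test_result("paired difference", m, se, df, t, tail_p(t, df, tails), tails)
}

#' Stay probabilities by previous reward and transition type
#'
#' The behavioural signature diagnostic for the two-step task: the
#' probability of repeating the previous first-stage choice, tabulated by
#' whether the previous trial was rewarded and whether its transition was
#' common or rare. A purely model-free agent shows a main effect of reward;
#' a model-based agent shows the reward-by-transition interaction. Cells
#' with no observations are reported as `NaN`, never imputed.
#'
#' @param trials Trial log (one or more sessions; sessions are delimited by
#'   `subject_id` x `condition`). Each session needs at least 2 trials.
#' @param common_prob Used only to label transitions: a transition is
#'   common when the reached state is the one commonly associated with the
#'   chosen action.
#' @return A 2 x 2 matrix of stay probabilities, rows `rewarded` /
#'   `unrewarded`, columns `common` / `rare`, with attribute `"n"` holding
#'   the cell counts.
#' @export
stay_probability_table <- function(trials, common_prob = 0.7) {
  key <- interaction(trials$subject_id, trials$condition, drop = TRUE)
  stay <- prev_rew <- prev_common <- logical(0)
  for (ses in split(trials, key)) {
    ses <- ses[order(ses$trial), , drop = FALSE]
    if (nrow(ses) < 2L)
      stop("each session needs at least 2 trials", call. = FALSE)
    idx <- 2:nrow(ses)
    stay <- c(stay, ses$choice1[idx] == ses$choice1[idx - 1L])
    prev_rew <- c(prev_rew, ses$reward[idx - 1L] == 1)
    # action a's common destination is state a
    prev_common <- c(prev_common, ses$state2[idx - 1L] == ses$choice1[idx - 1L])
  }
  cell <- function(r, cm) {
    sel <- prev_rew == r & prev_common == cm
    if (!any(sel)) NaN else mean(stay[sel])
  }
  counts <- matrix(c(sum(prev_rew & prev_common), sum(prev_rew & !prev_common),
                     sum(!prev_rew & prev_common), sum(!prev_rew & !prev_common)),
                   2L, 2L, byrow = TRUE)
  out <- matrix(c(cell(TRUE, TRUE), cell(TRUE, FALSE),
                  cell(FALSE, TRUE), cell(FALSE, FALSE)),
                2L, 2L, byrow = TRUE,
                dimnames = list(previous = c("rewarded", "unrewarded"),
                                transition = c("common", "rare")))
  attr(out, "n") <- counts
  out
}
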