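#' Read and write two-step trial logs
#'
#' Trial logs are plain CSV with the canonical header `subject_id,
#' condition, trial, choice1, state2, choice2, reward, block`; choices,
#' states and rewards are coded 0/1 and `trial` is 1-based.
#'
#' @param trials Trial-log `data.frame`.
#' @param path File path.
#' @return `read_trial_log()` returns the trial-log `data.frame`;
#'   `write_trial_log()` returns `path` invisibly.
#' @export
write_trial_log <- function(trials, path) {
  cols <- c("subject_id", "condition", "trial", "choice1", "state2",
            "choice2", "reward", "block")
  missing_cols <- setdiff(cols, names(trials))
  if (length(missing_cols))
    stop("trial log lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  utils::write.csv(trials[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "condition", "trial", "choice1", "state2",
              "choice2", "reward")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("trial log lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df
}

#' Write a fitted-parameter table
#'
#' One row per subject-condition with the natural-scale and unbounded
#' (`u_`-prefixed) MAP estimates, the final negative log posterior and the
#' convergence flag, as produced by [fit_cohort()].
#'
#' @param fits Fit table from [fit_cohort()].
#' @param path File path.
#' @export
write_parameter_table <- function(fits, path) {
  cols <- c("subject_id", "condition", param_names(),
            paste0("u_", param_names()), "nlp", "converged")
  utils::write.csv(fits[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a task configuration from a YAML or key-value file
#'
#' Accepts a YAML mapping (or flat `key: value` file) exposing any
#' [task_config()] fields; unspecified fields keep their defaults.
#'
#' @param path File path.
#' @return A [task_config()].
#' @export
read_task_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package", call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(task_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown task config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(task_config, vals)
}
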