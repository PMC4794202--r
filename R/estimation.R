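#' Parameter transformations between natural and unbounded scales
#'
#' Estimation runs unconstrained on a transformed scale: the bounded
#' learning-rate and eligibility parameters (`alpha1`, `alpha2`, `lam`) are
#' mapped by the logit, the non-negative weights (`beta2`, `beta_hb`,
#' `beta_gd`) by the log, and the perseveration parameter `p` by the
#' identity. The maps are bijective; `to_natural(to_unbounded(x)) == x`.
#'
#' @param params A [param_set()] strictly inside its bounds.
#' @return `to_unbounded()`: a named length-7 numeric vector on the
#'   unbounded scale; `to_natural()`: a [param_set()].
#' @examples
#' to_unbounded(param_set(0.5, 0.5, 0.5, 1, 1, 1, 0))  # all zero
#' @export
to_unbounded <- function(params) {
  validate_param_set(params)
  for (nm in c("beta2", "beta_hb", "beta_gd"))
    if (params[[nm]] <= 0)
      stop(sprintf("%s must be strictly positive for the log transform", nm),
           call. = FALSE)
  u <- c(stats::qlogis(params[["alpha1"]]),
         stats::qlogis(params[["alpha2"]]),
         stats::qlogis(params[["lam"]]),
         log(params[["beta2"]]),
         log(params[["beta_hb"]]),
         log(params[["beta_gd"]]),
         params[["p"]])
  names(u) <- param_names()
  u
}

#' @rdname to_unbounded
#' @param u Named or ordered length-7 numeric vector on the unbounded scale
#'   (order: alpha1, alpha2, lam, beta2, beta_hb, beta_gd, p).
#' @export
to_natural <- function(u) {
  stopifnot(length(u) == 7L, all(is.finite(u)))
  u <- as.numeric(u)
  # keep logistic outputs strictly inside (0, 1): beyond |u| ~ 37 the
  # logistic saturates in double precision
  eps <- 1e-15
  plogis_open <- function(x) pmin(pmax(stats::plogis(x), eps), 1 - eps)
  param_set(alpha1 = plogis_open(u[1L]),
            alpha2 = plogis_open(u[2L]),
            lam = plogis_open(u[3L]),
            beta2 = exp(u[4L]),
            beta_hb = exp(u[5L]),
            beta_gd = exp(u[6L]),
            p = u[7L])
}

#' Gaussian prior on the unbounded parameter scale
#'
#' Uncorrelated normal prior over the seven unbounded parameters. The
#' default (`mean = 0`, `sd = 100`) is deliberately broad: it regularises
#' degenerate sessions (e.g. a subject who always presses one key) without
#' noticeably biasing identifiable fits. On the unbounded scale a mean of 0
#' corresponds to learning rates of 0.5 and weights of 1.
#'
#' @param mean,sd Length-7 (or recycled length-1) numeric vectors; `sd > 0`.
#' @return Object of class `map_prior` with `mean` and `sd` vectors.
#' @export
map_prior <- function(mean = 0, sd = 100) {
  mean <- rep_len(as.numeric(mean), 7L)
  sd <- rep_len(as.numeric(sd), 7L)
  if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(sd <= 0))
    stop("prior means must be finite and prior SDs strictly positive", call. = FALSE)
  names(mean) <- names(sd) <- param_names()
  structure(list(mean = mean, sd = sd), class = "map_prior")
}

#' @export
print.map_prior <- function(x, ...) {
  cat("Gaussian prior on the unbounded parameter scale\n")
  print(rbind(mean = round(x$mean, 4), sd = round(x$sd, 4)))
  invisible(x)
}

#' Negative log posterior on the unbounded scale
#'
#' `session NLL at to_natural(u)` plus the Gaussian penalty
#' `sum_i (u_i - m_i)^2 / (2 s_i^2)`. The prior's additive normalisation
#' constants are dropped (they do not move the argmax), so printed
#' objective values are comparable only within this package.
#'
#' @param data Session trial log.
#' @param u Length-7 unbounded parameter vector.
#' @param prior A [map_prior()].
#' @inheritParams session_neg_log_likelihood
#' @return Finite scalar for finite `u`.
#' @export
neg_log_posterior <- function(data, u, prior = map_prior(), common_prob = 0.7,
                              q_init = 0.5) {
  nll <- session_neg_log_likelihood(data, to_natural(u),
                                    common_prob = common_prob, q_init = q_init)
  nll + sum((as.numeric(u) - prior$mean)^2 / (2 * prior$sd^2))
}

#' MAP estimation of the hybrid model for one session
#'
#' Maximum a posteriori estimation on the unbounded scale: a quasi-Newton
#' (BFGS) minimiser with numerical gradients is started from `n_restarts`
#' random points drawn Normal(0, `restart_sd`), and the restart with the
#' lowest negative log posterior wins. Restarts whose objective is not
#' finite at the start point are redrawn. The whole procedure is
#' deterministic given `seed`.
#'
#' @param data Session trial log (non-empty).
#' @param prior A [map_prior()]; the default is the broad Normal(0, 100).
#' @param n_restarts Number of independent optimisation runs (default 6).
#' @param restart_sd SD of the Gaussian start-point draws (default 0.1).
#' @param seed Integer seed for the start points.
#' @param hessian If `TRUE`, store the numerical Hessian at the optimum
#'   (needed for the Laplace variances of [em_prior_step()]).
#' @param max_iter,reltol Optimiser budget and convergence tolerance.
#' @inheritParams session_neg_log_likelihood
#' @return Object of class `map_fit`: `map_unbounded` (named vector),
#'   `map_natural` ([param_set()]), `neg_log_posterior`, `converged`,
#'   `n_restarts`, `best_restart`, and optionally `hessian`.
#' @examples
#' \donttest{
#' pars <- param_set(0.5, 0.6, 0.8, 3, 2, 3, 0.5)
#' dat <- simulate_session(pars, task_config(), seed = 1)
#' fit <- fit_map(dat, n_restarts = 2, seed = 1)
#' fit$map_natural
#' }
#' @export
fit_map <- function(data, prior = map_prior(), n_restarts = 6L,
                    restart_sd = 0.1, seed = 1L, hessian = FALSE,
                    max_iter = 500L, reltol = 1e-10, common_prob = 0.7,
                    q_init = 0.5) {
  if (nrow(data) == 0L) stop("cannot fit an empty session", call. = FALSE)
  stopifnot(n_restarts >= 1L)
  ch1 <- as.integer(data$choice1); st2 <- as.integer(data$state2)
  ch2 <- as.integer(data$choice2); rew <- as.numeric(data$reward)
  objective <- function(u) {
    nll_session_cpp(ch1, st2, ch2, rew, natural_vec(u), common_prob, q_init) +
      sum((u - prior$mean)^2 / (2 * prior$sd^2))
  }
  starts <- with_seed(seed, {
    draw <- function() stats::rnorm(7L, 0, restart_sd)
    lapply(seq_len(n_restarts), function(i) {
      s <- draw()
      tries <- 0L
      while (!is.finite(objective(s)) && tries < 50L) {
        s <- draw(); tries <- tries + 1L
      }
      s
    })
  })
  best <- NULL
  for (i in seq_len(n_restarts)) {
    res <- tryCatch(
      stats::optim(starts[[i]], objective, method = "BFGS",
                   control = list(maxit = max_iter, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$restart <- i
    }
  }
  if (is.null(best))
    stop("all optimisation restarts failed; inspect the session data", call. = FALSE)
  u <- best$par
  names(u) <- param_names()
  fit <- structure(
    list(map_unbounded = u,
         map_natural = to_natural(u),
         neg_log_posterior = best$value,
         converged = best$convergence == 0L,
         n_restarts = n_restarts,
         best_restart = best$restart),
    class = "map_fit")
  if (hessian)
    fit$hessian <- stats::optimHess(best$par, objective)
  fit
}

# natural-scale parameter vector from unbounded, no validation (hot path)
natural_vec <- function(u) {
  c(stats::plogis(u[1L]), stats::plogis(u[2L]), stats::plogis(u[3L]),
    exp(u[4L]), exp(u[5L]), exp(u[6L]), u[7L])
}

#' @export
print.map_fit <- function(x, ...) {
  cat(sprintf("MAP fit (neg. log posterior %.3f, %s, best of %d restarts)\n",
              x$neg_log_posterior,
              if (x$converged) "converged" else "NOT converged", x$n_restarts))
  print(round(unclass(x$map_natural), 4))
  invisible(x)
}

#' Fit every session of a cohort
#'
#' Runs [fit_map()] on each subject-by-condition session of a long trial
#' log and returns one row per session with the MAP estimates on both
#' scales.
#'
#' @param trials Trial log with `subject_id` and `condition` columns (as
#'   written by [generate_cohort_sessions()]).
#' @param seed Master seed; each session gets its own derived restart seed.
#' @inheritParams fit_map
#' @return A `data.frame` with columns `subject_id`, `condition`, the seven
#'   natural-scale parameters, their unbounded counterparts (prefix `u_`),
#'   `nlp` and `converged`.
#' @export
fit_cohort <- function(trials, prior = map_prior(), n_restarts = 6L,
                       restart_sd = 0.1, seed = 1L, hessian = FALSE,
                       common_prob = 0.7, q_init = 0.5) {
  key <- interaction(trials$subject_id, trials$condition, drop = TRUE)
  sessions <- split(trials, key)
  rows <- lapply(seq_along(sessions), function(i) {
    dat <- sessions[[i]]
    dat <- dat[order(dat$trial), , drop = FALSE]
    fit <- fit_map(dat, prior = prior, n_restarts = n_restarts,
                   restart_sd = restart_sd,
                   seed = derive_seed(seed, "fit", i), hessian = hessian,
                   common_prob = common_prob, q_init = q_init)
    out <- data.frame(subject_id = dat$subject_id[1L],
                      condition = dat$condition[1L],
                      t(as.numeric(fit$map_natural)),
                      t(as.numeric(fit$map_unbounded)),
                      nlp = fit$neg_log_posterior,
                      converged = fit$converged,
                      stringsAsFactors = FALSE)
    names(out)[3:9] <- param_names()
    names(out)[10:16] <- paste0("u_", param_names())
    if (hessian) out$laplace_var <- I(list(laplace_variances(fit)))
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$subject_id, res$condition), , drop = FALSE]
}

# diagonal Laplace (inverse-Hessian) variances, guarded against
# non-invertible Hessians
laplace_variances <- function(fit) {
  if (is.null(fit$hessian)) return(rep(NA_real_, 7L))
  v <- tryCatch(diag(solve(fit$hessian)), error = function(e) rep(NA_real_, 7L))
  ifelse(is.finite(v) & v > 0, v, NA_real_)
}

#' One-step empirical-Bayes (EM) prior update
#'
#' Re-estimates the Gaussian prior from the population of unbounded MAP
#' estimates and refits every session once under the new prior — one
#' iteration of Expectation Maximization, treating each session (two per
#' subject) as independent. The M-step sets the prior mean to the sample
#' mean of the unbounded MAPs and the prior variance to their sample
#' variance plus, when available, the mean per-fit Laplace
#' (inverse-Hessian diagonal) variance, floored at `var_floor`. The Laplace
#' inflation accounts for within-subject estimation uncertainty and can be
#' switched off.
#'
#' @param fits A cohort fit table from [fit_cohort()] (>= 2 sessions). If it
#'   was produced with `hessian = TRUE` the Laplace variances are used.
#' @param trials The trial log the fits came from.
#' @param use_laplace Include the mean Laplace variance in the prior
#'   variance (default `TRUE`; ignored when no Hessians were stored).
#' @param var_floor Lower bound on each prior variance.
#' @param seed Master seed for the refit restarts.
#' @inheritParams fit_cohort
#' @return List with `prior` (the EM [map_prior()]) and `fits` (the refitted
#'   cohort table).
#' @export
em_prior_step <- function(fits, trials, use_laplace = TRUE, var_floor = 1e-4,
                          n_restarts = 6L, restart_sd = 0.1, seed = 1L,
                          common_prob = 0.7, q_init = 0.5) {
  if (is.null(fits) || nrow(fits) < 2L)
    stop("EM prior update needs at least two fitted sessions", call. = FALSE)
  ucols <- paste0("u_", param_names())
  umat <- as.matrix(fits[, ucols])
  mu <- colMeans(umat)
  v <- apply(umat, 2L, stats::var)
  if (use_laplace && !is.null(fits$laplace_var)) {
    lap <- do.call(rbind, fits$laplace_var)
    lap_mean <- colMeans(lap, na.rm = TRUE)
    lap_mean[!is.finite(lap_mean)] <- 0
    v <- v + lap_mean
  }
  floored <- v < var_floor
  if (any(floored)) {
    warning("EM prior variance floored for: ",
            paste(param_names()[floored], collapse = ", "))
    v[floored] <- var_floor
  }
  prior <- map_prior(mean = unname(mu), sd = unname(sqrt(v)))
  refits <- fit_cohort(trials, prior = prior, n_restarts = n_restarts,
                       restart_sd = restart_sd,
                       seed = derive_seed(seed, "em_refit"),
                       common_prob = common_prob, q_init = q_init)
  list(prior = prior, fits = refits)
}
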