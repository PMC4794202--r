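---
title: "Methods: the hybrid habitual/goal-directed model and its estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hybrid habitual/goal-directed model and its estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the modelling, estimation and inference choices the
package makes, in the spirit of a methods section: what is computed, under
which assumptions, and where the genuinely open design decisions were
resolved.

## The task environment

The two-step task couples a first-stage choice to one of two second-stage
states through a *fixed* probabilistic transition: action $a \in \{0, 1\}$
reaches state $s = a$ with probability 0.7 (the *common* transition) and
the other state with probability 0.3 (*rare*). Each second-stage action
pays a 0/1 reward with a probability that drifts across trials as a
Gaussian random walk (step SD `walk_sd`) reflected at 0.25 and 0.75.
Default sessions have 201 trials with breaks after trials 67 and 134
(1-based); a 50-trial practice block uses an independent schedule and never
enters likelihoods. Breaks are schedule markers only: neither the
environment nor the agent changes behaviour at a break, and the
perseveration memory is deliberately *not* reset there (a configurable
choice — resetting would claim that a pause erases the motor-level
stickiness, which nothing in the data model supports).

Three conventions had to be fixed where the task description is silent:

* **Walk step SD.** Not dictated by the task structure; we default to
  0.025 per trial in probability units, the convention for this task
  class. It keeps arm identities stable over tens of trials while forcing
  continual relearning.
* **Initial walk values.** Drawn uniformly within the reflecting bounds,
  independently per arm.
* **Reflection.** Implemented as mirror reflection
  ($x \mapsto 2b - x$, applied repeatedly for multi-width overshoots), not
  clipping. Clipping would pile probability mass exactly on the bounds;
  reflection preserves the stationary uniform distribution on the
  interval. The mapping action $a$ → common state $a$ is an arbitrary but
  fixed labelling.

## The hybrid agent

Two systems value the first-stage actions. The *model-free* (habitual)
system learns by SARSA($\lambda$): after a trial with first-stage choice
$c_1$, second-stage state $s_2$, choice $c_2$ and reward $r$,

$$\delta_1 = Q_2(s_2, c_2) - Q_{MF}(c_1), \quad
  Q_{MF}(c_1) \mathrel{+}= \alpha_1\,\delta_1,$$
$$\delta_2 = r - Q_2(s_2, c_2), \quad
  Q_2(s_2, c_2) \mathrel{+}= \alpha_2\,\delta_2, \quad
  Q_{MF}(c_1) \mathrel{+}= \alpha_1 \lambda\,\delta_2,$$

with the stage-2 prediction error computed before the $Q_2$ write.
The *model-based* (goal-directed) system evaluates the same actions
prospectively through the true transition matrix, which the agent is
assumed to know: $Q_{MB}(a) = \sum_s P(s\,|\,a)\max_{a'}Q_2(s,a')$. Both
systems share the learned $Q_2$; they differ only in how first-stage
values are constructed.

Choice is softmax. At stage 1 the two systems' values are combined with
separate non-negative weights plus a perseveration bonus,
$P(a) \propto \exp(\beta_{HB} Q_{MF}(a) + \beta_{GD} Q_{MB}(a) + p\,\mathrm{rep}(a))$;
there is *no* separate stage-1 temperature — the weights double as
temperatures, which is what makes "habitual weight" and "goal-directed
weight" separately interpretable. At stage 2 a single inverse temperature
$\beta_2$ applies. Perseveration acts at stage 1 only.

The seven free parameters and their ranges:

| parameter | meaning | range | default interpretation |
|---|---|---|---|
| `alpha1` | stage-1 learning rate | (0, 1) | speed of habit formation |
| `alpha2` | stage-2 learning rate | (0, 1) | tracking of the reward walks |
| `lam` | eligibility ($\lambda$) | (0, 1) | how much $\delta_2$ reaches stage 1 |
| `beta2` | stage-2 inverse temperature | ≥ 0 | decisiveness at stage 2 |
| `beta_hb` | habitual weight | ≥ 0 | model-free contribution |
| `beta_gd` | goal-directed weight | ≥ 0 | model-based contribution |
| `p` | stage-1 perseveration | real | stickiness (+) or switching (−) |

Q-values initialise at 0.5, the midpoint of the 0/1 outcome range
(configurable); with rewards in $\{0,1\}$ every $Q_2$ update is a convex
combination, so $Q_2$ stays in $[0,1]$. The derived index
$\omega = \beta_{GD}/(\beta_{GD}+\beta_{HB})$ is exposed for reporting the
*relative* system balance but is never estimated as a free parameter.

### Numerical form of the likelihood

The session negative log-likelihood
$-\sum_t [\log P(c_{1,t}) + \log P(c_{2,t})]$ runs in compiled code. All
softmaxes are evaluated as log-softmaxes in max-shifted coordinates, and
the shift is never added back: with utilities of magnitude $10^{16}$
(reachable during unconstrained optimisation, where $\beta = e^u$), adding
$\log 2$ to the shifted maximum is below one ulp and would silently round
per-trial log-probabilities to zero, creating a spurious perfect-fit ridge.
Computing entirely in shifted coordinates makes the likelihood exact for
arbitrarily extreme parameters. Trials with any missing field are skipped
from both the likelihood and the learning update. A plain-R trial-by-trial
evaluator with identical semantics serves as the independent oracle in the
test suite (agreement to 1e-10 on all fixtures).

## MAP estimation

Bounded parameters are transformed to an unbounded scale — logit for
$\alpha_1, \alpha_2, \lambda$, log for $\beta_2, \beta_{HB}, \beta_{GD}$,
identity for $p$ — and the posterior under uncorrelated Normal(0, 100)
priors is maximised there. On this scale a prior mean of 0 corresponds to
learning rates of 0.5 and weights of 1; with SD 100 the prior is
essentially flat wherever the likelihood is informative and only prevents
outright divergence on degenerate sessions (e.g. a subject pressing one
key throughout). Additive normalisation constants of the prior are dropped
from the objective; printed objective values are therefore comparable only
within this package.

The optimiser is BFGS with numerical gradients, at most 500 iterations,
started from `n_restarts = 6` points drawn Normal(0, 0.1); non-finite
starts are redrawn; the restart with the lowest objective wins and the
whole procedure is deterministic given its seed. We use a tight relative
objective tolerance (1e-10) — the extra iterations are negligible against
the cost of a restart and remove one source of run-to-run jitter.

**What MAP under a broad prior cannot do.** When a subject's true
$\beta_{GD}$ (or $\beta_{HB}$) is near zero, the likelihood is nearly flat
in $\log\beta$ below some point, and the posterior mode sits far down the
ridge (around $u \approx -8$ under the SD-100 prior). Such sessions
produce heavy-tailed estimation errors on the unbounded scale no matter
how exact the optimiser is. This shows up in recovery experiments as a
handful of extreme outliers that depress Pearson true-versus-recovered
correlations for the weight parameters — most visibly in long sessions,
where everything else is estimated almost perfectly. The empirical-Bayes
prior (below) is the standard remedy; we keep the broad prior as the
primary method and report it as-is.

### One-step EM (empirical Bayes)

As a confirmatory variant, the prior is re-estimated from the population
of unbounded MAP estimates and every session is refit once. The M-step is
moment matching: prior mean = sample mean of the MAPs; prior variance =
sample variance *plus* the mean per-fit Laplace variance (diagonal of the
inverse Hessian at the optimum), floored at 1e-4. The Laplace inflation
acknowledges that the observed spread of MAPs understates the population
spread when individual fits are noisy; it is an approximation (a full EM
would iterate, and the exact E-step variance is not diagonal), can be
switched off (`use_laplace = FALSE`), and both variants are exposed
because the best choice is genuinely unsettled. Sessions are treated as
independent in the E-step, including the two sessions of one subject.

## The synthetic cohort

`cohort_config()` describes the simulated study the group analysis is
designed for: 33 subjects, two within-subject conditions (music, gaming)
with counterbalanced order, a working-memory covariate emulating a
backwards Digit Span score (mean 7.39, SD 1.78 — an SEM of 0.31 at
n = 33), and subject-level true parameters drawn on the unbounded scale.
Population means (0.4, 0.7, 1.3, 1.1, 0.6, 0.75, 0.75 in canonical order)
and between-subject SDs (1.0, 0.8, 1.0, 0.5, 0.8, 0.9, 0.5) were chosen
once so that natural-scale medians fall inside the interquartile ranges
reported for this task (e.g. median $\beta_{GD} \approx 2.1$ against
quartiles 0.84–5.19, median $\beta_2 \approx 3.0$ against 1.48–4.18).

The experimental effect enters only through unbounded $\beta_{GD}$ in the
gaming condition, shifted by
`effect_beta_gd_condition + effect_beta_gd_interaction * z_wm`. The
defaults (−0.17, +0.24) encode the qualitative pattern of interest: a
simple effect of −0.41 one SD below the working-memory mean and roughly
zero one SD above — gaming costs goal-directed control only where working
memory is scarce. The covariate is generated continuous (an integer
rounding flag exists); all other parameters are shared across a subject's
two conditions, which is the generator's way of saying "the break activity
affects nothing else".

What the generator deliberately does *not* emulate: real response times or
omissions, practice and fatigue drifts within a session, integer-valued
and possibly skewed Digit Span distributions, correlations between model
parameters and covariates, or model misspecification (real subjects are
not exact hybrid agents). Passing recovery tests therefore show that the
chain is *internally* consistent — the method recovers what this model
family injects — not that real data satisfy the model.

## Group-level inference

Fitted unbounded parameters (two rows per subject) are analysed with
linear mixed-effects models with random subject intercepts, via `lme4`:

* `fit_condition_model()`: `parameter ~ condition + (1 | subject)`, with
  condition coded music = 0, gaming = 1, so negative coefficients mean
  gaming-related reductions. In the balanced two-observation case the
  coefficient equals the paired mean difference — an identity the tests
  verify against an independently coded paired t-test.
* `fit_moderation_model()`: adds `condition × z(moderator)` and optional
  z-scored covariates. Moderators are z-scored across subjects inside the
  function, making coefficients standardised and scale-invariant.
* `simple_effects()`: re-centers the z-scored moderator at ±1 SD and
  refits, so the condition coefficient becomes the simple effect at that
  working-memory level; `simple(+1) − simple(−1) = 2 × interaction` holds
  identically and is asserted to 1e-6.
* `bonferroni()` applies `min(1, m·p)` with the family size `m` given
  explicitly (the exploratory family over the six non-focal parameters
  uses m = 6); `paired_t()` covers rating-scale comparisons.

Directed hypotheses use one-tailed p-values, declared per test
(gaming < music for $\beta_{GD}$; a positive working-memory slope after
gaming).

**Degrees of freedom.** The default is containment-style: a fixed effect
that varies within subjects is tested in the within-subject stratum
(df = N − subjects − number of within-subject terms), one that is constant
within subjects in the between-subject stratum. For the condition model
with 33 subjects this gives df = 32, for the moderation model df = 31 —
the values a paired analysis would produce. A Satterthwaite option
(`df_method = "satterthwaite"`, via `lmerTest`) is provided; no claim is
made that either reproduces any particular published df exactly, since df
conventions for such models are not unique.

The stay-probability table — P(repeat first-stage choice) by previous
reward × previous transition type — is the model-agnostic diagnostic: a
reward main effect is the habitual signature, a reward-by-transition
interaction the goal-directed one. Empty cells are reported as `NaN`,
never imputed.

## Pipelines, seeds and problem sizes

`run_full_pipeline()` chains generator → simulation → per-session MAP →
group tests (plus the EM variant and a broad-versus-EM concordance table
on request) and optionally writes all tables as CSV.
`run_recovery()` repeats the chain over replicate cohorts and reports
per-parameter recovery (Pearson correlation, bias, RMSE on the unbounded
scale) and per-hypothesis rejection rates. Every stage and unit draws its
seed deterministically from the master seed through an integer hash
(`derive_seed()`); no global random state crosses stage boundaries, so
results are reproducible and insensitive to evaluation order.

Problem sizes used by the package's own validation suite, chosen as the
smallest designs whose Monte-Carlo error is clearly below the effects
being checked: recovery at study scale uses 100 subjects × 2 sessions of
201 trials (and 2,000 trials for the long-session consistency check);
null calibration of the one-tailed interaction test uses 200 replicate
cohorts of 14 subjects × 80 trials with 2 restarts, judged against a 99%
binomial band around the nominal 5%; the injected-deficit pattern check
averages 12 study-sized cohorts (33 subjects × 201 trials, 6 restarts).

## Known limitations

* MAP point estimates on the log scale are ill-determined for
  near-zero weights (see above); group tests on $u_{\beta_{GD}}$ inherit
  that heavy-tailed noise, which mildly inflates small-sample type-I rates
  above nominal (still within the Monte-Carlo band in our calibration).
* The model family is fixed: no learned transition matrices, no
  alternative arbitration schemes, no model comparison.
* The EM step is a single moment-matching iteration with a diagonal
  Gaussian prior, not a full hierarchical fit; no MCMC.
* Only random-intercept group models are offered — no random slopes, which
  with two observations per subject would not be identifiable anyway.
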