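---
title: "The RLWM-LBA model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The RLWM-LBA model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model implemented by **rlwmlba**, the
assumptions behind it, the tunable quantities and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The task

The package generates and consumes an instrumental-learning task in which
a participant learns stimulus-action associations under deterministic,
binary feedback with three response keys. A session is 468 trials in 10
blocks with block-unique stimuli; blocks have set sizes 2-5 in the fixed
composition two blocks of 2, three of 3, two of 4 and three of 5, in a
seed-shuffled order. Each stimulus appears 12-14 times (total `13 *
set_size` trials per block), interleaved so the delay between successive
presentations of the same stimulus stays within `[1, 2 * set_size]` and its
pooled histogram is approximately uniform. A training block with 2 stimuli
ends at the first trial at or beyond 15 where trailing-10 accuracy exceeds
80%, and at 50 trials otherwise.

The interleaving algorithm is a randomized greedy scheduler (a stimulus
whose delay deadline arrives is placed immediately, otherwise stimuli are
sampled proportionally to their remaining presentations) inside a
rejection loop that accepts a sequence when the chi-square uniformity
statistic of the delay histogram falls below the 0.01-level critical
value. Exact uniformity is combinatorially infeasible for small blocks
(the mean of a uniform delay exceeds the mean achievable gap), so an
approximate criterion is the only coherent reading of the design; the
tolerance is configurable (`chisq_level`).

## The generative model

Learning is a mixture of two value systems over (stimulus, action) pairs,
both initialized at 1/3 at block start:

* **RL module** — delta rule `Q <- Q + a_eff * (r - Q)` with
  `a_eff = alpha` for positive prediction errors and
  `(1 - bias) * alpha` for negative ones.
* **WM module** — same rule with learning rate 1 (perfect updating toward
  the outcome, attenuated by the same `bias` after negative errors), plus
  a per-trial decay of *every* entry toward 1/3 by a fraction `phi`.

Each module maps values to a policy by a softmax with inverse temperature
`beta = 50` (fixed), and the policies mix as
`P = W * P_WM + (1 - W) * P_RL` with `W = rho * min(1, C / set_size)`:
working memory contributes less when the set size exceeds capacity `C`.

Choices and reaction times come from a three-accumulator linear ballistic
accumulator. The drift rate of action `a` is the mixed policy probability
scaled by `eta` and divided by the Shannon entropy (bits) of the
*stimulus-averaged* mixed policy — uncertainty about which action will be
required slows all accumulators. Start points are Uniform(0, `A`), drifts
are Normal(V, `s = 1`) across trials, the threshold is `b = A + k`, and
`rt = tau + decision time` with `tau = 0.15` s fixed.

### Fixed constants and why

`beta = 50` makes the softmax nearly greedy, so discrimination between
actions is carried by the value difference rather than a temperature;
`tau = 0.15` s is fixed because non-decision time trades off against `k`
at these RT scales and fixing it improves recovery; `s = 1` is the
standard LBA scaling constraint — some scale must be fixed for
identifiability, and `eta` absorbs it.

### Numerical choices

* **Entropy floor.** With `beta = 50` the average policy can become
  almost deterministic, driving the entropy divisor toward 0 and drift
  rates toward infinity. The divisor is floored at `h_floor = 0.01` bits
  (configurable). Below the floor the drifts simply scale with `eta`, so
  the floor acts as a cap on the entropy speed-up, not a change of model
  class.
* **Likelihood floor.** Per-trial log densities are floored at
  `log(1e-10)`, which keeps outlier RTs from dominating the fit. RTs at
  or below `tau` get the floor value and are flagged invalid rather than
  crashing.
* **Small-`A` limit.** The closed-form LBA density has a bracket of order
  `A` multiplied by `1/A`; below `A/(t*s) = 1e-6` it cancels
  catastrophically (we observed spurious per-trial log densities of +68
  at `A ~ 1e-45`, which creates a fake optimum at `A -> 0`). The
  implementation switches to the exact `A -> 0` limit (start point 0,
  finishing time `b/v`) in that regime, in both the R and C++ routes.
* **Within-trial order.** Policies and drifts are computed from the
  pre-trial state; the response is then sampled (or scored); the RL and
  WM updates apply to the chosen (stimulus, action) entry; decay then
  applies to all WM entries, including the just-updated one ("forgetting
  after updating"). The alternative order (decay before update) is not
  distinguishable from the task description alone; the chosen order
  follows the wording that forgetting happens after updating.
* **Non-responses.** The simulator enforces the 7-s response deadline:
  sampled RTs beyond it become non-responses, which are excluded from
  the likelihood but still advance WM decay (time passes). The default
  parameter region produces essentially none; they matter only for
  extreme planted effects (see below).
* **All-negative drifts.** The sampler redraws the drift vector when all
  three are negative (capped at 1000 attempts, then the max-V
  accumulator is forced); the likelihood leaves the defective density
  unnormalized. At fitted drift scales the non-termination mass is
  around 1% or less. Consequently, sampler win fractions are
  *conditional on termination* while integrated choice probabilities are
  defective; comparisons divide the latter by the total mass.

## Hierarchical estimation

Subject latents are `lambda = mu + sd * z` (non-centered), with normal
priors on the group means (the package's `prior_spec()`), lognormal
priors on the group SDs — `lognormal(log 0.5, 0.35)`, capacity SD
`lognormal(log 0.5, 0.55)` — and standard-normal `z`. Unit-interval
parameters squash through the cubic-logistic normal-CDF approximation
`inv_logit(0.07056 x^3 + 1.5976 x)`; positive parameters exponentiate;
capacity maps through `2 + 3 * inv_logit`.

The estimator is MAP: BFGS on the joint latent vector, group SDs
optimized on the log scale (the lognormal prior is evaluated there,
which includes the Jacobian). The likelihood of a subject depends on the
group parameters only through its own `lambda`, so the gradient needs
just 8 central-difference directional derivatives per subject,
distributed onto means, log-SDs and `z` by the chain rule — this keeps
quasi-Newton iterations cheap at hundreds of free parameters. Defaults:
4 seed-jittered restarts, 2000 iterations, relative tolerance 1e-8.
Non-convergence is reported, not raised. Published uses of this model family name no
optimizer; any mode-finder is admissible, and multi-start BFGS is the
simplest honest one.

Parameter recovery is the package's validity check: subjects drawn from
the prior (means at the prior modes, SDs at the lognormal median 0.5),
one session each, refit, Pearson correlations per parameter. At 20-50
subjects the start-point limit `A`, threshold `k` and drift scale `eta`
recover well (r above 0.9 in our runs), `phi` and `rho` moderately, and
`alpha` and `bias` poorly — `alpha` because the prior-modal learning rate
is small and working memory dominates behavior, `bias` because it only
acts on error trials, which are rare once learning converges. The
qualitative ordering (good recovery for `A` and `k`, `eta` better than
`bias`) matches published experience with this model family; exact correlations depend on cohort
size and are checked only against those qualitative bounds.

## The synthetic cohort: what it does and does not emulate

`generate_cohort()` draws covariates matching the reported sample — age
Normal(17.76, 2.42) truncated to [12.35, 24.31], 72% female, right-skewed
symptom scales (12 three-level depressive items, 7 four-level anxiety
items) — then latent parameters `mu + planted effects + Normal(0, 0.5)`
and simulates full sessions. Planted effects are linear on the *latent*
scale, where linearity is well-defined and matches the hierarchical
model's geometry. Symptom item distributions use geometric-decaying
response probabilities with a Beta(1.2, 3) per-subject severity: the
shape of community samples, not a fit to any reported frequencies.

The default planted age effect on the start point (standardized slope
-1.13, a strong age effect of the size reported for this task in adolescent cohorts) together with
residual SD 0.5 gives latent `A` an SD of about 1.24, so a few percent of
subjects receive extreme `A` values, respond slowly, and hit the 7-s
deadline often. That is a faithful consequence of the stated effect size,
not a bug; those subjects' trials thin out and their parameters recover
poorly, which attenuates but does not destroy the cohort-level effect.

A green test on this generator establishes that the pipeline recovers
what it planted under the model's own assumptions. It does not establish
robustness to model misspecification, real response-lapse processes,
item-level missingness, or pubertal-development ceiling effects — none of
which are emulated.

## Association and prediction analyses

All continuous predictors are standardized (population-SD convention;
with cohort-scale n the distinction from the sample SD is irrelevant,
but it is fixed and documented). Coefficient priors are N(0, 1)
throughout.

* **Linear**: Gibbs over coefficients (conjugate given the residual SD)
  with random-walk Metropolis on the log residual SD (half-normal
  prior). With the residual SD fixed, the posterior is the ridge-form
  conjugate closed form, which the tests use as an oracle.
* **Logistic (trial level)**: Bernoulli-logit with standardized task
  factors and subject random intercepts, fitted by penalized Laplace
  approximation (joint MAP with analytic gradients, Gaussian draws from
  the inverse Hessian). The intercept-SD coordinate is bounded away from
  0 because the joint MAP of (intercepts, SD) otherwise collapses into
  the usual funnel degeneracy.
* **Ordinal (item level)**: cumulative logit with ordered cutpoints
  (unconstrained first-cutpoint + log-spacing parameterization), subject
  intercepts, Metropolis-within-Gibbs. With two response levels it
  reduces to the logistic model, which is tested.
* **Savage-Dickey** Bayes factors: Gaussian KDE (Silverman bandwidth) of
  the posterior draws at 0, over the prior density at 0. Evidence bands
  follow the conventional anecdotal/moderate/strong/very strong/extreme
  cuts at 3, 10, 30, 100 and their reciprocals; on the alternative side
  the bands are closed toward 1 (BF01 = 0.3 reads "moderate"), matching
  the convention that band edges belong to the stronger-evidence side on
  the 1/BF01 scale.
* **Prediction**: ridge regression with the closed-form solve, penalty
  chosen on a 13-point log grid over `10^-3..10^3` by inner 10-fold CV,
  80/20 outer split stratified on 5 quantile bins of the outcome, 100
  repeats. Standardization statistics come from training folds only.
  Test r-squared is `1 - SSE/SST` and may be negative.

MCMC defaults are 4 chains of 5000 post-warmup draws with a split-chain
convergence statistic required below 1.02 — the package's own sampler
contract standing in for the original 4 x 10,000-iteration chains.

## Scaling of the acceptance checks

The acceptance runs are scaled to a single CPU: recovery uses 20
subjects with 2 restarts; the planted-effect cohort uses 50 subjects
with 1 restart; the null-calibration check (planted slope 0) uses 20
replicates formed as 4 independently fitted null cohorts of 12 subjects
crossed with 5 independent age draws each — valid because under the null
the age covariate is independent of everything by construction, so fresh
age draws against a fitted cohort are genuine null replicates of the
regression stage. Reported recovery correlations are therefore slightly
pessimistic relative to a 4-restart, larger-cohort run.

## Known limitations

* MAP gives point estimates; subject-level uncertainty is not
  propagated into the association stage (fitted-then-regressed pipelines generally share
  this property).
* The likelihood floor biases against extreme outlier RTs by design;
  datasets dominated by contaminant RTs need a dedicated lapse process.
* Only the selected entropy-scaled model variant is implemented; the
  supplementary model comparison among variants is out of scope.
* The delay-uniformity tolerance of the reference task software is
  unknown; ours is explicit and configurable.
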