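# rlwmlba

Joint modeling of choice and reaction time in reinforcement
learning / working memory (RLWM) tasks.

## The problem

Instrumental learning in humans mixes two systems: a slow, incremental
reinforcement-learning (RL) process and a fast but capacity-limited,
decaying working-memory (WM) process. The RLWM task separates them by
varying the number of stimulus-action associations per block (set sizes
2-5, three response keys, deterministic binary feedback), and the RLWM
computational model attributes behavior to the two systems through a
set-size-dependent mixture. Extending the model with a linear ballistic
accumulator (LBA) adds reaction times to the likelihood, which improves
parameter identifiability and captures how decision speed tracks
uncertainty during learning.

This package is a complete, tested pipeline for that analysis on
synthetic cohorts: task generation, the RLWM-LBA generative model and
likelihood, hierarchical Bayesian MAP fitting, parameter recovery,
posterior predictive checks, Bayesian association analyses with
Savage-Dickey Bayes factors, and a repeated cross-validated ridge
prediction pipeline. It is aimed at computational-psychiatry and
cognitive-modeling researchers who want to study the method itself —
power, recovery, null calibration — without access to a real cohort.

## The model

Per (stimulus, action) value tables, both initialized at 1/3:

* RL: `Q <- Q + a_eff (r - Q)`, `a_eff = alpha`, reduced to
  `(1 - bias) alpha` after negative prediction errors;
* WM: the same rule with learning rate 1, plus per-trial decay
  `Q <- Q + phi (1/3 - Q)` of every entry.

Policies are softmax with fixed inverse temperature `beta = 50`, mixed
as `W P_WM + (1 - W) P_RL` with `W = rho min(1, C / set_size)`. Drift
rates for the three LBA accumulators are
`V_a = eta P(a|s) / H_prior`, where `H_prior` is the Shannon entropy of
the stimulus-averaged policy; starts are Uniform(0, A), drifts
Normal(V, 1), threshold `b = A + k`, non-decision time `tau = 0.15` s.
Eight free parameters per subject (`alpha, bias, phi, rho, C, eta, A,
k`) are estimated hierarchically by MAP with non-centered subject
deviations and weakly informative group priors.

## Worked example

Simulate one subject at the group-prior modes and score it:

```r
library(rlwmlba)
sess   <- generate_session(seed = 1)          # 468 trials, 10 blocks
pars   <- transform_params(prior_spec()$mean_mu)
trials <- simulate_agent(sess, pars, seed = 1)

mean(trials$reward, na.rm = TRUE)       # 0.887  overall accuracy
median(trials$rt, na.rm = TRUE)         # 0.578  seconds
session_loglik(trials, pars)            # 50.1   joint choice+RT loglik
```

Accuracy 0.887 and sub-second RTs are typical for this parameter
region: working memory (`rho = 0.84`) solves small blocks almost
immediately, the RL module mops up slowly (`alpha = 0.023`), and the
entropy-scaled drifts speed responses up as the block's action mapping
becomes predictable.

Trial-level behavioral signatures on a small synthetic cohort:

```r
cohort <- generate_cohort(4, seed = 8)
m <- trial_logistic_model(cohort$trials, seed = 1)
m$odds_ratios
#             term odds_ratio or_low or_high      bf01
#          delay         0.98  0.838   1.140  1.21e+01
#       set_size         0.75  0.629   0.887  5.08e-02
# reward_history         2.82  2.298   3.452 1.48e-278
#          block         1.15  0.986   1.339  3.48e+00
```

Reward history raises the odds of a correct response, set size lowers
them (capacity-limited WM), and delay trends negative (WM decay) — the
signed pattern the model family predicts. `bf01` is the Savage-Dickey
Bayes factor of null over alternative; values below 1 favor an effect
(`interpret_bf()` maps them to evidence bands).

Fitting and recovery:

```r
fit <- fit_map(cohort$trials, restarts = 4, seed = 1)   # hierarchical MAP
rec <- recover_parameters(n_subjects = 20, seed = 1)    # simulate + refit
rec$correlations   # generating-vs-recovered Pearson r per parameter
```

## Command line

```sh
Rscript -e 'rlwmlba::rlwm_main()' simulate-cohort --n 50 --seed 1 --out out/
Rscript -e 'rlwmlba::rlwm_main()' fit --trials out/trials.csv --seed 1 --out fit/
Rscript -e 'rlwmlba::rlwm_main()' recover --n-subjects 20 --seed 1 --out rec/
```

Subcommands: `simulate-task`, `simulate-cohort`, `fit`, `recover`,
`ppc`, `associate`, `predict`; every run writes a manifest JSON with
config echo, seeds and file checksums.

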