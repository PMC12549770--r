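# Shared fixtures and independent oracles for the test suite.

# Independent R-side replay of the session likelihood, composed from the
# exported primitive operations. This is the oracle against which the C++
# replay (cpp_session_loglik) is cross-checked; it must stay independent
# of src/rlwm.cpp.
replay_loglik <- function(trials, pars) {
  cst <- rlwm_constants()
  trials <- trials[order(trials$block, trials$trial_in_block), ]
  total <- 0
  for (b in unique(trials$block)) {
    tb <- trials[trials$block == b, ]
    ids <- unique(tb$stimulus_id)
    ns <- length(ids)
    qrl <- matrix(1 / 3, ns, 3)
    qwm <- matrix(1 / 3, ns, 3)
    W <- mixing_weight(pars[["rho"]], pars[["C"]], ns)
    for (i in seq_len(nrow(tb))) {
      st <- match(tb$stimulus_id[i], ids)
      pol <- t(sapply(seq_len(ns), function(j)
        mixed_policy(softmax_policy(qwm[j, ]), softmax_policy(qrl[j, ]), W)))
      H <- prior_entropy(average_policy(pol))
      V <- drift_rates(pol[st, ], H, pars[["eta"]])
      a <- tb$action[i]
      if (!is.na(a)) {
        total <- total + as.numeric(
          lba_logpdf(a, tb$rt[i], V, pars[["A"]], pars[["k"]]))
        r <- tb$reward[i]
        qrl[st, a + 1] <- rl_update(qrl[st, a + 1], r,
                                    pars[["alpha"]], pars[["bias"]])
        qwm[st, a + 1] <- wm_update(qwm[st, a + 1], r, pars[["bias"]])
      }
      qwm <- wm_decay(qwm, pars[["phi"]])
    }
  }
  total
}

# random-but-reasonable natural-scale parameter draw (prior modes + noise)
draw_params <- function(seed, sd = 0.5) {
  priors <- prior_spec()
  lat <- with_seed_test(seed, priors$mean_mu + sd * rnorm(8))
  transform_params(setNames(lat, rlwm_param_names()))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(expr)
}

# small simulated cohort, built once per test run
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(6, seed = 101)
    cache
  }
})
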