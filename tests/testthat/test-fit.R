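# Small-scale fitting checks; the full-size recovery study runs in the
# acceptance suite.

make_mini_cohort <- function(n, seed) {
  priors <- prior_spec()
  z <- with_seed_test(seed, matrix(rnorm(n * 8), n, 8))
  lat <- sweep(z * 0.5, 2, priors$mean_mu, `+`)
  colnames(lat) <- rlwm_param_names()
  nat <- transform_params(lat)
  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    sess <- generate_session(seed = seed * 100 + i)
    simulate_agent(sess, nat[i, ], seed = seed * 200 + i,
                   subject_id = sprintf("m%02d", i))
  }))
  list(trials = trials, natural = nat)
}

test_that("fit_map returns a coherent optimum on a tiny cohort", {
  mc <- make_mini_cohort(2, seed = 21)
  fit <- fit_map(mc$trials, restarts = 1, seed = 1, maxit = 250)
  expect_s3_class(fit, "rlwm_fit")
  expect_equal(fit$n_subjects, 2L)
  expect_true(all(fit$sd > 0))
  # the returned value equals log_posterior at the returned point
  group <- list(mu = unname(fit$mu), log_sd = log(unname(fit$sd)), z = fit$z)
  expect_equal(log_posterior(mc$trials, group), fit$value, tolerance = 1e-6)
  # natural-scale output respects range constraints
  for (i in seq_len(nrow(fit$params)))
    expect_silent(rlwmlba:::validate_params(
      unlist(fit$params[i, rlwm_param_names()])))
  # fitted A and k land in the right region even at this tiny scale
  expect_equal(log(fit$params$A), log(mc$natural[, "A"]), tolerance = 0.75)
})

test_that("more restarts never decrease the best objective", {
  mc <- make_mini_cohort(1, seed = 22)
  f1 <- fit_map(mc$trials, restarts = 1, seed = 3, maxit = 120)
  f2 <- fit_map(mc$trials, restarts = 2, seed = 3, maxit = 120)
  expect_gte(f2$value + 1e-9, f1$value)
  # restart trace is recorded
  expect_equal(nrow(f2$trace), 2L)
})

test_that("fit_map validates inputs", {
  expect_error(fit_map(data.frame()), "no subjects|undefined columns")
  cohort <- fixture_cohort()
  tr <- cohort$trials[cohort$trials$subject_id == "s001", ]
  tr$action <- NA_integer_
  tr$rt <- NA_real_
  expect_error(fit_map(tr), "zero valid trials")
})

test_that("posterior predictive curves reproduce the learning signatures", {
  cohort <- fixture_cohort()
  params <- data.frame(subject_id = rownames(cohort$params_true),
                       cohort$params_true, stringsAsFactors = FALSE)
  curves <- posterior_predictive(params, cohort$trials, n_reps = 4, seed = 2)
  pred <- curves[curves$source == "predicted", ]
  expect_true(nrow(pred) > 0)
  # accuracy rises over iterations (first vs last third, per set size)
  for (ss in c(2, 5)) {
    p <- pred[pred$set_size == ss, ]
    p <- p[p$iteration <= 12, ]  # all iterations present
    third <- ceiling(nrow(p) / 3)
    expect_gt(mean(p$accuracy[(nrow(p) - third + 1):nrow(p)]),
              mean(p$accuracy[1:third]))
    # correct-trial RT shrinks from the first to the final iteration
    expect_gt(p$rt_correct[1], p$rt_correct[nrow(p)])
  }
  # accuracy falls with set size (averaged over early iterations)
  early <- pred[pred$iteration <= 5, ]
  m <- tapply(early$accuracy, early$set_size, mean)
  expect_gt(m["2"], m["5"])
  # n_reps = 0 returns the observed curves only
  obs_only <- posterior_predictive(params, cohort$trials, n_reps = 0)
  expect_true(all(obs_only$source == "observed"))
})
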