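test_that("C++ likelihood replay matches the R primitive-op oracle", {
  sess <- generate_session(seed = 301)
  for (i in 1:4) {
    pars <- draw_params(400 + i)
    tr <- simulate_agent(sess, pars, seed = 500 + i)
    expect_equal(session_loglik(tr, pars), replay_loglik(tr, pars),
                 tolerance = 1e-10)
    # and at parameters different from the generating ones
    other <- draw_params(600 + i)
    expect_equal(session_loglik(tr, other), replay_loglik(tr, other),
                 tolerance = 1e-10)
  }
})

test_that("session_loglik is stateless, pure, and handles edge cases", {
  cohort <- fixture_cohort()
  tr <- cohort$trials[cohort$trials$subject_id == "s002", ]
  pars <- draw_params(7)
  expect_identical(session_loglik(tr, pars), session_loglik(tr, pars))
  expect_equal(session_loglik(tr[0, ], pars), 0)
  bad <- tr
  bad$rt[3] <- NA  # choice present, rt missing
  expect_error(session_loglik(bad, pars), "choice but no RT")
})

test_that("likelihood peaks near generating parameters on average", {
  sess <- generate_session(seed = 310)
  set.seed(42)
  diffs <- vapply(1:8, function(i) {
    pars <- draw_params(800 + i)
    tr <- simulate_agent(sess, pars, seed = 900 + i)
    lat <- untransform_params(pars)
    pert <- transform_params(lat + rnorm(8, 0, 0.5))
    session_loglik(tr, pars) - session_loglik(tr, pert)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("frozen values at chance: alpha -> 0, rho = 0 gives ~1/3 accuracy", {
  pars <- subject_params(alpha = 1e-9, bias = 0.5, phi = 0.2, rho = 1e-9,
                         C = 3.5, eta = 5, A = 1.2, k = 1)
  sess <- generate_session(seed = 320)
  acc <- vapply(1:6, function(i) {
    mean(simulate_agent(sess, pars, seed = i)$reward, na.rm = TRUE)
  }, numeric(1))
  # binomial 95% band around 1/3 at 6 x 468 trials
  expect_lt(abs(mean(acc) - 1 / 3), 2 * sqrt(1 / 9 * 2 / (6 * 468)) + 0.02)
})

test_that("perfect WM retains the observed correct action", {
  pars <- subject_params(alpha = 1e-6, bias = 1e-9, phi = 1e-9, rho = 1 - 1e-9,
                         C = 5 - 1e-9, eta = 8, A = 0.3, k = 1)
  sess <- generate_session(seed = 330)
  tr <- simulate_agent(sess, pars, seed = 3)
  later <- tr[!is.na(tr$action) & tr$iteration >= 2, ]
  expect_gt(mean(later$reward), 0.95)
})

test_that("accuracy decreases with set size at capacity-limited parameters", {
  pars <- subject_params(alpha = 0.02, bias = 0.8, phi = 0.15, rho = 0.85,
                         C = 2.5, eta = 5, A = 1.2, k = 1)
  sess <- generate_session(seed = 340)
  accs <- sapply(1:8, function(i) {
    tr <- simulate_agent(sess, pars, seed = 40 + i)
    early <- tr[!is.na(tr$action) & tr$iteration <= 5, ]
    tapply(early$reward, early$set_size, mean)
  })
  m <- rowMeans(accs)
  expect_gt(m["2"], m["5"])
})

test_that("simulation is deterministic under seed and respects feedback", {
  sess <- generate_session(seed = 350)
  pars <- draw_params(5)
  a <- simulate_agent(sess, pars, seed = 10)
  b <- simulate_agent(sess, pars, seed = 10)
  expect_identical(a, b)
  ok <- !is.na(a$action)
  expect_equal(a$reward[ok], as.integer(a$action[ok] == a$correct_action[ok]))
  expect_true(all(a$rt[ok] > rlwm_constants()$tau &
                  a$rt[ok] <= rlwm_constants()$rt_max))
})
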