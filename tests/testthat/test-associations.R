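test_that("standardize: closed form, invariance, validation", {
  expect_equal(standardize(c(1, 2, 3)),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  x <- rnorm(50)
  expect_equal(standardize(5 * x - 2), standardize(x), tolerance = 1e-10)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "constant")
})

test_that("linear regression matches the conjugate closed form (fixed sigma)", {
  set.seed(9)
  n <- 150
  x <- rnorm(n)
  y <- 1.5 * x + rnorm(n, 0, 0.5)
  X <- cbind(x = standardize(x))
  r <- bayes_linear_regression(y, X, sigma_fixed = 0.5, chains = 2,
                               iter = 4000, warmup = 500, seed = 3)
  Xd <- cbind(1, X)
  prec <- crossprod(Xd) / 0.25 + diag(2)
  mean_cf <- solve(prec, crossprod(Xd, y) / 0.25)
  sd_cf <- sqrt(diag(solve(prec)))
  expect_equal(r$coefficients$x$mean, unname(mean_cf[2]), tolerance = 1e-2)
  expect_equal(sd(r$draws[, "x"]), unname(sd_cf[2]), tolerance = 0.03)
})

test_that("linear regression recovers a planted slope with free sigma", {
  set.seed(31)
  n <- 200
  x <- standardize(rnorm(n))
  y <- 2 * x + rnorm(n, 0, 0.1)
  r <- bayes_linear_regression(y, cbind(x = x), chains = 2, iter = 2500,
                               warmup = 500, seed = 5)
  co <- r$coefficients$x
  expect_equal(co$mean, 2, tolerance = 0.1)
  expect_true(co$ci[1] <= co$mean && co$mean <= co$ci[2])
  expect_lt(r$diagnostics$max_rhat, 1.02)
})

test_that("credible intervals achieve approximately nominal coverage", {
  # scaled-down coverage study: 300 pure-noise replicates at fast
  # sampler settings (a larger replicate count differs only in n)
  set.seed(12)
  hits <- vapply(1:300, function(i) {
    x <- standardize(rnorm(40))
    y <- rnorm(40)
    r <- bayes_linear_regression(y, cbind(x = x), chains = 1, iter = 500,
                                 warmup = 150, seed = i)
    ci <- r$coefficients$x$ci
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_equal(mean(hits), 0.95, tolerance = 0.035)
})

test_that("Savage-Dickey BF01: prior, conjugate and concentrated cases", {
  set.seed(2)
  expect_equal(savage_dickey_bf01(rnorm(1e5)), 1, tolerance = 0.1)
  m0 <- 0.3; v0 <- 0.04
  bf <- savage_dickey_bf01(rnorm(1e5, m0, sqrt(v0)))
  analytic <- dnorm(0, m0, sqrt(v0)) / dnorm(0, 0, 1)
  expect_equal(bf, analytic, tolerance = 0.05 * analytic)
  expect_lt(suppressWarnings(savage_dickey_bf01(rnorm(5000, 3, 0.1))), 0.01)
})

test_that("Savage-Dickey estimator error shrinks with draw count", {
  m0 <- 0.5; v0 <- 0.09
  analytic <- dnorm(0, m0, sqrt(v0)) / dnorm(0, 0, 1)
  err <- vapply(c(1e3, 1e5), function(n) {
    set.seed(4)
    mean(vapply(1:20, function(i)
      abs(savage_dickey_bf01(rnorm(n, m0, sqrt(v0))) - analytic),
      numeric(1)))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("evidence bands partition the BF axis with the stated boundaries", {
  expect_equal(interpret_bf(0.2), "moderate evidence for alternative")
  expect_equal(interpret_bf(15), "strong evidence for null")
  expect_equal(interpret_bf(0.005), "extreme evidence for alternative")
  expect_equal(interpret_bf(0.3), "moderate evidence for alternative")
  expect_equal(interpret_bf(1), "anecdotal evidence for null")
  expect_equal(interpret_bf(0.5), "anecdotal evidence for alternative")
  expect_equal(interpret_bf(200), "extreme evidence for null")
})

test_that("trial-level logistic model recovers a planted effect", {
  # Bernoulli data generated directly from the logistic model
  set.seed(21)
  ns <- 40; nt <- 100
  subj <- rep(sprintf("p%02d", 1:ns), each = nt)
  u <- rep(rnorm(ns, 0, 0.4), each = nt)
  rh <- rnorm(ns * nt)
  eta <- 0.3 + 0.5 * rh + u
  trials <- data.frame(
    subject_id = subj, block = 0L,
    trial_in_block = rep(0:(nt - 1), ns), set_size = 3L,
    stimulus_id = "x", correct_action = 0L,
    action = 0L, rt = 0.5,
    reward = rbinom(ns * nt, 1, plogis(eta)),
    iteration = 1L, delay = 2L, reward_history = rh,
    stringsAsFactors = FALSE
  )
  trials$noise_cov <- rnorm(ns * nt)
  m <- trial_logistic_model(trials,
                            predictors = c("reward_history", "noise_cov"),
                            seed = 2)
  or <- m$odds_ratios
  expect_gt(or$odds_ratio[or$term == "reward_history"], 1.4)
  expect_lt(or$odds_ratio[or$term == "reward_history"], 1.95)
  # null covariate: OR near 1, evidence leans to the null
  expect_equal(or$odds_ratio[or$term == "noise_cov"], 1, tolerance = 0.1)
  expect_gt(or$bf01[or$term == "noise_cov"], 1)
})

test_that("task factors show the signed OR pattern on a simulated cohort", {
  cohort <- fixture_cohort()
  m <- trial_logistic_model(cohort$trials, seed = 3)
  or <- m$odds_ratios
  expect_gt(or$odds_ratio[or$term == "reward_history"], 1)
  expect_lt(or$odds_ratio[or$term == "set_size"], 1)
  expect_lt(or$odds_ratio[or$term == "delay"], 1)
})

test_that("logistic model raises on separation", {
  cohort <- fixture_cohort()
  tr <- cohort$trials[!is.na(cohort$trials$action), ]
  tr$reward <- 1L
  expect_error(trial_logistic_model(tr), "separation")
})

test_that("ordinal regression recovers a planted latent slope", {
  set.seed(5)
  ns <- 150; items <- 7
  x <- rnorm(ns)
  u <- rnorm(ns, 0, 0.5)
  eta <- rep(0.8 * x + u, each = items)
  cuts <- c(-0.5, 0.8, 2)
  y <- vapply(eta, function(e) {
    p <- diff(c(0, plogis(cuts - e), 1))
    sample(0:3, 1, prob = p)
  }, integer(1))
  X <- cbind(x = rep(standardize(x), each = items))
  subj <- rep(sprintf("q%03d", 1:ns), each = items)
  m <- bayes_ordinal_regression(y, X, subj, chains = 2, iter = 1500,
                                warmup = 800, seed = 3)
  expect_equal(m$coefficients$x$mean, 0.8, tolerance = 0.2)
})

test_that("ordinal model under the null favors the null in most runs", {
  set.seed(6)
  bfs <- vapply(1:20, function(i) {
    ns <- 60; items <- 5
    u <- rnorm(ns, 0, 0.5)
    eta <- rep(u, each = items)
    y <- vapply(eta, function(e) {
      p <- diff(c(0, plogis(c(-0.5, 0.8, 2) - e), 1))
      sample(0:3, 1, prob = p)
    }, integer(1))
    X <- cbind(x = rep(standardize(rnorm(ns)), each = items))
    m <- bayes_ordinal_regression(y, X, rep(1:ns, each = items),
                                  chains = 1, iter = 800, warmup = 400,
                                  seed = i)
    m$coefficients$x$bf01
  }, numeric(1))
  expect_gt(mean(bfs > 1), 0.5)
})

test_that("ordinal model with K = 2 agrees with the logistic model", {
  set.seed(7)
  ns <- 50; nt <- 40
  subj <- rep(sprintf("r%02d", 1:ns), each = nt)
  u <- rep(rnorm(ns, 0, 0.3), each = nt)
  x <- rnorm(ns * nt)
  y <- rbinom(ns * nt, 1, plogis(0.2 + 0.6 * x + u))
  X <- cbind(x = standardize(x))
  mo <- bayes_ordinal_regression(y, X, subj, chains = 2, iter = 1500,
                                 warmup = 600, seed = 4)
  trials <- data.frame(subject_id = subj, block = 0L,
                       trial_in_block = rep(0:(nt - 1), ns), set_size = 3L,
                       stimulus_id = "x", correct_action = 0L, action = 0L,
                       rt = 0.5, reward = y, iteration = 1L, delay = 2L,
                       reward_history = 0L, xcov = x,
                       stringsAsFactors = FALSE)
  ml <- trial_logistic_model(trials, predictors = "xcov", seed = 5)
  # cumulative-logit slope at K = 2 equals the logistic slope
  expect_equal(mo$coefficients$x$mean, ml$coefficients$xcov$mean,
               tolerance = 0.12)
})

test_that("monotonicity: larger latent score raises top-level probability", {
  cuts <- c(-0.5, 0.8, 2)
  p_top <- function(eta) 1 - plogis(cuts[3] - eta)
  etas <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(p_top(etas)) > 0))
})
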