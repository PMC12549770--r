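# Bayesian association analyses: standardization, linear regression with
# N(0,1) coefficient priors, Savage-Dickey Bayes factors and their
# evidence bands, a trial-level mixed logistic model, and item-level
# cumulative-logit ordinal regression. Samplers are the package's own
# (Gibbs / Metropolis-within-Gibbs / penalized Laplace); convergence is
# summarized with the split-chain R-hat statistic.

#' Standardize a numeric vector (z-score, population SD)
#'
#' @param x Non-constant numeric vector.
#' @return Vector with mean 0 and population SD 1.
#' @export
standardize <- function(x) {
  if (!is.numeric(x)) stop("standardize: input must be numeric")
  s <- sqrt(mean((x - mean(x))^2))
  if (!is.finite(s) || s == 0) stop("standardize: constant input")
  (x - mean(x)) / s
}

# split-chain R-hat of a draws matrix (iterations x chains)
split_rhat <- function(draws) {
  n <- nrow(draws) %/% 2
  halves <- cbind(draws[seq_len(n), , drop = FALSE],
                  draws[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  B <- n * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

summarize_draws <- function(draws_mat, chains, prior_sd = 1) {
  # draws_mat: (iterations*chains) x p, chain index fastest over rows
  p <- ncol(draws_mat)
  iters <- nrow(draws_mat) / chains
  out <- lapply(seq_len(p), function(j) {
    d <- draws_mat[, j]
    ch <- matrix(d, nrow = iters, ncol = chains)
    list(mean = mean(d),
         ci = unname(quantile(d, c(0.025, 0.975))),
         bf01 = savage_dickey_bf01(d, prior_sd = prior_sd),
         rhat = split_rhat(ch))
  })
  names(out) <- colnames(draws_mat)
  out
}

#' Bayesian linear regression with N(0, 1) coefficient priors
#'
#' Gibbs sampler: coefficients are drawn from their conjugate
#' multivariate-normal conditional given the residual SD; the residual SD
#' (half-normal prior) is updated by random-walk Metropolis on the log
#' scale. With the residual SD held fixed the coefficient posterior is
#' the ridge-form conjugate closed form, which the unit tests use as an
#' oracle.
#'
#' @param y Numeric response.
#' @param X Numeric matrix of standardized predictors (an intercept
#'   column is added internally, also with a N(0, 1) prior).
#' @param chains,iter,warmup Sampler settings (post-warmup draws per
#'   chain = `iter`).
#' @param sigma_scale Scale of the half-normal prior on the residual SD.
#' @param sigma_fixed If not `NULL`, hold the residual SD fixed (no MH
#'   step); used for closed-form validation.
#' @param seed Integer seed.
#' @return Object of class `rlwm_regression`: per-coefficient posterior
#'   summaries (mean, equal-tailed 95% CI, BF01, split R-hat), the full
#'   draws matrix, and sampler diagnostics.
#' @export
bayes_linear_regression <- function(y, X, chains = 4L, iter = 5000L,
                                    warmup = 1000L, sigma_scale = 5,
                                    sigma_fixed = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  XtX <- crossprod(Xd)
  Xty <- crossprod(Xd, y)
  n <- length(y)
  draws <- matrix(NA_real_, iter * chains, p,
                  dimnames = list(NULL, colnames(Xd)))
  sigma_draws <- numeric(iter * chains)
  accept <- 0; total_mh <- 0
  with_seed(derive_seed(seed, 67L), {
    for (ch in seq_len(chains)) {
      sigma <- if (is.null(sigma_fixed)) sd(y) + 1e-6 else sigma_fixed
      beta <- rep(0, p)
      for (it in seq_len(warmup + iter)) {
        # conjugate beta | sigma: precision XtX/sigma^2 + I
        prec <- XtX / sigma^2 + diag(p)
        ch_prec <- chol(prec)
        mean_b <- backsolve(ch_prec, forwardsolve(t(ch_prec), Xty / sigma^2))
        beta <- mean_b + backsolve(ch_prec, rnorm(p))
        if (is.null(sigma_fixed)) {
          # RW-MH on log sigma, half-normal(0, sigma_scale) prior
          resid <- y - Xd %*% beta
          logpost <- function(ls) {
            s2 <- exp(ls)
            sum(dnorm(resid, 0, s2, log = TRUE)) +
              dnorm(s2, 0, sigma_scale, log = TRUE) + ls
          }
          prop <- log(sigma) + rnorm(1, 0, 0.15)
          total_mh <- total_mh + 1
          if (log(runif(1)) < logpost(prop) - logpost(log(sigma))) {
            sigma <- exp(prop); accept <- accept + 1
          }
        }
        if (it > warmup) {
          row <- (ch - 1L) * iter + (it - warmup)
          draws[row, ] <- beta
          sigma_draws[row] <- sigma
        }
      }
    }
  })
  summ <- summarize_draws(draws, chains)
  structure(list(
    coefficients = summ,
    draws = draws,
    sigma_draws = sigma_draws,
    chains = chains, iter = iter,
    diagnostics = list(
      accept_rate = if (total_mh) accept / total_mh else NA_real_,
      max_rhat = max(vapply(summ, `[[`, numeric(1), "rhat")),
      converged = max(vapply(summ, `[[`, numeric(1), "rhat")) < 1.02)
  ), class = "rlwm_regression")
}

#' @export
print.rlwm_regression <- function(x, ...) {
  tab <- do.call(rbind, lapply(names(x$coefficients), function(nm) {
    co <- x$coefficients[[nm]]
    data.frame(term = nm, mean = co$mean, ci_low = co$ci[1],
               ci_high = co$ci[2], bf01 = co$bf01,
               band = interpret_bf(co$bf01), rhat = co$rhat,
               stringsAsFactors = FALSE)
  }))
  print(tab, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Savage-Dickey density-ratio Bayes factor (BF01)
#'
#' `BF01 = p(coef = 0 | data) / p(coef = 0)`: the posterior density at
#' zero, estimated by Gaussian kernel density with Silverman's bandwidth,
#' divided by the prior density at zero (N(0, `prior_sd`)). BF01 below 1
#' favors the alternative, above 1 the null.
#'
#' @param draws Posterior draws of a single coefficient (>= 1000
#'   recommended).
#' @param prior_sd SD of the zero-centered normal coefficient prior.
#' @return Positive scalar BF01.
#' @export
savage_dickey_bf01 <- function(draws, prior_sd = 1) {
  if (length(draws) < 2) stop("savage_dickey_bf01: need posterior draws")
  if (0 < min(draws) || 0 > max(draws))
    warning("savage_dickey_bf01: 0 outside the range of the draws; ",
            "density estimate is an extrapolation")
  bw <- stats::bw.nrd0(draws)
  post0 <- mean(dnorm(0, mean = draws, sd = bw))
  # keep BF01 strictly positive even when the KDE underflows at 0
  max(post0 / dnorm(0, 0, prior_sd), 1e-300)
}

#' Evidence band of a Bayes factor
#'
#' Bands: BF01 in \[1, 3) anecdotal, \[3, 10) moderate, \[10, 30)
#' strong, \[30, 100) very strong, >= 100 extreme evidence for the null;
#' below 1 the mirrored bands ((0.1, 0.3\] moderate, (0.03, 0.1\]
#' strong, ...) are closed on the side nearer 1, i.e. closed-lower on
#' the evidence (1/BF01) scale, so BF01 = 0.3 is "moderate".
#'
#' @param bf01 Positive Bayes factor (null over alternative).
#' @return Character label.
#' @export
interpret_bf <- function(bf01) {
  stopifnot(bf01 > 0)
  if (bf01 >= 1) {
    cuts <- c(1, 3, 10, 30, 100)
    lab <- c("anecdotal", "moderate", "strong", "very strong", "extreme")
    paste(lab[findInterval(bf01, cuts)], "evidence for null")
  } else {
    cuts <- c(0, 0.01, 0.03, 0.1, 0.3)
    lab <- c("extreme", "very strong", "strong", "moderate", "anecdotal")
    paste(lab[findInterval(bf01, cuts, left.open = TRUE)],
          "evidence for alternative")
  }
}

#' Trial-level mixed-effects logistic regression
#'
#' Bernoulli-logit model of trial accuracy with standardized fixed
#' effects and per-subject random intercepts (shared Normal(0, sigma_u)
#' prior, half-normal(0, 1) hyperprior on sigma_u, N(0, 1) priors on the
#' fixed effects). Fitted by penalized Laplace approximation: joint MAP
#' over fixed effects, intercepts and log sigma_u with analytic
#' gradients, then a Gaussian approximation from the inverse Hessian
#' supplies posterior draws of the fixed effects for Savage-Dickey BFs.
#' First-presentation trials (undefined delay) and non-responses are
#' excluded. Coefficients are reported as odds ratios with exponentiated
#' CIs.
#'
#' @param trials Cohort trial table with task factors
#'   ([compute_task_factors()]).
#' @param covariates Optional covariate table (joined on `subject_id`).
#' @param predictors Character vector of predictor columns (standardized
#'   internally). Default: the task factors delay, set size, reward
#'   history, block.
#' @param n_draws Number of Gaussian-approximation draws.
#' @param seed Integer seed.
#' @return `rlwm_regression` object on the log-odds scale with an extra
#'   `odds_ratios` summary table.
#' @export
trial_logistic_model <- function(trials, covariates = NULL,
                                 predictors = c("delay", "set_size",
                                                "reward_history", "block"),
                                 n_draws = 4000L, seed = 1L) {
  tr <- trials[!is.na(trials$action) & !is.na(trials$delay), , drop = FALSE]
  if (!is.null(covariates))
    tr <- merge(tr, covariates, by = "subject_id", sort = FALSE)
  y <- as.numeric(tr$reward)
  if (all(y == y[1]))
    stop("trial_logistic_model: accuracy is constant (separation); ",
         "the model is unidentifiable on these trials")
  X <- sapply(predictors, function(p) standardize(as.numeric(tr[[p]])))
  subj <- factor(tr$subject_id)
  ns <- nlevels(subj)
  si <- as.integer(subj)
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)

  # theta = [beta (p), u (ns), log sigma_u]
  negpost <- function(theta) {
    beta <- theta[1:p]; u <- theta[p + seq_len(ns)]
    lsu <- theta[p + ns + 1L]; su <- exp(lsu)
    eta <- as.numeric(Xd %*% beta) + u[si]
    ll <- sum(y * eta - log1p(exp(eta)))
    lp <- sum(dnorm(beta, 0, 1, log = TRUE)) +
      sum(dnorm(u, 0, su, log = TRUE)) +
      dnorm(su, 0, 1, log = TRUE) + lsu
    -(ll + lp)
  }
  neggrad <- function(theta) {
    beta <- theta[1:p]; u <- theta[p + seq_len(ns)]
    lsu <- theta[p + ns + 1L]; su <- exp(lsu)
    eta <- as.numeric(Xd %*% beta) + u[si]
    mu <- plogis(eta)
    r <- y - mu
    g_beta <- as.numeric(crossprod(Xd, r)) - beta
    g_u <- as.numeric(tapply(r, si, sum)) - u / su^2
    g_lsu <- sum(u^2) / su^2 - ns - su^2 + 1
    -c(g_beta, g_u, g_lsu)
  }
  start <- c(rep(0, p), rep(0, ns), log(0.5))
  # bound log sigma_u away from the sigma -> 0 MAP funnel (complete
  # shrinkage of the intercepts would make the Hessian singular)
  lower <- c(rep(-Inf, p + ns), log(0.05))
  upper <- c(rep(Inf, p + ns), log(10))
  opt <- optim(start, negpost, neggrad, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = 1000, factr = 1e4))
  if (opt$convergence != 0)
    warning("trial_logistic_model: optimizer convergence code ",
            opt$convergence)
  H <- optimHess(opt$par, negpost, neggrad)
  Sigma <- tryCatch(solve(H),
                    error = function(e) solve(H + diag(1e-6, nrow(H))))
  Sb <- Sigma[1:p, 1:p, drop = FALSE]
  Sb <- (Sb + t(Sb)) / 2
  L <- chol(Sb + diag(1e-12, p))
  draws <- with_seed(derive_seed(seed, 71L), {
    z <- matrix(rnorm(n_draws * p), n_draws, p)
    sweep(z %*% L, 2, opt$par[1:p], `+`)
  })
  colnames(draws) <- colnames(Xd)
  summ <- summarize_draws(draws, chains = 1L)
  or_tab <- do.call(rbind, lapply(names(summ), function(nm) {
    co <- summ[[nm]]
    data.frame(term = nm, odds_ratio = exp(co$mean),
               or_low = exp(co$ci[1]), or_high = exp(co$ci[2]),
               bf01 = co$bf01, stringsAsFactors = FALSE)
  }))
  structure(list(coefficients = summ, draws = draws,
                 odds_ratios = or_tab, sigma_u = exp(opt$par[p + ns + 1L]),
                 chains = 1L, iter = n_draws,
                 diagnostics = list(convergence = opt$convergence,
                                    logpost = -opt$value,
                                    max_rhat = NA_real_)),
            class = "rlwm_regression")
}

#' Bayesian cumulative-logit ordinal regression with subject intercepts
#'
#' Item responses on an ordered K-level scale are modeled as
#' `P(Y <= k) = logistic(c_k - x'beta - u_subject)` with ordered
#' cutpoints, N(0, 1) priors on coefficients, Normal(0, sigma_u) subject
#' intercepts and a half-normal(0, 1) prior on sigma_u. Sampled by
#' Metropolis-within-Gibbs: random-walk updates of the coefficient block,
#' the unconstrained cutpoint block (first cutpoint plus log-spacings),
#' each subject intercept (vectorized, likelihood factorizes over
#' subjects) and log sigma_u.
#'
#' @param response Integer vector of item responses, values `0:(K-1)`.
#' @param X Matrix of standardized subject-level predictors, one row per
#'   observation.
#' @param subject Subject identifier per observation (multiple items per
#'   subject).
#' @param chains,iter,warmup Sampler settings.
#' @param seed Integer seed.
#' @return `rlwm_regression` object (coefficient summaries feed
#'   [savage_dickey_bf01()]).
#' @export
bayes_ordinal_regression <- function(response, X, subject, chains = 2L,
                                     iter = 2000L, warmup = 1000L,
                                     seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  levs <- sort(unique(response))
  K <- length(levs)
  if (K < 2) stop("bayes_ordinal_regression: need >= 2 observed levels")
  if (!all(levs == seq_len(K) - 1L)) {
    # collapse to observed levels (a globally unobserved level makes its
    # cutpoint unidentifiable)
    response <- match(response, levs) - 1L
  }
  y <- as.integer(response)
  subj <- factor(subject)
  ns <- nlevels(subj)
  si <- as.integer(subj)
  p <- ncol(X)
  n <- length(y)

  loglik <- function(beta, cuts, u) {
    eta <- as.numeric(X %*% beta) + u[si]
    upper <- c(cuts, Inf)[y + 1L]
    lower <- c(-Inf, cuts)[y + 1L]
    sum(log(pmax(plogis(upper - eta) - plogis(lower - eta), 1e-300)))
  }
  cuts_of <- function(cp) cp[1] + c(0, cumsum(exp(cp[-1])))

  total <- iter * chains
  draws <- matrix(NA_real_, total, p, dimnames = list(NULL, colnames(X)))
  acc <- c(beta = 0, cuts = 0, sigma = 0)
  with_seed(derive_seed(seed, 73L), {
    for (ch in seq_len(chains)) {
      beta <- rep(0, p)
      cp <- c(qlogis(mean(y == 0) + 1e-3),
              rep(log(1), K - 2L))  # cutpoint parameterization
      u <- rep(0, ns); lsu <- log(0.5)
      ll <- loglik(beta, cuts_of(cp), u)
      for (it in seq_len(warmup + iter)) {
        su <- exp(lsu)
        # beta block
        prop <- beta + rnorm(p, 0, 0.08)
        llp <- loglik(prop, cuts_of(cp), u)
        a <- llp - ll + sum(dnorm(prop, log = TRUE)) -
          sum(dnorm(beta, log = TRUE))
        if (log(runif(1)) < a) { beta <- prop; ll <- llp
          acc["beta"] <- acc["beta"] + 1 }
        # cutpoint block (vague N(0, 10) prior on the unconstrained rep)
        propc <- cp + rnorm(K - 1L, 0, 0.08)
        llp <- loglik(beta, cuts_of(propc), u)
        a <- llp - ll + sum(dnorm(propc, 0, 10, log = TRUE)) -
          sum(dnorm(cp, 0, 10, log = TRUE))
        if (log(runif(1)) < a) { cp <- propc; ll <- llp
          acc["cuts"] <- acc["cuts"] + 1 }
        # subject intercepts, componentwise (factorized likelihood)
        propu <- u + rnorm(ns, 0, 0.15)
        eta_base <- as.numeric(X %*% beta)
        upper <- c(cuts_of(cp), Inf)[y + 1L]
        lower <- c(-Inf, cuts_of(cp))[y + 1L]
        ll_obs_old <- log(pmax(plogis(upper - eta_base - u[si]) -
                               plogis(lower - eta_base - u[si]), 1e-300))
        ll_obs_new <- log(pmax(plogis(upper - eta_base - propu[si]) -
                               plogis(lower - eta_base - propu[si]), 1e-300))
        d_old <- tapply(ll_obs_old, si, sum)
        d_new <- tapply(ll_obs_new, si, sum)
        a_u <- (d_new + dnorm(propu, 0, su, log = TRUE)) -
          (d_old + dnorm(u, 0, su, log = TRUE))
        take <- log(runif(ns)) < a_u
        u[take] <- propu[take]
        # sigma_u, RW-MH on the log scale, half-normal(0, 1) prior
        propl <- lsu + rnorm(1, 0, 0.2)
        a <- sum(dnorm(u, 0, exp(propl), log = TRUE)) -
          sum(dnorm(u, 0, su, log = TRUE)) +
          dnorm(exp(propl), 0, 1, log = TRUE) + propl -
          dnorm(su, 0, 1, log = TRUE) - lsu
        if (log(runif(1)) < a) { lsu <- propl
          acc["sigma"] <- acc["sigma"] + 1 }
        ll <- loglik(beta, cuts_of(cp), u)
        if (it > warmup) draws[(ch - 1L) * iter + (it - warmup), ] <- beta
      }
    }
  })
  summ <- summarize_draws(draws, chains)
  mr <- max(vapply(summ, `[[`, numeric(1), "rhat"))
  structure(list(coefficients = summ, draws = draws,
                 chains = chains, iter = iter,
                 diagnostics = list(
                   accept_rate = acc / (chains * (warmup + iter)),
                   max_rhat = mr, converged = mr < 1.02)),
            class = "rlwm_regression")
}
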