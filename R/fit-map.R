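# Hierarchical MAP estimation with non-centered subject deviations.
#
# Parameter vector theta = [mu (8), log_sd (8), z (8 per subject)].
# Subject latents are lambda_s = mu + sd * z_s; the likelihood of subject
# s depends on theta only through lambda_s, so the gradient of the full
# posterior needs just 8 directional derivatives per subject (chain rule
# distributes them onto mu, log_sd and z). That keeps quasi-Newton
# iterations cheap even at hundreds of free parameters.

n_params <- 8L

split_cohort <- function(trials) {
  ids <- unique(trials$subject_id)
  lapply(setNames(ids, ids), function(id) {
    prep_session_trials(trials[trials$subject_id == id, , drop = FALSE])
  })
}

# C++-ready per-subject data
subject_cpp_data <- function(tr) {
  list(block = as.integer(tr$block),
       stim = as.integer(tr$.stim_index),
       set_size = as.integer(tr$set_size),
       correct = as.integer(tr$correct_action),
       choice = ifelse(is.na(tr$action), -1L, as.integer(tr$action)),
       rt = ifelse(is.na(tr$rt), -1, tr$rt))
}

subject_ll <- function(dat, latent) {
  cst <- rlwm_constants()
  nat <- transform_params(setNames(latent, rlwm_param_names()))
  cpp_session_loglik(dat$block, dat$stim, dat$set_size, dat$correct,
                     dat$choice, dat$rt, as.numeric(nat),
                     cst$beta, cst$tau, cst$s, cst$h_floor, cst$lp_floor)
}

theta_unpack <- function(theta, n_subj) {
  list(mu = theta[1:8],
       log_sd = theta[9:16],
       z = matrix(theta[-(1:16)], nrow = n_subj, ncol = 8, byrow = TRUE))
}

#' Hierarchical log-posterior of the RLWM-LBA model
#'
#' Sum of per-subject session log-likelihoods at the transformed subject
#' latents `mu + sd * z_s` plus the log prior densities of the group
#' means (normal), group SDs (lognormal, evaluated on the log scale) and
#' standardized deviations z (standard normal).
#'
#' @param trials Cohort trial data frame (multiple `subject_id`s), or a
#'   prepared cohort from an internal call.
#' @param group List with `mu`, `log_sd` (length-8 vectors) and `z`
#'   (subjects x 8 matrix).
#' @param priors Prior specification ([prior_spec()]).
#' @param parts If `TRUE`, return `c(total, loglik, logprior)`.
#' @return Scalar log-posterior (or the three-part decomposition).
#' @export
log_posterior <- function(trials, group, priors = prior_spec(),
                          parts = FALSE) {
  subj <- split_cohort(trials)
  n <- length(subj)
  if (n > 0 && (!is.matrix(group$z) || nrow(group$z) != n))
    stop("log_posterior: z must be a ", n, " x 8 matrix matching subjects")
  sdv <- exp(group$log_sd)
  ll <- 0
  for (i in seq_len(n)) {
    lam <- group$mu + sdv * group$z[i, ]
    if (any(!is.finite(lam)))
      stop("log_posterior: non-finite latent for subject ", names(subj)[i])
    ll <- ll + subject_ll(subject_cpp_data(subj[[i]]), lam)
  }
  lp <- log_prior(group$mu, group$log_sd, as.numeric(group$z), priors)
  if (parts) c(total = ll + lp, loglik = ll, logprior = lp) else ll + lp
}

# objective/gradient factory over the flat theta vector
make_objective <- function(subj_data, priors) {
  n <- length(subj_data)
  obj <- function(theta) {
    u <- theta_unpack(theta, n)
    sdv <- exp(u$log_sd)
    ll <- 0
    for (i in seq_len(n))
      ll <- ll + subject_ll(subj_data[[i]], u$mu + sdv * u$z[i, ])
    -(ll + log_prior(u$mu, u$log_sd, as.numeric(t(u$z)), priors))
  }
  grad <- function(theta) {
    u <- theta_unpack(theta, n)
    sdv <- exp(u$log_sd)
    g_mu <- numeric(8); g_lsd <- numeric(8)
    g_z <- matrix(0, n, 8)
    h <- 1e-4
    for (i in seq_len(n)) {
      lam <- u$mu + sdv * u$z[i, ]
      gs <- numeric(8)
      for (p in 1:8) {
        hp <- h * max(1, abs(lam[p]))
        lp <- lam; lp[p] <- lam[p] + hp
        lm <- lam; lm[p] <- lam[p] - hp
        gs[p] <- (subject_ll(subj_data[[i]], lp) -
                  subject_ll(subj_data[[i]], lm)) / (2 * hp)
      }
      g_mu <- g_mu + gs
      g_lsd <- g_lsd + gs * sdv * u$z[i, ]
      g_z[i, ] <- gs * sdv
    }
    g_mu <- g_mu - (u$mu - priors$mean_mu) / priors$mean_sd^2
    g_lsd <- g_lsd - (u$log_sd - priors$sd_meanlog) / priors$sd_sdlog^2
    g_z <- g_z - u$z
    -c(g_mu, g_lsd, as.numeric(t(g_z)))
  }
  list(obj = obj, grad = grad)
}

#' Fit the hierarchical RLWM-LBA model by MAP
#'
#' Quasi-Newton (BFGS) maximization of [log_posterior()] over the group
#' means, log group SDs and per-subject standardized deviations, with
#' multi-start: the first start is at the prior modes (z = 0), the
#' remaining `restarts - 1` add seed-controlled jitter. The best optimum
#' over restarts is returned; non-convergence is reported, not raised.
#'
#' @param trials Cohort trial data frame.
#' @param restarts Number of optimizer starts (default 4).
#' @param seed Integer seed for the start jitter.
#' @param maxit Maximum BFGS iterations per start (default 2000).
#' @param reltol Relative convergence tolerance (default 1e-8).
#' @param jitter SD of the start jitter on group-level coordinates.
#' @param verbose Print per-restart objective values.
#' @return Object of class `rlwm_fit`: group means / SDs (latent scale),
#'   z matrix, per-subject latent and natural parameters, objective
#'   value (log-posterior at the optimum), convergence codes and the
#'   per-restart objective trace.
#' @export
fit_map <- function(trials, restarts = 4L, seed = 1L, maxit = 2000L,
                    reltol = 1e-8, jitter = 0.25, verbose = FALSE) {
  subj <- split_cohort(trials)
  if (length(subj) == 0) stop("fit_map: no subjects in trials")
  n_valid <- vapply(subj, function(tr) sum(!is.na(tr$action)), integer(1))
  if (any(n_valid == 0))
    stop("fit_map: subjects with zero valid trials: ",
         paste(names(subj)[n_valid == 0], collapse = ", "))
  subj_data <- lapply(subj, subject_cpp_data)
  priors <- prior_spec()
  n <- length(subj_data)
  fo <- make_objective(subj_data, priors)
  theta0 <- c(priors$mean_mu, priors$sd_meanlog, rep(0, 8 * n))

  best <- NULL
  trace <- data.frame(restart = integer(0), value = numeric(0),
                      convergence = integer(0))
  for (r in seq_len(restarts)) {
    start <- theta0
    if (r > 1) {
      start[1:16] <- start[1:16] +
        with_seed(derive_seed(seed, 23L, r), rnorm(16, 0, jitter))
      start[-(1:16)] <- with_seed(derive_seed(seed, 29L, r),
                                  rnorm(8 * n, 0, 0.1))
    }
    res <- optim(start, fn = fo$obj, gr = fo$grad, method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol))
    trace <- rbind(trace, data.frame(restart = r, value = -res$value,
                                     convergence = res$convergence))
    if (verbose)
      message(sprintf("restart %d: logpost %.3f (conv %d)",
                      r, -res$value, res$convergence))
    if (is.null(best) || res$value < best$value) best <- res
  }

  u <- theta_unpack(best$par, n)
  sdv <- exp(u$log_sd)
  latent <- sweep(sweep(u$z, 2, sdv, `*`), 2, u$mu, `+`)
  colnames(latent) <- rlwm_param_names()
  rownames(latent) <- names(subj_data)
  natural <- transform_params(latent)
  params <- data.frame(subject_id = names(subj_data), natural,
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    mu = setNames(u$mu, rlwm_param_names()),
    sd = setNames(sdv, rlwm_param_names()),
    z = u$z,
    latent = latent,
    params = params,
    value = -best$value,
    convergence = best$convergence,
    converged = best$convergence == 0L,
    counts = best$counts,
    trace = trace,
    n_subjects = n
  ), class = "rlwm_fit")
}

#' @export
print.rlwm_fit <- function(x, ...) {
  cat("RLWM-LBA hierarchical MAP fit:", x$n_subjects, "subjects\n")
  cat(sprintf("log-posterior: %.3f (convergence code %d)\n",
              x$value, x$convergence))
  cat("group means (natural scale):\n")
  print(round(transform_params(x$mu), 4))
  invisible(x)
}

#' Posterior predictive learning and RT curves
#'
#' Simulates `n_reps` replicate sessions per subject from fitted (or any)
#' parameters on the subjects' own session designs and summarizes
#' accuracy and mean RT (correct and incorrect separately) by stimulus
#' iteration and set size, with the observed curves alongside.
#'
#' @param params Data frame with `subject_id` and natural-scale parameter
#'   columns (as in the `params` element of an `rlwm_fit`).
#' @param trials Observed cohort trial data frame (provides both the
#'   designs and the observed curves).
#' @param n_reps Replicates per subject; 0 returns observed curves only.
#' @param seed Integer seed.
#' @return Data frame with columns `source` ("observed"/"predicted"),
#'   `set_size`, `iteration`, `accuracy`, `rt_correct`, `rt_incorrect`.
#' @export
posterior_predictive <- function(params, trials, n_reps = 10L, seed = 1L) {
  obs <- ppc_curves(trials, "observed")
  if (n_reps < 1) return(obs)
  sims <- list()
  cst <- rlwm_constants()
  for (i in seq_len(nrow(params))) {
    id <- params$subject_id[i]
    pv <- unlist(params[i, rlwm_param_names()])
    tr <- prep_session_trials(trials[trials$subject_id == id, , drop = FALSE])
    for (rep in seq_len(n_reps)) {
      beh <- with_seed(derive_seed(seed, 31L, i, rep), cpp_simulate_session(
        as.integer(tr$block), as.integer(tr$.stim_index),
        as.integer(tr$set_size), as.integer(tr$correct_action),
        as.numeric(pv), cst$beta, cst$tau, cst$s, cst$h_floor, cst$rt_max))
      sim <- tr
      sim$action <- beh$action; sim$reward <- beh$reward; sim$rt <- beh$rt
      sim$.stim_index <- NULL
      sims[[length(sims) + 1L]] <- compute_task_factors(sim)
    }
  }
  rbind(obs, ppc_curves(do.call(rbind, sims), "predicted"))
}

ppc_curves <- function(trials, label) {
  tr <- trials[!is.na(trials$action), , drop = FALSE]
  key <- interaction(tr$set_size, tr$iteration, drop = TRUE)
  acc <- tapply(tr$reward, key, mean)
  rtc <- tapply(ifelse(tr$reward == 1, tr$rt, NA), key,
                function(x) mean(x, na.rm = TRUE))
  rti <- tapply(ifelse(tr$reward == 0, tr$rt, NA), key,
                function(x) mean(x, na.rm = TRUE))
  parts <- do.call(rbind, strsplit(names(acc), ".", fixed = TRUE))
  out <- data.frame(source = label,
                    set_size = as.integer(parts[, 1]),
                    iteration = as.integer(parts[, 2]),
                    accuracy = as.numeric(acc),
                    rt_correct = as.numeric(rtc),
                    rt_incorrect = as.numeric(rti),
                    stringsAsFactors = FALSE)
  out[order(out$set_size, out$iteration), , drop = FALSE]
}

#' Parameter-recovery study
#'
#' Draws subject parameters from the group prior (group means at the
#' prior modes, group SDs at the lognormal medians), simulates one full
#' session per subject, refits with [fit_map()], and reports the Pearson
#' correlation between generating and recovered natural-scale values per
#' parameter, plus the group-mean estimation error on the latent scale.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Integer seed.
#' @param restarts,maxit,reltol Passed to [fit_map()].
#' @return Object of class `rlwm_recovery`: list with `correlations`,
#'   `group_mean_error`, `fit`, `true` (natural-scale generating values)
#'   and `recovered`.
#' @export
recover_parameters <- function(n_subjects = 30L, seed = 1L, restarts = 2L,
                               maxit = 2000L, reltol = 1e-8) {
  priors <- prior_spec()
  z <- with_seed(derive_seed(seed, 37L), matrix(rnorm(n_subjects * 8),
                                                n_subjects, 8))
  latent <- sweep(z * 0.5, 2, priors$mean_mu, `+`)
  colnames(latent) <- rlwm_param_names()
  true_nat <- transform_params(latent)
  trials <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    sess <- generate_session(seed = derive_seed(seed, 41L, i))
    simulate_agent(sess, true_nat[i, ], seed = derive_seed(seed, 43L, i),
                   subject_id = sprintf("s%03d", i))
  }))
  fit <- fit_map(trials, restarts = restarts, seed = seed, maxit = maxit,
                 reltol = reltol)
  rec_nat <- as.matrix(fit$params[, rlwm_param_names()])
  correlations <- vapply(rlwm_param_names(), function(p)
    cor(true_nat[, p], rec_nat[, p]), numeric(1))
  structure(list(
    correlations = correlations,
    group_mean_error = fit$mu - priors$mean_mu,
    fit = fit,
    true = true_nat,
    recovered = rec_nat,
    n_subjects = n_subjects,
    seed = seed
  ), class = "rlwm_recovery")
}

#' @export
print.rlwm_recovery <- function(x, ...) {
  cat("RLWM-LBA parameter recovery,", x$n_subjects, "subjects\n")
  cat("recovery correlations (generating vs recovered):\n")
  print(round(x$correlations, 3))
  invisible(x)
}
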