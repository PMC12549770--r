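# Parameter transforms and the hierarchical group-level priors.
#
# Latent (unconstrained) scale -> natural scale:
#   alpha, bias, phi, rho : Phi_approx (cubic-logistic normal-CDF
#                           approximation), onto (0, 1)
#   C                     : 2 + 3 * inv_logit(C_raw), onto (2, 5)
#   eta, A, k             : exp, onto (0, Inf) (priors are on the log scale)

#' Cubic-logistic approximation to the standard normal CDF
#'
#' `inv_logit(0.07056 * x^3 + 1.5976 * x)`: the standard fast
#' approximation used to squash latent parameters into the unit interval.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @export
phi_approx <- function(x) {
  plogis(0.07056 * x^3 + 1.5976 * x)
}

phi_approx_inv <- function(p) {
  y <- qlogis(p)
  vapply(y, function(yy) {
    # single real root of 0.07056 x^3 + 1.5976 x - yy = 0 (monotone cubic)
    uniroot(function(x) 0.07056 * x^3 + 1.5976 * x - yy,
            lower = -50, upper = 50, tol = 1e-12)$root
  }, numeric(1))
}

#' Map latent parameters to the natural scale
#'
#' @param latent Named numeric vector (or matrix with named columns) of
#'   latent values for the 8 free parameters.
#' @return Natural-scale values, same shape, satisfying the
#'   [subject_params()] range constraints.
#' @export
transform_params <- function(latent) {
  f <- function(v) {
    out <- v
    for (p in c("alpha", "bias", "phi", "rho")) out[p] <- phi_approx(v[p])
    out["C"] <- 2 + 3 * plogis(v["C"])
    for (p in c("eta", "A", "k")) out[p] <- exp(v[p])
    out
  }
  if (is.matrix(latent)) t(apply(latent, 1, f)) else f(latent)
}

#' Map natural-scale parameters back to the latent scale
#'
#' Numerical inverse of [transform_params()] (exact for the log and logit
#' components, root-found for the cubic-logistic squash).
#'
#' @param natural Named numeric vector of natural-scale parameters.
#' @return Latent values.
#' @export
untransform_params <- function(natural) {
  out <- natural
  for (p in c("alpha", "bias", "phi", "rho"))
    out[p] <- phi_approx_inv(natural[p])
  out["C"] <- qlogis((natural["C"] - 2) / 3)
  for (p in c("eta", "A", "k")) out[p] <- log(natural[p])
  out
}

#' Group-level prior specification
#'
#' Priors on the latent-scale group means (normal) and group SDs
#' (lognormal), and standard-normal priors on the per-subject
#' standardized deviations z.
#'
#' @return List with `mean_mu`, `mean_sd` (normal priors on group means),
#'   `sd_meanlog`, `sd_sdlog` (lognormal priors on group SDs), all named
#'   by parameter.
#' @export
prior_spec <- function() {
  nm <- rlwm_param_names()
  list(
    mean_mu = setNames(c(-2, 1, -1, 1, 0, log(5), log(1.2), log(1)), nm),
    mean_sd = setNames(c(1, 1, 1, 1, 1.5, 0.3, 0.35, 0.3), nm),
    sd_meanlog = setNames(rep(log(0.5), 8), nm) ,
    sd_sdlog = setNames(c(rep(0.35, 4), 0.55, rep(0.35, 3)), nm)
  )
}

# log prior density of (mu, log_sd, z). The lognormal prior on sd is
# evaluated on the log scale including the Jacobian, i.e. as a normal
# density in log_sd.
log_prior <- function(mu, log_sd, z, priors = prior_spec()) {
  lp <- sum(dnorm(mu, priors$mean_mu, priors$mean_sd, log = TRUE)) +
    sum(dnorm(log_sd, priors$sd_meanlog, priors$sd_sdlog, log = TRUE))
  if (length(z)) lp <- lp + sum(dnorm(z, log = TRUE))
  lp
}
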