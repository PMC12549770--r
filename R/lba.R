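# Linear ballistic accumulator: density, defective likelihood, sampler.
#
# Each of the three response options accumulates evidence linearly from a
# start point drawn from Uniform(0, A) at a drift rate drawn (per trial)
# from Normal(V_i, s); the first accumulator to reach the threshold
# b = A + k determines choice and decision time, and rt = tau + time.

# Per-accumulator first-passage density f(t) and CDF F(t) for decision
# time t (Brown & Heathcote's closed form). The standard expressions have
# a bracket of order A multiplied by 1/A; when A/(t*s) falls below ~1e-6
# they cancel catastrophically, so the analytic A -> 0 limit (start point
# fixed at 0, finishing time b/v with v ~ N(V, s)) is used instead.
lba_dfun <- function(t, v, A, b, s) {
  ts <- t * s
  small <- A / ts < 1e-6
  z1 <- (b - t * v) / ts
  f <- numeric(length(t))
  if (any(small))
    f[small] <- b / (t[small]^2 * s) * dnorm(z1[small])
  if (any(!small)) {
    z2 <- (b - A - t[!small] * v) / ts[!small]
    f[!small] <- (1 / A) * (-v * pnorm(z2) + s * dnorm(z2) +
                            v * pnorm(z1[!small]) - s * dnorm(z1[!small]))
  }
  pmax(f, 0)
}

lba_pfun <- function(t, v, A, b, s) {
  ts <- t * s
  small <- A / ts < 1e-6
  z1 <- (b - t * v) / ts
  F <- numeric(length(t))
  if (any(small)) F[small] <- pnorm(-z1[small])
  if (any(!small)) {
    tns <- t[!small]; tsn <- ts[!small]
    z2 <- (b - A - tns * v) / tsn
    F[!small] <- 1 + (b - A - tns * v) / A * pnorm(z2) -
      (b - tns * v) / A * pnorm(z1[!small]) +
      tsn / A * dnorm(z2) - tsn / A * dnorm(z1[!small])
  }
  pmin(pmax(F, 0), 1)
}

#' LBA defective log-density of a choice and reaction time
#'
#' Likelihood of observing `choice` at time `rt`: the density of the
#' chosen accumulator finishing at `t = rt - tau` times the probability
#' that every other accumulator is still below threshold at `t`. The
#' density is "defective": integrated over all times and summed over
#' choices it equals the probability that at least one sampled drift is
#' positive, which is slightly below 1.
#'
#' The result is floored at `log(1e-10)` so that outlier RTs cannot
#' produce `-Inf`; an RT at or below `tau` (impossible under the model)
#' gets the floor value and is flagged via the `"invalid"` attribute.
#'
#' @param choice Chosen action, 0-based in `0:(length(V) - 1)` (vectors
#'   recycled against `rt`).
#' @param rt Reaction time in seconds.
#' @param V Drift-rate vector (one per accumulator).
#' @param A Start-point upper limit.
#' @param k Relative threshold; decision threshold is `b = A + k`.
#' @param s Drift-rate SD (fixed scaling constant, default 1).
#' @param tau Non-decision time (default 0.15 s).
#' @return Numeric vector of log-densities with a logical `"invalid"`
#'   attribute marking `rt <= tau` entries.
#' @export
lba_logpdf <- function(choice, rt, V, A, k,
                       s = rlwm_constants()$s, tau = rlwm_constants()$tau) {
  stopifnot(A > 0, k > 0, all(choice %in% (seq_along(V) - 1L)))
  b <- A + k
  n <- max(length(choice), length(rt))
  choice <- rep_len(as.integer(choice), n)
  rt <- rep_len(rt, n)
  invalid <- rt <= tau
  out <- rep(rlwm_constants()$lp_floor, n)
  if (any(!invalid)) {
    t <- rt[!invalid] - tau
    ch <- choice[!invalid] + 1L
    dens <- lba_dfun(t, V[ch], A, b, s)
    for (j in seq_along(V)) {
      other <- ch != j
      if (any(other))
        dens[other] <- dens[other] * (1 - lba_pfun(t[other], V[j], A, b, s))
    }
    out[!invalid] <- log(pmax(dens, 1e-10))
  }
  attr(out, "invalid") <- invalid
  out
}

#' Probability of a choice under the LBA (numerical integration)
#'
#' Integrates the defective density of `choice` over all decision times.
#' Used as an oracle against the Monte-Carlo race sampler.
#'
#' @inheritParams lba_logpdf
#' @return Scalar probability.
#' @export
lba_choice_prob <- function(choice, V, A, k,
                            s = rlwm_constants()$s,
                            tau = rlwm_constants()$tau) {
  b <- A + k
  ch <- as.integer(choice) + 1L
  f <- function(t) {
    d <- lba_dfun(t, V[ch], A, b, s)
    for (j in seq_along(V)) if (j != ch)
      d <- d * (1 - lba_pfun(t, V[j], A, b, s))
    d
  }
  integrate(f, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-10,
            stop.on.error = FALSE)$value
}

#' Total probability mass of the defective LBA density
#'
#' Sums [lba_choice_prob()] over choices. Equals
#' `1 - prod(pnorm(-V / s))`, the probability that at least one
#' accumulator samples a positive drift.
#'
#' @inheritParams lba_logpdf
#' @return Scalar mass (slightly below 1).
#' @export
lba_total_mass <- function(V, A, k, s = rlwm_constants()$s,
                           tau = rlwm_constants()$tau) {
  sum(vapply(seq_along(V) - 1L, lba_choice_prob, numeric(1),
             V = V, A = A, k = k, s = s, tau = tau))
}

#' Sample choices and reaction times from the LBA race
#'
#' Start points are Uniform(0, A), drifts Normal(V_i, s); the winner is
#' the positive-drift accumulator with the smallest `(b - start) / drift`.
#' Trials where every sampled drift is negative are re-drawn (up to 1000
#' attempts, after which the max-V accumulator is forced to a tiny
#' positive drift). Deterministic under `set.seed()`.
#'
#' @param n Number of trials to sample.
#' @inheritParams lba_logpdf
#' @return Data frame with 0-based `choice` and `rt` (seconds).
#' @export
lba_sample <- function(n, V, A, k, s = rlwm_constants()$s,
                       tau = rlwm_constants()$tau) {
  stopifnot(A > 0, k > 0)
  b <- A + k
  m <- length(V)
  start <- matrix(runif(n * m, 0, A), n, m)
  drift <- matrix(rnorm(n * m, mean = rep(V, each = n), sd = s), n, m)
  bad <- rowSums(drift > 0) == 0
  tries <- 0
  while (any(bad) && tries < 1000) {
    nb <- sum(bad)
    drift[bad, ] <- rnorm(nb * m, mean = rep(V, each = nb), sd = s)
    bad <- rowSums(drift > 0) == 0
    tries <- tries + 1
  }
  if (any(bad)) drift[bad, which.max(V)] <- 1e-6
  time <- (b - start) / drift
  time[drift <= 0] <- Inf
  winner <- max.col(-time, ties.method = "first")
  rt <- tau + time[cbind(seq_len(n), winner)]
  data.frame(choice = winner - 1L, rt = rt)
}
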