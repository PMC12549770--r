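# Elementary value-update and policy operations of the RLWM model.
# These are the reference R implementations; the session-level likelihood
# and simulator replay the same arithmetic in C++ (src/rlwm.cpp).

#' Delta-rule update of an RL value with a positive learning bias
#'
#' `q <- q + alpha_eff * (r - q)` where `alpha_eff = (1 - bias) * alpha`
#' when the prediction error `r - q` is negative and `alpha` otherwise.
#' A bias near 1 means negative feedback is largely neglected.
#'
#' @param q Current expected reward in \[0, 1\].
#' @param r Observed reward, 0 or 1 (any value in \[0, 1\] is accepted).
#' @param alpha Learning rate in \[0, 1\].
#' @param bias Positive learning bias in \[0, 1\].
#' @return Updated value, guaranteed to stay in \[0, 1\].
#' @export
rl_update <- function(q, r, alpha, bias) {
  delta <- r - q
  rate <- ifelse(delta < 0, (1 - bias) * alpha, alpha)
  q + rate * delta
}

#' Working-memory update (learning rate 1, biased for negative errors)
#'
#' Working memory updates perfectly toward the observed outcome
#' (`q <- r`) unless the prediction error is negative, in which case the
#' effective rate is `1 - bias`.
#'
#' @inheritParams rl_update
#' @return Updated working-memory value.
#' @export
wm_update <- function(q, r, bias) {
  rl_update(q, r, alpha = 1, bias = bias)
}

#' Trial-by-trial working-memory decay
#'
#' Every entry of the working-memory value table (all stimuli, all
#' actions) relaxes toward the initial value `1/3` by a fraction `phi`.
#'
#' @param q_wm Numeric vector or matrix of working-memory values.
#' @param phi Decay rate in \[0, 1\].
#' @param q_init Resting value (default `1/3`).
#' @return Decayed values, same shape as `q_wm`.
#' @export
wm_decay <- function(q_wm, phi, q_init = rlwm_constants()$q_init) {
  q_wm + phi * (q_init - q_wm)
}

#' Softmax choice rule
#'
#' Converts a row of action values into choice probabilities with inverse
#' temperature `beta` (fixed to 50 in the RLWM-LBA model). Uses
#' max-subtraction so that `beta * q` up to hundreds does not overflow.
#'
#' @param q Numeric vector of action values.
#' @param beta Inverse temperature.
#' @return Probability vector summing to 1.
#' @export
softmax_policy <- function(q, beta = rlwm_constants()$beta) {
  z <- beta * q
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Working-memory mixing weight
#'
#' `W = rho * min(1, C / set_size)`: the propensity to rely on working
#' memory, attenuated when the block's set size exceeds capacity `C`.
#'
#' @param rho Working-memory prior weight in \[0, 1\].
#' @param C Capacity.
#' @param set_size Number of stimuli in the current block.
#' @return Mixing weight in \[0, 1\].
#' @export
mixing_weight <- function(rho, C, set_size) {
  rho * min(1, C / set_size)
}

#' Mix the working-memory and RL policies
#'
#' @param p_wm,p_rl Probability vectors.
#' @param w Mixing weight from [mixing_weight()].
#' @return `w * p_wm + (1 - w) * p_rl`.
#' @export
mixed_policy <- function(p_wm, p_rl, w) {
  w * p_wm + (1 - w) * p_rl
}

#' Average policy across the stimuli of a block
#'
#' Column means of the per-stimulus mixed policies: the prior probability
#' of each action before the next stimulus is revealed.
#'
#' @param policies Matrix with one row per stimulus, one column per action.
#' @return Probability vector (length = number of actions).
#' @export
average_policy <- function(policies) {
  colMeans(policies)
}

#' Shannon entropy (bits) of an action policy
#'
#' `-sum(p * log2(p))` with the convention `0 * log2(0) = 0`. This is the
#' decision-uncertainty signal that divides the drift rates; when used as
#' a divisor it is floored at `h_floor` (see [drift_rates()]).
#'
#' @param p Probability vector.
#' @return Entropy in bits.
#' @export
prior_entropy <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Entropy-scaled LBA drift rates
#'
#' `V_a = eta * p_a / max(H, h_floor)`: choice probabilities scaled by
#' `eta` and divided by the prior entropy, so that high uncertainty slows
#' all accumulators.
#'
#' @param policy Mixed policy for the presented stimulus.
#' @param h_prior Prior entropy in bits.
#' @param eta Drift scaling parameter.
#' @param h_floor Floor for the entropy divisor (bits).
#' @return Vector of non-negative drift rates.
#' @export
drift_rates <- function(policy, h_prior, eta,
                        h_floor = rlwm_constants()$h_floor) {
  eta * policy / max(h_prior, h_floor)
}
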