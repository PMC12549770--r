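# Generative simulation and likelihood of full sessions (C++ backed).

# Order trials and attach the 0-based within-block stimulus index the C++
# replay needs. Mapping follows first appearance; any consistent mapping
# is equivalent because Q tables start uniform.
prep_session_trials <- function(trials) {
  trials <- trials[order(trials$block, trials$trial_in_block), , drop = FALSE]
  idx <- integer(nrow(trials))
  for (b in unique(trials$block)) {
    ib <- which(trials$block == b)
    ids <- trials$stimulus_id[ib]
    idx[ib] <- match(ids, unique(ids)) - 1L
  }
  trials$.stim_index <- idx
  trials
}

#' Simulate a subject playing an RLWM session
#'
#' Plays the RLWM-LBA generative model through a session design: on each
#' trial the mixed policy, prior entropy and drift rates are computed from
#' the pre-trial value tables, a (choice, RT) pair is sampled from the LBA
#' race, deterministic feedback is applied, and the RL / WM tables are
#' updated (WM decay last, over all entries). Sampled RTs beyond the 7 s
#' deadline are recorded as non-responses (`NA` action, reward and RT);
#' no learning occurs on those trials but WM decay still applies.
#'
#' @param session An `rlwm_session` design from [generate_session()].
#' @param params Natural-scale parameters ([subject_params()] or a named
#'   vector).
#' @param seed Integer seed (RNG state is restored afterwards).
#' @param subject_id Identifier written into the trial table.
#' @return Trial data frame with behavioral fields and task factors
#'   filled.
#' @export
simulate_agent <- function(session, params, seed = 1L, subject_id = "s01") {
  params <- validate_params(unclass(params))
  trials <- session_trials(session, subject_id = subject_id)
  trials <- prep_session_trials(trials)
  cst <- rlwm_constants()
  beh <- with_seed(derive_seed(seed, 17L), cpp_simulate_session(
    as.integer(trials$block), as.integer(trials$.stim_index),
    as.integer(trials$set_size), as.integer(trials$correct_action),
    as.numeric(params), cst$beta, cst$tau, cst$s, cst$h_floor, cst$rt_max))
  trials$action <- beh$action
  trials$reward <- beh$reward
  trials$rt <- beh$rt
  trials$.stim_index <- NULL
  compute_task_factors(trials)
}

#' Session log-likelihood under the RLWM-LBA model
#'
#' Replays the learning equations on the observed history (observed
#' choices and rewards drive the updates) and scores every responded
#' trial with the LBA defective log-density, floored at `log(1e-10)`.
#' Non-response trials (`NA` action) are excluded from the likelihood
#' but still advance working-memory decay. A pure function of
#' `(trials, params)`.
#'
#' @param trials Trial data frame for one subject (columns `block`,
#'   `trial_in_block`, `set_size`, `stimulus_id`, `correct_action`,
#'   `action`, `rt`).
#' @param params Natural-scale parameter vector.
#' @return Total log-likelihood (0 for an empty trial list).
#' @export
session_loglik <- function(trials, params) {
  params <- validate_params(unclass(params))
  if (nrow(trials) == 0) return(0)
  bad <- xor(is.na(trials$action), is.na(trials$rt))
  if (any(bad))
    stop("session_loglik: trials with a choice but no RT (or vice versa): ",
         paste(head(which(bad)), collapse = ", "))
  trials <- prep_session_trials(trials)
  cst <- rlwm_constants()
  act <- ifelse(is.na(trials$action), -1L, as.integer(trials$action))
  rt <- ifelse(is.na(trials$rt), -1, trials$rt)
  cpp_session_loglik(
    as.integer(trials$block), as.integer(trials$.stim_index),
    as.integer(trials$set_size), as.integer(trials$correct_action),
    act, rt, as.numeric(params), cst$beta, cst$tau, cst$s, cst$h_floor,
    cst$lp_floor)
}
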