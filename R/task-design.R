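# RLWM task generator: blocks with set sizes 2-5, pseudo-randomized
# interleaving with controlled delay distribution, deterministic feedback.

#' Generate one RLWM block design
#'
#' A block presents `set_size` block-unique stimuli, each 12-14 times for a
#' total of `13 * set_size` trials, in a pseudo-randomized interleaved
#' order. The gap between two successive presentations of the same
#' stimulus (the "delay") is constrained to `[1, 2 * set_size]` trials and
#' the pooled delay histogram is required to be approximately uniform: a
#' candidate sequence is accepted only when its chi-square uniformity
#' statistic falls below the 0.01-level critical value (configurable).
#' Candidate sequences are drawn by a randomized greedy scheduler (a
#' stimulus whose delay deadline is reached is placed immediately;
#' otherwise stimuli are sampled in proportion to remaining presentations)
#' inside a rejection-sampling loop.
#'
#' The correct action for each stimulus is drawn uniformly from `{0,1,2}`,
#' independently per stimulus, so the same action may be correct for
#' several stimuli.
#'
#' @param set_size Number of stimuli, 2-5.
#' @param block_index Non-negative integer identifying the block; part of
#'   the stimulus ids and of the RNG stream.
#' @param seed Integer seed; identical `(set_size, block_index, seed)`
#'   yields identical designs.
#' @param chisq_level Significance level defining the uniformity
#'   acceptance threshold (default 0.01).
#' @param max_iter Rejection-sampling budget (default 10000).
#' @return An object of class `rlwm_block`: list with `block_index`,
#'   `set_size`, `n_trials`, `stimulus_ids`, `stimulus_sequence` (ids),
#'   `stimulus_index` (0-based index into `stimulus_ids`) and
#'   `correct_action_map` (named 0-based actions).
#' @export
generate_block <- function(set_size, block_index = 0L, seed = 1L,
                           chisq_level = 0.01, max_iter = 10000L) {
  stopifnot(set_size %in% 2:5)
  with_seed(derive_seed(seed, 7L, block_index, set_size), {
    ns <- as.integer(set_size)
    n <- 13L * ns
    max_gap <- 2L * ns
    crit <- qchisq(1 - chisq_level, df = max_gap - 1L)

    counts <- rep(13L, ns)
    # realism: each stimulus appears 12-14 times; perturb with +1/-1 pairs
    n_swaps <- sample.int(ns %/% 2 + 1L, 1L) - 1L
    if (n_swaps > 0) {
      who <- sample.int(ns, 2L * n_swaps)
      counts[who[seq_len(n_swaps)]] <- 14L
      counts[who[n_swaps + seq_len(n_swaps)]] <- 12L
    }

    seq_idx <- NULL
    for (iter in seq_len(max_iter)) {
      cand <- schedule_block(counts, max_gap)
      if (is.null(cand)) next
      gaps <- delays_of(cand)
      stat <- delay_chisq(gaps, max_gap)
      if (stat < crit) { seq_idx <- cand; break }
    }
    if (is.null(seq_idx))
      stop("generate_block: no sequence satisfying the delay-uniformity ",
           "tolerance found within ", max_iter, " iterations")

    ids <- sprintf("b%02d_s%d", block_index, seq_len(ns))
    correct <- sample(0:2, ns, replace = TRUE)
    names(correct) <- ids
    structure(list(
      block_index = as.integer(block_index),
      set_size = ns,
      n_trials = n,
      stimulus_ids = ids,
      stimulus_sequence = ids[seq_idx],
      stimulus_index = seq_idx - 1L,
      correct_action_map = correct
    ), class = "rlwm_block")
  })
}

# Randomized greedy interleaver. Returns 1-based stimulus indices or NULL
# on a dead end (two stimuli forced into the same slot).
schedule_block <- function(counts, max_gap) {
  ns <- length(counts)
  n <- sum(counts)
  remaining <- counts
  last <- rep(NA_integer_, ns)
  out <- integer(n)
  for (t in seq_len(n)) {
    due <- which(!is.na(last) & remaining > 0L & (t - last) >= max_gap)
    if (length(due) > 1L) return(NULL)
    if (length(due) == 1L) {
      pick <- due
    } else {
      avail <- which(remaining > 0L)
      if (length(avail) == 1L) pick <- avail
      else pick <- sample(avail, 1L, prob = remaining[avail])
    }
    out[t] <- pick
    remaining[pick] <- remaining[pick] - 1L
    last[pick] <- t
  }
  out
}

# successive-presentation gaps, pooled over stimuli
delays_of <- function(seq_idx) {
  unlist(lapply(split(seq_along(seq_idx), seq_idx), diff), use.names = FALSE)
}

# chi-square statistic of the pooled delay histogram against the uniform
# distribution on 1..max_gap
delay_chisq <- function(gaps, max_gap) {
  obs <- tabulate(gaps, nbins = max_gap)
  expd <- length(gaps) / max_gap
  sum((obs - expd)^2 / expd)
}

#' Generate a full RLWM session design
#'
#' Ten blocks totalling 468 trials with the fixed set-size composition
#' (two blocks of set size 2, three of 3, two of 4, three of 5) in a
#' seed-determined shuffled order. Stimuli are block-unique.
#'
#' @param seed Integer seed.
#' @inheritParams generate_block
#' @return An object of class `rlwm_session`: list with `blocks` (list of
#'   [generate_block()] designs), `set_sizes`, `n_trials` and `seed`.
#' @export
generate_session <- function(seed = 1L, chisq_level = 0.01,
                             max_iter = 10000L) {
  composition <- c(2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L, 5L, 5L)
  order <- with_seed(derive_seed(seed, 11L), sample(composition))
  blocks <- lapply(seq_along(order), function(i)
    generate_block(order[i], block_index = i - 1L, seed = seed,
                   chisq_level = chisq_level, max_iter = max_iter))
  structure(list(
    blocks = blocks,
    set_sizes = order,
    n_trials = sum(vapply(blocks, `[[`, integer(1), "n_trials")),
    seed = as.integer(seed)
  ), class = "rlwm_session")
}

#' Flatten a session design into a trial table
#'
#' One row per trial with the design fields only (behavioral fields are
#' `NA` until simulated or observed).
#'
#' @param session An `rlwm_session`.
#' @param subject_id Subject identifier recorded on every row.
#' @return Trial data frame in the package's trial schema (see
#'   [write_trials()]).
#' @export
session_trials <- function(session, subject_id = "s01") {
  stopifnot(inherits(session, "rlwm_session"))
  rows <- lapply(session$blocks, function(b) {
    data.frame(
      subject_id = subject_id,
      block = b$block_index,
      trial_in_block = seq_len(b$n_trials) - 1L,
      set_size = b$set_size,
      stimulus_id = b$stimulus_sequence,
      correct_action = unname(b$correct_action_map[b$stimulus_sequence]),
      action = NA_integer_,
      reward = NA_integer_,
      rt = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  compute_task_factors(trials)
}

#' Run the training block against an agent policy
#'
#' Training uses 2 stimuli with deterministic feedback. It ends at the
#' first trial index `>= 15` at which mean accuracy over the last 10
#' trials exceeds 0.8, and otherwise after 50 trials.
#'
#' @param agent_policy Function of one argument, a list with `stimulus`
#'   (0-based index), `correct_action` and `trial`, returning a 0-based
#'   action. E.g. an always-correct agent is
#'   `function(info) info$correct_action`.
#' @param seed Integer seed controlling the stimulus order and correct
#'   actions.
#' @return Trial data frame (training block has `block = -1`).
#' @export
generate_training_block <- function(agent_policy, seed = 1L) {
  with_seed(derive_seed(seed, 13L), {
    max_gap <- 4L
    correct <- sample(0:2, 2L, replace = TRUE)
    last <- c(NA_integer_, NA_integer_)
    acc <- integer(0)
    rows <- list()
    for (t in 1:50) {
      due <- which(!is.na(last) & (t - last) >= max_gap)
      st <- if (length(due) >= 1L) due[1L] else sample(1:2, 1L)
      last[st] <- t
      action <- as.integer(agent_policy(list(
        stimulus = st - 1L, correct_action = correct[st], trial = t)))
      reward <- as.integer(action == correct[st])
      acc <- c(acc, reward)
      rows[[t]] <- data.frame(
        subject_id = "training", block = -1L, trial_in_block = t - 1L,
        set_size = 2L, stimulus_id = sprintf("train_s%d", st),
        correct_action = correct[st], action = action, reward = reward,
        rt = NA_real_, stringsAsFactors = FALSE
      )
      if (t >= 15L && mean(acc[(t - 9L):t]) > 0.8) break
    }
    trials <- do.call(rbind, rows)
    rownames(trials) <- NULL
    compute_task_factors(trials)
  })
}

#' Derive trial-level task factors
#'
#' Fills three derived columns, per stimulus within each block:
#' `iteration` (presentation count, starting at 1), `delay` (trials since
#' the previous presentation of the same stimulus; `NA` on the first
#' presentation) and `reward_history` (cumulative rewards for the
#' stimulus before the current trial). Idempotent: recomputing on its own
#' output changes nothing.
#'
#' @param trials Trial data frame ordered by `trial_in_block` within each
#'   block.
#' @return The trial data frame with `iteration`, `delay` and
#'   `reward_history` columns.
#' @export
compute_task_factors <- function(trials) {
  need <- c("block", "trial_in_block", "stimulus_id")
  if (!all(need %in% names(trials)))
    stop("compute_task_factors: missing columns: ",
         paste(setdiff(need, names(trials)), collapse = ", "))
  if (any(is.na(trials$stimulus_id)))
    stop("compute_task_factors: unknown (NA) stimulus ids")
  trials$iteration <- NA_integer_
  trials$delay <- NA_integer_
  trials$reward_history <- NA_integer_
  grp <- if ("subject_id" %in% names(trials))
    interaction(trials$subject_id, trials$block, drop = TRUE)
  else factor(trials$block)
  for (g in levels(grp)) {
    ib <- which(grp == g)
    b <- trials$block[ib[1]]
    tib <- trials$trial_in_block[ib]
    if (is.unsorted(tib, strictly = TRUE))
      stop("compute_task_factors: trials out of order in block ", b)
    for (s in unique(trials$stimulus_id[ib])) {
      is_ <- ib[trials$stimulus_id[ib] == s]
      pos <- trials$trial_in_block[is_]
      trials$iteration[is_] <- seq_along(is_)
      trials$delay[is_] <- c(NA_integer_, diff(pos))
      r <- trials$reward[is_]
      if (is.null(r)) r <- rep(NA_integer_, length(is_))
      r0 <- ifelse(is.na(r), 0L, as.integer(r))
      trials$reward_history[is_] <- cumsum(c(0L, r0[-length(r0)]))
    }
  }
  trials
}
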