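test_that("block designs satisfy all structural invariants", {
  for (ss in 2:5) {
    b <- generate_block(ss, block_index = 3L, seed = 11L)
    expect_equal(b$n_trials, 13L * ss)
    expect_length(b$stimulus_ids, ss)
    tab <- table(b$stimulus_sequence)
    expect_setequal(names(tab), b$stimulus_ids)
    expect_true(all(tab >= 12 & tab <= 14))
    expect_equal(sum(tab), 13L * ss)
    gaps <- unlist(lapply(split(seq_along(b$stimulus_index),
                                b$stimulus_index), diff))
    expect_true(all(gaps >= 1 & gaps <= 2 * ss))
    # uniformity statistic below the 0.01-level critical value
    obs <- tabulate(gaps, nbins = 2 * ss)
    stat <- sum((obs - length(gaps) / (2 * ss))^2 / (length(gaps) / (2 * ss)))
    expect_lt(stat, qchisq(0.99, df = 2 * ss - 1))
    expect_true(all(b$correct_action_map %in% 0:2))
  }
})

test_that("block generation is deterministic and seed-sensitive", {
  expect_identical(generate_block(4, 2L, seed = 5L),
                   generate_block(4, 2L, seed = 5L))
  b1 <- generate_block(4, 2L, seed = 5L)
  b2 <- generate_block(4, 2L, seed = 6L)
  expect_false(identical(b1$stimulus_sequence, b2$stimulus_sequence))
})

test_that("sessions have 468 trials, 10 blocks, fixed composition", {
  for (seed in c(1L, 77L)) {
    sess <- generate_session(seed = seed)
    expect_length(sess$blocks, 10L)
    expect_equal(sess$n_trials, 468L)
    expect_equal(sort(sess$set_sizes), c(2, 2, 3, 3, 3, 4, 4, 5, 5, 5))
    ids <- unlist(lapply(sess$blocks, `[[`, "stimulus_ids"))
    expect_equal(anyDuplicated(ids), 0L)  # block-unique stimuli
  }
  # different seeds: same composition, typically different order
  o1 <- generate_session(seed = 1L)$set_sizes
  o2 <- generate_session(seed = 2L)$set_sizes
  expect_false(identical(o1, o2))
})

test_that("training block implements the trailing-10 stopping rule", {
  always_right <- function(info) info$correct_action
  always_wrong <- function(info) (info$correct_action + 1L) %% 3L
  expect_equal(nrow(generate_training_block(always_right, seed = 1L)), 15L)
  expect_equal(nrow(generate_training_block(always_wrong, seed = 1L)), 50L)
  # correct from trial 16 onward: trailing-10 accuracy first exceeds 0.8
  # at the trial where 9 of the last 10 are correct; hand trace below
  late <- function(info)
    if (info$trial <= 15L) (info$correct_action + 1L) %% 3L
    else info$correct_action
  acc <- c(rep(0, 15), rep(1, 35))
  stops <- which(vapply(15:50, function(t) mean(acc[(t - 9):t]) > 0.8,
                        logical(1)))[1] + 14L
  expect_equal(nrow(generate_training_block(late, seed = 2L)), stops)
  expect_equal(stops, 24L)
})

test_that("task factors: iteration, delay, reward history", {
  tr <- data.frame(
    subject_id = "s", block = 0L, trial_in_block = 0:7,
    set_size = 2L,
    stimulus_id = c("a", "b", "b", "a", "b", "a", "a", "b"),
    correct_action = 0L,
    action = c(0L, 1L, 0L, 0L, 0L, 1L, 0L, 0L),
    reward = c(1L, 0L, 1L, 1L, 1L, 0L, 1L, 1L),
    rt = 0.5, stringsAsFactors = FALSE
  )
  out <- compute_task_factors(tr)
  expect_equal(out$iteration, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(out$delay, c(NA, NA, 1L, 3L, 2L, 2L, 1L, 3L))
  # cumulative rewards BEFORE the trial
  expect_equal(out$reward_history[out$stimulus_id == "a"], c(0L, 1L, 2L, 2L))
  expect_equal(out$reward_history[out$stimulus_id == "b"], c(0L, 0L, 1L, 2L))
  # idempotent
  expect_identical(compute_task_factors(out), out)
  # reward_history non-decreasing per stimulus
  for (s in c("a", "b"))
    expect_true(!is.unsorted(out$reward_history[out$stimulus_id == s]))
})

test_that("task factors validate ordering and stimulus ids", {
  tr <- data.frame(subject_id = "s", block = 0L, trial_in_block = c(1L, 0L),
                   set_size = 2L, stimulus_id = c("a", "a"),
                   correct_action = 0L, action = 0L, reward = 1L, rt = 0.4)
  expect_error(compute_task_factors(tr), "out of order")
  tr2 <- tr
  tr2$trial_in_block <- 0:1
  tr2$stimulus_id <- c("a", NA)
  expect_error(compute_task_factors(tr2), "stimulus ids")
})

test_that("task factors survive a CSV round trip", {
  cohort <- fixture_cohort()
  tr <- cohort$trials[cohort$trials$subject_id == "s001", ]
  f <- tempfile(fileext = ".csv")
  write_trials(tr, f)
  back <- compute_task_factors(read_trials(f))
  expect_equal(back$delay, tr$delay)
  expect_equal(back$reward_history, tr$reward_history)
  expect_equal(back$rt, tr$rt, tolerance = 1e-12)
  unlink(f)
})
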