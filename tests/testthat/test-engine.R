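# Experiment engine: sequence construction, response scoring and the adaptive
# rule.

test_that("sequences alternate target and distractor at a constant IOI", {
  ev <- build_sequence(12, deviant_rate = 0.25, ioi = 0.25, seed = 5)
  expect_equal(nrow(ev), 12 * 8)
  expect_equal(ev$role, rep(c("target", "distractor"), 48))
  expect_equal(diff(ev$onset), rep(0.25, nrow(ev) - 1))
  tg <- ev[ev$role == "target", ]
  expect_true(all(tg$f0 %in% TARGET_F0))
  ds <- ev[ev$role == "distractor", ]
  expect_true(all(ds$f0 >= DISTRACTOR_F0_RANGE[1] &
                    ds$f0 <= DISTRACTOR_F0_RANGE[2]))
})

test_that("deviant cycles swap the designated adjacent notes", {
  ev <- build_sequence(200, deviant_rate = 0.5, seed = 8)
  for (cy in unique(ev$cycle)) {
    tg <- ev[ev$cycle == cy & ev$role == "target", ]
    if (any(tg$is_deviant_member)) {
      expect_equal(tg$note_index, c(1, 3, 2, 4))
      expect_equal(which(tg$is_deviant_member), 2:3)
    } else {
      expect_equal(tg$note_index, 1:4)
    }
  }
})

test_that("deviant rate 0 yields no deviants and rate 1 only deviants", {
  ev0 <- build_sequence(100, deviant_rate = 0, seed = 1)
  expect_false(any(ev0$is_deviant_member))
  ev1 <- build_sequence(100, deviant_rate = 1, seed = 1)
  expect_equal(length(unique(ev1$cycle[ev1$is_deviant_member])), 100)
})

test_that("presses are classified by the (onset, onset + window] rule", {
  ev <- build_sequence(5, deviant_rate = 1, seed = 1)
  on1 <- min(ev$onset[ev$is_deviant_member & ev$cycle == 1])
  expect_equal(score_responses(ev, on1 + 1.4)$presses$class, "hit")
  expect_equal(score_responses(ev, on1 + 1.6)$presses$class, "false_alarm")
  # the onset itself is excluded, the window end included
  expect_equal(score_responses(ev, on1)$presses$class, "false_alarm")
  expect_equal(score_responses(ev, on1 + 1.5)$presses$class, "hit")
  # only the first press in a window is the hit
  res <- score_responses(ev, c(on1 + 0.3, on1 + 0.6))
  expect_equal(res$presses$class, c("hit", "false_alarm"))
})

test_that("overlapping windows resolve earliest-deviant-first", {
  ev <- build_sequence(2, deviant_rate = 1, seed = 3)  # onsets 0.5 and 2.5
  res <- score_responses(ev, 2.6, window = 3)
  expect_equal(res$cycles$outcome, c("hit", "miss"))
})

test_that("scoring conserves cycles and presses and ignores press order", {
  for (s in 1:20) {
    set.seed(s)
    ev <- build_sequence(40, deviant_rate = 0.3, seed = s)
    presses <- sort(stats::runif(stats::rpois(1, 10), 0, max(ev$onset) + 1.5))
    res <- score_responses(ev, presses)
    n_dev <- length(unique(ev$cycle[ev$is_deviant_member]))
    expect_equal(sum(res$cycles$outcome == "hit") +
                   sum(res$cycles$outcome == "miss"), n_dev)
    expect_equal(sum(res$counts$n_hits) +
                   sum(res$presses$class == "false_alarm"), length(presses))
    expect_equal(sum(res$counts$n_cycles), 40)
    expect_equal(sum(res$counts$n_deviants), n_dev)
    expect_equal(sum(res$counts$n_fa),
                 sum(res$presses$class == "false_alarm"))
    shuffled <- score_responses(ev, sample(presses))
    expect_equal(shuffled$counts, res$counts)
  }
})

test_that("three consecutive identical outcomes step the difficulty", {
  res <- adaptive_advance(rep("hit", 9), "increasing")
  expect_equal(res$difficulty, rep(1:3, each = 3))
  # an interrupted run does not advance; the counter restarts
  res2 <- adaptive_advance(c("hit", "hit", "miss", "hit", "hit", "hit"),
                           "increasing")
  expect_equal(res2$transitions$after_outcome, 6)
  expect_equal(res2$final$difficulty, 2L)
  # misses also step, and decreasing blocks start at 20 and move down
  res3 <- adaptive_advance(rep("miss", 6), "decreasing")
  expect_equal(res3$final$difficulty, 18L)
})

test_that("increasing blocks stop after three successive zero-hit levels", {
  res <- adaptive_advance(rep("miss", 9), "increasing")
  expect_equal(res$termination_reason, "no_hits_three_levels")
  expect_length(res$difficulty, 9)
  # a hit inside a level resets the zero-hit streak
  out <- c(rep("miss", 3), "hit", rep("miss", 3), rep("miss", 9))
  res2 <- adaptive_advance(out, "increasing")
  expect_equal(res2$termination_reason, "no_hits_three_levels")
  expect_length(res2$difficulty, 16)
  # decreasing blocks never use the zero-hit rule
  res3 <- adaptive_advance(rep("miss", 60), "decreasing")
  expect_equal(res3$termination_reason, "completed")
})

test_that("a decreasing block terminates only after visiting all 20 levels", {
  res <- adaptive_advance(rep("hit", 61), "decreasing")
  expect_equal(unique(res$difficulty), 20:1)
  expect_equal(res$termination_reason, "completed")
})

test_that("a responsive observer completes a decreasing block", {
  prof <- observer_profile("T", dprime = flat_dprime(4), criterion = 0,
                           lapse_rate = 0)
  blk <- simulate_block(prof, make_intensity_ladder(), "decreasing", seed = 7)
  expect_equal(blk$termination_reason, "completed")
  expect_setequal(blk$counts$difficulty, 1:20)
})

test_that("write_trial_log emits one row per event plus one per press", {
  prof <- observer_profile("T", dprime = flat_dprime(2))
  blk <- simulate_block(prof, make_log_ladder("temporal"), "increasing",
                        seed = 11, events = TRUE)
  path <- tempfile(fileext = ".csv")
  write_trial_log(blk, path, block_id = 3, feature = "temporal",
                  direction = "increasing")
  log <- utils::read.csv(path)
  expect_equal(nrow(log), nrow(blk$events) + nrow(blk$presses))
  expect_true(all(log$outcome[log$role == "press"] %in%
                    c("hit", "false_alarm")))
})
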