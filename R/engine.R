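# Adaptive deviant-detection task: sequence generation, response scoring and
# the three-consecutive-outcomes adaptive rule.

#' Build an interleaved target/distractor tone sequence
#'
#' The four-note target melody repeats in a continuous loop with one distractor
#' tone after every target tone (strict alternation, constant inter-onset
#' interval). Each melody cycle is independently a *deviant* with probability
#' `deviant_rate`: the two designated adjacent target notes (by default notes 2
#' and 3 of the cycle) are swapped in order.
#'
#' @param n_cycles number of four-note melody cycles.
#' @param deviant_rate probability that a cycle is a deviant, in [0, 1].
#' @param ioi inter-onset interval between successive tones, in seconds. The
#'   default 0.25 s makes the 1.5 s response window span six tones.
#' @param difficulty difficulty label (1..20) attached to every event.
#' @param deviant_pair the two adjacent target note indices that swap.
#' @param seed integer RNG seed.
#' @return data frame of tone events with columns `cycle`, `onset`, `role`
#'   (`target`/`distractor`), `note_index`, `f0`, `difficulty`,
#'   `is_deviant_member`.
#' @export
build_sequence <- function(n_cycles, deviant_rate = 0.25, ioi = 0.25,
                           difficulty = 1L, deviant_pair = c(2L, 3L),
                           seed = NULL) {
  stopifnot(deviant_rate >= 0, deviant_rate <= 1, ioi > 0,
            length(deviant_pair) == 2, diff(deviant_pair) == 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  deviant <- stats::runif(n_cycles) < deviant_rate
  ev <- vector("list", n_cycles)
  lo <- log(DISTRACTOR_F0_RANGE)
  for (cy in seq_len(n_cycles)) {
    order4 <- 1:4
    if (deviant[cy]) order4[deviant_pair] <- rev(order4[deviant_pair])
    t0 <- (cy - 1) * 8 * ioi
    ev[[cy]] <- data.frame(
      cycle = cy,
      onset = t0 + (0:7) * ioi,
      role = rep(c("target", "distractor"), 4),
      note_index = as.vector(rbind(order4, NA)),
      f0 = as.vector(rbind(TARGET_F0[order4],
                           exp(stats::runif(4, lo[1], lo[2])))),
      difficulty = difficulty,
      is_deviant_member = FALSE)
    if (deviant[cy]) {
      m <- ev[[cy]]$role == "target" &
        ev[[cy]]$note_index %in% deviant_pair
      ev[[cy]]$is_deviant_member <- m
    }
  }
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

deviant_onsets <- function(events) {
  dev <- events[events$is_deviant_member, c("cycle", "onset")]
  if (nrow(dev) == 0)
    return(data.frame(cycle = integer(), onset = numeric()))
  stats::aggregate(onset ~ cycle, dev, min)
}

#' Score key presses against a tone sequence
#'
#' A press within `window` seconds after a deviant onset (exclusive of the
#' onset itself, inclusive of the window end) is a hit for that deviant; only
#' the first qualifying press counts, any further press in the same window is
#' a false alarm. Deviants with no qualifying press are misses; all remaining
#' presses are false alarms; non-deviant cycles without presses are correct
#' rejections. Overlapping windows are resolved earliest-deviant-first.
#'
#' @param events data frame from [build_sequence()].
#' @param presses numeric vector of press times in seconds, sorted ascending.
#' @param window response window in seconds.
#' @return a `block_result`: list with `events`, `presses` (time, class,
#'   cycle), `cycles` (per-cycle outcome with difficulty label), `counts`
#'   (per-difficulty totals) and `termination_reason`.
#' @export
score_responses <- function(events, presses, window = 1.5) {
  presses <- sort(as.numeric(presses))
  dev <- deviant_onsets(events)
  claimed <- rep(FALSE, length(presses))
  hit_cycle <- rep(NA_integer_, length(presses))
  dev$hit <- FALSE
  for (i in seq_len(nrow(dev))) {     # earliest-deviant-first
    ok <- which(!claimed & presses > dev$onset[i] &
                  presses <= dev$onset[i] + window)
    if (length(ok)) {
      claimed[ok[1]] <- TRUE
      hit_cycle[ok[1]] <- dev$cycle[i]
      dev$hit[i] <- TRUE
    }
  }
  cyc <- unique(events[, c("cycle", "difficulty")])
  cyc$is_deviant <- cyc$cycle %in% dev$cycle
  cycle_start <- stats::aggregate(onset ~ cycle, events, min)
  # assign each press to the cycle whose span contains it (for bookkeeping)
  breaks <- c(cycle_start$onset, Inf)
  press_cycle <- if (length(presses))
    findInterval(presses, breaks) else integer()
  press_class <- ifelse(claimed, "hit", "false_alarm")
  cyc$outcome <- ifelse(cyc$is_deviant,
                        ifelse(cyc$cycle %in% dev$cycle[dev$hit], "hit", "miss"),
                        ifelse(cyc$cycle %in% press_cycle[!claimed],
                               "false_alarm", "correct_rejection"))
  counts <- do.call(rbind, lapply(split(cyc, cyc$difficulty), function(d) {
    fa <- sum(press_class == "false_alarm" &
                press_cycle %in% d$cycle)
    data.frame(difficulty = d$difficulty[1],
               n_cycles = nrow(d),
               n_deviants = sum(d$is_deviant),
               n_hits = sum(d$outcome == "hit"),
               n_fa = fa)
  }))
  rownames(counts) <- NULL
  structure(list(events = events,
                 presses = data.frame(time = presses, class = press_class,
                                      cycle = press_cycle),
                 cycles = cyc,
                 counts = counts[order(counts$difficulty), , drop = FALSE],
                 termination_reason = NA_character_),
            class = "block_result")
}

# Shared stepping rule: three consecutive identical deviant outcomes move the
# difficulty one step in the block's direction and reset the counter.
# Increasing blocks additionally terminate after three successive difficulty
# levels with zero hits.
advance_init <- function(direction = c("increasing", "decreasing"),
                         n_levels = 20L) {
  direction <- match.arg(direction)
  list(direction = direction, n_levels = n_levels,
       difficulty = if (direction == "increasing") 1L else n_levels,
       run_type = NA_character_, run_len = 0L,
       level_hits = 0L, zero_hit_run = 0L,
       done = FALSE, termination_reason = NA_character_)
}

advance_step <- function(state, outcome) {
  stopifnot(!state$done, outcome %in% c("hit", "miss"))
  if (outcome == "hit") state$level_hits <- state$level_hits + 1L
  if (identical(outcome, state$run_type)) {
    state$run_len <- state$run_len + 1L
  } else {
    state$run_type <- outcome
    state$run_len <- 1L
  }
  if (state$run_len == 3L) {
    # leaving the current level: track the zero-hit streak (increasing blocks)
    state$zero_hit_run <- if (state$level_hits == 0L)
      state$zero_hit_run + 1L else 0L
    if (state$direction == "increasing" && state$zero_hit_run >= 3L) {
      state$done <- TRUE
      state$termination_reason <- "no_hits_three_levels"
      return(state)
    }
    step <- if (state$direction == "increasing") 1L else -1L
    nxt <- state$difficulty + step
    if (nxt < 1L || nxt > state$n_levels) {
      state$done <- TRUE
      state$termination_reason <- "completed"
    } else {
      state$difficulty <- nxt
    }
    state$run_type <- NA_character_
    state$run_len <- 0L
    state$level_hits <- 0L
  }
  state
}

#' Trace the adaptive rule over a stream of deviant outcomes
#'
#' Movement between degrees of difficulty is unidirectional: three consecutive
#' hits *or* three consecutive misses (on deviant cycles) trigger a one-step
#' move in the block's direction. Increasing blocks terminate when three
#' successive difficulty levels elicit zero hits (the study's "manual
#' termination" rule, automated); either direction terminates on stepping past
#' its final level.
#'
#' @param outcomes character vector of `"hit"`/`"miss"` per deviant cycle.
#' @param direction `"increasing"` or `"decreasing"`.
#' @param n_levels number of difficulty levels.
#' @return list with `difficulty` (level in force at each outcome),
#'   `transitions` (data frame `after_outcome`, `from`, `to`),
#'   `termination_reason` (`NA` if the stream ended first) and `final` state.
#' @export
adaptive_advance <- function(outcomes, direction = c("increasing", "decreasing"),
                             n_levels = 20L) {
  state <- advance_init(match.arg(direction), n_levels)
  difficulty <- integer(length(outcomes))
  trans <- list()
  for (i in seq_along(outcomes)) {
    difficulty[i] <- state$difficulty
    prev <- state$difficulty
    state <- advance_step(state, outcomes[i])
    if (state$done || state$difficulty != prev)
      trans[[length(trans) + 1]] <- data.frame(after_outcome = i, from = prev,
                                               to = state$difficulty)
    if (state$done) {
      difficulty <- difficulty[seq_len(i)]
      break
    }
  }
  list(difficulty = difficulty,
       transitions = if (length(trans)) do.call(rbind, trans)
         else data.frame(after_outcome = integer(), from = integer(),
                         to = integer()),
       termination_reason = state$termination_reason,
       final = state)
}

#' Write a block result as a trial-log CSV
#'
#' One row per tone event, plus one row per key press (press rows carry
#' `press_time_s` and the press classification in `outcome`).
#'
#' @param block a `block_result` with events (from [score_responses()] or
#'   [simulate_block()] with `events = TRUE`).
#' @param path output CSV path.
#' @param block_id,feature,direction identifiers recorded on every row.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(block, path, block_id = 1L, feature = NA,
                            direction = NA) {
  stopifnot(inherits(block, "block_result"), !is.null(block$events))
  ev <- block$events
  cyc_out <- block$cycles$outcome[match(ev$cycle, block$cycles$cycle)]
  rows_ev <- data.frame(block_id = block_id, feature = feature,
                        direction = direction, event_onset_s = ev$onset,
                        role = ev$role, difficulty = ev$difficulty,
                        is_deviant = ev$is_deviant_member,
                        press_time_s = NA_real_, outcome = cyc_out)
  pr <- block$presses
  rows_pr <- if (nrow(pr)) data.frame(block_id = block_id, feature = feature,
                                      direction = direction,
                                      event_onset_s = NA_real_, role = "press",
                                      difficulty = block$cycles$difficulty[
                                        match(pr$cycle, block$cycles$cycle)],
                                      is_deviant = NA, press_time_s = pr$time,
                                      outcome = pr$class)
  else NULL
  out <- rbind(rows_ev, rows_pr)
  out <- out[order(ifelse(is.na(out$event_onset_s), out$press_time_s,
                          out$event_onset_s)), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
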