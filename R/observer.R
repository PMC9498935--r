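# Synthetic observers with known ground truth for both experiments.
#
# Generative model: equal-variance Gaussian yes/no signal detection with a
# symmetric criterion. On a deviant cycle the observer presses with probability
# (1 - lapse) * Phi(d'/2 - c); on a non-deviant cycle a false alarm occurs with
# probability Phi(-d'/2 - c). True sensitivity is linear in the stimulus's
# perceptual dissimilarity from the target, plus participant covariates.

#' Perceptual latent space
#'
#' Three monotone axis maps from physical feature values to perceptual
#' coordinates: linear for intensity, logarithmic for spectral and temporal
#' envelope. Coordinates are expressed in common dissimilarity units in which
#' the full Experiment-1 ladders span `spans[f]` units, zero at the target
#' value. The default spans keep the field-reported 4:2:1
#' (spectral:intensity:temporal) ratio and are normalized (see
#' [dissim_spans()]) so that the pipeline's procrustes-aligned MDS solution
#' recovers dissimilarities on the same scale.
#'
#' @param spans named numeric, dissimilarity units spanned by each full ladder.
#' @return object of class `latent_space`.
#' @export
latent_space <- function(spans = dissim_spans()) {
  stopifnot(all(FEATURES %in% names(spans)))
  structure(list(spans = spans[FEATURES]), class = "latent_space")
}

#' Axis transform of physical feature values
#'
#' Identity for intensity, natural log for spectral and temporal envelope: the
#' monotone maps under which the perceptual axes are modelled as linear.
#' @param feature feature name.
#' @param values physical values.
#' @export
feature_transform <- function(feature, values) {
  switch(feature,
         intensity = values,
         spectral = log(values),
         temporal = log(values),
         stop("unknown feature: ", feature))
}

#' Transformed width of a full Experiment-1 ladder
#' @param feature feature name.
#' @export
transform_range <- function(feature) {
  switch(feature,
         intensity = 38,
         spectral = log(25 / 3),
         temporal = log(160 / 60))
}

#' Default ladder spans on the common dissimilarity scale
#'
#' Closed-form calibration of the latent-space axis scales. The three full
#' Experiment-1 ladders are assigned dissimilarity spans in the ratio
#' spectral : intensity : temporal = 4 : 2 : 1, and the overall magnitude is
#' fixed by requiring that the optimal uniform procrustes scale between the
#' ideal 15-stimulus latent configuration and the unit-norm standardized
#' physical reference equals one, so that generated and pipeline-recovered
#' dissimilarities share a scale. With the study's level values this gives
#' spans of about 1.31 (intensity), 2.63 (spectral) and 0.66 (temporal).
#'
#' @param ratio named span ratios.
#' @return named numeric vector of spans.
#' @export
dissim_spans <- function(ratio = c(intensity = 2, spectral = 4, temporal = 1)) {
  lv <- make_exp2_levels()
  u0 <- vapply(FEATURES, function(f) {
    v <- if (f == "spectral") spectral_total_slope(lv[[f]]) else lv[[f]]
    t <- feature_transform(f, v)
    sd15 <- sqrt(3 * sum((t - mean(t))^2) / 14)  # each level occurs 3x
    ratio[f] * sd15 / transform_range(f)
  }, numeric(1))
  # z-scored reference has total sum of squares 3 * 14 = 42 before unit-norm
  a <- sum(u0) / (sqrt(42) * sum(u0^2))
  a * ratio[FEATURES]
}

#' Latent coordinate of physical values on one axis
#'
#' Signed perceptual coordinate (dissimilarity units, 0 at the target value).
#'
#' @param space a [latent_space()].
#' @param feature feature name.
#' @param values physical values (intensity: phons attenuation; spectral:
#'   absolute dB/harmonic; temporal: FDHM ms).
#' @export
latent_coord <- function(space, feature, values) {
  t <- feature_transform(feature, values)
  t0 <- feature_transform(feature, TARGET_VALUES[[feature]])
  unname(space$spans[feature]) * (t - t0) / transform_range(feature)
}

#' True dissimilarity of ladder values from the target
#' @inheritParams latent_coord
#' @export
true_dissimilarity <- function(space, feature, values) {
  abs(latent_coord(space, feature, values))
}

#' Latent 3-D coordinates of the 15 stimuli
#' @param space a [latent_space()].
#' @param set15 a `stimulus_set15`.
#' @return 15 x 3 matrix (columns intensity, spectral, temporal).
#' @export
latent_coords15 <- function(space, set15) {
  phys <- stimulus_physical(set15)
  vapply(FEATURES, function(f) latent_coord(space, f, phys[, f]),
         numeric(nrow(phys)))
}

#' Construct a simulated observer
#'
#' @param id participant identifier.
#' @param age_group `"younger"` or `"older"`.
#' @param msi Gold-MSI musical-training subscale score, in [7, 49].
#' @param pta pure-tone average of the better ear, dB HL.
#' @param dprime named list of per-feature numeric vectors of length 20 giving
#'   true d' at each degree of difficulty (non-increasing in difficulty).
#' @param criterion SDT criterion c in z units (positive = conservative).
#' @param lapse_rate probability of missing a detected deviant, in [0, 0.1]
#'   (a value of 1 is additionally allowed to model a fully unresponsive
#'   observer in degenerate-case tests).
#' @param rating_gain slider units per dissimilarity unit (Experiment 2).
#' @param rating_noise_sd rating noise SD in slider units.
#' @return object of class `observer_profile`.
#' @export
observer_profile <- function(id, age_group = "younger", msi = 28, pta = 5,
                             dprime, criterion = 0.5, lapse_rate = 0.02,
                             rating_gain = 150, rating_noise_sd = 6) {
  stopifnot(age_group %in% c("younger", "older"),
            msi >= 7, msi <= 49,
            lapse_rate >= 0, lapse_rate <= 0.1 || lapse_rate == 1)
  stopifnot(all(FEATURES %in% names(dprime)))
  for (f in FEATURES) {
    stopifnot(length(dprime[[f]]) == 20)
    if (any(diff(dprime[[f]]) > 1e-8))
      stop("true d' must be non-increasing in difficulty (", f, ")")
  }
  structure(list(id = id, age_group = age_group, msi = msi, pta = pta,
                 dprime = dprime, criterion = criterion,
                 lapse_rate = lapse_rate, rating_gain = rating_gain,
                 rating_noise_sd = rating_noise_sd),
            class = "observer_profile")
}

#' Simulate one adaptive block for an observer
#'
#' Per melody cycle, a deviant occurs with probability `deviant_rate`; the
#' observer's hit/false-alarm behaviour follows the equal-variance SDT model at
#' the current degree of difficulty, and hit/miss outcomes drive the adaptive
#' rule (see [adaptive_advance()]). With `events = TRUE`, a full tone-event
#' sequence with press times is materialized and scored through
#' [score_responses()]; the per-cycle RNG stream is identical in both modes, so
#' counts do not depend on `events`.
#'
#' @param profile an [observer_profile()].
#' @param ladder a `difficulty_ladder` identifying the manipulated feature.
#' @param direction `"increasing"` or `"decreasing"` difficulty.
#' @param seed integer RNG seed.
#' @param deviant_rate probability a cycle is a deviant.
#' @param ioi inter-onset interval in seconds; the response window is six
#'   tones, i.e. `6 * ioi` seconds.
#' @param events materialize tone events and presses (slower).
#' @param max_cycles safety bound on block length.
#' @return a `block_result` with per-difficulty `counts`, `termination_reason`,
#'   and (if `events`) the scored event/press tables.
#' @export
simulate_block <- function(profile, ladder, direction = "increasing", seed = 1,
                           deviant_rate = 0.25, ioi = 0.25, events = FALSE,
                           max_cycles = 5000L) {
  stopifnot(inherits(profile, "observer_profile"),
            inherits(ladder, "difficulty_ladder"))
  feature <- ladder$feature
  dp <- profile$dprime[[feature]]
  cc <- profile$criterion
  lapse <- profile$lapse_rate
  set.seed(as.integer(seed))
  state <- advance_init(direction)
  difficulty <- integer(max_cycles)
  is_dev <- logical(max_cycles)
  responded <- logical(max_cycles)
  u_press <- numeric(max_cycles)
  ncy <- 0L
  while (!state$done && ncy < max_cycles) {
    ncy <- ncy + 1L
    u <- stats::runif(3)      # deviant, outcome, press-time draws
    k <- state$difficulty
    difficulty[ncy] <- k
    u_press[ncy] <- u[3]
    if (u[1] < deviant_rate) {
      is_dev[ncy] <- TRUE
      hit <- u[2] < (1 - lapse) * stats::pnorm(dp[k] / 2 - cc)
      responded[ncy] <- hit
      state <- advance_step(state, if (hit) "hit" else "miss")
    } else {
      responded[ncy] <- u[2] < stats::pnorm(-dp[k] / 2 - cc)
    }
  }
  if (!state$done) state$termination_reason <- "max_cycles"
  difficulty <- difficulty[seq_len(ncy)]
  is_dev <- is_dev[seq_len(ncy)]
  responded <- responded[seq_len(ncy)]
  u_press <- u_press[seq_len(ncy)]

  counts <- data.frame(difficulty = sort(unique(difficulty)))
  counts$n_cycles <- as.integer(table(factor(difficulty,
                                             counts$difficulty)))
  tab <- function(x) as.integer(tapply(x, factor(difficulty,
                                                 counts$difficulty), sum))
  counts$n_deviants <- tab(is_dev)
  counts$n_hits <- tab(is_dev & responded)
  counts$n_fa <- tab(!is_dev & responded)

  res <- list(feature = feature, direction = direction, counts = counts,
              termination_reason = state$termination_reason,
              n_cycles = ncy)
  if (events) {
    seq_ev <- cycles_to_events(is_dev, difficulty, ioi, seed = seed + 1L)
    window <- 6 * ioi
    cyc_start <- (seq_along(difficulty) - 1) * 8 * ioi
    press <- numeric(0)
    hit_cy <- which(is_dev & responded)
    press <- c(press, cyc_start[hit_cy] + 2 * ioi +
                 window * (0.1 + 0.85 * u_press[hit_cy]))
    fa_cy <- which(!is_dev & responded)
    press <- c(press, cyc_start[fa_cy] +
                 8 * ioi * (0.05 + 0.9 * u_press[fa_cy]))
    scored <- score_responses(seq_ev, press, window = window)
    scored$termination_reason <- state$termination_reason
    res[c("events", "presses", "cycles")] <-
      scored[c("events", "presses", "cycles")]
    res$scored_counts <- scored$counts
  }
  structure(res, class = "block_result")
}

# Materialize tone events for given per-cycle deviant flags and difficulties.
# Distractor F0s are drawn in a separate RNG phase so that outcome streams are
# independent of whether events are materialized.
cycles_to_events <- function(deviant, difficulty, ioi = 0.25,
                             deviant_pair = c(2L, 3L), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(deviant)
  lo <- log(DISTRACTOR_F0_RANGE)
  order4 <- matrix(rep(1:4, n), nrow = n, byrow = TRUE)
  order4[deviant, deviant_pair] <- order4[deviant, rev(deviant_pair)]
  tgt_idx <- as.vector(t(order4))
  ev <- data.frame(
    cycle = rep(seq_len(n), each = 8),
    onset = rep((seq_len(n) - 1) * 8 * ioi, each = 8) + (0:7) * ioi,
    role = rep(c("target", "distractor"), 4 * n),
    note_index = as.vector(rbind(tgt_idx, NA)),
    f0 = as.vector(rbind(TARGET_F0[tgt_idx],
                         exp(stats::runif(4 * n, lo[1], lo[2])))),
    difficulty = rep(difficulty, each = 8))
  ev$is_deviant_member <- ev$role == "target" &
    rep(deviant, each = 8) & ev$note_index %in% deviant_pair
  ev
}

rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

# Table-1 style demographic cells: (MSI mean, MSI sd, PTA mean, PTA sd).
COHORT_CELLS <- list(
  younger_musician    = list(age = "younger", msi = c(38.9, 7.0), msi_rng = c(25, 49), pta = c(1.5, 2.5)),
  younger_nonmusician = list(age = "younger", msi = c(12.9, 5.5), msi_rng = c(7, 25),  pta = c(4.9, 6.7)),
  older_musician      = list(age = "older",   msi = c(35.9, 4.4), msi_rng = c(25, 49), pta = c(14.0, 9.9)),
  older_nonmusician   = list(age = "older",   msi = c(14.8, 6.7), msi_rng = c(7, 25),  pta = c(15.7, 7.8)))

#' Default effect specification for the synthetic cohort
#'
#' `msi_slope`: d' units per Gold-MSI unit (study-reported coefficients are
#' 0.03-0.06); `age_offsets`: additive d' offset for the older group, per
#' feature; `pta_slope`: d' units per dB HL; `beta_dissim`: d' units per
#' common-scale dissimilarity unit; `intercept_sd`: SD of the participant
#' random intercept in d' units.
#' @export
effect_spec <- function(msi_slope = 0.03,
                        age_offsets = c(intensity = 0, spectral = 0,
                                        temporal = 0),
                        pta_slope = 0, beta_dissim = 1.33,
                        intercept_sd = 0.1) {
  list(msi_slope = msi_slope, age_offsets = age_offsets,
       pta_slope = pta_slope, beta_dissim = beta_dissim,
       intercept_sd = intercept_sd)
}

#' True d' map for a participant
#'
#' d'(feature, difficulty) = beta_dissim * dissimilarity(feature, difficulty)
#' + msi_slope * (msi - 28) + age_offset(feature) + pta_slope * (pta - 10)
#' + participant intercept. MSI is centred at the scale midpoint 28 and PTA at
#' 10 dB HL.
#'
#' @param msi,pta,age_group,intercept participant covariates.
#' @param spec an [effect_spec()].
#' @param ladders list of the three ladders.
#' @param space a [latent_space()].
#' @return named list of numeric vectors of length 20.
#' @export
true_dprime_map <- function(msi, pta, age_group, intercept = 0,
                            spec = effect_spec(), ladders = make_ladders(),
                            space = latent_space()) {
  out <- lapply(FEATURES, function(f) {
    d <- spec$beta_dissim * true_dissimilarity(space, f, ladders[[f]]$values)
    d + spec$msi_slope * (msi - 28) +
      (age_group == "older") * spec$age_offsets[[f]] +
      spec$pta_slope * (pta - 10) + intercept
  })
  names(out) <- FEATURES
  out
}

#' Simulate a full Experiment-1 cohort
#'
#' Draws a demographically structured cohort (2 age groups x musician /
#' non-musician, Gold-MSI and PTA drawn from truncated normals matching the
#' study's demographic table) and runs all six adaptive blocks (3 features x
#' increasing/decreasing) per participant. All randomness derives from `seed`
#' through fixed per-participant, per-block substreams.
#'
#' @param seed cohort-level integer seed.
#' @param n_per_cell named integer vector of cell sizes (defaults to the
#'   study's 14/14/12/13).
#' @param spec an [effect_spec()].
#' @param criterion,lapse SDT parameters shared by all observers.
#' @param events materialize tone events (slow; off by default).
#' @param ladders,space design objects.
#' @return list with `profiles` (data frame), `blocks` (per-participant list of
#'   six `block_result`s), and the generating `spec`, `ladders`, `space`.
#' @export
simulate_cohort <- function(seed,
                            n_per_cell = c(younger_musician = 14,
                                           younger_nonmusician = 14,
                                           older_musician = 12,
                                           older_nonmusician = 13),
                            spec = effect_spec(), criterion = 0.5,
                            lapse = 0.02, events = FALSE,
                            ladders = make_ladders(),
                            space = latent_space()) {
  stopifnot(all(names(n_per_cell) %in% names(COHORT_CELLS)),
            all(n_per_cell >= 1))
  set.seed(as.integer(seed))
  profs <- list()
  for (cell in names(n_per_cell)) {
    p <- COHORT_CELLS[[cell]]
    n <- n_per_cell[[cell]]
    profs[[cell]] <- data.frame(
      cell = cell, age_group = p$age,
      msi = pmin(49, pmax(7, rtruncnorm1(n, p$msi[1], p$msi[2],
                                         p$msi_rng[1], p$msi_rng[2]))),
      pta = rtruncnorm1(n, p$pta[1], p$pta[2], lower = -10),
      intercept = stats::rnorm(n, 0, spec$intercept_sd))
  }
  profiles <- do.call(rbind, profs)
  profiles$participant <- sprintf("P%02d", seq_len(nrow(profiles)))
  rownames(profiles) <- NULL

  blocks <- vector("list", nrow(profiles))
  names(blocks) <- profiles$participant
  for (i in seq_len(nrow(profiles))) {
    dp <- true_dprime_map(profiles$msi[i], profiles$pta[i],
                          profiles$age_group[i], profiles$intercept[i],
                          spec, ladders, space)
    prof <- observer_profile(profiles$participant[i], profiles$age_group[i],
                             profiles$msi[i], max(profiles$pta[i], 0),
                             dprime = dp, criterion = criterion,
                             lapse_rate = lapse)
    blk <- list()
    b <- 0L
    for (f in FEATURES) for (dir in c("increasing", "decreasing")) {
      b <- b + 1L
      sub_seed <- (as.double(seed) + 104729 * i + 7919 * b) %% 2147483647
      blk[[paste(f, dir, sep = "_")]] <-
        simulate_block(prof, ladders[[f]], dir, seed = sub_seed,
                       events = events)
    }
    blocks[[i]] <- blk
  }
  list(profiles = profiles, blocks = blocks, spec = spec,
       ladders = ladders, space = space, seed = seed)
}

#' Simulate pairwise dissimilarity ratings for one observer
#'
#' For each of the 105 unordered pairs of the 15-stimulus set, the rating is
#' `clamp(round(gain * distance + noise), 0, 128)` where `distance` is the
#' Euclidean distance between the stimuli in the observer's latent space.
#' Ratings are dissimilarity-coded: identical stimuli rate 0.
#'
#' @param profile an [observer_profile()] (uses `rating_gain`,
#'   `rating_noise_sd`).
#' @param set15 a `stimulus_set15`.
#' @param space a [latent_space()].
#' @param seed integer RNG seed.
#' @return data frame with columns `participant`, `i`, `j`, `rating`
#'   (105 rows).
#' @export
simulate_ratings <- function(profile, set15, space = latent_space(),
                             seed = 1) {
  set.seed(as.integer(seed))
  xyz <- latent_coords15(space, set15)
  d <- as.matrix(stats::dist(xyz))
  pr <- utils::combn(15, 2)
  dd <- d[cbind(pr[1, ], pr[2, ])]
  noise <- stats::rnorm(length(dd), 0, profile$rating_noise_sd)
  rating <- pmin(128, pmax(0, round(profile$rating_gain * dd + noise)))
  data.frame(participant = profile$id, i = pr[1, ], j = pr[2, ],
             rating = rating)
}

#' Simulate an Experiment-2 rating cohort
#'
#' @param seed cohort seed.
#' @param n_younger,n_older group sizes (study: 6 and 6).
#' @param set15 a `stimulus_set15`.
#' @param space a [latent_space()].
#' @param rating_noise_sd rating noise SD in slider units.
#' @param gain_mean,gain_sd distribution of the per-participant slider gain.
#' @return list with `profiles`, `ratings` (per-participant list of rating
#'   tables), `set15`, `space`.
#' @export
simulate_exp2_cohort <- function(seed, n_younger = 6, n_older = 6,
                                 set15 = make_stimulus_set(seed),
                                 space = latent_space(), rating_noise_sd = 6,
                                 gain_mean = 150, gain_sd = 20) {
  force(set15)  # evaluate (and consume any RNG use) before reseeding
  set.seed(as.integer(seed))
  n <- n_younger + n_older
  age <- rep(c("younger", "older"), c(n_younger, n_older))
  gain <- rtruncnorm1(n, gain_mean, gain_sd, lower = 40)
  flat <- stats::setNames(rep(list(rep(0, 20)), 3), FEATURES)
  ratings <- vector("list", n)
  ids <- sprintf("R%02d", seq_len(n))
  for (i in seq_len(n)) {
    prof <- observer_profile(ids[i], age[i], dprime = flat,
                             rating_gain = gain[i],
                             rating_noise_sd = rating_noise_sd)
    sub_seed <- (as.double(seed) + 15485863 * i) %% 2147483647
    ratings[[i]] <- simulate_ratings(prof, set15, space, seed = sub_seed)
  }
  names(ratings) <- ids
  list(profiles = data.frame(participant = ids, age_group = age,
                             rating_gain = gain,
                             rating_noise_sd = rating_noise_sd),
       ratings = ratings, set15 = set15, space = space, seed = seed)
}
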