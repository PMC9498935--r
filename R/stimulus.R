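# Stimulus construction: difficulty ladders, the 15-stimulus factorial set,
# and harmonic-complex tone synthesis.

#' Feature names used throughout the package
#'
#' The three acoustic features manipulated in the streaming task: overall
#' intensity (phons of attenuation), spectral envelope (dB of attenuation per
#' successive harmonic) and temporal envelope (full duration at half maximum,
#' FDHM, in ms).
#' @export
FEATURES <- c("intensity", "spectral", "temporal")

#' Target-tone physical values
#'
#' 0 phons attenuation, 3 dB/harmonic spectral slope, 160 ms FDHM.
#' @export
TARGET_VALUES <- c(intensity = 0, spectral = 3, temporal = 160)

#' Target melody fundamental frequencies
#'
#' Equal temperament (A4 = 440 Hz): G4, C5, A5, D5.
#' @export
TARGET_F0 <- c(392.00, 523.25, 880.00, 587.33)

#' Distractor fundamental-frequency range
#'
#' The octave F4 to E5; distractor F0s are drawn log-uniformly inside it.
#' @export
DISTRACTOR_F0_RANGE <- c(349.23, 659.26)

#' Specify a harmonic-complex tone
#'
#' A tone is a sum of `n_harmonics` partials at integer multiples of `f0`,
#' successively attenuated by `spectral_slope` dB, shaped by a raised-cosine
#' onset/offset envelope. The temporal envelope is parameterized by its full
#' duration at half maximum (FDHM); with the raised-cosine segments, FDHM =
#' onset/2 + sustain + offset/2, so the sustain portion is derived from the
#' requested FDHM.
#'
#' @param f0 fundamental frequency in Hz.
#' @param n_harmonics number of harmonics (10 for all study stimuli).
#' @param spectral_slope attenuation per successive harmonic in dB, in [3, 25].
#' @param fdhm full duration at half maximum in ms, in [60, 160].
#' @param onset_ms,offset_ms raised-cosine ramp durations in ms.
#' @param attenuation nominal level reduction in phons (applied as dB).
#' @return an object of class `tone_spec`.
#' @export
tone_spec <- function(f0, n_harmonics = 10, spectral_slope = 3, fdhm = 160,
                      onset_ms = 30, offset_ms = 10, attenuation = 0) {
  stopifnot(f0 > 0, n_harmonics >= 1, attenuation >= 0)
  if (fdhm < 60 || fdhm > 160) stop("fdhm must lie in [60, 160] ms")
  if (spectral_slope < 0 || spectral_slope > 25)
    stop("spectral_slope must lie in [0, 25] dB per harmonic")
  sustain_ms <- fdhm - onset_ms / 2 - offset_ms / 2
  if (sustain_ms < 0) stop("fdhm too short for the requested ramps")
  structure(list(f0 = f0, n_harmonics = n_harmonics,
                 spectral_slope = spectral_slope, fdhm = fdhm,
                 onset_ms = onset_ms, sustain_ms = sustain_ms,
                 offset_ms = offset_ms, attenuation = attenuation),
            class = "tone_spec")
}

new_ladder <- function(feature, values, units) {
  stopifnot(length(values) == 20)
  structure(list(feature = feature, values = values, units = units),
            class = "difficulty_ladder")
}

#' @export
print.difficulty_ladder <- function(x, ...) {
  cat("Difficulty ladder (", x$feature, "), 20 levels in ", x$units, ":\n",
      sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' Intensity difficulty ladder
#'
#' Twenty degrees of difficulty in steps of 2 phons of attenuation, from
#' 38 phons (difficulty 1, easy segregation) to 0 phons (difficulty 20,
#' identical to the target level).
#'
#' @return a `difficulty_ladder` with `$values[k]` the attenuation in phons at
#'   difficulty `k`.
#' @export
make_intensity_ladder <- function() {
  new_ladder("intensity", seq(38, 0, by = -2), "phons attenuation")
}

#' Logarithmically spaced difficulty ladders
#'
#' Spectral envelope: 20 log-spaced attenuation slopes from 25 dB/harmonic
#' (difficulty 1) down to 3 dB/harmonic (difficulty 20, the target). Temporal
#' envelope: 20 log-spaced FDHM values from 60 ms (difficulty 1) up to 160 ms
#' (difficulty 20, the target).
#'
#' @param feature `"spectral"` or `"temporal"`.
#' @return a `difficulty_ladder`.
#' @export
make_log_ladder <- function(feature = c("spectral", "temporal")) {
  feature <- match.arg(feature)
  ends <- switch(feature,
                 spectral = c(hard = 25, target = 3),
                 temporal = c(hard = 60, target = 160))
  k <- 0:19
  values <- unname(ends["hard"] * (ends["target"] / ends["hard"])^(k / 19))
  units <- if (feature == "spectral") "dB per harmonic" else "ms FDHM"
  new_ladder(feature, values, units)
}

#' All three Experiment-1 ladders
#' @return named list of `difficulty_ladder` objects.
#' @export
make_ladders <- function() {
  list(intensity = make_intensity_ladder(),
       spectral  = make_log_ladder("spectral"),
       temporal  = make_log_ladder("temporal"))
}

#' Experiment-2 feature levels
#'
#' Five levels per feature, spanning the easy (near-target) half of each
#' feature's range. Intensity: 8, 6, 4, 2, 0 phons of attenuation. Spectral
#' envelope: 1.69, 1.19, 0.75, 0.35, 0 dB of attenuation per harmonic *in
#' addition to* the target's 3 dB slope (use [spectral_total_slope()] to obtain
#' absolute slopes). Temporal envelope: five log-spaced FDHM values from 100 to
#' 160 ms, rounded to the nearest ms (100, 112, 126, 142, 160). Level 5 equals
#' the target value for every feature.
#'
#' @return named list of numeric vectors of length 5 (level index 1..5).
#' @export
make_exp2_levels <- function() {
  fdhm <- round(100 * (160 / 100)^((0:4) / 4))
  list(intensity = c(8, 6, 4, 2, 0),
       spectral  = c(1.69, 1.19, 0.75, 0.35, 0),
       temporal  = fdhm)
}

#' Absolute spectral slope of an Experiment-2 level
#'
#' Experiment-2 spectral levels are expressed as attenuation added on top of
#' the 3 dB/harmonic target slope; this helper returns the absolute slope used
#' in synthesis and in the perceptual maps.
#'
#' @param level extra attenuation in dB per harmonic.
#' @return absolute attenuation per harmonic in dB.
#' @export
spectral_total_slope <- function(level) 3 + level

#' The 15-stimulus factorial set
#'
#' Builds the Experiment-2 stimulus set: three consecutive random permutation
#' blocks of the five levels for each feature, resampled (bounded retries)
#' until all 15 (intensity, spectral, temporal) level triples are distinct.
#' Each level index therefore occurs exactly three times per feature.
#'
#' @param seed integer seed for reproducibility.
#' @param max_tries retry bound for the distinctness rejection step.
#' @return a data frame of class `stimulus_set15` with columns `stimulus`,
#'   `intensity_level`, `spectral_level`, `temporal_level` (indices 1..5) and
#'   attribute `level_values` (from [make_exp2_levels()]).
#' @export
make_stimulus_set <- function(seed, max_tries = 1000L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  for (i in seq_len(max_tries)) {
    idx <- vapply(FEATURES, function(f) c(sample(5L), sample(5L), sample(5L)),
                  integer(15))
    if (!anyDuplicated(as.data.frame(idx))) {
      out <- data.frame(stimulus = 1:15,
                        intensity_level = idx[, "intensity"],
                        spectral_level = idx[, "spectral"],
                        temporal_level = idx[, "temporal"])
      attr(out, "level_values") <- make_exp2_levels()
      class(out) <- c("stimulus_set15", "data.frame")
      return(out)
    }
  }
  stop("could not build 15 distinct stimuli in ", max_tries,
       " tries; check the RNG state")  # practically unreachable
}

#' Physical values of the 15 stimuli
#'
#' @param set15 a `stimulus_set15`.
#' @return 15 x 3 matrix with columns `intensity` (phons attenuation),
#'   `spectral` (absolute dB/harmonic slope) and `temporal` (FDHM ms).
#' @export
stimulus_physical <- function(set15) {
  lv <- attr(set15, "level_values")
  cbind(intensity = lv$intensity[set15$intensity_level],
        spectral  = spectral_total_slope(lv$spectral[set15$spectral_level]),
        temporal  = lv$temporal[set15$temporal_level])
}

#' Synthesize a harmonic-complex tone
#'
#' Sum of `n_harmonics` sinusoids at multiples of `f0`, harmonic k attenuated
#' by (k-1) x `spectral_slope` dB, shaped by the raised-cosine onset/offset
#' envelope, normalized so the envelope peak equals the (attenuated) peak
#' amplitude. Phon attenuation is applied as an equal dB amplitude reduction
#' (nominal 1 phon = 1 dB mapping; the pipeline operates on nominal levels).
#'
#' @param spec a [tone_spec()].
#' @param sample_rate sampling rate in Hz; must be at least 4x the highest
#'   harmonic frequency unless `aliasing = "drop"`.
#' @param aliasing `"error"` rejects harmonics above Nyquist, `"drop"` silently
#'   removes them.
#' @return numeric vector of amplitude samples, with attributes `sample_rate`
#'   and `envelope`.
#' @export
synthesize_tone <- function(spec, sample_rate = 44100,
                            aliasing = c("error", "drop")) {
  aliasing <- match.arg(aliasing)
  stopifnot(inherits(spec, "tone_spec"))
  f_top <- spec$f0 * spec$n_harmonics
  harmonics <- seq_len(spec$n_harmonics)
  if (sample_rate < 4 * f_top) {
    if (aliasing == "error")
      stop("sample_rate must be >= 4x the highest harmonic (",
           4 * f_top, " Hz)")
    harmonics <- harmonics[harmonics * spec$f0 < sample_rate / 2]
  }
  dur_s <- (spec$onset_ms + spec$sustain_ms + spec$offset_ms) / 1000
  n <- round(dur_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  on_n <- round(spec$onset_ms / 1000 * sample_rate)
  off_n <- round(spec$offset_ms / 1000 * sample_rate)
  env <- rep(1, n)
  if (on_n > 0) env[1:on_n] <- 0.5 * (1 - cos(pi * (0:(on_n - 1)) / on_n))
  if (off_n > 0)
    env[(n - off_n + 1):n] <- 0.5 * (1 + cos(pi * (1:off_n) / off_n))
  amps <- 10^(-(harmonics - 1) * spec$spectral_slope / 20)
  wave <- rowSums(vapply(seq_along(harmonics), function(i) {
    amps[i] * sin(2 * pi * harmonics[i] * spec$f0 * t)
  }, numeric(n)))
  gain <- 10^(-spec$attenuation / 20) / sum(amps)
  wave <- gain * wave * env
  structure(wave, sample_rate = sample_rate, envelope = env * gain * sum(amps))
}

#' Measure the FDHM of a synthesized tone
#'
#' Recovers the amplitude envelope by demodulating the fundamental (complex
#' mixing at `f0` followed by a one-period moving average, which nulls all
#' other harmonics exactly) and returns the full duration at half of the
#' envelope maximum, with linear interpolation at the crossings.
#'
#' @param wave output of [synthesize_tone()].
#' @param f0 fundamental frequency in Hz.
#' @param sample_rate sampling rate in Hz (defaults to the wave's attribute).
#' @return FDHM in ms.
#' @export
measure_fdhm <- function(wave, f0, sample_rate = attr(wave, "sample_rate")) {
  n <- length(wave)
  t <- (seq_len(n) - 1) / sample_rate
  w <- as.numeric(wave)
  zr <- w * cos(2 * pi * f0 * t)
  zi <- -w * sin(2 * pi * f0 * t)
  p <- max(3L, round(sample_rate / f0))
  ma <- function(x) {   # one-period moving average
    cs <- cumsum(c(0, x))
    (cs[(p + 1):(n + 1)] - cs[1:(n - p + 1)]) / p
  }
  env <- sqrt(ma(zr)^2 + ma(zi)^2)
  n <- length(env)
  half <- max(env) / 2
  above <- env >= half
  idx <- which(above)
  i1 <- idx[1]; i2 <- idx[length(idx)]
  # linear interpolation just outside the half-max plateau
  frac1 <- if (i1 > 1) (half - env[i1 - 1]) / (env[i1] - env[i1 - 1]) else 0
  frac2 <- if (i2 < n) (env[i2] - half) / (env[i2] - env[i2 + 1]) else 0
  ((i2 + frac2) - (i1 - 1 + frac1)) / sample_rate * 1000
}

#' Write a waveform as 16-bit PCM WAV
#'
#' Minimal mono RIFF/WAVE writer (no WAV-writing package is required by the
#' pipeline, which treats audio export as an optional fidelity feature).
#'
#' @param wave numeric vector in [-1, 1].
#' @param path output file path.
#' @param sample_rate sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate = attr(wave, "sample_rate")) {
  if (is.null(sample_rate)) sample_rate <- 44100
  pcm <- as.integer(round(pmax(-1, pmin(1, as.numeric(wave))) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")  # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little") # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
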