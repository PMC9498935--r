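# Shared configuration for the numbered analysis scripts.
#
# Every script below sources this file. The master seed can be overridden with
# the STREAMSEG_SEED environment variable; all artifacts are reproducible from
# (configuration, seed) alone.

suppressPackageStartupMessages(library(streamseg))

SEED <- as.integer(Sys.getenv("STREAMSEG_SEED", "1"))
RESULTS <- file.path("results")

CONFIG <- run_config(
  seed = SEED,
  # Study-scale cohort: 14/14/12/13 across age x musicianship cells
  n_per_cell = c(younger_musician = 14, younger_nonmusician = 14,
                 older_musician = 12, older_nonmusician = 13),
  spec = effect_spec(),          # documented defaults; see ?effect_spec
  n_boot = 200, k = 6,           # 200 bootstrap resamples of 6 raters
  n_younger = 6, n_older = 6,    # Experiment-2 rating groups
  rating_noise_sd = 6,
  out_dir = NULL                 # per-script out_dir set below
)

dir.create(RESULTS, showWarnings = FALSE)
msg <- function(...) cat("[streamseg]", ..., "\n")
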