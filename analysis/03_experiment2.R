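#!/usr/bin/env Rscript
# Stage 3: Experiment 2 — dissimilarity ratings, bootstrap MDS and the
# common perceptual scale.
#
# Simulates the rating cohort, fits per-age-group bootstrap MDS ensembles and
# compares them stimulus by stimulus, pools all raters, fits the
# perceptual-to-physical scale map, remaps the Experiment-1 ladders onto the
# common dissimilarity scale, and fits the combined model with dissimilarity
# as a continuous predictor. Requires results/exp1/dprime.csv from stage 2.

# Run from the package root: Rscript analysis/03_experiment2.R
source(file.path("analysis", "00_config.R"))

dprime_path <- file.path(RESULTS, "exp1", "dprime.csv")
if (!file.exists(dprime_path))
  stop("missing ", dprime_path, "; run analysis/02_experiment1.R first")
dpr <- read.csv(dprime_path)

cfg <- CONFIG
cfg$out_dir <- file.path(RESULTS, "exp2")

exp2 <- run_exp2(cfg, exp1 = list(dprime = dpr))

msg("group comparison verdict:", attr(exp2$group_test, "verdict"),
    sprintf("(min adjusted p = %.3f)", min(exp2$group_test$p_adj)))
msg(sprintf("pooled MDS stress-1 = %.4f", exp2$ensembles$pooled$pooled_fit$stress))
print(exp2$scale_map)
cf <- exp2$combined$coefficients
msg(sprintf("combined model: dissimilarity slope = %.3f (R^2 = %.3f)",
            cf$estimate[cf$term == "dissimilarity"], exp2$combined$r2))
msg("Experiment-2 artifacts written to", cfg$out_dir)
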