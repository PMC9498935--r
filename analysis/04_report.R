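#!/usr/bin/env Rscript
# Stage 4: compact text report over the stage 2-3 artifacts.
#
# Reads the JSON/CSV outputs and writes results/report.txt summarizing the
# headline quantities of the run.

# Run from the package root: Rscript analysis/04_report.R
source(file.path("analysis", "00_config.R"))

need <- c(exp1 = file.path(RESULTS, "exp1", "exp1_inference.json"),
          exp2 = file.path(RESULTS, "exp2", "exp2_summary.json"))
for (p in need)
  if (!file.exists(p)) stop("missing ", p, "; run the earlier stages first")

exp1 <- jsonlite::read_json(need["exp1"], simplifyVector = TRUE)
exp2 <- jsonlite::read_json(need["exp2"], simplifyVector = TRUE)
smap <- read.csv(file.path(RESULTS, "exp2", "scale_map.csv"))

lines <- c(
  sprintf("streamseg run report (seed %d)", SEED),
  strrep("-", 50),
  "",
  "Experiment 1 (adaptive deviant detection):",
  vapply(names(exp1$omnibus), function(f)
    sprintf("  %-9s omnibus fit r = %.3f (R^2 = %.3f)", f,
            exp1$omnibus[[f]]$r, exp1$omnibus[[f]]$r2), ""),
  vapply(names(exp1$tost), function(f)
    sprintf("  %-9s age TOST p = %.3g (%s)", f, exp1$tost[[f]]$p_tost,
            if (isTRUE(exp1$tost[[f]]$equivalent)) "equivalent"
            else "inconclusive"), ""),
  "",
  "Experiment 2 (dissimilarity ratings and MDS):",
  sprintf("  group comparison verdict: %s", exp2$group_verdict),
  sprintf("  pooled MDS stress-1: %.4f", exp2$pooled_stress),
  "  scale map (feature -> axis, |r|):",
  vapply(seq_len(nrow(smap)), function(i)
    sprintf("    %-9s -> axis %d  r = %.3f  slope = %.3f", smap$feature[i],
            smap$axis[i], smap$r[i], smap$slope[i]), ""),
  "",
  "Common-scale combined model:",
  sprintf("  dissimilarity slope = %.3f",
          exp2$combined$coefficients$estimate[
            exp2$combined$coefficients$term == "dissimilarity"]),
  sprintf("  R^2 = %.3f", exp2$combined$r2))

writeLines(lines, file.path(RESULTS, "report.txt"))
writeLines(lines)
msg("report written to", file.path(RESULTS, "report.txt"))
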