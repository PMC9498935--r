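#!/usr/bin/env Rscript
# Stage 1: stimulus design artifacts.
#
# Writes the three 20-level difficulty ladders, the Experiment-2 levels, the
# 15-stimulus factorial set with its physical values, and a synthesis
# fidelity check (requested vs measured FDHM of the target tone).

# Run from the package root: Rscript analysis/01_design.R
source(file.path("analysis", "00_config.R"))

out <- file.path(RESULTS, "design")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

lads <- make_ladders()
ladder_tab <- do.call(rbind, lapply(FEATURES, function(f)
  data.frame(feature = f, difficulty = 1:20, value = lads[[f]]$values,
             units = lads[[f]]$units)))
write.csv(ladder_tab, file.path(out, "difficulty_ladders.csv"),
          row.names = FALSE)

lv <- make_exp2_levels()
write.csv(data.frame(level = 1:5, intensity_phon = lv$intensity,
                     spectral_extra_db = lv$spectral,
                     spectral_total_db = spectral_total_slope(lv$spectral),
                     temporal_fdhm_ms = lv$temporal),
          file.path(out, "exp2_levels.csv"), row.names = FALSE)

set15 <- make_stimulus_set(SEED)
phys <- stimulus_physical(set15)
write.csv(cbind(set15, phys), file.path(out, "stimulus_set15.csv"),
          row.names = FALSE)

fidelity <- do.call(rbind, lapply(c(60, 100, 160), function(fdhm) {
  w <- synthesize_tone(tone_spec(392, fdhm = fdhm))
  data.frame(f0 = 392, requested_fdhm_ms = fdhm,
             measured_fdhm_ms = measure_fdhm(w, 392))
}))
write.csv(fidelity, file.path(out, "synthesis_fidelity.csv"),
          row.names = FALSE)

msg("design artifacts written to", out)
print(fidelity)
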