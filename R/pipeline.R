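# Orchestration of the two-experiment pipeline. These functions are the
# programmatic entry points driven by the numbered scripts under analysis/.

#' Build a validated run configuration
#'
#' A run is reproducible from the configuration plus its seed alone; the
#' object is fully JSON-serializable.
#'
#' @param seed master integer seed.
#' @param n_per_cell Experiment-1 cell sizes (see [simulate_cohort()]).
#' @param spec an [effect_spec()].
#' @param n_boot,k bootstrap settings for the MDS ensembles.
#' @param n_younger,n_older Experiment-2 group sizes.
#' @param rating_noise_sd Experiment-2 rating noise.
#' @param smacof list of SMACOF settings (`n_starts`, `max_iter`, `tol`).
#' @param event_logs materialize full tone-event trial logs (slow).
#' @param out_dir output directory (`NULL` = return results only).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, n_per_cell = c(younger_musician = 14,
                                            younger_nonmusician = 14,
                                            older_musician = 12,
                                            older_nonmusician = 13),
                       spec = effect_spec(), n_boot = 200, k = 6,
                       n_younger = 6, n_older = 6, rating_noise_sd = 6,
                       smacof = list(n_starts = 8, max_iter = 300,
                                     tol = 1e-6),
                       event_logs = FALSE, out_dir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed),
            n_boot >= 1, k >= 1, all(n_per_cell >= 1))
  structure(list(seed = as.integer(seed), n_per_cell = n_per_cell,
                 spec = spec, n_boot = n_boot, k = k, n_younger = n_younger,
                 n_older = n_older, rating_noise_sd = rating_noise_sd,
                 smacof = smacof, event_logs = event_logs, out_dir = out_dir),
            class = "run_config")
}

write_if <- function(obj, config, file, writer = utils::write.csv) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    writer(obj, file.path(config$out_dir, file))
  }
  invisible(NULL)
}

#' Run the Experiment-1 pipeline on a synthetic cohort
#'
#' Simulates the cohort (six adaptive blocks per participant: three features x
#' increasing/decreasing), aggregates scored outcomes into the d' table, fits
#' the per-feature omnibus mixed models, and runs the TOST for the age
#' contrast of each feature. When `config$out_dir` is set, writes
#' `profiles.csv`, `dprime.csv`, per-difficulty `block_counts.csv` and an
#' `exp1_inference.json` summary.
#'
#' @param config a [run_config()].
#' @return list with `cohort`, `dprime` (a `dprime_table`), `omnibus` (per
#'   feature), `tost` (per feature), `pairwise` (per feature, adjusted p
#'   matrices).
#' @export
run_exp1 <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- simulate_cohort(config$seed, n_per_cell = config$n_per_cell,
                            spec = config$spec, events = config$event_logs)
  dp <- aggregate_dprime(cohort)
  omnibus <- list(); tosts <- list(); pairwise <- list()
  for (f in FEATURES) {
    sub <- dp[dp$feature == f, ]
    omnibus[[f]] <- fit_omnibus(sub, difficulty_as = "factor")
    tosts[[f]] <- tryCatch(
      tost(sub$d_prime[sub$age_group == "younger"],
           sub$d_prime[sub$age_group == "older"]),
      error = function(e) NULL)  # e.g. a cohort with only one age group
    pairwise[[f]] <- pairwise_bonferroni(sub)
  }
  counts <- do.call(rbind, lapply(names(cohort$blocks), function(pid) {
    do.call(rbind, lapply(cohort$blocks[[pid]], function(b) {
      cbind(participant = pid, feature = b$feature, direction = b$direction,
            b$counts)
    }))
  }))
  write_if(cohort$profiles, config, "profiles.csv",
           function(o, f) utils::write.csv(o, f, row.names = FALSE))
  write_if(dp, config, "dprime.csv",
           function(o, f) utils::write.csv(o, f, row.names = FALSE))
  write_if(counts, config, "block_counts.csv",
           function(o, f) utils::write.csv(o, f, row.names = FALSE))
  if (!is.null(config$out_dir)) {
    summ <- list(
      seed = config$seed,
      omnibus = lapply(omnibus, function(o)
        list(r = o$r, r_ci = o$r_ci, r2 = o$r2,
             coefficients = o$coefficients)),
      tost = lapply(tosts, function(t) unclass(t)))
    jsonlite::write_json(summ, file.path(config$out_dir,
                                         "exp1_inference.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, dprime = dp, omnibus = omnibus, tost = tosts,
       pairwise = pairwise)
}

#' Run the Experiment-2 pipeline and the common-scale analysis
#'
#' Simulates the rating cohort, fits the per-age-group bootstrap MDS ensembles
#' and compares them stimulus by stimulus; on a `"similar"` verdict (or
#' always, matching the study flow where no stimulus differed) pools all
#' participants into a single ensemble, fits the perceptual-to-physical scale
#' map, remaps the Experiment-1 ladders onto the common dissimilarity scale,
#' and, when Experiment-1 results are supplied, fits the combined model with
#' dissimilarity as a continuous predictor.
#'
#' @param config a [run_config()].
#' @param exp1 result of [run_exp1()]; required for the remapped combined
#'   model (pass `NULL` to skip it).
#' @return list with `cohort`, `ensembles` (younger, older, pooled),
#'   `group_test`, `scale_map`, `remap`, and (if `exp1` given) `remapped_data`
#'   and `combined` (an `omnibus_fit`).
#' @export
run_exp2 <- function(config, exp1 = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- simulate_exp2_cohort(config$seed + 1L,
                                 n_younger = config$n_younger,
                                 n_older = config$n_older,
                                 rating_noise_sd = config$rating_noise_sd)
  ref <- physical_reference(cohort$set15)
  grp <- split(seq_along(cohort$ratings), cohort$profiles$age_group)
  sm <- config$smacof
  fit_ens <- function(idx, seed_off)
    bootstrap_mds(cohort$ratings[idx], ref, n_boot = config$n_boot,
                  k = config$k, seed = config$seed + seed_off,
                  invert = FALSE,  # synthetic ratings are dissimilarity-coded
                  n_starts = sm$n_starts, max_iter = sm$max_iter,
                  tol = sm$tol)
  ens_y <- fit_ens(grp$younger, 11L)
  ens_o <- fit_ens(grp$older, 12L)
  gtest <- compare_groups(ens_y, ens_o, length(grp$younger),
                          length(grp$older))
  ens_all <- fit_ens(seq_along(cohort$ratings), 13L)
  smap <- fit_scale_map(ens_all, cohort$set15)
  remap <- remap_difficulty(make_ladders(), smap, cohort$set15)
  out <- list(cohort = cohort,
              ensembles = list(younger = ens_y, older = ens_o,
                               pooled = ens_all),
              group_test = gtest, scale_map = smap, remap = remap)
  if (!is.null(exp1)) {
    out$remapped_data <- build_remapped_dataset(exp1$dprime, remap)
    out$combined <- fit_omnibus(out$remapped_data,
                                difficulty_as = "dissimilarity")
  }
  if (!is.null(config$out_dir)) {
    write_if(do.call(rbind, cohort$ratings), config, "ratings.csv",
             function(o, f) utils::write.csv(o, f, row.names = FALSE))
    write_if(data.frame(stimulus = 1:15, ens_all$pooled,
                        volume = ens_all$volumes),
             config, "pooled_space.csv",
             function(o, f) utils::write.csv(o, f, row.names = FALSE))
    write_if(smap, config, "scale_map.csv",
             function(o, f) utils::write.csv(o, f, row.names = FALSE))
    write_if(remap, config, "dissimilarity_remap.csv",
             function(o, f) utils::write.csv(o, f, row.names = FALSE))
    summ <- list(seed = config$seed,
                 group_verdict = attr(gtest, "verdict"),
                 group_test = gtest,
                 pooled_stress = ens_all$pooled_fit$stress)
    if (!is.null(out$combined))
      summ$combined <- list(r = out$combined$r, r2 = out$combined$r2,
                            coefficients = out$combined$coefficients)
    jsonlite::write_json(summ, file.path(config$out_dir,
                                         "exp2_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
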