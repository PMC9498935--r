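# Signal-detection analysis: d' per degree of difficulty, feature and
# participant.

#' Compute d' from hit and false-alarm counts
#'
#' Equal-variance sensitivity d' = z(HR) - z(FAR) with the log-linear
#' correction HR = (hits + 0.5) / (deviants + 1), FAR = (fa + 0.5) /
#' (opportunities + 1), which keeps both rates strictly inside (0, 1) for all
#' counts (including perfect scores). False-alarm opportunities are counted
#' per non-deviant melody cycle.
#'
#' @param n_hits,n_deviants hit count and number of deviant cycles.
#' @param n_fa,n_opportunities false-alarm count and number of non-deviant
#'   cycles.
#' @return numeric d' (vectorized), with corrected rates as attributes
#'   `hit_rate` and `fa_rate`.
#' @export
compute_dprime <- function(n_hits, n_deviants, n_fa, n_opportunities) {
  stopifnot(all(n_deviants >= 1), all(n_opportunities >= 1),
            all(n_hits >= 0), all(n_fa >= 0),
            all(n_hits <= n_deviants), all(n_fa >= 0))
  hr <- (n_hits + 0.5) / (n_deviants + 1)
  far <- (n_fa + 0.5) / (n_opportunities + 1)
  structure(stats::qnorm(hr) - stats::qnorm(far),
            hit_rate = hr, fa_rate = far)
}

#' Aggregate scored blocks into a d' table
#'
#' Pools the increasing and the decreasing block of each feature within a
#' participant (block direction is not modelled downstream), sums counts per
#' degree of difficulty, and computes corrected rates and d' per
#' (participant, feature, difficulty) cell. Cells without any deviant or
#' without any non-deviant cycle are excluded with a warning; participants
#' missing a block are processed on the available data and flagged.
#'
#' @param cohort result of [simulate_cohort()], or a plain list with elements
#'   `blocks` (per-participant named lists of `block_result`s).
#' @return data frame of class `dprime_table`: `participant`, `feature`,
#'   `difficulty`, `n_deviants`, `n_hits`, `n_nondeviant_cycles`, `n_false_alarms`,
#'   `hit_rate`, `fa_rate`, `d_prime`, plus participant covariates when a
#'   `profiles` element is present.
#' @export
aggregate_dprime <- function(cohort) {
  blocks <- cohort$blocks
  rows <- list()
  dropped <- 0L
  for (pid in names(blocks)) {
    pb <- blocks[[pid]]
    feats <- unique(vapply(pb, `[[`, "", "feature"))
    if (length(pb) < 6)
      message("participant ", pid, " is missing ", 6 - length(pb), " block(s)")
    for (f in feats) {
      cts <- do.call(rbind, lapply(pb[vapply(pb, `[[`, "", "feature") == f],
                                   `[[`, "counts"))
      agg <- stats::aggregate(cbind(n_cycles, n_deviants, n_hits, n_fa) ~
                                difficulty, cts, sum)
      agg$n_opp <- agg$n_cycles - agg$n_deviants
      keep <- agg$n_deviants >= 1 & agg$n_opp >= 1
      dropped <- dropped + sum(!keep)
      agg <- agg[keep, , drop = FALSE]
      if (!nrow(agg)) next
      dp <- compute_dprime(agg$n_hits, agg$n_deviants, agg$n_fa, agg$n_opp)
      rows[[length(rows) + 1]] <- data.frame(
        participant = pid, feature = f, difficulty = agg$difficulty,
        n_deviants = agg$n_deviants, n_hits = agg$n_hits,
        n_nondeviant_cycles = agg$n_opp, n_false_alarms = agg$n_fa,
        hit_rate = attr(dp, "hit_rate"), fa_rate = attr(dp, "fa_rate"),
        d_prime = as.numeric(dp))
    }
  }
  if (dropped > 0)
    warning(dropped, " cell(s) without both deviant and non-deviant cycles ",
            "were excluded")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(cohort$profiles)) {
    m <- match(out$participant, cohort$profiles$participant)
    out$age_group <- cohort$profiles$age_group[m]
    out$msi <- cohort$profiles$msi[m]
    out$pta <- cohort$profiles$pta[m]
  }
  class(out) <- c("dprime_table", "data.frame")
  out
}
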