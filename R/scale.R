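# Mapping MDS dimensions onto physical features and re-expressing task
# difficulty on the common dissimilarity scale.

#' Fit the perceptual-to-physical scale map
#'
#' Regresses each axis of the pooled, reference-aligned MDS configuration on
#' the (log-transformed, for spectral and temporal envelope) physical values of
#' the 15 stimuli. Each axis is assigned to the feature with which it
#' correlates most strongly in absolute value; an ambiguous assignment (one
#' feature claiming two axes) is an error.
#'
#' @param ensemble an `mds_ensemble` (uses `$pooled`), or a 15 x 3 aligned
#'   configuration matrix.
#' @param set15 a `stimulus_set15`.
#' @return data frame of class `scale_map`: one row per feature with `axis`,
#'   `form` (`"linear"`/`"log"`), `slope`, `intercept`, `r`, `r_lo`, `r_hi`.
#' @export
fit_scale_map <- function(ensemble, set15) {
  conf <- if (inherits(ensemble, "mds_ensemble")) ensemble$pooled
          else as.matrix(ensemble)
  stopifnot(nrow(conf) == 15, ncol(conf) == 3)
  phys <- stimulus_physical(set15)
  x <- vapply(FEATURES, function(f) feature_transform(f, phys[, f]),
              numeric(15))
  rmat <- abs(stats::cor(conf, x))          # 3 axes x 3 features
  best_feature <- FEATURES[apply(rmat, 1, which.max)]
  if (anyDuplicated(best_feature))
    stop("ambiguous axis-feature assignment: |r| matrix ",
         paste(round(rmat, 3), collapse = " "))
  rows <- lapply(FEATURES, function(f) {
    ax <- which(best_feature == f)
    fit <- stats::lm(conf[, ax] ~ x[, f])
    ct <- stats::cor.test(conf[, ax], x[, f])
    data.frame(feature = f, axis = ax,
               form = if (f == "intensity") "linear" else "log",
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r = unname(ct$estimate), r_lo = ct$conf.int[1],
               r_hi = ct$conf.int[2])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scale_map", "data.frame")
  out
}

#' Re-express the difficulty ladders as dissimilarity from the target
#'
#' Pushes every ladder value through its feature's fitted perceptual map and
#' offsets so that difficulty 20 (identical to the target) maps to
#' dissimilarity 0. Ladder values outside the range of physical values the map
#' was fitted on are extrapolations and are flagged.
#'
#' @param ladders named list of `difficulty_ladder`s.
#' @param scale_map a `scale_map` from [fit_scale_map()].
#' @param set15 the stimulus set the map was fitted on (for the extrapolation
#'   flag); optional.
#' @return data frame with `feature`, `difficulty`, `dissimilarity`,
#'   `extrapolated`.
#' @export
remap_difficulty <- function(ladders, scale_map, set15 = NULL) {
  fitted_range <- if (!is.null(set15)) {
    phys <- stimulus_physical(set15)
    lapply(stats::setNames(FEATURES, FEATURES),
           function(f) range(phys[, f]))
  }
  rows <- lapply(names(ladders), function(f) {
    lad <- ladders[[f]]
    sm <- scale_map[scale_map$feature == f, ]
    if (nrow(sm) != 1) stop("no scale-map row for feature ", f)
    m <- sm$slope * feature_transform(f, lad$values) + sm$intercept
    m20 <- sm$slope * feature_transform(f, TARGET_VALUES[f]) + sm$intercept
    extrap <- if (is.null(fitted_range)) rep(FALSE, 20) else
      lad$values < fitted_range[[f]][1] | lad$values > fitted_range[[f]][2]
    if (any(extrap))
      message(sum(extrap), " ", f,
              " ladder values lie outside the fitted range (extrapolated)")
    data.frame(feature = f, difficulty = 1:20,
               dissimilarity = abs(m - m20), extrapolated = extrap)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Join d' cells to common-scale dissimilarities
#'
#' Attaches each (feature, difficulty) cell's dissimilarity value to the d'
#' table, producing the analysis table for the combined model in which
#' dissimilarity is a continuous predictor. Unmatched rows are excluded with a
#' message.
#'
#' @param dptable a `dprime_table`.
#' @param remap output of [remap_difficulty()].
#' @return the joined data frame (all `dptable` columns plus `dissimilarity`).
#' @export
build_remapped_dataset <- function(dptable, remap) {
  out <- merge(dptable, remap[, c("feature", "difficulty", "dissimilarity")],
               by = c("feature", "difficulty"))
  n_lost <- nrow(dptable) - nrow(out)
  if (n_lost > 0)
    message(n_lost, " d' row(s) had no matching dissimilarity and were excluded")
  out[order(out$participant, out$feature, out$difficulty), ]
}
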