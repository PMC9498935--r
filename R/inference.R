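# Study-level inference: mixed-effects omnibus models, Bonferroni pairwise
# comparisons, and the two-one-sided-tests (TOST) equivalence procedure.

#' Fit the omnibus mixed-effects model for one feature (or the combined model)
#'
#' Restricted-maximum-likelihood linear mixed model with random intercepts on
#' participants, Satterthwaite-method t-tests and p-values for the fixed
#' effects (delegated to `lmerTest`). The difficulty term enters either as a
#' categorical factor with difficulty 1 as the baseline, or as the continuous
#' `dissimilarity` predictor (combined model); `age_group` is a factor with
#' baseline `younger`; `msi` and `pta` are continuous. Model fit is summarized,
#' as in the study design, by the Pearson correlation between fitted values
#' and data with its 95% CI and R^2.
#'
#' @param data a `dprime_table` (with covariate columns), or the remapped
#'   table from [build_remapped_dataset()].
#' @param difficulty_as `"factor"` for the per-feature model,
#'   `"dissimilarity"` for the combined continuous model (which also includes
#'   `feature` with baseline intensity and the dissimilarity x feature,
#'   x musical-training interactions).
#' @param extra_terms additional right-hand-side terms, e.g. `"msi:age_group"`.
#' @return list of class `omnibus_fit`: `model`, `coefficients` (estimate, SE,
#'   df, t, p per fixed effect), `r`, `r_ci`, `r2`, `singular`, `formula`.
#' @export
fit_omnibus <- function(data, difficulty_as = c("factor", "dissimilarity"),
                        extra_terms = NULL) {
  difficulty_as <- match.arg(difficulty_as)
  df <- as.data.frame(data)
  stopifnot(all(c("d_prime", "participant", "age_group", "msi", "pta")
                %in% names(df)))
  df$age_group <- factor(df$age_group)
  if ("younger" %in% levels(df$age_group))
    df$age_group <- stats::relevel(df$age_group, ref = "younger")
  age_term <- if (nlevels(df$age_group) >= 2) "age_group" else NULL
  rhs <- if (difficulty_as == "factor") {
    df$difficulty <- factor(df$difficulty)
    if ("1" %in% levels(df$difficulty))
      df$difficulty <- stats::relevel(df$difficulty, ref = "1")
    paste(c("difficulty", age_term, "msi", "pta"), collapse = " + ")
  } else {
    stopifnot("dissimilarity" %in% names(df))
    df$feature <- stats::relevel(factor(df$feature), ref = "intensity")
    paste("dissimilarity * feature + dissimilarity * msi +",
          "dissimilarity:feature:msi + feature * age_group +",
          "feature * msi + age_group + pta")
  }
  if (!is.null(extra_terms))
    rhs <- paste(rhs, "+", paste(extra_terms, collapse = " + "))
  form <- stats::as.formula(paste("d_prime ~", rhs, "+ (1 | participant)"))
  fit <- tryCatch(lmerTest::lmer(form, data = df, REML = TRUE),
                  error = function(e) e)
  singular <- if (inherits(fit, "error")) TRUE else lme4::isSingular(fit)
  if (singular) {
    warning("mixed model is singular or failed (",
            if (inherits(fit, "error")) conditionMessage(fit)
            else "zero random-intercept variance",
            "); refitting fixed effects only")
    form_fe <- stats::as.formula(paste("d_prime ~", rhs))
    fit_fe <- stats::lm(form_fe, data = df)
    sm <- summary(fit_fe)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        df = fit_fe$df.residual, t = sm[, 3], p = sm[, 4])
    fitted_v <- stats::fitted(fit_fe)
    model <- fit_fe
  } else {
    sm <- stats::coef(summary(fit))
    coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], df = sm[, "df"],
                        t = sm[, "t value"], p = sm[, "Pr(>|t|)"])
    fitted_v <- stats::fitted(fit)
    model <- fit
  }
  rownames(coefs) <- NULL
  ct <- tryCatch(suppressWarnings(stats::cor.test(fitted_v, df$d_prime)),
                 error = function(e) NULL)
  r <- if (is.null(ct)) NA_real_ else unname(ct$estimate)
  structure(list(model = model, coefficients = coefs,
                 r = r, r_ci = if (is.null(ct) || is.na(r))
                                 c(NA_real_, NA_real_) else ct$conf.int,
                 r2 = if (is.null(ct) || is.na(r)) 0 else r^2,
                 singular = singular, formula = form),
            class = "omnibus_fit")
}

#' @export
print.omnibus_fit <- function(x, ...) {
  cat("Omnibus mixed model:", deparse(x$formula), "\n")
  cat("fit: r =", round(x$r, 3), "CI [", round(x$r_ci[1], 3), ",",
      round(x$r_ci[2], 3), "], R^2 =", round(x$r2, 3), "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons across factor levels
#'
#' Two-sample (Welch) t-tests for every unordered pair of levels, with
#' adjusted p = min(1, p * m), m = number of comparisons. Pairs where either
#' level has fewer than two observations are skipped (NA).
#'
#' @param data data frame.
#' @param value name of the response column.
#' @param group name of the factor column (e.g. difficulty).
#' @return symmetric matrix of adjusted p-values (diagonal NA) with attributes
#'   `m` (number of comparisons) and `raw` (unadjusted matrix).
#' @export
pairwise_bonferroni <- function(data, value = "d_prime",
                                group = "difficulty") {
  g <- factor(data[[group]])
  lv <- levels(g)
  y <- data[[value]]
  m <- choose(length(lv), 2)
  raw <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)[-length(lv)]) for (j in (i + 1):length(lv)) {
    a <- y[g == lv[i]]; b <- y[g == lv[j]]
    if (length(a) < 2 || length(b) < 2) next
    raw[i, j] <- raw[j, i] <- stats::t.test(a, b)$p.value
  }
  adj <- pmin(raw * m, 1)   # matrix first so dim attributes survive pmin
  attr(adj, "m") <- m
  attr(adj, "raw") <- raw
  adj
}

#' Two-one-sided-tests (TOST) equivalence procedure
#'
#' Equivalence bounds are set symmetrically at +/- `cohen_d_bound` x pooled SD
#' (expressed in the response's units, here d'). Both one-sided tests are
#' Welch t-tests of the group difference against the bounds; the equivalence
#' p-value is the larger of the two. The group difference, its 90% and 95%
#' CIs, and the ordinary two-sided test against zero are also reported.
#'
#' @param group_a,group_b numeric vectors of observations (each length >= 2).
#' @param cohen_d_bound smallest interesting effect size as a Cohen's d.
#' @param alpha significance level at which `equivalent` is declared.
#' @return list of class `tost_result`: `bounds`, `delta` (mean a - mean b),
#'   `se`, `df`, `t_lower`, `t_upper`, `p_lower`, `p_upper`, `p_tost`,
#'   `equivalent`, `ci90`, `ci95`, `p_zero`.
#' @export
tost <- function(group_a, group_b, cohen_d_bound = 0.2, alpha = 0.05) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  sd_pool <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  if (sd_pool == 0)
    stop("zero pooled variance: equivalence bounds are degenerate")
  bound <- cohen_d_bound * sd_pool
  delta <- mean(a) - mean(b)
  se <- sqrt(va / na + vb / nb)
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  t_lower <- (delta + bound) / se   # H0: delta <= -bound
  t_upper <- (delta - bound) / se   # H0: delta >= +bound
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  p_tost <- max(p_lower, p_upper)
  qs <- function(p) delta + c(-1, 1) * stats::qt(1 - (1 - p) / 2, df) * se
  structure(list(bounds = c(-bound, bound), delta = delta, se = se, df = df,
                 t_lower = t_lower, t_upper = t_upper, p_lower = p_lower,
                 p_upper = p_upper, p_tost = p_tost,
                 equivalent = p_tost < alpha,
                 ci90 = qs(0.90), ci95 = qs(0.95),
                 p_zero = 2 * stats::pt(-abs(delta / se), df)),
            class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat("TOST equivalence test: bounds [", round(x$bounds[1], 3), ",",
      round(x$bounds[2], 3), "]\n")
  cat("delta =", round(x$delta, 3), "90% CI [", round(x$ci90[1], 3), ",",
      round(x$ci90[2], 3), "]; p(TOST) =", signif(x$p_tost, 3),
      if (x$equivalent) "(equivalent)" else "(not equivalent)", "\n")
  invisible(x)
}
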