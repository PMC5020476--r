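#' Aortic location vocabulary
#'
#' The four thoracic-aorta measurement locations, with the descending aorta
#' at the diaphragm (the location least affected by coarctation) last so it
#' serves as the treatment-contrast reference level in the mixed model.
#' @export
aortic_locations <- c("aortic root", "ascending aorta", "isthmus",
                      "descending aorta at diaphragm")

#' Mann-Whitney U test
#'
#' Two-group comparison by the Mann-Whitney U (Wilcoxon rank-sum) statistic
#' with midrank tie handling. The two-tailed p-value is exact (by
#' enumeration over all group labelings) when `n + m <= 12` and there are no
#' ties, and otherwise uses the normal approximation with tie correction and
#' continuity correction. Computation is delegated to
#' [stats::wilcox.test()], which implements exactly these variants; the
#' degenerate all-identical case (rank variance zero) is reported as `p = 1`
#' with a flag rather than an error.
#'
#' @param x,y Numeric samples, both non-empty.
#' @return List with `U` (statistic for `x`), `p` (two-tailed), `method`
#'   (`"exact"` or `"normal-approx"`), and logical `degenerate`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples contain missing values")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = u, p = 1, method = "degenerate", degenerate = TRUE))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (n + m) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(U = unname(u), p = unname(wt$p.value),
       method = if (exact) "exact" else "normal-approx",
       degenerate = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with the two-tailed p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom. Invariant under strictly monotone transforms of either
#' variable.
#'
#' @param x,y Paired numeric samples, `n >= 3`.
#' @return List with `rho`, `p` (two-tailed) and `n`.
#' @export
spearman_rank <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must be paired (equal length)")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("Spearman correlation needs n >= 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("rank variance is zero; correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Adult blood-pressure staging
#'
#' Hypertension staging for adults (>= 18 years) following the European
#' task-force bands: stage 1 for systolic 140-159 mmHg and/or diastolic
#' 90-99 mmHg; stage 2 for systolic 160-179 and/or diastolic 100-109. The
#' higher of the two component stages wins; below both bands is normal and
#' above both stage-2 ceilings is reported as `"above-stage2"`.
#'
#' @param systolic,diastolic Cuff pressures in mmHg (vectorized).
#' @return Character vector: `"normal"`, `"stage1"`, `"stage2"` or
#'   `"above-stage2"`.
#' @examples
#' stage_hypertension_adult(145, 85)   # stage1
#' stage_hypertension_adult(150, 102)  # stage2
#' @export
stage_hypertension_adult <- function(systolic, diastolic) {
  if (length(systolic) != length(diastolic)) {
    stop("'systolic' and 'diastolic' must have equal length")
  }
  comp <- function(v, lo1, lo2, lo3) {
    ifelse(v >= lo3, 3L, ifelse(v >= lo2, 2L, ifelse(v >= lo1, 1L, 0L)))
  }
  s <- comp(systolic, 140, 160, 180)
  d <- comp(diastolic, 90, 100, 110)
  c("normal", "stage1", "stage2", "above-stage2")[pmax(s, d) + 1L]
}

#' Random-intercept mixed model for regional aortic distensibility
#'
#' Fits the distensibility of the four aortic locations as a linear
#' mixed-effects model with a subject-level random intercept to absorb the
#' intra-subject correlation of repeated (per-location) measurements:
#' \deqn{D_{ij} = \beta_0 + \beta_1 \cdot ageRepair_i + \beta_2 \cdot
#'   ageMRI_i + location_j + b_i + \epsilon_{ij}}
#' The location factor uses a treatment contrast with the descending aorta
#' at the diaphragm as reference level. Estimation is by REML (lme4);
#' p-values are two-sided Wald tests with residual degrees of freedom
#' `n_obs - n_fixed` -- an approximation, flagged because p-values near 0.05
#' can be sensitive to the df method.
#'
#' @param data Long-format data frame with columns `subject_id`, `location`
#'   (values from [aortic_locations]), `distensibility`, `age_at_repair`,
#'   `age_at_mri`. Each subject may contribute each location at most once.
#' @param reml Use REML (default) or ML.
#' @return Object of class `distensibility_lme`: `fixed_effects` (data frame
#'   with estimate, std_error, t, p), `random_intercept_sd`, `residual_sd`,
#'   `n_subjects`, `n_observations`, and the underlying `lme4` `fit`.
#' @export
fit_distensibility_lme <- function(data, reml = TRUE) {
  need <- c("subject_id", "location", "distensibility",
            "age_at_repair", "age_at_mri")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  bad <- setdiff(unique(as.character(data$location)), aortic_locations)
  if (length(bad)) {
    stop("unknown location level(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(data[, c("subject_id", "location")])) {
    stop("a subject contributes the same location more than once")
  }
  if (length(unique(data$location)) < 2L) {
    stop("singular design: only one measurement location present")
  }
  n_subj <- length(unique(data$subject_id))
  locs_per <- table(data$subject_id)
  if (n_subj < 2L || all(locs_per < 2L)) {
    stop("need >= 2 subjects with >= 2 locations each")
  }
  # reference level: descending aorta at the diaphragm
  data$location <- factor(as.character(data$location),
                          levels = rev(aortic_locations))
  data$location <- stats::relevel(data$location,
                                  ref = "descending aorta at diaphragm")

  fit <- tryCatch(
    lme4::lmer(
      distensibility ~ age_at_repair + age_at_mri + location +
        (1 | subject_id),
      data = data, REML = reml,
      control = lme4::lmerControl(check.conv.singular = "ignore")
    ),
    error = function(e) stop("mixed model failed to converge: ",
                             conditionMessage(e))
  )
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tval <- est / se
  df_resid <- nrow(data) - length(est)
  pval <- 2 * stats::pt(-abs(tval), df = df_resid)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fixed_effects = data.frame(
      term = names(est), estimate = unname(est), std_error = unname(se),
      t = unname(tval), p = unname(pval), stringsAsFactors = FALSE
    ),
    random_intercept_sd = vc$sdcor[vc$grp == "subject_id"][1],
    residual_sd = vc$sdcor[vc$grp == "Residual"][1],
    df_residual = df_resid,
    n_subjects = n_subj,
    n_observations = nrow(data),
    reml = reml,
    fit = fit
  ), class = "distensibility_lme")
}

#' @method print distensibility_lme
#' @export
print.distensibility_lme <- function(x, ...) {
  cat(sprintf(
    "<distensibility_lme> %d subjects, %d observations (%s)\n",
    x$n_subjects, x$n_observations, if (x$reml) "REML" else "ML"))
  fe <- x$fixed_effects
  fe$estimate <- signif(fe$estimate, 4)
  fe$std_error <- signif(fe$std_error, 4)
  fe$t <- signif(fe$t, 4)
  fe$p <- signif(fe$p, 3)
  print(fe, row.names = FALSE)
  cat(sprintf("random intercept SD %.3f, residual SD %.3f\n",
              x$random_intercept_sd, x$residual_sd))
  invisible(x)
}

#' @export
coef.distensibility_lme <- function(object, ...) {
  stats::setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}
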