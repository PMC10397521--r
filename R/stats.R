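#' Mean CBF per damage score for one subject
#'
#' Builds the per-score ROI table: one row per discrete damage score
#' (0.1..1.0) present in the lesion, with the mean CBF over the defined CBF
#' voxels at that score and the defined-voxel count. Scores whose voxels
#' are all undefined are omitted with a message.
#'
#' @param cbf CBF [volume()].
#' @param tigr a `tigr_map` from [tigr_score()] (aligned with `cbf`).
#' @param id subject identifier attached to the rows.
#' @return data.frame: `id`, `score`, `mean_cbf`, `n_voxels`.
#' @export
cbf_by_score <- function(cbf, tigr, id = "subject") {
  stopifnot(inherits(tigr, "tigr_map"))
  assert_aligned(cbf, tigr$scores, "CBF and damage map")
  s <- tigr$scores$data
  inside <- tigr$lesion$data > 0 & !is.na(s) & s > 0
  scores_present <- sort(unique(round(s[inside], 1)))
  rows <- lapply(scores_present, function(sc) {
    v <- cbf$data[inside & abs(s - sc) < 1e-9]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      message("score ", sc, ": no defined CBF voxels; row omitted")
      return(NULL)
    }
    data.frame(id = id, score = sc, mean_cbf = mean(v),
               n_voxels = length(v))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Per-subject linear regression of CBF on damage score
#'
#' Ordinary least squares of the per-score mean CBF on the damage score
#' (rows unweighted). Reports R-squared, the F statistic with df
#' (1, n - 2), the two-sided p value, the slope (mL/100g/min per unit
#' score) and its sign.
#'
#' @param rows data.frame from [cbf_by_score()] (>= 3 rows, one subject).
#' @return object of class `score_regression`: `r2`, `f_stat`, `df`,
#'   `p_value`, `slope`, `slope_sign` ("-", "+"), `n`, and the `lm` fit.
#' @export
fit_score_regression <- function(rows) {
  if (nrow(rows) < 3) stop("need at least 3 score rows")
  if (length(unique(rows$score)) < 2)
    stop("constant predictor: all rows share one score")
  fit <- stats::lm(mean_cbf ~ score, data = rows)
  sm <- summary(fit)
  slope <- stats::coef(fit)[["score"]]
  structure(list(r2 = sm$r.squared,
                 f_stat = unname(sm$fstatistic[1]),
                 df = unname(sm$fstatistic[2:3]),
                 p_value = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                     sm$fstatistic[3], lower.tail = FALSE)),
                 slope = slope,
                 slope_sign = if (slope < 0) "-" else "+",
                 n = nrow(rows), fit = fit),
            class = "score_regression")
}

#' @export
print.score_regression <- function(x, ...) {
  cat(sprintf(
    "<score_regression> R2 %.2f, F(%d,%d) %.2f, p %.3g, slope %.1f (%s)\n",
    x$r2, x$df[1], x$df[2], x$f_stat, x$p_value, x$slope, x$slope_sign))
  invisible(x)
}

#' Bonferroni assessment of per-subject p values
#'
#' Flags each subject's regression as significant at the Bonferroni
#' threshold `alpha / n_tests` and, separately, at the uncorrected level.
#'
#' @param p numeric p values (one per subject).
#' @param alpha familywise level before correction (default 0.01).
#' @param n_tests number of tests (default `length(p)`).
#' @param uncorrected_alpha level for the uncorrected flags (default 0.05).
#' @return data.frame with `p`, `bonferroni` and `uncorrected` logical
#'   flags; attributes `n_bonferroni`, `n_uncorrected`,
#'   `n_uncorrected_only`, `threshold`.
#' @export
bonferroni_assess <- function(p, alpha = 0.01, n_tests = length(p),
                              uncorrected_alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  thr <- alpha / n_tests
  out <- data.frame(p = p, bonferroni = p < thr,
                    uncorrected = p < uncorrected_alpha)
  attr(out, "threshold") <- thr
  attr(out, "n_bonferroni") <- sum(out$bonferroni)
  attr(out, "n_uncorrected") <- sum(out$uncorrected)
  attr(out, "n_uncorrected_only") <- sum(out$uncorrected & !out$bonferroni)
  out
}

factor_model_terms <- c("sex", "age", "age_x_time", "age_x_sex",
                        "damage", "time", "damage_x_sex", "damage_x_age",
                        "damage_x_time", "time_x_sex")

#' Group factorial model of lesion CBF
#'
#' Least-squares fit of per-score mean lesion CBF on tissue damage, time
#' since stroke, age and sex plus the six pairwise cross-terms (10 model
#' terms; residual df = rows - 11). Continuous factors are mean-centered
#' before cross-products are formed (reducing collinearity between main
#' effects and interactions); sex is effect-coded (F = +1, M = -1) so main
#' effects remain interpretable alongside the interactions. Per-term t
#' statistics and p values are reported unadjusted, plus the overall F.
#'
#' @param data data.frame with columns `mean_cbf`, `score` (damage,
#'   0.1..1.0), `age` (years), `sex` ("M"/"F"), `months_since_stroke`, and
#'   `wab_aq` when `include_wab = TRUE`. One row per subject-score cell.
#' @param include_wab also model the aphasia-severity score (WAB-AQ) main
#'   effect and its cross-terms with the other four factors.
#' @param center mean-center continuous factors before forming
#'   cross-products (raw scale behind this flag).
#' @return object of class `cbf_factor_model`: `terms` data.frame
#'   (term, estimate, t, p), `f_stat`, `df`, `p_value`, `n`, `fit`.
#' @export
fit_factor_model <- function(data, include_wab = FALSE, center = TRUE) {
  need <- c("mean_cbf", "score", "age", "sex", "months_since_stroke")
  if (include_wab) need <- c(need, "wab_aq")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(data[need])) stop("missing factor values are not allowed")
  if (length(unique(data$sex)) < 2) stop("need both sexes in the cohort")
  ctr <- function(x) if (center) x - mean(x) else x
  mf <- data.frame(
    cbf = data$mean_cbf,
    sex = ifelse(data$sex == "F", 1, -1),
    age = ctr(data$age),
    damage = ctr(data$score),
    time = ctr(data$months_since_stroke))
  mf$age_x_time <- mf$age * mf$time
  mf$age_x_sex <- mf$age * mf$sex
  mf$damage_x_sex <- mf$damage * mf$sex
  mf$damage_x_age <- mf$damage * mf$age
  mf$damage_x_time <- mf$damage * mf$time
  mf$time_x_sex <- mf$time * mf$sex
  terms <- factor_model_terms
  if (include_wab) {
    mf$wab <- ctr(data$wab_aq)
    mf$wab_x_damage <- mf$wab * mf$damage
    mf$wab_x_age <- mf$wab * mf$age
    mf$wab_x_time <- mf$wab * mf$time
    mf$wab_x_sex <- mf$wab * mf$sex
    terms <- c(terms, "wab", "wab_x_damage", "wab_x_age", "wab_x_time",
               "wab_x_sex")
  }
  fml <- stats::as.formula(paste("cbf ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = mf)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; aliased terms: ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  sm <- summary(fit)
  ct <- sm$coefficients[terms, , drop = FALSE]
  structure(list(
    terms = data.frame(term = terms, estimate = ct[, 1],
                       t = ct[, 3], p = ct[, 4], row.names = NULL),
    f_stat = unname(sm$fstatistic[1]),
    df = unname(sm$fstatistic[2:3]),
    p_value = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                               sm$fstatistic[3], lower.tail = FALSE)),
    n = nrow(mf), include_wab = include_wab, centered = center,
    fit = fit), class = "cbf_factor_model")
}

#' @export
print.cbf_factor_model <- function(x, ...) {
  cat(sprintf("<cbf_factor_model> F(%d,%d) = %.2f, p %.3g, n = %d rows\n",
              x$df[1], x$df[2], x$f_stat, x$p_value, x$n))
  tt <- x$terms
  tt$t <- sprintf("%.2f", tt$t)
  tt$p <- format.pval(tt$p, digits = 2)
  tt$estimate <- sprintf("%.3f", tt$estimate)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Paired t test between tissue-type CBF means
#'
#' Standard paired t test on per-subject differences (e.g. lesion vs
#' homologue white matter mean CBF).
#'
#' @param values_a,values_b per-subject means, paired by position.
#' @return list: `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_tissue_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length")
  if (length(values_a) < 2) stop("need at least 2 pairs")
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    if (all(d == 0))   # identical vectors: no difference at all
      return(list(t = 0, df = length(d) - 1, p_value = 1, mean_diff = 0))
    stop("zero-variance nonzero differences: paired t is unbounded")
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Group overlap mask
#'
#' Includes a voxel when at least `min_n` subjects' masks contain it.
#'
#' @param masks list of aligned [mask()]s.
#' @param min_n minimum subject count per voxel.
#' @return a [mask()]; also carries the per-voxel count as attribute
#'   `"count"`.
#' @export
group_overlap_mask <- function(masks, min_n) {
  stopifnot(length(masks) >= 1)
  for (m in masks[-1]) assert_aligned(masks[[1]], m, "overlap masks")
  cnt <- Reduce(`+`, lapply(masks, function(m) m$data))
  out <- mask(cnt >= min_n, masks[[1]]$spacing, masks[[1]]$origin, "overlap")
  attr(out, "count") <- cnt
  out
}

#' Voxelwise removal of a lesion-derived covariate
#'
#' For each voxel, regresses CBF across subjects on a per-subject scalar
#' (lesion volume or cavitation volume). Where the slope is significant at
#' `alpha`, the voxel's values are replaced by the residuals plus the
#' voxel's grand mean; elsewhere they are unchanged. Voxels undefined in
#' any subject are left unchanged.
#'
#' @param maps list of aligned CBF [volume()]s, one per subject (>= 3).
#' @param covariate numeric per-subject scalar (non-constant).
#' @param alpha significance level for the per-voxel slope test.
#' @return list: `maps` (residualized volumes), `significant` mask,
#'   `p` volume of per-voxel p values, `altered_fraction`.
#' @export
voxelwise_covariate_removal <- function(maps, covariate, alpha = 0.05) {
  n <- length(maps)
  if (n < 3) stop("need at least 3 subjects")
  if (length(covariate) != n)
    stop("one covariate value per subject required")
  if (stats::sd(covariate) == 0) stop("constant covariate")
  for (m in maps[-1]) assert_aligned(maps[[1]], m, "CBF maps")
  d <- dim(maps[[1]]$data)
  Y <- vapply(maps, function(m) as.vector(m$data), numeric(prod(d)))
  ok <- rowSums(is.na(Y)) == 0
  x <- covariate - mean(covariate)
  sxx <- sum(x^2)
  ybar <- rowMeans(Y)
  b1 <- (Y %*% x) / sxx
  fitted_dev <- outer(as.vector(b1), x)        # b1 * centered x
  resid <- Y - ybar - fitted_dev
  sse <- rowSums(resid^2)
  se_b1 <- sqrt(pmax(sse, 0) / (n - 2) / sxx)
  tstat <- as.vector(b1) / se_b1
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  sig <- ok & !is.na(p) & p < alpha
  out <- Y
  out[sig, ] <- resid[sig, ] + ybar[sig]
  res_maps <- lapply(seq_len(n), function(i)
    volume(array(out[, i], d), maps[[1]]$spacing, maps[[1]]$origin))
  p_arr <- array(p, d); p_arr[!ok] <- NA_real_
  list(maps = res_maps,
       significant = mask(array(sig, d), maps[[1]]$spacing,
                          maps[[1]]$origin, "covariate_significant"),
       p = volume(p_arr, maps[[1]]$spacing, maps[[1]]$origin),
       altered_fraction = sum(sig) / max(1, sum(ok)))
}
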