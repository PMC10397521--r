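#' Per-parameter variation ranges for a synthetic cohort
#'
#' Ranges from which [make_cohort()] draws per-subject parameters. Ages,
#' months since stroke and the female fraction follow the reference cohort
#' (ages 24-81, 9-121 months since a left-hemisphere stroke, 4 of 14
#' female). Lesion geometry varies within the left hemisphere. The lesion
#' rim CBF carries additive demographic effects
#' `rim_cbf = rim_cbf_base + age_effect*(age - mean age) +
#' time_effect*(months - mean months) + sex_effect*sex_code + subject noise`
#' with sex effect-coded (F = +1, M = -1), so the group factor model has
#' known signs to recover: damage negative (via `cbf_slope` > 0), age
#' positive, time since stroke negative, sex positive.
#'
#' @param age,months_since_stroke,wab_aq,radius,core_frac,rim_cbf,cbf_slope
#'   numeric length-2 ranges (min, max); a zero-width range fixes the
#'   parameter.
#' @param center_x,center_y,center_z ranges for the lesion centre, mm.
#' @param p_female probability a subject is female.
#' @param age_effect,time_effect,sex_effect demographic effects on rim CBF
#'   (mL/100g/min per year, per month, per sex code).
#' @param subject_sd between-subject SD of rim CBF, mL/100g/min.
#' @return list of class `cohort_variation`.
#' @export
cohort_variation <- function(age = c(24, 81),
                             months_since_stroke = c(9, 121),
                             wab_aq = c(27.4, 80.6),
                             p_female = 4 / 14,
                             center_x = c(-32, -25),
                             center_y = c(-4, 14),
                             center_z = c(-4, 12),
                             radius = c(17, 24),
                             core_frac = c(0.45, 0.7),
                             rim_cbf = c(40, 40),
                             cbf_slope = c(20, 20),
                             age_effect = 0.15,
                             time_effect = -0.05,
                             sex_effect = 2,
                             subject_sd = 1.5) {
  structure(as.list(environment()), class = "cohort_variation")
}

#' Generate a synthetic multi-subject cohort
#'
#' Draws `n_subjects` phantoms whose lesions differ in location, size and
#' demographic-driven rim CBF, together with a demographics table and a
#' manifest recording every generated parameter (the acceptance surface for
#' parameter recovery).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param base_spec [phantom_spec()] providing everything the variation
#'   does not override.
#' @param variation a [cohort_variation()]. Degenerate variation (every
#'   range zero-width) is permitted but flagged in the manifest.
#' @param seed integer seed.
#' @return list of class `stroke_cohort`: `subjects` (list of
#'   `stroke_phantom`), `demographics` (data.frame), `manifest`.
#' @export
make_cohort <- function(n_subjects, base_spec = phantom_spec(),
                        variation = cohort_variation(), seed = 1) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  v <- variation
  set.seed(seed)
  runif_rng <- function(r) stats::runif(n_subjects, r[1], r[2])
  age <- round(runif_rng(v$age))
  months <- round(runif_rng(v$months_since_stroke))
  wab <- round(runif_rng(v$wab_aq), 1)
  # fixed female count (round(p_female * n), at least 3 of each sex when
  # n allows): the factor model's three sex cross-terms need enough
  # subjects of each sex to be estimable
  lo <- min(3L, n_subjects %/% 2)
  n_f <- min(max(round(v$p_female * n_subjects), lo), n_subjects - lo)
  sex <- sample(c(rep("F", n_f), rep("M", n_subjects - n_f)))
  cx <- runif_rng(v$center_x); cy <- runif_rng(v$center_y)
  cz <- runif_rng(v$center_z)
  radius <- runif_rng(v$radius)
  core_frac <- runif_rng(v$core_frac)
  slope <- runif_rng(v$cbf_slope)
  sex_code <- ifelse(sex == "F", 1, -1)
  rim <- runif_rng(v$rim_cbf) +
    v$age_effect * (age - mean(age)) +
    v$time_effect * (months - mean(months)) +
    v$sex_effect * sex_code +
    stats::rnorm(n_subjects, sd = v$subject_sd)
  sub_seed <- sample.int(.Machine$integer.max %/% 2, n_subjects)

  ids <- sprintf("P%02d", seq_len(n_subjects))
  subjects <- vector("list", n_subjects)
  names(subjects) <- ids
  for (i in seq_len(n_subjects)) {
    spec_i <- phantom_spec(
      shape = base_spec$shape, spacing = base_spec$spacing,
      brain_semi = base_spec$brain_semi,
      t1w = base_spec$t1w, t2w = base_spec$t2w, pd = base_spec$pd,
      true_cbf = base_spec$true_cbf,
      lesion = utils::modifyList(base_spec$lesion,
                                 list(center = c(cx[i], cy[i], cz[i]),
                                      radius = radius[i],
                                      core_frac = core_frac[i],
                                      rim_cbf = rim[i],
                                      cbf_slope = slope[i])),
      noise = base_spec$noise, n_pairs = base_spec$n_pairs,
      motion = base_spec$motion, params = base_spec$params,
      demographics = list(age = age[i], sex = sex[i],
                          months_since_stroke = months[i], wab_aq = wab[i]),
      seed = sub_seed[i])
    subjects[[i]] <- make_phantom(spec_i)
  }
  demographics <- data.frame(
    id = ids, age = age, sex = sex, months_since_stroke = months,
    wab_aq = wab,
    lesion_volume_mm3 = vapply(subjects, function(s)
      s$truth$manifest$lesion_volume_mm3, numeric(1)),
    row.names = NULL)
  ranged <- c("age", "months_since_stroke", "wab_aq", "center_x",
              "center_y", "center_z", "radius", "core_frac", "rim_cbf",
              "cbf_slope")
  degenerate <- all(vapply(ranged, function(nm) diff(v[[nm]]) == 0,
                           logical(1)))
  manifest <- list(seed = seed, n_subjects = n_subjects,
                   degenerate_variation = degenerate,
                   variation = unclass(v),
                   subjects = data.frame(
                     id = ids, age = age, sex = sex, months = months,
                     wab_aq = wab, center_x = cx, center_y = cy,
                     center_z = cz, radius = radius, core_frac = core_frac,
                     rim_cbf = rim, cbf_slope = slope, seed = sub_seed))
  if (degenerate)
    warning("degenerate cohort variation: all parameter ranges are zero-width")
  structure(list(subjects = subjects, demographics = demographics,
                 manifest = manifest), class = "stroke_cohort")
}

#' @export
print.stroke_cohort <- function(x, ...) {
  cat(sprintf("<stroke_cohort> %d subjects (%d F / %d M), ages %d-%d\n",
              nrow(x$demographics), sum(x$demographics$sex == "F"),
              sum(x$demographics$sex == "M"),
              min(x$demographics$age), max(x$demographics$age)))
  invisible(x)
}
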