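#' Voxelwise T2w/T1w ratio
#'
#' Divides each T2w voxel by the aligned T1w voxel. Voxels where T1w is at
#' or below `t1w_threshold` (or either input is undefined) are marked
#' undefined.
#'
#' @param t2w,t1w aligned [volume()]s.
#' @param t1w_threshold T1w values at or below this are treated as signal
#'   void.
#' @return ratio [volume()], dimensionless.
#' @export
ratio_map <- function(t2w, t1w, t1w_threshold = 1e-6) {
  assert_aligned(t2w, t1w, "T2w and T1w")
  r <- t2w$data / t1w$data
  r[is.na(t1w$data) | t1w$data <= t1w_threshold] <- NA_real_
  volume(r, t2w$spacing, t2w$origin)
}

#' Subject-specific normalization bounds for the damage score
#'
#' The ratio is anchored to two intact-tissue references taken on the side
#' opposite the lesion: the mean ratio over the contralesional anterior
#' grey-matter ribbon eroded by one voxel (score 0.1) and over the
#' contralesional anterior lateral-ventricle CSF eroded by one voxel
#' (score 1.0). Anchoring to the subject's own intact tissue makes the
#' score comparable across subjects regardless of global intensity scaling,
#' atrophy or coil loading. The ROI summary is the mean (recorded in the
#' result).
#'
#' @param ratio ratio [volume()] from [ratio_map()].
#' @param gm,csf_ventricle,lesion,brain aligned [mask()]s; `csf_ventricle`
#'   is the lateral-ventricle CSF class.
#' @return list of class `tigr_bounds`: `gm_ref`, `csf_ref`, ROI voxel
#'   counts, `summary = "mean"`.
#' @export
normalization_bounds <- function(ratio, gm, csf_ventricle, lesion, brain) {
  assert_aligned(ratio, brain, "ratio and brain")
  contra <- contralesional_hemisphere(brain, lesion)
  roi_of <- function(m, nm) {
    m2 <- erode_mask(anterior_half(mask_and(m, contra), reference = brain), 1)
    if (sum(m2$data) == 0)
      stop("empty eroded contralesional anterior ROI: ", nm)
    m2
  }
  gm_roi <- roi_of(gm, "grey-matter ribbon")
  csf_roi <- roi_of(csf_ventricle, "lateral-ventricle CSF")
  mean_in <- function(m) mean(ratio$data[m$data > 0], na.rm = TRUE)
  gm_ref <- mean_in(gm_roi)
  csf_ref <- mean_in(csf_roi)
  if (!is.finite(gm_ref) || !is.finite(csf_ref) || gm_ref <= 0)
    stop("normalization bounds are not positive finite numbers")
  if (csf_ref <= gm_ref)
    stop("bounds-order error: CSF reference (", signif(csf_ref, 4),
         ") must exceed GM reference (", signif(gm_ref, 4), ")")
  structure(list(gm_ref = gm_ref, csf_ref = csf_ref,
                 n_gm = sum(gm_roi$data), n_csf = sum(csf_roi$data),
                 summary = "mean"),
            class = "tigr_bounds")
}

#' @export
print.tigr_bounds <- function(x, ...) {
  cat(sprintf(
    "<tigr_bounds> GM ref %.3f (n=%d), CSF ref %.3f (n=%d), summary %s\n",
    x$gm_ref, x$n_gm, x$csf_ref, x$n_csf, x$summary))
  invisible(x)
}

#' Tissue damage score from the normalized ratio
#'
#' Maps each lesion voxel's ratio `r` to a continuous score
#' `0.1 + 0.9 (r - gm_ref) / (csf_ref - gm_ref)`, clamps to [0.1, 1.0]
#' (the GM reference scores 0.1, "least damaged"; the CSF reference scores
#' 1.0, "most damaged"), then rounds to the nearest multiple of 0.1 with
#' ties toward higher damage. Ten discrete score values 0.1..1.0 are used.
#' Voxels outside the lesion score 0; undefined ratio voxels inside the
#' lesion stay undefined.
#'
#' @param ratio ratio [volume()].
#' @param bounds a `tigr_bounds` object (or list with `gm_ref`, `csf_ref`).
#' @param lesion lesion [mask()].
#' @return list of class `tigr_map`: `scores` volume (0 outside lesion,
#'   multiples of 0.1 in [0.1, 1] inside), plus `bounds` and `lesion`.
#' @export
tigr_score <- function(ratio, bounds, lesion) {
  assert_aligned(ratio, lesion, "ratio and lesion")
  if (!(bounds$csf_ref > bounds$gm_ref))
    stop("invalid bounds: csf_ref must exceed gm_ref")
  scores <- array(0, dim(ratio$data))
  inside <- lesion$data > 0
  r <- ratio$data[inside]
  cont <- 0.1 + 0.9 * (r - bounds$gm_ref) / (bounds$csf_ref - bounds$gm_ref)
  cont <- pmin(1, pmax(0.1, cont))
  # bin to multiples of 0.1, ties rounding toward higher damage
  binned <- floor(round(cont * 10, 9) + 0.5) / 10
  binned <- pmin(1, pmax(0.1, binned))
  scores[inside] <- binned
  structure(list(scores = volume(scores, ratio$spacing, ratio$origin),
                 bounds = bounds, lesion = lesion),
            class = "tigr_map")
}

#' @export
print.tigr_map <- function(x, ...) {
  s <- x$scores$data[x$lesion$data > 0]
  cat(sprintf("<tigr_map> %d lesion voxels", length(s)))
  s <- s[!is.na(s)]
  if (length(s))
    cat(sprintf("; score range %.1f-%.1f, median %.1f",
                min(s), max(s), stats::median(s)))
  cat("\n")
  invisible(x)
}

#' Split a damage map into cavitation and pericavitation
#'
#' Lesion voxels scoring 1.0 form the necrotic cavitation; all other lesion
#' voxels (0.1-0.9) form the surrounding pericavitational region. The two
#' masks are disjoint and their union is the lesion (undefined-score voxels
#' fall to pericavitation).
#'
#' @param tigr a `tigr_map` from [tigr_score()].
#' @return list: `cavitation` and `pericavitation` [mask()]s.
#' @export
cavitation_split <- function(tigr) {
  stopifnot(inherits(tigr, "tigr_map"))
  s <- tigr$scores
  inside <- tigr$lesion$data > 0
  cav <- inside & !is.na(s$data) & s$data == 1
  list(cavitation = mask(cav, s$spacing, s$origin, "cavitation"),
       pericavitation = mask(inside & !cav, s$spacing, s$origin,
                             "pericavitation"))
}

#' Percent cavitation of a lesion
#'
#' 100 * cavitation volume / lesion volume, reported to one decimal.
#'
#' @param lesion_mm3 lesion volume, mm^3 (> 0).
#' @param cavitation_mm3 cavitation volume, mm^3 (0 <= cav <= lesion).
#' @return percentage rounded to one decimal.
#' @export
percent_cavitation <- function(lesion_mm3, cavitation_mm3) {
  if (any(lesion_mm3 <= 0))
    stop("percent cavitation undefined for zero lesion volume")
  if (any(cavitation_mm3 < 0) || any(cavitation_mm3 > lesion_mm3))
    stop("cavitation volume must lie in [0, lesion volume]")
  round(100 * cavitation_mm3 / lesion_mm3, 1)
}

#' Full damage-mapping stage for one subject
#'
#' Convenience wrapper: ratio, bounds, score, cavitation split and a
#' summary table of per-score voxel counts and volumes.
#'
#' @param t1w,t2w anatomical [volume()]s.
#' @param lesion,gm,csf,brain [mask()]s.
#' @return list of class `tigr_result`: `tigr` (the `tigr_map`),
#'   `cavitation`, `pericavitation`, `percent_cavitation`, `summary`
#'   (data.frame: score, n_voxels, volume_mm3).
#' @export
tigr_run <- function(t1w, t2w, lesion, gm, csf, brain) {
  ratio <- ratio_map(t2w, t1w)
  bounds <- normalization_bounds(ratio, gm, csf, lesion, brain)
  tg <- tigr_score(ratio, bounds, lesion)
  split <- cavitation_split(tg)
  les_mm3 <- mask_volume_mm3(lesion)
  cav_mm3 <- mask_volume_mm3(split$cavitation)
  s <- tg$scores$data[lesion$data > 0]
  tab <- table(factor(round(s[!is.na(s)], 1), levels = seq(0.1, 1, 0.1)))
  summary <- data.frame(score = seq(0.1, 1, 0.1),
                        n_voxels = as.integer(tab),
                        volume_mm3 = as.integer(tab) * prod(lesion$spacing))
  structure(list(tigr = tg, cavitation = split$cavitation,
                 pericavitation = split$pericavitation,
                 percent_cavitation = percent_cavitation(les_mm3, cav_mm3),
                 summary = summary),
            class = "tigr_result")
}

#' @export
print.tigr_result <- function(x, ...) {
  cat(sprintf("<tigr_result> %.1f%% cavitation; per-score voxels:\n",
              x$percent_cavitation))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
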