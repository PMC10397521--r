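#' ROI summary statistics of a CBF map
#'
#' Mean, sample standard deviation (n-1 denominator) and defined-voxel
#' count of a CBF map inside a mask. Undefined voxels are excluded, never
#' zero-filled.
#'
#' @param cbf CBF [volume()].
#' @param roi [mask()] aligned with `cbf`.
#' @return list of class `roi_stats`: `mu`, `sigma`, `n`, `label`.
#' @export
roi_stats <- function(cbf, roi) {
  assert_aligned(cbf, roi, "CBF map and ROI")
  v <- cbf$data[roi$data > 0]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("ROI '", roi$label, "' has no defined voxels")
  structure(list(mu = mean(v),
                 sigma = if (length(v) > 1) stats::sd(v) else 0,
                 n = length(v), label = roi$label),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> %s: mu %.2f, sigma %.2f, n %d\n",
              x$label, x$mu, x$sigma, x$n))
  invisible(x)
}

#' ROI quality metrics for CBF maps
#'
#' Three dimensionless metrics assess a quantified CBF map:
#' signal-to-noise ratio `SNR = mu_tissue / sigma_air`, coefficient of
#' variation `CoV = sigma_tissue / mu_tissue`, and grey-to-white
#' contrast-to-noise ratio `CNR = (mu_GM - mu_WM) / sigma_air`, where the
#' air statistics come from a sphere placed outside the head.
#'
#' @param tissue,gm,wm,air [roi_stats()] objects.
#' @return a single numeric value.
#' @export
qc_snr <- function(tissue, air) {
  if (air$sigma <= 0) stop("air ROI has zero SD; SNR undefined")
  tissue$mu / air$sigma
}

#' @rdname qc_snr
#' @export
qc_cov <- function(tissue) {
  if (tissue$mu == 0) stop("tissue ROI mean is zero; CoV undefined")
  tissue$sigma / tissue$mu
}

#' @rdname qc_snr
#' @export
qc_cnr <- function(gm, wm, air) {
  if (air$sigma <= 0) stop("air ROI has zero SD; CNR undefined")
  (gm$mu - wm$mu) / air$sigma
}

#' @rdname qc_snr
#' @param cbf CBF [volume()].
#' @param tissue_roi,gm_roi,wm_roi,air_roi [mask()]s: the tissue ROI for
#'   SNR/CoV (e.g. the ACC sphere intersected with GM), GM and WM ROIs for
#'   CNR, and the out-of-head air sphere.
#' @return `qc_report()`: list of class `qc_report` with `snr`, `cov`,
#'   `cnr` and the four input `roi_stats`.
#' @export
qc_report <- function(cbf, tissue_roi, gm_roi, wm_roi, air_roi) {
  tissue <- roi_stats(cbf, tissue_roi)
  gm <- roi_stats(cbf, gm_roi)
  wm <- roi_stats(cbf, wm_roi)
  air <- roi_stats(cbf, air_roi)
  structure(list(snr = qc_snr(tissue, air), cov = qc_cov(tissue),
                 cnr = qc_cnr(gm, wm, air),
                 inputs = list(tissue = tissue, gm = gm, wm = wm,
                               air = air),
                 sd_convention = "sample (n-1)"),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> SNR %.2f, CoV %.3f, CNR %.2f\n",
              x$snr, x$cov, x$cnr))
  invisible(x)
}
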