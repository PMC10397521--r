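#' pCASL acquisition parameters
#'
#' Timing parameters of the 2D ascending pCASL acquisition. The post-label
#' delay experienced by a voxel grows with its slice index:
#' `PLD_slice = pld + slice_index * slice_time` (0-based slices along
#' `slice_axis`).
#'
#' @param pld post-labeling delay, ms.
#' @param tau labeling duration, ms.
#' @param slice_time per-slice acquisition time, ms.
#' @param slice_axis axis index (1..3) of the 2D slice stacking.
#' @param tr_m0 repetition time of the M0 calibration scan, ms.
#' @return list of class `acquisition_params`.
#' @export
acquisition_params <- function(pld = 2200, tau = 1500, slice_time = 37.5,
                               slice_axis = 3, tr_m0 = 10000) {
  stopifnot(pld > 0, tau > 0, slice_time > 0, slice_axis %in% 1:3)
  structure(list(pld = pld, tau = tau, slice_time = slice_time,
                 slice_axis = as.integer(slice_axis), tr_m0 = tr_m0),
            class = "acquisition_params")
}

#' Single-compartment quantification constants
#'
#' Consensus values for pCASL at 3T: blood-brain partition coefficient
#' lambda = 0.9 mL/g, labeling efficiency alpha = 0.85, arterial blood T1 =
#' 1650 ms, and the unit factor 6000 converting to mL/100g/min.
#'
#' @param lambda blood-brain partition coefficient, mL/g.
#' @param alpha labeling efficiency (0 < alpha <= 1).
#' @param t1_blood longitudinal relaxation time of arterial blood, ms.
#' @param scale unit factor to mL/100g/min.
#' @return list of class `quant_constants`.
#' @export
quant_constants <- function(lambda = 0.9, alpha = 0.85, t1_blood = 1650,
                            scale = 6000) {
  stopifnot(lambda > 0, alpha > 0, alpha <= 1, t1_blood > 0, scale > 0)
  structure(list(lambda = lambda, alpha = alpha, t1_blood = t1_blood,
                 scale = scale), class = "quant_constants")
}

#' Interleaved control/label perfusion series
#'
#' @param frames 4D array (x, y, z, frame) of raw ASL frames.
#' @param roles character per-frame tag, `"control"` or `"label"`; frames
#'   must pair up in acquisition order with equal counts (the interleaving
#'   order is recorded here, so either convention can be represented).
#' @param m0 M0 calibration [volume()] (or a 3D array sharing the grid).
#' @param params [acquisition_params()].
#' @param spacing voxel spacing, used when `m0` is a bare array.
#' @return list of class `perfusion_series`.
#' @export
perfusion_series <- function(frames, roles, m0, params = acquisition_params(),
                             spacing = c(1, 1, 1)) {
  if (length(dim(frames)) != 4L) stop("frames must be a 4D array")
  n <- dim(frames)[4]
  roles <- match.arg(roles, c("control", "label"), several.ok = TRUE)
  if (length(roles) != n) stop("one role per frame required")
  if (sum(roles == "control") != sum(roles == "label"))
    stop("unequal numbers of control and label frames")
  # frames must alternate so consecutive frames form a pair
  pr <- matrix(roles, nrow = 2)
  if (any(pr[1, ] == pr[2, ]))
    stop("frames do not pair up control/label in acquisition order")
  if (!is_volume(m0)) m0 <- volume(m0, spacing)
  if (!identical(dim(frames)[1:3], dim(m0$data)))
    stop("alignment error: frames and m0 differ in shape")
  structure(list(frames = frames, roles = roles, m0 = m0, params = params),
            class = "perfusion_series")
}

#' @export
print.perfusion_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<perfusion_series> %d frames (%d pairs, first frame %s) of %s voxels\n",
              d[4], d[4] / 2, x$roles[1],
              paste(d[1:3], collapse = "x")))
  invisible(x)
}

#' Motion-based censoring of control/label pairs
#'
#' A pair is censored when either of its two frames moves beyond the
#' thresholds: Euclidean norm of the three translations > `max_translation`
#' mm, or maximum absolute rotation > `max_rotation` degrees
#' (either-criterion reading of the censoring rule). Motion is taken
#' relative to the first frame, as recorded in the trace.
#'
#' @param max_translation mm (default 0.7).
#' @param max_rotation degrees (default 5).
#' @param min_pairs minimum number of surviving pairs; fewer is a hard
#'   error (default 32 of 40).
#' @return `censor_config()`: list of class `censor_config`.
#' @export
censor_config <- function(max_translation = 0.7, max_rotation = 5,
                          min_pairs = 32) {
  stopifnot(max_translation > 0, max_rotation > 0, min_pairs > 0)
  structure(list(max_translation = max_translation,
                 max_rotation = max_rotation,
                 min_pairs = as.integer(min_pairs)),
            class = "censor_config")
}

#' @rdname censor_config
#' @param trace data.frame with one row per frame and columns
#'   `tx, ty, tz` (mm) and `rx, ry, rz` (degrees).
#' @param config a `censor_config()`.
#' @return `censor_pairs()`: integer vector of kept pair indices (1-based),
#'   in order.
#' @export
censor_pairs <- function(trace, config = censor_config()) {
  need <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (!all(need %in% names(trace)))
    stop("motion trace must have columns ", paste(need, collapse = ", "))
  n_frames <- nrow(trace)
  if (n_frames %% 2 != 0) stop("trace must cover an even number of frames")
  tnorm <- sqrt(trace$tx^2 + trace$ty^2 + trace$tz^2)
  rmax <- pmax(abs(trace$rx), abs(trace$ry), abs(trace$rz))
  bad_frame <- tnorm > config$max_translation | rmax > config$max_rotation
  bad_pair <- matrix(bad_frame, nrow = 2)
  kept <- which(!(bad_pair[1, ] | bad_pair[2, ]))
  if (length(kept) < config$min_pairs)
    stop("motion censoring left ", length(kept), " pairs (of ",
         n_frames / 2, "); minimum is ", config$min_pairs)
  kept
}

#' Average control-minus-label difference signal
#'
#' Subtracts each kept label frame from its control frame and averages over
#' kept pairs.
#'
#' @param series a [perfusion_series()].
#' @param kept integer pair indices from [censor_pairs()].
#' @return the mean difference signal as a [volume()].
#' @export
subtract_pairs <- function(series, kept) {
  stopifnot(inherits(series, "perfusion_series"))
  if (length(kept) == 0) stop("no pairs to subtract")
  n_pairs <- dim(series$frames)[4] / 2
  if (any(kept < 1 | kept > n_pairs)) stop("pair index out of range")
  acc <- array(0, dim(series$frames)[1:3])
  for (p in kept) {
    f1 <- 2L * p - 1L; f2 <- 2L * p
    ctl <- if (series$roles[f1] == "control") f1 else f2
    lbl <- if (ctl == f1) f2 else f1
    acc <- acc + series$frames[, , , ctl] - series$frames[, , , lbl]
  }
  volume(acc / length(kept), series$m0$spacing, series$m0$origin)
}

# 1D sampled-Gaussian convolution matrix (rows renormalized at the edges)
gauss_band <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

#' Mask-renormalized Gaussian smoothing
#'
#' Separable 3D Gaussian smoothing with kernel SD
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis, converted to voxels via the
#' spacing. When `within` is given, smoothing is renormalized over the mask
#' (weights of voxels outside the mask, and of undefined voxels, are
#' redistributed), so a constant field over the mask is preserved exactly;
#' voxels outside the mask are returned unchanged. `fwhm = 0` is the
#' identity.
#'
#' @param vol a [volume()].
#' @param fwhm full width at half maximum, mm (>= 0).
#' @param within optional [mask()] restricting the smoothing support.
#' @return the smoothed volume.
#' @export
smooth_gaussian <- function(vol, fwhm, within = NULL) {
  stopifnot(is_volume(vol), fwhm >= 0)
  if (fwhm == 0) return(vol)
  sigma_vox <- (fwhm / (2 * sqrt(2 * log(2)))) / vol$spacing
  d <- dim(vol$data)
  K <- lapply(1:3, function(ax) gauss_band(d[ax], sigma_vox[ax]))
  conv3 <- function(x) {
    # axis 1
    x <- array(K[[1]] %*% matrix(x, d[1]), d)
    # axis 2
    x <- aperm(x, c(2, 1, 3))
    x <- array(K[[2]] %*% matrix(x, d[2]), d[c(2, 1, 3)])
    x <- aperm(x, c(2, 1, 3))
    # axis 3
    array(matrix(x, d[1] * d[2]) %*% t(K[[3]]), d)
  }
  if (is.null(within)) {
    x <- vol$data
    nas <- is.na(x)
    if (any(nas)) {
      w <- conv3(array(as.numeric(!nas), d))
      x[nas] <- 0
      out <- conv3(x) / pmax(w, .Machine$double.eps)
      out[nas] <- NA_real_
    } else {
      out <- conv3(x)
    }
  } else {
    assert_aligned(vol, within, "volume and smoothing mask")
    m <- within$data > 0 & !is.na(vol$data)
    x <- vol$data
    x[!m] <- 0
    num <- conv3(x)
    den <- conv3(array(as.numeric(m), d))
    out <- vol$data
    inside <- within$data > 0
    out[inside] <- num[inside] / pmax(den[inside], .Machine$double.eps)
    out[inside & is.na(vol$data)] <- NA_real_
  }
  volume(out, vol$spacing, vol$origin)
}

# per-voxel factor A with CBF = A * deltaM / m0; varies along the slice axis
cbf_scale_factor <- function(ref, params = acquisition_params(),
                             constants = quant_constants()) {
  d <- dim(ref$data)
  t1b <- constants$t1_blood
  slice_idx <- seq_len(d[params$slice_axis]) - 1
  pld_slice <- params$pld + slice_idx * params$slice_time
  a_slice <- constants$scale * constants$lambda * exp(pld_slice / t1b) /
    (2 * constants$alpha * (t1b / 1000) * (1 - exp(-params$tau / t1b)))
  perm <- c(params$slice_axis, setdiff(1:3, params$slice_axis))
  arr <- array(a_slice, d[perm])
  aperm(arr, order(perm))
}

#' Single-compartment CBF quantification
#'
#' Converts the averaged control-minus-label difference signal and the M0
#' calibration image to CBF in mL/100g/min under the single-compartment
#' model for a 2D ascending acquisition:
#' \deqn{CBF = \frac{6000 \,\lambda\, \Delta M \, e^{PLD_{slice}/T_{1b}}}
#'   {2 \alpha T_{1b}[s] \, M_0 \,(1 - e^{-\tau/T_{1b}})}}
#' with \eqn{PLD_{slice} = PLD + slice \cdot slice\_time}. Voxels with
#' M0 at or below `m0_threshold` are marked undefined.
#'
#' @param deltaM difference-signal [volume()].
#' @param m0 M0 [volume()].
#' @param params [acquisition_params()].
#' @param constants [quant_constants()].
#' @param m0_threshold voxels with `m0 <= m0_threshold` become `NA`.
#' @param brain optional brain [mask()]; if more than `tol_frac` of brain
#'   voxels have non-positive M0 a warning reports the count.
#' @param tol_frac tolerated fraction of non-positive M0 inside the brain.
#' @return CBF [volume()], mL/100g/min.
#' @export
quantify_cbf <- function(deltaM, m0, params = acquisition_params(),
                         constants = quant_constants(),
                         m0_threshold = 1e-6, brain = NULL,
                         tol_frac = 0.01) {
  assert_aligned(deltaM, m0, "difference signal and M0")
  A <- cbf_scale_factor(deltaM, params, constants)
  bad <- is.na(m0$data) | m0$data <= m0_threshold
  if (!is.null(brain)) {
    nb <- sum(bad & brain$data > 0)
    if (nb > tol_frac * sum(brain$data > 0))
      warning(nb, " brain voxels have non-positive M0 and were marked missing")
  }
  cbf <- A * deltaM$data / m0$data
  cbf[bad] <- NA_real_
  volume(cbf, deltaM$spacing, deltaM$origin)
}

#' Run a full ASL analysis pipeline variant
#'
#' The three variants share censoring and quantification and differ only in
#' the placement of the 4 mm FWHM Gaussian smoothing:
#' \describe{
#'   \item{`no_blur`}{censor, subtract, quantify.}
#'   \item{`blur4_native`}{censor, smooth the raw frames in native space,
#'     subtract, quantify. Smoothing each control and label frame and then
#'     averaging the differences equals smoothing the averaged difference
#'     signal (smoothing is linear), which is how it is computed.}
#'   \item{`blur4_mni`}{censor, subtract, quantify, smooth the CBF map in
#'     the common (template) space.}
#' }
#' Smoothing is renormalized within the brain mask, so out-of-brain noise
#' is untouched by either placement. Censoring decisions are identical
#' across variants.
#'
#' @param series a [perfusion_series()].
#' @param trace motion trace data.frame (see [censor_pairs()]).
#' @param brain brain [mask()].
#' @param variant one of `"no_blur"`, `"blur4_native"`, `"blur4_mni"`.
#' @param censor a [censor_config()].
#' @param fwhm smoothing kernel FWHM in mm (default 4; 0 disables smoothing
#'   in every variant).
#' @param constants [quant_constants()].
#' @return list of class `cbf_result`: `cbf` volume, `kept` pair indices,
#'   `variant`, `fwhm`, `params`, `constants`.
#' @export
cbf_pipeline <- function(series, trace, brain,
                         variant = c("no_blur", "blur4_native", "blur4_mni"),
                         censor = censor_config(), fwhm = 4,
                         constants = quant_constants()) {
  variant <- match.arg(variant)
  stopifnot(inherits(series, "perfusion_series"))
  assert_aligned(series$m0, brain, "series and brain mask")
  kept <- censor_pairs(trace, censor)
  dm <- subtract_pairs(series, kept)
  if (variant == "blur4_native")
    dm <- smooth_gaussian(dm, fwhm, within = brain)
  cbf <- quantify_cbf(dm, series$m0, series$params, constants, brain = brain)
  if (variant == "blur4_mni")
    cbf <- smooth_gaussian(cbf, fwhm, within = brain)
  structure(list(cbf = cbf, kept = kept, variant = variant, fwhm = fwhm,
                 params = series$params, constants = constants),
            class = "cbf_result")
}

#' @export
print.cbf_result <- function(x, ...) {
  cat(sprintf("<cbf_result> variant %s (fwhm %g mm), %d pairs kept\n",
              x$variant, x$fwhm, length(x$kept)))
  print(x$cbf)
  invisible(x)
}
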