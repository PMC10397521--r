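#' Specification of a synthetic stroke-brain phantom
#'
#' Collects every parameter of the synthetic dataset generator: grid
#' geometry, per-tissue image intensities and proton density, true CBF per
#' tissue, the lesion (location, size, graded damage profile and its CBF
#' model), acquisition parameters, additive noise levels, the motion model
#' and subject demographics. The defaults define the package's reference
#' study conditions; see the methods vignette for the rationale behind each
#' value.
#'
#' The brain is an ellipsoid centred on the world origin (midsagittal plane
#' at x = 0) with a cortical grey-matter shell, a white-matter core and two
#' anterior lateral-ventricle CSF ellipsoids. The lesion is a sphere in one
#' hemisphere; damage is 1.0 over a necrotic core (`core_frac` of the
#' radius) and ramps linearly from `rim_damage` (0.1) at the rim to
#' 1.0 at the core, and lesion CBF follows
#' `cbf = rim_cbf - cbf_slope * (damage - rim_damage)`, clipped at 0. The
#' optional `"gm_jump"` profile adds a step increase of `jump` at damage
#' >= 0.6, emulating a mid-score CBF rise from a white-to-grey tissue
#' transition.
#'
#' @param shape voxel counts per axis (default 64^3).
#' @param spacing voxel size mm (default 2 mm isotropic).
#' @param brain_semi ellipsoid semi-axes of the brain, mm.
#' @param t1w,t2w,pd named per-tissue intensities (gm, wm, csf, bg); `pd` is
#'   the proton density that scales the M0 and control images. The
#'   background value is the receiver noise floor, kept positive so air
#'   voxels carry defined (pure-noise) CBF values for the quality metrics.
#' @param true_cbf named per-tissue CBF, mL/100g/min (csf and bg must be 0).
#' @param lesion list: `center` (world mm), `radius` (mm), `rim_damage`,
#'   `core_frac` (fraction of the radius occupied by the fully necrotic
#'   damage-1.0 core; 0.6 gives ~22% cavitation by volume, inside the
#'   5-52% range seen across the reference cohort), `rim_cbf`
#'   (mL/100g/min at the rim), `cbf_slope` (mL/100g/min per unit damage,
#'   > 0 means CBF falls with damage), `profile` (`"linear"` or
#'   `"gm_jump"`), `jump` (mL/100g/min).
#' @param noise named additive Gaussian SDs: `t1w`, `t2w`, `asl` (per
#'   frame), `m0`.
#' @param n_pairs number of control/label pairs (>= 1).
#' @param motion list: `step_trans`/`step_rot` random-walk step SDs (mm,
#'   deg), `n_excursions` frames with injected large motion,
#'   `excursion_trans`/`excursion_rot` excursion magnitudes exceeding the
#'   censoring thresholds.
#' @param params [acquisition_params()].
#' @param demographics list: `age` (years), `sex` ("M"/"F"),
#'   `months_since_stroke`, `wab_aq`.
#' @param seed integer seed making the generator deterministic.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = c(2, 2, 2),
                         brain_semi = c(50, 58, 45),
                         t1w = c(gm = 100, wm = 120, csf = 40, bg = 5),
                         t2w = c(gm = 80, wm = 66, csf = 120, bg = 5),
                         pd = c(gm = 900, wm = 750, csf = 1200, bg = 30),
                         true_cbf = c(gm = 50, wm = 25, csf = 0, bg = 0),
                         lesion = list(),
                         noise = list(),
                         n_pairs = 40,
                         motion = list(),
                         params = acquisition_params(),
                         demographics = list(),
                         seed = 1) {
  lesion <- utils::modifyList(
    list(center = c(-25, 5, 5), radius = 22, rim_damage = 0.1,
         core_frac = 0.6, rim_cbf = 40, cbf_slope = 20,
         profile = "linear", jump = 8),
    lesion)
  noise <- utils::modifyList(
    list(t1w = 2, t2w = 2, asl = 2, m0 = 2), noise)
  motion <- utils::modifyList(
    list(step_trans = 0.02, step_rot = 0.1, n_excursions = 4,
         excursion_trans = 1.5, excursion_rot = 8), motion)
  demographics <- utils::modifyList(
    list(age = 55, sex = "M", months_since_stroke = 40, wab_aq = 65),
    demographics)
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               brain_semi = as.numeric(brain_semi),
               t1w = t1w, t2w = t2w, pd = pd, true_cbf = true_cbf,
               lesion = lesion, noise = noise, n_pairs = as.integer(n_pairs),
               motion = motion, params = params,
               demographics = demographics, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (spec$n_pairs < 1) stop("spec error: need at least one pair")
  if (spec$true_cbf[["csf"]] != 0 || spec$true_cbf[["bg"]] != 0)
    stop("spec error: CSF and background CBF must be 0")
  if (any(spec$true_cbf < 0)) stop("spec error: CBF must be >= 0")
  les <- spec$lesion
  if (abs(les$center[1]) < les$radius)
    stop("spec error: lesion of radius ", les$radius,
         " mm centred at x = ", les$center[1],
         " mm crosses the midsagittal plane")
  half_fov <- spec$shape * spec$spacing / 2
  if (any(abs(les$center) + les$radius > half_fov + max(spec$spacing)))
    stop("spec error: lesion exceeds the grid/hemisphere extent")
  if (!les$profile %in% c("linear", "gm_jump"))
    stop("spec error: unknown lesion CBF profile: ", les$profile)
  invisible(spec)
}

# per-voxel squared ellipsoidal coordinate for an axis-aligned ellipsoid
ellipsoid_rho2 <- function(ref, center, semi) {
  ex <- ((axis_coords(ref, 1) - center[1]) / semi[1])^2
  ey <- ((axis_coords(ref, 2) - center[2]) / semi[2])^2
  ez <- ((axis_coords(ref, 3) - center[3]) / semi[3])^2
  outer(outer(ex, ey, "+"), ez, "+")
}

#' Generate a synthetic stroke-brain dataset
#'
#' Produces every input the analysis stages consume -- T1w and T2w
#' anatomicals, GM/WM/CSF segmentation and brain masks, the lesion mask, an
#' interleaved control/label perfusion series with an M0 calibration volume,
#' and a per-frame rigid-motion trace -- together with a ground-truth record
#' (tissue labels, per-voxel damage, per-voxel true CBF, the frames that
#' carry injected motion excursions, and a parameter manifest).
#'
#' The control/label difference signal is constructed by inverting the
#' single-compartment quantification model at the true CBF, so with zero
#' noise the quantification stage recovers the true CBF exactly. Inside the
#' lesion the T2w/T1w ratio increases linearly with true damage between the
#' GM and CSF reference ratios, making the damage-score mapping exactly
#' invertible as well. Frames are interleaved control first (recorded in the
#' series metadata); excursion frames additionally carry inflated noise so
#' censoring is consequential.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `stroke_phantom` with elements `t1w`, `t2w`, `seg`
#'   (list of gm/wm/csf/brain masks), `lesion`, `series`
#'   ([perfusion_series()]), `motion` (data.frame: frame, tx, ty, tz, rx,
#'   ry, rz), `truth` (tissue/damage/cbf volumes, `corrupted_frames`,
#'   `manifest`), and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  ref <- volume(array(0, spec$shape), spec$spacing)

  rho2 <- ellipsoid_rho2(ref, c(0, 0, 0), spec$brain_semi)
  brain <- rho2 <= 1
  gm <- brain & rho2 > 0.88^2
  vent_l <- ellipsoid_rho2(ref, c(-14, 10, 6), c(6, 10, 8)) <= 1
  vent_r <- ellipsoid_rho2(ref, c(14, 10, 6), c(6, 10, 8)) <= 1
  csf <- (vent_l | vent_r) & brain & !gm
  wm <- brain & !gm & !csf

  les <- spec$lesion
  dx2 <- (axis_coords(ref, 1) - les$center[1])^2
  dy2 <- (axis_coords(ref, 2) - les$center[2])^2
  dz2 <- (axis_coords(ref, 3) - les$center[3])^2
  rad <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  lesion <- rad <= les$radius & brain

  # fully necrotic core (damage 1.0) out to core_frac * radius, then a
  # linear ramp down to rim_damage at the rim
  damage <- array(0, spec$shape)
  ramp <- pmin(1, (1 - rad[lesion] / les$radius) / (1 - les$core_frac))
  damage[lesion] <- les$rim_damage + (1 - les$rim_damage) * pmax(0, ramp)

  # tissue labels partition the brain: 1 GM, 2 WM, 3 CSF, 4 lesion
  tissue <- array(0L, spec$shape)
  tissue[gm] <- 1L; tissue[wm] <- 2L; tissue[csf] <- 3L
  tissue[lesion] <- 4L

  by_class <- function(tbl) {
    out <- array(tbl[["bg"]], spec$shape)
    out[gm] <- tbl[["gm"]]; out[wm] <- tbl[["wm"]]; out[csf] <- tbl[["csf"]]
    out
  }
  t1w_clean <- by_class(spec$t1w)
  pd_clean <- by_class(spec$pd)
  cbf_true <- by_class(spec$true_cbf)
  t2w_clean <- by_class(spec$t2w)

  # lesion: interpolate between GM-like and CSF-like with damage so the
  # T2w/T1w ratio rises linearly from the GM to the CSF reference ratio
  u <- (damage[lesion] - les$rim_damage) / (1 - les$rim_damage)
  r_gm <- spec$t2w[["gm"]] / spec$t1w[["gm"]]
  r_csf <- spec$t2w[["csf"]] / spec$t1w[["csf"]]
  t1w_clean[lesion] <- spec$t1w[["gm"]] +
    (spec$t1w[["csf"]] - spec$t1w[["gm"]]) * u
  t2w_clean[lesion] <- (r_gm + (r_csf - r_gm) * u) * t1w_clean[lesion]
  pd_clean[lesion] <- spec$pd[["gm"]] +
    (spec$pd[["csf"]] - spec$pd[["gm"]]) * u

  cbf_les <- les$rim_cbf - les$cbf_slope * (damage[lesion] - les$rim_damage)
  if (les$profile == "gm_jump")
    cbf_les <- cbf_les + ifelse(damage[lesion] >= 0.6, les$jump, 0)
  cbf_true[lesion] <- pmax(0, cbf_les)

  n_frames <- 2L * spec$n_pairs
  # motion: smooth random walk from the reference (first) frame ...
  mo <- spec$motion
  steps <- matrix(stats::rnorm(6 * n_frames,
                               sd = rep(c(mo$step_trans, mo$step_rot),
                                        each = 3 * n_frames)),
                  nrow = n_frames)
  trace <- apply(steps, 2, cumsum)
  trace <- sweep(trace, 2, trace[1, ])  # reference frame has zero motion
  # ... plus injected excursions exceeding the censoring thresholds
  corrupted <- integer(0)
  if (mo$n_excursions > 0) {
    corrupted <- sort(sample(2:n_frames, mo$n_excursions))
    for (k in seq_along(corrupted)) {
      f <- corrupted[k]
      if (k %% 2 == 1) trace[f, 1] <- trace[f, 1] + mo$excursion_trans
      else trace[f, 6] <- trace[f, 6] + mo$excursion_rot
    }
  }
  motion <- data.frame(frame = seq_len(n_frames) - 1L,
                       tx = trace[, 1], ty = trace[, 2], tz = trace[, 3],
                       rx = trace[, 4], ry = trace[, 5], rz = trace[, 6])

  # difference signal from inverting the quantification model at true CBF
  qk <- quant_constants()
  delta_true <- cbf_true * pd_clean /
    cbf_scale_factor(ref, params = spec$params, constants = qk)
  control_clean <- pd_clean
  label_clean <- control_clean - delta_true

  frames <- array(0, c(spec$shape, n_frames))
  roles <- rep(c("control", "label"), spec$n_pairs)
  nvox <- prod(spec$shape)
  for (f in seq_len(n_frames)) {
    base <- if (roles[f] == "control") control_clean else label_clean
    sd_f <- if (f %in% corrupted) 8 * spec$noise$asl else spec$noise$asl
    frames[, , , f] <- base +
      if (sd_f > 0) stats::rnorm(nvox, sd = sd_f) else 0
  }
  m0 <- volume(pd_clean +
                 if (spec$noise$m0 > 0)
                   stats::rnorm(nvox, sd = spec$noise$m0) else 0,
               spec$spacing)
  add_noise <- function(clean, sd)
    volume(clean + if (sd > 0) stats::rnorm(nvox, sd = sd) else 0,
           spec$spacing)

  lesion_mm3 <- sum(lesion) * prod(spec$spacing)
  manifest <- c(spec$demographics,
                list(seed = spec$seed,
                     lesion_center = les$center,
                     lesion_radius_mm = les$radius,
                     lesion_volume_mm3 = lesion_mm3,
                     lesion_volume_ml = lesion_mm3 / 1000,
                     rim_cbf = les$rim_cbf,
                     cbf_slope = les$cbf_slope,
                     profile = les$profile,
                     n_pairs = spec$n_pairs,
                     n_corrupted_frames = length(corrupted)))

  structure(list(
    t1w = add_noise(t1w_clean, spec$noise$t1w),
    t2w = add_noise(t2w_clean, spec$noise$t2w),
    seg = list(gm = mask(gm & !lesion, spec$spacing, label = "GM"),
               wm = mask(wm & !lesion, spec$spacing, label = "WM"),
               csf = mask(csf & !lesion, spec$spacing, label = "CSF"),
               brain = mask(brain, spec$spacing, label = "brain")),
    lesion = mask(lesion, spec$spacing, label = "lesion"),
    series = perfusion_series(frames, roles, m0, spec$params,
                              spacing = spec$spacing),
    motion = motion,
    truth = list(tissue = volume(tissue, spec$spacing),
                 damage = volume(damage, spec$spacing),
                 cbf = volume(cbf_true, spec$spacing),
                 corrupted_frames = corrupted,
                 manifest = manifest),
    spec = spec), class = "stroke_phantom")
}

#' @export
print.stroke_phantom <- function(x, ...) {
  m <- x$truth$manifest
  cat(sprintf(paste0("<stroke_phantom> %s grid at %s mm; lesion %.1f mL ",
                     "(radius %g mm), %d control/label pairs, ",
                     "%d motion-corrupted frames\n"),
              paste(x$spec$shape, collapse = "x"),
              paste(x$spec$spacing, collapse = "x"),
              m$lesion_volume_ml, m$lesion_radius_mm,
              m$n_pairs, m$n_corrupted_frames))
  invisible(x)
}
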