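---
title: "Methods: perfusion and tissue-damage mapping in chronic stroke lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perfusion and tissue-damage mapping in chronic stroke lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecbf)
```

## The problem

Chronic stroke lesions are not uniformly dead tissue. A necrotic,
CSF-filled cavitation is typically surrounded by pericavitational tissue
with graded damage that may still be metabolically active and hence a
candidate target for rehabilitation. This package implements a desk-scale,
fully testable version of a two-arm analysis of such lesions:

1. **Tissue damage** is quantified per voxel as a normalized T2w/T1w ratio
   ("TIGR"): damaged tissue loses T1w signal and gains T2w signal, so the
   ratio rises monotonically from intact grey matter toward free CSF.
2. **Perfusion** (cerebral blood flow, CBF, in mL/100 g/min) is quantified
   from an interleaved control/label pCASL series with a single-compartment
   model, under three placements of spatial smoothing.

The two maps are then related statistically: within each subject, mean CBF
per damage score is regressed on the score; across subjects, lesion CBF is
modelled with damage, age, sex, time since stroke and their cross-terms.

Because no patient data are distributed, every claim the package makes is
exercised on a synthetic stroke-brain phantom with known ground truth, and
two small published summary tables (demographics/lesion volumes and
per-subject fit statistics) ship as example data for the arithmetic-level
checks.

## The damage score

Given aligned T1w and T2w volumes and a binary lesion mask, the per-voxel
ratio $r = \mathrm{T2w}/\mathrm{T1w}$ is anchored to two subject-specific
references taken on the hemisphere *opposite* the lesion, restricted to the
anterior half of the brain and eroded by one voxel (6-connectivity):

* $r_{GM}$: mean ratio in the contralesional anterior grey-matter ribbon
  (score 0.1, "least damaged");
* $r_{CSF}$: mean ratio in the contralesional anterior lateral ventricle
  (score 1.0, "most damaged").

Each lesion voxel receives the continuous score
$c = 0.1 + 0.9\,(r - r_{GM})/(r_{CSF} - r_{GM})$, clamped to $[0.1, 1.0]$
and binned to the nearest multiple of 0.1. Anchoring to the subject's own
intact tissue makes the score invariant to global intensity scaling, coil
loading and head size; the suite asserts this invariance directly.

Decisions made where the procedure was genuinely open:

* **Ten discrete scores** (0.1, 0.2, ..., 1.0) are used. The per-score ROI
  analysis enumerates ten values, and the per-subject regression's
  F(1,8) degrees of freedom are only consistent with ten points; we follow
  that arithmetic.
* **Ties round toward higher damage** (0.55 bins to 0.6): conservative
  toward flagging damage; the direction is otherwise arbitrary and is
  asserted in the tests.
* **The ROI summary is the mean** (not the median); the choice is recorded
  in the `tigr_bounds` object.
* **"Anterior"** is implemented as the anterior half of the brain
  bounding box along the y axis — no atlas landmark is available in a
  synthetic common space.
* **Erosion uses the 6-connectivity element**, one voxel per iteration,
  the smallest standard reading of "eroded by one voxel".
* Voxels with undefined values are excluded from every mean/SD rather than
  zero-filled; zero-filling would bias CBF and ratio means downward.

Cavitation is defined as the score-1.0 region, pericavitation as
0.1–0.9, and percent cavitation as 100 x cavitation/lesion volume.

## CBF quantification and smoothing placement

Frames are censored pairwise using the rigid-motion trace: a control/label
pair is dropped when either frame exceeds 0.7 mm translation (Euclidean
norm) or 5 degrees rotation (maximum absolute). The combined
"0.7 mm and 5 degrees" rule is applied as *either-criterion* censoring —
the stricter interpretation — with both thresholds exposed in
`censor_config()`.
Fewer than 32 surviving pairs (of 40) is a hard error. Motion is taken
relative to the first frame.

The averaged difference signal $\Delta M$ and the M0 calibration image give

$$\mathrm{CBF} = \frac{6000\,\lambda\,\Delta M\,
  e^{PLD_{slice}/T_{1b}}}{2\,\alpha\,T_{1b}[s]\,M_0\,
  (1 - e^{-\tau/T_{1b}})}$$

with the 2D ascending acquisition's slice-dependent delay
$PLD_{slice} = PLD + \mathrm{slice} \times 37.5$ ms, $PLD = 2200$ ms,
$\tau = 1500$ ms. The constants default to the pCASL consensus values at
3T ($\lambda = 0.9$ mL/g, $\alpha = 0.85$, $T_{1b} = 1650$ ms), the
standard choice when a protocol specifies only a single-compartment
model; they are
config-exposed and recorded in every result object. No background
suppression and no lesion-specific tissue T1 correction are modelled —
the T1 of chronically lesioned tissue is unknown without an extra scan.

The three pipeline variants share censoring and quantification and differ
only in where the 4 mm FWHM Gaussian smoothing sits:

* `no_blur`: censor, subtract, quantify;
* `blur4_native`: censor, smooth the raw frames, subtract, quantify.
  Since smoothing is linear, smoothing every frame and averaging the
  differences equals smoothing the averaged difference, which is how it is
  computed;
* `blur4_mni`: censor, subtract, quantify, smooth the CBF map in the
  common space. (The package works in a single voxel-aligned space;
  no warp is applied, so "MNI" smoothing is smoothing in that common
  space.)

Smoothing is renormalized within the brain mask — a constant field over
the mask is preserved exactly, out-of-brain voxels are untouched — with a
sampled-Gaussian kernel, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per
axis converted to voxels. The quantification divides by M0 *after* any
native-space smoothing but *before* template-space smoothing; because grey
and white matter differ in proton density, the native placement mixes
M0-weighted signal across the GM/WM boundary and loses more grey-white
contrast than the template placement. That mechanism, verified
analytically in one dimension before implementation, is what the
pipeline-comparison test measures.

## Quality metrics

`qc_report()` computes, with the sample SD convention throughout:
SNR $= \mu_{tissue}/\sigma_{air}$, CoV
$= \sigma_{tissue}/\mu_{tissue}$, and GM-WM CNR
$= (\mu_{GM} - \mu_{WM})/\sigma_{air}$, with the air statistics from a
15 mm sphere placed outside the head. The air SD is computed on the
CBF-scaled map (the definition speaks of "the standard deviation of the
CBF"). Since smoothing is brain-masked, $\sigma_{air}$ is identical across
variants and the CNR ordering is carried entirely by the contrast
numerator. The absolute CNR magnitude depends on the background
proton-density floor of the M0 image (a scanner property); the phantom's
floor is deliberately low, so only orderings and ratios of these metrics
are meaningful, not their absolute values.

## The statistical models

**Per subject**, mean CBF per damage score is regressed on the score by
unweighted OLS (`fit_score_regression()`), reporting $R^2$, $F(1, n-2)$,
the two-sided p and the slope sign. The identity
$F = (n-2)R^2/(1-R^2)$ holds by construction and is asserted. Rows are
unweighted — the reference F(1,8) degrees of freedom are only consistent
with one row per score, voxel counts notwithstanding. Significance across
subjects uses the Bonferroni rule $p < 0.01/N$, with uncorrected flags at
0.05 reported alongside.

**Across subjects**, `fit_factor_model()` fits per-score mean lesion CBF
on ten terms: sex, age, damage, time since stroke, and the six pairwise
cross-terms (residual df $= n_{rows} - 11$; 14 subjects x 10 scores gives
F(10, 129)). Continuous factors are mean-centered before cross-products
are formed — simultaneous stable main effects and interactions require
it — and sex is effect-coded (F = +1, M = -1) so main effects remain
interpretable in the presence of interactions. Damage enters as the
continuous 0.1–1.0 score. Per-term t statistics are reported unadjusted.
An aphasia-severity (WAB-AQ) variant adds that score and its cross-terms.

Group-level spatial tools: `group_overlap_mask()` thresholds the
per-voxel subject count (minimum 10 of 14 in the reference cohort), and
`voxelwise_covariate_removal()` regresses each voxel's CBF across
subjects on lesion or cavitation volume, replacing values by residuals
plus the voxel grand mean only where the slope is significant at 0.05.
The package stops at the masked, covariate-residualized CBF stack — the
documented hand-off for multivariate brain-behavior mapping, which is an
external published method and out of scope here.

## The phantom: what it emulates and what it does not

`make_phantom()` builds a brain as an ellipsoid (semi-axes 50 x 58 x 45
mm) centred on the world origin with a ~6 mm cortical GM shell, WM
interior and two anterior ventricles; the midsagittal plane is world
x = 0. A spherical lesion sits in the left hemisphere with damage 1.0
over a necrotic core (`core_frac` = 0.6 of the radius, ~22% cavitation by
volume, inside the 5–52% range of the reference cohort) ramping linearly
to 0.1 at the rim. Lesion CBF follows
$\mathrm{CBF}(d) = 40 - 20\,(d - 0.1)$ mL/100 g/min, clipped at zero —
rim value and slope are the package's reference conditions for parameter
recovery. True CBF is 50/25/0 for GM/WM/CSF. An optional `gm_jump`
profile adds a step increase at damage 0.6, emulating the mid-score CBF
rise that a white-to-grey tissue transition would produce.

The ASL series is generated by *inverting* the quantification formula at
the true CBF, so with zero noise the pipeline recovers truth to machine
precision — the suite's strongest internal consistency check. Lesion T1w,
T2w and proton density interpolate from GM-like to CSF-like values with
damage, making the damage-score mapping exactly invertible as well.
Additive Gaussian noise (SD 2 on ASL frames and anatomicals, against
tissue intensities of 80–1200) and a motion random walk with four
injected excursions (1.5 mm or 8 degrees, against thresholds of 0.7 mm /
5 degrees) complete the default conditions: 40 control/label pairs on a
64^3 grid at 2 mm isotropic.

`make_cohort()` draws subjects with ages 24–81, 9–121 months since
stroke, 4/14 female, and varying lesion geometry; the lesion rim CBF
carries additive demographic effects (+0.15 mL/100g/min per year of age,
-0.05 per month since stroke, +2 for female, between-subject SD 1.5) so
the group model has known signs to recover. Every generated parameter is
recorded in the manifest.

What the phantom does **not** emulate — and hence what passing tests do
not show about real data: labeling physics (bolus dispersion, arterial
transit times), background suppression, Rician noise, motion-induced
*image* artifacts (the trace drives censoring only; frames are generated
aligned), registration/warping error, partial-volume effects beyond the
grid resolution, and hemorrhage. Conclusions about those effects require
real acquisitions.

## Numerical choices and problem sizes

* Smoothing kernels are sampled Gaussians truncated at 3 sigma with edge
  renormalization; the impulse-response test pins the kernel shape.
* M0 voxels at or below 1e-6 are marked undefined before division; the
  phantom's air keeps a small positive proton-density floor (30) so air
  ROIs carry defined pure-noise CBF for the quality metrics.
* Degenerate inputs error loudly rather than returning NaN: empty ROIs,
  constant predictors, rank-deficient designs (aliased terms are named),
  fewer than 32 surviving pairs, midline-straddling lesions.
* Replicate studies run at reduced size chosen once: cohort-recovery
  checks use 20 replicate 14-subject cohorts on a 32^3 grid at 4 mm (same
  field of view; fewer voxels per score ROI makes recovery *harder*), and
  pipeline-comparison checks use 20 noise realizations at the full 64^3
  default. The acceptance script reports the problem size next to every
  quantity.

## A worked example

```{r example, eval = FALSE}
ph <- make_phantom(phantom_spec(seed = 1))
res <- cbf_pipeline(ph$series, ph$motion, ph$seg$brain, "blur4_mni")
tg <- tigr_run(ph$t1w, ph$t2w, ph$lesion, ph$seg$gm, ph$seg$csf,
               ph$seg$brain)
rows <- cbf_by_score(res$cbf, tg$tigr)
fit_score_regression(rows)
```

## Known limitations

* A single common space: no registration, so resampling/interpolation
  effects at lesion edges are out of scope by design.
* The interleaving order (control first) is a recorded convention;
  label-first series are handled through the per-frame roles.
* The reference frame for motion is the first frame; a mean-frame
  reference would shift the censoring set for drifting traces.
* The quantification constants are consensus defaults, not fitted; lesion
  tissue T1 is unknown in the chronic stroke brain and no correction is
  attempted.
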