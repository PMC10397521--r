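# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# noiseless, motion-free phantom at the default grid
quiet_phantom <- function() cached("quiet", make_phantom(
  phantom_spec(noise = list(t1w = 0, t2w = 0, asl = 0, m0 = 0),
               motion = list(n_excursions = 0), seed = 42)))

# default study conditions (noise + motion excursions)
noisy_phantom <- function() cached("noisy", make_phantom(phantom_spec(seed = 42)))

# coarse spec for cohort-level work: same field of view, 4 mm voxels
coarse_spec <- function() phantom_spec(shape = c(32, 32, 32),
                                       spacing = c(4, 4, 4))

# one analyzed subject: phantom -> CBF map -> damage map -> score table
analyze_subject <- function(ph, variant = "blur4_mni", id = "subject") {
  res <- cbf_pipeline(ph$series, ph$motion, ph$seg$brain, variant)
  tg <- tigr_run(ph$t1w, ph$t2w, ph$lesion, ph$seg$gm, ph$seg$csf,
                 ph$seg$brain)
  list(cbf = res$cbf, tigr = tg,
       rows = cbf_by_score(res$cbf, tg$tigr, id = id))
}

# air sphere well outside the default phantom's brain ellipsoid
air_roi <- function(ref) sphere_mask(ref, c(40, 40, 40), 15, "air")

# tiny volume helpers for oracle tests
rand_vol <- function(d = c(6, 5, 4), spacing = c(1, 1, 1), min = 0.5,
                     max = 2) {
  volume(array(stats::runif(prod(d), min, max), d), spacing)
}
rand_mask <- function(d = c(6, 5, 4), p = 0.5, spacing = c(1, 1, 1)) {
  mask(array(stats::runif(prod(d)) < p, d), spacing)
}
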