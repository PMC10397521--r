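test_that("ratio_map divides voxelwise and flags signal voids", {
  t1 <- volume(array(2, c(3, 3, 3)))
  t2 <- volume(array(2, c(3, 3, 3)))
  expect_equal(ratio_map(t2, t1)$data, array(1, c(3, 3, 3)))
  t2$data[] <- 4
  expect_equal(ratio_map(t2, t1)$data, array(2, c(3, 3, 3)))
  set.seed(6)
  a <- rand_vol(); b <- rand_vol()
  r <- ratio_map(a, b)
  # scalar-loop oracle
  oracle <- array(NA_real_, dim(a$data))
  for (i in seq_along(oracle)) oracle[i] <- a$data[i] / b$data[i]
  expect_equal(r$data, oracle)
  b$data[1, 1, 1] <- 0
  expect_true(is.na(ratio_map(a, b)$data[1, 1, 1]))
  expect_error(ratio_map(a, rand_vol(c(2, 2, 2))), "alignment")
})

test_that("normalization bounds recover the phantom's tissue ratios", {
  ph <- quiet_phantom()
  r <- ratio_map(ph$t2w, ph$t1w)
  b <- normalization_bounds(r, ph$seg$gm, ph$seg$csf, ph$lesion,
                            ph$seg$brain)
  # uniform tissue ratios by construction: GM 80/100, CSF 120/40
  expect_equal(b$gm_ref, 0.8, tolerance = 1e-12)
  expect_equal(b$csf_ref, 3.0, tolerance = 1e-12)

  # with noise the means stay within 3 standard errors of the clean values
  phn <- noisy_phantom()
  rn <- ratio_map(phn$t2w, phn$t1w)
  bn <- normalization_bounds(rn, phn$seg$gm, phn$seg$csf, phn$lesion,
                             phn$seg$brain)
  # ratio noise SD via error propagation on (80 + e)/(100 + e), sd 2
  se_gm <- 0.8 * sqrt((2 / 80)^2 + (2 / 100)^2) / sqrt(bn$n_gm)
  se_csf <- 3.0 * sqrt((2 / 120)^2 + (2 / 40)^2) / sqrt(bn$n_csf)
  expect_lt(abs(bn$gm_ref - 0.8), 3 * se_gm)
  expect_lt(abs(bn$csf_ref - 3.0), 3 * se_csf)
})

test_that("bounds come only from the contralesional side", {
  # growing the lesion over the ipsilesional ventricle leaves them unchanged
  base <- phantom_spec(noise = list(t1w = 0, t2w = 0, asl = 0, m0 = 0),
                       motion = list(n_excursions = 0), seed = 42)
  big <- phantom_spec(lesion = list(radius = 26, center = c(-27, 5, 5)),
                      noise = list(t1w = 0, t2w = 0, asl = 0, m0 = 0),
                      motion = list(n_excursions = 0), seed = 42)
  get_bounds <- function(spec) {
    ph <- make_phantom(spec)
    r <- ratio_map(ph$t2w, ph$t1w)
    normalization_bounds(r, ph$seg$gm, ph$seg$csf, ph$lesion, ph$seg$brain)
  }
  b1 <- get_bounds(base); b2 <- get_bounds(big)
  expect_equal(b2$gm_ref, b1$gm_ref, tolerance = 1e-12)
  expect_equal(b2$csf_ref, b1$csf_ref, tolerance = 1e-12)
})

test_that("the damage score maps bounds to 0.1/1.0, clamps and bins ties up", {
  lesion <- mask(array(1, c(2, 2, 2)))
  b <- list(gm_ref = 0.8, csf_ref = 3.0)
  score_of <- function(r) {
    rv <- volume(array(r, c(2, 2, 2)))
    tigr_score(rv, b, lesion)$scores$data[1]
  }
  expect_equal(score_of(0.8), 0.1)    # GM reference -> least damaged
  expect_equal(score_of(3.0), 1.0)    # CSF reference -> most damaged
  expect_equal(score_of(0.2), 0.1)    # clamped below
  expect_equal(score_of(5.0), 1.0)    # clamped above
  # midpoint: continuous 0.55 bins to 0.6 under ties-toward-damage
  expect_equal(score_of((0.8 + 3.0) / 2), 0.6)

  # hand oracle on random ratios: formula + round-half-up
  set.seed(7)
  r <- runif(50, 0.5, 3.5)
  got <- sapply(r, score_of)
  cont <- pmin(1, pmax(0.1, 0.1 + 0.9 * (r - 0.8) / (3.0 - 0.8)))
  want <- sapply(cont, function(c0) {
    bins <- seq(0.1, 1, 0.1)
    cand <- bins[abs(bins - c0) == min(abs(bins - c0))]
    max(cand)  # ties toward higher damage
  })
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("scores are zero outside the lesion and multiples of 0.1 inside", {
  ph <- noisy_phantom()
  tg <- tigr_run(ph$t1w, ph$t2w, ph$lesion, ph$seg$gm, ph$seg$csf,
                 ph$seg$brain)$tigr
  s <- tg$scores$data
  les <- ph$lesion$data > 0
  expect_true(all(s[!les] == 0))
  expect_true(all(abs(s[les] * 10 - round(s[les] * 10)) < 1e-9))
  expect_true(all(s[les] >= 0.1 - 1e-9 & s[les] <= 1 + 1e-9))
})

test_that("the score is invariant to intensity rescaling", {
  ph <- noisy_phantom()
  r <- ratio_map(ph$t2w, ph$t1w)
  b <- normalization_bounds(r, ph$seg$gm, ph$seg$csf, ph$lesion,
                            ph$seg$brain)
  s0 <- tigr_score(r, b, ph$lesion)$scores$data
  # common positive rescaling of T1w and T2w leaves the ratio unchanged
  t1s <- ph$t1w; t1s$data <- t1s$data * 3.7
  t2s <- ph$t2w; t2s$data <- t2s$data * 3.7
  expect_equal(tigr_score(ratio_map(t2s, t1s), b, ph$lesion)$scores$data,
               s0, tolerance = 1e-9)
  # global scaling of the ratio together with its bounds
  r2 <- r; r2$data <- r2$data * 5
  b2 <- list(gm_ref = b$gm_ref * 5, csf_ref = b$csf_ref * 5)
  expect_equal(tigr_score(r2, b2, ph$lesion)$scores$data, s0,
               tolerance = 1e-9)
})

test_that("a higher ratio never lowers the score", {
  lesion <- mask(array(1, c(10, 1, 1)))
  b <- list(gm_ref = 1, csf_ref = 2)
  r <- volume(array(seq(0.5, 2.5, length.out = 10), c(10, 1, 1)))
  s <- tigr_score(r, b, lesion)$scores$data
  expect_true(all(diff(as.vector(s)) >= 0))
})

test_that("assigned scores track true damage closely at default noise", {
  ph <- noisy_phantom()
  tg <- tigr_run(ph$t1w, ph$t2w, ph$lesion, ph$seg$gm, ph$seg$csf,
                 ph$seg$brain)$tigr
  les <- ph$lesion$data > 0
  rho <- cor(ph$truth$damage$data[les], tg$scores$data[les],
             method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("cavitation and pericavitation partition the lesion", {
  ph <- noisy_phantom()
  tg <- tigr_run(ph$t1w, ph$t2w, ph$lesion, ph$seg$gm, ph$seg$csf,
                 ph$seg$brain)$tigr
  sp <- cavitation_split(tg)
  expect_equal(sum(sp$cavitation$data * sp$pericavitation$data), 0)
  expect_identical(sp$cavitation$data + sp$pericavitation$data,
                   ph$lesion$data)
  # voxel counts match an exhaustive scan of the score map
  s <- tg$scores$data[ph$lesion$data > 0]
  expect_equal(sum(sp$cavitation$data), sum(s == 1))
  expect_equal(sum(sp$pericavitation$data), sum(s < 1))
  # degenerate maps: all-1.0 and all-0.1 lesions
  uni <- function(val) {
    lesion <- mask(array(1, c(2, 2, 2)))
    rv <- volume(array(val, c(2, 2, 2)))
    cavitation_split(tigr_score(rv, list(gm_ref = 0.8, csf_ref = 3), lesion))
  }
  expect_equal(sum(uni(3.0)$pericavitation$data), 0)
  expect_equal(sum(uni(0.8)$cavitation$data), 0)
})

test_that("percent cavitation reproduces the reference-cohort column", {
  expect_equal(percent_cavitation(97078, 35999), 37.1)
  expect_equal(percent_cavitation(126164, 6537), 5.2)
  expect_equal(percent_cavitation(1, 1), 100.0)
  expect_error(percent_cavitation(0, 0), "zero lesion")
  expect_error(percent_cavitation(10, 11), "\\[0, lesion volume\\]")
})
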