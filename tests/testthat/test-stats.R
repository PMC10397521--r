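test_that("cbf_by_score averages defined CBF voxels per score ROI", {
  lesion <- mask(array(c(rep(1, 12), rep(0, 4)), c(4, 2, 2)))
  s <- array(0, c(4, 2, 2))
  s[lesion$data > 0] <- rep(c(0.1, 0.5, 1.0), each = 4)
  tg <- structure(list(scores = volume(s), lesion = lesion),
                  class = "tigr_map")
  cbf <- volume(array(30, c(4, 2, 2)))
  rows <- cbf_by_score(cbf, tg)
  expect_equal(rows$score, c(0.1, 0.5, 1.0))
  expect_equal(rows$mean_cbf, rep(30, 3))       # uniform CBF
  expect_equal(rows$n_voxels, rep(4, 3))
  # two-score lesion -> exactly two rows
  s2 <- s; s2[s2 == 0.5] <- 0.1
  tg2 <- structure(list(scores = volume(s2), lesion = lesion),
                   class = "tigr_map")
  expect_equal(nrow(cbf_by_score(cbf, tg2)), 2)
  # scores whose voxels are all undefined are omitted
  cbf$data[s == 1.0] <- NA
  expect_message(r3 <- cbf_by_score(cbf, tg), "row omitted")
  expect_equal(r3$score, c(0.1, 0.5))
})

test_that("per-score means follow the generated CBF-damage line", {
  ph <- quiet_phantom()
  an <- analyze_subject(ph, variant = "no_blur")
  rows <- an$rows
  # generator: cbf = 40 - 20 (damage - 0.1); per-score means sit near the
  # line evaluated at the mean within-bin damage
  fit <- fit_score_regression(rows)
  expect_equal(fit$slope, -20, tolerance = 0.05)
  expect_gt(fit$r2, 0.99)
  expect_equal(fit$slope_sign, "-")
})

test_that("score regression matches the closed-form and normal equations", {
  set.seed(10)
  for (k in 1:20) {
    n <- sample(3:12, 1)
    rows <- data.frame(id = "s", score = seq(0.1, 1, length.out = n),
                       mean_cbf = rnorm(n, 30, 5), n_voxels = 10)
    f <- fit_score_regression(rows)
    # normal-equations oracle
    x <- rows$score; y <- rows$mean_cbf
    b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    b0 <- mean(y) - b1 * mean(x)
    ssr <- sum((b0 + b1 * x - mean(y))^2)
    sst <- sum((y - mean(y))^2)
    r2 <- ssr / sst
    expect_equal(f$slope, b1, tolerance = 1e-8)
    expect_equal(f$r2, r2, tolerance = 1e-8)
    expect_equal(f$df, c(1, n - 2))
    # F = (n-2) R^2 / (1 - R^2) identically
    expect_equal(f$f_stat, (n - 2) * r2 / (1 - r2), tolerance = 1e-8)
    expect_equal(f$p_value, pf(f$f_stat, 1, n - 2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # collinear points: R^2 = 1, p ~ 0
  rows <- data.frame(score = seq(0.1, 1, 0.1),
                     mean_cbf = 40 - 20 * seq(0.1, 1, 0.1))
  f <- suppressWarnings(fit_score_regression(rows))
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_lt(f$p_value, 1e-12)
  expect_error(fit_score_regression(rows[1:2, ]), "at least 3")
  rows$score <- 0.5
  expect_error(fit_score_regression(rows), "constant predictor")
})

test_that("Bonferroni assessment flags and counts correctly", {
  out <- bonferroni_assess(c(1, 0.04, 0.0001), alpha = 0.01, n_tests = 14)
  expect_equal(attr(out, "threshold"), 0.01 / 14)
  expect_identical(out$bonferroni, c(FALSE, FALSE, TRUE))
  expect_identical(out$uncorrected, c(FALSE, TRUE, TRUE))
  expect_equal(attr(out, "n_uncorrected_only"), 1)
  expect_true(all(!bonferroni_assess(1, n_tests = 1)$uncorrected))
})

test_that("the factor model reports the design's degrees of freedom", {
  set.seed(11)
  demo <- data.frame(id = sprintf("P%02d", 1:14),
                     age = sample(24:81, 14),
                     sex = rep(c("F", "M"), c(4, 10)),
                     months_since_stroke = sample(9:121, 14),
                     wab_aq = runif(14, 27, 81))
  rows <- merge(data.frame(id = rep(demo$id, each = 10),
                           score = rep(seq(0.1, 1, 0.1), 14)),
                demo, by = "id")
  rows$mean_cbf <- 40 - 20 * (rows$score - 0.1) + rnorm(140, 0, 2)
  m <- fit_factor_model(rows)
  expect_equal(m$df, c(10, 129))   # 140 rows, 10 terms, intercept
  expect_equal(nrow(m$terms), 10)
  expect_setequal(m$terms$term,
                  c("sex", "age", "age_x_time", "age_x_sex", "damage",
                    "time", "damage_x_sex", "damage_x_age",
                    "damage_x_time", "time_x_sex"))
  # damage is the only real effect in this construction
  expect_lt(m$terms$t[m$terms$term == "damage"], -10)
  mw <- fit_factor_model(rows, include_wab = TRUE)
  expect_equal(mw$df, c(15, 124))
  expect_true("wab" %in% mw$terms$term)
})

test_that("with inert demographics the damage estimate equals pooled OLS", {
  # zero demographic effects, exact common slope: the factor model's
  # damage coefficient must equal the per-subject regression slope
  demo <- data.frame(id = sprintf("P%02d", 1:10),
                     age = c(40, 57, 63, 45, 52, 68, 71, 38, 49, 61),
                     sex = rep(c("F", "M"), 5),
                     months_since_stroke = c(10, 80, 31, 94, 22, 57, 13,
                                             66, 41, 103))
  rows <- merge(data.frame(id = rep(demo$id, each = 10),
                           score = rep(seq(0.1, 1, 0.1), 10)),
                demo, by = "id")
  rows$mean_cbf <- 40 - 20 * (rows$score - 0.1)
  m <- suppressWarnings(fit_factor_model(rows))
  f1 <- suppressWarnings(fit_score_regression(rows[rows$id == "P01", ]))
  expect_equal(m$terms$estimate[m$terms$term == "damage"], f1$slope,
               tolerance = 1e-8)
  expect_equal(f1$slope, -20, tolerance = 1e-10)
})

test_that("factor model input validation", {
  d <- data.frame(mean_cbf = 1:4, score = c(0.1, 0.2, 0.1, 0.2),
                  age = 50, sex = "M", months_since_stroke = 10)
  expect_error(fit_factor_model(d), "both sexes")
  d$sex <- c("M", "F", "M", "F"); d$age <- c(50, 50, 60, 60)
  d2 <- d; d2$months_since_stroke[2] <- NA
  expect_error(fit_factor_model(d2), "missing factor values")
})

test_that("paired tissue test matches the textbook formula", {
  set.seed(12)
  a <- rnorm(14, 50, 8); b <- rnorm(14, 30, 8)
  r <- paired_tissue_test(a, b)
  d <- a - b
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(14)), tolerance = 1e-12)
  expect_equal(r$df, 13)
  expect_equal(r$p_value, 2 * pt(abs(r$t), 13, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(paired_tissue_test(a, a)$t, 0)        # no difference
  expect_error(paired_tissue_test(a, a - 1), "unbounded")
  expect_error(paired_tissue_test(a, b[1:5]), "equal length")
})

test_that("group overlap masks threshold the per-voxel count", {
  d <- c(5, 4, 3)
  set.seed(13)
  masks <- lapply(1:14, function(i) rand_mask(d, p = 0.5))
  ov <- group_overlap_mask(masks, min_n = 10)
  cnt <- Reduce(`+`, lapply(masks, function(m) m$data))
  expect_identical(ov$data, array(as.numeric(cnt >= 10), d))
  # 14 identical masks with min_n 10 reproduce the mask
  same <- lapply(1:14, function(i) masks[[1]])
  expect_identical(group_overlap_mask(same, 10)$data, masks[[1]]$data)
  # disjoint masks with min_n 2 give an empty mask
  m1 <- mask(array(c(1, 0, 0, 0, 0, 0), c(6, 1, 1)))
  m2 <- mask(array(c(0, 1, 0, 0, 0, 0), c(6, 1, 1)))
  expect_equal(sum(group_overlap_mask(list(m1, m2), 2)$data), 0)
})

test_that("covariate removal residualizes only significant voxels", {
  set.seed(14)
  n <- 14; d <- c(4, 4, 2)
  cov <- rnorm(n, 100, 20)
  maps <- lapply(1:n, function(i) rand_vol(d, min = 20, max = 60))
  # voxel (1,1,1): exact linear function of the covariate
  for (i in 1:n) maps[[i]]$data[1, 1, 1] <- 5 + 0.3 * cov[i]
  out <- voxelwise_covariate_removal(maps, cov)
  expect_true(out$significant$data[1, 1, 1] == 1)
  vals <- sapply(out$maps, function(m) m$data[1, 1, 1])
  expect_equal(sd(vals), 0, tolerance = 1e-9)       # perfectly removed
  expect_equal(mean(vals), mean(5 + 0.3 * cov), tolerance = 1e-9)
  # non-significant voxels pass through unchanged
  keep <- which(out$significant$data == 0)[1]
  before <- sapply(maps, function(m) m$data[keep])
  after <- sapply(out$maps, function(m) m$data[keep])
  expect_identical(after, before)
  expect_error(voxelwise_covariate_removal(maps, rep(1, n)),
               "constant covariate")
  expect_error(voxelwise_covariate_removal(maps[1:2], cov[1:2]),
               "at least 3")
})
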