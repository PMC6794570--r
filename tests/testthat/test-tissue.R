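test_that("segmentation maps intensities to tissue fractions as specified", {
  mask <- matrix(1, 4, 4); mask[1, 1] <- 0
  t1w <- matrix(0.5, 4, 4)
  t1w[2, 2] <- 0.1          # = gm_min
  t1w[3, 3] <- 0.1 + 0.6    # = gm_min + wm_max
  tp <- segment_tissues(t1w, mask, wm_max = 0.6, gm_min = 0.1)
  expect_equal(tp$wm[2, 2], 0)
  expect_equal(tp$gm[2, 2], 1)
  expect_equal(tp$wm[3, 3], 1)
  expect_equal(tp$gm[3, 3], 0)
  expect_equal(tp$wm[1, 1], 0)   # outside mask
  expect_equal(tp$gm[1, 1], 0)
  expect_equal(tp$wm + tp$gm, mask)
  expect_error(segment_tissues(t1w, mask, wm_max = 0, gm_min = 0.1),
               "positive")
})

test_that("threshold estimation matches a brute-force percentile oracle", {
  set.seed(123)
  v <- runif(1e5)
  t1w <- matrix(v, 250, 400); mask <- matrix(1, 250, 400)
  th <- estimate_thresholds(t1w, mask)
  expect_equal(th$gm_min, percentile_oracle(v, 0.05), tolerance = 1e-10)
  expect_lt(abs(th$gm_min - 0.05), 0.01)
  expect_lt(abs(th$wm_max - 0.93), 0.01)

  two <- matrix(c(rep(0.4, 50), rep(0.9, 50)), 10, 10)
  th2 <- estimate_thresholds(two, matrix(1, 10, 10))
  expect_equal(th2$gm_min, 0.4)
  expect_equal(th2$wm_max, 0.5)

  expect_error(estimate_thresholds(matrix(0.7, 5, 5), matrix(1, 5, 5)),
               "degenerate")
  expect_error(estimate_thresholds(two, matrix(0, 10, 10)), "empty")
})

test_that("segmentation is invariant under affine intensity rescaling", {
  sc <- generate_phantom(11, 32, 4)
  th <- estimate_thresholds(sc$t1w, sc$mask)
  tp <- segment_tissues(sc$t1w, sc$mask, th$wm_max, th$gm_min)
  for (ab in list(c(2.5, 0.3), c(0.4, 1.0))) {
    t2 <- ab[1] * sc$t1w + ab[2]
    th2 <- estimate_thresholds(t2, sc$mask)
    tp2 <- segment_tissues(t2, sc$mask, th2$wm_max, th2$gm_min)
    expect_equal(tp2$wm, tp$wm, tolerance = 1e-10)
  }
})

test_that("lesion fields are Gaussian, additive and mask-limited", {
  mask <- matrix(1, 32, 32)
  expect_equal(render_lesions(list(), c(32, 32), mask), matrix(0, 32, 32))
  sp <- list(center = c(16, 16), radius = 4, amplitude = 0.5)
  f1 <- render_lesions(list(sp), c(32, 32), mask)
  expect_equal(f1[16, 16], 0.5)
  expect_equal(f1[16 + 2, 16], 0.5 * exp(-4 / (2 * 4)), tolerance = 1e-12)
  f2 <- render_lesions(list(sp, sp), c(32, 32), mask)
  expect_equal(f2, 2 * f1)
  mask0 <- mask; mask0[16, 16] <- 0
  expect_equal(render_lesions(list(sp), c(32, 32), mask0)[16, 16], 0)
  expect_error(render_lesions(rep(list(sp), 7), c(32, 32), mask), "at most 6")
})

test_that("identity augmentation is a no-op and exponent acts pointwise", {
  sc <- generate_phantom(5, 32, 4)
  th <- estimate_thresholds(sc$t1w, sc$mask)
  tp <- segment_tissues(sc$t1w, sc$mask, th$wm_max, th$gm_min)
  idp <- structure(list(r1 = 1, angle_deg = 0, crop = c(0L, 0L, 0L, 0L),
                        lesions = list(), seed = 0L),
                   class = "augment_params")
  ac <- augment_case(sc, tp, idp)
  expect_equal(ac$at1w, sc$t1w / max(sc$t1w), tolerance = 1e-12)
  expect_equal(ac$tissues$wm, tp$wm, tolerance = 1e-12)

  sqp <- idp; sqp$r1 <- 2
  ac2 <- augment_case(sc, tp, sqp)
  sn <- sc$t1w / max(sc$t1w)
  expect_equal(ac2$at1w, sn^2 / max(sn^2), tolerance = 1e-12)

  # hyper-intense lesion raises the pre-normalization signal at its center
  lesp <- idp
  ctr <- which(sc$mask == 1, arr.ind = TRUE)[200, ]
  lesp$lesions <- list(list(center = as.integer(ctr), radius = 3,
                            amplitude = 0.5))
  ac3 <- augment_case(sc, tp, lesp)
  les <- render_lesions(lesp$lesions, dim(sn), sc$mask)
  expect_true(all(sn + les >= sn))
  expect_gt(ac3$at1w[ctr[1], ctr[2]] * max(sn + les),
            sn[ctr[1], ctr[2]] - 1e-12)
})

test_that("the shared transform preserves tissue conservation", {
  sc <- generate_phantom(9, 32, 4)
  th <- estimate_thresholds(sc$t1w, sc$mask)
  tp <- segment_tissues(sc$t1w, sc$mask, th$wm_max, th$gm_min)
  for (seed in 1:5) {
    ap <- sample_augment_params(seed, sc$mask)
    ac <- augment_case(sc, tp, ap)
    expect_lt(max(abs(ac$tissues$wm + ac$tissues$gm - ac$tissues$mask)), 1e-6)
    expect_true(all(ac$tissues$wm >= 0 & ac$tissues$wm <= 1))
    expect_true(all(ac$at1w >= 0 & ac$at1w <= 1))
  }
})
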