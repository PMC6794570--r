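test_that("metabolite-map synthesis hits the mixing endpoints", {
  sc <- generate_phantom(4, 32, 4)
  tp <- structure(list(wm = sc$wm_true, gm = sc$gm_true, mask = sc$mask),
                  class = "tissue_pair")
  p <- sample_map_params(1)
  p$bias <- list(grad_row = 0, grad_col = 0, offset = 0); p$r3 <- 0
  p1 <- p; p1$r2 <- 1
  expect_equal(make_hrsi(tp, NULL, p1)$hr, tp$wm)
  p0 <- p; p0$r2 <- 0
  expect_equal(make_hrsi(tp, NULL, p0)$hr, tp$gm)
  ph <- p; ph$r2 <- 0.5
  expect_equal(make_hrsi(tp, NULL, ph)$hr, 0.5 * sc$mask)
  # negative lesion weight cannot push the map below zero
  pn <- p; pn$r3 <- -1
  les <- render_lesions(list(list(center = c(16, 16), radius = 4,
                                  amplitude = 0.9)), c(32, 32), sc$mask)
  expect_true(all(make_hrsi(tp, les, pn)$hr >= 0))
})

test_that("k-space truncation matches the direct-DFT oracle", {
  set.seed(31)
  for (n in c(8L, 16L)) {
    x <- matrix(runif(n * n), n, n)
    for (N in unique(c(4L, 6L, n / 2))) {
      got <- downsample_kspace(x, N, 0)
      want <- oracle_truncate(x, N)
      expect_lt(max(abs(got$native - want$native)), 1e-8)
      zf <- zero_fill_upsample(got$native, n)
      expect_lt(max(abs(zf - want$restored)), 1e-8)
    }
    # full-band round trip is the identity
    expect_lt(max(abs(downsample_kspace(x, n, 0)$native - x)), 1e-10)
    expect_lt(max(abs(zero_fill_upsample(x, n) - x)), 1e-10)
  }
})

test_that("constant images survive truncation at any resolution", {
  hr <- matrix(2.5, 8, 8)
  expect_lt(max(abs(downsample_kspace(hr, 4, 0)$native - 2.5)), 1e-10)
  hr128 <- matrix(0.7, 128, 128)
  for (N in c(16L, 24L, 32L))
    expect_lt(max(abs(downsample_kspace(hr128, N, 0)$native - 0.7)), 1e-10)
  expect_lt(max(abs(zero_fill_upsample(matrix(1.3, 16, 16), 64) - 1.3)), 1e-10)
})

test_that("noise-free truncation is linear and energy-bounded", {
  set.seed(8)
  x <- generate_phantom(2, 32, 4)$t1w
  a <- 3.7
  d1 <- downsample_kspace(x, 8, 0)$native
  d2 <- downsample_kspace(a * x, 8, 0)$native
  expect_equal(d2, a * d1, tolerance = 1e-10)
  # Parseval: truncation only removes coefficients (the native spectrum is
  # the retained block scaled by N^2/n^2)
  e_native <- sum(Mod(fft(d1))^2) * (32^2 / 8^2)^2
  e_hr <- sum(Mod(fft(x))^2)
  expect_lte(e_native, e_hr * (1 + 1e-12))
})

test_that("coarser truncation discards more information", {
  errs <- sapply(1:20, function(s) {
    hr <- sisr:::generate_case(s, 64L, 16L, c(0, 0))$hrsi
    vapply(c(8L, 16L, 32L), function(N) {
      zf <- zero_fill_upsample(downsample_kspace(hr, N, 0)$native, 64)
      mean((zf - hr)^2)
    }, 0)
  })
  expect_true(all(errs[1, ] >= errs[2, ] - 1e-12))
  expect_true(all(errs[2, ] >= errs[3, ] - 1e-12))
})

test_that("nearest-neighbor upscaling replicates source values only", {
  set.seed(5)
  nat <- matrix(runif(16 * 16), 16, 16)
  up <- nn_upscale(nat, 128)
  expect_equal(dim(up), c(128L, 128L))
  expect_true(all(up %in% nat))
  expect_lte(length(unique(as.vector(up))), 256)
  # non-integer factor: every source pixel of a 24-grid appears
  up24 <- nn_upscale(matrix(1:576, 24, 24), 128)
  expect_setequal(unique(as.vector(up24)), 1:576)
})

test_that("dataset streams are deterministic and duplicate-free", {
  d1 <- generate_dataset(5, hr_size = 32, lr_size = 8, seed = 3)
  d2 <- generate_dataset(5, hr_size = 32, lr_size = 8, seed = 3)
  expect_identical(d1, d2)
  expect_length(d1, 5)
  for (case in d1) {
    expect_equal(dim(case$at1w), c(32L, 32L))
    expect_equal(dim(case$lrsi), c(32L, 32L))
    expect_equal(dim(case$hrsi), c(32L, 32L))
  }
  hashes <- vapply(d1, function(cs) paste(format(sum(cs$hrsi), digits = 15),
                                          format(sum(cs$at1w), digits = 15)), "")
  expect_equal(anyDuplicated(hashes), 0L)
  expect_error(generate_dataset(0, seed = 1), "at least 1")
})

test_that("injected noise matches its stated image-domain level", {
  # flat image: the interior of the truncated map stays flat, so the
  # spatial std of the magnitude image reads the noise level directly
  set.seed(77)
  hits <- 0
  for (i in 1:200) {
    nf <- runif(1, 0.02, 0.05)
    lr <- downsample_kspace(matrix(1, 64, 64), 16, nf, seed = i)
    meas <- sd(lr$native)
    if (meas >= 0.015 && meas <= 0.06) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})
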