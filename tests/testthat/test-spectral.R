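test_that("basis spectra have the right location and width", {
  ax <- spectral_axis()
  f0 <- 42.577 * ax$b0_tesla
  # zero amplitude -> zero spectrum
  z <- metabolite_basis("z", c(2.0, 0))
  expect_equal(simulate_basis(z, ax), rep(0, ax$n_points))
  # peak lands in the bin nearest its offset frequency
  for (ppm in c(2.01, 3.19, 3.93)) {
    b <- metabolite_basis("t", c(ppm, 1))
    sp <- simulate_basis(b, ax)
    f <- (ppm - ax$reference_ppm) * f0
    expect_equal(which.max(sp), which.min(abs(ax$freq_hz - f)))
  }
  # linewidth: measure on a bin-centered peak (3.9 Hz bins)
  ppm_on_bin <- ax$reference_ppm - 56 * ax$bandwidth_hz / ax$n_points / f0
  sp <- simulate_basis(metabolite_basis("t", c(ppm_on_bin, 1), 8), ax)
  expect_equal(measure_fwhm(sp, ax$freq_hz), 8, tolerance = 0.15)
  # out-of-band peak rejected
  expect_error(simulate_basis(metabolite_basis("t", c(30, 1)), ax),
               "outside")
})

test_that("peak areas scale linearly with relative amplitude", {
  ax <- spectral_axis(n_points = 256L)
  a1 <- sum(simulate_basis(metabolite_basis("t", c(2.0, 1)), ax))
  a3 <- sum(simulate_basis(metabolite_basis("t", c(2.0, 3)), ax))
  expect_equal(a3 / a1, 3, tolerance = 1e-10)
})

test_that("volumes distribute spectra by map weight and location", {
  ax <- spectral_axis(n_points = 64L)
  bases <- list(A = metabolite_basis("A", c(2.0, 1)),
                B = metabolite_basis("B", c(3.2, 0.5)))
  mA <- matrix(0, 4, 4); mA[2, 3] <- 1
  mB <- matrix(0, 4, 4); mB[4, 1] <- 2
  vol <- build_si_volume(list(A = mA, B = mB), bases, ax)
  expect_equal(vol$data[2, 3, ], simulate_basis(bases$A, ax))
  expect_equal(vol$data[4, 1, ], 2 * simulate_basis(bases$B, ax))
  expect_equal(sum(vol$data[1, 1, ]), 0)
  # scaling a map scales its contribution
  vol2 <- build_si_volume(list(A = 3 * mA, B = mB), bases, ax)
  expect_equal(vol2$data[2, 3, ], 3 * vol$data[2, 3, ])
  expect_error(build_si_volume(list(A = mA), bases, ax), "mismatch")
})

test_that("point-by-point reconstruction honors the stub contract", {
  ax <- spectral_axis(n_points = 32L)
  sc <- generate_phantom(6, 16, 3)
  maps <- list(A = sc$wm_true, B = sc$gm_true)
  bases <- list(A = metabolite_basis("A", c(2.0, 1)),
                B = metabolite_basis("B", c(3.0, 0.7)))
  truth <- build_si_volume(maps, bases, ax)
  identity_stub <- function(at1w, lrsi) lrsi
  rec <- pointwise_superres(truth, sc$t1w, identity_stub)
  expect_equal(rec$data, truth$data, tolerance = 1e-12)
  for (v in list(c(8, 8), c(3, 12)))
    expect_equal(spectral_voxel_mse(rec, truth, v), 0)
  # zero volume stays zero, spike index is preserved
  zero_vol <- truth; zero_vol$data[] <- 0
  expect_equal(pointwise_superres(zero_vol, sc$t1w, identity_stub)$data,
               zero_vol$data)
  spike <- truth; spike$data[] <- 0; spike$data[5, 5, 17] <- 1
  rs <- pointwise_superres(spike, sc$t1w, identity_stub)
  expect_equal(which(rs$data != 0), which(spike$data != 0))
})

test_that("spectral voxel MSE behaves like a mean of squares", {
  ax <- spectral_axis(n_points = 16L)
  v <- build_si_volume(list(A = matrix(1, 2, 2)),
                       list(A = metabolite_basis("A", c(2.5, 1))), ax)
  w <- v; w$data[1, 1, ] <- w$data[1, 1, ] + 1
  expect_equal(spectral_voxel_mse(w, v, c(1, 1)), 1)
  expect_equal(spectral_voxel_mse(v, v, c(2, 2)), 0)
  expect_error(spectral_voxel_mse(v, v, c(5, 1)), "out of range")
})
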