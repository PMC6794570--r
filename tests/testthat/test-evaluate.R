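test_that("bicubic interpolation preserves constants and ramps", {
  expect_equal(bicubic_upsample(matrix(3, 8, 8), 32), matrix(3, 32, 32))
  expect_equal(bicubic_upsample(matrix(1:16, 4, 4), 4), matrix(1:16, 4, 4))
  # degree-1 polynomial reproduced away from borders
  N <- 16; n <- 64
  ramp <- outer(seq_len(N), seq_len(N), function(r, c) 0.3 * r + 0.1 * c)
  up <- bicubic_upsample(ramp, n)
  truth <- outer(seq_len(n), seq_len(n), function(r, c)
    0.3 * ((r - 0.5) * N / n + 0.5) + 0.1 * ((c - 0.5) * N / n + 0.5))
  interior <- 9:(n - 8)
  expect_lt(max(abs(up[interior, interior] - truth[interior, interior])), 1e-6)
  expect_error(bicubic_upsample(matrix(0, 8, 8), 4), "at least")
})

test_that("noise sweeps are reproducible and zero for the oracle", {
  meth <- list(oracle = function(case, lr) case$hrsi,
               nn = function(case, lr) lr$upscaled)
  r1 <- noise_sweep(meth, n_cases = 3, lr_size = 8, hr_size = 32, seed = 6)
  r2 <- noise_sweep(meth, n_cases = 3, lr_size = 8, hr_size = 32, seed = 6)
  expect_identical(r1$mse, r2$mse)
  expect_equal(unname(r1$mse["oracle", ]), rep(0, 3))
  expect_true(all(r1$mse >= 0))
})

test_that("ratio curves respond to tissue composition as constructed", {
  sc <- generate_phantom(12, 64, 6)
  tp <- structure(list(wm = sc$wm_true, gm = sc$gm_true, mask = sc$mask),
                  class = "tissue_pair")
  base_p <- sample_map_params(1)
  base_p$bias <- list(grad_row = 0, grad_col = 0, offset = 0); base_p$r3 <- 0
  mk <- function(r2) { p <- base_p; p$r2 <- r2; make_hrsi(tp, NULL, p)$hr }
  glu_like <- mk(0)    # all gray matter
  ch_like <- mk(1)     # all white matter
  cr_like <- mk(0.5)   # balanced
  cv <- ratio_vs_t1w(cr_like, cr_like, sc$t1w, sc$mask)
  ok <- !is.na(cv$mean_ratio)
  expect_equal(cv$mean_ratio[ok], rep(1, sum(ok)))
  expect_equal(ratio_curve_cor(cv, cv), 1)
  glu_curve <- ratio_vs_t1w(glu_like, cr_like, sc$t1w, sc$mask)
  ch_curve <- ratio_vs_t1w(ch_like, cr_like, sc$t1w, sc$mask)
  okg <- which(!is.na(glu_curve$mean_ratio))
  okc <- which(!is.na(ch_curve$mean_ratio))
  # brighter T1w = more WM: the GM-metabolite ratio falls, the WM one rises
  expect_lt(glu_curve$mean_ratio[max(okg)], glu_curve$mean_ratio[min(okg)])
  expect_gt(ch_curve$mean_ratio[max(okc)], ch_curve$mean_ratio[min(okc)])
})

test_that("mixing-ratio recovery is exact without noise", {
  for (s in 1:5) {
    case <- tiny_case(s, 64, 16, noise = c(0, 0))
    p <- sample_map_params(s * 7)
    p$bias <- list(grad_row = 0, grad_col = 0, offset = 0); p$r3 <- 0
    hr <- make_hrsi(case$tissues, NULL, p)$hr
    expect_equal(recover_r2(hr, case$tissues), p$r2, tolerance = 1e-6)
  }
})
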