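small_spec <- dunet_spec(input_size = 16, growth_maps = 4, n_pool = 2)

test_that("builder enforces its shape contract and is seed-deterministic", {
  expect_error(dunet_spec(input_size = 100, n_pool = 3), "divisible")
  m1 <- dunet(small_spec, seed = 5)
  m2 <- dunet(small_spec, seed = 5)
  expect_identical(m1$pars, m2$pars)
  expect_equal(m1$parameter_count, m2$parameter_count)
  set.seed(1)
  a <- matrix(runif(256), 16, 16); l <- matrix(runif(256), 16, 16)
  expect_identical(predict(m1, a, l), predict(m2, a, l))
})

test_that("capacity grows with the growth parameter", {
  p4 <- dunet(dunet_spec(16, 4, 2), 1)$parameter_count
  p8 <- dunet(dunet_spec(16, 8, 2), 1)$parameter_count
  expect_gt(p8, p4)
})

test_that("prediction has the contracted shape and is finite and repeatable", {
  m <- dunet(small_spec, seed = 2)
  set.seed(3)
  a <- matrix(runif(256), 16, 16); l <- matrix(runif(256), 16, 16)
  y1 <- predict(m, a, l)
  expect_equal(dim(y1), c(16L, 16L))
  expect_true(all(is.finite(y1)))
  expect_identical(y1, predict(m, a, l))
  expect_error(predict(m, a[1:8, 1:8], l), "16 x 16")
  # per-case predictions are independent: a loop over cases reproduces
  # each individual call
  cases <- lapply(1:3, function(i) {
    set.seed(i); list(a = matrix(runif(256), 16, 16),
                      l = matrix(runif(256), 16, 16))
  })
  batch <- lapply(cases, function(cs) predict(m, cs$a, cs$l))
  for (i in 1:3) expect_identical(batch[[i]],
                                  predict(m, cases[[i]]$a, cases[[i]]$l))
})

test_that("backpropagation matches numerical gradients", {
  spec <- dunet_spec(input_size = 8, growth_maps = 2, n_pool = 2)
  m <- dunet(spec, seed = 3)
  set.seed(1)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2))
  y <- matrix(runif(64), 8, 8)
  fw <- sisr:::dunet_forward(m, x, training = FALSE, keep_cache = TRUE)
  g <- sisr:::dunet_backward(m, fw$cache, 2 * (fw$y - y) / 64)
  eps <- 1e-6
  loss_at <- function(model) sum((sisr:::dunet_forward(model, x)$y - y)^2) / 64
  for (nm in c("enc1a.W", "enc2b.b", "bota.W", "dec1t.W", "dec2a.W",
               "final.W", "final.b")) {
    w <- m$pars[[nm]]
    for (i in unique(round(seq(1, length(w), length.out = 4)))) {
      mp <- m; mp$pars[[nm]][i] <- mp$pars[[nm]][i] + eps
      mm <- m; mm$pars[[nm]][i] <- mm$pars[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(as.numeric(g[[nm]][i]), num, tolerance = 1e-4)
    }
  }
})

test_that("the full-resolution feature collection reaches the final layer", {
  ch <- sisr:::dunet_channels(small_spec)
  g <- small_spec$growth_maps
  # final input = decoder dense output at full resolution, which carries
  # the 2 input channels, both encoder level-1 conv outputs, the upsampled
  # decoder feature and both decoder level-1 conv outputs
  expect_equal(ch$final_in, 2 + 2 * g + g + 2 * g)
  expect_equal(ch$bot_in, 2 + 2 * g * small_spec$n_pool)
})
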