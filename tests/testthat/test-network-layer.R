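test_that("a 1x1 grid reduces to the uncoupled oscillator equations", {
  img <- array(0.4, c(1, 1, 3))
  enc <- encode_image(img)
  st <- array(c(0.3, -0.2, 0.7), c(1, 1, 3))
  d <- layer1_rhs(st, enc)
  expect_equal(as.vector(d),
               rossler_rhs(c(0.3, -0.2, 0.7), rossler_params(o = enc$freq[1, 1])))
})

test_that("spatially uniform states receive zero coupling", {
  sc <- two_region_scene()
  enc <- encode_image(sc$image, delta_o = 0.35, sigma = 0.8)
  st <- array(rep(c(1.1, -0.4, 0.2), each = prod(enc$dims)),
              c(enc$dims, 3))
  d <- layer1_rhs(st, enc)
  expect_equal(d[, , 1], -enc$freq * (-0.4) - 0.2)
})

test_that("vectorized grid rhs equals a naive per-pixel loop", {
  set.seed(31)
  img <- array(runif(3 * 4 * 3), c(3, 4, 3))
  enc <- encode_image(img, delta_o = 0.2, sigma = 0.5, theta = 0.15)
  st <- array(rnorm(3 * 4 * 3), c(3, 4, 3))
  expect_equal(layer1_rhs(st, enc), naive_layer1_rhs(st, enc))
  expect_error(layer1_rhs(st[1:2, , ], enc), "mismatch")
})

test_that("the compiled grid integrator matches the generic R solver", {
  sc <- two_region_scene(H = 2, W = 3, obj_cols = 3)
  enc <- encode_image(sc$image, delta_o = 0.35, sigma = 0.8)
  fc <- frac_config(0.9, 0.01, 0.5, seed = 1)
  set.seed(1)
  init <- matrix(runif(18), 3, 6)
  sim <- simulate_layer1(enc, fc, init = init, keep_every = 1)
  rhs <- function(t, y) {
    st <- array(c(y[1:6], y[7:12], y[13:18]), c(2, 3, 3))
    d <- layer1_rhs(st, enc)
    c(d[, , 1], d[, , 2], d[, , 3])
  }
  y0 <- c(init[1, ], init[2, ], init[3, ])
  tr <- frac_integrate(rhs, y0, fc)
  expect_equal(t(sim$x), tr$states[, 1:6], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero couplings decouple pixels into independent oscillators", {
  img <- array(c(0.1, 0.9), c(1, 2, 3))  # two pixels, different frequencies
  enc <- encode_image(img, lambda_max_pos = 0, lambda_max_neg = 0)
  fc <- frac_config(0.9, 0.01, 5)
  init <- matrix(c(0.2, 0.4, 0.6, 0.8, 0.1, 0.3), 3, 2)
  sim <- simulate_layer1(enc, fc, init = init)
  for (px in 1:2) {
    single <- simulate_chain(chain_config(1, 0, enc$freq[1, px]), fc,
                             init = init[, px, drop = FALSE])
    expect_identical(sim$x[px, ], single$x[1, ])
  }
})

test_that("hybrid recording does not perturb the first layer (one-way drive)", {
  sc <- two_region_scene(H = 6, W = 8, obj_cols = 6:8)
  enc <- encode_image(sc$image, delta_o = 0.35, sigma = 0.8)
  fc <- frac_config(0.9, 0.01, 3, seed = 4)
  set.seed(4); init <- matrix(runif(3 * 48), 3, 48)
  plain <- simulate_layer1(enc, fc, init = init)
  rec <- simulate_layer1(enc, fc, groups = sc$labels, init = init)
  expect_identical(plain$x, rec$x)
  expect_identical(plain$y, rec$y)
  expect_equal(dim(rec$w), c(6, 301))
  # recorded hybrid equals the group mean of the kept states
  kept <- seq(1, 301, by = 10)
  labv <- as.vector(sc$labels)
  expect_equal(rec$w[1, kept], colMeans(rec$x[labv == 0, ]))
  expect_equal(rec$w[4, kept], colMeans(rec$x[labv == 1, ]))
})

test_that("objects desynchronize from the background while staying coherent", {
  sc <- two_region_scene()
  enc <- encode_image(sc$image, delta_o = 0.35, sigma = 0.8)
  fc <- frac_config(0.9, 0.01, 30, 2000, seed = 2)
  sim <- simulate_layer1(enc, fc)
  nt <- length(sim$times)
  labv <- as.vector(sc$labels)
  p0 <- sim$phases[labv == 0, nt]
  p1 <- sim$phases[labv == 1, nt]
  gap <- abs(mean(p1) - mean(p0))
  expect_gt(gap, 2)
  expect_lt(sd(p0), gap / 2)
  expect_lt(sd(p1), gap / 2)
  # the higher-contrast region grows phase faster
  expect_gt(mean(p1), mean(p0))
  # and the gap grows over the run
  mid <- which.min(abs(sim$times - 15))
  gap_mid <- abs(mean(sim$phases[labv == 1, mid]) -
                   mean(sim$phases[labv == 0, mid]))
  expect_gt(gap, gap_mid)
})

test_that("layer simulation is deterministic and reports divergence", {
  img <- array(0.5, c(2, 2, 3))
  enc <- encode_image(img)
  fc <- frac_config(0.9, 0.01, 2, seed = 9)
  s1 <- simulate_layer1(enc, fc)
  s2 <- simulate_layer1(enc, fc)
  expect_identical(s1$x, s2$x)
  huge <- matrix(1e5, 3, 4)
  expect_error(simulate_layer1(enc, fc, init = huge), "divergence")
})
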