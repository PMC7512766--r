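test_that("uniform images carry zero contrast and centred frequency", {
  img <- array(0.5, c(6, 8, 3))
  fs <- preprocess_image(img)
  expect_true(all(fs$gray == 0.5) && all(fs$b == 0.5))
  C <- contrast_map(fs)
  expect_true(all(C == 0))
  expect_true(all(frequency_map(C, 0.04) == 0.98))
})

test_that("grayscale input replicates onto colour channels; blur off is identity", {
  m <- matrix(seq(0, 1, length.out = 12), 3, 4)
  fs <- preprocess_image(m)
  expect_equal(fs$r, m)
  expect_equal(fs$g, m)
  expect_equal(fs$gray, m)
})

test_that("contrast is the weighted mean absolute deviation from feature means", {
  # single feature with weight 1, two pixels at 0 and 1 -> C = 0.5 each
  img <- array(0, c(1, 2, 3))
  img[1, 2, ] <- 1
  fs <- preprocess_image(img, weights = c(1, 0, 0, 0))
  expect_equal(contrast_map(fs), matrix(0.5, 1, 2))
  # random image against a per-pixel loop with default weights
  set.seed(21)
  img <- array(runif(5 * 4 * 3), c(5, 4, 3))
  fs <- preprocess_image(img)
  C <- contrast_map(fs)
  f <- fs[c("gray", "r", "g", "b")]
  w <- fs$weights
  mns <- vapply(f, mean, numeric(1))
  for (j in 1:5) for (k in 1:4) {
    expect_equal(C[j, k],
                 sum(w * abs(c(f$gray[j, k], f$r[j, k], f$g[j, k], f$b[j, k]) -
                               mns)) / sum(w))
  }
  expect_true(all(C >= 0 & C <= 1))
})

test_that("contrast depends on values only, not positions", {
  set.seed(8)
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  perm <- sample(36)
  img2 <- array(apply(img, 3, function(m) as.vector(m)[perm]), c(6, 6, 3))
  C1 <- as.vector(contrast_map(preprocess_image(img)))
  C2 <- as.vector(contrast_map(preprocess_image(img2)))
  expect_equal(C2, C1[perm])
})

test_that("frequency coding is the stated affine map of contrast", {
  expect_equal(frequency_map(matrix(0), 0.04), matrix(0.98))
  expect_equal(frequency_map(matrix(1), 0.04), matrix(1.02))
  expect_equal(frequency_map(matrix(0.5), 0.3), matrix(1))
  C <- matrix(seq(0, 1, 0.1))
  o <- frequency_map(C, 0.07)
  expect_true(all(diff(o[, 1]) > 0))
  expect_true(all(o >= 1 - 0.035 & o <= 1 + 0.035))
  expect_error(frequency_map(C, 0), "delta_o")
})

test_that("central frequency is the arithmetic mean of the map", {
  expect_equal(central_frequency(matrix(0.97, 3, 3)), 0.97)
  expect_equal(central_frequency(matrix(c(0.98, 1.02))), 1)
  set.seed(5)
  m <- matrix(runif(20, 0.9, 1.1), 4, 5)
  acc <- 0
  for (v in as.vector(m)) acc <- acc + v
  expect_equal(central_frequency(m), acc / 20)
})

test_that("coupling maps follow the Gaussian contrast coding", {
  cm <- coupling_maps(matrix(1), 0.05, 0.02, 0.2)
  expect_equal(cm$pos[1, 1], 0.05)
  expect_equal(cm$neg[1, 1], 0)
  cm0 <- coupling_maps(matrix(0), 0.05, 0.02, 0.2)
  expect_equal(cm0$pos[1, 1], 0.05 * exp(-12.5))
  expect_equal(cm0$neg[1, 1], 0.02 * (1 - exp(-12.5)))
  C <- matrix(seq(0, 1, 0.05))
  cm2 <- coupling_maps(C, 0.05, 0.02, 0.3)
  expect_true(all(diff(cm2$pos[, 1]) > 0))
  expect_true(all(diff(cm2$neg[, 1]) < 0))
  expect_true(all(cm2$pos >= 0 & cm2$pos <= 0.05))
  expect_true(all(cm2$neg >= 0 & cm2$neg <= 0.02))
  expect_error(coupling_maps(C, sigma = 0), "sigma")
})

test_that("topology links each pixel to its in-grid 8-neighbours exactly once", {
  img <- array(0.4, c(3, 4, 3))
  topo <- build_topology(preprocess_image(img), theta = 0.1)
  nlinks <- rowSums(topo$sign != 0)
  m <- matrix(nlinks, 3, 4)
  expect_equal(m[1, 1], 3)   # corner
  expect_equal(m[2, 1], 5)   # edge
  expect_equal(m[2, 2], 8)   # interior
  expect_true(all(topo$sign[topo$nbr >= 0] != 0))    # every pair classified
  expect_true(all(topo$sign[topo$nbr < 0] == 0))
  # uniform image: all links positive
  expect_true(all(topo$sign[topo$nbr >= 0] == 1))
})

test_that("topology is symmetric and splits by feature similarity", {
  sc <- two_region_scene()
  fs <- preprocess_image(sc$image)
  topo <- build_topology(fs, theta = 0.1)
  P <- prod(topo$dims)
  # symmetry: link (i -> t) has the same sign as (t -> i)
  for (i in seq_len(P)) for (q in 1:8) {
    t <- topo$nbr[i, q]
    if (t < 0) next
    back <- which(topo$nbr[t + 1, ] == i - 1)
    expect_equal(topo$sign[t + 1, back], topo$sign[i, q])
  }
  # cross-boundary links negative, within-region links positive
  labv <- as.vector(sc$labels)
  for (i in seq_len(P)) for (q in 1:8) {
    t <- topo$nbr[i, q]
    if (t < 0) next
    same <- labv[i] == labv[t + 1]
    expect_equal(topo$sign[i, q], if (same) 1L else 2L)
  }
})

test_that("resizing keeps features in range and the object structure", {
  sc <- make_scene(scene_preset("three-object", scale = 0.4))
  enc <- encode_image(sc$image, resize = c(42, 30))
  expect_equal(enc$dims, c(30, 42))
  expect_true(all(enc$contrast >= 0 & enc$contrast <= 1))
  # the three objects plus background survive the downscale
  expect_gte(length(unique(round(as.vector(enc$contrast), 2))), 4)
})

test_that("gaussian blur smooths a delta image without changing its mean much", {
  img <- array(0, c(9, 9, 3))
  img[5, 5, ] <- 1
  fs <- preprocess_image(img, blur = TRUE)
  expect_lt(max(fs$gray), 1)
  expect_gt(fs$gray[4, 5], 0)
  expect_equal(sum(fs$gray), 1, tolerance = 1e-6)
})
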