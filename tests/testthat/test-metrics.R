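test_that("histogram entropy hits its analytic anchors", {
  expect_equal(entropy_ie(matrix(0.37, 16, 16)), 0)
  expect_equal(entropy_ie(matrix(c(0, 1), 16, 16)), 1)
  img <- matrix(rep(0:255 / 255, each = 4), 32, 32)
  expect_equal(entropy_ie(img), 8)
})

test_that("mutual information equals entropy on itself and is symmetric", {
  x <- withr::with_seed(5, matrix(runif(64 * 64), 64))
  expect_equal(mutual_information(x, x), entropy_ie(x), tolerance = 1e-12)
  y <- withr::with_seed(6, matrix(runif(64 * 64), 64))
  expect_equal(mutual_information(x, y), mutual_information(y, x),
               tolerance = 1e-12)
  # independent coarse-binned noise at 128x128 carries almost no information
  a <- withr::with_seed(7, matrix(runif(128 * 128), 128))
  b <- withr::with_seed(8, matrix(runif(128 * 128), 128))
  expect_lt(mutual_information(a, b, bins = 16), 0.05)
})

test_that("edge transfer is perfect for identical images, poor for noise", {
  a <- withr::with_seed(9, {
    p <- make_pair(size = 64, seed = 9)
    p$structural
  })
  expect_gt(q_abf(a, a, a), 0.99)
  b <- make_pair(size = 64, seed = 10)$functional
  for (seed in 1:3) {
    noise <- withr::with_seed(seed + 40, matrix(runif(64 * 64), 64))
    expect_lt(q_abf(a, b, noise), 0.2)
  }
})

test_that("Q^AB/F agrees with the per-pixel reference and is symmetric", {
  withr::with_seed(11, {
    a <- matrix(runif(16 * 16), 16)
    b <- matrix(runif(16 * 16), 16)
    f <- (a + b) / 2
  })
  expect_equal(q_abf(a, b, f, normalize = FALSE), naive_qabf(a, b, f),
               tolerance = 1e-10)
  expect_equal(q_abf(a, b, f), q_abf(b, a, f), tolerance = 1e-12)
  expect_true(q_abf(a, b, f) >= 0 && q_abf(a, b, f) <= 1)
  expect_warning(got <- q_abf(matrix(0.5, 8, 8), matrix(0.5, 8, 8),
                              matrix(0.5, 8, 8)), "flat")
  expect_equal(got, 0)
})

test_that("gradient, spatial frequency and deviation vanish on constants", {
  c0 <- matrix(0.8, 12, 12)
  expect_equal(avg_gradient(c0), 0)
  expect_equal(global_sf(c0), 0)
  expect_equal(std_dev(c0), 0)
})

test_that("global SF of a unit checkerboard matches the closed form", {
  m <- 16; n <- 12
  board <- outer(seq_len(m), seq_len(n), function(i, j) (i + j) %% 2)
  expect_equal(global_sf(board), sqrt((n - 1) / n + (m - 1) / m),
               tolerance = 1e-12)
})

test_that("SSIM is 1 on identical images and below 1 otherwise", {
  x <- withr::with_seed(12, matrix(runif(32 * 32), 32))
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  y <- withr::with_seed(13, matrix(runif(32 * 32), 32))
  expect_lt(ssim(x, y), 0.5)
})

test_that("symmetric metrics are invariant to transposition and rotation", {
  x <- withr::with_seed(14, matrix(runif(20 * 20), 20))
  expect_equal(entropy_ie(t(x)), entropy_ie(x))
  expect_equal(std_dev(t(x)), std_dev(x))
  y <- withr::with_seed(15, matrix(runif(20 * 20), 20))
  expect_equal(mutual_information(t(x), t(y)), mutual_information(x, y))
  rot180 <- x[rev(seq_len(20)), rev(seq_len(20))]
  expect_equal(global_sf(rot180), global_sf(x), tolerance = 1e-12)
  # AG anchors forward differences on the interior grid, so exact symmetry
  # holds under transposition (rotation shifts the anchor by one pixel)
  expect_equal(avg_gradient(t(x)), avg_gradient(x), tolerance = 1e-12)
  expect_equal(avg_gradient(rot180), avg_gradient(x), tolerance = 1e-2)
})

test_that("the combined report carries every index with valid ranges", {
  p <- make_pair(size = 64, seed = 21)
  f <- fuse_baseline(p$structural, p$functional)
  rep <- fusion_metrics(p$structural, p$functional, f)
  expect_s3_class(rep, "fusion_metrics")
  expect_true(rep$q_abf >= 0 && rep$q_abf <= 1)
  expect_true(rep$ie >= 0 && rep$sd >= 0 && rep$mc >= 0)
  expect_true(rep$ssim <= 2 + 1e-12)
  expect_output(print(rep), "q_abf")
})
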