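test_that("coefficient fusion follows the L1 / opposing-sign rules", {
  # identical codes pass through unchanged (tie branch)
  a <- matrix(c(0.5, -0.2, 0, 0.1), 4, 1)
  expect_equal(fuse_codes(a, a), a)

  # larger-L1 column wins outright when no signs oppose
  a <- matrix(c(1, 0.5, 0), 3, 1)
  b <- matrix(c(0.2, 0.1, 0), 3, 1)
  expect_equal(fuse_codes(a, b), a)
  expect_equal(fuse_codes(b, a), a)

  # opposing-sign element with s_A > s_B and |a| < |b|: a + b/2
  a <- matrix(c(0.9, 0.2), 2, 1)
  b <- matrix(c(0.1, -0.5), 2, 1)
  f <- fuse_codes(a, b)
  expect_equal(f[1, 1], 0.9)                 # base rule keeps A
  expect_equal(f[2, 1], 0.2 + (-0.5) / 2)    # blended to -0.05
  # mirrored inputs give the mirrored branch
  f2 <- fuse_codes(b, a)
  expect_equal(f2[2, 1], 0.2 + (-0.5) / 2)

  # tie branch with opposing signs adds half the larger-magnitude entry
  a <- matrix(c(0.5, -0.3), 2, 1)
  b <- matrix(c(0.3, 0.5), 2, 1)   # both L1 = 0.8
  f <- fuse_codes(a, b)
  expect_equal(f[1, 1], (0.5 + 0.3) / 2)
  expect_equal(f[2, 1], (-0.3 + 0.5) / 2 + 0.5 / 2)
})

test_that("coefficient fusion is symmetric on L1 ties", {
  for (seed in 1:5) {
    a <- withr::with_seed(seed, matrix(rnorm(6 * 8), 6))
    # rescale columns of b to exactly match a's L1 norms
    b <- withr::with_seed(seed + 100, matrix(rnorm(6 * 8), 6))
    b <- sweep(b, 2, colSums(abs(a)) / colSums(abs(b)), `*`)
    expect_equal(fuse_codes(a, b), fuse_codes(b, a), tolerance = 1e-12)
  }
})

test_that("mean fusion selects by L1 norm and averages ties", {
  expect_equal(fuse_means(10, 20, 1.0, 0.5), 10)
  expect_equal(fuse_means(10, 20, 0.5, 1.0), 20)
  expect_equal(fuse_means(10, 20, 0.7, 0.7), 15)
  expect_equal(fuse_means(c(1, 2), c(1, 2), c(1, 1), c(1, 1)), c(1, 2))
  expect_error(fuse_means(1:3, 1:2, 1:3, 1:3), "length")
})

test_that("reconstruction from zero codes returns the mean surface", {
  codec <- patch_codec(c(12, 12), window = 4)
  D <- withr::with_seed(1, {
    D <- matrix(rnorm(16 * 20), 16)
    sweep(D, 2, sqrt(colSums(D^2)), `/`)
  })
  P <- prod(codec$patch_count)
  out <- reconstruct_low(D, matrix(0, 20, P), rep(0.4, P), codec)
  expect_equal(out, matrix(0.4, 12, 12), tolerance = 1e-12)
})

test_that("self-fusion of a band reproduces it within the coding tolerance", {
  for (seed in 1:3) {
    band <- withr::with_seed(seed, {
      z <- matrix(rnorm(20 * 20), 20)
      k <- outer(dnorm(-3:3), dnorm(-3:3)); k <- k / sum(k)
      0.5 + 0.3 * nsfuse:::.conv2_sym(z, k)
    })
    lf <- fuse_low_band(band, band, window = 4, n_atoms = 32,
                        iterations = 5, residual_tol = 0.01, seed = seed)
    rmse <- sqrt(mean((lf$fused - band)^2))
    expect_lte(rmse, 2 * 0.01)
  }
})

test_that("shape mismatches are rejected throughout", {
  expect_error(fuse_codes(matrix(0, 2, 2), matrix(0, 2, 3)), "dimensions")
  expect_error(fuse_low_band(matrix(0.1, 16, 16), matrix(0.1, 16, 18),
                             window = 4, n_atoms = 32), "dimensions")
})
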