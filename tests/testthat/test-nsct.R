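test_that("decomposition of a constant image has vanishing directional bands", {
  dec <- nsct_decompose(matrix(0.7, 64, 64), 4, c(4, 4, 8, 8))
  for (l in seq_along(dec$highs)) {
    for (b in dec$highs[[l]]) expect_lt(max(abs(b)), 1e-10 * 0.7)
  }
  expect_equal(nsct_reconstruct(dec), matrix(0.7, 64, 64), tolerance = 1e-10)
})

test_that("forward and inverse transforms are linear", {
  withr::with_seed(21, {
    x <- matrix(runif(48 * 48), 48)
    y <- matrix(runif(48 * 48), 48)
  })
  a <- 1.7; b <- -0.4
  dx <- nsct_decompose(x, 2, c(2, 4))
  dy <- nsct_decompose(y, 2, c(2, 4))
  dz <- nsct_decompose(a * x + b * y, 2, c(2, 4))
  expect_equal(dz$low, a * dx$low + b * dy$low, tolerance = 1e-10)
  for (l in 1:2) {
    for (d in seq_along(dz$highs[[l]])) {
      expect_equal(dz$highs[[l]][[d]],
                   a * dx$highs[[l]][[d]] + b * dy$highs[[l]][[d]],
                   tolerance = 1e-10)
    }
  }
})

test_that("band counts and shapes follow the direction plan", {
  x <- withr::with_seed(3, matrix(runif(64 * 64), 64))
  dec <- nsct_decompose(x, 4, c(4, 4, 8, 8))
  expect_equal(lengths(dec$highs), c(4L, 4L, 8L, 8L))
  expect_equal(sum(lengths(dec$highs)), 24L)
  for (l in seq_along(dec$highs)) {
    for (b in dec$highs[[l]]) expect_identical(dim(b), c(64L, 64L))
  }
  expect_identical(dim(dec$low), c(64L, 64L))
})

test_that("round-trip reconstruction is exact to floating point", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, matrix(runif(64 * 64), 64))
    dec <- nsct_decompose(x, 4, c(4, 4, 8, 8))
    expect_lt(max(abs(nsct_reconstruct(dec) - x)), 1e-6)
  }
  # zero decomposition reconstructs to zero
  dec0 <- nsct_decompose(matrix(0, 64, 64), 2, c(2, 2))
  expect_equal(nsct_reconstruct(dec0), matrix(0, 64, 64))
})

test_that("circular shifts commute with the transform", {
  x <- withr::with_seed(9, matrix(runif(64 * 64), 64))
  dec <- nsct_decompose(x, 3, c(2, 4, 4))
  dec_s <- nsct_decompose(circ_shift(x, 5, 3), 3, c(2, 4, 4))
  expect_lt(max(abs(dec_s$low - circ_shift(dec$low, 5, 3))), 1e-6)
  for (l in seq_along(dec$highs)) {
    for (d in seq_along(dec$highs[[l]])) {
      expect_lt(max(abs(dec_s$highs[[l]][[d]] -
                          circ_shift(dec$highs[[l]][[d]], 5, 3))), 1e-6)
    }
  }
})

test_that("frequency-domain filtering agrees with direct spatial convolution", {
  fb <- ns_filters()
  x <- withr::with_seed(4, matrix(runif(32 * 32), 32))
  for (k in list(fb$pyramid_analysis$h0, fb$fan_analysis$u0)) {
    spec <- nsfuse:::.taps_spectrum(nsfuse:::.kernel_taps(k), c(32L, 32L))
    via_fft <- nsfuse:::.ifft_real(stats::fft(x) * spec)
    expect_lt(max(abs(via_fft - nsfuse:::.conv2_circular_direct(x, k))), 1e-10)
  }
})

test_that("invalid inputs are rejected", {
  x <- matrix(runif(64 * 64), 64)
  xx <- x; xx[1, 1] <- NaN
  expect_error(nsct_decompose(xx), "non-finite")
  expect_error(nsct_decompose(x, 2, c(3, 4)), "power of two")
  expect_error(nsct_decompose(x, 3, c(2, 2)), "one entry per level")
  expect_error(nsct_decompose(matrix(runif(16 * 16), 16), 4, c(4, 4, 8, 8)),
               "smaller than the filter support")
  dec <- nsct_decompose(x, 2, c(2, 2))
  dec$highs[[1]][[1]] <- matrix(0, 8, 8)
  expect_error(nsct_reconstruct(dec), "shape")
})

test_that("subband export writes one PNG per band", {
  x <- withr::with_seed(2, matrix(runif(64 * 64), 64))
  dec <- nsct_decompose(x, 2, c(2, 2))
  d <- withr::local_tempdir()
  paths <- export_subbands(dec, d)
  expect_length(paths, 5L)   # low + 2 + 2
  expect_true(all(file.exists(paths)))
})
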