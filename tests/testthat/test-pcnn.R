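test_that("spatial frequency is zero for constants and localised at edges", {
  expect_true(all(spatial_frequency(matrix(0.4, 10, 10)) == 0))

  # vertical step edge: columns away from the jump see no differences
  x <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  sf <- spatial_frequency(x, 3)
  expect_true(all(sf[, c(1:3, 7:8)] == 0))
  expect_true(all(sf[, 4:6] > 0))
})

test_that("spatial frequency matches the double-loop oracle", {
  for (seed in 1:3) {
    x <- withr::with_seed(seed, matrix(rnorm(12 * 14), 12))
    expect_lt(max(abs(spatial_frequency(x, 3) -
                        naive_spatial_frequency(x, 3))), 1e-12)
  }
  x <- withr::with_seed(4, matrix(rnorm(15 * 11), 15))
  expect_lt(max(abs(spatial_frequency(x, 5) -
                      naive_spatial_frequency(x, 5))), 1e-12)
  expect_error(spatial_frequency(x, 4), "odd")
})

test_that("normalize01 maps ranges onto [0,1] and constants to zero", {
  expect_equal(normalize01(matrix(c(0, 5, 10), 1)),
               matrix(c(0, 0.5, 1), 1))
  expect_true(all(normalize01(matrix(3, 4, 4)) == 0))
  x <- withr::with_seed(2, matrix(rnorm(25), 5))
  n <- normalize01(x)
  expect_equal(range(n), c(0, 1))
})

test_that("link-strength maps are zero on constants and match hand values", {
  maps <- link_strength_maps(matrix(0.6, 9, 9))
  expect_true(all(maps$eol == 0) && all(maps$vi == 0) && all(maps$sd == 0))

  # single bright pixel in a zero 5x5 band, 3x3 window
  x <- matrix(0, 5, 5); x[3, 3] <- 1
  maps <- link_strength_maps(x, 3)
  expect_equal(maps$sd[3, 3], sqrt((8 * (1 / 9)^2 + (1 - 1 / 9)^2) / 9),
               tolerance = 1e-12)
})

test_that("link-strength maps match the double-loop oracle", {
  for (seed in 1:3) {
    x <- withr::with_seed(seed, matrix(rnorm(11 * 13), 11))
    got <- link_strength_maps(x, 3, vi_alpha = 0.7)
    ref <- naive_link_maps(x, 3, vi_alpha = 0.7)
    expect_lt(max(abs(got$eol - ref$eol)), 1e-12)
    # VI spans many orders of magnitude (1e-6 mean floor), compare relatively
    expect_lt(max(abs(got$vi - ref$vi) / pmax(abs(ref$vi), 1)), 1e-12)
    expect_lt(max(abs(got$sd - ref$sd)), 1e-12)
  }
})

test_that("the PCNN never fires on zero input and rejects negatives", {
  O <- pcnn_run(matrix(0, 6, 6), matrix(0.5, 6, 6), pcnn_params(N_max = 50))
  expect_true(all(O == 0))
  expect_error(pcnn_run(matrix(-0.1, 3, 3), matrix(0, 3, 3)), "non-negative")
})

test_that("uncoupled neurons reproduce the scalar recurrence exactly", {
  params <- pcnn_params()
  # analytic first firing for I = 0.5: smallest n with exp(-0.2 n) < 0.5
  o <- pcnn_scalar_oracle(0.5, params)
  expect_equal(o$fired_at[1], 4L)
  expect_equal(o$fired_at[1], which(exp(-0.2 * 1:100) < 0.5)[1])

  F_in <- withr::with_seed(31, matrix(runif(8 * 8), 8))
  O <- pcnn_run(F_in, matrix(0, 8, 8), params)
  O_ref <- apply(F_in, c(1, 2), function(i) pcnn_scalar_oracle(i, params)$O)
  expect_identical(O, O_ref)
  expect_true(all(O == round(O)) && max(O) <= params$N_max)
})

test_that("ignition counts are monotone in the input when uncoupled", {
  params <- pcnn_params(N_max = 60)
  for (seed in 1:5) {
    f1 <- withr::with_seed(seed, matrix(runif(6 * 6), 6))
    f2 <- pmin(f1 + withr::with_seed(seed + 50, matrix(runif(36, 0, 0.3), 6)), 1)
    O1 <- pcnn_run(f1, matrix(0, 6, 6), params)
    O2 <- pcnn_run(f2, matrix(0, 6, 6), params)
    expect_true(all(O2 >= O1))
  }
})

test_that("ignition combination weights maps by their own share", {
  c1 <- matrix(2, 3, 3)
  expect_equal(combine_ignitions(c1, c1, c1), c1)

  oe <- matrix(4, 1, 1); zero <- matrix(0, 1, 1)
  expect_equal(combine_ignitions(oe, zero, zero)[1, 1], 4)
  expect_equal(combine_ignitions(zero, zero, zero)[1, 1], 0)

  a <- matrix(c(1, 2), 1); b <- matrix(c(0, 4), 1); c <- matrix(c(3, 0), 1)
  got <- combine_ignitions(a, b, c)
  expect_equal(got[1, 1], (1 * 1 + 0 + 3 * 3) / 4)
  expect_equal(got[1, 2], (2 * 2 + 4 * 4) / 6)
})

test_that("coefficient selection follows the ignition comparison", {
  ha <- matrix(1:6 / 6, 2); hb <- -ha
  expect_equal(select_high(ha, hb, matrix(1, 2, 3), matrix(1, 2, 3)),
               (ha + hb) / 2)
  expect_equal(select_high(ha, hb, matrix(2, 2, 3), matrix(1, 2, 3)), ha)
  oa <- matrix(c(1, 0, 2, 2, 0, 1), 2); ob <- matrix(c(0, 1, 2, 0, 1, 2), 2)
  got <- select_high(ha, hb, oa, ob)
  ref <- ha
  for (i in seq_along(ha)) {
    ref[i] <- if (oa[i] > ob[i]) ha[i] else if (oa[i] < ob[i]) hb[i]
              else (ha[i] + hb[i]) / 2
  }
  expect_equal(got, ref)
})

test_that("high-band fusion is symmetric and exact on identical inputs", {
  params <- pcnn_params(N_max = 40)
  h <- withr::with_seed(17, matrix(rnorm(24 * 24, sd = 0.1), 24))
  expect_identical(fuse_high_band(h, h, params), h)

  hb <- withr::with_seed(18, matrix(rnorm(24 * 24, sd = 0.1), 24))
  expect_equal(fuse_high_band(h, hb, params), fuse_high_band(hb, h, params))
})

test_that("a silent band never outvotes an active one", {
  params <- pcnn_params(N_max = 40)
  h <- withr::with_seed(19, matrix(rnorm(20 * 20, sd = 0.2), 20))
  zero <- matrix(0, 20, 20)
  fused <- fuse_high_band(h, zero, params)
  # zero-input neurons never fire, so wherever A ignites the output is A
  sf <- normalize01(spatial_frequency(h))
  ls <- link_strength_maps(h)
  oa <- combine_ignitions(
    pcnn_run(sf, normalize01(ls$eol), params),
    pcnn_run(sf, normalize01(ls$vi), params),
    pcnn_run(sf, normalize01(ls$sd), params))
  expect_true(all(fused[oa > 0] == h[oa > 0]))
  expect_true(all(fused[oa == 0] == h[oa == 0] / 2))
})

test_that("parameter validation catches malformed settings", {
  expect_error(pcnn_params(V_L = -1), "positive")
  expect_error(pcnn_params(W = matrix(1, 3, 3)), "centre")
  W <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  W2 <- W; W2[1, 2] <- 2
  expect_error(pcnn_params(W = W2), "symmetric")
})
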