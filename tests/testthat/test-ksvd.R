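test_that("exact 1-sparse signals are coded exactly", {
  D <- withr::with_seed(1, {
    D <- matrix(rnorm(16 * 32), 16)
    sweep(D, 2, sqrt(colSums(D^2)), `/`)
  })
  x <- 3.5 * D[, 7, drop = FALSE]
  codes <- batch_omp(D, x, residual_tol = 1e-8)
  expect_equal(which(codes != 0), 7L)
  expect_equal(codes[7, 1], 3.5, tolerance = 1e-10)

  expect_true(all(batch_omp(D, matrix(0, 16, 1)) == 0))
})

test_that("Batch-OMP matches the naive OMP oracle on 2-sparse problems", {
  for (seed in 1:10) {
    prob <- withr::with_seed(seed, {
      D <- matrix(rnorm(16 * 32), 16)
      D <- sweep(D, 2, sqrt(colSums(D^2)), `/`)
      sup <- replicate(20, sample(32, 2))
      X <- sapply(seq_len(20), function(i) {
        D[, sup[, i]] %*% runif(2, 0.5, 2)
      })
      list(D = D, X = X)
    })
    fast <- batch_omp(prob$D, prob$X, residual_tol = 1e-6)
    slow <- naive_omp(prob$D, prob$X, residual_tol = 1e-6)
    expect_identical(fast != 0, slow != 0)
    expect_lt(max(abs(fast - slow)), 1e-8)
  }
})

test_that("a non-normalised dictionary is rejected", {
  D <- matrix(rnorm(16 * 32), 16)
  expect_error(batch_omp(D, matrix(0, 16, 2)), "unit")
})

test_that("K-SVD recovers a planted 1-sparse dictionary", {
  prob <- planted_problem(d = 8, K = 16, P = 200, seed = 5)
  model <- train_ksvd(prob$V, n_atoms = 16, iterations = 10,
                      residual_tol = 1e-7, seed = 2)
  codes <- batch_omp(model$dictionary, prob$V, residual_tol = 1e-7)
  resid <- sqrt(colSums((prob$V - model$dictionary %*% codes)^2))
  expect_lt(mean(resid), 1e-6)
})

test_that("the representation error is non-increasing across sweeps", {
  patches <- withr::with_seed(13, {
    base <- matrix(rnorm(25 * 40), 25) %*% matrix(rnorm(40 * 600), 40)
    base / max(abs(base))
  })
  model <- train_ksvd(patches, n_atoms = 64, iterations = 12,
                      residual_tol = 0.01, seed = 4)
  expect_true(all(diff(model$errors) <= 1e-8))
})

test_that("training is deterministic under a seed and validates its inputs", {
  V <- withr::with_seed(3, matrix(rnorm(9 * 50), 9))
  m1 <- train_ksvd(V, n_atoms = 16, iterations = 3, seed = 7)
  m2 <- train_ksvd(V, n_atoms = 16, iterations = 3, seed = 7)
  expect_identical(m1$dictionary, m2$dictionary)
  expect_lt(max(abs(sqrt(colSums(m1$dictionary^2)) - 1)), 1e-10)

  expect_error(train_ksvd(V[, 1:10], n_atoms = 16, iterations = 1),
               "samples")
  expect_error(train_ksvd(V, n_atoms = 9, iterations = 1), "overcomplete")
})

test_that("dictionaries survive a save/load round trip as text", {
  V <- withr::with_seed(3, matrix(rnorm(9 * 40), 9))
  m <- train_ksvd(V, n_atoms = 12, iterations = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".txt")
  save_dictionary(m, path)
  expect_equal(load_dictionary(path), m$dictionary, tolerance = 1e-15)
})
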