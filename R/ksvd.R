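# K-SVD dictionary learning and Batch-OMP sparse coding for the low-frequency
# subband fusion stage.

#' Batch orthogonal matching pursuit
#'
#' Sparse-codes every column of `samples` against a unit-norm dictionary.
#' Atoms are selected greedily by maximal absolute correlation with the
#' residual; after each selection the coefficients over the selected set are
#' refit by least squares.  Coding stops per column when the residual 2-norm
#' falls to `residual_tol * ||column||` (with an absolute floor of `1e-12`) or
#' when `max_atoms` atoms have been used.  The implementation is the
#' precomputed-Gram Batch-OMP formulation, which reproduces naive per-column
#' OMP output to floating-point accuracy.
#'
#' @param dictionary `d x K` matrix with unit-L2-norm columns.
#' @param samples `d x P` matrix of signals (typically zero-mean patches).
#' @param residual_tol Relative residual tolerance (default 0.01).
#' @param max_atoms Sparsity cap per column; defaults to `floor(d / 2)`.
#' @return `K x P` coefficient matrix (dense storage, sparse content).
#' @examples
#' D <- qr.Q(qr(matrix(rnorm(64), 8)))
#' a <- batch_omp(D, 3.5 * D[, 7, drop = FALSE])
#' which(a != 0); a[7, 1]
#' @export
batch_omp <- function(dictionary, samples, residual_tol = 0.01,
                      max_atoms = NULL) {
  if (!is.matrix(dictionary) || !is.matrix(samples)) {
    stop("`dictionary` and `samples` must be matrices", call. = FALSE)
  }
  if (nrow(dictionary) != nrow(samples)) {
    stop("dictionary and samples have different signal dimensions",
         call. = FALSE)
  }
  norms <- sqrt(colSums(dictionary^2))
  if (any(abs(norms - 1) > 1e-8)) {
    stop("dictionary atoms must have unit L2 norm", call. = FALSE)
  }
  if (is.null(max_atoms)) max_atoms <- max(1L, nrow(dictionary) %/% 2L)
  if (residual_tol < 0) stop("`residual_tol` must be >= 0", call. = FALSE)
  batch_omp_engine(dictionary, samples, residual_tol,
                   as.integer(max_atoms), 1e-12)
}

#' Train an overcomplete dictionary with K-SVD
#'
#' Alternates Batch-OMP sparse coding with atom-by-atom dictionary updates:
#' for each atom, the restricted representation error over the samples that
#' use it is approximated by its leading singular pair, which simultaneously
#' refreshes the atom and its active coefficients.  Atoms that fall out of
#' use are replaced by the currently worst-represented sample (renormalised).
#' The dictionary is initialised from `n_atoms` distinct sample columns drawn
#' under `seed`, so training is fully deterministic.
#'
#' A per-column safeguard keeps the previous iteration's coefficients for any
#' column whose fresh OMP code would increase its residual, making the
#' recorded representation error provably non-increasing across iterations.
#'
#' @param samples `d x P` matrix of (zero-mean) training columns, `P >=
#'   n_atoms`.
#' @param n_atoms Dictionary size `K`; must exceed the signal dimension `d`
#'   (overcomplete).
#' @param iterations Number of K-SVD sweeps (default 30).
#' @param residual_tol Relative OMP residual tolerance (default 0.01).
#' @param max_atoms Per-column sparsity cap; defaults to `floor(d / 2)`.
#' @param seed Integer seed for the initial atom draw.
#' @return Object of class `ksvd_dictionary`: `dictionary` (`d x K`,
#'   unit-norm columns), `errors` (Frobenius representation error after the
#'   coding stage of each iteration), and the training parameters.
#' @export
train_ksvd <- function(samples, n_atoms, iterations = 30L,
                       residual_tol = 0.01, max_atoms = NULL, seed = 1L) {
  if (!is.matrix(samples) || !all(is.finite(samples))) {
    stop("`samples` must be a finite numeric matrix", call. = FALSE)
  }
  d <- nrow(samples); P <- ncol(samples)
  if (n_atoms <= d) {
    stop("`n_atoms` must exceed the signal dimension (overcomplete dictionary)",
         call. = FALSE)
  }
  if (P < n_atoms) {
    stop("need at least as many training samples as atoms", call. = FALSE)
  }
  if (iterations < 1) stop("`iterations` must be >= 1", call. = FALSE)
  if (is.null(max_atoms)) max_atoms <- max(1L, d %/% 2L)

  D <- withr::with_seed(as.integer(seed), {
    norms <- sqrt(colSums(samples^2))
    usable <- which(norms > 1e-12)
    # greedy draw of distinct atoms: shuffle the usable columns and accept
    # each unless it duplicates an accepted atom (|correlation| = 1)
    cand <- if (length(usable)) sample(usable) else integer(0)
    acc <- matrix(0, d, n_atoms)
    k <- 0L
    for (j in cand) {
      if (k == n_atoms) break
      a <- samples[, j] / norms[j]
      if (k > 0L && max(abs(crossprod(acc[, seq_len(k), drop = FALSE], a)))
            > 1 - 1e-8) next
      k <- k + 1L
      acc[, k] <- a
    }
    while (k < n_atoms) {             # shortfall: random unit atoms
      k <- k + 1L
      a <- stats::rnorm(d)
      acc[, k] <- a / sqrt(sum(a^2))
    }
    acc
  })

  fit <- ksvd_engine(samples, D, as.integer(iterations), residual_tol,
                     as.integer(max_atoms), 1e-12)

  structure(list(dictionary = fit$dictionary, errors = as.numeric(fit$errors),
                 n_atoms = n_atoms,
                 iterations = as.integer(iterations),
                 residual_tol = residual_tol, max_atoms = max_atoms,
                 seed = as.integer(seed)),
            class = "ksvd_dictionary")
}

#' @export
print.ksvd_dictionary <- function(x, ...) {
  cat(sprintf(paste0("K-SVD dictionary: %d atoms of dimension %d, ",
                     "%d iterations, final error %.4g\n"),
              x$n_atoms, nrow(x$dictionary), x$iterations,
              x$errors[length(x$errors)]))
  invisible(x)
}

#' Persist / restore a trained dictionary
#'
#' Writes the atom matrix with shape metadata to a plain-text RDS-free format
#' (one header line plus one row per line), so dictionaries survive as text.
#'
#' @param model A `ksvd_dictionary` (or bare dictionary matrix).
#' @param path File path.
#' @return `save_dictionary` returns `path` invisibly; `load_dictionary`
#'   returns the dictionary matrix.
#' @export
save_dictionary <- function(model, path) {
  D <- if (inherits(model, "ksvd_dictionary")) model$dictionary else model
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("nsfuse-dictionary %d %d", nrow(D), ncol(D)), con)
  utils::write.table(format(D, digits = 17), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  header <- strsplit(readLines(path, n = 1L), " ")[[1]]
  if (length(header) != 3 || header[1] != "nsfuse-dictionary") {
    stop("not an nsfuse dictionary file", call. = FALSE)
  }
  vals <- utils::read.table(path, skip = 1L)
  D <- as.matrix(vals)
  dimnames(D) <- NULL
  if (!identical(dim(D), as.integer(header[2:3]))) {
    stop("dictionary file is corrupt", call. = FALSE)
  }
  D
}
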