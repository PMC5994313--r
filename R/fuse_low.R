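# Low-frequency subband fusion: the L1-norm / opposing-sign coefficient rules
# applied column-wise to the two sparse code matrices, the matching mean
# selection, and reconstruction by overlap averaging.

#' Fuse two sparse coefficient matrices column-wise
#'
#' For each patch column `i`, let `s_A` and `s_B` be the L1 norms of the two
#' coefficient columns.  The base rule keeps the column with the larger L1
#' norm (averaging on a tie).  Elements where the two codes carry opposite
#' signs are then overridden by a blend: if the winning column's entry is the
#' smaller in magnitude, half of the opposing entry is added
#' (`a + b/2` when `s_A > s_B` and `|a| < |b|`, symmetrically for B); on an
#' L1 tie the average plus half the larger-magnitude entry is used.
#'
#' @param codes_a,codes_b `K x P` coefficient matrices coded against the same
#'   dictionary.
#' @param tie_tol Relative tolerance declaring the two L1 norms tied
#'   (default `1e-12`).
#' @return `K x P` fused coefficient matrix.
#' @examples
#' a <- matrix(c(0.8, 0.2), 2); b <- matrix(c(0.1, -0.5), 2)
#' fuse_codes(a, b)   # column follows a; opposing entry blended to -0.05
#' @export
fuse_codes <- function(codes_a, codes_b, tie_tol = 1e-12) {
  if (!is.matrix(codes_a) || !is.matrix(codes_b)) {
    stop("codes must be matrices", call. = FALSE)
  }
  .assert_same_shape(codes_a, codes_b, "coefficient matrices")
  s_a <- colSums(abs(codes_a))
  s_b <- colSums(abs(codes_b))
  tie <- abs(s_a - s_b) <= tie_tol * pmax(s_a, s_b)
  a_wins <- !tie & s_a > s_b
  b_wins <- !tie & s_a < s_b

  fused <- codes_a
  fused[, b_wins] <- codes_b[, b_wins]
  fused[, tie] <- (codes_a[, tie] + codes_b[, tie]) / 2

  opp <- codes_a * codes_b < 0
  col_of <- col(codes_a)

  sel <- opp & a_wins[col_of] & abs(codes_a) < abs(codes_b)
  fused[sel] <- codes_a[sel] + codes_b[sel] / 2
  sel <- opp & b_wins[col_of] & abs(codes_a) > abs(codes_b)
  fused[sel] <- codes_b[sel] + codes_a[sel] / 2
  sel <- opp & tie[col_of] & abs(codes_a) > abs(codes_b)
  fused[sel] <- (codes_a[sel] + codes_b[sel]) / 2 + codes_a[sel] / 2
  sel <- opp & tie[col_of] & abs(codes_a) < abs(codes_b)
  fused[sel] <- (codes_a[sel] + codes_b[sel]) / 2 + codes_b[sel] / 2

  fused
}

#' Fuse the removed patch means
#'
#' Chooses per patch the mean of the source whose coefficient column has the
#' larger L1 norm; on a tie the two means are averaged.
#'
#' @param means_a,means_b Length-`P` mean vectors from [remove_means()].
#' @param s_a,s_b Per-column L1 norms of the corresponding code matrices.
#' @param tie_tol Relative tie tolerance.
#' @return Length-`P` fused mean vector.
#' @export
fuse_means <- function(means_a, means_b, s_a, s_b, tie_tol = 1e-12) {
  if (length(means_a) != length(means_b) || length(s_a) != length(means_a) ||
      length(s_b) != length(means_a)) {
    stop("mean and norm vectors must have equal length", call. = FALSE)
  }
  tie <- abs(s_a - s_b) <= tie_tol * pmax(s_a, s_b)
  out <- ifelse(s_a > s_b, means_a, means_b)
  out[tie] <- (means_a[tie] + means_b[tie]) / 2
  out
}

#' Rebuild the fused low-frequency band from fused codes and means
#'
#' Forms `V_F = D alpha_F + means` and reassembles the band by overlap
#' averaging through the codec.
#'
#' @param dictionary `d x K` dictionary with unit-norm atoms.
#' @param codes `K x P` fused coefficient matrix.
#' @param means Length-`P` fused mean vector.
#' @param codec The [patch_codec()] used for extraction.
#' @return Fused low-frequency band (matrix of shape `codec$source_shape`).
#' @export
reconstruct_low <- function(dictionary, codes, means, codec) {
  if (ncol(dictionary) != nrow(codes)) {
    stop("dictionary and codes are inconsistent", call. = FALSE)
  }
  if (length(means) != ncol(codes)) {
    stop("`means` length must equal the number of patches", call. = FALSE)
  }
  V <- dictionary %*% codes
  V <- sweep(V, 2, means, `+`)
  reconstruct_patches(V, codec)
}

#' Fuse two low-frequency subbands by joint sparse coding
#'
#' Runs the full low-frequency chain: sliding-window patch extraction from
#' both bands, per-patch mean removal, joint K-SVD training of one dictionary
#' on the concatenated zero-mean samples, Batch-OMP coding of each band,
#' column-wise coefficient fusion ([fuse_codes()]), mean fusion
#' ([fuse_means()]), and overlap-average reconstruction.
#'
#' @param band_a,band_b Registered low-frequency bands (equal shape).
#' @param window,step Sliding-window geometry (defaults 8 and 1).
#' @param n_atoms Dictionary size (default 256).
#' @param iterations K-SVD sweeps (default 30).
#' @param residual_tol Sparse coding error tolerance (default 0.01).
#' @param max_atoms Per-column sparsity cap; `NULL` for `floor(window^2/2)`.
#' @param seed Seed for the dictionary initialisation.
#' @param keep_model Keep the trained dictionary and codes in the result.
#' @return List of class `low_fusion`: `fused` (band matrix), and when
#'   `keep_model` is `TRUE` also `model`, `codes_a`, `codes_b`, `codec`.
#' @export
fuse_low_band <- function(band_a, band_b, window = 8L, step = 1L,
                          n_atoms = 256L, iterations = 30L,
                          residual_tol = 0.01, max_atoms = NULL,
                          seed = 1L, keep_model = FALSE) {
  .assert_image(band_a); .assert_image(band_b)
  .assert_same_shape(band_a, band_b, "low-frequency bands")
  codec <- patch_codec(dim(band_a), window, step)

  va <- remove_means(extract_patches(band_a, codec))
  vb <- remove_means(extract_patches(band_b, codec))

  model <- train_ksvd(cbind(va$centered, vb$centered), n_atoms = n_atoms,
                      iterations = iterations, residual_tol = residual_tol,
                      max_atoms = max_atoms, seed = seed)
  D <- model$dictionary
  codes_a <- batch_omp(D, va$centered, residual_tol, max_atoms)
  codes_b <- batch_omp(D, vb$centered, residual_tol, max_atoms)

  s_a <- colSums(abs(codes_a))
  s_b <- colSums(abs(codes_b))
  fused_codes <- fuse_codes(codes_a, codes_b)
  fused_means <- fuse_means(va$means, vb$means, s_a, s_b)
  fused <- reconstruct_low(D, fused_codes, fused_means, codec)

  out <- list(fused = fused)
  if (keep_model) {
    out$model <- model
    out$codes_a <- codes_a
    out$codes_b <- codes_b
    out$codec <- codec
  }
  structure(out, class = "low_fusion")
}
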