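# Sliding-window patch extraction / overlap-average reconstruction shared by
# the sparse low-frequency fusion stage.  With step 1 the band is padded
# symmetrically by n - 1 pixels per side, so an M x N band yields
# (M + n - 1) x (N + n - 1) patches and every interior pixel is covered by
# exactly n^2 windows.

#' Patch extraction geometry
#'
#' Fixes the sliding-window geometry (window side, step, padding) shared by
#' [extract_patches()] and [reconstruct_patches()] so that extraction followed
#' by overlap-average reconstruction is the identity.
#'
#' @param source_shape Integer vector `c(rows, cols)` of the band.
#' @param window Window side length `n` in pixels (default 8).
#' @param step Step `S` of the sliding window in pixels (default 1).
#' @return Object of class `patch_codec` with fields `window`, `step`, `pad`
#'   (`n - 1` per side), `source_shape`, `padded_shape`, `patch_count`
#'   (windows per row/column direction) and the window positions.
#' @examples
#' patch_codec(c(8, 8), window = 8)$patch_count   # 15 x 15 -> 225 patches
#' @export
patch_codec <- function(source_shape, window = 8L, step = 1L) {
  if (length(source_shape) != 2 || any(source_shape < 1)) {
    stop("`source_shape` must be c(rows, cols)", call. = FALSE)
  }
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1 || step < 1) {
    stop("`window` and `step` must be positive", call. = FALSE)
  }
  pad <- window - 1L
  if (pad >= min(source_shape)) {
    stop("band is smaller than the patch window", call. = FALSE)
  }
  padded <- as.integer(source_shape) + 2L * pad
  rows <- seq.int(1L, padded[1] - window + 1L, by = step)
  cols <- seq.int(1L, padded[2] - window + 1L, by = step)
  structure(list(
    window = window, step = step, pad = pad,
    source_shape = as.integer(source_shape),
    padded_shape = padded,
    patch_count = c(length(rows), length(cols)),
    row_starts = rows, col_starts = cols
  ), class = "patch_codec")
}

#' Extract sliding-window patches as a sample matrix
#'
#' Vectorises each `n x n` window of the symmetrically padded band into one
#' column (column-major within the window).  Columns are ordered row-major
#' over window positions: all column positions of the first window row first.
#'
#' @param band Numeric matrix with shape `codec$source_shape`.
#' @param codec A [patch_codec()].
#' @return `n^2 x P` numeric matrix; for step 1, `P = (M+n-1)(N+n-1)`.
#' @export
extract_patches <- function(band, codec) {
  .assert_image(band)
  if (!identical(dim(band), codec$source_shape)) {
    stop("`band` shape does not match the codec", call. = FALSE)
  }
  n <- codec$window
  xp <- .pad_sym(band, codec$pad)
  P <- prod(codec$patch_count)
  V <- matrix(0, n * n, P)
  p <- 1L
  for (r in codec$row_starts) {
    for (cc in codec$col_starts) {
      V[, p] <- xp[r:(r + n - 1L), cc:(cc + n - 1L)]
      p <- p + 1L
    }
  }
  V
}

#' Reassemble a band from patch columns by overlap averaging
#'
#' Places each column back at its window position on the padded canvas, sets
#' every pixel to the mean of all overlapping contributions, then crops the
#' padding.  Inverse of [extract_patches()] on exact patches.
#'
#' @param V `n^2 x P` sample matrix in the column order produced by
#'   [extract_patches()].
#' @param codec The same [patch_codec()].
#' @return Numeric matrix of shape `codec$source_shape`.
#' @export
reconstruct_patches <- function(V, codec) {
  n <- codec$window
  if (nrow(V) != n * n || ncol(V) != prod(codec$patch_count)) {
    stop("`V` shape does not match the codec", call. = FALSE)
  }
  acc <- matrix(0, codec$padded_shape[1], codec$padded_shape[2])
  cnt <- matrix(0, codec$padded_shape[1], codec$padded_shape[2])
  p <- 1L
  for (r in codec$row_starts) {
    for (cc in codec$col_starts) {
      ri <- r:(r + n - 1L); ci <- cc:(cc + n - 1L)
      acc[ri, ci] <- acc[ri, ci] + matrix(V[, p], n, n)
      cnt[ri, ci] <- cnt[ri, ci] + 1
      p <- p + 1L
    }
  }
  if (any(cnt == 0)) stop("codec does not cover the full canvas", call. = FALSE)
  out <- acc / cnt
  pad <- codec$pad
  out[pad + seq_len(codec$source_shape[1]),
      pad + seq_len(codec$source_shape[2]), drop = FALSE]
}

# Per-pixel window coverage on the padded canvas (cropped); used to verify
# the overlap-averaging weight map (n^2 on the interior for step 1).
.overlap_counts <- function(codec) {
  n <- codec$window
  cnt <- matrix(0, codec$padded_shape[1], codec$padded_shape[2])
  for (r in codec$row_starts) {
    for (cc in codec$col_starts) {
      cnt[r:(r + n - 1L), cc:(cc + n - 1L)] <-
        cnt[r:(r + n - 1L), cc:(cc + n - 1L)] + 1
    }
  }
  pad <- codec$pad
  cnt[pad + seq_len(codec$source_shape[1]),
      pad + seq_len(codec$source_shape[2]), drop = FALSE]
}

#' Remove per-patch means from a sample matrix
#'
#' @param V Sample matrix (patches as columns).
#' @return List with `centered` (each column sums to zero) and `means`
#'   (length-`P` vector of the removed column means), so that
#'   `centered + rep(means, each = nrow(V))` restores `V` exactly.
#' @export
remove_means <- function(V) {
  if (!is.matrix(V) || !all(is.finite(V))) {
    stop("`V` must be a finite numeric matrix", call. = FALSE)
  }
  m <- colMeans(V)
  list(centered = sweep(V, 2, m), means = m)
}
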