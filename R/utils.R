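# Shared low-level numerics: padding, small-kernel convolution (spatial,
# reflect-padded) and circular convolution in the frequency domain.  Images are
# plain numeric matrices indexed [row, column].

.assert_image <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

.assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical dimensions (%s vs %s)",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

# Symmetric (mirror-with-edge) padding by pr rows / pc columns per side.
.pad_sym <- function(x, pr, pc = pr) {
  nr <- nrow(x); nc <- ncol(x)
  if (pr >= nr || pc >= nc) {
    stop("padding exceeds image size", call. = FALSE)
  }
  ri <- if (pr > 0) c(pr:1, 1:nr, nr:(nr - pr + 1)) else 1:nr
  ci <- if (pc > 0) c(pc:1, 1:nc, nc:(nc - pc + 1)) else 1:nc
  x[ri, ci, drop = FALSE]
}

# Shift with symmetric edge handling: value at (i, j) becomes x(i + dr, j + dc).
.shift_sym <- function(x, dr, dc) {
  p <- max(abs(dr), abs(dc))
  if (p == 0) return(x)
  xp <- .pad_sym(x, p)
  xp[seq_len(nrow(x)) + p + dr, seq_len(ncol(x)) + p + dc, drop = FALSE]
}

# 2-D convolution with an odd-sized kernel and symmetric boundary handling.
.conv2_sym <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  xp <- .pad_sym(x, pr, pc)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      v <- k[i, j]
      if (v == 0) next
      mr <- i - pr - 1L; mc <- j - pc - 1L
      out <- out + v * xp[seq_len(nr) + pr - mr, seq_len(nc) + pc - mc,
                          drop = FALSE]
    }
  }
  out
}

# Windowed sum over an l x l neighbourhood (symmetric boundaries), written as
# an explicit shift-accumulate so tests can mirror it with a per-pixel loop.
.box_sum <- function(x, l) {
  p <- (l - 1L) %/% 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (dr in -p:p) {
    for (dc in -p:p) {
      out <- out + .shift_sym(x, dr, dc)
    }
  }
  out
}

.box_mean <- function(x, l) .box_sum(x, l) / (l * l)

# --- circular (periodic) convolution machinery for the NSCT ------------------

# A kernel in "tap" form: values plus integer (row, col) offsets from the
# filter origin.  Upsampling by an integer matrix M maps offset o to M %*% o.
.kernel_taps <- function(k) {
  cr <- (nrow(k) + 1L) %/% 2L
  cc <- (ncol(k) + 1L) %/% 2L
  idx <- which(k != 0, arr.ind = TRUE)
  list(values = k[idx], dr = idx[, 1L] - cr, dc = idx[, 2L] - cc)
}

.upsample_taps <- function(taps, M) {
  dr <- M[1, 1] * taps$dr + M[1, 2] * taps$dc
  dc <- M[2, 1] * taps$dr + M[2, 2] * taps$dc
  list(values = taps$values, dr = dr, dc = dc)
}

.taps_support <- function(taps) {
  c(diff(range(taps$dr)) + 1L, diff(range(taps$dc)) + 1L)
}

# DFT of the (circularly wrapped) impulse response on an H x W grid.
.taps_spectrum <- function(taps, dims) {
  k <- matrix(0, dims[1], dims[2])
  r <- (taps$dr %% dims[1]) + 1L
  c <- (taps$dc %% dims[2]) + 1L
  for (t in seq_along(taps$values)) {
    k[r[t], c[t]] <- k[r[t], c[t]] + taps$values[t]
  }
  stats::fft(k)
}

.ifft_real <- function(spec) {
  Re(stats::fft(spec, inverse = TRUE)) / length(spec)
}

# Direct spatial circular convolution; the frequency-domain path must agree
# with this to high precision (used as an oracle in the tests).
.conv2_circular_direct <- function(x, k) {
  taps <- .kernel_taps(k)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (t in seq_along(taps$values)) {
    ri <- ((seq_len(nr) - 1L - taps$dr[t]) %% nr) + 1L
    ci <- ((seq_len(nc) - 1L - taps$dc[t]) %% nc) + 1L
    out <- out + taps$values[t] * x[ri, ci, drop = FALSE]
  }
  out
}

#' Rescale a map linearly onto `[0, 1]`
#'
#' Applies `(x - min) / (max - min)`.  A constant map (zero range) is mapped to
#' all zeros rather than producing `NaN`, which is the convention the PCNN
#' stage relies on: a featureless subband must not excite any neuron.
#'
#' @param x Numeric matrix (or vector) with finite entries.
#' @return Object of the same shape with values in `[0, 1]`.
#' @examples
#' normalize01(matrix(c(0, 5, 10), 1))
#' @export
normalize01 <- function(x) {
  if (!all(is.finite(x))) stop("`x` contains non-finite values", call. = FALSE)
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    x[] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Lightweight content checksum used for provenance records.
.content_checksum <- function(x) {
  v <- as.numeric(x)
  sprintf("%.8e:%.8e:%d", sum(v), sum(v * seq_along(v) %% 997), length(v))
}
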