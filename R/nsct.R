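# Nonsubsampled contourlet transform: a-trous nonsubsampled pyramid plus an
# iterated nonsubsampled directional filter bank.  All filtering is circular
# (periodic extension) and performed in the frequency domain; every subband
# keeps the source image size.
#
# Scale ordering is fixed as coarse -> fine: highs[[1]] holds the directional
# bands of the coarsest scale, highs[[levels]] the finest.

.is_pow2 <- function(x) x >= 2 & bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L

# Upsampling matrices of the directional tree.  Depth position t of the
# binary tree uses: identity (t = 1), the quincunx matrix (t = 2), and
# parallelogram matrices built from 2 * diag(2^(t-3), 1) shears for t >= 3,
# with sheared fan kernels providing the finer wedge splits.
.SHEARS <- list(matrix(c(1, 1, 0, 1), 2, byrow = TRUE),
                matrix(c(1, -1, 0, 1), 2, byrow = TRUE),
                matrix(c(1, 0, 1, 1), 2, byrow = TRUE),
                matrix(c(1, 0, -1, 1), 2, byrow = TRUE))

.shear_taps <- function(taps, R) {
  list(values = taps$values,
       dr = R[1, 1] * taps$dr + R[1, 2] * taps$dc,
       dc = R[2, 1] * taps$dr + R[2, 2] * taps$dc)
}

# Stage plan for one directional tree of the given depth: for each tree level
# t and each parent channel k, the tap set of the splitting lowpass filter.
.dfb_stage_taps <- function(u0_taps, t, k) {
  if (t == 1L) return(u0_taps)
  if (t == 2L) {
    Q <- matrix(c(1, -1, 1, 1), 2, byrow = TRUE)
    return(.upsample_taps(u0_taps, Q))
  }
  half <- 2L^(t - 3L)           # 2^(t-3) parents per quadrant group
  nparents <- 2L^(t - 1L)
  first <- k <= nparents / 2L
  kk <- if (first) k else k - nparents / 2L
  slk <- 2L * ((kk - 1L) %/% 2L) - 2L^(t - 3L) + 1L
  M <- if (first) {
    2L * matrix(c(half, 0L, -slk, 1L), 2, byrow = TRUE)
  } else {
    2L * matrix(c(1L, 0L, -slk, half), 2, byrow = TRUE)
  }
  shear <- .SHEARS[[if (first) ((kk - 1L) %% 2L) + 1L else ((kk - 1L) %% 2L) + 3L]]
  .upsample_taps(.shear_taps(u0_taps, shear), M)
}

# Split a band spectrum into 2^depth directional band spectra.  Each split is
# complementary (child2 = parent - child1), so the leaves sum exactly to the
# parent band: reconstruction is plain summation.
.nsdfb_split <- function(spec, depth, u0_taps, dims) {
  bands <- list(spec)
  for (t in seq_len(depth)) {
    nxt <- vector("list", 2L * length(bands))
    for (k in seq_along(bands)) {
      taps <- .dfb_stage_taps(u0_taps, t, k)
      hspec <- .taps_spectrum(taps, dims)
      c0 <- bands[[k]] * hspec
      nxt[[2L * k - 1L]] <- c0
      nxt[[2L * k]] <- bands[[k]] - c0
    }
    bands <- nxt
  }
  bands
}

.max_dfb_support <- function(u0_taps, depth) {
  s <- c(1L, 1L)
  for (t in seq_len(depth)) {
    for (k in seq_len(2L^(t - 1L))) {
      s <- pmax(s, .taps_support(.dfb_stage_taps(u0_taps, t, k)))
    }
  }
  s
}

#' Nonsubsampled contourlet decomposition
#'
#' Decomposes a 2-D image into one lowpass approximation band and, per scale,
#' a set of directional highpass bands.  The pyramid stage is the a-trous
#' scheme: at scale `j` the pyramid filters are upsampled by zero insertion
#' with factor `2^(j-1)`, so no band is ever downsampled and every output has
#' the shape of `image`.  Each scale's highpass band is further split by an
#' iterated two-channel fan filter bank (quincunx/parallelogram upsampling)
#' into `directions[l]` wedge-oriented bands.  All convolutions use circular
#' (periodic) extension, which makes the transform exactly shift-invariant
#' under circular shifts, and the transform is linear.
#'
#' @param image Numeric matrix, typically scaled to `[0, 1]`.
#' @param levels Number of pyramid scales (>= 1).
#' @param directions Integer vector of length `levels`, ordered coarse to
#'   fine; each entry must be a power of two (>= 2) and gives the number of
#'   directional bands at that scale.
#' @param filters Filter bank from [ns_filters()].
#' @return An object of class `nsct_decomposition` with elements `low`
#'   (matrix), `highs` (list over scales, coarse to fine, of lists of
#'   directional band matrices), `levels`, `directions`, `source_shape`, and
#'   the filter labels.
#' @examples
#' x <- matrix(runif(64 * 64), 64)
#' dec <- nsct_decompose(x, levels = 2, directions = c(2, 4))
#' max(abs(nsct_reconstruct(dec) - x))
#' @export
nsct_decompose <- function(image, levels = 4L,
                           directions = c(4L, 4L, 8L, 8L),
                           filters = ns_filters()) {
  .assert_image(image)
  if (length(levels) != 1 || levels < 1 || levels != round(levels)) {
    stop("`levels` must be a positive integer", call. = FALSE)
  }
  levels <- as.integer(levels)
  if (length(directions) != levels) {
    stop("`directions` must have one entry per level", call. = FALSE)
  }
  if (!all(.is_pow2(directions))) {
    stop("each entry of `directions` must be a power of two (>= 2)",
         call. = FALSE)
  }
  dims <- dim(image)

  h0_taps <- .kernel_taps(filters$pyramid_analysis$h0)
  u0_taps <- .kernel_taps(filters$fan_analysis$u0)

  # Support checks: deepest pyramid scale and widest directional stage.
  deepest <- .taps_support(.upsample_taps(h0_taps, diag(2) * 2^(levels - 1L)))
  dfb_sup <- .max_dfb_support(u0_taps, max(as.integer(log2(directions))))
  need <- pmax(deepest, dfb_sup)
  if (any(dims < need)) {
    stop(sprintf(paste0("image (%dx%d) is smaller than the filter support ",
                        "(%dx%d) at the deepest level; reduce `levels` or ",
                        "`directions`"),
                 dims[1], dims[2], need[1], need[2]), call. = FALSE)
  }

  X <- stats::fft(image)
  low_spec <- X
  high_specs <- vector("list", levels)   # index = fine-to-coarse scale j
  for (j in seq_len(levels)) {
    M <- diag(2) * 2^(j - 1L)
    hspec <- .taps_spectrum(.upsample_taps(h0_taps, M), dims)
    new_low <- low_spec * hspec
    high_specs[[j]] <- low_spec - new_low
    low_spec <- new_low
  }

  highs <- vector("list", levels)        # coarse -> fine
  for (l in seq_len(levels)) {
    j <- levels - l + 1L
    depth <- as.integer(log2(directions[l]))
    specs <- .nsdfb_split(high_specs[[j]], depth, u0_taps, dims)
    highs[[l]] <- lapply(specs, .ifft_real)
  }

  structure(list(
    low = .ifft_real(low_spec),
    highs = highs,
    levels = levels,
    directions = as.integer(directions),
    source_shape = dims,
    pyramid_name = filters$pyramid_name,
    directional_name = filters$directional_name
  ), class = "nsct_decomposition")
}

#' Inverse nonsubsampled contourlet transform
#'
#' Exact inverse of [nsct_decompose()] up to floating point error.  Because
#' every analysis split is complementary with unit-impulse synthesis filters,
#' the reconstruction is the sum of the lowpass band and every directional
#' band.
#'
#' @param dec An `nsct_decomposition`.
#' @param filters Filter bank; kept for interface symmetry with the analysis
#'   side (the synthesis kernels are unit impulses).
#' @return Numeric matrix of shape `dec$source_shape`.
#' @export
nsct_reconstruct <- function(dec, filters = NULL) {
  if (!inherits(dec, "nsct_decomposition")) {
    stop("`dec` must be an nsct_decomposition", call. = FALSE)
  }
  shape <- dec$source_shape
  if (!identical(dim(dec$low), shape)) {
    stop("low band shape does not match source_shape", call. = FALSE)
  }
  out <- dec$low
  for (l in seq_along(dec$highs)) {
    if (length(dec$highs[[l]]) != dec$directions[l]) {
      stop("directional band count mismatch", call. = FALSE)
    }
    for (b in dec$highs[[l]]) {
      if (!identical(dim(b), shape)) {
        stop("directional band shape does not match source_shape",
             call. = FALSE)
      }
      out <- out + b
    }
  }
  out
}

#' @export
print.nsct_decomposition <- function(x, ...) {
  cat(sprintf("NSCT decomposition: %dx%d image, %d levels, directions [%s]\n",
              x$source_shape[1], x$source_shape[2], x$levels,
              paste(x$directions, collapse = ", ")))
  cat(sprintf("  filters: pyramid '%s', directional '%s'; %d bands total\n",
              x$pyramid_name, x$directional_name,
              1L + sum(x$directions)))
  invisible(x)
}

#' Write subbands as normalised PNG files (debug aid)
#'
#' @param dec An `nsct_decomposition`.
#' @param dir Output directory; created if missing.  Bands are written as
#'   `low.png` and `level_<l>/dir_<d>.png`, each min-max normalised.
#' @return Invisibly, the paths written.
#' @export
export_subbands <- function(dec, dir) {
  if (!inherits(dec, "nsct_decomposition")) {
    stop("`dec` must be an nsct_decomposition", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "low.png")
  png::writePNG(normalize01(dec$low), paths)
  for (l in seq_along(dec$highs)) {
    d <- file.path(dir, sprintf("level_%d", l))
    dir.create(d, showWarnings = FALSE)
    for (k in seq_along(dec$highs[[l]])) {
      p <- file.path(d, sprintf("dir_%d.png", k))
      png::writePNG(normalize01(dec$highs[[l]][[k]]), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
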