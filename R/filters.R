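# Filter bank construction for the nonsubsampled contourlet transform.
#
# Both stages use complementary analysis pairs: a zero-phase lowpass H0 with
# unit DC gain and its complement H1 = delta - H0 (pyramid), and a fan filter
# U0 with complement U1 = delta - U0 (directional stage).  With synthesis
# filters equal to the unit impulse, analysis-then-synthesis is
# H0 + (delta - H0) = delta, so perfect reconstruction holds exactly for any
# image, any upsampling of the kernels, and any boundary rule.

.PYRAMID_NAMES <- c("pyrexc", "maxflat")
.DIRECTIONAL_NAMES <- c("vk", "dmaxflat7")

# 1-D zero-phase interpolating (halfband) maxflat prototypes; taps sum to 1
# and H(w) + H(pi - w) = 1.
.halfband_prototype <- function(order) {
  switch(as.character(order),
    "7"  = c(-1, 0, 9, 16, 9, 0, -1) / 32,
    "11" = c(3, 0, -25, 0, 150, 256, 150, 0, -25, 0, 3) / 512,
    stop("unsupported halfband order", call. = FALSE)
  )
}

.delta_kernel <- function(n = 1L) {
  k <- matrix(0, n, n)
  k[(n + 1L) %/% 2L, (n + 1L) %/% 2L] <- 1
  k
}

# Full 2-D convolution of two small kernels (used only at build time).
.conv2_full <- function(a, b) {
  ra <- nrow(a); ca <- ncol(a); rb <- nrow(b); cb <- ncol(b)
  out <- matrix(0, ra + rb - 1L, ca + cb - 1L)
  for (i in seq_len(ra)) {
    for (j in seq_len(ca)) {
      if (a[i, j] == 0) next
      out[i:(i + rb - 1L), j:(j + cb - 1L)] <-
        out[i:(i + rb - 1L), j:(j + cb - 1L)] + a[i, j] * b
    }
  }
  out
}

.pad_center <- function(k, dims) {
  out <- matrix(0, dims[1], dims[2])
  r0 <- (dims[1] - nrow(k)) %/% 2L
  c0 <- (dims[2] - ncol(k)) %/% 2L
  out[r0 + seq_len(nrow(k)), c0 + seq_len(ncol(k))] <- k
  out
}

# McClellan transform of a 1-D zero-phase halfband onto the diamond contour
# (cos w1 + cos w2) / 2; odd Chebyshev terms keep the halfband identity, so
# D(w) + D(w + (pi, pi)) = 1 and the result is a diamond-shaped lowpass.
.mcclellan_diamond <- function(h1d) {
  n <- length(h1d)
  center <- (n + 1L) %/% 2L
  base <- matrix(c(0, 0.25, 0,
                   0.25, 0, 0.25,
                   0, 0.25, 0), 3, 3, byrow = TRUE)
  kmax <- center - 1L
  # Chebyshev kernel polynomials T_k evaluated at the transform kernel.
  cheb <- vector("list", kmax + 1L)
  cheb[[1]] <- matrix(1, 1, 1)            # T_0
  if (kmax >= 1) cheb[[2]] <- base        # T_1
  if (kmax >= 2) {
    for (k in 2:kmax) {
      dims <- rep(2L * k + 1L, 2)
      cheb[[k + 1L]] <- 2 * .conv2_full(base, cheb[[k]]) -
        .pad_center(cheb[[k - 1L]], dims)
    }
  }
  dims <- rep(2L * kmax + 1L, 2)
  out <- .pad_center(matrix(h1d[center], 1, 1), dims)
  for (k in seq_len(kmax)) {
    a <- 2 * h1d[center + k]
    if (a != 0) out <- out + a * .pad_center(cheb[[k + 1L]], dims)
  }
  out
}

# Shift the diamond passband by pi along the column frequency axis -> fan.
.modulate_cols <- function(k) {
  cc <- (ncol(k) + 1L) %/% 2L
  sweep(k, 2, (-1)^(seq_len(ncol(k)) - cc), `*`)
}

#' Build the NSCT analysis/synthesis filter bank
#'
#' Constructs the two-channel pyramid pair and the two-channel fan pair used
#' by [nsct_decompose()].  The lowpass/fan filters are zero-phase maxflat
#' designs (the fan via a McClellan diamond transform, modulated by pi along
#' one frequency axis); each highpass/complementary channel is
#' `delta - lowpass`, and the synthesis filters are unit impulses, so the
#' analysis/synthesis pairs satisfy the two-dimensional perfect-reconstruction
#' identity exactly.
#'
#' @param pyramid_name Scale-decomposition filter label: `"pyrexc"`
#'   (7-tap halfband prototype, the default) or `"maxflat"` (11-tap).
#' @param directional_name Directional filter label: `"vk"` (7x7 fan,
#'   default) or `"dmaxflat7"` (11x11 fan).
#' @return An object of class `ns_filter_bank`: lists `pyramid_analysis`
#'   (`h0`, `h1`), `pyramid_synthesis` (`g0`, `g1`), `fan_analysis`
#'   (`u0`, `u1`), `fan_synthesis`, plus the two name labels.  All kernels
#'   have odd dimensions and finite support.
#' @examples
#' fb <- ns_filters()
#' dim(fb$fan_analysis$u0)
#' @seealso [nsct_decompose()], [nsct_reconstruct()]
#' @export
ns_filters <- function(pyramid_name = "pyrexc", directional_name = "vk") {
  if (!is.character(pyramid_name) || length(pyramid_name) != 1 ||
      !(pyramid_name %in% .PYRAMID_NAMES)) {
    stop(sprintf("unknown pyramid filter %s; supported: %s",
                 deparse(pyramid_name),
                 paste(.PYRAMID_NAMES, collapse = ", ")), call. = FALSE)
  }
  if (!is.character(directional_name) || length(directional_name) != 1 ||
      !(directional_name %in% .DIRECTIONAL_NAMES)) {
    stop(sprintf("unknown directional filter %s; supported: %s",
                 deparse(directional_name),
                 paste(.DIRECTIONAL_NAMES, collapse = ", ")), call. = FALSE)
  }
  hp <- .halfband_prototype(if (pyramid_name == "pyrexc") 7 else 11)
  h0 <- outer(hp, hp)
  h1 <- .delta_kernel(nrow(h0)) - h0

  dp <- .halfband_prototype(if (directional_name == "vk") 7 else 11)
  diamond <- .mcclellan_diamond(dp)
  u0 <- .modulate_cols(diamond)
  u1 <- .delta_kernel(nrow(u0)) - u0

  structure(list(
    pyramid_analysis = list(h0 = h0, h1 = h1),
    pyramid_synthesis = list(g0 = .delta_kernel(), g1 = .delta_kernel()),
    fan_analysis = list(u0 = u0, u1 = u1),
    fan_synthesis = list(v0 = .delta_kernel(), v1 = .delta_kernel()),
    pyramid_name = pyramid_name,
    directional_name = directional_name
  ), class = "ns_filter_bank")
}

#' @export
print.ns_filter_bank <- function(x, ...) {
  cat(sprintf("NSCT filter bank: pyramid '%s' (%dx%d), directional '%s' (%dx%d)\n",
              x$pyramid_name, nrow(x$pyramid_analysis$h0),
              ncol(x$pyramid_analysis$h0),
              x$directional_name, nrow(x$fan_analysis$u0),
              ncol(x$fan_analysis$u0)))
  invisible(x)
}

#' Perfect-reconstruction residual of a filter bank
#'
#' Analyses `image` with both two-channel stages of `filters` (circular
#' convolution), resynthesises, and returns the maximum absolute deviation
#' from the input.  Zero (to floating point) certifies the
#' perfect-reconstruction identity.
#'
#' @param filters An [ns_filters()] bank.
#' @param image Numeric matrix used as the probe.
#' @return Named numeric vector with components `pyramid` and `fan`.
#' @export
filter_pr_error <- function(filters, image) {
  .assert_image(image)
  stage <- function(a0, a1, s0, s1) {
    y <- .conv2_circular_direct(.conv2_circular_direct(image, a0), s0) +
      .conv2_circular_direct(.conv2_circular_direct(image, a1), s1)
    max(abs(y - image))
  }
  c(pyramid = stage(filters$pyramid_analysis$h0, filters$pyramid_analysis$h1,
                    filters$pyramid_synthesis$g0, filters$pyramid_synthesis$g1),
    fan = stage(filters$fan_analysis$u0, filters$fan_analysis$u1,
                filters$fan_synthesis$v0, filters$fan_synthesis$v1))
}
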