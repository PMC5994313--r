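# High-frequency subband fusion with a simplified pulse-coupled neural
# network.  The neuron feedback input is the normalised local spatial
# frequency of the band; link strengths are adaptive maps (Laplacian energy,
# visibility, local standard deviation); the per-pixel cumulative ignition
# counts of the three runs are combined by self-weighting and arbitrate which
# source supplies each coefficient.

#' Simplified-PCNN parameter set
#'
#' @param V_L Link amplification factor (default 1).
#' @param V_theta Threshold amplification factor (default 20).
#' @param alpha_L Link decay time constant (default 1).
#' @param alpha_theta Threshold decay time constant (default 0.2).
#' @param N_max Iteration cap (default 100).
#' @param W 3x3 link kernel, zero centre; default is the inverse Euclidean
#'   distance kernel `[[0.707,1,0.707],[1,0,1],[0.707,1,0.707]]`.
#' @return Object of class `pcnn_params`.
#' @export
pcnn_params <- function(V_L = 1, V_theta = 20, alpha_L = 1,
                        alpha_theta = 0.2, N_max = 100L, W = NULL) {
  if (is.null(W)) {
    W <- matrix(c(0.707, 1, 0.707,
                  1,     0, 1,
                  0.707, 1, 0.707), 3, 3, byrow = TRUE)
  }
  if (any(c(V_L, V_theta, alpha_L, alpha_theta) <= 0)) {
    stop("amplification and decay constants must be positive", call. = FALSE)
  }
  if (N_max < 1) stop("`N_max` must be >= 1", call. = FALSE)
  if (!is.matrix(W) || nrow(W) != ncol(W) || nrow(W) %% 2 == 0) {
    stop("`W` must be a square odd-sized matrix", call. = FALSE)
  }
  ctr <- (nrow(W) + 1L) %/% 2L
  if (W[ctr, ctr] != 0) stop("the centre of `W` must be zero", call. = FALSE)
  if (max(abs(W - t(W))) > 0) stop("`W` must be symmetric", call. = FALSE)
  structure(list(V_L = V_L, V_theta = V_theta, alpha_L = alpha_L,
                 alpha_theta = alpha_theta, N_max = as.integer(N_max), W = W),
            class = "pcnn_params")
}

#' Local spatial frequency map
#'
#' Per pixel, the row frequency `RF` is the root of the windowed mean of
#' squared horizontal first differences, the column frequency `CF` likewise
#' for vertical differences, and `SF = sqrt(RF^2 + CF^2)`.  Differences and
#' the windowed mean both use symmetric (reflect) boundary handling; the
#' first difference in each row/column is zero.
#'
#' @param band Numeric matrix (any real-valued subband).
#' @param window Odd window side length, >= 3 (default 3).
#' @return Non-negative matrix of the same shape.
#' @export
spatial_frequency <- function(band, window = 3L) {
  .assert_image(band)
  if (window %% 2 == 0 || window < 3) {
    stop("`window` must be odd and >= 3", call. = FALSE)
  }
  nr <- nrow(band); nc <- ncol(band)
  dh <- matrix(0, nr, nc)
  dh[, 2:nc] <- band[, 2:nc, drop = FALSE] - band[, 1:(nc - 1), drop = FALSE]
  dv <- matrix(0, nr, nc)
  dv[2:nr, ] <- band[2:nr, , drop = FALSE] - band[1:(nr - 1), , drop = FALSE]
  sqrt(.box_mean(dh^2, window) + .box_mean(dv^2, window))
}

#' Adaptive link-strength maps
#'
#' Computes, over an `l x l` window around each pixel: the Laplacian energy
#' `EOL` (windowed sum of squared `f_uu + f_vv` second differences), the
#' visibility `VI` (mean of `(1/m)^alpha |f - m| / m` with `m` the window
#' mean, floored at `1e-6`), and the local standard deviation `SD`.
#'
#' @param band Numeric matrix.
#' @param window Odd window side `l` (default 3).
#' @param vi_alpha Visibility exponent (default 0.7).
#' @return List of matrices `eol`, `vi`, `sd`, all non-negative.
#' @export
link_strength_maps <- function(band, window = 3L, vi_alpha = 0.7) {
  .assert_image(band)
  if (window %% 2 == 0 || window < 3) {
    stop("`window` must be odd and >= 3", call. = FALSE)
  }
  l <- as.integer(window)
  p <- (l - 1L) %/% 2L

  # second differences with symmetric edges
  f_uu <- .shift_sym(band, -1, 0) - 2 * band + .shift_sym(band, 1, 0)
  f_vv <- .shift_sym(band, 0, -1) - 2 * band + .shift_sym(band, 0, 1)
  eol <- .box_sum((f_uu + f_vv)^2, l)

  m <- .box_mean(band, l)
  m_safe <- pmax(m, 1e-6)
  abs_acc <- matrix(0, nrow(band), ncol(band))
  sq_acc <- matrix(0, nrow(band), ncol(band))
  for (dr in -p:p) {
    for (dc in -p:p) {
      s <- .shift_sym(band, dr, dc)
      abs_acc <- abs_acc + abs(s - m)
      sq_acc <- sq_acc + (s - m)^2
    }
  }
  vi <- (1 / m_safe)^vi_alpha * abs_acc / (l * l * m_safe)
  sd <- sqrt(sq_acc / (l * l))
  list(eol = eol, vi = vi, sd = sd)
}

#' Run the simplified PCNN to an ignition-count map
#'
#' Iterates, for `n = 1..N_max` with `L(0) = U(0) = 0`, `theta(0) = 1`,
#' `Y(0) = 0`:
#' `L[n] = exp(-alpha_L) L[n-1] + V_L (W * Y[n-1])`,
#' `U[n] = F (1 + beta L[n])`,
#' `theta[n] = exp(-alpha_theta) theta[n-1] + V_theta Y[n-1]`,
#' `Y[n] = 1` where `U[n] > theta[n]`, else 0, accumulating the ignition
#' count `O[n] = O[n-1] + Y[n]`.  The link convolution uses symmetric
#' boundary handling.
#'
#' @param F_input Feedback input map in `[0, 1]` (non-negative).
#' @param beta Link-strength map (non-negative), same shape.
#' @param params A [pcnn_params()] set.
#' @return Integer-valued ignition-count matrix `O`, bounded by `N_max`.
#' @export
pcnn_run <- function(F_input, beta, params = pcnn_params()) {
  .assert_image(F_input); .assert_image(beta)
  .assert_same_shape(F_input, beta, "PCNN inputs")
  if (any(F_input < 0) || any(beta < 0)) {
    stop("PCNN inputs must be non-negative", call. = FALSE)
  }
  decay_L <- exp(-params$alpha_L)
  decay_T <- exp(-params$alpha_theta)
  L <- matrix(0, nrow(F_input), ncol(F_input))
  theta <- matrix(1, nrow(F_input), ncol(F_input))
  Y <- matrix(0, nrow(F_input), ncol(F_input))
  O <- matrix(0, nrow(F_input), ncol(F_input))
  for (n in seq_len(params$N_max)) {
    L <- decay_L * L + params$V_L * .conv2_sym(Y, params$W)
    U <- F_input * (1 + beta * L)
    theta <- decay_T * theta + params$V_theta * Y
    Y <- (U > theta) * 1
    O <- O + Y
  }
  O
}

#' Combine three ignition maps by self-weighting
#'
#' Per pixel the weights are each map's share of the three-map total; where
#' the total is zero the weights fall back to 1/3 each.  With
#' `global_weights = TRUE` the weights are scalars computed from the summed
#' ignition totals instead.
#'
#' @param o_eol,o_vi,o_sd Ignition-count maps of equal shape.
#' @param global_weights Use one scalar weight triple for the whole map.
#' @return Weighted ignition map.
#' @export
combine_ignitions <- function(o_eol, o_vi, o_sd, global_weights = FALSE) {
  .assert_same_shape(o_eol, o_vi, "ignition maps")
  .assert_same_shape(o_eol, o_sd, "ignition maps")
  if (global_weights) {
    tot <- sum(o_eol) + sum(o_vi) + sum(o_sd)
    if (tot <= 0) return((o_eol + o_vi + o_sd) / 3)
    return((sum(o_eol) * o_eol + sum(o_vi) * o_vi + sum(o_sd) * o_sd) / tot)
  }
  total <- o_eol + o_vi + o_sd
  out <- (o_eol^2 + o_vi^2 + o_sd^2)
  nz <- total > 0
  out[nz] <- out[nz] / total[nz]
  out[!nz] <- 0   # 1/3-weight fallback of an all-zero pixel is zero
  out
}

#' Select high-frequency coefficients by ignition comparison
#'
#' Per pixel the coefficient of the source with the larger combined ignition
#' count wins; ties (within `tie_tol`) average the two coefficients.
#'
#' @param band_a,band_b High-frequency bands.
#' @param o_a,o_b Combined ignition maps.
#' @param tie_tol Absolute tie tolerance (default `1e-12`).
#' @return Fused band.
#' @export
select_high <- function(band_a, band_b, o_a, o_b, tie_tol = 1e-12) {
  .assert_same_shape(band_a, band_b, "bands")
  .assert_same_shape(o_a, o_b, "ignition maps")
  .assert_same_shape(band_a, o_a, "bands and ignition maps")
  tie <- abs(o_a - o_b) <= tie_tol
  out <- ifelse(o_a > o_b, band_a, band_b)
  out[tie] <- (band_a[tie] + band_b[tie]) / 2
  out
}

#' Fuse one pair of high-frequency directional bands
#'
#' Composes the full adaptive chain for one band pair: local spatial
#' frequency ([spatial_frequency()]) normalised to `[0, 1]` as the feedback
#' input; three PCNN runs per source with the normalised Laplacian-energy,
#' visibility and standard-deviation maps as link strengths; self-weighted
#' ignition combination; and per-pixel coefficient selection.  Symmetric in
#' its two inputs and exact on identical inputs.
#'
#' @param band_a,band_b Registered directional bands of equal shape.
#' @param params A [pcnn_params()] set.
#' @param sf_window Spatial-frequency window (default 3).
#' @param ls_window Link-strength window (default 3).
#' @param vi_alpha Visibility exponent (default 0.7).
#' @param global_weights Passed to [combine_ignitions()].
#' @return Fused band matrix.
#' @export
fuse_high_band <- function(band_a, band_b, params = pcnn_params(),
                           sf_window = 3L, ls_window = 3L, vi_alpha = 0.7,
                           global_weights = FALSE) {
  .assert_same_shape(band_a, band_b, "high-frequency bands")
  ignition <- function(band) {
    f <- normalize01(spatial_frequency(band, sf_window))
    ls <- link_strength_maps(band, ls_window, vi_alpha)
    combine_ignitions(
      pcnn_run(f, normalize01(ls$eol), params),
      pcnn_run(f, normalize01(ls$vi), params),
      pcnn_run(f, normalize01(ls$sd), params),
      global_weights = global_weights
    )
  }
  select_high(band_a, band_b, ignition(band_a), ignition(band_b))
}
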