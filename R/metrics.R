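# Fusion quality metrics: histogram entropy, joint-histogram mutual
# information, the Xydeas-Petrovic edge-transfer index Q^AB/F, SSIM, global
# spatial frequency, average gradient, standard deviation, and a mean local
# contrast ("clarity") summary.

.quantize_levels <- function(img, bins) {
  q <- round(img * (bins - 1))
  pmin(pmax(q, 0), bins - 1)
}

#' Shannon entropy of the grey-level histogram
#'
#' @param img Image matrix with values in `[0, 1]`.
#' @param bins Number of grey levels (default 256).
#' @return Entropy in bits (`-sum p log2 p` over non-empty bins).
#' @examples
#' entropy_ie(matrix(0.5, 8, 8))                     # 0 bits
#' entropy_ie(matrix(c(0, 1), 8, 8))                 # 1 bit
#' @export
entropy_ie <- function(img, bins = 256L) {
  .assert_image(img)
  q <- .quantize_levels(img, bins)
  p <- tabulate(q + 1L, nbins = bins) / length(q)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between two images
#'
#' Joint-histogram mutual information over `bins` grey levels,
#' `sum p(a, f) log2(p(a, f) / (p(a) p(f)))`.
#'
#' @param a,f Image matrices in `[0, 1]`, equal shape.
#' @param bins Number of grey levels (default 256).
#' @return Mutual information in bits; `mutual_information(x, x)` equals
#'   [entropy_ie()] of `x`.
#' @export
mutual_information <- function(a, f, bins = 256L) {
  .assert_image(a); .assert_image(f)
  .assert_same_shape(a, f, "images")
  qa <- .quantize_levels(a, bins)
  qf <- .quantize_levels(f, bins)
  joint <- tabulate(qa * bins + qf + 1L, nbins = bins * bins) / length(qa)
  pj <- matrix(joint, bins, bins, byrow = TRUE)   # rows = a levels
  pa <- rowSums(pj); pf <- colSums(pj)
  nz <- which(pj > 0, arr.ind = TRUE)
  sum(pj[nz] * log2(pj[nz] / (pa[nz[, 1]] * pf[nz[, 2]])))
}

.sobel_maps <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  gx <- .conv2_sym(img, kx)
  gy <- .conv2_sym(img, t(kx))
  g <- sqrt(gx^2 + gy^2)
  a <- atan2(gy, gx)
  a[a > pi / 2] <- a[a > pi / 2] - pi    # fold to orientation in (-pi/2, pi/2]
  a[a <= -pi / 2] <- a[a <= -pi / 2] + pi
  list(g = g, a = a)
}

.edge_preservation <- function(src, fus, cfg) {
  gmax <- pmax(src$g, fus$g)
  G <- ifelse(gmax == 0, 1, pmin(src$g, fus$g) / ifelse(gmax == 0, 1, gmax))
  d <- abs(src$a - fus$a)
  d <- pmin(d, pi - d)
  A <- 1 - d / (pi / 2)
  Qg <- cfg$gamma_g / (1 + exp(cfg$kappa_g * (G - cfg$sigma_g)))
  Qa <- cfg$gamma_a / (1 + exp(cfg$kappa_a * (A - cfg$sigma_a)))
  Qg * Qa
}

#' Edge-information transfer index Q^AB/F
#'
#' Scores how much of each source's Sobel edge strength and orientation
#' survives into the fused image.  Per pixel the relative strength
#' (`min/max` of source and fused gradient magnitude) and the orientation
#' agreement (folded to orientation distance, scaled to `[0, 1]`) are pushed
#' through the Xydeas-Petrovic sigmoids and multiplied; the per-source
#' preservation maps are averaged with the source edge strengths as weights.
#'
#' With `normalize = TRUE` (default) the preservation product is scaled by
#' its value at perfect transfer so the index attains exactly 1 when the
#' fused image reproduces both (identical) sources; `normalize = FALSE`
#' keeps the literal sigmoid scaling, whose maximum is about 0.975.
#'
#' @param a,b Source images in `[0, 1]`.
#' @param f Fused image, same shape.
#' @param gamma_g,kappa_g,sigma_g Strength sigmoid constants (defaults
#'   0.9994, -15, 0.5).
#' @param gamma_a,kappa_a,sigma_a Orientation sigmoid constants (defaults
#'   0.9879, -22, 0.8).
#' @param normalize Scale so that perfect transfer scores 1 (default TRUE).
#' @return Scalar in `[0, 1]`; 0 (with a warning) when both sources are
#'   completely flat.
#' @export
q_abf <- function(a, b, f, gamma_g = 0.9994, kappa_g = -15, sigma_g = 0.5,
                  gamma_a = 0.9879, kappa_a = -22, sigma_a = 0.8,
                  normalize = TRUE) {
  .assert_image(a); .assert_image(b); .assert_image(f)
  .assert_same_shape(a, f, "images"); .assert_same_shape(b, f, "images")
  cfg <- list(gamma_g = gamma_g, kappa_g = kappa_g, sigma_g = sigma_g,
              gamma_a = gamma_a, kappa_a = kappa_a, sigma_a = sigma_a)
  sa <- .sobel_maps(a); sb <- .sobel_maps(b); sf <- .sobel_maps(f)
  qaf <- .edge_preservation(sa, sf, cfg)
  qbf <- .edge_preservation(sb, sf, cfg)
  wa <- sa$g; wb <- sb$g
  denom <- sum(wa + wb)
  if (denom == 0) {
    warning("both sources are flat; Q^AB/F undefined, returning 0")
    return(0)
  }
  q <- sum(qaf * wa + qbf * wb) / denom
  if (normalize) {
    peak <- (gamma_g / (1 + exp(kappa_g * (1 - sigma_g)))) *
      (gamma_a / (1 + exp(kappa_a * (1 - sigma_a))))
    q <- q / peak
  }
  min(max(q, 0), 1)
}

#' Average gradient
#'
#' Mean over the common interior grid of
#' `sqrt((df/dx)^2 + (df/dy)^2) / sqrt(2)` with forward first differences.
#'
#' @param img Image matrix.
#' @return Non-negative scalar; 0 for a constant image.
#' @export
avg_gradient <- function(img) {
  .assert_image(img)
  m <- nrow(img); n <- ncol(img)
  dx <- img[1:(m - 1), 2:n, drop = FALSE] - img[1:(m - 1), 1:(n - 1), drop = FALSE]
  dy <- img[2:m, 1:(n - 1), drop = FALSE] - img[1:(m - 1), 1:(n - 1), drop = FALSE]
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Global spatial frequency
#'
#' Full-frame row/column frequency: `RF` is the root mean (over all `M x N`
#' pixels) of squared horizontal first differences, `CF` the vertical
#' counterpart, and `SF = sqrt(RF^2 + CF^2)`.
#'
#' @param img Image matrix.
#' @return Non-negative scalar; 0 for a constant image.
#' @export
global_sf <- function(img) {
  .assert_image(img)
  m <- nrow(img); n <- ncol(img)
  rf2 <- sum((img[, 2:n, drop = FALSE] - img[, 1:(n - 1), drop = FALSE])^2) / (m * n)
  cf2 <- sum((img[2:m, , drop = FALSE] - img[1:(m - 1), , drop = FALSE])^2) / (m * n)
  sqrt(rf2 + cf2)
}

#' Standard deviation of an image
#'
#' Population standard deviation of the pixel values.
#'
#' @param img Image matrix.
#' @return Non-negative scalar.
#' @export
std_dev <- function(img) {
  .assert_image(img)
  sqrt(mean((img - mean(img))^2))
}

.gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Structural similarity index
#'
#' Mean SSIM over the image with the standard 11x11 Gaussian window
#' (`sigma = 1.5`) and constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for
#' dynamic range `L = 1`.
#'
#' @param x,y Image matrices in `[0, 1]`, equal shape.
#' @return Scalar in `[-1, 1]`; `ssim(x, x)` is 1.
#' @export
ssim <- function(x, y) {
  .assert_image(x); .assert_image(y)
  .assert_same_shape(x, y, "images")
  k <- .gaussian_kernel()
  C1 <- 0.01^2; C2 <- 0.03^2
  mx <- .conv2_sym(x, k); my <- .conv2_sym(y, k)
  sxx <- .conv2_sym(x * x, k) - mx^2
  syy <- .conv2_sym(y * y, k) - my^2
  sxy <- .conv2_sym(x * y, k) - mx * my
  map <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(map)
}

#' Mean local contrast ("clarity")
#'
#' Windowed standard deviation divided by the windowed mean, averaged over
#' the image.  This is a non-canonical stand-in for the clarity summary used
#' in fusion tables (no standard formula exists); it is reported for
#' completeness only.
#'
#' @param img Image matrix in `[0, 1]`.
#' @param window Odd window side (default 3).
#' @return Non-negative scalar.
#' @export
mean_contrast <- function(img, window = 3L) {
  .assert_image(img)
  l <- as.integer(window)
  m <- .box_mean(img, l)
  s2 <- .box_mean(img^2, l) - m^2
  mean(sqrt(pmax(s2, 0)) / pmax(m, 0.01))
}

#' Full fusion quality report
#'
#' Evaluates the metric suite for a fused image against its two sources.
#' `mi` is the summed form `MI(A,F) + MI(B,F)` and `ssim` the summed
#' `SSIM(A,F) + SSIM(B,F)` (the convention under which combined-structural
#' scores can exceed 1).
#'
#' @param a,b Source images in `[0, 1]`.
#' @param f Fused image.
#' @param bins Histogram bins for entropy / mutual information.
#' @return Object of class `fusion_metrics`: scalars `ie`, `sf_global`,
#'   `ag`, `mi`, `sd`, `q_abf`, `ssim`, `mc` plus a parameter echo.
#' @export
fusion_metrics <- function(a, b, f, bins = 256L) {
  structure(list(
    ie = entropy_ie(f, bins),
    sf_global = global_sf(f),
    ag = avg_gradient(f),
    mi = mutual_information(a, f, bins) + mutual_information(b, f, bins),
    sd = std_dev(f),
    q_abf = q_abf(a, b, f),
    ssim = ssim(a, f) + ssim(b, f),
    mc = mean_contrast(f),
    params = list(bins = bins, ssim_window = 11L, ssim_sigma = 1.5,
                  mc_window = 3L)
  ), class = "fusion_metrics")
}

#' @export
print.fusion_metrics <- function(x, ...) {
  cat("Fusion quality report\n")
  for (k in c("ie", "sf_global", "ag", "mi", "sd", "q_abf", "ssim", "mc")) {
    cat(sprintf("  %-9s %.6f\n", paste0(k, ":"), x[[k]]))
  }
  invisible(x)
}
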