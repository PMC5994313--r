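# Seeded generator of complementary multimodal phantom pairs: a "structural"
# image (sharp, high-contrast boundaries: a bone-like ring plus thresholded
# random shapes) and a "functional" image (smooth activity blobs and
# band-limited texture confined to the ring interior).  Ground-truth feature
# masks let tests assert which source carries which feature.

.gauss_blob <- function(rr, cc, r0, c0, sigma) {
  exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sigma^2))
}

# Band-limited noise: white noise smoothed with a Gaussian kernel, zero-mean,
# unit max-abs.
.smooth_noise <- function(size, sigma) {
  z <- matrix(stats::rnorm(size * size), size)
  k1 <- exp(-(seq(-ceiling(3 * sigma), ceiling(3 * sigma)))^2 / (2 * sigma^2))
  k <- outer(k1, k1); k <- k / sum(k)
  s <- .conv2_sym(z, k)
  s <- s - mean(s)
  s / max(abs(s))
}

#' Generate a complementary structural/functional phantom pair
#'
#' The structural phantom carries a high-contrast ring (bone-like boundary)
#' and thresholded smooth random shapes outside the ring; its interior is
#' flat.  The functional phantom is flat where the structural features live
#' and carries smooth Gaussian activity blobs plus low-amplitude band-limited
#' texture strictly inside the ring.  Every named feature therefore has
#' strong contrast in exactly one of the two images, which is what the
#' fusion pipeline must preserve.
#'
#' @param size Image side length in pixels (>= 64; default 128).
#' @param seed Integer seed; the pair is a pure function of `(size, seed,
#'   noise_sigma)`.
#' @param noise_sigma Standard deviation of additive Gaussian noise
#'   (default 0.005); images are clipped to `[0, 1]`.
#' @return Object of class `phantom_pair`: matrices `structural` and
#'   `functional` in `[0, 1]`; `masks`, a named list of logical matrices
#'   (`ring`, `blobs`, `shapes`, `interior`, `background`); and the
#'   generator arguments.
#' @examples
#' p <- make_pair(size = 64, seed = 1)
#' feature_contrast(p$structural, p$masks$ring, p$masks$background)
#' @export
make_pair <- function(size = 128L, seed = 1L, noise_sigma = 0.005) {
  size <- as.integer(size)
  if (size < 64L) stop("`size` must be >= 64", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)

  withr::with_seed(as.integer(seed), {
    rr <- matrix(seq_len(size), size, size)
    cc <- t(rr)
    ctr <- (size + 1) / 2
    rad <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
    r_ring <- 0.32 * size
    w_ring <- 0.035 * size
    ring <- abs(rad - r_ring) <= w_ring
    interior_all <- rad < r_ring - w_ring
    exterior <- rad > r_ring + w_ring

    # structural: flat base, bright ring, thresholded smooth shapes outside
    structural <- matrix(0.25, size, size)
    structural[ring] <- 0.85
    shape_field <- .smooth_noise(size, sigma = 0.06 * size)
    shapes <- shape_field > stats::quantile(shape_field[exterior], 0.8) &
      rad > r_ring + 3 * w_ring
    structural[shapes] <- 0.62

    # functional: flat base, smooth blobs + texture inside the ring
    functional <- matrix(0.2, size, size)
    n_blobs <- 3L
    blob_map <- matrix(0, size, size)
    margin <- r_ring - 3 * w_ring
    ang <- stats::runif(n_blobs, 0, 2 * pi)
    dist <- stats::runif(n_blobs, 0.15, 0.55) * margin
    sig <- stats::runif(n_blobs, 0.05, 0.08) * size
    for (b in seq_len(n_blobs)) {
      blob_map <- pmax(blob_map, .gauss_blob(rr, cc,
                                             ctr + dist[b] * sin(ang[b]),
                                             ctr + dist[b] * cos(ang[b]),
                                             sig[b]))
    }
    inside <- rad < r_ring - 2 * w_ring
    blob_map[!inside] <- 0
    functional <- functional + 0.55 * blob_map
    blobs <- blob_map > 0.65

    texture_zone <- inside & !(blob_map > 0.2)
    texture <- 0.06 * .smooth_noise(size, sigma = 0.015 * size)
    functional[texture_zone] <- functional[texture_zone] + texture[texture_zone]

    if (noise_sigma > 0) {
      structural <- structural + matrix(stats::rnorm(size^2, 0, noise_sigma), size)
      functional <- functional + matrix(stats::rnorm(size^2, 0, noise_sigma), size)
    }
    structural <- pmin(pmax(structural, 0), 1)
    functional <- pmin(pmax(functional, 0), 1)

    background <- exterior & !shapes & rad > r_ring + 3 * w_ring
    interior_flat <- interior_all & !(blob_map > 0.1) & !texture_zone

    structure(list(
      structural = structural,
      functional = functional,
      masks = list(ring = ring, blobs = blobs, shapes = shapes,
                   interior = interior_flat, background = background),
      seed = as.integer(seed), size = size, noise_sigma = noise_sigma
    ), class = "phantom_pair")
  })
}

#' Contrast of a masked feature against a reference region
#'
#' @param img Image matrix.
#' @param mask Logical matrix selecting the feature pixels.
#' @param ref_mask Logical matrix selecting the reference (surround) pixels.
#' @return `|mean(img[mask]) - mean(img[ref_mask])|`.
#' @export
feature_contrast <- function(img, mask, ref_mask) {
  if (!any(mask) || !any(ref_mask)) {
    stop("empty feature or reference mask", call. = FALSE)
  }
  abs(mean(img[mask]) - mean(img[ref_mask]))
}

#' Luminance-exact hot-body colormap
#'
#' Maps `t` in `[0, 1]` to an RGB ramp black -> red -> yellow -> white whose
#' BT.601 luminance (`0.299 R + 0.587 G + 0.114 B`) equals `t` exactly, so a
#' pseudo-colored activity map can be inverted back to its scalar values.
#'
#' @param t Numeric vector/matrix in `[0, 1]`.
#' @return If `t` is a matrix, an `H x W x 3` array; otherwise an
#'   `length(t) x 3` matrix.
#' @export
heat_colormap <- function(t) {
  tv <- pmin(pmax(as.numeric(t), 0), 1)
  R <- pmin(1, 3 * tv)
  G <- pmin(pmax((tv - 0.299 * R) / 0.587, 0), 1)
  B <- pmin(pmax((tv - 0.299 * R - 0.587 * G) / 0.114, 0), 1)
  if (is.matrix(t)) {
    out <- array(0, c(nrow(t), ncol(t), 3L))
    out[, , 1] <- R; out[, , 2] <- G; out[, , 3] <- B
    out
  } else {
    cbind(R = R, G = G, B = B)
  }
}

#' Generate a grayscale-structural / pseudo-color-functional pair
#'
#' Emulates an anatomy + functional-activity pairing: the structural phantom
#' from [make_pair()] (noise-free) together with an RGB rendering of a
#' blobs-only activity map through [heat_colormap()].  Chroma is non-zero
#' only where the activity is, and the luminance of the color image equals
#' the activity map by construction.
#'
#' @param size Image side length (>= 64; default 128).
#' @param seed Integer seed.
#' @return List of class `phantom_color_pair`: `gray` (matrix), `color`
#'   (`H x W x 3` array), `activity` (the scalar map the color encodes),
#'   `masks`, `seed`, `size`.
#' @export
make_color_pair <- function(size = 128L, seed = 1L) {
  pair <- make_pair(size = size, seed = seed, noise_sigma = 0)
  activity <- withr::with_seed(as.integer(seed) + 1L, {
    rr <- matrix(seq_len(pair$size), pair$size, pair$size)
    cc <- t(rr)
    ctr <- (pair$size + 1) / 2
    rad <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
    r_in <- 0.32 * pair$size - 2 * 0.035 * pair$size
    blob_map <- matrix(0, pair$size, pair$size)
    ang <- stats::runif(3, 0, 2 * pi)
    dist <- stats::runif(3, 0.1, 0.5) * r_in
    sig <- stats::runif(3, 0.05, 0.08) * pair$size
    for (b in 1:3) {
      blob_map <- pmax(blob_map, .gauss_blob(rr, cc,
                                             ctr + dist[b] * sin(ang[b]),
                                             ctr + dist[b] * cos(ang[b]),
                                             sig[b]))
    }
    blob_map[rad >= r_in] <- 0
    blob_map[blob_map < 1e-3] <- 0          # hard support for chroma checks
    0.85 * blob_map
  })
  structure(list(
    gray = pair$structural,
    color = heat_colormap(activity),
    activity = activity,
    masks = c(pair$masks, list(activity_support = activity > 0)),
    seed = as.integer(seed), size = pair$size
  ), class = "phantom_color_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("Phantom pair: %dx%d, seed %d, noise sigma %.3g\n",
              x$size, x$size, x$seed, x$noise_sigma))
  invisible(x)
}
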