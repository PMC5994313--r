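# End-to-end orchestration: configuration, image I/O, grayscale and color
# fusion, and simple baselines.

#' Fusion pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated record.  The
#' defaults are the reference parameter set: 4 decomposition levels with
#' "pyrexc"/"vk" filters, an 8x8 sliding window with step 1, 256 atoms, 30
#' K-SVD iterations, sparse error 0.01, and the PCNN constants
#' `V_L = 1`, `V_theta = 20`, `alpha_L = 1`, `alpha_theta = 0.2`,
#' `N_max = 100`.
#'
#' @param nsct List overriding `levels`, `directions`, `pyramid_name`,
#'   `directional_name`.
#' @param sparse List overriding `window`, `step`, `n_atoms`,
#'   `ksvd_iterations`, `sparse_error`, `seed`.
#' @param pcnn List overriding `V_L`, `V_theta`, `alpha_L`, `alpha_theta`,
#'   `N_max`, `sf_window`, `ls_window`, `vi_alpha`, `global_weights`.
#' @param color_mode `"luminance-fuse"` (fuse the luminance channel, pass
#'   chroma through untouched) or `"per-channel"`.
#' @param output_dtype `"uint8"` or `"float"`; controls file output rounding.
#' @return Object of class `fusion_config`.
#' @export
fusion_config <- function(nsct = list(), sparse = list(), pcnn = list(),
                          color_mode = c("luminance-fuse", "per-channel"),
                          output_dtype = c("uint8", "float")) {
  color_mode <- match.arg(color_mode)
  output_dtype <- match.arg(output_dtype)
  merge <- function(defaults, user) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) {
      stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    utils::modifyList(defaults, user)
  }
  cfg <- structure(list(
    nsct = merge(list(levels = 4L, directions = c(4L, 4L, 8L, 8L),
                      pyramid_name = "pyrexc", directional_name = "vk"),
                 nsct),
    sparse = merge(list(window = 8L, step = 1L, n_atoms = 256L,
                        ksvd_iterations = 30L, sparse_error = 0.01,
                        seed = 1L), sparse),
    pcnn = merge(list(V_L = 1, V_theta = 20, alpha_L = 1, alpha_theta = 0.2,
                      N_max = 100L, sf_window = 3L, ls_window = 3L,
                      vi_alpha = 0.7, global_weights = FALSE), pcnn),
    color_mode = color_mode,
    output_dtype = output_dtype
  ), class = "fusion_config")
  validate_fusion_config(cfg)
}

#' @rdname fusion_config
#' @param config A `fusion_config` to validate.
#' @export
validate_fusion_config <- function(config) {
  ns <- config$nsct
  if (ns$levels < 1 || length(ns$directions) != ns$levels ||
      !all(.is_pow2(ns$directions))) {
    stop("invalid nsct config: need levels >= 1 and one power-of-two ",
         "direction count per level", call. = FALSE)
  }
  ns_filters(ns$pyramid_name, ns$directional_name)   # validates the labels
  sp <- config$sparse
  if (sp$window < 2 || sp$step < 1 || sp$sparse_error < 0 ||
      sp$ksvd_iterations < 1 || sp$n_atoms <= sp$window^2) {
    stop("invalid sparse config (window >= 2, step >= 1, sparse_error >= 0, ",
         "ksvd_iterations >= 1, n_atoms > window^2)", call. = FALSE)
  }
  pc <- config$pcnn
  pcnn_params(pc$V_L, pc$V_theta, pc$alpha_L, pc$alpha_theta, pc$N_max)
  if (pc$sf_window %% 2 == 0 || pc$ls_window %% 2 == 0) {
    stop("PCNN windows must be odd", call. = FALSE)
  }
  config
}

#' Read / write a fusion configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_fusion_config` returns a validated `fusion_config`;
#'   `write_fusion_config` returns `path` invisibly.  A config round-trips
#'   through serialization unchanged.
#' @export
read_fusion_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  fusion_config(nsct = raw$nsct %||% list(),
                sparse = raw$sparse %||% list(),
                pcnn = raw$pcnn %||% list(),
                color_mode = raw$color_mode %||% "luminance-fuse",
                output_dtype = raw$output_dtype %||% "uint8")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_fusion_config
#' @param config A `fusion_config`.
#' @export
write_fusion_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# ---- image I/O --------------------------------------------------------------

#' Read / write images (PNG, TIFF)
#'
#' 8-bit (or 16-bit) grayscale and RGB images are mapped to `[0, 1]`
#' doubles; alpha channels are dropped; on write, `uint8` output rounds
#' symmetrically back to 8 bits.
#'
#' @param path Image file; format follows the extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return `read_image`: a matrix (grayscale) or `H x W x 3` array (RGB).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (supported: png, tif, tiff)",
                 ext), call. = FALSE)
  )
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (length(dim(img)) == 3) {
    img <- img[, , 1]
  }
  img
}

#' @rdname read_image
#' @param img Matrix or `H x W x 3` array in `[0, 1]`.
#' @param dtype `"uint8"` quantizes to 8 bits; `"float"` writes as-is.
#' @export
write_image <- function(img, path, dtype = "uint8") {
  img <- pmin(pmax(img, 0), 1)
  if (dtype == "uint8") img <- round(img * 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop(sprintf("unsupported image format '.%s' (supported: png, tif, tiff)",
                 ext), call. = FALSE)
  )
  invisible(path)
}

#' RGB / YCbCr conversion (BT.601, chroma centred at zero)
#'
#' @param rgb `H x W x 3` array in `[0, 1]`.
#' @return `rgb_to_ycbcr`: list of matrices `y`, `cb`, `cr`;
#'   `ycbcr_to_rgb` the inverse array (not clipped).
#' @export
rgb_to_ycbcr <- function(rgb) {
  R <- rgb[, , 1]; G <- rgb[, , 2]; B <- rgb[, , 3]
  y <- 0.299 * R + 0.587 * G + 0.114 * B
  list(y = y, cb = (B - y) * 0.564, cr = (R - y) * 0.713)
}

#' @rdname rgb_to_ycbcr
#' @param y,cb,cr Luminance and chroma planes.
#' @export
ycbcr_to_rgb <- function(y, cb, cr) {
  R <- y + cr / 0.713
  B <- y + cb / 0.564
  G <- (y - 0.299 * R - 0.114 * B) / 0.587
  out <- array(0, c(nrow(y), ncol(y), 3L))
  out[, , 1] <- R; out[, , 2] <- G; out[, , 3] <- B
  out
}

# ---- fusion drivers ---------------------------------------------------------

.check_registered <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop("source images are not registered: shapes differ (",
         paste(dim(a)[1:2], collapse = "x"), " vs ",
         paste(dim(b)[1:2], collapse = "x"), ")", call. = FALSE)
  }
}

#' Fuse two registered grayscale images
#'
#' Runs the full pipeline: NSCT decomposition of both sources, sparse-coding
#' fusion of the low-frequency bands ([fuse_low_band()]), PCNN fusion of
#' every directional high-frequency band ([fuse_high_band()]), and inverse
#' NSCT.  Deterministic for a fixed config (the only randomness is the
#' seeded dictionary initialisation).
#'
#' @param a,b Numeric matrices in `[0, 1]`, equal shape.
#' @param config A [fusion_config()].
#' @param keep_decompositions Retain the three decompositions in the result.
#' @param compute_metrics Attach a [fusion_metrics()] report.
#' @return Object of class `fusion_result`: `fused` (matrix in `[0, 1]`),
#'   `clipped_pixels` (count clipped into range), `metrics` (optional),
#'   `decompositions` (optional), `config`, `provenance`.
#' @examples
#' \donttest{
#' p <- make_pair(size = 64, seed = 3)
#' cfg <- fusion_config(sparse = list(ksvd_iterations = 2L, n_atoms = 128L))
#' res <- fuse_gray(p$structural, p$functional, cfg)
#' range(res$fused)
#' }
#' @export
fuse_gray <- function(a, b, config = fusion_config(),
                      keep_decompositions = FALSE, compute_metrics = FALSE) {
  .assert_image(a, "a"); .assert_image(b, "b")
  .check_registered(a, b)
  if (min(a, b) < -1e-9 || max(a, b) > 1 + 1e-9) {
    stop("inputs must be scaled to [0, 1]", call. = FALSE)
  }
  validate_fusion_config(config)
  fb <- ns_filters(config$nsct$pyramid_name, config$nsct$directional_name)
  dec_a <- nsct_decompose(a, config$nsct$levels, config$nsct$directions, fb)
  dec_b <- nsct_decompose(b, config$nsct$levels, config$nsct$directions, fb)

  sp <- config$sparse
  low <- fuse_low_band(dec_a$low, dec_b$low, window = sp$window,
                       step = sp$step, n_atoms = sp$n_atoms,
                       iterations = sp$ksvd_iterations,
                       residual_tol = sp$sparse_error, seed = sp$seed)

  pc <- config$pcnn
  params <- pcnn_params(pc$V_L, pc$V_theta, pc$alpha_L, pc$alpha_theta,
                        pc$N_max)
  highs <- vector("list", dec_a$levels)
  for (l in seq_len(dec_a$levels)) {
    highs[[l]] <- vector("list", dec_a$directions[l])
    for (d in seq_len(dec_a$directions[l])) {
      highs[[l]][[d]] <- fuse_high_band(dec_a$highs[[l]][[d]],
                                        dec_b$highs[[l]][[d]],
                                        params = params,
                                        sf_window = pc$sf_window,
                                        ls_window = pc$ls_window,
                                        vi_alpha = pc$vi_alpha,
                                        global_weights = pc$global_weights)
    }
  }
  dec_f <- structure(list(low = low$fused, highs = highs,
                          levels = dec_a$levels,
                          directions = dec_a$directions,
                          source_shape = dec_a$source_shape,
                          pyramid_name = dec_a$pyramid_name,
                          directional_name = dec_a$directional_name),
                     class = "nsct_decomposition")
  raw <- nsct_reconstruct(dec_f, fb)
  clipped <- sum(raw < 0 | raw > 1)
  fused <- pmin(pmax(raw, 0), 1)

  out <- list(
    fused = fused,
    clipped_pixels = clipped,
    config = config,
    provenance = list(seed = sp$seed,
                      source_shape = dim(a),
                      checksum_a = .content_checksum(a),
                      checksum_b = .content_checksum(b))
  )
  if (keep_decompositions) {
    out$decompositions <- list(a = dec_a, b = dec_b, fused = dec_f)
  }
  if (compute_metrics) out$metrics <- fusion_metrics(a, b, fused)
  structure(out, class = "fusion_result")
}

#' Fuse a grayscale image with a pseudo-color functional image
#'
#' In `"luminance-fuse"` mode (default) the color image is converted to
#' YCbCr, its luminance is fused with the grayscale image via [fuse_gray()],
#' and the untouched chroma planes are recombined — so chrominance passes
#' through bit-exactly (the result's `chroma` field is the input's chroma).
#' In `"per-channel"` mode each RGB channel is fused with the gray image
#' independently.
#'
#' @param gray Grayscale matrix in `[0, 1]`.
#' @param color `H x W x 3` RGB array in `[0, 1]`, same spatial shape.
#' @param config A [fusion_config()]; `config$color_mode` selects the mode.
#' @return `fusion_result` whose `fused` is an `H x W x 3` array; in
#'   luminance mode also `luma` (the fused luminance) and `chroma`
#'   (`cb`/`cr` pass-through planes).
#' @export
fuse_color <- function(gray, color, config = fusion_config()) {
  .assert_image(gray, "gray")
  if (length(dim(color)) != 3 || dim(color)[3] != 3) {
    stop("`color` must be an H x W x 3 array", call. = FALSE)
  }
  .check_registered(gray, color)
  if (config$color_mode == "per-channel") {
    fused <- array(0, dim(color))
    results <- vector("list", 3)
    for (ch in 1:3) {
      results[[ch]] <- fuse_gray(gray, color[, , ch], config)
      fused[, , ch] <- results[[ch]]$fused
    }
    res <- results[[1]]
    res$fused <- fused
    return(res)
  }
  ycc <- rgb_to_ycbcr(color)
  res <- fuse_gray(gray, ycc$y, config)
  rgb <- ycbcr_to_rgb(res$fused, ycc$cb, ycc$cr)
  res$luma <- res$fused
  res$chroma <- list(cb = ycc$cb, cr = ycc$cr)
  res$clipped_pixels <- res$clipped_pixels + sum(rgb < 0 | rgb > 1)
  res$fused <- pmin(pmax(rgb, 0), 1)
  res
}

#' Reference baseline fusions
#'
#' Pixel averaging and choose-maximum, used as comparison baselines in
#' property tests and quality benchmarks.
#'
#' @param a,b Registered images of equal shape.
#' @param method `"average"` or `"max"`.
#' @return Fused matrix.
#' @export
fuse_baseline <- function(a, b, method = c("average", "max")) {
  method <- match.arg(method)
  .assert_same_shape(a, b, "images")
  if (method == "average") (a + b) / 2 else pmax(a, b)
}

#' @export
print.fusion_result <- function(x, ...) {
  d <- dim(x$fused)
  cat(sprintf("Fusion result: %s image, %d pixel(s) clipped\n",
              paste(d, collapse = "x"), x$clipped_pixels))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
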