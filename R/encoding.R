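#' Read a raster image as an H x W x 3 array
#'
#' Reads PNG/PPM (and other formats supported by EBImage) into the package's
#' internal representation: an array with dimensions (rows, columns,
#' channel), values in `[0, 1]`, grayscale replicated onto R, G, B.
#'
#' @param path Image file.
#' @return `H x W x 3` numeric array in `[0, 1]`.
#' @export
read_scene_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image '%s'", path))
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- as.array(img)
  if (length(d) == 2) {
    m <- t(a)  # EBImage stores (x, y); internal is (row, col)
    arr <- array(rep(m, 3), c(dim(m), 3))
  } else {
    a <- a[, , 1:min(3, d[3]), drop = FALSE]
    arr <- aperm(a, c(2, 1, 3))
    if (dim(arr)[3] == 1) arr <- array(rep(arr, 3), c(dim(arr)[1:2], 3))
  }
  pmin(pmax(arr, 0), 1)
}

# default feature weights: gray carries half the weight, each colour a sixth
default_feature_weights <- function() c(gray = 0.5, r = 1/6, g = 1/6, b = 1/6)

#' Extract the normalized feature stack of an image
#'
#' Builds the four per-pixel features the encoder works with: gray intensity
#' (mean of R, G, B) and the three colour channels, each in `[0, 1]`, with
#' optional Gaussian denoising and resizing.
#'
#' @param image `H x W x 3` array in `[0, 1]`, an `H x W` gray matrix, or a
#'   file path.
#' @param blur If `TRUE`, apply a 3 x 3 Gaussian kernel (sd 1 pixel) to each
#'   feature; intended for natural images. Default `FALSE`.
#' @param resize Optional target size `c(width, height)` in pixels.
#' @param weights Feature weights (gray, r, g, b); default `(0.5, 1/6, 1/6,
#'   1/6)`.
#' @return An object of class `feature_stack`: list of matrices `gray`, `r`,
#'   `g`, `b` plus `weights`.
#' @export
preprocess_image <- function(image, blur = FALSE, resize = NULL,
                             weights = default_feature_weights()) {
  if (is.character(image)) image <- read_scene_image(image)
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("`image` must be an H x W x 3 array, gray matrix, or file path")
  if (min(image) < 0 || max(image) > 1)
    stop("image values must lie in [0, 1]")
  if (length(weights) != 4 || sum(weights) <= 0)
    stop("`weights` must be 4 non-negative values with positive sum")
  if (!is.null(resize)) {
    stopifnot(length(resize) == 2, all(resize >= 1))
    image <- aperm(as.array(EBImage::resize(
      EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color"),
      w = as.integer(resize[1]), h = as.integer(resize[2]))), c(2, 1, 3))
    image <- pmin(pmax(image, 0), 1)
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  ch <- function(i) matrix(image[, , i], H, W)  # keep dims for 1-row/col images
  feats <- list(gray = (ch(1) + ch(2) + ch(3)) / 3,
                r = ch(1), g = ch(2), b = ch(3))
  if (isTRUE(blur)) {
    k <- outer(dnorm(-1:1), dnorm(-1:1))
    k <- k / sum(k)
    feats <- lapply(feats, function(m)
      EBImage::filter2(m, k, boundary = "replicate"))
  }
  structure(c(feats, list(weights = as.numeric(weights))),
            class = "feature_stack")
}

#' Per-pixel contrast map
#'
#' Weighted mean absolute deviation of each pixel's features from the
#' image-wide feature means:
#' `C = sum_l w_l |f_l - mean(f_l)| / sum_l w_l`. Lies in `[0, 1]` for
#' features in `[0, 1]`.
#'
#' @param features A [preprocess_image()] feature stack.
#' @return `H x W` contrast matrix.
#' @export
contrast_map <- function(features) {
  stopifnot(inherits(features, "feature_stack"))
  w <- features$weights
  f <- features[c("gray", "r", "g", "b")]
  acc <- 0
  for (l in 1:4) acc <- acc + w[l] * abs(f[[l]] - mean(f[[l]]))
  acc / sum(w)
}

#' Contrast-to-frequency coding
#'
#' Affine map of contrast onto natural frequency:
#' `o = 1 - 0.5 delta_o + delta_o * C`, so `C` in `[0, 1]` spans
#' `[1 - 0.5 delta_o, 1 + 0.5 delta_o]` and higher contrast means a faster
#' oscillator.
#'
#' @param contrast Contrast matrix from [contrast_map()].
#' @param delta_o Frequency span (> 0). Default 0.04, mapping contrast onto
#'   `[0.98, 1.02]` (the model's two object-frequency bands).
#' @return Frequency matrix of the same shape.
#' @export
frequency_map <- function(contrast, delta_o = 0.04) {
  if (delta_o <= 0) stop("`delta_o` must be positive")
  1 - 0.5 * delta_o + delta_o * contrast
}

#' Natural frequency of the central unit
#'
#' The central (second-layer) oscillator runs at the arithmetic mean of all
#' first-layer frequencies.
#'
#' @param freq Frequency matrix from [frequency_map()].
#' @return Scalar mean frequency.
#' @export
central_frequency <- function(freq) {
  if (length(freq) == 0) stop("empty frequency map")
  mean(freq)
}

#' Contrast-dependent coupling strengths
#'
#' Gaussian-in-contrast coupling coding: with
#' `g = exp(-(1 - C)^2 / (2 sigma^2))`, the positive (binding) strength is
#' `lambda+ = lambda_max_pos * g` (increasing in contrast) and the negative
#' (separating) strength is `lambda- = lambda_max_neg * (1 - g)`
#' (decreasing in contrast). Both are returned as non-negative magnitudes;
#' the network applies `lambda-` repulsively.
#'
#' @param contrast Contrast matrix.
#' @param lambda_max_pos,lambda_max_neg Maximum positive/negative coupling
#'   strengths. Defaults 0.05 and 0.02.
#' @param sigma Width of the contrast-coupling Gaussian (> 0); set according
#'   to the image. Default 0.2.
#' @return List with matrices `pos` and `neg`.
#' @export
coupling_maps <- function(contrast, lambda_max_pos = 0.05,
                          lambda_max_neg = 0.02, sigma = 0.2) {
  if (sigma <= 0) stop("`sigma` must be positive")
  g <- exp(-(1 - contrast)^2 / (2 * sigma^2))
  list(pos = lambda_max_pos * g, neg = lambda_max_neg * (1 - g))
}

# matrix shifted by (dj, dk), NA outside
shift_mat <- function(m, dj, dk) {
  M <- nrow(m); N <- ncol(m)
  out <- matrix(NA_real_, M, N)
  js <- seq_len(M); ks <- seq_len(N)
  jv <- js + dj; kv <- ks + dk
  jok <- jv >= 1 & jv <= M; kok <- kv >= 1 & kv <= N
  out[js[jok], ks[kok]] <- m[jv[jok], kv[kok]]
  out
}

neighbour_offsets <- function() {
  o <- expand.grid(dj = -1:1, dk = -1:1)
  o[!(o$dj == 0 & o$dk == 0), ]
}

#' Similarity-gated 8-neighbour coupling topology
#'
#' Every in-grid pair of 8-neighbours carries exactly one link: positive
#' (binding) if the weighted feature distance between the two pixels is at
#' most `theta`, negative (separating) otherwise. The split is symmetric and
#' the two link sets partition the 8-neighbour graph.
#'
#' @param features A [preprocess_image()] feature stack.
#' @param theta Similarity threshold (>= 0) on the weighted mean absolute
#'   feature difference. Default 0.1.
#' @return An object of class `coupling_topology`: `nbr` (npix x 8 matrix of
#'   0-based neighbour linear indices, -1 where absent), `sign` (npix x 8;
#'   0 none, 1 positive, 2 negative), `dims`, `theta`. Pixels are in
#'   column-major order.
#' @export
build_topology <- function(features, theta = 0.1) {
  stopifnot(inherits(features, "feature_stack"))
  if (theta < 0) stop("`theta` must be >= 0")
  f <- features[c("gray", "r", "g", "b")]
  w <- features$weights / sum(features$weights)
  M <- nrow(f$gray); N <- ncol(f$gray)
  P <- M * N
  offs <- neighbour_offsets()
  nbr <- matrix(-1L, P, 8)
  sgn <- matrix(0L, P, 8)
  J <- matrix(seq_len(M), M, N)
  K <- matrix(rep(seq_len(N), each = M), M, N)
  for (q in seq_len(8)) {
    dj <- offs$dj[q]; dk <- offs$dk[q]
    dist <- 0
    for (l in 1:4) dist <- dist + w[l] * abs(f[[l]] - shift_mat(f[[l]], dj, dk))
    valid <- !is.na(dist)
    tgt <- (K + dk - 1L) * M + (J + dj) - 1L   # 0-based linear index
    nbr[, q] <- ifelse(valid, tgt, -1L)
    sgn[, q] <- ifelse(valid, ifelse(dist <= theta, 1L, 2L), 0L)
  }
  structure(list(nbr = nbr, sign = sgn, dims = c(M, N), theta = theta),
            class = "coupling_topology")
}

#' Encode an image into oscillator-network parameters
#'
#' Full first-layer encoding: feature extraction, contrast map, per-pixel
#' natural frequencies, positive/negative coupling strengths and the
#' similarity-gated 8-neighbour topology, plus the central-unit frequency.
#'
#' @inheritParams preprocess_image
#' @inheritParams frequency_map
#' @inheritParams coupling_maps
#' @inheritParams build_topology
#' @return An object of class `scene_encoding` with elements `features`,
#'   `contrast`, `freq`, `o_r`, `lambda_pos`, `lambda_neg`, `topology`,
#'   `dims` and `params`.
#' @export
encode_image <- function(image, delta_o = 0.04, sigma = 0.2,
                         lambda_max_pos = 0.05, lambda_max_neg = 0.02,
                         theta = 0.1, weights = default_feature_weights(),
                         blur = FALSE, resize = NULL) {
  feats <- preprocess_image(image, blur = blur, resize = resize,
                            weights = weights)
  ctr <- contrast_map(feats)
  freq <- frequency_map(ctr, delta_o)
  cpl <- coupling_maps(ctr, lambda_max_pos, lambda_max_neg, sigma)
  topo <- build_topology(feats, theta)
  structure(list(features = feats, contrast = ctr, freq = freq,
                 o_r = central_frequency(freq),
                 lambda_pos = cpl$pos, lambda_neg = cpl$neg,
                 topology = topo, dims = dim(ctr),
                 params = list(delta_o = delta_o, sigma = sigma,
                               lambda_max_pos = lambda_max_pos,
                               lambda_max_neg = lambda_max_neg,
                               theta = theta, blur = blur)),
            class = "scene_encoding")
}

#' @export
print.scene_encoding <- function(x, ...) {
  cat(sprintf("<scene_encoding> %d x %d pixels, o in [%.4f, %.4f], o_r = %.4f\n",
              x$dims[1], x$dims[2], min(x$freq), max(x$freq), x$o_r))
  invisible(x)
}

#' @importFrom stats dnorm
NULL
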