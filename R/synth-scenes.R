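#' Specify a synthetic test scene
#'
#' Describes an artificial image: K uniformly coloured, pairwise
#' non-overlapping objects (rectangles or ellipses) on a uniform background.
#' Scenes of this structure are the model's standard test inputs, since they
#' come with exact ground-truth labels.
#'
#' @param width,height Canvas size in pixels.
#' @param background Length-3 RGB vector in `[0, 1]`.
#' @param objects List of objects; each is a list with `shape` ("rectangle"
#'   or "ellipse"), centre `x` (column), `y` (row), size `w`, `h` (pixels)
#'   and `color` (RGB in `[0, 1]`).
#' @param noise_sd Optional additive Gaussian pixel noise sd (default 0).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width, height, background = c(0.5, 0.5, 0.5),
                       objects = list(), noise_sd = 0, seed = 1L) {
  stopifnot(width >= 1, height >= 1, length(background) == 3,
            all(background >= 0 & background <= 1))
  for (ob in objects) {
    stopifnot(ob$shape %in% c("rectangle", "ellipse"),
              length(ob$color) == 3, all(ob$color >= 0 & ob$color <= 1))
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 background = as.numeric(background), objects = objects,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

object_mask <- function(ob, width, height) {
  m <- matrix(FALSE, height, width)
  cx <- ob$x; cy <- ob$y
  hw <- ob$w / 2; hh <- ob$h / 2
  cols <- seq_len(width); rows <- seq_len(height)
  if (ob$shape == "rectangle") {
    jc <- rows >= cy - hh & rows <= cy + hh
    kc <- cols >= cx - hw & cols <= cx + hw
    m[jc, kc] <- TRUE
  } else {
    xx <- matrix(rep(cols, each = height), height, width)
    yy <- matrix(rows, height, width)
    m <- ((xx - cx) / hw)^2 + ((yy - cy) / hh)^2 <= 1
  }
  m
}

#' Render a synthetic scene with ground-truth labels
#'
#' Deterministic given the spec (and its seed, when noise is enabled).
#' Labels are 0 for background and 1..K for the objects in list order.
#'
#' @param spec A [scene_spec()] or preset name accepted by [scene_preset()].
#' @return An object of class `synthetic_scene`: list with `image`
#'   (`H x W x 3` in `[0, 1]`), `labels` (`H x W` integer matrix) and `spec`.
#' @examples
#' sc <- make_scene(scene_preset("three-object", scale = 0.2))
#' table(sc$labels)
#' @export
make_scene <- function(spec) {
  if (is.character(spec)) spec <- scene_preset(spec)
  stopifnot(inherits(spec, "scene_spec"))
  W <- spec$width; H <- spec$height
  img <- array(rep(spec$background, each = H * W), c(H, W, 3))
  labels <- matrix(0L, H, W)
  masks <- lapply(spec$objects, object_mask, width = W, height = H)
  for (i in seq_along(masks)) {
    ob <- spec$objects[[i]]
    if (ob$x - ob$w / 2 < 1 || ob$x + ob$w / 2 > W ||
        ob$y - ob$h / 2 < 1 || ob$y + ob$h / 2 > H)
      stop(sprintf("object %d extends outside the canvas", i))
    if (!any(masks[[i]])) stop(sprintf("object %d is empty", i))
    for (j in seq_along(masks)) {
      if (j < i && any(masks[[i]] & masks[[j]]))
        stop(sprintf("objects %d and %d overlap", j, i))
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[masks[[i]]] <- ob$color[ch]
      img[, , ch] <- plane
    }
    labels[masks[[i]]] <- i
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img <- pmin(pmax(img + array(stats::rnorm(length(img), 0, spec$noise_sd),
                                 dim(img)), 0), 1)
  }
  structure(list(image = img, labels = labels, spec = spec),
            class = "synthetic_scene")
}

#' Built-in scene and chain presets
#'
#' Three presets cover the model's standard experiments:
#' \describe{
#'   \item{`"three-object"`}{Blue, yellow and green rectangles on a gray
#'     210 x 151 background (four groups including background). Colours are
#'     chosen so encoded contrasts are strictly ordered (yellow > green >
#'     blue > background), giving an unambiguous salience order.}
#'   \item{`"five-object"`}{Yellow, purple, green, azure and red objects on
#'     gray (six groups); contrasts again strictly ordered.}
#'   \item{`"two-band-chain"`}{Not an image: a coupled chain whose first half
#'     has frequencies evenly spaced in `[1.01, 1.02]` and second half in
#'     `[0.98, 0.99]`, for controller-only experiments. Returns a list with a
#'     [chain_config()] and the two group memberships.}
#' }
#'
#' @param name Preset name.
#' @param scale Spatial scale factor for the image presets; `scale = 0.2`
#'   gives the 42 x 30 test-size canvas. Default 1 (210 x 151).
#' @param n Chain length for `"two-band-chain"`. Default 10.
#' @param lambda Chain coupling strength for `"two-band-chain"`.
#'   Default -0.09.
#' @return A [scene_spec()], or for `"two-band-chain"` a list with elements
#'   `config` and `groups`.
#' @export
scene_preset <- function(name, scale = 1, n = 10, lambda = -0.09) {
  rect <- function(x, y, w, h, color)
    list(shape = "rectangle", x = x * scale, y = y * scale,
         w = w * scale, h = h * scale, color = color)
  ell <- function(x, y, w, h, color)
    list(shape = "ellipse", x = x * scale, y = y * scale,
         w = w * scale, h = h * scale, color = color)
  switch(
    name,
    "three-object" = scene_spec(
      width = round(210 * scale), height = round(151 * scale),
      background = c(0.08, 0.08, 0.08),
      objects = list(
        rect(40, 75, 44, 44, c(0.305, 0.366, 0.609)),  # blue (least salient object)
        rect(105, 75, 44, 44, c(0.971, 0.971, 0.243)), # yellow (most salient)
        rect(170, 75, 44, 44, c(0.362, 1.000, 0.362))) # green
    ),
    "five-object" = scene_spec(
      width = round(210 * scale), height = round(151 * scale),
      background = c(0.08, 0.08, 0.08),
      objects = list(
        rect(38, 40, 36, 36, c(0.968, 0.968, 0.242)),  # yellow (most salient)
        rect(105, 40, 36, 36, c(0.736, 0.303, 0.866)), # purple
        ell(172, 40, 36, 36, c(0.319, 0.997, 0.319)),  # green
        ell(55, 112, 40, 36, c(0.334, 0.473, 0.557)),  # azure
        rect(150, 112, 40, 36, c(0.626, 0.250, 0.219))) # red
    ),
    "two-band-chain" = {
      n1 <- ceiling(n / 2)
      freqs <- c(seq(1.01, 1.02, length.out = n1),
                 seq(0.98, 0.99, length.out = n - n1))
      list(config = chain_config(n, lambda, freqs),
           groups = rep(1:2, c(n1, n - n1)))
    },
    stop(sprintf("unknown preset '%s'", name))
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  k <- max(x$labels)
  cat(sprintf("<synthetic_scene> %d x %d pixels, %d object%s + background\n",
              nrow(x$labels), ncol(x$labels), k, if (k == 1) "" else "s"))
  invisible(x)
}
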