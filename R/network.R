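#' Right-hand side of the first-layer oscillator grid
#'
#' Reference (vectorized R) evaluation of the image network dynamics: each
#' pixel oscillator follows the Rossler equations at its encoded frequency,
#' with the x-equation augmented by the similarity-gated coupling
#' `+ lambda+ * sum_pos(x_q - x_jk) - lambda- * sum_neg(x_q - x_jk)` over its
#' 8-neighbours. The compiled simulator ([simulate_layer1()]) performs the
#' identical arithmetic.
#'
#' @param state `M x N x 3` array of oscillator states (planes x, y, z).
#' @param encoding A [encode_image()] result.
#' @param params A [rossler_params()] (a, b, c used).
#' @return `M x N x 3` array of derivatives.
#' @export
layer1_rhs <- function(state, encoding, params = rossler_params()) {
  stopifnot(inherits(encoding, "scene_encoding"))
  dm <- encoding$dims
  if (!all(dim(state) == c(dm, 3))) stop("state/encoding shape mismatch")
  P <- prod(dm)
  x <- as.vector(state[, , 1]); y <- as.vector(state[, , 2])
  z <- as.vector(state[, , 3])
  topo <- encoding$topology
  sp <- numeric(P); sn <- numeric(P)
  for (q in 1:8) {
    idx <- topo$nbr[, q]
    v <- idx >= 0
    d <- numeric(P)
    d[v] <- x[idx[v] + 1L] - x[v]
    sp <- sp + d * (topo$sign[, q] == 1L)
    sn <- sn + d * (topo$sign[, q] == 2L)
  }
  o <- as.vector(encoding$freq)
  dx <- -o * y - z + as.vector(encoding$lambda_pos) * sp -
    as.vector(encoding$lambda_neg) * sn
  dy <- o * x + params$a * y
  dz <- params$b + z * (x - params$c)
  array(c(dx, dy, dz), c(dm, 3))
}

#' Simulate the first-layer oscillator grid
#'
#' Integrates the image network with the compiled Grunwald-Letnikov scheme.
#' Initial states are drawn i.i.d. uniform on `[0, 1]^3` per pixel under
#' `fcfg$seed` unless `init` is given. When `groups` is supplied, the hybrid
#' (group-mean) state `w` and hybrid drift (group-mean right-hand side) are
#' recorded at full step resolution for the control layer; recording is
#' purely observational and does not alter the dynamics.
#'
#' @param encoding A [encode_image()] result.
#' @param fcfg A [frac_config()].
#' @param groups Optional `M x N` integer label matrix (e.g. segmentation or
#'   ground-truth labels); group ids are its sorted unique values.
#' @param init Optional `3 x (M*N)` matrix of initial states (pixels in
#'   column-major order).
#' @param keep_every Keep every `keep_every`-th step for the phase/state
#'   outputs. Default 10.
#' @param params A [rossler_params()].
#' @return An object of class `layer1_sim`: subsampled `times`, `x`, `y`
#'   (npix x kept), unwrapped `phases`, `final` state, and when `groups` was
#'   given `w` / `omega` (3G x steps matrices, rows grouped by group) plus
#'   `group_ids`.
#' @export
simulate_layer1 <- function(encoding, fcfg, groups = NULL, init = NULL,
                            keep_every = 10, params = rossler_params()) {
  stopifnot(inherits(encoding, "scene_encoding"), inherits(fcfg, "frac_config"))
  dm <- encoding$dims
  P <- prod(dm)
  if (is.null(init)) {
    if (!is.null(fcfg$seed)) set.seed(fcfg$seed)
    init <- matrix(runif(3 * P), 3, P)
  }
  if (!is.matrix(init) || nrow(init) != 3 || ncol(init) != P)
    stop("`init` must be a 3 x (M*N) matrix")
  nsteps <- floor(fcfg$t_end / fcfg$h)
  L <- as.integer(min(fcfg$memory_length, nsteps))
  gvec <- integer(0); gids <- integer(0)
  if (!is.null(groups)) {
    if (!all(dim(groups) == dm)) stop("groups/encoding shape mismatch")
    gids <- sort(unique(as.vector(groups)))
    gvec <- match(as.vector(groups), gids) - 1L
  }
  res <- sim_grid_gl(as.vector(encoding$freq),
                     as.vector(encoding$lambda_pos),
                     as.vector(encoding$lambda_neg),
                     encoding$topology$nbr, encoding$topology$sign,
                     fcfg$alpha, fcfg$h, nsteps, L,
                     params$a, params$b, params$c,
                     init, as.integer(keep_every), gvec, length(gids))
  times <- seq(0, by = fcfg$h * keep_every, length.out = ncol(res$x))
  out <- list(times = times, x = res$x, y = res$y,
              phases = unwrap_rows(atan2(res$y, res$x)),
              final = res$final, dims = dm, o_r = encoding$o_r,
              fcfg = fcfg, params = params, keep_every = keep_every,
              init = init, group_ids = gids)
  if (length(gids)) { out$w <- res$w; out$omega <- res$omega }
  structure(out, class = "layer1_sim")
}

#' @export
print.layer1_sim <- function(x, ...) {
  cat(sprintf(
    "<layer1_sim> %d x %d grid, t in [0, %g], %d kept samples%s\n",
    x$dims[1], x$dims[2], max(x$times), length(x$times),
    if (length(x$group_ids))
      sprintf(", hybrid signals for %d groups", length(x$group_ids)) else ""))
  invisible(x)
}
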