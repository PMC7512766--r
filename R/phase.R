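#' Wrapped oscillator phase
#'
#' Quadrant-correct phase angle of the (x, y) projection of an oscillator
#' state, in `(-pi, pi]`. A two-argument arctangent is used so the phase is
#' continuous around the attractor (a plain `atan(y/x)` loses the quadrant
#' and breaks unwrapping).
#'
#' @param x,y Coordinates (vectors of equal length). The origin has no
#'   defined phase and raises an error.
#' @return Angles in `(-pi, pi]`.
#' @examples
#' wrapped_phase(1, 0)    # 0
#' wrapped_phase(0, 1)    # pi/2
#' wrapped_phase(-1, -1)  # -3*pi/4
#' @export
wrapped_phase <- function(x, y) {
  if (any(x == 0 & y == 0)) stop("phase undefined at the origin (x = y = 0)")
  atan2(y, x)
}

#' Unwrap a wrapped phase series
#'
#' Adds multiples of 2*pi so that successive increments lie in `(-pi, pi]`,
#' turning a sawtooth of wrapped angles into a continuous, trend-increasing
#' phase. The first sample is unchanged. Requires sampling fine enough that
#' true increments stay below pi in magnitude.
#'
#' @param w Numeric vector of wrapped phases (radians).
#' @return The unwrapped series.
#' @export
unwrap_phase <- function(w) {
  if (length(w) < 2) return(w)
  d <- diff(w)
  w + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

# row-wise unwrap of a (series x time) matrix, vectorized
unwrap_rows <- function(W) {
  if (is.null(dim(W))) return(unwrap_phase(W))
  if (ncol(W) < 2) return(W)
  d <- W[, -1, drop = FALSE] - W[, -ncol(W), drop = FALSE]
  corr <- -2 * pi * round(d / (2 * pi))
  cum <- matrixStats_rowCumsum(corr)
  W + cbind(0, cum)
}

matrixStats_rowCumsum <- function(m) {
  # cumulative sum along rows of a matrix (apply returns transposed)
  if (ncol(m) == 1) return(m)
  t(apply(m, 1, cumsum))
}

#' Phase trace of simulated oscillators
#'
#' Computes per-oscillator unwrapped phases from x/y trajectories.
#'
#' @param x,y Matrices (oscillators x time points).
#' @param times Sampling times.
#' @return An object of class `phase_trace`: list with `times` and `psi`
#'   (oscillators x time points, unwrapped radians).
#' @export
phase_trace <- function(x, y, times) {
  x <- rbind(x); y <- rbind(y)
  stopifnot(all(dim(x) == dim(y)), length(times) == ncol(x))
  structure(list(times = as.numeric(times),
                 psi = unwrap_rows(wrapped_phase(x, y))),
            class = "phase_trace")
}

#' Phase standard deviation of a labelled group
#'
#' Population (divide-by-n) standard deviation of the member oscillators'
#' unwrapped phases at one time point.
#'
#' @param psi Matrix of unwrapped phases (oscillators x time points).
#' @param labels Integer label per oscillator (0 = background).
#' @param group Group id to evaluate.
#' @param time_index Column of `psi` to evaluate at.
#' @return Non-negative scalar.
#' @export
group_phase_std <- function(psi, labels, group, time_index) {
  labels <- as.integer(labels)
  if (!group %in% labels) stop(sprintf("unknown group id %s", group))
  pop_sd(psi[labels == group, time_index])
}

#' Detect phase synchronization between two phase series
#'
#' Two oscillators are phase synchronized on a window when their phase
#' difference stays bounded: after removing the median offset, the maximum
#' absolute residual difference must stay below `bound`.
#'
#' @param psi_a,psi_b Unwrapped phase series (equal length).
#' @param window Logical or integer index selecting the comparison window.
#' @param bound Positive bound on the centred phase difference (radians).
#' @return `TRUE` iff the centred difference stays below `bound` on the window.
#' @export
sync_detect <- function(psi_a, psi_b, window = seq_along(psi_a), bound = pi) {
  stopifnot(length(psi_a) == length(psi_b), bound > 0)
  d <- (psi_a - psi_b)[window]
  max(abs(d - median(d))) < bound
}

#' Segment oscillators by phase at a readout time
#'
#' One-dimensional phase-gap clustering: pixel phases are sorted and cut
#' wherever the gap between consecutive sorted phases exceeds
#' `gap_threshold`; each connected run becomes one group. The cluster holding
#' the most image-border pixels becomes the background (label 0); remaining
#' clusters are labelled 1..K in order of decreasing mean phase (fastest
#' group first).
#'
#' @param psi_readout Matrix (M x N) or vector of unwrapped pixel phases at
#'   the readout time.
#' @param gap_threshold Minimum phase gap (radians) that separates clusters.
#'   Default 0.5.
#' @param dims Grid dimensions `c(M, N)`; required when `psi_readout` is a
#'   vector (column-major pixel order).
#' @return Integer label matrix (M x N); labels contiguous from 0.
#' @export
segment_by_phase <- function(psi_readout, gap_threshold = 0.5, dims = NULL) {
  if (is.matrix(psi_readout)) {
    dims <- dim(psi_readout)
    v <- as.vector(psi_readout)
  } else {
    if (is.null(dims)) stop("`dims` required for vector input")
    v <- as.numeric(psi_readout)
  }
  stopifnot(gap_threshold > 0, length(v) == prod(dims))
  ord <- order(v)
  sv <- v[ord]
  cuts <- which(diff(sv) > gap_threshold)
  cl_sorted <- cumsum(c(1L, as.integer(seq_along(sv)[-1] %in% (cuts + 1L))))
  cl <- integer(length(v))
  cl[ord] <- cl_sorted
  # background = cluster holding the most border pixels
  m <- matrix(cl, dims[1], dims[2])
  border <- c(m[1, ], m[dims[1], ], m[, 1], m[, dims[2]])
  bg <- as.integer(names(which.max(table(border))))
  ids <- setdiff(sort(unique(cl)), bg)
  mean_phase <- vapply(ids, function(i) mean(v[cl == i]), numeric(1))
  ids <- ids[order(-mean_phase)]
  lab <- integer(length(v))
  for (k in seq_along(ids)) lab[cl == ids[k]] <- k
  matrix(lab, dims[1], dims[2])
}

#' Gray-level entropy of segmented regions
#'
#' Shannon entropy (base 2) of the 256-bin gray-level histogram inside each
#' labelled region, plus the mean over object (non-background) labels. Lower
#' entropy means more homogeneous segments.
#'
#' @param labels Integer label matrix (M x N), 0 = background.
#' @param image `M x N x 3` array in `[0, 1]`, or an M x N gray matrix.
#' @return List with `per_label` (named vector, one entry per label incl.
#'   background) and `mean_object` (mean over labels > 0; `NaN` if none).
#' @export
segmentation_entropy <- function(labels, image) {
  gray <- if (length(dim(image)) == 3) {
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  } else image
  stopifnot(all(dim(gray) == dim(labels)))
  lev <- pmin(pmax(floor(gray * 255), 0), 255)
  ids <- sort(unique(as.vector(labels)))
  ent <- vapply(ids, function(i) {
    p <- tabulate(lev[labels == i] + 1L, nbins = 256L)
    p <- p[p > 0] / sum(p)
    -sum(p * log2(p))
  }, numeric(1))
  names(ent) <- ids
  list(per_label = ent, mean_object = mean(ent[ids > 0]))
}
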