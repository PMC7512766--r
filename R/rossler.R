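#' Rossler oscillator parameters
#'
#' System parameters of the (fractional-order) Rossler oscillator used
#' throughout the model:
#' `D^a x = -o y - z`, `D^a y = o x + a y`, `D^a z = b + z (x - c)`,
#' with defaults `a = 0.48`, `b = 0.6`, `c = 6` and natural frequency `o`.
#'
#' @param a,b,c Dimensionless system parameters.
#' @param o Natural frequency (> 0); sets the oscillator's phase velocity.
#' @return An object of class `rossler_params`.
#' @export
rossler_params <- function(a = 0.48, b = 0.6, c = 6, o = 1) {
  if (!is.numeric(o) || o <= 0) stop("`o` must be positive")
  structure(list(a = a, b = b, c = c, o = o), class = "rossler_params")
}

#' Right-hand side of a single Rossler oscillator
#'
#' @param state Numeric length-3 vector `(x, y, z)`.
#' @param params A [rossler_params()].
#' @return Numeric length-3 derivative `(-o y - z, o x + a y, b + z (x - c))`.
#' @examples
#' rossler_rhs(c(0, 0, 0), rossler_params())  # (0, 0, 0.6)
#' @export
rossler_rhs <- function(state, params = rossler_params()) {
  if (length(state) != 3 || any(!is.finite(state)))
    stop("`state` must be a finite length-3 vector")
  x <- state[1]; y <- state[2]; z <- state[3]
  c(-params$o * y - z,
    params$o * x + params$a * y,
    params$b + z * (x - params$c))
}

#' Configuration of a coupled Rossler chain
#'
#' A 1-D chain of `n` oscillators coupled through the x-equation with scalar
#' strength `lambda` (negative values are diffusive/synchronizing). Ends are
#' free: a missing neighbour contributes nothing and the self term is scaled
#' to the number of present neighbours.
#'
#' @param n Number of oscillators (>= 1).
#' @param lambda Coupling strength (may be negative).
#' @param frequencies Length-`n` vector of positive natural frequencies.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n, lambda = 0, frequencies = rep(1, n)) {
  n <- as.integer(n)
  if (n < 1) stop("`n` must be >= 1")
  if (length(frequencies) != n) stop("`frequencies` must have length `n`")
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  structure(list(n = n, lambda = lambda, frequencies = as.numeric(frequencies)),
            class = "chain_config")
}

#' Right-hand side of the coupled Rossler chain
#'
#' Oscillator `j` receives the coupling term
#' `lambda * (k_j x_j - sum of present neighbours)` in its x-equation, where
#' `k_j` is the number of present neighbours (1 at the ends, 2 inside); the
#' y and z equations are uncoupled.
#'
#' @param states `n x 3` matrix of oscillator states (columns x, y, z).
#' @param config A [chain_config()].
#' @param params A [rossler_params()]; its `o` is ignored in favour of
#'   `config$frequencies`.
#' @return `n x 3` matrix of derivatives.
#' @export
chain_rhs <- function(states, config, params = rossler_params()) {
  stopifnot(inherits(config, "chain_config"))
  states <- rbind(states)
  if (nrow(states) != config$n || ncol(states) != 3)
    stop("`states` must be an n x 3 matrix matching the chain config")
  x <- states[, 1]; y <- states[, 2]; z <- states[, 3]
  n <- config$n
  o <- config$frequencies
  left <- c(NA, x[-n]); right <- c(x[-1], NA)
  nb <- ifelse(is.na(left), 0, left) + ifelse(is.na(right), 0, right)
  deg <- (!is.na(left)) + (!is.na(right))
  cbind(-o * y - z + config$lambda * (deg * x - nb),
        o * x + params$a * y,
        params$b + z * (x - params$c))
}

#' Simulate a coupled Rossler chain
#'
#' Integrates the chain with the Grunwald-Letnikov scheme (compiled fast
#' path) and returns subsampled x/y trajectories plus unwrapped phases.
#'
#' @param config A [chain_config()].
#' @param fcfg A [frac_config()]; initial states are drawn i.i.d. uniform on
#'   `[0, 1]^3` under `fcfg$seed` unless `init` is given.
#' @param params A [rossler_params()] (a, b, c used; per-oscillator
#'   frequencies come from `config`).
#' @param init Optional `3 x n` matrix of initial states.
#' @param keep_every Keep every `keep_every`-th step for output. Default 10.
#' @return An object of class `chain_sim`: `times`, `x`, `y` (n x kept),
#'   `phases` (unwrapped, n x kept), plus the configurations.
#' @export
simulate_chain <- function(config, fcfg, params = rossler_params(),
                           init = NULL, keep_every = 10) {
  stopifnot(inherits(config, "chain_config"), inherits(fcfg, "frac_config"))
  if (is.null(init)) {
    if (!is.null(fcfg$seed)) set.seed(fcfg$seed)
    init <- matrix(runif(3 * config$n), 3, config$n)
  }
  if (!is.matrix(init) || nrow(init) != 3 || ncol(init) != config$n)
    stop("`init` must be a 3 x n matrix")
  nsteps <- floor(fcfg$t_end / fcfg$h)
  L <- as.integer(min(fcfg$memory_length, nsteps))
  res <- sim_chain_gl(config$frequencies, config$lambda, fcfg$alpha, fcfg$h,
                      nsteps, L, params$a, params$b, params$c, init,
                      as.integer(keep_every))
  times <- seq(0, by = fcfg$h * keep_every, length.out = ncol(res$x))
  structure(list(times = times, x = res$x, y = res$y,
                 phases = unwrap_rows(atan2(res$y, res$x)),
                 config = config, fcfg = fcfg, params = params, init = init),
            class = "chain_sim")
}

#' Scan the chain coupling strength
#'
#' For each coupling strength on a grid, simulates the chain and computes the
#' time-averaged cross-oscillator standard deviation of unwrapped phases over
#' the second half of the run (the first half is discarded as transient).
#' Runs that diverge are recorded as `NA` rather than aborting.
#'
#' @param lambdas Numeric grid of coupling strengths (non-empty).
#' @param n Number of oscillators. Default 10.
#' @param frequencies Natural frequencies; default evenly spaced on
#'   `[0.98, 1.02]` (the union of the model's two object-frequency bands).
#' @param fcfg A [frac_config()]; default `t_end = 200`. All grid points share
#'   the initial states drawn under `fcfg$seed`.
#' @param params A [rossler_params()].
#' @param keep_every Subsampling of the analysed trajectory. Default 10.
#' @return An object of class `coupling_scan`: a data frame with columns
#'   `lambda` and `phase_std`, with the scan settings attached.
#' @examples
#' \donttest{
#' sc <- scan_coupling(seq(-0.15, 0, by = 0.01),
#'                     fcfg = frac_config(t_end = 200, seed = 1))
#' sc$lambda[which.min(sc$phase_std)]
#' }
#' @export
scan_coupling <- function(lambdas, n = 10,
                          frequencies = seq(0.98, 1.02, length.out = n),
                          fcfg = frac_config(t_end = 200),
                          params = rossler_params(), keep_every = 10) {
  if (length(lambdas) < 1) stop("`lambdas` must be non-empty")
  if (!is.null(fcfg$seed)) set.seed(fcfg$seed)
  init <- matrix(runif(3 * n), 3, n)
  std <- vapply(lambdas, function(l) {
    cfg <- chain_config(n, l, frequencies)
    sim <- tryCatch(
      simulate_chain(cfg, fcfg, params, init = init, keep_every = keep_every),
      error = function(e) NULL)
    if (is.null(sim)) return(NA_real_)
    keep <- sim$times > fcfg$t_end / 2
    mean(apply(sim$phases[, keep, drop = FALSE], 2, pop_sd))
  }, numeric(1))
  structure(data.frame(lambda = lambdas, phase_std = std),
            class = c("coupling_scan", "data.frame"),
            n = n, frequencies = frequencies, fcfg = fcfg)
}

#' @export
plot.coupling_scan <- function(x, ...) {
  plot(x$lambda, x$phase_std, type = "b", pch = 16,
       xlab = expression(lambda), ylab = "time-averaged phase std", ...)
  i <- which.min(x$phase_std)
  graphics::points(x$lambda[i], x$phase_std[i], col = 2, pch = 16, cex = 1.4)
  invisible(x)
}

# population (divide-by-n) standard deviation
pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
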