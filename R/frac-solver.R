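#' Solver configuration for fractional-order systems
#'
#' Bundles the numerical settings used by every fractional integration in the
#' package: the Caputo derivative order `alpha`, the step size `h`, the run
#' length `t_end`, the short-memory window `memory_length` (in steps;
#' `Inf` keeps the whole history) and an optional `seed` used by callers that
#' draw random initial conditions.
#'
#' @param alpha Fractional derivative order, in (0, 1]. Default 0.9, the order
#'   used for every oscillator in the model.
#' @param h Time step (> 0). Default 0.01.
#' @param t_end Integration end time (> 0).
#' @param memory_length Short-memory truncation of the Grunwald-Letnikov
#'   history convolution, in steps (>= 1, or `Inf` for untruncated).
#'   Default 2000 steps (20 time units at the default `h`).
#' @param seed Optional integer seed for randomized initial conditions.
#' @return An object of class `frac_config`.
#' @seealso [frac_integrate()]
#' @export
frac_config <- function(alpha = 0.9, h = 0.01, t_end = 100,
                        memory_length = 2000, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("`alpha` must be a single number in (0, 1]")
  if (!is.numeric(h) || length(h) != 1 || h <= 0)
    stop("`h` must be a single positive number")
  if (!is.numeric(t_end) || length(t_end) != 1 || t_end <= 0)
    stop("`t_end` must be a single positive number")
  if (!is.numeric(memory_length) || length(memory_length) != 1 ||
      (is.finite(memory_length) && memory_length < 1))
    stop("`memory_length` must be >= 1 (or Inf)")
  structure(
    list(alpha = alpha, h = h, t_end = t_end,
         memory_length = memory_length,
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "frac_config")
}

#' Grunwald-Letnikov binomial weights
#'
#' Coefficients `c_k = (-1)^k choose(alpha, k)` of the Grunwald-Letnikov
#' discretization of the fractional derivative, computed by the stable
#' recurrence `c_0 = 1`, `c_k = (1 - (1 + alpha)/k) c_{k-1}`. For
#' `0 < alpha <= 1` all weights after the first are non-positive.
#'
#' @param alpha Fractional order in (0, 1].
#' @param n_terms Number of coefficients to return (>= 1).
#' @return Numeric vector `c_0, ..., c_{n_terms - 1}`.
#' @examples
#' gl_coefficients(0.9, 3)  # 1, -0.9, -0.045
#' @export
gl_coefficients <- function(alpha, n_terms) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("`alpha` must be a single number in (0, 1]")
  if (!is.numeric(n_terms) || length(n_terms) != 1 || n_terms < 1)
    stop("`n_terms` must be >= 1")
  n_terms <- as.integer(n_terms)
  cf <- numeric(n_terms)
  cf[1] <- 1
  if (n_terms > 1)
    for (k in seq_len(n_terms - 1)) cf[k + 1] <- (1 - (1 + alpha) / k) * cf[k]
  cf
}

#' Create a trajectory buffer for stepwise fractional integration
#'
#' Holds the state of an ongoing Grunwald-Letnikov integration: the current
#' state, the step counter and the ring buffer of state deviations from the
#' initial condition that the fractional memory convolution consumes
#' (retained up to `memory_length` steps).
#'
#' @param y0 Numeric initial state vector.
#' @param config A [frac_config()].
#' @return An object of class `frac_buffer`.
#' @seealso [frac_step()]
#' @export
frac_buffer <- function(y0, config) {
  stopifnot(inherits(config, "frac_config"))
  y0 <- as.numeric(y0)
  if (length(y0) < 1 || any(!is.finite(y0))) stop("`y0` must be finite")
  nmax <- floor(config$t_end / config$h)
  L <- as.integer(min(config$memory_length, nmax))
  cw <- gl_coefficients(config$alpha, L + 1L)
  structure(
    list(y0 = y0, state = y0, t = 0, n = 0L, L = L,
         S = matrix(0, length(y0), L),
         cw = cw, qsum = cumsum(cw)),
    class = "frac_buffer")
}

#' Advance a fractional integration by one Grunwald-Letnikov step
#'
#' Applies one explicit GL update with Caputo-style constant pre-history,
#' `s_n = h^alpha F(s_{n-1}) - sum_{k=1}^{m} c_k s_{n-k} + q_m s_0` with
#' `m = min(n-1, L)` and `q_m` the cumulative weight sum `c_0 + ... + c_m`
#' (the constant-pre-history correction). For `alpha = 1` the update is
#' exactly a forward Euler step, `s_n = s_{n-1} + h F(s_{n-1})`.
#'
#' @param rhs Function `rhs(t, y)` returning the derivative vector.
#' @param buffer A [frac_buffer()].
#' @param config The [frac_config()] used to create the buffer.
#' @return The updated buffer (state advanced by one step of size `h`).
#' @export
frac_step <- function(rhs, buffer, config) {
  stopifnot(inherits(buffer, "frac_buffer"), inherits(config, "frac_config"))
  f <- as.numeric(rhs(buffer$t, buffer$state))
  if (length(f) != length(buffer$state))
    stop("rhs returned a vector of the wrong length")
  n <- buffer$n + 1L
  L <- buffer$L
  m <- min(n - 1L, L)
  buffer$S[, ((n - 2L) %% L) + 1L] <- buffer$state  # store s_{n-1}
  mem <- if (m > 0) {
    cols <- ((n - 1L - seq_len(m)) %% L) + 1L
    as.vector(buffer$S[, cols, drop = FALSE] %*% buffer$cw[2:(m + 1L)])
  } else 0
  buffer$state <- config$h^config$alpha * f - mem +
    buffer$qsum[m + 1L] * buffer$y0
  buffer$t <- buffer$t + config$h
  buffer$n <- n
  if (any(!is.finite(buffer$state)) || max(abs(buffer$state)) > 1e6)
    stop(sprintf("numerical divergence at step %d (t = %g)", n, buffer$t))
  buffer
}

#' Integrate a fractional-order system
#'
#' Solves `D^alpha y = F(t, y)` with constant pre-history (Caputo-style
#' initial condition) on `[0, t_end]`. Two schemes are available: the default
#' explicit Grunwald-Letnikov method with short-memory truncation (`"gl"`,
#' fast, used by all network simulations) and the Adams-Bashforth-Moulton
#' predictor-corrector (`"abm"`, higher accuracy, no memory truncation,
#' intended for scalar/low-dimensional validation runs).
#'
#' @param rhs Function `rhs(t, y)` returning the derivative vector.
#' @param y0 Numeric initial state.
#' @param config A [frac_config()].
#' @param method `"gl"` or `"abm"`.
#' @return An object of class `frac_trajectory`: list with `times` (length
#'   `floor(t_end/h) + 1`), `states` (one row per time point) and the call
#'   settings. Deterministic given identical inputs.
#' @examples
#' cfg <- frac_config(alpha = 0.9, h = 0.01, t_end = 1)
#' tr <- frac_integrate(function(t, y) -y, 1, cfg)
#' tail(tr$states[, 1], 1)  # ~ E_0.9(-t^0.9) at t = 1
#' @export
frac_integrate <- function(rhs, y0, config, method = c("gl", "abm")) {
  stopifnot(inherits(config, "frac_config"))
  method <- match.arg(method)
  y0 <- as.numeric(y0)
  nsteps <- floor(config$t_end / config$h)
  d <- length(y0)
  states <- matrix(NA_real_, nsteps + 1L, d)
  states[1, ] <- y0
  times <- seq(0, by = config$h, length.out = nsteps + 1L)
  if (method == "gl") {
    buf <- frac_buffer(y0, config)
    for (n in seq_len(nsteps)) {
      buf <- tryCatch(frac_step(rhs, buf, config), error = function(e)
        stop(sprintf("%s (t = %g)", conditionMessage(e), times[n + 1L]),
             call. = FALSE))
      states[n + 1L, ] <- buf$state
    }
  } else {
    states <- abm_integrate(rhs, y0, config$alpha, config$h, nsteps)
  }
  structure(list(times = times, states = states, config = config,
                 method = method),
            class = "frac_trajectory")
}

# Adams-Bashforth-Moulton predictor-corrector for Caputo systems
# (fractional Adams method). O(n^2) in the number of steps; no truncation.
abm_integrate <- function(rhs, y0, alpha, h, nsteps) {
  d <- length(y0)
  states <- matrix(NA_real_, nsteps + 1L, d)
  states[1, ] <- y0
  fhist <- matrix(NA_real_, nsteps + 1L, d)
  fhist[1, ] <- as.numeric(rhs(0, y0))
  ga1 <- gamma(alpha + 1)
  ga2 <- gamma(alpha + 2)
  ii <- 0:(nsteps + 1L)
  pow_a <- ii^alpha          # i^alpha
  pow_a1 <- ii^(alpha + 1)   # i^(alpha+1)
  for (n in 0:(nsteps - 1L)) {
    j <- 0:n
    i <- n - j                        # lag index
    b <- pow_a[i + 2L] - pow_a[i + 1L]   # (i+1)^a - i^a
    fcur <- fhist[1:(n + 1L), , drop = FALSE]
    yp <- y0 + h^alpha / ga1 * as.vector(crossprod(fcur, b))
    a <- pow_a1[i + 1L] + pow_a1[i + 3L] - 2 * pow_a1[i + 2L]  # j = 1..n form
    a[1] <- n^(alpha + 1) - (n - alpha) * (n + 1)^alpha        # j = 0 term
    fp <- as.numeric(rhs((n + 1L) * h, yp))
    ynew <- y0 + h^alpha / ga2 * (as.vector(crossprod(fcur, a)) + fp)
    if (any(!is.finite(ynew)) || max(abs(ynew)) > 1e6)
      stop(sprintf("numerical divergence at step %d (t = %g)",
                   n + 1L, (n + 1L) * h))
    states[n + 2L, ] <- ynew
    fhist[n + 2L, ] <- as.numeric(rhs((n + 1L) * h, ynew))
  }
  states
}

#' @export
as.data.frame.frac_trajectory <- function(x, ...) {
  df <- data.frame(time = x$times, x$states)
  names(df) <- c("time", colnames(x$states) %||%
                   paste0("y", seq_len(ncol(x$states))))
  df
}

#' Write a trajectory to CSV
#'
#' @param traj A `frac_trajectory`.
#' @param path Output file; header is `time,<var names>`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.frac_trajectory <- function(x, ...) {
  cat(sprintf(
    "<frac_trajectory> %d states x %d time points, alpha = %g, h = %g, %s\n",
    ncol(x$states), length(x$times), x$config$alpha, x$config$h, x$method))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
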