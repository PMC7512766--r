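#' Hybrid (group-mean) state of a set of oscillators
#'
#' The hybrid system summarizing an object group is the componentwise
#' arithmetic mean of its member oscillators' states; its phase growth
#' matches the members', so one drive signal can represent the group.
#'
#' @param state `M x N x 3` state array, or `3 x npix` matrix.
#' @param members Linear pixel indices (column-major) or logical mask
#'   selecting the group; must be non-empty.
#' @return Numeric length-3 vector `(w_x, w_y, w_z)`.
#' @export
hybrid_state <- function(state, members) {
  sm <- if (length(dim(state)) == 3) {
    rbind(as.vector(state[, , 1]), as.vector(state[, , 2]),
          as.vector(state[, , 3]))
  } else state
  if (is.logical(members)) members <- which(members)
  if (length(members) == 0) stop("`members` must be non-empty")
  rowMeans(sm[, members, drop = FALSE])
}

#' Hybrid drift of a group
#'
#' Componentwise mean of the member oscillators' first-layer right-hand
#' sides. Because the hybrid state is a linear average, this mean of
#' derivatives is exactly the derivative of the hybrid state, and is what
#' the active controller injects as the drive dynamics.
#'
#' @param state `M x N x 3` state array.
#' @param members Linear pixel indices or logical mask (non-empty).
#' @param encoding A [encode_image()] result.
#' @param params A [rossler_params()].
#' @return Numeric length-3 drift vector.
#' @export
hybrid_drift <- function(state, members, encoding,
                         params = rossler_params()) {
  rhs <- layer1_rhs(state, encoding, params)
  hybrid_state(rhs, members)
}

#' Active-control law for the central unit
#'
#' Exact-cancellation active control: the control input
#' `u = drift - F_r(response) - K e` removes the response system's own
#' dynamics `F_r` (free Rossler at the central frequency), injects the
#' hybrid drive's dynamics and adds linear error feedback, so the
#' closed-loop error obeys the stable linear fractional dynamics
#' `D^alpha e = -K e` (K > 0 satisfies the fractional stability condition
#' `|arg(-K)| = pi > alpha pi / 2` for every alpha in (0, 1]).
#'
#' @param response Central-unit state `(x_r, y_r, z_r)`.
#' @param hybrid Hybrid state `(w_x, w_y, w_z)` of the attended group.
#' @param drift Hybrid drift from [hybrid_drift()].
#' @param gains Positive feedback gain K (scalar or per-component length 3).
#' @param o_r Central-unit natural frequency.
#' @param params A [rossler_params()].
#' @return Control vector `u = (u_x, u_y, u_z)`.
#' @export
active_control <- function(response, hybrid, drift, gains = 1, o_r = 1,
                           params = rossler_params()) {
  if (any(gains <= 0) || !length(gains) %in% c(1, 3))
    stop("`gains` must be positive (scalar or length 3)")
  pr <- params; pr$o <- o_r
  e <- response - hybrid
  drift - rossler_rhs(response, pr) - gains * e
}

#' Rank object groups by salience
#'
#' Salience is read out dynamically: more salient objects carry higher
#' contrast, hence higher natural frequency, hence faster phase growth.
#' Groups are ordered by descending mean phase velocity (mean increment of
#' unwrapped phase per time unit over the warm-up window, averaged over
#' members); ties break lexicographically by group id.
#'
#' @param psi Matrix of unwrapped phases (oscillators x time points).
#' @param times Sampling times.
#' @param labels Integer label per oscillator.
#' @param window Length-2 time window `c(from, to)` within the sampled range.
#' @return Integer vector of group ids, most salient first.
#' @export
rank_groups_by_salience <- function(psi, times, labels,
                                    window = range(times)) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(psi), length(window) == 2)
  i1 <- which.min(abs(times - window[1]))
  i2 <- which.min(abs(times - window[2]))
  if (i2 <= i1) stop("`window` must span at least one sampling interval")
  vel <- (psi[, i2] - psi[, i1]) / (times[i2] - times[i1])
  ids <- sort(unique(labels))
  gv <- vapply(ids, function(g) mean(vel[labels == g]), numeric(1))
  ids[order(-gv, ids)]
}

#' Build a time-division attention schedule
#'
#' One epoch per group, in the given order: epoch k (k = 0, 1, ...) locks
#' onto group k with onset `t1 + k (span + gap)` and offset `onset + span`.
#' The controller is off during the inter-epoch gap.
#'
#' @param groups Ordered group ids (distinct), most salient first.
#' @param t1 First onset time (>= 0). Default 20.
#' @param span Attention span F_t: duration of each lock epoch (> 0).
#'   Default 10.
#' @param gap Inter-epoch gap (>= 0). Default 0.01.
#' @return An object of class `attention_schedule`: data frame with columns
#'   `group`, `onset`, `offset`.
#' @examples
#' build_schedule(1:3)$onset  # 20, 30.01, 40.02
#' @export
build_schedule <- function(groups, t1 = 20, span = 10, gap = 0.01) {
  stopifnot(t1 >= 0, span > 0, gap >= 0)
  if (anyDuplicated(groups)) stop("`groups` must be distinct")
  k <- seq_along(groups) - 1
  onset <- t1 + k * (span + gap)
  structure(data.frame(group = groups, onset = onset, offset = onset + span),
            class = c("attention_schedule", "data.frame"),
            t1 = t1, span = span, gap = gap)
}

#' Run the central unit over an attention schedule
#'
#' Simulates the second layer: a single Rossler oscillator at the central
#' frequency `o_r`, driven one-way by the recorded hybrid signals of a
#' [simulate_layer1()] run (the first layer is never perturbed). During each
#' epoch the active-control law targets that epoch's hybrid system; between
#' epochs and after the last epoch the control is off and the unit runs
#' free.
#'
#' @param sim A [simulate_layer1()] result with recorded hybrid signals
#'   (`groups` supplied).
#' @param schedule An [build_schedule()] schedule over group ids present in
#'   `sim$group_ids`; must fit within the simulated time range.
#' @param gains Positive feedback gain K. Default 1.
#' @param central_init Optional initial state; default drawn uniform on
#'   `[0, 1]^3` under `sim$fcfg$seed + 1`.
#' @param lock_bound Phase bound (radians) of the lock criterion: an epoch
#'   counts as locked when `|psi_central - psi_hybrid|` stays below it over
#'   the final half of the epoch. Default `pi` (phase synchronization =
#'   bounded phase difference).
#' @return An object of class `attention_run`: `times`, central `x`, `y`,
#'   unwrapped phase `psi`, per-group hybrid phases `psi_hybrid`, the
#'   schedule with lock report (`locked`, `mean_abs_err`), the error trace
#'   `e` (3 x steps, `NA` outside epochs), `transitions`, `o_r`, `gains`.
#' @export
run_attention <- function(sim, schedule, gains = 1, central_init = NULL,
                          lock_bound = pi) {
  stopifnot(inherits(sim, "layer1_sim"), inherits(schedule, "attention_schedule"))
  if (is.null(sim$w)) stop("`sim` must be run with `groups` to record hybrids")
  if (any(gains <= 0)) stop("`gains` must be positive")
  fcfg <- sim$fcfg
  h <- fcfg$h
  nsteps <- ncol(sim$omega)
  t_end <- nsteps * h
  if (nrow(schedule) > 0) {
    if (!all(schedule$group %in% sim$group_ids))
      stop("schedule refers to groups without recorded hybrid signals")
    if (max(schedule$offset) > t_end + 1e-9)
      stop("schedule overruns the simulated time range")
  }
  if (is.null(central_init)) {
    set.seed((fcfg$seed %||% 0L) + 1L)
    central_init <- runif(3)
  }
  params <- sim$params
  pr <- params; pr$o <- sim$o_r

  # per-step target group (0 = controller off), evaluated at the step start
  tgrid <- (seq_len(nsteps) - 1L) * h
  target <- integer(nsteps)
  for (i in seq_len(nrow(schedule))) {
    g <- match(schedule$group[i], sim$group_ids)
    target[tgrid >= schedule$onset[i] - 1e-12 &
             tgrid < schedule$offset[i] - 1e-12] <- g
  }

  L <- as.integer(min(fcfg$memory_length, nsteps))
  cw <- gl_coefficients(fcfg$alpha, L + 1L)
  qs <- cumsum(cw)
  ha <- h^fcfg$alpha
  s <- as.numeric(central_init)
  S <- matrix(0, 3, L)         # ring of past states; s_i in column (i %% L) + 1
  S[, 1] <- s
  keep_every <- sim$keep_every
  nk <- nsteps %/% keep_every + 1L
  xs <- numeric(nk); ys <- numeric(nk)
  xs[1] <- s[1]; ys[1] <- s[2]
  evals <- matrix(NA_real_, 3, nsteps)
  ki <- 1L
  for (n in seq_len(nsteps)) {
    g <- target[n]
    f <- if (g > 0L) {
      rows <- (3L * (g - 1L) + 1L):(3L * g)
      e <- s - sim$w[rows, n]
      evals[, n] <- e
      sim$omega[rows, n] - gains * e   # F_r(s) + u with exact cancellation
    } else {
      rossler_rhs(s, pr)
    }
    m <- min(n - 1L, L)
    mem <- if (m > 0) {
      cols <- ((n - seq_len(m)) %% L) + 1L
      as.vector(S[, cols, drop = FALSE] %*% cw[2:(m + 1L)])
    } else 0
    s <- ha * f - mem + qs[m + 1L] * central_init
    S[, (n %% L) + 1L] <- s
    if (any(!is.finite(s)) || max(abs(s)) > 1e6)
      stop(sprintf("numerical divergence in central unit at step %d", n))
    if (n %% keep_every == 0) { ki <- ki + 1L; xs[ki] <- s[1]; ys[ki] <- s[2] }
  }
  psi <- unwrap_phase(atan2(ys, xs))
  kept <- seq(1L, nsteps + 1L, by = keep_every)
  G <- length(sim$group_ids)
  psi_h <- matrix(NA_real_, G, length(kept))
  for (g in seq_len(G)) {
    rows <- (3L * (g - 1L) + 1L):(3L * g)
    psi_h[g, ] <- unwrap_phase(atan2(sim$w[rows[2], kept], sim$w[rows[1], kept]))
  }
  times <- sim$times

  sched <- as.data.frame(schedule)
  sched$locked <- logical(nrow(sched))
  sched$mean_abs_err <- numeric(nrow(sched))
  for (i in seq_len(nrow(sched))) {
    g <- match(sched$group[i], sim$group_ids)
    half <- times >= (sched$onset[i] + sched$offset[i]) / 2 &
      times <= sched$offset[i] + 1e-9
    sched$locked[i] <- phase_locked(psi[half], psi_h[g, half], lock_bound)
    ehalf <- tgrid >= (sched$onset[i] + sched$offset[i]) / 2 &
      tgrid < sched$offset[i]
    sched$mean_abs_err[i] <-
      mean(sqrt(colSums(evals[, ehalf, drop = FALSE]^2)))
  }
  structure(list(times = times, x = xs, y = ys, psi = psi,
                 psi_hybrid = psi_h, group_ids = sim$group_ids,
                 schedule = sched, e = evals, lock_bound = lock_bound,
                 transitions = sum(sched$locked), o_r = sim$o_r,
                 gains = gains, central_init = central_init),
            class = "attention_run")
}

#' Count attention transitions
#'
#' Number of schedule epochs in which the central unit met the lock
#' criterion (phase difference to the target hybrid bounded over the final
#' half of the epoch). On a successful scan this equals the number of
#' attended groups.
#'
#' @param run An [run_attention()] result.
#' @param bound Optional phase bound (radians) to re-evaluate the lock
#'   criterion at; default uses the bound stored in `run`.
#' @return Integer count.
#' @export
count_transitions <- function(run, bound = NULL) {
  stopifnot(inherits(run, "attention_run"))
  if (is.null(bound)) return(run$transitions)
  sched <- run$schedule
  n <- 0L
  for (i in seq_len(nrow(sched))) {
    g <- match(sched$group[i], run$group_ids)
    half <- run$times >= (sched$onset[i] + sched$offset[i]) / 2 &
      run$times <= sched$offset[i] + 1e-9
    if (phase_locked(run$psi[half], run$psi_hybrid[g, half], bound)) n <- n + 1L
  }
  n
}

# Lock test on a window: the phase difference must stay within `bound` of an
# integer number of full turns (phase synchronization is bounded phase
# difference; whole 2*pi turns wound up during the free run or the lock-in
# transient do not break the lock).
phase_locked <- function(psi_a, psi_b, bound) {
  d <- psi_a - psi_b
  turns <- 2 * pi * round(median(d) / (2 * pi))
  all(abs(d - turns) < bound)
}

#' @export
print.attention_run <- function(x, ...) {
  cat(sprintf("<attention_run> %d epochs, %d locked (bound %.3g rad), o_r = %.4f\n",
              nrow(x$schedule), x$transitions, x$lock_bound, x$o_r))
  if (nrow(x$schedule)) print(x$schedule, row.names = FALSE)
  invisible(x)
}
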