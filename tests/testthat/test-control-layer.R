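test_that("hybrid state is the componentwise mean of its members", {
  st <- array(0, c(2, 2, 3))
  st[, , 1] <- matrix(c(0, 2, 5, 7), 2, 2)
  st[, , 2] <- 1; st[, , 3] <- -2
  expect_equal(hybrid_state(st, c(1, 2)), c(1, 1, -2))
  expect_equal(hybrid_state(st, rep(TRUE, 4)), c(3.5, 1, -2))
  # linearity: hybrid of a union of equal-sized groups = mean of hybrids
  h12 <- hybrid_state(st, c(1, 2)); h34 <- hybrid_state(st, c(3, 4))
  expect_equal(hybrid_state(st, 1:4), (h12 + h34) / 2)
  expect_error(hybrid_state(st, integer(0)), "non-empty")
})

test_that("hybrid drift is the mean member right-hand side", {
  set.seed(12)
  img <- array(runif(2 * 3 * 3), c(2, 3, 3))
  enc <- encode_image(img, delta_o = 0.2, sigma = 0.5)
  st <- array(rnorm(18), c(2, 3, 3))
  d <- layer1_rhs(st, enc)
  expect_equal(hybrid_drift(st, 4, enc), c(d[, , 1][4], d[, , 2][4], d[, , 3][4]))
  # identical members share the common rhs
  stu <- array(rep(c(0.5, -0.1, 0.4), each = 6), c(2, 3, 3))
  du <- layer1_rhs(stu, enc)
  expect_equal(hybrid_drift(stu, c(1, 2), enc),
               colMeans(cbind(as.vector(du[, , 1])[1:2],
                              as.vector(du[, , 2])[1:2],
                              as.vector(du[, , 3])[1:2])))
})

test_that("hybrid drift equals the discrete derivative of the hybrid (alpha = 1)", {
  sc <- two_region_scene(H = 4, W = 6, obj_cols = 5:6)
  enc <- encode_image(sc$image, delta_o = 0.35, sigma = 0.8)
  fc <- frac_config(alpha = 1, h = 0.01, t_end = 0.05, seed = 3)
  sim <- simulate_layer1(enc, fc, groups = sc$labels, keep_every = 1)
  # forward Euler: w_{n+1} - w_n = h * Omega_n, exactly
  for (n in 1:4) {
    expect_equal(sim$w[, n + 1] - sim$w[, n], 0.01 * sim$omega[, n],
                 tolerance = 1e-12)
  }
})

test_that("active control cancels the response dynamics and feeds back the error", {
  s <- c(1.2, -0.3, 0.5)
  pr_o <- 0.97
  drift <- rossler_rhs(s, rossler_params(o = pr_o))
  # e = 0 and matching drift: nothing to correct
  expect_equal(active_control(s, s, drift, gains = 1, o_r = pr_o), c(0, 0, 0))
  # matching drift, pure feedback on e = (1, 0, 0)
  hyb <- s - c(1, 0, 0)
  u <- active_control(s, hyb, drift, gains = 1, o_r = pr_o)
  expect_equal(u, c(-1, 0, 0))
  expect_error(active_control(s, hyb, drift, gains = -1), "gains")
})

test_that("closed-loop error decays as the Mittag-Leffler function", {
  K <- 1; alpha <- 0.9
  p1 <- rossler_params(o = 1.02)
  o_r <- 0.95
  rhs <- function(t, y) {
    sd <- y[1:3]; sr <- y[4:6]
    fd <- rossler_rhs(sd, p1)
    u <- active_control(sr, sd, fd, gains = K, o_r = o_r)
    c(fd, rossler_rhs(sr, rossler_params(o = o_r)) + u)
  }
  set.seed(9)
  y0 <- c(runif(3), runif(3) + c(2, -1, 1))
  tr <- frac_integrate(rhs, y0, frac_config(alpha, 0.01, 10))
  e0 <- y0[4:6] - y0[1:3]
  for (tt in c(1, 2, 5, 10)) {
    i <- which.min(abs(tr$times - tt))
    e <- tr$states[i, 4:6] - tr$states[i, 1:3]
    expect_equal(unname(e), e0 * ml_series(alpha, -K * tr$times[i]^alpha),
                 tolerance = 0.02)
    expect_lt(max(abs(e - e0 * ml_series(alpha, -K * tr$times[i]^alpha))),
              0.01)
  }
  # error is far below its initial size after ten time units
  iN <- length(tr$times)
  expect_lt(sqrt(sum((tr$states[iN, 4:6] - tr$states[iN, 1:3])^2)),
            0.05 * sqrt(sum(e0^2)))
})

test_that("salience ranking orders groups by phase velocity, ties by id", {
  t <- seq(0, 10, 0.1)
  psi <- rbind(1.02 * t, 1.02 * t, 0.98 * t, 0.98 * t)
  expect_equal(rank_groups_by_salience(psi, t, c(1, 1, 2, 2)), c(1, 2))
  expect_equal(rank_groups_by_salience(psi, t, c(2, 2, 1, 1)), c(2, 1))
  expect_equal(rank_groups_by_salience(psi[1:2, ], t, c(7, 7)), 7)
  psi_tie <- rbind(t, t)
  expect_equal(rank_groups_by_salience(psi_tie, t, c(5, 3)), c(3, 5))
})

test_that("schedule onsets chain with the inter-epoch gap", {
  sch <- build_schedule(1:3, t1 = 20, span = 10, gap = 0.01)
  expect_equal(sch$onset, c(20, 30.01, 40.02))
  expect_equal(sch$offset, c(30, 40.01, 50.02))
  one <- build_schedule(4, t1 = 20, span = 10)
  expect_equal(c(one$onset, one$offset), c(20, 30))
  expect_error(build_schedule(c(1, 1)), "distinct")
  empty <- build_schedule(integer(0))
  expect_equal(nrow(empty), 0)
})

test_that("the controlled central unit locks to each scheduled hybrid in turn", {
  sc <- two_region_scene()
  enc <- encode_image(sc$image, delta_o = 0.35, sigma = 0.8)
  fc <- frac_config(0.9, 0.01, 16, 2000, seed = 2)
  sim <- simulate_layer1(enc, fc, groups = sc$labels)
  sch <- build_schedule(c(1L, 0L), t1 = 3, span = 5, gap = 0.01)
  att <- run_attention(sim, sch)
  expect_true(all(att$schedule$locked))
  expect_equal(att$transitions, 2L)
  expect_equal(count_transitions(att), 2L)
  # during each epoch's final half the phase velocities agree
  for (i in 1:2) {
    g <- match(att$schedule$group[i], att$group_ids)
    half <- att$times >= (att$schedule$onset[i] + att$schedule$offset[i]) / 2 &
      att$times <= att$schedule$offset[i]
    vc <- diff(range(att$psi[half])) / diff(range(att$times[half]))
    vh <- diff(range(att$psi_hybrid[g, half])) / diff(range(att$times[half]))
    expect_equal(vc, vh, tolerance = 0.05)
  }
  # state error shrinks over each epoch
  expect_true(all(att$schedule$mean_abs_err < 0.2))
  # the hybrid phase velocity matches its members' mean velocity
  labv <- as.vector(sc$labels)
  i1 <- which.min(abs(sim$times - 8)); i0 <- which.min(abs(sim$times - 3))
  for (g in 1:2) {
    vh <- (sim$phases[labv == (g - 1), i1] - sim$phases[labv == (g - 1), i0]) /
      (sim$times[i1] - sim$times[i0])
    rows <- (3 * (g - 1) + 1):(3 * g)
    kept <- seq(1, ncol(sim$w), by = 10)
    ph <- unwrap_phase(atan2(sim$w[rows[2], kept], sim$w[rows[1], kept]))
    vw <- (ph[i1] - ph[i0]) / (sim$times[i1] - sim$times[i0])
    expect_equal(mean(vh), vw, tolerance = 0.15)
  }
})

test_that("an empty schedule leaves the central unit as a free oscillator", {
  sc <- two_region_scene(H = 4, W = 6, obj_cols = 5:6)
  enc <- encode_image(sc$image, delta_o = 0.35, sigma = 0.8)
  fc <- frac_config(0.9, 0.01, 4, seed = 2)
  sim <- simulate_layer1(enc, fc, groups = sc$labels)
  att <- run_attention(sim, build_schedule(integer(0)),
                       central_init = c(0.3, 0.4, 0.5))
  tr <- frac_integrate(function(t, y) rossler_rhs(y, rossler_params(o = sim$o_r)),
                       c(0.3, 0.4, 0.5), fc)
  expect_equal(att$x, tr$states[seq(1, 401, 10), 1], tolerance = 1e-12)
  expect_equal(count_transitions(att), 0L)
})

test_that("schedules overrunning the simulated range are rejected", {
  sc <- two_region_scene(H = 4, W = 6, obj_cols = 5:6)
  enc <- encode_image(sc$image, delta_o = 0.35, sigma = 0.8)
  fc <- frac_config(0.9, 0.01, 4, seed = 2)
  sim <- simulate_layer1(enc, fc, groups = sc$labels)
  expect_error(run_attention(sim, build_schedule(0:1, t1 = 1, span = 10)),
               "overruns")
  expect_error(run_attention(sim, build_schedule(7, t1 = 0, span = 2)),
               "groups")
  sim_plain <- simulate_layer1(enc, fc)
  expect_error(run_attention(sim_plain, build_schedule(integer(0))),
               "record")
})
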