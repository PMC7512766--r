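# Independent oracles used across the suite. These deliberately avoid the
# package's own vectorized/compiled code paths.

# Mittag-Leffler E_alpha(z) by direct series summation
ml_series <- function(alpha, z, kmax = 250) {
  k <- 0:kmax
  sum(z^k / gamma(alpha * k + 1))
}

# GL binomial weights via the gamma-function form (-1)^k * choose(alpha, k)
gl_binomial <- function(alpha, k) {
  (-1)^k * gamma(alpha + 1) / (gamma(k + 1) * gamma(alpha - k + 1))
}

# naive per-oscillator evaluation of the coupled chain right-hand side
naive_chain_rhs <- function(states, lambda, o, a = 0.48, b = 0.6, cc = 6) {
  n <- nrow(states)
  out <- matrix(NA_real_, n, 3)
  for (j in seq_len(n)) {
    x <- states[j, 1]; y <- states[j, 2]; z <- states[j, 3]
    cpl <- 0; deg <- 0
    if (j > 1) { cpl <- cpl + states[j - 1, 1]; deg <- deg + 1 }
    if (j < n) { cpl <- cpl + states[j + 1, 1]; deg <- deg + 1 }
    out[j, ] <- c(-o[j] * y - z + lambda * (deg * x - cpl),
                  o[j] * x + a * y,
                  b + z * (x - cc))
  }
  out
}

# naive per-pixel evaluation of the first-layer grid right-hand side
naive_layer1_rhs <- function(state, enc, a = 0.48, b = 0.6, cc = 6) {
  M <- enc$dims[1]; N <- enc$dims[2]
  out <- array(NA_real_, c(M, N, 3))
  f <- enc$features[c("gray", "r", "g", "b")]
  w <- enc$features$weights / sum(enc$features$weights)
  theta <- enc$topology$theta
  for (j in 1:M) for (k in 1:N) {
    x <- state[j, k, 1]; y <- state[j, k, 2]; z <- state[j, k, 3]
    sp <- 0; sn <- 0
    for (dj in -1:1) for (dk in -1:1) {
      if (dj == 0 && dk == 0) next
      jj <- j + dj; kk <- k + dk
      if (jj < 1 || jj > M || kk < 1 || kk > N) next
      d <- 0
      for (l in 1:4) d <- d + w[l] * abs(f[[l]][j, k] - f[[l]][jj, kk])
      if (d <= theta) sp <- sp + state[jj, kk, 1] - x
      else sn <- sn + state[jj, kk, 1] - x
    }
    o <- enc$freq[j, k]
    out[j, k, ] <- c(-o * y - z + enc$lambda_pos[j, k] * sp -
                       enc$lambda_neg[j, k] * sn,
                     o * x + a * y,
                     b + z * (x - cc))
  }
  out
}

# Rand index of two labelings
rand_index <- function(a, b) {
  e1071::classAgreement(table(as.vector(a), as.vector(b)))$rand
}

# small two-region test scene: dark background, bright right strip
two_region_scene <- function(H = 10, W = 12, obj_cols = 9:12) {
  img <- array(0.08, c(H, W, 3))
  img[, obj_cols, 1] <- 0.9
  img[, obj_cols, 2] <- 0.9
  img[, obj_cols, 3] <- 0.2
  lab <- matrix(0L, H, W)
  lab[, obj_cols] <- 1L
  list(image = img, labels = lab)
}
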