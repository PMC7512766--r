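// Grunwald-Letnikov integration of fractional-order Rossler systems.
//
// Explicit GL scheme with Caputo-style constant pre-history:
//
//   s_n = h^alpha F(s_{n-1}) - sum_{k=1}^{m} c_k s_{n-k} + q_m s_0,
//   m = min(n-1, L),  q_m = c_0 + ... + c_m,
//
// with binomial weights c_0 = 1, c_k = (1 - (1+alpha)/k) c_{k-1} and the
// short-memory truncation at L steps. At alpha = 1 (c_1 = -1, c_k = 0 for
// k >= 2, q_m = 0) the update is exactly forward Euler.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static std::vector<double> gl_weights(double alpha, int n) {
  std::vector<double> c(n);
  c[0] = 1.0;
  for (int k = 1; k < n; ++k) c[k] = (1.0 - (1.0 + alpha) / k) * c[k - 1];
  return c;
}

static inline void check_finite(double v, int step, const char *what) {
  if (!std::isfinite(v) || std::fabs(v) > 1e6) {
    stop("numerical divergence in %s at step %d", what, step);
  }
}

// Chain of N oscillators coupled in the x-equation:
//   D^a x_j = -o_j y_j - z_j + lambda * (k_j x_j - sum of present neighbours)
// Free boundaries: the self term is scaled by the number of present
// neighbours (k_j = 1 at the ends, 2 inside).
// [[Rcpp::export]]
List sim_chain_gl(NumericVector o, double lambda, double alpha, double h,
                  int nsteps, int L, double a, double b, double cc,
                  NumericMatrix init, int keep_every) {
  const int N = o.size();
  if (init.nrow() != 3 || init.ncol() != N) stop("init must be 3 x N");
  if (L < 1) stop("memory length must be >= 1");
  std::vector<double> cw = gl_weights(alpha, L + 1);
  std::vector<double> qs(L + 1);
  qs[0] = cw[0];
  for (int k = 1; k <= L; ++k) qs[k] = qs[k - 1] + cw[k];
  const double ha = std::pow(h, alpha);

  std::vector<double> x(N), y(N), z(N), x0(N), y0(N), z0(N);
  for (int j = 0; j < N; ++j) {
    x[j] = x0[j] = init(0, j);
    y[j] = y0[j] = init(1, j);
    z[j] = z0[j] = init(2, j);
  }
  // ring buffers of past states; state s_i lives in column (i % L)
  std::vector<double> Sx((size_t)L * N, 0.0), Sy((size_t)L * N, 0.0),
      Sz((size_t)L * N, 0.0);
  for (int j = 0; j < N; ++j) { Sx[j] = x[j]; Sy[j] = y[j]; Sz[j] = z[j]; }
  std::vector<double> fx(N), fy(N), fz(N), ax(N), ay(N), az(N);

  const int nkept = nsteps / keep_every + 1;
  NumericMatrix Xk(N, nkept), Yk(N, nkept);
  for (int j = 0; j < N; ++j) { Xk(j, 0) = x[j]; Yk(j, 0) = y[j]; }
  int ki = 0;

  for (int n = 1; n <= nsteps; ++n) {
    for (int j = 0; j < N; ++j) {
      double cpl = 0.0;
      int deg = 0;
      if (j > 0) { cpl += x[j - 1]; ++deg; }
      if (j < N - 1) { cpl += x[j + 1]; ++deg; }
      fx[j] = -o[j] * y[j] - z[j] + lambda * (deg * x[j] - cpl);
      fy[j] = o[j] * x[j] + a * y[j];
      fz[j] = b + z[j] * (x[j] - cc);
    }
    const int m = std::min(n - 1, L);
    std::fill(ax.begin(), ax.end(), 0.0);
    std::fill(ay.begin(), ay.end(), 0.0);
    std::fill(az.begin(), az.end(), 0.0);
    for (int k = 1; k <= m; ++k) {
      const double w = cw[k];
      const size_t col = (size_t)((n - k) % L) * N;
      for (int j = 0; j < N; ++j) {
        ax[j] += w * Sx[col + j];
        ay[j] += w * Sy[col + j];
        az[j] += w * Sz[col + j];
      }
    }
    const double q = qs[m];
    for (int j = 0; j < N; ++j) {
      x[j] = ha * fx[j] - ax[j] + q * x0[j];
      y[j] = ha * fy[j] - ay[j] + q * y0[j];
      z[j] = ha * fz[j] - az[j] + q * z0[j];
      check_finite(x[j], n, "chain x");
      check_finite(z[j], n, "chain z");
    }
    const size_t cn = (size_t)(n % L) * N;
    for (int j = 0; j < N; ++j) {
      Sx[cn + j] = x[j]; Sy[cn + j] = y[j]; Sz[cn + j] = z[j];
    }
    if (n % keep_every == 0) {
      ++ki;
      for (int j = 0; j < N; ++j) { Xk(j, ki) = x[j]; Yk(j, ki) = y[j]; }
    }
    if (n % 2000 == 0) checkUserInterrupt();
  }
  return List::create(_["x"] = Xk, _["y"] = Yk);
}

// First-layer grid (image network). Per-pixel natural frequencies o, positive
// coupling strength lamp acting on similar (positive-link) 8-neighbours and
// negative (repulsive) strength lamn acting on dissimilar neighbours:
//   D^a x_i = -o_i y_i - z_i + lamp_i * sum_pos(x_q - x_i)
//                            - lamn_i * sum_neg(x_q - x_i)
// nbr: npix x 8 matrix of 0-based neighbour linear indices (-1 = absent);
// sgn: npix x 8 link codes (0 none, 1 positive, 2 negative).
// If ngroups > 0, `groups` assigns each pixel a 0-based group id and the
// group-mean (hybrid) state w and group-mean right-hand side (hybrid drift)
// are recorded at every step for the control layer.
// [[Rcpp::export]]
List sim_grid_gl(NumericVector o, NumericVector lamp, NumericVector lamn,
                 IntegerMatrix nbr, IntegerMatrix sgn, double alpha, double h,
                 int nsteps, int L, double a, double b, double cc,
                 NumericMatrix init, int keep_every, IntegerVector groups,
                 int ngroups) {
  const int P = o.size();
  if (init.nrow() != 3 || init.ncol() != P) stop("init must be 3 x npix");
  if (nbr.nrow() != P || sgn.nrow() != P) stop("topology/pixel size mismatch");
  if (L < 1) stop("memory length must be >= 1");
  const bool hyb = ngroups > 0;
  if (hyb && groups.size() != P) stop("groups/pixel size mismatch");

  std::vector<double> cw = gl_weights(alpha, L + 1);
  std::vector<double> qs(L + 1);
  qs[0] = cw[0];
  for (int k = 1; k <= L; ++k) qs[k] = qs[k - 1] + cw[k];
  const double ha = std::pow(h, alpha);

  std::vector<double> x(P), y(P), z(P), x0(P), y0(P), z0(P);
  for (int i = 0; i < P; ++i) {
    x[i] = x0[i] = init(0, i);
    y[i] = y0[i] = init(1, i);
    z[i] = z0[i] = init(2, i);
  }
  std::vector<double> Sx((size_t)L * P, 0.0), Sy((size_t)L * P, 0.0),
      Sz((size_t)L * P, 0.0);
  for (int i = 0; i < P; ++i) { Sx[i] = x[i]; Sy[i] = y[i]; Sz[i] = z[i]; }
  std::vector<double> fx(P), fy(P), fz(P), ax(P), ay(P), az(P);

  const int nkept = nsteps / keep_every + 1;
  NumericMatrix Xk(P, nkept), Yk(P, nkept);
  for (int i = 0; i < P; ++i) { Xk(i, 0) = x[i]; Yk(i, 0) = y[i]; }
  int ki = 0;

  NumericMatrix W, Om;
  std::vector<int> gsize;
  if (hyb) {
    W = NumericMatrix(3 * ngroups, nsteps + 1);
    Om = NumericMatrix(3 * ngroups, nsteps);
    gsize.assign(ngroups, 0);
    for (int i = 0; i < P; ++i) {
      if (groups[i] < 0 || groups[i] >= ngroups) stop("bad group id");
      ++gsize[groups[i]];
    }
    for (int g = 0; g < ngroups; ++g)
      if (gsize[g] == 0) stop("empty group %d", g + 1);
    for (int i = 0; i < P; ++i) {
      const int g = groups[i];
      W(3 * g, 0) += x[i]; W(3 * g + 1, 0) += y[i]; W(3 * g + 2, 0) += z[i];
    }
    for (int g = 0; g < ngroups; ++g)
      for (int r = 0; r < 3; ++r) W(3 * g + r, 0) /= gsize[g];
  }

  for (int n = 1; n <= nsteps; ++n) {
    for (int i = 0; i < P; ++i) {
      double sp = 0.0, sn = 0.0;
      for (int q = 0; q < 8; ++q) {
        const int t = nbr(i, q);
        if (t < 0) continue;
        const int s = sgn(i, q);
        if (s == 1) sp += x[t] - x[i];
        else if (s == 2) sn += x[t] - x[i];
      }
      fx[i] = -o[i] * y[i] - z[i] + lamp[i] * sp - lamn[i] * sn;
      fy[i] = o[i] * x[i] + a * y[i];
      fz[i] = b + z[i] * (x[i] - cc);
    }
    if (hyb) {
      for (int i = 0; i < P; ++i) {
        const int g = groups[i];
        Om(3 * g, n - 1) += fx[i];
        Om(3 * g + 1, n - 1) += fy[i];
        Om(3 * g + 2, n - 1) += fz[i];
      }
      for (int g = 0; g < ngroups; ++g)
        for (int r = 0; r < 3; ++r) Om(3 * g + r, n - 1) /= gsize[g];
    }
    const int m = std::min(n - 1, L);
    std::fill(ax.begin(), ax.end(), 0.0);
    std::fill(ay.begin(), ay.end(), 0.0);
    std::fill(az.begin(), az.end(), 0.0);
    for (int k = 1; k <= m; ++k) {
      const double w = cw[k];
      const size_t col = (size_t)((n - k) % L) * P;
      for (int i = 0; i < P; ++i) {
        ax[i] += w * Sx[col + i];
        ay[i] += w * Sy[col + i];
        az[i] += w * Sz[col + i];
      }
    }
    const double q = qs[m];
    for (int i = 0; i < P; ++i) {
      x[i] = ha * fx[i] - ax[i] + q * x0[i];
      y[i] = ha * fy[i] - ay[i] + q * y0[i];
      z[i] = ha * fz[i] - az[i] + q * z0[i];
      check_finite(x[i], n, "grid x");
      check_finite(z[i], n, "grid z");
    }
    const size_t cn = (size_t)(n % L) * P;
    for (int i = 0; i < P; ++i) {
      Sx[cn + i] = x[i]; Sy[cn + i] = y[i]; Sz[cn + i] = z[i];
    }
    if (hyb) {
      for (int i = 0; i < P; ++i) {
        const int g = groups[i];
        W(3 * g, n) += x[i]; W(3 * g + 1, n) += y[i]; W(3 * g + 2, n) += z[i];
      }
      for (int g = 0; g < ngroups; ++g)
        for (int r = 0; r < 3; ++r) W(3 * g + r, n) /= gsize[g];
    }
    if (n % keep_every == 0) {
      ++ki;
      for (int i = 0; i < P; ++i) { Xk(i, ki) = x[i]; Yk(i, ki) = y[i]; }
    }
    if (n % 500 == 0) checkUserInterrupt();
  }

  NumericMatrix fin(3, P);
  for (int i = 0; i < P; ++i) { fin(0, i) = x[i]; fin(1, i) = y[i]; fin(2, i) = z[i]; }
  List out = List::create(_["x"] = Xk, _["y"] = Yk, _["final"] = fin);
  if (hyb) { out["w"] = W; out["omega"] = Om; }
  return out;
}
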