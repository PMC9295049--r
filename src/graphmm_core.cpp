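// Compiled core of the graph mixture model.
//
// For a fixed local subgraph, the marginal density given block-constant
// means reduces, via the matrix determinant lemma, to
//   log f = const - cX*log(1 + MX*qX) - cY*log(1 + MY*qY)
// with qX = (xbar - mu_X)' A0^{-1} (xbar - mu_X)  (A0 = A + (MX-1) S1 fixed
// across configurations) and qY analogous.  Means are block-constant, so
// with Z the vertex-to-block incidence matrix everything collapses to
// block-aggregated quantities:
//   qX(phi) = q0X - 2 phi.ax + phi' GA phi,   ax = Z'A0inv xbar,
//   GA = Z'A0inv Z,  q0X = xbar'A0inv xbar,
// and the Y-part likewise with the effective block means c_k = phi_k +
// delta_k d_k.  The Laplace objective then has closed-form gradient and
// Hessian in dimension K + #active <= 18, and each configuration is
// maximized by a damped Newton iteration on stack-allocated buffers.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

constexpr int KMAX = 12;     // blocks per local subgraph
constexpr int DMAX = 2 * KMAX;

// row-major lower Cholesky of symmetric d x d matrix; false if not PD
bool chol_small(int d, const double* H, double* L) {
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = H[i * d + j];
      for (int k = 0; k < j; ++k) s -= L[i * d + k] * L[j * d + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * d + i] = std::sqrt(s);
      } else {
        L[i * d + j] = s / L[j * d + j];
      }
    }
  }
  return true;
}

void chol_solve(int d, const double* L, const double* b, double* x) {
  for (int i = 0; i < d; ++i) {           // L z = b
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * d + k] * x[k];
    x[i] = s / L[i * d + i];
  }
  for (int i = d - 1; i >= 0; --i) {      // L' x = z
    double s = x[i];
    for (int k = i + 1; k < d; ++k) s -= L[k * d + i] * x[k];
    x[i] = s / L[i * d + i];
  }
}

// per-partition block-aggregated statistics
struct PartStats {
  int K;
  double GA[KMAX * KMAX], GB[KMAX * KMAX];
  double ax[KMAX], by[KMAX];        // Z'A0inv xbar, Z'B0inv ybar
  double xblk[KMAX], dblk[KMAX];    // block means of xbar and ybar - xbar
  double pblk[KMAX];                // block means of the pooled group mean
  int bsize[KMAX];
};

void aggregate_partition(const int* memb, int n, int K, const arma::mat& A0inv,
                         const arma::mat& B0inv, const double* A0x,
                         const double* B0y, const double* xbar,
                         const double* ybar, double wpool, PartStats& ps) {
  ps.K = K;
  std::fill(ps.GA, ps.GA + K * K, 0.0);
  std::fill(ps.GB, ps.GB + K * K, 0.0);
  std::fill(ps.ax, ps.ax + K, 0.0);
  std::fill(ps.by, ps.by + K, 0.0);
  std::fill(ps.xblk, ps.xblk + K, 0.0);
  std::fill(ps.dblk, ps.dblk + K, 0.0);
  std::fill(ps.pblk, ps.pblk + K, 0.0);
  std::fill(ps.bsize, ps.bsize + K, 0);
  for (int v = 0; v < n; ++v) {
    const int k = memb[v];
    ps.ax[k] += A0x[v];
    ps.by[k] += B0y[v];
    ps.xblk[k] += xbar[v];
    ps.dblk[k] += ybar[v] - xbar[v];
    ps.pblk[k] += wpool * xbar[v] + (1.0 - wpool) * ybar[v];
    ps.bsize[k] += 1;
    for (int w = 0; w < n; ++w) {
      const int l = memb[w];
      ps.GA[k * K + l] += A0inv(v, w);
      ps.GB[k * K + l] += B0inv(v, w);
    }
  }
  for (int k = 0; k < K; ++k) {
    ps.xblk[k] /= ps.bsize[k];
    ps.dblk[k] /= ps.bsize[k];
    ps.pblk[k] /= ps.bsize[k];
  }
}

struct ConfigScales {
  double q0X, q0Y, cX, cY, MX, MY, mu0, tau2, delta0, sigma2;
};

// Laplace log marginal (without the configuration-independent constant) of
// one (partition, delta) configuration, by damped Newton ascent from a
// given start for the block base means
double config_laplace_start(const PartStats& ps, const int* delta,
                            const ConfigScales& sc, const double* phi0) {
  const int K = ps.K;
  int act[KMAX], A = 0;
  for (int k = 0; k < K; ++k)
    if (delta[k]) act[A++] = k;
  const int d = K + A;

  double theta[DMAX];
  for (int k = 0; k < K; ++k) theta[k] = phi0[k];
  for (int j = 0; j < A; ++j) theta[K + j] = ps.dblk[act[j]];

  double cvec[KMAX], gaphi[KMAX], gbc[KMAX];
  double g[DMAX], H[DMAX * DMAX], L[DMAX * DMAX], s[DMAX], tn[DMAX];

  // objective only (for line search)
  auto h_of = [&](const double* th) {
    double c[KMAX];
    for (int k = 0; k < K; ++k) c[k] = th[k];
    for (int j = 0; j < A; ++j) c[act[j]] += th[K + j];
    double qX = sc.q0X, qY = sc.q0Y;
    for (int k = 0; k < K; ++k) {
      double sa = 0, sb = 0;
      for (int l = 0; l < K; ++l) {
        sa += ps.GA[k * K + l] * th[l];
        sb += ps.GB[k * K + l] * c[l];
      }
      qX += th[k] * (sa - 2.0 * ps.ax[k]);
      qY += c[k] * (sb - 2.0 * ps.by[k]);
    }
    double h = -sc.cX * std::log1p(sc.MX * qX) -
               sc.cY * std::log1p(sc.MY * qY);
    h += -0.5 * K * std::log(2.0 * M_PI * sc.tau2);
    for (int k = 0; k < K; ++k) {
      const double r = th[k] - sc.mu0;
      h -= r * r / (2.0 * sc.tau2);
    }
    if (A) {
      h += -0.5 * A * std::log(2.0 * M_PI * sc.sigma2);
      for (int j = 0; j < A; ++j) {
        const double r = th[K + j] - sc.delta0;
        h -= r * r / (2.0 * sc.sigma2);
      }
    }
    return h;
  };

  double h = 0.0, tX = 1.0, tY = 1.0;
  // full evaluation at current theta: h, gradient, Hessian
  auto eval_full = [&]() {
    for (int k = 0; k < K; ++k) cvec[k] = theta[k];
    for (int j = 0; j < A; ++j) cvec[act[j]] += theta[K + j];
    double qX = sc.q0X, qY = sc.q0Y;
    for (int k = 0; k < K; ++k) {
      double sa = 0, sb = 0;
      for (int l = 0; l < K; ++l) {
        sa += ps.GA[k * K + l] * theta[l];
        sb += ps.GB[k * K + l] * cvec[l];
      }
      gaphi[k] = sa;
      gbc[k] = sb;
      qX += theta[k] * (sa - 2.0 * ps.ax[k]);
      qY += cvec[k] * (sb - 2.0 * ps.by[k]);
    }
    tX = 1.0 + sc.MX * qX;
    tY = 1.0 + sc.MY * qY;
    h = -sc.cX * std::log(tX) - sc.cY * std::log(tY) -
        0.5 * K * std::log(2.0 * M_PI * sc.tau2);
    const double wX = 2.0 * sc.cX * sc.MX / tX;
    const double wY = 2.0 * sc.cY * sc.MY / tY;
    double zA[KMAX], zB[KMAX];
    for (int k = 0; k < K; ++k) {
      zA[k] = ps.ax[k] - gaphi[k];
      zB[k] = ps.by[k] - gbc[k];
      const double r = theta[k] - sc.mu0;
      h -= r * r / (2.0 * sc.tau2);
      g[k] = wX * zA[k] + wY * zB[k] - r / sc.tau2;
    }
    if (A) h -= 0.5 * A * std::log(2.0 * M_PI * sc.sigma2);
    for (int j = 0; j < A; ++j) {
      const double r = theta[K + j] - sc.delta0;
      h -= r * r / (2.0 * sc.sigma2);
      g[K + j] = wY * zB[act[j]] - r / sc.sigma2;
    }
    // Hessian of h: for -c log(1+Mq), -w G + (w^2/c) z z'
    const double vX = wX * wX / sc.cX, vY = wY * wY / sc.cY;
    for (int a = 0; a < d; ++a) {
      const int ka = a < K ? a : act[a - K];
      const bool xa = a < K;
      for (int b = 0; b <= a; ++b) {
        const int kb = b < K ? b : act[b - K];
        const bool xb = b < K;
        double v = -wY * ps.GB[ka * K + kb] + vY * zB[ka] * zB[kb];
        if (xa && xb) v += -wX * ps.GA[ka * K + kb] + vX * zA[ka] * zA[kb];
        H[a * d + b] = H[b * d + a] = v;
      }
      H[a * d + a] -= (a < K) ? 1.0 / sc.tau2 : 1.0 / sc.sigma2;
    }
  };

  eval_full();
  for (int iter = 0; iter < 60; ++iter) {
    double gmax = 0.0;
    for (int a = 0; a < d; ++a) gmax = std::max(gmax, std::fabs(g[a]));
    if (gmax < 1e-8 * (1.0 + std::fabs(h))) break;
    // negate Hessian, ridge until PD
    double negH[DMAX * DMAX];
    for (int a = 0; a < d * d; ++a) negH[a] = -H[a];
    double ridge = 0.0;
    while (!chol_small(d, negH, L)) {
      double dmax = 0.0;
      for (int a = 0; a < d; ++a) dmax = std::max(dmax, negH[a * d + a]);
      ridge = (ridge == 0.0) ? 1e-8 * (1.0 + dmax) : ridge * 10.0;
      for (int a = 0; a < d * d; ++a) negH[a] = -H[a];
      for (int a = 0; a < d; ++a) negH[a * d + a] += ridge;
      if (ridge > 1e8) break;  // degenerate; stop iterating
    }
    if (ridge > 1e8) break;
    chol_solve(d, L, g, s);
    double gs = 0.0;
    for (int a = 0; a < d; ++a) gs += g[a] * s[a];
    double t = 1.0;
    bool ok = false;
    double h_new = h;
    for (int ls = 0; ls < 30; ++ls) {
      for (int a = 0; a < d; ++a) tn[a] = theta[a] + t * s[a];
      h_new = h_of(tn);
      if (h_new >= h + 1e-4 * t * gs || h_new > h) {
        ok = true;
        break;
      }
      t *= 0.5;
    }
    if (!ok) break;
    double move = 0.0;
    for (int a = 0; a < d; ++a) {
      move = std::max(move, std::fabs(t * s[a]));
      theta[a] = tn[a];
    }
    eval_full();
    if (move < 1e-11) break;
  }

  // Laplace: h + d/2 log(2 pi) - 1/2 logdet(-H)
  double negH[DMAX * DMAX];
  for (int a = 0; a < d * d; ++a) negH[a] = -H[a];
  double ridge = 0.0;
  while (!chol_small(d, negH, L)) {
    double dmax = 0.0;
    for (int a = 0; a < d; ++a) dmax = std::max(dmax, negH[a * d + a]);
    ridge = (ridge == 0.0) ? 1e-10 * (1.0 + dmax) : ridge * 10.0;
    for (int a = 0; a < d * d; ++a) negH[a] = -H[a];
    for (int a = 0; a < d; ++a) negH[a * d + a] += ridge;
    if (ridge > 1e8) Rcpp::stop("Hessian not negative definite at mode");
  }
  double ld = 0.0;
  for (int a = 0; a < d; ++a) ld += std::log(L[a * d + a]);
  return h + 0.5 * d * std::log(2.0 * M_PI) - ld;
}

// the objective can be bimodal in the base mean of a null block (product of
// two t-forms, one per group); start each null block at its pooled mean
// (its natural estimate under no shift) and each shifted block at its
// group-1 mean, which places the search in the dominant basin
double config_laplace(const PartStats& ps, const int* delta,
                      const ConfigScales& sc) {
  double phi0[KMAX];
  for (int k = 0; k < ps.K; ++k)
    phi0[k] = delta[k] ? ps.xblk[k] : ps.pblk[k];
  return config_laplace_start(ps, delta, sc, phi0);
}

}  // namespace

// Laplace log marginal (minus the configuration-independent constant) of a
// single (partition, delta) configuration.
// [[Rcpp::export]]
double graphmm_config_logmarg(
    const arma::ivec& memb, const arma::ivec& delta, const arma::vec& xbar,
    const arma::vec& ybar, const arma::mat& A0inv, const arma::mat& B0inv,
    double cX, double cY, double MX, double MY, double mu0, double tau2,
    double delta0, double sigma2) {
  const int n = memb.n_elem;
  const int K = memb.max() + 1;
  if (K > KMAX) Rcpp::stop("too many blocks for the compiled kernel");
  arma::vec A0x = A0inv * xbar, B0y = B0inv * ybar;
  PartStats ps;
  std::vector<int> mb(memb.begin(), memb.end());
  aggregate_partition(mb.data(), n, K, A0inv, B0inv, A0x.memptr(),
                      B0y.memptr(), xbar.memptr(), ybar.memptr(),
                      MX / (MX + MY), ps);
  ConfigScales sc{arma::dot(xbar, A0x), arma::dot(ybar, B0y), cX, cY,
                  MX, MY, mu0, tau2, delta0, sigma2};
  std::vector<int> dl(delta.begin(), delta.end());
  return config_laplace(ps, dl.data(), sc);
}

// Local FDR of the centre vertex of one subgraph: mixture over all
// (partition, delta) configurations.  `membs` holds one partition per
// column as a 0-based membership vector; the uniform partition prior and
// the constant cancel in the normalization.
// [[Rcpp::export]]
double graphmm_center_lfdr(
    const arma::imat& membs, int center0, const arma::vec& xbar,
    const arma::vec& ybar, const arma::mat& A0inv, const arma::mat& B0inv,
    double cX, double cY, double MX, double MY, double mu0, double tau2,
    double delta0, double sigma2, double p0) {
  const int n = membs.n_rows, P = membs.n_cols;
  const double lp0 = std::log(p0), lp1 = std::log1p(-p0);
  arma::vec A0x = A0inv * xbar, B0y = B0inv * ybar;
  ConfigScales sc{arma::dot(xbar, A0x), arma::dot(ybar, B0y), cX, cY,
                  MX, MY, mu0, tau2, delta0, sigma2};
  std::vector<double> lws;
  std::vector<char> is_null;
  lws.reserve(1u << 12);
  is_null.reserve(1u << 12);
  std::vector<int> mb(n);
  int delta[KMAX];
  PartStats ps;
  for (int ip = 0; ip < P; ++ip) {
    int K = 0;
    for (int v = 0; v < n; ++v) {
      mb[v] = membs(v, ip);
      K = std::max(K, mb[v] + 1);
    }
    if (K > KMAX) Rcpp::stop("too many blocks for the compiled kernel");
    aggregate_partition(mb.data(), n, K, A0inv, B0inv, A0x.memptr(),
                        B0y.memptr(), xbar.memptr(), ybar.memptr(),
                        MX / (MX + MY), ps);
    const int kc = mb[center0];
    for (unsigned mask = 0; mask < (1u << K); ++mask) {
      double prior = 0.0;
      for (int k = 0; k < K; ++k) {
        delta[k] = (mask >> k) & 1u;
        prior += delta[k] ? lp1 : lp0;
      }
      if (!std::isfinite(prior)) continue;  // p0 at 0/1: zero-mass configs
      lws.push_back(prior + config_laplace(ps, delta, sc));
      is_null.push_back(delta[kc] == 0);
    }
  }
  if (lws.empty()) return 1.0;
  const double m = *std::max_element(lws.begin(), lws.end());
  double den = 0.0, num = 0.0;
  for (size_t i = 0; i < lws.size(); ++i) {
    const double w = std::exp(lws[i] - m);
    den += w;
    if (is_null[i]) num += w;
  }
  return std::min(1.0, std::max(0.0, num / den));
}
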