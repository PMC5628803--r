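#include <RcppArmadillo.h>
#include <queue>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Synthesize T x V voxel time series for one phantom subject.
//
// Each column v is
//   baseline[v] + drift[v]*(t_idx) + sum_j amps[v]*sin(2*pi*freqs(v,j)*t + phases(v,j))
//   + confound(t)*confound_w[v] + AR(1) noise (innovation sd = noise_sd)
// with t = t_idx * tr, t_idx = 0..T-1.
//
// Noise comes from a Mersenne-Twister stream seeded with noise_seed so the
// result is fully determined by the arguments.
// [[Rcpp::export]]
arma::mat synth_signals_cpp(const int nt, const double tr,
                            const arma::mat& freqs, const arma::mat& phases,
                            const arma::vec& amps, const arma::vec& baseline,
                            const arma::vec& drift, const double noise_sd,
                            const double ar, const arma::vec& confound,
                            const arma::vec& confound_w,
                            const unsigned int noise_seed) {
  const arma::uword V = amps.n_elem;
  const arma::uword J = freqs.n_cols;
  arma::vec tsec = arma::regspace<arma::vec>(0, nt - 1) * tr;
  arma::vec tidx = arma::regspace<arma::vec>(0, nt - 1);

  arma::mat S(nt, V);
  S.each_row() = baseline.t();
  S += tidx * drift.t();
  if (confound_w.n_elem == V && arma::any(confound_w != 0.0))
    S += confound * confound_w.t();

  for (arma::uword j = 0; j < J; ++j) {
    arma::mat ang = tsec * (2.0 * arma::datum::pi * freqs.col(j)).t();
    ang.each_row() += phases.col(j).t();
    arma::mat osc = arma::sin(ang);
    osc.each_row() %= amps.t();
    S += osc;
  }

  if (noise_sd > 0.0) {
    std::mt19937_64 rng(noise_seed);
    std::normal_distribution<double> gauss(0.0, noise_sd);
    arma::mat E(nt, V);
    for (arma::uword v = 0; v < V; ++v)
      for (int t = 0; t < nt; ++t) E(t, v) = gauss(rng);
    if (ar != 0.0) {
      for (int t = 1; t < nt; ++t) E.row(t) += ar * E.row(t - 1);
    }
    S += E;
  }
  return S;
}

// Label connected components of a 3D logical mask (stored as int vector in
// column-major order) under face (6), edge (18) or corner (26) adjacency.
// Returns an integer vector of labels, 0 for background, 1..n_components
// in order of first-encountered voxel.
// [[Rcpp::export]]
IntegerVector label_components_cpp(const LogicalVector& mask,
                                   const IntegerVector& dims,
                                   const int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }

  int next_label = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    labels[i] = ++next_label;
    q.push(i);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int cz = cur / (nx * ny);
      int rem = cur - cz * nx * ny;
      int cy = rem / nx;
      int cx = rem - cy * nx;
      for (const auto& o : offs) {
        int x = cx + o[0], y = cy + o[1], z = cz + o[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        int idx = x + nx * (y + ny * z);
        if (mask[idx] && labels[idx] == 0) {
          labels[idx] = next_label;
          q.push(idx);
        }
      }
    }
  }
  return labels;
}
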