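// Batch realization kernels for the per-generation inner loops.
//
// Both kernels iterate the synchronous network map
//   s(t+1) = clamp(sbasal + W s(t) [+ sqrt(eta) z], smin, smax)
// for Tr steps from the basal state. The deterministic kernel carries one
// weight configuration per individual on a shared edge set (network
// establishment); the stochastic kernel shares W across individuals and
// varies eta (noise evolution).
//
// The stochastic kernel draws its Gaussians from a self-contained
// xoshiro256++ generator with a 128-layer ziggurat normal sampler
// (Marsaglia & Tsang construction), seeded explicitly per call. A noise run
// consumes ~1e8 draws, so draw speed dominates the runtime; the explicit
// seed keeps runs bit-reproducible and independent of the R RNG state.

#include <RcppArmadillo.h>
#include <cmath>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline uint64_t rotl64(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

// xoshiro256++ seeded through splitmix64
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  uint64_t next() {
    const uint64_t r = rotl64(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl64(s[3], 45);
    return r;
  }
  double unif() { // [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int32_t next32() { return (int32_t)(next() >> 32); }
};

// 128-layer ziggurat tables for the standard normal
struct ZigTables {
  double kn[128], wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (dn / q) * m1;
    kn[1] = 0.0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (dn / tn) * m1;
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

static const ZigTables& zigTables() {
  static ZigTables t;
  return t;
}

static inline double rnormZig(Xoshiro& g) {
  const ZigTables& z = zigTables();
  const double r = 3.442619855899;
  for (;;) {
    const int32_t hz = g.next32();
    const int iz = hz & 127;
    if (std::fabs((double)hz) < z.kn[iz]) return hz * z.wn[iz];
    if (iz == 0) { // tail beyond r
      double x, y;
      do {
        x = -std::log(1.0 - g.unif()) / r;
        y = -std::log(1.0 - g.unif());
      } while (y + y < x * x);
      return hz > 0 ? r + x : -(r + x);
    }
    const double x = hz * z.wn[iz];
    if (z.fn[iz] + g.unif() * (z.fn[iz - 1] - z.fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
  }
}

// Deterministic batch realization with per-individual weights.
// ei, ej: 0-based target/regulator gene of each of E edges (shared layout);
// wv: N x E matrix, row k = individual k's weights. Returns the final n x N
// state matrix and the per-individual oscillation statistic Phi computed
// over the last tau + 1 steps.
// [[Rcpp::export(name = ".realizeDetermBatch", rng = false)]]
List realizeDetermBatch(const arma::uvec& ei, const arma::uvec& ej,
                        const arma::mat& wv, int n, double sbasal,
                        double smin, double smax, int Tr, int tau) {
  const arma::uword N = wv.n_rows, E = wv.n_cols;
  arma::mat S(N, (arma::uword)n);
  S.fill(sbasal);
  arma::mat A(N, (arma::uword)n);
  const int B = tau + 1;
  arma::cube buf(N, (arma::uword)n, (arma::uword)B);
  const int bufStart = Tr - tau; // record states t = Tr-tau .. Tr
  for (int t = 1; t <= Tr; ++t) {
    A.zeros();
    for (arma::uword e = 0; e < E; ++e)
      A.col(ei[e]) += wv.col(e) % S.col(ej[e]);
    S = arma::clamp(A + sbasal, smin, smax);
    if (t >= bufStart) buf.slice((arma::uword)(t - bufStart)) = S;
  }
  arma::vec phi(N, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    phi += arma::sum(arma::abs(buf.slice((arma::uword)b) - S), 1) / n;
  phi /= tau;
  return List::create(_["final"] = wrap(arma::mat(S.t())),
                      _["phi"] = wrap(phi));
}

// Stochastic batch realization with a shared weight matrix.
// W: n x n; etaSd: n x N per-gene, per-individual noise standard deviations;
// seed: nonnegative integer-valued seed for the internal generator.
// Returns the final n x N state matrix and the fraction of clamped draws.
// [[Rcpp::export(name = ".realizeStochShared", rng = false)]]
List realizeStochShared(const arma::mat& W, const arma::mat& etaSd,
                        double sbasal, double smin, double smax, int Tr,
                        double seed) {
  const arma::uword n = W.n_rows, N = etaSd.n_cols;
  Xoshiro rng((uint64_t)seed);
  arma::mat S(n, N);
  S.fill(sbasal);
  arma::mat A(n, N);
  double clamped = 0.0;
  for (int t = 0; t < Tr; ++t) {
    A = W * S;
    for (arma::uword k = 0; k < N; ++k) {
      for (arma::uword i = 0; i < n; ++i) {
        double v = sbasal + A(i, k) + etaSd(i, k) * rnormZig(rng);
        if (v < smin) { v = smin; clamped += 1.0; }
        else if (v > smax) { v = smax; clamped += 1.0; }
        S(i, k) = v;
      }
    }
  }
  return List::create(
      _["final"] = wrap(S),
      _["clampedFraction"] = clamped / ((double)n * (double)N * (double)Tr));
}

// Raw access to the internal normal sampler, for calibration tests.
// [[Rcpp::export(name = ".zigguratDraws", rng = false)]]
NumericVector zigguratDraws(int nDraws, double seed) {
  Xoshiro rng((uint64_t)seed);
  NumericVector out(nDraws);
  for (int i = 0; i < nDraws; ++i) out[i] = rnormZig(rng);
  return out;
}
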