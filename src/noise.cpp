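#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cstdint>
#include <cmath>
#include <vector>

// Seeded white-noise generation for sensor-noise matrices.
//
// The experiment drivers draw of order 1e10 Gaussian deviates for the
// sensor-noise term e in m = l q + e; xoshiro256++ feeding a 128-layer
// ziggurat generates them two orders of magnitude faster than R's
// inversion sampler while remaining fully deterministic given the integer
// seed. Source time courses (small) are drawn with R's own RNG.

namespace {

struct Xoshiro256pp {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    for (int i = 0; i < 16; ++i) next();  // decorrelate nearby seeds
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1), never 0 or 1
  double unif01() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  int32_t next_i32() { return static_cast<int32_t>(next() >> 32); }
};

// Marsaglia-Tsang 128-layer ziggurat for the standard normal
struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];

  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<uint32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }

  double nfix(Xoshiro256pp &rng, int32_t hz, uint32_t iz) const {
    const double r = 3.442619855899;
    double x, y;
    for (;;) {
      x = hz * wn[iz];
      if (iz == 0) {  // base strip: exact tail sampling
        do {
          x = -std::log(rng.unif01()) / r;
          y = -std::log(rng.unif01());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      if (fn[iz] + rng.unif01() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x)) {
        return x;
      }
      hz = rng.next_i32();
      iz = static_cast<uint32_t>(hz) & 127u;
      if (iabs(hz) < kn[iz]) return hz * wn[iz];
    }
  }

  static uint32_t iabs(int32_t hz) {
    return hz < 0 ? static_cast<uint32_t>(-static_cast<int64_t>(hz))
                  : static_cast<uint32_t>(hz);
  }

  double draw(Xoshiro256pp &rng) const {
    const int32_t hz = rng.next_i32();
    const uint32_t iz = static_cast<uint32_t>(hz) & 127u;
    if (iabs(hz) < kn[iz]) return hz * wn[iz];
    return nfix(rng, hz, iz);
  }
};

const Ziggurat &ziggurat() {
  static Ziggurat z;
  return z;
}

void fill_normal(double *p, R_xlen_t n, double sd, uint64_t seed) {
  Xoshiro256pp rng(seed);
  const Ziggurat &z = ziggurat();
  for (R_xlen_t i = 0; i < n; ++i) p[i] = z.draw(rng) * sd;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".noise_matrix")]]
Rcpp::NumericMatrix noise_matrix_cpp(int nrow, int ncol, double sd, double seed) {
  if (nrow < 0 || ncol < 0) Rcpp::stop("matrix dimensions must be non-negative");
  if (!(sd >= 0) || !std::isfinite(sd)) Rcpp::stop("sd must be finite and >= 0");
  if (!std::isfinite(seed) || seed < 0) Rcpp::stop("seed must be a non-negative number");

  Rcpp::NumericMatrix out(nrow, ncol);
  const R_xlen_t n = static_cast<R_xlen_t>(nrow) * ncol;
  if (n == 0) return out;
  if (sd == 0.0) {
    std::fill(out.begin(), out.end(), 0.0);
    return out;
  }
  fill_normal(out.begin(), n, sd, static_cast<uint64_t>(seed));
  return out;
}

// Cross moments of a freshly drawn noise matrix E (nch x N, sd, seed)
// without materialising E at the R level or copying for demeaning:
// returns EE^T (full symmetric), rowSums(E), and E q^T for a given
// (already centred) source matrix q (S x N; S may be 0).
//' @noRd
// [[Rcpp::export(name = ".noise_crossmoments")]]
Rcpp::List noise_crossmoments_cpp(int nch, int nsamp, double sd, double seed,
                                  Rcpp::NumericMatrix q) {
  if (nch <= 0 || nsamp <= 0) Rcpp::stop("dimensions must be positive");
  if (!(sd >= 0) || !std::isfinite(sd)) Rcpp::stop("sd must be finite and >= 0");
  const int s_src = q.nrow();
  if (s_src > 0 && q.ncol() != nsamp) Rcpp::stop("q must be S x N");

  std::vector<double> e(static_cast<size_t>(nch) * nsamp);
  fill_normal(e.data(), static_cast<R_xlen_t>(nch) * nsamp, sd,
              static_cast<uint64_t>(seed));

  Rcpp::NumericMatrix eet(nch, nch);
  const double one = 1.0, zero = 0.0;
  // EE^T via dsyrk on the upper triangle (E is nch x N, column-major)
  F77_CALL(dsyrk)("U", "N", &nch, &nsamp, &one, e.data(), &nch, &zero,
                  eet.begin(), &nch FCONE FCONE);
  for (int j = 0; j < nch; ++j) {
    for (int i = j + 1; i < nch; ++i) eet(i, j) = eet(j, i);
  }

  Rcpp::NumericVector rs(nch);
  const double *pe = e.data();
  for (int t = 0; t < nsamp; ++t) {
    const double *col = pe + static_cast<size_t>(t) * nch;
    for (int i = 0; i < nch; ++i) rs[i] += col[i];
  }

  Rcpp::NumericMatrix eq(nch, s_src);
  if (s_src > 0) {
    // E q^T = E %*% t(q): (nch x N) (N x S)
    const int n_ = nsamp;
    F77_CALL(dgemm)("N", "T", &nch, &s_src, &n_, &one, e.data(), &nch,
                    q.begin(), &s_src, &zero, eq.begin(), &nch FCONE FCONE);
  }
  return Rcpp::List::create(Rcpp::Named("eet") = eet,
                            Rcpp::Named("rowsums") = rs,
                            Rcpp::Named("eq") = eq);
}
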