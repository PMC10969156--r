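// Ensemble Euler-Maruyama drivers for the coupled Duffing-van der Pol
// oscillator and the Ornstein-Uhlenbeck validation process.
//
// The integrator advances all trajectories one step at a time and never
// retains per-step history: memory stays proportional to the ensemble size,
// which is what makes large-ensemble runs feasible. Recorded slices are
// handed to an R consumer closure at a fixed cadence (including t = 0).
//
// Noise is generated from a self-contained xoshiro256++ stream (seeded via
// splitmix64) with Marsaglia-Tsang ziggurat normals, so a run is fully
// reproducible from one integer seed independently of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

namespace {

// ---------------------------------------------------------------- RNG core

struct Xoshiro256pp {
  uint64_t s[4];

  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed into the full state
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      s[i] = x ^ (x >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
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

  // one 32-bit word per call (high half, then low half of a 64-bit draw)
  uint64_t cache = 0;
  bool has_cache = false;
  inline uint32_t next_u32() {
    if (has_cache) {
      has_cache = false;
      return static_cast<uint32_t>(cache);
    }
    cache = next();
    has_cache = true;
    return static_cast<uint32_t>(cache >> 32);
  }

  inline double uni() {  // uniform on (0,1)
    return (next_u32() + 0.5) * 2.3283064365386963e-10;  // 2^-32
  }
};

// ------------------------------------------------- ziggurat normal sampler
// Marsaglia & Tsang (2000) 128-layer ziggurat.

struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];
  Xoshiro256pp rng;

  explicit Ziggurat(uint64_t seed) : rng(seed) {
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

  inline double draw() {
    for (;;) {
      const int32_t hz = static_cast<int32_t>(rng.next_u32());
      const uint32_t iz = hz & 127u;
      if (static_cast<uint32_t>(hz < 0 ? -hz : hz) < kn[iz])
        return hz * wn[iz];
      // tail / wedge rejection
      const double r = 3.442619855899;
      if (iz == 0) {
        double x, y;
        do {
          x = -std::log(rng.uni()) / r;
          y = -std::log(rng.uni());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      const double x = hz * wn[iz];
      if (fn[iz] + rng.uni() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

inline bool all_finite(const std::vector<double>& v) {
  for (double x : v)
    if (!std::isfinite(x)) return false;
  return true;
}

}  // namespace

// Standard-normal draws from the internal generator; exposed so the noise
// stream itself can be validated statistically.
// [[Rcpp::export(name = ".zig_normals")]]
Rcpp::NumericVector zig_normals(int n, double seed) {
  Ziggurat zig(static_cast<uint64_t>(seed));
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = zig.draw();
  return out;
}

// Drive the coupled Duffing-van der Pol ensemble. `x` is n x 4 (columns
// x1, x2, x3, x4), `par` is c(k1, k2, b1, b2, eps1, eps2, mu). The consumer
// is called at t0 and after every `steps_per_record` EM steps.
// [[Rcpp::export(name = ".sim_oscillator")]]
void sim_oscillator(Rcpp::NumericMatrix x, Rcpp::NumericVector par,
                    double t0, double dt, double record_dt,
                    int steps_per_record, int n_records, double seed,
                    Rcpp::Function consumer, bool record_all) {
  const int n = x.nrow();
  const double k1 = par[0], k2 = par[1], b1 = par[2], b2 = par[3],
               e1 = par[4], e2 = par[5], mu = par[6];
  const double sq = mu * std::sqrt(dt);
  const bool noisy = (mu != 0.0);

  std::vector<double> x1(n), x2(n), x3(n), x4(n), z(noisy ? n : 0);
  for (int i = 0; i < n; ++i) {
    x1[i] = x(i, 0);
    x2[i] = x(i, 1);
    x3[i] = x(i, 2);
    x4[i] = x(i, 3);
  }

  Ziggurat zig(static_cast<uint64_t>(seed));

  auto emit = [&](int m) {
    const double t = t0 + m * record_dt;
    Rcpp::NumericVector r1(x1.begin(), x1.end());
    Rcpp::NumericVector r2(x2.begin(), x2.end());
    if (record_all) {
      Rcpp::NumericVector r3(x3.begin(), x3.end());
      Rcpp::NumericVector r4(x4.begin(), x4.end());
      consumer(t, r1, r2, r3, r4);
    } else {
      consumer(t, r1, r2);
    }
  };

  emit(0);
  for (int m = 1; m <= n_records; ++m) {
    for (int s = 0; s < steps_per_record; ++s) {
      if (noisy)
        for (int i = 0; i < n; ++i) z[i] = zig.draw();
      for (int i = 0; i < n; ++i) {
        const double X1 = x1[i], X2 = x2[i], X3 = x3[i], X4 = x4[i];
        const double d = X1 - X2;
        const double d3 = d * d * d;
        const double f3 = -(k1 + k2) * X1 + k2 * X2 - b1 * X1 * X1 * X1 -
                          b2 * d3 + e1 * X3 * (1.0 - X1 * X1);
        const double f4 =
            k2 * X1 - k2 * X2 + b2 * d3 + e2 * X4 * (1.0 - X2 * X2);
        x1[i] = X1 + X3 * dt;
        x2[i] = X2 + X4 * dt;
        x3[i] = X3 + f3 * dt;
        x4[i] = X4 + f4 * dt + (noisy ? sq * z[i] : 0.0);
      }
    }
    if (!(all_finite(x1) && all_finite(x2) && all_finite(x3) &&
          all_finite(x4)))
      Rcpp::stop(
          "integration blow-up: non-finite state detected in the recording "
          "interval ending at t = %g",
          t0 + m * record_dt);
    emit(m);
    Rcpp::checkUserInterrupt();
  }
}

// Ornstein-Uhlenbeck ensemble dX = -theta * X dt + q dW, used as an analytic
// validation process for the density/measure estimators.
// [[Rcpp::export(name = ".sim_ou")]]
void sim_ou(Rcpp::NumericVector x0, double theta, double q, double t0,
            double dt, double record_dt, int steps_per_record, int n_records,
            double seed, Rcpp::Function consumer) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  const double sq = q * std::sqrt(dt);
  Ziggurat zig(static_cast<uint64_t>(seed));

  auto emit = [&](int m) {
    const double t = t0 + m * record_dt;
    Rcpp::NumericVector r(x.begin(), x.end());
    consumer(t, r);
  };

  emit(0);
  for (int m = 1; m <= n_records; ++m) {
    for (int s = 0; s < steps_per_record; ++s)
      for (int i = 0; i < n; ++i)
        x[i] += -theta * x[i] * dt + sq * zig.draw();
    if (!all_finite(x))
      Rcpp::stop(
          "integration blow-up: non-finite state detected in the recording "
          "interval ending at t = %g",
          t0 + m * record_dt);
    emit(m);
    Rcpp::checkUserInterrupt();
  }
}
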