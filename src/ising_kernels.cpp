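// 2D Ising kernels: exact small-lattice enumeration and single-flip
// Metropolis Monte Carlo with a self-contained, platform-stable RNG.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact thermal averages by summation over all 2^N spin states.
// Ground-state energy -2NJ anchors the Boltzmann factors, so every
// exponent is <= 0.  Returns plain averages (weights never overflow).
// [[Rcpp::export]]
List cpp_enumerate_ising(int L, double J, double inv_t) {
  const int N = L * L;
  if (N > 16) stop("spin-state enumeration is limited to L <= 4");
  // bond list: right and down neighbors with wraparound
  std::vector<int> bi, bj;
  for (int r = 0; r < L; ++r) {
    for (int c = 0; c < L; ++c) {
      const int s = r * L + c;
      bi.push_back(s); bj.push_back(r * L + (c + 1) % L);
      bi.push_back(s); bj.push_back(((r + 1) % L) * L + c);
    }
  }
  const int nb = (int)bi.size();
  const double e_ground = -2.0 * N * J;
  double W = 0.0, WE = 0.0, WE2 = 0.0, WM = 0.0;
  const uint32_t nstates = (uint32_t)1 << N;
  for (uint32_t s = 0; s < nstates; ++s) {
    int sum_ss = 0;
    for (int b = 0; b < nb; ++b) {
      const int si = (s >> bi[b]) & 1, sj = (s >> bj[b]) & 1;
      sum_ss += (si == sj) ? 1 : -1;
    }
    const double E = -J * sum_ss;
#if defined(__GNUC__) || defined(__clang__)
    const int nup = __builtin_popcount(s);
#else
    int nup = 0;
    for (uint32_t q = s; q; q &= q - 1) ++nup;
#endif
    const double M = std::abs(2.0 * nup - N);
    const double w = std::exp(-(E - e_ground) * inv_t);
    W += w;
    WE += w * E;
    WE2 += w * E * E;
    WM += w * M;
  }
  return List::create(_["mean_absM"] = WM / W, _["mean_E"] = WE / W,
                      _["mean_E2"] = WE2 / W,
                      _["log_Z"] = std::log(W) - e_ground * inv_t);
}

// ---------------------------------------------------------------------------
// Metropolis Monte Carlo.  One sweep = N attempted single-spin flips at
// uniformly random sites.  Thermalization runs `sweeps` sweeps, then
// `sweeps` sampling sweeps with one (E, |M|) measurement per sweep.
// mt19937_64 with a fixed output-to-uniform mapping keeps runs
// bit-reproducible across platforms for a given seed.
// [[Rcpp::export]]
List cpp_mc_run(int L, double J, double inv_t, int sweeps, double seed,
                bool random_init, int trace_len) {
  const int N = L * L;
  std::mt19937_64 rng((uint64_t)seed);
  auto u01 = [&rng]() {
    return (double)(rng() >> 11) * (1.0 / 9007199254740992.0);
  };
  // neighbor table
  std::vector<int> nbr(4 * N);
  for (int r = 0; r < L; ++r) {
    for (int c = 0; c < L; ++c) {
      const int s = r * L + c;
      nbr[4 * s + 0] = r * L + (c + 1) % L;
      nbr[4 * s + 1] = r * L + (c + L - 1) % L;
      nbr[4 * s + 2] = ((r + 1) % L) * L + c;
      nbr[4 * s + 3] = ((r + L - 1) % L) * L + c;
    }
  }
  std::vector<int8_t> spin(N);
  if (random_init) {
    for (int i = 0; i < N; ++i) spin[i] = (u01() < 0.5) ? -1 : 1;
  } else {
    std::fill(spin.begin(), spin.end(), 1);
  }
  double E = 0.0;
  int Mtot = 0;
  for (int i = 0; i < N; ++i) {
    Mtot += spin[i];
    E += -J * spin[i] * (spin[nbr[4 * i + 0]] + spin[nbr[4 * i + 2]]);
  }
  // acceptance probabilities for the two uphill energy changes 4J, 8J
  const double p4 = std::exp(-4.0 * J * inv_t), p8 = std::exp(-8.0 * J * inv_t);
  std::vector<double> samp_E, samp_absM;
  samp_E.reserve(sweeps);
  samp_absM.reserve(sweeps);
  std::vector<double> trace_de;
  std::vector<int> trace_acc;
  int64_t accepted = 0, attempted = 0;
  for (int phase = 0; phase < 2; ++phase) {
    for (int sw = 0; sw < sweeps; ++sw) {
      for (int a = 0; a < N; ++a) {
        const int i = (int)(u01() * N);
        const int h = spin[nbr[4 * i]] + spin[nbr[4 * i + 1]] +
                      spin[nbr[4 * i + 2]] + spin[nbr[4 * i + 3]];
        const double dE = 2.0 * J * spin[i] * h;
        bool acc;
        if (dE <= 0.0) {
          acc = true;
        } else {
          const double p = (dE <= 4.0 * J + 1e-12) ? p4 : p8;
          acc = (u01() < p);
        }
        if ((int)trace_de.size() < trace_len) {
          trace_de.push_back(dE);
          trace_acc.push_back(acc ? 1 : 0);
        }
        ++attempted;
        if (acc) {
          ++accepted;
          Mtot -= 2 * spin[i];
          E += dE;
          spin[i] = -spin[i];
        }
      }
      if (phase == 1) {
        samp_E.push_back(E);
        samp_absM.push_back(std::abs((double)Mtot));
      }
    }
  }
  return List::create(
      _["E"] = NumericVector(samp_E.begin(), samp_E.end()),
      _["absM"] = NumericVector(samp_absM.begin(), samp_absM.end()),
      _["accepted_fraction"] = (double)accepted / (double)attempted,
      _["trace_dE"] = NumericVector(trace_de.begin(), trace_de.end()),
      _["trace_accepted"] = IntegerVector(trace_acc.begin(), trace_acc.end()));
}
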