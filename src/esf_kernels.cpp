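// Elementary symmetric function kernels.
//
// All ESF arithmetic is over nonnegative weights, so every convolution
// summand is nonnegative and the split-merge route involves no
// subtraction.  Two representations are provided: plain doubles (used
// when the whole computation provably fits the double range) and
// log-domain coefficients combined by log-sum-exp (used for large or
// extreme-magnitude weight sets, e.g. lattice systems at low
// temperature).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
// Terms further than this below the running maximum contribute < 2e-22
// relative per term to a log-sum-exp and are skipped.
static const double LSE_CUTOFF = 50.0;

// ---------------------------------------------------------------------------
// plain schoolbook convolution: c[k] = sum_j a[j] b[k-j]
// [[Rcpp::export]]
NumericVector cpp_conv_plain(NumericVector a, NumericVector b) {
  const int na = a.size(), nb = b.size();
  NumericVector c(na + nb - 1);
  for (int i = 0; i < na; ++i) {
    const double ai = a[i];
    if (ai == 0.0) continue;
    for (int j = 0; j < nb; ++j) c[i + j] += ai * b[j];
  }
  return c;
}

// log-domain convolution with an optional per-term pair factor:
//   log c[k] = LSE_j ( la[j] + lb[k-j] + lx * j * (k-j) )
// lx = 0 gives the ordinary ESF merge.  Two passes per output index:
// locate the maximum without exp() calls, then accumulate only the
// terms within LSE_CUTOFF of it.
static std::vector<double> conv_log_vec(const std::vector<double>& la,
                                        const std::vector<double>& lb,
                                        double lx, int64_t* ops) {
  const int na = (int)la.size(), nb = (int)lb.size();
  std::vector<double> c(na + nb - 1, NEG_INF);
  for (int k = 0; k < na + nb - 1; ++k) {
    const int jlo = std::max(0, k - nb + 1), jhi = std::min(na - 1, k);
    double mx = NEG_INF;
    if (lx == 0.0) {
      for (int j = jlo; j <= jhi; ++j) {
        const double s = la[j] + lb[k - j];
        if (s > mx) mx = s;
      }
    } else {
      for (int j = jlo; j <= jhi; ++j) {
        const double s = la[j] + lb[k - j] + lx * (double)j * (double)(k - j);
        if (s > mx) mx = s;
      }
    }
    if (ops) *ops += (jhi - jlo + 1);
    if (mx == NEG_INF) continue;  // all summands zero
    double acc = 0.0;
    const double thr = mx - LSE_CUTOFF;
    if (lx == 0.0) {
      for (int j = jlo; j <= jhi; ++j) {
        const double s = la[j] + lb[k - j];
        if (s >= thr) acc += std::exp(s - mx);
      }
    } else {
      for (int j = jlo; j <= jhi; ++j) {
        const double s = la[j] + lb[k - j] + lx * (double)j * (double)(k - j);
        if (s >= thr) acc += std::exp(s - mx);
      }
    }
    c[k] = mx + std::log(acc);
  }
  return c;
}

// [[Rcpp::export]]
NumericVector cpp_conv_log(NumericVector la, NumericVector lb, double lx) {
  std::vector<double> a(la.begin(), la.end()), b(lb.begin(), lb.end());
  std::vector<double> c = conv_log_vec(a, b, lx, nullptr);
  return NumericVector(c.begin(), c.end());
}

// ---------------------------------------------------------------------------
// binary split-merge over weights [lo, hi): left branch floor(n/2)
static std::vector<double> split_merge_log_rec(const std::vector<double>& lw,
                                               int lo, int hi, int64_t* ops) {
  const int n = hi - lo;
  if (n == 1) {
    // leaf ESF: (1, w_i) -> logs (0, log w_i)
    std::vector<double> leaf(2);
    leaf[0] = 0.0;
    leaf[1] = lw[lo];
    return leaf;
  }
  const int mid = lo + n / 2;
  std::vector<double> a = split_merge_log_rec(lw, lo, mid, ops);
  std::vector<double> b = split_merge_log_rec(lw, mid, hi, ops);
  return conv_log_vec(a, b, 0.0, ops);
}

// [[Rcpp::export]]
List cpp_esf_split_merge_log(NumericVector log_w) {
  std::vector<double> lw(log_w.begin(), log_w.end());
  int64_t ops = 0;
  std::vector<double> c = split_merge_log_rec(lw, 0, (int)lw.size(), &ops);
  return List::create(_["log_coeffs"] = NumericVector(c.begin(), c.end()),
                      _["ops"] = (double)ops);
}

static std::vector<double> split_merge_plain_rec(const std::vector<double>& w,
                                                 int lo, int hi, int64_t* ops) {
  const int n = hi - lo;
  if (n == 1) return std::vector<double>{1.0, w[lo]};
  const int mid = lo + n / 2;
  std::vector<double> a = split_merge_plain_rec(w, lo, mid, ops);
  std::vector<double> b = split_merge_plain_rec(w, mid, hi, ops);
  std::vector<double> c(a.size() + b.size() - 1, 0.0);
  for (size_t i = 0; i < a.size(); ++i) {
    const double ai = a[i];
    for (size_t j = 0; j < b.size(); ++j) c[i + j] += ai * b[j];
  }
  if (ops) *ops += (int64_t)a.size() * (int64_t)b.size();
  return c;
}

// [[Rcpp::export]]
List cpp_esf_split_merge_plain(NumericVector w) {
  std::vector<double> wv(w.begin(), w.end());
  int64_t ops = 0;
  std::vector<double> c = split_merge_plain_rec(wv, 0, (int)wv.size(), &ops);
  return List::create(_["coeffs"] = NumericVector(c.begin(), c.end()),
                      _["ops"] = (double)ops);
}

// ---------------------------------------------------------------------------
// brute-force oracle: direct enumeration of all 2^M subsets.  Subset
// products are formed incrementally (prod[s] = prod[s without lowest
// bit] * w[lowest bit]) so each subset costs one multiply.
// [[Rcpp::export]]
NumericVector cpp_esf_bruteforce(NumericVector w) {
  const int m = w.size();
  if (m > 25) stop("brute-force ESF enumeration is limited to M <= 25");
  const uint64_t nsub = (uint64_t)1 << m;
  std::vector<double> prod(nsub);
  NumericVector e(m + 1);
  prod[0] = 1.0;
  e[0] = 1.0;
  for (uint64_t s = 1; s < nsub; ++s) {
    const uint64_t low = s & (~s + 1);  // lowest set bit
    int bit = 0;
    uint64_t t = low;
    while (t > 1) { t >>= 1; ++bit; }
    const double p = prod[s ^ low] * w[bit];
    prod[s] = p;
#if defined(__GNUC__) || defined(__clang__)
    e[__builtin_popcountll(s)] += p;
#else
    {
      int pc = 0;
      for (uint64_t q = s; q; q &= q - 1) ++pc;
      e[pc] += p;
    }
#endif
  }
  return e;
}

// ---------------------------------------------------------------------------
// double-double ("compensated") arithmetic: an unevaluated sum of two
// doubles carrying ~31-32 significant digits.  Used for the
// extended-precision Newton's-identity route, whose alternating-sign
// recursion genuinely needs the head room.
struct dd {
  double hi, lo;
};

static inline dd dd_from(double x) { return {x, 0.0}; }

static inline dd two_sum(double a, double b) {
  double s = a + b;
  double bb = s - a;
  double err = (a - (s - bb)) + (b - bb);
  return {s, err};
}

static inline dd dd_add(dd a, dd b) {
  dd s = two_sum(a.hi, b.hi);
  double lo = a.lo + b.lo + s.lo;
  dd r = two_sum(s.hi, lo);
  return r;
}

static inline dd two_prod(double a, double b) {
  double p = a * b;
  double err = std::fma(a, b, -p);
  return {p, err};
}

static inline dd dd_mul(dd a, dd b) {
  dd p = two_prod(a.hi, b.hi);
  p.lo += a.hi * b.lo + a.lo * b.hi;
  dd r = two_sum(p.hi, p.lo);
  return r;
}

static inline dd dd_neg(dd a) { return {-a.hi, -a.lo}; }

// full-precision division of a double-double by a double
static inline dd dd_div_d(dd a, double b) {
  double q0 = a.hi / b;
  dd p = two_prod(q0, b);
  double r = ((a.hi - p.hi) - p.lo) + a.lo;
  double q1 = r / b;
  return two_sum(q0, q1);
}

// Newton's identities in double-double precision:
//   k e_k = sum_{j=1..k} (-1)^{j-1} e_{k-j} p_j,  p_j = sum_i w_i^j
// [[Rcpp::export]]
NumericVector cpp_esf_newton_dd(NumericVector w) {
  const int m = w.size();
  // power sums p_1..p_m
  std::vector<dd> p(m + 1, dd_from(0.0));
  std::vector<dd> wpow(m);
  for (int i = 0; i < m; ++i) wpow[i] = dd_from(w[i]);
  for (int j = 1; j <= m; ++j) {
    dd s = dd_from(0.0);
    for (int i = 0; i < m; ++i) {
      s = dd_add(s, wpow[i]);
      wpow[i] = dd_mul(wpow[i], dd_from(w[i]));
    }
    p[j] = s;
  }
  std::vector<dd> e(m + 1, dd_from(0.0));
  e[0] = dd_from(1.0);
  for (int k = 1; k <= m; ++k) {
    dd s = dd_from(0.0);
    for (int j = 1; j <= k; ++j) {
      dd term = dd_mul(e[k - j], p[j]);
      s = dd_add(s, (j % 2 == 1) ? term : dd_neg(term));
    }
    e[k] = dd_div_d(s, (double)k);
  }
  NumericVector out(m + 1);
  for (int k = 0; k <= m; ++k) out[k] = e[k].hi + e[k].lo;
  return out;
}
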