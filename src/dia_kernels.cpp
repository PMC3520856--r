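// Direct interaction algorithm kernels: the merge-level-averaging
// convolution tree and the exact k-resolved enumeration oracle.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double LSE_CUTOFF = 50.0;

// ---------------------------------------------------------------------------
// Merge tree over the M non-selected particles (leaf order = input
// order, left branch floor(n/2)).  Internal nodes are indexed in
// pre-order; each carries the sum of indirect pair energies crossing
// its two branches, so the per-merge average cross interaction is
// cross_sum / (nA * nB).

struct TreeNode {
  int lo, mid, hi;
  int left, right;  // node ids of internal children, -1 for leaf children
};

static int build_nodes(std::vector<TreeNode>& nodes, int lo, int hi) {
  const int n = hi - lo;
  if (n == 1) return -1;
  const int id = (int)nodes.size();
  nodes.push_back({lo, lo + n / 2, hi, -1, -1});
  const int mid = lo + n / 2;
  int l = build_nodes(nodes, lo, mid);
  int r = build_nodes(nodes, mid, hi);
  nodes[id].left = l;
  nodes[id].right = r;
  return id;
}

static std::vector<double> merge_log(const std::vector<double>& la,
                                     const std::vector<double>& lb,
                                     double lx, int64_t* ops) {
  const int na = (int)la.size(), nb = (int)lb.size();
  std::vector<double> c(na + nb - 1, NEG_INF);
  for (int k = 0; k < na + nb - 1; ++k) {
    const int jlo = std::max(0, k - nb + 1), jhi = std::min(na - 1, k);
    double mx = NEG_INF;
    for (int j = jlo; j <= jhi; ++j) {
      const double s = la[j] + lb[k - j] + lx * (double)j * (double)(k - j);
      if (s > mx) mx = s;
    }
    *ops += (jhi - jlo + 1);
    if (mx == NEG_INF) continue;
    double acc = 0.0;
    const double thr = mx - LSE_CUTOFF;
    for (int j = jlo; j <= jhi; ++j) {
      const double s = la[j] + lb[k - j] + lx * (double)j * (double)(k - j);
      if (s >= thr) acc += std::exp(s - mx);
    }
    c[k] = mx + std::log(acc);
  }
  return c;
}

static std::vector<double> eval_tree(const std::vector<TreeNode>& nodes,
                                     const std::vector<double>& cross_lx,
                                     const std::vector<double>& lw, int id,
                                     int lo, int hi, int64_t* ops) {
  if (hi - lo == 1) return std::vector<double>{0.0, lw[lo]};
  const TreeNode& nd = nodes[id];
  std::vector<double> a = eval_tree(nodes, cross_lx, lw, nd.left, nd.lo, nd.mid, ops);
  std::vector<double> b = eval_tree(nodes, cross_lx, lw, nd.right, nd.mid, nd.hi, ops);
  return merge_log(a, b, cross_lx[id], ops);
}

// leaf_logw: log Boltzmann factors of the M non-selected particles.
// pair_a/pair_b: 0-based leaf positions of each indirect pair (a < b);
// pair_g: its interaction energy; inv_t = 1/(kB T).
// Returns log of the k-resolved partition contribution, k = 0..M.
// [[Rcpp::export]]
List cpp_dia_tree_log(NumericVector leaf_logw, IntegerVector pair_a,
                      IntegerVector pair_b, NumericVector pair_g,
                      double inv_t) {
  const int m = leaf_logw.size();
  std::vector<double> lw(leaf_logw.begin(), leaf_logw.end());
  if (m == 1) {
    return List::create(
        _["log_z"] = NumericVector::create(0.0, lw[0]),
        _["ops"] = 0.0);
  }
  std::vector<TreeNode> nodes;
  nodes.reserve(m);
  build_nodes(nodes, 0, m);
  // route every indirect pair to the merge where its endpoints first
  // fall on opposite branches (their lowest common ancestor)
  std::vector<double> cross_sum(nodes.size(), 0.0);
  for (int p = 0; p < pair_a.size(); ++p) {
    const int a = pair_a[p], b = pair_b[p];
    int id = 0;
    for (;;) {
      const TreeNode& nd = nodes[id];
      if (b < nd.mid) {
        id = nd.left;
      } else if (a >= nd.mid) {
        id = nd.right;
      } else {
        cross_sum[id] += pair_g[p];
        break;
      }
    }
  }
  std::vector<double> cross_lx(nodes.size());
  for (size_t i = 0; i < nodes.size(); ++i) {
    const double na = (double)(nodes[i].mid - nodes[i].lo);
    const double nb = (double)(nodes[i].hi - nodes[i].mid);
    cross_lx[i] = -(cross_sum[i] / (na * nb)) * inv_t;
  }
  int64_t ops = 0;
  std::vector<double> z = eval_tree(nodes, cross_lx, lw, 0, 0, m, &ops);
  return List::create(_["log_z"] = NumericVector(z.begin(), z.end()),
                      _["ops"] = (double)ops);
}

// ---------------------------------------------------------------------------
// Exact enumeration of all 2^n microstates, k-resolved by the count of
// non-selected particles in state 1 and split by the selected
// particle's state.  Gray-code order so each visited state differs
// from the previous by one flip.
// [[Rcpp::export]]
List cpp_partition_bruteforce(NumericVector self_e, IntegerVector pair_i,
                              IntegerVector pair_j, NumericVector pair_g,
                              int selected, double offset, double inv_t) {
  const int n = self_e.size();
  if (n > 20) stop("brute-force partition enumeration is limited to n <= 20");
  const int m = n - 1;
  // map non-selected particles to slots 0..m-1
  std::vector<int> slot_of(n, -1), part_of(m);
  {
    int s = 0;
    for (int i = 0; i < n; ++i)
      if (i != selected) { slot_of[i] = s; part_of[s] = i; ++s; }
  }
  // adjacency among non-selected slots, and couplings to the selected
  std::vector<std::vector<std::pair<int, double>>> adj(m);
  std::vector<double> sel_g(m, 0.0);
  for (int p = 0; p < pair_i.size(); ++p) {
    const int a = pair_i[p], b = pair_j[p];
    const double g = pair_g[p];
    if (a == selected) {
      sel_g[slot_of[b]] += g;
    } else if (b == selected) {
      sel_g[slot_of[a]] += g;
    } else {
      adj[slot_of[a]].push_back({slot_of[b], g});
      adj[slot_of[b]].push_back({slot_of[a], g});
    }
  }
  std::vector<double> slot_self(m);
  for (int s = 0; s < m; ++s) slot_self[s] = self_e[part_of[s]];

  const uint64_t nstates = (uint64_t)1 << m;
  std::vector<uint8_t> in_set(m, 0);

  // pass 1: minimum energy over both selected states (for stable exp)
  // pass 2: accumulate
  double e0 = 0.0, d = 0.0;  // e0: energy of the non-selected set; d: coupling to selected
  double emin = std::numeric_limits<double>::infinity();
  const double self_sel = self_e[selected];
  for (int pass = 0; pass < 2; ++pass) {
    std::fill(in_set.begin(), in_set.end(), 0);
    e0 = 0.0;
    d = 0.0;
    int k = 0;
    std::vector<double> acc0, acc1;
    if (pass == 1) {
      acc0.assign(n, 0.0);
      acc1.assign(n, 0.0);
    }
    for (uint64_t g = 0;; ++g) {
      const double ea = offset + e0;              // selected in state 0
      const double eb = ea + self_sel + d;        // selected in state 1
      if (pass == 0) {
        if (ea < emin) emin = ea;
        if (eb < emin) emin = eb;
      } else {
        acc0[k] += std::exp(-(ea - emin) * inv_t);
        acc1[k] += std::exp(-(eb - emin) * inv_t);
      }
      if (g + 1 >= nstates) break;
      // flip the bit that changes between gray(g) and gray(g+1)
      const uint64_t diff = (g + 1) & ~g;  // lowest zero-run carry bit
      int bit = 0;
      uint64_t t = diff;
      while (t > 1) { t >>= 1; ++bit; }
      double de = slot_self[bit];
      for (const auto& nb : adj[bit])
        if (in_set[nb.first]) de += nb.second;
      if (in_set[bit]) {
        e0 -= de;
        d -= sel_g[bit];
        in_set[bit] = 0;
        --k;
      } else {
        e0 += de;
        d += sel_g[bit];
        in_set[bit] = 1;
        ++k;
      }
    }
    if (pass == 1) {
      NumericVector lz0(n), lz1(n);
      for (int kk = 0; kk < n; ++kk) {
        lz0[kk] = acc0[kk] > 0.0 ? std::log(acc0[kk]) - emin * inv_t : NEG_INF;
        lz1[kk] = acc1[kk] > 0.0 ? std::log(acc1[kk]) - emin * inv_t : NEG_INF;
      }
      return List::create(_["log_z0"] = lz0, _["log_z1"] = lz1);
    }
  }
  return List::create();  // unreachable
}
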