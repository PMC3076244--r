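#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// Canonical certificate of a small labeled graph via color refinement with
// individualization on ties. Substructures are tiny (tens of vertices), so
// the worst-case branching is irrelevant in practice; what matters is that
// isomorphic labeled graphs always map to the same string.

namespace {

struct LGraph {
  int n;
  std::vector<int> nlab;                              // node label ranks
  std::vector<std::array<int, 3>> edges;              // u, v, elab rank
  std::vector<std::vector<std::pair<int, int>>> adj;  // (elab, nbr)
};

// 1-WL refinement: split color classes by the multiset of (edge label,
// neighbor color) pairs until the partition stabilizes.
void refine(const LGraph& g, std::vector<int>& col) {
  const int n = g.n;
  int ncls = 0;
  {
    std::vector<int> u(col);
    std::sort(u.begin(), u.end());
    ncls = (int)(std::unique(u.begin(), u.end()) - u.begin());
  }
  while (true) {
    std::vector<std::string> sig(n);
    for (int v = 0; v < n; ++v) {
      std::vector<std::pair<int, int>> nb;
      nb.reserve(g.adj[v].size());
      for (const auto& e : g.adj[v]) nb.emplace_back(e.first, col[e.second]);
      std::sort(nb.begin(), nb.end());
      std::string s = std::to_string(col[v]);
      for (const auto& p : nb) {
        s += '|';
        s += std::to_string(p.first);
        s += ':';
        s += std::to_string(p.second);
      }
      sig[v] = std::move(s);
    }
    std::vector<std::string> uniq(sig);
    std::sort(uniq.begin(), uniq.end());
    uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
    const int newcls = (int)uniq.size();
    for (int v = 0; v < n; ++v)
      col[v] = (int)(std::lower_bound(uniq.begin(), uniq.end(), sig[v]) -
                     uniq.begin());
    if (newcls == ncls) break;
    ncls = newcls;
  }
}

bool discrete(const std::vector<int>& col) {
  std::vector<int> u(col);
  std::sort(u.begin(), u.end());
  return std::unique(u.begin(), u.end()) - u.begin() == (long)u.size();
}

std::string emit(const LGraph& g, const std::vector<int>& col) {
  const int n = g.n;
  std::vector<int> pos(n);  // pos[v] = canonical index of v
  for (int v = 0; v < n; ++v) pos[v] = col[v];
  std::vector<int> order(n);
  for (int v = 0; v < n; ++v) order[col[v]] = v;
  std::string s = "V";
  for (int i = 0; i < n; ++i) {
    s += ',';
    s += std::to_string(g.nlab[order[i]]);
  }
  std::vector<std::array<int, 3>> es;
  es.reserve(g.edges.size());
  for (const auto& e : g.edges) {
    int a = pos[e[0]], b = pos[e[1]];
    if (a > b) std::swap(a, b);
    es.push_back({a, b, e[2]});
  }
  std::sort(es.begin(), es.end());
  s += ";E";
  for (const auto& e : es) {
    s += ',';
    s += std::to_string(e[0]);
    s += '-';
    s += std::to_string(e[1]);
    s += ':';
    s += std::to_string(e[2]);
  }
  return s;
}

std::string canon(const LGraph& g, std::vector<int> col, int depth_guard) {
  refine(g, col);
  if (discrete(col)) return emit(g, col);
  if (depth_guard > 64) stop("canonical labeling recursion limit exceeded");
  // smallest non-singleton color class, by color value
  const int n = g.n;
  std::vector<int> cnt(n, 0);
  for (int v = 0; v < n; ++v) cnt[col[v]]++;
  int target = -1;
  for (int c = 0; c < n; ++c)
    if (cnt[c] > 1) {
      target = c;
      break;
    }
  std::string best;
  for (int v = 0; v < n; ++v) {
    if (col[v] != target) continue;
    std::vector<int> col2(col);
    col2[v] = n;  // fresh color; refine() re-ranks densely
    std::string cert = canon(g, col2, depth_guard + 1);
    if (best.empty() || cert < best) best = std::move(cert);
  }
  return best;
}

int rank_of(const std::vector<std::string>& uniq, const std::string& s) {
  return (int)(std::lower_bound(uniq.begin(), uniq.end(), s) - uniq.begin());
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".canonical_certificate_cpp")]]
std::string canonical_certificate_cpp(CharacterVector node_labels,
                                      IntegerMatrix edges,
                                      CharacterVector edge_labels) {
  const int n = node_labels.size();
  const int m = edges.nrow();
  if ((int)edge_labels.size() != m) stop("edge label / edge count mismatch");

  std::vector<std::string> nl(n), el(m);
  for (int i = 0; i < n; ++i) nl[i] = as<std::string>(node_labels[i]);
  for (int i = 0; i < m; ++i) el[i] = as<std::string>(edge_labels[i]);

  std::vector<std::string> nuniq(nl), euniq(el);
  std::sort(nuniq.begin(), nuniq.end());
  nuniq.erase(std::unique(nuniq.begin(), nuniq.end()), nuniq.end());
  std::sort(euniq.begin(), euniq.end());
  euniq.erase(std::unique(euniq.begin(), euniq.end()), euniq.end());

  LGraph g;
  g.n = n;
  g.nlab.resize(n);
  g.adj.assign(n, {});
  for (int i = 0; i < n; ++i) g.nlab[i] = rank_of(nuniq, nl[i]);
  for (int i = 0; i < m; ++i) {
    int u = edges(i, 0), v = edges(i, 1);
    if (u < 0 || v < 0 || u >= n || v >= n) stop("edge index out of range");
    int er = rank_of(euniq, el[i]);
    g.edges.push_back({u, v, er});
    g.adj[u].emplace_back(er, v);
    g.adj[v].emplace_back(er, u);
  }

  std::vector<int> col(g.nlab);
  std::string body = canon(g, col, 0);

  // header pins the actual label strings so distinct chemistry never
  // collapses onto the same rank pattern
  std::string h = "G" + std::to_string(n) + ";L[";
  for (size_t i = 0; i < nuniq.size(); ++i) {
    if (i) h += ',';
    h += nuniq[i];
  }
  h += "];B[";
  for (size_t i = 0; i < euniq.size(); ++i) {
    if (i) h += ',';
    h += euniq[i];
  }
  h += "];";
  return h + body;
}

//' @noRd
// [[Rcpp::export(name = ".fnv1a_hash_cpp")]]
double fnv1a_hash_cpp(CharacterVector encodings, int bits) {
  if (bits < 1 || bits > 32) stop("hash_bits must be in [1, 32]");
  const uint64_t mask =
      (bits >= 64) ? ~0ULL : ((1ULL << (unsigned)bits) - 1ULL);
  if (encodings.size() != 1) stop("one encoding at a time");
  std::string s = as<std::string>(encodings[0]);
  uint64_t h = 0xcbf29ce484222325ULL;  // FNV-1a 64-bit offset basis
  for (unsigned char c : s) {
    h ^= (uint64_t)c;
    h *= 1099511628211ULL;
  }
  return (double)(h & mask);
}

// ------------------------------------------------------------------
// Dual coordinate descent for L2-regularized L1-loss (hinge) linear SVC
// on binary 0/1 features; the classical liblinear algorithm with per-class
// costs and an optional bias handled as an augmented constant feature.
// ------------------------------------------------------------------

namespace {
// deterministic xorshift64 RNG so fits are identical across platforms
struct XS64 {
  uint64_t s;
  explicit XS64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};
}  // namespace

//' @noRd
// [[Rcpp::export(name = ".dcd_svm_cpp")]]
List dcd_svm_cpp(List rows, IntegerVector y, int nfeat, double Cpos,
                 double Cneg, bool bias_term, double eps, int max_iter,
                 int seed) {
  const int l = rows.size();
  if (y.size() != l) stop("label / row count mismatch");
  const int dim = nfeat + (bias_term ? 1 : 0);

  std::vector<std::vector<int>> X(l);
  std::vector<double> Qii(l), Ci(l);
  for (int i = 0; i < l; ++i) {
    IntegerVector r = rows[i];
    X[i].assign(r.begin(), r.end());
    for (int c : X[i])
      if (c < 0 || c >= nfeat) stop("feature index out of range");
    Qii[i] = (double)X[i].size() + (bias_term ? 1.0 : 0.0);
    if (Qii[i] == 0.0) Qii[i] = 1.0;  // empty row, bias-less: inert
    Ci[i] = (y[i] > 0) ? Cpos : Cneg;
  }

  std::vector<double> w(dim, 0.0), alpha(l, 0.0);
  std::vector<int> idx(l);
  for (int i = 0; i < l; ++i) idx[i] = i;
  XS64 rng((uint64_t)seed * 2654435761ULL + 1ULL);

  int iter = 0;
  double viol = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    // Fisher-Yates shuffle
    for (int i = l - 1; i > 0; --i) std::swap(idx[i], idx[rng.below(i + 1)]);
    double PGmax = -1e300, PGmin = 1e300;
    for (int k = 0; k < l; ++k) {
      const int i = idx[k];
      double wx = 0.0;
      for (int c : X[i]) wx += w[c];
      if (bias_term) wx += w[nfeat];
      const double G = (double)y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) PG = std::min(G, 0.0);
      else if (alpha[i] >= Ci[i]) PG = std::max(G, 0.0);
      PGmax = std::max(PGmax, PG);
      PGmin = std::min(PGmin, PG);
      if (std::fabs(PG) > 1e-12) {
        const double a_old = alpha[i];
        double a_new = a_old - G / Qii[i];
        a_new = std::min(std::max(a_new, 0.0), Ci[i]);
        const double d = (a_new - a_old) * (double)y[i];
        if (d != 0.0) {
          for (int c : X[i]) w[c] += d;
          if (bias_term) w[nfeat] += d;
          alpha[i] = a_new;
        }
      }
    }
    viol = PGmax - PGmin;
    if (viol < eps) {
      ++iter;
      break;
    }
  }

  NumericVector wout(nfeat);
  for (int j = 0; j < nfeat; ++j) wout[j] = w[j];
  const double bias = bias_term ? w[nfeat] : 0.0;
  NumericVector fx(l);
  for (int i = 0; i < l; ++i) {
    double wx = 0.0;
    for (int c : X[i]) wx += w[c];
    fx[i] = wx + bias;
  }
  return List::create(
      Named("weights") = wout, Named("bias") = bias,
      Named("decision_values") = fx, Named("iterations") = iter,
      Named("max_violation") = viol,
      Named("converged") = (viol < eps));
}
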