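#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// All-pairs shortest path lengths by Dijkstra from every source.
// `len` holds connection lengths (1/weight); entries that are zero,
// negative or non-finite are treated as absent edges. Unreachable
// pairs come back as Inf.
// [[Rcpp::export]]
NumericMatrix cpp_shortest_paths(NumericMatrix len) {
  const int n = len.nrow();
  if (len.ncol() != n) stop("length matrix must be square");
  NumericMatrix D(n, n);
  std::vector<double> dist(n);
  std::vector<bool> done(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(done.begin(), done.end(), false);
    dist[s] = 0.0;
    for (int it = 0; it < n; ++it) {
      int u = -1;
      double best = R_PosInf;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = true;
      for (int v = 0; v < n; ++v) {
        if (done[v] || v == u) continue;
        double w = len(u, v);
        if (R_FINITE(w) && w > 0.0 && dist[u] + w < dist[v]) dist[v] = dist[u] + w;
      }
    }
    for (int v = 0; v < n; ++v) D(s, v) = dist[v];
  }
  return D;
}

// Newman-Girvan weighted modularity of a partition at resolution gamma.
static double modularity_of(const NumericMatrix& W, const std::vector<int>& memb,
                            double gamma, double two_m) {
  const int n = W.nrow();
  int k = 0;
  for (int i = 0; i < n; ++i) k = std::max(k, memb[i] + 1);
  std::vector<double> win(k, 0.0), wtot(k, 0.0);
  for (int i = 0; i < n; ++i) {
    double ki = 0.0;
    for (int j = 0; j < n; ++j) {
      ki += W(i, j);
      if (memb[i] == memb[j]) win[memb[i]] += W(i, j);
    }
    wtot[memb[i]] += ki;
  }
  double Q = 0.0;
  for (int c = 0; c < k; ++c)
    Q += win[c] / two_m - gamma * (wtot[c] / two_m) * (wtot[c] / two_m);
  return Q;
}

// One greedy Louvain run over a randomised node order. The aggregated
// graph keeps internal weight (doubled) on the diagonal so that node
// strengths and 2m are invariant across levels.
static std::vector<int> louvain_once(const NumericMatrix& W, double gamma,
                                     double two_m) {
  const int n0 = W.nrow();
  int n = n0;
  std::vector<double> A(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) A[static_cast<size_t>(i) * n + j] = W(i, j);
  std::vector<int> node2final(n0);
  for (int i = 0; i < n0; ++i) node2final[i] = i;

  bool levelImproved = true;
  while (levelImproved) {
    std::vector<double> strength(n, 0.0);
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += A[static_cast<size_t>(i) * n + j];
      strength[i] = s;
    }
    std::vector<int> comm(n);
    for (int i = 0; i < n; ++i) comm[i] = i;
    std::vector<double> wtot(strength);

    bool moved = true;
    bool anyMove = false;
    std::vector<double> links(n);
    while (moved) {
      moved = false;
      IntegerVector ord = sample(n, n, false);  // R RNG: seeded from R side
      for (int oi = 0; oi < n; ++oi) {
        int i = ord[oi] - 1;
        std::fill(links.begin(), links.end(), 0.0);
        for (int j = 0; j < n; ++j)
          if (j != i) links[comm[j]] += A[static_cast<size_t>(i) * n + j];
        int c0 = comm[i];
        wtot[c0] -= strength[i];
        double stay = links[c0] - gamma * strength[i] * wtot[c0] / two_m;
        // random improving move (not best-gain): diversifies the local
        // optima reached across restarts
        int chosen = c0;
        int nImp = 0;
        for (int c = 0; c < n; ++c) {
          if (c == c0) continue;
          double g = links[c] - gamma * strength[i] * wtot[c] / two_m;
          if (g > stay + 1e-12) {
            ++nImp;
            if (unif_rand() < 1.0 / nImp) chosen = c;
          }
        }
        comm[i] = chosen;
        wtot[chosen] += strength[i];
        if (chosen != c0) { moved = true; anyMove = true; }
      }
    }

    // relabel communities consecutively
    std::vector<int> relab(n, -1);
    int k = 0;
    for (int i = 0; i < n; ++i)
      if (relab[comm[i]] < 0) relab[comm[i]] = k++;
    for (int i = 0; i < n; ++i) comm[i] = relab[comm[i]];
    for (int i = 0; i < n0; ++i) node2final[i] = comm[node2final[i]];

    if (!anyMove || k == n) break;

    // aggregate
    std::vector<double> B(static_cast<size_t>(k) * k, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        B[static_cast<size_t>(comm[i]) * k + comm[j]] += A[static_cast<size_t>(i) * n + j];
    A.swap(B);
    n = k;
    levelImproved = true;
  }
  return node2final;
}

// Single-node refinement on the original graph: best-gain moves between
// existing communities (or out to an empty one) until no move improves.
// Escapes local optima created by the aggregation phase.
static void refine_local(const NumericMatrix& W, std::vector<int>& memb,
                         double gamma, double two_m) {
  const int n = W.nrow();
  std::vector<double> strength(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) strength[i] += W(i, j);
  std::vector<double> wtot(n, 0.0);
  for (int i = 0; i < n; ++i) wtot[memb[i]] += strength[i];
  std::vector<double> links(n);
  bool moved = true;
  while (moved) {
    moved = false;
    for (int i = 0; i < n; ++i) {
      std::fill(links.begin(), links.end(), 0.0);
      for (int j = 0; j < n; ++j)
        if (j != i) links[memb[j]] += W(i, j);
      int c0 = memb[i];
      wtot[c0] -= strength[i];
      // find an empty community slot so splits are reachable
      int empty = -1;
      for (int c = 0; c < n; ++c)
        if (wtot[c] == 0.0 && links[c] == 0.0 && c != c0) { empty = c; break; }
      double bestGain = links[c0] - gamma * strength[i] * wtot[c0] / two_m;
      int bestC = c0;
      for (int c = 0; c < n; ++c) {
        if (c == c0) continue;
        if (wtot[c] == 0.0 && c != empty) continue;
        double g = links[c] - gamma * strength[i] * wtot[c] / two_m;
        if (g > bestGain + 1e-12) { bestGain = g; bestC = c; }
      }
      memb[i] = bestC;
      wtot[bestC] += strength[i];
      if (bestC != c0) moved = true;
    }
  }
  // relabel consecutively
  std::vector<int> relab(n, -1);
  int k = 0;
  for (int i = 0; i < n; ++i)
    if (relab[memb[i]] < 0) relab[memb[i]] = k++;
  for (int i = 0; i < n; ++i) memb[i] = relab[memb[i]];
}

// Best-of-n_restarts Louvain modularity maximisation; returns the
// highest Q found with its membership (1-based).
// [[Rcpp::export]]
List cpp_louvain(NumericMatrix W, double gamma, int n_restarts) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  double two_m = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) two_m += W(i, j);
  if (two_m <= 0.0) stop("graph has no edges");
  double bestQ = R_NegInf;
  IntegerVector bestMemb(n);
  for (int r = 0; r < n_restarts; ++r) {
    std::vector<int> memb = louvain_once(W, gamma, two_m);
    // iterated local search: alternate single-node refinement on the
    // original graph with Louvain passes on the community graph until
    // the partition stops improving
    double Qcur = R_NegInf;
    for (int it = 0; it < 50; ++it) {
      refine_local(W, memb, gamma, two_m);
      int k = 0;
      for (int i = 0; i < n; ++i) k = std::max(k, memb[i] + 1);
      if (k > 1) {
        NumericMatrix B(k, k);
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < n; ++j) B(memb[i], memb[j]) += W(i, j);
        std::vector<int> am = louvain_once(B, gamma, two_m);
        for (int i = 0; i < n; ++i) memb[i] = am[memb[i]];
      }
      double Qnew = modularity_of(W, memb, gamma, two_m);
      if (Qnew <= Qcur + 1e-12) break;
      Qcur = Qnew;
    }
    refine_local(W, memb, gamma, two_m);
    double Q = modularity_of(W, memb, gamma, two_m);
    if (Q > bestQ + 1e-12) {
      bestQ = Q;
      for (int i = 0; i < n; ++i) bestMemb[i] = memb[i] + 1;
    }
  }
  return List::create(_["Q"] = bestQ, _["membership"] = bestMemb);
}
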