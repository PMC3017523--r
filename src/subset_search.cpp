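// Compiled kernels for the model-space search. Both operate on centered
// cross-products (G = X'X, g = X'y, yy = y'y after mean removal), so the
// intercept is implicit and the RSS of a subset S is yy - g_S' G_S^{-1} g_S.
#include <RcppArmadillo.h>
#include <queue>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double subset_rss(const arma::mat& G, const arma::vec& g, double yy,
                         const arma::uvec& S) {
  arma::vec b;
  bool ok = arma::solve(b, G.submat(S, S), g.elem(S),
                        arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
  if (!ok) return R_PosInf;  // singular subset: treated as unusable
  double rss = yy - arma::dot(g.elem(S), b);
  return rss < 0.0 ? 0.0 : rss;
}

// Enumerate all predictor subsets of sizes 0..kmax and keep, per size, the
// nbest with smallest RSS. Lexicographic enumeration; on RSS ties the
// lexicographically first (lowest-index) subset wins, making the output
// deterministic. Returns a list indexed by size with elements
// `subsets` (m x k matrix of 1-based indices, rows sorted by RSS) and `rss`.
// [[Rcpp::export]]
List subset_search_cpp(const arma::mat& G, const arma::vec& g, double yy,
                       int kmax, int nbest) {
  const int p = G.n_rows;
  if (kmax < 0) kmax = 0;
  if (kmax > p) kmax = p;
  List out(kmax + 1);
  out[0] = List::create(_["subsets"] = IntegerMatrix(1, 0),
                        _["rss"] = NumericVector::create(yy));
  typedef std::pair<double, std::vector<int> > Entry;
  for (int k = 1; k <= kmax; ++k) {
    std::priority_queue<Entry> heap;  // max-heap: top is worst kept
    std::vector<int> idx(k);
    for (int i = 0; i < k; ++i) idx[i] = i;
    arma::uvec S(k);
    for (;;) {
      for (int i = 0; i < k; ++i) S[i] = idx[i];
      double rss = subset_rss(G, g, yy, S);
      if ((int)heap.size() < nbest) {
        heap.push(Entry(rss, idx));
      } else if (rss < heap.top().first) {
        heap.pop();
        heap.push(Entry(rss, idx));
      }
      int i = k - 1;
      while (i >= 0 && idx[i] == p - k + i) --i;
      if (i < 0) break;
      ++idx[i];
      for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
      if (k > 64) Rcpp::checkUserInterrupt();  // unreachable guard
    }
    const int m = heap.size();
    IntegerMatrix subs(m, k);
    NumericVector rssv(m);
    for (int r = m - 1; r >= 0; --r) {
      rssv[r] = heap.top().first;
      const std::vector<int>& v = heap.top().second;
      for (int c = 0; c < k; ++c) subs(r, c) = v[c] + 1;
      heap.pop();
    }
    out[k] = List::create(_["subsets"] = subs, _["rss"] = rssv);
  }
  return out;
}

// Greedy forward path: at each step add the candidate minimizing the RSS
// (equivalently, minimizing any size-penalized criterion among same-size
// additions). Ties break to the lowest variable index. Returns the full
// p-step path; the caller truncates it by the AIC stopping rule.
// [[Rcpp::export]]
List forward_rss_cpp(const arma::mat& G, const arma::vec& g, double yy) {
  const int p = G.n_rows;
  std::vector<int> active;
  std::vector<int> order;
  std::vector<double> rss_path;
  std::vector<bool> in(p, false);
  active.reserve(p); order.reserve(p); rss_path.reserve(p);
  for (int step = 0; step < p; ++step) {
    double best = R_PosInf;
    int bestj = -1;
    arma::uvec S(active.size() + 1);
    for (size_t i = 0; i < active.size(); ++i) S[i] = active[i];
    for (int j = 0; j < p; ++j) {
      if (in[j]) continue;
      S[active.size()] = j;
      double rss = subset_rss(G, g, yy, S);
      if (rss < best) { best = rss; bestj = j; }
    }
    if (bestj < 0) break;  // all remaining candidates singular
    in[bestj] = true;
    active.push_back(bestj);
    order.push_back(bestj + 1);
    rss_path.push_back(best);
  }
  return List::create(_["order"] = wrap(order), _["rss"] = wrap(rss_path));
}
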