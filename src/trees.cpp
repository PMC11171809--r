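// Greedy CART trees with per-split random feature subsetting, plus bagged
// forests. All randomness comes from R's RNG so fits are reproducible under
// set.seed(). Trees are flattened to parallel arrays for cheap serialization.
#include <Rcpp.h>
#include <algorithm>
#include <limits>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;  // -1 => leaf
  double thr = 0.0;
  int left = -1, right = -1;
  std::vector<double> value;  // k=1 mean (regression) or k class proportions
};

struct Builder {
  const NumericMatrix &X;
  const NumericVector &y;  // class labels 0..k-1 when classif
  bool classif;
  int n_class, max_depth, min_node, mtry;
  const std::vector<int> &cand;
  std::vector<Node> nodes;

  Builder(const NumericMatrix &X_, const NumericVector &y_, bool cl, int k,
          int md, int mn, int mt, const std::vector<int> &cand_)
      : X(X_), y(y_), classif(cl), n_class(k), max_depth(md), min_node(mn),
        mtry(mt), cand(cand_) {}

  std::vector<double> leaf_value(const std::vector<int> &rows) const {
    if (classif) {
      std::vector<double> p(n_class, 0.0);
      for (int r : rows) p[(int)y[r]] += 1.0;
      for (double &v : p) v /= (double)rows.size();
      return p;
    }
    double s = 0.0;
    for (int r : rows) s += y[r];
    return std::vector<double>(1, s / (double)rows.size());
  }

  int build(std::vector<int> &rows, int depth) {
    const int id = (int)nodes.size();
    nodes.push_back(Node());
    nodes[id].value = leaf_value(rows);
    const int n = (int)rows.size();
    if (depth >= max_depth || n < 2 * min_node) return id;

    // sample mtry candidate features without replacement
    std::vector<int> feats = cand;
    const int m = std::min<int>(mtry, (int)feats.size());
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(unif_rand() * (double)(feats.size() - i));
      if (j >= (int)feats.size()) j = (int)feats.size() - 1;
      std::swap(feats[i], feats[j]);
    }

    int best_f = -1;
    double best_thr = 0.0;
    double best_score = -std::numeric_limits<double>::infinity();
    std::vector<std::pair<double, int> > xv(n);

    for (int fi = 0; fi < m; ++fi) {
      const int f = feats[fi];
      for (int i = 0; i < n; ++i) xv[i] = std::make_pair(X(rows[i], f), rows[i]);
      std::sort(xv.begin(), xv.end());
      if (xv.front().first == xv.back().first) continue;
      if (classif) {
        std::vector<double> cl(n_class, 0.0), cr(n_class, 0.0);
        for (int i = 0; i < n; ++i) cr[(int)y[xv[i].second]] += 1.0;
        for (int i = 0; i < n - 1; ++i) {
          const int c = (int)y[xv[i].second];
          cl[c] += 1.0;
          cr[c] -= 1.0;
          const int nl = i + 1, nr = n - nl;
          if (nl < min_node || nr < min_node) continue;
          if (xv[i].first == xv[i + 1].first) continue;
          double sl = 0.0, sr = 0.0;
          for (int k = 0; k < n_class; ++k) {
            sl += cl[k] * cl[k];
            sr += cr[k] * cr[k];
          }
          const double score = sl / nl + sr / nr;  // == n - weighted Gini
          if (score > best_score + 1e-12) {
            best_score = score;
            best_f = f;
            best_thr = (xv[i].first + xv[i + 1].first) / 2.0;
          }
        }
      } else {
        double suml = 0.0, sumr = 0.0;
        for (int i = 0; i < n; ++i) sumr += y[xv[i].second];
        for (int i = 0; i < n - 1; ++i) {
          const double v = y[xv[i].second];
          suml += v;
          sumr -= v;
          const int nl = i + 1, nr = n - nl;
          if (nl < min_node || nr < min_node) continue;
          if (xv[i].first == xv[i + 1].first) continue;
          const double score = suml * suml / nl + sumr * sumr / nr;
          if (score > best_score + 1e-12) {
            best_score = score;
            best_f = f;
            best_thr = (xv[i].first + xv[i + 1].first) / 2.0;
          }
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> lrows, rrows;
    lrows.reserve(n);
    rrows.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(rows[i], best_f) <= best_thr)
        lrows.push_back(rows[i]);
      else
        rrows.push_back(rows[i]);
    }
    if (lrows.empty() || rrows.empty()) return id;  // numeric degeneracy guard
    const int l = build(lrows, depth + 1);
    const int r = build(rrows, depth + 1);
    nodes[id].feat = best_f;
    nodes[id].thr = best_thr;
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }
};

List flatten(const std::vector<Node> &nodes, int k) {
  const int n = (int)nodes.size();
  IntegerVector feat(n), left(n), right(n);
  NumericVector thr(n);
  NumericMatrix val(n, k);
  for (int i = 0; i < n; ++i) {
    feat[i] = nodes[i].feat;
    thr[i] = nodes[i].thr;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    for (int j = 0; j < k; ++j) val(i, j) = nodes[i].value[j];
  }
  return List::create(Named("feat") = feat, Named("thr") = thr,
                      Named("left") = left, Named("right") = right,
                      Named("value") = val);
}

void predict_one_tree(const List &tree, const NumericMatrix &X,
                      NumericMatrix &out, double w) {
  IntegerVector feat = tree["feat"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["thr"];
  NumericMatrix val = tree["value"];
  const int k = val.ncol();
  for (int i = 0; i < X.nrow(); ++i) {
    int node = 0;
    while (feat[node] >= 0)
      node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
    for (int j = 0; j < k; ++j) out(i, j) += w * val(node, j);
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_fit_tree")]]
List cpp_fit_tree(NumericMatrix X, NumericVector y, bool classif, int n_class,
                  int max_depth, int min_node, int mtry, IntegerVector rows,
                  IntegerVector cand) {
  std::vector<int> rws(rows.begin(), rows.end());
  std::vector<int> cnd(cand.begin(), cand.end());
  Builder b(X, y, classif, n_class, max_depth, min_node, mtry, cnd);
  std::vector<int> r0 = rws;
  b.build(r0, 0);
  return flatten(b.nodes, classif ? n_class : 1);
}

// [[Rcpp::export(name = ".cpp_fit_forest")]]
List cpp_fit_forest(NumericMatrix X, NumericVector y, bool classif,
                    int n_class, int n_trees, int max_depth, int min_node,
                    int mtry, bool bootstrap) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> cand(p);
  for (int j = 0; j < p; ++j) cand[j] = j;
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> rows(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int j = (int)(unif_rand() * (double)n);
        rows[i] = (j >= n) ? n - 1 : j;
      }
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    Builder b(X, y, classif, n_class, max_depth, min_node, mtry, cand);
    b.build(rows, 0);
    forest[t] = flatten(b.nodes, classif ? n_class : 1);
  }
  return forest;
}

// [[Rcpp::export(name = ".cpp_predict_tree")]]
NumericMatrix cpp_predict_tree(List tree, NumericMatrix X) {
  NumericMatrix val = tree["value"];
  NumericMatrix out(X.nrow(), val.ncol());
  predict_one_tree(tree, X, out, 1.0);
  return out;
}

// [[Rcpp::export(name = ".cpp_predict_forest")]]
NumericMatrix cpp_predict_forest(List forest, NumericMatrix X, int k) {
  NumericMatrix out(X.nrow(), k);
  const int T = forest.size();
  for (int t = 0; t < T; ++t) predict_one_tree(forest[t], X, out, 1.0 / T);
  return out;
}
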