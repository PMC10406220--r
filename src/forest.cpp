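// Bagged classification trees with CART-style surrogate splits.
//
// Binary classification only (y in {0, 1}; 1 = patient class). Trees are grown
// to purity on bootstrap samples, with `mtry` features drawn at each node and
// the Gini-best threshold chosen among rows where the candidate is observed.
// Missing values are routed by ranked surrogate splits (Breiman et al. CART
// convention) and, failing all surrogates, by the majority child. All
// randomness comes from R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Surrogate {
  int feature;      // 0-based
  double threshold;
  int dir;          // +1: value <= threshold goes with primary-left; -1: opposite
  double agreement;
};

struct TreeBuild {
  std::vector<int> feature;        // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;    // -1 for leaf
  std::vector<double> n0, n1;      // in-bag class counts (with multiplicity)
  std::vector<int> fallback;       // 0 = left, 1 = right
  std::vector<std::vector<Surrogate> > surr;
  int new_node() {
    feature.push_back(-1); threshold.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1);
    n0.push_back(0.0); n1.push_back(0.0);
    fallback.push_back(0);
    surr.push_back(std::vector<Surrogate>());
    return (int)feature.size() - 1;
  }
};

inline bool obs(double v) { return !ISNAN(v); }

inline double gini(double c0, double c1) {
  double n = c0 + c1;
  if (n <= 0) return 0.0;
  double p0 = c0 / n, p1 = c1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

// Draw k distinct integers from 0..(p-1) via partial Fisher-Yates (R RNG).
void sample_features(int p, int k, std::vector<int>& pool, std::vector<int>& out) {
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)std::floor(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

struct BestSplit {
  int feature = -1;
  double threshold = NA_REAL;
  double decrease = 0.0;
  bool found = false;
};

// Best Gini split for one feature among rows where it is observed.
// Impurity decrease is scaled by the observed fraction of node rows.
void best_split_for_feature(const NumericMatrix& X, const IntegerVector& y,
                            const std::vector<int>& rows, int f,
                            BestSplit& best) {
  std::vector<std::pair<double,int> > xy;
  xy.reserve(rows.size());
  for (size_t i = 0; i < rows.size(); ++i) {
    double v = X(rows[i], f);
    if (obs(v)) xy.push_back(std::make_pair(v, y[rows[i]]));
  }
  size_t m = xy.size();
  if (m < 2) return;
  std::sort(xy.begin(), xy.end());
  if (xy.front().first == xy.back().first) return;
  double tot1 = 0.0;
  for (size_t i = 0; i < m; ++i) tot1 += xy[i].second;
  double tot0 = (double)m - tot1;
  double gp = gini(tot0, tot1);
  double n_node = (double)rows.size();
  double c1 = 0.0;
  for (size_t i = 0; i + 1 < m; ++i) {
    c1 += xy[i].second;
    if (xy[i].first == xy[i + 1].first) continue;
    double nl = (double)(i + 1), nr = (double)m - nl;
    double l1 = c1, l0 = nl - c1;
    double r1 = tot1 - c1, r0 = nr - (tot1 - c1);
    double dec = ((double)m / n_node) *
      (gp - (nl / (double)m) * gini(l0, l1) - (nr / (double)m) * gini(r0, r1));
    if (dec > best.decrease + 1e-12 ||
        (!best.found && dec > 1e-12)) {
      best.found = true;
      best.decrease = dec;
      best.feature = f;
      best.threshold = (xy[i].first + xy[i + 1].first) / 2.0;
    }
  }
}

// Surrogate search: for each other feature, the (threshold, direction)
// maximizing agreement with the primary split over rows where both are
// observed; kept only if it beats the majority-direction baseline.
void find_surrogates(const NumericMatrix& X, const std::vector<int>& rows,
                     int f_primary, double t_primary, int max_surrogates,
                     std::vector<Surrogate>& out) {
  int p = X.ncol();
  std::vector<Surrogate> cand;
  for (int s = 0; s < p; ++s) {
    if (s == f_primary) continue;
    // rows with both features observed; primary-left indicator
    std::vector<std::pair<double,int> > sv;  // (surrogate value, goes_left)
    for (size_t i = 0; i < rows.size(); ++i) {
      double vp = X(rows[i], f_primary), vs = X(rows[i], s);
      if (obs(vp) && obs(vs))
        sv.push_back(std::make_pair(vs, vp <= t_primary ? 1 : 0));
    }
    size_t m = sv.size();
    if (m < 2) continue;
    std::sort(sv.begin(), sv.end());
    if (sv.front().first == sv.back().first) continue;
    double nLb = 0.0;
    for (size_t i = 0; i < m; ++i) nLb += sv[i].second;
    double nRb = (double)m - nLb;
    double baseline = std::max(nLb, nRb) / (double)m;
    double bestAg = -1.0, bestThr = NA_REAL;
    int bestDir = 1;
    double cL = 0.0;
    for (size_t i = 0; i + 1 < m; ++i) {
      cL += sv[i].second;
      if (sv[i].first == sv[i + 1].first) continue;
      double nle = (double)(i + 1);
      double agPlus  = (cL + (nRb - (nle - cL))) / (double)m;
      double agMinus = ((nle - cL) + (nLb - cL)) / (double)m;
      if (agPlus > bestAg) { bestAg = agPlus; bestThr = (sv[i].first + sv[i+1].first) / 2.0; bestDir = 1; }
      if (agMinus > bestAg) { bestAg = agMinus; bestThr = (sv[i].first + sv[i+1].first) / 2.0; bestDir = -1; }
    }
    if (bestAg > baseline + 1e-12) {
      Surrogate sg; sg.feature = s; sg.threshold = bestThr;
      sg.dir = bestDir; sg.agreement = bestAg;
      cand.push_back(sg);
    }
  }
  std::stable_sort(cand.begin(), cand.end(),
                   [](const Surrogate& a, const Surrogate& b) {
                     if (a.agreement != b.agreement) return a.agreement > b.agreement;
                     return a.feature < b.feature;
                   });
  if ((int)cand.size() > max_surrogates) cand.resize(max_surrogates);
  out = cand;
}

// Route one node-resident row: primary, then surrogates, then fallback.
// Returns 0 = left, 1 = right.
inline int route_row(const NumericMatrix& X, int row, int f, double thr,
                     const std::vector<Surrogate>& surr, int fallback) {
  double v = X(row, f);
  if (obs(v)) return v <= thr ? 0 : 1;
  for (size_t k = 0; k < surr.size(); ++k) {
    double vs = X(row, surr[k].feature);
    if (obs(vs)) {
      bool le = vs <= surr[k].threshold;
      bool goLeft = (surr[k].dir == 1) ? le : !le;
      return goLeft ? 0 : 1;
    }
  }
  return fallback;
}

void grow(TreeBuild& tb, int node, std::vector<int> rows,
          const NumericMatrix& X, const IntegerVector& y,
          int mtry, int max_surrogates,
          std::vector<int>& pool, std::vector<int>& feat_buf) {
  double c0 = 0.0, c1 = 0.0;
  for (size_t i = 0; i < rows.size(); ++i) {
    if (y[rows[i]] == 1) c1 += 1.0; else c0 += 1.0;
  }
  tb.n0[node] = c0; tb.n1[node] = c1;
  if (rows.size() < 2 || c0 == 0.0 || c1 == 0.0) return;  // leaf

  sample_features(X.ncol(), mtry, pool, feat_buf);
  BestSplit best;
  for (size_t i = 0; i < feat_buf.size(); ++i)
    best_split_for_feature(X, y, rows, feat_buf[i], best);
  if (!best.found) return;  // no valid split among the drawn features

  find_surrogates(X, rows, best.feature, best.threshold, max_surrogates,
                  tb.surr[node]);

  // fallback = majority child by primary routing of observed rows (tie: left)
  double nl = 0.0, nr = 0.0;
  for (size_t i = 0; i < rows.size(); ++i) {
    double v = X(rows[i], best.feature);
    if (obs(v)) { if (v <= best.threshold) nl += 1.0; else nr += 1.0; }
  }
  int fallback = (nr > nl) ? 1 : 0;

  std::vector<int> lrows, rrows;
  for (size_t i = 0; i < rows.size(); ++i) {
    int side = route_row(X, rows[i], best.feature, best.threshold,
                         tb.surr[node], fallback);
    if (side == 0) lrows.push_back(rows[i]); else rrows.push_back(rows[i]);
  }
  if (lrows.empty() || rrows.empty()) {  // degenerate routing: stay a leaf
    tb.surr[node].clear();
    return;
  }
  tb.feature[node] = best.feature;
  tb.threshold[node] = best.threshold;
  tb.fallback[node] = fallback;
  int l = tb.new_node(), r = tb.new_node();
  tb.left[node] = l; tb.right[node] = r;
  rows.clear(); rows.shrink_to_fit();
  grow(tb, l, std::move(lrows), X, y, mtry, max_surrogates, pool, feat_buf);
  grow(tb, r, std::move(rrows), X, y, mtry, max_surrogates, pool, feat_buf);
}

List pack_tree(const TreeBuild& tb, const IntegerVector& inbag) {
  int n_nodes = (int)tb.feature.size();
  NumericMatrix nodes(n_nodes, 7);
  colnames(nodes) = CharacterVector::create("feature", "threshold", "left",
                                            "right", "n0", "n1", "fallback");
  int n_surr = 0;
  for (int i = 0; i < n_nodes; ++i) n_surr += (int)tb.surr[i].size();
  NumericMatrix sm(n_surr, 5);
  colnames(sm) = CharacterVector::create("node", "feature", "threshold",
                                         "dir", "agreement");
  int k = 0;
  for (int i = 0; i < n_nodes; ++i) {
    nodes(i, 0) = tb.feature[i] >= 0 ? tb.feature[i] + 1 : NA_REAL;
    nodes(i, 1) = tb.threshold[i];
    nodes(i, 2) = tb.left[i]  >= 0 ? tb.left[i]  + 1 : NA_REAL;
    nodes(i, 3) = tb.right[i] >= 0 ? tb.right[i] + 1 : NA_REAL;
    nodes(i, 4) = tb.n0[i];
    nodes(i, 5) = tb.n1[i];
    nodes(i, 6) = tb.fallback[i];
    for (size_t j = 0; j < tb.surr[i].size(); ++j, ++k) {
      sm(k, 0) = i + 1;
      sm(k, 1) = tb.surr[i][j].feature + 1;
      sm(k, 2) = tb.surr[i][j].threshold;
      sm(k, 3) = tb.surr[i][j].dir;
      sm(k, 4) = tb.surr[i][j].agreement;
    }
  }
  return List::create(_["nodes"] = nodes, _["surrogates"] = sm,
                      _["inbag"] = inbag);
}

// Unpacked tree view for fast prediction.
struct TreeView {
  NumericMatrix nodes;
  std::vector<std::vector<Surrogate> > surr;
  explicit TreeView(const List& tree) : nodes(as<NumericMatrix>(tree["nodes"])) {
    NumericMatrix sm = tree["surrogates"];
    surr.resize(nodes.nrow());
    for (int i = 0; i < sm.nrow(); ++i) {
      Surrogate s;
      s.feature = (int)sm(i, 1) - 1;
      s.threshold = sm(i, 2);
      s.dir = (int)sm(i, 3);
      s.agreement = sm(i, 4);
      surr[(int)sm(i, 0) - 1].push_back(s);
    }
  }
};

// Predict one row; `override_feat`/`override_row` (0-based) implement a
// permuted feature without copying X: values of that feature are read from
// another row. Pass override_feat = -1 for plain prediction.
int predict_row(const TreeView& tv, const NumericMatrix& X, int row,
                int override_feat, int override_row) {
  int node = 0;
  for (;;) {
    double f = tv.nodes(node, 0);
    if (ISNAN(f)) {  // leaf: majority class, tie -> 0 (control)
      return tv.nodes(node, 5) > tv.nodes(node, 4) ? 1 : 0;
    }
    int fi = (int)f - 1;
    int src = (fi == override_feat) ? override_row : row;
    double v = X(src, fi);
    int side;
    if (obs(v)) {
      side = v <= tv.nodes(node, 1) ? 0 : 1;
    } else {
      side = -1;
      const std::vector<Surrogate>& ss = tv.surr[node];
      for (size_t k = 0; k < ss.size(); ++k) {
        int sfi = ss[k].feature;
        int ssrc = (sfi == override_feat) ? override_row : row;
        double vs = X(ssrc, sfi);
        if (obs(vs)) {
          bool le = vs <= ss[k].threshold;
          bool goLeft = (ss[k].dir == 1) ? le : !le;
          side = goLeft ? 0 : 1;
          break;
        }
      }
      if (side < 0) side = (int)tv.nodes(node, 6);
    }
    node = (side == 0) ? (int)tv.nodes(node, 2) - 1 : (int)tv.nodes(node, 3) - 1;
  }
}

void features_used(const TreeView& tv, std::vector<bool>& used) {
  std::fill(used.begin(), used.end(), false);
  for (int i = 0; i < tv.nodes.nrow(); ++i) {
    double f = tv.nodes(i, 0);
    if (!ISNAN(f)) used[(int)f - 1] = true;
    for (size_t k = 0; k < tv.surr[i].size(); ++k)
      used[tv.surr[i][k].feature] = true;
  }
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int max_surrogates) {
  RNGScope scope;
  int n = X.nrow();
  List trees(n_trees);
  std::vector<int> pool(X.ncol()), feat_buf;
  for (int t = 0; t < n_trees; ++t) {
    IntegerVector inbag(n, 0);
    std::vector<int> rows;
    rows.reserve(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)std::floor(unif_rand() * n);
      if (j >= n) j = n - 1;
      inbag[j] += 1;
      rows.push_back(j);
    }
    TreeBuild tb;
    int root = tb.new_node();
    grow(tb, root, std::move(rows), X, y, mtry, max_surrogates, pool, feat_buf);
    trees[t] = pack_tree(tb, inbag);
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
IntegerMatrix rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  IntegerMatrix votes(n, 2);  // columns: votes for class 0, class 1
  for (int t = 0; t < T; ++t) {
    TreeView tv(trees[t]);
    for (int i = 0; i < n; ++i) {
      int cls = predict_row(tv, X, i, -1, -1);
      votes(i, cls) += 1;
    }
  }
  return votes;
}

// [[Rcpp::export(name = ".rf_oob_votes_cpp")]]
IntegerMatrix rf_oob_votes_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  IntegerMatrix votes(n, 2);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector inbag = tree["inbag"];
    TreeView tv(tree);
    for (int i = 0; i < n; ++i) {
      if (inbag[i] == 0) {
        int cls = predict_row(tv, X, i, -1, -1);
        votes(i, cls) += 1;
      }
    }
  }
  return votes;
}

// Out-of-bag permutation importance: per tree and feature, the increase in
// that tree's OOB error after permuting the feature across the tree's OOB
// rows (fresh permutation per tree, R RNG); score = mean over trees / sd
// over trees (sd = 0 -> 0). Features a tree never touches contribute 0.
// [[Rcpp::export(name = ".rf_importance_cpp")]]
NumericVector rf_importance_cpp(List trees, NumericMatrix X, IntegerVector y) {
  RNGScope scope;
  int n = X.nrow(), p = X.ncol(), T = trees.size();
  NumericMatrix delta(T, p);
  std::vector<bool> used(p);
  int t_valid = 0;
  std::vector<bool> tree_ok(T, false);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector inbag = tree["inbag"];
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (inbag[i] == 0) oob.push_back(i);
    int m = (int)oob.size();
    if (m == 0) continue;
    tree_ok[t] = true; ++t_valid;
    TreeView tv(tree);
    double base_err = 0.0;
    for (int i = 0; i < m; ++i)
      if (predict_row(tv, X, oob[i], -1, -1) != y[oob[i]]) base_err += 1.0;
    base_err /= m;
    features_used(tv, used);
    std::vector<int> perm(oob);
    for (int j = 0; j < p; ++j) {
      if (!used[j]) { continue; }  // delta stays 0
      // fresh permutation of the OOB rows for feature j
      for (int i = m - 1; i > 0; --i) {
        int k = (int)std::floor(unif_rand() * (i + 1));
        if (k > i) k = i;
        std::swap(perm[i], perm[k]);
      }
      double err = 0.0;
      for (int i = 0; i < m; ++i)
        if (predict_row(tv, X, oob[i], j, perm[i]) != y[oob[i]]) err += 1.0;
      err /= m;
      delta(t, j) = err - base_err;
    }
  }
  NumericVector score(p);
  if (t_valid < 1) return score;
  for (int j = 0; j < p; ++j) {
    double mean = 0.0;
    for (int t = 0; t < T; ++t) if (tree_ok[t]) mean += delta(t, j);
    mean /= t_valid;
    double ss = 0.0;
    for (int t = 0; t < T; ++t)
      if (tree_ok[t]) ss += (delta(t, j) - mean) * (delta(t, j) - mean);
    double sd = t_valid > 1 ? std::sqrt(ss / (t_valid - 1)) : 0.0;
    score[j] = sd > 0 ? mean / sd : 0.0;
  }
  return score;
}
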