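#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// CART growth for the bagged-tree ensemble: greedy binary splits on the
// Gini criterion, mtry features drawn per node with R's RNG (so forests
// are reproducible under set.seed in R). Trees are grown to purity
// (min_node = 1) as is standard for classification forests.

struct Node {
  int var;       // -1 for a leaf
  double split;  // goes left if x <= split
  int left, right;
  int pred;      // majority class (0-based)
};

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, IntegerVector boot,
                   int mtry, int nclass, int min_node) {
  const int p = X.ncol();
  std::vector<Node> nodes;
  std::vector<std::pair<int, std::vector<int> > > stack;  // node id, rows
  std::vector<int> root_rows(boot.size());
  for (int i = 0; i < boot.size(); ++i) root_rows[i] = boot[i] - 1;
  nodes.push_back(Node());
  stack.push_back(std::make_pair(0, root_rows));

  std::vector<int> counts(nclass);
  while (!stack.empty()) {
    const int id = stack.back().first;
    std::vector<int> rows = stack.back().second;
    stack.pop_back();
    const int m = (int)rows.size();

    std::fill(counts.begin(), counts.end(), 0);
    for (int i = 0; i < m; ++i) counts[y[rows[i]]]++;
    int pred = 0;
    for (int c = 1; c < nclass; ++c)
      if (counts[c] > counts[pred]) pred = c;
    const bool pure = counts[pred] == m;

    nodes[id].pred = pred;
    nodes[id].var = -1;
    if (pure || m <= min_node) continue;

    // candidate features, sampled without replacement via R's RNG
    IntegerVector feats = Rcpp::sample(p, std::min(mtry, p));

    double best_score = -1.0;
    int best_var = -1;
    double best_split = 0.0;
    std::vector<int> ord(m);
    std::vector<int> cl(nclass), cr(nclass);
    for (int fi = 0; fi < feats.size(); ++fi) {
      const int f = feats[fi] - 1;
      for (int i = 0; i < m; ++i) ord[i] = rows[i];
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return X(a, f) < X(b, f); });
      if (X(ord[0], f) == X(ord[m - 1], f)) continue;  // constant in node
      std::fill(cl.begin(), cl.end(), 0);
      std::fill(cr.begin(), cr.end(), 0);
      double sum_l2 = 0.0, sum_r2 = 0.0;
      for (int i = 0; i < m; ++i) sum_r2 += 2.0 * (cr[y[ord[i]]]++) + 1.0;
      for (int i = 0; i < m - 1; ++i) {
        const int c = y[ord[i]];
        sum_l2 += 2.0 * (cl[c]++) + 1.0;
        sum_r2 -= 2.0 * (--cr[c]) + 1.0;
        if (X(ord[i + 1], f) > X(ord[i], f)) {
          const double score = sum_l2 / (i + 1) + sum_r2 / (m - i - 1);
          if (score > best_score) {
            best_score = score;
            best_var = f;
            best_split = (X(ord[i], f) + X(ord[i + 1], f)) / 2.0;
          }
        }
      }
    }
    if (best_var < 0) continue;  // no valid split: stay a leaf

    std::vector<int> lrows, rrows;
    for (int i = 0; i < m; ++i) {
      if (X(rows[i], best_var) <= best_split) lrows.push_back(rows[i]);
      else rrows.push_back(rows[i]);
    }
    if (lrows.empty() || rrows.empty()) continue;

    nodes[id].var = best_var;
    nodes[id].split = best_split;
    nodes.push_back(Node());
    const int lid = (int)nodes.size() - 1;
    nodes.push_back(Node());
    const int rid = (int)nodes.size() - 1;
    nodes[id].left = lid;
    nodes[id].right = rid;
    stack.push_back(std::make_pair(lid, lrows));
    stack.push_back(std::make_pair(rid, rrows));
  }

  const int nn = (int)nodes.size();
  IntegerVector var(nn), left(nn), right(nn), pred(nn);
  NumericVector split(nn);
  for (int i = 0; i < nn; ++i) {
    var[i] = nodes[i].var;
    split[i] = nodes[i].var < 0 ? 0.0 : nodes[i].split;
    left[i] = nodes[i].var < 0 ? 0 : nodes[i].left + 1;
    right[i] = nodes[i].var < 0 ? 0 : nodes[i].right + 1;
    pred[i] = nodes[i].pred;
  }
  return List::create(_["var"] = var, _["split"] = split, _["left"] = left,
                      _["right"] = right, _["pred"] = pred);
}

// Route rows of X down a tree; returns the terminal node id (1-based) and
// the predicted class (0-based) per row.
// [[Rcpp::export]]
List cpp_tree_apply(List tree, NumericMatrix X, IntegerVector rows) {
  IntegerVector var = tree["var"], left = tree["left"],
                right = tree["right"], pred = tree["pred"];
  NumericVector split = tree["split"];
  const int n = rows.size();
  IntegerVector leaf(n), cls(n);
  for (int i = 0; i < n; ++i) {
    const int r = rows[i] - 1;
    int node = 0;
    while (var[node] >= 0)
      node = (X(r, var[node]) <= split[node] ? left[node] : right[node]) - 1;
    leaf[i] = node + 1;
    cls[i] = pred[node];
  }
  return List::create(_["leaf"] = leaf, _["class"] = cls);
}

// Accumulate co-occurrence counts: prox(i, j) += 1 when samples i and j
// share a terminal node in this tree. Modifies `prox` in place.
// [[Rcpp::export]]
void cpp_prox_update(NumericMatrix prox, IntegerVector leaf) {
  const int n = leaf.size();
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      if (leaf[i] == leaf[j]) {
        prox(i, j) += 1.0;
        if (j != i) prox(j, i) += 1.0;
      }
}
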