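#include <Rcpp.h>
using namespace Rcpp;

// Path-dependent TreeSHAP for regression tree ensembles.
//
// A tree is encoded as parallel vectors over nodes (0-based):
//   left[j], right[j]  child ids, -1 for a leaf
//   feature[j]         0-based split feature (ignored at leaves)
//   threshold[j]       split value; x[feature] <= threshold goes left
//   value[j]           leaf prediction (ignored at internal nodes)
//   cover[j]           number of reference rows reaching node j (root > 0)
//
// Shapley values are computed with the polynomial-time path algorithm:
// a path of unique features is maintained, each entry holding the
// fraction of zero (feature blocked) and one (feature followed) paths
// and a permutation weight; at a leaf, unwinding each entry yields that
// feature's weighted contribution.

struct PathElem {
  int d;        // feature on this path entry (-1 for the root dummy)
  double z;     // fraction of paths that flow through when feature is absent
  double o;     // fraction of paths that flow through when feature is present
  double w;     // permutation weight
};

static void extend_path(std::vector<PathElem> &m, double pz, double po, int pi) {
  int l = (int)m.size();               // entries m[0..l-1]; we append m[l]
  PathElem e;
  e.d = pi; e.z = pz; e.o = po; e.w = (l == 0) ? 1.0 : 0.0;
  m.push_back(e);
  for (int i = l - 1; i >= 0; i--) {
    m[i + 1].w += po * m[i].w * (i + 1) / (double)(l + 1);
    m[i].w = pz * m[i].w * (double)(l - i) / (double)(l + 1);
  }
}

static std::vector<PathElem> unwind_path(const std::vector<PathElem> &m, int i) {
  int l = (int)m.size() - 1;           // index of last entry
  std::vector<PathElem> out(m.begin(), m.end() - 1);
  double n = m[l].w;
  double oz = m[i].z, oo = m[i].o;
  for (int j = l - 1; j >= 0; j--) {
    if (oo != 0) {
      double t = out[j].w;
      out[j].w = n * (double)(l + 1) / ((double)(j + 1) * oo);
      n = t - out[j].w * oz * (double)(l - j) / (double)(l + 1);
    } else {
      out[j].w = out[j].w * (double)(l + 1) / (oz * (double)(l - j));
    }
  }
  for (int j = i; j < l; j++) {
    out[j].d = m[j + 1].d;
    out[j].z = m[j + 1].z;
    out[j].o = m[j + 1].o;
  }
  return out;
}

static double unwound_sum(const std::vector<PathElem> &m, int i) {
  // sum of weights of UNWIND(m, i) without materializing it
  int l = (int)m.size() - 1;
  double total = 0.0;
  double n = m[l].w;
  double oz = m[i].z, oo = m[i].o;
  if (oo != 0) {
    for (int j = l - 1; j >= 0; j--) {
      double t = n * (double)(l + 1) / ((double)(j + 1) * oo);
      total += t;
      n = m[j].w - t * oz * (double)(l - j) / (double)(l + 1);
    }
  } else {
    for (int j = l - 1; j >= 0; j--) {
      total += m[j].w * (double)(l + 1) / (oz * (double)(l - j));
    }
  }
  return total;
}

struct TreeArrays {
  const int *left, *right, *feature;
  const double *threshold, *value, *cover;
};

static void recurse(const TreeArrays &t, const double *x, double *phi,
                    int node, std::vector<PathElem> m,
                    double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  int l = (int)m.size();
  if (t.left[node] < 0) {  // leaf
    for (int i = 1; i < l; i++) {
      double w = unwound_sum(m, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * t.value[node];
    }
    return;
  }
  int d = t.feature[node];
  int a = t.left[node], b = t.right[node];
  int hot = (x[d] <= t.threshold[node]) ? a : b;
  int cold = (hot == a) ? b : a;
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < l; i++) {
    if (m[i].d == d) { k = i; break; }
  }
  if (k >= 0) {
    iz = m[k].z; io = m[k].o;
    m = unwind_path(m, k);
  }
  double rj = t.cover[node];
  recurse(t, x, phi, hot, m, iz * t.cover[hot] / rj, io, d);
  recurse(t, x, phi, cold, m, iz * t.cover[cold] / rj, 0.0, d);
}

// [[Rcpp::export(name = ".treeshap_single_tree")]]
NumericMatrix treeshap_single_tree(IntegerVector left, IntegerVector right,
                                   IntegerVector feature, NumericVector threshold,
                                   NumericVector value, NumericVector cover,
                                   NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  TreeArrays t = {left.begin(), right.begin(), feature.begin(),
                  threshold.begin(), value.begin(), cover.begin()};
  NumericMatrix phi(n, p);
  std::vector<double> xrow(p);
  for (int r = 0; r < n; r++) {
    for (int j = 0; j < p; j++) xrow[j] = X(r, j);
    std::vector<double> ph(p, 0.0);
    std::vector<PathElem> m;
    recurse(t, xrow.data(), ph.data(), 0, m, 1.0, 1.0, -1);
    for (int j = 0; j < p; j++) phi(r, j) = ph[j];
  }
  return phi;
}

// [[Rcpp::export(name = ".treeshap_forest")]]
List treeshap_forest(List trees, NumericMatrix X) {
  // trees: list of lists with elements left, right, feature, threshold,
  // value, cover. Returns averaged phi matrix and averaged base value.
  int n = X.nrow(), p = X.ncol();
  int ntree = trees.size();
  NumericMatrix phi(n, p);
  double base = 0.0;
  std::vector<double> xrow(p);
  for (int k = 0; k < ntree; k++) {
    List tr = trees[k];
    IntegerVector left = tr["left"], right = tr["right"], feature = tr["feature"];
    NumericVector threshold = tr["threshold"], value = tr["value"], cover = tr["cover"];
    TreeArrays t = {left.begin(), right.begin(), feature.begin(),
                    threshold.begin(), value.begin(), cover.begin()};
    // expected value of the tree under the cover distribution
    int nn = left.size();
    double ev = 0.0;
    for (int j = 0; j < nn; j++) {
      if (left[j] < 0) ev += cover[j] / cover[0] * value[j];
    }
    base += ev;
    for (int r = 0; r < n; r++) {
      for (int j = 0; j < p; j++) xrow[j] = X(r, j);
      std::vector<double> ph(p, 0.0);
      std::vector<PathElem> m;
      recurse(t, xrow.data(), ph.data(), 0, m, 1.0, 1.0, -1);
      for (int j = 0; j < p; j++) phi(r, j) += ph[j];
    }
  }
  for (int r = 0; r < n; r++)
    for (int j = 0; j < p; j++) phi(r, j) /= (double)ntree;
  return List::create(_["phi"] = phi, _["base_value"] = base / (double)ntree);
}

// [[Rcpp::export(name = ".tree_node_stats")]]
List tree_node_stats(IntegerVector left, IntegerVector right,
                     IntegerVector feature, NumericVector threshold,
                     NumericMatrix X, NumericVector y) {
  // Drop reference rows through a tree: per-node row counts and mean of y
  // among rows reaching each node (used for covers and leaf refitting).
  int n = X.nrow(), nn = left.size();
  NumericVector cover(nn), ysum(nn);
  for (int r = 0; r < n; r++) {
    int node = 0;
    for (;;) {
      cover[node] += 1.0;
      ysum[node] += y[r];
      if (left[node] < 0) break;
      node = (X(r, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
  }
  return List::create(_["cover"] = cover, _["ymean"] = ysum / cover);
}

// [[Rcpp::export(name = ".tree_predict")]]
NumericVector tree_predict(IntegerVector left, IntegerVector right,
                           IntegerVector feature, NumericVector threshold,
                           NumericVector value, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; r++) {
    int node = 0;
    while (left[node] >= 0)
      node = (X(r, feature[node]) <= threshold[node]) ? left[node] : right[node];
    out[r] = value[node];
  }
  return out;
}
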