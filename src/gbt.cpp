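#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Flat tree representation shared with the R side:
//   feature      : 0-based split feature, -1 for a leaf
//   threshold    : split point; rows with x < threshold go left
//   default_left : 1 if missing values are routed left
//   left, right  : 0-based child node ids
//   cover        : sum of second-order statistics (hessians) reaching the node
//   value        : leaf increment on the margin scale (learning rate folded in)

struct TreeView {
  IntegerVector feature, default_left, left, right;
  NumericVector threshold, cover, value;
  explicit TreeView(const List& tr)
    : feature(as<IntegerVector>(tr["feature"])),
      default_left(as<IntegerVector>(tr["default_left"])),
      left(as<IntegerVector>(tr["left"])),
      right(as<IntegerVector>(tr["right"])),
      threshold(as<NumericVector>(tr["threshold"])),
      cover(as<NumericVector>(tr["cover"])),
      value(as<NumericVector>(tr["value"])) {}
};

// ---------------------------------------------------------------- tree build

// Exact greedy level-wise builder. `presort` holds, per feature, the 0-based
// row ids with an observed value, sorted ascending; rows missing the feature
// are absent and contribute the per-node "missing" statistics instead.
// [[Rcpp::export]]
List cpp_build_tree(const NumericMatrix& X, const NumericVector& g,
                    const NumericVector& h, const IntegerVector& rows,
                    const List& presort, int max_depth, double lambda,
                    double min_gain, double min_child_weight, double eta) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> node_of(n, -1);
  double G0 = 0.0, H0 = 0.0;
  for (int idx = 0; idx < rows.size(); ++idx) {
    int r = rows[idx];
    node_of[r] = 0;
    G0 += g[r];
    H0 += h[r];
  }

  std::vector<int> feat{-1}, defl{1}, lt{-1}, rt{-1};
  std::vector<double> thr{0.0}, Gn{G0}, Hn{H0};

  std::vector<int> level_nodes{0};
  const double eps = 1e-12;

  for (int depth = 0; depth < max_depth && !level_nodes.empty(); ++depth) {
    const int nl = (int)level_nodes.size();
    std::vector<int> local(Gn.size(), -1);
    for (int i = 0; i < nl; ++i) local[level_nodes[i]] = i;

    std::vector<double> best_gain(nl, min_gain + eps), best_thr(nl, 0.0);
    std::vector<int> best_feat(nl, -1), best_defl(nl, 1);

    // map each row to its local level index once per level (-1: inactive)
    std::vector<int> lrow(n, -1);
    for (int i = 0; i < n; ++i) {
      int nd = node_of[i];
      if (nd >= 0 && nd < (int)local.size()) lrow[i] = local[nd];
    }

    std::vector<double> Gobs(nl), Hobs(nl), Gna(nl), Hna(nl), pscore(nl),
        cg(nl), ch(nl), prev(nl);
    std::vector<char> started(nl);
    const double* gp = REAL(g);
    const double* hp = REAL(h);
    const double* xbase = REAL(X);

    for (int f = 0; f < p; ++f) {
      SEXP ordS = presort[f];
      const int* ordp = INTEGER(ordS);
      const int m = Rf_length(ordS);
      const double* xp = xbase + (R_xlen_t)n * f;
      std::fill(Gobs.begin(), Gobs.end(), 0.0);
      std::fill(Hobs.begin(), Hobs.end(), 0.0);
      for (int t = 0; t < m; ++t) {
        const int r = ordp[t];
        const int li = lrow[r];
        if (li < 0) continue;
        Gobs[li] += gp[r];
        Hobs[li] += hp[r];
      }
      for (int li = 0; li < nl; ++li) {
        const int nd = level_nodes[li];
        Gna[li] = Gn[nd] - Gobs[li];
        Hna[li] = Hn[nd] - Hobs[li];
        pscore[li] = Gn[nd] * Gn[nd] / (Hn[nd] + lambda);
      }
      std::fill(cg.begin(), cg.end(), 0.0);
      std::fill(ch.begin(), ch.end(), 0.0);
      std::fill(started.begin(), started.end(), 0);
      for (int t = 0; t < m; ++t) {
        const int r = ordp[t];
        const int li = lrow[r];
        if (li < 0) continue;
        const double v = xp[r];
        if (started[li] && v > prev[li]) {
          const int nd = level_nodes[li];
          const double Gtot = Gn[nd], Htot = Hn[nd];
          // candidate threshold between the two distinct observed values
          const double cand = prev[li] + (v - prev[li]) / 2.0;
          // missing routed left, then missing routed right
          const int nopt = (Hna[li] > 0.0 || Gna[li] != 0.0) ? 2 : 1;
          for (int opt = 0; opt < nopt; ++opt) {
            const double GL = cg[li] + (opt == 0 ? Gna[li] : 0.0);
            const double HL = ch[li] + (opt == 0 ? Hna[li] : 0.0);
            const double GR = Gtot - GL, HR = Htot - HL;
            if (HL < min_child_weight || HR < min_child_weight) continue;
            const double gain = 0.5 * (GL * GL / (HL + lambda) +
                                       GR * GR / (HR + lambda) - pscore[li]);
            if (gain > best_gain[li]) {
              best_gain[li] = gain;
              best_feat[li] = f;
              best_thr[li] = cand;
              best_defl[li] = (opt == 0) ? 1 : 0;
            }
          }
        }
        cg[li] += gp[r];
        ch[li] += hp[r];
        prev[li] = v;
        started[li] = 1;
      }
    }

    // materialize the chosen splits and partition the rows
    std::vector<int> next_level;
    for (int li = 0; li < nl; ++li) {
      if (best_feat[li] < 0) continue;
      int nd = level_nodes[li];
      int L = (int)Gn.size(), R = L + 1;
      feat[nd] = best_feat[li];
      thr[nd] = best_thr[li];
      defl[nd] = best_defl[li];
      lt[nd] = L;
      rt[nd] = R;
      for (int c = 0; c < 2; ++c) {
        feat.push_back(-1);
        defl.push_back(1);
        lt.push_back(-1);
        rt.push_back(-1);
        thr.push_back(0.0);
        Gn.push_back(0.0);
        Hn.push_back(0.0);
      }
      next_level.push_back(L);
      next_level.push_back(R);
    }
    if (next_level.empty()) break;
    for (int idx = 0; idx < rows.size(); ++idx) {
      int r = rows[idx];
      int nd = node_of[r];
      if (nd < 0 || nd >= (int)local.size()) continue;
      if (local[nd] < 0 || feat[nd] < 0) continue;
      double v = X(r, feat[nd]);
      int child;
      if (ISNAN(v))
        child = defl[nd] ? lt[nd] : rt[nd];
      else
        child = (v < thr[nd]) ? lt[nd] : rt[nd];
      node_of[r] = child;
      Gn[child] += g[r];
      Hn[child] += h[r];
    }
    level_nodes = next_level;
  }

  const int nn = (int)Gn.size();
  NumericVector value(nn);
  for (int i = 0; i < nn; ++i)
    if (feat[i] < 0) value[i] = -eta * Gn[i] / (Hn[i] + lambda);

  return List::create(
      _["feature"] = IntegerVector(feat.begin(), feat.end()),
      _["threshold"] = NumericVector(thr.begin(), thr.end()),
      _["default_left"] = IntegerVector(defl.begin(), defl.end()),
      _["left"] = IntegerVector(lt.begin(), lt.end()),
      _["right"] = IntegerVector(rt.begin(), rt.end()),
      _["cover"] = NumericVector(Hn.begin(), Hn.end()),
      _["value"] = value);
}

// ---------------------------------------------------------------- prediction

static inline double predict_row(const TreeView& T, const NumericMatrix& X,
                                 int row) {
  int node = 0;
  while (T.feature[node] >= 0) {
    double v = X(row, T.feature[node]);
    if (ISNAN(v))
      node = T.default_left[node] ? T.left[node] : T.right[node];
    else
      node = (v < T.threshold[node]) ? T.left[node] : T.right[node];
  }
  return T.value[node];
}

// Sum of routed leaf values over an ensemble (no base score).
// [[Rcpp::export]]
NumericVector cpp_predict_trees(const List& trees, const NumericMatrix& X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < trees.size(); ++t) {
    TreeView T(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += predict_row(T, X, i);
  }
  return out;
}

// ------------------------------------------------------- Shapley attribution
//
// Polynomial-time path-dependent Shapley recursion for tree ensembles with
// cover-weighted conditional expectations. `condition` = 0 computes plain
// attributions; +1/-1 conditions the game on `cond_feat` being always known
// (routed by x) / always unknown (cover-averaged), which yields pairwise
// interaction values as differences of conditioned attribution vectors.

struct PE {
  int d;
  double z, o, w;
};

static void extend_path(std::vector<PE>& path, double pz, double po, int pi) {
  const int l = (int)path.size();
  PE e;
  e.d = pi;
  e.z = pz;
  e.o = po;
  e.w = (l == 0) ? 1.0 : 0.0;
  path.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    path[i + 1].w += po * path[i].w * (i + 1) / (double)(l + 1);
    path[i].w = pz * path[i].w * (l - i) / (double)(l + 1);
  }
}

static void unwind_path(std::vector<PE>& path, int k) {
  const int l = (int)path.size() - 1;
  const double o = path[k].o, z = path[k].z;
  double nxt = path[l].w;
  if (o != 0) {
    for (int i = l - 1; i >= 0; --i) {
      double tmp = path[i].w;
      path[i].w = nxt * (l + 1) / ((i + 1) * o);
      nxt = tmp - path[i].w * z * (l - i) / (double)(l + 1);
    }
  } else {
    for (int i = l - 1; i >= 0; --i)
      path[i].w = path[i].w * (l + 1) / (z * (l - i));
  }
  for (int i = k; i < l; ++i) {
    path[i].d = path[i + 1].d;
    path[i].z = path[i + 1].z;
    path[i].o = path[i + 1].o;
  }
  path.pop_back();
}

static double unwound_sum(const std::vector<PE>& path, int k) {
  const int l = (int)path.size() - 1;
  const double o = path[k].o, z = path[k].z;
  double total = 0.0;
  if (o != 0) {
    double nxt = path[l].w;
    for (int i = l - 1; i >= 0; --i) {
      double t = nxt * (l + 1) / ((i + 1) * o);
      total += t;
      nxt = path[i].w - t * z * (l - i) / (double)(l + 1);
    }
  } else {
    for (int i = l - 1; i >= 0; --i)
      total += path[i].w * (l + 1) / (z * (l - i));
  }
  return total;
}

static void shap_recurse(const TreeView& T, int node, const NumericMatrix& X,
                         int row, std::vector<PE> path, double pz, double po,
                         int pi, int condition, int cond_feat, double cond_frac,
                         double* phi) {
  if (!(condition != 0 && pi == cond_feat)) extend_path(path, pz, po, pi);

  const int f = T.feature[node];
  if (f < 0) {
    const double v = T.value[node];
    const int l = (int)path.size() - 1;
    for (int i = 1; i <= l; ++i) {
      double w = unwound_sum(path, i);
      phi[path[i].d] += w * (path[i].o - path[i].z) * v * cond_frac;
    }
    return;
  }

  double xv = X(row, f);
  int hot, cold;
  if (ISNAN(xv))
    hot = T.default_left[node] ? T.left[node] : T.right[node];
  else
    hot = (xv < T.threshold[node]) ? T.left[node] : T.right[node];
  cold = (hot == T.left[node]) ? T.right[node] : T.left[node];
  const double w = T.cover[node];
  const double hz = T.cover[hot] / w, cz = T.cover[cold] / w;

  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)path.size(); ++i)
    if (path[i].d == f) {
      k = i;
      break;
    }
  if (k >= 0) {
    iz = path[k].z;
    io = path[k].o;
    unwind_path(path, k);
  }

  if (condition != 0 && f == cond_feat) {
    if (condition > 0) {
      shap_recurse(T, hot, X, row, path, 1.0, 1.0, f, condition, cond_feat,
                   cond_frac, phi);
    } else {
      shap_recurse(T, hot, X, row, path, 1.0, 1.0, f, condition, cond_feat,
                   cond_frac * hz, phi);
      shap_recurse(T, cold, X, row, path, 1.0, 1.0, f, condition, cond_feat,
                   cond_frac * cz, phi);
    }
  } else {
    shap_recurse(T, hot, X, row, path, iz * hz, io, f, condition, cond_feat,
                 cond_frac, phi);
    shap_recurse(T, cold, X, row, path, iz * cz, 0.0, f, condition, cond_feat,
                 cond_frac, phi);
  }
}

// Per-row Shapley attributions (margin scale, base value excluded).
// condition: 0 none, +1 cond_feat always known, -1 cond_feat always unknown.
// [[Rcpp::export]]
NumericMatrix cpp_tree_shap(const List& trees, const NumericMatrix& X,
                            int n_features, int condition, int cond_feat) {
  const int n = X.nrow();
  NumericMatrix phi(n, n_features);
  std::vector<double> acc(n_features);
  for (int t = 0; t < trees.size(); ++t) {
    TreeView T(trees[t]);
    for (int i = 0; i < n; ++i) {
      std::fill(acc.begin(), acc.end(), 0.0);
      std::vector<PE> path;
      path.reserve(16);
      shap_recurse(T, 0, X, i, path, 1.0, 1.0, -1, condition, cond_feat, 1.0,
                   acc.data());
      for (int j = 0; j < n_features; ++j) phi(i, j) += acc[j];
    }
  }
  return phi;
}
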