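// Honest causal tree ensemble: residual-based greedy splitting, honest
// leaf estimation and out-of-bag CATE accumulation. The splitting statistic
// is n_L * n_R * (tau_L - tau_R)^2 with tau the residual-ratio effect
// estimate inside each child, computed on the grow half only; leaves are
// populated by the estimate half.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// platform-stable integer draw in [0, n)
static inline int rnd_int(std::mt19937& g, int n) {
  return (int)(g() % (uint32_t)n);
}

struct Node {
  int var;      // 0-based split variable, -1 for leaf
  double thr;
  int left, right;
  int depth;
  std::vector<int> members;  // estimate-half rows (0-based), leaves only
};

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericVector& wr;
  const NumericVector& yr;
  const IntegerVector& W;
  int mtry, min_node, min_arm;
  double alpha;  // child-size floor as a fraction of the parent node
  std::mt19937& gen;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const NumericVector& wr_,
              const NumericVector& yr_, const IntegerVector& W_,
              int mtry_, int min_node_, int min_arm_, double alpha_,
              std::mt19937& g)
    : X(X_), wr(wr_), yr(yr_), W(W_),
      mtry(mtry_), min_node(min_node_), min_arm(min_arm_), alpha(alpha_),
      gen(g) {}

  int grow(std::vector<int>& rows, int depth) {
    int id = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, depth, {}});
    int n = (int)rows.size();
    if (n < 2 * min_node) return id;

    int K = X.ncol();
    // draw mtry candidate variables, then visit in ascending order for
    // deterministic tie-breaking
    std::vector<int> vars(K);
    for (int j = 0; j < K; ++j) vars[j] = j;
    int m = std::min(mtry, K);
    for (int j = 0; j < m; ++j) {
      int k = j + rnd_int(gen, K - j);
      std::swap(vars[j], vars[k]);
    }
    vars.resize(m);
    std::sort(vars.begin(), vars.end());

    // parent effect estimate and one-step pseudo-outcomes: a child's
    // effect deviation from the parent is estimated by the child mean of
    // rho, so the split statistic n_L n_R (tau_L - tau_R)^2 becomes
    // n_L n_R (mean rho_L - mean rho_R)^2 -- a difference in leaf means
    // with denominators that stay proportional to child size
    double tot_swy = 0, tot_sww = 0;
    int tot_tr = 0;
    for (int i = 0; i < n; ++i) {
      int r = rows[i];
      tot_swy += wr[r] * yr[r];
      tot_sww += wr[r] * wr[r];
      tot_tr += W[r];
    }
    if (tot_sww <= 1e-12) return id;  // degenerate: no treatment variation
    double tauP = tot_swy / tot_sww;
    double vP = tot_sww / n;
    std::vector<double> rho(n);
    for (int i = 0; i < n; ++i) {
      int r = rows[i];
      rho[i] = wr[r] * (yr[r] - wr[r] * tauP) / vP;
    }

    int child_floor = std::max(min_node, (int)std::ceil(alpha * n));
    double best_crit = 0.0, best_thr = 0.0;
    int best_var = -1;
    std::vector<double> vals(n);

    for (int vi = 0; vi < m; ++vi) {
      int v = vars[vi];
      for (int i = 0; i < n; ++i) vals[i] = X(rows[i], v);
      std::vector<int> idx(n);
      for (int i = 0; i < n; ++i) idx[i] = i;
      std::stable_sort(idx.begin(), idx.end(),
                       [&](int a, int b) { return vals[a] < vals[b]; });
      double srL = 0, swwL = 0;
      int trL = 0;
      for (int i = 0; i < n - 1; ++i) {
        int r = rows[idx[i]];
        srL += rho[idx[i]];
        swwL += wr[r] * wr[r];
        trL += W[r];
        double xv = vals[idx[i]], xn = vals[idx[i + 1]];
        if (xn <= xv) continue;  // not a boundary between distinct values
        int nL = i + 1, nR = n - nL;
        if (nL < child_floor || nR < child_floor) continue;
        int trR = tot_tr - trL;
        if (trL < min_arm || (nL - trL) < min_arm) continue;
        if (trR < min_arm || (nR - trR) < min_arm) continue;
        if (swwL <= 1e-12 || tot_sww - swwL <= 1e-12) continue;
        double d = srL / nL - (0.0 - srL) / nR;  // sum(rho) = 0 in the parent
        double crit = (double)nL * (double)nR * d * d;
        if (crit > best_crit) {
          best_crit = crit;
          best_var = v;
          best_thr = 0.5 * (xv + xn);
        }
      }
    }

    if (best_var < 0 || best_crit <= 0.0) return id;

    std::vector<int> lrows, rrows;
    lrows.reserve(n); rrows.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(rows[i], best_var) <= best_thr) lrows.push_back(rows[i]);
      else rrows.push_back(rows[i]);
    }
    nodes[id].var = best_var;
    nodes[id].thr = best_thr;
    int l = grow(lrows, depth + 1);
    int r = grow(rrows, depth + 1);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  // route estimate rows to leaves
  void populate(int root, const std::vector<int>& est) {
    for (int r : est) {
      int id = root;
      while (nodes[id].var >= 0) {
        id = (X(r, nodes[id].var) <= nodes[id].thr) ? nodes[id].left
                                                    : nodes[id].right;
      }
      nodes[id].members.push_back(r);
    }
  }

  // collapse leaves without estimate rows into their siblings;
  // returns the new subtree root or -2 when the subtree is entirely empty
  int prune(int id) {
    if (nodes[id].var < 0) return nodes[id].members.empty() ? -2 : id;
    int l = prune(nodes[id].left);
    int r = prune(nodes[id].right);
    if (l == -2 && r == -2) { nodes[id].var = -1; return -2; }
    if (l == -2) return r;
    if (r == -2) return l;
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  void set_depths(int root) {
    std::vector<std::pair<int, int>> stack{{root, 0}};
    while (!stack.empty()) {
      auto [id, d] = stack.back();
      stack.pop_back();
      nodes[id].depth = d;
      if (nodes[id].var >= 0) {
        stack.push_back({nodes[id].left, d + 1});
        stack.push_back({nodes[id].right, d + 1});
      }
    }
  }
};

// [[Rcpp::export(name = ".cf_grow_forest")]]
List cf_grow_forest(NumericMatrix X, NumericVector wr, NumericVector yr,
                    IntegerVector W, int B, double subsample_frac,
                    double honesty_frac, int mtry, int min_node, int min_arm,
                    double alpha, int seed) {
  int n = X.nrow();
  std::mt19937 gen((uint32_t)seed);
  List trees(B);
  NumericVector oob_num(n, 0.0), oob_den(n, 0.0);
  IntegerVector oob_count(n, 0);

  std::vector<int> perm(n);
  for (int b = 0; b < B; ++b) {
    // subsample without replacement
    for (int i = 0; i < n; ++i) perm[i] = i;
    int m = std::max(2, (int)std::floor(subsample_frac * n));
    for (int i = 0; i < m; ++i) {
      int k = i + rnd_int(gen, n - i);
      std::swap(perm[i], perm[k]);
    }
    int n_grow = std::max(1, (int)std::floor(honesty_frac * m));
    std::vector<int> grow_idx(perm.begin(), perm.begin() + n_grow);
    std::vector<int> est_idx(perm.begin() + n_grow, perm.begin() + m);
    std::vector<bool> in_sub(n, false);
    for (int i = 0; i < m; ++i) in_sub[perm[i]] = true;

    TreeBuilder tb(X, wr, yr, W, mtry, min_node, min_arm, alpha, gen);
    std::vector<int> growrows(grow_idx);
    int root = tb.grow(growrows, 0);
    tb.populate(root, est_idx);
    int newroot = tb.prune(root);
    if (newroot == -2) {  // no estimate rows reached any leaf: make a stump
      tb.nodes.clear();
      tb.nodes.push_back(Node{-1, 0.0, -1, -1, 0, est_idx});
      newroot = 0;
    }
    tb.set_depths(newroot);

    // per-leaf honest sufficient statistics, then OOB accumulation
    int nn = (int)tb.nodes.size();
    std::vector<double> leafS1(nn, 0.0), leafS2(nn, 0.0);
    for (int id = 0; id < nn; ++id) {
      const Node& nd = tb.nodes[id];
      if (nd.var >= 0 || nd.members.empty()) continue;
      double s1 = 0, s2 = 0;
      for (int r : nd.members) {
        s1 += wr[r] * yr[r];
        s2 += wr[r] * wr[r];
      }
      double sz = (double)nd.members.size();
      leafS1[id] = s1 / sz;
      leafS2[id] = s2 / sz;
    }
    for (int r = 0; r < n; ++r) {
      if (in_sub[r]) continue;
      int id = newroot;
      while (tb.nodes[id].var >= 0) {
        id = (X(r, tb.nodes[id].var) <= tb.nodes[id].thr)
               ? tb.nodes[id].left : tb.nodes[id].right;
      }
      if (tb.nodes[id].members.empty()) continue;
      oob_num[r] += leafS1[id];
      oob_den[r] += leafS2[id];
      oob_count[r] += 1;
    }

    // export tree structure (1-based indices for R)
    IntegerVector var(nn), left(nn), right(nn), depth(nn);
    NumericVector thr(nn);
    List members(nn);
    for (int id = 0; id < nn; ++id) {
      const Node& nd = tb.nodes[id];
      var[id] = nd.var >= 0 ? nd.var + 1 : NA_INTEGER;
      thr[id] = nd.var >= 0 ? nd.thr : NA_REAL;
      left[id] = nd.left >= 0 ? nd.left + 1 : NA_INTEGER;
      right[id] = nd.right >= 0 ? nd.right + 1 : NA_INTEGER;
      depth[id] = nd.depth;
      if (nd.var < 0 && !nd.members.empty()) {
        IntegerVector mem(nd.members.size());
        for (size_t i = 0; i < nd.members.size(); ++i) mem[i] = nd.members[i] + 1;
        members[id] = mem;
      } else {
        members[id] = IntegerVector(0);
      }
    }
    IntegerVector gidx(grow_idx.size()), eidx(est_idx.size());
    for (size_t i = 0; i < grow_idx.size(); ++i) gidx[i] = grow_idx[i] + 1;
    for (size_t i = 0; i < est_idx.size(); ++i) eidx[i] = est_idx[i] + 1;
    trees[b] = List::create(
      _["root"] = newroot + 1, _["var"] = var, _["threshold"] = thr,
      _["left"] = left, _["right"] = right, _["depth"] = depth,
      _["members"] = members, _["grow_idx"] = gidx, _["est_idx"] = eidx);
  }

  return List::create(_["trees"] = trees, _["oob_num"] = oob_num,
                      _["oob_den"] = oob_den, _["oob_count"] = oob_count);
}

static inline int descend(const IntegerVector& var, const NumericVector& thr,
                          const IntegerVector& left, const IntegerVector& right,
                          const NumericMatrix& X, int row, int root) {
  int id = root;
  while (var[id] != NA_INTEGER) {
    id = (X(row, var[id] - 1) <= thr[id]) ? left[id] - 1 : right[id] - 1;
  }
  return id;
}

// forest weights alpha_i(x) for a single query row of Xq, averaged over the
// trees listed in `use_trees` (1-based); normalised to sum to 1 over the
// contributing trees
// [[Rcpp::export(name = ".cf_forest_weights")]]
NumericVector cf_forest_weights(List trees, NumericMatrix Xq, int qrow,
                                int n_train, IntegerVector use_trees) {
  NumericVector alpha(n_train, 0.0);
  int contributing = 0;
  for (int t = 0; t < use_trees.size(); ++t) {
    List tr = trees[use_trees[t] - 1];
    IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["threshold"];
    List members = tr["members"];
    int id = descend(var, thr, left, right, Xq, qrow - 1, (int)tr["root"] - 1);
    IntegerVector mem = members[id];
    if (mem.size() == 0) continue;
    ++contributing;
    double w = 1.0 / mem.size();
    for (int i = 0; i < mem.size(); ++i) alpha[mem[i] - 1] += w;
  }
  if (contributing > 0) for (int i = 0; i < n_train; ++i) alpha[i] /= contributing;
  return alpha;
}

// CATE predictions for query rows using all trees: the weighted residual
// ratio with alpha weights accumulated over trees
// [[Rcpp::export(name = ".cf_predict")]]
NumericVector cf_predict(List trees, NumericMatrix Xq, NumericVector wr,
                         NumericVector yr) {
  int nq = Xq.nrow();
  NumericVector out(nq, NA_REAL);
  int B = trees.size();
  for (int q = 0; q < nq; ++q) {
    double num = 0, den = 0;
    for (int b = 0; b < B; ++b) {
      List tr = trees[b];
      IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
      NumericVector thr = tr["threshold"];
      List members = tr["members"];
      int id = descend(var, thr, left, right, Xq, q, (int)tr["root"] - 1);
      IntegerVector mem = members[id];
      if (mem.size() == 0) continue;
      double s1 = 0, s2 = 0;
      for (int i = 0; i < mem.size(); ++i) {
        int r = mem[i] - 1;
        s1 += wr[r] * yr[r];
        s2 += wr[r] * wr[r];
      }
      num += s1 / mem.size();
      den += s2 / mem.size();
    }
    if (den > 0) out[q] = num / den;
  }
  return out;
}
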