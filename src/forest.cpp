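#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Classification forest used by the ranking models. CART trees on
// quantile-binned features (<= 255 cut points per feature), bootstrap
// resampling and per-node feature subsampling. Sample weights implement
// class balancing; node-size limits are on raw counts. All randomness is
// drawn from R's RNG so set.seed() in R makes fits reproducible.

namespace {

struct Tree {
  std::vector<int> var;      // -1 for leaf
  std::vector<double> thr;   // x <= thr goes left
  std::vector<int> left, right;
  std::vector<double> pred;  // weighted positive fraction

  int add_node() {
    var.push_back(-1);
    thr.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(0.0);
    return static_cast<int>(var.size()) - 1;
  }
};

struct NodeTask {
  int node, start, end, depth;
};

// quantile-style cut points; at most max_cuts, placed between distinct values
std::vector<double> make_cuts(const double* x, int n, int max_cuts) {
  std::vector<double> v(x, x + n);
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  std::vector<double> cuts;
  const int nu = static_cast<int>(v.size());
  if (nu <= 1) return cuts;
  if (nu - 1 <= max_cuts) {
    cuts.reserve(nu - 1);
    for (int i = 0; i + 1 < nu; ++i) cuts.push_back(0.5 * (v[i] + v[i + 1]));
  } else {
    cuts.reserve(max_cuts);
    for (int i = 1; i <= max_cuts; ++i) {
      int pos = static_cast<int>(static_cast<double>(i) * nu / (max_cuts + 1));
      if (pos < 1) pos = 1;
      if (pos > nu - 1) pos = nu - 1;
      cuts.push_back(0.5 * (v[pos - 1] + v[pos]));
    }
    cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
  }
  return cuts;
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, NumericVector w,
                int n_trees, int mtry, int max_depth, int min_node,
                double sample_frac) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n || w.size() != n)
    stop("rf_fit_cpp: label/weight length mismatch");
  if (mtry < 1 || mtry > p) stop("rf_fit_cpp: invalid mtry");

  const int max_cuts = 63;
  std::vector<std::vector<double> > cuts(p);
  std::vector<std::vector<uint16_t> > bins(p);
  for (int j = 0; j < p; ++j) {
    cuts[j] = make_cuts(&X(0, j), n, max_cuts);
    bins[j].resize(n);
    for (int i = 0; i < n; ++i) {
      const double* c0 = cuts[j].data();
      bins[j][i] = static_cast<uint16_t>(
          std::upper_bound(c0, c0 + cuts[j].size(), X(i, j)) - c0);
    }
  }

  const int n_samp = std::max(1, static_cast<int>(sample_frac * n));
  std::vector<int> idx(n_samp), buf(n_samp), feat(p);
  const int nbin = max_cuts + 1;
  std::vector<double> wpos(nbin), wneg(nbin);
  std::vector<int> cnt(nbin);

  List out(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n_samp; ++i) {
      int k = static_cast<int>(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
    }

    Tree tree;
    std::vector<NodeTask> stack;
    stack.push_back(NodeTask{tree.add_node(), 0, n_samp, 0});

    while (!stack.empty()) {
      NodeTask tk = stack.back();
      stack.pop_back();
      const int cnt_node = tk.end - tk.start;

      double wp = 0.0, wn = 0.0;
      for (int i = tk.start; i < tk.end; ++i) {
        const int s = idx[i];
        if (y[s] == 1) wp += w[s]; else wn += w[s];
      }
      const double wtot = wp + wn;
      tree.pred[tk.node] = (wtot > 0.0) ? wp / wtot : 0.5;

      if (tk.depth >= max_depth || cnt_node < 2 * min_node ||
          wp == 0.0 || wn == 0.0)
        continue;

      // parent sum-of-squares criterion; maximize child purity gain
      const double parent_score = (wp * wp + wn * wn) / wtot;
      double best_gain = 1e-12;
      int best_f = -1, best_bin = -1;

      for (int j = 0; j < p; ++j) feat[j] = j;
      for (int m = 0; m < mtry; ++m) {
        int r = m + static_cast<int>(unif_rand() * (p - m));
        if (r >= p) r = p - 1;
        std::swap(feat[m], feat[r]);
        const int f = feat[m];
        const int nb = static_cast<int>(cuts[f].size()) + 1;
        if (nb <= 1) continue;

        const uint16_t* bf = bins[f].data();
        // histograms are kept all-zero between uses (re-zeroed after the
        // scan by walking the node's samples, cost proportional to node
        // size rather than bin count)
        for (int i = tk.start; i < tk.end; ++i) {
          const int s = idx[i];
          const int b = bf[s];
          if (y[s] == 1) wpos[b] += w[s]; else wneg[b] += w[s];
          cnt[b]++;
        }

        double lp = 0.0, ln = 0.0;
        int lc = 0;
        for (int b = 0; b + 1 < nb; ++b) {
          lp += wpos[b];
          ln += wneg[b];
          lc += cnt[b];
          if (lc < min_node) continue;
          if (cnt_node - lc < min_node) break;
          const double wl = lp + ln, wr = wtot - wl;
          if (wl <= 0.0 || wr <= 0.0) continue;
          const double rp = wp - lp, rn = wn - ln;
          const double gain = (lp * lp + ln * ln) / wl +
                              (rp * rp + rn * rn) / wr - parent_score;
          if (gain > best_gain) {
            best_gain = gain;
            best_f = f;
            best_bin = b;
          }
        }
        for (int i = tk.start; i < tk.end; ++i) {
          const int b = bf[idx[i]];
          wpos[b] = wneg[b] = 0.0;
          cnt[b] = 0;
        }
      }

      if (best_f < 0) continue;

      // stable partition of idx[start,end) on bin <= best_bin
      const uint16_t* bf = bins[best_f].data();
      int nl = 0, nr = 0;
      for (int i = tk.start; i < tk.end; ++i) {
        if (bf[idx[i]] <= best_bin) buf[nl++] = idx[i];
      }
      const int mid = tk.start + nl;
      for (int i = tk.start; i < tk.end; ++i) {
        if (bf[idx[i]] > best_bin) buf[nl + nr++] = idx[i];
      }
      std::copy(buf.begin(), buf.begin() + nl + nr, idx.begin() + tk.start);

      const int lnode = tree.add_node();
      const int rnode = tree.add_node();
      tree.var[tk.node] = best_f;
      tree.thr[tk.node] = cuts[best_f][best_bin];
      tree.left[tk.node] = lnode;
      tree.right[tk.node] = rnode;
      stack.push_back(NodeTask{rnode, mid, tk.end, tk.depth + 1});
      stack.push_back(NodeTask{lnode, tk.start, mid, tk.depth + 1});
    }

    const int nn = static_cast<int>(tree.var.size());
    NumericMatrix nodes(nn, 5);
    for (int i = 0; i < nn; ++i) {
      nodes(i, 0) = tree.var[i];
      nodes(i, 1) = tree.thr[i];
      nodes(i, 2) = tree.left[i];
      nodes(i, 3) = tree.right[i];
      nodes(i, 4) = tree.pred[i];
    }
    out[t] = nodes;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int nt = trees.size();
  NumericVector out(n);
  const double* xp = REAL(X);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix nodes = trees[t];
    const int nn = nodes.nrow();
    const double* vr = REAL(nodes);
    const double* th = vr + nn;
    const double* lf = th + nn;
    const double* rg = lf + nn;
    const double* pr = rg + nn;
    for (int i = 0; i < n; ++i) {
      int cur = 0;
      while (vr[cur] >= 0) {
        const int f = static_cast<int>(vr[cur]);
        cur = static_cast<int>(
            (xp[i + static_cast<size_t>(f) * n] <= th[cur]) ? lf[cur]
                                                            : rg[cur]);
      }
      out[i] += pr[cur];
    }
  }
  if (nt > 0) for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
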