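#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Biased second-order random walks (return parameter p, in-out parameter q)
// plus skip-gram training with negative sampling, over the nodes of a single
// graph. Uses R's RNG throughout so results are reproducible under set.seed().

static int sample_weighted(const std::vector<double> &w) {
  double tot = 0.0;
  for (double x : w) tot += x;
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (u <= acc) return (int)i;
  }
  return (int)w.size() - 1;
}

// [[Rcpp::export(name = ".n2v_walks")]]
IntegerMatrix n2v_walks(List adj, int walks_per_node, int walk_length,
                        double p, double q) {
  int n = adj.size();
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = adj[i];
    for (int j = 0; j < a.size(); ++j) nbr[i].push_back(a[j] - 1);
  }
  int n_walks = n * walks_per_node;
  IntegerMatrix walks(n_walks, walk_length);
  int w = 0;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int start = 0; start < n; ++start, ++w) {
      int prev = -1, cur = start;
      walks(w, 0) = cur + 1;
      for (int step = 1; step < walk_length; ++step) {
        const std::vector<int> &nb = nbr[cur];
        if (nb.empty()) { walks(w, step) = cur + 1; continue; }
        int nxt;
        if (prev < 0) {
          nxt = nb[(int)(unif_rand() * nb.size()) % nb.size()];
        } else {
          std::vector<double> wts(nb.size());
          for (size_t k = 0; k < nb.size(); ++k) {
            int x = nb[k];
            if (x == prev) wts[k] = 1.0 / p;
            else {
              bool adj_prev = false;
              for (int y : nbr[prev]) if (y == x) { adj_prev = true; break; }
              wts[k] = adj_prev ? 1.0 : 1.0 / q;
            }
          }
          nxt = nb[sample_weighted(wts)];
        }
        walks(w, step) = nxt + 1;
        prev = cur;
        cur = nxt;
      }
    }
  }
  return walks;
}

// [[Rcpp::export(name = ".n2v_train")]]
NumericMatrix n2v_train(IntegerMatrix walks, int n_nodes, int dim, int window,
                        int epochs, int n_neg, double lr0) {
  NumericMatrix U(n_nodes, dim), V(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d) {
      U(i, d) = (unif_rand() - 0.5) / dim;
      V(i, d) = 0.0;
    }
  int n_walks = walks.nrow(), L = walks.ncol();
  // total center-context pairs per epoch, for linear lr decay
  long total = (long)n_walks * L * 2 * window * (long)epochs;
  long seen = 0;
  const double lr_min = 1e-4;
  std::vector<double> grad_c(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < n_walks; ++w) {
      for (int ci = 0; ci < L; ++ci) {
        int c = walks(w, ci) - 1;
        for (int off = -window; off <= window; ++off) {
          if (off == 0) continue;
          ++seen;
          int ti = ci + off;
          if (ti < 0 || ti >= L) continue;
          int t = walks(w, ti) - 1;
          double lr = lr0 * (1.0 - (double)seen / (double)(total + 1));
          if (lr < lr_min) lr = lr_min;
          std::fill(grad_c.begin(), grad_c.end(), 0.0);
          // one positive (label 1) + n_neg uniform negatives (label 0)
          for (int s = 0; s <= n_neg; ++s) {
            int tgt;
            double label;
            if (s == 0) { tgt = t; label = 1.0; }
            else {
              tgt = (int)(unif_rand() * n_nodes) % n_nodes;
              if (tgt == t) continue;
              label = 0.0;
            }
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += U(c, d) * V(tgt, d);
            double pred = 1.0 / (1.0 + std::exp(-dot));
            double g = lr * (label - pred);
            for (int d = 0; d < dim; ++d) {
              grad_c[d] += g * V(tgt, d);
              V(tgt, d) += g * U(c, d);
            }
          }
          for (int d = 0; d < dim; ++d) U(c, d) += grad_c[d];
        }
      }
    }
  }
  return U;
}
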