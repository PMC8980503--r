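// Backfitting MCMC for a sum-of-trees (BART) model with a regularizing tree
// prior.  Continuous outcome only; y is rescaled to [-0.5, 0.5] on the R side.
//
// Tree moves: GROW / PRUNE / CHANGE, Metropolis-Hastings on the integrated
// likelihood of the partial residuals (leaf means marginalized analytically
// under the conjugate normal prior), then leaf values redrawn from their
// normal full conditionals and sigma from its scaled-inverse-chi-square full
// conditional.  Split rules: threshold on observed values for continuous
// covariates, level-subset (bitmask) for categorical covariates.
//
// All randomness comes from R's RNG so set.seed() on the R side gives full
// reproducibility.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tree {
  // parallel arrays; a node is dead once pruned (alive=false).  left == -1
  // marks a leaf.  For categorical splits `cut` holds a bitmask of levels
  // routed left, stored in a double (levels < 53 so this is exact).
  std::vector<int> var, left, right, parent;
  std::vector<double> cut, value;
  std::vector<bool> alive;

  int root;

  Tree() {
    var.push_back(-1); cut.push_back(0.0); left.push_back(-1);
    right.push_back(-1); parent.push_back(-1); value.push_back(0.0);
    alive.push_back(true);
    root = 0;
  }

  bool is_leaf(int i) const { return left[i] < 0; }

  int new_node(int par) {
    var.push_back(-1); cut.push_back(0.0); left.push_back(-1);
    right.push_back(-1); parent.push_back(par); value.push_back(0.0);
    alive.push_back(true);
    return (int)var.size() - 1;
  }

  int depth(int i) const {
    int d = 0;
    while (parent[i] >= 0) { i = parent[i]; ++d; }
    return d;
  }

  void leaves(std::vector<int>& out) const {
    out.clear();
    for (int i = 0; i < (int)var.size(); ++i)
      if (alive[i] && is_leaf(i)) out.push_back(i);
  }

  // internal nodes whose both children are leaves ("prunable")
  void nog_nodes(std::vector<int>& out) const {
    out.clear();
    for (int i = 0; i < (int)var.size(); ++i)
      if (alive[i] && !is_leaf(i) && is_leaf(left[i]) && is_leaf(right[i]))
        out.push_back(i);
  }
};

inline bool go_left(int v, double x, double cutv, int vtype) {
  if (vtype == 0) return x <= cutv;
  uint64_t mask = (uint64_t)cutv;
  int lev = (int)x;
  return (mask >> lev) & 1u;
}

// marginal log-likelihood contribution of one leaf (terms that vary with the
// tree only; constants in n cancel within a move)
inline double leaf_loglik(double n, double s, double s2, double s2mu) {
  return 0.5 * (std::log(s2) - std::log(s2 + n * s2mu)) +
         s2mu * s * s / (2.0 * s2 * (s2 + n * s2mu));
}

inline double split_prob(double alpha, double beta, int d) {
  return alpha * std::pow(1.0 + d, -beta);
}

int sample_int(int n) {  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// Draw a split rule for `node_obs` on variable v from the GLOBAL candidate
// set (all observed unique values of the variable, max excluded), so the
// rule-proposal distribution is identical at every node and cancels exactly
// in the Metropolis-Hastings ratio; proposals that would leave a child empty
// are rejected by the caller.  For categorical: present levels assigned
// left/right, rejected until both sides nonempty; absent global levels coin-
// flipped so prediction at unseen levels is defined.
bool draw_rule(const NumericMatrix& X, const IntegerVector& vtype,
               const IntegerVector& nlev, const List& cutpoints,
               const std::vector<int>& node_obs, int v, double& cut_out) {
  if (vtype[v] == 0) {
    NumericVector cand = cutpoints[v];
    if (cand.size() < 1) return false;
    cut_out = cand[sample_int((int)cand.size())];
    return true;
  } else {
    int L = nlev[v];
    std::vector<bool> present(L, false);
    int npres = 0;
    for (int i : node_obs) {
      int lev = (int)X(i, v);
      if (!present[lev]) { present[lev] = true; ++npres; }
    }
    if (npres < 2) return false;
    for (int tries = 0; tries < 200; ++tries) {
      uint64_t mask = 0;
      int nl = 0, nr = 0;
      for (int l = 0; l < L; ++l) {
        bool leftside = unif_rand() < 0.5;
        if (leftside) mask |= (uint64_t(1) << l);
        if (present[l]) { if (leftside) ++nl; else ++nr; }
      }
      if (nl > 0 && nr > 0) { cut_out = (double)mask; return true; }
    }
    return false;
  }
}

} // namespace

// [[Rcpp::export(name = ".bart_mcmc")]]
List bart_mcmc(NumericMatrix X, NumericVector y, IntegerVector vtype,
               IntegerVector nlev, List cutpoints, int m, double alpha, double beta,
               double sigma_mu, double nu, double lambda, double sigma_init,
               double sigma_fixed, int n_burn, int n_draws, int thin,
               double p_grow, double p_prune, double p_change) {
  const int n = X.nrow();
  const int p = X.ncol();

  RNGScope scope;

  std::vector<Tree> trees(m);
  std::vector<std::vector<int>> leaf_of(m, std::vector<int>(n, 0));
  std::vector<std::vector<double>> treefit(m, std::vector<double>(n, 0.0));
  std::vector<double> allfit(n, 0.0);

  double sigma = (sigma_fixed > 0.0) ? sigma_fixed : sigma_init;
  const double s2mu = sigma_mu * sigma_mu;

  int total_iter = n_burn + n_draws * thin;
  List kept_states(n_draws);
  NumericVector kept_sigma(n_draws);
  int kept = 0;

  // acceptance bookkeeping
  long prop_cnt[3] = {0, 0, 0}, acc_cnt[3] = {0, 0, 0};

  std::vector<double> resid(n);
  std::vector<int> node_obs, lv, nog;

  for (int iter = 0; iter < total_iter; ++iter) {
    if (iter % 64 == 0) Rcpp::checkUserInterrupt();

    for (int t = 0; t < m; ++t) {
      Tree& tr = trees[t];
      std::vector<int>& lo = leaf_of[t];

      for (int i = 0; i < n; ++i) resid[i] = y[i] - allfit[i] + treefit[t][i];
      const double s2 = sigma * sigma;

      // ---- structural move ----
      double u = unif_rand();
      int move = (u < p_grow) ? 0 : (u < p_grow + p_prune) ? 1 : 2;

      if (move == 0) {
        // GROW
        tr.leaves(lv);
        int b = (int)lv.size();
        int leaf = lv[sample_int(b)];
        node_obs.clear();
        for (int i = 0; i < n; ++i) if (lo[i] == leaf) node_obs.push_back(i);
        int v = sample_int(p);
        double cutv;
        ++prop_cnt[0];
        if (!node_obs.empty() && draw_rule(X, vtype, nlev, cutpoints, node_obs, v, cutv)) {
          double nL = 0, nR = 0, sL = 0, sR = 0, s0 = 0;
          for (int i : node_obs) {
            s0 += resid[i];
            if (go_left(v, X(i, v), cutv, vtype[v])) { ++nL; sL += resid[i]; }
            else { ++nR; sR += resid[i]; }
          }
          double n0 = (double)node_obs.size();
          if (nL > 0 && nR > 0) {  // nonempty-leaf constraint
            int d = tr.depth(leaf);
            double psd = split_prob(alpha, beta, d);
            double psd1 = split_prob(alpha, beta, d + 1);
            tr.nog_nodes(nog);
            int w2_new = (int)nog.size() + 1;
            int par = tr.parent[leaf];
            if (par >= 0 && tr.is_leaf(tr.left[par] == leaf ? tr.right[par]
                                                            : tr.left[par]))
              w2_new -= 1;  // parent was a nog node, no longer is
            double logA =
                leaf_loglik(nL, sL, s2, s2mu) + leaf_loglik(nR, sR, s2, s2mu) -
                leaf_loglik(n0, s0, s2, s2mu) + std::log(psd) +
                2.0 * std::log(1.0 - psd1) - std::log(1.0 - psd) +
                std::log(p_prune) - std::log(p_grow) + std::log((double)b) -
                std::log((double)w2_new);
            if (std::log(unif_rand()) < logA) {
              int l = tr.new_node(leaf), r = tr.new_node(leaf);
              tr.var[leaf] = v; tr.cut[leaf] = cutv;
              tr.left[leaf] = l; tr.right[leaf] = r;
              for (int i : node_obs)
                lo[i] = go_left(v, X(i, v), cutv, vtype[v]) ? l : r;
              ++acc_cnt[0];
            }
          }
        }
      } else if (move == 1) {
        // PRUNE
        tr.nog_nodes(nog);
        if (!nog.empty()) {
          ++prop_cnt[1];
          int node = nog[sample_int((int)nog.size())];
          int l = tr.left[node], r = tr.right[node];
          double nL = 0, nR = 0, sL = 0, sR = 0;
          for (int i = 0; i < n; ++i) {
            if (lo[i] == l) { ++nL; sL += resid[i]; }
            else if (lo[i] == r) { ++nR; sR += resid[i]; }
          }
          double n0 = nL + nR, s0 = sL + sR;
          int d = tr.depth(node);
          double psd = split_prob(alpha, beta, d);
          double psd1 = split_prob(alpha, beta, d + 1);
          tr.leaves(lv);
          int b_new = (int)lv.size() - 1;
          double logA =
              leaf_loglik(n0, s0, s2, s2mu) - leaf_loglik(nL, sL, s2, s2mu) -
              leaf_loglik(nR, sR, s2, s2mu) - std::log(psd) -
              2.0 * std::log(1.0 - psd1) + std::log(1.0 - psd) +
              std::log(p_grow) - std::log(p_prune) +
              std::log((double)nog.size()) - std::log((double)b_new);
          if (std::log(unif_rand()) < logA) {
            tr.alive[l] = tr.alive[r] = false;
            tr.left[node] = tr.right[node] = -1;
            tr.var[node] = -1;
            for (int i = 0; i < n; ++i)
              if (lo[i] == l || lo[i] == r) lo[i] = node;
            ++acc_cnt[1];
          }
        }
      } else {
        // CHANGE (rule of a node whose children are both leaves)
        tr.nog_nodes(nog);
        if (!nog.empty()) {
          ++prop_cnt[2];
          int node = nog[sample_int((int)nog.size())];
          int l = tr.left[node], r = tr.right[node];
          node_obs.clear();
          double nL = 0, nR = 0, sL = 0, sR = 0;
          for (int i = 0; i < n; ++i) {
            if (lo[i] == l) { node_obs.push_back(i); ++nL; sL += resid[i]; }
            else if (lo[i] == r) { node_obs.push_back(i); ++nR; sR += resid[i]; }
          }
          int v = sample_int(p);
          double cutv;
          if (draw_rule(X, vtype, nlev, cutpoints, node_obs, v, cutv)) {
            double nL2 = 0, nR2 = 0, sL2 = 0, sR2 = 0;
            for (int i : node_obs) {
              if (go_left(v, X(i, v), cutv, vtype[v])) { ++nL2; sL2 += resid[i]; }
              else { ++nR2; sR2 += resid[i]; }
            }
            if (nL2 > 0 && nR2 > 0) {
              double logA = leaf_loglik(nL2, sL2, s2, s2mu) +
                            leaf_loglik(nR2, sR2, s2, s2mu) -
                            leaf_loglik(nL, sL, s2, s2mu) -
                            leaf_loglik(nR, sR, s2, s2mu);
              if (std::log(unif_rand()) < logA) {
                tr.var[node] = v; tr.cut[node] = cutv;
                for (int i : node_obs)
                  lo[i] = go_left(v, X(i, v), cutv, vtype[v]) ? l : r;
                ++acc_cnt[2];
              }
            }
          }
        }
      }

      // ---- leaf values from conjugate full conditionals ----
      {
        int nn = (int)tr.var.size();
        std::vector<double> cnt(nn, 0.0), sum(nn, 0.0);
        for (int i = 0; i < n; ++i) { cnt[lo[i]] += 1.0; sum[lo[i]] += resid[i]; }
        tr.leaves(lv);
        for (int leaf : lv) {
          if (cnt[leaf] <= 0.0)
            stop("internal error: empty leaf after accepted move");
          double post_var = s2 * s2mu / (s2 + cnt[leaf] * s2mu);
          double post_mean = sum[leaf] * s2mu / (s2 + cnt[leaf] * s2mu);
          tr.value[leaf] = post_mean + norm_rand() * std::sqrt(post_var);
        }
        for (int i = 0; i < n; ++i) {
          double nf = tr.value[lo[i]];
          allfit[i] += nf - treefit[t][i];
          treefit[t][i] = nf;
        }
      }
    }

    // ---- sigma ----
    if (sigma_fixed <= 0.0) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = y[i] - allfit[i];
        sse += e * e;
      }
      double chi = R::rchisq(nu + n);
      sigma = std::sqrt((nu * lambda + sse) / chi);
    }

    // ---- record ----
    if (iter >= n_burn && (iter - n_burn) % thin == 0 && kept < n_draws) {
      List forest(m);
      for (int t = 0; t < m; ++t) {
        Tree& tr = trees[t];
        // compact alive nodes, root first (preorder)
        std::vector<int> order, stack;
        stack.push_back(tr.root);
        while (!stack.empty()) {
          int nd = stack.back(); stack.pop_back();
          order.push_back(nd);
          if (!tr.is_leaf(nd)) {
            stack.push_back(tr.right[nd]);
            stack.push_back(tr.left[nd]);
          }
        }
        std::vector<int> newid(tr.var.size(), -1);
        for (int k = 0; k < (int)order.size(); ++k) newid[order[k]] = k;
        NumericMatrix mat((int)order.size(), 5);
        for (int k = 0; k < (int)order.size(); ++k) {
          int nd = order[k];
          bool lf = tr.is_leaf(nd);
          mat(k, 0) = lf ? -1.0 : (double)tr.var[nd];
          mat(k, 1) = tr.cut[nd];
          mat(k, 2) = lf ? -1.0 : (double)newid[tr.left[nd]];
          mat(k, 3) = lf ? -1.0 : (double)newid[tr.right[nd]];
          mat(k, 4) = tr.value[nd];
        }
        forest[t] = mat;
      }
      kept_states[kept] = forest;
      kept_sigma[kept] = sigma;
      ++kept;
    }
  }

  NumericVector prop(3), acc(3);
  for (int j = 0; j < 3; ++j) { prop[j] = (double)prop_cnt[j]; acc[j] = (double)acc_cnt[j]; }

  return List::create(_["states"] = kept_states, _["sigma"] = kept_sigma,
                      _["proposals"] = prop, _["accepts"] = acc);
}

// [[Rcpp::export(name = ".bart_predict")]]
NumericMatrix bart_predict_cpp(List states, NumericMatrix X,
                               IntegerVector vtype) {
  const int S = states.size();
  const int n = X.nrow();
  NumericMatrix out(S, n);
  for (int s = 0; s < S; ++s) {
    List forest = states[s];
    const int m = forest.size();
    for (int t = 0; t < m; ++t) {
      NumericMatrix tr = forest[t];
      for (int i = 0; i < n; ++i) {
        int nd = 0;
        while (tr(nd, 0) >= 0.0) {
          int v = (int)tr(nd, 0);
          nd = go_left(v, X(i, v), tr(nd, 1), vtype[v]) ? (int)tr(nd, 2)
                                                        : (int)tr(nd, 3);
        }
        out(s, i) += tr(nd, 4);
      }
    }
  }
  return out;
}
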