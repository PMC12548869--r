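#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// x log x with the 0 log 0 = 0 convention.
static inline double xlx(double x) { return x > 0 ? x * std::log(x) : 0.0; }

// Single-node Metropolis MCMC for the bipartite Poisson degree-corrected
// SBM with profiled (maximum-likelihood) rates.  One sweep proposes one
// move per node; states are retained every `thin` sweeps after `burn_in`.
// Uses R's RNG so that chains are reproducible via set.seed().
// [[Rcpp::export]]
List dcsbm_mcmc(IntegerVector edge_u, IntegerVector edge_v,
                int n_u, int n_v, int k_u, int k_v,
                IntegerVector init_gu, IntegerVector init_gv,
                int sweeps, int burn_in, int thin) {
  const int m = edge_u.size();
  std::vector<int> gu(init_gu.begin(), init_gu.end());
  std::vector<int> gv(init_gv.begin(), init_gv.end());

  // adjacency lists
  std::vector<std::vector<int>> adj_u(n_u), adj_v(n_v);
  for (int e = 0; e < m; e++) {
    adj_u[edge_u[e]].push_back(edge_v[e]);
    adj_v[edge_v[e]].push_back(edge_u[e]);
  }

  // sufficient statistics: m_rs (k_u x k_v), kappa_r, kappa_s
  std::vector<double> mrs((size_t)k_u * k_v, 0.0);
  std::vector<double> kr(k_u, 0.0), ks(k_v, 0.0);
  for (int e = 0; e < m; e++) {
    mrs[(size_t)gu[edge_u[e]] * k_v + gv[edge_v[e]]] += 1.0;
    kr[gu[edge_u[e]]] += 1.0;
    ks[gv[edge_v[e]]] += 1.0;
  }

  // partition-dependent part of the profile log-likelihood
  double ll = 0.0;
  for (size_t i = 0; i < mrs.size(); i++) ll += xlx(mrs[i]);
  for (int r = 0; r < k_u; r++) ll -= xlx(kr[r]);
  for (int s = 0; s < k_v; s++) ll -= xlx(ks[s]);

  const int n_total = n_u + n_v;
  const int n_keep = (sweeps - burn_in + thin - 1) / thin;
  IntegerMatrix keep_gu(n_u, n_keep), keep_gv(n_v, n_keep);
  NumericVector keep_ll(n_keep);
  int kept = 0;
  long long proposed = 0, accepted = 0;
  std::vector<double> t_cnt(std::max(k_u, k_v), 0.0);

  GetRNGstate();
  for (int sw = 0; sw < sweeps; sw++) {
    for (int step = 0; step < n_total; step++) {
      int node = (int)(unif_rand() * n_total);
      if (node >= n_total) node = n_total - 1;
      double delta = 0.0;
      if (node < n_u) {  // move a drug node
        if (k_u < 2) continue;
        int u = node, r_old = gu[u];
        int r_new = (int)(unif_rand() * k_u);
        if (r_new >= k_u) r_new = k_u - 1;
        proposed++;
        if (r_new == r_old) { accepted++; continue; }
        const std::vector<int>& nb = adj_u[u];
        double d = (double)nb.size();
        // edges from u into each disease group
        for (int s = 0; s < k_v; s++) t_cnt[s] = 0.0;
        for (size_t j = 0; j < nb.size(); j++) t_cnt[gv[nb[j]]] += 1.0;
        for (int s = 0; s < k_v; s++) {
          double t = t_cnt[s];
          if (t == 0.0) continue;
          double a = mrs[(size_t)r_old * k_v + s];
          double b = mrs[(size_t)r_new * k_v + s];
          delta += xlx(a - t) - xlx(a) + xlx(b + t) - xlx(b);
        }
        delta -= xlx(kr[r_old] - d) - xlx(kr[r_old]);
        delta -= xlx(kr[r_new] + d) - xlx(kr[r_new]);
        if (delta >= 0.0 || unif_rand() < std::exp(delta)) {
          accepted++;
          for (int s = 0; s < k_v; s++) {
            double t = t_cnt[s];
            if (t == 0.0) continue;
            mrs[(size_t)r_old * k_v + s] -= t;
            mrs[(size_t)r_new * k_v + s] += t;
          }
          kr[r_old] -= d; kr[r_new] += d;
          gu[u] = r_new;
          ll += delta;
        }
      } else {  // move a disease node
        if (k_v < 2) continue;
        int v = node - n_u, s_old = gv[v];
        int s_new = (int)(unif_rand() * k_v);
        if (s_new >= k_v) s_new = k_v - 1;
        proposed++;
        if (s_new == s_old) { accepted++; continue; }
        const std::vector<int>& nb = adj_v[v];
        double d = (double)nb.size();
        for (int r = 0; r < k_u; r++) t_cnt[r] = 0.0;
        for (size_t j = 0; j < nb.size(); j++) t_cnt[gu[nb[j]]] += 1.0;
        for (int r = 0; r < k_u; r++) {
          double t = t_cnt[r];
          if (t == 0.0) continue;
          double a = mrs[(size_t)r * k_v + s_old];
          double b = mrs[(size_t)r * k_v + s_new];
          delta += xlx(a - t) - xlx(a) + xlx(b + t) - xlx(b);
        }
        delta -= xlx(ks[s_old] - d) - xlx(ks[s_old]);
        delta -= xlx(ks[s_new] + d) - xlx(ks[s_new]);
        if (delta >= 0.0 || unif_rand() < std::exp(delta)) {
          accepted++;
          for (int r = 0; r < k_u; r++) {
            double t = t_cnt[r];
            if (t == 0.0) continue;
            mrs[(size_t)r * k_v + s_old] -= t;
            mrs[(size_t)r * k_v + s_new] += t;
          }
          ks[s_old] -= d; ks[s_new] += d;
          gv[v] = s_new;
          ll += delta;
        }
      }
    }
    if (sw >= burn_in && (sw - burn_in) % thin == 0 && kept < n_keep) {
      for (int u = 0; u < n_u; u++) keep_gu(u, kept) = gu[u];
      for (int v = 0; v < n_v; v++) keep_gv(v, kept) = gv[v];
      keep_ll[kept] = ll;
      kept++;
    }
  }
  PutRNGstate();

  // degree terms and -m make the retained values full profile log-likelihoods
  double base = -(double)m;
  for (int u = 0; u < n_u; u++) base += xlx((double)adj_u[u].size());
  for (int v = 0; v < n_v; v++) base += xlx((double)adj_v[v].size());
  for (int i = 0; i < kept; i++) keep_ll[i] += base;

  return List::create(
    _["gu"] = keep_gu, _["gv"] = keep_gv, _["loglik"] = keep_ll,
    _["acceptance_rate"] =
        proposed > 0 ? (double)accepted / (double)proposed : 1.0);
}
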