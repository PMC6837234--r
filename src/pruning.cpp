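#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning under the frequency-scaled single-rate CTMC
// (F81-style generalization). Transition kernel in closed form:
//   p_ij(t) = pi_j + (delta_ij - pi_j) * exp(-mu * t)
// so a child's message to its parent is
//   m_i = e * L_i + (1 - e) * sum_j pi_j L_j,   e = exp(-mu * t).
// Branch lengths are expected in the same time units as mu^-1.
//
// Tree encoding (prepared in R by prep_tree): postorder edge list with
// 0-based parent/child indices, tips 0..ntip-1, root = ntip.

static double loglik_tree(const IntegerVector& parent,
                          const IntegerVector& child,
                          const NumericVector& len,
                          const IntegerVector& states,  // per tip, -1 missing
                          const NumericVector& pi,
                          double mu,
                          int ntip, int nnode) {
  const int k = pi.size();
  const int ntot = ntip + nnode;
  std::vector<double> L(ntot * k);
  for (int t = 0; t < ntip; ++t) {
    double* Lt = &L[t * k];
    int s = states[t];
    if (s < 0) { for (int i = 0; i < k; ++i) Lt[i] = 1.0; }
    else { for (int i = 0; i < k; ++i) Lt[i] = 0.0; Lt[s] = 1.0; }
  }
  for (int n = ntip; n < ntot; ++n)
    for (int i = 0; i < k; ++i) L[n * k + i] = 1.0;

  double logscale = 0.0;
  const int nedge = parent.size();
  for (int e = 0; e < nedge; ++e) {
    const int pa = parent[e], ch = child[e];
    const double ee = std::exp(-mu * len[e]);
    const double* Lc = &L[ch * k];
    double* Lp = &L[pa * k];
    double pidot = 0.0;
    for (int j = 0; j < k; ++j) pidot += pi[j] * Lc[j];
    double mx = 0.0;
    for (int i = 0; i < k; ++i) {
      const double m = ee * Lc[i] + (1.0 - ee) * pidot;
      Lp[i] *= m;
      if (Lp[i] > mx) mx = Lp[i];
    }
    if (mx > 0.0 && (mx < 1e-200 || mx > 1e200)) {
      for (int i = 0; i < k; ++i) Lp[i] /= mx;
      logscale += std::log(mx);
    }
  }
  double lik = 0.0;
  const double* Lr = &L[ntip * k];
  for (int i = 0; i < k; ++i) lik += pi[i] * Lr[i];
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + logscale;
}

// [[Rcpp::export(name = ".loglik_cpp")]]
double loglik_cpp(List tree, IntegerVector states, NumericVector pi,
                  double mu) {
  return loglik_tree(tree["parent"], tree["child"], tree["len"], states, pi,
                     mu, as<int>(tree["ntip"]), as<int>(tree["nnode"]));
}

struct PriorSpec {
  int type;       // 0 uniform(0, upper), 1 exponential(mean)
  double p1;
  double logdens(double mu) const {
    if (type == 0) return (mu >= 0.0 && mu <= p1) ? -std::log(p1) : R_NegInf;
    return (mu >= 0.0) ? -std::log(p1) - mu / p1 : R_NegInf;
  }
};

// per-character data: one (pruned, postorder-encoded) tree per tree index,
// the matching tip states, and the character's stationary frequencies
struct CharData {
  std::vector<IntegerVector> parent, child, states;
  std::vector<NumericVector> len;
  std::vector<int> ntip, nnode;
  NumericVector pi;
};

// Metropolis-Hastings sampler for the base rate mu (log-scale Gaussian
// random walk), with optional uniform tree-swap proposals across a
// posterior tree sample. Several characters may be analysed jointly as
// replicates sharing mu (their log-likelihoods add). `beta` tempers the
// likelihood (power posterior) for the stepping-stone sampler; beta = 0
// samples the prior. Uses R's RNG, so runs reproduce via set.seed().
//
// `chars` is a list over characters; each element is a list with `trees`
// (list of encoded trees), `states` (list of tip-state vectors, one per
// tree) and `pi`.
// [[Rcpp::export(name = ".mcmc_cpp")]]
List mcmc_cpp(List chars, int ntree,
              int prior_type, double prior_par,
              int total, int burnin, int thin,
              double init_mu, double init_step,
              double beta, bool tree_moves) {
  RNGScope scope;
  const int nchar = chars.size();
  PriorSpec prior{prior_type, prior_par};

  std::vector<CharData> cd(nchar);
  for (int c = 0; c < nchar; ++c) {
    List ch = chars[c];
    List trees = ch["trees"], states = ch["states"];
    cd[c].pi = as<NumericVector>(ch["pi"]);
    for (int t = 0; t < ntree; ++t) {
      List tr = trees[t];
      cd[c].parent.push_back(tr["parent"]);
      cd[c].child.push_back(tr["child"]);
      cd[c].len.push_back(tr["len"]);
      cd[c].ntip.push_back(as<int>(tr["ntip"]));
      cd[c].nnode.push_back(as<int>(tr["nnode"]));
      cd[c].states.push_back(as<IntegerVector>(states[t]));
    }
  }

  auto ll = [&](double mu, int t) {
    double s = 0.0;
    for (int c = 0; c < nchar; ++c)
      s += loglik_tree(cd[c].parent[t], cd[c].child[t], cd[c].len[t],
                       cd[c].states[t], cd[c].pi, mu,
                       cd[c].ntip[t], cd[c].nnode[t]);
    return s;
  };

  double mu = init_mu, step = init_step;
  int tree_ix = 0;
  double cur_ll = ll(mu, tree_ix);
  double cur_lp = prior.logdens(mu);

  const int ndraw = (total - burnin) / thin;
  NumericVector mu_draws(ndraw), ll_draws(ndraw);
  IntegerVector tree_draws(ndraw);
  int drawn = 0;
  long acc = 0, prop = 0;        // rate moves overall
  int win_acc = 0, win_prop = 0; // adaptation window (burn-in only)

  for (int it = 1; it <= total; ++it) {
    const bool do_tree = tree_moves && ntree > 1 && unif_rand() < 0.5;
    if (do_tree) {
      int cand = (int)(unif_rand() * ntree);
      if (cand == ntree) cand = ntree - 1;
      const double cand_ll = ll(mu, cand);
      if (std::log(unif_rand()) < beta * (cand_ll - cur_ll)) {
        tree_ix = cand; cur_ll = cand_ll;
      }
    } else {
      const double mu_new = mu * std::exp(norm_rand() * step);
      const double lp_new = prior.logdens(mu_new);
      double lr = lp_new - cur_lp + std::log(mu_new) - std::log(mu);
      double ll_new = cur_ll;
      if (R_finite(lp_new)) {
        ll_new = ll(mu_new, tree_ix);
        lr += beta * (ll_new - cur_ll);
      }
      ++prop; ++win_prop;
      if (R_finite(lp_new) && std::log(unif_rand()) < lr) {
        mu = mu_new; cur_ll = ll_new; cur_lp = lp_new;
        ++acc; ++win_acc;
      }
      // adapt the proposal scale toward 20-40% acceptance during burn-in,
      // frozen afterwards so the retained chain satisfies detailed balance
      if (it <= burnin && win_prop >= 50) {
        const double r = (double)win_acc / win_prop;
        if (r > 0.4) step *= 1.25; else if (r < 0.2) step /= 1.25;
        win_acc = 0; win_prop = 0;
      }
    }
    if (it > burnin && (it - burnin) % thin == 0 && drawn < ndraw) {
      mu_draws[drawn] = mu;
      ll_draws[drawn] = cur_ll;
      tree_draws[drawn] = tree_ix + 1;
      ++drawn;
    }
  }
  return List::create(_["mu"] = mu_draws, _["loglik"] = ll_draws,
                      _["tree"] = tree_draws,
                      _["acceptance"] = prop ? (double)acc / prop : NA_REAL,
                      _["step"] = step);
}
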