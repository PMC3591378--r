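// Gibbs sweep for the mixed-stock model: latent origins z_i, stock
// proportions theta (Dirichlet), and optionally population allele
// frequencies (Dirichlet, conditioned on baseline counts plus the allele
// counts of mixture fish currently assigned to each population).
//
// All randomness comes from R's RNG so that set.seed() in R makes a run
// bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Sample a categorical index from unnormalized log-weights.
static int sample_cat_log(const arma::rowvec& logw, const arma::vec& theta) {
  const int K = logw.n_elem;
  double m = logw.max();
  arma::vec w(K);
  if (!std::isfinite(m)) {
    // no admissible origin: fall back to the mixture proportions alone
    w = theta;
  } else {
    for (int k = 0; k < K; ++k) w[k] = std::exp(logw[k] - m);
  }
  double s = arma::accu(w);
  if (!(s > 0.0)) w.fill(1.0), s = static_cast<double>(K);
  double u = unif_rand() * s, acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
List gibbs_gsi_cpp(const arma::mat& X,            // n x C copy counts
                   const arma::mat& prior_counts, // C x K (allele prior + baseline)
                   const arma::mat& logP_fixed,   // C x K, used when !update_freqs
                   const arma::uvec& block,       // C, 0-based locus per column
                   const int n_loci,
                   const arma::vec& alpha,        // K mixture Dirichlet prior
                   const arma::vec& theta0,       // K starting proportions
                   const int n_iter, const int thin,
                   const int burn_in_retained,
                   const bool update_freqs) {
  const int n = X.n_rows, C = X.n_cols, K = alpha.n_elem;
  const int n_ret = n_iter / thin;

  arma::mat theta_draws(n_ret, K, arma::fill::zeros);
  arma::mat zcount(n, K, arma::fill::zeros);
  arma::ivec z(n, arma::fill::zeros);
  arma::vec theta = theta0;
  arma::mat L(n, K);            // per-fish per-pop log-likelihood
  arma::mat M(C, K, arma::fill::zeros);  // mixture allele counts by origin
  arma::mat logP(C, K);

  if (!update_freqs) L = X * logP_fixed;

  int ret = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    if (update_freqs) {
      // p_{k,l} ~ Dirichlet(prior + baseline + assigned mixture counts);
      // on the first sweep M is zero, i.e. the baseline posterior.
      for (int k = 0; k < K; ++k) {
        arma::vec g(C);
        for (int c = 0; c < C; ++c)
          g[c] = R::rgamma(prior_counts(c, k) + M(c, k), 1.0);
        arma::vec bs(n_loci, arma::fill::zeros);
        for (int c = 0; c < C; ++c) bs[block[c]] += g[c];
        for (int c = 0; c < C; ++c) logP(c, k) = std::log(g[c] / bs[block[c]]);
      }
      L = X * logP;
    }

    arma::vec logtheta = arma::log(theta);
    arma::ivec nk(K, arma::fill::zeros);
    if (update_freqs) M.zeros();
    for (int i = 0; i < n; ++i) {
      arma::rowvec lw = L.row(i) + logtheta.t();
      int zi = sample_cat_log(lw, theta);
      z[i] = zi;
      nk[zi] += 1;
      if (update_freqs) M.col(zi) += X.row(i).t();
    }

    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      theta[k] = R::rgamma(alpha[k] + nk[k], 1.0);
      tot += theta[k];
    }
    theta /= tot;

    if (iter % thin == 0) {
      theta_draws.row(ret) = theta.t();
      if (ret >= burn_in_retained)
        for (int i = 0; i < n; ++i) zcount(i, z[i]) += 1.0;
      ++ret;
    }
  }

  return List::create(_["theta"] = theta_draws, _["zcount"] = zcount);
}
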