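#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Blocked conjugate Gibbs sampler for the Gaussian mixed model
//   y = W theta + e,  e ~ N(0, sigma2_e I)
// where theta stacks the fixed effects (first p_fixed columns of W, prior
// N(0, 1/fixed_prec) each) and B random-effect blocks. Block b has prior
// N(0, sigma2_b K_b) with K_b = A (the phylogenetic covariance, precision
// Ainv passed in) for the block indexed by phylo_block, and K_b = I otherwise.
//
// Each iteration draws (i) all location effects jointly from their
// multivariate-normal full conditional (the mixed-model equations given the
// current variances), then (ii) each variance from its inverse-gamma full
// conditional: shape pr_shape + k/2, rate pr_scale + S/2 with S the block
// quadratic form (u' Ainv u for the phylogenetic block, the residual sum of
// squares for sigma2_e).
//
// All randomness comes from R's RNG, so set.seed() on the R side makes runs
// exactly reproducible. Retained draws are iterations t with t > burn_in and
// (t - burn_in) % thin == 0. The stored deviance is the Gaussian deviance
// conditional on the location effects: n log(2 pi sigma2_e) + SSE / sigma2_e.

// [[Rcpp::export]]
List gibbs_mixed_cpp(const arma::vec& y, const arma::mat& W, int p_fixed,
                     const arma::ivec& block_start, const arma::ivec& block_size,
                     int phylo_block, const arma::mat& Ainv,
                     double fixed_prec, double pr_shape, double pr_scale,
                     int iterations, int burn_in, int thin,
                     bool update_variances,
                     arma::vec var_start, double resid_start) {
  const int n = y.n_elem;
  const int q = W.n_cols;
  const int B = block_start.n_elem;
  if (!y.is_finite()) stop("non-finite response");

  arma::mat WtW = W.t() * W;
  arma::vec Wty = W.t() * y;

  arma::vec s2 = var_start;       // one per random block
  double s2e = resid_start;

  const int nkeep = (iterations - burn_in) / thin;
  arma::mat theta_out(nkeep, q);
  arma::mat var_out(nkeep, B + 1);
  arma::vec dev_out(nkeep);

  arma::vec theta(q, arma::fill::zeros);
  arma::mat P(q, q), U(q, q);
  arma::vec z(q);
  int kept = 0;

  for (int t = 1; t <= iterations; ++t) {
    // --- joint location update ---
    P = WtW / s2e;
    for (int j = 0; j < p_fixed; ++j) P(j, j) += fixed_prec;
    for (int b = 0; b < B; ++b) {
      int r0 = block_start(b) - 1;           // 1-based from R
      int r1 = r0 + block_size(b) - 1;
      if (b == phylo_block - 1) {
        P.submat(r0, r0, r1, r1) += Ainv / s2(b);
      } else {
        for (int j = r0; j <= r1; ++j) P(j, j) += 1.0 / s2(b);
      }
    }
    bool ok = arma::chol(U, P);
    if (!ok) {                               // near-singular: tiny ridge
      P.diag() += 1e-8 * P.diag().max();
      if (!arma::chol(U, P)) stop("location-update precision not positive definite");
    }
    arma::vec mu = arma::solve(arma::trimatu(U),
                   arma::solve(arma::trimatl(U.t()), Wty / s2e));
    for (int j = 0; j < q; ++j) z(j) = R::norm_rand();
    theta = mu + arma::solve(arma::trimatu(U), z);

    arma::vec e = y - W * theta;
    double sse = arma::dot(e, e);
    if (!std::isfinite(sse)) stop("divergent quadratic form in residual update");

    // --- variance updates ---
    if (update_variances) {
      s2e = 1.0 / R::rgamma(pr_shape + 0.5 * n, 1.0 / (pr_scale + 0.5 * sse));
      for (int b = 0; b < B; ++b) {
        int r0 = block_start(b) - 1;
        int r1 = r0 + block_size(b) - 1;
        arma::vec u = theta.subvec(r0, r1);
        double S;
        if (b == phylo_block - 1) S = arma::as_scalar(u.t() * Ainv * u);
        else S = arma::dot(u, u);
        s2(b) = 1.0 / R::rgamma(pr_shape + 0.5 * block_size(b),
                                1.0 / (pr_scale + 0.5 * S));
      }
    }

    // --- retention ---
    if (t > burn_in && (t - burn_in) % thin == 0 && kept < nkeep) {
      theta_out.row(kept) = theta.t();
      for (int b = 0; b < B; ++b) var_out(kept, b) = s2(b);
      var_out(kept, B) = s2e;
      dev_out(kept) = n * std::log(2.0 * M_PI * s2e) + sse / s2e;
      ++kept;
    }
  }

  return List::create(_["theta"] = theta_out,
                      _["sigma2"] = var_out,
                      _["deviance"] = dev_out,
                      _["n_kept"] = kept);
}
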