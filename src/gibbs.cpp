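// Spike-and-slab gLV Gibbs sampler kernel.
//
// Per sweep, for each species i: collapsed update of every free
// (off-diagonal / higher-order) indicator with the coefficient
// integrated out analytically, then a joint draw of the included
// coefficients from their Gaussian full conditional (excluded ones from
// the prior), then the conjugate scaled-inverse-chi-squared update of
// v_w[i]; after all species, the shared v_r and v_a updates.
//
// All per-sweep algebra runs on the precomputed per-species Gram matrix
// G = X'X, cross-moment c = X'y and y'y, so the cost per sweep is
// independent of the number of regression rows. Coefficients are
// handled in the prior-standardized parameterization beta = sqrt(V) *
// gamma (gamma ~ N(0, I) a priori), which keeps the small linear
// systems well conditioned despite the raw CFU/ml covariate scales.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rinvchisq(double nu, double tau2) {
  return nu * tau2 / R::rchisq(nu);
}

// log marginal likelihood of one species' rows, coefficients of the
// included columns integrated over Normal(0, pvar) priors
static double marg_loglik(const arma::mat& G, const arma::vec& cy,
                          double yy, double n, const arma::uvec& idx,
                          const arma::vec& pvar, double vw) {
  double base = -0.5 * n * std::log(2.0 * M_PI * vw) - 0.5 * yy / vw;
  if (idx.n_elem == 0) return base;
  arma::vec sv = arma::sqrt(pvar.elem(idx));
  arma::mat A = (sv * sv.t()) % G.submat(idx, idx) / vw;
  A.diag() += 1.0;
  arma::vec b = sv % cy.elem(idx) / vw;
  arma::mat L = arma::chol(A, "lower");
  arma::vec u = arma::solve(arma::trimatl(L), b, arma::solve_opts::fast);
  double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  return base - 0.5 * logdet + 0.5 * arma::dot(u, u);
}

// [[Rcpp::export(name = "gibbs_kernel")]]
List gibbs_kernel(List G_list, List cy_list, NumericVector yy_vec,
                  NumericVector n_vec, IntegerMatrix free_cols,
                  IntegerVector is_r_col, NumericVector prior_vals,
                  int iterations, int burn_in, bool fix_variances,
                  double v_r0, double v_a0, NumericVector v_w0,
                  NumericMatrix init_beta) {
  const int S = yy_vec.size();
  const int p = free_cols.nrow();
  const double eta_r = prior_vals[0], theta_r = prior_vals[1];
  const double eta_a = prior_vals[2], theta_a = prior_vals[3];
  const double eta_w = prior_vals[4], theta_w = prior_vals[5];
  const double pi_edge = prior_vals[6];
  const double lpo = std::log(pi_edge) - std::log1p(-pi_edge);
  const bool higher_order = p > S + 1;

  std::vector<arma::mat> G(S);
  std::vector<arma::vec> cy(S);
  for (int i = 0; i < S; ++i) {
    G[i] = as<arma::mat>(G_list[i]);
    cy[i] = as<arma::vec>(cy_list[i]);
  }

  arma::umat freem(p, S);
  for (int i = 0; i < S; ++i)
    for (int c = 0; c < p; ++c) freem(c, i) = free_cols(c, i);

  // state
  arma::umat z(p, S, arma::fill::ones);      // column inclusion per species
  arma::mat beta(p, S);
  for (int i = 0; i < S; ++i)
    for (int c = 0; c < p; ++c) beta(c, i) = init_beta(c, i);
  double v_r = v_r0, v_a = v_a0;
  arma::vec v_w(S);
  for (int i = 0; i < S; ++i) v_w[i] = v_w0[i];

  const int n_keep = iterations - burn_in;
  arma::mat out_r(n_keep, S), out_vw(n_keep, S);
  arma::mat out_a(n_keep, S * S, arma::fill::zeros);
  arma::mat out_z(n_keep, S * S, arma::fill::zeros);
  arma::vec out_vr(n_keep), out_va(n_keep);
  arma::mat out_a3, out_a4, out_z3, out_z4;
  if (higher_order) {
    out_a3.set_size(n_keep, S); out_a4.set_size(n_keep, S);
    out_z3.set_size(n_keep, S); out_z4.set_size(n_keep, S);
  }

  arma::vec pvar(p);
  auto refresh_pvar = [&]() {
    for (int c = 0; c < p; ++c) pvar[c] = is_r_col[c] ? v_r : v_a;
  };

  for (int it = 0; it < iterations; ++it) {
    refresh_pvar();
    for (int i = 0; i < S; ++i) {
      const double n_i = n_vec[i], yy = yy_vec[i];
      // --- indicators (collapsed) ---
      for (int c = 0; c < p; ++c) {
        if (!freem(c, i)) continue;
        z(c, i) = 1;
        arma::uvec idx1 = arma::find(z.col(i) == 1);
        double m1 = marg_loglik(G[i], cy[i], yy, n_i, idx1, pvar, v_w[i]);
        z(c, i) = 0;
        arma::uvec idx0 = arma::find(z.col(i) == 1);
        double m0 = marg_loglik(G[i], cy[i], yy, n_i, idx0, pvar, v_w[i]);
        double p1 = 1.0 / (1.0 + std::exp(-(m1 - m0 + lpo)));
        z(c, i) = (R::unif_rand() < p1) ? 1 : 0;
      }
      // --- coefficients ---
      for (int c = 0; c < p; ++c)
        beta(c, i) = R::norm_rand() * std::sqrt(pvar[c]);
      arma::uvec idx = arma::find(z.col(i) == 1);
      if (idx.n_elem > 0) {
        arma::vec sv = arma::sqrt(pvar.elem(idx));
        arma::mat A = (sv * sv.t()) % G[i].submat(idx, idx) / v_w[i];
        A.diag() += 1.0;
        arma::vec b = sv % cy[i].elem(idx) / v_w[i];
        arma::mat L = arma::chol(A, "lower");
        arma::vec u = arma::solve(arma::trimatl(L), b, arma::solve_opts::fast);
        arma::vec gm = arma::solve(arma::trimatu(L.t()), u, arma::solve_opts::fast);
        arma::vec zr(idx.n_elem);
        for (arma::uword k = 0; k < idx.n_elem; ++k) zr[k] = R::norm_rand();
        arma::vec gam = gm + arma::solve(arma::trimatu(L.t()), zr, arma::solve_opts::fast);
        for (arma::uword k = 0; k < idx.n_elem; ++k)
          beta(idx[k], i) = sv[k] * gam[k];
      }
      // --- process-noise variance ---
      if (!fix_variances) {
        arma::vec be(p, arma::fill::zeros);
        for (int c = 0; c < p; ++c) if (z(c, i)) be[c] = beta(c, i);
        double ss = yy - 2.0 * arma::dot(be, cy[i]) +
          arma::as_scalar(be.t() * G[i] * be);
        if (ss < 0) ss = 0;
        v_w[i] = rinvchisq(eta_w + n_i,
                           (eta_w * theta_w + ss) / (eta_w + n_i));
      }
    }
    // --- shared coefficient variances ---
    if (!fix_variances) {
      double ss_r = 0;
      for (int i = 0; i < S; ++i) ss_r += beta(0, i) * beta(0, i);
      v_r = rinvchisq(eta_r + S, (eta_r * theta_r + ss_r) / (eta_r + S));
      double ss_a = 0; int n_a = 0;
      for (int i = 0; i < S; ++i)
        for (int c = 1; c < p; ++c) { ss_a += beta(c, i) * beta(c, i); ++n_a; }
      v_a = rinvchisq(eta_a + n_a, (eta_a * theta_a + ss_a) / (eta_a + n_a));
    }
    // --- store ---
    if (it >= burn_in) {
      int k = it - burn_in;
      for (int i = 0; i < S; ++i) {
        out_r(k, i) = beta(0, i);
        out_vw(k, i) = v_w[i];
        for (int j = 0; j < S; ++j) {
          out_a(k, j * S + i) = beta(1 + j, i);
          out_z(k, j * S + i) = z(1 + j, i);
        }
        if (higher_order) {
          out_a3(k, i) = beta(p - 2, i); out_z3(k, i) = z(p - 2, i);
          out_a4(k, i) = beta(p - 1, i); out_z4(k, i) = z(p - 1, i);
        }
      }
      out_vr[k] = v_r; out_va[k] = v_a;
    }
  }

  List out = List::create(
    Named("r") = wrap(out_r), Named("a") = wrap(out_a),
    Named("z") = wrap(out_z), Named("v_r") = wrap(out_vr),
    Named("v_a") = wrap(out_va), Named("v_w") = wrap(out_vw));
  if (higher_order) {
    out["a3"] = wrap(out_a3); out["z3"] = wrap(out_z3);
    out["a4"] = wrap(out_a4); out["z4"] = wrap(out_z4);
  }
  return out;
}
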