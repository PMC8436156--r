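// Blocked Gibbs sampler for the multivariate phylogenetic mixed model
//
//   y_i = x_i' beta + u_{species(i), trait(i)} [+ s_{species(i), trait(i)}] + e_i
//
//   vec(U) ~ N(0, Vp (x) A)   phylogenetic species effects, trait-major stacking
//   vec(S) ~ N(0, Vs (x) I)   optional non-phylogenetic species effects
//   e_i    ~ N(0, ve[trait(i)])   diagonal residual covariance
//
// Updates: (beta, U, S) jointly from their Gaussian full conditional;
// Vp, Vs from inverse-Wishart full conditionals; ve[t] from inverse-gamma.
// All randomness goes through R's RNG so results are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Wishart(df, scale S) draw via the Bartlett decomposition.
static mat rwishart(double df, const mat& S) {
  const uword k = S.n_cols;
  mat L = chol(S, "lower");
  mat B(k, k, fill::zeros);
  for (uword i = 0; i < k; ++i) {
    B(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (uword j = 0; j < i; ++j) B(i, j) = R::norm_rand();
  }
  mat LB = L * B;
  return LB * LB.t();
}

// Inverse-Wishart(df, scale S): draw W ~ Wishart(df, S^-1), return W^-1.
static mat riwishart(double df, const mat& S) {
  mat W = rwishart(df, inv_sympd(symmatu(S)));
  return inv_sympd(symmatu(W));
}

// Cholesky with escalating diagonal jitter; stops with a diagnostic if the
// conditional precision stays non-PD.
static mat chol_jitter(const mat& C) {
  mat L;
  if (chol(L, C, "lower")) return L;
  double base = mean(C.diag());
  for (int e = 8; e >= 2; --e) {
    double jit = base * std::pow(10.0, -(double)e);
    if (chol(L, C + jit * eye(C.n_rows, C.n_cols), "lower")) return L;
  }
  Rcpp::stop("conditional precision matrix is not positive definite after jitter");
  return L;
}

// [[Rcpp::export]]
Rcpp::List gibbs_pmm_cpp(const arma::vec& y,
                         const arma::uvec& trait,    // 0-based, length n
                         const arma::uvec& species,  // 0-based, length n
                         const arma::mat& X,
                         const arma::mat& Ainv,
                         const int k, const int m,
                         const arma::mat& vp_scale, const double vp_df,
                         const arma::mat& vs_scale, const double vs_df,
                         const arma::vec& ve_shape, const arma::vec& ve_rate,
                         const double beta_prec,
                         const bool include_phylo,
                         const bool include_species_term,
                         const bool vp_fixed, const arma::mat& fix_vp,
                         const bool ve_fixed, const arma::vec& fix_ve,
                         const arma::mat& vp_init, const arma::vec& ve_init,
                         const int n_iter, const int burn_in, const int thin,
                         const bool store_u) {
  const uword n = y.n_elem;
  const uword p = X.n_cols;
  const uword q = (uword)m * (uword)k;
  const uword off_u = p;
  const uword off_s = p + (include_phylo ? q : 0);
  const uword d = p + (include_phylo ? q : 0) + (include_species_term ? q : 0);

  // --- sufficient statistics (fixed across iterations) ---
  std::vector<uvec> rows_t(k);
  for (int t = 0; t < k; ++t) rows_t[t] = find(trait == (uword)t);

  std::vector<mat> XtX(k);
  std::vector<vec> Xty(k);
  vec n_t(k, fill::zeros);
  for (int t = 0; t < k; ++t) {
    const mat Xt = X.rows(rows_t[t]);
    XtX[t] = Xt.t() * Xt;
    Xty[t] = Xt.t() * y.elem(rows_t[t]);
    n_t(t) = (double)rows_t[t].n_elem;
  }

  // per-cell (trait, species) statistics; cell index c = t*m + s
  uvec cell(n);
  for (uword i = 0; i < n; ++i) cell(i) = trait(i) * (uword)m + species(i);
  vec n_cell(q, fill::zeros), y_cell(q, fill::zeros);
  mat Xsum_cell(q, p, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    n_cell(cell(i)) += 1.0;
    y_cell(cell(i)) += y(i);
    Xsum_cell.row(cell(i)) += X.row(i);
  }

  // --- state ---
  mat Vp = vp_fixed ? fix_vp : vp_init;
  mat Vs = include_species_term ? vp_init : mat(k, k, fill::eye);
  vec ve = ve_fixed ? fix_ve : ve_init;
  vec theta(d, fill::zeros);

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  mat beta_draws(n_keep, p);
  mat vp_draws(include_phylo ? n_keep : 0, (uword)k * k);
  mat ve_draws(n_keep, k);
  mat vs_draws(include_species_term ? n_keep : 0, (uword)k * k);
  mat u_draws((store_u && include_phylo) ? n_keep : 0, q);
  int kept = 0;

  mat C(d, d);
  vec b(d), zn(d);

  for (int iter = 0; iter < n_iter; ++iter) {
    // ---- (beta, u, s) joint update ----
    C.zeros();
    b.zeros();
    for (int t = 0; t < k; ++t) {
      const double w = 1.0 / ve(t);
      C.submat(0, 0, p - 1, p - 1) += w * XtX[t];
      b.subvec(0, p - 1) += w * Xty[t];
    }
    C.submat(0, 0, p - 1, p - 1).diag() += beta_prec;

    if (include_phylo || include_species_term) {
      for (uword c = 0; c < q; ++c) {
        if (n_cell(c) == 0) continue;
        const double w = 1.0 / ve(c / m);
        if (include_phylo) {
          C(off_u + c, off_u + c) += w * n_cell(c);
          b(off_u + c) += w * y_cell(c);
          for (uword j = 0; j < p; ++j) {
            C(j, off_u + c) += w * Xsum_cell(c, j);
            C(off_u + c, j) += w * Xsum_cell(c, j);
          }
        }
        if (include_species_term) {
          C(off_s + c, off_s + c) += w * n_cell(c);
          b(off_s + c) += w * y_cell(c);
          for (uword j = 0; j < p; ++j) {
            C(j, off_s + c) += w * Xsum_cell(c, j);
            C(off_s + c, j) += w * Xsum_cell(c, j);
          }
          if (include_phylo) {
            C(off_u + c, off_s + c) += w * n_cell(c);
            C(off_s + c, off_u + c) += w * n_cell(c);
          }
        }
      }
    }
    if (include_phylo) {  // prior precision kron(Vp^-1, Ainv)
      const mat Vpinv = inv_sympd(symmatu(Vp));
      for (int t1 = 0; t1 < k; ++t1)
        for (int t2 = 0; t2 < k; ++t2)
          C.submat(off_u + t1 * m, off_u + t2 * m,
                   off_u + t1 * m + m - 1, off_u + t2 * m + m - 1) +=
              Vpinv(t1, t2) * Ainv;
    }
    if (include_species_term) {  // prior precision kron(Vs^-1, I)
      const mat Vsinv = inv_sympd(symmatu(Vs));
      for (int t1 = 0; t1 < k; ++t1)
        for (int t2 = 0; t2 < k; ++t2)
          C.submat(off_s + t1 * m, off_s + t2 * m,
                   off_s + t1 * m + m - 1, off_s + t2 * m + m - 1).diag() +=
              Vsinv(t1, t2);
    }

    const mat L = chol_jitter(symmatu(C));
    const vec mu = solve(trimatu(L.t()), solve(trimatl(L), b));
    for (uword j = 0; j < d; ++j) zn(j) = R::norm_rand();
    theta = mu + solve(trimatu(L.t()), zn);

    const vec beta = theta.subvec(0, p - 1);

    // ---- residuals per trait ----
    vec ss(k, fill::zeros);
    {
      const vec xb = X * beta;
      for (uword i = 0; i < n; ++i) {
        double r = y(i) - xb(i);
        if (include_phylo) r -= theta(off_u + cell(i));
        if (include_species_term) r -= theta(off_s + cell(i));
        ss(trait(i)) += r * r;
      }
    }

    // ---- ve update ----
    if (!ve_fixed) {
      for (int t = 0; t < k; ++t) {
        const double shape = ve_shape(t) + 0.5 * n_t(t);
        const double rate = ve_rate(t) + 0.5 * ss(t);
        ve(t) = 1.0 / R::rgamma(shape, 1.0 / rate);
      }
    }

    // ---- Vp update ----
    if (include_phylo && !vp_fixed) {
      mat U(m, k);
      for (int t = 0; t < k; ++t)
        U.col(t) = theta.subvec(off_u + t * m, off_u + t * m + m - 1);
      const mat S = vp_scale + U.t() * Ainv * U;
      Vp = riwishart(vp_df + m, symmatu(S));
    }

    // ---- Vs update ----
    if (include_species_term) {
      mat Us(m, k);
      for (int t = 0; t < k; ++t)
        Us.col(t) = theta.subvec(off_s + t * m, off_s + t * m + m - 1);
      const mat S = vs_scale + Us.t() * Us;
      Vs = riwishart(vs_df + m, symmatu(S));
    }

    // ---- record ----
    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      beta_draws.row(kept) = beta.t();
      ve_draws.row(kept) = ve.t();
      if (include_phylo)
        vp_draws.row(kept) = vectorise(vp_fixed ? fix_vp : Vp).t();
      if (include_species_term) vs_draws.row(kept) = vectorise(Vs).t();
      if (store_u && include_phylo)
        u_draws.row(kept) = theta.subvec(off_u, off_u + q - 1).t();
      ++kept;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("beta") = beta_draws, Rcpp::Named("vp") = vp_draws,
      Rcpp::Named("ve") = ve_draws, Rcpp::Named("vs") = vs_draws,
      Rcpp::Named("u") = u_draws, Rcpp::Named("n_kept") = kept);
}
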