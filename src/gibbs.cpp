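// Gibbs samplers for the Bayesian multi-trait (MT) and multi-trait
// multi-environment (MTME) genomic prediction models.
//
// Both samplers work in the eigenbasis of the genomic relationship matrix
// G = V diag(d) V', which makes every genetic-value full conditional a set
// of independent t x t solves and keeps each sweep O(n^2 t) without ever
// materializing a Kronecker covariance. R's RNG is used throughout
// (RcppArmadillo routes arma::randn/randu through it), so set.seed() in R
// makes chains reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

// Wishart_p(nu, S) via Bartlett; inverse-Wishart draw = inv(Wishart(nu, inv(S)))
static mat rwishart(double nu, const mat& S) {
  uword p = S.n_rows;
  mat A(p, p, arma::fill::zeros);
  for (uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat L = arma::chol(S, "lower");
  mat LA = L * A;
  return LA * LA.t();
}

static mat riwishart(double nu, const mat& S) {
  mat Sinv = arma::inv_sympd(arma::symmatu(S));
  mat W = rwishart(nu, Sinv);
  return arma::inv_sympd(arma::symmatu(W));
}

// draw x ~ N(P^{-1} b, P^{-1}) given precision P and linear term b
static vec rmvnorm_prec(const mat& P, const vec& b) {
  mat U = arma::chol(arma::symmatu(P));           // P = U'U
  vec m = arma::solve(arma::trimatu(U), arma::solve(arma::trimatl(U.t()), b));
  vec z(b.n_elem);
  for (uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return m + arma::solve(arma::trimatu(U), z);
}

static void check_finite(const mat& x, int iter, const char* what) {
  if (!x.is_finite())
    stop("non-finite draw of %s at iteration %d", what, iter);
}

// ---------------------------------------------------------------- MT model
//
// Y (n x t): y_i = mu + u_i + e_i, U ~ MN(0, G, Sigma), e_i ~ N(0, diag(r)).
// miss: 1 where the cell is missing (data-augmented).
// [[Rcpp::export(name = ".mt_gibbs")]]
List mt_gibbs(const arma::mat& Y0, const arma::umat& miss,
              const arma::mat& V, const arma::vec& d,
              double nu_sigma, const arma::mat& S_sigma,
              double nu_r, const arma::vec& s2_r,
              int n_burn, int n_iter, int thin) {
  const uword n = Y0.n_rows, t = Y0.n_cols;
  mat Y = Y0;
  // initialize missing cells at trait means of observed cells
  for (uword a = 0; a < t; ++a) {
    arma::uvec obs = arma::find(miss.col(a) == 0);
    vec ya = Y.col(a);
    double m = obs.n_elem ? arma::mean(ya.elem(obs)) : 0.0;
    arma::uvec mis = arma::find(miss.col(a) == 1);
    ya.elem(mis).fill(m);
    Y.col(a) = ya;
  }
  vec mu = arma::mean(Y, 0).t();
  mat U(n, t, arma::fill::zeros);
  mat Sigma = arma::diagmat(arma::var(Y, 0, 0).t() * 0.5 + 1e-6);
  vec r = arma::var(Y, 0, 0).t() * 0.5 + 1e-6;
  vec dinv = 1.0 / d;

  int n_keep = n_iter / thin;
  mat U_sum(n, t, arma::fill::zeros), U_ss(n, t, arma::fill::zeros);
  mat Sigma_draws(n_keep, t * t), mu_draws(n_keep, t), r_draws(n_keep, t);
  int kept = 0;

  for (int it = 0; it < n_burn + n_iter; ++it) {
    // (1) intercepts, flat prior
    for (uword a = 0; a < t; ++a) {
      double m = arma::mean(Y.col(a) - U.col(a));
      mu(a) = m + R::norm_rand() * std::sqrt(r(a) / (double)n);
    }
    // (2) genetic values in the eigenbasis of G
    mat Yc = Y;
    Yc.each_row() -= mu.t();
    mat Yt = V.t() * Yc;
    mat Sigma_inv = arma::inv_sympd(arma::symmatu(Sigma));
    mat R_inv = arma::diagmat(1.0 / r);
    mat Ut(n, t);
    for (uword i = 0; i < n; ++i) {
      mat P = Sigma_inv * dinv(i) + R_inv;
      Ut.row(i) = rmvnorm_prec(P, R_inv * Yt.row(i).t()).t();
    }
    U = V * Ut;
    // (3) genetic covariance
    mat S = S_sigma + Ut.t() * (Ut.each_col() % dinv);
    Sigma = riwishart(nu_sigma + (double)n, S);
    check_finite(Sigma, it, "Sigma");
    // (4) residual variances, scaled-inv-chisq
    mat E = Yc - U;
    for (uword a = 0; a < t; ++a) {
      double sse = arma::dot(E.col(a), E.col(a));
      r(a) = (nu_r * s2_r(a) + sse) / R::rchisq(nu_r + (double)n);
      if (!std::isfinite(r(a)) || r(a) <= 0.0)
        stop("non-finite residual variance at iteration %d", it);
    }
    // (5) data augmentation of missing cells (diagonal R: independent traits)
    for (uword a = 0; a < t; ++a) {
      arma::uvec mis = arma::find(miss.col(a) == 1);
      for (uword k = 0; k < mis.n_elem; ++k)
        Y(mis(k), a) = mu(a) + U(mis(k), a) + R::norm_rand() * std::sqrt(r(a));
    }
    if (it >= n_burn && ((it - n_burn) % thin == thin - 1)) {
      U_sum += U; U_ss += U % U;
      Sigma_draws.row(kept) = arma::vectorise(Sigma).t();
      mu_draws.row(kept) = mu.t();
      r_draws.row(kept) = r.t();
      ++kept;
    }
  }
  mat U_mean = U_sum / (double)kept;
  mat U_sd = arma::sqrt(arma::clamp(U_ss / (double)kept - U_mean % U_mean,
                                    0.0, arma::datum::inf));
  return List::create(_["U_mean"] = U_mean, _["U_sd"] = U_sd,
                      _["Sigma_draws"] = Sigma_draws,
                      _["mu_draws"] = mu_draws, _["r_draws"] = r_draws,
                      _["n_kept"] = kept);
}

// -------------------------------------------------------------- MTME model
//
// Y (j x t), j = n*l, environment-major blocks of n lines:
//   Y = X Beta + Z1 B1 + Z2 B2 + E
// B1 ~ MN(0, G, Sigma_t), B2 ~ MN(0, Sigma_E (x) G, Sigma_t),
// E rows iid N(0, Re) (unstructured residual covariance).
// [[Rcpp::export(name = ".mtme_gibbs")]]
List mtme_gibbs(const arma::mat& Y0, const arma::umat& miss,
                const arma::mat& V, const arma::vec& d,
                int l, double nu_t, double nu_E, double nu_R,
                int n_burn, int n_iter, int thin) {
  const uword n = V.n_rows, t = Y0.n_cols, j = Y0.n_rows;
  if (j != n * (uword)l) stop("Y rows must equal n * l (environment-major)");
  mat Y = Y0;
  // initialize missing cells at their (env, trait) observed column means
  for (int e = 0; e < l; ++e) {
    for (uword a = 0; a < t; ++a) {
      double s = 0.0; int c = 0;
      for (uword i = 0; i < n; ++i)
        if (!miss(e * n + i, a)) { s += Y(e * n + i, a); ++c; }
      double m0 = c ? s / c : 0.0;
      for (uword i = 0; i < n; ++i)
        if (miss(e * n + i, a)) Y(e * n + i, a) = m0;
    }
  }
  mat Beta(l, t, arma::fill::zeros), B1(n, t, arma::fill::zeros),
      B2(j, t, arma::fill::zeros);
  mat Sigma_t = arma::eye(t, t) * 0.5, Sigma_E = arma::eye(l, l),
      Re = arma::diagmat(arma::var(Y, 0, 0).t() * 0.5 + 1e-6);
  mat S_t0 = arma::eye(t, t), S_E0 = arma::eye(l, l), S_R0 = arma::eye(t, t);
  vec dinv = 1.0 / d;

  int n_keep = n_iter / thin, kept = 0;
  mat Beta_sum(l, t, arma::fill::zeros), B1_sum(n, t, arma::fill::zeros),
      B2_sum(j, t, arma::fill::zeros), B1_ss(n, t, arma::fill::zeros);
  mat St_draws(n_keep, t * t), SE_draws(n_keep, l * l), Re_draws(n_keep, t * t);

  for (int it = 0; it < n_burn + n_iter; ++it) {
    mat Re_inv = arma::inv_sympd(arma::symmatu(Re));
    mat St_inv = arma::inv_sympd(arma::symmatu(Sigma_t));
    vec lamE; mat Q;
    arma::eig_sym(lamE, Q, arma::symmatu(Sigma_E));
    lamE = arma::clamp(lamE, 1e-10, arma::datum::inf);

    // (1) environment fixed effects, flat prior
    for (int e = 0; e < l; ++e) {
      mat Rm = Y.rows(e * n, (e + 1) * n - 1) - B1 -
               B2.rows(e * n, (e + 1) * n - 1);
      vec m = arma::mean(Rm, 0).t();
      mat Lc = arma::chol(arma::symmatu(Re) / (double)n, "lower");
      vec z(t); for (uword a = 0; a < t; ++a) z(a) = R::norm_rand();
      Beta.row(e) = (m + Lc * z).t();
    }
    // (2) genotype main effects: precision St_inv/d_i + l * Re_inv
    mat Wsum(n, t, arma::fill::zeros);
    for (int e = 0; e < l; ++e) {
      mat blk = Y.rows(e * n, (e + 1) * n - 1) -
                B2.rows(e * n, (e + 1) * n - 1);
      blk.each_row() -= Beta.row(e);
      Wsum += blk;
    }
    mat Wt = V.t() * Wsum;
    mat B1t(n, t);
    for (uword i = 0; i < n; ++i) {
      mat P = St_inv * dinv(i) + Re_inv * (double)l;
      B1t.row(i) = rmvnorm_prec(P, Re_inv * Wt.row(i).t()).t();
    }
    B1 = V * B1t;
    // (3) GxE effects in the (Q (x) V) basis
    arma::cube T(n, t, l);                    // V' (per-env residual)
    for (int e = 0; e < l; ++e) {
      mat blk = Y.rows(e * n, (e + 1) * n - 1) - B1;
      blk.each_row() -= Beta.row(e);
      T.slice(e) = V.t() * blk;
    }
    arma::cube B2tt(n, t, l);                 // draws in transformed basis
    for (int f = 0; f < l; ++f) {
      mat Wf(n, t, arma::fill::zeros);
      for (int e = 0; e < l; ++e) Wf += Q(e, f) * T.slice(e);
      for (uword i = 0; i < n; ++i) {
        mat P = St_inv / (lamE(f) * d(i)) + Re_inv;
        B2tt.slice(f).row(i) = rmvnorm_prec(P, Re_inv * Wf.row(i).t()).t();
      }
    }
    arma::cube T2(n, t, l);                   // back to G-eigen basis only
    for (int e = 0; e < l; ++e) {
      T2.slice(e).zeros();
      for (int f = 0; f < l; ++f) T2.slice(e) += Q(e, f) * B2tt.slice(f);
      B2.rows(e * n, (e + 1) * n - 1) = V * T2.slice(e);
    }
    // (4) trait covariance pooling B1 and B2
    mat S = S_t0 + B1t.t() * (B1t.each_col() % dinv);
    for (int f = 0; f < l; ++f)
      S += B2tt.slice(f).t() * (B2tt.slice(f).each_col() % (dinv / lamE(f)));
    Sigma_t = riwishart(nu_t + (double)(n + j), S);
    check_finite(Sigma_t, it, "Sigma_t");
    St_inv = arma::inv_sympd(arma::symmatu(Sigma_t));
    // (5) environment covariance: S_E = sum_ab St_inv(a,b) M_a' G^{-1} M_b,
    // with M_a the n x l reshape of trait a's GxE effects; in the G
    // eigenbasis M_a' G^{-1} M_b = C_a' D^{-1} C_b with C_a(, e) = T2_e(, a)
    mat SE = S_E0;
    arma::cube C(n, l, t);
    for (uword a = 0; a < t; ++a)
      for (int e = 0; e < l; ++e) C.slice(a).col(e) = T2.slice(e).col(a);
    for (uword a = 0; a < t; ++a)
      for (uword b = 0; b < t; ++b)
        SE += St_inv(a, b) *
              (C.slice(a).t() * (C.slice(b).each_col() % dinv));
    SE = arma::symmatu((SE + SE.t()) / 2.0);
    Sigma_E = riwishart(nu_E + (double)n * (double)t, SE);
    check_finite(Sigma_E, it, "Sigma_E");
    // the b1/b2 split shares Sigma_t, so the Sigma_E scale rides a
    // likelihood-flat direction; pinning the geometric mean of its
    // diagonal to 1 each sweep identifies the decomposition (the scale is
    // re-absorbed by Sigma_t's own full conditional next sweep)
    double gm = std::exp(arma::mean(arma::log(Sigma_E.diag())));
    Sigma_E /= gm;
    Sigma_t *= gm;                 // keeps the b2 prior invariant
    St_inv /= gm;
    // (6) residual covariance
    mat Efull = Y - B2;
    for (int e = 0; e < l; ++e) {
      Efull.rows(e * n, (e + 1) * n - 1) -= B1;
      Efull.rows(e * n, (e + 1) * n - 1).each_row() -= Beta.row(e);
    }
    Re = riwishart(nu_R + (double)j, S_R0 + Efull.t() * Efull);
    check_finite(Re, it, "Re");
    // (7) data augmentation: conditional normal within each row
    for (uword rix = 0; rix < j; ++rix) {
      arma::uvec mm = arma::find(miss.row(rix).t() == 1);
      if (!mm.n_elem) continue;
      arma::uvec oo = arma::find(miss.row(rix).t() == 0);
      int e = rix / n;
      arma::rowvec fit = Beta.row(e) + B1.row(rix - e * n) + B2.row(rix);
      vec em;
      if (!oo.n_elem) {
        mat Lc = arma::chol(arma::symmatu(Re), "lower");
        vec z(t); for (uword a = 0; a < t; ++a) z(a) = R::norm_rand();
        vec efull = Lc * z;
        em = efull.elem(mm);
      } else {
        vec eo = (Y.row(rix) - fit).t();
        mat Roo = Re.submat(oo, oo), Rmo = Re.submat(mm, oo),
            Rmm = Re.submat(mm, mm);
        mat K = Rmo * arma::inv_sympd(arma::symmatu(Roo));
        vec cm = K * eo.elem(oo);
        mat cv = arma::symmatu(Rmm - K * Rmo.t());
        mat Lc = arma::chol(cv + arma::eye(mm.n_elem, mm.n_elem) * 1e-12,
                            "lower");
        vec z(mm.n_elem); for (uword a = 0; a < mm.n_elem; ++a) z(a) = R::norm_rand();
        em = cm + Lc * z;
      }
      for (uword k = 0; k < mm.n_elem; ++k)
        Y(rix, mm(k)) = fit(mm(k)) + em(k);
    }
    if (it >= n_burn && ((it - n_burn) % thin == thin - 1)) {
      Beta_sum += Beta; B1_sum += B1; B2_sum += B2; B1_ss += B1 % B1;
      St_draws.row(kept) = arma::vectorise(Sigma_t).t();
      SE_draws.row(kept) = arma::vectorise(Sigma_E).t();
      Re_draws.row(kept) = arma::vectorise(Re).t();
      ++kept;
    }
  }
  mat B1_mean = B1_sum / (double)kept;
  mat B1_sd = arma::sqrt(arma::clamp(B1_ss / (double)kept - B1_mean % B1_mean,
                                     0.0, arma::datum::inf));
  return List::create(_["Beta_mean"] = Beta_sum / (double)kept,
                      _["B1_mean"] = B1_mean, _["B1_sd"] = B1_sd,
                      _["B2_mean"] = B2_sum / (double)kept,
                      _["St_draws"] = St_draws, _["SE_draws"] = SE_draws,
                      _["Re_draws"] = Re_draws, _["n_kept"] = kept);
}
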