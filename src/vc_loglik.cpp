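// Profile-likelihood kernels for pedigree variance-component models.
//
// All three entry points work on data rotated by the eigenvectors of the
// (block-diagonal, by pedigree) additive relationship matrix A = 2*Phi.
// After the rotation U'Y the stacked nk x nk covariance
//   Omega = A (x) G + I (x) E
// becomes block diagonal with n blocks M_i = d_i G + E (d_i eigenvalues of A),
// so one likelihood evaluation costs O(n k^3) instead of O((nk)^3).
// Mean-model coefficients are profiled out by GLS inside each call.
//
// Region kernels K = Z Z' (Z pre-scaled loadings) enter through the
// Woodbury identity so the cost stays O(n m^2) in the number m of region
// variants.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.837877066409345483560659472811;

static Rcpp::List ll_fail() {
  return Rcpp::List::create(Rcpp::Named("ll") = R_NegInf,
                            Rcpp::Named("ok") = false,
                            Rcpp::Named("beta") = R_NilValue);
}

static Rcpp::List ll_pack(double ll, const vec& beta) {
  return Rcpp::List::create(Rcpp::Named("ll") = ll,
                            Rcpp::Named("ok") = true,
                            Rcpp::Named("beta") = beta);
}

// Solve A beta = b with A = X' Omega^-1 X from its Cholesky; returns the
// profile log-likelihood. A must be positive definite (full-rank design).
static bool gls_finish(const mat& A, const vec& b, double yWy, double logdet,
                       double N, double& ll, vec& beta) {
  mat RA;
  if (!chol(RA, A)) return false;
  beta = solve(trimatu(RA), solve(trimatl(RA.t()), b));
  double quad = yWy - dot(beta, b);
  ll = -0.5 * (N * LOG2PI + logdet + quad);
  return true;
}

// Multivariate (k traits) profile log-likelihood, no region kernel.
// d: n eigenvalues of A; Yt: n x k rotated traits; Xt: n x p0 rotated
// covariates (intercept included); gt: rotated dosage (ignored if mode 0);
// mode: 0 no SNV term, 1 shared beta, 2 per-trait beta.
// [[Rcpp::export(name = ".vc_ll_rot")]]
Rcpp::List vc_ll_rot(const arma::vec& d, const arma::mat& Yt,
                     const arma::mat& Xt, const arma::vec& gt,
                     const int mode, const arma::mat& G, const arma::mat& E) {
  const uword n = Yt.n_rows, k = Yt.n_cols, p0 = Xt.n_cols;
  const uword pg = (mode == 0) ? 0 : (mode == 1 ? 1 : k);
  const uword p = k * p0 + pg;
  mat A(p, p, fill::zeros);
  vec b(p, fill::zeros);
  double yWy = 0.0, logdet = 0.0;
  mat M(k, k), R(k, k), Minv(k, k), xx(p0, p0);

  for (uword i = 0; i < n; ++i) {
    M = d(i) * G + E;
    if (!chol(R, M)) return ll_fail();
    logdet += 2.0 * accu(log(R.diag()));
    Minv = inv(trimatu(R));
    Minv = Minv * Minv.t();
    const rowvec x = Xt.row(i);
    const vec y = Yt.row(i).t();
    const vec My = Minv * y;
    yWy += dot(y, My);
    xx = x.t() * x;
    for (uword t = 0; t < k; ++t) {
      for (uword s = 0; s < k; ++s)
        A.submat(t * p0, s * p0, t * p0 + p0 - 1, s * p0 + p0 - 1) +=
            Minv(t, s) * xx;
      b.subvec(t * p0, t * p0 + p0 - 1) += My(t) * x.t();
    }
    if (mode == 1) {
      const double g = gt(i);
      A(p - 1, p - 1) += g * g * accu(Minv);
      for (uword t = 0; t < k; ++t) {
        const double rs = accu(Minv.row(t));
        A.submat(t * p0, p - 1, t * p0 + p0 - 1, p - 1) += g * rs * x.t();
        A.submat(p - 1, t * p0, p - 1, t * p0 + p0 - 1) += g * rs * x;
      }
      b(p - 1) += g * accu(My);
    } else if (mode == 2) {
      const double g = gt(i);
      const uword off = k * p0;
      for (uword t = 0; t < k; ++t) {
        for (uword s = 0; s < k; ++s) {
          A(off + t, off + s) += g * g * Minv(t, s);
          A.submat(t * p0, off + s, t * p0 + p0 - 1, off + s) +=
              g * Minv(t, s) * x.t();
          A.submat(off + s, t * p0, off + s, t * p0 + p0 - 1) +=
              g * Minv(t, s) * x;
        }
        b(off + t) += g * My(t);
      }
    }
  }
  double ll;
  vec beta;
  if (!gls_finish(A, b, yWy, logdet, (double)(n * k), ll, beta))
    return ll_fail();
  return ll_pack(ll, beta);
}

// Entries of M_i^-1 (M_i = d_i G + E) for all i at once, via closed-form
// adjugates for k <= 3 (columns of W in t*k+s order) plus the summed
// log-determinant. Returns false if any M_i is not positive definite.
static bool minv_entries(const vec& d, const mat& G, const mat& E,
                         const uword k, mat& W, double& logdet) {
  const uword n = d.n_elem;
  W.set_size(n, k * k);
  if (k == 1) {
    vec m = d * G(0, 0) + E(0, 0);
    if (m.min() <= 0) return false;
    W.col(0) = 1.0 / m;
    logdet = accu(log(m));
  } else if (k == 2) {
    vec m11 = d * G(0, 0) + E(0, 0), m12 = d * G(0, 1) + E(0, 1),
        m22 = d * G(1, 1) + E(1, 1);
    vec det = m11 % m22 - m12 % m12;
    if (m11.min() <= 0 || det.min() <= 0) return false;
    W.col(0) = m22 / det;
    W.col(1) = -m12 / det;
    W.col(2) = W.col(1);
    W.col(3) = m11 / det;
    logdet = accu(log(det));
  } else if (k == 3) {
    vec m11 = d * G(0, 0) + E(0, 0), m12 = d * G(0, 1) + E(0, 1),
        m13 = d * G(0, 2) + E(0, 2), m22 = d * G(1, 1) + E(1, 1),
        m23 = d * G(1, 2) + E(1, 2), m33 = d * G(2, 2) + E(2, 2);
    vec a11 = m22 % m33 - m23 % m23;
    vec a12 = m13 % m23 - m12 % m33;
    vec a13 = m12 % m23 - m13 % m22;
    vec a22 = m11 % m33 - m13 % m13;
    vec a23 = m12 % m13 - m11 % m23;
    vec a33 = m11 % m22 - m12 % m12;
    vec det = m11 % a11 + m12 % a12 + m13 % a13;
    vec det2 = m11 % m22 - m12 % m12;
    if (m11.min() <= 0 || det2.min() <= 0 || det.min() <= 0) return false;
    W.col(0) = a11 / det;
    W.col(1) = a12 / det;
    W.col(2) = a13 / det;
    W.col(3) = W.col(1);
    W.col(4) = a22 / det;
    W.col(5) = a23 / det;
    W.col(6) = W.col(2);
    W.col(7) = W.col(5);
    W.col(8) = a33 / det;
    logdet = accu(log(det));
  } else {
    logdet = 0.0;
    mat M(k, k), R(k, k);
    for (uword i = 0; i < n; ++i) {
      M = d(i) * G + E;
      if (!chol(R, M)) return false;
      logdet += 2.0 * accu(log(R.diag()));
      mat Minv = inv(trimatu(R));
      Minv = Minv * Minv.t();
      for (uword t = 0; t < k; ++t)
        for (uword s = 0; s < k; ++s) W(i, t * k + s) = Minv(t, s);
    }
  }
  return true;
}

// As vc_ll_rot, but also returns the analytic gradient of the profile
// log-likelihood with respect to the log-Cholesky parameters of G and E
// (theta layout: k log-diagonals, then strict lower triangle column-major,
// G block first). Uses the envelope theorem: at the GLS coefficients the
// profile gradient equals the partial derivative holding beta fixed,
//   dl/dP = -0.5 sum_i [tr(M_i^-1 dM_i) - q_i' dM_i q_i],  q_i = M_i^-1 r_i.
// [[Rcpp::export(name = ".vc_ll_rot_grad")]]
Rcpp::List vc_ll_rot_grad(const arma::vec& d, const arma::mat& Yt,
                          const arma::mat& Xt, const arma::vec& gt,
                          const int mode, const arma::vec& thetaG,
                          const arma::vec& thetaE) {
  const uword n = Yt.n_rows, k = Yt.n_cols, p0 = Xt.n_cols;
  const uword pg = (mode == 0) ? 0 : (mode == 1 ? 1 : k);
  const uword p = k * p0 + pg;
  const uword nc = k * (k + 1) / 2;
  // rebuild Cholesky factors from theta
  mat Lg(k, k, fill::zeros), Le(k, k, fill::zeros);
  {
    uword pos = k;
    for (uword j = 0; j < k; ++j) {
      Lg(j, j) = std::exp(thetaG(j));
      Le(j, j) = std::exp(thetaE(j));
    }
    for (uword c = 0; c < k; ++c)
      for (uword r2 = c + 1; r2 < k; ++r2) {
        Lg(r2, c) = thetaG(pos);
        Le(r2, c) = thetaE(pos);
        ++pos;
      }
  }
  const mat G = Lg * Lg.t(), E = Le * Le.t();

  mat W;
  double logdet;
  if (!minv_entries(d, G, E, k, W, logdet)) return ll_fail();

  // My(:, t) = sum_s W(:, t*k+s) % Y(:, s)
  mat My(n, k, fill::zeros);
  for (uword t = 0; t < k; ++t)
    for (uword s = 0; s < k; ++s) My.col(t) += W.col(t * k + s) % Yt.col(s);
  const double yWy = accu(Yt % My);

  mat A(p, p, fill::zeros);
  vec b(p, fill::zeros);
  for (uword t = 0; t < k; ++t) {
    for (uword s = t; s < k; ++s) {
      const mat B = Xt.t() * (Xt.each_col() % W.col(t * k + s));
      A.submat(t * p0, s * p0, t * p0 + p0 - 1, s * p0 + p0 - 1) = B;
      if (s != t)
        A.submat(s * p0, t * p0, s * p0 + p0 - 1, t * p0 + p0 - 1) = B.t();
    }
    b.subvec(t * p0, t * p0 + p0 - 1) = Xt.t() * My.col(t);
  }
  if (mode == 1) {
    vec sumW(n, fill::zeros), rowMy(n, fill::zeros);
    for (uword t = 0; t < k; ++t) {
      vec rs(n, fill::zeros);
      for (uword s = 0; s < k; ++s) rs += W.col(t * k + s);
      sumW += rs;
      const vec cross = Xt.t() * (gt % rs);
      A.submat(t * p0, p - 1, t * p0 + p0 - 1, p - 1) = cross;
      A.submat(p - 1, t * p0, p - 1, t * p0 + p0 - 1) = cross.t();
      rowMy += My.col(t);
    }
    A(p - 1, p - 1) = accu(gt % gt % sumW);
    b(p - 1) = accu(gt % rowMy);
  } else if (mode == 2) {
    const uword off = k * p0;
    for (uword t = 0; t < k; ++t) {
      for (uword s = 0; s < k; ++s) {
        A(off + t, off + s) = accu(gt % gt % W.col(t * k + s));
        const vec cross = Xt.t() * (gt % W.col(t * k + s));
        A.submat(t * p0, off + s, t * p0 + p0 - 1, off + s) = cross;
        A.submat(off + s, t * p0, off + s, t * p0 + p0 - 1) = cross.t();
      }
      b(off + t) = accu(gt % My.col(t));
    }
  }
  double ll;
  vec beta;
  if (!gls_finish(A, b, yWy, logdet, (double)(n * k), ll, beta))
    return ll_fail();

  // residuals and gradient accumulators, all vectorized over individuals
  mat Bmat(p0, k);
  for (uword t = 0; t < k; ++t) Bmat.col(t) = beta.subvec(t * p0, t * p0 + p0 - 1);
  mat Rm = Yt - Xt * Bmat;
  if (mode == 1) Rm.each_col() -= gt * beta(p - 1);
  if (mode == 2)
    for (uword t = 0; t < k; ++t) Rm.col(t) -= gt * beta(k * p0 + t);
  mat Q(n, k, fill::zeros);
  for (uword t = 0; t < k; ++t)
    for (uword s = 0; s < k; ++s) Q.col(t) += W.col(t * k + s) % Rm.col(s);
  mat SP(k, k), Sq(k, k), TP(k, k), Tq(k, k);
  for (uword t = 0; t < k; ++t)
    for (uword s = 0; s < k; ++s) {
      SP(t, s) = dot(d, W.col(t * k + s));
      TP(t, s) = accu(W.col(t * k + s));
      Sq(t, s) = dot(d % Q.col(t), Q.col(s));
      Tq(t, s) = dot(Q.col(t), Q.col(s));
    }
  const mat CG = 0.5 * (Sq - SP);  // dl = <CG, dG>
  const mat CE = 0.5 * (Tq - TP);
  const mat DLg = 2.0 * CG * Lg;  // dl/dLg (CG symmetric)
  const mat DLe = 2.0 * CE * Le;
  vec gG(nc), gE(nc);
  for (uword j = 0; j < k; ++j) {
    gG(j) = DLg(j, j) * Lg(j, j);  // chain rule through log-diagonal
    gE(j) = DLe(j, j) * Le(j, j);
  }
  {
    uword pos = k;
    for (uword c = 0; c < k; ++c)
      for (uword r2 = c + 1; r2 < k; ++r2) {
        gG(pos) = DLg(r2, c);
        gE(pos) = DLe(r2, c);
        ++pos;
      }
  }
  return Rcpp::List::create(Rcpp::Named("ll") = ll,
                            Rcpp::Named("ok") = true,
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("grad") = join_cols(gG, gE));
}

// Univariate profile log-likelihood with a region kernel:
//   Omega = diag(s2g * d + s2e) + s2k * Zt Zt'
// Zt: rotated kernel loadings (n x m, K = Zt Zt'). geno: 0/1 flag for a
// dosage column gt in the mean model.
// [[Rcpp::export(name = ".vc_ll_kern1")]]
Rcpp::List vc_ll_kern1(const arma::vec& d, const arma::vec& yt,
                       const arma::mat& Xt, const arma::mat& Zt,
                       const double s2g, const double s2e, const double s2k,
                       const arma::vec& gt, const int geno) {
  const uword n = yt.n_elem, p0 = Xt.n_cols, m = Zt.n_cols;
  const uword p = p0 + (geno ? 1 : 0);
  vec v = s2g * d + s2e;
  if (v.min() <= 0) return ll_fail();
  mat X(n, p);
  X.cols(0, p0 - 1) = Xt;
  if (geno) X.col(p - 1) = gt;
  double logdet = accu(log(v));
  mat B(n, p + 1);
  B.cols(0, p - 1) = X;
  B.col(p) = yt;
  mat OmB = B.each_col() / v;
  if (s2k > 0 && m > 0) {
    mat DZ = Zt.each_col() / v;
    mat C = Zt.t() * DZ;
    C.diag() += 1.0 / s2k;
    mat RC;
    if (!chol(RC, C)) return ll_fail();
    logdet += 2.0 * accu(log(RC.diag())) + m * std::log(s2k);
    mat T = Zt.t() * OmB;  // m x (p+1), OmB currently D^-1 B
    OmB -= DZ * solve(trimatu(RC), solve(trimatl(RC.t()), T));
  }
  mat A = X.t() * OmB.cols(0, p - 1);
  vec b = X.t() * OmB.col(p);
  double yWy = dot(yt, OmB.col(p));
  double ll;
  vec beta;
  if (!gls_finish(A, b, yWy, logdet, (double)n, ll, beta)) return ll_fail();
  return ll_pack(ll, beta);
}

// Multivariate profile log-likelihood with a rank-1-across-traits region
// kernel: Omega = blkdiag(M_i = d_i G + E) + (Zt (x) u)(Zt (x) u)'.
// u carries the per-trait kernel-effect standard deviations. No SNV term
// (gene-centric models have no dosage column).
// [[Rcpp::export(name = ".vc_ll_kernmv")]]
Rcpp::List vc_ll_kernmv(const arma::vec& d, const arma::mat& Yt,
                        const arma::mat& Xt, const arma::mat& Zt,
                        const arma::mat& G, const arma::mat& E,
                        const arma::vec& u) {
  const uword n = Yt.n_rows, k = Yt.n_cols, p0 = Xt.n_cols, m = Zt.n_cols;
  const uword p = k * p0;
  mat A0(p, p, fill::zeros);
  vec b0(p, fill::zeros);
  double yWy = 0.0, logdet = 0.0;
  mat M(k, k), R(k, k), Minv(k, k), xx(p0, p0);
  mat Minvu(n, k);  // row i: (M_i^-1 u)'
  vec uMu(n), ay(n);

  for (uword i = 0; i < n; ++i) {
    M = d(i) * G + E;
    if (!chol(R, M)) return ll_fail();
    logdet += 2.0 * accu(log(R.diag()));
    Minv = inv(trimatu(R));
    Minv = Minv * Minv.t();
    const rowvec x = Xt.row(i);
    const vec y = Yt.row(i).t();
    const vec My = Minv * y;
    yWy += dot(y, My);
    xx = x.t() * x;
    for (uword t = 0; t < k; ++t) {
      for (uword s = 0; s < k; ++s)
        A0.submat(t * p0, s * p0, t * p0 + p0 - 1, s * p0 + p0 - 1) +=
            Minv(t, s) * xx;
      b0.subvec(t * p0, t * p0 + p0 - 1) += My(t) * x.t();
    }
    const vec Mu = Minv * u;
    Minvu.row(i) = Mu.t();
    uMu(i) = dot(u, Mu);
    ay(i) = dot(Mu, y);
  }

  if (m > 0 && accu(abs(u)) > 0) {
    // C = I_m + W' B^-1 W with W = Zt (x) u
    mat C = Zt.t() * (Zt.each_col() % uMu);
    C.diag() += 1.0;
    mat RC;
    if (!chol(RC, C)) return ll_fail();
    logdet += 2.0 * accu(log(RC.diag()));
    // S = X_stack' B^-1 W (p x m), s_y = W' B^-1 y_stack (m)
    mat S(p, m, fill::zeros);
    for (uword t = 0; t < k; ++t)
      S.rows(t * p0, t * p0 + p0 - 1) =
          Xt.t() * (Zt.each_col() % Minvu.col(t));
    vec sy = Zt.t() * ay;
    mat CiSt = solve(trimatu(RC), solve(trimatl(RC.t()), S.t()));
    vec Cisy = solve(trimatu(RC), solve(trimatl(RC.t()), sy));
    A0 -= S * CiSt;
    b0 -= S * Cisy;
    yWy -= dot(sy, Cisy);
  }
  double ll;
  vec beta;
  if (!gls_finish(A0, b0, yWy, logdet, (double)(n * k), ll, beta))
    return ll_fail();
  return ll_pack(ll, beta);
}
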