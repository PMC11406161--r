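// Marginal Gaussian log-likelihood and analytic gradient for the
// phylogenetic longitudinal model. The observation covariance is
//   Sigma = v_e * (W % rho^D2) + v_f*Sf + v_h*Sh + v_d*Sd + v_s*Ss + nug*I
// where W is the temporal-kernel weight (same-individual indicator in
// nested mode, expanded species correlation in composite mode), D2 the
// squared scaled time differences, and S* the group-sharing structures.
// The structures are fixed for a given model frame, so they are stored
// once behind an external pointer and only the parameters vary per call.
// The kernel term is stored sparsely (W is mostly zero), and the dense
// Cholesky/inverse pair goes through LAPACK dpotrf/dpotri once per call.

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct EwlModel {
  arma::mat X;
  arma::vec y;
  arma::mat Sf, Sh, Sd, Ss;
  arma::uvec kr, kc;   // row/col indices of nonzero kernel weights
  arma::vec wnz, d2nz; // weights and (dt/ref)^2 at those entries
  double nugget;
};

// [[Rcpp::export]]
SEXP ewl_model_build(const arma::mat& X, const arma::vec& y,
                     const arma::mat& W, const arma::mat& D2,
                     const arma::mat& Sf, const arma::mat& Sh,
                     const arma::mat& Sd, const arma::mat& Ss,
                     double nugget) {
  arma::uvec idx = arma::find(W != 0);
  arma::uword n = W.n_rows;
  EwlModel* m = new EwlModel;
  m->X = X; m->y = y; m->Sf = Sf; m->Sh = Sh; m->Sd = Sd; m->Ss = Ss;
  m->kr = idx - n * (idx / n);
  m->kc = idx / n;
  m->wnz = W.elem(idx);
  m->d2nz = D2.elem(idx);
  m->nugget = nugget;
  XPtr<EwlModel> ptr(m, true);
  return ptr;
}

// In-place symmetric inverse + log-determinant via dpotrf/dpotri.
// Returns false if the matrix is not positive definite.
static bool sym_inv_logdet(arma::mat& A, double& logdet) {
  int n = A.n_rows, info = 0;
  F77_CALL(dpotrf)("L", &n, A.memptr(), &n, &info FCONE);
  if (info != 0) return false;
  logdet = 0.0;
  for (int i = 0; i < n; ++i) logdet += 2.0 * std::log(A(i, i));
  F77_CALL(dpotri)("L", &n, A.memptr(), &n, &info FCONE);
  if (info != 0) return false;
  A = arma::symmatl(A);
  return true;
}

// v is ordered (frog, housing, date, species, error); returns the Gaussian
// log-likelihood and its gradient w.r.t. beta, each variance, and rho.
// [[Rcpp::export]]
List ewl_model_lpgrad(SEXP ptr, const arma::vec& beta, const arma::vec& v,
                      double rho) {
  XPtr<EwlModel> mp(ptr);
  const EwlModel& m = *mp;
  const arma::uword n = m.y.n_elem;
  const double lrho = std::log(rho);

  arma::vec kv = m.wnz % arma::exp(lrho * m.d2nz);
  arma::mat Sig = v(0) * m.Sf + v(1) * m.Sh + v(2) * m.Sd + v(3) * m.Ss;
  Sig.diag() += m.nugget;
  for (arma::uword j = 0; j < kv.n_elem; ++j) {
    Sig(m.kr[j], m.kc[j]) += v(4) * kv[j];
  }

  double logdet;
  if (!sym_inv_logdet(Sig, logdet)) {
    return List::create(_["ok"] = false);
  }
  const arma::mat& Sinv = Sig;  // now holds the inverse

  arma::vec r = m.y - m.X * beta;
  arma::vec alpha = Sinv * r;
  double ll = -0.5 * n * std::log(2.0 * M_PI) - 0.5 * logdet -
              0.5 * arma::dot(r, alpha);

  arma::vec gbeta = m.X.t() * alpha;

  auto vgrad = [&](const arma::mat& S) {
    return 0.5 * (arma::as_scalar(alpha.t() * S * alpha) -
                  arma::accu(Sinv % S));
  };
  arma::vec gv(5);
  gv(0) = vgrad(m.Sf);
  gv(1) = vgrad(m.Sh);
  gv(2) = vgrad(m.Sd);
  gv(3) = vgrad(m.Ss);

  // kernel term and its rho derivative, on the sparse entries only;
  // dK/drho = W % D2 % rho^(D2 - 1), zero wherever D2 is zero
  arma::vec dkv = m.wnz % m.d2nz % arma::exp(lrho * (m.d2nz - 1.0));
  double quadK = 0, trK = 0, quadD = 0, trD = 0;
  for (arma::uword j = 0; j < kv.n_elem; ++j) {
    const double aa = alpha[m.kr[j]] * alpha[m.kc[j]];
    const double ss = Sinv(m.kr[j], m.kc[j]);
    quadK += kv[j] * aa;  trK += kv[j] * ss;
    quadD += dkv[j] * aa; trD += dkv[j] * ss;
  }
  gv(4) = 0.5 * (quadK - trK);
  double grho = v(4) * 0.5 * (quadD - trD);

  return List::create(_["ok"] = true, _["ll"] = ll, _["gbeta"] = gbeta,
                      _["gv"] = gv, _["grho"] = grho);
}
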