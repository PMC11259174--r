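// Single-precision kernels for the feedforward (EKF-input) TD3 hot path.
// Shapes follow the R convention: X is M x in, W is in x out, Z = X W + b.
// The R implementations in R/nn_core.R remain the reference; the test suite
// checks these kernels against them.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::fmat as_f(SEXP s) {
  NumericMatrix m(s);
  arma::fmat out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.memptr());
  return out;
}
static arma::frowvec as_frow(SEXP s) {
  NumericVector v(s);
  arma::frowvec out(v.size());
  std::copy(v.begin(), v.end(), out.memptr());
  return out;
}
static NumericMatrix wrap_f(const arma::fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
static NumericMatrix wrap_frow(const arma::frowvec& v) {
  NumericMatrix out(1, v.n_elem);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

struct P3 {
  arma::fmat W1, W2, W3;
  arma::frowvec b1, b2, b3;
};

// params: list(W1, b1, W2, b2, W3, b3)
static P3 unpack(const List& params) {
  P3 p;
  p.W1 = as_f(params[0]); p.b1 = as_frow(params[1]);
  p.W2 = as_f(params[2]); p.b2 = as_frow(params[3]);
  p.W3 = as_f(params[4]); p.b3 = as_frow(params[5]);
  return p;
}

struct FwdCache {
  arma::fmat A1, A2, out;
};

static FwdCache fwd(const arma::fmat& X, const P3& p, bool tanh_out) {
  FwdCache c;
  c.A1 = X * p.W1; c.A1.each_row() += p.b1;
  c.A1.transform([](float z) { return z > 0.0f ? z : 0.0f; });
  c.A2 = c.A1 * p.W2; c.A2.each_row() += p.b2;
  c.A2.transform([](float z) { return z > 0.0f ? z : 0.0f; });
  c.out = c.A2 * p.W3; c.out.each_row() += p.b3;
  if (tanh_out) c.out = arma::tanh(c.out);
  return c;
}

// backward through the 3-layer net; dY is M x out. Fills grads, optionally
// computes dX (gradient w.r.t. the inputs).
static List bwd(const arma::fmat& X, const P3& p, const FwdCache& c,
                arma::fmat dY, bool tanh_out, bool want_dX,
                arma::fmat* dX_out) {
  if (tanh_out) dY %= (1.0f - arma::square(c.out));
  arma::fmat gW3 = c.A2.t() * dY;
  arma::frowvec gb3 = arma::sum(dY, 0);
  arma::fmat d2 = dY * p.W3.t();
  d2 %= arma::conv_to<arma::fmat>::from(c.A2 > 0.0f);
  arma::fmat gW2 = c.A1.t() * d2;
  arma::frowvec gb2 = arma::sum(d2, 0);
  arma::fmat d1 = d2 * p.W2.t();
  d1 %= arma::conv_to<arma::fmat>::from(c.A1 > 0.0f);
  arma::fmat gW1 = X.t() * d1;
  arma::frowvec gb1 = arma::sum(d1, 0);
  if (want_dX) *dX_out = d1 * p.W1.t();
  return List::create(wrap_f(gW1), wrap_frow(gb1),
                      wrap_f(gW2), wrap_frow(gb2),
                      wrap_f(gW3), wrap_frow(gb3));
}

// [[Rcpp::export]]
NumericMatrix cpp_mlp3_fwd(NumericMatrix X, List params, bool tanh_out) {
  P3 p = unpack(params);
  FwdCache c = fwd(as_f(X), p, tanh_out);
  return wrap_f(c.out);
}

// Fused twin-critic regression step: forward + squared-error backward for
// one critic. Returns list(loss, grads).
// [[Rcpp::export]]
List cpp_critic_loss_grads(NumericMatrix X, NumericVector y, List params) {
  P3 p = unpack(params);
  arma::fmat Xf = as_f(X);
  FwdCache c = fwd(Xf, p, false);
  arma::fvec q = c.out.col(0);
  arma::fvec yv(y.size());
  std::copy(y.begin(), y.end(), yv.memptr());
  arma::fvec err = q - yv;
  double loss = arma::mean(arma::square(err));
  arma::fmat dY(err.n_elem, 1);
  dY.col(0) = 2.0f * err / (float)err.n_elem;
  List grads = bwd(Xf, p, c, dY, false, false, nullptr);
  return List::create(Named("loss") = loss, Named("grads") = grads);
}

// Actor ascent step gradients: a = actor(feat); J = mean critic([feat, a]);
// returns list(objective, actor grads) with the gradient of J.
// [[Rcpp::export]]
List cpp_actor_obj_grads(NumericMatrix feat, List actor_params,
                         List critic_params) {
  P3 pa = unpack(actor_params);
  P3 pc = unpack(critic_params);
  arma::fmat F = as_f(feat);
  FwdCache ca = fwd(F, pa, true);
  arma::fmat FA = arma::join_rows(F, ca.out);
  FwdCache cc = fwd(FA, pc, false);
  double obj = arma::mean(cc.out.col(0));
  arma::fmat dq(FA.n_rows, 1);
  dq.fill(1.0f / (float)FA.n_rows);
  arma::fmat dFA;
  bwd(FA, pc, cc, dq, false, true, &dFA);
  arma::fmat dA = dFA.cols(F.n_cols, FA.n_cols - 1);
  List ga = bwd(F, pa, ca, dA, true, false, nullptr);
  return List::create(Named("objective") = obj, Named("grads") = ga);
}

// Adam over a flat list of parameter arrays. Purely functional: returns
// fresh params, m, and v so no R object is ever mutated through a view.
// [[Rcpp::export]]
List cpp_adam_step(List params, List grads, List m, List v, int t,
                   double lr, double beta1, double beta2, double eps,
                   bool maximize) {
  int n = params.size();
  List out_p(n), out_m(n), out_v(n);
  double bc1 = 1.0 - std::pow(beta1, t);
  double bc2 = 1.0 - std::pow(beta2, t);
  double sgn = maximize ? -1.0 : 1.0;
  for (int i = 0; i < n; ++i) {
    NumericVector p(params[i]);
    NumericVector g(grads[i]);
    NumericVector mi(m[i]);
    NumericVector vi(v[i]);
    int len = p.size();
    NumericVector pn(len), mn(len), vn(len);
    pn.attr("dim") = p.attr("dim");
    mn.attr("dim") = Rf_getAttrib(mi, R_DimSymbol);
    vn.attr("dim") = Rf_getAttrib(vi, R_DimSymbol);
    for (int j = 0; j < len; ++j) {
      double gj = sgn * g[j];
      mn[j] = beta1 * mi[j] + (1.0 - beta1) * gj;
      vn[j] = beta2 * vi[j] + (1.0 - beta2) * gj * gj;
      pn[j] = p[j] - lr * (mn[j] / bc1) / (std::sqrt(vn[j] / bc2) + eps);
    }
    out_p[i] = pn; out_m[i] = mn; out_v[i] = vn;
  }
  return List::create(Named("params") = out_p, Named("m") = out_m,
                      Named("v") = out_v);
}
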