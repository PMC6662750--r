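// Full-batch resilient backpropagation (iRprop-) for a 1-hidden-layer MLP
// with tanh hidden units and a logistic output, minimizing MSE.
//
// The caller supplies the (already scaled) design matrix without the bias
// column, targets in [0, 1], and the initial weights; all randomness lives on
// the R side so training here is fully deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List rprop_fit(const arma::mat& X, const arma::vec& y,
                     arma::mat W1, arma::vec w2,
                     const int max_epochs, const double step_tol,
                     const double eta_plus, const double eta_minus,
                     const double delta0, const double delta_max) {
  const uword n = X.n_rows;
  const uword H = W1.n_cols;           // W1 is (I+1) x H, last row = bias
  mat Xb = join_rows(X, ones<vec>(n)); // n x (I+1)

  mat D1(size(W1), fill::value(delta0));
  vec d2(size(w2), fill::value(delta0));
  mat G1_prev(size(W1), fill::zeros);
  vec g2_prev(size(w2), fill::zeros);
  const double delta_min = 1e-9;

  double mse = datum::inf, mse0 = datum::nan;
  int epoch = 0;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    mat Z = tanh(Xb * W1);                       // n x H
    mat Zb = join_rows(Z, ones<vec>(n));         // n x (H+1)
    vec yhat = 1.0 / (1.0 + exp(-(Zb * w2)));
    vec e = yhat - y;
    mse = dot(e, e) / n;
    if (epoch == 0) mse0 = mse;
    if (!std::isfinite(mse)) break;

    vec dpre_out = (2.0 / n) * e % yhat % (1.0 - yhat);
    vec g2 = Zb.t() * dpre_out;                  // (H+1)
    mat dZ = dpre_out * w2.head(H).t();          // n x H
    mat dpre_h = dZ % (1.0 - square(Z));
    mat G1 = Xb.t() * dpre_h;                    // (I+1) x H

    // iRprop-: grow/shrink per-weight steps by gradient sign agreement;
    // on a sign change shrink the step and skip the update this epoch.
    mat s1 = sign(G1 % G1_prev);
    D1.elem(find(s1 > 0)) *= eta_plus;
    D1.elem(find(s1 < 0)) *= eta_minus;
    D1 = clamp(D1, delta_min, delta_max);
    G1.elem(find(s1 < 0)).zeros();
    W1 -= sign(G1) % D1;
    G1_prev = G1;

    vec s2 = sign(g2 % g2_prev);
    d2.elem(find(s2 > 0)) *= eta_plus;
    d2.elem(find(s2 < 0)) *= eta_minus;
    d2 = clamp(d2, delta_min, delta_max);
    g2.elem(find(s2 < 0)).zeros();
    w2 -= sign(g2) % d2;
    g2_prev = g2;

    if (D1.max() < step_tol && d2.max() < step_tol) { ++epoch; break; }
  }
  // final MSE with the returned weights
  mat Z = tanh(Xb * W1);
  mat Zb = join_rows(Z, ones<vec>(n));
  vec yhat = 1.0 / (1.0 + exp(-(Zb * w2)));
  vec e = yhat - y;
  mse = dot(e, e) / n;

  return Rcpp::List::create(Rcpp::Named("W1") = W1,
                            Rcpp::Named("w2") = w2,
                            Rcpp::Named("mse") = mse,
                            Rcpp::Named("mse0") = mse0,
                            Rcpp::Named("epochs") = epoch);
}

// [[Rcpp::export]]
arma::vec mlp_forward(const arma::mat& X, const arma::mat& W1,
                      const arma::vec& w2) {
  mat Xb = join_rows(X, ones<vec>(X.n_rows));
  mat Z = tanh(Xb * W1);
  mat Zb = join_rows(Z, ones<vec>(X.n_rows));
  return 1.0 / (1.0 + exp(-(Zb * w2)));
}
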