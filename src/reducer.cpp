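// Full-batch gradient-descent trainer for the 4-layer dimensionality
// reduction network (sigmoid hidden layers, auxiliary sigmoid head with
// binary cross-entropy). Deterministic given the initial weights.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List train_mlp_cpp(const arma::mat& X, const arma::vec& y,
                         arma::mat W1, arma::rowvec b1,
                         arma::mat W2, arma::rowvec b2,
                         arma::mat W3, arma::rowvec b3,
                         arma::vec w4, double b4,
                         double lr, double momentum,
                         int max_epochs, double tol, int patience,
                         int min_epochs) {
  const double n = (double) X.n_rows;
  mat V1(size(W1), fill::zeros), V2(size(W2), fill::zeros),
      V3(size(W3), fill::zeros);
  rowvec v1(size(b1), fill::zeros), v2(size(b2), fill::zeros),
         v3(size(b3), fill::zeros);
  vec v4(size(w4), fill::zeros);
  double vb4 = 0.0;
  std::vector<double> loss_trace;
  loss_trace.reserve(max_epochs);
  int epochs_run = 0;
  const double eps = 1e-12;

  for (int e = 0; e < max_epochs; ++e) {
    mat A1 = sigm(X * W1 + repmat(b1, X.n_rows, 1));
    mat A2 = sigm(A1 * W2 + repmat(b2, A1.n_rows, 1));
    mat A3 = sigm(A2 * W3 + repmat(b3, A2.n_rows, 1));
    vec p = 1.0 / (1.0 + exp(-(A3 * w4 + b4)));
    double loss = -mean(y % log(p + eps) + (1.0 - y) % log(1.0 - p + eps));
    if (!std::isfinite(loss))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", e + 1);
    loss_trace.push_back(loss);
    epochs_run = e + 1;
    // early stop on loss plateau, but never before the warm-up floor:
    // the loss surface is nearly flat right after initialization and a
    // plateau there does not mean convergence
    if (e >= min_epochs && e >= patience &&
        loss_trace[e - patience] - loss < tol) break;

    vec dout = (p - y) / n;                    // dL/dz_out
    vec g4 = A3.t() * dout;
    double gb4 = accu(dout);
    mat d3 = (dout * w4.t()) % (A3 % (1.0 - A3));
    mat G3 = A2.t() * d3;
    rowvec gb3 = sum(d3, 0);
    mat d2 = (d3 * W3.t()) % (A2 % (1.0 - A2));
    mat G2 = A1.t() * d2;
    rowvec gb2 = sum(d2, 0);
    mat d1 = (d2 * W2.t()) % (A1 % (1.0 - A1));
    mat G1 = X.t() * d1;
    rowvec gb1 = sum(d1, 0);

    V1 = momentum * V1 - lr * G1;  W1 += V1;
    v1 = momentum * v1 - lr * gb1; b1 += v1;
    V2 = momentum * V2 - lr * G2;  W2 += V2;
    v2 = momentum * v2 - lr * gb2; b2 += v2;
    V3 = momentum * V3 - lr * G3;  W3 += V3;
    v3 = momentum * v3 - lr * gb3; b3 += v3;
    v4 = momentum * v4 - lr * g4;  w4 += v4;
    vb4 = momentum * vb4 - lr * gb4; b4 += vb4;
  }
  return Rcpp::List::create(
    Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
    Rcpp::Named("W2") = W2, Rcpp::Named("b2") = b2,
    Rcpp::Named("W3") = W3, Rcpp::Named("b3") = b3,
    Rcpp::Named("w4") = w4, Rcpp::Named("b4") = b4,
    Rcpp::Named("loss") = loss_trace,
    Rcpp::Named("epochs") = epochs_run);
}

// [[Rcpp::export]]
arma::mat encode_mlp_cpp(const arma::mat& X,
                         const arma::mat& W1, const arma::rowvec& b1,
                         const arma::mat& W2, const arma::rowvec& b2,
                         const arma::mat& W3, const arma::rowvec& b3) {
  mat A1 = sigm(X * W1 + repmat(b1, X.n_rows, 1));
  mat A2 = sigm(A1 * W2 + repmat(b2, A1.n_rows, 1));
  return sigm(A2 * W3 + repmat(b3, A2.n_rows, 1));
}
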