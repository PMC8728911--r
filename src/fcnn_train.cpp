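// Minibatch SGD-with-momentum training loop for the fully connected
// angle regressor, under the periodic mean-absolute-error loss and the
// step-halving learning-rate schedule. The R wrapper owns all RNG
// (initial weights and per-epoch shuffle orders are passed in), so runs
// are reproducible from a single seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double wrap_deg(double x) {
  double r = x - 360.0 * std::floor(x / 360.0);  // in [0, 360)
  if (r > 180.0) r -= 360.0;
  return r;
}

static vec forward(const std::vector<mat> &W, const std::vector<rowvec> &b,
                   const mat &X, std::vector<mat> *acts) {
  const size_t L = W.size();
  mat a = X;
  for (size_t l = 0; l + 1 < L; ++l) {
    a = a * W[l];
    a.each_row() += b[l];
    a = 1.0 / (1.0 + exp(-a));
    if (acts) (*acts)[l] = a;
  }
  mat out = a * W[L - 1];
  out.each_row() += b[L - 1];
  return out.col(0);
}

static double periodic_mae(const vec &pred, const vec &y) {
  double s = 0.0;
  for (uword i = 0; i < y.n_elem; ++i)
    s += std::fabs(wrap_deg(pred[i] - y[i]));
  return s / y.n_elem;
}

// [[Rcpp::export(name = ".cpp_fcnn_train")]]
Rcpp::List cpp_fcnn_train(const arma::mat &X, const arma::vec &y,
                          const arma::mat &Xval, const arma::vec &yval,
                          Rcpp::List W0, Rcpp::List b0,
                          const arma::imat &orders,  // n x max_epochs, 1-based
                          int batch_size, double lr0, double lr_factor,
                          int patience, double lr_floor, double momentum,
                          int max_epochs, bool monitor_val) {
  const size_t L = W0.size();
  std::vector<mat> W(L), vW(L), bestW(L), acts(L);
  std::vector<rowvec> b(L), vb(L), bestb(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(W0[l]);
    b[l] = Rcpp::as<rowvec>(b0[l]);
    vW[l] = zeros<mat>(W[l].n_rows, W[l].n_cols);
    vb[l] = zeros<rowvec>(b[l].n_elem);
    bestW[l] = W[l];
    bestb[l] = b[l];
  }
  const uword n = X.n_rows;
  double lr = lr0, best = datum::inf;
  int stall = 0;
  std::vector<double> h_train, h_val, h_lr;

  for (int ep = 0; ep < max_epochs; ++ep) {
    double ae_sum = 0.0;
    for (uword start = 0; start < n; start += batch_size) {
      const uword end = std::min<uword>(start + batch_size, n) - 1;
      const uword m = end - start + 1;
      uvec idx(m);
      for (uword k = 0; k < m; ++k)
        idx[k] = static_cast<uword>(orders(start + k, ep)) - 1;
      mat Xb = X.rows(idx);
      vec yb = y.elem(idx);
      vec out = forward(W, b, Xb, &acts);
      // subgradient of the periodic AE: sign of the wrapped residual
      vec delta(m);
      for (uword k = 0; k < m; ++k) {
        double r = wrap_deg(out[k] - yb[k]);
        ae_sum += std::fabs(r);
        delta[k] = (r > 0) - (r < 0);
      }
      delta /= static_cast<double>(m);
      mat d = delta;  // m x 1
      for (size_t l = L; l-- > 0;) {
        const mat &a_prev = (l == 0) ? Xb : acts[l - 1];
        mat gW = a_prev.t() * d;
        rowvec gb = sum(d, 0);
        if (l > 0) {
          const mat &a = acts[l - 1];
          d = (d * W[l].t()) % (a % (1.0 - a));
        }
        vW[l] = momentum * vW[l] - lr * gW;
        W[l] += vW[l];
        vb[l] = momentum * vb[l] - lr * gb;
        b[l] += vb[l];
      }
    }
    double train_loss = ae_sum / n;
    double val_loss = periodic_mae(forward(W, b, Xval, nullptr), yval);
    h_train.push_back(train_loss);
    h_val.push_back(val_loss);
    h_lr.push_back(lr);
    double monitored = monitor_val ? val_loss : train_loss;
    if (monitored < best) {
      best = monitored;
      for (size_t l = 0; l < L; ++l) { bestW[l] = W[l]; bestb[l] = b[l]; }
      stall = 0;
    } else if (++stall >= patience) {
      lr *= lr_factor;
      stall = 0;
      if (lr < lr_floor) break;
    }
  }
  Rcpp::List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = bestW[l];
    bout[l] = Rcpp::NumericVector(bestb[l].begin(), bestb[l].end());
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = Wout, Rcpp::Named("b") = bout,
    Rcpp::Named("train_loss") = h_train, Rcpp::Named("val_loss") = h_val,
    Rcpp::Named("lr") = h_lr, Rcpp::Named("best") = best);
}
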