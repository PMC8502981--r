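// Echo state network mechanics: teacher-forced state collection and
// closed-loop forecasting. The leaky update is
//   h_t = (1 - alpha) h_{t-1} + alpha * tanh(W_in x_t + W h_{t-1})
// and the readout acts on [1; x_t; h_t] (constant bias column prepended).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Run the reservoir over a sequence of inputs (rows of X), returning the
// state after each input as rows of H.
// [[Rcpp::export(name = ".esn_collect_states")]]
arma::mat esn_collect_states(const arma::mat& W_in, const arma::mat& W,
                             double alpha, const arma::mat& X,
                             const arma::vec& h0) {
  const arma::uword T = X.n_rows, n = W.n_rows;
  arma::mat H(T, n);
  arma::vec h = h0;
  for (arma::uword t = 0; t < T; ++t) {
    h = (1.0 - alpha) * h +
        alpha * arma::tanh(W_in * X.row(t).t() + W * h);
    H.row(t) = h.t();
  }
  return H;
}

// Closed-loop (recursive) forecast: at each step the exogenous input slots
// come from `exo` (n_steps x (n_in - 1)), the voltage slot (last input
// column) is the previous prediction, and the readout produces the next
// prediction. Returns the prediction vector and the final reservoir state.
// [[Rcpp::export(name = ".esn_forecast")]]
List esn_forecast(const arma::mat& W_in, const arma::mat& W,
                  const arma::vec& w_out, double alpha, const arma::vec& h0,
                  const arma::mat& exo, double v0, int n_steps) {
  const arma::uword n_in = W_in.n_cols;
  arma::vec h = h0;
  arma::vec x(n_in);
  arma::vec pred(n_steps);
  double v_prev = v0;

  for (int t = 0; t < n_steps; ++t) {
    if (exo.n_cols > 0) x.head(n_in - 1) = exo.row(t).t();
    x(n_in - 1) = v_prev;
    h = (1.0 - alpha) * h + alpha * arma::tanh(W_in * x + W * h);
    // readout on [1; x; h]
    double y = w_out(0) + arma::dot(w_out.subvec(1, n_in), x) +
               arma::dot(w_out.subvec(n_in + 1, n_in + W.n_rows), h);
    if (!std::isfinite(y))
      stop("closed-loop forecast diverged at step %d", t + 1);
    pred(t) = y;
    v_prev = y;
  }
  return List::create(_["predictions"] = pred, _["state"] = h);
}

// Voltage-adaptive undersampling: walk the series once, keeping a point iff
// its voltage differs from the last *kept* voltage by at least dv_threshold
// or the time since the last kept point exceeds dt_max. Returns 1-based
// indices of kept points; the first point is always kept.
// [[Rcpp::export(name = ".resample_keep_idx")]]
IntegerVector resample_keep_idx(const NumericVector& time,
                                const NumericVector& voltage,
                                double dv_threshold, double dt_max) {
  const R_xlen_t n = time.size();
  std::vector<int> keep;
  keep.reserve(n);
  if (n == 0) return IntegerVector(0);
  keep.push_back(1);
  double t_last = time[0], v_last = voltage[0];
  for (R_xlen_t i = 1; i < n; ++i) {
    if (std::fabs(voltage[i] - v_last) >= dv_threshold ||
        (time[i] - t_last) > dt_max) {
      keep.push_back(static_cast<int>(i + 1));
      t_last = time[i];
      v_last = voltage[i];
    }
  }
  return wrap(keep);
}
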