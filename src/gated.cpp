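// LSTM / GRU sequence-to-sequence regressors: forward pass, full
// backpropagation through time, Adam training, and closed-loop forecasting.
//
// LSTM cell:
//   i = sigma(Wi x + Ui h + bi),  f = sigma(Wf x + Uf h + bf)
//   o = sigma(Wo x + Uo h + bo),  cb = tanh(Wc x + Uc h + bc)
//   c_t = f .* c_{t-1} + i .* cb,  h_t = tanh(c_t) .* o
// GRU cell:
//   z = sigma(Wz x + Uz h + bz),  r = sigma(Wr x + Ur h + br)
//   hb = tanh(Wh x + Uh (r .* h) + bh),  h_t = (1 - z) .* h + z .* hb
// A fully connected layer maps the top hidden state to the scalar output:
//   y_t = Wy h_t + by, trained with mean squared error over the sequence.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

inline arma::vec sigmoid(const arma::vec& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// Parameter pack: per layer a fixed-order vector of matrices (biases are
// column vectors), then Wy (1 x H) and by (1 x 1) appended at the end.
// LSTM layer order: Wi Ui bi Wf Uf bf Wo Uo bo Wc Uc bc   (12 blocks)
// GRU  layer order: Wz Uz bz Wr Ur br Wh Uh bh            (9 blocks)
struct ParamPack {
  bool lstm;
  int n_layers;
  std::vector<arma::mat> blocks;

  int per_layer() const { return lstm ? 12 : 9; }
  arma::mat& L(int layer, int k) { return blocks[layer * per_layer() + k]; }
  const arma::mat& L(int layer, int k) const {
    return blocks[layer * per_layer() + k];
  }
  arma::mat& Wy() { return blocks[blocks.size() - 2]; }
  const arma::mat& Wy() const { return blocks[blocks.size() - 2]; }
  arma::mat& by() { return blocks[blocks.size() - 1]; }
  const arma::mat& by() const { return blocks[blocks.size() - 1]; }
};

const char* lstm_names[12] = {"Wi", "Ui", "bi", "Wf", "Uf", "bf",
                              "Wo", "Uo", "bo", "Wc", "Uc", "bc"};
const char* gru_names[9] = {"Wz", "Uz", "bz", "Wr", "Ur", "br",
                            "Wh", "Uh", "bh"};

ParamPack unpack(const List& params) {
  ParamPack p;
  std::string kind = as<std::string>(params["kind"]);
  p.lstm = (kind == "lstm");
  List layers = params["layers"];
  p.n_layers = layers.size();
  const char** nm = p.lstm ? lstm_names : gru_names;
  for (int l = 0; l < p.n_layers; ++l) {
    List layer = layers[l];
    for (int k = 0; k < p.per_layer(); ++k)
      p.blocks.push_back(as<arma::mat>(layer[nm[k]]));
  }
  p.blocks.push_back(as<arma::mat>(params["Wy"]));
  p.blocks.push_back(as<arma::mat>(params["by"]));
  return p;
}

List repack(const ParamPack& p, const std::string& kind) {
  const char** nm = p.lstm ? lstm_names : gru_names;
  List layers(p.n_layers);
  for (int l = 0; l < p.n_layers; ++l) {
    List layer;
    for (int k = 0; k < p.per_layer(); ++k) layer[nm[k]] = p.L(l, k);
    layers[l] = layer;
  }
  return List::create(_["kind"] = kind, _["layers"] = layers,
                      _["Wy"] = p.Wy(), _["by"] = p.by());
}

// Per-layer forward caches for one sequence.
struct LayerCache {
  arma::mat x;            // inputs to this layer, n_in x T
  arma::mat h;            // hidden states, H x T
  arma::mat c;            // cell states (LSTM), H x T
  arma::mat gi, gf, go, gc;  // LSTM gates / candidates
  arma::mat gz, gr, gh;      // GRU gates / candidate
};

// One forward step of layer `l`; state vectors h and c are updated in
// place. If cache != nullptr the step is recorded at column t.
void step_layer(const ParamPack& p, int l, const arma::vec& x, arma::vec& h,
                arma::vec& c, LayerCache* cache, arma::uword t) {
  if (p.lstm) {
    arma::vec i = sigmoid(p.L(l, 0) * x + p.L(l, 1) * h + p.L(l, 2));
    arma::vec f = sigmoid(p.L(l, 3) * x + p.L(l, 4) * h + p.L(l, 5));
    arma::vec o = sigmoid(p.L(l, 6) * x + p.L(l, 7) * h + p.L(l, 8));
    arma::vec cb = arma::tanh(p.L(l, 9) * x + p.L(l, 10) * h + p.L(l, 11));
    c = f % c + i % cb;
    h = arma::tanh(c) % o;
    if (cache) {
      cache->x.col(t) = x; cache->gi.col(t) = i; cache->gf.col(t) = f;
      cache->go.col(t) = o; cache->gc.col(t) = cb; cache->c.col(t) = c;
      cache->h.col(t) = h;
    }
  } else {
    arma::vec z = sigmoid(p.L(l, 0) * x + p.L(l, 1) * h + p.L(l, 2));
    arma::vec r = sigmoid(p.L(l, 3) * x + p.L(l, 4) * h + p.L(l, 5));
    arma::vec hb = arma::tanh(p.L(l, 6) * x + p.L(l, 7) * (r % h) + p.L(l, 8));
    h = (1.0 - z) % h + z % hb;
    if (cache) {
      cache->x.col(t) = x; cache->gz.col(t) = z; cache->gr.col(t) = r;
      cache->gh.col(t) = hb; cache->h.col(t) = h;
    }
  }
}

// Full-sequence forward pass. X is n_in x T. Returns outputs (length T) and
// fills caches (one per layer) when requested.
arma::vec forward_seq(const ParamPack& p, const arma::mat& X,
                      std::vector<LayerCache>* caches) {
  const arma::uword T = X.n_cols;
  std::vector<arma::vec> h(p.n_layers), c(p.n_layers);
  for (int l = 0; l < p.n_layers; ++l) {
    const arma::uword H = p.L(l, 0).n_rows;
    h[l].zeros(H);
    c[l].zeros(H);
    if (caches) {
      LayerCache& cc = (*caches)[l];
      cc.x.set_size(p.L(l, 0).n_cols, T);
      cc.h.set_size(H, T);
      if (p.lstm) {
        cc.c.set_size(H, T);
        cc.gi.set_size(H, T); cc.gf.set_size(H, T);
        cc.go.set_size(H, T); cc.gc.set_size(H, T);
      } else {
        cc.gz.set_size(H, T); cc.gr.set_size(H, T); cc.gh.set_size(H, T);
      }
    }
  }
  arma::vec out(T);
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec x = X.col(t);
    for (int l = 0; l < p.n_layers; ++l) {
      step_layer(p, l, x, h[l], c[l], caches ? &(*caches)[l] : nullptr, t);
      x = h[l];
    }
    out(t) = arma::as_scalar(p.Wy() * x) + p.by()(0, 0);
  }
  return out;
}

// MSE loss and full BPTT gradient. Returns loss; grad blocks match p.
double loss_grad(const ParamPack& p, const arma::mat& X, const arma::vec& y,
                 ParamPack& grad) {
  const arma::uword T = X.n_cols;
  std::vector<LayerCache> caches(p.n_layers);
  arma::vec out = forward_seq(p, X, &caches);
  arma::vec resid = out - y;
  const double loss = arma::dot(resid, resid) / T;

  grad.lstm = p.lstm;
  grad.n_layers = p.n_layers;
  grad.blocks.clear();
  for (const arma::mat& b : p.blocks)
    grad.blocks.push_back(arma::zeros<arma::mat>(b.n_rows, b.n_cols));

  // dL/dy_t = 2 resid_t / T; output layer grads and dh contributions.
  // dh_top[t] = Wy^T dLdy_t (+ recurrent terms added during the backward
  // sweep below).
  const int L = p.n_layers;
  std::vector<arma::vec> dh(L), dc(L);
  for (int l = 0; l < L; ++l) {
    dh[l].zeros(caches[l].h.n_rows);
    dc[l].zeros(caches[l].h.n_rows);
  }

  for (arma::uword tt = T; tt-- > 0;) {
    const double dy = 2.0 * resid(tt) / T;
    grad.Wy() += dy * caches[L - 1].h.col(tt).t();
    grad.by()(0, 0) += dy;
    // gradient flowing into the top layer's h at time tt
    arma::vec dx_upper = p.Wy().t() * dy;
    for (int l = L - 1; l >= 0; --l) {
      LayerCache& cc = caches[l];
      arma::vec dht = dh[l] + dx_upper;
      arma::vec h_prev = (tt == 0) ? arma::zeros<arma::vec>(cc.h.n_rows)
                                   : arma::vec(cc.h.col(tt - 1));
      arma::vec dx;  // gradient wrt this layer's input at time tt
      if (p.lstm) {
        arma::vec i = cc.gi.col(tt), f = cc.gf.col(tt), o = cc.go.col(tt),
                  cb = cc.gc.col(tt), ct = cc.c.col(tt);
        arma::vec c_prev = (tt == 0) ? arma::zeros<arma::vec>(ct.n_elem)
                                     : arma::vec(cc.c.col(tt - 1));
        arma::vec tc = arma::tanh(ct);
        arma::vec do_ = dht % tc;
        arma::vec dct = dc[l] + dht % o % (1.0 - tc % tc);
        arma::vec df = dct % c_prev;
        arma::vec di = dct % cb;
        arma::vec dcb = dct % i;
        arma::vec dai = di % i % (1.0 - i);
        arma::vec daf = df % f % (1.0 - f);
        arma::vec dao = do_ % o % (1.0 - o);
        arma::vec dac = dcb % (1.0 - cb % cb);
        const arma::vec& xt = cc.x.col(tt);
        grad.L(l, 0) += dai * xt.t();  grad.L(l, 1) += dai * h_prev.t();
        grad.L(l, 2) += dai;
        grad.L(l, 3) += daf * xt.t();  grad.L(l, 4) += daf * h_prev.t();
        grad.L(l, 5) += daf;
        grad.L(l, 6) += dao * xt.t();  grad.L(l, 7) += dao * h_prev.t();
        grad.L(l, 8) += dao;
        grad.L(l, 9) += dac * xt.t();  grad.L(l, 10) += dac * h_prev.t();
        grad.L(l, 11) += dac;
        dx = p.L(l, 0).t() * dai + p.L(l, 3).t() * daf +
             p.L(l, 6).t() * dao + p.L(l, 9).t() * dac;
        dh[l] = p.L(l, 1).t() * dai + p.L(l, 4).t() * daf +
                p.L(l, 7).t() * dao + p.L(l, 10).t() * dac;
        dc[l] = dct % f;
      } else {
        arma::vec z = cc.gz.col(tt), r = cc.gr.col(tt), hb = cc.gh.col(tt);
        arma::vec dz = dht % (hb - h_prev);
        arma::vec dhb = dht % z;
        arma::vec dh_prev = dht % (1.0 - z);
        arma::vec dah = dhb % (1.0 - hb % hb);
        arma::vec drh = p.L(l, 7).t() * dah;  // grad wrt (r .* h_prev)
        arma::vec dr = drh % h_prev;
        dh_prev += drh % r;
        arma::vec daz = dz % z % (1.0 - z);
        arma::vec dar = dr % r % (1.0 - r);
        const arma::vec& xt = cc.x.col(tt);
        grad.L(l, 0) += daz * xt.t();  grad.L(l, 1) += daz * h_prev.t();
        grad.L(l, 2) += daz;
        grad.L(l, 3) += dar * xt.t();  grad.L(l, 4) += dar * h_prev.t();
        grad.L(l, 5) += dar;
        grad.L(l, 6) += dah * xt.t();
        grad.L(l, 7) += dah * (r % h_prev).t();
        grad.L(l, 8) += dah;
        dx = p.L(l, 0).t() * daz + p.L(l, 3).t() * dar + p.L(l, 6).t() * dah;
        dh[l] = dh_prev + p.L(l, 1).t() * daz + p.L(l, 4).t() * dar;
      }
      dx_upper = dx;  // feeds layer l-1's hidden state at the same time
    }
  }
  return loss;
}

}  // namespace

// Forward pass over a sequence; returns per-step outputs and the final
// hidden (and cell) states of every layer.
// [[Rcpp::export(name = ".gated_forward")]]
List gated_forward(const List& params, const arma::mat& X) {
  ParamPack p = unpack(params);
  const arma::uword T = X.n_cols;
  std::vector<arma::vec> h(p.n_layers), c(p.n_layers);
  for (int l = 0; l < p.n_layers; ++l) {
    h[l].zeros(p.L(l, 0).n_rows);
    c[l].zeros(p.L(l, 0).n_rows);
  }
  arma::vec out(T);
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec x = X.col(t);
    for (int l = 0; l < p.n_layers; ++l) {
      step_layer(p, l, x, h[l], c[l], nullptr, t);
      x = h[l];
    }
    out(t) = arma::as_scalar(p.Wy() * x) + p.by()(0, 0);
  }
  List hs(p.n_layers), cs(p.n_layers);
  for (int l = 0; l < p.n_layers; ++l) { hs[l] = h[l]; cs[l] = c[l]; }
  return List::create(_["outputs"] = out, _["h"] = hs, _["c"] = cs);
}

// Loss and analytic gradients for one sequence (used by the
// finite-difference gradient check as well as by training).
// [[Rcpp::export(name = ".gated_loss_grad")]]
List gated_loss_grad(const List& params, const arma::mat& X,
                     const arma::vec& y) {
  ParamPack p = unpack(params), g;
  double loss = loss_grad(p, X, y, g);
  return List::create(_["loss"] = loss,
                      _["grad"] = repack(g, as<std::string>(params["kind"])));
}

// Full-batch Adam training of the sequence-to-sequence regressor.
// [[Rcpp::export(name = ".gated_train")]]
List gated_train(const List& params, const arma::mat& X, const arma::vec& y,
                 int epochs, double lr, double beta1, double beta2,
                 double eps) {
  ParamPack p = unpack(params);
  std::vector<arma::mat> m, v;
  for (const arma::mat& b : p.blocks) {
    m.push_back(arma::zeros<arma::mat>(b.n_rows, b.n_cols));
    v.push_back(arma::zeros<arma::mat>(b.n_rows, b.n_cols));
  }
  arma::vec losses(epochs);
  ParamPack g;
  for (int e = 0; e < epochs; ++e) {
    losses(e) = loss_grad(p, X, y, g);
    if (!std::isfinite(losses(e)))
      stop("training loss became non-finite at epoch %d", e + 1);
    const double bc1 = 1.0 - std::pow(beta1, e + 1);
    const double bc2 = 1.0 - std::pow(beta2, e + 1);
    for (std::size_t k = 0; k < p.blocks.size(); ++k) {
      m[k] = beta1 * m[k] + (1.0 - beta1) * g.blocks[k];
      v[k] = beta2 * v[k] + (1.0 - beta2) * arma::square(g.blocks[k]);
      p.blocks[k] -= lr * (m[k] / bc1) / (arma::sqrt(v[k] / bc2) + eps);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["params"] = repack(p, as<std::string>(params["kind"])),
      _["loss_history"] = losses);
}

// Closed-loop forecast: exogenous slots from `exo` (n_steps x (n_in - 1)),
// voltage slot (last input) fed back from the previous prediction. Initial
// per-layer states h0/c0 are the states after the training-tail warm-up.
// [[Rcpp::export(name = ".gated_forecast")]]
List gated_forecast(const List& params, const List& h0, const List& c0,
                    const arma::mat& exo, double v0, int n_steps) {
  ParamPack p = unpack(params);
  std::vector<arma::vec> h(p.n_layers), c(p.n_layers);
  for (int l = 0; l < p.n_layers; ++l) {
    h[l] = as<arma::vec>(h0[l]);
    c[l] = p.lstm ? as<arma::vec>(c0[l])
                  : arma::zeros<arma::vec>(h[l].n_elem);
  }
  const arma::uword n_in = p.L(0, 0).n_cols;
  arma::vec x(n_in), pred(n_steps);
  double v_prev = v0;
  for (int t = 0; t < n_steps; ++t) {
    if (exo.n_cols > 0) x.head(n_in - 1) = exo.row(t).t();
    x(n_in - 1) = v_prev;
    arma::vec xi = x;
    for (int l = 0; l < p.n_layers; ++l) {
      step_layer(p, l, xi, h[l], c[l], nullptr, 0);
      xi = h[l];
    }
    double yv = arma::as_scalar(p.Wy() * xi) + p.by()(0, 0);
    if (!std::isfinite(yv))
      stop("closed-loop forecast diverged at step %d", t + 1);
    pred(t) = yv;
    v_prev = yv;
  }
  return List::create(_["predictions"] = pred);
}
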