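// Stacked bi-directional LSTM frame classifier: forward pass,
// weighted-cross-entropy loss and full backpropagation through time.
// Parameters live in a named R list of matrices:
//   W<l><d>, U<l><d>, b<l><d>  for layer l = 1..L, direction d in {f, b}
//     W: 4H x D_l, U: 4H x H, b: 4H   (gate order: input, forget, cell, out)
//   Wo: 3 x 2H, bo: 3               (time-distributed dense + softmax)
// Dropout is applied to each layer's concatenated output during training
// (inverted dropout, masks drawn from R's RNG so set.seed() governs them).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct LayerCache {
  mat I, F, G, O, C, H;  // T x H gate activations and states
};

static mat lstm_dir_forward(const mat& W, const mat& U, const vec& b,
                            const mat& X, bool fwd, LayerCache* cache) {
  const int T = X.n_rows;
  const int H = U.n_cols;
  mat Hs(T, H, fill::zeros);
  if (cache) {
    cache->I.set_size(T, H); cache->F.set_size(T, H); cache->G.set_size(T, H);
    cache->O.set_size(T, H); cache->C.set_size(T, H); cache->H.set_size(T, H);
  }
  vec h(H, fill::zeros), c(H, fill::zeros);
  for (int step = 0; step < T; ++step) {
    const int t = fwd ? step : (T - 1 - step);
    vec z = W * X.row(t).t() + U * h + b;
    vec i = 1.0 / (1.0 + exp(-z.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + exp(-z.subvec(H, 2 * H - 1)));
    vec g = tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = 1.0 / (1.0 + exp(-z.subvec(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    h = o % tanh(c);
    if (cache) {
      cache->I.row(t) = i.t(); cache->F.row(t) = f.t(); cache->G.row(t) = g.t();
      cache->O.row(t) = o.t(); cache->C.row(t) = c.t(); cache->H.row(t) = h.t();
    }
    Hs.row(t) = h.t();
  }
  return Hs;
}

static void lstm_dir_backward(const mat& W, const mat& U,
                              const mat& X, const LayerCache& cc,
                              const mat& dH, bool fwd,
                              mat& dW, mat& dU, vec& db, mat& dX) {
  const int T = X.n_rows;
  const int H = U.n_cols;
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (int step = T - 1; step >= 0; --step) {
    const int t = fwd ? step : (T - 1 - step);
    const int tprev = fwd ? t - 1 : t + 1;  // previous in processing order
    vec i = cc.I.row(t).t(), f = cc.F.row(t).t(), g = cc.G.row(t).t();
    vec o = cc.O.row(t).t(), c = cc.C.row(t).t();
    vec cprev = (step > 0) ? vec(cc.C.row(tprev).t()) : vec(H, fill::zeros);
    vec hprev = (step > 0) ? vec(cc.H.row(tprev).t()) : vec(H, fill::zeros);
    vec tc = tanh(c);
    vec dh = dH.row(t).t() + dh_next;
    vec dc = dc_next + dh % o % (1.0 - tc % tc);
    vec do_ = dh % tc;
    vec dz(4 * H);
    dz.subvec(0, H - 1) = (dc % g) % i % (1.0 - i);
    dz.subvec(H, 2 * H - 1) = (dc % cprev) % f % (1.0 - f);
    dz.subvec(2 * H, 3 * H - 1) = (dc % i) % (1.0 - g % g);
    dz.subvec(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dc_next = dc % f;
    dW += dz * X.row(t);
    dU += dz * hprev.t();
    db += dz;
    dh_next = U.t() * dz;
    dX.row(t) += (W.t() * dz).t();
  }
}

static mat softmax_rows(const mat& logits) {
  mat p = logits;
  for (uword t = 0; t < p.n_rows; ++t) {
    rowvec r = p.row(t) - p.row(t).max();
    r = exp(r);
    p.row(t) = r / accu(r);
  }
  return p;
}

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_run(Rcpp::List params, const arma::mat& X,
                          const arma::ivec& classes, const arma::vec& weights,
                          int n_layers, int hidden, double dropout,
                          bool training, bool want_grad) {
  const int T = X.n_rows;
  const int H = hidden;
  std::vector<mat> inputs(n_layers + 1);   // input to each layer (post dropout)
  std::vector<mat> raw_out(n_layers);      // concatenated BiLSTM output pre dropout
  std::vector<mat> masks(n_layers);        // dropout masks
  std::vector<LayerCache> cache_f(n_layers), cache_b(n_layers);
  inputs[0] = X;

  char nm[16];
  for (int l = 0; l < n_layers; ++l) {
    snprintf(nm, sizeof nm, "W%df", l + 1); mat Wf = params[nm];
    snprintf(nm, sizeof nm, "U%df", l + 1); mat Uf = params[nm];
    snprintf(nm, sizeof nm, "b%df", l + 1); vec bf = params[nm];
    snprintf(nm, sizeof nm, "W%db", l + 1); mat Wb = params[nm];
    snprintf(nm, sizeof nm, "U%db", l + 1); mat Ub = params[nm];
    snprintf(nm, sizeof nm, "b%db", l + 1); vec bb = params[nm];
    LayerCache* cf = want_grad ? &cache_f[l] : nullptr;
    LayerCache* cb = want_grad ? &cache_b[l] : nullptr;
    mat Hf = lstm_dir_forward(Wf, Uf, bf, inputs[l], true, cf);
    mat Hb = lstm_dir_forward(Wb, Ub, bb, inputs[l], false, cb);
    raw_out[l] = join_rows(Hf, Hb);
    mat out = raw_out[l];
    if (training && dropout > 0.0) {
      mat m(T, 2 * H);
      for (uword k = 0; k < m.n_elem; ++k) {
        m(k) = (R::unif_rand() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
      }
      masks[l] = m;
      out %= m;
    }
    inputs[l + 1] = out;
  }

  mat Wo = params["Wo"];
  vec bo = params["bo"];
  mat logits = inputs[n_layers] * Wo.t();
  logits.each_row() += bo.t();
  mat probs = softmax_rows(logits);

  const double wsum = accu(weights);
  double loss = 0.0;
  mat dlogits(T, 3, fill::zeros);
  for (int t = 0; t < T; ++t) {
    const int k = classes[t];
    const double w = (wsum > 0) ? weights[t] / wsum : 0.0;
    loss += -std::log(std::max(probs(t, k), 1e-12)) * w;
    if (want_grad && w > 0) {
      dlogits.row(t) = w * probs.row(t);
      dlogits(t, k) -= w;
    }
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loss") = loss,
                                      Rcpp::Named("probs") = probs);
  if (!want_grad) return out;

  Rcpp::List grads;
  grads["Wo"] = mat(dlogits.t() * inputs[n_layers]);
  grads["bo"] = vec(sum(dlogits, 0).t());
  mat dOut = dlogits * Wo;  // gradient w.r.t. input of the dense layer
  for (int l = n_layers - 1; l >= 0; --l) {
    if (training && dropout > 0.0) dOut %= masks[l];
    mat dHf = dOut.cols(0, H - 1);
    mat dHb = dOut.cols(H, 2 * H - 1);
    snprintf(nm, sizeof nm, "W%df", l + 1); mat Wf = params[nm];
    snprintf(nm, sizeof nm, "U%df", l + 1); mat Uf = params[nm];
    snprintf(nm, sizeof nm, "W%db", l + 1); mat Wb = params[nm];
    snprintf(nm, sizeof nm, "U%db", l + 1); mat Ub = params[nm];
    const int D = inputs[l].n_cols;
    mat dWf(4 * H, D, fill::zeros), dUf(4 * H, H, fill::zeros);
    mat dWb(4 * H, D, fill::zeros), dUb(4 * H, H, fill::zeros);
    vec dbf(4 * H, fill::zeros), dbb(4 * H, fill::zeros);
    mat dX(T, D, fill::zeros);
    lstm_dir_backward(Wf, Uf, inputs[l], cache_f[l], dHf, true, dWf, dUf, dbf, dX);
    lstm_dir_backward(Wb, Ub, inputs[l], cache_b[l], dHb, false, dWb, dUb, dbb, dX);
    snprintf(nm, sizeof nm, "W%df", l + 1); grads[nm] = dWf;
    snprintf(nm, sizeof nm, "U%df", l + 1); grads[nm] = dUf;
    snprintf(nm, sizeof nm, "b%df", l + 1); grads[nm] = dbf;
    snprintf(nm, sizeof nm, "W%db", l + 1); grads[nm] = dWb;
    snprintf(nm, sizeof nm, "U%db", l + 1); grads[nm] = dUb;
    snprintf(nm, sizeof nm, "b%db", l + 1); grads[nm] = dbb;
    dOut = dX;
  }
  out["grads"] = grads;
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_bilstm_predict(Rcpp::List params, const arma::mat& X,
                             int n_layers, int hidden) {
  ivec classes(X.n_rows, fill::zeros);
  vec weights(X.n_rows, fill::zeros);
  Rcpp::List res = cpp_bilstm_run(params, X, classes, weights, n_layers,
                                  hidden, 0.0, false, false);
  return Rcpp::as<arma::mat>(res["probs"]);
}
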