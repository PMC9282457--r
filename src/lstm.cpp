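// Minimal masked-sequence LSTM binary classifier: forward pass, backprop
// through time and Adam, single-threaded for bitwise reproducibility.
// Layout: x is a cube (features x time x samples), mask (time x samples)
// with padding at the old end; the last timestep is always valid.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Weights {
  mat Wx;   // 4H x F   gate order: input, forget, cell, output
  mat Wh;   // 4H x H
  vec b;    // 4H
  vec w_out;  // H
  double b_out;
};

struct Grads {
  mat Wx, Wh;
  vec b, w_out;
  double b_out;
  explicit Grads(const Weights& w)
      : Wx(size(w.Wx), fill::zeros), Wh(size(w.Wh), fill::zeros),
        b(w.b.n_elem, fill::zeros), w_out(w.w_out.n_elem, fill::zeros),
        b_out(0.0) {}
};

inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

Weights init_weights(int hidden, int n_feat, std::mt19937& rng) {
  const double r = 1.0 / std::sqrt(static_cast<double>(hidden));
  std::uniform_real_distribution<double> unif(-r, r);
  Weights w;
  w.Wx.set_size(4 * hidden, n_feat);
  w.Wh.set_size(4 * hidden, hidden);
  w.b.zeros(4 * hidden);
  w.w_out.set_size(hidden);
  for (uword i = 0; i < w.Wx.n_elem; ++i) w.Wx(i) = unif(rng);
  for (uword i = 0; i < w.Wh.n_elem; ++i) w.Wh(i) = unif(rng);
  for (uword i = 0; i < w.w_out.n_elem; ++i) w.w_out(i) = unif(rng);
  // forget-gate bias starts at 1 so early gradients flow through time
  w.b.subvec(hidden, 2 * hidden - 1).fill(1.0);
  w.b_out = 0.0;
  return w;
}

// Forward pass over a batch; caches everything needed for BPTT.
struct Cache {
  std::vector<mat> I, F, G, O, C, Cprev, Hprev, tanhC;
  std::vector<rowvec> m;
  mat h_last;  // H x B
};

mat batch_inputs(const cube& x, const uvec& idx, uword t) {
  mat out(x.n_rows, idx.n_elem);
  for (uword j = 0; j < idx.n_elem; ++j) out.col(j) = x.slice(idx(j)).col(t);
  return out;
}

void forward(const Weights& w, const cube& x, const mat& mask,
             const uvec& idx, int hidden, Cache& cc) {
  const uword T = x.n_cols, B = idx.n_elem;
  const uword H = static_cast<uword>(hidden);
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  cc.I.resize(T); cc.F.resize(T); cc.G.resize(T); cc.O.resize(T);
  cc.C.resize(T); cc.Cprev.resize(T); cc.Hprev.resize(T); cc.tanhC.resize(T);
  cc.m.resize(T);
  for (uword t = 0; t < T; ++t) {
    rowvec m(B);
    for (uword j = 0; j < B; ++j) m(j) = mask(t, idx(j));
    mat xt = batch_inputs(x, idx, t);
    mat z = w.Wx * xt + w.Wh * h;
    z.each_col() += w.b;
    mat I = sigmoid(z.rows(0, H - 1));
    mat F = sigmoid(z.rows(H, 2 * H - 1));
    mat G = tanh(z.rows(2 * H, 3 * H - 1));
    mat O = sigmoid(z.rows(3 * H, 4 * H - 1));
    mat c_new = F % c + I % G;
    mat th = tanh(c_new);
    mat h_new = O % th;
    cc.Cprev[t] = c; cc.Hprev[t] = h;
    cc.I[t] = I; cc.F[t] = F; cc.G[t] = G; cc.O[t] = O;
    cc.C[t] = c_new; cc.tanhC[t] = th; cc.m[t] = m;
    // masked steps carry state through unchanged
    c = c_new.each_row() % m + c.each_row() % (1.0 - m);
    h = h_new.each_row() % m + h.each_row() % (1.0 - m);
  }
  cc.h_last = h;
}

// Returns per-sample probabilities given final hidden states.
vec output_probs(const Weights& w, const mat& h) {
  vec logit = h.t() * w.w_out + w.b_out;
  return 1.0 / (1.0 + exp(-logit));
}

// Backprop for one batch. dlogit: per-sample dL/dlogit (already includes
// class weights and 1/B). drop: dropout mask applied to h_last (or empty).
void backward(const Weights& w, const cube& x, const uvec& idx,
              const Cache& cc, const vec& dlogit, const mat& drop,
              Grads& g) {
  const uword T = cc.I.size();
  const uword H = w.w_out.n_elem;
  const uword B = idx.n_elem;
  mat h_eff = drop.n_elem ? mat(cc.h_last % drop) : cc.h_last;
  g.w_out += h_eff * dlogit;
  g.b_out += accu(dlogit);
  mat dh = w.w_out * dlogit.t();  // H x B
  if (drop.n_elem) dh %= drop;
  mat dc(H, B, fill::zeros);
  for (uword t = T; t-- > 0;) {
    const rowvec& m = cc.m[t];
    mat dh_new = dh.each_row() % m;
    mat dh_carry = dh.each_row() % (1.0 - m);
    mat dc_new = dc.each_row() % m;
    mat dc_carry = dc.each_row() % (1.0 - m);
    const mat& I = cc.I[t];
    const mat& F = cc.F[t];
    const mat& G = cc.G[t];
    const mat& O = cc.O[t];
    const mat& th = cc.tanhC[t];
    mat dO = dh_new % th;
    mat dct = dc_new + dh_new % O % (1.0 - th % th);
    mat dI = dct % G;
    mat dG = dct % I;
    mat dF = dct % cc.Cprev[t];
    mat dz(4 * H, B);
    dz.rows(0, H - 1) = dI % I % (1.0 - I);
    dz.rows(H, 2 * H - 1) = dF % F % (1.0 - F);
    dz.rows(2 * H, 3 * H - 1) = dG % (1.0 - G % G);
    dz.rows(3 * H, 4 * H - 1) = dO % O % (1.0 - O);
    mat xt = batch_inputs(x, idx, t);
    g.Wx += dz * xt.t();
    g.Wh += dz * cc.Hprev[t].t();
    g.b += sum(dz, 1);
    dh = w.Wh.t() * dz + dh_carry;
    dc = dct % F + dc_carry;
  }
}

struct Adam {
  Grads m, v;
  double lr, b1, b2, eps;
  long step;
  Adam(const Weights& w, double lr_)
      : m(w), v(w), lr(lr_), b1(0.9), b2(0.999), eps(1e-8), step(0) {}
  template <class T>
  void upd(T& w, T& mm, T& vv, const T& g, double c1, double c2) {
    mm = b1 * mm + (1.0 - b1) * g;
    vv = b2 * vv + (1.0 - b2) * (g % g);
    w -= lr * (mm / c1) / (sqrt(vv / c2) + eps);
  }
  void update(Weights& w, const Grads& g) {
    ++step;
    const double c1 = 1.0 - std::pow(b1, step);
    const double c2 = 1.0 - std::pow(b2, step);
    upd(w.Wx, m.Wx, v.Wx, g.Wx, c1, c2);
    upd(w.Wh, m.Wh, v.Wh, g.Wh, c1, c2);
    upd(w.b, m.b, v.b, g.b, c1, c2);
    upd(w.w_out, m.w_out, v.w_out, g.w_out, c1, c2);
    // scalar Adam for the output bias
    m.b_out = b1 * m.b_out + (1.0 - b1) * g.b_out;
    v.b_out = b2 * v.b_out + (1.0 - b2) * g.b_out * g.b_out;
    w.b_out -= lr * (m.b_out / c1) / (std::sqrt(v.b_out / c2) + eps);
  }
};

vec predict_all(const Weights& w, const cube& x, const mat& mask,
                int hidden, int batch) {
  const uword n = x.n_slices;
  vec p(n);
  for (uword from = 0; from < n; from += batch) {
    uword to = std::min<uword>(from + batch, n) - 1;
    uvec idx = regspace<uvec>(from, to);
    Cache cc;
    forward(w, x, mask, idx, hidden, cc);
    p.subvec(from, to) = output_probs(w, cc.h_last);
  }
  return p;
}

double weighted_bce(const vec& p, const vec& y, double w_pos, double w_neg) {
  const double eps = 1e-12;
  vec wts = y * w_pos + (1.0 - y) * w_neg;
  vec ll = y % log(p + eps) + (1.0 - y) % log(1.0 - p + eps);
  return -accu(wts % ll) / p.n_elem;
}

Rcpp::List weights_to_list(const Weights& w) {
  return Rcpp::List::create(
      Rcpp::Named("Wx") = w.Wx, Rcpp::Named("Wh") = w.Wh,
      Rcpp::Named("b") = w.b, Rcpp::Named("w_out") = w.w_out,
      Rcpp::Named("b_out") = w.b_out);
}

Weights weights_from_list(const Rcpp::List& l) {
  Weights w;
  w.Wx = Rcpp::as<mat>(l["Wx"]);
  w.Wh = Rcpp::as<mat>(l["Wh"]);
  w.b = Rcpp::as<vec>(l["b"]);
  w.w_out = Rcpp::as<vec>(l["w_out"]);
  w.b_out = Rcpp::as<double>(l["b_out"]);
  return w;
}

}  // namespace

// [[Rcpp::export(name = ".lstm_train")]]
Rcpp::List lstm_train(const arma::cube& x_train, const arma::mat& m_train,
                      const arma::vec& y_train, const arma::cube& x_val,
                      const arma::mat& m_val, const arma::vec& y_val,
                      int hidden, double dropout, double lr, int batch,
                      int max_epochs, int patience, double w_pos,
                      double w_neg, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  const int F = x_train.n_rows;
  Weights w = init_weights(hidden, F, rng);
  Adam opt(w, lr);
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  const uword n = x_train.n_slices;
  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  Weights best = w;
  double best_val = datum::inf;
  int best_epoch = 0, bad_epochs = 0, epochs_run = 0;
  std::vector<double> tr_hist, val_hist;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double tr_loss = 0.0;
    uword n_seen = 0;
    for (uword from = 0; from < n; from += batch) {
      uword to = std::min<uword>(from + batch, n);
      uvec idx(to - from);
      for (uword j = 0; j < idx.n_elem; ++j) idx(j) = order[from + j];
      Cache cc;
      forward(w, x_train, m_train, idx, hidden, cc);
      mat drop;
      if (dropout > 0.0) {
        drop.set_size(size(cc.h_last));
        const double keep = 1.0 - dropout;
        for (uword i = 0; i < drop.n_elem; ++i)
          drop(i) = (unif01(rng) < keep) ? 1.0 / keep : 0.0;
      }
      mat h_eff = drop.n_elem ? mat(cc.h_last % drop) : cc.h_last;
      vec p = output_probs(w, h_eff);
      vec yb(idx.n_elem);
      for (uword j = 0; j < idx.n_elem; ++j) yb(j) = y_train(idx(j));
      vec wts = yb * w_pos + (1.0 - yb) * w_neg;
      const double eps_p = 1e-12;
      tr_loss += -accu(wts % (yb % log(p + eps_p) +
                              (1.0 - yb) % log(1.0 - p + eps_p)));
      n_seen += idx.n_elem;
      vec dlogit = wts % (p - yb) / static_cast<double>(idx.n_elem);
      Grads g(w);
      backward(w, x_train, idx, cc, dlogit, drop, g);
      opt.update(w, g);
    }
    epochs_run = epoch;
    tr_hist.push_back(tr_loss / n_seen);
    vec pv = predict_all(w, x_val, m_val, hidden, batch);
    double vloss = weighted_bce(pv, y_val, w_pos, w_neg);
    val_hist.push_back(vloss);
    if (vloss < best_val - 1e-7) {
      best_val = vloss;
      best = w;
      best_epoch = epoch;
      bad_epochs = 0;
    } else if (++bad_epochs >= patience) {
      break;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = weights_to_list(best),
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("epochs_run") = epochs_run,
      Rcpp::Named("train_loss") = tr_hist,
      Rcpp::Named("val_loss") = val_hist,
      Rcpp::Named("best_val_loss") = best_val);
}

// [[Rcpp::export(name = ".lstm_predict")]]
arma::vec lstm_predict(const Rcpp::List& weights, const arma::cube& x,
                       const arma::mat& mask, int batch) {
  Weights w = weights_from_list(weights);
  return predict_all(w, x, mask, w.w_out.n_elem, batch);
}
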