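// Compact CNN-LSTM sequence classifier for windowed tilt/IMU channels.
//
// Layout: conv1d(F1, k) + ReLU -> maxpool(p) -> conv1d(F2, k) + ReLU ->
// maxpool(p) -> LSTM(H, last hidden state) -> dense(K) + softmax,
// trained with class-weighted cross-entropy and Adam.  Everything is
// batched as dense matrix products so BLAS does the heavy lifting; all
// randomness (init, shuffling) flows from one integer seed so training
// is bit-reproducible for a fixed thread count.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Config {
  int L, C, k, F1, F2, pool, H, K;
  int L1, L2, L3, L4;
};

Config make_config(int L, int C, const Rcpp::List &cfg) {
  Config c;
  c.L = L;
  c.C = C;
  c.k = Rcpp::as<int>(cfg["kernel"]);
  c.F1 = Rcpp::as<int>(cfg["filters1"]);
  c.F2 = Rcpp::as<int>(cfg["filters2"]);
  c.pool = Rcpp::as<int>(cfg["pool"]);
  c.H = Rcpp::as<int>(cfg["hidden"]);
  c.K = Rcpp::as<int>(cfg["n_class"]);
  c.L1 = c.L - c.k + 1;
  c.L2 = c.L1 / c.pool;
  c.L3 = c.L2 - c.k + 1;
  c.L4 = c.L3 / c.pool;
  if (c.L1 < 1 || c.L3 < 1 || c.L4 < 1)
    Rcpp::stop("window too short for the convolution/pooling stack");
  return c;
}

struct Params {
  mat W1, W2, Wx, Wh, Wd;
  rowvec b1, b2, bl, bd;

  static Params zeros_like(const Config &c) {
    Params p;
    p.W1.zeros(c.k * c.C, c.F1);
    p.b1.zeros(c.F1);
    p.W2.zeros(c.k * c.F1, c.F2);
    p.b2.zeros(c.F2);
    p.Wx.zeros(c.F2, 4 * c.H);
    p.Wh.zeros(c.H, 4 * c.H);
    p.bl.zeros(4 * c.H);
    p.Wd.zeros(c.H, c.K);
    p.bd.zeros(c.K);
    return p;
  }
};

void glorot_fill(mat &m, std::mt19937 &rng) {
  double s = std::sqrt(6.0 / (m.n_rows + m.n_cols));
  std::uniform_real_distribution<double> u(-s, s);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) m(i, j) = u(rng);
}

Params init_params(const Config &c, std::mt19937 &rng) {
  Params p = Params::zeros_like(c);
  glorot_fill(p.W1, rng);
  glorot_fill(p.W2, rng);
  glorot_fill(p.Wx, rng);
  glorot_fill(p.Wh, rng);
  glorot_fill(p.Wd, rng);
  // forget-gate bias starts open so gradients flow through time early on
  p.bl.subvec(c.H, 2 * c.H - 1).fill(1.0);
  return p;
}

// caches kept from the forward pass for backprop
struct Cache {
  mat M1, A1, P1, M2, A2, P2;   // im2col inputs, relu activations, pooled
  umat amax1, amax2;            // argmax row indices into A1/A2
  cube I, F, G, O, Cs, Hs;      // LSTM gate/state histories (B x H x T)
  mat h_last;                   // B x H
  mat probs;                    // B x K
};

inline mat sigmoid(const mat &x) { return 1.0 / (1.0 + exp(-x)); }

// x: cube (B, L, C)
void forward(const cube &x, const Params &p, const Config &c, Cache &cc) {
  const int B = x.n_rows;

  cc.M1.set_size(B * c.L1, c.k * c.C);
  for (int ch = 0; ch < c.C; ++ch)
    for (int j = 0; j < c.k; ++j)
      for (int t = 0; t < c.L1; ++t)
        for (int b = 0; b < B; ++b)
          cc.M1(b * c.L1 + t, ch * c.k + j) = x(b, t + j, ch);

  cc.A1 = cc.M1 * p.W1;
  cc.A1.each_row() += p.b1;
  cc.A1.transform([](double v) { return v > 0.0 ? v : 0.0; });

  // max-pool along time within each window
  cc.P1.set_size(B * c.L2, c.F1);
  cc.amax1.set_size(B * c.L2, c.F1);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.L2; ++t) {
      const int orow = b * c.L2 + t;
      for (int f = 0; f < c.F1; ++f) {
        int best = b * c.L1 + t * c.pool;
        double bv = cc.A1(best, f);
        for (int q = 1; q < c.pool; ++q) {
          int r = b * c.L1 + t * c.pool + q;
          if (cc.A1(r, f) > bv) { bv = cc.A1(r, f); best = r; }
        }
        cc.P1(orow, f) = bv;
        cc.amax1(orow, f) = best;
      }
    }

  cc.M2.set_size(B * c.L3, c.k * c.F1);
  for (int f = 0; f < c.F1; ++f)
    for (int j = 0; j < c.k; ++j)
      for (int t = 0; t < c.L3; ++t)
        for (int b = 0; b < B; ++b)
          cc.M2(b * c.L3 + t, f * c.k + j) = cc.P1(b * c.L2 + t + j, f);

  cc.A2 = cc.M2 * p.W2;
  cc.A2.each_row() += p.b2;
  cc.A2.transform([](double v) { return v > 0.0 ? v : 0.0; });

  cc.P2.set_size(B * c.L4, c.F2);
  cc.amax2.set_size(B * c.L4, c.F2);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.L4; ++t) {
      const int orow = b * c.L4 + t;
      for (int f = 0; f < c.F2; ++f) {
        int best = b * c.L3 + t * c.pool;
        double bv = cc.A2(best, f);
        for (int q = 1; q < c.pool; ++q) {
          int r = b * c.L3 + t * c.pool + q;
          if (cc.A2(r, f) > bv) { bv = cc.A2(r, f); best = r; }
        }
        cc.P2(orow, f) = bv;
        cc.amax2(orow, f) = best;
      }
    }

  // LSTM over the L4 pooled steps
  cc.I.set_size(B, c.H, c.L4); cc.F.set_size(B, c.H, c.L4);
  cc.G.set_size(B, c.H, c.L4); cc.O.set_size(B, c.H, c.L4);
  cc.Cs.set_size(B, c.H, c.L4); cc.Hs.set_size(B, c.H, c.L4);

  mat h(B, c.H, fill::zeros), cs(B, c.H, fill::zeros);
  mat xt(B, c.F2);
  for (int t = 0; t < c.L4; ++t) {
    for (int b = 0; b < B; ++b) xt.row(b) = cc.P2.row(b * c.L4 + t);
    mat gates = xt * p.Wx + h * p.Wh;
    gates.each_row() += p.bl;
    mat gi = sigmoid(gates.cols(0, c.H - 1));
    mat gf = sigmoid(gates.cols(c.H, 2 * c.H - 1));
    mat gg = tanh(gates.cols(2 * c.H, 3 * c.H - 1));
    mat go = sigmoid(gates.cols(3 * c.H, 4 * c.H - 1));
    cs = gf % cs + gi % gg;
    h = go % tanh(cs);
    cc.I.slice(t) = gi; cc.F.slice(t) = gf;
    cc.G.slice(t) = gg; cc.O.slice(t) = go;
    cc.Cs.slice(t) = cs; cc.Hs.slice(t) = h;
  }
  cc.h_last = h;

  mat logits = h * p.Wd;
  logits.each_row() += p.bd;
  logits.each_col() -= max(logits, 1);
  mat e = exp(logits);
  cc.probs = e.each_col() / sum(e, 1);
}

// y: 0-based labels; w: per-class loss weights (length K)
double loss_and_grad(const cube &x, const ivec &y, const vec &w,
                     const Params &p, const Config &c, Params &g) {
  const int B = x.n_rows;
  Cache cc;
  forward(x, p, c, cc);

  vec wi(B);
  for (int b = 0; b < B; ++b) wi(b) = w(y(b));
  const double wsum = accu(wi);

  double loss = 0.0;
  mat dlogits = cc.probs;
  for (int b = 0; b < B; ++b) {
    loss -= wi(b) * std::log(std::max(cc.probs(b, y(b)), 1e-12));
    dlogits(b, y(b)) -= 1.0;
    dlogits.row(b) *= wi(b) / wsum;
  }
  loss /= wsum;

  g = Params::zeros_like(c);
  g.Wd = cc.h_last.t() * dlogits;
  g.bd = sum(dlogits, 0);
  mat dh = dlogits * p.Wd.t();
  mat dc(B, c.H, fill::zeros);
  mat dP2(B * c.L4, c.F2, fill::zeros);

  for (int t = c.L4 - 1; t >= 0; --t) {
    const mat &gi = cc.I.slice(t), &gf = cc.F.slice(t);
    const mat &gg = cc.G.slice(t), &go = cc.O.slice(t);
    const mat &cs = cc.Cs.slice(t);
    mat tc = tanh(cs);
    mat dct = dh % go % (1.0 - tc % tc) + dc;
    mat c_prev = (t == 0) ? mat(B, c.H, fill::zeros) : mat(cc.Cs.slice(t - 1));
    mat h_prev = (t == 0) ? mat(B, c.H, fill::zeros) : mat(cc.Hs.slice(t - 1));

    mat dgi = dct % gg % gi % (1.0 - gi);
    mat dgf = dct % c_prev % gf % (1.0 - gf);
    mat dgg = dct % gi % (1.0 - gg % gg);
    mat dgo = dh % tc % go % (1.0 - go);

    mat dgates = join_rows(join_rows(dgi, dgf), join_rows(dgg, dgo));

    mat xt(B, c.F2);
    for (int b = 0; b < B; ++b) xt.row(b) = cc.P2.row(b * c.L4 + t);

    g.Wx += xt.t() * dgates;
    g.Wh += h_prev.t() * dgates;
    g.bl += sum(dgates, 0);

    mat dxt = dgates * p.Wx.t();
    for (int b = 0; b < B; ++b) dP2.row(b * c.L4 + t) += dxt.row(b);

    dh = dgates * p.Wh.t();
    dc = dct % gf;
  }

  // unpool 2 -> relu' -> conv2 grads -> col2im back to P1
  mat dA2(B * c.L3, c.F2, fill::zeros);
  for (uword r = 0; r < dP2.n_rows; ++r)
    for (int f = 0; f < c.F2; ++f)
      if (cc.A2(cc.amax2(r, f), f) > 0.0)
        dA2(cc.amax2(r, f), f) += dP2(r, f);

  g.W2 = cc.M2.t() * dA2;
  g.b2 = sum(dA2, 0);
  mat dM2 = dA2 * p.W2.t();

  mat dP1(B * c.L2, c.F1, fill::zeros);
  for (int f = 0; f < c.F1; ++f)
    for (int j = 0; j < c.k; ++j)
      for (int t = 0; t < c.L3; ++t)
        for (int b = 0; b < B; ++b)
          dP1(b * c.L2 + t + j, f) += dM2(b * c.L3 + t, f * c.k + j);

  mat dA1(B * c.L1, c.F1, fill::zeros);
  for (uword r = 0; r < dP1.n_rows; ++r)
    for (int f = 0; f < c.F1; ++f)
      if (cc.A1(cc.amax1(r, f), f) > 0.0)
        dA1(cc.amax1(r, f), f) += dP1(r, f);

  g.W1 = cc.M1.t() * dA1;
  g.b1 = sum(dA1, 0);

  return loss;
}

cube slice_rows(const cube &x, const uvec &idx) {
  cube out(idx.n_elem, x.n_cols, x.n_slices);
  for (uword s = 0; s < x.n_slices; ++s)
    for (uword j = 0; j < x.n_cols; ++j)
      for (uword i = 0; i < idx.n_elem; ++i)
        out(i, j, s) = x(idx(i), j, s);
  return out;
}

cube as_cube(const Rcpp::NumericVector &x) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 3) Rcpp::stop("window array must have dim (n, len, channels)");
  cube out(d[0], d[1], d[2]);
  std::copy(x.begin(), x.end(), out.memptr());
  return out;
}

Rcpp::List params_to_list(const Params &p) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = p.W1, Rcpp::Named("b1") = p.b1,
      Rcpp::Named("W2") = p.W2, Rcpp::Named("b2") = p.b2,
      Rcpp::Named("Wx") = p.Wx, Rcpp::Named("Wh") = p.Wh,
      Rcpp::Named("bl") = p.bl, Rcpp::Named("Wd") = p.Wd,
      Rcpp::Named("bd") = p.bd);
}

Params params_from_list(const Rcpp::List &l) {
  Params p;
  p.W1 = Rcpp::as<mat>(l["W1"]); p.b1 = Rcpp::as<rowvec>(l["b1"]);
  p.W2 = Rcpp::as<mat>(l["W2"]); p.b2 = Rcpp::as<rowvec>(l["b2"]);
  p.Wx = Rcpp::as<mat>(l["Wx"]); p.Wh = Rcpp::as<mat>(l["Wh"]);
  p.bl = Rcpp::as<rowvec>(l["bl"]);
  p.Wd = Rcpp::as<mat>(l["Wd"]); p.bd = Rcpp::as<rowvec>(l["bd"]);
  return p;
}

struct Adam {
  Params m, v;
  double lr, b1, b2, eps;
  long t;
  Adam(const Config &c, double lr_) :
      m(Params::zeros_like(c)), v(Params::zeros_like(c)),
      lr(lr_), b1(0.9), b2(0.999), eps(1e-8), t(0) {}

  template <typename T>
  void upd1(T &w, T &mw, T &vw, const T &gw, double corr1, double corr2) {
    mw = b1 * mw + (1 - b1) * gw;
    vw = b2 * vw + (1 - b2) * (gw % gw);
    w -= lr * (mw / corr1) / (sqrt(vw / corr2) + eps);
  }

  void step(Params &p, const Params &g) {
    ++t;
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    upd1(p.W1, m.W1, v.W1, g.W1, c1, c2); upd1(p.b1, m.b1, v.b1, g.b1, c1, c2);
    upd1(p.W2, m.W2, v.W2, g.W2, c1, c2); upd1(p.b2, m.b2, v.b2, g.b2, c1, c2);
    upd1(p.Wx, m.Wx, v.Wx, g.Wx, c1, c2); upd1(p.Wh, m.Wh, v.Wh, g.Wh, c1, c2);
    upd1(p.bl, m.bl, v.bl, g.bl, c1, c2);
    upd1(p.Wd, m.Wd, v.Wd, g.Wd, c1, c2); upd1(p.bd, m.bd, v.bd, g.bd, c1, c2);
  }
};

double grad_sq_norm(const Params &g) {
  return accu(g.W1 % g.W1) + accu(g.b1 % g.b1) + accu(g.W2 % g.W2) +
         accu(g.b2 % g.b2) + accu(g.Wx % g.Wx) + accu(g.Wh % g.Wh) +
         accu(g.bl % g.bl) + accu(g.Wd % g.Wd) + accu(g.bd % g.bd);
}

void scale_params(Params &g, double s) {
  g.W1 *= s; g.b1 *= s; g.W2 *= s; g.b2 *= s;
  g.Wx *= s; g.Wh *= s; g.bl *= s; g.Wd *= s; g.bd *= s;
}

double eval_loss(const cube &x, const ivec &y, const vec &w,
                 const Params &p, const Config &c) {
  Cache cc;
  forward(x, p, c, cc);
  double loss = 0.0, wsum = 0.0;
  for (uword b = 0; b < x.n_rows; ++b) {
    loss -= w(y(b)) * std::log(std::max(cc.probs(b, y(b)), 1e-12));
    wsum += w(y(b));
  }
  return loss / wsum;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_lstm_train")]]
Rcpp::List cnn_lstm_train(Rcpp::NumericVector x_train, Rcpp::IntegerVector y_train,
                          Rcpp::NumericVector x_val, Rcpp::IntegerVector y_val,
                          Rcpp::NumericVector class_weights, Rcpp::List cfg) {
  cube xt = as_cube(x_train);
  cube xv = as_cube(x_val);
  ivec yt = Rcpp::as<ivec>(y_train);
  ivec yv = Rcpp::as<ivec>(y_val);
  vec w = Rcpp::as<vec>(class_weights);

  Config c = make_config(xt.n_cols, xt.n_slices, cfg);
  const int epochs = Rcpp::as<int>(cfg["epochs"]);
  const int batch = Rcpp::as<int>(cfg["batch"]);
  const int patience = Rcpp::as<int>(cfg["patience"]);
  const double lr = Rcpp::as<double>(cfg["lr"]);
  const double clip = Rcpp::as<double>(cfg["clip"]);
  const unsigned seed = Rcpp::as<unsigned>(cfg["seed"]);

  std::mt19937 rng(seed);
  Params p = init_params(c, rng);
  Adam opt(c, lr);

  const int n = xt.n_rows;
  std::vector<uword> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  Params best = p;
  double best_val = datum::inf;
  int best_epoch = 0, stale = 0;
  std::vector<double> tr_hist, val_hist;

  for (int ep = 1; ep <= epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    int nb = 0;
    for (int s = 0; s < n; s += batch) {
      int e = std::min(n, s + batch);
      uvec bi(e - s);
      for (int i = s; i < e; ++i) bi(i - s) = idx[i];
      cube xb = slice_rows(xt, bi);
      ivec yb(e - s);
      for (int i = s; i < e; ++i) yb(i - s) = yt(idx[i]);
      Params g;
      ep_loss += loss_and_grad(xb, yb, w, p, c, g);
      double gn = std::sqrt(grad_sq_norm(g));
      if (gn > clip) scale_params(g, clip / gn);
      opt.step(p, g);
      ++nb;
    }
    tr_hist.push_back(ep_loss / std::max(nb, 1));

    double vl = (xv.n_rows > 0) ? eval_loss(xv, yv, w, p, c)
                                : tr_hist.back();
    val_hist.push_back(vl);
    if (vl < best_val - 1e-5) {
      best_val = vl;
      best = p;
      best_epoch = ep;
      stale = 0;
    } else if (++stale >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = params_to_list(best),
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("train_loss") = tr_hist,
      Rcpp::Named("val_loss") = val_hist);
}

// [[Rcpp::export(name = ".cnn_lstm_predict")]]
arma::mat cnn_lstm_predict(Rcpp::NumericVector x, Rcpp::List weights,
                           Rcpp::List cfg) {
  cube xc = as_cube(x);
  Config c = make_config(xc.n_cols, xc.n_slices, cfg);
  Params p = params_from_list(weights);
  // predict in chunks to bound the cache memory
  const int B = xc.n_rows;
  mat out(B, c.K);
  const int chunk = 512;
  for (int s = 0; s < B; s += chunk) {
    int e = std::min(B, s + chunk);
    uvec bi(e - s);
    for (int i = s; i < e; ++i) bi(i - s) = i;
    Cache cc;
    forward(slice_rows(xc, bi), p, c, cc);
    out.rows(s, e - 1) = cc.probs;
  }
  return out;
}

// [[Rcpp::export(name = ".cnn_lstm_loss_grad")]]
Rcpp::List cnn_lstm_loss_grad(Rcpp::NumericVector x, Rcpp::IntegerVector y,
                              Rcpp::NumericVector class_weights,
                              Rcpp::List weights, Rcpp::List cfg) {
  cube xc = as_cube(x);
  Config c = make_config(xc.n_cols, xc.n_slices, cfg);
  Params p = params_from_list(weights);
  Params g;
  double loss = loss_and_grad(xc, Rcpp::as<ivec>(y),
                              Rcpp::as<vec>(class_weights), p, c, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = params_to_list(g));
}

// [[Rcpp::export(name = ".cnn_lstm_init")]]
Rcpp::List cnn_lstm_init(int L, int C, Rcpp::List cfg, unsigned seed) {
  Config c = make_config(L, C, cfg);
  std::mt19937 rng(seed);
  return params_to_list(init_params(c, rng));
}
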