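// Small recurrent sequence classifier: GRU or tanh-RNN cell, per-step
// sigmoid readout, mean per-step binary cross-entropy, full BPTT, Adam.
// Deterministic: all randomness (weight init, sequence order) is supplied
// by the caller; nothing here draws random numbers.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline vec sigm(const vec& x) { return 1.0 / (1.0 + exp(-x)); }
static inline double sigm1(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct GruW {
  mat W, U;     // 3H x F, 3H x H (row blocks: update z, reset r, cand c)
  vec b;        // 3H
  vec wo;       // H
  double bo;
};

static int gru_size(int F, int H) { return 3 * H * (F + H + 1) + H + 1; }
static int rnn_size(int F, int H) { return H * (F + H + 1) + H + 1; }

static GruW unpack_gru(const vec& w, int F, int H) {
  GruW g;
  int p = 0;
  g.W = reshape(w.subvec(p, p + 3 * H * F - 1), 3 * H, F); p += 3 * H * F;
  g.U = reshape(w.subvec(p, p + 3 * H * H - 1), 3 * H, H); p += 3 * H * H;
  g.b = w.subvec(p, p + 3 * H - 1); p += 3 * H;
  g.wo = w.subvec(p, p + H - 1); p += H;
  g.bo = w(p);
  return g;
}

static vec pack_gru(const GruW& g) {
  return join_cols(join_cols(vectorise(g.W), vectorise(g.U)),
                   join_cols(g.b, join_cols(g.wo, vec{g.bo})));
}

// Forward pass; optionally keep per-step internals for BPTT.
static vec gru_forward(const mat& X, const GruW& g, int H,
                       mat* Hs = nullptr, mat* Zs = nullptr,
                       mat* Rs = nullptr, mat* Cs = nullptr) {
  const int T = X.n_rows;
  vec h(H, fill::zeros), p(T);
  if (Hs) { Hs->set_size(H, T); Zs->set_size(H, T);
            Rs->set_size(H, T); Cs->set_size(H, T); }
  for (int t = 0; t < T; ++t) {
    vec a = g.W * X.row(t).t() + g.U * h + g.b;
    vec z = sigm(a.subvec(0, H - 1));
    vec r = sigm(a.subvec(H, 2 * H - 1));
    // candidate uses the reset-gated previous state
    vec ac = g.W.rows(2 * H, 3 * H - 1) * X.row(t).t() +
             g.U.rows(2 * H, 3 * H - 1) * (r % h) + g.b.subvec(2 * H, 3 * H - 1);
    vec c = tanh(ac);
    h = (1.0 - z) % h + z % c;
    p(t) = sigm1(dot(g.wo, h) + g.bo);
    if (Hs) { Hs->col(t) = h; Zs->col(t) = z; Rs->col(t) = r; Cs->col(t) = c; }
  }
  return p;
}

// One-sequence gradient; returns packed gradient, writes loss.
static vec gru_grad(const mat& X, double y, const GruW& g, int H,
                    double* loss_out) {
  const int T = X.n_rows, F = X.n_cols;
  mat Hs, Zs, Rs, Cs;
  vec p = gru_forward(X, g, H, &Hs, &Zs, &Rs, &Cs);
  vec pc = clamp(p, 1e-7, 1.0 - 1e-7);
  *loss_out = -mean(y * log(pc) + (1.0 - y) * log(1.0 - pc));

  GruW d;
  d.W = zeros(3 * H, F); d.U = zeros(3 * H, H);
  d.b = zeros<vec>(3 * H); d.wo = zeros<vec>(H); d.bo = 0.0;
  vec dh_next(H, fill::zeros);
  const mat Uz = g.U.rows(0, H - 1), Ur = g.U.rows(H, 2 * H - 1),
            Uc = g.U.rows(2 * H, 3 * H - 1);
  for (int t = T - 1; t >= 0; --t) {
    vec h = Hs.col(t);
    vec hprev = (t == 0) ? vec(H, fill::zeros) : Hs.col(t - 1);
    vec z = Zs.col(t), r = Rs.col(t), c = Cs.col(t);
    double dlogit = (p(t) - y) / T;
    vec dh = dh_next + dlogit * g.wo;
    d.wo += dlogit * h;
    d.bo += dlogit;

    vec dc = dh % z % (1.0 - c % c);                 // d a_c
    vec dz = dh % (c - hprev) % z % (1.0 - z);       // d a_z
    vec drh = Uc.t() * dc;                           // d (r % hprev)
    vec dr = drh % hprev % r % (1.0 - r);            // d a_r
    vec x = X.row(t).t();

    d.W.rows(0, H - 1) += dz * x.t();
    d.W.rows(H, 2 * H - 1) += dr * x.t();
    d.W.rows(2 * H, 3 * H - 1) += dc * x.t();
    d.U.rows(0, H - 1) += dz * hprev.t();
    d.U.rows(H, 2 * H - 1) += dr * hprev.t();
    d.U.rows(2 * H, 3 * H - 1) += dc * (r % hprev).t();
    d.b.subvec(0, H - 1) += dz;
    d.b.subvec(H, 2 * H - 1) += dr;
    d.b.subvec(2 * H, 3 * H - 1) += dc;

    dh_next = dh % (1.0 - z) + Uz.t() * dz + Ur.t() * dr + drh % r;
  }
  return pack_gru(d);
}

struct RnnW { mat W, U; vec b, wo; double bo; };

static RnnW unpack_rnn(const vec& w, int F, int H) {
  RnnW g; int p = 0;
  g.W = reshape(w.subvec(p, p + H * F - 1), H, F); p += H * F;
  g.U = reshape(w.subvec(p, p + H * H - 1), H, H); p += H * H;
  g.b = w.subvec(p, p + H - 1); p += H;
  g.wo = w.subvec(p, p + H - 1); p += H;
  g.bo = w(p);
  return g;
}

static vec pack_rnn(const RnnW& g) {
  return join_cols(join_cols(vectorise(g.W), vectorise(g.U)),
                   join_cols(g.b, join_cols(g.wo, vec{g.bo})));
}

static vec rnn_forward(const mat& X, const RnnW& g, int H, mat* Hs = nullptr) {
  const int T = X.n_rows;
  vec h(H, fill::zeros), p(T);
  if (Hs) Hs->set_size(H, T);
  for (int t = 0; t < T; ++t) {
    h = tanh(g.W * X.row(t).t() + g.U * h + g.b);
    p(t) = sigm1(dot(g.wo, h) + g.bo);
    if (Hs) Hs->col(t) = h;
  }
  return p;
}

static vec rnn_grad(const mat& X, double y, const RnnW& g, int H,
                    double* loss_out) {
  const int T = X.n_rows, F = X.n_cols;
  mat Hs;
  vec p = rnn_forward(X, g, H, &Hs);
  vec pc = clamp(p, 1e-7, 1.0 - 1e-7);
  *loss_out = -mean(y * log(pc) + (1.0 - y) * log(1.0 - pc));
  RnnW d; d.W = zeros(H, F); d.U = zeros(H, H);
  d.b = zeros<vec>(H); d.wo = zeros<vec>(H); d.bo = 0.0;
  vec dh_next(H, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec h = Hs.col(t);
    vec hprev = (t == 0) ? vec(H, fill::zeros) : Hs.col(t - 1);
    double dlogit = (p(t) - y) / T;
    vec dh = dh_next + dlogit * g.wo;
    d.wo += dlogit * h; d.bo += dlogit;
    vec da = dh % (1.0 - h % h);
    d.W += da * X.row(t);
    d.U += da * hprev.t();
    d.b += da;
    dh_next = g.U.t() * da;
  }
  return pack_rnn(d);
}

static double seq_loss(const vec& p, double y) {
  vec pc = clamp(p, 1e-7, 1.0 - 1e-7);
  return -mean(y * log(pc) + (1.0 - y) * log(1.0 - pc));
}

// [[Rcpp::export]]
Rcpp::List cpp_rnn_train(Rcpp::List X_list, Rcpp::NumericVector y,
                         std::string cell, int hidden,
                         Rcpp::NumericVector w_init,
                         Rcpp::IntegerMatrix order, double lr,
                         Rcpp::IntegerVector val_idx, int patience,
                         double clip) {
  const int n = X_list.size();
  std::vector<mat> X(n);
  for (int i = 0; i < n; ++i) X[i] = Rcpp::as<mat>(X_list[i]);
  const int F = X[0].n_cols;
  const bool gru = (cell == "gru");
  const int P = gru ? gru_size(F, hidden) : rnn_size(F, hidden);
  if ((int)w_init.size() != P) Rcpp::stop("weight vector has wrong length");
  vec w = Rcpp::as<vec>(w_init);

  vec m(P, fill::zeros), v(P, fill::zeros);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  const int epochs = order.nrow();
  std::vector<double> tr_loss, va_loss;
  vec best_w = w;
  double best_val = datum::inf;
  int best_epoch = 0, since_best = 0;

  for (int e = 0; e < epochs; ++e) {
    double lsum = 0.0; int lcount = 0;
    for (int k = 0; k < order.ncol(); ++k) {
      int i = order(e, k) - 1;
      if (i < 0) continue;  // padding
      double loss;
      vec grad = gru ? gru_grad(X[i], y[i], unpack_gru(w, F, hidden), hidden,
                                &loss)
                     : rnn_grad(X[i], y[i], unpack_rnn(w, F, hidden), hidden,
                                &loss);
      if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss");
      double gn = norm(grad);
      if (gn > clip) grad *= clip / gn;
      ++step;
      m = b1 * m + (1 - b1) * grad;
      v = b2 * v + (1 - b2) * square(grad);
      vec mhat = m / (1 - std::pow(b1, (double)step));
      vec vhat = v / (1 - std::pow(b2, (double)step));
      w -= lr * mhat / (sqrt(vhat) + eps);
      lsum += loss; ++lcount;
    }
    tr_loss.push_back(lcount ? lsum / lcount : NA_REAL);

    if (val_idx.size() > 0) {
      double vsum = 0.0;
      for (int k = 0; k < val_idx.size(); ++k) {
        int i = val_idx[k] - 1;
        vec p = gru ? gru_forward(X[i], unpack_gru(w, F, hidden), hidden)
                    : rnn_forward(X[i], unpack_rnn(w, F, hidden), hidden);
        vsum += seq_loss(p, y[i]);
      }
      double vl = vsum / val_idx.size();
      va_loss.push_back(vl);
      if (vl < best_val - 1e-6) {
        best_val = vl; best_w = w; best_epoch = e + 1; since_best = 0;
      } else if (++since_best >= patience) {
        break;
      }
    } else {
      best_w = w; best_epoch = e + 1;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = Rcpp::wrap(best_w),
      Rcpp::Named("train_loss") = tr_loss,
      Rcpp::Named("val_loss") = va_loss,
      Rcpp::Named("best_epoch") = best_epoch);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_rnn_predict(Rcpp::NumericMatrix x,
                                    Rcpp::NumericVector w, std::string cell,
                                    int hidden) {
  mat X = Rcpp::as<mat>(x);
  vec wv = Rcpp::as<vec>(w);
  vec p = (cell == "gru")
              ? gru_forward(X, unpack_gru(wv, X.n_cols, hidden), hidden)
              : rnn_forward(X, unpack_rnn(wv, X.n_cols, hidden), hidden);
  return Rcpp::wrap(p);
}

// [[Rcpp::export]]
int cpp_rnn_n_weights(int n_features, int hidden, std::string cell) {
  return cell == "gru" ? gru_size(n_features, hidden)
                       : rnn_size(n_features, hidden);
}
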