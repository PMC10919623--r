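// Batched LSTM / Bi-LSTM sequence classifiers with BPTT and Adam.
// Two fixed architectures over (window_len x 3) acceleration windows:
//   arch 0 ("lstm"):   LSTM -> [covariates] -> Dense(ReLU)+Dropout -> Softmax
//   arch 1 ("bilstm"): Conv1D(ReLU) -> MaxPool -> BiLSTM -> LSTM -> LSTM
//                      -> [covariates] -> Dense(ReLU)+Dropout -> Softmax
// All randomness (init, shuffling, dropout) comes from one mt19937_64
// stream so training is bitwise-reproducible given the seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

struct RNG {
  std::mt19937_64 g;
  explicit RNG(uint64_t s) : g(s) {}
  double unif() { return std::uniform_real_distribution<double>(0, 1)(g); }
};

static mat glorot(int nin, int nout, RNG& r) {
  double lim = std::sqrt(6.0 / (nin + nout));
  mat W(nin, nout);
  for (uword i = 0; i < W.n_elem; ++i) W(i) = (r.unif() * 2 - 1) * lim;
  return W;
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// one trainable tensor with gradient and Adam moments
struct P {
  mat W, G, M, V;
  void zero_state() { G = zeros(size(W)); M = G; V = G; }
};

struct LSTMLayer {
  int nin = 0, H = 0;
  bool reverse = false;
  P Wx, Wh, B;
  // caches indexed by processing step s (reversed layers run backwards)
  std::vector<mat> X, Hs, Cprev, I, F, Gt, O, Th;

  void build(int nin_, int H_, RNG& r, bool rev = false) {
    nin = nin_; H = H_; reverse = rev;
    Wx.W = glorot(nin, 4 * H, r);
    Wh.W = glorot(H, 4 * H, r);
    B.W = zeros(1, 4 * H);
    B.W.cols(H, 2 * H - 1).fill(1.0);  // forget-gate bias
    Wx.zero_state(); Wh.zero_state(); B.zero_state();
  }

  std::vector<mat> fwd(const std::vector<mat>& Xin, bool cache) {
    int T = Xin.size(), Bz = Xin[0].n_rows;
    std::vector<mat> out(T);
    if (cache) {
      X.assign(T, mat()); Hs.assign(T, mat()); Cprev.assign(T, mat());
      I.assign(T, mat()); F.assign(T, mat()); Gt.assign(T, mat());
      O.assign(T, mat()); Th.assign(T, mat());
    }
    mat h = zeros(Bz, H), c = zeros(Bz, H);
    for (int s = 0; s < T; ++s) {
      int t = reverse ? T - 1 - s : s;
      mat Z = Xin[t] * Wx.W + h * Wh.W;
      Z.each_row() += B.W.row(0);
      mat i = sigm(Z.cols(0, H - 1));
      mat f = sigm(Z.cols(H, 2 * H - 1));
      mat g = tanh(Z.cols(2 * H, 3 * H - 1));
      mat o = sigm(Z.cols(3 * H, 4 * H - 1));
      mat cp = c;
      c = f % c + i % g;
      mat th = tanh(c);
      h = o % th;
      if (cache) {
        X[s] = Xin[t]; Hs[s] = h; Cprev[s] = cp;
        I[s] = i; F[s] = f; Gt[s] = g; O[s] = o; Th[s] = th;
      }
      out[t] = h;
    }
    return out;
  }

  // dOut indexed by original time t; returns dX in original time order
  std::vector<mat> bwd(const std::vector<mat>& dOut) {
    int T = X.size(), Bz = X[0].n_rows;
    std::vector<mat> dX(T);
    mat dh = zeros(Bz, H), dc = zeros(Bz, H);
    for (int s = T - 1; s >= 0; --s) {
      int t = reverse ? T - 1 - s : s;
      mat dhh = dh;
      if (dOut[t].n_elem) dhh += dOut[t];
      mat dO = dhh % Th[s];
      mat dC = dc + dhh % O[s] % (1 - Th[s] % Th[s]);
      mat dI = dC % Gt[s];
      mat dG = dC % I[s];
      mat dF = dC % Cprev[s];
      dc = dC % F[s];
      mat dZ(Bz, 4 * H);
      dZ.cols(0, H - 1) = dI % I[s] % (1 - I[s]);
      dZ.cols(H, 2 * H - 1) = dF % F[s] % (1 - F[s]);
      dZ.cols(2 * H, 3 * H - 1) = dG % (1 - Gt[s] % Gt[s]);
      dZ.cols(3 * H, 4 * H - 1) = dO % O[s] % (1 - O[s]);
      Wx.G += X[s].t() * dZ;
      if (s > 0) Wh.G += Hs[s - 1].t() * dZ;
      B.G += sum(dZ, 0);
      dh = dZ * Wh.W.t();
      dX[t] = dZ * Wx.W.t();
    }
    return dX;
  }
};

struct DenseLayer {
  int nin = 0, nout = 0;
  bool relu = false;
  P W, B;
  mat Xc, Mask;
  void build(int i, int o, bool r, RNG& rng) {
    nin = i; nout = o; relu = r;
    W.W = glorot(i, o, rng);
    B.W = zeros(1, o);
    W.zero_state(); B.zero_state();
  }
  mat fwd(const mat& x, bool cache) {
    mat z = x * W.W;
    z.each_row() += B.W.row(0);
    if (relu) {
      mat m = conv_to<mat>::from(z > 0);
      z = z % m;
      if (cache) Mask = m;
    }
    if (cache) Xc = x;
    return z;
  }
  mat bwd(const mat& dz_) {
    mat dz = relu ? mat(dz_ % Mask) : dz_;
    W.G += Xc.t() * dz;
    B.G += sum(dz, 0);
    return dz * W.W.t();
  }
};

struct ConvLayer {
  int C = 0, Fq = 0, K = 0, Tout = 0;
  P W, B;
  std::vector<mat> Xc, Mask;
  void build(int C_, int F_, int K_, RNG& r) {
    C = C_; Fq = F_; K = K_;
    W.W = glorot(K * C, F_, r);
    B.W = zeros(1, F_);
    W.zero_state(); B.zero_state();
  }
  std::vector<mat> fwd(const std::vector<mat>& X, bool cache) {
    int T = X.size(), Bz = X[0].n_rows;
    Tout = T - K + 1;
    std::vector<mat> out(Tout);
    if (cache) { Xc = X; Mask.assign(Tout, mat()); }
    mat U(Bz, K * C);
    for (int t = 0; t < Tout; ++t) {
      for (int k = 0; k < K; ++k) U.cols(k * C, (k + 1) * C - 1) = X[t + k];
      mat z = U * W.W;
      z.each_row() += B.W.row(0);
      mat m = conv_to<mat>::from(z > 0);
      out[t] = z % m;
      if (cache) Mask[t] = m;
    }
    return out;
  }
  std::vector<mat> bwd(const std::vector<mat>& dOut) {
    int T = Xc.size(), Bz = Xc[0].n_rows;
    std::vector<mat> dX(T, zeros(Bz, C));
    mat U(Bz, K * C);
    for (int t = 0; t < Tout; ++t) {
      mat dz = dOut[t] % Mask[t];
      for (int k = 0; k < K; ++k) U.cols(k * C, (k + 1) * C - 1) = Xc[t + k];
      W.G += U.t() * dz;
      B.G += sum(dz, 0);
      mat dU = dz * W.W.t();
      for (int k = 0; k < K; ++k) dX[t + k] += dU.cols(k * C, (k + 1) * C - 1);
    }
    return dX;
  }
};

struct PoolLayer {
  int S = 2, Tin = 0, Tout = 0, F = 0;
  std::vector<mat> Arg;  // winning offset per element, as double matrix
  std::vector<mat> fwd(const std::vector<mat>& X, bool cache) {
    Tin = X.size(); F = X[0].n_cols; Tout = Tin / S;
    std::vector<mat> out(Tout);
    if (cache) Arg.assign(Tout, mat());
    for (int t = 0; t < Tout; ++t) {
      mat m = X[t * S];
      mat a = zeros(size(m));
      for (int k = 1; k < S; ++k) {
        mat sel = conv_to<mat>::from(X[t * S + k] > m);
        a = a % (1 - sel) + k * sel;
        m = arma::max(m, X[t * S + k]);
      }
      out[t] = m;
      if (cache) Arg[t] = a;
    }
    return out;
  }
  std::vector<mat> bwd(const std::vector<mat>& dOut, int Bz) {
    std::vector<mat> dX(Tin, zeros(Bz, F));
    for (int t = 0; t < Tout; ++t) {
      for (int k = 0; k < S; ++k) {
        mat sel = conv_to<mat>::from(Arg[t] == (double)k);
        dX[t * S + k] += dOut[t] % sel;
      }
    }
    return dX;
  }
};

struct Net {
  int arch = 0, T = 0, C = 3, K = 2, H = 32, D = 32, Fq = 32, kernel = 5,
      pool = 2, ncov = 0;
  bool mean_head = false;  // temporal mean of recurrent outputs vs last
  int Tlast = 0;           // sequence length feeding the head
  double dropout = 0.5;
  LSTMLayer l1, bf, bb, l2, l3;
  ConvLayer conv;
  PoolLayer pl;
  DenseLayer dense, out;
  std::vector<P*> params;
  mat dropmask;  // last training-step mask

  void build(const List& cfg, RNG& r) {
    arch = Rcpp::as<int>(cfg["arch"]);
    T = Rcpp::as<int>(cfg["window_len"]);
    C = Rcpp::as<int>(cfg["n_channels"]);
    K = Rcpp::as<int>(cfg["n_classes"]);
    H = Rcpp::as<int>(cfg["recurrent_units"]);
    D = Rcpp::as<int>(cfg["dense_units"]);
    Fq = Rcpp::as<int>(cfg["conv_filters"]);
    kernel = Rcpp::as<int>(cfg["conv_kernel"]);
    pool = Rcpp::as<int>(cfg["pool_size"]);
    ncov = Rcpp::as<int>(cfg["n_covariates"]);
    mean_head = Rcpp::as<std::string>(cfg["head_pooling"]) == "mean";
    dropout = Rcpp::as<double>(cfg["dropout_rate"]);
    params.clear();
    if (arch == 0) {
      l1.build(C, H, r);
      dense.build(H + ncov, D, true, r);
      out.build(D, K, false, r);
      for (P* p : {&l1.Wx, &l1.Wh, &l1.B, &dense.W, &dense.B, &out.W,
                   &out.B}) params.push_back(p);
    } else {
      conv.build(C, Fq, kernel, r);
      pl.S = pool;
      bf.build(Fq, H, r, false);
      bb.build(Fq, H, r, true);
      l2.build(2 * H, H, r);
      l3.build(H, H, r);
      dense.build(H + ncov, D, true, r);
      out.build(D, K, false, r);
      for (P* p : {&conv.W, &conv.B, &bf.Wx, &bf.Wh, &bf.B, &bb.Wx, &bb.Wh,
                   &bb.B, &l2.Wx, &l2.Wh, &l2.B, &l3.Wx, &l3.Wh, &l3.B,
                   &dense.W, &dense.B, &out.W, &out.B}) params.push_back(p);
    }
  }

  // forward to class probabilities; train=true caches and applies dropout
  mat fwd(const std::vector<mat>& X, const mat& cov, bool train, RNG* r) {
    int Bz = X[0].n_rows;
    mat h;
    std::vector<mat>* top;
    std::vector<mat> seq, s3;
    if (arch == 0) {
      seq = l1.fwd(X, train);
      top = &seq;
    } else {
      std::vector<mat> c1 = pl.fwd(conv.fwd(X, train), train);
      std::vector<mat> f = bf.fwd(c1, train), b = bb.fwd(c1, train);
      std::vector<mat> bi(c1.size());
      for (size_t t = 0; t < c1.size(); ++t) bi[t] = join_rows(f[t], b[t]);
      std::vector<mat> s2 = l2.fwd(bi, train);
      s3 = l3.fwd(s2, train);
      top = &s3;
    }
    Tlast = top->size();
    if (mean_head) {
      h = (*top)[0];
      for (int t = 1; t < Tlast; ++t) h += (*top)[t];
      h /= Tlast;
    } else {
      h = (*top)[Tlast - 1];
    }
    mat feat = ncov > 0 ? join_rows(h, cov) : h;
    mat d = dense.fwd(feat, train);
    if (train && dropout > 0) {
      dropmask = mat(Bz, D);
      double q = 1.0 - dropout;
      for (uword i = 0; i < dropmask.n_elem; ++i)
        dropmask(i) = (r->unif() < q) ? 1.0 / q : 0.0;
      d = d % dropmask;
    }
    mat logits = out.fwd(d, train);
    logits.each_col() -= max(logits, 1);
    mat e = exp(logits);
    e.each_col() /= sum(e, 1);
    return e;
  }

  void bwd(const mat& dlogits) {
    mat dd = out.bwd(dlogits);
    if (dropout > 0) dd = dd % dropmask;
    mat dfeat = dense.bwd(dd);
    mat dh = ncov > 0 ? mat(dfeat.cols(0, dh_width() - 1)) : dfeat;
    if (arch == 0) {
      std::vector<mat> dseq(T);
      if (mean_head) {
        mat share = dh / T;
        for (int t = 0; t < T; ++t) dseq[t] = share;
      } else {
        dseq[T - 1] = dh;
      }
      l1.bwd(dseq);
    } else {
      int Tp = pl.Tout;
      std::vector<mat> ds3(Tp);
      if (mean_head) {
        mat share = dh / Tp;
        for (int t = 0; t < Tp; ++t) ds3[t] = share;
      } else {
        ds3[Tp - 1] = dh;
      }
      std::vector<mat> ds2 = l3.bwd(ds3);
      std::vector<mat> dbi = l2.bwd(ds2);
      std::vector<mat> df(Tp), db(Tp);
      for (int t = 0; t < Tp; ++t) {
        df[t] = dbi[t].cols(0, H - 1);
        db[t] = dbi[t].cols(H, 2 * H - 1);
      }
      std::vector<mat> dp = bf.bwd(df);
      std::vector<mat> dpb = bb.bwd(db);
      for (int t = 0; t < Tp; ++t) dp[t] += dpb[t];
      conv.bwd(pl.bwd(dp, dp[0].n_rows));
    }
  }

  int dh_width() const { return H; }

  void adam_step(double lr, int step, double clip, double wd) {
    double n2 = 0;
    for (P* p : params) n2 += accu(square(p->G));
    double sc = 1.0;
    if (clip > 0 && std::sqrt(n2) > clip) sc = clip / std::sqrt(n2);
    double b1 = 1 - std::pow(0.9, step), b2 = 1 - std::pow(0.999, step);
    for (P* p : params) {
      mat g = p->G * sc;
      p->M = 0.9 * p->M + 0.1 * g;
      p->V = 0.999 * p->V + 0.001 * square(g);
      p->W -= lr * (p->M / b1) / (sqrt(p->V / b2) + 1e-8);
      if (wd > 0) p->W -= lr * wd * p->W;  // decoupled weight decay
      p->G.zeros();
    }
  }

  List export_weights() const {
    List w(params.size());
    for (size_t i = 0; i < params.size(); ++i) w[i] = params[i]->W;
    return w;
  }
  void import_weights(const List& w) {
    for (size_t i = 0; i < params.size(); ++i)
      params[i]->W = Rcpp::as<mat>(w[i]);
  }
};

// gather a mini-batch as T matrices of (batch x channels)
static std::vector<mat> batch_seq(const cube& X, const uvec& idx) {
  int T = X.n_cols, C = X.n_slices;
  std::vector<mat> out(T, mat(idx.n_elem, C));
  for (int c = 0; c < C; ++c) {
    mat sub = X.slice(c).rows(idx);
    for (int t = 0; t < T; ++t) out[t].col(c) = sub.col(t);
  }
  return out;
}

static double batch_eval(Net& net, const cube& X, const mat& cov,
                         const ivec& y, double* loss_out) {
  int n = X.n_rows, bs = 512;
  double correct = 0, loss = 0;
  for (int at = 0; at < n; at += bs) {
    int hi = std::min(at + bs, n) - 1;
    uvec idx = regspace<uvec>(at, hi);
    std::vector<mat> Xb = batch_seq(X, idx);
    mat cb = net.ncov > 0 ? mat(cov.rows(idx)) : mat();
    mat P = net.fwd(Xb, cb, false, nullptr);
    for (uword i = 0; i < idx.n_elem; ++i) {
      int yi = y[idx[i]];
      loss -= std::log(std::max(P(i, yi), 1e-12));
      uword am = 0;
      for (uword k = 1; k < P.n_cols; ++k) if (P(i, k) > P(i, am)) am = k;
      if ((int)am == yi) correct += 1;
    }
  }
  if (loss_out) *loss_out = loss / n;
  return correct / n;
}

// [[Rcpp::export]]
List cpp_fit(arma::cube X, arma::mat cov, arma::ivec y, arma::cube Xv,
             arma::mat covv, arma::ivec yv, List cfg) {
  int epochs = Rcpp::as<int>(cfg["epochs"]);
  int bs = Rcpp::as<int>(cfg["batch_size"]);
  double lr = Rcpp::as<double>(cfg["learning_rate"]);
  bool cosine = Rcpp::as<std::string>(cfg["lr_schedule"]) == "cosine";
  double clip = Rcpp::as<double>(cfg["clip_norm"]);
  double wd = Rcpp::as<double>(cfg["weight_decay"]);
  double ls = Rcpp::as<double>(cfg["label_smoothing"]);
  uint64_t seed = (uint64_t)Rcpp::as<double>(cfg["seed"]);
  RNG r(seed);
  Net net;
  net.build(cfg, r);
  int n = X.n_rows;
  std::vector<uword> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  vec tr_loss(epochs), tr_acc(epochs), va_loss(epochs), va_acc(epochs);
  int step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    // cosine decay from lr to 0.05*lr across epochs
    double lr_ep = lr;
    if (cosine && epochs > 1) {
      lr_ep = lr * (0.05 + 0.95 * 0.5 *
                    (1 + std::cos(M_PI * ep / (epochs - 1))));
    }
    std::shuffle(ord.begin(), ord.end(), r.g);
    double loss = 0, correct = 0;
    for (int at = 0; at < n; at += bs) {
      int m = std::min(bs, n - at);
      uvec idx(m);
      for (int i = 0; i < m; ++i) idx[i] = ord[at + i];
      std::vector<mat> Xb = batch_seq(X, idx);
      mat cb = net.ncov > 0 ? mat(cov.rows(idx)) : mat();
      mat P = net.fwd(Xb, cb, true, &r);
      // gradient of CE against target (1-ls)*onehot + ls/K uniform
      mat dlog = P;
      if (ls > 0) dlog -= ls / net.K;
      for (int i = 0; i < m; ++i) {
        int yi = y[idx[i]];
        dlog(i, yi) -= 1.0 - ls;
        loss -= std::log(std::max(P(i, yi), 1e-12));
        uword am = 0;
        for (uword k = 1; k < P.n_cols; ++k) if (P(i, k) > P(i, am)) am = k;
        if ((int)am == yi) correct += 1;
      }
      dlog /= m;
      net.bwd(dlog);
      net.adam_step(lr_ep, ++step, clip, wd);
    }
    tr_loss[ep] = loss / n;
    tr_acc[ep] = correct / n;
    if (Xv.n_rows > 0) {
      double vl = 0;
      va_acc[ep] = batch_eval(net, Xv, covv, yv, &vl);
      va_loss[ep] = vl;
    } else {
      va_acc[ep] = datum::nan;
      va_loss[ep] = datum::nan;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
      Named("weights") = net.export_weights(),
      Named("history") = List::create(
          Named("train_loss") = tr_loss, Named("train_acc") = tr_acc,
          Named("val_loss") = va_loss, Named("val_acc") = va_acc));
}

// [[Rcpp::export]]
arma::mat cpp_predict(arma::cube X, arma::mat cov, List weights, List cfg) {
  RNG r(1);
  Net net;
  net.build(cfg, r);
  net.import_weights(weights);
  int n = X.n_rows, bs = 512;
  mat P(n, net.K);
  for (int at = 0; at < n; at += bs) {
    int hi = std::min(at + bs, n) - 1;
    uvec idx = regspace<uvec>(at, hi);
    std::vector<mat> Xb = batch_seq(X, idx);
    mat cb = net.ncov > 0 ? mat(cov.rows(idx)) : mat();
    P.rows(idx) = net.fwd(Xb, cb, false, nullptr);
  }
  return P;
}
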