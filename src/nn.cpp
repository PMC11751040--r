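// CNN -> BiLSTM -> additive-attention -> FNN classifier for centered-residue
// PTM windows. Forward pass, hand-derived backprop and Adam live here; the R
// layer only prepares encoded arrays and interprets the outputs.
//
// Layout conventions: one window is an L x F matrix in R (timesteps x feature
// channels); internally we work channels x time. All randomness (init,
// shuffling, dropout) comes from std::mt19937 seeded from R, so a seed fully
// determines initial parameters, the training trajectory and eval outputs.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Cfg {
  bool use_cnn, use_bilstm, use_attention;
  int L, F;              // window length, encoder row width
  int c1, c2, k1, k2, pool;
  int h;                 // LSTM hidden units per direction
  int A;                 // attention projection dim
  int f1, f2;            // fully connected widths
  double dropout;
  // derived
  int T;                 // retained timesteps after conv/pool (or L)
  int Din;               // channels entering the BiLSTM stage
  int D;                 // width of O columns (2h if bilstm else Din)
  int DH;                // width of H (== D)
};

static Cfg parse_cfg(const Rcpp::List& cfg) {
  Cfg c;
  c.use_cnn = Rcpp::as<bool>(cfg["use_cnn"]);
  c.use_bilstm = Rcpp::as<bool>(cfg["use_bilstm"]);
  c.use_attention = Rcpp::as<bool>(cfg["use_attention"]);
  c.L = Rcpp::as<int>(cfg["L"]);
  c.F = Rcpp::as<int>(cfg["feature_dim"]);
  Rcpp::IntegerVector cc = cfg["conv_channels"], ks = cfg["kernel_sizes"], fs = cfg["fc_sizes"];
  c.c1 = cc[0]; c.c2 = cc[1]; c.k1 = ks[0]; c.k2 = ks[1];
  c.pool = Rcpp::as<int>(cfg["pool_size"]);
  c.h = Rcpp::as<int>(cfg["lstm_hidden"]);
  c.A = Rcpp::as<int>(cfg["attention_dim"]);
  c.f1 = fs[0]; c.f2 = fs[1];
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  if (c.use_cnn) {
    int minL = c.k1 + c.k2 - 2 + c.pool;  // need >= 1 pooled timestep
    if (c.L < minL)
      Rcpp::stop("window length L=%d too small for the conv/pool stack; minimum L is %d",
                 c.L, minL);
    int t2 = c.L - c.k1 + 1 - c.k2 + 1;
    c.T = t2 / c.pool;
    c.Din = c.c2;
  } else {
    c.T = c.L;
    c.Din = c.F;
  }
  c.D = c.use_bilstm ? 2 * c.h : c.Din;
  c.DH = c.D;
  return c;
}

struct Params {
  mat conv1_w, conv2_w;          // c1 x (k1*F), c2 x (k2*c1)
  vec conv1_b, conv2_b;
  mat f_wx, f_wh, b_wx, b_wh;    // 4h x Din, 4h x h (forward / backward dir)
  vec f_b, b_b;
  mat att_w1, att_w2;            // A x D
  vec att_v;                     // A
  mat fc1_w, fc2_w, out_w;
  vec fc1_b, fc2_b, out_b;
};

static const char* PNAMES[] = {
  "conv1_w","conv1_b","conv2_w","conv2_b",
  "lstm_f_wx","lstm_f_wh","lstm_f_b","lstm_b_wx","lstm_b_wh","lstm_b_b",
  "att_w1","att_w2","att_v",
  "fc1_w","fc1_b","fc2_w","fc2_b","out_w","out_b"};

static std::vector<mat*> plist(Params& p) {
  // biases stored as vec; wrap them into single-column views at the List edge
  return {&p.conv1_w, nullptr, &p.conv2_w, nullptr,
          &p.f_wx, &p.f_wh, nullptr, &p.b_wx, &p.b_wh, nullptr,
          &p.att_w1, &p.att_w2, nullptr,
          &p.fc1_w, nullptr, &p.fc2_w, nullptr, &p.out_w, nullptr};
}
static std::vector<vec*> vlist(Params& p) {
  return {nullptr, &p.conv1_b, nullptr, &p.conv2_b,
          nullptr, nullptr, &p.f_b, nullptr, nullptr, &p.b_b,
          nullptr, nullptr, &p.att_v,
          nullptr, &p.fc1_b, nullptr, &p.fc2_b, nullptr, &p.out_b};
}

static bool param_active(const Cfg& c, int i) {
  if (i <= 3) return c.use_cnn;
  if (i <= 9) return c.use_bilstm;
  if (i <= 12) return c.use_attention;
  return true;
}

static Rcpp::List params_to_list(Params& p, const Cfg& c) {
  Rcpp::List out;
  auto ms = plist(p); auto vs = vlist(p);
  for (int i = 0; i < 19; ++i) {
    if (!param_active(c, i)) continue;
    if (ms[i]) out[PNAMES[i]] = Rcpp::wrap(*ms[i]);
    else out[PNAMES[i]] = Rcpp::wrap(*vs[i]);
  }
  return out;
}

static Params params_from_list(const Rcpp::List& l, const Cfg& c) {
  Params p;
  auto ms = plist(p); auto vs = vlist(p);
  for (int i = 0; i < 19; ++i) {
    if (!param_active(c, i)) continue;
    if (ms[i]) *ms[i] = Rcpp::as<mat>(l[PNAMES[i]]);
    else *vs[i] = Rcpp::as<vec>(l[PNAMES[i]]);
  }
  return p;
}

static mat glorot(int nr, int nc, std::mt19937& rng) {
  double lim = std::sqrt(6.0 / (nr + nc));
  std::uniform_real_distribution<double> U(-lim, lim);
  mat m(nr, nc);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) m(i, j) = U(rng);
  return m;
}

// [[Rcpp::export(name = ".nn_init")]]
Rcpp::List nn_init(Rcpp::List cfg, int seed) {
  Cfg c = parse_cfg(cfg);
  std::mt19937 rng(static_cast<uint32_t>(seed));
  Params p;
  if (c.use_cnn) {
    p.conv1_w = glorot(c.c1, c.k1 * c.F, rng); p.conv1_b = zeros<vec>(c.c1);
    p.conv2_w = glorot(c.c2, c.k2 * c.c1, rng); p.conv2_b = zeros<vec>(c.c2);
  }
  if (c.use_bilstm) {
    p.f_wx = glorot(4 * c.h, c.Din, rng); p.f_wh = glorot(4 * c.h, c.h, rng);
    p.b_wx = glorot(4 * c.h, c.Din, rng); p.b_wh = glorot(4 * c.h, c.h, rng);
    // zero biases (forget gate included): the recurrence starts with short
    // memory, so timesteps keep positional meaning for the attention stage
    p.f_b = zeros<vec>(4 * c.h); p.b_b = zeros<vec>(4 * c.h);
  }
  if (c.use_attention) {
    p.att_w1 = glorot(c.A, c.D, rng);
    p.att_w2 = glorot(c.A, c.DH, rng);
    p.att_v = glorot(c.A, 1, rng).col(0);
  }
  p.fc1_w = glorot(c.f1, c.D, rng); p.fc1_b = zeros<vec>(c.f1);
  p.fc2_w = glorot(c.f2, c.f1, rng); p.fc2_b = zeros<vec>(c.f2);
  p.out_w = glorot(2, c.f2, rng); p.out_b = zeros<vec>(2);
  return params_to_list(p, c);
}

struct Cache {
  mat A;                 // F x L input (channels x time)
  mat P1, R1, P2, R2;    // conv patch matrices and post-ReLU maps
  umat poolidx;          // argmax column in R2 per (channel, pooled t)
  mat M;                 // Din x T entering the recurrent stage
  // per direction: inputs in processing order, gate activations, states
  mat fx, fi, ff, fg, fo, fc_, fth, fh;
  mat bx, bi, bf, bg, bo, bc_, bth, bh;
  mat O;                 // D x T
  vec H;                 // DH
  mat u, tanh_u;         // A x T (attention pre-activations)
  vec a;                 // T attention weights
  vec ctx;               // D
  vec z1, r1, d1, z2, r2, d2;  // FNN activations and dropout masks
  vec probs;             // 2
};

static void lstm_forward(const mat& X, const mat& Wx, const mat& Wh, const vec& b,
                         int h, mat& gi, mat& gf, mat& gg, mat& go,
                         mat& cs, mat& th, mat& hs) {
  int T = X.n_cols;
  gi.set_size(h, T); gf.set_size(h, T); gg.set_size(h, T); go.set_size(h, T);
  cs.set_size(h, T); th.set_size(h, T); hs.set_size(h, T);
  vec hprev = zeros<vec>(h), cprev = zeros<vec>(h);
  for (int t = 0; t < T; ++t) {
    vec z = Wx * X.col(t) + Wh * hprev + b;
    vec i = 1.0 / (1.0 + exp(-z.subvec(0, h - 1)));
    vec f = 1.0 / (1.0 + exp(-z.subvec(h, 2 * h - 1)));
    vec g = tanh(z.subvec(2 * h, 3 * h - 1));
    vec o = 1.0 / (1.0 + exp(-z.subvec(3 * h, 4 * h - 1)));
    vec cc = f % cprev + i % g;
    vec tc = tanh(cc);
    vec hh = o % tc;
    gi.col(t) = i; gf.col(t) = f; gg.col(t) = g; go.col(t) = o;
    cs.col(t) = cc; th.col(t) = tc; hs.col(t) = hh;
    hprev = hh; cprev = cc;
  }
}

// backprop one direction; dh_ext is h x T in processing order; returns dX
static mat lstm_backward(const mat& X, const mat& Wx, const mat& Wh,
                         const mat& gi, const mat& gf, const mat& gg, const mat& go,
                         const mat& cs, const mat& th,
                         const mat& hs, const mat& dh_ext,
                         mat& dWx, mat& dWh, vec& db) {
  int T = X.n_cols, h = gi.n_rows;
  mat dX = zeros<mat>(X.n_rows, T);
  vec dh_next = zeros<vec>(h), dc_next = zeros<vec>(h);
  for (int t = T - 1; t >= 0; --t) {
    vec dh = dh_ext.col(t) + dh_next;
    vec i = gi.col(t), f = gf.col(t), g = gg.col(t), o = go.col(t), tc = th.col(t);
    vec do_ = dh % tc;
    vec dzo = do_ % o % (1.0 - o);
    vec dc = dh % o % (1.0 - tc % tc) + dc_next;
    vec cprev = (t > 0) ? vec(cs.col(t - 1)) : zeros<vec>(h);
    vec hprev = (t > 0) ? vec(hs.col(t - 1)) : zeros<vec>(h);
    vec dzf = (dc % cprev) % f % (1.0 - f);
    vec dzi = (dc % g) % i % (1.0 - i);
    vec dzg = (dc % i) % (1.0 - g % g);
    vec dz = join_cols(dzi, join_cols(dzf, join_cols(dzg, dzo)));
    dWx += dz * X.col(t).t();
    dWh += dz * hprev.t();
    db += dz;
    dh_next = Wh.t() * dz;
    dc_next = dc % f;
    dX.col(t) = Wx.t() * dz;
  }
  return dX;
}

static vec softmax(const vec& s) {
  vec e = exp(s - s.max());
  return e / accu(e);
}

static void forward_one(const mat& X, const Params& p, const Cfg& c,
                        bool train, std::mt19937* rng, Cache& K) {
  K.A = X.t();  // F x L
  if (c.use_cnn) {
    int T1 = c.L - c.k1 + 1;
    K.P1.set_size(c.k1 * c.F, T1);
    for (int t = 0; t < T1; ++t)
      K.P1.col(t) = vectorise(K.A.cols(t, t + c.k1 - 1));
    mat o1 = p.conv1_w * K.P1;
    o1.each_col() += p.conv1_b;
    K.R1 = clamp(o1, 0.0, datum::inf);
    int T2 = T1 - c.k2 + 1;
    K.P2.set_size(c.k2 * c.c1, T2);
    for (int t = 0; t < T2; ++t)
      K.P2.col(t) = vectorise(K.R1.cols(t, t + c.k2 - 1));
    mat o2 = p.conv2_w * K.P2;
    o2.each_col() += p.conv2_b;
    K.R2 = clamp(o2, 0.0, datum::inf);
    K.M.set_size(c.c2, c.T);
    K.poolidx.set_size(c.c2, c.T);
    for (int t = 0; t < c.T; ++t) {
      int lo = t * c.pool;
      for (int ch = 0; ch < c.c2; ++ch) {
        uword best = lo;
        for (int j = lo + 1; j < lo + c.pool; ++j)
          if (K.R2(ch, j) > K.R2(ch, best)) best = j;
        K.poolidx(ch, t) = best;
        K.M(ch, t) = K.R2(ch, best);
      }
    }
  } else {
    K.M = K.A;
  }
  if (c.use_bilstm) {
    lstm_forward(K.M, p.f_wx, p.f_wh, p.f_b, c.h, K.fi, K.ff, K.fg, K.fo, K.fc_, K.fth, K.fh);
    mat Mrev = fliplr(K.M);
    lstm_forward(Mrev, p.b_wx, p.b_wh, p.b_b, c.h, K.bi, K.bf, K.bg, K.bo, K.bc_, K.bth, K.bh);
    K.O.set_size(2 * c.h, c.T);
    for (int t = 0; t < c.T; ++t) {
      K.O.col(t) = join_cols(K.fh.col(t), K.bh.col(c.T - 1 - t));
    }
    K.H = join_cols(K.fh.col(c.T - 1), K.bh.col(c.T - 1));
  } else {
    K.O = K.M;
    K.H = mean(K.M, 1);
  }
  if (c.use_attention) {
    vec w2h = p.att_w2 * K.H;
    K.u = p.att_w1 * K.O;
    K.u.each_col() += w2h;
    K.tanh_u = tanh(K.u);
    vec s = K.tanh_u.t() * p.att_v;
    K.a = softmax(s);
    K.ctx = K.O * K.a;
  } else {
    K.a = ones<vec>(c.T) / c.T;  // uniform placeholder so the interface is stable
    K.ctx = K.H;
  }
  K.z1 = p.fc1_w * K.ctx + p.fc1_b;
  K.r1 = clamp(K.z1, 0.0, datum::inf);
  if (train && c.dropout > 0) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    K.d1.set_size(c.f1);
    for (int i = 0; i < c.f1; ++i)
      K.d1(i) = (U(*rng) < c.dropout) ? 0.0 : 1.0 / (1.0 - c.dropout);
    K.r1 %= K.d1;
  }
  K.z2 = p.fc2_w * K.r1 + p.fc2_b;
  K.r2 = clamp(K.z2, 0.0, datum::inf);
  if (train && c.dropout > 0) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    K.d2.set_size(c.f2);
    for (int i = 0; i < c.f2; ++i)
      K.d2(i) = (U(*rng) < c.dropout) ? 0.0 : 1.0 / (1.0 - c.dropout);
    K.r2 %= K.d2;
  }
  K.probs = softmax(p.out_w * K.r2 + p.out_b);
}

static void backward_one(int y, const Params& p, const Cfg& c, const Cache& K, Params& G) {
  vec dlogit = K.probs;
  dlogit(y) -= 1.0;                      // d CE / d logits
  G.out_w += dlogit * K.r2.t();
  G.out_b += dlogit;
  vec dr2 = p.out_w.t() * dlogit;
  if (K.d2.n_elem) dr2 %= K.d2;
  vec dz2 = dr2 % conv_to<vec>::from(K.z2 > 0);
  G.fc2_w += dz2 * K.r1.t();
  G.fc2_b += dz2;
  vec dr1 = p.fc2_w.t() * dz2;
  if (K.d1.n_elem) dr1 %= K.d1;
  vec dz1 = dr1 % conv_to<vec>::from(K.z1 > 0);
  G.fc1_w += dz1 * K.ctx.t();
  G.fc1_b += dz1;
  vec dctx = p.fc1_w.t() * dz1;

  mat dO = zeros<mat>(c.D, c.T);
  vec dH = zeros<vec>(c.DH);
  if (c.use_attention) {
    // ctx = O a ; scores via v' tanh(w1 O_t + w2 H)
    dO += dctx * K.a.t();
    vec da = K.O.t() * dctx;
    vec ds = K.a % (da - dot(K.a, da));
    mat du = (p.att_v * ds.t()) % (1.0 - K.tanh_u % K.tanh_u);  // A x T
    G.att_v += K.tanh_u * ds;
    G.att_w1 += du * K.O.t();
    G.att_w2 += sum(du, 1) * K.H.t();
    dO += p.att_w1.t() * du;
    dH += p.att_w2.t() * sum(du, 1);
  } else {
    dH += dctx;
  }

  mat dM;
  if (c.use_bilstm) {
    mat dhf = dO.rows(0, c.h - 1);                    // h x T, forward order
    mat dhb_time = dO.rows(c.h, 2 * c.h - 1);         // h x T in sequence time
    dhf.col(c.T - 1) += dH.subvec(0, c.h - 1);
    mat dhb = fliplr(dhb_time);                       // processing order of the reverse pass
    dhb.col(c.T - 1) += dH.subvec(c.h, 2 * c.h - 1);
    mat dXf = lstm_backward(K.M, p.f_wx, p.f_wh, K.fi, K.ff, K.fg, K.fo, K.fc_, K.fth,
                            K.fh, dhf, G.f_wx, G.f_wh, G.f_b);
    mat Mrev = fliplr(K.M);
    mat dXb = lstm_backward(Mrev, p.b_wx, p.b_wh, K.bi, K.bf, K.bg, K.bo, K.bc_, K.bth,
                            K.bh, dhb, G.b_wx, G.b_wh, G.b_b);
    dM = dXf + fliplr(dXb);
  } else {
    dM = dO;
    dM.each_col() += dH / c.T;  // H was the column mean of M
  }

  if (c.use_cnn) {
    mat dR2 = zeros<mat>(size(K.R2));
    for (int t = 0; t < c.T; ++t)
      for (int ch = 0; ch < c.c2; ++ch)
        dR2(ch, K.poolidx(ch, t)) += dM(ch, t);
    mat do2 = dR2 % conv_to<mat>::from(K.R2 > 0);
    G.conv2_w += do2 * K.P2.t();
    G.conv2_b += sum(do2, 1);
    mat dP2 = p.conv2_w.t() * do2;
    mat dR1 = zeros<mat>(size(K.R1));
    int T2 = K.P2.n_cols;
    for (int t = 0; t < T2; ++t)
      dR1.cols(t, t + c.k2 - 1) += reshape(dP2.col(t), c.c1, c.k2);
    mat do1 = dR1 % conv_to<mat>::from(K.R1 > 0);
    G.conv1_w += do1 * K.P1.t();
    G.conv1_b += sum(do1, 1);
    // input gradients not needed: the encoding is fixed
  }
}

static void zero_like(const Params& p, const Cfg& c, Params& g) {
  Params& pp = const_cast<Params&>(p);
  auto ms = plist(pp); auto gs = plist(g);
  auto vs = vlist(pp); auto gv = vlist(g);
  for (int i = 0; i < 19; ++i) {
    if (!param_active(c, i)) continue;
    if (ms[i]) *gs[i] = zeros<mat>(size(*ms[i]));
    else *gv[i] = zeros<vec>(size(*vs[i]));
  }
}

struct Adam {
  Params m, v;
  long t = 0;
  void init(const Params& p, const Cfg& c) { zero_like(p, c, m); zero_like(p, c, v); }
  void step(Params& p, Params& g, const Cfg& c, double lr) {
    ++t;
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    double corr1 = 1.0 - std::pow(b1, (double)t), corr2 = 1.0 - std::pow(b2, (double)t);
    auto ps = plist(p); auto gs = plist(g); auto msl = plist(m); auto vsl = plist(v);
    auto pv = vlist(p); auto gv = vlist(g); auto mv = vlist(m); auto vv = vlist(v);
    for (int i = 0; i < 19; ++i) {
      if (!param_active(c, i)) continue;
      if (ps[i]) {
        *msl[i] = b1 * (*msl[i]) + (1 - b1) * (*gs[i]);
        *vsl[i] = b2 * (*vsl[i]) + (1 - b2) * square(*gs[i]);
        *ps[i] -= lr * ((*msl[i]) / corr1) / (sqrt((*vsl[i]) / corr2) + eps);
      } else {
        *mv[i] = b1 * (*mv[i]) + (1 - b1) * (*gv[i]);
        *vv[i] = b2 * (*vv[i]) + (1 - b2) * square(*gv[i]);
        *pv[i] -= lr * ((*mv[i]) / corr1) / (sqrt((*vv[i]) / corr2) + eps);
      }
    }
  }
};

static double dataset_loss(const cube& X, const ivec& y, const Params& p, const Cfg& c) {
  double loss = 0;
  Cache K;
  for (uword i = 0; i < X.n_slices; ++i) {
    forward_one(X.slice(i), p, c, false, nullptr, K);
    loss += -std::log(std::max(K.probs(y(i)), 1e-12));
  }
  return loss / X.n_slices;
}

// [[Rcpp::export(name = ".nn_train")]]
Rcpp::List nn_train(arma::cube X, arma::ivec y, Rcpp::List params, Rcpp::List cfg,
                    int epochs, int batch_size, double lr, int seed, int patience,
                    Rcpp::Nullable<arma::cube> Xval = R_NilValue,
                    Rcpp::Nullable<arma::ivec> yval = R_NilValue) {
  Cfg c = parse_cfg(cfg);
  Params p = params_from_list(params, c);
  int n = X.n_slices;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  Adam opt; opt.init(p, c);
  bool has_val = Xval.isNotNull();
  cube Xv; ivec yv;
  if (has_val) { Xv = Rcpp::as<cube>(Xval); yv = Rcpp::as<ivec>(yval); }

  std::vector<double> hist, vhist;
  Params best = p;
  double best_val = datum::inf;
  int best_epoch = 0, bad = 0;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  Params g; zero_like(p, c, g);
  Cache K;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(s + batch_size, n);
      zero_like(p, c, g);
      for (int b = s; b < e; ++b) {
        const mat& Xi = X.slice(idx[b]);
        forward_one(Xi, p, c, true, &rng, K);
        double li = -std::log(std::max(K.probs(y(idx[b])), 1e-12));
        ep_loss += li;
        backward_one(y(idx[b]), p, c, K, g);
      }
      double inv = 1.0 / (e - s);
      auto gs = plist(g); auto gv = vlist(g);
      for (int i = 0; i < 19; ++i) {
        if (!param_active(c, i)) continue;
        if (gs[i]) *gs[i] *= inv; else *gv[i] *= inv;
      }
      opt.step(p, g, c, lr);
    }
    ep_loss /= n;
    if (!std::isfinite(ep_loss))
      Rcpp::stop("NaN/Inf training loss at epoch %d (lr=%g); aborting", ep + 1, lr);
    hist.push_back(ep_loss);
    if (has_val) {
      double vl = dataset_loss(Xv, yv, p, c);
      vhist.push_back(vl);
      if (vl < best_val - 1e-8) { best_val = vl; best = p; best_epoch = ep + 1; bad = 0; }
      else if (++bad >= patience && patience > 0) break;
    }
    Rcpp::checkUserInterrupt();
  }
  if (has_val && patience > 0) p = best; else best_epoch = (int)hist.size();
  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_list(p, c),
      Rcpp::Named("loss_history") = hist,
      Rcpp::Named("val_loss_history") = vhist,
      Rcpp::Named("best_epoch") = best_epoch);
}

// mean cross-entropy gradient over a batch, dropout off (used by the
// finite-difference checks in the test suite)
// [[Rcpp::export(name = ".nn_grad")]]
Rcpp::List nn_grad(arma::cube X, arma::ivec y, Rcpp::List params, Rcpp::List cfg) {
  Cfg c = parse_cfg(cfg);
  Params p = params_from_list(params, c);
  Params g; zero_like(p, c, g);
  Cache K;
  int n = X.n_slices;
  double loss = 0;
  for (int i = 0; i < n; ++i) {
    forward_one(X.slice(i), p, c, false, nullptr, K);
    loss += -std::log(std::max(K.probs(y(i)), 1e-12));
    backward_one(y(i), p, c, K, g);
  }
  auto gs = plist(g); auto gv = vlist(g);
  for (int i = 0; i < 19; ++i) {
    if (!param_active(c, i)) continue;
    if (gs[i]) *gs[i] /= n; else *gv[i] /= n;
  }
  Rcpp::List out = params_to_list(g, c);
  out.attr("loss") = loss / n;
  return out;
}

// [[Rcpp::export(name = ".nn_forward")]]
Rcpp::List nn_forward(arma::cube X, Rcpp::List params, Rcpp::List cfg,
                      bool features = false) {
  Cfg c = parse_cfg(cfg);
  Params p = params_from_list(params, c);
  int n = X.n_slices;
  mat probs(n, 2), attn(n, c.T);
  mat f_enc, f_cnn, f_lstm, f_ctx;
  if (features) {
    f_enc.set_size(n, c.L * c.F);
    f_cnn.set_size(n, c.Din * c.T);
    f_lstm.set_size(n, c.DH);
    f_ctx.set_size(n, c.D);
  }
  Cache K;
  for (int i = 0; i < n; ++i) {
    forward_one(X.slice(i), p, c, false, nullptr, K);
    probs.row(i) = K.probs.t();
    attn.row(i) = K.a.t();
    if (features) {
      f_enc.row(i) = vectorise(X.slice(i)).t();
      f_cnn.row(i) = vectorise(K.M).t();
      f_lstm.row(i) = K.H.t();
      f_ctx.row(i) = K.ctx.t();
    }
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("probs") = probs,
      Rcpp::Named("attention") = attn,
      Rcpp::Named("timesteps") = c.T);
  if (features)
    out["features"] = Rcpp::List::create(
        Rcpp::Named("encoding") = f_enc, Rcpp::Named("cnn") = f_cnn,
        Rcpp::Named("bilstm") = f_lstm, Rcpp::Named("attention") = f_ctx);
  return out;
}

// [[Rcpp::export(name = ".nn_timesteps")]]
int nn_timesteps(Rcpp::List cfg) {
  return parse_cfg(cfg).T;
}
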