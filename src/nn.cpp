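// Minimal trainable network engine for the diffusion denoiser (U-Net with a
// transformer mid-block) and the SE-U-Net localizer. Single precision,
// explicit backward passes, Adam. Feature maps are stored per sample as
// (C x H*W) matrices with spatial index j = h + H*w (R column-major order).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;
using Batch = std::vector<fmat>;

static inline bool all_zero(const fmat& m) { return arma::accu(arma::abs(m)) == 0.0f; }

// ---------------------------------------------------------------------------
// RNG (own Box-Muller over mt19937 so initialization is reproducible)
struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  double unif() { return (gen() + 0.5) / 4294967296.0; }
  double gauss() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

struct Param {
  fmat w, g, m, v;
  void init(int r, int c, double sd, Rng& rng, double fill = NA_REAL) {
    w.set_size(r, c);
    if (std::isnan(fill)) {
      for (arma::uword i = 0; i < w.n_elem; ++i) w(i) = (float)(sd * rng.gauss());
    } else {
      w.fill((float)fill);
    }
    g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
};

// ---------------------------------------------------------------------------
// Layers

struct Conv {
  // im2col layout: row index t*cin + c so that, for a fixed output pixel and
  // kernel tap t, the cin source values are one contiguous memcpy. The whole
  // batch shares a single col matrix -> one large GEMM per layer.
  int cin, cout, H, W, Ho, Wo, stride;
  Param Wt, b;                       // Wt: (cout, 9*cin)
  arma::Mat<int> idx;                // (9, Ho*Wo) spatial gather map, -1 = pad
  fmat col_big;                      // cached (9*cin, N*Ho*Wo)

  void build(int cin_, int cout_, int H_, int W_, int stride_, Rng& rng,
             double w_sd = -1.0, double b_fill = 0.0) {
    cin = cin_; cout = cout_; H = H_; W = W_; stride = stride_;
    Ho = H / stride; Wo = W / stride;
    double sd = w_sd > 0 ? w_sd : std::sqrt(2.0 / (cin * 9.0));
    Wt.init(cout, cin * 9, sd, rng);
    b.init(cout, 1, 0.0, rng, b_fill);
    idx.set_size(9, Ho * Wo);
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        int o = ho + Ho * wo;
        for (int kc = 0; kc < 3; ++kc)
          for (int kr = 0; kr < 3; ++kr) {
            int hi = ho * stride + kr - 1, wi = wo * stride + kc - 1;
            idx(kr + 3 * kc, o) =
              (hi >= 0 && hi < H && wi >= 0 && wi < W) ? hi + H * wi : -1;
          }
      }
  }

  Batch forward(const Batch& x, bool train) {
    size_t N = x.size();
    int P = Ho * Wo;
    fmat col(cin * 9, N * P);
    for (size_t n = 0; n < N; ++n) {
      const float* xr = x[n].memptr();
      for (int o = 0; o < P; ++o) {
        float* dst = col.colptr(n * P + o);
        for (int t = 0; t < 9; ++t) {
          int s = idx(t, o);
          if (s >= 0) std::memcpy(dst + t * cin, xr + (size_t)cin * s,
                                  cin * sizeof(float));
          else std::memset(dst + t * cin, 0, cin * sizeof(float));
        }
      }
    }
    fmat y_big = Wt.w * col;
    y_big.each_col() += b.w.col(0);
    Batch y(N);
    for (size_t n = 0; n < N; ++n)
      y[n] = y_big.cols(n * P, (n + 1) * P - 1);
    if (train) col_big = std::move(col);
    return y;
  }

  Batch backward(const Batch& dy) {
    size_t N = dy.size();
    int P = Ho * Wo;
    std::vector<size_t> keep;
    for (size_t n = 0; n < N; ++n) if (!all_zero(dy[n])) keep.push_back(n);
    size_t K = keep.size();
    Batch dx(N);
    for (size_t n = 0; n < N; ++n) dx[n].zeros(cin, H * W);
    if (K == 0) return dx;
    fmat dy_sub(cout, K * P), col_sub(cin * 9, K * P);
    for (size_t k = 0; k < K; ++k) {
      dy_sub.cols(k * P, (k + 1) * P - 1) = dy[keep[k]];
      col_sub.cols(k * P, (k + 1) * P - 1) =
        col_big.cols(keep[k] * P, (keep[k] + 1) * P - 1);
    }
    Wt.g += dy_sub * col_sub.t();
    b.g += arma::sum(dy_sub, 1);
    fmat dcol = Wt.w.t() * dy_sub;
    for (size_t k = 0; k < K; ++k) {
      float* dr = dx[keep[k]].memptr();
      for (int o = 0; o < P; ++o) {
        const float* src = dcol.colptr(k * P + o);
        for (int t = 0; t < 9; ++t) {
          int s = idx(t, o);
          if (s < 0) continue;
          float* d0 = dr + (size_t)cin * s;
          const float* s0 = src + t * cin;
          for (int c = 0; c < cin; ++c) d0[c] += s0[c];
        }
      }
    }
    return dx;
  }
};

struct Act {  // 0 = SiLU, 1 = ReLU, 2 = sigmoid
  int kind;
  Batch cache;
  explicit Act(int k = 0) : kind(k) {}
  Batch forward(const Batch& x, bool train) {
    Batch y(x.size());
    for (size_t n = 0; n < x.size(); ++n) {
      if (kind == 0) y[n] = x[n] % (1.0f / (1.0f + arma::exp(-x[n])));
      else if (kind == 1) y[n] = arma::max(x[n], fmat(arma::size(x[n]), arma::fill::zeros));
      else y[n] = 1.0f / (1.0f + arma::exp(-x[n]));
    }
    if (train) cache = (kind == 2) ? y : x;
    return y;
  }
  Batch backward(const Batch& dy) {
    Batch dx(dy.size());
    for (size_t n = 0; n < dy.size(); ++n) {
      if (all_zero(dy[n])) { dx[n].zeros(arma::size(dy[n])); continue; }
      if (kind == 0) {
        fmat s = 1.0f / (1.0f + arma::exp(-cache[n]));
        dx[n] = dy[n] % (s % (1.0f + cache[n] % (1.0f - s)));
      } else if (kind == 1) {
        dx[n] = dy[n] % arma::conv_to<fmat>::from(cache[n] > 0.0f);
      } else {
        dx[n] = dy[n] % (cache[n] % (1.0f - cache[n]));
      }
    }
    return dx;
  }
};

struct Upsample2x {  // nearest neighbour H,W -> 2H,2W
  int H, W;
  void build(int H_, int W_) { H = H_; W = W_; }
  Batch forward(const Batch& x) {
    Batch y(x.size());
    int H2 = 2 * H, W2 = 2 * W;
    for (size_t n = 0; n < x.size(); ++n) {
      y[n].set_size(x[n].n_rows, H2 * W2);
      for (int w2 = 0; w2 < W2; ++w2)
        for (int h2 = 0; h2 < H2; ++h2)
          y[n].col(h2 + H2 * w2) = x[n].col((h2 / 2) + H * (w2 / 2));
    }
    return y;
  }
  Batch backward(const Batch& dy) {
    Batch dx(dy.size());
    int H2 = 2 * H, W2 = 2 * W;
    for (size_t n = 0; n < dy.size(); ++n) {
      dx[n].zeros(dy[n].n_rows, H * W);
      if (all_zero(dy[n])) continue;
      for (int w2 = 0; w2 < W2; ++w2)
        for (int h2 = 0; h2 < H2; ++h2)
          dx[n].col((h2 / 2) + H * (w2 / 2)) += dy[n].col(h2 + H2 * w2);
    }
    return dx;
  }
};

struct SEBlock {  // squeeze-and-excitation channel attention
  int C, Ch;
  Param W1, b1, W2, b2;
  Batch xc; std::vector<fvec> zc, hc, sc;
  void build(int C_, int ratio, Rng& rng) {
    C = C_; Ch = std::max(1, C / ratio);
    W1.init(Ch, C, std::sqrt(2.0 / C), rng);
    b1.init(Ch, 1, 0.0, rng, 0.0);
    W2.init(C, Ch, std::sqrt(2.0 / Ch), rng);
    b2.init(C, 1, 0.0, rng, 0.0);
  }
  Batch forward(const Batch& x, bool train) {
    size_t N = x.size();
    Batch y(N);
    if (train) { xc.assign(N, fmat()); zc.assign(N, fvec()); hc.assign(N, fvec()); sc.assign(N, fvec()); }
    for (size_t n = 0; n < N; ++n) {
      fvec z = arma::mean(x[n], 1);
      fvec h = arma::max(W1.w * z + b1.w.col(0), fvec(Ch, arma::fill::zeros));
      fvec s = 1.0f / (1.0f + arma::exp(-(W2.w * h + b2.w.col(0))));
      y[n] = x[n].each_col() % s;
      if (train) { xc[n] = x[n]; zc[n] = z; hc[n] = h; sc[n] = s; }
    }
    return y;
  }
  Batch backward(const Batch& dy) {
    size_t N = dy.size();
    Batch dx(N);
    for (size_t n = 0; n < N; ++n) {
      if (all_zero(dy[n])) { dx[n].zeros(arma::size(dy[n])); continue; }
      fvec ds = arma::sum(dy[n] % xc[n], 1);
      fvec dpre2 = ds % sc[n] % (1.0f - sc[n]);
      W2.g += dpre2 * hc[n].t(); b2.g += dpre2;
      fvec dh = W2.w.t() * dpre2;
      fvec dpre1 = dh % arma::conv_to<fvec>::from(hc[n] > 0.0f);
      W1.g += dpre1 * zc[n].t(); b1.g += dpre1;
      fvec dz = W1.w.t() * dpre1;
      dx[n] = dy[n].each_col() % sc[n];
      dx[n].each_col() += dz / (float)xc[n].n_cols;
    }
    return dx;
  }
};

struct Linear {  // applied tokenwise: X (d_in, Ntok) -> (d_out, Ntok)
  Param Wt, b;
  Batch xc;
  void build(int din, int dout, Rng& rng, double sd = -1.0) {
    Wt.init(dout, din, sd > 0 ? sd : std::sqrt(2.0 / din), rng);
    b.init(dout, 1, 0.0, rng, 0.0);
  }
  Batch forward(const Batch& x, bool train) {
    Batch y(x.size());
    if (train) xc = x;
    for (size_t n = 0; n < x.size(); ++n) {
      y[n] = Wt.w * x[n];
      y[n].each_col() += b.w.col(0);
    }
    return y;
  }
  Batch backward(const Batch& dy) {
    Batch dx(dy.size());
    for (size_t n = 0; n < dy.size(); ++n) {
      if (all_zero(dy[n])) { dx[n].zeros(xc[n].n_rows, dy[n].n_cols); continue; }
      Wt.g += dy[n] * xc[n].t();
      b.g += arma::sum(dy[n], 1);
      dx[n] = Wt.w.t() * dy[n];
    }
    return dx;
  }
};

struct LayerNorm {  // per-token over the feature dimension
  int d;
  Param gamma, beta;
  Batch xhat; std::vector<arma::frowvec> istd;
  void build(int d_, Rng& rng) {
    d = d_;
    gamma.init(d, 1, 0.0, rng, 1.0);
    beta.init(d, 1, 0.0, rng, 0.0);
  }
  Batch forward(const Batch& x, bool train) {
    Batch y(x.size());
    if (train) { xhat.assign(x.size(), fmat()); istd.assign(x.size(), arma::frowvec()); }
    for (size_t n = 0; n < x.size(); ++n) {
      arma::frowvec mu = arma::mean(x[n], 0);
      arma::frowvec va = arma::var(x[n], 1, 0);  // population variance
      arma::frowvec is = 1.0f / arma::sqrt(va + 1e-5f);
      fmat xh = (x[n].each_row() - mu).each_row() % is;
      y[n] = (xh.each_col() % gamma.w.col(0)).each_col() + beta.w.col(0);
      if (train) { xhat[n] = std::move(xh); istd[n] = is; }
    }
    return y;
  }
  Batch backward(const Batch& dy) {
    Batch dx(dy.size());
    for (size_t n = 0; n < dy.size(); ++n) {
      if (all_zero(dy[n])) { dx[n].zeros(arma::size(dy[n])); continue; }
      gamma.g += arma::sum(dy[n] % xhat[n], 1);
      beta.g += arma::sum(dy[n], 1);
      fmat dxh = dy[n].each_col() % gamma.w.col(0);
      arma::frowvec m1 = arma::mean(dxh, 0);
      arma::frowvec m2 = arma::mean(dxh % xhat[n], 0);
      fmat tmp = dxh.each_row() - m1;
      tmp -= xhat[n].each_row() % m2;
      dx[n] = tmp.each_row() % istd[n];
    }
    return dx;
  }
};

struct MHSA {  // multi-head self-attention over tokens X (d, Ntok)
  int d, heads, dh;
  Param Wq, Wk, Wv, Wo, bq, bk, bv, bo;
  Batch xc, Qc, Kc, Vc, Oc;
  std::vector<arma::fcube> Pc;
  void build(int d_, int heads_, Rng& rng) {
    d = d_; heads = heads_; dh = d / heads;
    double sd = std::sqrt(1.0 / d);
    Wq.init(d, d, sd, rng); Wk.init(d, d, sd, rng);
    Wv.init(d, d, sd, rng); Wo.init(d, d, sd, rng);
    bq.init(d, 1, 0, rng, 0); bk.init(d, 1, 0, rng, 0);
    bv.init(d, 1, 0, rng, 0); bo.init(d, 1, 0, rng, 0);
  }
  Batch forward(const Batch& x, bool train) {
    size_t N = x.size();
    Batch y(N);
    if (train) {
      xc = x; Qc.assign(N, fmat()); Kc.assign(N, fmat()); Vc.assign(N, fmat());
      Oc.assign(N, fmat()); Pc.assign(N, arma::fcube());
    }
    float scale = 1.0f / std::sqrt((float)dh);
    for (size_t n = 0; n < N; ++n) {
      int T = x[n].n_cols;
      fmat Q = Wq.w * x[n]; Q.each_col() += bq.w.col(0);
      fmat K = Wk.w * x[n]; K.each_col() += bk.w.col(0);
      fmat V = Wv.w * x[n]; V.each_col() += bv.w.col(0);
      fmat O(d, T);
      arma::fcube P(T, T, heads);
      for (int h = 0; h < heads; ++h) {
        auto rows = arma::span(h * dh, (h + 1) * dh - 1);
        fmat sc_ = (K.rows(rows).t() * Q.rows(rows)) * scale;  // (T, T)
        sc_.each_row() -= arma::max(sc_, 0);
        fmat e = arma::exp(sc_);
        e.each_row() /= arma::sum(e, 0);
        O.rows(rows) = V.rows(rows) * e;
        P.slice(h) = e;
      }
      y[n] = Wo.w * O; y[n].each_col() += bo.w.col(0);
      if (train) { Qc[n] = std::move(Q); Kc[n] = std::move(K); Vc[n] = std::move(V);
                   Oc[n] = std::move(O); Pc[n] = std::move(P); }
    }
    return y;
  }
  Batch backward(const Batch& dy) {
    size_t N = dy.size();
    Batch dx(N);
    float scale = 1.0f / std::sqrt((float)dh);
    for (size_t n = 0; n < N; ++n) {
      if (all_zero(dy[n])) { dx[n].zeros(arma::size(dy[n])); continue; }
      Wo.g += dy[n] * Oc[n].t();
      bo.g += arma::sum(dy[n], 1);
      fmat dO = Wo.w.t() * dy[n];
      fmat dQ(arma::size(dO)), dK(arma::size(dO)), dV(arma::size(dO));
      for (int h = 0; h < heads; ++h) {
        auto rows = arma::span(h * dh, (h + 1) * dh - 1);
        const fmat& P = Pc[n].slice(h);
        dV.rows(rows) = dO.rows(rows) * P.t();
        fmat dP = Vc[n].rows(rows).t() * dO.rows(rows);      // (T, T)
        arma::frowvec dot = arma::sum(P % dP, 0);
        fmat dS = P % (dP.each_row() - dot);
        dQ.rows(rows) = Kc[n].rows(rows) * dS * scale;
        dK.rows(rows) = Qc[n].rows(rows) * dS.t() * scale;
      }
      Wq.g += dQ * xc[n].t(); bq.g += arma::sum(dQ, 1);
      Wk.g += dK * xc[n].t(); bk.g += arma::sum(dK, 1);
      Wv.g += dV * xc[n].t(); bv.g += arma::sum(dV, 1);
      dx[n] = Wq.w.t() * dQ + Wk.w.t() * dK + Wv.w.t() * dV;
    }
    return dx;
  }
};

// Additive sinusoidal time embedding on tokens (no parameters).
static fvec time_embedding(double t, int d) {
  fvec e(d);
  int half = d / 2;
  for (int i = 0; i < half; ++i) {
    double freq = std::exp(-std::log(10000.0) * i / std::max(1, half - 1));
    e(2 * i) = (float)std::sin(t * freq);
    e(2 * i + 1) = (float)std::cos(t * freq);
  }
  if (d % 2 == 1) e(d - 1) = 0.0f;
  return e;
}

// ---------------------------------------------------------------------------
// Parameter registry / Adam

struct ModelBase {
  std::vector<std::pair<std::string, Param*>> plist;
  long adam_t = 0;
  void reg(const std::string& nm, Param& p) { plist.emplace_back(nm, &p); }
  void zero_grad() { for (auto& pr : plist) pr.second->g.zeros(); }
  void adam_step(double lr, double b1, double b2, double eps) {
    adam_t++;
    double c1 = 1.0 - std::pow(b1, (double)adam_t);
    double c2 = 1.0 - std::pow(b2, (double)adam_t);
    for (auto& pr : plist) {
      Param& p = *pr.second;
      p.m = (float)b1 * p.m + (float)(1.0 - b1) * p.g;
      p.v = (float)b2 * p.v + (float)(1.0 - b2) * (p.g % p.g);
      p.w -= (float)lr * (p.m / (float)c1) / (arma::sqrt(p.v / (float)c2) + (float)eps);
      p.g.zeros();
    }
  }
  long n_params() const {
    long n = 0;
    for (auto& pr : plist) n += pr.second->w.n_elem;
    return n;
  }
};

// ---------------------------------------------------------------------------
// Denoiser: U-Net with transformer mid-block, additive sinusoidal time
// embedding on the mid tokens.

struct Denoiser : ModelBase {
  int H, W, w1, w2, w3, depth, heads;
  Conv c0, c1, d1, c2, d2, u1c, u2c, outc;
  Act a0{0}, a1{0}, ad1{0}, a2{0}, ad2{0}, au1{0}, au2{0};
  std::vector<LayerNorm> ln1, ln2;
  std::vector<MHSA> attn;
  std::vector<Linear> fc1, fc2;
  std::vector<Act> amlp;
  Upsample2x up1, up2;
  Batch skip1, skip2;  // cached encoder outputs for the decoder concat

  Denoiser(int H_, int W_, int w1_, int w2_, int w3_, int depth_, int heads_,
           uint32_t seed)
      : H(H_), W(W_), w1(w1_), w2(w2_), w3(w3_), depth(depth_), heads(heads_) {
    Rng rng(seed);
    c0.build(1, w1, H, W, 1, rng);
    c1.build(w1, w1, H, W, 1, rng);
    d1.build(w1, w2, H, W, 2, rng);
    c2.build(w2, w2, H / 2, W / 2, 1, rng);
    d2.build(w2, w3, H / 2, W / 2, 2, rng);
    ln1.resize(depth); ln2.resize(depth); attn.resize(depth);
    fc1.resize(depth); fc2.resize(depth);
    amlp.assign(depth, Act(0));
    for (int l = 0; l < depth; ++l) {
      ln1[l].build(w3, rng); attn[l].build(w3, heads, rng);
      ln2[l].build(w3, rng);
      fc1[l].build(w3, 4 * w3, rng);
      fc2[l].build(4 * w3, w3, rng, std::sqrt(1.0 / (4.0 * w3)));
    }
    up1.build(H / 4, W / 4);
    u1c.build(w3 + w2, w2, H / 2, W / 2, 1, rng);
    up2.build(H / 2, W / 2);
    u2c.build(w2 + w1, w1, H, W, 1, rng);
    outc.build(w1, 1, H, W, 1, rng, 1e-3);

    reg("c0.W", c0.Wt); reg("c0.b", c0.b);
    reg("c1.W", c1.Wt); reg("c1.b", c1.b);
    reg("d1.W", d1.Wt); reg("d1.b", d1.b);
    reg("c2.W", c2.Wt); reg("c2.b", c2.b);
    reg("d2.W", d2.Wt); reg("d2.b", d2.b);
    for (int l = 0; l < depth; ++l) {
      std::string p = "mid" + std::to_string(l) + ".";
      reg(p + "ln1.g", ln1[l].gamma); reg(p + "ln1.b", ln1[l].beta);
      reg(p + "Wq", attn[l].Wq); reg(p + "bq", attn[l].bq);
      reg(p + "Wk", attn[l].Wk); reg(p + "bk", attn[l].bk);
      reg(p + "Wv", attn[l].Wv); reg(p + "bv", attn[l].bv);
      reg(p + "Wo", attn[l].Wo); reg(p + "bo", attn[l].bo);
      reg(p + "ln2.g", ln2[l].gamma); reg(p + "ln2.b", ln2[l].beta);
      reg(p + "fc1.W", fc1[l].Wt); reg(p + "fc1.b", fc1[l].b);
      reg(p + "fc2.W", fc2[l].Wt); reg(p + "fc2.b", fc2[l].b);
    }
    reg("u1.W", u1c.Wt); reg("u1.b", u1c.b);
    reg("u2.W", u2c.Wt); reg("u2.b", u2c.b);
    reg("out.W", outc.Wt); reg("out.b", outc.b);
  }

  Batch forward(const Batch& x, const std::vector<double>& t, bool train) {
    Batch h = a0.forward(c0.forward(x, train), train);
    h = a1.forward(c1.forward(h, train), train);
    skip1 = h;
    h = ad1.forward(d1.forward(h, train), train);
    h = a2.forward(c2.forward(h, train), train);
    skip2 = h;
    h = ad2.forward(d2.forward(h, train), train);
    // mid: tokens are the columns of (w3, H/4*W/4)
    for (size_t n = 0; n < h.size(); ++n)
      h[n].each_col() += time_embedding(t[n], w3);
    for (int l = 0; l < depth; ++l) {
      Batch r = attn[l].forward(ln1[l].forward(h, train), train);
      for (size_t n = 0; n < h.size(); ++n) h[n] += r[n];
      Batch r2 = fc2[l].forward(
          amlp[l].forward(fc1[l].forward(ln2[l].forward(h, train), train), train), train);
      for (size_t n = 0; n < h.size(); ++n) h[n] += r2[n];
    }
    h = up1.forward(h);
    for (size_t n = 0; n < h.size(); ++n) h[n] = arma::join_cols(h[n], skip2[n]);
    h = au1.forward(u1c.forward(h, train), train);
    h = up2.forward(h);
    for (size_t n = 0; n < h.size(); ++n) h[n] = arma::join_cols(h[n], skip1[n]);
    h = au2.forward(u2c.forward(h, train), train);
    return outc.forward(h, train);
  }

  void backward(const Batch& dy) {
    Batch d = outc.backward(dy);
    d = u2c.backward(au2.backward(d));
    Batch dskip1(d.size());
    for (size_t n = 0; n < d.size(); ++n) {
      dskip1[n] = d[n].rows(w2, w2 + w1 - 1);
      d[n] = d[n].rows(0, w2 - 1);
    }
    d = up2.backward(d);
    d = u1c.backward(au1.backward(d));
    Batch dskip2(d.size());
    for (size_t n = 0; n < d.size(); ++n) {
      dskip2[n] = d[n].rows(w3, w3 + w2 - 1);
      d[n] = d[n].rows(0, w3 - 1);
    }
    d = up1.backward(d);
    for (int l = depth - 1; l >= 0; --l) {
      Batch dr = ln2[l].backward(fc1[l].backward(amlp[l].backward(fc2[l].backward(d))));
      for (size_t n = 0; n < d.size(); ++n) d[n] += dr[n];
      Batch da = ln1[l].backward(attn[l].backward(d));
      for (size_t n = 0; n < d.size(); ++n) d[n] += da[n];
    }
    // time embedding is additive: gradient passes through unchanged
    d = d2.backward(ad2.backward(d));
    for (size_t n = 0; n < d.size(); ++n) d[n] += dskip2[n];
    d = c2.backward(a2.backward(d));
    d = d1.backward(ad1.backward(d));
    for (size_t n = 0; n < d.size(); ++n) d[n] += dskip1[n];
    d = c1.backward(a1.backward(d));
    c0.backward(a0.backward(d));
  }
};

// ---------------------------------------------------------------------------
// Localizer: SE-U-Net, 3 encoder stages each closed by an SE block,
// 2-channel input (image, reconstruction), sigmoid output.

struct Localizer : ModelBase {
  int H, W, w1, w2, w3;
  Conv e0, e1, p1, e2, p2, e3, u1c, u2c, outc;
  Act ae0{1}, ae1{1}, ap1{1}, ae2{1}, ap2{1}, ae3{1}, au1{1}, au2{1}, sig{2};
  SEBlock se1, se2, se3;
  Upsample2x up1, up2;
  Batch skip1, skip2;

  Localizer(int H_, int W_, int w1_, int w2_, int w3_, int ratio, uint32_t seed)
      : H(H_), W(W_), w1(w1_), w2(w2_), w3(w3_) {
    Rng rng(seed);
    e0.build(2, w1, H, W, 1, rng);
    e1.build(w1, w1, H, W, 1, rng);
    se1.build(w1, ratio, rng);
    p1.build(w1, w2, H, W, 2, rng);
    e2.build(w2, w2, H / 2, W / 2, 1, rng);
    se2.build(w2, ratio, rng);
    p2.build(w2, w3, H / 2, W / 2, 2, rng);
    e3.build(w3, w3, H / 4, W / 4, 1, rng);
    se3.build(w3, ratio, rng);
    up1.build(H / 4, W / 4);
    u1c.build(w3 + w2, w2, H / 2, W / 2, 1, rng);
    up2.build(H / 2, W / 2);
    u2c.build(w2 + w1, w1, H, W, 1, rng);
    outc.build(w1, 1, H, W, 1, rng, 1e-2, -2.0);  // focal-style prior bias

    reg("e0.W", e0.Wt); reg("e0.b", e0.b);
    reg("e1.W", e1.Wt); reg("e1.b", e1.b);
    reg("se1.W1", se1.W1); reg("se1.b1", se1.b1);
    reg("se1.W2", se1.W2); reg("se1.b2", se1.b2);
    reg("p1.W", p1.Wt); reg("p1.b", p1.b);
    reg("e2.W", e2.Wt); reg("e2.b", e2.b);
    reg("se2.W1", se2.W1); reg("se2.b1", se2.b1);
    reg("se2.W2", se2.W2); reg("se2.b2", se2.b2);
    reg("p2.W", p2.Wt); reg("p2.b", p2.b);
    reg("e3.W", e3.Wt); reg("e3.b", e3.b);
    reg("se3.W1", se3.W1); reg("se3.b1", se3.b1);
    reg("se3.W2", se3.W2); reg("se3.b2", se3.b2);
    reg("u1.W", u1c.Wt); reg("u1.b", u1c.b);
    reg("u2.W", u2c.Wt); reg("u2.b", u2c.b);
    reg("out.W", outc.Wt); reg("out.b", outc.b);
  }

  Batch forward(const Batch& x, bool train) {
    Batch h = ae0.forward(e0.forward(x, train), train);
    h = ae1.forward(e1.forward(h, train), train);
    h = se1.forward(h, train);
    skip1 = h;
    h = ap1.forward(p1.forward(h, train), train);
    h = ae2.forward(e2.forward(h, train), train);
    h = se2.forward(h, train);
    skip2 = h;
    h = ap2.forward(p2.forward(h, train), train);
    h = ae3.forward(e3.forward(h, train), train);
    h = se3.forward(h, train);
    h = up1.forward(h);
    for (size_t n = 0; n < h.size(); ++n) h[n] = arma::join_cols(h[n], skip2[n]);
    h = au1.forward(u1c.forward(h, train), train);
    h = up2.forward(h);
    for (size_t n = 0; n < h.size(); ++n) h[n] = arma::join_cols(h[n], skip1[n]);
    h = au2.forward(u2c.forward(h, train), train);
    return sig.forward(outc.forward(h, train), train);
  }

  void backward(const Batch& dy) {
    Batch d = outc.backward(sig.backward(dy));
    d = u2c.backward(au2.backward(d));
    Batch dskip1(d.size());
    for (size_t n = 0; n < d.size(); ++n) {
      dskip1[n] = d[n].rows(w2, w2 + w1 - 1);
      d[n] = d[n].rows(0, w2 - 1);
    }
    d = up2.backward(d);
    d = u1c.backward(au1.backward(d));
    Batch dskip2(d.size());
    for (size_t n = 0; n < d.size(); ++n) {
      dskip2[n] = d[n].rows(w3, w3 + w2 - 1);
      d[n] = d[n].rows(0, w3 - 1);
    }
    d = up1.backward(d);
    d = se3.backward(d);
    d = e3.backward(ae3.backward(d));
    d = p2.backward(ap2.backward(d));
    for (size_t n = 0; n < d.size(); ++n) d[n] += dskip2[n];
    d = se2.backward(d);
    d = e2.backward(ae2.backward(d));
    d = p1.backward(ap1.backward(d));
    for (size_t n = 0; n < d.size(); ++n) d[n] += dskip1[n];
    d = se1.backward(d);
    e0.backward(ae0.backward(e1.backward(ae1.backward(d))));
  }
};

// ---------------------------------------------------------------------------
// R interface helpers

static Batch array_to_batch(const Rcpp::NumericVector& x, int C) {
  Rcpp::IntegerVector dm = x.attr("dim");
  int H = dm[0], W = dm[1];
  int N = (dm.size() == 3 && C == 1) ? dm[2] : (dm.size() == 4 ? dm[3] : 1);
  if (dm.size() == 2) N = 1;
  int HW = H * W;
  Batch b(N);
  const double* p = x.begin();
  for (int n = 0; n < N; ++n) {
    b[n].set_size(C, HW);
    for (int c = 0; c < C; ++c) {
      const double* src = p + (size_t)n * C * HW + (size_t)c * HW;
      for (int j = 0; j < HW; ++j) b[n](c, j) = (float)src[j];
    }
  }
  return b;
}

static Rcpp::NumericVector batch_to_array(const Batch& b, int H, int W) {
  int N = b.size();
  int C = b[0].n_rows, HW = H * W;
  Rcpp::NumericVector out((size_t)N * C * HW);
  double* p = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < HW; ++j)
        p[(size_t)n * C * HW + (size_t)c * HW + j] = b[n](c, j);
  if (C == 1) out.attr("dim") = Rcpp::IntegerVector::create(H, W, N);
  else out.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  return out;
}

template <class M>
Rcpp::List params_out(M* m, bool grads) {
  Rcpp::List out;
  for (auto& pr : m->plist) {
    const fmat& src = grads ? pr.second->g : pr.second->w;
    Rcpp::NumericMatrix w(src.n_rows, src.n_cols);
    for (arma::uword i = 0; i < src.n_elem; ++i) w[i] = src(i);
    out[pr.first] = w;
  }
  return out;
}

template <class M>
void params_in(M* m, const Rcpp::List& lst) {
  for (auto& pr : m->plist) {
    if (!lst.containsElementNamed(pr.first.c_str()))
      Rcpp::stop("missing parameter: %s", pr.first);
    Rcpp::NumericMatrix w = lst[pr.first];
    if ((arma::uword)w.nrow() != pr.second->w.n_rows ||
        (arma::uword)w.ncol() != pr.second->w.n_cols)
      Rcpp::stop("parameter shape mismatch: %s", pr.first);
    for (arma::uword i = 0; i < pr.second->w.n_elem; ++i) pr.second->w(i) = (float)w[i];
  }
}

// ---- denoiser --------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_den_create(int H, int W, int w1, int w2, int w3, int depth, int heads,
                    int seed) {
  if (H % 4 || W % 4) Rcpp::stop("H and W must be divisible by 4");
  if (w3 % heads) Rcpp::stop("mid width must be divisible by heads");
  Rcpp::XPtr<Denoiser> p(new Denoiser(H, W, w1, w2, w3, depth, heads,
                                      (uint32_t)seed), true);
  return p;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_den_forward(SEXP ptr, Rcpp::NumericVector x,
                                    Rcpp::NumericVector t, bool train) {
  Rcpp::XPtr<Denoiser> m(ptr);
  Batch b = array_to_batch(x, 1);
  std::vector<double> tv(t.begin(), t.end());
  if ((int)tv.size() == 1 && b.size() > 1) tv.assign(b.size(), tv[0]);
  Batch y = m->forward(b, tv, train);
  return batch_to_array(y, m->H, m->W);
}

// [[Rcpp::export]]
void cpp_den_backward(SEXP ptr, Rcpp::NumericVector dy) {
  Rcpp::XPtr<Denoiser> m(ptr);
  m->backward(array_to_batch(dy, 1));
}

// [[Rcpp::export]]
void cpp_den_adam(SEXP ptr, double lr, double b1, double b2, double eps) {
  Rcpp::XPtr<Denoiser>(ptr)->adam_step(lr, b1, b2, eps);
}

// [[Rcpp::export]]
void cpp_den_zero_grad(SEXP ptr) { Rcpp::XPtr<Denoiser>(ptr)->zero_grad(); }

// [[Rcpp::export]]
Rcpp::List cpp_den_params(SEXP ptr, bool grads) {
  return params_out(Rcpp::XPtr<Denoiser>(ptr).get(), grads);
}

// [[Rcpp::export]]
void cpp_den_set_params(SEXP ptr, Rcpp::List lst) {
  params_in(Rcpp::XPtr<Denoiser>(ptr).get(), lst);
}

// [[Rcpp::export]]
double cpp_den_n_params(SEXP ptr) {
  return (double)Rcpp::XPtr<Denoiser>(ptr)->n_params();
}

// ---- localizer -------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_loc_create(int H, int W, int w1, int w2, int w3, int ratio, int seed) {
  if (H % 4 || W % 4) Rcpp::stop("H and W must be divisible by 4");
  Rcpp::XPtr<Localizer> p(new Localizer(H, W, w1, w2, w3, ratio,
                                        (uint32_t)seed), true);
  return p;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_loc_forward(SEXP ptr, Rcpp::NumericVector x, bool train) {
  Rcpp::XPtr<Localizer> m(ptr);
  Batch y = m->forward(array_to_batch(x, 2), train);
  return batch_to_array(y, m->H, m->W);
}

// [[Rcpp::export]]
void cpp_loc_backward(SEXP ptr, Rcpp::NumericVector dy) {
  Rcpp::XPtr<Localizer> m(ptr);
  m->backward(array_to_batch(dy, 1));
}

// [[Rcpp::export]]
void cpp_loc_adam(SEXP ptr, double lr, double b1, double b2, double eps) {
  Rcpp::XPtr<Localizer>(ptr)->adam_step(lr, b1, b2, eps);
}

// [[Rcpp::export]]
void cpp_loc_zero_grad(SEXP ptr) { Rcpp::XPtr<Localizer>(ptr)->zero_grad(); }

// [[Rcpp::export]]
Rcpp::List cpp_loc_params(SEXP ptr, bool grads) {
  return params_out(Rcpp::XPtr<Localizer>(ptr).get(), grads);
}

// [[Rcpp::export]]
void cpp_loc_set_params(SEXP ptr, Rcpp::List lst) {
  params_in(Rcpp::XPtr<Localizer>(ptr).get(), lst);
}

// [[Rcpp::export]]
double cpp_loc_n_params(SEXP ptr) {
  return (double)Rcpp::XPtr<Localizer>(ptr)->n_params();
}
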