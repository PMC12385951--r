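// 1-D residual dilated pyramid network: forward, backprop and Adam.
//
// Activations are stored as (channels x time*batch) single-precision
// matrices, with sample b occupying the contiguous column block
// [b*T, (b+1)*T).  Convolutions are im2col + GEMM.  All randomness
// (shuffling, dropout) comes from a std::mt19937 seeded explicitly, so
// training histories are bitwise reproducible on a fixed seed.

#include <RcppArmadillo.h>
#include <limits>
#include <random>
#include <string>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;
using arma::frowvec;
using arma::umat;
using arma::uword;

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.1f;
static const float LOG_FLOOR = -27.631021f; // log(1e-12): probability floor in the loss

// ---------------------------------------------------------------------------
// conversions

static fmat as_f(SEXP s) {
  Rcpp::NumericMatrix m(s);
  arma::mat d(m.begin(), m.nrow(), m.ncol(), false);
  return arma::conv_to<fmat>::from(d);
}

static fvec as_fv(SEXP s) {
  Rcpp::NumericVector v(s);
  arma::vec d(v.begin(), v.size(), false);
  return arma::conv_to<fvec>::from(d);
}

static Rcpp::NumericMatrix to_R(const fmat& m) {
  return Rcpp::wrap(arma::conv_to<arma::mat>::from(m));
}

static Rcpp::NumericVector to_Rv(const fvec& v) {
  Rcpp::NumericVector out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out[i] = v(i);
  return out;
}

// ---------------------------------------------------------------------------
// layer primitives

struct Conv {
  fmat W, dW;        // (out, in*k); column j*in + c holds tap j, channel c
  int in = 0, out = 0, k = 1, s = 1, d = 1, p = 0;
  fmat col;          // cached im2col matrix for backward

  int t_out(int T) const { return (T + 2 * p - d * (k - 1) - 1) / s + 1; }

  fmat im2col(const fmat& x, int T, int B) const {
    const int to = t_out(T);
    fmat C(in * k, (uword)to * B, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      for (int j = 0; j < k; ++j) {
        const int off = j * d - p; // input index = t*s + off
        int tlo = off < 0 ? (-off + s - 1) / s : 0;
        int thi = (T - 1 - off) / s;
        if (thi > to - 1) thi = to - 1;
        if (tlo > thi) continue;
        if (s == 1) {
          C.submat(j * in, (uword)b * to + tlo,
                   (j + 1) * in - 1, (uword)b * to + thi) =
            x.cols((uword)b * T + tlo + off, (uword)b * T + thi + off);
        } else {
          for (int t = tlo; t <= thi; ++t)
            C.submat(j * in, (uword)b * to + t, (j + 1) * in - 1,
                     (uword)b * to + t) =
              x.col((uword)b * T + (uword)t * s + off);
        }
      }
    }
    return C;
  }

  fmat fwd(const fmat& x, int T, int B, bool cache) {
    fmat C = im2col(x, T, B);
    fmat y = W * C;
    if (cache) col = std::move(C);
    return y;
  }

  fmat bwd(const fmat& dy, int T, int B) {
    dW += dy * col.t();
    fmat dC = W.t() * dy;
    const int to = t_out(T);
    fmat dx(in, (uword)T * B, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      for (int j = 0; j < k; ++j) {
        const int off = j * d - p;
        int tlo = off < 0 ? (-off + s - 1) / s : 0;
        int thi = (T - 1 - off) / s;
        if (thi > to - 1) thi = to - 1;
        if (tlo > thi) continue;
        if (s == 1) {
          dx.cols((uword)b * T + tlo + off, (uword)b * T + thi + off) +=
            dC.submat(j * in, (uword)b * to + tlo,
                      (j + 1) * in - 1, (uword)b * to + thi);
        } else {
          for (int t = tlo; t <= thi; ++t)
            dx.col((uword)b * T + (uword)t * s + off) +=
              dC.submat(j * in, (uword)b * to + t,
                        (j + 1) * in - 1, (uword)b * to + t);
        }
      }
    }
    return dx;
  }
};

// Batch norm over the column dimension (channels are rows).  Works both for
// temporal maps (C, T*B) and for fused vectors (F, B).
struct BNorm {
  fvec g, b, rm, rv, dg, db;
  fmat xhat;
  fvec istd;
  // exact-statistics collection (post-training recalibration pass)
  bool collect = false;
  fvec asum, asq;
  double acnt = 0.0;

  void finalize_stats() {
    if (acnt <= 1.0) return;
    fvec mu = asum / (float)acnt;
    fvec va = asq / (float)acnt - mu % mu;
    va *= (float)(acnt / (acnt - 1.0));
    rm = mu;
    rv = arma::clamp(va, 0.0f, std::numeric_limits<float>::max());
  }

  fmat fwd(const fmat& x, bool train) {
    if (train && collect) {
      if (asum.n_elem == 0) {
        asum.zeros(x.n_rows);
        asq.zeros(x.n_rows);
        acnt = 0.0;
      }
      asum += arma::sum(x, 1);
      asq += arma::sum(x % x, 1);
      acnt += x.n_cols;
    }
    if (!train) {
      fvec is = 1.0f / arma::sqrt(rv + BN_EPS);
      fmat y = x;
      y.each_col() -= rm;
      y.each_col() %= (g % is);
      y.each_col() += b;
      return y;
    }
    const uword N = x.n_cols;
    fvec mu = arma::mean(x, 1);
    fvec va = arma::var(x, 1, 1); // population variance per channel
    istd = 1.0f / arma::sqrt(va + BN_EPS);
    xhat = x;
    xhat.each_col() -= mu;
    xhat.each_col() %= istd;
    fmat y = xhat;
    y.each_col() %= g;
    y.each_col() += b;
    const float corr = N > 1 ? (float)N / (N - 1) : 1.0f;
    rm = (1.0f - BN_MOM) * rm + BN_MOM * mu;
    rv = (1.0f - BN_MOM) * rv + BN_MOM * (va * corr);
    return y;
  }

  fmat bwd(const fmat& dy) {
    const float N = (float)dy.n_cols;
    dg += arma::sum(dy % xhat, 1);
    db += arma::sum(dy, 1);
    fmat dxh = dy;
    dxh.each_col() %= g;
    fvec s1 = arma::sum(dxh, 1);
    fvec s2 = arma::sum(dxh % xhat, 1);
    fmat dx = dxh * N;
    dx.each_col() -= s1;
    fmat t = xhat;
    t.each_col() %= s2;
    dx -= t;
    dx.each_col() %= (istd / N);
    return dx;
  }
};

struct ReLU {
  fmat mask;
  fmat fwd(const fmat& x, bool cache) {
    fmat y(arma::size(x));
    if (cache) {
      mask.set_size(arma::size(x));
      const float* xi = x.memptr();
      float* yi = y.memptr();
      float* mi = mask.memptr();
      for (uword i = 0; i < x.n_elem; ++i) {
        const bool pos = xi[i] > 0.0f;
        yi[i] = pos ? xi[i] : 0.0f;
        mi[i] = pos ? 1.0f : 0.0f;
      }
    } else {
      const float* xi = x.memptr();
      float* yi = y.memptr();
      for (uword i = 0; i < x.n_elem; ++i) yi[i] = xi[i] > 0.0f ? xi[i] : 0.0f;
    }
    return y;
  }
  fmat bwd(const fmat& dy) const { return dy % mask; }
};

struct Dropout {
  float p = 0.0f;
  bool enabled = true;
  fmat mask;
  fmat fwd(const fmat& x, bool train, std::mt19937& rng) {
    if (!train || !enabled || p <= 0.0f) return x;
    std::uniform_real_distribution<float> U(0.0f, 1.0f);
    mask.set_size(arma::size(x));
    const float scale = 1.0f / (1.0f - p);
    for (uword i = 0; i < mask.n_elem; ++i)
      mask(i) = U(rng) < p ? 0.0f : scale;
    return x % mask;
  }
  fmat bwd(const fmat& dy, bool train) const {
    if (!train || !enabled || p <= 0.0f) return dy;
    return dy % mask;
  }
};

// Global max over time: (C, T*B) -> (C, B)
struct GlobalMax {
  umat idx;
  fmat fwd(const fmat& x, int T, int B) {
    const uword C = x.n_rows;
    fmat y(C, B);
    idx.set_size(C, B);
    for (int b = 0; b < B; ++b) {
      // column-major scan: one contiguous column at a time
      y.col(b) = x.col((uword)b * T);
      for (uword c = 0; c < C; ++c) idx(c, b) = 0;
      for (int t = 1; t < T; ++t) {
        const float* xc = x.colptr((uword)b * T + t);
        float* yc = y.colptr(b);
        for (uword c = 0; c < C; ++c)
          if (xc[c] > yc[c]) {
            yc[c] = xc[c];
            idx(c, b) = t;
          }
      }
    }
    return y;
  }
  fmat bwd(const fmat& dy, int T, int B) const {
    fmat dx(dy.n_rows, (uword)T * B, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (uword c = 0; c < dy.n_rows; ++c)
        dx(c, (uword)b * T + idx(c, b)) += dy(c, b);
    return dx;
  }
};

// Non-overlapping temporal max pooling with window = stride = w
struct MaxPool {
  int w = 4;
  umat idx; // argmax per (channel, pooled position * batch)
  fmat fwd(const fmat& x, int T, int B) {
    const int to = T / w;
    fmat y(x.n_rows, (uword)to * B);
    idx.set_size(x.n_rows, (uword)to * B);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < to; ++t) {
        fmat blk = x.cols((uword)b * T + (uword)t * w,
                          (uword)b * T + (uword)(t + 1) * w - 1);
        for (uword c = 0; c < x.n_rows; ++c) {
          uword j = blk.row(c).index_max();
          idx(c, (uword)b * to + t) = j;
          y(c, (uword)b * to + t) = blk(c, j);
        }
      }
    return y;
  }
  fmat bwd(const fmat& dy, int T, int B) const {
    const int to = T / w;
    fmat dx(dy.n_rows, (uword)T * B, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < to; ++t)
        for (uword c = 0; c < dy.n_rows; ++c)
          dx(c, (uword)b * T + (uword)t * w + idx(c, (uword)b * to + t)) +=
            dy(c, (uword)b * to + t);
    return dx;
  }
};

// ---------------------------------------------------------------------------
// entropy descriptors of feature maps (per channel, per sample)

// Differential entropy with cached moments for backprop.
struct DiffEntropy {
  float eps = 1e-6f;
  fmat mu, va;
  int T = 0;
  fmat fwd(const fmat& x, int T_, int B) {
    T = T_;
    mu.set_size(x.n_rows, B);
    va.set_size(x.n_rows, B);
    fmat y(x.n_rows, B);
    for (int b = 0; b < B; ++b) {
      fmat blk = x.cols((uword)b * T, (uword)(b + 1) * T - 1);
      mu.col(b) = arma::mean(blk, 1);
      va.col(b) = arma::var(blk, 0, 1); // unbiased (N-1)
    }
    y = 0.5f * arma::log(2.0f * (float)M_PI * (float)M_E * (va + eps));
    return y;
  }
  fmat bwd(const fmat& dy, const fmat& x, int B) const {
    fmat dx(x.n_rows, x.n_cols, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      fmat cen = x.cols((uword)b * T, (uword)(b + 1) * T - 1);
      cen.each_col() -= mu.col(b);
      fvec f = (dy.col(b) / (va.col(b) + eps)) / (float)(T - 1);
      cen.each_col() %= f;
      dx.cols((uword)b * T, (uword)(b + 1) * T - 1) = cen;
    }
    return dx;
  }
};

// Histogram / spectral descriptors (no gradient; used for the entropy-type
// sensitivity variants).
static float hist_entropy(const frowvec& v, int nb, const std::string& kind,
                          float order) {
  const float lo = v.min(), hi = v.max();
  std::vector<double> p(nb, 0.0);
  if (hi <= lo) {
    p[0] = 1.0;
  } else {
    const float wdt = (hi - lo) / nb;
    for (uword i = 0; i < v.n_elem; ++i) {
      int bin = (int)((v(i) - lo) / wdt);
      if (bin >= nb) bin = nb - 1;
      p[bin] += 1.0;
    }
    for (int i = 0; i < nb; ++i) p[i] /= v.n_elem;
  }
  if (kind == "shannon") {
    double h = 0.0;
    for (double q : p)
      if (q > 0.0) h -= q * std::log(q);
    return (float)h;
  }
  if (kind == "renyi") {
    double s = 0.0;
    for (double q : p) s += std::pow(q, (double)order);
    return (float)(std::log(s) / (1.0 - order));
  }
  // tsallis
  double s = 0.0;
  for (double q : p) s += std::pow(q, (double)order);
  return (float)((1.0 - s) / (order - 1.0));
}

static float spectral_entropy_row(const frowvec& v) {
  const uword T = v.n_elem;
  arma::vec x = arma::conv_to<arma::vec>::from(v.t());
  arma::cx_vec F = arma::fft(x);
  const uword nf = T / 2; // bins 1..floor(T/2); DC excluded
  arma::vec P(nf);
  for (uword i = 0; i < nf; ++i) P(i) = std::norm(F(i + 1));
  double tot = arma::accu(P);
  if (tot <= 0.0) return 0.0f;
  double h = 0.0;
  for (uword i = 0; i < nf; ++i) {
    double q = P(i) / tot;
    if (q > 0.0) h -= q * std::log(q);
  }
  return (float)h;
}

static fmat entropy_features(const fmat& x, int T, int B,
                             const std::string& kind, float eps, int nb,
                             float order) {
  fmat y(x.n_rows, B);
  for (int b = 0; b < B; ++b) {
    fmat blk = x.cols((uword)b * T, (uword)(b + 1) * T - 1);
    for (uword c = 0; c < x.n_rows; ++c) {
      frowvec row = blk.row(c);
      if (kind == "spectral")
        y(c, b) = spectral_entropy_row(row);
      else
        y(c, b) = hist_entropy(row, nb, kind, order);
    }
  }
  return y;
}

// ---------------------------------------------------------------------------
// composite blocks

struct ResBlock {
  Conv c1, c2, sc;
  BNorm bn1, bn2, scbn;
  ReLU r1, rout;
  Dropout drop;
  int T_in = 0, T_mid = 0;

  fmat fwd(const fmat& x, int T, int B, bool train, std::mt19937& rng) {
    T_in = T;
    T_mid = c1.t_out(T);
    fmat a = c1.fwd(x, T, B, train);
    a = bn1.fwd(a, train);
    a = r1.fwd(a, train);
    fmat m = c2.fwd(a, T_mid, B, train);
    m = bn2.fwd(m, train);
    fmat s = sc.fwd(x, T, B, train);
    s = scbn.fwd(s, train);
    fmat y = rout.fwd(m + s, train);
    return drop.fwd(y, train, rng);
  }

  fmat bwd(const fmat& dy_in, int B, bool train) {
    fmat dy = drop.bwd(dy_in, train);
    dy = rout.bwd(dy);
    fmat ds = scbn.bwd(dy);
    fmat dx = sc.bwd(ds, T_in, B);
    fmat dm = bn2.bwd(dy);
    fmat da = c2.bwd(dm, T_mid, B);
    da = r1.bwd(da);
    da = bn1.bwd(da);
    dx += c1.bwd(da, T_in, B);
    return dx;
  }
};

struct DcpmLayer {
  Conv c;
  BNorm bn;
  ReLU r;
};

struct NetCfg {
  int in_ch = 1, n_classes = 5;
  int rcm_k = 5, dcpm_k = 5;
  int c1 = 64, c2 = 128, dcpm_ch = 128;
  std::vector<int> dil{1, 2, 4, 8, 16};
  float rcm_drop = 0.3f, head_drop = 0.5f;
  bool use_rcm = true, use_dcpm = true, use_ent = true;
  std::string ent_kind = "differential";
  float ent_eps = 1e-6f;
  int ent_bins = 16;
  float ent_order = 2.0f;

  int width() const { return use_rcm ? c2 : dcpm_ch; }
  int fused_dim() const { return (use_ent ? 4 : 2) * width(); }
};

static NetCfg parse_cfg(const Rcpp::List& L) {
  NetCfg c;
  c.in_ch = Rcpp::as<int>(L["in_channels"]);
  c.n_classes = Rcpp::as<int>(L["n_classes"]);
  c.rcm_k = Rcpp::as<int>(L["rcm_kernel"]);
  c.dcpm_k = Rcpp::as<int>(L["dcpm_kernel"]);
  Rcpp::IntegerVector rc = L["rcm_channels"];
  c.c1 = rc[0];
  c.c2 = rc[1];
  c.dcpm_ch = Rcpp::as<int>(L["dcpm_channels"]);
  Rcpp::IntegerVector dl = L["dcpm_dilations"];
  c.dil.assign(dl.begin(), dl.end());
  c.rcm_drop = (float)Rcpp::as<double>(L["rcm_dropout"]);
  c.head_drop = (float)Rcpp::as<double>(L["head_dropout"]);
  c.use_rcm = Rcpp::as<bool>(L["use_rcm"]);
  c.use_dcpm = Rcpp::as<bool>(L["use_dcpm"]);
  c.use_ent = Rcpp::as<bool>(L["use_entropy"]);
  Rcpp::List es = L["entropy"];
  c.ent_kind = Rcpp::as<std::string>(es["kind"]);
  c.ent_eps = (float)Rcpp::as<double>(es["eps"]);
  c.ent_bins = Rcpp::as<int>(es["n_bins"]);
  c.ent_order = (float)Rcpp::as<double>(es["order"]);
  return c;
}

// Registry entry for a trainable tensor (flat float view).
struct Par {
  std::string name;
  float* w;
  float* g;
  uword n;
};

struct Net {
  NetCfg cfg;
  ResBlock rb[2];
  Conv adapt_c;          // w/o RCM adapter
  BNorm adapt_bn;
  ReLU adapt_r;
  MaxPool adapt_pool;
  std::vector<DcpmLayer> dcpm;
  GlobalMax gmax_b, gmax_m;
  DiffEntropy dent_b, dent_m;
  BNorm bn_pb, bn_pm, bn_eb, bn_em;
  BNorm head_bn;
  ReLU head_r;
  Dropout head_drop;
  fmat head_W, head_dW;
  fvec head_b, head_db;

  // caches for backward
  fmat x_in, branch_out, main_out, fused_cache, head_h;
  int T_in = 0, Tq = 0, B_cur = 0;

  std::vector<Par> reg;        // trainable parameters
  std::vector<BNorm*> bns;     // for exporting running stats

  void init_conv(Conv& cv, const Rcpp::List& P, const std::string& nm, int in,
                 int out, int k, int s, int d, int p) {
    cv.W = as_f(P[nm]);
    if ((int)cv.W.n_rows != out || (int)cv.W.n_cols != in * k)
      Rcpp::stop("parameter '%s' has shape (%d,%d), expected (%d,%d)", nm,
                 (int)cv.W.n_rows, (int)cv.W.n_cols, out, in * k);
    cv.in = in; cv.out = out; cv.k = k; cv.s = s; cv.d = d; cv.p = p;
    cv.dW.zeros(out, (uword)in * k);
    reg.push_back({nm, cv.W.memptr(), cv.dW.memptr(), cv.W.n_elem});
  }

  void init_bn(BNorm& bn, const Rcpp::List& P, const std::string& nm, int C) {
    bn.g = as_fv(P[nm + "_gamma"]);
    bn.b = as_fv(P[nm + "_beta"]);
    bn.rm = as_fv(P[nm + "_rmean"]);
    bn.rv = as_fv(P[nm + "_rvar"]);
    if ((int)bn.g.n_elem != C)
      Rcpp::stop("parameter '%s_gamma' has length %d, expected %d", nm,
                 (int)bn.g.n_elem, C);
    bn.dg.zeros(C);
    bn.db.zeros(C);
    reg.push_back({nm + "_gamma", bn.g.memptr(), bn.dg.memptr(), bn.g.n_elem});
    reg.push_back({nm + "_beta", bn.b.memptr(), bn.db.memptr(), bn.b.n_elem});
    bns.push_back(&bn);
  }

  void build(const Rcpp::List& P, const NetCfg& c) {
    cfg = c;
    const int kr = c.rcm_k, pr = (kr - 1) / 2;
    if (c.use_rcm) {
      init_conv(rb[0].c1, P, "rcm1_conv1_W", c.in_ch, c.c1, kr, 2, 1, pr);
      init_bn(rb[0].bn1, P, "rcm1_bn1", c.c1);
      init_conv(rb[0].c2, P, "rcm1_conv2_W", c.c1, c.c1, kr, 1, 2, 2 * pr);
      init_bn(rb[0].bn2, P, "rcm1_bn2", c.c1);
      init_conv(rb[0].sc, P, "rcm1_sc_W", c.in_ch, c.c1, 1, 2, 1, 0);
      init_bn(rb[0].scbn, P, "rcm1_scbn", c.c1);
      rb[0].drop.p = c.rcm_drop;
      init_conv(rb[1].c1, P, "rcm2_conv1_W", c.c1, c.c2, kr, 2, 1, pr);
      init_bn(rb[1].bn1, P, "rcm2_bn1", c.c2);
      init_conv(rb[1].c2, P, "rcm2_conv2_W", c.c2, c.c2, kr, 1, 2, 2 * pr);
      init_bn(rb[1].bn2, P, "rcm2_bn2", c.c2);
      init_conv(rb[1].sc, P, "rcm2_sc_W", c.c1, c.c2, 1, 2, 1, 0);
      init_bn(rb[1].scbn, P, "rcm2_scbn", c.c2);
      rb[1].drop.p = c.rcm_drop;
    } else {
      init_conv(adapt_c, P, "adapt_W", c.in_ch, c.dcpm_ch, 1, 1, 1, 0);
      init_bn(adapt_bn, P, "adapt_bn", c.dcpm_ch);
      adapt_pool.w = 4;
    }
    if (c.use_dcpm) {
      dcpm.resize(c.dil.size());
      const int kd = c.dcpm_k, pd = (kd - 1) / 2;
      for (size_t i = 0; i < c.dil.size(); ++i) {
        std::string nm = "dcpm" + std::to_string(i + 1);
        init_conv(dcpm[i].c, P, nm + "_W", c.dcpm_ch, c.dcpm_ch, kd, 1,
                  c.dil[i], c.dil[i] * pd);
        init_bn(dcpm[i].bn, P, nm + "_bn", c.dcpm_ch);
      }
    }
    const int w = c.width();
    init_bn(bn_pb, P, "ffem_bn_pb", w);
    init_bn(bn_pm, P, "ffem_bn_pm", w);
    if (c.use_ent) {
      init_bn(bn_eb, P, "ffem_bn_eb", w);
      init_bn(bn_em, P, "ffem_bn_em", w);
      dent_b.eps = c.ent_eps;
      dent_m.eps = c.ent_eps;
    }
    init_bn(head_bn, P, "head_bn", c.fused_dim());
    head_W = as_f(P["head_W"]);
    if ((int)head_W.n_rows != c.n_classes ||
        (int)head_W.n_cols != c.fused_dim())
      Rcpp::stop("head_W has shape (%d,%d), expected (%d,%d)",
                 (int)head_W.n_rows, (int)head_W.n_cols, c.n_classes,
                 c.fused_dim());
    head_b = as_fv(P["head_b"]);
    head_dW.zeros(arma::size(head_W));
    head_db.zeros(head_b.n_elem);
    reg.push_back({"head_W", head_W.memptr(), head_dW.memptr(), head_W.n_elem});
    reg.push_back({"head_b", head_b.memptr(), head_db.memptr(), head_b.n_elem});
    head_drop.p = c.head_drop;
  }

  void zero_grad() {
    for (auto& pr : reg) std::fill(pr.g, pr.g + pr.n, 0.0f);
  }

  fmat fwd_branch(const fmat& x, int T, int B, bool train, std::mt19937& rng) {
    if (cfg.use_rcm) {
      fmat h = rb[0].fwd(x, T, B, train, rng);
      return rb[1].fwd(h, rb[0].c1.t_out(T), B, train, rng);
    }
    fmat a = adapt_c.fwd(x, T, B, train);
    a = adapt_bn.fwd(a, train);
    a = adapt_r.fwd(a, train);
    return adapt_pool.fwd(a, T, B);
  }

  fmat bwd_branch(const fmat& dy, int T, int B, bool train) {
    if (cfg.use_rcm) {
      fmat d1 = rb[1].bwd(dy, B, train);
      return rb[0].bwd(d1, B, train);
    }
    fmat d = adapt_pool.bwd(dy, T, B);
    d = adapt_r.bwd(d);
    d = adapt_bn.bwd(d);
    return adapt_c.bwd(d, T, B);
  }

  fmat fwd_dcpm(const fmat& x, int T, int B, bool train) {
    fmat h = x;
    for (auto& L : dcpm) {
      h = L.c.fwd(h, T, B, train);
      h = L.bn.fwd(h, train);
      h = L.r.fwd(h, train);
    }
    return h;
  }

  fmat bwd_dcpm(const fmat& dy, int T, int B) {
    fmat d = dy;
    for (int i = (int)dcpm.size() - 1; i >= 0; --i) {
      d = dcpm[i].r.bwd(d);
      d = dcpm[i].bn.bwd(d);
      d = dcpm[i].c.bwd(d, T, B);
    }
    return d;
  }

  // fused feature matrix (F, B); caches pathway outputs for backward
  fmat fwd_ffem(const fmat& fb, const fmat& fm, int T, int B, bool train) {
    fmat pb = bn_pb.fwd(gmax_b.fwd(fb, T, B), train);
    fmat pm = bn_pm.fwd(gmax_m.fwd(fm, T, B), train);
    if (!cfg.use_ent) return arma::join_cols(pb, pm);
    fmat eb, em;
    if (cfg.ent_kind == "differential") {
      eb = dent_b.fwd(fb, T, B);
      em = dent_m.fwd(fm, T, B);
    } else {
      eb = entropy_features(fb, T, B, cfg.ent_kind, cfg.ent_eps, cfg.ent_bins,
                            cfg.ent_order);
      em = entropy_features(fm, T, B, cfg.ent_kind, cfg.ent_eps, cfg.ent_bins,
                            cfg.ent_order);
    }
    eb = bn_eb.fwd(eb, train);
    em = bn_em.fwd(em, train);
    return arma::join_cols(arma::join_cols(pb, pm), arma::join_cols(eb, em));
  }

  void bwd_ffem(const fmat& dfused, int T, int B, fmat& dfb, fmat& dfm) {
    const int w = cfg.width();
    dfb = gmax_b.bwd(bn_pb.bwd(dfused.rows(0, w - 1)), T, B);
    dfm = gmax_m.bwd(bn_pm.bwd(dfused.rows(w, 2 * w - 1)), T, B);
    if (!cfg.use_ent) return;
    fmat deb = bn_eb.bwd(dfused.rows(2 * w, 3 * w - 1));
    fmat dem = bn_em.bwd(dfused.rows(3 * w, 4 * w - 1));
    if (cfg.ent_kind == "differential") {
      // non-differential descriptors are treated as stop-gradient features
      dfb += dent_b.bwd(deb, branch_out, B);
      dfm += dent_m.bwd(dem, main_out, B);
    }
  }

  fmat fwd_head(const fmat& fused, bool train, std::mt19937& rng) {
    fmat h = head_bn.fwd(fused, train);
    h = head_r.fwd(h, train);
    h = head_drop.fwd(h, train, rng);
    if (train) head_h = h;
    fmat z = head_W * h;
    z.each_col() += head_b;
    return z;
  }

  fmat bwd_head(const fmat& dz, bool train) {
    head_dW += dz * head_h.t();
    head_db += arma::sum(dz, 1);
    fmat dh = head_W.t() * dz;
    dh = head_drop.bwd(dh, train);
    dh = head_r.bwd(dh);
    return head_bn.bwd(dh);
  }

  // Full forward.  stage: "logits", "rcm", "dcpm", "fused".
  fmat fwd(const fmat& x, int T, int B, bool train, std::mt19937& rng,
           const std::string& stage = "logits") {
    T_in = T;
    B_cur = B;
    if (train) x_in = x;
    branch_out = fwd_branch(x, T, B, train, rng);
    Tq = (int)(branch_out.n_cols / B);
    if (stage == "rcm") {
      GlobalMax g;
      return g.fwd(branch_out, Tq, B);
    }
    main_out = cfg.use_dcpm ? fwd_dcpm(branch_out, Tq, B, train) : branch_out;
    if (stage == "dcpm") {
      GlobalMax g;
      return g.fwd(main_out, Tq, B);
    }
    fused_cache = fwd_ffem(branch_out, main_out, Tq, B, train);
    if (stage == "fused") return fused_cache;
    return fwd_head(fused_cache, train, rng);
  }

  void bwd(const fmat& dlogits, bool train) {
    fmat dfused = bwd_head(dlogits, train);
    fmat dfb, dfm;
    bwd_ffem(dfused, Tq, B_cur, dfb, dfm);
    if (cfg.use_dcpm)
      dfb += bwd_dcpm(dfm, Tq, B_cur);
    else
      dfb += dfm;
    bwd_branch(dfb, T_in, B_cur, train);
  }

};

static void collect_bns(Net& n, std::vector<std::pair<std::string, BNorm*>>& v) {
  if (n.cfg.use_rcm) {
    v.push_back({"rcm1_bn1", &n.rb[0].bn1});
    v.push_back({"rcm1_bn2", &n.rb[0].bn2});
    v.push_back({"rcm1_scbn", &n.rb[0].scbn});
    v.push_back({"rcm2_bn1", &n.rb[1].bn1});
    v.push_back({"rcm2_bn2", &n.rb[1].bn2});
    v.push_back({"rcm2_scbn", &n.rb[1].scbn});
  } else {
    v.push_back({"adapt_bn", &n.adapt_bn});
  }
  if (n.cfg.use_dcpm)
    for (size_t i = 0; i < n.dcpm.size(); ++i)
      v.push_back({"dcpm" + std::to_string(i + 1) + "_bn", &n.dcpm[i].bn});
  v.push_back({"ffem_bn_pb", &n.bn_pb});
  v.push_back({"ffem_bn_pm", &n.bn_pm});
  if (n.cfg.use_ent) {
    v.push_back({"ffem_bn_eb", &n.bn_eb});
    v.push_back({"ffem_bn_em", &n.bn_em});
  }
  v.push_back({"head_bn", &n.head_bn});
}

static Rcpp::List export_params(Net& net, const Rcpp::List& templ) {
  Rcpp::List out = Rcpp::clone(templ);
  for (const auto& pr : net.reg) {
    Rcpp::NumericVector v = Rcpp::as<Rcpp::NumericVector>(out[pr.name]);
    for (uword i = 0; i < pr.n; ++i) v[i] = pr.w[i];
  }
  std::vector<std::pair<std::string, BNorm*>> nb;
  collect_bns(net, nb);
  for (auto& kv : nb) {
    Rcpp::NumericVector rm =
      Rcpp::as<Rcpp::NumericVector>(out[kv.first + "_rmean"]);
    Rcpp::NumericVector rv =
      Rcpp::as<Rcpp::NumericVector>(out[kv.first + "_rvar"]);
    for (uword i = 0; i < kv.second->rm.n_elem; ++i) {
      rm[i] = kv.second->rm(i);
      rv[i] = kv.second->rv(i);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// loss

// logits (C,B), labels 0-based.  Returns loss; fills dz and n_correct.
static double smoothed_ce(const fmat& logits, const Rcpp::IntegerVector& y,
                          const arma::uvec& idx, float alpha, fmat& dz,
                          int& n_correct) {
  const int C = logits.n_rows, B = logits.n_cols;
  fmat z = logits;
  frowvec zmax = arma::max(z, 0);
  z.each_row() -= zmax;
  fmat ez = arma::exp(z);
  frowvec s = arma::sum(ez, 0);
  fmat p = ez;
  p.each_row() /= s;
  fmat logp = z;
  logp.each_row() -= arma::log(s);
  logp.transform([](float v) { return v < LOG_FLOOR ? LOG_FLOOR : v; });
  const float off = alpha / C, on = 1.0f - alpha + alpha / C;
  double loss = 0.0;
  n_correct = 0;
  dz = p;
  for (int b = 0; b < B; ++b) {
    const int lab = y[idx(b)];
    double l = 0.0;
    for (int j = 0; j < C; ++j) l -= (j == lab ? on : off) * logp(j, b);
    loss += l;
    dz(lab, b) -= on;
    for (int j = 0; j < C; ++j)
      if (j != lab) dz(j, b) -= off;
    if ((int)p.col(b).index_max() == lab) ++n_correct;
  }
  dz /= (float)B;
  return loss / B;
}

// ---------------------------------------------------------------------------
// exported entry points

// Build a (ch, T*B) activation matrix from an R sample matrix (n, ch*T),
// for the samples listed in idx.  Sample rows store channel-major blocks:
// row = c(ch1[1..T], ch2[1..T], ...).
static fmat gather_batch(const fmat& Xt, const arma::uvec& idx, int ch, int T) {
  const int B = idx.n_elem;
  fmat x(ch, (uword)T * B);
  for (int b = 0; b < B; ++b) {
    // Xt is (ch*T, n); column idx(b) is one sample
    fmat s(const_cast<float*>(Xt.colptr(idx(b))), T, ch, false, true);
    x.cols((uword)b * T, (uword)(b + 1) * T - 1) = s.t();
  }
  return x;
}

// [[Rcpp::export]]
Rcpp::List cpp_train_epoch(Rcpp::List params, Rcpp::List opt, Rcpp::List mcfg,
                           Rcpp::List tcfg, Rcpp::NumericMatrix X,
                           Rcpp::IntegerVector y, int epoch_seed) {
  NetCfg cfg = parse_cfg(mcfg);
  Net net;
  net.build(params, cfg);

  const int n = X.nrow();
  const int T = X.ncol() / cfg.in_ch;
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  fmat Xt = arma::conv_to<fmat>::from(Xd.t()); // (ch*T, n)

  const float lr = (float)Rcpp::as<double>(tcfg["lr"]);
  const float wd = (float)Rcpp::as<double>(tcfg["weight_decay"]);
  const int bs = Rcpp::as<int>(tcfg["batch_size"]);
  const float clip = (float)Rcpp::as<double>(tcfg["clip_norm"]);
  const float alpha = (float)Rcpp::as<double>(tcfg["smoothing_alpha"]);
  const float b1 = 0.9f, b2 = 0.999f, aeps = 1e-8f;

  // Adam state
  long tstep = (long)Rcpp::as<double>(opt["t"]);
  Rcpp::List mL = opt["m"], vL = opt["v"];
  std::vector<fvec> m(net.reg.size()), v(net.reg.size());
  for (size_t i = 0; i < net.reg.size(); ++i) {
    m[i] = as_fv(mL[net.reg[i].name]);
    v[i] = as_fv(vL[net.reg[i].name]);
  }

  std::mt19937 rng((unsigned)epoch_seed);
  arma::uvec perm(n);
  for (int i = 0; i < n; ++i) perm(i) = i;
  for (int i = n - 1; i > 0; --i) {
    std::uniform_int_distribution<int> U(0, i);
    std::swap(perm(i), perm(U(rng)));
  }

  double loss_sum = 0.0;
  long correct = 0;
  for (int start = 0; start < n; start += bs) {
    const int B = std::min(bs, n - start);
    arma::uvec idx = perm.subvec(start, start + B - 1);
    fmat xb = gather_batch(Xt, idx, cfg.in_ch, T);
    net.zero_grad();
    fmat logits = net.fwd(xb, T, B, true, rng, "logits");
    fmat dz;
    int nc = 0;
    double l = smoothed_ce(logits, y, idx, alpha, dz, nc);
    if (!std::isfinite(l))
      Rcpp::stop("non-finite training loss at step %ld (batch start %d)",
                 tstep + 1, start);
    loss_sum += l * B;
    correct += nc;
    net.bwd(dz, true);

    // global-norm gradient clipping
    double sq = 0.0;
    for (auto& pr : net.reg)
      for (uword i = 0; i < pr.n; ++i) sq += (double)pr.g[i] * pr.g[i];
    const double gn = std::sqrt(sq);
    const float scale = (clip > 0 && gn > clip) ? (float)(clip / gn) : 1.0f;

    ++tstep;
    const float bc1 = 1.0f - std::pow(b1, (float)tstep);
    const float bc2 = 1.0f - std::pow(b2, (float)tstep);
    for (size_t i = 0; i < net.reg.size(); ++i) {
      Par& pr = net.reg[i];
      float* mi = m[i].memptr();
      float* vi = v[i].memptr();
      for (uword j = 0; j < pr.n; ++j) {
        float g = pr.g[j] * scale + wd * pr.w[j];
        mi[j] = b1 * mi[j] + (1.0f - b1) * g;
        vi[j] = b2 * vi[j] + (1.0f - b2) * g * g;
        pr.w[j] -= lr * (mi[j] / bc1) / (std::sqrt(vi[j] / bc2) + aeps);
      }
    }
  }

  Rcpp::List mOut = Rcpp::clone(mL), vOut = Rcpp::clone(vL);
  for (size_t i = 0; i < net.reg.size(); ++i) {
    mOut[net.reg[i].name] = to_Rv(m[i]);
    vOut[net.reg[i].name] = to_Rv(v[i]);
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = export_params(net, params),
    Rcpp::Named("opt") = Rcpp::List::create(Rcpp::Named("t") = (double)tstep,
                                            Rcpp::Named("m") = mOut,
                                            Rcpp::Named("v") = vOut),
    Rcpp::Named("loss") = loss_sum / n,
    Rcpp::Named("acc") = (double)correct / n);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_forward(Rcpp::List params, Rcpp::List mcfg,
                                Rcpp::NumericMatrix X, std::string stage) {
  NetCfg cfg = parse_cfg(mcfg);
  Net net;
  net.build(params, cfg);
  const int n = X.nrow();
  const int T = X.ncol() / cfg.in_ch;
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  fmat Xt = arma::conv_to<fmat>::from(Xd.t());
  std::mt19937 rng(0);
  const int chunk = 256;
  fmat out;
  for (int start = 0; start < n; start += chunk) {
    const int B = std::min(chunk, n - start);
    arma::uvec idx(B);
    for (int i = 0; i < B; ++i) idx(i) = start + i;
    fmat xb = gather_batch(Xt, idx, cfg.in_ch, T);
    fmat o = net.fwd(xb, T, B, false, rng, stage);
    if (out.n_elem == 0) out.set_size(o.n_rows, n);
    out.cols(start, start + B - 1) = o;
  }
  return to_R(out.t()); // (n, dim)
}

// Post-training batch-norm recalibration: with frozen weights, run one
// deterministic pass over the training data (batch statistics for
// normalization, dropout off) while accumulating exact per-channel
// moments, then replace every running mean/variance with the aggregate.
// Makes evaluation-mode normalization consistent with the converged
// training-mode behavior instead of a momentum-lagged average.
// [[Rcpp::export]]
Rcpp::List cpp_bn_recalibrate(Rcpp::List params, Rcpp::List mcfg,
                              Rcpp::NumericMatrix X, int batch_size) {
  NetCfg cfg = parse_cfg(mcfg);
  Net net;
  net.build(params, cfg);
  std::vector<std::pair<std::string, BNorm*>> nb;
  collect_bns(net, nb);
  for (auto& kv : nb) kv.second->collect = true;
  net.rb[0].drop.enabled = false;
  net.rb[1].drop.enabled = false;
  net.head_drop.enabled = false;
  const int n = X.nrow();
  const int T = X.ncol() / cfg.in_ch;
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  fmat Xt = arma::conv_to<fmat>::from(Xd.t());
  std::mt19937 rng(0);
  for (int start = 0; start < n; start += batch_size) {
    const int B = std::min(batch_size, n - start);
    if (B < 2) break; // a singleton batch has no batch statistics
    arma::uvec idx(B);
    for (int i = 0; i < B; ++i) idx(i) = start + i;
    fmat xb = gather_batch(Xt, idx, cfg.in_ch, T);
    net.fwd(xb, T, B, true, rng, "logits");
  }
  for (auto& kv : nb) kv.second->finalize_stats();
  return export_params(net, params);
}

// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List params, Rcpp::List mcfg,
                         Rcpp::NumericMatrix X, Rcpp::IntegerVector y,
                         double alpha, int seed, bool train_mode) {
  NetCfg cfg = parse_cfg(mcfg);
  Net net;
  net.build(params, cfg);
  const int n = X.nrow();
  const int T = X.ncol() / cfg.in_ch;
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  fmat Xt = arma::conv_to<fmat>::from(Xd.t());
  arma::uvec idx(n);
  for (int i = 0; i < n; ++i) idx(i) = i;
  fmat xb = gather_batch(Xt, idx, cfg.in_ch, T);
  std::mt19937 rng((unsigned)seed);
  net.zero_grad();
  fmat logits = net.fwd(xb, T, n, train_mode, rng, "logits");
  fmat dz;
  int nc = 0;
  double l = smoothed_ce(logits, y, idx, (float)alpha, dz, nc);
  if (train_mode) net.bwd(dz, true);
  Rcpp::List grads;
  for (auto& pr : net.reg) {
    Rcpp::NumericVector g(pr.n);
    for (uword i = 0; i < pr.n; ++i) g[i] = pr.g[i];
    grads[pr.name] = g;
  }
  return Rcpp::List::create(Rcpp::Named("loss") = l,
                            Rcpp::Named("acc") = (double)nc / n,
                            Rcpp::Named("grads") = grads);
}

// single feature map (channels x time) helpers, evaluation mode -------------

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_conv1d(Rcpp::NumericMatrix x, Rcpp::NumericMatrix W,
                               int k, int stride, int dilation, int pad) {
  Conv cv;
  cv.W = as_f(W);
  cv.out = W.nrow();
  cv.in = W.ncol() / k;
  cv.k = k;
  cv.s = stride;
  cv.d = dilation;
  cv.p = pad;
  fmat xf = as_f(x);
  if ((int)xf.n_rows != cv.in)
    Rcpp::stop("input has %d channels, kernel expects %d", (int)xf.n_rows,
               cv.in);
  return to_R(cv.fwd(xf, xf.n_cols, 1, false));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_resblock(Rcpp::List params, Rcpp::List mcfg, int block,
                                 Rcpp::NumericMatrix x) {
  NetCfg cfg = parse_cfg(mcfg);
  if (!cfg.use_rcm) Rcpp::stop("model was built without the residual module");
  Net net;
  net.build(params, cfg);
  fmat xf = as_f(x);
  std::mt19937 rng(0);
  const int T = xf.n_cols;
  if (block < 1 || block > 2) Rcpp::stop("block must be 1 or 2");
  return to_R(net.rb[block - 1].fwd(xf, T, 1, false, rng));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_dcpm(Rcpp::List params, Rcpp::List mcfg,
                             Rcpp::NumericMatrix x) {
  NetCfg cfg = parse_cfg(mcfg);
  if (!cfg.use_dcpm) Rcpp::stop("model was built without the dilated pyramid");
  Net net;
  net.build(params, cfg);
  fmat xf = as_f(x);
  return to_R(net.fwd_dcpm(xf, xf.n_cols, 1, false));
}

// [[Rcpp::export]]
Rcpp::List cpp_ffem(Rcpp::List params, Rcpp::List mcfg,
                    Rcpp::NumericMatrix xbranch, Rcpp::NumericMatrix xmain) {
  NetCfg cfg = parse_cfg(mcfg);
  Net net;
  net.build(params, cfg);
  fmat fb = as_f(xbranch), fm = as_f(xmain);
  const int T = fb.n_cols;
  GlobalMax gb, gm;
  fmat pb_raw = gb.fwd(fb, T, 1), pm_raw = gm.fwd(fm, T, 1);
  fmat fused = net.fwd_ffem(fb, fm, T, 1, false);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("pooled_branch") = to_Rv(pb_raw.col(0)),
    Rcpp::Named("pooled_main") = to_Rv(pm_raw.col(0)),
    Rcpp::Named("fused") = to_Rv(fused.col(0)));
  if (cfg.use_ent) {
    fmat eb, em;
    if (cfg.ent_kind == "differential") {
      DiffEntropy de;
      de.eps = cfg.ent_eps;
      eb = de.fwd(fb, T, 1);
      em = de.fwd(fm, T, 1);
    } else {
      eb = entropy_features(fb, T, 1, cfg.ent_kind, cfg.ent_eps, cfg.ent_bins,
                            cfg.ent_order);
      em = entropy_features(fm, T, 1, cfg.ent_kind, cfg.ent_eps, cfg.ent_bins,
                            cfg.ent_order);
    }
    out["entropy_branch"] = to_Rv(eb.col(0));
    out["entropy_main"] = to_Rv(em.col(0));
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_head(Rcpp::List params, Rcpp::List mcfg,
                             Rcpp::NumericMatrix fused) {
  NetCfg cfg = parse_cfg(mcfg);
  Net net;
  net.build(params, cfg);
  fmat f = as_f(fused); // (n, F) R-side -> transpose
  fmat ft = f.t();
  std::mt19937 rng(0);
  fmat z = net.fwd_head(ft, false, rng);
  return to_R(z.t());
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_entropy_map(Rcpp::NumericMatrix x, std::string kind,
                                    double eps, int n_bins, double order) {
  fmat xf = as_f(x);
  const int T = xf.n_cols;
  if (kind == "differential") {
    DiffEntropy de;
    de.eps = (float)eps;
    return to_R(de.fwd(xf, T, 1));
  }
  return to_R(entropy_features(xf, T, 1, kind, (float)eps, n_bins,
                               (float)order));
}
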