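// 3D convolutional networks for unpaired volume-to-volume translation.
// Feature maps are arma::fmat with channels as rows and voxels as columns;
// voxel (i1,i2,i3) on a grid (n1,n2,n3) sits in column i1 + n1*(i2 + n2*i3),
// matching R's column-major array layout. Convolutions are kernel-3, pad-1,
// realized as vol2col gather + sgemm; upsampling is a kernel-2 stride-2
// transposed convolution (disjoint 2x2x2 blocks, no overlap).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cstring>
#include <cmath>

using namespace arma;

struct Dims {
  int a, b, c;
  long n() const { return (long)a * b * c; }
};
static inline Dims halfd(Dims d) { return {d.a / 2, d.b / 2, d.c / 2}; }
static inline Dims dbld(Dims d) { return {d.a * 2, d.b * 2, d.c * 2}; }

// ---------------------------------------------------------------------------
// vol2col / col2vol for kernel 3, padding 1, stride s (1 or 2).
// col has 27*C rows; row block for kernel offset t = (d1+1)+3*(d2+1)+9*(d3+1)
// occupies rows [t*C, (t+1)*C).
// ---------------------------------------------------------------------------
static void vol2col(const fmat& in, Dims d, int s, fmat& col) {
  const int C = in.n_rows;
  const Dims od = (s == 1) ? d : halfd(d);
  col.zeros(27 * C, od.n());
  for (int t = 0; t < 27; ++t) {
    const int d1 = t % 3 - 1, d2 = (t / 3) % 3 - 1, d3 = t / 9 - 1;
    for (int o3 = 0; o3 < od.c; ++o3) {
      const int i3 = s * o3 + d3;
      if (i3 < 0 || i3 >= d.c) continue;
      for (int o2 = 0; o2 < od.b; ++o2) {
        const int i2 = s * o2 + d2;
        if (i2 < 0 || i2 >= d.b) continue;
        for (int o1 = 0; o1 < od.a; ++o1) {
          const int i1 = s * o1 + d1;
          if (i1 < 0 || i1 >= d.a) continue;
          const long o = o1 + (long)od.a * (o2 + (long)od.b * o3);
          const long i = i1 + (long)d.a * (i2 + (long)d.b * i3);
          std::memcpy(col.colptr(o) + t * C, in.colptr(i), C * sizeof(float));
        }
      }
    }
  }
}

static void col2vol_acc(const fmat& dcol, Dims d, int s, fmat& gin) {
  const int C = gin.n_rows;
  const Dims od = (s == 1) ? d : halfd(d);
  for (int t = 0; t < 27; ++t) {
    const int d1 = t % 3 - 1, d2 = (t / 3) % 3 - 1, d3 = t / 9 - 1;
    for (int o3 = 0; o3 < od.c; ++o3) {
      const int i3 = s * o3 + d3;
      if (i3 < 0 || i3 >= d.c) continue;
      for (int o2 = 0; o2 < od.b; ++o2) {
        const int i2 = s * o2 + d2;
        if (i2 < 0 || i2 >= d.b) continue;
        for (int o1 = 0; o1 < od.a; ++o1) {
          const int i1 = s * o1 + d1;
          if (i1 < 0 || i1 >= d.a) continue;
          const long o = o1 + (long)od.a * (o2 + (long)od.b * o3);
          const long i = i1 + (long)d.a * (i2 + (long)d.b * i3);
          const float* src = dcol.colptr(o) + t * C;
          float* dst = gin.colptr(i);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Parameters
// ---------------------------------------------------------------------------
struct Param {
  fmat W;          // conv: (Cout, 27*Cin); tconv: (8*Cout, Cin)
  fvec b;          // optional bias (Cout)
  bool has_b = false;
  int Cin = 0, Cout = 0, stride = 1;
  int kind = 0;    // 0 = conv k3 pad1, 1 = tconv k2 s2
  fmat gW, mW, vW;
  fvec gb, mb, vb;

  void alloc(int kind_, int Cin_, int Cout_, int stride_, bool bias) {
    kind = kind_; Cin = Cin_; Cout = Cout_; stride = stride_; has_b = bias;
    if (kind == 0) W.zeros(Cout, 27 * Cin); else W.zeros(8 * Cout, Cin);
    gW.zeros(size(W)); mW.zeros(size(W)); vW.zeros(size(W));
    if (has_b) { b.zeros(Cout); gb.zeros(Cout); mb.zeros(Cout); vb.zeros(Cout); }
  }
  long fan_in() const { return kind == 0 ? 27L * Cin : (long)Cin; }
  long n_par() const { return (long)W.n_elem + (has_b ? (long)b.n_elem : 0); }
};

// Zero-pad a (C, N) feature map by one voxel on each face.
static fmat pad1(const fmat& x, Dims d) {
  const int C = x.n_rows;
  const Dims pd = {d.a + 2, d.b + 2, d.c + 2};
  fmat out(C, pd.n(), fill::zeros);
  for (int i3 = 0; i3 < d.c; ++i3)
    for (int i2 = 0; i2 < d.b; ++i2) {
      const long src = (long)d.a * (i2 + (long)d.b * i3);
      const long dst = 1 + (long)pd.a * (i2 + 1 + (long)pd.b * (i3 + 1));
      std::memcpy(out.colptr(dst), x.colptr(src),
                  (size_t)C * d.a * sizeof(float));
    }
  return out;
}

static fmat unpad1(const fmat& xp, Dims d) {
  const int C = xp.n_rows;
  const Dims pd = {d.a + 2, d.b + 2, d.c + 2};
  fmat out(C, d.n());
  for (int i3 = 0; i3 < d.c; ++i3)
    for (int i2 = 0; i2 < d.b; ++i2) {
      const long dst = (long)d.a * (i2 + (long)d.b * i3);
      const long src = 1 + (long)pd.a * (i2 + 1 + (long)pd.b * (i3 + 1));
      std::memcpy(out.colptr(dst), xp.colptr(src),
                  (size_t)C * d.a * sizeof(float));
    }
  return out;
}

extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* A, const int* lda, const float* B,
                       const int* ldb, const float* beta, float* C,
                       const int* ldc);

static void sgemm_acc(char ta, char tb, int m, int n, int k, const float* A,
                      int lda, const float* B, int ldb, float* C, int ldc) {
  const float one = 1.0f;
  sgemm_(&ta, &tb, &m, &n, &k, &one, A, &lda, B, &ldb, &one, C, &ldc);
}

// Stride-1 kernel-3 convolution as 27 shifted sgemm accumulations on the
// padded grid: interior outputs are exact, padded-border outputs (which may
// wrap across rows) are discarded by unpad1. Accumulation is done in place
// with beta = 1 to avoid subview temporaries.
static fmat conv_fwd_s1(const Param& p, const fmat& x, Dims d) {
  const int Ci = p.Cin, Co = p.Cout;
  const Dims pd = {d.a + 2, d.b + 2, d.c + 2};
  const long Np = pd.n();
  fmat xp = pad1(x, d);
  fmat op(Co, Np, fill::zeros);
  for (int t = 0; t < 27; ++t) {
    const int d1 = t % 3 - 1, d2 = (t / 3) % 3 - 1, d3 = t / 9 - 1;
    const long s = d1 + (long)pd.a * (d2 + (long)pd.b * d3);
    const long lo = std::max(0L, -s), hi = Np - 1 - std::max(0L, s);
    sgemm_acc('N', 'N', Co, (int)(hi - lo + 1), Ci,
              p.W.colptr((long)t * Ci), Co, xp.colptr(lo + s), Ci,
              op.colptr(lo), Co);
  }
  fmat out = unpad1(op, d);
  if (p.has_b) out.each_col() += p.b;
  return out;
}

static fmat conv_bwd_s1(Param& p, const fmat& x, Dims d, const fmat& gout,
                        bool accum) {
  const int Ci = p.Cin, Co = p.Cout;
  const Dims pd = {d.a + 2, d.b + 2, d.c + 2};
  const long Np = pd.n();
  fmat xp = pad1(x, d);
  fmat gp = pad1(gout, d);  // border gradient entries are zero
  for (int t = 0; t < 27; ++t) {
    const int d1 = t % 3 - 1, d2 = (t / 3) % 3 - 1, d3 = t / 9 - 1;
    const long s = d1 + (long)pd.a * (d2 + (long)pd.b * d3);
    if (accum) {
      const long lo = std::max(0L, -s), hi = Np - 1 - std::max(0L, s);
      sgemm_acc('N', 'T', Co, Ci, (int)(hi - lo + 1), gp.colptr(lo), Co,
                xp.colptr(lo + s), Ci, p.gW.colptr((long)t * Ci), Co);
    }
  }
  if (accum && p.has_b) p.gb += sum(gout, 1);
  fmat ginp(Ci, Np, fill::zeros);
  for (int t = 0; t < 27; ++t) {
    const int d1 = t % 3 - 1, d2 = (t / 3) % 3 - 1, d3 = t / 9 - 1;
    const long s = d1 + (long)pd.a * (d2 + (long)pd.b * d3);
    const long lo = std::max(0L, s), hi = Np - 1 - std::max(0L, -s);
    sgemm_acc('T', 'N', Ci, (int)(hi - lo + 1), Co, p.W.colptr((long)t * Ci),
              Co, gp.colptr(lo - s), Co, ginp.colptr(lo), Ci);
  }
  return unpad1(ginp, d);
}

static fmat conv_fwd(const Param& p, const fmat& x, Dims d) {
  if (p.stride == 1) return conv_fwd_s1(p, x, d);
  fmat col; vol2col(x, d, p.stride, col);
  fmat out = p.W * col;
  if (p.has_b) out.each_col() += p.b;
  return out;
}

static fmat conv_bwd(Param& p, const fmat& x, Dims d, const fmat& gout,
                     bool accum) {
  if (p.stride == 1) return conv_bwd_s1(p, x, d, gout, accum);
  fmat col; vol2col(x, d, p.stride, col);
  if (accum) {
    p.gW += gout * col.t();
    if (p.has_b) p.gb += sum(gout, 1);
  }
  fmat dcol = p.W.t() * gout;
  fmat gin(x.n_rows, x.n_cols, fill::zeros);
  col2vol_acc(dcol, d, p.stride, gin);
  return gin;
}

// transposed conv, kernel 2 stride 2: output voxel (2i+t) receives exactly one
// contribution, so forward is a gemm followed by a pure rearrangement.
static fmat tconv_fwd(const Param& p, const fmat& x, Dims d) {
  const int Co = p.Cout;
  fmat M = p.W * x;                       // (8*Co, Nin)
  Dims od = dbld(d);
  fmat out(Co, od.n());
  for (int o3 = 0; o3 < od.c; ++o3) {
    const int i3 = o3 / 2, t3 = o3 % 2;
    for (int o2 = 0; o2 < od.b; ++o2) {
      const int i2 = o2 / 2, t2 = o2 % 2;
      for (int o1 = 0; o1 < od.a; ++o1) {
        const int i1 = o1 / 2, t1 = o1 % 2;
        const int t = t1 + 2 * (t2 + 2 * t3);
        const long o = o1 + (long)od.a * (o2 + (long)od.b * o3);
        const long i = i1 + (long)d.a * (i2 + (long)d.b * i3);
        std::memcpy(out.colptr(o), M.colptr(i) + t * Co, Co * sizeof(float));
      }
    }
  }
  if (p.has_b) out.each_col() += p.b;
  return out;
}

static fmat tconv_bwd(Param& p, const fmat& x, Dims d, const fmat& gout,
                      bool accum) {
  const int Co = p.Cout;
  Dims od = dbld(d);
  fmat Mg(8 * Co, x.n_cols, fill::zeros);
  for (int o3 = 0; o3 < od.c; ++o3) {
    const int i3 = o3 / 2, t3 = o3 % 2;
    for (int o2 = 0; o2 < od.b; ++o2) {
      const int i2 = o2 / 2, t2 = o2 % 2;
      for (int o1 = 0; o1 < od.a; ++o1) {
        const int i1 = o1 / 2, t1 = o1 % 2;
        const int t = t1 + 2 * (t2 + 2 * t3);
        const long o = o1 + (long)od.a * (o2 + (long)od.b * o3);
        const long i = i1 + (long)d.a * (i2 + (long)d.b * i3);
        std::memcpy(Mg.colptr(i) + t * Co, gout.colptr(o), Co * sizeof(float));
      }
    }
  }
  if (accum) {
    p.gW += Mg * x.t();
    if (p.has_b) p.gb += sum(gout, 1);
  }
  return p.W.t() * Mg;
}

// max pooling over disjoint 2x2x2 blocks; idx stores the winning input column
// per (channel, output voxel).
static fmat maxpool_fwd(const fmat& x, Dims d, Mat<uword>& idx) {
  const int C = x.n_rows;
  Dims od = halfd(d);
  fmat out(C, od.n());
  idx.set_size(C, od.n());
  for (int o3 = 0; o3 < od.c; ++o3)
    for (int o2 = 0; o2 < od.b; ++o2)
      for (int o1 = 0; o1 < od.a; ++o1) {
        const long o = o1 + (long)od.a * (o2 + (long)od.b * o3);
        float* op = out.colptr(o);
        uword* ip = idx.colptr(o);
        bool first = true;
        for (int t = 0; t < 8; ++t) {
          const int i1 = 2 * o1 + (t & 1), i2 = 2 * o2 + ((t >> 1) & 1),
                    i3 = 2 * o3 + (t >> 2);
          const long i = i1 + (long)d.a * (i2 + (long)d.b * i3);
          const float* xp = x.colptr(i);
          if (first) {
            for (int c = 0; c < C; ++c) { op[c] = xp[c]; ip[c] = i; }
            first = false;
          } else {
            for (int c = 0; c < C; ++c)
              if (xp[c] > op[c]) { op[c] = xp[c]; ip[c] = i; }
          }
        }
      }
  return out;
}

static fmat maxpool_bwd(const fmat& g, const Mat<uword>& idx, Dims d_pre) {
  const int C = g.n_rows;
  fmat gin(C, d_pre.n(), fill::zeros);
  for (uword o = 0; o < g.n_cols; ++o) {
    const float* gp = g.colptr(o);
    const uword* ip = idx.colptr(o);
    for (int c = 0; c < C; ++c) gin(c, ip[c]) += gp[c];
  }
  return gin;
}

// instance normalization (per channel over voxels, no learned affine)
static fmat in_fwd(const fmat& x, fmat& xhat, fvec& istd) {
  fvec mu = mean(x, 1);
  fmat xc = x.each_col() - mu;
  fvec v = mean(square(xc), 1);
  istd = 1.0f / sqrt(v + 1e-5f);
  xc.each_col() %= istd;
  xhat = xc;
  return xhat;
}

static fmat in_bwd(const fmat& xhat, const fvec& istd, const fmat& gy) {
  fvec m1 = mean(gy, 1);
  fvec m2 = mean(gy % xhat, 1);
  fmat gx = gy;
  gx.each_col() -= m1;
  gx -= xhat.each_col() % m2;
  gx.each_col() %= istd;
  return gx;
}

static fmat relu_fwd(fmat x) { x.transform([](float v) { return v > 0 ? v : 0.0f; }); return x; }
static fmat relu_bwd(const fmat& g, const fmat& y) {
  fmat gx = g;
  for (uword k = 0; k < gx.n_elem; ++k) if (y[k] <= 0) gx[k] = 0;
  return gx;
}
static fmat lrelu_fwd(fmat x) { x.transform([](float v) { return v > 0 ? v : 0.2f * v; }); return x; }
static fmat lrelu_bwd(const fmat& g, const fmat& y) {
  fmat gx = g;
  for (uword k = 0; k < gx.n_elem; ++k) if (y[k] < 0) gx[k] *= 0.2f;
  return gx;
}
static fmat tanh_fwd(const fmat& x) { return tanh(x); }
static fmat sigm_fwd(const fmat& x) { return 1.0f / (1.0f + exp(-x)); }

// ---------------------------------------------------------------------------
// Generator: U-Net with L encode/decode levels + R residual blocks.
// ---------------------------------------------------------------------------
struct UNetGCfg { int L = 3, R = 6, base = 8, in_ch = 1; bool tanh_out = true; };

struct Tape {
  std::vector<fmat> cin;     // conv/tconv inputs per parameter index
  std::vector<Dims> dims;    // grid dims at each conv input
  std::vector<fmat> xhat;    // instance-norm caches
  std::vector<fvec> istd;
  std::vector<fmat> act;     // post-activation outputs
  std::vector<Mat<uword>> pidx;  // pooling argmax (generator only)
  std::vector<Dims> pool_dims;   // dims before each pooling
  void resize(int np, int L) {
    cin.assign(np, fmat()); dims.assign(np, Dims{0, 0, 0});
    xhat.assign(np, fmat()); istd.assign(np, fvec());
    act.assign(np, fmat());
    pidx.assign(L, Mat<uword>()); pool_dims.assign(L, Dims{0, 0, 0});
  }
};

struct UNetG {
  UNetGCfg cfg;
  std::vector<Param> P;
  long t = 0;  // adam step counter

  int ch(int l) const { return cfg.base << l; }
  int o_ch(int l) const { return l >= 1 ? ch(l - 1) : ch(0); }
  int a_ch(int l) const { return l == cfg.L - 1 ? ch(cfg.L - 1) : o_ch(l + 1); }
  int np() const { return 2 * cfg.L + 2 * cfg.R + 3 * cfg.L + 1; }
  int enc_idx(int l, int j) const { return 2 * l + j; }
  int res_idx(int r, int j) const { return 2 * cfg.L + 2 * r + j; }
  int dec_idx(int l, int j) const {  // l is the level (0 shallow .. L-1 deep)
    return 2 * cfg.L + 2 * cfg.R + 3 * (cfg.L - 1 - l) + j;  // j: 0 tconv, 1, 2
  }
  int fin_idx() const { return np() - 1; }

  void build() {
    P.assign(np(), Param());
    for (int l = 0; l < cfg.L; ++l) {
      int cin = (l == 0) ? cfg.in_ch : ch(l - 1);
      P[enc_idx(l, 0)].alloc(0, cin, ch(l), 1, false);
      P[enc_idx(l, 1)].alloc(0, ch(l), ch(l), 1, false);
    }
    int cL = ch(cfg.L - 1);
    for (int r = 0; r < cfg.R; ++r) {
      P[res_idx(r, 0)].alloc(0, cL, cL, 1, false);
      P[res_idx(r, 1)].alloc(0, cL, cL, 1, false);
    }
    for (int l = cfg.L - 1; l >= 0; --l) {
      int a = a_ch(l);
      P[dec_idx(l, 0)].alloc(1, a, a, 2, false);
      P[dec_idx(l, 1)].alloc(0, a + ch(l), o_ch(l), 1, false);
      P[dec_idx(l, 2)].alloc(0, o_ch(l), o_ch(l), 1, false);
    }
    P[fin_idx()].alloc(0, o_ch(0), cfg.in_ch, 1, true);
  }

  fmat fwd(const fmat& x0, Dims d0, Tape& T) {
    const int L = cfg.L, R = cfg.R;
    T.resize(np(), L);
    Dims d = d0;
    fmat cur = x0;
    std::vector<fmat> skips(L);
    for (int l = 0; l < L; ++l) {
      for (int j = 0; j < 2; ++j) {
        int i = enc_idx(l, j);
        T.cin[i] = cur; T.dims[i] = d;
        cur = conv_fwd(P[i], cur, d);
        cur = in_fwd(cur, T.xhat[i], T.istd[i]);
        cur = relu_fwd(cur); T.act[i] = cur;
      }
      skips[l] = cur;
      T.pool_dims[l] = d;
      cur = maxpool_fwd(cur, d, T.pidx[l]);
      d = halfd(d);
    }
    for (int r = 0; r < R; ++r) {
      fmat inp = cur;
      int i1 = res_idx(r, 0), i2 = res_idx(r, 1);
      T.cin[i1] = cur; T.dims[i1] = d;
      cur = relu_fwd(in_fwd(conv_fwd(P[i1], cur, d), T.xhat[i1], T.istd[i1]));
      T.act[i1] = cur;
      T.cin[i2] = cur; T.dims[i2] = d;
      cur = in_fwd(conv_fwd(P[i2], cur, d), T.xhat[i2], T.istd[i2]);
      cur += inp;
    }
    for (int l = L - 1; l >= 0; --l) {
      int it = dec_idx(l, 0), i1 = dec_idx(l, 1), i2 = dec_idx(l, 2);
      T.cin[it] = cur; T.dims[it] = d;
      cur = tconv_fwd(P[it], cur, d);
      d = dbld(d);
      cur = join_cols(cur, skips[l]);
      T.cin[i1] = cur; T.dims[i1] = d;
      cur = relu_fwd(in_fwd(conv_fwd(P[i1], cur, d), T.xhat[i1], T.istd[i1]));
      T.act[i1] = cur;
      T.cin[i2] = cur; T.dims[i2] = d;
      cur = relu_fwd(in_fwd(conv_fwd(P[i2], cur, d), T.xhat[i2], T.istd[i2]));
      T.act[i2] = cur;
    }
    int f = fin_idx();
    T.cin[f] = cur; T.dims[f] = d;
    cur = conv_fwd(P[f], cur, d);
    if (cfg.tanh_out) { cur = tanh_fwd(cur); T.act[f] = cur; }
    return cur;
  }

  fmat bwd(Tape& T, const fmat& gout0, bool accum) {
    const int L = cfg.L, R = cfg.R;
    fmat gcur = gout0;
    int f = fin_idx();
    if (cfg.tanh_out) gcur = gcur % (1.0f - square(T.act[f]));
    gcur = conv_bwd(P[f], T.cin[f], T.dims[f], gcur, accum);
    std::vector<fmat> gskip(L);
    for (int l = 0; l < L; ++l) {  // reverse of the decoder loop
      int it = dec_idx(l, 0), i1 = dec_idx(l, 1), i2 = dec_idx(l, 2);
      gcur = relu_bwd(gcur, T.act[i2]);
      gcur = in_bwd(T.xhat[i2], T.istd[i2], gcur);
      gcur = conv_bwd(P[i2], T.cin[i2], T.dims[i2], gcur, accum);
      gcur = relu_bwd(gcur, T.act[i1]);
      gcur = in_bwd(T.xhat[i1], T.istd[i1], gcur);
      gcur = conv_bwd(P[i1], T.cin[i1], T.dims[i1], gcur, accum);
      const int a = P[it].Cout;
      gskip[l] = gcur.rows(a, gcur.n_rows - 1);
      fmat gtop = gcur.rows(0, a - 1);
      gcur = tconv_bwd(P[it], T.cin[it], T.dims[it], gtop, accum);
    }
    for (int r = R - 1; r >= 0; --r) {
      int i1 = res_idx(r, 0), i2 = res_idx(r, 1);
      fmat gres = gcur;  // identity path
      fmat gg = in_bwd(T.xhat[i2], T.istd[i2], gcur);
      gg = conv_bwd(P[i2], T.cin[i2], T.dims[i2], gg, accum);
      gg = relu_bwd(gg, T.act[i1]);
      gg = in_bwd(T.xhat[i1], T.istd[i1], gg);
      gg = conv_bwd(P[i1], T.cin[i1], T.dims[i1], gg, accum);
      gcur = gres + gg;
    }
    for (int l = L - 1; l >= 0; --l) {
      gcur = maxpool_bwd(gcur, T.pidx[l], T.pool_dims[l]);
      gcur += gskip[l];
      for (int j = 1; j >= 0; --j) {
        int i = enc_idx(l, j);
        gcur = relu_bwd(gcur, T.act[i]);
        gcur = in_bwd(T.xhat[i], T.istd[i], gcur);
        gcur = conv_bwd(P[i], T.cin[i], T.dims[i], gcur, accum);
      }
    }
    return gcur;
  }
};

// ---------------------------------------------------------------------------
// Discriminator: B stride-2 conv blocks (IN + leaky ReLU) + 1x stride-1 conv
// to a single-channel patch score map, sigmoid output.
// ---------------------------------------------------------------------------
struct PatchDCfg { int B = 4, base = 8, in_ch = 1; };

struct PatchD {
  PatchDCfg cfg;
  std::vector<Param> P;
  long t = 0;

  int ch(int i) const { return cfg.base << std::min(i, 3); }
  int np() const { return cfg.B + 1; }

  void build() {
    P.assign(np(), Param());
    for (int i = 0; i < cfg.B; ++i) {
      int cin = (i == 0) ? cfg.in_ch : ch(i - 1);
      P[i].alloc(0, cin, ch(i), 2, false);
    }
    P[cfg.B].alloc(0, ch(cfg.B - 1), 1, 1, true);
  }

  fmat fwd(const fmat& x0, Dims d0, Tape& T) {
    T.resize(np(), 0);
    Dims d = d0;
    fmat cur = x0;
    for (int i = 0; i < cfg.B; ++i) {
      T.cin[i] = cur; T.dims[i] = d;
      cur = conv_fwd(P[i], cur, d);
      d = halfd(d);
      cur = in_fwd(cur, T.xhat[i], T.istd[i]);
      cur = lrelu_fwd(cur); T.act[i] = cur;
    }
    int f = cfg.B;
    T.cin[f] = cur; T.dims[f] = d;
    cur = sigm_fwd(conv_fwd(P[f], cur, d));
    T.act[f] = cur;
    return cur;
  }

  fmat bwd(Tape& T, const fmat& gout0, bool accum) {
    int f = cfg.B;
    fmat gcur = gout0 % T.act[f] % (1.0f - T.act[f]);
    gcur = conv_bwd(P[f], T.cin[f], T.dims[f], gcur, accum);
    for (int i = cfg.B - 1; i >= 0; --i) {
      gcur = lrelu_bwd(gcur, T.act[i]);
      gcur = in_bwd(T.xhat[i], T.istd[i], gcur);
      gcur = conv_bwd(P[i], T.cin[i], T.dims[i], gcur, accum);
    }
    return gcur;
  }
};

// ---------------------------------------------------------------------------
// Adam
// ---------------------------------------------------------------------------
static void zero_grads(std::vector<Param>& P) {
  for (auto& p : P) { p.gW.zeros(); if (p.has_b) p.gb.zeros(); }
}

static void adam_step(std::vector<Param>& P, long& t, float lr, float b1,
                      float b2) {
  ++t;
  const float c1 = 1.0f - std::pow(b1, (float)t);
  const float c2 = 1.0f - std::pow(b2, (float)t);
  const float eps = 1e-8f;
  for (auto& p : P) {
    p.mW = b1 * p.mW + (1 - b1) * p.gW;
    p.vW = b2 * p.vW + (1 - b2) * square(p.gW);
    p.W -= lr * (p.mW / c1) / (sqrt(p.vW / c2) + eps);
    if (p.has_b) {
      p.mb = b1 * p.mb + (1 - b1) * p.gb;
      p.vb = b2 * p.vb + (1 - b2) * square(p.gb);
      p.b -= lr * (p.mb / c1) / (sqrt(p.vb / c2) + eps);
    }
  }
}

// ---------------------------------------------------------------------------
// CycleGAN model container
// ---------------------------------------------------------------------------
struct CGModel {
  UNetG g1, g2;
  PatchD da, db;
  Dims d;
};

static const float SCORE_EPS = 1e-7f;

static fmat clampscore(fmat s) {
  s.transform([](float v) {
    if (v < SCORE_EPS) return SCORE_EPS;
    if (v > 1.0f - SCORE_EPS) return 1.0f - SCORE_EPS;
    return v;
  });
  return s;
}

// value of the printed adversarial objective E[log D(y)] + E[log(1-D(G(x)))]
static double adv_value(const fmat& s_real, const fmat& s_fake) {
  fmat r = clampscore(s_real), f = clampscore(s_fake);
  return (double)(mean(mean(log(r))) + mean(mean(log(1.0f - f))));
}

// gradient of the generator's adversarial term wrt fake scores
static fmat gen_adv_grad(const fmat& s_fake, bool nonsat, double* val) {
  fmat f = clampscore(s_fake);
  const float N = (float)f.n_elem;
  fmat g;
  if (nonsat) {               // minimize -E[log D(G(x))]
    *val = -(double)mean(mean(log(f)));
    g = -1.0f / (N * f);
  } else {                    // minimize E[log(1 - D(G(x)))] (printed form)
    *val = (double)mean(mean(log(1.0f - f)));
    g = -1.0f / (N * (1.0f - f));
  }
  return g;
}

static double l1_mean(const fmat& a, const fmat& b) {
  return (double)mean(mean(abs(a - b)));
}

static fmat l1_grad(const fmat& rec, const fmat& x, float scale) {
  fmat g = rec - x;
  g.transform([](float v) { return v > 0 ? 1.0f : (v < 0 ? -1.0f : 0.0f); });
  return g * scale;
}

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------
static fmat vec2map(const Rcpp::NumericVector& x) {
  fmat m(1, x.size());
  for (long i = 0; i < (long)x.size(); ++i) m(0, i) = (float)x[i];
  return m;
}

static Rcpp::NumericVector map2vec(const fmat& m) {
  Rcpp::NumericVector out(m.n_elem);
  for (long i = 0; i < (long)m.n_elem; ++i) out[i] = (double)m[i];
  return out;
}

// [[Rcpp::export]]
SEXP cg_build(Rcpp::List gen_cfg, Rcpp::List disc_cfg,
              Rcpp::IntegerVector dims) {
  auto* m = new CGModel();
  m->d = {dims[0], dims[1], dims[2]};
  UNetGCfg gc;
  gc.L = Rcpp::as<int>(gen_cfg["n_levels"]);
  gc.R = Rcpp::as<int>(gen_cfg["n_resblocks"]);
  gc.base = Rcpp::as<int>(gen_cfg["base_channels"]);
  gc.tanh_out = Rcpp::as<bool>(gen_cfg["tanh_out"]);
  PatchDCfg dc;
  dc.B = Rcpp::as<int>(disc_cfg["n_blocks"]);
  dc.base = Rcpp::as<int>(disc_cfg["base_channels"]);
  m->g1.cfg = gc; m->g2.cfg = gc;
  m->da.cfg = dc; m->db.cfg = dc;
  m->g1.build(); m->g2.build(); m->da.build(); m->db.build();
  Rcpp::XPtr<CGModel> p(m, true);
  return p;
}

template <typename NetT>
static Rcpp::List net_info(const NetT& net) {
  Rcpp::List out;
  for (size_t i = 0; i < net.P.size(); ++i) {
    const Param& p = net.P[i];
    out.push_back(Rcpp::List::create(
        Rcpp::Named("w_rows") = (int)p.W.n_rows,
        Rcpp::Named("w_cols") = (int)p.W.n_cols,
        Rcpp::Named("fan_in") = (double)p.fan_in(),
        Rcpp::Named("has_b") = p.has_b,
        Rcpp::Named("b_len") = p.has_b ? (int)p.b.n_elem : 0));
  }
  return out;
}

// [[Rcpp::export]]
bool cg_ptr_ok(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != nullptr;
}

// [[Rcpp::export]]
Rcpp::List cg_param_info(SEXP ptr) {
  Rcpp::XPtr<CGModel> m(ptr);
  return Rcpp::List::create(
      Rcpp::Named("g1") = net_info(m->g1), Rcpp::Named("g2") = net_info(m->g2),
      Rcpp::Named("da") = net_info(m->da), Rcpp::Named("db") = net_info(m->db));
}

template <typename NetT>
static Rcpp::NumericVector net_get(const NetT& net) {
  long n = 0;
  for (const auto& p : net.P) n += p.n_par();
  Rcpp::NumericVector out(n);
  long k = 0;
  for (const auto& p : net.P) {
    for (uword i = 0; i < p.W.n_elem; ++i) out[k++] = (double)p.W[i];
    if (p.has_b) for (uword i = 0; i < p.b.n_elem; ++i) out[k++] = (double)p.b[i];
  }
  return out;
}

template <typename NetT>
static void net_set(NetT& net, const Rcpp::NumericVector& v) {
  long n = 0;
  for (const auto& p : net.P) n += p.n_par();
  if ((long)v.size() != n) Rcpp::stop("parameter vector length mismatch");
  long k = 0;
  for (auto& p : net.P) {
    for (uword i = 0; i < p.W.n_elem; ++i) p.W[i] = (float)v[k++];
    if (p.has_b) for (uword i = 0; i < p.b.n_elem; ++i) p.b[i] = (float)v[k++];
  }
}

// [[Rcpp::export]]
Rcpp::List cg_get_params(SEXP ptr) {
  Rcpp::XPtr<CGModel> m(ptr);
  return Rcpp::List::create(
      Rcpp::Named("g1") = net_get(m->g1), Rcpp::Named("g2") = net_get(m->g2),
      Rcpp::Named("da") = net_get(m->da), Rcpp::Named("db") = net_get(m->db));
}

// [[Rcpp::export]]
void cg_set_params(SEXP ptr, Rcpp::List params) {
  Rcpp::XPtr<CGModel> m(ptr);
  net_set(m->g1, params["g1"]); net_set(m->g2, params["g2"]);
  net_set(m->da, params["da"]); net_set(m->db, params["db"]);
}

// [[Rcpp::export]]
Rcpp::IntegerVector cg_param_counts(SEXP ptr) {
  Rcpp::XPtr<CGModel> m(ptr);
  auto cnt = [](const std::vector<Param>& P) {
    long n = 0; for (const auto& p : P) n += p.n_par(); return (int)n;
  };
  return Rcpp::IntegerVector::create(
      Rcpp::Named("g1") = cnt(m->g1.P), Rcpp::Named("g2") = cnt(m->g2.P),
      Rcpp::Named("da") = cnt(m->da.P), Rcpp::Named("db") = cnt(m->db.P));
}

// [[Rcpp::export]]
Rcpp::NumericVector cg_forward(SEXP ptr, std::string which,
                               Rcpp::NumericVector x) {
  Rcpp::XPtr<CGModel> m(ptr);
  fmat in = vec2map(x);
  Tape T;
  fmat out;
  if (which == "g1") out = m->g1.fwd(in, m->d, T);
  else if (which == "g2") out = m->g2.fwd(in, m->d, T);
  else if (which == "da") out = m->da.fwd(in, m->d, T);
  else if (which == "db") out = m->db.fwd(in, m->d, T);
  else Rcpp::stop("unknown network: %s", which);
  return map2vec(out);
}

// One alternating optimization step on a single (x, y) pair.
// Returns c(adv_A, adv_B, cyc, gen_obj, disc_obj) where adv_* are the values
// of the printed adversarial objective for each direction.
// [[Rcpp::export]]
Rcpp::NumericVector cg_train_step(SEXP ptr, Rcpp::NumericVector x_,
                                  Rcpp::NumericVector y_, double lambda,
                                  double lr, double beta1, double beta2,
                                  bool nonsat) {
  Rcpp::XPtr<CGModel> m(ptr);
  const fmat x = vec2map(x_), y = vec2map(y_);
  const float lam = (float)lambda;
  const long Nvox = x.n_elem;

  Tape t1, t2, t3, t4, td_fy, td_fx, td_y, td_x;
  fmat fy = m->g1.fwd(x, m->d, t1);
  fmat rx = m->g2.fwd(fy, m->d, t2);
  fmat fx = m->g2.fwd(y, m->d, t3);
  fmat ry = m->g1.fwd(fx, m->d, t4);
  fmat sB_f = m->db.fwd(fy, m->d, td_fy);
  fmat sA_f = m->da.fwd(fx, m->d, td_fx);

  const double cycA = l1_mean(rx, x), cycB = l1_mean(ry, y);

  // ---- generator update ----
  zero_grads(m->g1.P); zero_grads(m->g2.P);
  double advg_B, advg_A;
  fmat gs_B = gen_adv_grad(sB_f, nonsat, &advg_B);
  fmat gs_A = gen_adv_grad(sA_f, nonsat, &advg_A);
  fmat g_fy = m->db.bwd(td_fy, gs_B, false);
  g_fy += m->g2.bwd(t2, l1_grad(rx, x, lam / Nvox), true);
  m->g1.bwd(t1, g_fy, true);
  fmat g_fx = m->da.bwd(td_fx, gs_A, false);
  g_fx += m->g1.bwd(t4, l1_grad(ry, y, lam / Nvox), true);
  m->g2.bwd(t3, g_fx, true);
  adam_step(m->g1.P, m->g1.t, (float)lr, (float)beta1, (float)beta2);
  // keep one shared step counter cadence for both generators
  adam_step(m->g2.P, m->g2.t, (float)lr, (float)beta1, (float)beta2);
  const double gen_obj = advg_A + advg_B + lambda * (cycA + cycB);

  // ---- discriminator update (fakes detached: generator already stepped,
  //      but the cached D tapes were computed on the fixed fakes) ----
  fmat sB_r = m->db.fwd(y, m->d, td_y);
  fmat sA_r = m->da.fwd(x, m->d, td_x);
  const double adv_B = adv_value(sB_r, sB_f);
  const double adv_A = adv_value(sA_r, sA_f);
  zero_grads(m->da.P); zero_grads(m->db.P);
  {
    fmat r = clampscore(sB_r), f = clampscore(sB_f);
    const float Nr = (float)r.n_elem, Nf = (float)f.n_elem;
    m->db.bwd(td_y, -1.0f / (Nr * r), true);
    m->db.bwd(td_fy, 1.0f / (Nf * (1.0f - f)), true);
  }
  {
    fmat r = clampscore(sA_r), f = clampscore(sA_f);
    const float Nr = (float)r.n_elem, Nf = (float)f.n_elem;
    m->da.bwd(td_x, -1.0f / (Nr * r), true);
    m->da.bwd(td_fx, 1.0f / (Nf * (1.0f - f)), true);
  }
  adam_step(m->da.P, m->da.t, (float)lr, (float)beta1, (float)beta2);
  adam_step(m->db.P, m->db.t, (float)lr, (float)beta1, (float)beta2);
  const double disc_obj = -(adv_A + adv_B);

  return Rcpp::NumericVector::create(
      Rcpp::Named("adv_a") = adv_A, Rcpp::Named("adv_b") = adv_B,
      Rcpp::Named("cyc") = cycA + cycB, Rcpp::Named("gen_obj") = gen_obj,
      Rcpp::Named("disc_obj") = disc_obj);
}

// Generator objective and its parameter gradients, without updating anything.
// Used by finite-difference gradient checks.
// [[Rcpp::export]]
Rcpp::List cg_gen_grads(SEXP ptr, Rcpp::NumericVector x_,
                        Rcpp::NumericVector y_, double lambda, bool nonsat) {
  Rcpp::XPtr<CGModel> m(ptr);
  const fmat x = vec2map(x_), y = vec2map(y_);
  const float lam = (float)lambda;
  const long Nvox = x.n_elem;
  Tape t1, t2, t3, t4, td1, td2;
  fmat fy = m->g1.fwd(x, m->d, t1);
  fmat rx = m->g2.fwd(fy, m->d, t2);
  fmat fx = m->g2.fwd(y, m->d, t3);
  fmat ry = m->g1.fwd(fx, m->d, t4);
  fmat sB_f = m->db.fwd(fy, m->d, td1);
  fmat sA_f = m->da.fwd(fx, m->d, td2);
  zero_grads(m->g1.P); zero_grads(m->g2.P);
  double advg_B, advg_A;
  fmat gs_B = gen_adv_grad(sB_f, nonsat, &advg_B);
  fmat gs_A = gen_adv_grad(sA_f, nonsat, &advg_A);
  fmat g_fy = m->db.bwd(td1, gs_B, false);
  g_fy += m->g2.bwd(t2, l1_grad(rx, x, lam / Nvox), true);
  m->g1.bwd(t1, g_fy, true);
  fmat g_fx = m->da.bwd(td2, gs_A, false);
  g_fx += m->g1.bwd(t4, l1_grad(ry, y, lam / Nvox), true);
  m->g2.bwd(t3, g_fx, true);
  const double loss =
      advg_A + advg_B + lambda * (l1_mean(rx, x) + l1_mean(ry, y));
  auto grads = [](const std::vector<Param>& P) {
    long n = 0; for (const auto& p : P) n += p.n_par();
    Rcpp::NumericVector out(n);
    long k = 0;
    for (const auto& p : P) {
      for (uword i = 0; i < p.gW.n_elem; ++i) out[k++] = (double)p.gW[i];
      if (p.has_b) for (uword i = 0; i < p.gb.n_elem; ++i) out[k++] = (double)p.gb[i];
    }
    return out;
  };
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("g1") = grads(m->g1.P),
                            Rcpp::Named("g2") = grads(m->g2.P));
}

// Discriminator objective (to be minimized) and gradients, fakes held fixed.
// [[Rcpp::export]]
Rcpp::List cg_disc_grads(SEXP ptr, Rcpp::NumericVector x_,
                         Rcpp::NumericVector y_) {
  Rcpp::XPtr<CGModel> m(ptr);
  const fmat x = vec2map(x_), y = vec2map(y_);
  Tape tg1, tg2, td_fy, td_fx, td_y, td_x;
  fmat fy = m->g1.fwd(x, m->d, tg1);
  fmat fx = m->g2.fwd(y, m->d, tg2);
  fmat sB_f = m->db.fwd(fy, m->d, td_fy);
  fmat sA_f = m->da.fwd(fx, m->d, td_fx);
  fmat sB_r = m->db.fwd(y, m->d, td_y);
  fmat sA_r = m->da.fwd(x, m->d, td_x);
  zero_grads(m->da.P); zero_grads(m->db.P);
  {
    fmat r = clampscore(sB_r), f = clampscore(sB_f);
    const float Nr = (float)r.n_elem, Nf = (float)f.n_elem;
    m->db.bwd(td_y, -1.0f / (Nr * r), true);
    m->db.bwd(td_fy, 1.0f / (Nf * (1.0f - f)), true);
  }
  {
    fmat r = clampscore(sA_r), f = clampscore(sA_f);
    const float Nr = (float)r.n_elem, Nf = (float)f.n_elem;
    m->da.bwd(td_x, -1.0f / (Nr * r), true);
    m->da.bwd(td_fx, 1.0f / (Nf * (1.0f - f)), true);
  }
  const double loss = -(adv_value(sB_r, sB_f) + adv_value(sA_r, sA_f));
  auto grads = [](const std::vector<Param>& P) {
    long n = 0; for (const auto& p : P) n += p.n_par();
    Rcpp::NumericVector out(n);
    long k = 0;
    for (const auto& p : P) {
      for (uword i = 0; i < p.gW.n_elem; ++i) out[k++] = (double)p.gW[i];
      if (p.has_b) for (uword i = 0; i < p.gb.n_elem; ++i) out[k++] = (double)p.gb[i];
    }
    return out;
  };
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("da") = grads(m->da.P),
                            Rcpp::Named("db") = grads(m->db.P));
}
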