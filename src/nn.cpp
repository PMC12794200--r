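// Minimal CNN / LSTM regression engine for EEG window decoding.
//
// Tensors are arma::fcube with dimensions (C, T, B): C = feature maps x spatial
// rows (rows vary fastest), T = time samples, B = batch (windows). Single
// precision throughout; all randomness comes from one std::mt19937 owned by the
// network, so a fixed seed reproduces initialization and dropout exactly.

#include <RcppArmadillo.h>
#include <memory>
#include <random>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using arma::fcube;
using arma::fmat;
using arma::fvec;
using arma::frowvec;
using arma::uword;

namespace {

typedef std::mt19937 Rng;

float runif_sym(Rng& rng, float limit) {
  std::uniform_real_distribution<float> d(-limit, limit);
  return d(rng);
}

void glorot_fill(fmat& w, double fan_in, double fan_out, Rng& rng) {
  const float limit = (float)std::sqrt(6.0 / (fan_in + fan_out));
  for (uword i = 0; i < w.n_elem; ++i) w(i) = runif_sym(rng, limit);
}

// View cube memory as (C*T, B) or (C, T*B) matrices without copying.
inline fmat flat_ctb(const fcube& x) {
  return fmat(const_cast<float*>(x.memptr()), x.n_rows * x.n_cols, x.n_slices,
              false, true);
}
inline fmat flat_c_tb(const fcube& x) {
  return fmat(const_cast<float*>(x.memptr()), x.n_rows, x.n_cols * x.n_slices,
              false, true);
}

struct Layer {
  virtual ~Layer() {}
  // y = f(x); when train, keep caches for backward().
  virtual fcube forward(const fcube& x, bool train) = 0;
  virtual fcube backward(const fcube& gy) = 0;
  virtual std::vector<fmat*> params() { return {}; }
  virtual std::vector<fmat*> grads() { return {}; }
  // running statistics etc. that must travel with the weights
  virtual std::vector<fmat*> state_extra() { return {}; }
  virtual void init(Rng&) {}
  virtual void drop_cache() {}
};

// ---------------------------------------------------------------------------
// Temporal convolution on a multi-row input (first layer; M = 1, R rows):
// output channel layout is interleaved, c = f + F*r, which lets the GEMM
// write straight into the output cube with no scatter pass. Downstream
// layers that care about the (filter, row) structure must use their
// interleaved variants; fully connected spatial convolutions are
// permutation-invariant and need no change.
struct TemporalConvInterleaved : Layer {
  uword R, F, K, lpad, rpad;
  bool use_bias;
  fmat W;  // (F, K)
  fmat b;  // (F, 1)
  fmat dW, db;
  fmat cols;  // (Ncols, K) cache, Ncols = R*Tout*B
  uword Tin, Tout, B;

  TemporalConvInterleaved(uword R_, uword F_, uword K_, uword lp, uword rp,
                          bool bias)
      : R(R_), F(F_), K(K_), lpad(lp), rpad(rp), use_bias(bias) {
    W.set_size(F, K);
    b.zeros(F, 1);
    dW.zeros(F, K);
    db.zeros(F, 1);
  }
  void init(Rng& rng) override { glorot_fill(W, (double)K, (double)F * K, rng); }

  fcube forward(const fcube& x, bool train) override {
    Tin = x.n_cols;
    B = x.n_slices;
    Tout = Tin + lpad + rpad - K + 1;
    fcube xp;
    const fcube* xs = &x;
    if (lpad + rpad > 0) {
      xp.zeros(R, Tin + lpad + rpad, B);
      xp.cols(lpad, lpad + Tin - 1) = x;
      xs = &xp;
    }
    const uword Ncols = R * Tout * B;
    fmat cl(Ncols, K);
    for (uword k = 0; k < K; ++k) {
      float* dst = cl.colptr(k);
      for (uword s = 0; s < B; ++s)
        std::memcpy(dst + s * R * Tout, xs->slice_memptr(s) + k * R,
                    sizeof(float) * R * Tout);
    }
    fcube y(F * R, Tout, B);
    fmat ym(y.memptr(), F, Ncols, false, true);
    ym = W * cl.t();
    if (use_bias) ym.each_col() += b.col(0);
    if (train) cols = std::move(cl);
    return y;
  }

  fcube backward(const fcube& gy) override {
    const uword Ncols = R * Tout * B;
    fmat gm(const_cast<float*>(gy.memptr()), F, Ncols, false, true);
    dW = gm * cols;
    if (use_bias) db = arma::sum(gm, 1);
    fmat dcols = gm.t() * W;  // (Ncols, K)
    cols.reset();
    const uword Tp = Tin + lpad + rpad;
    fcube dxp(R, Tp, B, arma::fill::zeros);
    for (uword k = 0; k < K; ++k) {
      const float* src = dcols.colptr(k);
      for (uword s = 0; s < B; ++s) {
        float* d0 = dxp.slice_memptr(s) + k * R;
        const float* s0 = src + s * R * Tout;
        for (uword i = 0; i < R * Tout; ++i) d0[i] += s0[i];
      }
    }
    if (lpad + rpad == 0) return dxp;
    return dxp.cols(lpad, lpad + Tin - 1);
  }

  std::vector<fmat*> params() override {
    return use_bias ? std::vector<fmat*>{&W, &b} : std::vector<fmat*>{&W};
  }
  std::vector<fmat*> grads() override {
    return use_bias ? std::vector<fmat*>{&dW, &db} : std::vector<fmat*>{&dW};
  }
  void drop_cache() override { cols.reset(); }
};

// ---------------------------------------------------------------------------
// General temporal convolution over single-row feature maps (deeper blocks,
// pointwise convolutions). Input (M, T, B) -> (F, Tout, B).
// im2col/GEMM formulation; column index n = r + R*(t + Tout*b).
struct TemporalConv : Layer {
  uword M, R, F, K, lpad, rpad;
  bool use_bias;
  fmat W;   // (F, M*K), column index m*K + k
  fmat b;   // (F, 1)
  fmat dW, db;
  fmat Xcolt;  // (Ncols, M*K) cache
  uword Tin, Tout, B;

  TemporalConv(uword M_, uword R_, uword F_, uword K_, uword lp, uword rp,
               bool bias)
      : M(M_), R(R_), F(F_), K(K_), lpad(lp), rpad(rp), use_bias(bias) {
    W.set_size(F, M * K);
    b.zeros(F, 1);
    dW.zeros(F, M * K);
    db.zeros(F, 1);
  }
  void init(Rng& rng) override { glorot_fill(W, (double)M * K, (double)F * K, rng); }

  void build_cols(const fcube& xp, fmat& cols, uword Tout_) const {
    // cols: (R*Tout*B, M*K)
    const uword C = M * R;
    for (uword m = 0; m < M; ++m) {
      for (uword k = 0; k < K; ++k) {
        float* dst = cols.colptr(m * K + k);
        for (uword s = 0; s < xp.n_slices; ++s) {
          const float* sl = xp.slice_memptr(s);
          if (M == 1) {
            std::memcpy(dst + s * R * Tout_, sl + k * R,
                        sizeof(float) * R * Tout_);
          } else {
            for (uword t = 0; t < Tout_; ++t)
              for (uword r = 0; r < R; ++r)
                dst[r + R * (t + Tout_ * s)] = sl[m * R + r + (t + k) * C];
          }
        }
      }
    }
  }

  fcube forward(const fcube& x, bool train) override {
    Tin = x.n_cols;
    B = x.n_slices;
    Tout = Tin + lpad + rpad - K + 1;
    fcube xp;
    const fcube* xs = &x;
    if (lpad + rpad > 0) {
      xp.zeros(x.n_rows, Tin + lpad + rpad, B);
      xp.cols(lpad, lpad + Tin - 1) = x;
      xs = &xp;
    }
    const uword Ncols = R * Tout * B;
    fmat cols(Ncols, M * K);
    build_cols(*xs, cols, Tout);
    fmat Yt = cols * W.t();  // (Ncols, F)
    if (use_bias) for (uword f = 0; f < F; ++f) Yt.col(f) += b(f, 0);
    if (train) Xcolt = std::move(cols);
    fcube y(F * R, Tout, B);
    for (uword f = 0; f < F; ++f) {
      const float* src = Yt.colptr(f);
      for (uword s = 0; s < B; ++s) {
        float* sl = y.slice_memptr(s);
        for (uword t = 0; t < Tout; ++t)
          std::memcpy(sl + f * R + t * F * R, src + R * (t + Tout * s),
                      sizeof(float) * R);
      }
    }
    return y;
  }

  fcube backward(const fcube& gy) override {
    const uword Ncols = R * Tout * B;
    fmat Gt(Ncols, F);
    for (uword f = 0; f < F; ++f) {
      float* dst = Gt.colptr(f);
      for (uword s = 0; s < B; ++s) {
        const float* sl = gy.slice_memptr(s);
        for (uword t = 0; t < Tout; ++t)
          std::memcpy(dst + R * (t + Tout * s), sl + f * R + t * F * R,
                      sizeof(float) * R);
      }
    }
    dW = Gt.t() * Xcolt;
    if (use_bias) db = arma::sum(Gt, 0).t();
    fmat dcols = Gt * W;  // (Ncols, M*K)
    const uword C = M * R, Tp = Tin + lpad + rpad;
    fcube dxp(C, Tp, B, arma::fill::zeros);
    for (uword m = 0; m < M; ++m) {
      for (uword k = 0; k < K; ++k) {
        const float* src = dcols.colptr(m * K + k);
        for (uword s = 0; s < B; ++s) {
          float* sl = dxp.slice_memptr(s);
          if (M == 1) {
            float* d0 = sl + k * R;
            const float* s0 = src + s * R * Tout;
            for (uword i = 0; i < R * Tout; ++i) d0[i] += s0[i];
          } else {
            for (uword t = 0; t < Tout; ++t)
              for (uword r = 0; r < R; ++r)
                sl[m * R + r + (t + k) * C] += src[r + R * (t + Tout * s)];
          }
        }
      }
    }
    Xcolt.reset();
    if (lpad + rpad == 0) return dxp;
    return dxp.cols(lpad, lpad + Tin - 1);
  }

  std::vector<fmat*> params() override {
    return use_bias ? std::vector<fmat*>{&W, &b} : std::vector<fmat*>{&W};
  }
  std::vector<fmat*> grads() override {
    return use_bias ? std::vector<fmat*>{&dW, &db} : std::vector<fmat*>{&dW};
  }
  void drop_cache() override { Xcolt.reset(); }
};

// ---------------------------------------------------------------------------
// Depthwise temporal convolution: each map has its own (1, K) kernel.
// Input (M, T, B) -> (M, Tout, B); rows per map must be 1.
struct DepthwiseTemporalConv : Layer {
  uword M, K, lpad, rpad;
  fmat W, dW;  // (M, K)
  fcube xp_cache;
  uword Tin, Tout;

  DepthwiseTemporalConv(uword M_, uword K_, uword lp, uword rp)
      : M(M_), K(K_), lpad(lp), rpad(rp) {
    W.set_size(M, K);
    dW.zeros(M, K);
  }
  void init(Rng& rng) override { glorot_fill(W, (double)K, (double)K, rng); }

  fcube forward(const fcube& x, bool train) override {
    Tin = x.n_cols;
    Tout = Tin + lpad + rpad - K + 1;
    fcube xp(M, Tin + lpad + rpad, x.n_slices, arma::fill::zeros);
    xp.cols(lpad, lpad + Tin - 1) = x;
    fcube y(M, Tout, x.n_slices, arma::fill::zeros);
    for (uword m = 0; m < M; ++m)
      for (uword k = 0; k < K; ++k)
        y.subcube(m, 0, 0, m, Tout - 1, x.n_slices - 1) +=
            W(m, k) * xp.subcube(m, k, 0, m, k + Tout - 1, x.n_slices - 1);
    if (train) xp_cache = std::move(xp);
    return y;
  }
  fcube backward(const fcube& gy) override {
    const uword B = gy.n_slices;
    dW.zeros();
    fcube dxp(M, Tin + lpad + rpad, B, arma::fill::zeros);
    for (uword m = 0; m < M; ++m)
      for (uword k = 0; k < K; ++k) {
        dW(m, k) = arma::accu(
            gy.subcube(m, 0, 0, m, Tout - 1, B - 1) %
            xp_cache.subcube(m, k, 0, m, k + Tout - 1, B - 1));
        dxp.subcube(m, k, 0, m, k + Tout - 1, B - 1) +=
            W(m, k) * gy.subcube(m, 0, 0, m, Tout - 1, B - 1);
      }
    xp_cache.reset();
    return dxp.cols(lpad, lpad + Tin - 1);
  }
  std::vector<fmat*> params() override { return {&W}; }
  std::vector<fmat*> grads() override { return {&dW}; }
  void drop_cache() override { xp_cache.reset(); }
};

// ---------------------------------------------------------------------------
// Spatial convolution: kernel (R, 1) spanning all rows and maps.
// Input (M*R, T, B) -> (F, T, B); a plain GEMM over the flattened time axis.
struct SpatialConv : Layer {
  uword Cin, F;
  bool use_bias;
  fmat W, b, dW, db;  // W: (F, Cin)
  fcube x_cache;

  SpatialConv(uword Cin_, uword F_, bool bias)
      : Cin(Cin_), F(F_), use_bias(bias) {
    W.set_size(F, Cin);
    b.zeros(F, 1);
    dW.zeros(F, Cin);
    db.zeros(F, 1);
  }
  void init(Rng& rng) override { glorot_fill(W, (double)Cin, (double)F, rng); }

  fcube forward(const fcube& x, bool train) override {
    fmat xm = flat_c_tb(x);
    fcube y(F, x.n_cols, x.n_slices);
    fmat ym = flat_c_tb(y);
    ym = W * xm;
    if (use_bias) ym.each_col() += b.col(0);
    if (train) x_cache = x;
    return y;
  }
  fcube backward(const fcube& gy) override {
    fmat gym = flat_c_tb(gy);
    fmat xm = flat_c_tb(x_cache);
    dW = gym * xm.t();
    if (use_bias) db = arma::sum(gym, 1);
    fcube dx(Cin, gy.n_cols, gy.n_slices);
    fmat dxm = flat_c_tb(dx);
    dxm = W.t() * gym;
    x_cache.reset();
    return dx;
  }
  std::vector<fmat*> params() override {
    return use_bias ? std::vector<fmat*>{&W, &b} : std::vector<fmat*>{&W};
  }
  std::vector<fmat*> grads() override {
    return use_bias ? std::vector<fmat*>{&dW, &db} : std::vector<fmat*>{&dW};
  }
  void drop_cache() override { x_cache.reset(); }
};

// ---------------------------------------------------------------------------
// Depthwise spatial convolution: per input map, D kernels of shape (R, 1).
// Input is interleaved (c = m + M*r, as produced by the first temporal
// convolution); output maps are laid out d*M + m, one plain row per map.
struct DepthwiseSpatialConv : Layer {
  uword M, R, D;
  fmat W, dW;  // (D*M, R), row d*M + m
  fcube x_cache;

  DepthwiseSpatialConv(uword M_, uword R_, uword D_) : M(M_), R(R_), D(D_) {
    W.set_size(D * M, R);
    dW.zeros(D * M, R);
  }
  void init(Rng& rng) override { glorot_fill(W, (double)R, (double)R * D, rng); }

  fcube forward(const fcube& x, bool train) override {
    fmat xm = flat_c_tb(x);
    fcube y(D * M, x.n_cols, x.n_slices, arma::fill::zeros);
    fmat ym = flat_c_tb(y);
    for (uword r = 0; r < R; ++r) {
      auto blk = xm.rows(M * r, M * r + M - 1);
      for (uword d = 0; d < D; ++d) {
        fvec v = W.col(r).rows(d * M, d * M + M - 1);
        ym.rows(d * M, d * M + M - 1) += blk.each_col() % v;
      }
    }
    if (train) x_cache = x;
    return y;
  }
  fcube backward(const fcube& gy) override {
    fmat gym = flat_c_tb(gy);
    fmat xm = flat_c_tb(x_cache);
    fcube dx(M * R, gy.n_cols, gy.n_slices, arma::fill::zeros);
    fmat dxm = flat_c_tb(dx);
    dW.zeros();
    for (uword r = 0; r < R; ++r) {
      auto xblk = xm.rows(M * r, M * r + M - 1);
      auto dblk = dxm.rows(M * r, M * r + M - 1);
      for (uword d = 0; d < D; ++d) {
        auto gblk = gym.rows(d * M, d * M + M - 1);
        dW.col(r).rows(d * M, d * M + M - 1) = arma::sum(gblk % xblk, 1);
        fvec v = W.col(r).rows(d * M, d * M + M - 1);
        dblk += gblk.each_col() % v;
      }
    }
    x_cache.reset();
    return dx;
  }
  std::vector<fmat*> params() override { return {&W}; }
  std::vector<fmat*> grads() override { return {&dW}; }
  void drop_cache() override { x_cache.reset(); }
};

// ---------------------------------------------------------------------------
// Batch normalization over an interleaved multi-row tensor (c = m + M*r):
// per-map statistics accumulated in single linear passes over the memory.
struct BatchNormInterleaved : Layer {
  uword M, R;
  float eps, momentum;
  fmat gamma, beta, dgamma, dbeta;
  fmat run_mean, run_var;
  fcube xhat;
  fvec invstd;

  BatchNormInterleaved(uword M_, uword R_, float eps_ = 1e-3f,
                       float mom_ = 0.99f)
      : M(M_), R(R_), eps(eps_), momentum(mom_) {
    gamma.ones(M, 1);
    beta.zeros(M, 1);
    dgamma.zeros(M, 1);
    dbeta.zeros(M, 1);
    run_mean.zeros(M, 1);
    run_var.ones(M, 1);
    invstd.zeros(M);
  }

  fcube forward(const fcube& x, bool train) override {
    fcube y(arma::size(x));
    const uword nblk = x.n_elem / M;
    const double N = (double)nblk;
    fvec mu(M), var(M);
    if (train) {
      arma::vec s1(M, arma::fill::zeros), s2(M, arma::fill::zeros);
      const float* p = x.memptr();
      for (uword blk = 0; blk < nblk; ++blk) {
        const float* q = p + blk * M;
        for (uword m = 0; m < M; ++m) {
          s1(m) += q[m];
          s2(m) += (double)q[m] * q[m];
        }
      }
      for (uword m = 0; m < M; ++m) {
        mu(m) = (float)(s1(m) / N);
        var(m) = (float)(s2(m) / N - (s1(m) / N) * (s1(m) / N));
        run_mean(m, 0) = momentum * run_mean(m, 0) + (1 - momentum) * mu(m);
        run_var(m, 0) = momentum * run_var(m, 0) + (1 - momentum) * var(m);
      }
    } else {
      for (uword m = 0; m < M; ++m) {
        mu(m) = run_mean(m, 0);
        var(m) = run_var(m, 0);
      }
    }
    for (uword m = 0; m < M; ++m) invstd(m) = 1.0f / std::sqrt(var(m) + eps);
    if (train) xhat.set_size(arma::size(x));
    const float* p = x.memptr();
    float* py = y.memptr();
    float* ph = train ? xhat.memptr() : nullptr;
    for (uword blk = 0; blk < nblk; ++blk) {
      const uword off = blk * M;
      for (uword m = 0; m < M; ++m) {
        const float xh = (p[off + m] - mu(m)) * invstd(m);
        if (ph) ph[off + m] = xh;
        py[off + m] = gamma(m, 0) * xh + beta(m, 0);
      }
    }
    return y;
  }
  fcube backward(const fcube& gy) override {
    const uword nblk = gy.n_elem / M;
    const double N = (double)nblk;
    arma::vec sg(M, arma::fill::zeros), sgx(M, arma::fill::zeros);
    const float* pg = gy.memptr();
    const float* ph = xhat.memptr();
    for (uword blk = 0; blk < nblk; ++blk) {
      const uword off = blk * M;
      for (uword m = 0; m < M; ++m) {
        sg(m) += pg[off + m];
        sgx(m) += (double)pg[off + m] * ph[off + m];
      }
    }
    fcube dx(arma::size(gy));
    float* pd = dx.memptr();
    for (uword m = 0; m < M; ++m) {
      dgamma(m, 0) = (float)sgx(m);
      dbeta(m, 0) = (float)sg(m);
    }
    for (uword blk = 0; blk < nblk; ++blk) {
      const uword off = blk * M;
      for (uword m = 0; m < M; ++m) {
        pd[off + m] = (gamma(m, 0) * invstd(m) / (float)N) *
                      ((float)N * pg[off + m] - (float)sg(m) -
                       ph[off + m] * (float)sgx(m));
      }
    }
    xhat.reset();
    return dx;
  }
  std::vector<fmat*> params() override { return {&gamma, &beta}; }
  std::vector<fmat*> grads() override { return {&dgamma, &dbeta}; }
  std::vector<fmat*> state_extra() override { return {&run_mean, &run_var}; }
  void drop_cache() override { xhat.reset(); }
};

// ---------------------------------------------------------------------------
// Batch normalization per feature map over (rows x time x batch).
struct BatchNorm : Layer {
  uword M, R;
  float eps, momentum;
  fmat gamma, beta, dgamma, dbeta;      // (M, 1)
  fmat run_mean, run_var;               // (M, 1)
  fcube xhat;
  fvec invstd;

  BatchNorm(uword M_, uword R_, float eps_ = 1e-3f, float mom_ = 0.99f)
      : M(M_), R(R_), eps(eps_), momentum(mom_) {
    gamma.ones(M, 1);
    beta.zeros(M, 1);
    dgamma.zeros(M, 1);
    dbeta.zeros(M, 1);
    run_mean.zeros(M, 1);
    run_var.ones(M, 1);
    invstd.zeros(M);
  }

  fcube forward(const fcube& x, bool train) override {
    fcube y(arma::size(x));
    const uword T = x.n_cols, B = x.n_slices;
    const double N = (double)R * T * B;
    if (train) xhat.set_size(arma::size(x));
    for (uword m = 0; m < M; ++m) {
      auto xv = x.subcube(m * R, 0, 0, m * R + R - 1, T - 1, B - 1);
      float mu, var;
      if (train) {
        mu = (float)(arma::accu(xv) / N);
        var = (float)(arma::accu(arma::square(xv - mu)) / N);
        run_mean(m, 0) = momentum * run_mean(m, 0) + (1 - momentum) * mu;
        run_var(m, 0) = momentum * run_var(m, 0) + (1 - momentum) * var;
      } else {
        mu = run_mean(m, 0);
        var = run_var(m, 0);
      }
      const float is = 1.0f / std::sqrt(var + eps);
      invstd(m) = is;
      if (train) {
        xhat.subcube(m * R, 0, 0, m * R + R - 1, T - 1, B - 1) = (xv - mu) * is;
        y.subcube(m * R, 0, 0, m * R + R - 1, T - 1, B - 1) =
            gamma(m, 0) * xhat.subcube(m * R, 0, 0, m * R + R - 1, T - 1, B - 1) +
            beta(m, 0);
      } else {
        y.subcube(m * R, 0, 0, m * R + R - 1, T - 1, B - 1) =
            gamma(m, 0) * ((xv - mu) * is) + beta(m, 0);
      }
    }
    return y;
  }
  fcube backward(const fcube& gy) override {
    const uword T = gy.n_cols, B = gy.n_slices;
    const double N = (double)R * T * B;
    fcube dx(arma::size(gy));
    for (uword m = 0; m < M; ++m) {
      auto gv = gy.subcube(m * R, 0, 0, m * R + R - 1, T - 1, B - 1);
      auto xh = xhat.subcube(m * R, 0, 0, m * R + R - 1, T - 1, B - 1);
      const double sg = arma::accu(gv);
      const double sgx = arma::accu(gv % xh);
      dgamma(m, 0) = (float)sgx;
      dbeta(m, 0) = (float)sg;
      dx.subcube(m * R, 0, 0, m * R + R - 1, T - 1, B - 1) =
          (gamma(m, 0) * invstd(m) / (float)N) *
          ((float)N * gv - (float)sg - xh * (float)sgx);
    }
    xhat.reset();
    return dx;
  }
  std::vector<fmat*> params() override { return {&gamma, &beta}; }
  std::vector<fmat*> grads() override { return {&dgamma, &dbeta}; }
  std::vector<fmat*> state_extra() override { return {&run_mean, &run_var}; }
  void drop_cache() override { xhat.reset(); }
};

// ---------------------------------------------------------------------------
struct Activation : Layer {
  enum Kind { ELU, SQUARE, LOG, LINEAR } kind;
  fcube x_cache;
  static constexpr float log_eps = 1e-6f;

  explicit Activation(Kind k) : kind(k) {}
  fcube forward(const fcube& x, bool train) override {
    if (train) x_cache = x;
    fcube y(arma::size(x));
    switch (kind) {
      case ELU:
        for (uword i = 0; i < x.n_elem; ++i)
          y(i) = x(i) > 0 ? x(i) : std::expm1(x(i));
        break;
      case SQUARE: y = arma::square(x); break;
      case LOG:
        for (uword i = 0; i < x.n_elem; ++i)
          y(i) = std::log(std::max(x(i), log_eps));
        break;
      case LINEAR: y = x; break;
    }
    return y;
  }
  fcube backward(const fcube& gy) override {
    fcube dx(arma::size(gy));
    switch (kind) {
      case ELU:
        for (uword i = 0; i < gy.n_elem; ++i)
          dx(i) = x_cache(i) > 0 ? gy(i) : gy(i) * std::exp(x_cache(i));
        break;
      case SQUARE: dx = 2.0f * (gy % x_cache); break;
      case LOG:
        for (uword i = 0; i < gy.n_elem; ++i)
          dx(i) = x_cache(i) > log_eps ? gy(i) / x_cache(i) : 0.0f;
        break;
      case LINEAR: dx = gy; break;
    }
    x_cache.reset();
    return dx;
  }
  void drop_cache() override { x_cache.reset(); }
};

// ---------------------------------------------------------------------------
// Pooling along time, per row. size P, stride S, no padding.
struct Pool : Layer {
  bool is_max;
  uword P, S, Tin, Tout;
  arma::ucube argmax;  // for max pooling

  Pool(bool mx, uword P_, uword S_) : is_max(mx), P(P_), S(S_) {}
  fcube forward(const fcube& x, bool train) override {
    Tin = x.n_cols;
    if (Tin < P) Rcpp::stop("pooling window longer than input");
    Tout = (Tin - P) / S + 1;
    const uword C = x.n_rows, B = x.n_slices;
    fcube y(C, Tout, B);
    if (is_max && train) argmax.set_size(C, Tout, B);
    for (uword s = 0; s < B; ++s) {
      for (uword j = 0; j < Tout; ++j) {
        for (uword c = 0; c < C; ++c) {
          if (is_max) {
            float best = x(c, j * S, s);
            uword bi = j * S;
            for (uword p = 1; p < P; ++p)
              if (x(c, j * S + p, s) > best) { best = x(c, j * S + p, s); bi = j * S + p; }
            y(c, j, s) = best;
            if (train) argmax(c, j, s) = bi;
          } else {
            float acc = 0;
            for (uword p = 0; p < P; ++p) acc += x(c, j * S + p, s);
            y(c, j, s) = acc / P;
          }
        }
      }
    }
    return y;
  }
  fcube backward(const fcube& gy) override {
    const uword C = gy.n_rows, B = gy.n_slices;
    fcube dx(C, Tin, B, arma::fill::zeros);
    for (uword s = 0; s < B; ++s)
      for (uword j = 0; j < Tout; ++j)
        for (uword c = 0; c < C; ++c) {
          if (is_max) {
            dx(c, argmax(c, j, s), s) += gy(c, j, s);
          } else {
            const float g = gy(c, j, s) / P;
            for (uword p = 0; p < P; ++p) dx(c, j * S + p, s) += g;
          }
        }
    argmax.reset();
    return dx;
  }
  void drop_cache() override { argmax.reset(); }
};

// ---------------------------------------------------------------------------
struct Dropout : Layer {
  float p;
  Rng* rng;
  fcube mask;
  explicit Dropout(float p_, Rng* rng_) : p(p_), rng(rng_) {}
  fcube forward(const fcube& x, bool train) override {
    if (!train || p <= 0) return x;
    std::uniform_real_distribution<float> u(0.0f, 1.0f);
    mask.set_size(arma::size(x));
    const float scale = 1.0f / (1.0f - p);
    for (uword i = 0; i < mask.n_elem; ++i)
      mask(i) = u(*rng) < p ? 0.0f : scale;
    return x % mask;
  }
  fcube backward(const fcube& gy) override {
    if (p <= 0 || mask.n_elem == 0) return gy;
    fcube dx = gy % mask;
    mask.reset();
    return dx;
  }
  void drop_cache() override { mask.reset(); }
};

// ---------------------------------------------------------------------------
// Heads map the final feature cube to one scalar per window.
struct Head {
  virtual ~Head() {}
  virtual frowvec forward(const fcube& x, bool train) = 0;
  virtual fcube backward(const frowvec& dpred) = 0;
  virtual std::vector<fmat*> params() = 0;
  virtual std::vector<fmat*> grads() = 0;
  virtual void init(Rng&) = 0;
  virtual void drop_cache() {}
};

struct DenseHead : Head {
  uword C, T;
  fmat W, b, dW, db;  // W: (1, C*T)
  fcube x_cache;
  DenseHead(uword C_, uword T_) : C(C_), T(T_) {
    W.set_size(1, C * T);
    b.zeros(1, 1);
    dW.zeros(1, C * T);
    db.zeros(1, 1);
  }
  void init(Rng& rng) override { glorot_fill(W, (double)C * T, 1.0, rng); }
  frowvec forward(const fcube& x, bool train) override {
    fmat xm = flat_ctb(x);
    frowvec out = W * xm + b(0, 0);
    if (train) x_cache = x;
    return out;
  }
  fcube backward(const frowvec& dpred) override {
    fmat xm = flat_ctb(x_cache);
    dW = dpred * xm.t();
    db(0, 0) = arma::accu(dpred);
    fcube dx(C, T, x_cache.n_slices);
    fmat dxm = flat_ctb(dx);
    dxm = W.t() * dpred;
    x_cache.reset();
    return dx;
  }
  std::vector<fmat*> params() override { return {&W, &b}; }
  std::vector<fmat*> grads() override { return {&dW, &db}; }
  void drop_cache() override { x_cache.reset(); }
};

// One LSTM layer; gate order in the stacked weight matrices is (i, f, g, o).
struct LstmCell {
  uword Fin, U;
  fmat Wx, Wh, b;     // (4U, Fin), (4U, U), (4U, 1)
  fmat dWx, dWh, db;
  // caches per step
  std::vector<fmat> xs, is, fs, gs, os, cs, hcs, hs;

  LstmCell(uword Fin_, uword U_) : Fin(Fin_), U(U_) {
    Wx.set_size(4 * U, Fin);
    Wh.set_size(4 * U, U);
    b.zeros(4 * U, 1);
    dWx.zeros(4 * U, Fin);
    dWh.zeros(4 * U, U);
    db.zeros(4 * U, 1);
  }
  void init(Rng& rng) {
    glorot_fill(Wx, (double)Fin, 4.0 * U, rng);
    glorot_fill(Wh, (double)U, 4.0 * U, rng);
    b.zeros();
    b.rows(U, 2 * U - 1).fill(1.0f);  // forget-gate bias
  }
  static fmat sigm(const fmat& z) { return 1.0f / (1.0f + arma::exp(-z)); }

  // xseq: vector of (Fin, B); returns all h states (U, B) per step.
  std::vector<fmat> forward(const std::vector<fmat>& xseq, uword B, bool train) {
    fmat h(U, B, arma::fill::zeros), c(U, B, arma::fill::zeros);
    std::vector<fmat> hs_out;
    if (train) { xs.clear(); is.clear(); fs.clear(); gs.clear(); os.clear();
                 cs.clear(); hcs.clear(); hs.clear(); }
    for (const fmat& x : xseq) {
      fmat z = Wx * x + Wh * h;
      z.each_col() += b.col(0);
      fmat ig = sigm(z.rows(0, U - 1));
      fmat fg = sigm(z.rows(U, 2 * U - 1));
      fmat gg = arma::tanh(z.rows(2 * U, 3 * U - 1));
      fmat og = sigm(z.rows(3 * U, 4 * U - 1));
      fmat c_prev = c;
      c = fg % c + ig % gg;
      fmat hc = arma::tanh(c);
      fmat h_new = og % hc;
      if (train) {
        xs.push_back(x); is.push_back(ig); fs.push_back(fg); gs.push_back(gg);
        os.push_back(og); cs.push_back(c_prev); hcs.push_back(hc); hs.push_back(h);
      }
      h = h_new;
      hs_out.push_back(h);
    }
    return hs_out;
  }

  // dh_seq: per-step external gradient on h (may be zero except last step).
  // Returns per-step gradients on x.
  std::vector<fmat> backward(const std::vector<fmat>& dh_seq, uword B) {
    const uword Tn = dh_seq.size();
    dWx.zeros(); dWh.zeros(); db.zeros();
    fmat dh(U, B, arma::fill::zeros), dc(U, B, arma::fill::zeros);
    std::vector<fmat> dxs(Tn);
    for (uword tt = Tn; tt-- > 0;) {
      dh += dh_seq[tt];
      fmat d_o = dh % hcs[tt];
      dc += dh % os[tt] % (1.0f - arma::square(hcs[tt]));
      fmat d_i = dc % gs[tt];
      fmat d_g = dc % is[tt];
      fmat d_f = dc % cs[tt];
      fmat dc_prev = dc % fs[tt];
      fmat dz(4 * U, B);
      dz.rows(0, U - 1) = d_i % is[tt] % (1.0f - is[tt]);
      dz.rows(U, 2 * U - 1) = d_f % fs[tt] % (1.0f - fs[tt]);
      dz.rows(2 * U, 3 * U - 1) = d_g % (1.0f - arma::square(gs[tt]));
      dz.rows(3 * U, 4 * U - 1) = d_o % os[tt] % (1.0f - os[tt]);
      dWx += dz * xs[tt].t();
      dWh += dz * hs[tt].t();
      db += arma::sum(dz, 1);
      dxs[tt] = Wx.t() * dz;
      dh = Wh.t() * dz;
      dc = dc_prev;
    }
    xs.clear(); is.clear(); fs.clear(); gs.clear(); os.clear();
    cs.clear(); hcs.clear(); hs.clear();
    return dxs;
  }
  void drop_cache() {
    xs.clear(); is.clear(); fs.clear(); gs.clear(); os.clear();
    cs.clear(); hcs.clear(); hs.clear();
  }
};

// Two stacked LSTM layers (first returns the full sequence, second its final
// state) followed by a single linear unit; dropout between the LSTM layers.
struct LstmHead : Head {
  uword Fin, Tn, U;
  float drop_p;
  Rng* rng;
  LstmCell l1, l2;
  fmat Wd, bd, dWd, dbd;  // dense: (1, U)
  std::vector<fmat> h1_cache, h2_cache, drop_masks;
  uword B_cache;

  LstmHead(uword Fin_, uword Tn_, uword U_, float p, Rng* rng_)
      : Fin(Fin_), Tn(Tn_), U(U_), drop_p(p), rng(rng_), l1(Fin_, U_), l2(U_, U_) {
    Wd.set_size(1, U);
    bd.zeros(1, 1);
    dWd.zeros(1, U);
    dbd.zeros(1, 1);
  }
  void init(Rng& r) override {
    l1.init(r);
    l2.init(r);
    glorot_fill(Wd, (double)U, 1.0, r);
  }
  frowvec forward(const fcube& x, bool train) override {
    const uword B = x.n_slices;
    B_cache = B;
    std::vector<fmat> xseq(Tn);
    for (uword t = 0; t < Tn; ++t) {
      fmat xt(Fin, B);
      for (uword s = 0; s < B; ++s)
        std::memcpy(xt.colptr(s), x.slice_memptr(s) + t * Fin,
                    sizeof(float) * Fin);
      xseq[t] = std::move(xt);
    }
    std::vector<fmat> h1 = l1.forward(xseq, B, train);
    if (train && drop_p > 0) {
      std::uniform_real_distribution<float> u(0.0f, 1.0f);
      const float scale = 1.0f / (1.0f - drop_p);
      drop_masks.assign(Tn, fmat());
      for (uword t = 0; t < Tn; ++t) {
        fmat m(U, B);
        for (uword i = 0; i < m.n_elem; ++i) m(i) = u(*rng) < drop_p ? 0.0f : scale;
        drop_masks[t] = m;
        h1[t] = h1[t] % m;
      }
    }
    std::vector<fmat> h2 = l2.forward(h1, B, train);
    if (train) { h1_cache = h1; h2_cache = h2; }
    frowvec out = Wd * h2.back() + bd(0, 0);
    return out;
  }
  fcube backward(const frowvec& dpred) override {
    const uword B = B_cache;
    dWd = dpred * h2_cache.back().t();
    dbd(0, 0) = arma::accu(dpred);
    std::vector<fmat> dh2(Tn, fmat(U, B, arma::fill::zeros));
    dh2[Tn - 1] = Wd.t() * dpred;
    std::vector<fmat> dh1 = l2.backward(dh2, B);
    if (drop_p > 0 && !drop_masks.empty())
      for (uword t = 0; t < Tn; ++t) dh1[t] = dh1[t] % drop_masks[t];
    std::vector<fmat> dx = l1.backward(dh1, B);
    fcube g(Fin, Tn, B);
    for (uword t = 0; t < Tn; ++t)
      for (uword s = 0; s < B; ++s)
        std::memcpy(g.slice_memptr(s) + t * Fin, dx[t].colptr(s),
                    sizeof(float) * Fin);
    h1_cache.clear(); h2_cache.clear(); drop_masks.clear();
    return g;
  }
  std::vector<fmat*> params() override {
    return {&l1.Wx, &l1.Wh, &l1.b, &l2.Wx, &l2.Wh, &l2.b, &Wd, &bd};
  }
  std::vector<fmat*> grads() override {
    return {&l1.dWx, &l1.dWh, &l1.db, &l2.dWx, &l2.dWh, &l2.db, &dWd, &dbd};
  }
  void drop_cache() override {
    l1.drop_cache(); l2.drop_cache();
    h1_cache.clear(); h2_cache.clear(); drop_masks.clear();
  }
};

// ---------------------------------------------------------------------------
struct Network {
  std::vector<std::unique_ptr<Layer>> layers;
  std::unique_ptr<Head> head;
  Rng rng;
  // Adam state
  std::vector<fmat> adam_m, adam_v;
  long adam_t = 0;
  float beta1 = 0.9f, beta2 = 0.999f, adam_eps = 1e-7f;

  std::vector<fmat*> all_params() {
    std::vector<fmat*> ps;
    for (auto& l : layers)
      for (fmat* p : l->params()) ps.push_back(p);
    for (fmat* p : head->params()) ps.push_back(p);
    return ps;
  }
  std::vector<fmat*> all_grads() {
    std::vector<fmat*> gs;
    for (auto& l : layers)
      for (fmat* g : l->grads()) gs.push_back(g);
    for (fmat* g : head->grads()) gs.push_back(g);
    return gs;
  }
  std::vector<fmat*> all_state() {
    std::vector<fmat*> ss = all_params();
    for (auto& l : layers)
      for (fmat* s : l->state_extra()) ss.push_back(s);
    return ss;
  }

  frowvec forward(const fcube& x, bool train) {
    fcube cur = x;
    for (auto& l : layers) cur = l->forward(cur, train);
    return head->forward(cur, train);
  }
  // mean squared error + backprop; returns loss
  double backprop(const fcube& x, const frowvec& y) {
    frowvec pred = forward(x, true);
    frowvec err = pred - y;
    const double loss = arma::accu(arma::square(err)) / (double)y.n_elem;
    frowvec dpred = (2.0f / (float)y.n_elem) * err;
    fcube g = head->backward(dpred);
    for (auto it = layers.rbegin(); it != layers.rend(); ++it)
      g = (*it)->backward(g);
    return loss;
  }
  void adam_step(float lr) {
    std::vector<fmat*> ps = all_params();
    std::vector<fmat*> gs = all_grads();
    if (adam_m.empty()) {
      for (fmat* p : ps) {
        adam_m.emplace_back(arma::size(*p), arma::fill::zeros);
        adam_v.emplace_back(arma::size(*p), arma::fill::zeros);
      }
    }
    ++adam_t;
    const float bc1 = 1.0f - std::pow(beta1, (float)adam_t);
    const float bc2 = 1.0f - std::pow(beta2, (float)adam_t);
    for (size_t i = 0; i < ps.size(); ++i) {
      adam_m[i] = beta1 * adam_m[i] + (1 - beta1) * (*gs[i]);
      adam_v[i] = beta2 * adam_v[i] + (1 - beta2) * arma::square(*gs[i]);
      *ps[i] -= lr * (adam_m[i] / bc1) / (arma::sqrt(adam_v[i] / bc2) + adam_eps);
    }
  }
  void drop_caches() {
    for (auto& l : layers) l->drop_cache();
    head->drop_cache();
  }
};

Activation::Kind act_kind(const std::string& s) {
  if (s == "elu") return Activation::ELU;
  if (s == "square") return Activation::SQUARE;
  if (s == "log") return Activation::LOG;
  if (s == "linear") return Activation::LINEAR;
  Rcpp::stop("unknown activation: " + s);
}

fcube r_to_fcube(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector dims = x.attr("dim");
  if (dims.size() != 3) Rcpp::stop("input must be a 3-d array (C, T, B)");
  fcube out(dims[0], dims[1], dims[2]);
  const double* src = x.begin();
  for (uword i = 0; i < out.n_elem; ++i) out(i) = (float)src[i];
  return out;
}

}  // namespace

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP nn_create(Rcpp::List layer_specs, int seed) {
  std::unique_ptr<Network> net(new Network());
  net->rng.seed((unsigned)seed);
  auto u = [](Rcpp::List& l, const char* nm) {
    return (uword)Rcpp::as<int>(l[nm]);
  };
  for (R_xlen_t i = 0; i < layer_specs.size(); ++i) {
    Rcpp::List sp = layer_specs[i];
    std::string type = Rcpp::as<std::string>(sp["type"]);
    if (type == "conv_t") {
      if (u(sp, "rows") > 1) {
        if (u(sp, "maps_in") != 1)
          Rcpp::stop("multi-row temporal conv requires a single input map");
        net->layers.emplace_back(new TemporalConvInterleaved(
            u(sp, "rows"), u(sp, "maps_out"), u(sp, "k"), u(sp, "lpad"),
            u(sp, "rpad"), Rcpp::as<bool>(sp["bias"])));
      } else {
        net->layers.emplace_back(new TemporalConv(
            u(sp, "maps_in"), u(sp, "rows"), u(sp, "maps_out"), u(sp, "k"),
            u(sp, "lpad"), u(sp, "rpad"), Rcpp::as<bool>(sp["bias"])));
      }
    } else if (type == "conv_dw_t") {
      net->layers.emplace_back(new DepthwiseTemporalConv(
          u(sp, "maps"), u(sp, "k"), u(sp, "lpad"), u(sp, "rpad")));
    } else if (type == "conv_s") {
      net->layers.emplace_back(new SpatialConv(
          u(sp, "c_in"), u(sp, "maps_out"), Rcpp::as<bool>(sp["bias"])));
    } else if (type == "conv_dw_s") {
      net->layers.emplace_back(new DepthwiseSpatialConv(
          u(sp, "maps"), u(sp, "rows"), u(sp, "mult")));
    } else if (type == "bn") {
      if (u(sp, "rows") > 1) {
        net->layers.emplace_back(
            new BatchNormInterleaved(u(sp, "maps"), u(sp, "rows")));
      } else {
        net->layers.emplace_back(new BatchNorm(u(sp, "maps"), u(sp, "rows")));
      }
    } else if (type == "act") {
      net->layers.emplace_back(
          new Activation(act_kind(Rcpp::as<std::string>(sp["fun"]))));
    } else if (type == "pool") {
      net->layers.emplace_back(new Pool(
          Rcpp::as<std::string>(sp["fun"]) == "max", u(sp, "p"), u(sp, "s")));
    } else if (type == "dropout") {
      net->layers.emplace_back(
          new Dropout((float)Rcpp::as<double>(sp["p"]), &net->rng));
    } else if (type == "dense_head") {
      net->head.reset(new DenseHead(u(sp, "c_in"), u(sp, "t_in")));
    } else if (type == "lstm_head") {
      net->head.reset(new LstmHead(u(sp, "c_in"), u(sp, "t_in"),
                                   u(sp, "units"),
                                   (float)Rcpp::as<double>(sp["dropout"]),
                                   &net->rng));
    } else {
      Rcpp::stop("unknown layer type: " + type);
    }
  }
  if (!net->head) Rcpp::stop("network has no head layer");
  for (auto& l : net->layers) l->init(net->rng);
  net->head->init(net->rng);
  Rcpp::XPtr<Network> ptr(net.release(), true);
  return ptr;
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_predict(SEXP net_ptr, Rcpp::NumericVector x) {
  Rcpp::XPtr<Network> net(net_ptr);
  frowvec pred = net->forward(r_to_fcube(x), false);
  return Rcpp::NumericVector(pred.begin(), pred.end());
}

// [[Rcpp::export]]
double nn_train_batch(SEXP net_ptr, Rcpp::NumericVector x,
                      Rcpp::NumericVector y, double lr) {
  Rcpp::XPtr<Network> net(net_ptr);
  fcube xc = r_to_fcube(x);
  frowvec yv(y.size());
  for (R_xlen_t i = 0; i < y.size(); ++i) yv(i) = (float)y[i];
  const double loss = net->backprop(xc, yv);
  net->adam_step((float)lr);
  net->drop_caches();
  return loss;
}

// [[Rcpp::export]]
double nn_eval_loss(SEXP net_ptr, Rcpp::NumericVector x, Rcpp::NumericVector y) {
  Rcpp::XPtr<Network> net(net_ptr);
  frowvec pred = net->forward(r_to_fcube(x), false);
  double acc = 0;
  for (R_xlen_t i = 0; i < y.size(); ++i) {
    const double e = (double)pred(i) - y[i];
    acc += e * e;
  }
  return acc / y.size();
}

// [[Rcpp::export]]
Rcpp::List nn_loss_grad(SEXP net_ptr, Rcpp::NumericVector x,
                        Rcpp::NumericVector y) {
  Rcpp::XPtr<Network> net(net_ptr);
  fcube xc = r_to_fcube(x);
  frowvec yv(y.size());
  for (R_xlen_t i = 0; i < y.size(); ++i) yv(i) = (float)y[i];
  const double loss = net->backprop(xc, yv);
  std::vector<fmat*> gs = net->all_grads();
  size_t n = 0;
  for (fmat* g : gs) n += g->n_elem;
  Rcpp::NumericVector out((R_xlen_t)n);
  size_t off = 0;
  for (fmat* g : gs) {
    for (uword i = 0; i < g->n_elem; ++i) out[off + i] = (*g)(i);
    off += g->n_elem;
  }
  net->drop_caches();
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = out);
}

// Train-mode loss without any parameter update (for finite-difference checks;
// dropout layers must have p = 0 for this to be deterministic).
// [[Rcpp::export]]
double nn_train_loss(SEXP net_ptr, Rcpp::NumericVector x,
                     Rcpp::NumericVector y) {
  Rcpp::XPtr<Network> net(net_ptr);
  frowvec pred = net->forward(r_to_fcube(x), true);
  net->drop_caches();
  double acc = 0;
  for (R_xlen_t i = 0; i < y.size(); ++i) {
    const double e = (double)pred(i) - y[i];
    acc += e * e;
  }
  return acc / y.size();
}

// [[Rcpp::export]]
int nn_num_params(SEXP net_ptr) {
  Rcpp::XPtr<Network> net(net_ptr);
  size_t n = 0;
  for (fmat* p : net->all_params()) n += p->n_elem;
  return (int)n;
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_get_state(SEXP net_ptr) {
  Rcpp::XPtr<Network> net(net_ptr);
  std::vector<fmat*> ss = net->all_state();
  size_t n = 0;
  for (fmat* s : ss) n += s->n_elem;
  Rcpp::NumericVector out((R_xlen_t)n);
  size_t off = 0;
  for (fmat* s : ss) {
    for (uword i = 0; i < s->n_elem; ++i) out[off + i] = (*s)(i);
    off += s->n_elem;
  }
  return out;
}

// [[Rcpp::export]]
void nn_set_state(SEXP net_ptr, Rcpp::NumericVector state) {
  Rcpp::XPtr<Network> net(net_ptr);
  std::vector<fmat*> ss = net->all_state();
  size_t n = 0;
  for (fmat* s : ss) n += s->n_elem;
  if ((size_t)state.size() != n) Rcpp::stop("state vector has wrong length");
  size_t off = 0;
  for (fmat* s : ss) {
    for (uword i = 0; i < s->n_elem; ++i) (*s)(i) = (float)state[off + i];
    off += s->n_elem;
  }
}

// Overwrite a single parameter entry (finite-difference tests).
// [[Rcpp::export]]
void nn_poke_param(SEXP net_ptr, int index, double value) {
  Rcpp::XPtr<Network> net(net_ptr);
  std::vector<fmat*> ps = net->all_params();
  size_t off = 0;
  for (fmat* p : ps) {
    if ((size_t)index < off + p->n_elem) {
      (*p)((uword)(index - off)) = (float)value;
      return;
    }
    off += p->n_elem;
  }
  Rcpp::stop("parameter index out of range");
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_get_params(SEXP net_ptr) {
  Rcpp::XPtr<Network> net(net_ptr);
  std::vector<fmat*> ps = net->all_params();
  size_t n = 0;
  for (fmat* p : ps) n += p->n_elem;
  Rcpp::NumericVector out((R_xlen_t)n);
  size_t off = 0;
  for (fmat* p : ps) {
    for (uword i = 0; i < p->n_elem; ++i) out[off + i] = (*p)(i);
    off += p->n_elem;
  }
  return out;
}
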