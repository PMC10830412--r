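// 1D convolutional network engine for sequence-to-accessibility /
// sequence-to-activity models.
//
// Layout conventions:
//  * A batch of B sequences of length L with C channels is a matrix
//    (C x L*B); sample s occupies columns [s*L, (s+1)*L).
//  * Convolutions are im2col + gemm with zero "same" padding (odd kernels);
//    the first convolution has a fast gather/scatter path for one-hot
//    (integer-coded) input that skips materializing the im2col matrix.
//  * Max-pooling is size 3 / stride 3 / valid (trailing remainder dropped).
//  * Batch norm follows Keras conventions (eps 1e-3, biased batch variance,
//    running stats at inference) with momentum 0.9 so the running statistics
//    converge within desk-scale step counts.
//  * Dropout is inverted dropout on the dense activations, training only.
//  * Arithmetic is single precision internally (converted at the R
//    boundary); accumulations that feed losses/metrics return doubles.
//
// All randomness (shuffling, dropout masks) flows from one std::mt19937 so a
// fixed seed reproduces training exactly; matrix products go through the
// BLAS that R is linked against.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

typedef float real;
typedef arma::Mat<real> FMat;
typedef arma::Col<real> FVec;
typedef arma::Row<real> FRow;

static const real BN_EPS = 1e-3f;
static const real BN_MOMENTUM = 0.9f;

static FMat r_to_f(SEXP x) { return arma::conv_to<FMat>::from(as<arma::mat>(x)); }
static FVec r_to_fv(SEXP x) { return arma::conv_to<FVec>::from(as<arma::vec>(x)); }

struct ConvLayer {
  FMat W;       // F x (Cin*k)
  FVec b;       // F
  FVec gamma, beta, rmean, rvar;
  int k;
};

struct DenseLayer {
  FMat W;       // units x in
  FVec b;
  FVec gamma, beta, rmean, rvar;
};

struct Net {
  std::vector<ConvLayer> conv;
  std::vector<DenseLayer> dense;
  FMat headW;   // 1 x in
  real headb;
  bool sigmoid_head;
  int input_length;
  real dropout;
  int pool = 3;
};

static Net net_from_r(const List& params, const List& arch) {
  Net net;
  net.input_length = as<int>(arch["input_length"]);
  net.sigmoid_head = as<std::string>(arch["head"]) == "sigmoid";
  net.dropout = (real)as<double>(arch["dropout"]);
  IntegerVector widths = arch["conv_widths"];
  List conv = params["conv"];
  for (int i = 0; i < conv.size(); ++i) {
    List ly = conv[i];
    ConvLayer c;
    c.W = r_to_f(ly["W"]);
    c.b = r_to_fv(ly["b"]);
    c.gamma = r_to_fv(ly["gamma"]);
    c.beta = r_to_fv(ly["beta"]);
    c.rmean = r_to_fv(ly["rmean"]);
    c.rvar = r_to_fv(ly["rvar"]);
    c.k = widths[i];
    net.conv.push_back(std::move(c));
  }
  List dense = params["dense"];
  for (int i = 0; i < dense.size(); ++i) {
    List ly = dense[i];
    DenseLayer d;
    d.W = r_to_f(ly["W"]);
    d.b = r_to_fv(ly["b"]);
    d.gamma = r_to_fv(ly["gamma"]);
    d.beta = r_to_fv(ly["beta"]);
    d.rmean = r_to_fv(ly["rmean"]);
    d.rvar = r_to_fv(ly["rvar"]);
    net.dense.push_back(std::move(d));
  }
  List head = params["head"];
  net.headW = r_to_f(head["W"]);
  net.headb = (real)as<arma::vec>(head["b"])(0);
  return net;
}

static SEXP f_to_r(const FMat& m) { return wrap(arma::conv_to<arma::mat>::from(m)); }
static SEXP fv_to_r(const FVec& v) { return wrap(arma::conv_to<arma::vec>::from(v)); }

static List net_to_r(const Net& net) {
  List conv(net.conv.size());
  for (size_t i = 0; i < net.conv.size(); ++i) {
    const ConvLayer& c = net.conv[i];
    conv[i] = List::create(_["W"] = f_to_r(c.W), _["b"] = fv_to_r(c.b),
                           _["gamma"] = fv_to_r(c.gamma),
                           _["beta"] = fv_to_r(c.beta),
                           _["rmean"] = fv_to_r(c.rmean),
                           _["rvar"] = fv_to_r(c.rvar));
  }
  List dense(net.dense.size());
  for (size_t i = 0; i < net.dense.size(); ++i) {
    const DenseLayer& d = net.dense[i];
    dense[i] = List::create(_["W"] = f_to_r(d.W), _["b"] = fv_to_r(d.b),
                            _["gamma"] = fv_to_r(d.gamma),
                            _["beta"] = fv_to_r(d.beta),
                            _["rmean"] = fv_to_r(d.rmean),
                            _["rvar"] = fv_to_r(d.rvar));
  }
  arma::vec hb(1); hb(0) = net.headb;
  return List::create(_["conv"] = conv, _["dense"] = dense,
                      _["head"] = List::create(_["W"] = f_to_r(net.headW),
                                               _["b"] = hb));
}

// ---- primitive ops ---------------------------------------------------------

// X: (C x L*B) -> (C*k x L*B), zero same-padding
static FMat im2col(const FMat& X, int L, int B, int k) {
  int C = X.n_rows;
  int pad = k / 2;
  FMat out(C * k, (size_t)L * B, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    size_t off = (size_t)s * L;
    for (int t = 0; t < k; ++t) {
      int shift = t - pad;  // input position = output position + shift
      int lo = std::max(0, -shift), hi = std::min(L, L - shift);
      if (lo >= hi) continue;
      out.submat(t * C, off + lo, (t + 1) * C - 1, off + hi - 1) =
        X.cols(off + lo + shift, off + hi - 1 + shift);
    }
  }
  return out;
}

// scatter-add transpose of im2col: G (C*k x L*B) -> (C x L*B)
static FMat col2im(const FMat& G, int L, int B, int k, int C) {
  int pad = k / 2;
  FMat out(C, (size_t)L * B, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    size_t off = (size_t)s * L;
    for (int t = 0; t < k; ++t) {
      int shift = t - pad;
      int lo = std::max(0, -shift), hi = std::min(L, L - shift);
      if (lo >= hi) continue;
      out.cols(off + lo + shift, off + hi - 1 + shift) +=
        G.submat(t * C, off + lo, (t + 1) * C - 1, off + hi - 1);
    }
  }
  return out;
}

// first-conv fast path on integer-coded one-hot input: Y[f, j] =
// b[f] + sum_t W[f, base(j+t-pad)*...]; a zero code (N or padding)
// contributes nothing.
static FMat conv1_forward_codes(const ConvLayer& c, const IntegerMatrix& codes,
                                const arma::uvec& idx) {
  int L = codes.nrow(), B = idx.n_elem, k = c.k, F = c.W.n_rows, pad = k / 2;
  FMat Y(F, (size_t)L * B);
  Y.each_col() = c.b;
  for (int s = 0; s < B; ++s) {
    int col0 = idx(s);
    size_t off = (size_t)s * L;
    const int* cd = &codes(0, col0);
    for (int l = 0; l < L; ++l) {
      int base = cd[l];
      if (base == 0) continue;
      // input position l feeds outputs j = l - (t - pad), t = 0..k-1
      int jlo = std::max(0, l - (k - 1) + pad), jhi = std::min(L - 1, l + pad);
      for (int j = jlo; j <= jhi; ++j) {
        int t = l - j + pad;
        const real* w = c.W.colptr((size_t)t * 4 + (base - 1));
        real* y = Y.colptr(off + j);
        for (int f = 0; f < F; ++f) y[f] += w[f];
      }
    }
  }
  return Y;
}

// matching backward: accumulate dW from dPre without the im2col matrix
static void conv1_backward_codes(const ConvLayer& c, const FMat& dPre,
                                 const IntegerMatrix& codes,
                                 const arma::uvec& idx, FMat& dW, FVec& db) {
  int L = codes.nrow(), B = idx.n_elem, k = c.k, F = c.W.n_rows, pad = k / 2;
  dW.zeros(c.W.n_rows, c.W.n_cols);
  db = arma::sum(dPre, 1);
  for (int s = 0; s < B; ++s) {
    int col0 = idx(s);
    size_t off = (size_t)s * L;
    const int* cd = &codes(0, col0);
    for (int l = 0; l < L; ++l) {
      int base = cd[l];
      if (base == 0) continue;
      int jlo = std::max(0, l - (k - 1) + pad), jhi = std::min(L - 1, l + pad);
      for (int j = jlo; j <= jhi; ++j) {
        int t = l - j + pad;
        real* w = dW.colptr((size_t)t * 4 + (base - 1));
        const real* g = dPre.colptr(off + j);
        for (int f = 0; f < F; ++f) w[f] += g[f];
      }
    }
  }
}

// max-pool size/stride `pool`, valid; records argmax column for backward
static FMat maxpool(const FMat& X, int L, int B, int pool,
                    arma::umat* argmax) {
  int Lp = L / pool;
  int C = X.n_rows;
  FMat out(C, (size_t)Lp * B);
  if (argmax) argmax->set_size(C, (size_t)Lp * B);
  for (int s = 0; s < B; ++s) {
    size_t offi = (size_t)s * L, offo = (size_t)s * Lp;
    for (int j = 0; j < Lp; ++j) {
      size_t base = offi + (size_t)j * pool;
      real* o = out.colptr(offo + j);
      const real* x0 = X.colptr(base);
      for (int cc = 0; cc < C; ++cc) o[cc] = x0[cc];
      arma::uword* am = argmax ? argmax->colptr(offo + j) : nullptr;
      if (am) for (int cc = 0; cc < C; ++cc) am[cc] = base;
      for (int t = 1; t < pool; ++t) {
        const real* xt = X.colptr(base + t);
        for (int cc = 0; cc < C; ++cc) {
          if (xt[cc] > o[cc]) {
            o[cc] = xt[cc];
            if (am) am[cc] = base + t;
          }
        }
      }
    }
  }
  return out;
}

static FMat maxpool_backward(const FMat& dY, const arma::umat& argmax,
                             int C, size_t ncol_in) {
  FMat dX(C, ncol_in, arma::fill::zeros);
  for (size_t j = 0; j < dY.n_cols; ++j) {
    const real* g = dY.colptr(j);
    const arma::uword* am = argmax.colptr(j);
    for (int cc = 0; cc < C; ++cc) dX(cc, am[cc]) += g[cc];
  }
  return dX;
}

struct BNCache {
  FVec invstd;
  FMat xhat;
};

// batch norm across columns, per row, fused loops; training mode updates
// running stats; output overwrites X
static void bn_forward(FMat& X, ConvLayer* cl, DenseLayer* dl, bool training,
                       BNCache* cache) {
  FVec& gamma = cl ? cl->gamma : dl->gamma;
  FVec& beta = cl ? cl->beta : dl->beta;
  FVec& rmean = cl ? cl->rmean : dl->rmean;
  FVec& rvar = cl ? cl->rvar : dl->rvar;
  int C = X.n_rows;
  size_t M = X.n_cols;
  FVec mu(C), invstd(C);
  if (training) {
    // double accumulators: single-pass moments over up to ~1e5 columns
    std::vector<double> s1(C, 0.0), s2(C, 0.0);
    for (size_t j = 0; j < M; ++j) {
      const real* x = X.colptr(j);
      for (int c = 0; c < C; ++c) { s1[c] += x[c]; s2[c] += (double)x[c] * x[c]; }
    }
    for (int c = 0; c < C; ++c) {
      double m = s1[c] / M;
      double v = s2[c] / M - m * m;
      if (v < 0) v = 0;
      mu[c] = (real)m;
      invstd[c] = 1.0f / std::sqrt((real)v + BN_EPS);
      rmean[c] = BN_MOMENTUM * rmean[c] + (1 - BN_MOMENTUM) * (real)m;
      rvar[c] = BN_MOMENTUM * rvar[c] + (1 - BN_MOMENTUM) * (real)v;
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rmean[c];
      invstd[c] = 1.0f / std::sqrt(rvar[c] + BN_EPS);
    }
  }
  if (cache) {
    cache->invstd = invstd;
    cache->xhat.set_size(C, M);
  }
  for (size_t j = 0; j < M; ++j) {
    real* x = X.colptr(j);
    real* xh = cache ? cache->xhat.colptr(j) : nullptr;
    for (int c = 0; c < C; ++c) {
      real h = (x[c] - mu[c]) * invstd[c];
      if (xh) xh[c] = h;
      x[c] = gamma[c] * h + beta[c];
    }
  }
}

// backward through training-mode batch norm (fused)
static FMat bn_backward(const FMat& dY, const BNCache& cache,
                        const FVec& gamma, FVec& dgamma, FVec& dbeta) {
  int C = dY.n_rows;
  size_t M = dY.n_cols;
  std::vector<double> sg(C, 0.0), sb(C, 0.0);
  for (size_t j = 0; j < M; ++j) {
    const real* g = dY.colptr(j);
    const real* xh = cache.xhat.colptr(j);
    for (int c = 0; c < C; ++c) {
      sg[c] += (double)g[c] * xh[c];
      sb[c] += g[c];
    }
  }
  dgamma.set_size(C); dbeta.set_size(C);
  for (int c = 0; c < C; ++c) { dgamma[c] = (real)sg[c]; dbeta[c] = (real)sb[c]; }
  FMat dX(C, M);
  FVec a(C), b(C), scale(C);
  for (int c = 0; c < C; ++c) {
    a[c] = dbeta[c] / M;       // mean of dxhat/gamma terms
    b[c] = dgamma[c] / M;
    scale[c] = gamma[c] * cache.invstd[c];
  }
  for (size_t j = 0; j < M; ++j) {
    const real* g = dY.colptr(j);
    const real* xh = cache.xhat.colptr(j);
    real* o = dX.colptr(j);
    for (int c = 0; c < C; ++c)
      o[c] = scale[c] * (g[c] - a[c] - xh[c] * b[c]);
  }
  return dX;
}

// backward through inference-mode batch norm (fixed affine map)
static FMat bn_backward_inference(const FMat& dY, const FVec& gamma,
                                  const FVec& invstd) {
  FMat dX = dY;
  int C = dY.n_rows;
  for (size_t j = 0; j < dX.n_cols; ++j) {
    real* o = dX.colptr(j);
    for (int c = 0; c < C; ++c) o[c] *= gamma[c] * invstd[c];
  }
  return dX;
}

static inline void relu_inplace(FMat& X) {
  real* p = X.memptr();
  for (size_t i = 0; i < X.n_elem; ++i) if (p[i] < 0) p[i] = 0;
}

// multiply gradient by the ReLU derivative; the pre-ReLU activation is
// reconstructed from the cached normalized values as gamma*xhat + beta
static inline void relu_backward_bn(FMat& dY, const FMat& xhat,
                                    const FVec& gamma, const FVec& beta) {
  int C = dY.n_rows;
  for (size_t j = 0; j < dY.n_cols; ++j) {
    real* g = dY.colptr(j);
    const real* xh = xhat.colptr(j);
    for (int c = 0; c < C; ++c)
      if (gamma[c] * xh[c] + beta[c] <= 0) g[c] = 0;
  }
}

// codes (L x B, values 0..4) -> one-hot (4 x L*B)
static FMat codes_to_onehot(const IntegerMatrix& codes, const arma::uvec& idx) {
  int L = codes.nrow(), B = idx.n_elem;
  FMat X(4, (size_t)L * B, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    int col0 = idx(s);
    size_t off = (size_t)s * L;
    for (int l = 0; l < L; ++l) {
      int c = codes(l, col0);
      if (c > 0) X(c - 1, off + l) = 1.0f;
    }
  }
  return X;
}

// ---- forward / backward ----------------------------------------------------

struct ForwardCache {
  std::vector<FMat> conv_in_cols;   // im2col inputs (empty for codes conv1)
  std::vector<BNCache> conv_bn;
  std::vector<arma::umat> conv_argmax;
  std::vector<int> conv_L;          // input length to each conv
  FMat flat;                        // dense input
  std::vector<FMat> dense_in;
  std::vector<BNCache> dense_bn;
  std::vector<FMat> dense_mask;     // dropout masks (scaled)
  FMat head_in;
};

// shared tail of the forward pass after the first convolution's
// pre-batch-norm output Z1 has been computed
static FRow forward_tail(Net& net, FMat Z, int B, bool training,
                         std::mt19937* rng, ForwardCache* cache) {
  int L = net.input_length;
  FMat A;
  for (size_t i = 0; i < net.conv.size(); ++i) {
    ConvLayer& c = net.conv[i];
    if (i > 0) {
      FMat cols = im2col(A, L, B, c.k);
      Z = c.W * cols;
      Z.each_col() += c.b;
      if (cache) cache->conv_in_cols.push_back(std::move(cols));
    }
    BNCache bnc;
    bn_forward(Z, &c, nullptr, training, cache ? &bnc : nullptr);
    if (cache) {
      cache->conv_bn.push_back(std::move(bnc));
      cache->conv_L.push_back(L);
    }
    relu_inplace(Z);
    arma::umat argmax;
    A = maxpool(Z, L, B, net.pool, cache ? &argmax : nullptr);
    if (cache) cache->conv_argmax.push_back(std::move(argmax));
    L = L / net.pool;
  }
  // flatten: each sample's (C x L) block -> one column of length C*L
  int C = A.n_rows;
  FMat F(C * L, B);
  for (int s = 0; s < B; ++s) {
    std::memcpy(F.colptr(s), A.colptr((size_t)s * L),
                sizeof(real) * (size_t)C * L);
  }
  if (cache) cache->flat = F;
  for (size_t i = 0; i < net.dense.size(); ++i) {
    DenseLayer& d = net.dense[i];
    if (cache) cache->dense_in.push_back(F);
    FMat Zd = d.W * F;
    Zd.each_col() += d.b;
    BNCache bnc;
    bn_forward(Zd, nullptr, &d, training, cache ? &bnc : nullptr);
    if (cache) cache->dense_bn.push_back(std::move(bnc));
    relu_inplace(Zd);
    if (training && net.dropout > 0) {
      FMat mask(Zd.n_rows, Zd.n_cols);
      real keep = 1.0f - net.dropout;
      real* mp = mask.memptr();
      for (size_t jj = 0; jj < mask.n_elem; ++jj) {
        double u = ((*rng)() >> 5) * (1.0 / 134217728.0);  // 27-bit uniform
        mp[jj] = (u < keep) ? 1.0f / keep : 0.0f;
      }
      Zd %= mask;
      if (cache) cache->dense_mask.push_back(std::move(mask));
    } else if (cache) {
      cache->dense_mask.push_back(FMat());
    }
    F = std::move(Zd);
  }
  if (cache) cache->head_in = F;
  FRow out = net.headW * F;
  out += net.headb;
  if (net.sigmoid_head)
    out.transform([](real v) { return 1.0f / (1.0f + std::exp(-v)); });
  return out;
}

// forward from integer codes (one-hot fast path for conv1)
static FRow forward_codes(Net& net, const IntegerMatrix& codes,
                          const arma::uvec& idx, bool training,
                          std::mt19937* rng, ForwardCache* cache) {
  FMat Z = conv1_forward_codes(net.conv[0], codes, idx);
  if (cache) cache->conv_in_cols.push_back(FMat());  // placeholder
  return forward_tail(net, std::move(Z), idx.n_elem, training, rng, cache);
}

// forward from a dense 4 x (L*B) input (attribution path)
static FRow forward_dense(Net& net, const FMat& X, int B, ForwardCache* cache) {
  ConvLayer& c1 = net.conv[0];
  FMat cols = im2col(X, net.input_length, B, c1.k);
  FMat Z = c1.W * cols;
  Z.each_col() += c1.b;
  if (cache) cache->conv_in_cols.push_back(std::move(cols));
  return forward_tail(net, std::move(Z), B, false, nullptr, cache);
}

struct Grads {
  std::vector<ConvLayer> conv;   // only W,b,gamma,beta used
  std::vector<DenseLayer> dense;
  FMat headW;
  real headb;
};

// backward from d(loss)/d(pre-head-activation z); returns the gradient
// w.r.t. the conv1 pre-activation (so the caller finishes conv1's backward
// by the codes or dense path); if want_input_grad, instead completes conv1
// backprop to the input and returns dX
static FMat backward(Net& net, ForwardCache& cache, const FRow& dz, int B,
                     Grads* g, bool want_input_grad, bool training_mode) {
  FMat dF = net.headW.t() * dz;  // in x B
  if (g) {
    g->headW = dz * cache.head_in.t();
    g->headb = arma::accu(dz);
  }
  for (int i = (int)net.dense.size() - 1; i >= 0; --i) {
    DenseLayer& d = net.dense[i];
    if (training_mode && net.dropout > 0 && !cache.dense_mask[i].is_empty())
      dF %= cache.dense_mask[i];
    relu_backward_bn(dF, cache.dense_bn[i].xhat, d.gamma, d.beta);
    FVec dgamma, dbeta;
    FMat dZ = training_mode
      ? bn_backward(dF, cache.dense_bn[i], d.gamma, dgamma, dbeta)
      : bn_backward_inference(dF, d.gamma, cache.dense_bn[i].invstd);
    if (g) {
      if (training_mode) { g->dense[i].gamma = dgamma; g->dense[i].beta = dbeta; }
      g->dense[i].W = dZ * cache.dense_in[i].t();
      g->dense[i].b = arma::sum(dZ, 1);
    }
    dF = d.W.t() * dZ;
  }
  // unflatten
  int nconv = net.conv.size();
  int Lout = cache.conv_L[nconv - 1] / net.pool;
  int C = net.conv[nconv - 1].W.n_rows;
  FMat dA(C, (size_t)Lout * B);
  for (int s = 0; s < B; ++s) {
    std::memcpy(dA.colptr((size_t)s * Lout), dF.colptr(s),
                sizeof(real) * (size_t)C * Lout);
  }
  for (int i = nconv - 1; i >= 0; --i) {
    ConvLayer& c = net.conv[i];
    int L = cache.conv_L[i];
    FMat dZ = maxpool_backward(dA, cache.conv_argmax[i], c.W.n_rows,
                               (size_t)L * B);
    relu_backward_bn(dZ, cache.conv_bn[i].xhat, c.gamma, c.beta);
    FVec dgamma, dbeta;
    FMat dPre = training_mode
      ? bn_backward(dZ, cache.conv_bn[i], c.gamma, dgamma, dbeta)
      : bn_backward_inference(dZ, c.gamma, cache.conv_bn[i].invstd);
    if (g && training_mode) {
      g->conv[i].gamma = dgamma;
      g->conv[i].beta = dbeta;
    }
    if (i > 0) {
      if (g) {
        g->conv[i].W = dPre * cache.conv_in_cols[i].t();
        g->conv[i].b = arma::sum(dPre, 1);
      }
      int Cin = c.W.n_cols / c.k;
      FMat dCols = c.W.t() * dPre;
      dA = col2im(dCols, L, B, c.k, Cin);
    } else {
      // conv1: the caller owns dW (codes path) or we finish to the input
      if (g && !cache.conv_in_cols[0].is_empty()) {
        g->conv[0].W = dPre * cache.conv_in_cols[0].t();
        g->conv[0].b = arma::sum(dPre, 1);
      }
      if (want_input_grad) {
        FMat dCols = c.W.t() * dPre;
        return col2im(dCols, L, B, c.k, 4);
      }
      return dPre;  // codes path finishes dW outside
    }
  }
  return dA;  // unreachable
}

// ---- Adam ------------------------------------------------------------------

struct AdamState {
  std::vector<FMat> m, v;
  long t = 0;
};

static void adam_register(AdamState& st, size_t nr, size_t nc) {
  st.m.push_back(FMat(nr, nc, arma::fill::zeros));
  st.v.push_back(FMat(nr, nc, arma::fill::zeros));
}

static void adam_update_raw(real* p, const real* grad, size_t n, AdamState& st,
                            size_t i, real lr) {
  const real b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  real bc1 = 1 - std::pow(b1, (real)st.t);
  real bc2 = 1 - std::pow(b2, (real)st.t);
  real* m = st.m[i].memptr();
  real* v = st.v[i].memptr();
  for (size_t jj = 0; jj < n; ++jj) {
    m[jj] = b1 * m[jj] + (1 - b1) * grad[jj];
    v[jj] = b2 * v[jj] + (1 - b2) * grad[jj] * grad[jj];
    p[jj] -= lr * (m[jj] / bc1) / (std::sqrt(v[jj] / bc2) + eps);
  }
}

static void adam_update(FMat& p, const FMat& grad, AdamState& st, size_t i,
                        real lr) {
  adam_update_raw(p.memptr(), grad.memptr(), p.n_elem, st, i, lr);
}

static void adam_update_vec(FVec& p, const FVec& grad, AdamState& st, size_t i,
                            real lr) {
  adam_update_raw(p.memptr(), grad.memptr(), p.n_elem, st, i, lr);
}

// ---- loss ------------------------------------------------------------------

static double loss_value(const FRow& pred, const FRow& y, bool bce) {
  double acc = 0;
  size_t n = pred.n_elem;
  for (size_t i = 0; i < n; ++i) {
    if (bce) {
      double p = std::min(std::max((double)pred[i], 1e-12), 1 - 1e-12);
      acc += -(y[i] * std::log(p) + (1 - y[i]) * std::log(1 - p));
    } else {
      double d = (double)pred[i] - y[i];
      acc += d * d;
    }
  }
  return acc / n;
}

static FRow loss_dz(const FRow& pred, const FRow& y, bool bce) {
  real B = pred.n_elem;
  // for BCE the gradient is taken w.r.t. the pre-sigmoid activation
  if (bce) return (pred - y) / B;
  return 2.0f * (pred - y) / B;
}

static FRow predict_codes(Net& net, const IntegerMatrix& codes, int batch) {
  int n = codes.ncol();
  FRow out(n);
  for (int start = 0; start < n; start += batch) {
    int B = std::min(batch, n - start);
    arma::uvec idx(B);
    for (int i = 0; i < B; ++i) idx(i) = start + i;
    out.subvec(start, start + B - 1) =
      forward_codes(net, codes, idx, false, nullptr, nullptr);
  }
  return out;
}

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_cnn_predict(List params, List arch, IntegerMatrix codes,
                              int batch = 256) {
  Net net = net_from_r(params, arch);
  FRow out = predict_codes(net, codes, batch);
  NumericVector res(out.n_elem);
  for (size_t i = 0; i < out.n_elem; ++i) res[i] = out[i];
  return res;
}

// dense input X: 4 x (L*B); returns predictions (optionally pre-activation)
// [[Rcpp::export]]
NumericVector cpp_cnn_predict_dense(List params, List arch, NumericMatrix X,
                                    bool raw = false, int batch = 256) {
  Net net = net_from_r(params, arch);
  if (raw) net.sigmoid_head = false;
  int L = net.input_length;
  int n = X.ncol() / L;
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  NumericVector res(n);
  for (int start = 0; start < n; start += batch) {
    int B = std::min(batch, n - start);
    FMat Xb = arma::conv_to<FMat>::from(
      Xd.cols((size_t)start * L, (size_t)(start + B) * L - 1));
    FRow out = forward_dense(net, Xb, B, nullptr);
    for (int i = 0; i < B; ++i) res[start + i] = out[i];
  }
  return res;
}

// gradient of the (pre-activation) scalar output w.r.t. the dense input,
// evaluated in inference mode; X is 4 x (L*B)
// [[Rcpp::export]]
NumericMatrix cpp_cnn_input_grad(List params, List arch, NumericMatrix X,
                                 int batch = 64) {
  Net net = net_from_r(params, arch);
  net.sigmoid_head = false;  // attribute the logit for classifiers
  int L = net.input_length;
  int n = X.ncol() / L;
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  arma::mat grad(4, Xd.n_cols);
  for (int start = 0; start < n; start += batch) {
    int B = std::min(batch, n - start);
    FMat Xb = arma::conv_to<FMat>::from(
      Xd.cols((size_t)start * L, (size_t)(start + B) * L - 1));
    ForwardCache cache;
    forward_dense(net, Xb, B, &cache);
    FRow dz(B, arma::fill::ones);
    FMat dX = backward(net, cache, dz, B, nullptr, true, false);
    grad.cols((size_t)start * L, (size_t)(start + B) * L - 1) =
      arma::conv_to<arma::mat>::from(dX);
  }
  return wrap(grad);
}

// training-mode loss and parameter gradients for one batch (no update);
// dropout is ignored. Used for gradient verification in the test suite.
// [[Rcpp::export]]
List cpp_cnn_loss_grad(List params, List arch, IntegerMatrix codes,
                       NumericVector y, std::string loss) {
  Net net = net_from_r(params, arch);
  net.dropout = 0;
  bool bce = loss == "bce";
  int B = codes.ncol();
  arma::uvec idx(B);
  for (int i = 0; i < B; ++i) idx(i) = i;
  FRow yb(B);
  for (int i = 0; i < B; ++i) yb[i] = (real)y[i];
  ForwardCache cache;
  FRow pred = forward_codes(net, codes, idx, true, nullptr, &cache);
  double l = loss_value(pred, yb, bce);
  FRow dz = loss_dz(pred, yb, bce);
  Grads g;
  g.conv.resize(net.conv.size());
  g.dense.resize(net.dense.size());
  FMat dPre1 = backward(net, cache, dz, B, &g, false, true);
  conv1_backward_codes(net.conv[0], dPre1, codes, idx, g.conv[0].W,
                       g.conv[0].b);
  List gconv(g.conv.size());
  for (size_t i = 0; i < g.conv.size(); ++i)
    gconv[i] = List::create(_["W"] = f_to_r(g.conv[i].W),
                            _["b"] = fv_to_r(g.conv[i].b),
                            _["gamma"] = fv_to_r(g.conv[i].gamma),
                            _["beta"] = fv_to_r(g.conv[i].beta));
  List gdense(g.dense.size());
  for (size_t i = 0; i < g.dense.size(); ++i)
    gdense[i] = List::create(_["W"] = f_to_r(g.dense[i].W),
                             _["b"] = fv_to_r(g.dense[i].b),
                             _["gamma"] = fv_to_r(g.dense[i].gamma),
                             _["beta"] = fv_to_r(g.dense[i].beta));
  return List::create(_["loss"] = l, _["conv"] = gconv, _["dense"] = gdense,
                      _["head"] = List::create(_["W"] = f_to_r(g.headW),
                                               _["b"] = (double)g.headb));
}

// training-mode loss only (for finite-difference checks)
// [[Rcpp::export]]
double cpp_cnn_loss(List params, List arch, IntegerMatrix codes,
                    NumericVector y, std::string loss) {
  Net net = net_from_r(params, arch);
  net.dropout = 0;
  bool bce = loss == "bce";
  int B = codes.ncol();
  arma::uvec idx(B);
  for (int i = 0; i < B; ++i) idx(i) = i;
  FRow yb(B);
  for (int i = 0; i < B; ++i) yb[i] = (real)y[i];
  FRow pred = forward_codes(net, codes, idx, true, nullptr, nullptr);
  return loss_value(pred, yb, bce);
}

// full training loop with early stopping and best-weight restoration
// [[Rcpp::export]]
List cpp_cnn_train(List params, List arch, IntegerMatrix codes,
                   NumericVector y, IntegerMatrix val_codes,
                   NumericVector val_y, std::string loss, double lr,
                   int batch_size, int patience, int max_epochs, int seed) {
  Net net = net_from_r(params, arch);
  bool bce = loss == "bce";
  int n = codes.ncol();
  if (n == 0) stop("empty training set");
  std::mt19937 rng((unsigned)seed);

  // Adam state: conv (W,b,gamma,beta) x layers, dense likewise, head (W,b)
  AdamState st;
  for (auto& c : net.conv) {
    adam_register(st, c.W.n_rows, c.W.n_cols);
    adam_register(st, c.b.n_elem, 1);
    adam_register(st, c.gamma.n_elem, 1);
    adam_register(st, c.beta.n_elem, 1);
  }
  for (auto& d : net.dense) {
    adam_register(st, d.W.n_rows, d.W.n_cols);
    adam_register(st, d.b.n_elem, 1);
    adam_register(st, d.gamma.n_elem, 1);
    adam_register(st, d.beta.n_elem, 1);
  }
  adam_register(st, 1, net.headW.n_cols);
  adam_register(st, 1, 1);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> train_hist, val_hist;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = -1, wait = 0;
  List best_params = net_to_r(net);
  std::string status = "max_epochs";
  FRow ya(y.size());
  for (int i = 0; i < y.size(); ++i) ya[i] = (real)y[i];
  FRow vya(val_y.size());
  for (int i = 0; i < val_y.size(); ++i) vya[i] = (real)val_y[i];

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates with explicit arithmetic for cross-platform determinism
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(rng() % (unsigned)(i + 1));
      std::swap(order[i], order[j]);
    }
    double epoch_loss = 0; long seen = 0;
    bool nan_hit = false;
    for (int start = 0; start < n; start += batch_size) {
      int B = std::min(batch_size, n - start);
      arma::uvec idx(B);
      FRow yb(B);
      for (int i = 0; i < B; ++i) {
        idx(i) = order[start + i];
        yb(i) = ya(order[start + i]);
      }
      ForwardCache cache;
      FRow pred = forward_codes(net, codes, idx, true, &rng, &cache);
      double l = loss_value(pred, yb, bce);
      if (!std::isfinite(l)) { nan_hit = true; break; }
      epoch_loss += l * B; seen += B;
      FRow dz = loss_dz(pred, yb, bce);
      Grads g;
      g.conv.resize(net.conv.size());
      g.dense.resize(net.dense.size());
      FMat dPre1 = backward(net, cache, dz, B, &g, false, true);
      conv1_backward_codes(net.conv[0], dPre1, codes, idx, g.conv[0].W,
                           g.conv[0].b);
      st.t += 1;
      size_t pi = 0;
      real flr = (real)lr;
      for (size_t i = 0; i < net.conv.size(); ++i) {
        adam_update(net.conv[i].W, g.conv[i].W, st, pi++, flr);
        adam_update_vec(net.conv[i].b, g.conv[i].b, st, pi++, flr);
        adam_update_vec(net.conv[i].gamma, g.conv[i].gamma, st, pi++, flr);
        adam_update_vec(net.conv[i].beta, g.conv[i].beta, st, pi++, flr);
      }
      for (size_t i = 0; i < net.dense.size(); ++i) {
        adam_update(net.dense[i].W, g.dense[i].W, st, pi++, flr);
        adam_update_vec(net.dense[i].b, g.dense[i].b, st, pi++, flr);
        adam_update_vec(net.dense[i].gamma, g.dense[i].gamma, st, pi++, flr);
        adam_update_vec(net.dense[i].beta, g.dense[i].beta, st, pi++, flr);
      }
      adam_update(net.headW, g.headW, st, pi++, flr);
      {
        FVec hb(1), ghb(1);
        hb(0) = net.headb; ghb(0) = g.headb;
        adam_update_vec(hb, ghb, st, pi++, flr);
        net.headb = hb(0);
      }
    }
    if (nan_hit) { status = "nan"; break; }
    train_hist.push_back(epoch_loss / seen);
    FRow vpred = predict_codes(net, val_codes, 256);
    double vl = loss_value(vpred, vya, bce);
    val_hist.push_back(vl);
    if (vl < best_val) {
      best_val = vl;
      best_epoch = epoch;
      best_params = net_to_r(net);
      wait = 0;
    } else {
      wait += 1;
      if (wait >= patience) { status = "early_stop"; break; }
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["params"] = best_params,
    _["train_loss"] = train_hist,
    _["val_loss"] = val_hist,
    _["best_epoch"] = best_epoch + 1,
    _["best_val_loss"] = best_val,
    _["status"] = status);
}
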