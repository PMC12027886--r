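// Shallow CNN used for grade classification: two valid 7x7 convolution
// blocks (conv -> batch norm -> ReLU -> 2x2 max pool [-> dropout]), flatten,
// optional concatenation of three scalar features, then dense 64 -> 32 -> 7
// with softmax. Forward + backward are implemented here in single precision
// so the convolution GEMMs hit BLAS sgemm; gradients are returned to R where
// the Adam update runs in double precision.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;
using arma::umat;

#ifdef __GLIBC__
#include <malloc.h>
// The training step allocates ~100 MB of short-lived buffers (patch
// matrices, feature maps); with glibc's default mmap threshold each step
// would fault fresh zero pages in and out. Raising the threshold lets the
// heap recycle those buffers across steps.
static const int cg_malloc_tuned = [] {
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  return 1;
}();
#endif

// Single-precision GEMM on raw pointers (resolved from the BLAS R links),
// used to multiply per-image row blocks of the cached patch matrix without
// copying them out first.
extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* a, const int* lda, const float* b,
                       const int* ldb, const float* beta, float* c,
                       const int* ldc);

static void sgemm_block(char transa, int m, int n, int k, const float* a,
                        int lda, const float* b, int ldb, float beta,
                        float* c, int ldc) {
  const float alpha = 1.0f;
  const char tb = 'N';
  sgemm_(&transa, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

static const float BN_EPS = 1e-5f;
static double cg_T[32];
static arma::wall_clock cg_wc;
#define TIC cg_wc.tic()
#define TOC(i) cg_T[i] += cg_wc.toc()
// [[Rcpp::export]]
Rcpp::NumericVector cnn_timers() { Rcpp::NumericVector v(32); for(int i=0;i<32;++i){v[i]=cg_T[i];cg_T[i]=0;} return v; }

// Feature maps are stored as matrices with rows indexed (spatial, image):
// row = (h + H*w) + H*W*i, one column per channel. im2col turns such a map
// into the patch matrix M ((n*OH*OW) x (k*k*C)) with output position
// o = oh + OH*ow and patch element q = kh + k*kw + k*k*c.
static fmat im2col(const fmat& X, int H, int W, int n, int k) {
  const int C = X.n_cols, OH = H - k + 1, OW = W - k + 1, OP = OH * OW;
  fmat M(static_cast<arma::uword>(n) * OP, static_cast<arma::uword>(k) * k * C);
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        float* dst = M.colptr(kh + k * kw + k * k * c);
        for (int i = 0; i < n; ++i) {
          const float* im = src + static_cast<size_t>(H) * W * i;
          float* out = dst + static_cast<size_t>(OP) * i;
          for (int ow = 0; ow < OW; ++ow) {
            const float* col = im + static_cast<size_t>(H) * (ow + kw) + kh;
            std::copy(col, col + OH, out + static_cast<size_t>(OH) * ow);
          }
        }
      }
    }
  }
  return M;
}

// Adjoint of im2col: scatter-add patch gradients back onto the feature map.
static fmat col2im(const fmat& dM, int H, int W, int C, int n, int k) {
  const int OH = H - k + 1, OW = W - k + 1, OP = OH * OW;
  fmat out(static_cast<arma::uword>(n) * H * W, C, arma::fill::zeros);
  // rows of `out` indexed (h + H*w) + H*W*i
  for (int c = 0; c < C; ++c) {
    float* dst = out.colptr(c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const float* src = dM.colptr(kh + k * kw + k * k * c);
        for (int i = 0; i < n; ++i) {
          float* im = dst + static_cast<size_t>(H) * W * i;
          const float* grad = src + static_cast<size_t>(OP) * i;
          for (int ow = 0; ow < OW; ++ow) {
            float* col = im + static_cast<size_t>(H) * (ow + kw) + kh;
            const float* g = grad + static_cast<size_t>(OH) * ow;
            for (int oh = 0; oh < OH; ++oh) col[oh] += g[oh];
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling (stride 2, floor semantics) on an (n*OP) x F map.
static fmat maxpool(const fmat& Y, int OH, int OW, int n, umat& argmax) {
  const int PH = OH / 2, PW = OW / 2, OP = OH * OW, PP = PH * PW;
  const int F = Y.n_cols;
  fmat Q(static_cast<arma::uword>(n) * PP, F);
  argmax.set_size(Q.n_rows, F);
  for (int f = 0; f < F; ++f) {
    const float* y = Y.colptr(f);
    float* q = Q.colptr(f);
    arma::uword* am = argmax.colptr(f);
    for (int i = 0; i < n; ++i) {
      const size_t yo = static_cast<size_t>(OP) * i;
      const size_t qo = static_cast<size_t>(PP) * i;
      for (int pw = 0; pw < PW; ++pw) {
        for (int ph = 0; ph < PH; ++ph) {
          float best = -std::numeric_limits<float>::infinity();
          size_t besti = 0;
          for (int dx = 0; dx < 2; ++dx) {
            for (int dy = 0; dy < 2; ++dy) {
              size_t idx = yo + (2 * ph + dy) + static_cast<size_t>(OH) * (2 * pw + dx);
              if (y[idx] > best) { best = y[idx]; besti = idx; }
            }
          }
          q[qo + ph + static_cast<size_t>(PH) * pw] = best;
          am[qo + ph + static_cast<size_t>(PH) * pw] = besti;
        }
      }
    }
  }
  return Q;
}

static fmat maxpool_back(const fmat& dQ, const umat& argmax,
                         arma::uword in_rows) {
  fmat dY(in_rows, dQ.n_cols, arma::fill::zeros);
  for (arma::uword f = 0; f < dQ.n_cols; ++f) {
    float* dy = dY.colptr(f);
    const float* dq = dQ.colptr(f);
    const arma::uword* am = argmax.colptr(f);
    for (arma::uword r = 0; r < dQ.n_rows; ++r) dy[am[r]] += dq[r];
  }
  return dY;
}

struct BnCache { frowvec mu, invstd; fmat xhat; };

static fmat bn_forward_train(const fmat& A, const frowvec& g,
                             const frowvec& be, BnCache& cache) {
  cache.mu = arma::mean(A, 0);
  frowvec var = arma::mean(arma::square(A.each_row() - cache.mu), 0);
  cache.invstd = 1.0f / arma::sqrt(var + BN_EPS);
  cache.xhat = (A.each_row() - cache.mu).each_row() % cache.invstd;
  fmat out = cache.xhat.each_row() % g;
  out.each_row() += be;
  return out;
}

static fmat bn_forward_infer(const fmat& A, const frowvec& g,
                             const frowvec& be, const frowvec& rm,
                             const frowvec& rv) {
  frowvec invstd = 1.0f / arma::sqrt(rv + BN_EPS);
  fmat out = (A.each_row() - rm).each_row() % (g % invstd);
  out.each_row() += be;
  return out;
}

static fmat bn_backward(const fmat& dZ, const frowvec& g, const BnCache& cache,
                        frowvec& dg, frowvec& dbe) {
  dg = arma::sum(dZ % cache.xhat, 0);
  dbe = arma::sum(dZ, 0);
  const float N = static_cast<float>(dZ.n_rows);
  fmat dA = dZ;
  dA.each_row() -= dbe / N;
  dA -= cache.xhat.each_row() % (dg / N);
  dA.each_row() %= (g % cache.invstd);
  return dA;
}

// Inverted dropout with R's RNG so runs are reproducible under set.seed().
static fmat dropout_mask(arma::uword nr, arma::uword nc, double rate) {
  fmat m(nr, nc);
  const float scale = 1.0f / (1.0f - static_cast<float>(rate));
  float* p = m.memptr();
  for (arma::uword i = 0; i < nr * nc; ++i)
    p[i] = (unif_rand() < rate) ? 0.0f : scale;
  return m;
}

static fmat as_f(const List& L, const char* name) {
  return arma::conv_to<fmat>::from(as<arma::mat>(L[name]));
}
static frowvec as_frow(const List& L, const char* name) {
  return arma::conv_to<frowvec>::from(as<arma::rowvec>(L[name]));
}

// Convert the (H, W, C, n) input array into the matrix-form feature map
// ((n*H*W) x C) used by im2col.
static fmat input_to_map(const NumericVector& x, int H, int W, int C, int n) {
  fmat X(static_cast<arma::uword>(n) * H * W, C);
  const double* src = x.begin();
  for (int c = 0; c < C; ++c) {
    float* dst = X.colptr(c);
    for (int i = 0; i < n; ++i) {
      const double* im = src + (static_cast<size_t>(i) * C + c) * H * W;
      float* out = dst + static_cast<size_t>(H) * W * i;
      for (int j = 0; j < H * W; ++j) out[j] = static_cast<float>(im[j]);
    }
  }
  return X;
}

struct Dims {
  int H, W, C, n, k, F1, F2, H1, W1, PH1, PW1, H2, W2, PH2, PW2, D0;
};

static Dims get_dims(const NumericVector& x, const List& params, int k) {
  Dims d;
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("input must be a 4-d array (H, W, C, n)");
  d.H = dm[0]; d.W = dm[1]; d.C = dm[2]; d.n = dm[3]; d.k = k;
  d.F1 = as<arma::mat>(params["W1"]).n_cols;
  d.F2 = as<arma::mat>(params["W2"]).n_cols;
  d.H1 = d.H - k + 1; d.W1 = d.W - k + 1;
  d.PH1 = d.H1 / 2;   d.PW1 = d.W1 / 2;
  d.H2 = d.PH1 - k + 1; d.W2 = d.PW1 - k + 1;
  d.PH2 = d.H2 / 2;   d.PW2 = d.W2 / 2;
  d.D0 = d.PH2 * d.PW2 * d.F2;
  if (d.H1 < 1 || d.W1 < 1 || d.H2 < 1 || d.W2 < 1 ||
      d.PH2 < 1 || d.PW2 < 1)
    stop("input too small for the configured kernel/pooling");
  return d;
}

static fmat flatten_map(const fmat& Q, int PP, int n) {
  const int F = Q.n_cols;
  fmat Z(n, static_cast<arma::uword>(PP) * F);
  for (int f = 0; f < F; ++f) {
    const float* q = Q.colptr(f);
    for (int i = 0; i < n; ++i)
      for (int p = 0; p < PP; ++p)
        Z(i, p + static_cast<arma::uword>(PP) * f) =
          q[p + static_cast<size_t>(PP) * i];
  }
  return Z;
}

static fmat unflatten_map(const fmat& dZ, int PP, int F, int n) {
  fmat dQ(static_cast<arma::uword>(n) * PP, F);
  for (int f = 0; f < F; ++f) {
    float* q = dQ.colptr(f);
    for (int i = 0; i < n; ++i)
      for (int p = 0; p < PP; ++p)
        q[p + static_cast<size_t>(PP) * i] =
          dZ(i, p + static_cast<arma::uword>(PP) * f);
  }
  return dQ;
}

static fmat softmax_rows(fmat S) {
  fvec mx = arma::max(S, 1);
  S.each_col() -= mx;
  S = arma::exp(S);
  fvec sums = arma::sum(S, 1);
  S.each_col() /= sums;
  return S;
}

// Training batches are drawn with replacement from a fixed dataset, so the
// first-layer im2col of every image can be computed once per training run
// and batch patch matrices assembled by copying row blocks.
struct ConvCache {
  fmat M;            // ((n*OP) x (k*k*C)) patch matrix of the whole dataset
  Dims d;
};

// [[Rcpp::export]]
SEXP make_conv_cache(List params, NumericVector x, int kernel) {
  XPtr<ConvCache> p(new ConvCache, true);
  p->d = get_dims(x, params, kernel);
  fmat X0 = input_to_map(x, p->d.H, p->d.W, p->d.C, p->d.n);
  p->M = im2col(X0, p->d.H, p->d.W, p->d.n, p->d.k);
  return p;
}

// `Mfull` holds first-layer patches for a whole dataset (rows
// (o + OP*image)); `img` names the batch's images. The two heavy GEMMs
// (conv-1 forward, conv-1 weight gradient) run per image directly on the
// cached rows via strided BLAS calls, so no batch patch matrix is copied.
static List grad_core(const fmat& Mfull, const std::vector<int>& img, Dims d,
                      List params, Nullable<NumericMatrix> feats_,
                      IntegerVector y, bool use_feats, bool use_dropout,
                      double drop_conv, double drop_dense) {
  const int n = d.n;
  const int OP1 = d.H1 * d.W1, K1 = d.k * d.k * d.C;
  if (y.size() != n) stop("length(y) != number of images");

  fmat W1 = as_f(params, "W1"), W2 = as_f(params, "W2");
  frowvec g1 = as_frow(params, "g1"), be1 = as_frow(params, "be1");
  frowvec g2 = as_frow(params, "g2"), be2 = as_frow(params, "be2");
  fmat Wd1 = as_f(params, "Wd1"), Wd2 = as_f(params, "Wd2"),
       Wd3 = as_f(params, "Wd3");
  frowvec bd1 = as_frow(params, "bd1"), bd2 = as_frow(params, "bd2"),
          bd3 = as_frow(params, "bd3");

  fmat feats;
  if (use_feats) {
    if (feats_.isNull()) stop("variant with scalar features needs 'feats'");
    feats = arma::conv_to<fmat>::from(as<arma::mat>(feats_.get()));
    if ((int)feats.n_rows != n) stop("nrow(feats) != number of images");
  }

  // ---- forward ----
  TIC;
  fmat A1(static_cast<arma::uword>(n) * OP1, d.F1);
  for (int i = 0; i < n; ++i)
    sgemm_block('N', OP1, d.F1, K1, Mfull.colptr(0) + (size_t)OP1 * img[i],
                Mfull.n_rows, W1.memptr(), K1, 0.0f,
                A1.memptr() + (size_t)OP1 * i, A1.n_rows);
  TOC(1);
  BnCache bn1;
  TIC; fmat Z1 = bn_forward_train(A1, g1, be1, bn1);
  fmat R1 = arma::clamp(Z1, 0.0f, std::numeric_limits<float>::infinity()); TOC(2);
  umat am1;
  TIC; fmat Q1 = maxpool(R1, d.H1, d.W1, n, am1); TOC(3);
  fmat dm1;
  TIC; if (use_dropout && drop_conv > 0) {
    dm1 = dropout_mask(Q1.n_rows, Q1.n_cols, drop_conv);
    Q1 %= dm1;
  } TOC(4);

  TIC; fmat M2 = im2col(Q1, d.PH1, d.PW1, n, d.k); TOC(5);
  TIC; fmat A2 = M2 * W2; TOC(6);
  TIC;
  BnCache bn2;
  fmat Z2 = bn_forward_train(A2, g2, be2, bn2);
  fmat R2 = arma::clamp(Z2, 0.0f, std::numeric_limits<float>::infinity());
  umat am2;
  fmat Q2 = maxpool(R2, d.H2, d.W2, n, am2);
  fmat dm2;
  if (use_dropout && drop_conv > 0) {
    dm2 = dropout_mask(Q2.n_rows, Q2.n_cols, drop_conv);
    Q2 %= dm2;
  }

  TOC(7);
  TIC; fmat Z = flatten_map(Q2, d.PH2 * d.PW2, n);
  fmat Zc = use_feats ? arma::join_rows(Z, feats) : Z;
  if ((int)Wd1.n_rows != (int)Zc.n_cols)
    stop("dense-1 weight shape does not match the flattened features");

  fmat U1 = Zc * Wd1; U1.each_row() += bd1;
  fmat R3 = arma::clamp(U1, 0.0f, std::numeric_limits<float>::infinity());
  fmat dm3;
  if (use_dropout && drop_dense > 0) {
    dm3 = dropout_mask(R3.n_rows, R3.n_cols, drop_dense);
    R3 %= dm3;
  }
  fmat U2 = R3 * Wd2; U2.each_row() += bd2;
  fmat R4 = arma::clamp(U2, 0.0f, std::numeric_limits<float>::infinity());
  fmat dm4;
  if (use_dropout && drop_dense > 0) {
    dm4 = dropout_mask(R4.n_rows, R4.n_cols, drop_dense);
    R4 %= dm4;
  }
  fmat S = R4 * Wd3; S.each_row() += bd3;
  fmat P = softmax_rows(S);
  TOC(8);
  TIC;
  double loss = 0;
  for (int i = 0; i < n; ++i) {
    int cls = y[i] - 1;
    if (cls < 0 || cls >= (int)P.n_cols) stop("label outside 1..n_classes");
    loss -= std::log(std::max(P(i, cls), 1e-12f));
  }
  loss /= n;

  // ---- backward ----
  fmat dS = P;
  for (int i = 0; i < n; ++i) dS(i, y[i] - 1) -= 1.0f;
  dS /= static_cast<float>(n);

  fmat dWd3 = R4.t() * dS;
  frowvec dbd3 = arma::sum(dS, 0);
  fmat dR4 = dS * Wd3.t();
  if (dm4.n_elem) dR4 %= dm4;
  fmat dU2 = dR4 % (U2 > 0);
  fmat dWd2 = R3.t() * dU2;
  frowvec dbd2 = arma::sum(dU2, 0);
  fmat dR3 = dU2 * Wd2.t();
  if (dm3.n_elem) dR3 %= dm3;
  fmat dU1 = dR3 % (U1 > 0);
  fmat dWd1 = Zc.t() * dU1;
  frowvec dbd1 = arma::sum(dU1, 0);
  fmat dZc = dU1 * Wd1.t();
  fmat dZ = use_feats ? fmat(dZc.cols(0, d.D0 - 1)) : dZc;

  TOC(9);
  TIC;
  fmat dQ2 = unflatten_map(dZ, d.PH2 * d.PW2, d.F2, n);
  if (dm2.n_elem) dQ2 %= dm2;
  fmat dR2 = maxpool_back(dQ2, am2, R2.n_rows);
  fmat dZ2 = dR2 % (Z2 > 0);
  frowvec dg2, dbe2;
  fmat dA2 = bn_backward(dZ2, g2, bn2, dg2, dbe2);
  TOC(10);
  TIC; fmat dW2 = M2.t() * dA2;
  fmat dM2 = dA2 * W2.t(); TOC(11);
  TIC; fmat dQ1 = col2im(dM2, d.PH1, d.PW1, d.F1, n, d.k); TOC(12);
  TIC; if (dm1.n_elem) dQ1 %= dm1;
  fmat dR1 = maxpool_back(dQ1, am1, R1.n_rows); TOC(13);
  TIC; fmat dZ1 = dR1 % (Z1 > 0); TOC(14);
  frowvec dg1, dbe1;
  TIC; fmat dA1 = bn_backward(dZ1, g1, bn1, dg1, dbe1); TOC(15);
  TIC;
  fmat dW1(K1, d.F1, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    sgemm_block('T', K1, d.F1, OP1, Mfull.colptr(0) + (size_t)OP1 * img[i],
                Mfull.n_rows, dA1.memptr() + (size_t)OP1 * i, dA1.n_rows,
                1.0f, dW1.memptr(), K1);
  TOC(16);
  // no gradient w.r.t. the input image is needed (first layer)

  TIC;
  frowvec var1 = 1.0f / arma::square(bn1.invstd) - BN_EPS;
  frowvec var2 = 1.0f / arma::square(bn2.invstd) - BN_EPS;

  List ret = List::create(
    _["loss"] = loss,
    _["grads"] = List::create(
      _["W1"] = arma::conv_to<arma::mat>::from(dW1),
      _["g1"] = arma::conv_to<arma::rowvec>::from(dg1),
      _["be1"] = arma::conv_to<arma::rowvec>::from(dbe1),
      _["W2"] = arma::conv_to<arma::mat>::from(dW2),
      _["g2"] = arma::conv_to<arma::rowvec>::from(dg2),
      _["be2"] = arma::conv_to<arma::rowvec>::from(dbe2),
      _["Wd1"] = arma::conv_to<arma::mat>::from(dWd1),
      _["bd1"] = arma::conv_to<arma::rowvec>::from(dbd1),
      _["Wd2"] = arma::conv_to<arma::mat>::from(dWd2),
      _["bd2"] = arma::conv_to<arma::rowvec>::from(dbd2),
      _["Wd3"] = arma::conv_to<arma::mat>::from(dWd3),
      _["bd3"] = arma::conv_to<arma::rowvec>::from(dbd3)),
    _["bn"] = List::create(
      _["mu1"] = arma::conv_to<arma::rowvec>::from(bn1.mu),
      _["var1"] = arma::conv_to<arma::rowvec>::from(var1),
      _["mu2"] = arma::conv_to<arma::rowvec>::from(bn2.mu),
      _["var2"] = arma::conv_to<arma::rowvec>::from(var2)));
  TOC(17);
  return ret;
}

// One forward/backward pass on a batch; returns the mean cross-entropy loss,
// gradients for every parameter, and the batch statistics of both batch-norm
// layers (the caller maintains the running averages).
// [[Rcpp::export]]
List cnn_grad(List params, NumericVector x, Nullable<NumericMatrix> feats_,
              IntegerVector y, int kernel, bool use_feats, bool use_dropout,
              double drop_conv, double drop_dense) {
  Dims d = get_dims(x, params, kernel);
  fmat X0 = input_to_map(x, d.H, d.W, d.C, d.n);
  fmat M1 = im2col(X0, d.H, d.W, d.n, d.k);
  std::vector<int> img(d.n);
  for (int i = 0; i < d.n; ++i) img[i] = i;
  return grad_core(M1, img, d, params, feats_, y, use_feats, use_dropout,
                   drop_conv, drop_dense);
}

// Cached flavour: gathers the batch's first-layer patch rows from a
// make_conv_cache() object instead of rebuilding im2col each step.
// [[Rcpp::export]]
List cnn_grad_cached(List params, SEXP cache, IntegerVector idx,
                     Nullable<NumericMatrix> feats_, IntegerVector y,
                     bool use_feats, bool use_dropout, double drop_conv,
                     double drop_dense) {
  XPtr<ConvCache> cc(cache);
  Dims d = cc->d;
  std::vector<int> img(idx.size());
  for (int i = 0; i < idx.size(); ++i) {
    img[i] = idx[i] - 1;
    if (img[i] < 0 || img[i] >= cc->d.n) stop("batch index out of range");
  }
  d.n = idx.size();
  return grad_core(cc->M, img, d, params, feats_, y, use_feats, use_dropout,
                   drop_conv, drop_dense);
}

// Inference pass: batch norm uses the running statistics and dropout is
// inactive, so repeated calls on the same input are identical.
// [[Rcpp::export]]
NumericMatrix cnn_forward(List params, List bn_state, NumericVector x,
                          Nullable<NumericMatrix> feats_, int kernel,
                          bool use_feats) {
  Dims d = get_dims(x, params, kernel);
  const int n = d.n;

  fmat W1 = as_f(params, "W1"), W2 = as_f(params, "W2");
  frowvec g1 = as_frow(params, "g1"), be1 = as_frow(params, "be1");
  frowvec g2 = as_frow(params, "g2"), be2 = as_frow(params, "be2");
  fmat Wd1 = as_f(params, "Wd1"), Wd2 = as_f(params, "Wd2"),
       Wd3 = as_f(params, "Wd3");
  frowvec bd1 = as_frow(params, "bd1"), bd2 = as_frow(params, "bd2"),
          bd3 = as_frow(params, "bd3");
  frowvec rm1 = as_frow(bn_state, "rm1"), rv1 = as_frow(bn_state, "rv1");
  frowvec rm2 = as_frow(bn_state, "rm2"), rv2 = as_frow(bn_state, "rv2");

  fmat feats;
  if (use_feats) {
    if (feats_.isNull()) stop("variant with scalar features needs 'feats'");
    feats = arma::conv_to<fmat>::from(as<arma::mat>(feats_.get()));
    if ((int)feats.n_rows != n) stop("nrow(feats) != number of images");
  }

  fmat X0 = input_to_map(x, d.H, d.W, d.C, n);
  fmat A1 = im2col(X0, d.H, d.W, n, d.k) * W1;
  fmat R1 = arma::clamp(bn_forward_infer(A1, g1, be1, rm1, rv1), 0.0f,
                        std::numeric_limits<float>::infinity());
  umat am;
  fmat Q1 = maxpool(R1, d.H1, d.W1, n, am);
  fmat A2 = im2col(Q1, d.PH1, d.PW1, n, d.k) * W2;
  fmat R2 = arma::clamp(bn_forward_infer(A2, g2, be2, rm2, rv2), 0.0f,
                        std::numeric_limits<float>::infinity());
  fmat Q2 = maxpool(R2, d.H2, d.W2, n, am);
  fmat Z = flatten_map(Q2, d.PH2 * d.PW2, n);
  fmat Zc = use_feats ? arma::join_rows(Z, feats) : Z;
  fmat U1 = Zc * Wd1; U1.each_row() += bd1;
  U1 = arma::clamp(U1, 0.0f, std::numeric_limits<float>::infinity());
  fmat U2 = U1 * Wd2; U2.each_row() += bd2;
  U2 = arma::clamp(U2, 0.0f, std::numeric_limits<float>::infinity());
  fmat S = U2 * Wd3; S.each_row() += bd3;
  fmat P = softmax_rows(S);
  return wrap(arma::conv_to<arma::mat>::from(P));
}
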