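// 3D convolutional network for voxelized heme pockets.
//
// Layer stack (fixed): conv(2x2x2, pad 0) -> 64ch; conv(2x2x2, pad 1)
// -> 128ch; batchnorm; conv(2x2x2, pad 0) -> 128ch; ReLU; batchnorm;
// maxpool(2, stride 2); flatten; linear 128; ReLU; dropout 0.4;
// linear 64; batchnorm; ReLU; linear K; sigmoid.  Loss is binary
// cross-entropy summed over the K sigmoid outputs.  Optimizer is plain
// SGD.  All convolutions run as im2col + sgemm in single precision.
//
// Input layout per sample: channel-major cube, linear index
//   c*n^3 + z*n^2 + y*n + x   (x fastest),
// which matches an R array of dim c(n, n, n, 4) flattened by as.vector.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::frowvec;
using arma::fvec;
using arma::uword;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

struct ConvShape {
  int cin, cout, nin, nout, pad;
};

// ---------------------------------------------------------------------
// im2col / col2im for kernel 2, arbitrary symmetric zero padding.
// X: (cin, B*nin^3) activation matrix; col: (cin*8, B*nout^3).

static void im2col(const fmat& X, fmat& col, const ConvShape& s, int B) {
  const int nin = s.nin, nout = s.nout, pad = s.pad, cin = s.cin;
  const long vin = (long)nin * nin * nin, vout = (long)nout * nout * nout;
  col.zeros(cin * 8, (uword)B * vout);
  for (int b = 0; b < B; ++b) {
    for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
        for (int kx = 0; kx < 2; ++kx) {
          const int krow = kz * 4 + ky * 2 + kx;
          for (int oz = 0; oz < nout; ++oz) {
            const int iz = oz + kz - pad;
            if (iz < 0 || iz >= nin) continue;
            for (int oy = 0; oy < nout; ++oy) {
              const int iy = oy + ky - pad;
              if (iy < 0 || iy >= nin) continue;
              // contiguous run over ox where ix in range
              int ox0 = std::max(0, pad - kx);
              int ox1 = std::min(nout - 1, nin - 1 + pad - kx);
              if (ox0 > ox1) continue;
              const long ccol0 = (long)b * vout +
                (long)oz * nout * nout + (long)oy * nout;
              const long cin0 = (long)b * vin +
                (long)iz * nin * nin + (long)iy * nin;
              for (int ox = ox0; ox <= ox1; ++ox) {
                const float* s = X.colptr(cin0 + (ox + kx - pad));
                float* d = col.colptr(ccol0 + ox) + krow;
                for (int c = 0; c < cin; ++c) d[c * 8] = s[c];
              }
            }
          }
        }
  }
}

static void col2im(const fmat& dcol, fmat& dX, const ConvShape& s, int B) {
  const int nin = s.nin, nout = s.nout, pad = s.pad, cin = s.cin;
  const long vin = (long)nin * nin * nin, vout = (long)nout * nout * nout;
  dX.zeros(cin, (uword)B * vin);
  for (int b = 0; b < B; ++b) {
    for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
        for (int kx = 0; kx < 2; ++kx) {
          const int krow = kz * 4 + ky * 2 + kx;
          for (int oz = 0; oz < nout; ++oz) {
            const int iz = oz + kz - pad;
            if (iz < 0 || iz >= nin) continue;
            for (int oy = 0; oy < nout; ++oy) {
              const int iy = oy + ky - pad;
              if (iy < 0 || iy >= nin) continue;
              int ox0 = std::max(0, pad - kx);
              int ox1 = std::min(nout - 1, nin - 1 + pad - kx);
              const long ccol0 = (long)b * vout +
                (long)oz * nout * nout + (long)oy * nout;
              const long cin0 = (long)b * vin +
                (long)iz * nin * nin + (long)iy * nin;
              for (int ox = ox0; ox <= ox1; ++ox) {
                float* d = dX.colptr(cin0 + (ox + kx - pad));
                const float* s = dcol.colptr(ccol0 + ox) + krow;
                for (int c = 0; c < cin; ++c) d[c] += s[c * 8];
              }
            }
          }
        }
  }
}

// ---------------------------------------------------------------------
// Parameter container

struct Params {
  fmat c1W, c2W, c3W, f1W, f2W, f3W;
  fvec c1b, c2b, c3b, f1b, f2b, f3b;
  fvec bn1g, bn1b, bn1m, bn1v;   // after conv2 (3d, 128 ch)
  fvec bn2g, bn2b, bn2m, bn2v;   // after conv3+relu (3d, 128 ch)
  fvec bn3g, bn3b, bn3m, bn3v;   // after fc2 (1d, 64)
};

struct Shapes {
  int n, K;
  ConvShape s1, s2, s3;
  int npool, flat;
};

static Shapes make_shapes(int n, int K) {
  if (n < 8) Rcpp::stop("input grid must have at least 8 points per edge");
  Shapes s;
  s.n = n; s.K = K;
  s.s1 = {4, 64, n, n - 1, 0};
  s.s2 = {64, 128, n - 1, n, 1};
  s.s3 = {128, 128, n, n - 1, 0};
  s.npool = (n - 1) / 2;
  s.flat = 128 * s.npool * s.npool * s.npool;
  return s;
}

static fmat init_mat(int rows, int cols, int fan_in, std::mt19937& rng) {
  const float b = 1.0f / std::sqrt((float)fan_in);
  std::uniform_real_distribution<float> u(-b, b);
  fmat m(rows, cols);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) m(i, j) = u(rng);
  return m;
}

static fvec init_vec(int len, int fan_in, std::mt19937& rng) {
  const float b = 1.0f / std::sqrt((float)fan_in);
  std::uniform_real_distribution<float> u(-b, b);
  fvec v(len);
  for (uword i = 0; i < v.n_elem; ++i) v(i) = u(rng);
  return v;
}

static Params init_params(const Shapes& sh, int seed) {
  std::mt19937 rng((unsigned)seed);
  Params p;
  p.c1W = init_mat(64, 4 * 8, 4 * 8, rng);    p.c1b = init_vec(64, 4 * 8, rng);
  p.c2W = init_mat(128, 64 * 8, 64 * 8, rng); p.c2b = init_vec(128, 64 * 8, rng);
  p.c3W = init_mat(128, 128 * 8, 128 * 8, rng);
  p.c3b = init_vec(128, 128 * 8, rng);
  p.f1W = init_mat(128, sh.flat, sh.flat, rng);
  p.f1b = init_vec(128, sh.flat, rng);
  p.f2W = init_mat(64, 128, 128, rng);        p.f2b = init_vec(64, 128, rng);
  p.f3W = init_mat(sh.K, 64, 64, rng);        p.f3b = init_vec(sh.K, 64, rng);
  auto bn = [](fvec& g, fvec& b2, fvec& m, fvec& v, int c) {
    g.ones(c); b2.zeros(c); m.zeros(c); v.ones(c);
  };
  bn(p.bn1g, p.bn1b, p.bn1m, p.bn1v, 128);
  bn(p.bn2g, p.bn2b, p.bn2m, p.bn2v, 128);
  bn(p.bn3g, p.bn3b, p.bn3m, p.bn3v, 64);
  return p;
}

// R <-> C++ parameter conversion -----------------------------------------

static Rcpp::List params_to_r(const Params& p) {
  using Rcpp::Named;
  auto M = [](const fmat& m) { return Rcpp::wrap(arma::conv_to<arma::mat>::from(m)); };
  auto V = [](const fvec& v) { return Rcpp::wrap(arma::conv_to<arma::vec>::from(v)); };
  return Rcpp::List::create(
    Named("conv1_W") = M(p.c1W), Named("conv1_b") = V(p.c1b),
    Named("conv2_W") = M(p.c2W), Named("conv2_b") = V(p.c2b),
    Named("bn1_gamma") = V(p.bn1g), Named("bn1_beta") = V(p.bn1b),
    Named("bn1_mean") = V(p.bn1m), Named("bn1_var") = V(p.bn1v),
    Named("conv3_W") = M(p.c3W), Named("conv3_b") = V(p.c3b),
    Named("bn2_gamma") = V(p.bn2g), Named("bn2_beta") = V(p.bn2b),
    Named("bn2_mean") = V(p.bn2m), Named("bn2_var") = V(p.bn2v),
    Named("fc1_W") = M(p.f1W), Named("fc1_b") = V(p.f1b),
    Named("fc2_W") = M(p.f2W), Named("fc2_b") = V(p.f2b),
    Named("bn3_gamma") = V(p.bn3g), Named("bn3_beta") = V(p.bn3b),
    Named("bn3_mean") = V(p.bn3m), Named("bn3_var") = V(p.bn3v),
    Named("fc3_W") = M(p.f3W), Named("fc3_b") = V(p.f3b));
}

static Params params_from_r(const Rcpp::List& l) {
  Params p;
  auto M = [&](const char* nm) {
    return arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(l[nm]));
  };
  auto V = [&](const char* nm) {
    return arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(l[nm]));
  };
  p.c1W = M("conv1_W"); p.c1b = V("conv1_b");
  p.c2W = M("conv2_W"); p.c2b = V("conv2_b");
  p.bn1g = V("bn1_gamma"); p.bn1b = V("bn1_beta");
  p.bn1m = V("bn1_mean"); p.bn1v = V("bn1_var");
  p.c3W = M("conv3_W"); p.c3b = V("conv3_b");
  p.bn2g = V("bn2_gamma"); p.bn2b = V("bn2_beta");
  p.bn2m = V("bn2_mean"); p.bn2v = V("bn2_var");
  p.f1W = M("fc1_W"); p.f1b = V("fc1_b");
  p.f2W = M("fc2_W"); p.f2b = V("fc2_b");
  p.bn3g = V("bn3_gamma"); p.bn3b = V("bn3_beta");
  p.bn3m = V("bn3_mean"); p.bn3v = V("bn3_var");
  p.f3W = M("fc3_W"); p.f3b = V("fc3_b");
  return p;
}

// ---------------------------------------------------------------------
// Layer helpers

static void add_bias(fmat& Y, const fvec& b) { Y.each_col() += b; }

// rowwise batch norm; returns normalized activations, stores caches
struct BNCache {
  fvec mean, invstd;
  fmat xhat;
};

static fmat bn_forward_train(const fmat& X, fvec& gamma, fvec& beta,
                             fvec& rmean, fvec& rvar, BNCache& cache) {
  const float m = (float)X.n_cols;
  cache.mean = arma::mean(X, 1);
  fmat centered = X.each_col() - cache.mean;
  fvec var = arma::mean(arma::square(centered), 1);
  cache.invstd = 1.0f / arma::sqrt(var + BN_EPS);
  cache.xhat = centered.each_col() % cache.invstd;
  float unbias = m > 1.0f ? m / (m - 1.0f) : 1.0f;
  rmean = (1.0f - BN_MOMENTUM) * rmean + BN_MOMENTUM * cache.mean;
  rvar = (1.0f - BN_MOMENTUM) * rvar + BN_MOMENTUM * (var * unbias);
  fmat out = cache.xhat.each_col() % gamma;
  out.each_col() += beta;
  return out;
}

static fmat bn_forward_eval(const fmat& X, const fvec& gamma,
                            const fvec& beta, const fvec& rmean,
                            const fvec& rvar) {
  fvec invstd = 1.0f / arma::sqrt(rvar + BN_EPS);
  fmat out = (X.each_col() - rmean);
  out.each_col() %= (gamma % invstd);
  out.each_col() += beta;
  return out;
}

static fmat bn_backward(const fmat& dY, const BNCache& cache,
                        const fvec& gamma, fvec& dgamma, fvec& dbeta) {
  const float m = (float)dY.n_cols;
  dgamma = arma::sum(dY % cache.xhat, 1);
  dbeta = arma::sum(dY, 1);
  fmat t = dY.each_col() % gamma;          // dL/dxhat
  fvec sum_t = arma::sum(t, 1);
  fvec sum_tx = arma::sum(t % cache.xhat, 1);
  fmat dX = t * m;
  dX.each_col() -= sum_t;
  dX -= cache.xhat.each_col() % sum_tx;
  dX.each_col() %= (cache.invstd / m);
  return dX;
}

// maxpool kernel 2 stride 2 over cube of edge v (floor), per channel
static fmat maxpool_forward(const fmat& X, int v, int B,
                            arma::umat& argmax) {
  const int p = v / 2;
  const long vin = (long)v * v * v, vout = (long)p * p * p;
  const int C = X.n_rows;
  fmat Y(C, (uword)B * vout);
  argmax.set_size(C, (uword)B * vout);
  for (int b = 0; b < B; ++b)
    for (int oz = 0; oz < p; ++oz)
      for (int oy = 0; oy < p; ++oy)
        for (int ox = 0; ox < p; ++ox) {
          const long oc = (long)b * vout + (long)oz * p * p +
            (long)oy * p + ox;
          const float* ptrs[8];
          long idxs[8];
          int t = 0;
          for (int kz = 0; kz < 2; ++kz)
            for (int ky = 0; ky < 2; ++ky)
              for (int kx = 0; kx < 2; ++kx) {
                idxs[t] = (long)b * vin + (long)(2 * oz + kz) * v * v +
                  (long)(2 * oy + ky) * v + (2 * ox + kx);
                ptrs[t] = X.colptr(idxs[t]);
                ++t;
              }
          float* yp = Y.colptr(oc);
          uword* ap = argmax.colptr(oc);
          for (int c = 0; c < C; ++c) {
            float best = ptrs[0][c];
            long besti = idxs[0];
            for (int u = 1; u < 8; ++u)
              if (ptrs[u][c] > best) { best = ptrs[u][c]; besti = idxs[u]; }
            yp[c] = best;
            ap[c] = (uword)besti;
          }
        }
  return Y;
}

static fmat maxpool_backward(const fmat& dY, const arma::umat& argmax,
                             int v, int B) {
  const int C = dY.n_rows;
  fmat dX(C, (uword)B * v * v * v, arma::fill::zeros);
  for (uword j = 0; j < dY.n_cols; ++j)
    for (int c = 0; c < C; ++c)
      dX(c, argmax(c, j)) += dY(c, j);
  return dX;
}

// reshape pooled maps (C, B*v) -> flat (C*v, B)
static fmat to_flat(const fmat& X, int B) {
  const int C = X.n_rows;
  const long v = X.n_cols / B;
  fmat Y(C * v, B);
  for (int b = 0; b < B; ++b)
    for (long j = 0; j < v; ++j)
      for (int c = 0; c < C; ++c)
        Y((uword)(c * v + j), b) = X(c, (uword)b * v + j);
  return Y;
}

static fmat from_flat(const fmat& Y, int C, int B) {
  const long v = Y.n_rows / C;
  fmat X(C, (uword)B * v);
  for (int b = 0; b < B; ++b)
    for (long j = 0; j < v; ++j)
      for (int c = 0; c < C; ++c)
        X(c, (uword)b * v + j) = Y((uword)(c * v + j), b);
  return X;
}

// ---------------------------------------------------------------------
// Forward pass (shared by train/eval); caches live in the struct.

struct Cache {
  fmat x0, col1, a1, col2, a2, bn1out, col3, a3, relu3, bn2out, pooled,
    flat, z1, r1, drop, z2, bn3out, r2, probs;
  BNCache bn1c, bn2c, bn3c;
  arma::umat argmax;
  fmat dropmask;
};

static fmat forward(const Params& p, const Shapes& sh, const fmat& X,
                    int B, bool training, Cache* cache,
                    std::mt19937* rng) {
  Cache local;
  Cache& c = cache ? *cache : local;
  Params& pp = const_cast<Params&>(p);
  // samples arrive as one feature column per sample; rearrange into the
  // channel-major activation layout (4, B*n^3)
  c.x0 = from_flat(X, 4, B);
  // conv1
  im2col(c.x0, c.col1, sh.s1, B);
  c.a1 = p.c1W * c.col1; add_bias(c.a1, p.c1b);
  // conv2 (pad 1)
  im2col(c.a1, c.col2, sh.s2, B);
  c.a2 = p.c2W * c.col2; add_bias(c.a2, p.c2b);
  // bn1
  c.bn1out = training
    ? bn_forward_train(c.a2, pp.bn1g, pp.bn1b, pp.bn1m, pp.bn1v, c.bn1c)
    : bn_forward_eval(c.a2, p.bn1g, p.bn1b, p.bn1m, p.bn1v);
  // conv3
  im2col(c.bn1out, c.col3, sh.s3, B);
  c.a3 = p.c3W * c.col3; add_bias(c.a3, p.c3b);
  // relu then bn2
  c.relu3 = arma::clamp(c.a3, 0.0f, std::numeric_limits<float>::max());
  c.bn2out = training
    ? bn_forward_train(c.relu3, pp.bn2g, pp.bn2b, pp.bn2m, pp.bn2v, c.bn2c)
    : bn_forward_eval(c.relu3, p.bn2g, p.bn2b, p.bn2m, p.bn2v);
  // maxpool + flatten
  c.pooled = maxpool_forward(c.bn2out, sh.s3.nout, B, c.argmax);
  c.flat = to_flat(c.pooled, B);
  // fc1 + relu + dropout
  c.z1 = p.f1W * c.flat; add_bias(c.z1, p.f1b);
  c.r1 = arma::clamp(c.z1, 0.0f, std::numeric_limits<float>::max());
  if (training) {
    std::uniform_real_distribution<float> u(0.0f, 1.0f);
    c.dropmask.set_size(c.r1.n_rows, c.r1.n_cols);
    for (uword j = 0; j < c.dropmask.n_cols; ++j)
      for (uword i = 0; i < c.dropmask.n_rows; ++i)
        c.dropmask(i, j) = (u(*rng) < 0.4f) ? 0.0f : (1.0f / 0.6f);
    c.drop = c.r1 % c.dropmask;
  } else {
    c.drop = c.r1;
  }
  // fc2 + bn3 + relu
  c.z2 = p.f2W * c.drop; add_bias(c.z2, p.f2b);
  c.bn3out = training
    ? bn_forward_train(c.z2, pp.bn3g, pp.bn3b, pp.bn3m, pp.bn3v, c.bn3c)
    : bn_forward_eval(c.z2, p.bn3g, p.bn3b, p.bn3m, p.bn3v);
  c.r2 = arma::clamp(c.bn3out, 0.0f, std::numeric_limits<float>::max());
  // fc3 + sigmoid
  fmat z3 = p.f3W * c.r2; add_bias(z3, p.f3b);
  c.probs = 1.0f / (1.0f + arma::exp(-z3));
  return c.probs;
}

// gradient container mirrors Params (bn running stats have no grads)
struct Grads {
  fmat c1W, c2W, c3W, f1W, f2W, f3W;
  fvec c1b, c2b, c3b, f1b, f2b, f3b;
  fvec bn1g, bn1b, bn2g, bn2b, bn3g, bn3b;
};

static void backward(const Params& p, const Shapes& sh, const fmat& X,
                     const fmat& Y, Cache& c, int B, Grads& g) {
  // BCE summed over labels, averaged over the batch
  fmat dz3 = (c.probs - Y) / (float)B;                 // K x B
  g.f3W = dz3 * c.r2.t(); g.f3b = arma::sum(dz3, 1);
  fmat dr2 = p.f3W.t() * dz3;
  dr2 %= arma::conv_to<fmat>::from(c.bn3out > 0.0f);
  fmat dz2 = bn_backward(dr2, c.bn3c, p.bn3g, g.bn3g, g.bn3b);
  g.f2W = dz2 * c.drop.t(); g.f2b = arma::sum(dz2, 1);
  fmat ddrop = p.f2W.t() * dz2;
  ddrop %= c.dropmask;
  ddrop %= arma::conv_to<fmat>::from(c.z1 > 0.0f);
  g.f1W = ddrop * c.flat.t(); g.f1b = arma::sum(ddrop, 1);
  fmat dflat = p.f1W.t() * ddrop;
  fmat dpooled = from_flat(dflat, 128, B);
  fmat dbn2 = maxpool_backward(dpooled, c.argmax, sh.s3.nout, B);
  fmat drelu3 = bn_backward(dbn2, c.bn2c, p.bn2g, g.bn2g, g.bn2b);
  drelu3 %= arma::conv_to<fmat>::from(c.a3 > 0.0f);
  g.c3W = drelu3 * c.col3.t(); g.c3b = arma::sum(drelu3, 1);
  fmat dcol3 = p.c3W.t() * drelu3;
  fmat dbn1;
  col2im(dcol3, dbn1, sh.s3, B);
  fmat da2 = bn_backward(dbn1, c.bn1c, p.bn1g, g.bn1g, g.bn1b);
  g.c2W = da2 * c.col2.t(); g.c2b = arma::sum(da2, 1);
  fmat dcol2 = p.c2W.t() * da2;
  fmat da1;
  col2im(dcol2, da1, sh.s2, B);
  g.c1W = da1 * c.col1.t(); g.c1b = arma::sum(da1, 1);
  // no gradient w.r.t. the input needed
}

static void sgd_step(Params& p, const Grads& g, float lr) {
  p.c1W -= lr * g.c1W; p.c1b -= lr * g.c1b;
  p.c2W -= lr * g.c2W; p.c2b -= lr * g.c2b;
  p.c3W -= lr * g.c3W; p.c3b -= lr * g.c3b;
  p.f1W -= lr * g.f1W; p.f1b -= lr * g.f1b;
  p.f2W -= lr * g.f2W; p.f2b -= lr * g.f2b;
  p.f3W -= lr * g.f3W; p.f3b -= lr * g.f3b;
  p.bn1g -= lr * g.bn1g; p.bn1b -= lr * g.bn1b;
  p.bn2g -= lr * g.bn2g; p.bn2b -= lr * g.bn2b;
  p.bn3g -= lr * g.bn3g; p.bn3b -= lr * g.bn3b;
}

static double batch_loss(const fmat& probs, const fmat& Y) {
  fmat p = arma::clamp(probs, 1e-7f, 1.0f - 1e-7f);
  fmat l = -(Y % arma::log(p) + (1.0f - Y) % arma::log(1.0f - p));
  return arma::accu(l) / (double)Y.n_cols;   // sum over labels, mean over batch
}

// ---------------------------------------------------------------------
// Exported interface

// [[Rcpp::export]]
Rcpp::List cnn_init_cpp(int n, int K, int seed) {
  Shapes sh = make_shapes(n, K);
  Params p = init_params(sh, seed);
  Rcpp::List out = params_to_r(p);
  out.attr("flat") = sh.flat;
  return out;
}

// X: (4*n^3) x N column-per-sample matrix; Y: K x N 0/1 matrix
// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List params_r, const arma::mat& X,
                         const arma::mat& Y, int n, int epochs,
                         double lr, int batch_size, int seed) {
  const int N = X.n_cols;
  if (N == 0) Rcpp::stop("empty training set");
  const int K = Y.n_rows;
  Shapes sh = make_shapes(n, K);
  if ((long)X.n_rows != 4L * n * n * n)
    Rcpp::stop("sample length does not match 4*n^3");
  Params p = params_from_r(params_r);
  fmat Xf = arma::conv_to<fmat>::from(X);
  fmat Yf = arma::conv_to<fmat>::from(Y);
  std::mt19937 rng((unsigned)seed);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  std::vector<double> losses;
  losses.reserve(epochs);
  const long F = 4L * n * n * n;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double esum = 0.0;
    int nb = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int B = std::min(batch_size, N - start);
      fmat xb(F, B), yb(K, B);
      for (int b = 0; b < B; ++b) {
        xb.col(b) = Xf.col(idx[start + b]);
        yb.col(b) = Yf.col(idx[start + b]);
      }
      Cache cache;
      forward(p, sh, xb, B, true, &cache, &rng);
      esum += batch_loss(cache.probs, yb);
      ++nb;
      Grads g;
      backward(p, sh, xb, yb, cache, B, g);
      sgd_step(p, g, (float)lr);
      if ((start / batch_size) % 16 == 0) Rcpp::checkUserInterrupt();
    }
    losses.push_back(esum / nb);
    if (!std::isfinite(losses.back()))
      Rcpp::stop("training loss became non-finite at epoch %d", e + 1);
  }
  return Rcpp::List::create(Rcpp::Named("params") = params_to_r(p),
                            Rcpp::Named("loss") = losses);
}

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(Rcpp::List params_r, const arma::mat& X, int n,
                          int K) {
  Shapes sh = make_shapes(n, K);
  if ((long)X.n_rows != 4L * n * n * n)
    Rcpp::stop("sample length does not match 4*n^3");
  Params p = params_from_r(params_r);
  const int N = X.n_cols;
  arma::mat out(K, N);
  // evaluate in moderate chunks to bound im2col memory
  const int chunk = std::max(1, 4096 / std::max(1, n * n * n / 256));
  for (int start = 0; start < N; start += chunk) {
    const int B = std::min(chunk, N - start);
    fmat xb = arma::conv_to<fmat>::from(
      X.cols(start, start + B - 1));
    fmat probs = forward(p, sh, xb, B, false, nullptr, nullptr);
    out.cols(start, start + B - 1) =
      arma::conv_to<arma::mat>::from(probs);
  }
  return out;
}
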