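// Convolutional network for preictal/interictal window classification.
//
// Per conv block: convolution (valid padding, stride 1, no bias) -> batch
// normalization -> ReLU -> max pooling -> dropout; the last block's output
// is flattened into a dense ReLU head ending in a single sigmoid unit,
// trained with binary cross-entropy and Adam.
//
// Layout: activations of a block live in one matrix of shape
// maps x (h*w*n) with columns ordered sample-major, spatial (h fast)
// within a sample, so batch normalization is a per-row reduction over
// contiguous maps-length columns, each sample's block is a contiguous
// submatrix (flattening is a reinterpret), and convolution is a single
// GEMM per block over an im2col matrix built for the whole batch. Weight
// matrices are maps x (kh*kw*cin) with column index (j*kh + i)*cin + c
// (offset-major, channel-minor), matching the im2col row order.
//
// Arithmetic is single precision (standard for neural-network training);
// parameters cross the R boundary as double-precision arrays so
// checkpoints are ordinary R objects.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace Rcpp;

namespace {

typedef float real;
typedef arma::fmat RMat;
typedef arma::fvec RVec;
typedef arma::frowvec RRow;
typedef arma::fcube RCube;

struct ConvBlock {
  int maps, kh, kw, ph, pw;
  double dropout;
  RMat W;               // maps x (kh*kw*cin)
  RVec gamma, beta, run_mean, run_var;
  int cin, hin, win, hc, wc, hp, wp;
};

struct Dense {
  RMat W;               // out x in
  RVec b;
};

struct Net {
  std::vector<ConvBlock> conv;
  std::vector<Dense> dense;
  int n_ch, n_samp, flat;
};

const real BN_EPS = 1e-5f;
const real BN_MOMENTUM = 0.1f;

int trace_shapes(Net& net, int* bad) {
  int h = net.n_ch, w = net.n_samp;
  for (size_t i = 0; i < net.conv.size(); ++i) {
    ConvBlock& B = net.conv[i];
    B.hin = h; B.win = w;
    if (h < B.kh || w < B.kw) { if (bad) *bad = (int)i + 1; return -1; }
    B.hc = h - B.kh + 1; B.wc = w - B.kw + 1;
    B.hp = B.hc / B.ph; B.wp = B.wc / B.pw;
    if (B.hp < 1 || B.wp < 1) { if (bad) *bad = (int)i + 1; return -1; }
    h = B.hp; w = B.wp;
  }
  net.flat = net.conv.empty() ? net.n_ch * net.n_samp
                              : net.conv.back().maps * h * w;
  return 0;
}

RMat to_real(const arma::mat& m) { return arma::conv_to<RMat>::from(m); }
RVec to_real_v(const arma::vec& v) { return arma::conv_to<RVec>::from(v); }

Net net_from_list(const List& params) {
  Net net;
  net.n_ch = as<int>(params["n_channels"]);
  net.n_samp = as<int>(params["n_samples"]);
  List conv = params["conv"];
  int cin = 1;
  for (int i = 0; i < conv.size(); ++i) {
    List b = conv[i];
    ConvBlock B;
    B.maps = as<int>(b["maps"]); B.kh = as<int>(b["kh"]);
    B.kw = as<int>(b["kw"]); B.ph = as<int>(b["ph"]); B.pw = as<int>(b["pw"]);
    B.dropout = as<double>(b["dropout"]);
    B.cin = cin;
    B.W = to_real(as<arma::mat>(b["W"]));
    B.gamma = to_real_v(as<arma::vec>(b["gamma"]));
    B.beta = to_real_v(as<arma::vec>(b["beta"]));
    B.run_mean = to_real_v(as<arma::vec>(b["run_mean"]));
    B.run_var = to_real_v(as<arma::vec>(b["run_var"]));
    cin = B.maps;
    net.conv.push_back(B);
  }
  List dense = params["dense"];
  for (int i = 0; i < dense.size(); ++i) {
    List d = dense[i];
    Dense D;
    D.W = to_real(as<arma::mat>(d["W"]));
    D.b = to_real_v(as<arma::vec>(d["b"]));
    net.dense.push_back(D);
  }
  int bad = 0;
  if (trace_shapes(net, &bad) < 0)
    stop("input too small for conv/pool block %d", bad);
  return net;
}

List net_to_list(const Net& net) {
  List conv(net.conv.size());
  for (size_t i = 0; i < net.conv.size(); ++i) {
    const ConvBlock& B = net.conv[i];
    conv[i] = List::create(
      _["maps"] = B.maps, _["kh"] = B.kh, _["kw"] = B.kw,
      _["ph"] = B.ph, _["pw"] = B.pw, _["dropout"] = B.dropout,
      _["W"] = arma::conv_to<arma::mat>::from(B.W),
      _["gamma"] = arma::conv_to<arma::vec>::from(B.gamma),
      _["beta"] = arma::conv_to<arma::vec>::from(B.beta),
      _["run_mean"] = arma::conv_to<arma::vec>::from(B.run_mean),
      _["run_var"] = arma::conv_to<arma::vec>::from(B.run_var));
  }
  List dense(net.dense.size());
  for (size_t i = 0; i < net.dense.size(); ++i)
    dense[i] = List::create(
      _["W"] = arma::conv_to<arma::mat>::from(net.dense[i].W),
      _["b"] = arma::conv_to<arma::vec>::from(net.dense[i].b));
  return List::create(_["n_channels"] = net.n_ch, _["n_samples"] = net.n_samp,
                      _["conv"] = conv, _["dense"] = dense);
}

// im2col over the whole batch. src: cin x (hin*win*n), sample-major
// columns; dst: (kh*kw*cin) x (hc*wc*n).
void im2col(const RMat& src, const ConvBlock& B, int n, RMat& dst) {
  const int hin = B.hin, hc = B.hc, wc = B.wc, cin = B.cin;
  const size_t hw_in = (size_t)B.hin * B.win, hw_out = (size_t)hc * wc;
  dst.set_size(B.kh * B.kw * cin, hw_out * n);
  const size_t drows = dst.n_rows;
  for (int s = 0; s < n; ++s)
    for (int j = 0; j < B.kw; ++j)
      for (int i = 0; i < B.kh; ++i) {
        const int rb = (j * B.kh + i) * cin;
        for (int w = 0; w < wc; ++w) {
          const real* sp = src.colptr(s * hw_in + (size_t)(w + j) * hin + i);
          real* dp = dst.colptr(s * hw_out + (size_t)w * hc) + rb;
          for (int h = 0; h < hc; ++h) {
            const real* c0 = sp + (size_t)h * cin;
            real* d0 = dp + (size_t)h * drows;
            for (int c = 0; c < cin; ++c) d0[c] = c0[c];
          }
        }
      }
}

// scatter-add transpose of im2col
void col2im_add(const RMat& cols, const ConvBlock& B, int n, RMat& gsrc) {
  const int hin = B.hin, hc = B.hc, wc = B.wc, cin = B.cin;
  const size_t hw_in = (size_t)B.hin * B.win, hw_out = (size_t)hc * wc;
  const size_t srows = cols.n_rows;
  for (int s = 0; s < n; ++s)
    for (int j = 0; j < B.kw; ++j)
      for (int i = 0; i < B.kh; ++i) {
        const int rb = (j * B.kh + i) * cin;
        for (int w = 0; w < wc; ++w) {
          real* dp = gsrc.colptr(s * hw_in + (size_t)(w + j) * hin + i);
          const real* sp = cols.colptr(s * hw_out + (size_t)w * hc) + rb;
          for (int h = 0; h < hc; ++h) {
            real* d0 = dp + (size_t)h * cin;
            const real* c0 = sp + (size_t)h * srows;
            for (int c = 0; c < cin; ++c) d0[c] += c0[c];
          }
        }
      }
}

struct BlockCache {
  RMat cols;                    // im2col input (freed during backward)
  RMat xhat;                    // normalized conv output
  RMat pooled;                  // block output (after dropout)
  arma::Mat<unsigned char> arg; // pooling winner offset (jj*ph+ii)
  arma::Mat<unsigned char> keep;// dropout keep mask (empty if inactive)
  RVec invstd;
};

struct BatchCache {
  std::vector<BlockCache> blk;
  std::vector<RMat> dense_in, dense_pre;
  RRow prob;
};

// Forward one batch; idx selects slices of X (n_ch x n_samp x n).
// training: batchnorm normalizes with batch statistics (updating running
// ones with `bn_momentum`) and dropout is live unless `use_dropout` is
// false (the statistics-refresh pass runs with frozen weights, dropout
// off, and cumulative-average momentum).
void forward(Net& net, const RCube& X, const arma::uvec& idx,
             bool training, std::mt19937& rng, BatchCache& C,
             bool need_cache, real bn_momentum = BN_MOMENTUM,
             bool use_dropout = true) {
  const int n = (int)idx.n_elem;
  C.blk.assign(net.conv.size(), BlockCache());
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  RMat cur(1, (size_t)net.n_ch * net.n_samp * n);
  {
    const size_t hw = (size_t)net.n_ch * net.n_samp;
    for (int s = 0; s < n; ++s)
      std::copy(X.slice_memptr(idx(s)), X.slice_memptr(idx(s)) + hw,
                cur.memptr() + s * hw);
  }

  for (size_t b = 0; b < net.conv.size(); ++b) {
    ConvBlock& B = net.conv[b];
    BlockCache& K = C.blk[b];
    const size_t hw_out = (size_t)B.hc * B.wc, hw_pool = (size_t)B.hp * B.wp;
    im2col(cur, B, n, K.cols);
    RMat out = B.W * K.cols;                   // maps x hw_out*n
    cur.reset();
    const int M = B.maps;
    const size_t ncol = out.n_cols;
    const real cnt = (real)((double)ncol);
    // batch statistics (single pass over the matrix)
    RVec mean(M), var(M);
    if (training) {
      std::vector<double> s1(M, 0.0), s2(M, 0.0);
      const real* p = out.memptr();
      for (size_t c = 0; c < ncol; ++c, p += M)
        for (int m = 0; m < M; ++m) { s1[m] += p[m]; s2[m] += (double)p[m] * p[m]; }
      for (int m = 0; m < M; ++m) {
        mean(m) = (real)(s1[m] / ncol);
        var(m) = (real)(s2[m] / ncol - (s1[m] / ncol) * (s1[m] / ncol));
        if (var(m) < 0) var(m) = 0;
      }
      real corr = cnt / std::max(cnt - 1.0f, 1.0f);
      B.run_mean = (1 - bn_momentum) * B.run_mean + bn_momentum * mean;
      B.run_var = (1 - bn_momentum) * B.run_var + bn_momentum * corr * var;
    } else {
      mean = B.run_mean; var = B.run_var;
    }
    K.invstd.set_size(M);
    for (int m = 0; m < M; ++m)
      K.invstd(m) = 1.0f / std::sqrt(var(m) + BN_EPS);
    // normalize, scale-shift, ReLU in one pass (xhat cached if needed)
    if (need_cache) K.xhat.set_size(M, ncol);
    {
      real* p = out.memptr();
      real* xh = need_cache ? K.xhat.memptr() : nullptr;
      for (size_t c = 0; c < ncol; ++c, p += M) {
        for (int m = 0; m < M; ++m) {
          real z = (p[m] - mean(m)) * K.invstd(m);
          if (xh) xh[m] = z;
          real a = B.gamma(m) * z + B.beta(m);
          p[m] = a > 0 ? a : 0;
        }
        if (xh) xh += M;
      }
    }
    // max pooling
    K.pooled.set_size(M, hw_pool * n);
    if (need_cache) K.arg.set_size(M, hw_pool * n);
    for (int s = 0; s < n; ++s)
      for (int w = 0; w < B.wp; ++w)
        for (int h = 0; h < B.hp; ++h) {
          const size_t oc = (size_t)s * hw_pool + (size_t)w * B.hp + h;
          real* op = K.pooled.colptr(oc);
          unsigned char* ap = need_cache ? K.arg.colptr(oc) : nullptr;
          bool first = true;
          for (int jj = 0; jj < B.pw; ++jj)
            for (int ii = 0; ii < B.ph; ++ii) {
              const size_t ic = (size_t)s * hw_out
                + (size_t)(w * B.pw + jj) * B.hc + h * B.ph + ii;
              const real* ip = out.colptr(ic);
              const unsigned char off = (unsigned char)(jj * B.ph + ii);
              if (first) {
                for (int m = 0; m < M; ++m) op[m] = ip[m];
                if (ap) for (int m = 0; m < M; ++m) ap[m] = off;
                first = false;
              } else {
                for (int m = 0; m < M; ++m)
                  if (ip[m] > op[m]) { op[m] = ip[m]; if (ap) ap[m] = off; }
              }
            }
        }
    if (training && use_dropout && B.dropout > 0) {
      const double keep = 1.0 - B.dropout;
      const real scale = (real)(1.0 / keep);
      K.keep.set_size(M, hw_pool * n);
      real* pp = K.pooled.memptr();
      unsigned char* kp = K.keep.memptr();
      const size_t ne = K.pooled.n_elem;
      for (size_t t = 0; t < ne; ++t) {
        if (unif(rng) < keep) { kp[t] = 1; pp[t] *= scale; }
        else { kp[t] = 0; pp[t] = 0.0f; }
      }
    }
    if (!need_cache) K.cols.reset();
    cur = K.pooled;
  }
  RMat h = arma::reshape(cur, net.flat, n);
  C.dense_in.clear(); C.dense_pre.clear();
  for (size_t d = 0; d < net.dense.size(); ++d) {
    if (need_cache) C.dense_in.push_back(h);
    RMat z = net.dense[d].W * h;
    z.each_col() += net.dense[d].b;
    if (need_cache) C.dense_pre.push_back(z);
    if (d + 1 < net.dense.size())
      h = arma::clamp(z, 0.0f, std::numeric_limits<real>::max());
    else
      h = 1.0f / (1.0f + arma::exp(-z));
  }
  C.prob = h.row(0);
}

struct Grads {
  std::vector<RMat> convW;
  std::vector<RVec> gamma, beta;
  std::vector<RMat> denseW;
  std::vector<RVec> denseB;
};

void backward(Net& net, int n, const RRow& y, BatchCache& C, Grads& G) {
  G.convW.resize(net.conv.size());
  G.gamma.resize(net.conv.size()); G.beta.resize(net.conv.size());
  G.denseW.resize(net.dense.size()); G.denseB.resize(net.dense.size());

  RMat dz = (C.prob - y) / (real)n;            // 1 x n
  for (int d = (int)net.dense.size() - 1; d >= 0; --d) {
    G.denseW[d] = dz * C.dense_in[d].t();
    G.denseB[d] = arma::sum(dz, 1);
    RMat dh = net.dense[d].W.t() * dz;
    if (d > 0) {
      const RMat& pre = C.dense_pre[d - 1];
      dz = dh;
      real* p = dz.memptr(); const real* q = pre.memptr();
      for (size_t t = 0; t < dz.n_elem; ++t) if (q[t] <= 0) p[t] = 0;
    } else {
      dz = dh;
    }
  }
  const ConvBlock& last = net.conv.back();
  RMat dpool = arma::reshape(dz, last.maps, (size_t)last.hp * last.wp * n);
  for (int b = (int)net.conv.size() - 1; b >= 0; --b) {
    ConvBlock& B = net.conv[b];
    BlockCache& K = C.blk[b];
    const size_t hw_out = (size_t)B.hc * B.wc, hw_pool = (size_t)B.hp * B.wp;
    const int M = B.maps;
    if (K.keep.n_elem) {
      const real scale = (real)(1.0 / (1.0 - B.dropout));
      real* dp = dpool.memptr();
      const unsigned char* kp = K.keep.memptr();
      for (size_t t = 0; t < dpool.n_elem; ++t)
        dp[t] = kp[t] ? dp[t] * scale : 0.0f;
    }
    // unpool + ReLU gate: gradient reaches only the pooling winner, and
    // only if its (pre-dropout) pooled value was positive
    RMat dout(M, hw_out * n, arma::fill::zeros);
    for (int s = 0; s < n; ++s)
      for (int w = 0; w < B.wp; ++w)
        for (int h = 0; h < B.hp; ++h) {
          const size_t oc = (size_t)s * hw_pool + (size_t)w * B.hp + h;
          const real* gp = dpool.colptr(oc);
          const real* pv = K.pooled.colptr(oc);
          const unsigned char* ap = K.arg.colptr(oc);
          const size_t base = (size_t)s * hw_out + (size_t)(w * B.pw) * B.hc
            + (size_t)h * B.ph;
          for (int m = 0; m < M; ++m) {
            if (gp[m] == 0.0f || pv[m] <= 0.0f) continue;
            const int ii = ap[m] % B.ph, jj = ap[m] / B.ph;
            dout.at(m, base + (size_t)jj * B.hc + ii) += gp[m];
          }
        }
    dpool.reset();
    // fused batchnorm backward: pass 1 accumulates the reductions
    const size_t ncol = dout.n_cols;
    std::vector<double> sbeta(M, 0.0), sgamma(M, 0.0);
    {
      const real* dp = dout.memptr(); const real* xh = K.xhat.memptr();
      for (size_t c = 0; c < ncol; ++c, dp += M, xh += M)
        for (int m = 0; m < M; ++m) {
          sbeta[m] += dp[m];
          sgamma[m] += (double)dp[m] * xh[m];
        }
    }
    G.gamma[b].set_size(M); G.beta[b].set_size(M);
    for (int m = 0; m < M; ++m) {
      G.gamma[b](m) = (real)sgamma[m]; G.beta[b](m) = (real)sbeta[m];
    }
    // pass 2: dpre = invstd*gamma/cnt * (cnt*dout - sbeta - xhat*sgamma)
    {
      const real cnt = (real)((double)ncol);
      std::vector<real> a(M), c1(M), c2(M);
      for (int m = 0; m < M; ++m) {
        a[m] = K.invstd(m) * B.gamma(m) / cnt;
        c1[m] = (real)sbeta[m];
        c2[m] = (real)sgamma[m];
      }
      real* dp = dout.memptr(); const real* xh = K.xhat.memptr();
      for (size_t c = 0; c < ncol; ++c, dp += M, xh += M)
        for (int m = 0; m < M; ++m)
          dp[m] = a[m] * (cnt * dp[m] - c1[m] - xh[m] * c2[m]);
    }
    K.xhat.reset();
    G.convW[b] = dout * K.cols.t();
    K.cols.reset();
    if (b > 0) {
      RMat dcols = B.W.t() * dout;
      dout.reset();
      const ConvBlock& P = net.conv[b - 1];
      dpool.zeros(P.maps, (size_t)P.hp * P.wp * n);
      col2im_add(dcols, B, n, dpool);
    }
  }
}

struct AdamState {
  std::vector<RMat> mW, vW;
  std::vector<RVec> mg, vg, mb, vb;
  std::vector<RMat> mDW, vDW;
  std::vector<RVec> mDb, vDb;
  long t = 0;
  void init(const Net& net) {
    size_t nc = net.conv.size(), nd = net.dense.size();
    mW.resize(nc); vW.resize(nc); mg.resize(nc); vg.resize(nc);
    mb.resize(nc); vb.resize(nc);
    for (size_t i = 0; i < nc; ++i) {
      mW[i].zeros(net.conv[i].W.n_rows, net.conv[i].W.n_cols);
      vW[i] = mW[i];
      mg[i].zeros(net.conv[i].maps); vg[i] = mg[i];
      mb[i] = mg[i]; vb[i] = mg[i];
    }
    mDW.resize(nd); vDW.resize(nd); mDb.resize(nd); vDb.resize(nd);
    for (size_t i = 0; i < nd; ++i) {
      mDW[i].zeros(net.dense[i].W.n_rows, net.dense[i].W.n_cols);
      vDW[i] = mDW[i];
      mDb[i].zeros(net.dense[i].b.n_elem); vDb[i] = mDb[i];
    }
  }
};

template <class T>
void adam_update(T& w, T& m, T& v, const T& g, real lr, long t) {
  const real b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  real c1 = 1 - std::pow(b1, (real)t), c2 = 1 - std::pow(b2, (real)t);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}

void apply_grads(Net& net, Grads& G, AdamState& A, real lr) {
  ++A.t;
  for (size_t i = 0; i < net.conv.size(); ++i) {
    adam_update(net.conv[i].W, A.mW[i], A.vW[i], G.convW[i], lr, A.t);
    adam_update(net.conv[i].gamma, A.mg[i], A.vg[i], G.gamma[i], lr, A.t);
    adam_update(net.conv[i].beta, A.mb[i], A.vb[i], G.beta[i], lr, A.t);
  }
  for (size_t i = 0; i < net.dense.size(); ++i) {
    adam_update(net.dense[i].W, A.mDW[i], A.vDW[i], G.denseW[i], lr, A.t);
    adam_update(net.dense[i].b, A.mDb[i], A.vDb[i], G.denseB[i], lr, A.t);
  }
}

// Precise-BN refresh: recompute the running statistics under the current
// weights with dropout off, as the cumulative average of batch statistics.
// Without this the running averages lag the rapidly-moving weights of a
// short training run and inference collapses.
void refresh_bn_stats(Net& net, const RCube& X, const arma::uvec& order,
                      int batch_size, std::mt19937& rng) {
  const int n = (int)order.n_elem;
  long k = 0;
  for (int at = 0; at < n; at += batch_size) {
    int hi = std::min(at + batch_size, n);
    if (hi - at < 2) continue;
    ++k;
    BatchCache C;
    forward(net, X, order.subvec(at, hi - 1), true, rng, C, false,
            (real)(1.0 / k), false);
  }
}

double bce(const RRow& p, const RRow& y) {
  const double eps = 1e-9;
  double L = 0;
  for (arma::uword i = 0; i < p.n_elem; ++i) {
    double pi = std::min(std::max((double)p(i), eps), 1 - eps);
    L += -(y(i) * std::log(pi) + (1 - y(i)) * std::log(1 - pi));
  }
  return L / p.n_elem;
}

RCube cube_from_r(NumericVector x, int n_ch, int n_samp) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3 || dim[0] != n_ch || dim[1] != n_samp)
    stop("window shape mismatch: model expects %d x %d", n_ch, n_samp);
  RCube X(dim[0], dim[1], dim[2]);
  std::copy(x.begin(), x.end(), X.memptr());
  return X;
}

} // namespace

// [[Rcpp::export(name = ".cnn_shape_trace")]]
IntegerVector cnn_shape_trace(int n_channels, int n_samples, List blocks) {
  Net net; net.n_ch = n_channels; net.n_samp = n_samples;
  int cin = 1;
  for (int i = 0; i < blocks.size(); ++i) {
    List b = blocks[i];
    ConvBlock B;
    B.maps = as<int>(b["maps"]); B.kh = as<int>(b["kh"]);
    B.kw = as<int>(b["kw"]); B.ph = as<int>(b["ph"]); B.pw = as<int>(b["pw"]);
    B.dropout = 0; B.cin = cin; cin = B.maps;
    net.conv.push_back(B);
  }
  int bad = 0;
  if (trace_shapes(net, &bad) < 0)
    stop("input too small for conv/pool block %d", bad);
  int h = net.conv.empty() ? n_channels : net.conv.back().hp;
  int w = net.conv.empty() ? n_samples : net.conv.back().wp;
  return IntegerVector::create(_["channel_extent"] = h,
                               _["time_extent"] = w,
                               _["flatten_dim"] = net.flat);
}

// [[Rcpp::export(name = ".cnn_init")]]
List cnn_init(int n_channels, int n_samples, List blocks,
              IntegerVector dense_units, int seed) {
  Net net; net.n_ch = n_channels; net.n_samp = n_samples;
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  int cin = 1;
  for (int i = 0; i < blocks.size(); ++i) {
    List b = blocks[i];
    ConvBlock B;
    B.maps = as<int>(b["maps"]); B.kh = as<int>(b["kh"]);
    B.kw = as<int>(b["kw"]); B.ph = as<int>(b["ph"]); B.pw = as<int>(b["pw"]);
    B.dropout = as<double>(b["dropout"]);
    B.cin = cin;
    int fan_in = B.kh * B.kw * cin;
    B.W.set_size(B.maps, fan_in);
    double sd = std::sqrt(2.0 / fan_in);
    for (auto& v : B.W) v = (real)(sd * gauss(rng));
    B.gamma.ones(B.maps); B.beta.zeros(B.maps);
    B.run_mean.zeros(B.maps); B.run_var.ones(B.maps);
    cin = B.maps;
    net.conv.push_back(B);
  }
  int bad = 0;
  if (trace_shapes(net, &bad) < 0)
    stop("input too small for conv/pool block %d", bad);
  int in = net.flat;
  for (int i = 0; i <= dense_units.size(); ++i) {
    int out = (i < dense_units.size()) ? dense_units[i] : 1;
    Dense D; D.W.set_size(out, in); D.b.zeros(out);
    double sd = std::sqrt(2.0 / in);
    for (auto& v : D.W) v = (real)(sd * gauss(rng));
    net.dense.push_back(D);
    in = out;
  }
  return net_to_list(net);
}

// [[Rcpp::export(name = ".cnn_predict")]]
NumericVector cnn_predict(List params, NumericVector x) {
  Net net = net_from_list(params);
  RCube X = cube_from_r(x, net.n_ch, net.n_samp);
  int n = (int)X.n_slices;
  NumericVector out(n);
  std::mt19937 rng(0);
  const int chunk = 64;
  for (int at = 0; at < n; at += chunk) {
    int hi = std::min(at + chunk, n);
    arma::uvec idx = arma::regspace<arma::uvec>(at, hi - 1);
    BatchCache C;
    forward(net, X, idx, false, rng, C, false);
    for (int i = at; i < hi; ++i) out[i] = C.prob(i - at);
  }
  return out;
}

// Full-batch loss and analytic parameter gradients (train-mode batchnorm;
// dropout is inactive when all rates are 0). Used by the finite-difference
// gradient-check tests.
// [[Rcpp::export(name = ".cnn_loss_grad")]]
List cnn_loss_grad(List params, NumericVector x, NumericVector y_) {
  Net net = net_from_list(params);
  RCube X = cube_from_r(x, net.n_ch, net.n_samp);
  int n = (int)X.n_slices;
  RRow y(n);
  for (int i = 0; i < n; ++i) y(i) = (real)y_[i];
  arma::uvec idx = arma::regspace<arma::uvec>(0, n - 1);
  std::mt19937 rng(1);
  BatchCache C;
  forward(net, X, idx, true, rng, C, true);
  double L = bce(C.prob, y);
  Grads G;
  backward(net, n, y, C, G);
  List convG(net.conv.size());
  for (size_t i = 0; i < net.conv.size(); ++i)
    convG[i] = List::create(
      _["W"] = arma::conv_to<arma::mat>::from(G.convW[i]),
      _["gamma"] = arma::conv_to<arma::vec>::from(G.gamma[i]),
      _["beta"] = arma::conv_to<arma::vec>::from(G.beta[i]));
  List denseG(net.dense.size());
  for (size_t i = 0; i < net.dense.size(); ++i)
    denseG[i] = List::create(
      _["W"] = arma::conv_to<arma::mat>::from(G.denseW[i]),
      _["b"] = arma::conv_to<arma::vec>::from(G.denseB[i]));
  return List::create(_["loss"] = L, _["conv"] = convG, _["dense"] = denseG);
}

// Train (or fine-tune) with Adam + BCE. X: channels x samples x n.
// If n_val > 0 the last n_val slices of X/y form a validation split used
// for early stopping with the given patience; the best-validation
// parameters are returned. Otherwise all epochs run.
// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train(List params, NumericVector x, NumericVector y_,
               int n_val, double lr, int batch_size, int max_epochs,
               int patience, int seed) {
  Net net = net_from_list(params);
  RCube X = cube_from_r(x, net.n_ch, net.n_samp);
  int n_tot = (int)X.n_slices;
  if (n_val < 0 || n_val >= n_tot) stop("invalid validation size");
  int n = n_tot - n_val;
  if (n < 1) stop("no training samples");
  RRow y(n_tot);
  for (int i = 0; i < n_tot; ++i) y(i) = (real)y_[i];

  std::mt19937 rng((unsigned)seed + 1u);
  AdamState adam; adam.init(net);
  std::vector<double> train_loss, val_loss;
  List best = net_to_list(net);
  double best_val = arma::datum::inf;
  int since_best = 0;

  arma::uvec order = arma::regspace<arma::uvec>(0, n - 1);
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> d(0, i);
      std::swap(order(i), order(d(rng)));
    }
    double ep_loss = 0; int nb = 0;
    for (int at = 0; at < n; at += batch_size) {
      int hi = std::min(at + batch_size, n);
      if (hi - at < 2) continue;               // batchnorm needs >= 2
      arma::uvec idx = order.subvec(at, hi - 1);
      RRow yb(hi - at);
      for (int i = 0; i < hi - at; ++i) yb(i) = y(idx(i));
      BatchCache C;
      forward(net, X, idx, true, rng, C, true);
      double L = bce(C.prob, yb);
      if (!std::isfinite(L))
        stop("training diverged (non-finite loss at epoch %d)", epoch + 1);
      ep_loss += L; ++nb;
      Grads G;
      backward(net, (int)idx.n_elem, yb, C, G);
      apply_grads(net, G, adam, (real)lr);
      Rcpp::checkUserInterrupt();
    }
    train_loss.push_back(nb ? ep_loss / nb : NA_REAL);
    if (n_val > 0) {
      refresh_bn_stats(net, X, order, batch_size, rng);
      arma::uvec vidx = arma::regspace<arma::uvec>(n, n_tot - 1);
      BatchCache C;
      forward(net, X, vidx, false, rng, C, false);
      RRow yv = y.subvec(n, n_tot - 1);
      double vl = bce(C.prob, yv);
      val_loss.push_back(vl);
      if (vl < best_val - 1e-9) {
        best_val = vl; best = net_to_list(net); since_best = 0;
      } else if (++since_best >= patience) break;
    }
  }
  if (n_val == 0) {
    refresh_bn_stats(net, X, order, batch_size, rng);
    best = net_to_list(net);
  }
  return List::create(
    _["params"] = best,
    _["train_loss"] = NumericVector(train_loss.begin(), train_loss.end()),
    _["val_loss"] = NumericVector(val_loss.begin(), val_loss.end()),
    _["best_val_loss"] = (n_val > 0) ? best_val : NA_REAL);
}
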