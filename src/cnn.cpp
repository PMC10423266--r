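// Dual-branch convolutional network for paired coronal/sagittal MIP images.
//
// Each branch: 4 valid 3x3 convolution blocks (16/32/64/128 feature maps,
// ReLU, spatial dropout) with max pooling (3,3), (3,3), (2,2) after the first
// three blocks and global average pooling after the fourth. Branch features
// are concatenated into a 2-way dense softmax head. Implemented with
// im2col + GEMM in single precision; all randomness (dropout masks, batch
// shuffling) is drawn from R's RNG so results are reproducible via set.seed().

#include <RcppArmadillo.h>
#include <dlfcn.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// The GEMMs here are small and skinny; multi-threaded OpenBLAS oversubscribes
// and can be several-fold slower than a single thread. Pin BLAS to one thread
// for the duration of a call, restoring the previous setting afterwards.
struct BlasThreadGuard {
  typedef void (*set_fn)(int);
  typedef int (*get_fn)(void);
  set_fn set = nullptr;
  int prev = 0;
  BlasThreadGuard() {
    set = (set_fn)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
    get_fn get = (get_fn)dlsym(RTLD_DEFAULT, "openblas_get_num_threads");
    if (set && get) {
      prev = get();
      set(1);
    } else {
      set = nullptr;
    }
  }
  ~BlasThreadGuard() {
    if (set && prev > 0) set(prev);
  }
};

static const int NCONV = 4;
static const int POOL[3] = {3, 3, 2};

struct Net {
  fmat W[NCONV];
  frowvec b[NCONV];
  fmat Wd;
  frowvec bd;
};

struct Grad {
  fmat W[NCONV];
  frowvec b[NCONV];
  fmat Wd;
  frowvec bd;

  void zeros_like(const Net& n) {
    for (int l = 0; l < NCONV; ++l) {
      W[l].zeros(n.W[l].n_rows, n.W[l].n_cols);
      b[l].zeros(n.b[l].n_elem);
    }
    Wd.zeros(n.Wd.n_rows, n.Wd.n_cols);
    bd.zeros(n.bd.n_elem);
  }
};

static Net net_from_list(const List& wl) {
  Net n;
  for (int l = 0; l < NCONV; ++l) {
    n.W[l] = conv_to<fmat>::from(as<mat>(wl["W" + std::to_string(l + 1)]));
    n.b[l] = conv_to<frowvec>::from(as<rowvec>(wl["b" + std::to_string(l + 1)]));
  }
  n.Wd = conv_to<fmat>::from(as<mat>(wl["Wd"]));
  n.bd = conv_to<frowvec>::from(as<rowvec>(wl["bd"]));
  return n;
}

static List net_to_list(const Net& n) {
  List out;
  for (int l = 0; l < NCONV; ++l) {
    out["W" + std::to_string(l + 1)] = wrap(conv_to<mat>::from(n.W[l]));
    out["b" + std::to_string(l + 1)] = wrap(conv_to<rowvec>::from(n.b[l]));
  }
  out["Wd"] = wrap(conv_to<mat>::from(n.Wd));
  out["bd"] = wrap(conv_to<rowvec>::from(n.bd));
  return out;
}

// im2col for a valid 3x3 convolution: (H,W,C) -> (Ho*Wo, 9*C).
// Column order (c, dx, dy) must match the weight-row order used at init.
static void im2col3(const fcube& in, fmat& out) {
  const uword H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const uword Ho = H - 2, Wo = W - 2;
  out.set_size(Ho * Wo, 9 * C);
  uword k = 0;
  for (uword c = 0; c < C; ++c)
    for (uword dx = 0; dx < 3; ++dx)
      for (uword dy = 0; dy < 3; ++dy)
        out.col(k++) = vectorise(in.slice(c).submat(dy, dx, dy + Ho - 1, dx + Wo - 1));
}

// Scatter-accumulate transpose of im2col3.
static void col2im3(const fmat& cols, uword H, uword W, uword C, fcube& out) {
  const uword Ho = H - 2, Wo = W - 2;
  out.zeros(H, W, C);
  uword k = 0;
  for (uword c = 0; c < C; ++c)
    for (uword dx = 0; dx < 3; ++dx)
      for (uword dy = 0; dy < 3; ++dy) {
        const fmat m(const_cast<float*>(cols.colptr(k)), Ho, Wo, false, true);
        out.slice(c).submat(dy, dx, dy + Ho - 1, dx + Wo - 1) += m;
        ++k;
      }
}

// Non-overlapping max pooling with stride == window; trailing rows/cols that
// do not fill a window are dropped. Argmax stored as in-slice linear index.
static void maxpool_fwd(const fcube& in, int p, fcube& out, Mat<uword>& idx) {
  const uword H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const uword Ho = H / p, Wo = W / p;
  out.set_size(Ho, Wo, C);
  idx.set_size(Ho * Wo, C);
  for (uword c = 0; c < C; ++c) {
    const fmat& s = in.slice(c);
    for (uword j = 0; j < Wo; ++j)
      for (uword i = 0; i < Ho; ++i) {
        float best = -std::numeric_limits<float>::infinity();
        uword bi = 0;
        for (uword dj = 0; dj < (uword)p; ++dj)
          for (uword di = 0; di < (uword)p; ++di) {
            const uword r = i * p + di, cc = j * p + dj;
            const float v = s(r, cc);
            if (v > best) { best = v; bi = r + cc * H; }
          }
        out(i, j, c) = best;
        idx(i + j * Ho, c) = bi;
      }
  }
}

struct Cache {
  fmat A[NCONV];             // im2col of each conv input
  fmat Z[NCONV];             // conv output after ReLU and dropout (npix x C)
  frowvec dmask[NCONV];      // spatial dropout channel multipliers
  Mat<uword> pidx[3];        // pooling argmax
  uword zdim[NCONV][2];      // spatial dims of conv output l
  uword indim[NCONV][3];     // spatial dims + channels of conv input l
  frowvec gap;
};

// Forward pass of one branch on a single image.
static void branch_fwd(const Net& net, const fmat& img, double drop,
                       bool training, Cache& cc) {
  fcube cur(img.n_rows, img.n_cols, 1);
  cur.slice(0) = img;
  for (int l = 0; l < NCONV; ++l) {
    cc.indim[l][0] = cur.n_rows;
    cc.indim[l][1] = cur.n_cols;
    cc.indim[l][2] = cur.n_slices;
    im2col3(cur, cc.A[l]);
    fmat Z = cc.A[l] * net.W[l];
    Z.each_row() += net.b[l];
    Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    const uword C = Z.n_cols;
    cc.dmask[l].ones(C);
    if (training && drop > 0) {
      const float scale = 1.0f / (1.0f - (float)drop);
      for (uword c = 0; c < C; ++c) {
        if (unif_rand() < drop) {
          cc.dmask[l](c) = 0.0f;
          Z.col(c).zeros();
        } else {
          cc.dmask[l](c) = scale;
          Z.col(c) *= scale;
        }
      }
    }
    const uword Ho = cc.indim[l][0] - 2, Wo = cc.indim[l][1] - 2;
    cc.zdim[l][0] = Ho;
    cc.zdim[l][1] = Wo;
    cc.Z[l] = Z;
    if (l < NCONV - 1) {
      const fcube zc(const_cast<float*>(cc.Z[l].memptr()), Ho, Wo, C, false, true);
      fcube pooled;
      maxpool_fwd(zc, POOL[l], pooled, cc.pidx[l]);
      cur = pooled;
    } else {
      cc.gap = mean(cc.Z[l], 0);
    }
  }
}

// Backward pass of one branch; accumulates into g. dgap is dLoss/dGAP.
static void branch_bwd(const Net& net, const Cache& cc, const frowvec& dgap,
                       Grad& g) {
  const uword np3 = cc.zdim[3][0] * cc.zdim[3][1];
  fmat dZ(np3, net.W[3].n_cols);
  for (uword c = 0; c < dZ.n_cols; ++c) dZ.col(c).fill(dgap(c) / (float)np3);

  for (int l = NCONV - 1; l >= 0; --l) {
    // through dropout (channel scale) and ReLU (mask from stored activations)
    for (uword c = 0; c < dZ.n_cols; ++c) dZ.col(c) *= cc.dmask[l](c);
    dZ.elem(find(cc.Z[l] <= 0)).zeros();

    g.W[l] += cc.A[l].t() * dZ;
    g.b[l] += sum(dZ, 0);

    if (l == 0) break;
    const fmat dA = dZ * net.W[l].t();
    fcube dPooled;
    col2im3(dA, cc.indim[l][0], cc.indim[l][1], cc.indim[l][2], dPooled);

    // max-pool backward into conv-output grid of layer l-1
    const uword Ho = cc.zdim[l - 1][0], Wo = cc.zdim[l - 1][1];
    const uword C = dPooled.n_slices;
    dZ.zeros(Ho * Wo, C);
    const uword Po = dPooled.n_rows, Qo = dPooled.n_cols;
    for (uword c = 0; c < C; ++c) {
      const fmat& dp = dPooled.slice(c);
      for (uword j = 0; j < Qo; ++j)
        for (uword i = 0; i < Po; ++i)
          dZ(cc.pidx[l - 1](i + j * Po, c), c) += dp(i, j);
    }
  }
}

// Forward + (optionally) backward for one sample; returns per-sample loss.
static double sample_pass(const Net& net, const fmat& cor, const fmat& sag,
                          int y, double drop, bool training, bool with_grad,
                          Grad* g, frowvec* probs_out) {
  Cache cc_c, cc_s;
  branch_fwd(net, cor, drop, training, cc_c);
  branch_fwd(net, sag, drop, training, cc_s);
  frowvec z = join_rows(cc_c.gap, cc_s.gap);
  frowvec logits = z * net.Wd + net.bd;
  logits -= logits.max();
  frowvec ex = exp(logits);
  frowvec p = ex / accu(ex);
  if (probs_out) *probs_out = p;
  const double eps = 1e-12;
  const double loss = -std::log((double)p(y) + eps);
  if (with_grad) {
    frowvec dlog = p;
    dlog(y) -= 1.0f;
    g->Wd += z.t() * dlog;
    g->bd += dlog;
    const frowvec dz = dlog * net.Wd.t();
    const uword h = cc_c.gap.n_elem;
    branch_bwd(net, cc_c, dz.cols(0, h - 1), *g);
    branch_bwd(net, cc_s, dz.cols(h, 2 * h - 1), *g);
  }
  return loss;
}

static fcube as_fcube(const NumericVector& x) {
  const IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("image stack must be a 3-d array (H, W, N)");
  const cube c(const_cast<double*>(x.begin()), d[0], d[1], d[2], false);
  return conv_to<fcube>::from(c);
}

struct Adam {
  Grad m, v;
  long t = 0;
  void init(const Net& n) { m.zeros_like(n); v.zeros_like(n); t = 0; }
};

static void adam_update_mat(fmat& w, fmat& m, fmat& v, const fmat& g,
                            float lr, float b1, float b2, float eps,
                            float c1, float c2) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * square(g);
  w -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

static void adam_update_vec(frowvec& w, frowvec& m, frowvec& v, const frowvec& g,
                            float lr, float b1, float b2, float eps,
                            float c1, float c2) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * square(g);
  w -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

// [[Rcpp::export]]
List cnn_train_cpp(List weights, NumericVector xc, NumericVector xs,
                   IntegerVector y, IntegerVector train_idx, int epochs,
                   double lr, double decay, int batch_size,
                   double dropout_rate) {
  BlasThreadGuard blas_guard;
  Net net = net_from_list(weights);
  const fcube Xc = as_fcube(xc), Xs = as_fcube(xs);
  const int ntr = train_idx.size();
  if (ntr < 1) stop("empty training set");
  if (batch_size < 1) stop("batch_size must be >= 1");

  Adam opt;
  opt.init(net);
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  NumericVector epoch_loss(epochs);
  std::vector<int> idx(train_idx.begin(), train_idx.end());

  for (int e = 0; e < epochs; ++e) {
    // Fisher-Yates shuffle from R's RNG
    for (int i = ntr - 1; i > 0; --i) {
      const int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(idx[i], idx[j]);
    }
    double tot = 0.0;
    for (int s0 = 0; s0 < ntr; s0 += batch_size) {
      const int s1 = std::min(s0 + batch_size, ntr);
      const int bs = s1 - s0;
      Grad g;
      g.zeros_like(net);
      for (int s = s0; s < s1; ++s) {
        const int i = idx[s] - 1;  // 1-based from R
        tot += sample_pass(net, Xc.slice(i), Xs.slice(i), y[i], dropout_rate,
                           true, true, &g, nullptr);
      }
      const float inv = 1.0f / (float)bs;
      for (int l = 0; l < NCONV; ++l) { g.W[l] *= inv; g.b[l] *= inv; }
      g.Wd *= inv; g.bd *= inv;

      opt.t += 1;
      const float lrt = (float)(lr / (1.0 + decay * (double)opt.t));
      const float c1 = 1.0f - std::pow(b1, (float)opt.t);
      const float c2 = 1.0f - std::pow(b2, (float)opt.t);
      for (int l = 0; l < NCONV; ++l) {
        adam_update_mat(net.W[l], opt.m.W[l], opt.v.W[l], g.W[l], lrt, b1, b2, eps, c1, c2);
        adam_update_vec(net.b[l], opt.m.b[l], opt.v.b[l], g.b[l], lrt, b1, b2, eps, c1, c2);
      }
      adam_update_mat(net.Wd, opt.m.Wd, opt.v.Wd, g.Wd, lrt, b1, b2, eps, c1, c2);
      adam_update_vec(net.bd, opt.m.bd, opt.v.bd, g.bd, lrt, b1, b2, eps, c1, c2);
      Rcpp::checkUserInterrupt();
    }
    epoch_loss[e] = tot / ntr;
  }
  return List::create(_["weights"] = net_to_list(net),
                      _["epoch_loss"] = epoch_loss);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(List weights, NumericVector xc, NumericVector xs) {
  BlasThreadGuard blas_guard;
  const Net net = net_from_list(weights);
  const fcube Xc = as_fcube(xc), Xs = as_fcube(xs);
  const int n = Xc.n_slices;
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    frowvec p;
    sample_pass(net, Xc.slice(i), Xs.slice(i), 0, 0.0, false, false, nullptr, &p);
    out(i, 0) = p(0);
    out(i, 1) = p(1);
  }
  return out;
}

// Mean loss and gradients over a set of samples (no parameter update);
// used for finite-difference gradient checks and transfer sanity checks.
// [[Rcpp::export]]
List cnn_loss_grad_cpp(List weights, NumericVector xc, NumericVector xs,
                       IntegerVector y, double dropout_rate) {
  BlasThreadGuard blas_guard;
  const Net net = net_from_list(weights);
  const fcube Xc = as_fcube(xc), Xs = as_fcube(xs);
  const int n = Xc.n_slices;
  Grad g;
  g.zeros_like(net);
  double tot = 0.0;
  for (int i = 0; i < n; ++i)
    tot += sample_pass(net, Xc.slice(i), Xs.slice(i), y[i], dropout_rate,
                       dropout_rate > 0, true, &g, nullptr);
  const float inv = 1.0f / (float)n;
  Net gn;
  for (int l = 0; l < NCONV; ++l) { gn.W[l] = g.W[l] * inv; gn.b[l] = g.b[l] * inv; }
  gn.Wd = g.Wd * inv;
  gn.bd = g.bd * inv;
  return List::create(_["loss"] = tot / n, _["grads"] = net_to_list(gn));
}
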