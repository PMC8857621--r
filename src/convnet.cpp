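// Compact encoder-decoder segmentation networks (U-Net with skip
// concatenation, SegNet-style with max-pooling-index unpooling), trained
// with Adam on pixel-wise cross-entropy. Convolutions are 3x3, stride 1,
// zero padding 1, evaluated as im2col + BLAS GEMM in single precision.
// No deep-learning framework is available in this stack, so the forward
// and backward passes are written out explicitly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>

using namespace Rcpp;
using arma::fcube;
using arma::fmat;
using arma::fvec;
using arma::uword;

namespace {

// im2col for a 3x3 kernel with zero padding 1.
// Layout: (H*W) rows x (C*9) columns; column index k = ch*9 + dc*3 + dr,
// pixel index p = r + c*H (column-major, matching R / Armadillo).
void im2col3(const fcube& x, fmat& col) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  col.zeros(H * W, C * 9);
  for (uword ch = 0; ch < C; ++ch) {
    const fmat& xs = x.slice(ch);
    for (int dc = 0; dc < 3; ++dc) {
      for (int dr = 0; dr < 3; ++dr) {
        float* d = col.colptr(ch * 9 + dc * 3 + dr);
        const int r0 = std::max(0, 1 - dr);            // first valid output row
        const int r1 = std::min((int)H, (int)H + 1 - dr);
        for (int c = 0; c < (int)W; ++c) {
          const int sc = c + dc - 1;
          if (sc < 0 || sc >= (int)W) continue;
          const float* s = xs.colptr(sc) + (r0 + dr - 1);
          std::copy(s, s + (r1 - r0), d + c * H + r0);
        }
      }
    }
  }
}

// Adjoint of im2col3: scatter-add columns back into an image cube.
void col2im3(const fmat& col, uword H, uword W, uword C, fcube& gx) {
  gx.zeros(H, W, C);
  for (uword ch = 0; ch < C; ++ch) {
    fmat& gs = gx.slice(ch);
    for (int dc = 0; dc < 3; ++dc) {
      for (int dr = 0; dr < 3; ++dr) {
        const float* s = col.colptr(ch * 9 + dc * 3 + dr);
        const int r0 = std::max(0, 1 - dr);
        const int r1 = std::min((int)H, (int)H + 1 - dr);
        for (int c = 0; c < (int)W; ++c) {
          const int sc = c + dc - 1;
          if (sc < 0 || sc >= (int)W) continue;
          float* d = gs.colptr(sc) + (r0 + dr - 1);
          const float* sp = s + c * H + r0;
          for (int r = 0; r < r1 - r0; ++r) d[r] += sp[r];
        }
      }
    }
  }
}

fcube mat_to_cube(const fmat& m, uword H, uword W) {
  fcube out(H, W, m.n_cols);
  std::memcpy(out.memptr(), m.memptr(), sizeof(float) * m.n_elem);
  return out;
}

fmat cube_to_mat(const fcube& x) {
  fmat out(x.n_rows * x.n_cols, x.n_slices);
  std::memcpy(out.memptr(), x.memptr(), sizeof(float) * x.n_elem);
  return out;
}

// y = conv3x3(x, W) + b, W is (C_in*9) x C_out
fcube conv3_fwd(const fcube& x, const fmat& W, const fvec& b, fmat& col) {
  im2col3(x, col);
  fmat y = col * W;
  y.each_row() += b.t();
  return mat_to_cube(y, x.n_rows, x.n_cols);
}

void conv3_bwd(const fcube& x, const fmat& W, const fcube& gy,
               fmat& gW, fvec& gb, fcube& gx, fmat& col) {
  im2col3(x, col);
  fmat gym = cube_to_mat(gy);
  gW = col.t() * gym;
  gb = arma::sum(gym, 0).t();
  fmat gcol = gym * W.t();
  col2im3(gcol, x.n_rows, x.n_cols, x.n_slices, gx);
}

void relu_inplace(fcube& x) { x.transform([](float v) { return v > 0.f ? v : 0.f; }); }

void relu_bwd_inplace(fcube& g, const fcube& out) {
  for (uword i = 0; i < g.n_elem; ++i)
    if (out[i] <= 0.f) g[i] = 0.f;
}

// 2x2 max pooling, stride 2; idx stores the linear index into x of each max.
fcube maxpool2(const fcube& x, arma::uvec& idx) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  fcube y(Ho, Wo, C);
  idx.set_size(Ho * Wo * C);
  uword q = 0;
  for (uword ch = 0; ch < C; ++ch) {
    for (uword c = 0; c < Wo; ++c) {
      for (uword r = 0; r < Ho; ++r) {
        const uword base = ch * H * W + (2 * c) * H + 2 * r;
        uword best = base;
        float bv = x[base];
        const uword cand[3] = {base + 1, base + H, base + H + 1};
        for (int t = 0; t < 3; ++t)
          if (x[cand[t]] > bv) { bv = x[cand[t]]; best = cand[t]; }
        y(r, c, ch) = bv;
        idx[q++] = best;
      }
    }
  }
  return y;
}

fcube maxpool2_bwd(const fcube& gy, const arma::uvec& idx,
                   uword H, uword W, uword C) {
  fcube gx(H, W, C, arma::fill::zeros);
  for (uword q = 0; q < gy.n_elem; ++q) gx[idx[q]] += gy[q];
  return gx;
}

// SegNet-style unpooling: place values at the remembered max locations.
fcube maxunpool(const fcube& x, const arma::uvec& idx,
                uword H, uword W) {
  fcube y(H, W, x.n_slices, arma::fill::zeros);
  for (uword q = 0; q < x.n_elem; ++q) y[idx[q]] = x[q];
  return y;
}

fcube maxunpool_bwd(const fcube& gy, const arma::uvec& idx,
                    uword Ho, uword Wo, uword C) {
  fcube gx(Ho, Wo, C);
  for (uword q = 0; q < gx.n_elem; ++q) gx[q] = gy[idx[q]];
  return gx;
}

// Nearest-neighbour 2x upsampling.
fcube upsample2(const fcube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fcube y(2 * H, 2 * W, C);
  for (uword ch = 0; ch < C; ++ch)
    for (uword c = 0; c < 2 * W; ++c) {
      const float* s = x.slice(ch).colptr(c / 2);
      float* d = y.slice(ch).colptr(c);
      for (uword r = 0; r < 2 * H; ++r) d[r] = s[r / 2];
    }
  return y;
}

fcube upsample2_bwd(const fcube& gy) {
  const uword H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  fcube gx(H, W, C, arma::fill::zeros);
  for (uword ch = 0; ch < C; ++ch)
    for (uword c = 0; c < 2 * W; ++c) {
      const float* s = gy.slice(ch).colptr(c);
      float* d = gx.slice(ch).colptr(c / 2);
      for (uword r = 0; r < 2 * H; ++r) d[r / 2] += s[r];
    }
  return gx;
}

struct Net {
  std::string arch;  // "unet" or "segnet"
  int depth, base, in_ch, classes;
  std::vector<fmat> W;
  std::vector<fvec> b;

  int n_conv() const { return 2 * depth + 2; }

  // Channel plan. Conv ids: 0..depth-1 encoder, depth bottleneck,
  // depth+1 .. 2*depth decoder (processed from the deepest level down),
  // 2*depth+1 final 1x1 classifier.
  void channels(int id, int& cin, int& cout) const {
    const int D = depth;
    if (id < D) {                       // encoder level id
      cin = (id == 0) ? in_ch : base << (id - 1);
      cout = base << id;
    } else if (id == D) {               // bottleneck
      cin = base << (D - 1);
      cout = (arch == "unet") ? (base << D) : (base << (D - 1));
    } else if (id <= 2 * D) {           // decoder, level = 2*D - id
      const int lev = 2 * D - id;
      if (arch == "unet") {
        const int above = (lev == D - 1) ? (base << D) : (base << (lev + 1));
        cin = (base << lev) + above;    // skip concat + upsampled
        cout = base << lev;
      } else {
        cin = base << lev;              // unpooled map, channels preserved
        cout = (lev == 0) ? base : (base << (lev - 1));
      }
    } else {                            // 1x1 classifier
      cin = base;
      cout = classes;
    }
  }
};

Net net_from_r(List weights, List cfg) {
  Net net;
  net.arch = as<std::string>(cfg["arch"]);
  net.depth = as<int>(cfg["depth"]);
  net.base = as<int>(cfg["base_filters"]);
  net.in_ch = as<int>(cfg["in_channels"]);
  net.classes = as<int>(cfg["classes"]);
  List Wl = weights["W"], bl = weights["b"];
  for (int i = 0; i < net.n_conv(); ++i) {
    net.W.push_back(arma::conv_to<fmat>::from(as<arma::mat>(Wl[i])));
    net.b.push_back(arma::conv_to<fvec>::from(as<arma::vec>(bl[i])));
  }
  return net;
}

List net_to_r(const Net& net) {
  List Wl(net.n_conv()), bl(net.n_conv());
  for (int i = 0; i < net.n_conv(); ++i) {
    Wl[i] = wrap(arma::conv_to<arma::mat>::from(net.W[i]));
    bl[i] = wrap(arma::conv_to<arma::vec>::from(net.b[i]));
  }
  return List::create(_["W"] = Wl, _["b"] = bl);
}

struct Cache {
  std::vector<fcube> conv_in, conv_out;
  std::vector<arma::uvec> pidx;
  std::vector<uword> lvl_H, lvl_W;  // spatial dims entering pooling per level
  fmat probs;                       // HW x classes
};

// Forward pass; fills cache when train = true.
fmat forward(const Net& net, const fcube& x, Cache& cache, bool train, fmat& col) {
  const int D = net.depth;
  cache.conv_in.assign(net.n_conv(), fcube());
  cache.conv_out.assign(net.n_conv(), fcube());
  cache.pidx.assign(D, arma::uvec());
  cache.lvl_H.assign(D, 0);
  cache.lvl_W.assign(D, 0);

  fcube cur = x;
  for (int i = 0; i < D; ++i) {
    if (train) cache.conv_in[i] = cur;
    fcube y = conv3_fwd(cur, net.W[i], net.b[i], col);
    relu_inplace(y);
    cache.conv_out[i] = y;  // needed for skips even at prediction time
    cache.lvl_H[i] = y.n_rows;
    cache.lvl_W[i] = y.n_cols;
    cur = maxpool2(y, cache.pidx[i]);
  }
  if (train) cache.conv_in[D] = cur;
  cur = conv3_fwd(cur, net.W[D], net.b[D], col);
  relu_inplace(cur);
  if (train) cache.conv_out[D] = cur;

  for (int lev = D - 1; lev >= 0; --lev) {
    const int id = 2 * D - lev;
    fcube inp;
    if (net.arch == "unet") {
      fcube up = upsample2(cur);
      inp = arma::join_slices(cache.conv_out[lev], up);
    } else {
      inp = maxunpool(cur, cache.pidx[lev], cache.lvl_H[lev], cache.lvl_W[lev]);
    }
    if (train) cache.conv_in[id] = inp;
    cur = conv3_fwd(inp, net.W[id], net.b[id], col);
    relu_inplace(cur);
    if (train) cache.conv_out[id] = cur;
  }

  // 1x1 classifier + softmax
  const int oid = 2 * D + 1;
  fmat xo = cube_to_mat(cur);
  if (train) cache.conv_in[oid] = cur;
  fmat logits = xo * net.W[oid];
  logits.each_row() += net.b[oid].t();
  logits.each_col() -= arma::max(logits, 1);
  fmat p = arma::exp(logits);
  p.each_col() /= arma::sum(p, 1);
  cache.probs = p;
  return p;
}

// Backward pass from softmax cross-entropy; y holds 0-based labels per pixel.
void backward(const Net& net, const arma::uvec& y, const Cache& cache,
              std::vector<fmat>& gW, std::vector<fvec>& gb, fmat& col) {
  const int D = net.depth;
  const uword HW = cache.probs.n_rows;
  fmat g = cache.probs;
  for (uword p = 0; p < HW; ++p) g(p, y[p]) -= 1.f;
  g /= (float)HW;

  const int oid = 2 * D + 1;
  fmat xo = cube_to_mat(cache.conv_in[oid]);
  gW[oid] += xo.t() * g;
  gb[oid] += arma::sum(g, 0).t();
  fmat gm = g * net.W[oid].t();
  fcube gcur = mat_to_cube(gm, cache.conv_in[oid].n_rows, cache.conv_in[oid].n_cols);

  std::vector<fcube> gskip(D);
  for (int lev = 0; lev < D; ++lev) {
    const int id = 2 * D - lev;
    relu_bwd_inplace(gcur, cache.conv_out[id]);
    fmat gWi;
    fvec gbi;
    fcube gin;
    conv3_bwd(cache.conv_in[id], net.W[id], gcur, gWi, gbi, gin, col);
    gW[id] += gWi;
    gb[id] += gbi;
    if (net.arch == "unet") {
      const uword skipC = cache.conv_out[lev].n_slices;
      gskip[lev] = gin.slices(0, skipC - 1);
      fcube gup = gin.slices(skipC, gin.n_slices - 1);
      gcur = upsample2_bwd(gup);
    } else {
      gcur = maxunpool_bwd(gin, cache.pidx[lev], cache.lvl_H[lev] / 2,
                           cache.lvl_W[lev] / 2, gin.n_slices);
    }
  }

  relu_bwd_inplace(gcur, cache.conv_out[D]);
  {
    fmat gWi;
    fvec gbi;
    fcube gin;
    conv3_bwd(cache.conv_in[D], net.W[D], gcur, gWi, gbi, gin, col);
    gW[D] += gWi;
    gb[D] += gbi;
    gcur = gin;
  }

  for (int i = D - 1; i >= 0; --i) {
    fcube gfull = maxpool2_bwd(gcur, cache.pidx[i], cache.lvl_H[i],
                               cache.lvl_W[i], cache.conv_out[i].n_slices);
    if (net.arch == "unet") gfull += gskip[i];
    relu_bwd_inplace(gfull, cache.conv_out[i]);
    fmat gWi;
    fvec gbi;
    fcube gin;
    conv3_bwd(cache.conv_in[i], net.W[i], gfull, gWi, gbi, gin, col);
    gW[i] += gWi;
    gb[i] += gbi;
    gcur = gin;
  }
}

fcube image_from_r(const double* px, uword H, uword W, uword C) {
  fcube x(H, W, C);
  const uword n = H * W * C;
  for (uword i = 0; i < n; ++i) x[i] = (float)(px[i] / 255.0);
  return x;
}

}  // namespace

// [[Rcpp::export(name = ".cn_init")]]
List cn_init(int base, int depth, int in_channels, int classes,
             std::string arch, int seed) {
  Net net;
  net.arch = arch;
  net.depth = depth;
  net.base = base;
  net.in_ch = in_channels;
  net.classes = classes;
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<float> N(0.f, 1.f);
  for (int id = 0; id < net.n_conv(); ++id) {
    int cin, cout;
    net.channels(id, cin, cout);
    const int k = (id == 2 * depth + 1) ? 1 : 9;
    const float sd = std::sqrt(2.0f / (float)(cin * k));
    fmat Wm(cin * k, cout);
    for (uword i = 0; i < Wm.n_elem; ++i) Wm[i] = sd * N(rng);
    net.W.push_back(Wm);
    net.b.push_back(fvec(cout, arma::fill::zeros));
  }
  return net_to_r(net);
}

// [[Rcpp::export(name = ".cn_train")]]
List cn_train(NumericVector x, IntegerVector y, List weights, List cfg) {
  IntegerVector xd = x.attr("dim");
  const uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  Net net = net_from_r(weights, cfg);
  const int epochs = as<int>(cfg["epochs"]);
  const int batch = as<int>(cfg["batch_size"]);
  const double lr = as<double>(cfg["learning_rate"]);
  const bool shuffle = as<bool>(cfg["shuffle"]);
  const int seed = as<int>(cfg["seed"]);
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;

  const int nc = net.n_conv();
  std::vector<fmat> mW(nc), vW(nc), gW(nc);
  std::vector<fvec> mb(nc), vb(nc), gb(nc);
  for (int i = 0; i < nc; ++i) {
    mW[i].zeros(arma::size(net.W[i]));
    vW[i].zeros(arma::size(net.W[i]));
    mb[i].zeros(net.b[i].n_elem);
    vb[i].zeros(net.b[i].n_elem);
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;

  NumericVector ep_loss(epochs), ep_acc(epochs);
  const uword HW = H * W;
  fmat col;  // im2col scratch, reused across calls
  Cache cache;
  long t = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    if (shuffle) std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0, correct = 0.0;
    uword done = 0;
    while (done < N) {
      const uword nb = std::min<uword>(batch, N - done);
      for (int i = 0; i < nc; ++i) {
        gW[i].zeros(arma::size(net.W[i]));
        gb[i].zeros(net.b[i].n_elem);
      }
      for (uword j = 0; j < nb; ++j) {
        const uword img = order[done + j];
        fcube xi = image_from_r(REAL(x) + (size_t)img * H * W * C, H, W, C);
        arma::uvec yi(HW);
        const int* yp = INTEGER(y) + (size_t)img * HW;
        for (uword p = 0; p < HW; ++p) yi[p] = (uword)yp[p];
        forward(net, xi, cache, true, col);
        const float* pm = cache.probs.memptr();
        const uword K = cache.probs.n_cols;
        for (uword p = 0; p < HW; ++p) {
          loss_sum += -std::log(std::max(pm[p + yi[p] * HW], 1e-12f));
          uword am = 0;
          float bv = pm[p];
          for (uword k = 1; k < K; ++k)
            if (pm[p + k * HW] > bv) { bv = pm[p + k * HW]; am = k; }
          if (am == yi[p]) correct += 1.0;
        }
        backward(net, yi, cache, gW, gb, col);
      }
      ++t;
      const float bc = std::sqrt(1.f - std::pow(b2, (float)t)) /
                       (1.f - std::pow(b1, (float)t));
      for (int i = 0; i < nc; ++i) {
        gW[i] /= (float)nb;
        gb[i] /= (float)nb;
        mW[i] = b1 * mW[i] + (1.f - b1) * gW[i];
        vW[i] = b2 * vW[i] + (1.f - b2) * arma::square(gW[i]);
        net.W[i] -= (float)lr * bc * mW[i] / (arma::sqrt(vW[i]) + eps);
        mb[i] = b1 * mb[i] + (1.f - b1) * gb[i];
        vb[i] = b2 * vb[i] + (1.f - b2) * arma::square(gb[i]);
        net.b[i] -= (float)lr * bc * mb[i] / (arma::sqrt(vb[i]) + eps);
      }
      done += nb;
      Rcpp::checkUserInterrupt();
    }
    ep_loss[ep] = loss_sum / (double)(N * HW);
    ep_acc[ep] = correct / (double)(N * HW);
  }

  return List::create(_["weights"] = net_to_r(net), _["loss"] = ep_loss,
                      _["accuracy"] = ep_acc);
}

// [[Rcpp::export(name = ".cn_predict")]]
NumericVector cn_predict(NumericVector x, List weights, List cfg) {
  IntegerVector xd = x.attr("dim");
  const uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  Net net = net_from_r(weights, cfg);
  NumericVector out((size_t)H * W * net.classes * N);
  out.attr("dim") = IntegerVector::create(H, W, net.classes, N);
  fmat col;
  Cache cache;
  for (uword img = 0; img < N; ++img) {
    fcube xi = image_from_r(REAL(x) + (size_t)img * H * W * C, H, W, C);
    fmat p = forward(net, xi, cache, false, col);
    double* d = REAL(out) + (size_t)img * H * W * net.classes;
    for (uword k = 0; k < p.n_elem; ++k) d[k] = (double)p[k];
    Rcpp::checkUserInterrupt();
  }
  return out;
}
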