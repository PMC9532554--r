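// Low-level numerical kernels: GEMM-based 3D convolution (forward/backward),
// trilinear warping with clamp-to-edge sampling and its gradient with respect
// to the displacement field, nearest-neighbour label warping, point sampling,
// and separable sliding-window (box) sums used by the LNCC loss.
//
// Array layouts (R column-major):
//   feature maps  (D, H, W, C)  -- voxel index d fastest, channel slowest
//   flows         (3, D, H, W)  -- component fastest
//   conv weights  (k, k, k, Cin, Cout)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dim4(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Zero-pad x (D,H,W,C) by `pad` voxels on every spatial side.  The
// convolution path runs in single precision: activations and their GEMMs are
// float32 (as is conventional for this class of network), which halves the
// memory traffic of im2col/col2im; everything crossing the R boundary stays
// double.
static arma::fvec pad_volume(const double* x, int D, int H, int W, int C, int pad) {
  const int Dp = D + 2 * pad, Hp = H + 2 * pad, Wp = W + 2 * pad;
  arma::fvec xp(static_cast<size_t>(Dp) * Hp * Wp * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double* src = x + static_cast<size_t>(D) * (h + static_cast<size_t>(H) * (w + static_cast<size_t>(W) * c));
        float* dst = xp.memptr() +
          static_cast<size_t>(pad) +
          static_cast<size_t>(Dp) * ((h + pad) + static_cast<size_t>(Hp) * ((w + pad) + static_cast<size_t>(Wp) * c));
        for (int d = 0; d < D; ++d) dst[d] = static_cast<float>(src[d]);
      }
  return xp;
}

// im2col, transposed orientation: rows = output voxels (Do fastest), columns =
// kernel taps ordered (kd, kh, kw, cin).  With this layout Y = cols * W' is
// directly the (Do,Ho,Wo,Cout) output in column-major order.
static arma::fmat im2col_t(const arma::fvec& xp, int Dp, int Hp, int Wp, int C,
                           int k, int stride, int Do, int Ho, int Wo) {
  const size_t N = static_cast<size_t>(Do) * Ho * Wo;
  arma::fmat cols(N, static_cast<size_t>(k) * k * k * C);
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          const size_t r = kd + static_cast<size_t>(k) * (kh + static_cast<size_t>(k) * (kw + static_cast<size_t>(k) * c));
          float* dst = cols.colptr(r);
          for (int wo = 0; wo < Wo; ++wo)
            for (int ho = 0; ho < Ho; ++ho) {
              const float* src = xp.memptr() + kd +
                static_cast<size_t>(Dp) * ((ho * stride + kh) + static_cast<size_t>(Hp) * ((wo * stride + kw) + static_cast<size_t>(Wp) * c));
              float* out = dst + static_cast<size_t>(Do) * (ho + static_cast<size_t>(Ho) * wo);
              if (stride == 1) {
                std::memcpy(out, src, sizeof(float) * Do);
              } else {
                for (int d = 0; d < Do; ++d) out[d] = src[static_cast<size_t>(d) * stride];
              }
            }
        }
  return cols;
}

// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  int xd[4], wd5[4];
  get_dim4(x, xd);
  IntegerVector wdim = w.attr("dim");
  if (wdim.size() != 5) stop("weights must be a 5-d array");
  const int k = wdim[0], Ci = wdim[3], Co = wdim[4];
  (void)wd5;
  if (wdim[1] != k || wdim[2] != k) stop("kernel must be cubic");
  if (xd[3] != Ci) stop("input channel mismatch");
  const int D = xd[0], H = xd[1], W = xd[2];
  const int Do = (D + 2 * pad - k) / stride + 1;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Do < 1 || Ho < 1 || Wo < 1) stop("conv output would be empty");

  arma::fvec xp = pad_volume(x.begin(), D, H, W, Ci, pad);
  arma::fmat cols = im2col_t(xp, D + 2 * pad, H + 2 * pad, W + 2 * pad, Ci, k, stride, Do, Ho, Wo);
  const size_t R = static_cast<size_t>(k) * k * k * Ci;
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
    arma::mat(const_cast<double*>(w.begin()), R, Co, false, true));
  arma::fmat Y = cols * Wm;  // N x Co
  Y.each_row() += arma::conv_to<arma::frowvec>::from(
    arma::rowvec(const_cast<double*>(b.begin()), Co, false, true));

  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv3d_bwd")]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad) {
  int xd[4], gd[4];
  get_dim4(x, xd);
  get_dim4(gy, gd);
  IntegerVector wdim = w.attr("dim");
  const int k = wdim[0], Ci = wdim[3], Co = wdim[4];
  const int D = xd[0], H = xd[1], W = xd[2];
  const int Do = gd[0], Ho = gd[1], Wo = gd[2];
  if (gd[3] != Co) stop("gradient channel mismatch");
  const size_t N = static_cast<size_t>(Do) * Ho * Wo;
  const size_t R = static_cast<size_t>(k) * k * k * Ci;

  arma::fvec xp = pad_volume(x.begin(), D, H, W, Ci, pad);
  const int Dp = D + 2 * pad, Hp = H + 2 * pad, Wp = W + 2 * pad;
  arma::fmat cols = im2col_t(xp, Dp, Hp, Wp, Ci, k, stride, Do, Ho, Wo);
  arma::fmat GY = arma::conv_to<arma::fmat>::from(
    arma::mat(const_cast<double*>(gy.begin()), N, Co, false, true));
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
    arma::mat(const_cast<double*>(w.begin()), R, Co, false, true));

  arma::fmat GW = cols.t() * GY;          // R x Co, same layout as w
  arma::frowvec GB = arma::sum(GY, 0);    // 1 x Co
  arma::fmat Gcols = GY * Wm.t();         // N x R

  // col2im: scatter-add Gcols back onto the padded input grid, then crop.
  arma::fvec gxp(static_cast<size_t>(Dp) * Hp * Wp * Ci, arma::fill::zeros);
  for (int c = 0; c < Ci; ++c)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          const size_t r = kd + static_cast<size_t>(k) * (kh + static_cast<size_t>(k) * (kw + static_cast<size_t>(k) * c));
          const float* src = Gcols.colptr(r);
          for (int wo = 0; wo < Wo; ++wo)
            for (int ho = 0; ho < Ho; ++ho) {
              float* dst = gxp.memptr() + kd +
                static_cast<size_t>(Dp) * ((ho * stride + kh) + static_cast<size_t>(Hp) * ((wo * stride + kw) + static_cast<size_t>(Wp) * c));
              const float* g = src + static_cast<size_t>(Do) * (ho + static_cast<size_t>(Ho) * wo);
              if (stride == 1) {
                for (int d = 0; d < Do; ++d) dst[d] += g[d];
              } else {
                for (int d = 0; d < Do; ++d) dst[static_cast<size_t>(d) * stride] += g[d];
              }
            }
        }
  NumericVector gx(static_cast<size_t>(D) * H * W * Ci);
  for (int c = 0; c < Ci; ++c)
    for (int w2 = 0; w2 < W; ++w2)
      for (int h = 0; h < H; ++h) {
        const float* src = gxp.memptr() + pad +
          static_cast<size_t>(Dp) * ((h + pad) + static_cast<size_t>(Hp) * ((w2 + pad) + static_cast<size_t>(Wp) * c));
        double* dst = gx.begin() + static_cast<size_t>(D) * (h + static_cast<size_t>(H) * (w2 + static_cast<size_t>(W) * c));
        for (int d = 0; d < D; ++d) dst[d] = static_cast<double>(src[d]);
      }
  gx.attr("dim") = IntegerVector::create(D, H, W, Ci);

  NumericVector gwv(GW.begin(), GW.end());
  gwv.attr("dim") = wdim;
  NumericVector gbv(GB.begin(), GB.end());
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sample of channel-stacked x (D,H,W,C) at p = voxel + u(voxel),
// clamp-to-edge.  Shared sampling weights across channels.
// [[Rcpp::export(name = ".cpp_warp_trilinear")]]
NumericVector cpp_warp_trilinear(NumericVector x, NumericVector u) {
  int xd[4];
  get_dim4(x, xd);
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const double* U = u.begin();
  NumericVector out(static_cast<size_t>(D) * H * W * C);
  const size_t sC = static_cast<size_t>(D) * H * W;
  const double* X = x.begin();
  size_t v = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d, ++v) {
        const double pd = clampd(d + U[3 * v], 0.0, D - 1.0);
        const double ph = clampd(h + U[3 * v + 1], 0.0, H - 1.0);
        const double pw = clampd(w + U[3 * v + 2], 0.0, W - 1.0);
        int fd = std::min(static_cast<int>(pd), D - 2);
        int fh = std::min(static_cast<int>(ph), H - 2);
        int fw = std::min(static_cast<int>(pw), W - 2);
        const double td = pd - fd, th = ph - fh, tw = pw - fw;
        const size_t i000 = fd + static_cast<size_t>(D) * (fh + static_cast<size_t>(H) * fw);
        const size_t iH = D, iW = static_cast<size_t>(D) * H;
        const double w000 = (1 - td) * (1 - th) * (1 - tw), w100 = td * (1 - th) * (1 - tw);
        const double w010 = (1 - td) * th * (1 - tw), w110 = td * th * (1 - tw);
        const double w001 = (1 - td) * (1 - th) * tw, w101 = td * (1 - th) * tw;
        const double w011 = (1 - td) * th * tw, w111 = td * th * tw;
        for (int c = 0; c < C; ++c) {
          const double* Xc = X + sC * c;
          out[v + sC * c] =
            w000 * Xc[i000] + w100 * Xc[i000 + 1] +
            w010 * Xc[i000 + iH] + w110 * Xc[i000 + iH + 1] +
            w001 * Xc[i000 + iW] + w101 * Xc[i000 + iW + 1] +
            w011 * Xc[i000 + iH + iW] + w111 * Xc[i000 + iH + iW + 1];
        }
      }
  out.attr("dim") = IntegerVector::create(D, H, W, C);
  return out;
}

// Gradient of sum(gy * warp(x, u)) with respect to u.  Clamped coordinates
// carry zero gradient along the clamped axis.
// [[Rcpp::export(name = ".cpp_warp_trilinear_bwd_flow")]]
NumericVector cpp_warp_trilinear_bwd_flow(NumericVector x, NumericVector u,
                                          NumericVector gy) {
  int xd[4];
  get_dim4(x, xd);
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const double* U = u.begin();
  const double* X = x.begin();
  const double* G = gy.begin();
  NumericVector gu(u.size());
  const size_t sC = static_cast<size_t>(D) * H * W;
  size_t v = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d, ++v) {
        const double rd = d + U[3 * v], rh = h + U[3 * v + 1], rw = w + U[3 * v + 2];
        const bool cd = (rd < 0.0 || rd > D - 1.0);
        const bool ch = (rh < 0.0 || rh > H - 1.0);
        const bool cw = (rw < 0.0 || rw > W - 1.0);
        const double pd = clampd(rd, 0.0, D - 1.0);
        const double ph = clampd(rh, 0.0, H - 1.0);
        const double pw = clampd(rw, 0.0, W - 1.0);
        int fd = std::min(static_cast<int>(pd), D - 2);
        int fh = std::min(static_cast<int>(ph), H - 2);
        int fw = std::min(static_cast<int>(pw), W - 2);
        const double td = pd - fd, th = ph - fh, tw = pw - fw;
        const size_t i000 = fd + static_cast<size_t>(D) * (fh + static_cast<size_t>(H) * fw);
        const size_t iH = D, iW = static_cast<size_t>(D) * H;
        double gd = 0, gh = 0, gw2 = 0;
        for (int c = 0; c < C; ++c) {
          const double* Xc = X + sC * c;
          const double g = G[v + sC * c];
          const double c000 = Xc[i000], c100 = Xc[i000 + 1];
          const double c010 = Xc[i000 + iH], c110 = Xc[i000 + iH + 1];
          const double c001 = Xc[i000 + iW], c101 = Xc[i000 + iW + 1];
          const double c011 = Xc[i000 + iH + iW], c111 = Xc[i000 + iH + iW + 1];
          if (!cd)
            gd += g * ((c100 - c000) * (1 - th) * (1 - tw) + (c110 - c010) * th * (1 - tw) +
                       (c101 - c001) * (1 - th) * tw + (c111 - c011) * th * tw);
          if (!ch)
            gh += g * ((c010 - c000) * (1 - td) * (1 - tw) + (c110 - c100) * td * (1 - tw) +
                       (c011 - c001) * (1 - td) * tw + (c111 - c101) * td * tw);
          if (!cw)
            gw2 += g * ((c001 - c000) * (1 - td) * (1 - th) + (c101 - c100) * td * (1 - th) +
                        (c011 - c010) * (1 - td) * th + (c111 - c110) * td * th);
        }
        gu[3 * v] = gd;
        gu[3 * v + 1] = gh;
        gu[3 * v + 2] = gw2;
      }
  gu.attr("dim") = u.attr("dim");
  return gu;
}

// Nearest-neighbour label warp: index floor(p + 0.5) per axis, clamped.
// [[Rcpp::export(name = ".cpp_warp_nearest")]]
IntegerVector cpp_warp_nearest(IntegerVector lab, NumericVector u) {
  IntegerVector dm = lab.attr("dim");
  const int D = dm[0], H = dm[1], W = dm[2];
  const double* U = u.begin();
  IntegerVector out(lab.size());
  size_t v = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d, ++v) {
        int id = static_cast<int>(std::floor(d + U[3 * v] + 0.5));
        int ih = static_cast<int>(std::floor(h + U[3 * v + 1] + 0.5));
        int iw = static_cast<int>(std::floor(w + U[3 * v + 2] + 0.5));
        id = id < 0 ? 0 : (id > D - 1 ? D - 1 : id);
        ih = ih < 0 ? 0 : (ih > H - 1 ? H - 1 : ih);
        iw = iw < 0 ? 0 : (iw > W - 1 ? W - 1 : iw);
        out[v] = lab[id + static_cast<size_t>(D) * (ih + static_cast<size_t>(H) * iw)];
      }
  out.attr("dim") = dm;
  return out;
}

// Trilinear sampling of a single-channel volume at arbitrary points (N x 3,
// 0-based voxel coordinates), clamp-to-edge.
// [[Rcpp::export(name = ".cpp_sample_points")]]
NumericVector cpp_sample_points(NumericVector vol, NumericMatrix pts) {
  IntegerVector dm = vol.attr("dim");
  const int D = dm[0], H = dm[1], W = dm[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double* X = vol.begin();
  for (int i = 0; i < n; ++i) {
    const double pd = clampd(pts(i, 0), 0.0, D - 1.0);
    const double ph = clampd(pts(i, 1), 0.0, H - 1.0);
    const double pw = clampd(pts(i, 2), 0.0, W - 1.0);
    int fd = std::min(static_cast<int>(pd), D - 2);
    int fh = std::min(static_cast<int>(ph), H - 2);
    int fw = std::min(static_cast<int>(pw), W - 2);
    const double td = pd - fd, th = ph - fh, tw = pw - fw;
    const size_t i000 = fd + static_cast<size_t>(D) * (fh + static_cast<size_t>(H) * fw);
    const size_t iH = D, iW = static_cast<size_t>(D) * H;
    out[i] =
      (1 - td) * (1 - th) * (1 - tw) * X[i000] + td * (1 - th) * (1 - tw) * X[i000 + 1] +
      (1 - td) * th * (1 - tw) * X[i000 + iH] + td * th * (1 - tw) * X[i000 + iH + 1] +
      (1 - td) * (1 - th) * tw * X[i000 + iW] + td * (1 - th) * tw * X[i000 + iW + 1] +
      (1 - td) * th * tw * X[i000 + iH + iW] + td * th * tw * X[i000 + iH + iW + 1];
  }
  return out;
}

// Sliding-window sum over windows [p-r, p+r] truncated at the volume border,
// separable per axis.  Window membership is symmetric, so this operator is
// self-adjoint (used by the LNCC gradient).
// [[Rcpp::export(name = ".cpp_boxsum")]]
NumericVector cpp_boxsum(NumericVector x, int r) {
  IntegerVector dm = x.attr("dim");
  const int D = dm[0], H = dm[1], W = dm[2];
  std::vector<double> a(x.begin(), x.end()), b(x.size());
  // axis 0 (stride 1)
  {
    std::vector<double> pre(D + 1);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const size_t off = static_cast<size_t>(D) * (h + static_cast<size_t>(H) * w);
        pre[0] = 0.0;
        for (int d = 0; d < D; ++d) pre[d + 1] = pre[d] + a[off + d];
        for (int d = 0; d < D; ++d) {
          const int lo = std::max(0, d - r), hi = std::min(D - 1, d + r);
          b[off + d] = pre[hi + 1] - pre[lo];
        }
      }
    std::swap(a, b);
  }
  // axis 1 (stride D)
  {
    std::vector<double> pre(H + 1);
    for (int w = 0; w < W; ++w)
      for (int d = 0; d < D; ++d) {
        const size_t off = d + static_cast<size_t>(D) * static_cast<size_t>(H) * w;
        pre[0] = 0.0;
        for (int h = 0; h < H; ++h) pre[h + 1] = pre[h] + a[off + static_cast<size_t>(D) * h];
        for (int h = 0; h < H; ++h) {
          const int lo = std::max(0, h - r), hi = std::min(H - 1, h + r);
          b[off + static_cast<size_t>(D) * h] = pre[hi + 1] - pre[lo];
        }
      }
    std::swap(a, b);
  }
  // axis 2 (stride D*H)
  {
    const size_t s = static_cast<size_t>(D) * H;
    std::vector<double> pre(W + 1);
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const size_t off = d + static_cast<size_t>(D) * h;
        pre[0] = 0.0;
        for (int w = 0; w < W; ++w) pre[w + 1] = pre[w] + a[off + s * w];
        for (int w = 0; w < W; ++w) {
          const int lo = std::max(0, w - r), hi = std::min(W - 1, w + r);
          b[off + s * w] = pre[hi + 1] - pre[lo];
        }
      }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dm;
  return out;
}
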