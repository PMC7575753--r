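// Low-level neural-network operators used by the 2D U-Net.
// All tensors are R arrays in (H, W, C, N) order, column-major, double
// precision. Convolutions are 3x3, stride 1, "same" zero padding,
// implemented as im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::ivec4 tensor_dims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D (H, W, C, N) tensor");
  return arma::ivec4{d[0], d[1], d[2], d[3]};
}

// Build the im2col matrix (H*W) x (9*Cin) for one sample, in single
// precision (the GEMMs run in float32, the framework-standard precision
// for network training; parameters stay double on the R side).
// Column index = 9*c + (dr + 3*dc), dr/dc in {0,1,2} meaning offsets -1..1;
// this matches the column-major flattening of a (3, 3, Cin, Cout) weight
// array into a (9*Cin, Cout) matrix.
static void im2col3(const double* x, int H, int W, int C, arma::fmat& K) {
  K.zeros(static_cast<arma::uword>(H) * W, static_cast<arma::uword>(9) * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + static_cast<size_t>(c) * H * W;
    for (int dc = 0; dc < 3; ++dc) {
      for (int dr = 0; dr < 3; ++dr) {
        float* col = K.colptr(9 * c + dr + 3 * dc);
        const int roff = dr - 1, coff = dc - 1;
        const int c0 = std::max(0, -coff), c1 = std::min(W, W - coff);
        const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
        for (int cc = c0; cc < c1; ++cc) {
          const double* src = xc + static_cast<size_t>(cc + coff) * H + roff;
          float* dst = col + static_cast<size_t>(cc) * H;
          for (int r = r0; r < r1; ++r) dst[r] = static_cast<float>(src[r]);
        }
      }
    }
  }
}

// Scatter-add of the columns of G (H*W x 9*Cin) back onto the input grid
// (transpose of im2col3).
static void col2im3(const arma::fmat& G, int H, int W, int C, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* dxc = dx + static_cast<size_t>(c) * H * W;
    for (int dc = 0; dc < 3; ++dc) {
      for (int dr = 0; dr < 3; ++dr) {
        const float* col = G.colptr(9 * c + dr + 3 * dc);
        const int roff = dr - 1, coff = dc - 1;
        const int c0 = std::max(0, -coff), c1 = std::min(W, W - coff);
        const int r0 = std::max(0, -roff), r1 = std::min(H, H - roff);
        for (int cc = c0; cc < c1; ++cc) {
          double* dst = dxc + static_cast<size_t>(cc + coff) * H + roff;
          const float* src = col + static_cast<size_t>(cc) * H;
          for (int r = r0; r < r1; ++r) dst[r] += src[r];
        }
      }
    }
  }
}

static arma::fmat to_fmat(const double* p, arma::uword nr, arma::uword nc) {
  arma::fmat out(nr, nc);
  float* o = out.memptr();
  const size_t n = static_cast<size_t>(nr) * nc;
  for (size_t i = 0; i < n; ++i) o[i] = static_cast<float>(p[i]);
  return out;
}

// [[Rcpp::export(name = ".conv3x3_forward")]]
NumericVector conv3x3_forward(NumericVector x, NumericVector w,
                              NumericVector b, bool relu = false) {
  arma::ivec4 dx = tensor_dims(x);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  IntegerVector dw = w.attr("dim");
  if (dw.size() != 4 || dw[0] != 3 || dw[1] != 3 || dw[2] != Cin)
    stop("weight must be a (3, 3, Cin, Cout) array matching the input");
  const int Cout = dw[3];
  if (b.size() != Cout) stop("bias length must equal Cout");

  const arma::fmat Wm = to_fmat(w.begin(), 9 * Cin, Cout);
  NumericVector out(static_cast<R_xlen_t>(H) * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);

  arma::fmat K, Y;
  const size_t in_stride = static_cast<size_t>(H) * W * Cin;
  const size_t out_stride = static_cast<size_t>(H) * W * Cout;
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + n * in_stride, H, W, Cin, K);
    Y = K * Wm;
    for (int o = 0; o < Cout; ++o) Y.col(o) += static_cast<float>(b[o]);
    double* op = out.begin() + n * out_stride;
    const float* yp = Y.memptr();
    if (relu) {
      for (size_t i = 0; i < out_stride; ++i)
        op[i] = yp[i] > 0.0f ? yp[i] : 0.0;
    } else {
      for (size_t i = 0; i < out_stride; ++i) op[i] = yp[i];
    }
  }
  return out;
}

// Backward pass. When `relu_out` (the forward ReLU output of this conv) is
// supplied, the incoming gradient is masked by out > 0 on the fly, fusing
// the ReLU backward into the conversion pass.
// [[Rcpp::export(name = ".conv3x3_backward")]]
List conv3x3_backward(NumericVector x, NumericVector w, NumericVector dy,
                      Nullable<NumericVector> relu_out = R_NilValue) {
  arma::ivec4 dxd = tensor_dims(x);
  const int H = dxd[0], W = dxd[1], Cin = dxd[2], N = dxd[3];
  IntegerVector dw_dim = w.attr("dim");
  const int Cout = dw_dim[3];
  arma::ivec4 dyd = tensor_dims(dy);
  if (dyd[0] != H || dyd[1] != W || dyd[2] != Cout || dyd[3] != N)
    stop("dy dims do not match forward output");

  const arma::fmat Wm = to_fmat(w.begin(), 9 * Cin, Cout);
  NumericVector dx(static_cast<R_xlen_t>(H) * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector dwv(static_cast<R_xlen_t>(9) * Cin * Cout);
  dwv.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
  arma::mat dWm(dwv.begin(), 9 * Cin, Cout, false, true);
  NumericVector dbv(Cout);

  const double* mask = relu_out.isNotNull()
    ? NumericVector(relu_out).begin() : nullptr;

  arma::fmat K, G, dY;
  const size_t in_stride = static_cast<size_t>(H) * W * Cin;
  const size_t out_stride = static_cast<size_t>(H) * W * Cout;
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + n * in_stride, H, W, Cin, K);
    const double* dyp = dy.begin() + n * out_stride;
    dY.set_size(static_cast<arma::uword>(H) * W, Cout);
    float* dyf = dY.memptr();
    if (mask) {
      const double* mp = mask + n * out_stride;
      for (size_t i = 0; i < out_stride; ++i)
        dyf[i] = mp[i] > 0.0 ? static_cast<float>(dyp[i]) : 0.0f;
    } else {
      for (size_t i = 0; i < out_stride; ++i)
        dyf[i] = static_cast<float>(dyp[i]);
    }
    dWm += arma::conv_to<arma::mat>::from(K.t() * dY);
    for (int o = 0; o < Cout; ++o) dbv[o] += arma::accu(dY.col(o));
    G = dY * Wm.t();
    col2im3(G, H, W, Cin, dx.begin() + n * in_stride);
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// 2x2 max pooling, stride 2. H and W must be even. Returns the pooled map
// and the within-window argmax (0..3, column-major within the window) needed
// for the backward pass.
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  arma::ivec4 d = tensor_dims(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 != 0 || W % 2 != 0) stop("maxpool2 requires even H and W");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  const size_t planes = static_cast<size_t>(C) * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xpl = xp + p * H * W;
    double* ypl = yp + p * Ho * Wo;
    int* ipl = ip + p * Ho * Wo;
    for (int cc = 0; cc < Wo; ++cc) {
      for (int r = 0; r < Ho; ++r) {
        const double* base = xpl + static_cast<size_t>(2 * cc) * H + 2 * r;
        double v[4] = {base[0], base[1], base[H], base[H + 1]};
        int best = 0;
        for (int k = 1; k < 4; ++k) if (v[k] > v[best]) best = k;
        ypl[static_cast<size_t>(cc) * Ho + r] = v[best];
        ipl[static_cast<size_t>(cc) * Ho + r] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx) {
  arma::ivec4 d = tensor_dims(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = 2 * Ho, W = 2 * Wo;
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);

  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  const size_t planes = static_cast<size_t>(C) * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* dypl = dyp + p * Ho * Wo;
    const int* ipl = ip + p * Ho * Wo;
    double* dxpl = dxp + p * H * W;
    for (int cc = 0; cc < Wo; ++cc) {
      for (int r = 0; r < Ho; ++r) {
        const int k = ipl[static_cast<size_t>(cc) * Ho + r];
        const int rr = 2 * r + (k & 1), ccx = 2 * cc + (k >> 1);
        dxpl[static_cast<size_t>(ccx) * H + rr] +=
            dypl[static_cast<size_t>(cc) * Ho + r];
      }
    }
  }
  return dx;
}

// Nearest-neighbor 2x upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export(name = ".upsample2_forward")]]
NumericVector upsample2_forward(NumericVector x) {
  arma::ivec4 d = tensor_dims(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t planes = static_cast<size_t>(C) * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xpl = xp + p * H * W;
    double* ypl = yp + p * Ho * Wo;
    for (int cc = 0; cc < W; ++cc) {
      for (int r = 0; r < H; ++r) {
        const double v = xpl[static_cast<size_t>(cc) * H + r];
        double* base = ypl + static_cast<size_t>(2 * cc) * Ho + 2 * r;
        base[0] = v; base[1] = v; base[Ho] = v; base[Ho + 1] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
NumericVector upsample2_backward(NumericVector dy) {
  arma::ivec4 d = tensor_dims(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  if (Ho % 2 != 0 || Wo % 2 != 0) stop("upsample2 adjoint requires even dims");
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const size_t planes = static_cast<size_t>(C) * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* dypl = dyp + p * Ho * Wo;
    double* dxpl = dxp + p * H * W;
    for (int cc = 0; cc < W; ++cc) {
      for (int r = 0; r < H; ++r) {
        const double* base = dypl + static_cast<size_t>(2 * cc) * Ho + 2 * r;
        dxpl[static_cast<size_t>(cc) * H + r] =
            base[0] + base[1] + base[Ho] + base[Ho + 1];
      }
    }
  }
  return dx;
}
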