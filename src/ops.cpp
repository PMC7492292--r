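// Low-level compute kernels: 2D convolution (im2col + GEMM), max-pooling,
// nearest-neighbour upsampling, connected-component labelling and binary
// morphology. All array arguments use R's column-major layout with image
// dimensions (H, W, C, N): H = rows, W = cols, C = channels, N = batch.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill the im2col matrix (H*W rows, Cin*k*k cols) for one sample.
// Column r of `colmat` corresponds to (ci, dc, dr) with
// r = ci*k*k + dc*k + dr; entry (h + H*w, r) = x(h+dr-pad, w+dc-pad, ci),
// zero outside the image (same-padding).
static void im2col(const double* xn, int H, int W, int Cin, int k, int pad,
                   arma::mat& colmat) {
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = xn + (size_t)ci * H * W;
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        int r = ci * k * k + dc * k + dr;
        double* col = colmat.colptr(r);
        int offc = dc - pad, offr = dr - pad;
        for (int w = 0; w < W; ++w) {
          double* dst = col + (size_t)w * H;
          int wc = w + offc;
          if (wc < 0 || wc >= W) { std::fill(dst, dst + H, 0.0); continue; }
          const double* src = xc + (size_t)wc * H;
          int h0 = std::max(0, -offr), h1 = std::min(H, H - offr);
          if (h0 > 0) std::fill(dst, dst + h0, 0.0);
          for (int h = h0; h < h1; ++h) dst[h] = src[h + offr];
          if (h1 < H) std::fill(dst + h1, dst + H, 0.0);
        }
      }
    }
  }
}

// Scatter-add of the im2col adjoint: dcol (H*W x Cin*k*k) back onto dxn.
static void col2im(const arma::mat& dcol, int H, int W, int Cin, int k,
                   int pad, double* dxn) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = dxn + (size_t)ci * H * W;
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        int r = ci * k * k + dc * k + dr;
        const double* col = dcol.colptr(r);
        int offc = dc - pad, offr = dr - pad;
        for (int w = 0; w < W; ++w) {
          int wc = w + offc;
          if (wc < 0 || wc >= W) continue;
          double* dst = xc + (size_t)wc * H;
          const double* src = col + (size_t)w * H;
          int h0 = std::max(0, -offr), h1 = std::min(H, H - offr);
          for (int h = h0; h < h1; ++h) dst[h + offr] += src[h];
        }
      }
    }
  }
}

// Same-padding 2D convolution, stride 1.
// x: (H,W,Cin,N); wt: (Cin*k*k) x Cout; b: length Cout. Returns (H,W,Cout,N).
// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericMatrix wt, NumericVector b, int k) {
  int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  int Cout = wt.ncol(), K = Cin * k * k, pad = k / 2;
  if (wt.nrow() != K) stop("weight/kernel mismatch");
  size_t P = (size_t)H * W;
  NumericVector y((size_t)P * Cout * N);
  arma::mat Wm(wt.begin(), K, Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  arma::mat colmat(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * P * Cin, H, W, Cin, k, pad, colmat);
    arma::mat Yn = colmat * Wm;
    Yn.each_row() += bv;
    std::copy(Yn.memptr(), Yn.memptr() + P * Cout,
              y.begin() + (size_t)n * P * Cout);
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// Gradients of the same-padding convolution.
// dy: (H,W,Cout,N). Returns list(dx, dwt, db).
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim, NumericMatrix wt,
                    int k, NumericVector dy) {
  int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  int Cout = wt.ncol(), K = Cin * k * k, pad = k / 2;
  size_t P = (size_t)H * W;
  NumericVector dx(x.size());
  arma::mat Wm(wt.begin(), K, Cout, false);
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat colmat(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * P * Cin, H, W, Cin, k, pad, colmat);
    arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)n * P * Cout,
                  P, Cout, false);
    dW += colmat.t() * dYn;
    db += arma::sum(dYn, 0);
    arma::mat dcol = dYn * Wm.t();
    col2im(dcol, H, W, Cin, k, pad, dx.begin() + (size_t)n * P * Cin);
  }
  dx.attr("dim") = xdim;
  NumericMatrix dwt(K, Cout);
  std::copy(dW.memptr(), dW.memptr() + (size_t)K * Cout, dwt.begin());
  NumericVector dbv(Cout);
  std::copy(db.memptr(), db.memptr() + Cout, dbv.begin());
  return List::create(_["dx"] = dx, _["dwt"] = dwt, _["db"] = dbv);
}

// 2x2 max pooling, stride 2. H and W must be even.
// Returns list(y = (H/2,W/2,C,N), idx = 1-based argmax linear indices into x).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = H / 2, Wo = W / 2;
  size_t no = (size_t)Ho * Wo * C * N;
  NumericVector y(no);
  IntegerVector idx(no);
  const double* xp = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t i00 = base + (size_t)(2 * w) * H + 2 * h;
          size_t best = i00;
          if (xp[i00 + 1] > xp[best]) best = i00 + 1;
          if (xp[i00 + H] > xp[best]) best = i00 + H;
          if (xp[i00 + H + 1] > xp[best]) best = i00 + H + 1;
          // column-major output: h fastest
          size_t oo = ((size_t)n * C + c) * Ho * Wo + (size_t)w * Ho + h;
          y[oo] = xp[best];
          idx[oo] = (int)(best + 1);
          ++o;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t bi = ((size_t)n * C + c) * H * W;
      size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double v = xp[bi + (size_t)w * H + h];
          size_t o = bo + (size_t)(2 * w) * Ho + 2 * h;
          yp[o] = v; yp[o + 1] = v; yp[o + Ho] = v; yp[o + Ho + 1] = v;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy, IntegerVector ydim) {
  int Ho = ydim[0], Wo = ydim[1], C = ydim[2], N = ydim[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t bo = ((size_t)n * C + c) * Ho * Wo;
      size_t bi = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          size_t o = bo + (size_t)(2 * w) * Ho + 2 * h;
          dxp[bi + (size_t)w * H + h] =
            dyp[o] + dyp[o + 1] + dyp[o + Ho] + dyp[o + Ho + 1];
        }
    }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Connected-component labelling of a binary matrix, 8- or 4-connectivity.
// Labels are assigned in column-major first-encounter order, starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix m, int connectivity) {
  int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (m(h, w) == 0 || lab(h, w) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(h, w));
      lab(h, w) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back(); stack.pop_back();
        for (int d = 0; d < nn; ++d) {
          int r = p.first + dr8[d], c = p.second + dc8[d];
          if (r < 0 || r >= H || c < 0 || c >= W) continue;
          if (m(r, c) != 0 && lab(r, c) == 0) {
            lab(r, c) = next;
            stack.push_back(std::make_pair(r, c));
          }
        }
      }
    }
  lab.attr("n") = next;
  return lab;
}

// Binary dilation/erosion with a (2r+1)x(2r+1) square structuring element
// (Chebyshev ball). Pixels outside the image count as background.
// [[Rcpp::export]]
IntegerMatrix cpp_binary_morph(IntegerMatrix m, int r, bool dilate) {
  int H = m.nrow(), W = m.ncol();
  IntegerMatrix tmp(H, W), out(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      int acc = dilate ? 0 : 1;
      for (int d = -r; d <= r; ++d) {
        int c = w + d;
        int v = (c < 0 || c >= W) ? 0 : m(h, c);
        if (dilate) { if (v) { acc = 1; break; } }
        else if (!v) { acc = 0; break; }
      }
      tmp(h, w) = acc;
    }
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      int acc = dilate ? 0 : 1;
      for (int d = -r; d <= r; ++d) {
        int rr = h + d;
        int v = (rr < 0 || rr >= H) ? 0 : tmp(rr, w);
        if (dilate) { if (v) { acc = 1; break; } }
        else if (!v) { acc = 0; break; }
      }
      out(h, w) = acc;
    }
  return out;
}
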