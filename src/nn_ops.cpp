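#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are C x (H*W) matrices, spatial index j = y*W + x (row-major
// over the image plane). Images at the I/O boundary are H x W x C arrays in
// R's column-major layout.

// [[Rcpp::export]]
NumericVector resize_image_cpp(NumericVector img, int out_h, int out_w) {
  IntegerVector dims = img.attr("dim");
  int H = dims[0], W = dims[1], C = dims.size() > 2 ? dims[2] : 1;
  NumericVector out(out_h * out_w * C);
  out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int c = 0; c < C; ++c) {
    const double *src = &img[(size_t)c * H * W];
    double *dst = &out[(size_t)c * out_h * out_w];
    for (int ox = 0; ox < out_w; ++ox) {
      double fx = (ox + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(fx);
      double wx = fx - x0;
      int x0c = std::min(std::max(x0, 0), W - 1);
      int x1c = std::min(std::max(x0 + 1, 0), W - 1);
      for (int oy = 0; oy < out_h; ++oy) {
        double fy = (oy + 0.5) * sy - 0.5;
        int y0 = (int)std::floor(fy);
        double wy = fy - y0;
        int y0c = std::min(std::max(y0, 0), H - 1);
        int y1c = std::min(std::max(y0 + 1, 0), H - 1);
        double v00 = src[y0c + (size_t)x0c * H], v01 = src[y0c + (size_t)x1c * H];
        double v10 = src[y1c + (size_t)x0c * H], v11 = src[y1c + (size_t)x1c * H];
        dst[oy + (size_t)ox * out_h] =
          (1 - wy) * ((1 - wx) * v00 + wx * v01) +
          wy * ((1 - wx) * v10 + wx * v11);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericMatrix X, int H, int W, int k, int stride,
                         int pad) {
  int C = X.nrow();
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, Ho * Wo);
  for (int yo = 0; yo < Ho; ++yo) {
    for (int xo = 0; xo < Wo; ++xo) {
      int col = yo * Wo + xo;
      double *dst = &out(0, col);
      for (int ky = 0; ky < k; ++ky) {
        int yi = yo * stride + ky - pad;
        for (int kx = 0; kx < k; ++kx) {
          int xi = xo * stride + kx - pad;
          int roff = (ky * k + kx);
          if (yi < 0 || yi >= H || xi < 0 || xi >= W) {
            for (int c = 0; c < C; ++c) dst[c * k * k + roff] = 0.0;
          } else {
            int j = yi * W + xi;
            const double *src = &X(0, j);
            for (int c = 0; c < C; ++c) dst[c * k * k + roff] = src[c];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im_cpp(NumericMatrix cols, int H, int W, int C, int k,
                         int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C, H * W);
  for (int yo = 0; yo < Ho; ++yo) {
    for (int xo = 0; xo < Wo; ++xo) {
      int col = yo * Wo + xo;
      const double *src = &cols(0, col);
      for (int ky = 0; ky < k; ++ky) {
        int yi = yo * stride + ky - pad;
        if (yi < 0 || yi >= H) continue;
        for (int kx = 0; kx < k; ++kx) {
          int xi = xo * stride + kx - pad;
          if (xi < 0 || xi >= W) continue;
          int j = yi * W + xi;
          int roff = ky * k + kx;
          double *dst = &out(0, j);
          for (int c = 0; c < C; ++c) dst[c] += src[c * k * k + roff];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List maxpool_cpp(NumericMatrix X, int H, int W, int k, int stride, int pad) {
  int C = X.nrow();
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix Y(C, Ho * Wo);
  IntegerMatrix idx(C, Ho * Wo);  // 0-based argmax spatial index into H*W
  for (int yo = 0; yo < Ho; ++yo) {
    for (int xo = 0; xo < Wo; ++xo) {
      int col = yo * Wo + xo;
      for (int c = 0; c < C; ++c) {
        double best = R_NegInf;
        int besti = -1;
        for (int ky = 0; ky < k; ++ky) {
          int yi = yo * stride + ky - pad;
          if (yi < 0 || yi >= H) continue;
          for (int kx = 0; kx < k; ++kx) {
            int xi = xo * stride + kx - pad;
            if (xi < 0 || xi >= W) continue;
            double v = X(c, yi * W + xi);
            if (v > best) { best = v; besti = yi * W + xi; }
          }
        }
        Y(c, col) = besti < 0 ? 0.0 : best;
        idx(c, col) = besti;
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool_bwd_cpp(NumericMatrix dY, IntegerMatrix idx, int HW) {
  int C = dY.nrow(), n = dY.ncol();
  NumericMatrix dX(C, HW);
  for (int j = 0; j < n; ++j)
    for (int c = 0; c < C; ++c)
      if (idx(c, j) >= 0) dX(c, idx(c, j)) += dY(c, j);
  return dX;
}

// [[Rcpp::export]]
NumericMatrix upsample2_cpp(NumericMatrix X, int H, int W) {
  int C = X.nrow();
  NumericMatrix Y(C, 4 * H * W);
  int W2 = 2 * W;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int j = y * W + x;
      int o = 2 * y * W2 + 2 * x;
      for (int c = 0; c < C; ++c) {
        double v = X(c, j);
        Y(c, o) = v; Y(c, o + 1) = v;
        Y(c, o + W2) = v; Y(c, o + W2 + 1) = v;
      }
    }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix upsample2_bwd_cpp(NumericMatrix dY, int H, int W) {
  // H, W are the *input* (coarse) dimensions
  int C = dY.nrow();
  NumericMatrix dX(C, H * W);
  int W2 = 2 * W;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int j = y * W + x;
      int o = 2 * y * W2 + 2 * x;
      for (int c = 0; c < C; ++c)
        dX(c, j) = dY(c, o) + dY(c, o + 1) + dY(c, o + W2) + dY(c, o + W2 + 1);
    }
  return dX;
}
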