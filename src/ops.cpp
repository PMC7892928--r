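#include <Rcpp.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Feature tensors are column-major arrays with dim (C, H, W, N).
// im2col for a 3x3 same-padded convolution produces a (9*C) x (H*W*N)
// matrix whose row index is k*C + c with k = (dh+1) + 3*(dw+1),
// dh, dw in {-1,0,1}; columns iterate (h, w, n) in array order so the
// GEMM result W %*% col can be reinterpreted as a (Cout, H, W, N) array
// without any copy.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int C, int H, int W, int N) {
  // every entry is written below (memcpy or memset), so skip R's zeroing
  NumericMatrix col(Rf_allocMatrix(REALSXP, 9 * C, (R_xlen_t)H * W * N));
  const double* xp = x.begin();
  double* cp = col.begin();
  const R_xlen_t colstride = 9 * C;
  for (int n = 0; n < N; ++n) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* dst0 = cp + colstride * ((R_xlen_t)h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
        for (int dw = -1; dw <= 1; ++dw) {
          const int w2 = w + dw;
          for (int dh = -1; dh <= 1; ++dh) {
            const int h2 = h + dh;
            const int k = (dh + 1) + 3 * (dw + 1);
            double* dst = dst0 + (R_xlen_t)k * C;
            if (h2 < 0 || h2 >= H || w2 < 0 || w2 >= W) {
              std::memset(dst, 0, sizeof(double) * C);
            } else {
              const double* src = xp + (R_xlen_t)C * (h2 + (R_xlen_t)H * (w2 + (R_xlen_t)W * n));
              std::memcpy(dst, src, sizeof(double) * C);
            }
          }
        }
      }
    }
  }
  return col;
}

// Adjoint of cpp_im2col: scatter-add a (9*C) x (H*W*N) gradient back to
// the (C, H, W, N) input layout.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcol, int C, int H, int W, int N) {
  NumericVector dx((R_xlen_t)C * H * W * N);
  double* xp = dx.begin();
  const double* cp = dcol.begin();
  const R_xlen_t colstride = 9 * C;
  for (int n = 0; n < N; ++n) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* src0 = cp + colstride * ((R_xlen_t)h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
        for (int dw = -1; dw <= 1; ++dw) {
          const int w2 = w + dw;
          if (w2 < 0 || w2 >= W) continue;
          for (int dh = -1; dh <= 1; ++dh) {
            const int h2 = h + dh;
            if (h2 < 0 || h2 >= H) continue;
            const int k = (dh + 1) + 3 * (dw + 1);
            const double* src = src0 + (R_xlen_t)k * C;
            double* dst = xp + (R_xlen_t)C * (h2 + (R_xlen_t)H * (w2 + (R_xlen_t)W * n));
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return dx;
}

// 2x2 max pooling with stride 2 on (C, H, W, N); H and W must be even.
// Returns the pooled tensor and 1-based argmax indices into x for the
// backward pass.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int C, int H, int W, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)C * Ho * Wo * N);
  IntegerVector idx((R_xlen_t)C * Ho * Wo * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t out0 = (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          R_xlen_t bestix = 0;
          for (int dw = 0; dw < 2; ++dw) {
            for (int dh = 0; dh < 2; ++dh) {
              const R_xlen_t ix = c + (R_xlen_t)C * ((2 * ho + dh) +
                (R_xlen_t)H * ((2 * wo + dw) + (R_xlen_t)W * n));
              if (xp[ix] > best) { best = xp[ix]; bestix = ix; }
            }
          }
          yp[out0 + c] = best;
          ip[out0 + c] = (int)(bestix + 1);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector idx,
                             int C, int H, int W, int N) {
  NumericVector dx((R_xlen_t)C * H * W * N);
  double* xp = dx.begin();
  const double* dp = dy.begin();
  const int* ip = idx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[ip[i] - 1] += dp[i];
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return dx;
}

// Connected-component labeling of a 3D binary array under 26-connectivity.
// Components are numbered 1, 2, ... in order of the first voxel reached by
// a column-major scan, so label order is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, int X, int Y, int Z) {
  IntegerVector lab((R_xlen_t)X * Y * Z);
  const int* mp = mask.begin();
  int* lp = lab.begin();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < (R_xlen_t)X * Y * Z; ++start) {
    if (mp[start] == 0 || lp[start] != 0) continue;
    ++next;
    lp[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int x = (int)(v % X);
      const int y = (int)((v / X) % Y);
      const int z = (int)(v / ((R_xlen_t)X * Y));
      for (int dz = -1; dz <= 1; ++dz) {
        const int z2 = z + dz;
        if (z2 < 0 || z2 >= Z) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int y2 = y + dy;
          if (y2 < 0 || y2 >= Y) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int x2 = x + dx;
            if (x2 < 0 || x2 >= X) continue;
            const R_xlen_t u = x2 + (R_xlen_t)X * (y2 + (R_xlen_t)Y * z2);
            if (mp[u] != 0 && lp[u] == 0) {
              lp[u] = next;
              stack.push_back(u);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(X, Y, Z);
  return lab;
}
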