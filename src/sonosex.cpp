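#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 8-connected component labelling of a logical mask (BFS flood fill).
// Returns an integer matrix of labels, 0 = background, components
// numbered in raster-scan order of their first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Inverse-mapped affine resample with bilinear interpolation, zero fill.
// For output pixel (r, c) (0-based) the source location is
//   rs = a11*r + a12*c + b1,  cs = a21*r + a22*c + b2.
// With clamp_edges the source location is clamped to the image extent
// (border replication; used by pure resizing so constant images stay
// constant), otherwise out-of-range samples read zero.
// [[Rcpp::export]]
NumericMatrix affine_warp(const NumericMatrix& img,
                          double a11, double a12, double a21, double a22,
                          double b1, double b2, int out_h, int out_w,
                          bool clamp_edges = false) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(out_h, out_w);
  for (int c = 0; c < out_w; ++c) {
    for (int r = 0; r < out_h; ++r) {
      double rs = a11 * r + a12 * c + b1;
      double cs = a21 * r + a22 * c + b2;
      if (clamp_edges) {
        rs = std::min(std::max(rs, 0.0), (double)(nr - 1));
        cs = std::min(std::max(cs, 0.0), (double)(nc - 1));
      }
      int r0 = (int)std::floor(rs), c0 = (int)std::floor(cs);
      double fr = rs - r0, fc = cs - c0;
      double v = 0.0;
      for (int dr = 0; dr <= 1; ++dr) {
        for (int dc = 0; dc <= 1; ++dc) {
          int ri = r0 + dr, ci = c0 + dc;
          if (ri < 0 || ci < 0 || ri >= nr || ci >= nc) continue;
          double w = (dr ? fr : 1.0 - fr) * (dc ? fc : 1.0 - fc);
          v += w * img(ri, ci);
        }
      }
      out(r, c) = v;
    }
  }
  return out;
}

// --- CNN kernels -----------------------------------------------------------
// Activations for a batch of N single- or multi-channel feature maps are
// stored as an (N*H*W) x C matrix; the row for image n, row r, col c is
// n*H*W + r*W + c (all 0-based).

// im2col for a 3x3 kernel, stride 1, zero padding 1.
// Output: (N*H*W) x (9*C); column k*C + ch holds channel ch at kernel
// offset k (k = (dr+1)*3 + (dc+1)).
// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& x, int n, int h, int w) {
  const int c = x.ncol();
  NumericMatrix out(x.nrow(), 9 * c);
  for (int ch = 0; ch < c; ++ch) {
    for (int k = 0; k < 9; ++k) {
      int dr = k / 3 - 1, dc = k % 3 - 1;
      int ocol = k * c + ch;
      for (int img = 0; img < n; ++img) {
        int base = img * h * w;
        for (int r = 0; r < h; ++r) {
          int rs = r + dr;
          if (rs < 0 || rs >= h) continue;
          for (int cc = 0; cc < w; ++cc) {
            int cs = cc + dc;
            if (cs < 0 || cs >= w) continue;
            out(base + r * w + cc, ocol) = x(base + rs * w + cs, ch);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add a (N*H*W) x (9*C) column gradient back
// to an (N*H*W) x C input gradient.
// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& cols, int n, int h, int w, int c) {
  NumericMatrix out(n * h * w, c);
  for (int ch = 0; ch < c; ++ch) {
    for (int k = 0; k < 9; ++k) {
      int dr = k / 3 - 1, dc = k % 3 - 1;
      int icol = k * c + ch;
      for (int img = 0; img < n; ++img) {
        int base = img * h * w;
        for (int r = 0; r < h; ++r) {
          int rs = r + dr;
          if (rs < 0 || rs >= h) continue;
          for (int cc = 0; cc < w; ++cc) {
            int cs = cc + dc;
            if (cs < 0 || cs >= w) continue;
            out(base + rs * w + cs, ch) += cols(base + r * w + cc, icol);
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling, stride 2. Returns pooled values and the (1-based) input
// row index of each maximum so the backward pass can scatter gradients.
// [[Rcpp::export]]
List maxpool2(const NumericMatrix& x, int n, int h, int w) {
  const int c = x.ncol(), ho = h / 2, wo = w / 2;
  NumericMatrix out(n * ho * wo, c);
  IntegerMatrix arg(n * ho * wo, c);
  for (int ch = 0; ch < c; ++ch) {
    for (int img = 0; img < n; ++img) {
      int base = img * h * w, obase = img * ho * wo;
      for (int r = 0; r < ho; ++r) {
        for (int cc = 0; cc < wo; ++cc) {
          double best = R_NegInf; int besti = -1;
          for (int dr = 0; dr < 2; ++dr) {
            for (int dc = 0; dc < 2; ++dc) {
              int idx = base + (2 * r + dr) * w + (2 * cc + dc);
              if (x(idx, ch) > best) { best = x(idx, ch); besti = idx; }
            }
          }
          out(obase + r * wo + cc, ch) = best;
          arg(obase + r * wo + cc, ch) = besti + 1;
        }
      }
    }
  }
  return List::create(_["values"] = out, _["argmax"] = arg);
}

// Backward of maxpool2: route gradients to the argmax positions.
// [[Rcpp::export]]
NumericMatrix maxpool2_backward(const NumericMatrix& grad,
                                const IntegerMatrix& argmax, int n_in) {
  const int c = grad.ncol();
  NumericMatrix out(n_in, c);
  for (int ch = 0; ch < c; ++ch)
    for (int i = 0; i < grad.nrow(); ++i)
      out(argmax(i, ch) - 1, ch) += grad(i, ch);
  return out;
}
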