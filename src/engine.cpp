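// Compact CPU engine for the small 2D/3D convolutional networks used by the
// segmentation pipeline, plus voxel utilities that have no counterpart in the
// installed image packages (3D connected components, non-local-means).
//
// Tensor convention: channel-first flat arrays with dims (C, X, Y, Z), column
// major, so the C channel values of a voxel are contiguous.  Convolutions are
// im2col + dgemm; backward recomputes im2col (memory traded for time).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// K gets one column per output voxel, rows ordered c + C*(ix + kx*(iy + ky*iz))
static void im2col(const double* x, int C, int X, int Y, int Z,
                   int kx, int ky, int kz, int sx, int sy, int sz,
                   int px, int py, int pz, arma::mat& K) {
  const int Xo = out_len(X, kx, sx, px);
  const int Yo = out_len(Y, ky, sy, py);
  const int Zo = out_len(Z, kz, sz, pz);
  K.zeros(C * kx * ky * kz, (arma::uword)Xo * Yo * Zo);
  for (int oz = 0; oz < Zo; ++oz) {
    for (int oy = 0; oy < Yo; ++oy) {
      for (int ox = 0; ox < Xo; ++ox) {
        const arma::uword col = ox + (arma::uword)Xo * (oy + (arma::uword)Yo * oz);
        double* kc = K.colptr(col);
        for (int iz = 0; iz < kz; ++iz) {
          const int zi = oz * sz - pz + iz;
          if (zi < 0 || zi >= Z) continue;
          for (int iy = 0; iy < ky; ++iy) {
            const int yi = oy * sy - py + iy;
            if (yi < 0 || yi >= Y) continue;
            for (int ix = 0; ix < kx; ++ix) {
              const int xi = ox * sx - px + ix;
              if (xi < 0 || xi >= X) continue;
              const double* src = x + (size_t)C * (xi + (size_t)X * (yi + (size_t)Y * zi));
              double* dst = kc + (size_t)C * (ix + (size_t)kx * (iy + (size_t)ky * iz));
              std::copy(src, src + C, dst);
            }
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& K, double* dx, int C, int X, int Y, int Z,
                   int kx, int ky, int kz, int sx, int sy, int sz,
                   int px, int py, int pz) {
  const int Xo = out_len(X, kx, sx, px);
  const int Yo = out_len(Y, ky, sy, py);
  const int Zo = out_len(Z, kz, sz, pz);
  for (int oz = 0; oz < Zo; ++oz) {
    for (int oy = 0; oy < Yo; ++oy) {
      for (int ox = 0; ox < Xo; ++ox) {
        const arma::uword col = ox + (arma::uword)Xo * (oy + (arma::uword)Yo * oz);
        const double* kc = K.colptr(col);
        for (int iz = 0; iz < kz; ++iz) {
          const int zi = oz * sz - pz + iz;
          if (zi < 0 || zi >= Z) continue;
          for (int iy = 0; iy < ky; ++iy) {
            const int yi = oy * sy - py + iy;
            if (yi < 0 || yi >= Y) continue;
            for (int ix = 0; ix < kx; ++ix) {
              const int xi = ox * sx - px + ix;
              if (xi < 0 || xi >= X) continue;
              double* dst = dx + (size_t)C * (xi + (size_t)X * (yi + (size_t)Y * zi));
              const double* src = kc + (size_t)C * (ix + (size_t)kx * (iy + (size_t)ky * iz));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(const NumericVector& x, const IntegerVector& xd,
                          const arma::mat& W, const arma::vec& b,
                          const IntegerVector& k, const IntegerVector& s,
                          const IntegerVector& p) {
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int Xo = out_len(X, k[0], s[0], p[0]);
  const int Yo = out_len(Y, k[1], s[1], p[1]);
  const int Zo = out_len(Z, k[2], s[2], p[2]);
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("conv: output would be empty");
  arma::mat K;
  im2col(REAL(x), C, X, Y, Z, k[0], k[1], k[2], s[0], s[1], s[2], p[0], p[1], p[2], K);
  arma::mat Ymat = W * K;                    // (Cout x Nout)
  Ymat.each_col() += b;
  NumericVector out(Ymat.n_elem);
  std::copy(Ymat.memptr(), Ymat.memptr() + Ymat.n_elem, REAL(out));
  out.attr("dim") = IntegerVector::create((int)W.n_rows, Xo, Yo, Zo);
  return out;
}

// [[Rcpp::export]]
List nn_conv_bwd(const NumericVector& x, const IntegerVector& xd,
                 const arma::mat& W, const NumericVector& dy,
                 const IntegerVector& k, const IntegerVector& s,
                 const IntegerVector& p) {
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  arma::mat K;
  im2col(REAL(x), C, X, Y, Z, k[0], k[1], k[2], s[0], s[1], s[2], p[0], p[1], p[2], K);
  const arma::mat dY((double*)REAL(dy), W.n_rows, K.n_cols, false, true);
  arma::mat dW = dY * K.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dK = W.t() * dY;
  NumericVector dx((R_xlen_t)C * X * Y * Z);   // zero-initialised
  col2im(dK, REAL(dx), C, X, Y, Z, k[0], k[1], k[2], s[0], s[1], s[2], p[0], p[1], p[2]);
  dx.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Non-overlapping max pooling with per-axis factors; idx is 0-based into x.
// [[Rcpp::export]]
List nn_pool_fwd(const NumericVector& x, const IntegerVector& xd, const IntegerVector& f) {
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int Xo = X / fx, Yo = Y / fy, Zo = Z / fz;
  NumericVector y((R_xlen_t)C * Xo * Yo * Zo);
  IntegerVector idx(y.size());
  const double* px = REAL(x);
  double* py = REAL(y);
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; size_t bi = 0;
          for (int iz = 0; iz < fz; ++iz)
            for (int iy = 0; iy < fy; ++iy)
              for (int ix = 0; ix < fx; ++ix) {
                const size_t li = c + (size_t)C * ((ox * fx + ix) +
                                   (size_t)X * ((oy * fy + iy) + (size_t)Y * (oz * fz + iz)));
                if (px[li] > best) { best = px[li]; bi = li; }
              }
          const size_t lo = c + (size_t)C * (ox + (size_t)Xo * (oy + (size_t)Yo * oz));
          py[lo] = best; idx[lo] = (int)bi;
        }
  y.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_pool_bwd(const NumericVector& dy, const IntegerVector& idx,
                          const IntegerVector& xd) {
  NumericVector dx((R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3]);
  double* pdx = REAL(dx);
  const double* pdy = REAL(dy);
  for (R_xlen_t i = 0; i < dy.size(); ++i) pdx[idx[i]] += pdy[i];
  dx.attr("dim") = xd;
  return dx;
}

// [[Rcpp::export]]
NumericVector nn_upsample_fwd(const NumericVector& x, const IntegerVector& xd,
                              const IntegerVector& f) {
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int Xo = X * f[0], Yo = Y * f[1], Zo = Z * f[2];
  NumericVector y((R_xlen_t)C * Xo * Yo * Zo);
  const double* px = REAL(x); double* py = REAL(y);
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        const double* src = px + (size_t)C * ((ox / f[0]) + (size_t)X * ((oy / f[1]) + (size_t)Y * (oz / f[2])));
        double* dst = py + (size_t)C * (ox + (size_t)Xo * (oy + (size_t)Yo * oz));
        std::copy(src, src + C, dst);
      }
  y.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample_bwd(const NumericVector& dy, const IntegerVector& yd,
                              const IntegerVector& f) {
  const int C = yd[0], Xo = yd[1], Yo = yd[2], Zo = yd[3];
  const int X = Xo / f[0], Y = Yo / f[1], Z = Zo / f[2];
  NumericVector dx((R_xlen_t)C * X * Y * Z);
  const double* pdy = REAL(dy); double* pdx = REAL(dx);
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        double* dst = pdx + (size_t)C * ((ox / f[0]) + (size_t)X * ((oy / f[1]) + (size_t)Y * (oz / f[2])));
        const double* src = pdy + (size_t)C * (ox + (size_t)Xo * (oy + (size_t)Yo * oz));
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  dx.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return dx;
}

// 3D connected-component labelling, 26-connectivity, BFS.  dims = (X, Y, Z).
// [[Rcpp::export]]
IntegerVector cc_label_3d(const LogicalVector& mask, const IntegerVector& dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  IntegerVector lab((R_xlen_t)X * Y * Z);
  const int* pm = LOGICAL(mask);
  int* pl = INTEGER(lab);
  int next = 0;
  std::vector<size_t> queue;
  for (size_t start = 0; start < (size_t)X * Y * Z; ++start) {
    if (!pm[start] || pl[start]) continue;
    ++next;
    pl[start] = next;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      const size_t v = queue.back(); queue.pop_back();
      const int x = v % X, y = (v / X) % Y, z = v / ((size_t)X * Y);
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz; if (zz < 0 || zz >= Z) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy; if (yy < 0 || yy >= Y) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int xx = x + dx; if (xx < 0 || xx >= X) continue;
            const size_t w = xx + (size_t)X * (yy + (size_t)Y * zz);
            if (pm[w] && !pl[w]) { pl[w] = next; queue.push_back(w); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Classical non-local-means on one 2D slice: mean squared patch distances
// within a search window, Gaussian weighting exp(-d2/h^2); h <= 0 returns the
// input.  Implemented per displacement with an integral image over the
// squared-difference field, so the cost is O(search^2 * pixels) independent
// of the patch size.  Borders are handled by clamped (replicate) padding.
// [[Rcpp::export]]
NumericMatrix nlm_denoise_slice(const NumericMatrix& img, int patch, int search, double h) {
  const int R = img.nrow(), C = img.ncol();
  NumericMatrix out(R, C);
  if (h <= 0) { std::copy(img.begin(), img.end(), out.begin()); return out; }
  const int pr = patch / 2, sr = search / 2;
  const int m = sr + pr;                 // padding margin
  const int Rp = R + 2 * m, Cp = C + 2 * m;
  const double h2 = h * h;
  std::vector<double> pad((size_t)Rp * Cp);
  for (int c = 0; c < Cp; ++c) {
    const int cc = std::min(std::max(c - m, 0), C - 1);
    for (int r = 0; r < Rp; ++r) {
      const int rr = std::min(std::max(r - m, 0), R - 1);
      pad[r + (size_t)Rp * c] = img(rr, cc);
    }
  }
  std::vector<double> wsum((size_t)R * C, 0.0), acc((size_t)R * C, 0.0);
  std::vector<double> integ((size_t)(Rp + 1) * (Cp + 1));
  for (int dc = -sr; dc <= sr; ++dc) {
    for (int dr = -sr; dr <= sr; ++dr) {
      // integral image of squared differences for this displacement
      for (int c = 0; c < Cp; ++c) {
        double colsum = 0.0;
        const int cs = std::min(std::max(c + dc, 0), Cp - 1);
        for (int r = 0; r < Rp; ++r) {
          const int rs = std::min(std::max(r + dr, 0), Rp - 1);
          const double d = pad[r + (size_t)Rp * c] - pad[rs + (size_t)Rp * cs];
          colsum += d * d;
          integ[(r + 1) + (size_t)(Rp + 1) * (c + 1)] =
            integ[(r + 1) + (size_t)(Rp + 1) * c] + colsum;
        }
      }
      const double npx = (double)patch * patch;
      for (int c = 0; c < C; ++c) {
        const int c0 = c + m - pr, c1 = c + m + pr + 1;
        for (int r = 0; r < R; ++r) {
          const int r0 = r + m - pr, r1 = r + m + pr + 1;
          const double d2 = (integ[r1 + (size_t)(Rp + 1) * c1] -
                             integ[r0 + (size_t)(Rp + 1) * c1] -
                             integ[r1 + (size_t)(Rp + 1) * c0] +
                             integ[r0 + (size_t)(Rp + 1) * c0]) / npx;
          const double w = std::exp(-d2 / h2);
          wsum[r + (size_t)R * c] += w;
          acc[r + (size_t)R * c] += w * pad[(r + m + dr) + (size_t)Rp * (c + m + dc)];
        }
      }
    }
  }
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < R; ++r)
      out(r, c) = acc[r + (size_t)R * c] / wsum[r + (size_t)R * c];
  return out;
}
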