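// Low-level numerical kernels.
//
// Tensor convention shared with the R side: an activation is a C x N double
// matrix (channels x spatial sites) plus a spatial extent (D, H, W); the
// column index is n = z + D*y + D*H*x, i.e. z (axial) varies fastest.
// Convolutions are stride-1 "same" with per-axis dilation; padding is
// computed by the caller as dil*(k-1)/2.
//
// GEMMs run in single precision for CPU throughput; inputs/outputs stay
// double on the R side. im2col buffers are chunked over output sites to
// bound peak memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Output sites per im2col chunk: small enough that the float buffers stay
// cache/allocator friendly even when the caller holds a large live heap of
// activation caches.
static const arma::uword CHUNK = 12288;

// Fill one im2col chunk: rows r = c + C*(tz + kz*(ty + ky*tx)),
// columns are output sites n0..n0+len-1.
static void fill_col(arma::fmat& col, const double* x,
                     int C, int D, int H, int W,
                     int kz, int ky, int kx,
                     int dz, int dy, int dx,
                     int pz, int py, int px,
                     arma::uword n0, arma::uword len) {
  const int DH = D * H;
  for (arma::uword j = 0; j < len; ++j) {
    arma::uword n = n0 + j;
    int z = (int)(n % D);
    int y = (int)((n / D) % H);
    int xx = (int)(n / DH);
    float* dst = col.colptr(j);
    int r = 0;
    for (int tx = 0; tx < kx; ++tx) {
      int xs = xx + tx * dx - px;
      for (int ty = 0; ty < ky; ++ty) {
        int ys = y + ty * dy - py;
        for (int tz = 0; tz < kz; ++tz) {
          int zs = z + tz * dz - pz;
          // r runs over taps in (tz fastest, ty, tx) order times C channels
          int rr = (tz + kz * (ty + ky * tx)) * C;
          if (zs < 0 || zs >= D || ys < 0 || ys >= H || xs < 0 || xs >= W) {
            for (int c = 0; c < C; ++c) dst[rr + c] = 0.0f;
          } else {
            const double* src = x + (size_t)C * (zs + D * (ys + (size_t)H * xs));
            for (int c = 0; c < C; ++c) dst[rr + c] = (float)src[c];
          }
          (void)r;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericMatrix conv3d_fwd(NumericMatrix x, IntegerVector sdim,
                         NumericMatrix wmat, NumericVector bias,
                         IntegerVector k, IntegerVector dil,
                         IntegerVector pad) {
  const int C = x.nrow();
  const int D = sdim[0], H = sdim[1], W = sdim[2];
  const arma::uword N = (arma::uword)D * H * W;
  const int kz = k[0], ky = k[1], kx = k[2];
  const int R = C * kz * ky * kx;
  if (wmat.ncol() != R) stop("weight/kernel shape mismatch");
  const int Cout = wmat.nrow();

  arma::fmat Wf(Cout, R);
  for (int j = 0; j < R; ++j)
    for (int i = 0; i < Cout; ++i) Wf(i, j) = (float)wmat(i, j);

  NumericMatrix out(Cout, (int)N);
  arma::fmat col(R, std::min<arma::uword>(CHUNK, N));
  for (arma::uword n0 = 0; n0 < N; n0 += CHUNK) {
    arma::uword len = std::min<arma::uword>(CHUNK, N - n0);
    if (col.n_cols != len) col.set_size(R, len);
    fill_col(col, x.begin(), C, D, H, W, kz, ky, kx,
             dil[0], dil[1], dil[2], pad[0], pad[1], pad[2], n0, len);
    arma::fmat o = Wf * col; // Cout x len
    for (arma::uword j = 0; j < len; ++j) {
      double* dst = &out(0, (int)(n0 + j));
      const float* src = o.colptr(j);
      for (int i = 0; i < Cout; ++i) dst[i] = (double)src[i] + bias[i];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd_input")]]
NumericMatrix conv3d_bwd_input(NumericMatrix gout, IntegerVector sdim,
                               NumericMatrix wmat, int Cin,
                               IntegerVector k, IntegerVector dil,
                               IntegerVector pad) {
  const int D = sdim[0], H = sdim[1], W = sdim[2];
  const arma::uword N = (arma::uword)D * H * W;
  const int kz = k[0], ky = k[1], kx = k[2];
  const int R = Cin * kz * ky * kx;
  const int Cout = wmat.nrow();
  const int DH = D * H;

  arma::fmat Wf(Cout, R);
  for (int j = 0; j < R; ++j)
    for (int i = 0; i < Cout; ++i) Wf(i, j) = (float)wmat(i, j);

  NumericMatrix gx(Cin, (int)N); // zero-initialised
  arma::fmat Wt = Wf.t();        // R x Cout, hoisted out of the chunk loop
  arma::uword c0 = std::min<arma::uword>(CHUNK, N);
  arma::fmat g(Cout, c0);
  arma::fmat gcol(R, c0);
  for (arma::uword n0 = 0; n0 < N; n0 += CHUNK) {
    arma::uword len = std::min<arma::uword>(CHUNK, N - n0);
    if (g.n_cols != len) { g.set_size(Cout, len); gcol.set_size(R, len); }
    for (arma::uword j = 0; j < len; ++j) {
      const double* src = &gout(0, (int)(n0 + j));
      float* dst = g.colptr(j);
      for (int i = 0; i < Cout; ++i) dst[i] = (float)src[i];
    }
    gcol = Wt * g; // R x len
    // col2vol scatter-add
    for (arma::uword j = 0; j < len; ++j) {
      arma::uword n = n0 + j;
      int z = (int)(n % D);
      int y = (int)((n / D) % H);
      int xx = (int)(n / DH);
      const float* src = gcol.colptr(j);
      for (int tx = 0; tx < kx; ++tx) {
        int xs = xx + tx * dil[2] - pad[2];
        if (xs < 0 || xs >= W) continue;
        for (int ty = 0; ty < ky; ++ty) {
          int ys = y + ty * dil[1] - pad[1];
          if (ys < 0 || ys >= H) continue;
          for (int tz = 0; tz < kz; ++tz) {
            int zs = z + tz * dil[0] - pad[0];
            if (zs < 0 || zs >= D) continue;
            int rr = (tz + kz * (ty + ky * tx)) * Cin;
            double* dst = &gx(0, zs + D * (ys + H * xs));
            for (int c = 0; c < Cin; ++c) dst[c] += (double)src[rr + c];
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export(name = ".conv3d_bwd_weight")]]
NumericMatrix conv3d_bwd_weight(NumericMatrix x, IntegerVector sdim,
                                NumericMatrix gout,
                                IntegerVector k, IntegerVector dil,
                                IntegerVector pad) {
  const int C = x.nrow();
  const int D = sdim[0], H = sdim[1], W = sdim[2];
  const arma::uword N = (arma::uword)D * H * W;
  const int kz = k[0], ky = k[1], kx = k[2];
  const int R = C * kz * ky * kx;
  const int Cout = gout.nrow();

  arma::fmat gW(Cout, R, arma::fill::zeros);
  arma::fmat col(R, std::min<arma::uword>(CHUNK, N));
  arma::fmat g(Cout, std::min<arma::uword>(CHUNK, N));
  for (arma::uword n0 = 0; n0 < N; n0 += CHUNK) {
    arma::uword len = std::min<arma::uword>(CHUNK, N - n0);
    if (col.n_cols != len) { col.set_size(R, len); g.set_size(Cout, len); }
    fill_col(col, x.begin(), C, D, H, W, kz, ky, kx,
             dil[0], dil[1], dil[2], pad[0], pad[1], pad[2], n0, len);
    for (arma::uword j = 0; j < len; ++j) {
      const double* src = &gout(0, (int)(n0 + j));
      float* dst = g.colptr(j);
      for (int i = 0; i < Cout; ++i) dst[i] = (float)src[i];
    }
    gW += g * col.t();
  }
  NumericMatrix out(Cout, R);
  for (int j = 0; j < R; ++j)
    for (int i = 0; i < Cout; ++i) out(i, j) = (double)gW(i, j);
  return out;
}

// ---------------------------------------------------------------------------
// Anisotropic squared Euclidean distance transform (lower-envelope method),
// distance in mm to the nearest feature (TRUE) voxel.

static void dt1d(const double* f, double* d, int* v, double* zb,
                 int n, double s) {
  // f: squared distances at sample points spaced s apart
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sq = f[q] + s2 * q * q;
    while (true) {
      double num = sq - (f[v[k]] + s2 * v[k] * v[k]);
      double den = 2.0 * s2 * (q - v[k]);
      double sc = num / den;
      if (sc <= zb[k]) { --k; } else {
        ++k; v[k] = q; zb[k] = sc; zb[k + 1] = INFINITY; break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector feature, IntegerVector sdim,
                     NumericVector spacing) {
  const int D = sdim[0], H = sdim[1], W = sdim[2];
  const size_t N = (size_t)D * H * W;
  // large finite sentinel instead of INF: scan lines without any feature
  // would otherwise produce INF - INF = NaN in the envelope updates
  const double BIG = 1e30;
  NumericVector out((R_xlen_t)N);
  double* f = out.begin();
  for (size_t i = 0; i < N; ++i) f[i] = feature[i] ? 0.0 : BIG;

  int nmax = std::max(D, std::max(H, W));
  std::vector<double> buf(nmax), dbuf(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (stride 1 within each (y,x) column)
  for (int xx = 0; xx < W; ++xx)
    for (int y = 0; y < H; ++y) {
      double* p = f + (size_t)D * (y + (size_t)H * xx);
      dt1d(p, dbuf.data(), v.data(), zb.data(), D, spacing[0]);
      std::copy(dbuf.begin(), dbuf.begin() + D, p);
    }
  // pass along y (stride D)
  for (int xx = 0; xx < W; ++xx)
    for (int z = 0; z < D; ++z) {
      for (int y = 0; y < H; ++y) buf[y] = f[z + (size_t)D * (y + (size_t)H * xx)];
      dt1d(buf.data(), dbuf.data(), v.data(), zb.data(), H, spacing[1]);
      for (int y = 0; y < H; ++y) f[z + (size_t)D * (y + (size_t)H * xx)] = dbuf[y];
    }
  // pass along x (stride D*H)
  for (int y = 0; y < H; ++y)
    for (int z = 0; z < D; ++z) {
      for (int xx = 0; xx < W; ++xx) buf[xx] = f[z + (size_t)D * (y + (size_t)H * xx)];
      dt1d(buf.data(), dbuf.data(), v.data(), zb.data(), W, spacing[2]);
      for (int xx = 0; xx < W; ++xx) f[z + (size_t)D * (y + (size_t)H * xx)] = dbuf[xx];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Connected components with 26-connectivity (BFS flood fill).

// [[Rcpp::export(name = ".label_components_26")]]
IntegerVector label_components_26(LogicalVector mask, IntegerVector sdim) {
  const int D = sdim[0], H = sdim[1], W = sdim[2];
  const size_t N = (size_t)D * H * W;
  IntegerVector lab((R_xlen_t)N); // zeros
  std::vector<size_t> stack;
  int next = 0;
  for (size_t i = 0; i < N; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % D);
      int y = (int)((cur / D) % H);
      int xx = (int)(cur / ((size_t)D * H));
      for (int dx = -1; dx <= 1; ++dx) {
        int xs = xx + dx; if (xs < 0 || xs >= W) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int ys = y + dy; if (ys < 0 || ys >= H) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zs = z + dz; if (zs < 0 || zs >= D) continue;
            size_t nb = zs + (size_t)D * (ys + (size_t)H * xs);
            if (mask[nb] && lab[nb] == 0) { lab[nb] = next; stack.push_back(nb); }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
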