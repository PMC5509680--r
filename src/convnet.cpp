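// Compute kernels for the patch classifier and volume post-processing.
// Convolutions use "full" padding semantics: output edge = input edge + k - 1
// (cross-correlation; out-of-range input positions contribute zero).
#include <RcppArmadillo.h>
using namespace Rcpp;

// x: (H,W,C,B) column-major; w: (k,k,C,F); bias: length F.
// Returns y: (H+k-1, W+k-1, F, B). The im2col matrix is built for a chunk
// of samples at a time so the gemm operates on large matrices.

// Transposed im2col: Xc is (P*nb) x KC so that the innermost (oh) loop
// writes contiguously; the gemm then runs on a tall-skinny matrix and the
// output block is already in (p, f) order.
static void fill_im2col_t(const double* xp, arma::mat& Xc, int H, int W,
                          int C, int k, int Ho, int Wo, int b0, int nb) {
  const int P = Ho * Wo;
  const size_t rows = Xc.n_rows;
  Xc.zeros();
  for (int s = 0; s < nb; ++s) {
    const int b = b0 + s;
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + ((size_t)c + (size_t)C * b) * (size_t)(H * W);
      for (int kw = 0; kw < k; ++kw) {
        for (int kh = 0; kh < k; ++kh) {
          const int r = kh + k * kw + k * k * c;
          double* dst0 = Xc.memptr() + (size_t)r * rows + (size_t)s * P;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow + kw - (k - 1);
            if (iw < 0 || iw >= W) continue;
            const int oh0 = std::max(0, (k - 1) - kh);
            const int oh1 = std::min(Ho - 1, (k - 1) - kh + H - 1);
            double* dst = dst0 + (size_t)Ho * ow;
            const double* xcol = xs + H * iw + (kh - (k - 1));
            for (int oh = oh0; oh <= oh1; ++oh) dst[oh] = xcol[oh];
          }
        }
      }
    }
  }
}

static int conv_chunk(int KC, int P) {
  const double target = 4e6;  // doubles per im2col buffer (~32 MB)
  int nb = (int)(target / ((double)KC * P));
  if (nb < 1) nb = 1;
  return nb;
}

// [[Rcpp::export]]
NumericVector cpp_conv_full_forward(NumericVector x, NumericVector w,
                                    NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int k = wd[0], F = wd[3];
  const int Ho = H + k - 1, Wo = W + k - 1;
  const int KC = k * k * C, P = Ho * Wo;
  arma::mat Wm(w.begin(), KC, F, false, true);
  NumericVector out((R_xlen_t)Ho * Wo * F * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, B);
  const double* xp = x.begin();
  double* op = out.begin();
  const int chunk = conv_chunk(KC, P);
  arma::mat Xc((size_t)P * std::min(chunk, B), KC);
  for (int b0 = 0; b0 < B; b0 += chunk) {
    const int nb = std::min(chunk, B - b0);
    if ((size_t)P * nb != Xc.n_rows) Xc.set_size((size_t)P * nb, KC);
    fill_im2col_t(xp, Xc, H, W, C, k, Ho, Wo, b0, nb);
    arma::mat Y = Xc * Wm;  // (P*nb) x F
    for (int s = 0; s < nb; ++s)
      for (int f = 0; f < F; ++f) {
        double* od = op + (size_t)P * ((size_t)f + (size_t)F * (b0 + s));
        const double* yc = Y.colptr(f) + (size_t)s * P;
        const double bf = bias[f];
        for (int p = 0; p < P; ++p) od[p] = yc[p] + bf;
      }
  }
  return out;
}

// Gradients of the full convolution. dy: (Ho,Wo,F,B).
// [[Rcpp::export]]
List cpp_conv_full_backward(NumericVector x, NumericVector w,
                            NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int k = wd[0], F = wd[3];
  const int Ho = H + k - 1, Wo = W + k - 1;
  const int KC = k * k * C, P = Ho * Wo;
  arma::mat Wm(w.begin(), KC, F, false, true);
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericVector dw((R_xlen_t)k * k * C * F);
  dw.attr("dim") = IntegerVector::create(k, k, C, F);
  NumericVector db(F);
  arma::mat dWm(dw.begin(), KC, F, false, true);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const int chunk = conv_chunk(KC, P);
  const int nb0 = std::min(chunk, B);
  arma::mat Xc((size_t)P * nb0, KC);
  arma::mat dYt((size_t)P * nb0, F);
  for (int b0 = 0; b0 < B; b0 += chunk) {
    const int nb = std::min(chunk, B - b0);
    if ((size_t)P * nb != Xc.n_rows) {
      Xc.set_size((size_t)P * nb, KC);
      dYt.set_size((size_t)P * nb, F);
    }
    fill_im2col_t(xp, Xc, H, W, C, k, Ho, Wo, b0, nb);
    for (int s = 0; s < nb; ++s)
      for (int f = 0; f < F; ++f) {
        const double* dd = dyp + (size_t)P * ((size_t)f + (size_t)F * (b0 + s));
        double* yc = dYt.colptr(f) + (size_t)s * P;
        std::copy(dd, dd + P, yc);
      }
    db += NumericVector(wrap(arma::sum(dYt, 0).t()));
    dWm += Xc.t() * dYt;
    arma::mat dXt = dYt * Wm.t();  // (P*nb) x KC
    const size_t rows = dXt.n_rows;
    for (int s = 0; s < nb; ++s) {
      const int b = b0 + s;
      for (int c = 0; c < C; ++c) {
        double* ds = dxp + ((size_t)c + (size_t)C * b) * (size_t)(H * W);
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh) {
            const int r = kh + k * kw + k * k * c;
            const double* src0 = dXt.memptr() + (size_t)r * rows +
              (size_t)s * P;
            for (int ow = 0; ow < Wo; ++ow) {
              const int iw = ow + kw - (k - 1);
              if (iw < 0 || iw >= W) continue;
              const int oh0 = std::max(0, (k - 1) - kh);
              const int oh1 = std::min(Ho - 1, (k - 1) - kh + H - 1);
              const double* src = src0 + (size_t)Ho * ow;
              double* dcol = ds + H * iw + (kh - (k - 1));
              for (int oh = oh0; oh <= oh1; ++oh) dcol[oh] += src[oh];
            }
          }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2 (non-overlapping; odd trailing row/col dropped).
// Returns y (floor(H/2), floor(W/2), C, B) and the absolute argmax index
// into x (1-based, for the R-side backward pass).
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector idx(Ho * (R_xlen_t)Wo * C * B);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  R_xlen_t o = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)c + (R_xlen_t)C * b) * H * W;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          R_xlen_t best = base + 2 * oh + (R_xlen_t)H * (2 * ow);
          double bv = xp[best];
          const int dh[3] = {1, 0, 1}, dw_[3] = {0, 1, 1};
          for (int q = 0; q < 3; ++q) {
            R_xlen_t cand = base + (2 * oh + dh[q]) + (R_xlen_t)H * (2 * ow + dw_[q]);
            if (xp[cand] > bv) { bv = xp[cand]; best = cand; }
          }
          yp[o] = bv;
          ip[o] = (int)(best + 1);
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Extract in-plane M x M multiparametric patches around voxel coords.
// vol: (nx,ny,nz,C); coords: n x 3 (1-based voxel indices); out-of-bound
// positions are zero-filled. Returns (M,M,C,n).
// [[Rcpp::export]]
NumericVector cpp_extract_patches(NumericVector vol, IntegerMatrix coords,
                                  int M) {
  IntegerVector vd = vol.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2], C = vd[3];
  const int n = coords.nrow(), h = (M - 1) / 2;
  NumericVector out((R_xlen_t)M * M * C * n);
  out.attr("dim") = IntegerVector::create(M, M, C, n);
  const double* vp = vol.begin();
  double* op = out.begin();
  for (int i = 0; i < n; ++i) {
    const int x0 = coords(i, 0) - 1, y0 = coords(i, 1) - 1,
              z0 = coords(i, 2) - 1;
    for (int c = 0; c < C; ++c) {
      const double* vs =
          vp + ((R_xlen_t)z0 + (R_xlen_t)nz * c) * nx * ny;
      double* os = op + ((R_xlen_t)c + (R_xlen_t)C * i) * M * M;
      for (int py = 0; py < M; ++py) {
        const int y = y0 + py - h;
        if (y < 0 || y >= ny) continue;
        for (int px = 0; px < M; ++px) {
          const int x = x0 + px - h;
          if (x < 0 || x >= nx) continue;
          os[px + M * py] = vs[x + nx * y];
        }
      }
    }
  }
  return out;
}

// Trilinear interpolation of vol (nx,ny,nz) at continuous 1-based voxel
// coordinates pts (n x 3); coordinates are clamped to the volume edge.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, NumericMatrix pts) {
  IntegerVector vd = vol.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double* vp = vol.begin();
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0) - 1.0, y = pts(i, 1) - 1.0, z = pts(i, 2) - 1.0;
    x = std::min(std::max(x, 0.0), (double)(nx - 1));
    y = std::min(std::max(y, 0.0), (double)(ny - 1));
    z = std::min(std::max(z, 0.0), (double)(nz - 1));
    const int x0 = std::min((int)x, nx - 2 >= 0 ? nx - 2 : 0);
    const int y0 = std::min((int)y, ny - 2 >= 0 ? ny - 2 : 0);
    const int z0 = std::min((int)z, nz - 2 >= 0 ? nz - 2 : 0);
    const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    #define V(ix, iy, iz) vp[(ix) + (R_xlen_t)nx * ((iy) + (R_xlen_t)ny * (iz))]
    const double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
    const double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
    const double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
    const double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
    #undef V
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Label connected components of a 3D binary mask (6 or 26 connectivity).
// Labels are assigned in increasing order of the component's smallest
// linear (column-major) voxel index, starting at 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, int connectivity) {
  IntegerVector md = mask.attr("dim");
  const int nx = md[0], ny = md[1], nz = md[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(nvox);
  lab.attr("dim") = md;
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
          continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int x = (int)(v % nx), y = (int)((v / nx) % ny),
                z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t q = 0; q < offs.size(); ++q) {
        const int xx = x + offs[q][0], yy = y + offs[q][1], zz = z + offs[q][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[u] && !lab[u]) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  return lab;
}
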