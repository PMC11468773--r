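// Numerical kernels: separable Gaussian smoothing, greedy 3D NMS,
// window local-maxima extraction, and the convolution forward/backward
// primitives used by the exploration and detector networks.
//
// Tensor layout (column-major, matching R arrays):
//   2D feature maps: (W, H, C)
//   3D feature maps: (W, H, D, C)
//   conv2d weights:  (k, k, Cin, Cout)
//   conv3d weights:  (3, 3, 3, Cin, Cout)
// All convolutions are stride 1, zero-padded "same".

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect-101 style without repeating the edge twice for n > 1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth3d(NumericVector vol, double sigma) {
  IntegerVector d = vol.attr("dim");
  int W = d[0], H = d[1], D = d[2];
  NumericVector out = clone(vol);
  if (sigma <= 0) return out;
  int h = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * h + 1);
  double s = 0;
  for (int i = -h; i <= h; i++) {
    ker[i + h] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + h];
  }
  for (auto &k : ker) k /= s;
  NumericVector tmp(W * H * D);
  // along x
  for (int z = 0; z < D; z++)
    for (int y = 0; y < H; y++) {
      size_t base = (size_t)W * (y + (size_t)H * z);
      for (int x = 0; x < W; x++) {
        double acc = 0;
        for (int i = -h; i <= h; i++)
          acc += ker[i + h] * out[base + reflect_idx(x + i, W)];
        tmp[base + x] = acc;
      }
    }
  // along y
  for (int z = 0; z < D; z++)
    for (int x = 0; x < W; x++) {
      size_t base = (size_t)W * (size_t)H * z + x;
      for (int y = 0; y < H; y++) {
        double acc = 0;
        for (int i = -h; i <= h; i++)
          acc += ker[i + h] * tmp[base + (size_t)W * reflect_idx(y + i, H)];
        out[base + (size_t)W * y] = acc;
      }
    }
  // along z
  for (int y = 0; y < H; y++)
    for (int x = 0; x < W; x++) {
      size_t base = x + (size_t)W * y;
      for (int z = 0; z < D; z++) {
        double acc = 0;
        for (int i = -h; i <= h; i++)
          acc += ker[i + h] * out[base + (size_t)W * H * reflect_idx(z + i, D)];
        tmp[base + (size_t)W * H * z] = acc;
      }
    }
  tmp.attr("dim") = d;
  return tmp;
}

// Greedy 3D non-maximum suppression. Candidates above `threshold` are visited
// by decreasing response (ties: lexicographically smallest (x,y,z) first); a
// candidate is kept iff its Euclidean distance to every kept point exceeds
// `radius`. Returns a (n x 4) matrix of 0-based x,y,z and the response.
// [[Rcpp::export]]
NumericMatrix cpp_nms3d(NumericVector resp, double radius, double threshold,
                        int max_candidates) {
  IntegerVector d = resp.attr("dim");
  int W = d[0], H = d[1], D = d[2];
  struct Cand { double v; int x, y, z; };
  std::vector<Cand> cands;
  for (int z = 0; z < D; z++)
    for (int y = 0; y < H; y++)
      for (int x = 0; x < W; x++) {
        double v = resp[x + (size_t)W * (y + (size_t)H * z)];
        if (v > threshold) cands.push_back({v, x, y, z});
      }
  std::stable_sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
    if (a.v != b.v) return a.v > b.v;
    if (a.x != b.x) return a.x < b.x;
    if (a.y != b.y) return a.y < b.y;
    return a.z < b.z;
  });
  double r2 = radius * radius;
  std::vector<Cand> kept;
  for (const auto &c : cands) {
    if ((int)kept.size() >= max_candidates) break;
    bool ok = true;
    for (const auto &k : kept) {
      double dx = c.x - k.x, dy = c.y - k.y, dz = c.z - k.z;
      if (dx * dx + dy * dy + dz * dz <= r2) { ok = false; break; }
    }
    if (ok) kept.push_back(c);
  }
  NumericMatrix out(kept.size(), 4);
  for (size_t i = 0; i < kept.size(); i++) {
    out(i, 0) = kept[i].x; out(i, 1) = kept[i].y;
    out(i, 2) = kept[i].z; out(i, 3) = kept[i].v;
  }
  return out;
}

// Keep voxel v iff it exceeds `threshold` and within the centered cubic
// window of side `kernel` every other voxel u satisfies heat[u] < heat[v],
// or heat[u] == heat[v] with v lexicographically smaller than u.
// [[Rcpp::export]]
NumericMatrix cpp_local_max3d(NumericVector heat, int kernel, double threshold) {
  IntegerVector d = heat.attr("dim");
  int W = d[0], H = d[1], D = d[2];
  int h = kernel / 2;
  std::vector<std::array<double, 4>> kept;
  for (int z = 0; z < D; z++)
    for (int y = 0; y < H; y++)
      for (int x = 0; x < W; x++) {
        double v = heat[x + (size_t)W * (y + (size_t)H * z)];
        if (v <= threshold) continue;
        bool keep = true;
        for (int dz = -h; dz <= h && keep; dz++)
          for (int dy = -h; dy <= h && keep; dy++)
            for (int dx = -h; dx <= h && keep; dx++) {
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= W || yy >= H || zz >= D)
                continue;
              if (dx == 0 && dy == 0 && dz == 0) continue;
              double u = heat[xx + (size_t)W * (yy + (size_t)H * zz)];
              if (u > v) keep = false;
              else if (u == v) {
                // lexicographic tie-break on (x,y,z)
                bool v_smaller = (x < xx) || (x == xx && (y < yy || (y == yy && z < zz)));
                if (!v_smaller) keep = false;
              }
            }
        if (keep) kept.push_back({(double)x, (double)y, (double)z, v});
      }
  NumericMatrix out(kept.size(), 4);
  for (size_t i = 0; i < kept.size(); i++)
    for (int j = 0; j < 4; j++) out(i, j) = kept[i][j];
  return out;
}

// ---------------------------------------------------------------------------
// conv2d, stride 1, zero-padded same: shift-slab accumulation (the channel
// counts here are small, so slab loops beat im2col/GEMM on allocation cost)

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  int W = dx[0], H = dx[1], Cin = dx[2];
  int k = dw[0], Cout = dw[3], c = (k - 1) / 2;
  NumericVector y((size_t)W * H * Cout);
  for (int co = 0; co < Cout; co++) {
    double *yp = &y[(size_t)W * H * co];
    double bv = b[co];
    for (size_t p = 0; p < (size_t)W * H; p++) yp[p] = bv;
    for (int ci = 0; ci < Cin; ci++) {
      const double *xp = &x[(size_t)W * H * ci];
      for (int j = 0; j < k; j++) {
        int dyy = j - c;
        int ylo = std::max(0, -dyy), yhi = std::min(H, H - dyy);
        for (int i = 0; i < k; i++) {
          int dxx = i - c;
          double wv = w[i + (size_t)k * (j + (size_t)k * (ci + (size_t)Cin * co))];
          if (wv == 0) continue;
          int xlo = std::max(0, -dxx), xhi = std::min(W, W - dxx);
          for (int yy = ylo; yy < yhi; yy++) {
            double *yrow = yp + (size_t)W * yy;
            const double *xrow = xp + (size_t)W * (yy + dyy) + dxx;
            for (int xx = xlo; xx < xhi; xx++) yrow[xx] += wv * xrow[xx];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(W, H, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  int W = dx[0], H = dx[1], Cin = dx[2];
  int k = dw[0], Cout = dw[3], c = (k - 1) / 2;
  NumericVector gx((size_t)W * H * Cin), gw(dw[0] * (size_t)dw[1] * Cin * Cout),
      gb(Cout);
  for (int co = 0; co < Cout; co++) {
    const double *gp = &gy[(size_t)W * H * co];
    double acc = 0;
    for (size_t p = 0; p < (size_t)W * H; p++) acc += gp[p];
    gb[co] = acc;
    for (int ci = 0; ci < Cin; ci++) {
      const double *xp = &x[(size_t)W * H * ci];
      double *gxp = &gx[(size_t)W * H * ci];
      for (int j = 0; j < k; j++) {
        int dyy = j - c;
        int ylo = std::max(0, -dyy), yhi = std::min(H, H - dyy);
        for (int i = 0; i < k; i++) {
          int dxx = i - c;
          int xlo = std::max(0, -dxx), xhi = std::min(W, W - dxx);
          double wv = w[i + (size_t)k * (j + (size_t)k * (ci + (size_t)Cin * co))];
          double gwv = 0;
          for (int yy = ylo; yy < yhi; yy++) {
            const double *grow = gp + (size_t)W * yy;
            const double *xrow = xp + (size_t)W * (yy + dyy) + dxx;
            double *gxrow = gxp + (size_t)W * (yy + dyy) + dxx;
            for (int xx = xlo; xx < xhi; xx++) {
              gwv += grow[xx] * xrow[xx];
              gxrow[xx] += wv * grow[xx];
            }
          }
          gw[i + (size_t)k * (j + (size_t)k * (ci + (size_t)Cin * co))] = gwv;
        }
      }
    }
  }
  gw.attr("dim") = dw;
  gx.attr("dim") = dx;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  int W = dx[0], H = dx[1], C = dx[2];
  int Wo = W / 2, Ho = H / 2;
  NumericVector y((size_t)Wo * Ho * C);
  IntegerVector idx((size_t)Wo * Ho * C);
  for (int c = 0; c < C; c++)
    for (int j = 0; j < Ho; j++)
      for (int i = 0; i < Wo; i++) {
        double best = -std::numeric_limits<double>::infinity();
        size_t bi = 0;
        for (int dj = 0; dj < 2; dj++)
          for (int di = 0; di < 2; di++) {
            size_t p = (2 * i + di) + (size_t)W * ((2 * j + dj) + (size_t)H * c);
            if (x[p] > best) { best = x[p]; bi = p; }
          }
        size_t q = i + (size_t)Wo * (j + (size_t)Ho * c);
        y[q] = best;
        idx[q] = (int)bi;
      }
  y.attr("dim") = IntegerVector::create(Wo, Ho, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(IntegerVector idx, NumericVector gy,
                              IntegerVector dims_in) {
  NumericVector gx((size_t)dims_in[0] * dims_in[1] * dims_in[2]);
  for (R_xlen_t q = 0; q < gy.size(); q++) gx[idx[q]] += gy[q];
  gx.attr("dim") = dims_in;
  return gx;
}

// transpose convolution, kernel 2x2, stride 2 (doubles spatial size)
// weights: (2, 2, Cin, Cout)
// [[Rcpp::export]]
NumericVector cpp_tconv2_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  int W = dx[0], H = dx[1], Cin = dx[2], Cout = dw[3];
  int Wo = 2 * W, Ho = 2 * H;
  NumericVector y((size_t)Wo * Ho * Cout);
  for (int co = 0; co < Cout; co++)
    for (size_t p = 0; p < (size_t)Wo * Ho; p++) y[p + (size_t)Wo * Ho * co] = b[co];
  for (int co = 0; co < Cout; co++)
    for (int ci = 0; ci < Cin; ci++)
      for (int dj = 0; dj < 2; dj++)
        for (int di = 0; di < 2; di++) {
          double wv = w[di + 2 * (dj + 2 * (ci + (size_t)Cin * co))];
          for (int j = 0; j < H; j++)
            for (int i = 0; i < W; i++)
              y[(2 * i + di) + (size_t)Wo * ((2 * j + dj) + (size_t)Ho * co)] +=
                  wv * x[i + (size_t)W * (j + (size_t)H * ci)];
        }
  y.attr("dim") = IntegerVector::create(Wo, Ho, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_tconv2_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  int W = dx[0], H = dx[1], Cin = dx[2], Cout = dw[3];
  int Wo = 2 * W, Ho = 2 * H;
  NumericVector gx((size_t)W * H * Cin), gw(dw[0] * dw[1] * (size_t)Cin * Cout),
      gb(Cout);
  for (int co = 0; co < Cout; co++)
    for (size_t p = 0; p < (size_t)Wo * Ho; p++) gb[co] += gy[p + (size_t)Wo * Ho * co];
  for (int co = 0; co < Cout; co++)
    for (int ci = 0; ci < Cin; ci++)
      for (int dj = 0; dj < 2; dj++)
        for (int di = 0; di < 2; di++) {
          double wv = w[di + 2 * (dj + 2 * (ci + (size_t)Cin * co))];
          double acc = 0;
          for (int j = 0; j < H; j++)
            for (int i = 0; i < W; i++) {
              double g = gy[(2 * i + di) + (size_t)Wo * ((2 * j + dj) + (size_t)Ho * co)];
              gx[i + (size_t)W * (j + (size_t)H * ci)] += wv * g;
              acc += g * x[i + (size_t)W * (j + (size_t)H * ci)];
            }
          gw[di + 2 * (dj + 2 * (ci + (size_t)Cin * co))] = acc;
        }
  gx.attr("dim") = dx;
  gw.attr("dim") = dw;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// conv3d, kernel 3x3x3, zero-padded same: shift-slab accumulation

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int chunk = 8) {
  (void)chunk;
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  int W = dx[0], H = dx[1], D = dx[2], Cin = dx[3], Cout = dw[4];
  size_t WH = (size_t)W * H, WHD = WH * D;
  NumericVector y(WHD * Cout);
  for (int co = 0; co < Cout; co++) {
    double *yp = &y[WHD * co];
    double bv = b[co];
    for (size_t p = 0; p < WHD; p++) yp[p] = bv;
    for (int ci = 0; ci < Cin; ci++) {
      const double *xp = &x[WHD * ci];
      for (int l = 0; l < 3; l++) {
        int dzz = l - 1;
        int zlo = std::max(0, -dzz), zhi = std::min(D, D - dzz);
        for (int j = 0; j < 3; j++) {
          int dyy = j - 1;
          int ylo = std::max(0, -dyy), yhi = std::min(H, H - dyy);
          for (int i = 0; i < 3; i++) {
            int dxx = i - 1;
            int xlo = std::max(0, -dxx), xhi = std::min(W, W - dxx);
            double wv = w[i + 3 * (j + 3 * (l + 3 * (ci + (size_t)Cin * co)))];
            for (int zz = zlo; zz < zhi; zz++)
              for (int yy = ylo; yy < yhi; yy++) {
                double *yrow = yp + WH * zz + (size_t)W * yy;
                const double *xrow =
                    xp + WH * (zz + dzz) + (size_t)W * (yy + dyy) + dxx;
                for (int xx = xlo; xx < xhi; xx++) yrow[xx] += wv * xrow[xx];
              }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(W, H, D, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int chunk = 8) {
  (void)chunk;
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  int W = dx[0], H = dx[1], D = dx[2], Cin = dx[3], Cout = dw[4];
  size_t WH = (size_t)W * H, WHD = WH * D;
  NumericVector gx(WHD * Cin), gw((size_t)27 * Cin * Cout), gb(Cout);
  for (int co = 0; co < Cout; co++) {
    const double *gp = &gy[WHD * co];
    double acc = 0;
    for (size_t p = 0; p < WHD; p++) acc += gp[p];
    gb[co] = acc;
    for (int ci = 0; ci < Cin; ci++) {
      const double *xp = &x[WHD * ci];
      double *gxp = &gx[WHD * ci];
      for (int l = 0; l < 3; l++) {
        int dzz = l - 1;
        int zlo = std::max(0, -dzz), zhi = std::min(D, D - dzz);
        for (int j = 0; j < 3; j++) {
          int dyy = j - 1;
          int ylo = std::max(0, -dyy), yhi = std::min(H, H - dyy);
          for (int i = 0; i < 3; i++) {
            int dxx = i - 1;
            int xlo = std::max(0, -dxx), xhi = std::min(W, W - dxx);
            double wv = w[i + 3 * (j + 3 * (l + 3 * (ci + (size_t)Cin * co)))];
            double gwv = 0;
            for (int zz = zlo; zz < zhi; zz++)
              for (int yy = ylo; yy < yhi; yy++) {
                const double *grow = gp + WH * zz + (size_t)W * yy;
                const double *xrow =
                    xp + WH * (zz + dzz) + (size_t)W * (yy + dyy) + dxx;
                double *gxrow =
                    gxp + WH * (zz + dzz) + (size_t)W * (yy + dyy) + dxx;
                for (int xx = xlo; xx < xhi; xx++) {
                  gwv += grow[xx] * xrow[xx];
                  gxrow[xx] += wv * grow[xx];
                }
              }
            gw[i + 3 * (j + 3 * (l + 3 * (ci + (size_t)Cin * co)))] = gwv;
          }
        }
      }
    }
  }
  gw.attr("dim") = dw;
  gx.attr("dim") = dx;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
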