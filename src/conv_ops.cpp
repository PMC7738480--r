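// Low-level tensor kernels for the segmentation network and metrics.
//
// Feature maps are stored channel-major: an (C x N) matrix whose columns are
// voxels/pixels in R array order, i.e. column index = i + H*(j + W*(d + D*n))
// for row i, column j, slice d, batch item n. Convolutions are computed as
// im2col followed by a single GEMM; the col2im adjoint implements both the
// data gradient of a convolution and the forward pass of a strided
// transposed convolution.

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// im2col / col2im (2D kernels operate with kz = 1, sz = 1, pz = 0)
// ---------------------------------------------------------------------------

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::mat& X, int H, int W, int D, int B,
                     int k, int kz, int s, int sz, int p, int pz) {
  const int C = X.n_rows;
  const int Ho = out_size(H, k, s, p);
  const int Wo = out_size(W, k, s, p);
  const int Do = out_size(D, kz, sz, pz);
  const int K = k * k * kz;
  arma::mat out(C * K, (arma::uword)Ho * Wo * Do * B, arma::fill::zeros);

  const double* xp = X.memptr();
  double* op = out.memptr();
  const arma::uword ldx = C;
  const arma::uword ldo = (arma::uword)C * K;

  for (int n = 0; n < B; ++n) {
    const arma::uword xoff = (arma::uword)n * H * W * D;
    const arma::uword ooff = (arma::uword)n * Ho * Wo * Do;
    for (int od = 0; od < Do; ++od) {
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          const arma::uword ocol = ooff + oi + (arma::uword)Ho * (oj + (arma::uword)Wo * od);
          double* dst0 = op + ocol * ldo;
          for (int kd = 0; kd < kz; ++kd) {
            const int si_d = od * sz + kd - pz;
            for (int kj = 0; kj < k; ++kj) {
              const int si_j = oj * s + kj - p;
              for (int ki = 0; ki < k; ++ki) {
                const int si_i = oi * s + ki - p;
                const int kk = ki + k * (kj + k * kd);
                if (si_i >= 0 && si_i < H && si_j >= 0 && si_j < W &&
                    si_d >= 0 && si_d < D) {
                  const arma::uword xcol = xoff + si_i +
                    (arma::uword)H * (si_j + (arma::uword)W * si_d);
                  std::memcpy(dst0 + (arma::uword)kk * C, xp + xcol * ldx,
                              C * sizeof(double));
                }
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add column blocks back onto the image grid.
// [[Rcpp::export]]
arma::mat cpp_col2im(const arma::mat& cols, int C, int H, int W, int D, int B,
                     int k, int kz, int s, int sz, int p, int pz) {
  const int Ho = out_size(H, k, s, p);
  const int Wo = out_size(W, k, s, p);
  const int Do = out_size(D, kz, sz, pz);
  const int K = k * k * kz;
  arma::mat X(C, (arma::uword)H * W * D * B, arma::fill::zeros);

  const double* cp = cols.memptr();
  double* xp = X.memptr();
  const arma::uword ldc = (arma::uword)C * K;

  for (int n = 0; n < B; ++n) {
    const arma::uword xoff = (arma::uword)n * H * W * D;
    const arma::uword ooff = (arma::uword)n * Ho * Wo * Do;
    for (int od = 0; od < Do; ++od) {
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          const arma::uword ocol = ooff + oi + (arma::uword)Ho * (oj + (arma::uword)Wo * od);
          const double* src0 = cp + ocol * ldc;
          for (int kd = 0; kd < kz; ++kd) {
            const int si_d = od * sz + kd - pz;
            for (int kj = 0; kj < k; ++kj) {
              const int si_j = oj * s + kj - p;
              for (int ki = 0; ki < k; ++ki) {
                const int si_i = oi * s + ki - p;
                const int kk = ki + k * (kj + k * kd);
                if (si_i >= 0 && si_i < H && si_j >= 0 && si_j < W &&
                    si_d >= 0 && si_d < D) {
                  const arma::uword xcol = xoff + si_i +
                    (arma::uword)H * (si_j + (arma::uword)W * si_d);
                  double* dst = xp + xcol * C;
                  const double* src = src0 + (arma::uword)kk * C;
                  for (int c = 0; c < C; ++c) dst[c] += src[c];
                }
              }
            }
          }
        }
      }
    }
  }
  return X;
}

// ---------------------------------------------------------------------------
// Max pooling, kernel 2 stride 2 (pool_z = false leaves the third axis alone,
// which is how batches of 2D slices are pooled)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool(const arma::mat& X, int H, int W, int D, int B, bool pool_z) {
  const int C = X.n_rows;
  const int Ho = H / 2, Wo = W / 2;
  const int Do = pool_z ? D / 2 : D;
  const int kd_n = pool_z ? 2 : 1;
  arma::mat Y(C, (arma::uword)Ho * Wo * Do * B);
  arma::umat idx(C, Y.n_cols);

  for (int n = 0; n < B; ++n) {
    const arma::uword xoff = (arma::uword)n * H * W * D;
    const arma::uword ooff = (arma::uword)n * Ho * Wo * Do;
    for (int od = 0; od < Do; ++od) {
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          const arma::uword ocol = ooff + oi + (arma::uword)Ho * (oj + (arma::uword)Wo * od);
          bool first = true;
          for (int kd = 0; kd < kd_n; ++kd) {
            const int sd = pool_z ? 2 * od + kd : od;
            for (int kj = 0; kj < 2; ++kj) {
              for (int ki = 0; ki < 2; ++ki) {
                const arma::uword xcol = xoff + (2 * oi + ki) +
                  (arma::uword)H * ((2 * oj + kj) + (arma::uword)W * sd);
                if (first) {
                  Y.col(ocol) = X.col(xcol);
                  idx.col(ocol).fill(xcol);
                  first = false;
                } else {
                  for (int c = 0; c < C; ++c) {
                    const double v = X(c, xcol);
                    if (v > Y(c, ocol)) { Y(c, ocol) = v; idx(c, ocol) = xcol; }
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::mat& dY, const arma::umat& idx,
                          int ncol_in) {
  const int C = dY.n_rows;
  arma::mat dX(C, ncol_in, arma::fill::zeros);
  for (arma::uword j = 0; j < dY.n_cols; ++j)
    for (int c = 0; c < C; ++c)
      dX(c, idx(c, j)) += dY(c, j);
  return dX;
}

// ---------------------------------------------------------------------------
// Grayscale erosion by a flat disk, per 2D slice, replicate border padding.
// Returns the eroded map and the argmin source column for the backward pass.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_erode_disk(const arma::mat& X, int H, int W, int B, int radius) {
  const int C = X.n_rows;
  std::vector<int> off_i, off_j;
  for (int dj = -radius; dj <= radius; ++dj)
    for (int di = -radius; di <= radius; ++di)
      if (di * di + dj * dj <= radius * radius) {
        off_i.push_back(di); off_j.push_back(dj);
      }
  const int K = (int)off_i.size();

  arma::mat Y(C, X.n_cols);
  arma::umat idx(C, X.n_cols);
  for (int n = 0; n < B; ++n) {
    const arma::uword off = (arma::uword)n * H * W;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const arma::uword ocol = off + i + (arma::uword)H * j;
        bool first = true;
        for (int t = 0; t < K; ++t) {
          int si = i + off_i[t], sj = j + off_j[t];
          if (si < 0) si = 0; else if (si >= H) si = H - 1;  // replicate pad
          if (sj < 0) sj = 0; else if (sj >= W) sj = W - 1;
          const arma::uword xcol = off + si + (arma::uword)H * sj;
          if (first) {
            Y.col(ocol) = X.col(xcol);
            idx.col(ocol).fill(xcol);
            first = false;
          } else {
            for (int c = 0; c < C; ++c) {
              const double v = X(c, xcol);
              if (v < Y(c, ocol)) { Y(c, ocol) = v; idx(c, ocol) = xcol; }
            }
          }
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// ---------------------------------------------------------------------------
// Exact 3D squared Euclidean distance transform (lower-envelope algorithm).
// Returns, for every voxel, the squared distance (in voxel units) to the
// nearest TRUE voxel of `site`.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int kk = 0;
  v[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INFINITY) continue;
    if (f[v[0]] == INFINITY && kk == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) / (2.0 * q - 2.0 * v[kk]);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INFINITY;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INFINITY) { d[q] = INFINITY; continue; }
    while (z[j + 1] < q) ++j;
    d[q] = (double)(q - v[j]) * (q - v[j]) + f[v[j]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector site, IntegerVector dims) {
  const int H = dims[0], W = dims[1], D = dims.size() > 2 ? dims[2] : 1;
  const size_t N = (size_t)H * W * D;
  std::vector<double> g(N);
  for (size_t t = 0; t < N; ++t) g[t] = site[t] ? 0.0 : INFINITY;

  const int nmax = std::max(H, std::max(W, D));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along rows (i)
  for (int dd = 0; dd < D; ++dd)
    for (int j = 0; j < W; ++j) {
      const size_t base = (size_t)H * (j + (size_t)W * dd);
      for (int i = 0; i < H; ++i) f[i] = g[base + i];
      dt1d(f, d, H, v, z);
      for (int i = 0; i < H; ++i) g[base + i] = d[i];
    }
  // pass along columns (j)
  for (int dd = 0; dd < D; ++dd)
    for (int i = 0; i < H; ++i) {
      const size_t base = (size_t)i + (size_t)H * W * dd;
      for (int j = 0; j < W; ++j) f[j] = g[base + (size_t)H * j];
      dt1d(f, d, W, v, z);
      for (int j = 0; j < W; ++j) g[base + (size_t)H * j] = d[j];
    }
  // pass along slices (d)
  if (D > 1)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const size_t base = (size_t)i + (size_t)H * j;
        for (int dd = 0; dd < D; ++dd) f[dd] = g[base + (size_t)H * W * dd];
        dt1d(f, d, D, v, z);
        for (int dd = 0; dd < D; ++dd) g[base + (size_t)H * W * dd] = d[dd];
      }

  NumericVector out(N);
  for (size_t t = 0; t < N; ++t) out[t] = g[t];
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on the Kuhn 6-tetrahedra cube decomposition.
// Produces a watertight triangulation of the `field == level` isosurface;
// vertices are deduplicated by the lattice edge they sit on. Vertex
// coordinates are 0-based voxel indices (callers scale to mm).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims, double level) {
  const int H = dims[0], W = dims[1], D = dims[2];
  auto val = [&](int i, int j, int d) -> double {
    return field[(size_t)i + (size_t)H * (j + (size_t)W * d)];
  };
  auto gid = [&](int i, int j, int d) -> uint64_t {
    return (uint64_t)i + (uint64_t)H * (j + (uint64_t)W * d);
  };

  // Kuhn decomposition: 6 tetrahedra per cube, all sharing the 0-7 diagonal.
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
  };

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  int ci[8], cj[8], cd[8];
  double cf[8];
  uint64_t cg[8];

  auto edge_point = [&](int a, int b) -> int {
    uint64_t ka = cg[a], kb = cg[b];
    if (ka > kb) std::swap(ka, kb);
    const uint64_t key = ka * (uint64_t)1e10 + kb;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    const double t = (level - cf[a]) / (cf[b] - cf[a]);
    vx.push_back(ci[a] + t * (ci[b] - ci[a]));
    vy.push_back(cj[a] + t * (cj[b] - cj[a]));
    vz.push_back(cd[a] + t * (cd[b] - cd[a]));
    const int id = (int)vx.size() - 1;
    edge_vertex[key] = id;
    return id;
  };

  for (int d = 0; d + 1 < D; ++d) {
    for (int j = 0; j + 1 < W; ++j) {
      for (int i = 0; i + 1 < H; ++i) {
        for (int c = 0; c < 8; ++c) {
          ci[c] = i + (c & 1); cj[c] = j + ((c >> 1) & 1); cd[c] = d + ((c >> 2) & 1);
          cf[c] = val(ci[c], cj[c], cd[c]);
          cg[c] = gid(ci[c], cj[c], cd[c]);
        }
        for (int t = 0; t < 6; ++t) {
          const int* tv = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cf[tv[c]] > level) in[nin++] = tv[c]; else out[nout++] = tv[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            const int p0 = edge_point(in[0], out[0]);
            const int p1 = edge_point(in[0], out[1]);
            const int p2 = edge_point(in[0], out[2]);
            tri.push_back(p0); tri.push_back(p1); tri.push_back(p2);
          } else if (nin == 3) {
            const int p0 = edge_point(out[0], in[0]);
            const int p1 = edge_point(out[0], in[1]);
            const int p2 = edge_point(out[0], in[2]);
            tri.push_back(p0); tri.push_back(p1); tri.push_back(p2);
          } else {  // nin == 2: quad split into two triangles
            const int p00 = edge_point(in[0], out[0]);
            const int p01 = edge_point(in[0], out[1]);
            const int p10 = edge_point(in[1], out[0]);
            const int p11 = edge_point(in[1], out[1]);
            tri.push_back(p00); tri.push_back(p01); tri.push_back(p10);
            tri.push_back(p10); tri.push_back(p01); tri.push_back(p11);
          }
        }
      }
    }
  }

  const int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int t = 0; t < nv; ++t) { V(t, 0) = vx[t]; V(t, 1) = vy[t]; V(t, 2) = vz[t]; }
  const int nf = (int)tri.size() / 3;
  IntegerMatrix F(nf, 3);
  for (int t = 0; t < nf; ++t) {
    F(t, 0) = tri[3 * t] + 1; F(t, 1) = tri[3 * t + 1] + 1; F(t, 2) = tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Consolidated layer kernels: convolution, transposed convolution, ELU and
// batch-norm forward/backward as single C++ calls (keeps the large im2col
// buffers out of R).
// ---------------------------------------------------------------------------

static void im2col_into(arma::mat& cols, const arma::mat& X, int H, int W,
                        int D, int B, int k, int kz, int s, int sz,
                        int p, int pz) {
  const int C = X.n_rows;
  const int Ho = out_size(H, k, s, p);
  const int Wo = out_size(W, k, s, p);
  const int Do = out_size(D, kz, sz, pz);
  const int K = k * k * kz;
  cols.zeros(C * K, (arma::uword)Ho * Wo * Do * B);
  const double* xp = X.memptr();
  double* op = cols.memptr();
  const arma::uword ldo = (arma::uword)C * K;
  for (int n = 0; n < B; ++n) {
    const arma::uword xoff = (arma::uword)n * H * W * D;
    const arma::uword ooff = (arma::uword)n * Ho * Wo * Do;
    for (int od = 0; od < Do; ++od) {
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          const arma::uword ocol = ooff + oi + (arma::uword)Ho * (oj + (arma::uword)Wo * od);
          double* dst0 = op + ocol * ldo;
          for (int kd = 0; kd < kz; ++kd) {
            const int si_d = od * sz + kd - pz;
            if (si_d < 0 || si_d >= D) continue;
            for (int kj = 0; kj < k; ++kj) {
              const int si_j = oj * s + kj - p;
              if (si_j < 0 || si_j >= W) continue;
              for (int ki = 0; ki < k; ++ki) {
                const int si_i = oi * s + ki - p;
                if (si_i < 0 || si_i >= H) continue;
                const int kk = ki + k * (kj + k * kd);
                const arma::uword xcol = xoff + si_i +
                  (arma::uword)H * (si_j + (arma::uword)W * si_d);
                std::memcpy(dst0 + (arma::uword)kk * C, xp + xcol * C,
                            C * sizeof(double));
              }
            }
          }
        }
      }
    }
  }
}

static void col2im_into(arma::mat& X, const arma::mat& cols, int C, int H,
                        int W, int D, int B, int k, int kz, int s, int sz,
                        int p, int pz) {
  const int Ho = out_size(H, k, s, p);
  const int Wo = out_size(W, k, s, p);
  const int Do = out_size(D, kz, sz, pz);
  const int K = k * k * kz;
  X.zeros(C, (arma::uword)H * W * D * B);
  const double* cp = cols.memptr();
  double* xp = X.memptr();
  const arma::uword ldc = (arma::uword)C * K;
  for (int n = 0; n < B; ++n) {
    const arma::uword xoff = (arma::uword)n * H * W * D;
    const arma::uword ooff = (arma::uword)n * Ho * Wo * Do;
    for (int od = 0; od < Do; ++od) {
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          const arma::uword ocol = ooff + oi + (arma::uword)Ho * (oj + (arma::uword)Wo * od);
          const double* src0 = cp + ocol * ldc;
          for (int kd = 0; kd < kz; ++kd) {
            const int si_d = od * sz + kd - pz;
            if (si_d < 0 || si_d >= D) continue;
            for (int kj = 0; kj < k; ++kj) {
              const int si_j = oj * s + kj - p;
              if (si_j < 0 || si_j >= W) continue;
              for (int ki = 0; ki < k; ++ki) {
                const int si_i = oi * s + ki - p;
                if (si_i < 0 || si_i >= H) continue;
                const int kk = ki + k * (kj + k * kd);
                const arma::uword xcol = xoff + si_i +
                  (arma::uword)H * (si_j + (arma::uword)W * si_d);
                double* dst = xp + xcol * C;
                const double* src = src0 + (arma::uword)kk * C;
                for (int c = 0; c < C; ++c) dst[c] += src[c];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, const arma::mat& Wm,
                       const arma::vec& b, int H, int W, int D, int B,
                       int k, bool d3) {
  const int kz = d3 ? k : 1;
  const int pz = d3 ? (k - 1) / 2 : 0;
  arma::mat cols;
  im2col_into(cols, X, H, W, D, B, k, kz, 1, 1, (k - 1) / 2, pz);
  arma::mat y = Wm * cols;
  y.each_col() += b;
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& X, const arma::mat& Wm,
                  const arma::mat& dY, int H, int W, int D, int B,
                  int k, bool d3) {
  const int kz = d3 ? k : 1;
  const int pz = d3 ? (k - 1) / 2 : 0;
  arma::mat cols;
  im2col_into(cols, X, H, W, D, B, k, kz, 1, 1, (k - 1) / 2, pz);
  arma::mat dW = dY * cols.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dcols = Wm.t() * dY;
  arma::mat dX;
  col2im_into(dX, dcols, X.n_rows, H, W, D, B, k, kz, 1, 1, (k - 1) / 2, pz);
  return List::create(_["dx"] = dX, _["dW"] = dW, _["db"] = db);
}

// transposed conv (kernel 3, stride 2): forward = col2im adjoint
// [[Rcpp::export]]
arma::mat cpp_convt_fwd(const arma::mat& X, const arma::mat& Wm,
                        const arma::vec& b, int Hs, int Ws, int Ds, int B,
                        bool d3) {
  const int kz = d3 ? 3 : 1;
  const int sz = d3 ? 2 : 1;
  const int pz = d3 ? 1 : 0;
  const int Hb = 2 * Hs, Wb = 2 * Ws;
  const int Db = d3 ? 2 * Ds : Ds;
  arma::mat cols = Wm.t() * X;
  arma::mat Y;
  col2im_into(Y, cols, Wm.n_cols / (9 * kz), Hb, Wb, Db, B, 3, kz, 2, sz, 1, pz);
  Y.each_col() += b;
  return Y;
}

// [[Rcpp::export]]
List cpp_convt_bwd(const arma::mat& X, const arma::mat& Wm,
                   const arma::mat& dYb, int Hs, int Ws, int Ds, int B,
                   bool d3) {
  const int kz = d3 ? 3 : 1;
  const int sz = d3 ? 2 : 1;
  const int pz = d3 ? 1 : 0;
  const int Hb = 2 * Hs, Wb = 2 * Ws;
  const int Db = d3 ? 2 * Ds : Ds;
  arma::mat M;
  im2col_into(M, dYb, Hb, Wb, Db, B, 3, kz, 2, sz, 1, pz);
  arma::mat dX = Wm * M;
  arma::mat dW = X * M.t();
  arma::vec db = arma::sum(dYb, 1);
  return List::create(_["dx"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
arma::mat cpp_elu_fwd(const arma::mat& X) {
  arma::mat Y = X;
  double* y = Y.memptr();
  const arma::uword n = Y.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (y[i] < 0) y[i] = std::expm1(y[i]);
  return Y;
}

// gradient from the output alone: y < 0 iff x < 0, and dy/dx = y + 1 there
// [[Rcpp::export]]
arma::mat cpp_elu_bwd(const arma::mat& dY, const arma::mat& Y) {
  arma::mat dX = dY;
  double* dx = dX.memptr();
  const double* y = Y.memptr();
  const arma::uword n = dX.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (y[i] < 0) dx[i] *= (y[i] + 1);
  return dX;
}

// [[Rcpp::export]]
List cpp_bn_fwd(const arma::mat& X, const arma::vec& gamma,
                const arma::vec& beta, const arma::vec& mean_in,
                const arma::vec& var_in, bool training, double eps) {
  const int C = X.n_rows;
  arma::vec m(C), v(C);
  if (training) {
    m = arma::mean(X, 1);
    v = arma::var(X, 1, 1);  // population variance per row
  } else {
    m = mean_in;
    v = var_in;
  }
  arma::vec inv = 1.0 / arma::sqrt(v + eps);
  arma::mat xhat = X;
  xhat.each_col() -= m;
  xhat.each_col() %= inv;
  arma::mat Y = xhat;
  Y.each_col() %= gamma;
  Y.each_col() += beta;
  return List::create(_["y"] = Y, _["xhat"] = xhat, _["inv"] = inv,
                      _["m"] = m, _["v"] = v);
}

// [[Rcpp::export]]
List cpp_bn_bwd(const arma::mat& dY, const arma::mat& xhat,
                const arma::vec& inv, const arma::vec& gamma) {
  const double n = (double)dY.n_cols;
  arma::vec dgamma = arma::sum(dY % xhat, 1);
  arma::vec dbeta = arma::sum(dY, 1);
  arma::mat dxhat = dY;
  dxhat.each_col() %= gamma;
  arma::vec s1 = arma::sum(dxhat, 1);
  arma::vec s2 = arma::sum(dxhat % xhat, 1);
  arma::mat dX = n * dxhat;
  dX.each_col() -= s1;
  dX -= xhat.each_col() % s2;
  dX.each_col() %= (inv / n);
  return List::create(_["dx"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
arma::mat cpp_softmax(const arma::mat& Z) {
  arma::mat Y = Z;
  const int L = Y.n_rows;
  for (arma::uword j = 0; j < Y.n_cols; ++j) {
    double mx = Y(0, j);
    for (int l = 1; l < L; ++l) mx = std::max(mx, Y(l, j));
    double s = 0;
    for (int l = 0; l < L; ++l) { Y(l, j) = std::exp(Y(l, j) - mx); s += Y(l, j); }
    for (int l = 0; l < L; ++l) Y(l, j) /= s;
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_softmax_bwd(const arma::mat& dP, const arma::mat& P) {
  arma::mat dZ = P % dP;
  arma::rowvec s = arma::sum(dZ, 0);
  dZ -= P.each_row() % s;
  return dZ;
}
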