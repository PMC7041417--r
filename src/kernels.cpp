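// Low-level numerical kernels for the 3D U-Net and volume post-processing.
// Convolutions use slab-wise im2col + GEMM so peak memory stays bounded even
// for 64^3 patches with wide feature maps.

#include <RcppArmadillo.h>
#include <vector>
#include <cstring>

using namespace Rcpp;

// Largest im2col buffer, in doubles (~256 MB).
static const double MAX_COL_DOUBLES = 3.3e7;

static inline arma::uword slab_depth(int k3cin, int n1, int n2) {
  double per_slice = (double)k3cin * n1 * n2;
  int zs = (int)std::floor(MAX_COL_DOUBLES / per_slice);
  return (arma::uword)std::max(1, zs);
}

// Gather a z-slab of the zero-padded receptive fields into colT
// (n1*n2*zs rows, k^3*Cin cols). x has dims (n1,n2,n3,cin).
static void im2col_slab(const double* x, int n1, int n2, int n3, int cin,
                        int k, int z0, int zs, arma::mat& colT) {
  const int p = k / 2;
  colT.zeros();
  const arma::uword plane = (arma::uword)n1 * n2;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + (arma::uword)ci * plane * n3;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const int r = kx + k * (ky + k * kz) + k * k * k * ci;
          double* dst0 = colT.colptr(r);
          const int x_lo = std::max(0, p - kx);
          const int x_hi = std::min(n1 - 1, n1 - 1 + p - kx);
          if (x_hi < x_lo) continue;
          const size_t run = (size_t)(x_hi - x_lo + 1);
          for (int z = z0; z < z0 + zs; ++z) {
            const int sz = z + kz - p;
            if (sz < 0 || sz >= n3) continue;
            for (int y = 0; y < n2; ++y) {
              const int sy = y + ky - p;
              if (sy < 0 || sy >= n2) continue;
              const double* src = xc + (arma::uword)sz * plane +
                                  (arma::uword)sy * n1 + (x_lo + kx - p);
              double* dst = dst0 + (arma::uword)(z - z0) * plane +
                            (arma::uword)y * n1 + x_lo;
              std::memcpy(dst, src, run * sizeof(double));
            }
          }
        }
      }
    }
  }
}

// Same-size zero-padded 3D convolution. x: (n1,n2,n3,cin), w: (k,k,k,cin,cout),
// b: length cout. Returns list(y, col): y is (n1,n2,n3,cout); col is the
// whole-volume im2col matrix when keep_col is true and it fits in the buffer
// budget (reused by the backward pass), NULL otherwise.
// [[Rcpp::export(name = ".conv3d_fwd")]]
List conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                bool keep_col = false) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], cin = xd[3];
  const int k = wd[0], cout = wd[4];
  if (wd[3] != cin) stop("conv3d_fwd: weight/input channel mismatch");
  const int k3cin = k * k * k * cin;
  const arma::uword N = (arma::uword)n1 * n2 * n3;

  NumericVector y(N * cout);
  y.attr("dim") = IntegerVector::create(n1, n2, n3, cout);
  arma::mat Y((double*)y.begin(), N, cout, false, true);
  const arma::mat W((double*)w.begin(), k3cin, cout, false, true);
  const arma::rowvec bv((double*)b.begin(), cout, false, true);

  if (k == 1) {  // 1x1x1 convolution is a plain GEMM
    const arma::mat X((double*)x.begin(), N, cin, false, true);
    Y = X * W;
    Y.each_row() += bv;
    return List::create(_["y"] = y, _["col"] = R_NilValue);
  }

  if (keep_col && (double)N * k3cin <= MAX_COL_DOUBLES) {
    NumericMatrix colR(N, k3cin);
    arma::mat colT((double*)colR.begin(), N, k3cin, false, true);
    im2col_slab(x.begin(), n1, n2, n3, cin, k, 0, n3, colT);
    Y = colT * W;
    Y.each_row() += bv;
    return List::create(_["y"] = y, _["col"] = colR);
  }

  const int zs_max = (int)slab_depth(k3cin, n1, n2);
  arma::mat colT;
  for (int z0 = 0; z0 < n3; z0 += zs_max) {
    const int zs = std::min(zs_max, n3 - z0);
    const arma::uword ncol = (arma::uword)n1 * n2 * zs;
    colT.set_size(ncol, k3cin);
    im2col_slab(x.begin(), n1, n2, n3, cin, k, z0, zs, colT);
    Y.rows((arma::uword)n1 * n2 * z0, (arma::uword)n1 * n2 * z0 + ncol - 1) =
        colT * W;
  }
  Y.each_row() += bv;
  return List::create(_["y"] = y, _["col"] = R_NilValue);
}

// Gradients of the convolution. dy: (n1,n2,n3,cout). dW uses the im2col
// matrix of x (taken from `col` when the forward pass cached it); dX is the
// full correlation of dy with the flipped kernel, computed via im2col of dy.
// Returns list(dx, dw, db).
// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                Nullable<NumericMatrix> col = R_NilValue) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], cin = xd[3];
  const int k = wd[0], cout = wd[4];
  const int k3 = k * k * k, k3cin = k3 * cin, k3cout = k3 * cout;
  const arma::uword N = (arma::uword)n1 * n2 * n3;

  NumericVector dx(x.size()), dw(w.size()), db(cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat dW((double*)dw.begin(), k3cin, cout, false, true);
  const arma::mat W((double*)w.begin(), k3cin, cout, false, true);
  const arma::mat DY((double*)dy.begin(), N, cout, false, true);
  arma::mat DX((double*)dx.begin(), N, cin, false, true);

  arma::rowvec dbv = arma::sum(DY, 0);
  std::memcpy(db.begin(), dbv.memptr(), cout * sizeof(double));

  if (k == 1) {
    const arma::mat X((double*)x.begin(), N, cin, false, true);
    dW = X.t() * DY;
    DX = DY * W.t();
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  }

  // dW = col(x)^T * dy
  if (col.isNotNull()) {
    NumericMatrix colR(col);
    const arma::mat colT((double*)colR.begin(), N, k3cin, false, true);
    dW = colT.t() * DY;
  } else {
    const int zs_max = (int)slab_depth(k3cin, n1, n2);
    arma::mat colT;
    for (int z0 = 0; z0 < n3; z0 += zs_max) {
      const int zs = std::min(zs_max, n3 - z0);
      const arma::uword ncol = (arma::uword)n1 * n2 * zs;
      colT.set_size(ncol, k3cin);
      im2col_slab(x.begin(), n1, n2, n3, cin, k, z0, zs, colT);
      dW += colT.t() * DY.rows((arma::uword)n1 * n2 * z0,
                               (arma::uword)n1 * n2 * z0 + ncol - 1);
    }
  }

  // Wflip[(kx,ky,kz), co -> ci] = W[k-1-kx, k-1-ky, k-1-kz, ci, co]
  arma::mat Wflip(k3cout, cin);
  const double* wp = w.begin();
  for (int ci = 0; ci < cin; ++ci)
    for (int co = 0; co < cout; ++co)
      for (int kz = 0; kz < k; ++kz)
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx) {
            int src = (k - 1 - kx) + k * ((k - 1 - ky) + k * (k - 1 - kz)) +
                      k3 * (ci + (arma::uword)cin * co);
            Wflip(kx + k * (ky + k * kz) + k3 * co, ci) = wp[src];
          }

  const int zs_max2 = (int)slab_depth(k3cout, n1, n2);
  arma::mat colY;
  for (int z0 = 0; z0 < n3; z0 += zs_max2) {
    const int zs = std::min(zs_max2, n3 - z0);
    const arma::uword ncol = (arma::uword)n1 * n2 * zs;
    colY.set_size(ncol, k3cout);
    im2col_slab(dy.begin(), n1, n2, n3, cout, k, z0, zs, colY);
    DX.rows((arma::uword)n1 * n2 * z0, (arma::uword)n1 * n2 * z0 + ncol - 1) =
        colY * Wflip;
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2x2 max pooling with stride 2. Returns pooled array and 1-based argmax
// indices into x (for the backward pass). Spatial dims must be even.
// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], nc = xd[3];
  if (n1 % 2 || n2 % 2 || n3 % 2) stop("maxpool3d: spatial dims must be even");
  const int m1 = n1 / 2, m2 = n2 / 2, m3 = n3 / 2;
  NumericVector y((R_xlen_t)m1 * m2 * m3 * nc);
  IntegerVector arg((R_xlen_t)m1 * m2 * m3 * nc);
  y.attr("dim") = IntegerVector::create(m1, m2, m3, nc);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  const arma::uword plane = (arma::uword)n1 * n2;
  R_xlen_t o = 0;
  for (int c = 0; c < nc; ++c) {
    const arma::uword cb = (arma::uword)c * plane * n3;
    for (int z = 0; z < m3; ++z)
      for (int yj = 0; yj < m2; ++yj)
        for (int xi = 0; xi < m1; ++xi, ++o) {
          double best = -HUGE_VAL;
          arma::uword besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dxi = 0; dxi < 2; ++dxi) {
                arma::uword idx = cb + (arma::uword)(2 * z + dz) * plane +
                                  (arma::uword)(2 * yj + dy) * n1 +
                                  (2 * xi + dxi);
                if (xp[idx] > best) { best = xp[idx]; besti = idx; }
              }
          yp[o] = best;
          ap[o] = (int)(besti + 1);
        }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
NumericVector maxpool3d_bwd(IntegerVector argmax, NumericVector dy,
                            IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ap = argmax.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[ap[i] - 1] += dyp[i];
  return dx;
}

// Nearest-neighbour 2x upsampling of (n1,n2,n3,c).
// [[Rcpp::export(name = ".upsample3d_fwd")]]
NumericVector upsample3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], nc = xd[3];
  const int m1 = 2 * n1, m2 = 2 * n2, m3 = 2 * n3;
  NumericVector y((R_xlen_t)m1 * m2 * m3 * nc);
  y.attr("dim") = IntegerVector::create(m1, m2, m3, nc);
  const double* xp = x.begin();
  double* yp = y.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < nc; ++c) {
    const arma::uword cb = (arma::uword)c * n1 * n2 * n3;
    for (int z = 0; z < m3; ++z)
      for (int yj = 0; yj < m2; ++yj) {
        const arma::uword rb =
            cb + (arma::uword)(z / 2) * n1 * n2 + (arma::uword)(yj / 2) * n1;
        for (int xi = 0; xi < m1; ++xi, ++o) yp[o] = xp[rb + xi / 2];
      }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample3d_bwd")]]
NumericVector upsample3d_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int m1 = yd[0], m2 = yd[1], m3 = yd[2], nc = yd[3];
  const int n1 = m1 / 2, n2 = m2 / 2, n3 = m3 / 2;
  NumericVector dx((R_xlen_t)n1 * n2 * n3 * nc);
  dx.attr("dim") = IntegerVector::create(n1, n2, n3, nc);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < nc; ++c) {
    const arma::uword cb = (arma::uword)c * n1 * n2 * n3;
    for (int z = 0; z < m3; ++z)
      for (int yj = 0; yj < m2; ++yj) {
        const arma::uword rb =
            cb + (arma::uword)(z / 2) * n1 * n2 + (arma::uword)(yj / 2) * n1;
        for (int xi = 0; xi < m1; ++xi, ++o) dxp[rb + xi / 2] += dyp[o];
      }
  }
  return dx;
}

// 3D connected-component labelling of a binary volume under 6/18/26
// connectivity. Components are numbered in raster discovery order, which
// makes size ties deterministic. Returns list(labels, sizes).
// [[Rcpp::export(name = ".label_components_3d")]]
List label_components_3d(LogicalVector mask, int connectivity) {
  IntegerVector md = mask.attr("dim");
  const int n1 = md[0], n2 = md[1], n3 = md[2];
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        offs.push_back({dx, dy, dz});
      }
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector labels(N);
  labels.attr("dim") = md;
  const int* mp = mask.begin();
  int* lp = labels.begin();
  std::vector<double> sizes;
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (mp[s] != 1 || lp[s] != 0) continue;
    ++next;
    double size = 0;
    queue.clear();
    queue.push_back(s);
    lp[s] = next;
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      ++size;
      int xi = (int)(v % n1), yj = (int)((v / n1) % n2), z = (int)(v / ((R_xlen_t)n1 * n2));
      for (auto& o : offs) {
        int nx = xi + o[0], ny = yj + o[1], nz = z + o[2];
        if (nx < 0 || nx >= n1 || ny < 0 || ny >= n2 || nz < 0 || nz >= n3)
          continue;
        R_xlen_t w = nx + (R_xlen_t)n1 * (ny + (R_xlen_t)n2 * nz);
        if (mp[w] == 1 && lp[w] == 0) { lp[w] = next; queue.push_back(w); }
      }
    }
    sizes.push_back(size);
  }
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}

// For each row of A (points, in mm), the Euclidean distance to the nearest
// row of B. Brute force; surface point sets in this pipeline are small.
// [[Rcpp::export(name = ".nn_directed_dists")]]
NumericVector nn_directed_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  std::vector<double> bx(m), by(m), bz(m);
  for (int j = 0; j < m; ++j) { bx[j] = B(j, 0); by[j] = B(j, 1); bz[j] = B(j, 2); }
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = HUGE_VAL;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - bx[j], dy = ay - by[j], dz = az - bz[j];
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Padded-layout convolution path used by the training loop. Activations are
// stored with a one-voxel zero halo: dims (n1+2, n2+2, n3+2, c). A 3^3
// convolution then decomposes into 27 GEMMs on row-offset views of the
// flattened (Npad x C) matrix — no im2col buffer, far less memory traffic.
// Halo rows accumulate garbage during the GEMMs and are re-zeroed before
// return, which also keeps the zero-padding semantics of the convolution.

#include <R_ext/BLAS.h>

static void zero_halo(double* a, int p1, int p2, int p3, int nc) {
  const arma::uword plane = (arma::uword)p1 * p2;
  for (int c = 0; c < nc; ++c) {
    double* ac = a + (arma::uword)c * plane * p3;
    std::memset(ac, 0, plane * sizeof(double));                    // z = 0
    std::memset(ac + plane * (p3 - 1), 0, plane * sizeof(double)); // z = p3-1
    for (int z = 1; z < p3 - 1; ++z) {
      double* az = ac + plane * z;
      std::memset(az, 0, p1 * sizeof(double));                     // y = 0
      std::memset(az + (arma::uword)p1 * (p2 - 1), 0, p1 * sizeof(double));
      for (int y = 1; y < p2 - 1; ++y) {
        az[(arma::uword)p1 * y] = 0;                               // x = 0
        az[(arma::uword)p1 * y + p1 - 1] = 0;                      // x = p1-1
      }
    }
  }
}

// Add a one-voxel zero halo: (n1,n2,n3,c) -> (n1+2,n2+2,n3+2,c).
// [[Rcpp::export(name = ".pad_halo")]]
NumericVector pad_halo(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], nc = xd[3];
  const int p1 = n1 + 2, p2 = n2 + 2, p3 = n3 + 2;
  NumericVector y((R_xlen_t)p1 * p2 * p3 * nc);
  y.attr("dim") = IntegerVector::create(p1, p2, p3, nc);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < n3; ++z)
      for (int yj = 0; yj < n2; ++yj) {
        const double* src = xp + ((arma::uword)c * n3 + z) * n1 * n2 +
                            (arma::uword)yj * n1;
        double* dst = yp + ((arma::uword)c * p3 + z + 1) * p1 * p2 +
                      (arma::uword)(yj + 1) * p1 + 1;
        std::memcpy(dst, src, n1 * sizeof(double));
      }
  return y;
}

// Drop the halo: (p1,p2,p3,c) -> (p1-2,p2-2,p3-2,c).
// [[Rcpp::export(name = ".unpad_halo")]]
NumericVector unpad_halo(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int p1 = xd[0], p2 = xd[1], p3 = xd[2], nc = xd[3];
  const int n1 = p1 - 2, n2 = p2 - 2, n3 = p3 - 2;
  NumericVector y((R_xlen_t)n1 * n2 * n3 * nc);
  y.attr("dim") = IntegerVector::create(n1, n2, n3, nc);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < n3; ++z)
      for (int yj = 0; yj < n2; ++yj) {
        const double* src = xp + ((arma::uword)c * p3 + z + 1) * p1 * p2 +
                            (arma::uword)(yj + 1) * p1 + 1;
        double* dst = yp + ((arma::uword)c * n3 + z) * n1 * n2 +
                      (arma::uword)yj * n1;
        std::memcpy(dst, src, n1 * sizeof(double));
      }
  return y;
}

// 3^3 zero-padded convolution on halo-padded activations.
// x: (p1,p2,p3,cin) with zero halo; w: (3,3,3,cin,cout); returns
// (p1,p2,p3,cout) with zero halo.
// [[Rcpp::export(name = ".convp_fwd")]]
NumericVector convp_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int p1 = xd[0], p2 = xd[1], p3 = xd[2], cin = xd[3];
  const int k = wd[0], cout = wd[4];
  if (k != 3) stop("convp_fwd supports 3^3 kernels");
  const arma::uword Npad = (arma::uword)p1 * p2 * p3;
  NumericVector y(Npad * cout);
  y.attr("dim") = IntegerVector::create(p1, p2, p3, cout);
  double* yp = y.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  std::vector<double> Wo((size_t)cin * cout);
  const double one = 1.0;
  const int ldx = (int)Npad;
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const ptrdiff_t off = (kx - 1) + (ptrdiff_t)p1 * (ky - 1) +
                              (ptrdiff_t)p1 * p2 * (kz - 1);
        for (int co = 0; co < cout; ++co)
          for (int ci = 0; ci < cin; ++ci)
            Wo[(size_t)ci + (size_t)cin * co] =
                wp[kx + 3 * (ky + 3 * kz) + 27 * ((arma::uword)ci +
                   (arma::uword)cin * co)];
        const ptrdiff_t r0 = off < 0 ? -off : 0;
        const ptrdiff_t r1 = (ptrdiff_t)Npad - 1 - (off > 0 ? off : 0);
        const int m = (int)(r1 - r0 + 1);
        const int n = cout, kk = cin;
        F77_CALL(dgemm)("N", "N", &m, &n, &kk, &one, xp + r0 + off, &ldx,
                        Wo.data(), &kk, &one, yp + r0, &ldx
                        FCONE FCONE);
      }
  // bias on interior, then re-zero the halo
  for (int co = 0; co < cout; ++co) {
    double* yc = yp + (arma::uword)co * Npad;
    const double bc = b[co];
    for (arma::uword i = 0; i < Npad; ++i) yc[i] += bc;
  }
  zero_halo(yp, p1, p2, p3, cout);
  return y;
}

// Gradients of convp_fwd. dy must have a zero halo (it does when produced by
// chaining these kernels). Returns list(dx, dw, db); dx has a zero halo.
// [[Rcpp::export(name = ".convp_bwd")]]
List convp_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int p1 = xd[0], p2 = xd[1], p3 = xd[2], cin = xd[3];
  const int cout = wd[4];
  const arma::uword Npad = (arma::uword)p1 * p2 * p3;
  NumericVector dx(x.size()), dw(w.size()), db(cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  for (int co = 0; co < cout; ++co) {
    const double* dyc = dyp + (arma::uword)co * Npad;
    double s = 0;
    for (arma::uword i = 0; i < Npad; ++i) s += dyc[i];
    db[co] = s;
  }
  std::vector<double> Wo((size_t)cin * cout), dWo((size_t)cin * cout);
  const double one = 1.0, zero = 0.0;
  const int ldx = (int)Npad;
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const ptrdiff_t off = (kx - 1) + (ptrdiff_t)p1 * (ky - 1) +
                              (ptrdiff_t)p1 * p2 * (kz - 1);
        const ptrdiff_t r0 = off < 0 ? -off : 0;
        const ptrdiff_t r1 = (ptrdiff_t)Npad - 1 - (off > 0 ? off : 0);
        const int m = (int)(r1 - r0 + 1);
        // dW_o = X(shifted)^T . dY : (cin x cout)
        {
          const int mm = cin, nn = cout;
          F77_CALL(dgemm)("T", "N", &mm, &nn, &m, &one, xp + r0 + off, &ldx,
                          dyp + r0, &ldx, &zero, dWo.data(), &mm FCONE FCONE);
          for (int co = 0; co < cout; ++co)
            for (int ci = 0; ci < cin; ++ci)
              dwp[kx + 3 * (ky + 3 * kz) + 27 * ((arma::uword)ci +
                  (arma::uword)cin * co)] = dWo[(size_t)ci + (size_t)cin * co];
        }
        // dX(shifted) += dY . W_o^T
        for (int co = 0; co < cout; ++co)
          for (int ci = 0; ci < cin; ++ci)
            Wo[(size_t)ci + (size_t)cin * co] =
                wp[kx + 3 * (ky + 3 * kz) + 27 * ((arma::uword)ci +
                   (arma::uword)cin * co)];
        {
          const int nn = cin, kk2 = cout;
          F77_CALL(dgemm)("N", "T", &m, &nn, &kk2, &one, dyp + r0, &ldx,
                          Wo.data(), &nn, &one, dxp + r0 + off, &ldx
                          FCONE FCONE);
        }
      }
  zero_halo(dxp, p1, p2, p3, cin);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 1x1x1 convolution (classifier head) on halo-padded activations.
// [[Rcpp::export(name = ".conv1p_fwd")]]
NumericVector conv1p_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int p1 = xd[0], p2 = xd[1], p3 = xd[2], cin = xd[3];
  const int cout = wd[4];
  const arma::uword Npad = (arma::uword)p1 * p2 * p3;
  NumericVector y(Npad * cout);
  y.attr("dim") = IntegerVector::create(p1, p2, p3, cout);
  arma::mat Y((double*)y.begin(), Npad, cout, false, true);
  const arma::mat X((double*)x.begin(), Npad, cin, false, true);
  const arma::mat W((double*)w.begin(), cin, cout, false, true);
  const arma::rowvec bv((double*)b.begin(), cout, false, true);
  Y = X * W;
  Y.each_row() += bv;
  zero_halo(y.begin(), p1, p2, p3, cout);
  return y;
}

// [[Rcpp::export(name = ".conv1p_bwd")]]
List conv1p_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int p1 = xd[0], p2 = xd[1], p3 = xd[2], cin = xd[3];
  const int cout = wd[4];
  const arma::uword Npad = (arma::uword)p1 * p2 * p3;
  NumericVector dx(x.size()), dw(w.size()), db(cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat DX((double*)dx.begin(), Npad, cin, false, true);
  arma::mat dW((double*)dw.begin(), cin, cout, false, true);
  const arma::mat X((double*)x.begin(), Npad, cin, false, true);
  const arma::mat W((double*)w.begin(), cin, cout, false, true);
  const arma::mat DY((double*)dy.begin(), Npad, cout, false, true);
  arma::rowvec dbv = arma::sum(DY, 0);
  std::memcpy(db.begin(), dbv.memptr(), cout * sizeof(double));
  dW = X.t() * DY;
  DX = DY * W.t();
  zero_halo(dx.begin(), p1, p2, p3, cin);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2x2 max pooling on halo-padded activations (interior dims must be even).
// Output is halo-padded at half resolution. argmax indices are 1-based into x.
// [[Rcpp::export(name = ".poolp_fwd")]]
List poolp_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int p1 = xd[0], p2 = xd[1], p3 = xd[2], nc = xd[3];
  const int n1 = p1 - 2, n2 = p2 - 2, n3 = p3 - 2;
  if (n1 % 2 || n2 % 2 || n3 % 2) stop("poolp: interior dims must be even");
  const int q1 = n1 / 2 + 2, q2 = n2 / 2 + 2, q3 = n3 / 2 + 2;
  NumericVector y((R_xlen_t)q1 * q2 * q3 * nc);
  IntegerVector arg(y.size());
  y.attr("dim") = IntegerVector::create(q1, q2, q3, nc);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  const arma::uword plane = (arma::uword)p1 * p2;
  for (int c = 0; c < nc; ++c) {
    const arma::uword cb = (arma::uword)c * plane * p3;
    const arma::uword ob = (arma::uword)c * q1 * q2 * q3;
    for (int z = 0; z < n3 / 2; ++z)
      for (int yj = 0; yj < n2 / 2; ++yj)
        for (int xi = 0; xi < n1 / 2; ++xi) {
          double best = -HUGE_VAL;
          arma::uword besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dxi = 0; dxi < 2; ++dxi) {
                arma::uword idx = cb + (arma::uword)(2 * z + dz + 1) * plane +
                                  (arma::uword)(2 * yj + dy + 1) * p1 +
                                  (2 * xi + dxi + 1);
                if (xp[idx] > best) { best = xp[idx]; besti = idx; }
              }
          arma::uword o = ob + (arma::uword)(z + 1) * q1 * q2 +
                          (arma::uword)(yj + 1) * q1 + (xi + 1);
          yp[o] = best;
          ap[o] = (int)(besti + 1);
        }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".poolp_bwd")]]
NumericVector poolp_bwd(IntegerVector argmax, NumericVector dy,
                        IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ap = argmax.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    if (ap[i] > 0) dxp[ap[i] - 1] += dyp[i];
  return dx;
}

// Nearest-neighbour 2x upsampling on halo-padded activations.
// [[Rcpp::export(name = ".upsamplep_fwd")]]
NumericVector upsamplep_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int p1 = xd[0], p2 = xd[1], p3 = xd[2], nc = xd[3];
  const int n1 = p1 - 2, n2 = p2 - 2, n3 = p3 - 2;
  const int q1 = 2 * n1 + 2, q2 = 2 * n2 + 2, q3 = 2 * n3 + 2;
  NumericVector y((R_xlen_t)q1 * q2 * q3 * nc);
  y.attr("dim") = IntegerVector::create(q1, q2, q3, nc);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < nc; ++c) {
    const arma::uword cb = (arma::uword)c * p1 * p2 * p3;
    const arma::uword ob = (arma::uword)c * q1 * q2 * q3;
    for (int z = 0; z < 2 * n3; ++z)
      for (int yj = 0; yj < 2 * n2; ++yj) {
        const double* src = xp + cb + (arma::uword)(z / 2 + 1) * p1 * p2 +
                            (arma::uword)(yj / 2 + 1) * p1 + 1;
        double* dst = yp + ob + (arma::uword)(z + 1) * q1 * q2 +
                      (arma::uword)(yj + 1) * q1 + 1;
        for (int xi = 0; xi < 2 * n1; ++xi) dst[xi] = src[xi / 2];
      }
  }
  return y;
}

// [[Rcpp::export(name = ".upsamplep_bwd")]]
NumericVector upsamplep_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int q1 = yd[0], q2 = yd[1], q3 = yd[2], nc = yd[3];
  const int n1 = (q1 - 2) / 2, n2 = (q2 - 2) / 2, n3 = (q3 - 2) / 2;
  const int p1 = n1 + 2, p2 = n2 + 2, p3 = n3 + 2;
  NumericVector dx((R_xlen_t)p1 * p2 * p3 * nc);
  dx.attr("dim") = IntegerVector::create(p1, p2, p3, nc);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < nc; ++c) {
    const arma::uword cb = (arma::uword)c * q1 * q2 * q3;
    const arma::uword ob = (arma::uword)c * p1 * p2 * p3;
    for (int z = 0; z < 2 * n3; ++z)
      for (int yj = 0; yj < 2 * n2; ++yj) {
        const double* src = dyp + cb + (arma::uword)(z + 1) * q1 * q2 +
                            (arma::uword)(yj + 1) * q1 + 1;
        double* dst = dxp + ob + (arma::uword)(z / 2 + 1) * p1 * p2 +
                      (arma::uword)(yj / 2 + 1) * p1 + 1;
        for (int xi = 0; xi < 2 * n1; ++xi) dst[xi / 2] += src[xi];
      }
  }
  return dx;
}
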