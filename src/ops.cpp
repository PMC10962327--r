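// Low-level volumetric neural-network primitives and image filters.
// Volumes are stored as dense column-major R arrays with dim (X, Y, Z, C);
// convolution weights keep the canonical (out, in, kx, ky, kz) layout so the
// layout logic lives in one place.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::uword idx4(arma::uword x, arma::uword y, arma::uword z,
                               arma::uword c, arma::uword X, arma::uword Y,
                               arma::uword Z) {
  return x + X * (y + Y * (z + Z * c));
}

// transposed im2col (patches as rows) for a 3x3x3 kernel with zero padding
// 1, restricted to output slabs z in [z0, z1).  Row order: voxel (x fastest,
// then y, then z); column order: kx + 3*ky + 9*kz + 27*ci.  The transposed
// layout keeps every read and write contiguous.
static void im2col3T(const double* x, arma::uword X, arma::uword Y,
                     arma::uword Z, arma::uword C, arma::uword z0,
                     arma::uword z1, arma::mat& colT) {
  const arma::uword K = 27 * C;
  const arma::uword N = X * Y * (z1 - z0);
  colT.set_size(N, K);
  colT.zeros();
  for (arma::uword ci = 0; ci < C; ++ci) {
    for (int kz = -1; kz <= 1; ++kz) {
      for (int ky = -1; ky <= 1; ++ky) {
        for (int kx = -1; kx <= 1; ++kx) {
          const arma::uword r =
              (arma::uword)(kx + 1) + 3 * (ky + 1) + 9 * (kz + 1) + 27 * ci;
          double* dst = colT.colptr(r);
          for (arma::uword z = z0; z < z1; ++z) {
            const int zs = (int)z + kz;
            if (zs < 0 || zs >= (int)Z) continue;
            for (arma::uword y = 0; y < Y; ++y) {
              const int ys = (int)y + ky;
              if (ys < 0 || ys >= (int)Y) continue;
              const arma::uword n0 = X * (y + Y * (z - z0));
              const double* src =
                  x + idx4(0, (arma::uword)ys, (arma::uword)zs, ci, X, Y, Z) +
                  kx;
              const int xlo = kx < 0 ? 1 : 0;
              const int xhi = kx > 0 ? (int)X - 1 : (int)X;
              for (int xo = xlo; xo < xhi; ++xo) dst[n0 + xo] = src[xo];
            }
          }
        }
      }
    }
  }
}

static arma::uword slab_size(arma::uword X, arma::uword Y, arma::uword C) {
  // keep each im2col block under ~128 MB
  const double bytes_per_slab = 27.0 * C * X * Y * 8.0;
  arma::uword zs = (arma::uword)std::max(1.0, std::floor(128e6 / bytes_per_slab));
  return zs;
}

// Forward 3x3x3 same-size convolution.  w: (Cout, Cin, 3, 3, 3); b: Cout.
// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const arma::uword X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const arma::uword Co = wd[0], Ci = wd[1];
  if (Ci != C) stop("conv3d: input channels (%d) != kernel in-channels (%d)",
                    (int)C, (int)Ci);
  // repack weights to (27*Ci x Co) with row order matching im2col3T columns
  arma::mat Wt(27 * Ci, Co);
  const double* wp = w.begin();
  for (arma::uword o = 0; o < Co; ++o)
    for (arma::uword ci = 0; ci < Ci; ++ci)
      for (arma::uword t = 0; t < 27; ++t)
        Wt.at(t + 27 * ci, o) = wp[o + Co * (ci + Ci * t)];

  NumericVector out(X * Y * Z * Co);
  out.attr("dim") = IntegerVector::create(X, Y, Z, Co);
  arma::mat colT;
  const arma::uword zs = slab_size(X, Y, Ci);
  for (arma::uword z0 = 0; z0 < Z; z0 += zs) {
    const arma::uword z1 = std::min(Z, z0 + zs);
    im2col3T(x.begin(), X, Y, Z, C, z0, z1, colT);
    arma::mat Yt = colT * Wt;  // N x Co
    const arma::uword N = colT.n_rows;
    for (arma::uword o = 0; o < Co; ++o) {
      double* dst = out.begin() + X * Y * (z0 + Z * o);
      const double* src = Yt.colptr(o);
      const double bo = b[o];
      for (arma::uword n = 0; n < N; ++n) dst[n] = src[n] + bo;
    }
  }
  return out;
}

// Backward pass of the same convolution.  Returns dx, dw, db.
// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const arma::uword X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const arma::uword Co = wd[0], Ci = wd[1];
  const double* wp = w.begin();
  // both gradients come from one im2col of dy:
  //   dx = dy (*) flip(w)   and   dw[o,ci,k] = <x[., ci], dy shifted by -k>
  // Wflip[t + 27 o, ci] = w[o, ci, 26 - t] (26 - t flips all three offsets)
  arma::mat Wflip(27 * Co, Ci);
  for (arma::uword ci = 0; ci < Ci; ++ci)
    for (arma::uword o = 0; o < Co; ++o)
      for (arma::uword t = 0; t < 27; ++t)
        Wflip.at(t + 27 * o, ci) = wp[o + Co * (ci + Ci * (26 - t))];

  arma::vec db(Co, arma::fill::zeros);
  for (arma::uword o = 0; o < Co; ++o) {
    const double* src = dy.begin() + X * Y * Z * o;
    double acc = 0;
    for (arma::uword n = 0; n < X * Y * Z; ++n) acc += src[n];
    db[o] = acc;
  }

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat dWx(Ci, 27 * Co, arma::fill::zeros);
  arma::mat colTdy;
  const arma::uword zs = slab_size(X, Y, Co);
  for (arma::uword z0 = 0; z0 < Z; z0 += zs) {
    const arma::uword z1 = std::min(Z, z0 + zs);
    const arma::uword N = X * Y * (z1 - z0);
    im2col3T(dy.begin(), X, Y, Z, Co, z0, z1, colTdy);
    arma::mat dXm = colTdy * Wflip;  // N x Ci
    for (arma::uword ci = 0; ci < Ci; ++ci) {
      double* dst = dx.begin() + X * Y * (z0 + Z * ci);
      std::copy(dXm.colptr(ci), dXm.colptr(ci) + N, dst);
    }
    arma::mat Xm(const_cast<double*>(x.begin()), X * Y * Z, Ci, false, true);
    dWx += Xm.rows(X * Y * z0, X * Y * z1 - 1).t() * colTdy;
  }

  NumericVector dwR(w.size());
  dwR.attr("dim") = wd;
  double* dwp = dwR.begin();
  for (arma::uword o = 0; o < Co; ++o)
    for (arma::uword ci = 0; ci < Ci; ++ci)
      for (arma::uword t = 0; t < 27; ++t)
        dwp[o + Co * (ci + Ci * t)] = dWx.at(ci, (26 - t) + 27 * o);
  return List::create(_["dx"] = dx, _["dw"] = dwR,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2x2 max pooling with stride 2.  Returns pooled values and 1-based argmax
// linear indices into the input.
// [[Rcpp::export]]
List maxpool3d_forward_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const arma::uword X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  if (X % 2 || Y % 2 || Z % 2) stop("maxpool3d: spatial dims must be even");
  const arma::uword Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector out(Xo * Yo * Zo * C);
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  IntegerVector arg(out.size());
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  arma::uword n = 0;
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword z = 0; z < Zo; ++z)
      for (arma::uword y = 0; y < Yo; ++y)
        for (arma::uword xo = 0; xo < Xo; ++xo, ++n) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword besti = 0;
          for (arma::uword dz = 0; dz < 2; ++dz)
            for (arma::uword dy = 0; dy < 2; ++dy)
              for (arma::uword dx = 0; dx < 2; ++dx) {
                const arma::uword i =
                    idx4(2 * xo + dx, 2 * y + dy, 2 * z + dz, c, X, Y, Z);
                if (xp[i] > best) { best = xp[i]; besti = i; }
              }
          op[n] = best;
          ap[n] = (int)(besti + 1);
        }
  return List::create(_["y"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_backward_cpp(NumericVector dy, IntegerVector argmax,
                                     IntegerVector in_dim) {
  NumericVector dx((arma::uword)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  for (R_xlen_t n = 0; n < dy.size(); ++n) dx[argmax[n] - 1] += dy[n];
  return dx;
}

// Transposed convolution, kernel 2x2x2, stride 2 (non-overlapping blocks).
// w: (Cin, Cout, 2, 2, 2); output dims are doubled.
// [[Rcpp::export]]
NumericVector convtranspose3d_forward_cpp(NumericVector x, NumericVector w,
                                          NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const arma::uword X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const arma::uword Ciw = wd[0], Co = wd[1];
  if (Ci != Ciw) stop("convtranspose3d: channel mismatch");
  const arma::uword N = X * Y * Z;
  arma::mat Xm(const_cast<double*>(x.begin()), N, Ci, false, true);
  // W8: (Ci x Co*8), column t + 8*o holds w[ci, o, offset t]
  arma::mat W8(Ci, Co * 8);
  const double* wp = w.begin();
  for (arma::uword ci = 0; ci < Ci; ++ci)
    for (arma::uword o = 0; o < Co; ++o)
      for (arma::uword t = 0; t < 8; ++t)
        W8.at(ci, t + 8 * o) = wp[ci + Ciw * (o + Co * t)];
  arma::mat Ob = Xm * W8;  // N x Co*8
  NumericVector out(8 * N * Co);
  out.attr("dim") = IntegerVector::create(2 * X, 2 * Y, 2 * Z, Co);
  double* op = out.begin();
  const arma::uword X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  for (arma::uword o = 0; o < Co; ++o) {
    const double bo = b[o];
    for (arma::uword t = 0; t < 8; ++t) {
      const arma::uword dx = t & 1, dy = (t >> 1) & 1, dz = (t >> 2) & 1;
      const arma::uword colj = t + 8 * o;
      arma::uword n = 0;
      for (arma::uword z = 0; z < Z; ++z)
        for (arma::uword y = 0; y < Y; ++y)
          for (arma::uword xx = 0; xx < X; ++xx, ++n)
            op[idx4(2 * xx + dx, 2 * y + dy, 2 * z + dz, o, X2, Y2, Z2)] =
                Ob.at(n, colj) + bo;
    }
  }
  return out;
}

// [[Rcpp::export]]
List convtranspose3d_backward_cpp(NumericVector x, NumericVector w,
                                  NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const arma::uword X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const arma::uword Co = wd[1];
  const arma::uword N = X * Y * Z;
  const arma::uword X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  // gather dy into N x Co*8
  arma::mat dOb(N, Co * 8);
  const double* dp = dy.begin();
  arma::vec db(Co, arma::fill::zeros);
  for (arma::uword o = 0; o < Co; ++o) {
    double acc = 0.0;
    for (arma::uword t = 0; t < 8; ++t) {
      const arma::uword dxo = t & 1, dyo = (t >> 1) & 1, dzo = (t >> 2) & 1;
      const arma::uword colj = t + 8 * o;
      arma::uword n = 0;
      for (arma::uword z = 0; z < Z; ++z)
        for (arma::uword y = 0; y < Y; ++y)
          for (arma::uword xx = 0; xx < X; ++xx, ++n) {
            const double v =
                dp[idx4(2 * xx + dxo, 2 * y + dyo, 2 * z + dzo, o, X2, Y2, Z2)];
            dOb.at(n, colj) = v;
            acc += v;
          }
    }
    db[o] = acc;
  }
  arma::mat Xm(const_cast<double*>(x.begin()), N, Ci, false, true);
  arma::mat dW8 = Xm.t() * dOb;       // Ci x Co*8
  arma::mat W8(Ci, Co * 8);
  const double* wp = w.begin();
  for (arma::uword ci = 0; ci < Ci; ++ci)
    for (arma::uword o = 0; o < Co; ++o)
      for (arma::uword t = 0; t < 8; ++t)
        W8.at(ci, t + 8 * o) = wp[ci + Ci * (o + Co * t)];
  arma::mat dXm = dOb * W8.t();       // N x Ci
  NumericVector dx(N * Ci);
  dx.attr("dim") = xd;
  std::copy(dXm.begin(), dXm.end(), dx.begin());
  NumericVector dwR(w.size());
  dwR.attr("dim") = wd;
  double* dwp = dwR.begin();
  for (arma::uword ci = 0; ci < Ci; ++ci)
    for (arma::uword o = 0; o < Co; ++o)
      for (arma::uword t = 0; t < 8; ++t)
        dwp[ci + Ci * (o + Co * t)] = dW8.at(ci, t + 8 * o);
  return List::create(_["dx"] = dx, _["dw"] = dwR,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Separable Gaussian blur of a 3D array with per-axis sigma (voxels),
// reflect boundary, kernel truncated at 4 sigma (or given half width).
static void blur_axis(std::vector<double>& v, arma::uword X, arma::uword Y,
                      arma::uword Z, int axis, double sigma, int halfw) {
  if (sigma <= 0) return;
  const int hw = halfw > 0 ? halfw : std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * hw + 1);
  double s = 0;
  for (int i = -hw; i <= hw; ++i) {
    k[i + hw] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + hw];
  }
  for (auto& kv : k) kv /= s;
  const arma::uword dims[3] = {X, Y, Z};
  const arma::uword L = dims[axis];
  std::vector<double> line(L), outl(L);
  const arma::uword strides[3] = {1, X, X * Y};
  const arma::uword st = strides[axis];
  // iterate over all lines along `axis`
  arma::uword n_outer1 = axis == 0 ? Y : X;
  arma::uword n_outer2 = axis == 2 ? Y : Z;
  for (arma::uword b = 0; b < n_outer2; ++b) {
    for (arma::uword a = 0; a < n_outer1; ++a) {
      arma::uword base;
      if (axis == 0) base = X * (a + Y * b);
      else if (axis == 1) base = a + X * Y * b;
      else base = a + X * b;
      for (arma::uword i = 0; i < L; ++i) line[i] = v[base + i * st];
      for (arma::uword i = 0; i < L; ++i) {
        double acc = 0;
        for (int j = -hw; j <= hw; ++j) {
          int src = (int)i + j;
          // reflect (mirror without repeating the edge sample: scipy 'reflect'
          // = numpy 'symmetric'): -1 -> 0, L -> L-1
          while (src < 0 || src >= (int)L) {
            if (src < 0) src = -src - 1;
            if (src >= (int)L) src = 2 * (int)L - src - 1;
          }
          acc += k[j + hw] * line[src];
        }
        outl[i] = acc;
      }
      for (arma::uword i = 0; i < L; ++i) v[base + i * st] = outl[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector gaussian_blur3d_cpp(NumericVector x, NumericVector sigma,
                                  int halfw) {
  IntegerVector xd = x.attr("dim");
  const arma::uword X = xd[0], Y = xd[1], Z = xd[2];
  std::vector<double> v(x.begin(), x.end());
  for (int axis = 0; axis < 3; ++axis)
    blur_axis(v, X, Y, Z, axis, sigma[axis], halfw);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = xd;
  return out;
}

// Trilinear resampling of a 3D array onto a new grid.  Both grids share the
// same physical field of view anchored at the first voxel centre; coordinates
// map through voxel centres: p_mm = (i + 0.5) * v.
// [[Rcpp::export]]
NumericVector resample_trilinear_cpp(NumericVector x, IntegerVector new_dim,
                                     NumericVector old_vox,
                                     NumericVector new_vox) {
  IntegerVector xd = x.attr("dim");
  const arma::uword X = xd[0], Y = xd[1], Z = xd[2];
  const arma::uword Xo = new_dim[0], Yo = new_dim[1], Zo = new_dim[2];
  NumericVector out(Xo * Yo * Zo);
  out.attr("dim") = new_dim;
  const double* xp = x.begin();
  double* op = out.begin();
  const arma::uword od[3] = {X, Y, Z};
  auto clampi = [](int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); };
  arma::uword n = 0;
  for (arma::uword z = 0; z < Zo; ++z)
    for (arma::uword y = 0; y < Yo; ++y)
      for (arma::uword xx = 0; xx < Xo; ++xx, ++n) {
        double f[3], w0[3];
        int i0[3], i1[3];
        const double cc[3] = {(xx + 0.5) * new_vox[0] / old_vox[0] - 0.5,
                              (y + 0.5) * new_vox[1] / old_vox[1] - 0.5,
                              (z + 0.5) * new_vox[2] / old_vox[2] - 0.5};
        for (int a = 0; a < 3; ++a) {
          const int fl = (int)std::floor(cc[a]);
          f[a] = cc[a] - fl;
          i0[a] = clampi(fl, (int)od[a]);
          i1[a] = clampi(fl + 1, (int)od[a]);
          w0[a] = 1.0 - f[a];
        }
        double acc = 0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const double wgt = (dx ? f[0] : w0[0]) * (dy ? f[1] : w0[1]) *
                                 (dz ? f[2] : w0[2]);
              const arma::uword i =
                  (arma::uword)(dx ? i1[0] : i0[0]) +
                  X * ((arma::uword)(dy ? i1[1] : i0[1]) +
                       Y * (arma::uword)(dz ? i1[2] : i0[2]));
              acc += wgt * xp[i];
            }
        op[n] = acc;
      }
  return out;
}
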