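// Low-level 3D CNN kernels: im2col convolution, pooling, nearest-neighbour
// upsampling, batch normalisation and leaky-ReLU, all operating on R arrays
// laid out (x, y, z, channel, sample) in column-major order.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static NumericVector alloc5(int a, int b, int c, int d, int e) {
  NumericVector out((R_xlen_t)a * b * c * d * e);
  out.attr("dim") = IntegerVector::create(a, b, c, d, e);
  return out;
}

// Unpack one sample (X,Y,Z,Cin) into a P x K patch matrix,
// K = k^3 * Cin, P = Xo*Yo*Zo; out-of-bounds voxels contribute 0.
// P-major layout keeps the inner loop writing contiguous memory.
static void im2col(const double* x, int X, int Y, int Z, int Cin,
                   int k, int stride, int pad,
                   int Xo, int Yo, int Zo, arma::mat& col) {
  const int P = (int)col.n_rows;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)ci * X * Y * Z;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          const int r = dx + k * (dy + k * (dz + k * ci));
          double* cr = col.colptr(r);
          int p = 0;
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride - pad + dz;
            const bool zok = (zi >= 0 && zi < Z);
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - pad + dy;
              if (!zok || yi < 0 || yi >= Y) {
                for (int xo = 0; xo < Xo; ++xo, ++p) cr[p] = 0.0;
                continue;
              }
              const double* slab = xc + ((size_t)zi * Y + yi) * X;
              if (stride == 1 && pad <= dx && Xo - 1 + dx - pad < X) {
                const double* src = slab + dx - pad;
                for (int xo = 0; xo < Xo; ++xo, ++p) cr[p] = src[xo];
              } else {
                for (int xo = 0; xo < Xo; ++xo, ++p) {
                  const int xi = xo * stride - pad + dx;
                  cr[p] = (xi >= 0 && xi < X) ? slab[xi] : 0.0;
                }
              }
            }
          }
        }
  }
}

// Scatter-accumulate the P x K patch matrix back onto the input grid.
static void col2im(const arma::mat& col, double* gx,
                   int X, int Y, int Z, int Cin,
                   int k, int stride, int pad,
                   int Xo, int Yo, int Zo) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = gx + (size_t)ci * X * Y * Z;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          const int r = dx + k * (dy + k * (dz + k * ci));
          const double* cr = col.colptr(r);
          int p = 0;
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * stride - pad + dz;
            if (zi < 0 || zi >= Z) { p += Xo * Yo; continue; }
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - pad + dy;
              if (yi < 0 || yi >= Y) { p += Xo; continue; }
              double* slab = xc + ((size_t)zi * Y + yi) * X;
              if (stride == 1 && pad <= dx && Xo - 1 + dx - pad < X) {
                double* dst = slab + dx - pad;
                for (int xo = 0; xo < Xo; ++xo, ++p) dst[xo] += cr[p];
              } else {
                for (int xo = 0; xo < Xo; ++xo, ++p) {
                  const int xi = xo * stride - pad + dx;
                  if (xi >= 0 && xi < X) slab[xi] += cr[p];
                }
              }
            }
          }
        }
  }
}


// ---- direct convolution paths -------------------------------------------
// Specialised kernels for the two convolutions the networks actually use:
// 3^3 with pad 1 (stride 1 or 2) and 1^3 with pad 0.  They avoid the 27x
// patch materialisation of im2col, which dominates at small channel counts.

static inline void k3_bounds(int d, int stride, int X, int Xo,
                             int& lo, int& hi) {
  // valid output range where xi = xo*stride + d - 1 lies in [0, X)
  lo = 0;
  while (lo < Xo && lo * stride + d - 1 < 0) ++lo;
  hi = Xo - 1;
  while (hi >= 0 && hi * stride + d - 1 > X - 1) --hi;
}

static void conv_k3_fwd_one(const double* x, const double* w,
                            const double* b, double* out,
                            int X, int Y, int Z, int Cin, int Cout,
                            int s, int Xo, int Yo, int Zo) {
  const size_t Pi = (size_t)X * Y * Z, Po = (size_t)Xo * Yo * Zo;
  std::vector<double> acc(Xo);
  for (int co = 0; co < Cout; ++co) {
    double* oc = out + (size_t)co * Po;
    const double* wco = w + 27 * (size_t)co * Cin;
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo) {
        std::fill(acc.begin(), acc.end(), b[co]);
        for (int ci = 0; ci < Cin; ++ci) {
          const double* ic = x + (size_t)ci * Pi;
          const double* wp = wco + 27 * ci;
          for (int dz = 0; dz < 3; ++dz) {
            const int zi = zo * s + dz - 1;
            if (zi < 0 || zi >= Z) continue;
            for (int dy = 0; dy < 3; ++dy) {
              const int yi = yo * s + dy - 1;
              if (yi < 0 || yi >= Y) continue;
              const double* irow = ic + ((size_t)zi * Y + yi) * X;
              const double* w3 = wp + 3 * (dy + 3 * dz);
              const double w0 = w3[0], w1 = w3[1], w2 = w3[2];
              if (s == 1) {
                // fused three-tap pass; x edges handled separately
                acc[0] += w1 * irow[0] + w2 * irow[1];
                for (int xo = 1; xo < Xo - 1; ++xo)
                  acc[xo] += w0 * irow[xo - 1] + w1 * irow[xo] +
                             w2 * irow[xo + 1];
                acc[Xo - 1] += w0 * irow[Xo - 2] + w1 * irow[Xo - 1];
              } else {
                acc[0] += w1 * irow[0] + w2 * irow[1];
                const int hi = (2 * (Xo - 1) + 1 <= X - 1) ? Xo - 1 : Xo - 2;
                for (int xo = 1; xo <= hi; ++xo) {
                  const double* src = irow + 2 * xo;
                  acc[xo] += w0 * src[-1] + w1 * src[0] + w2 * src[1];
                }
                if (hi == Xo - 2) {
                  const double* src = irow + 2 * (Xo - 1);
                  acc[Xo - 1] += w0 * src[-1] + w1 * src[0];
                }
              }
            }
          }
        }
        double* orow = oc + ((size_t)zo * Yo + yo) * Xo;
        std::copy(acc.begin(), acc.end(), orow);
      }
  }
}

static inline int dx_idx(int dx, int dy, int dz) {
  return dx + 3 * (dy + 3 * dz);
}

static void conv_k3_bwd_one(const double* x, const double* w,
                            const double* go, double* gw, double* gb,
                            double* gx,  // may be null
                            int X, int Y, int Z, int Cin, int Cout,
                            int s, int Xo, int Yo, int Zo) {
  const size_t Pi = (size_t)X * Y * Z, Po = (size_t)Xo * Yo * Zo;
  for (int co = 0; co < Cout; ++co) {
    const double* gc = go + (size_t)co * Po;
    double acc_b = 0.0;
    for (size_t i = 0; i < Po; ++i) acc_b += gc[i];
    gb[co] += acc_b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* ic = x + (size_t)ci * Pi;
      double* gxc = gx ? gx + (size_t)ci * Pi : (double*)0;
      const double* wp = w + 27 * ((size_t)co * Cin + ci);
      double* gwp = gw + 27 * ((size_t)co * Cin + ci);
      for (int dz = 0; dz < 3; ++dz)
        for (int dy = 0; dy < 3; ++dy) {
          const double* w3 = wp + 3 * (dy + 3 * dz);
          const double w0 = w3[0], w1 = w3[1], w2 = w3[2];
          double a0 = 0.0, a1 = 0.0, a2 = 0.0;
          for (int zo = 0; zo < Zo; ++zo) {
            const int zi = zo * s + dz - 1;
            if (zi < 0 || zi >= Z) continue;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * s + dy - 1;
              if (yi < 0 || yi >= Y) continue;
              const double* irow = ic + ((size_t)zi * Y + yi) * X;
              const double* grow = gc + ((size_t)zo * Yo + yo) * Xo;
              double* gxrow = gxc ? gxc + ((size_t)zi * Y + yi) * X
                                  : (double*)0;
              // xo = 0: only taps with xi >= 0 contribute
              {
                const double gv = grow[0];
                a1 += gv * irow[0];
                a2 += gv * irow[1];
                if (gxrow) { gxrow[0] += w1 * gv; gxrow[1] += w2 * gv; }
              }
              if (s == 1) {
                for (int xo = 1; xo < Xo - 1; ++xo) {
                  const double gv = grow[xo];
                  const double* src = irow + xo;
                  a0 += gv * src[-1]; a1 += gv * src[0]; a2 += gv * src[1];
                  if (gxrow) {
                    double* dst = gxrow + xo;
                    dst[-1] += w0 * gv; dst[0] += w1 * gv; dst[1] += w2 * gv;
                  }
                }
                {
                  const double gv = grow[Xo - 1];
                  a0 += gv * irow[Xo - 2]; a1 += gv * irow[Xo - 1];
                  if (gxrow) {
                    gxrow[Xo - 2] += w0 * gv;
                    gxrow[Xo - 1] += w1 * gv;
                  }
                }
              } else {
                for (int xo = 1; xo < Xo; ++xo) {
                  const double gv = grow[xo];
                  const double* src = irow + 2 * xo;
                  a0 += gv * src[-1]; a1 += gv * src[0]; a2 += gv * src[1];
                  if (gxrow) {
                    double* dst = gxrow + 2 * xo;
                    dst[-1] += w0 * gv; dst[0] += w1 * gv; dst[1] += w2 * gv;
                  }
                }
              }
            }
          }
          gwp[dx_idx(0, dy, dz)] += a0;
          gwp[dx_idx(1, dy, dz)] += a1;
          gwp[dx_idx(2, dy, dz)] += a2;
        }
    }
  }
}

// gather the stride-2 sub-grid of one sample into a P_out x Cin matrix
static void gather_stride2(const double* x, int X, int Y, int Z, int Cin,
                           int Xo, int Yo, int Zo, arma::mat& m) {
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)ci * X * Y * Z;
    double* col = m.colptr(ci);
    size_t p = 0;
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo) {
        const double* row = xc + ((size_t)(2 * zo) * Y + 2 * yo) * X;
        for (int xo = 0; xo < Xo; ++xo, ++p) col[p] = row[2 * xo];
      }
  }
}

static void scatter_stride2(const arma::mat& m, double* gx,
                            int X, int Y, int Z, int Cin,
                            int Xo, int Yo, int Zo) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = gx + (size_t)ci * X * Y * Z;
    const double* col = m.colptr(ci);
    size_t p = 0;
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo) {
        double* row = xc + ((size_t)(2 * zo) * Y + 2 * yo) * X;
        for (int xo = 0; xo < Xo; ++xo, ++p) row[2 * xo] += col[p];
      }
  }
}

static IntegerVector dims5(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 5) stop("expected a 5-d array (x, y, z, channel, sample)");
  return d;
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector dx = dims5(x), dw = dims5(w);
  const int X = dx[0], Y = dx[1], Z = dx[2], Cin = dx[3], N = dx[4];
  const int k = dw[0], Cout = dw[4];
  if (dw[3] != Cin) stop("input channel mismatch in conv3d");
  const int Xo = out_size(X, k, stride, pad), Yo = out_size(Y, k, stride, pad),
            Zo = out_size(Z, k, stride, pad);
  const int K = k * k * k * Cin, P = Xo * Yo * Zo;
  const int Pi = X * Y * Z;

  NumericVector out = alloc5(Xo, Yo, Zo, Cout, N);
  arma::vec bias(b.begin(), Cout, false, true);
  const size_t in_stride = (size_t)Pi * Cin;
  const size_t out_stride = (size_t)P * Cout;

  if (k == 3 && pad == 1 && (stride == 1 || stride == 2)) {
    for (int n = 0; n < N; ++n)
      conv_k3_fwd_one(x.begin() + n * in_stride, w.begin(), b.begin(),
                      out.begin() + n * out_stride, X, Y, Z, Cin, Cout,
                      stride, Xo, Yo, Zo);
    return out;
  }
  arma::mat Wk(w.begin(), K, Cout, false, true);
  if (k == 1 && pad == 0 && stride == 1) {
    for (int n = 0; n < N; ++n) {
      arma::mat xm((double*)x.begin() + n * in_stride, P, Cin, false, true);
      arma::mat o(out.begin() + n * out_stride, P, Cout, false, true);
      o = xm * Wk;
      o.each_row() += bias.t();
    }
    return out;
  }
  if (k == 1 && pad == 0 && stride == 2) {
    arma::mat xm(P, Cin);
    for (int n = 0; n < N; ++n) {
      gather_stride2(x.begin() + n * in_stride, X, Y, Z, Cin, Xo, Yo, Zo,
                     xm);
      arma::mat o(out.begin() + n * out_stride, P, Cout, false, true);
      o = xm * Wk;
      o.each_row() += bias.t();
    }
    return out;
  }
  // generic im2col fallback
  arma::mat col(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * in_stride, X, Y, Z, Cin, k, stride, pad,
           Xo, Yo, Zo, col);
    arma::mat o(out.begin() + n * out_stride, P, Cout, false, true);
    o = col * Wk;
    o.each_row() += bias.t();
  }
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                int stride, int pad, bool need_gx) {
  IntegerVector dx = dims5(x), dw = dims5(w), dg = dims5(gout);
  const int X = dx[0], Y = dx[1], Z = dx[2], Cin = dx[3], N = dx[4];
  const int k = dw[0], Cout = dw[4];
  const int Xo = dg[0], Yo = dg[1], Zo = dg[2];
  const int K = k * k * k * Cin, P = Xo * Yo * Zo;
  const int Pi = X * Y * Z;

  NumericVector gw = alloc5(k, k, k, Cin, Cout);
  NumericVector gb(Cout);
  NumericVector gx;
  if (need_gx) gx = alloc5(X, Y, Z, Cin, N);
  const size_t in_stride = (size_t)Pi * Cin;
  const size_t out_stride = (size_t)P * Cout;

  if (k == 3 && pad == 1 && (stride == 1 || stride == 2)) {
    for (int n = 0; n < N; ++n)
      conv_k3_bwd_one(x.begin() + n * in_stride, w.begin(),
                      (double*)gout.begin() + n * out_stride, gw.begin(),
                      gb.begin(),
                      need_gx ? gx.begin() + n * in_stride : (double*)0,
                      X, Y, Z, Cin, Cout, stride, Xo, Yo, Zo);
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  arma::mat Wk(w.begin(), K, Cout, false, true);
  arma::mat Gw(gw.begin(), K, Cout, false, true);
  arma::vec Gb(gb.begin(), Cout, false, true);
  if (k == 1 && pad == 0 && (stride == 1 || stride == 2)) {
    arma::mat xm;
    if (stride == 2) xm.set_size(P, Cin);
    for (int n = 0; n < N; ++n) {
      arma::mat g((double*)gout.begin() + n * out_stride, P, Cout, false,
                  true);
      if (stride == 1) {
        arma::mat x1((double*)x.begin() + n * in_stride, P, Cin, false,
                     true);
        Gw += x1.t() * g;
      } else {
        gather_stride2(x.begin() + n * in_stride, X, Y, Z, Cin, Xo, Yo, Zo,
                       xm);
        Gw += xm.t() * g;
      }
      Gb += arma::sum(g, 0).t();
      if (need_gx) {
        if (stride == 1) {
          arma::mat gi(gx.begin() + n * in_stride, P, Cin, false, true);
          gi += g * Wk.t();
        } else {
          arma::mat gi = g * Wk.t();
          scatter_stride2(gi, gx.begin() + n * in_stride, X, Y, Z, Cin,
                          Xo, Yo, Zo);
        }
      }
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  arma::mat col(P, K), gcol(P, K);
  for (int n = 0; n < N; ++n) {
    arma::mat g((double*)gout.begin() + n * out_stride, P, Cout, false, true);
    im2col(x.begin() + n * in_stride, X, Y, Z, Cin, k, stride, pad,
           Xo, Yo, Zo, col);
    Gw += col.t() * g;
    Gb += arma::sum(g, 0).t();
    if (need_gx) {
      gcol = g * Wk.t();
      col2im(gcol, gx.begin() + n * in_stride, X, Y, Z, Cin, k, stride, pad,
             Xo, Yo, Zo);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x, int k, int stride) {
  IntegerVector d = dims5(x);
  const int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  const int Xo = X / stride, Yo = Y / stride, Zo = Z / stride;
  NumericVector out = alloc5(Xo, Yo, Zo, C, N);
  IntegerVector idx(out.size());  // 0-based linear index into x
  const size_t plane = (size_t)X * Y;
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * X * Y * Z;
      for (int zo = 0; zo < Zo; ++zo)
        for (int yo = 0; yo < Yo; ++yo)
          for (int xo = 0; xo < Xo; ++xo, ++o) {
            double best = -std::numeric_limits<double>::infinity();
            size_t besti = 0;
            for (int dz = 0; dz < k; ++dz) {
              const int zi = zo * stride + dz; if (zi >= Z) break;
              for (int dy = 0; dy < k; ++dy) {
                const int yi = yo * stride + dy; if (yi >= Y) break;
                for (int dxx = 0; dxx < k; ++dxx) {
                  const int xi = xo * stride + dxx; if (xi >= X) break;
                  const size_t i = base + (size_t)zi * plane + (size_t)yi * X + xi;
                  if (x[i] > best) { best = x[i]; besti = i; }
                }
              }
            }
            out[o] = best;
            idx[o] = (int)besti;
          }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector g, IntegerVector idx,
                            IntegerVector in_dim) {
  NumericVector gx = alloc5(in_dim[0], in_dim[1], in_dim[2], in_dim[3],
                             in_dim[4]);
  for (R_xlen_t i = 0; i < g.size(); ++i) gx[idx[i]] += g[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector avgpool3d_fwd(NumericVector x, int k, int stride) {
  IntegerVector d = dims5(x);
  const int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  const int Xo = X / stride, Yo = Y / stride, Zo = Z / stride;
  NumericVector out = alloc5(Xo, Yo, Zo, C, N);
  const double inv = 1.0 / (k * k * k);
  const size_t plane = (size_t)X * Y;
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * X * Y * Z;
      for (int zo = 0; zo < Zo; ++zo)
        for (int yo = 0; yo < Yo; ++yo)
          for (int xo = 0; xo < Xo; ++xo, ++o) {
            double s = 0.0;
            for (int dz = 0; dz < k; ++dz)
              for (int dy = 0; dy < k; ++dy)
                for (int dxx = 0; dxx < k; ++dxx)
                  s += x[base + (size_t)(zo * stride + dz) * plane +
                         (size_t)(yo * stride + dy) * X + (xo * stride + dxx)];
            out[o] = s * inv;
          }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool3d_bwd(NumericVector g, IntegerVector in_dim,
                            int k, int stride) {
  const int X = in_dim[0], Y = in_dim[1], Z = in_dim[2], C = in_dim[3],
            N = in_dim[4];
  const int Xo = X / stride, Yo = Y / stride, Zo = Z / stride;
  NumericVector gx = alloc5(X, Y, Z, C, N);
  const double inv = 1.0 / (k * k * k);
  const size_t plane = (size_t)X * Y;
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * X * Y * Z;
      for (int zo = 0; zo < Zo; ++zo)
        for (int yo = 0; yo < Yo; ++yo)
          for (int xo = 0; xo < Xo; ++xo, ++o) {
            const double v = g[o] * inv;
            for (int dz = 0; dz < k; ++dz)
              for (int dy = 0; dy < k; ++dy)
                for (int dxx = 0; dxx < k; ++dxx)
                  gx[base + (size_t)(zo * stride + dz) * plane +
                     (size_t)(yo * stride + dy) * X + (xo * stride + dxx)] += v;
          }
    }
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample3d_fwd(NumericVector x, int f) {
  IntegerVector d = dims5(x);
  const int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  const int Xo = X * f, Yo = Y * f, Zo = Z * f;
  NumericVector out = alloc5(Xo, Yo, Zo, C, N);
  const size_t plane_o = (size_t)Xo * Yo;
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * plane_o * Zo;
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
          for (int x0 = 0; x0 < X; ++x0, ++i) {
            const double v = x[i];
            for (int dz = 0; dz < f; ++dz)
              for (int dy = 0; dy < f; ++dy)
                for (int dxx = 0; dxx < f; ++dxx)
                  out[base + (size_t)(z * f + dz) * plane_o +
                      (size_t)(y * f + dy) * Xo + (x0 * f + dxx)] = v;
          }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector upsample3d_bwd(NumericVector g, int f) {
  IntegerVector d = dims5(g);
  const int Xo = d[0], Yo = d[1], Zo = d[2], C = d[3], N = d[4];
  const int X = Xo / f, Y = Yo / f, Z = Zo / f;
  NumericVector gx = alloc5(X, Y, Z, C, N);
  const size_t plane_o = (size_t)Xo * Yo;
  size_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * plane_o * Zo;
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
          for (int x0 = 0; x0 < X; ++x0, ++i) {
            double s = 0.0;
            for (int dz = 0; dz < f; ++dz)
              for (int dy = 0; dy < f; ++dy)
                for (int dxx = 0; dxx < f; ++dxx)
                  s += g[base + (size_t)(z * f + dz) * plane_o +
                         (size_t)(y * f + dy) * Xo + (x0 * f + dxx)];
            gx[i] = s;
          }
    }
  return gx;
}

// Batch normalisation over (x, y, z, sample) per channel.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            double eps) {
  IntegerVector d = dims5(x);
  const int C = d[3], N = d[4];
  const size_t V = (size_t)d[0] * d[1] * d[2];   // voxels per channel-sample
  const size_t M = V * N;                        // elements per channel
  NumericVector y(x.size());
  y.attr("dim") = d;
  NumericVector mean(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * V;
      for (size_t i = 0; i < V; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    const double mu = s / M;
    double var = s2 / M - mu * mu;
    if (var < 0) var = 0;
    const double is = 1.0 / std::sqrt(var + eps);
    mean[c] = mu; invstd[c] = is;
    const double a = gamma[c] * is, b0 = beta[c] - a * mu;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * V;
      double* yc = y.begin() + ((size_t)n * C + c) * V;
      for (size_t i = 0; i < V; ++i) yc[i] = a * xc[i] + b0;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector x, NumericVector gy, NumericVector gamma,
            NumericVector mean, NumericVector invstd) {
  IntegerVector d = dims5(x);
  const int C = d[3], N = d[4];
  const size_t V = (size_t)d[0] * d[1] * d[2];
  const double M = (double)V * N;
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c];
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * V;
      const double* gc = gy.begin() + ((size_t)n * C + c) * V;
      for (size_t i = 0; i < V; ++i) {
        sg += gc[i];
        sgx += gc[i] * (xc[i] - mu) * is;
      }
    }
    ggamma[c] = sgx; gbeta[c] = sg;
    const double k1 = gamma[c] * is;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * V;
      const double* gc = gy.begin() + ((size_t)n * C + c) * V;
      double* oc = gx.begin() + ((size_t)n * C + c) * V;
      for (size_t i = 0; i < V; ++i) {
        const double xhat = (xc[i] - mu) * is;
        oc[i] = k1 * (gc[i] - (sg + xhat * sgx) / M);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector bn_eval(NumericVector x, NumericVector gamma, NumericVector beta,
                      NumericVector rmean, NumericVector rvar, double eps) {
  IntegerVector d = dims5(x);
  const int C = d[3], N = d[4];
  const size_t V = (size_t)d[0] * d[1] * d[2];
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double a = gamma[c] / std::sqrt(rvar[c] + eps);
    const double b0 = beta[c] - a * rmean[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * V;
      double* yc = y.begin() + ((size_t)n * C + c) * V;
      for (size_t i = 0; i < V; ++i) yc[i] = a * xc[i] + b0;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  double* yi = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    yi[i] = xi[i] > 0 ? xi[i] : slope * xi[i];
  return y;
}

// [[Rcpp::export]]
NumericVector lrelu_bwd(NumericVector y, NumericVector g, double slope) {
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  const double* yi = y.begin();
  const double* gi = g.begin();
  double* oi = gx.begin();
  const R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i)
    oi[i] = yi[i] > 0 ? gi[i] : slope * gi[i];
  return gx;
}
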