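// Low-level neural-network primitives.
//
// Feature maps are stored channel-LAST in column-major R arrays with
// dim = c(nx, ny, nz, C); a 2-D map is the degenerate case nz = 1.
// Convolutions use "same" zero padding and are computed directly,
// row-wise, with no im2col temporary.  Weights for a k-kernel convolution
// are (prod(k) * C_in) x C_out matrices with row index kk + K * c_in,
// kernel offset kk running dx fastest.

#include <Rcpp.h>
using namespace Rcpp;

struct ConvGeom {
  int Cin, nx, ny, nz;
  int kx, ky, kz, px, py, pz, K;
  long n;     // spatial voxels
};

static ConvGeom conv_geom(const IntegerVector& xdim, const IntegerVector& ks) {
  ConvGeom g;
  g.nx = xdim[0]; g.ny = xdim[1]; g.nz = xdim[2]; g.Cin = xdim[3];
  g.kx = ks[0]; g.ky = ks[1]; g.kz = ks[2];
  g.px = (g.kx - 1) / 2; g.py = (g.ky - 1) / 2; g.pz = (g.kz - 1) / 2;
  g.K = g.kx * g.ky * g.kz;
  g.n = (long)g.nx * g.ny * g.nz;
  return g;
}

// Direct convolution: for every output x-row, accumulate the contributions
// of the 3^d shifted input rows of every input channel.  Works row-wise so
// the working set stays in cache and no im2col temporary is materialized.
// Computation runs in float by default (ample for network training) or in
// double when exact gradient verification is wanted.

template <typename T>
static void conv_fw_impl(const double* xd, const ConvGeom& g,
                         const double* Wp, long Wld, const double* b,
                         int Cout, double* outd) {
  std::vector<T> xf(g.n * g.Cin), of(g.n * Cout);
  for (long v = 0; v < g.n * g.Cin; ++v) xf[v] = (T)xd[v];
  const T* xp = xf.data();
  T* op = of.data();
  for (int co = 0; co < Cout; ++co) {
    T* oc = op + g.n * co;
    T bb = (T)b[co];
    for (long v = 0; v < g.n; ++v) oc[v] = bb;
  }
  for (int k = 0; k < g.nz; ++k) {
    for (int j = 0; j < g.ny; ++j) {
      long rb = (long)g.nx * (j + (long)g.ny * k);
      for (int cin = 0; cin < g.Cin; ++cin) {
        const T* xc = xp + g.n * cin;
        for (int dz = 0; dz < g.kz; ++dz) {
          int sk = k + dz - g.pz;
          if (sk < 0 || sk >= g.nz) continue;
          for (int dy = 0; dy < g.ky; ++dy) {
            int sj = j + dy - g.py;
            if (sj < 0 || sj >= g.ny) continue;
            const T* xrow = xc + (long)g.nx * (sj + (long)g.ny * sk);
            for (int co = 0; co < Cout; ++co) {
              T* __restrict yr = op + g.n * co + rb;
              const double* wcol = Wp + Wld * co + g.K * cin +
                                   g.kx * (dy + g.ky * dz);
              const T* __restrict xr = xrow;
              if (g.kx == 3) {
                T w0 = (T)wcol[0], w1 = (T)wcol[1], w2 = (T)wcol[2];
                int nx = g.nx;
                yr[0] += w1 * xr[0] + w2 * xr[1];
#pragma GCC ivdep
                for (int i = 1; i < nx - 1; ++i)
                  yr[i] += w0 * xr[i - 1] + w1 * xr[i] + w2 * xr[i + 1];
                if (nx > 1) yr[nx - 1] += w0 * xr[nx - 2] + w1 * xr[nx - 1];
              } else {
                T w = (T)wcol[0];
#pragma GCC ivdep
                for (int i = 0; i < g.nx; ++i) yr[i] += w * xr[i];
              }
            }
          }
        }
      }
    }
  }
  for (long v = 0; v < g.n * Cout; ++v) outd[v] = (double)of[v];
}

// [[Rcpp::export]]
NumericVector nn_conv_fw(NumericVector x, IntegerVector xdim,
                         NumericMatrix W, NumericVector b, IntegerVector ks,
                         bool use_double = false) {
  ConvGeom g = conv_geom(xdim, ks);
  int Cout = W.ncol();
  if (W.nrow() != g.Cin * g.K) stop("conv: weight shape mismatch");
  NumericVector out(g.n * Cout);
  if (use_double)
    conv_fw_impl<double>(REAL(x), g, REAL(W), W.nrow(), REAL(b), Cout, REAL(out));
  else
    conv_fw_impl<float>(REAL(x), g, REAL(W), W.nrow(), REAL(b), Cout, REAL(out));
  return out;
}

template <typename T>
static void conv_bw_impl(const double* xd, const ConvGeom& g,
                         const double* Wp, long Wld, int Cout,
                         const double* dyd, double* dWp, double* dbp,
                         double* dxd) {
  std::vector<T> xf(g.n * g.Cin), df(g.n * Cout), gf(g.n * g.Cin, (T)0);
  for (long v = 0; v < g.n * g.Cin; ++v) xf[v] = (T)xd[v];
  for (long v = 0; v < g.n * Cout; ++v) df[v] = (T)dyd[v];
  const T* xp = xf.data();
  const T* dp = df.data();
  T* gp = gf.data();
  for (int co = 0; co < Cout; ++co) {
    const T* dc = dp + g.n * co;
    double s = 0.0;
    for (long v = 0; v < g.n; ++v) s += dc[v];
    dbp[co] = s;
  }
  for (int k = 0; k < g.nz; ++k) {
    for (int j = 0; j < g.ny; ++j) {
      long rb = (long)g.nx * (j + (long)g.ny * k);
      for (int cin = 0; cin < g.Cin; ++cin) {
        const T* xc = xp + g.n * cin;
        T* dxc = gp + g.n * cin;
        for (int dz = 0; dz < g.kz; ++dz) {
          int sk = k + dz - g.pz;
          if (sk < 0 || sk >= g.nz) continue;
          for (int dy_ = 0; dy_ < g.ky; ++dy_) {
            int sj = j + dy_ - g.py;
            if (sj < 0 || sj >= g.ny) continue;
            long srb = (long)g.nx * (sj + (long)g.ny * sk);
            const T* xrow = xc + srb;
            T* dxrow = dxc + srb;
            for (int co = 0; co < Cout; ++co) {
              const T* __restrict dr = dp + g.n * co + rb;
              double* dwcol = dWp + Wld * co + g.K * cin +
                              g.kx * (dy_ + g.ky * dz);
              const double* wcol = Wp + Wld * co + g.K * cin +
                                   g.kx * (dy_ + g.ky * dz);
              const T* __restrict xr = xrow;
              T* __restrict ds = dxrow;
              int nx = g.nx;
              if (g.kx == 3) {
                T w0 = (T)wcol[0], w1 = (T)wcol[1], w2 = (T)wcol[2];
                T a0 = 0, a1 = 0, a2 = 0;
                // gather form: ds[i] += w2*dr[i-1] + w1*dr[i] + w0*dr[i+1]
                a1 += xr[0] * dr[0];
                if (nx > 1) {
                  a2 += xr[1] * dr[0];
                  ds[0] += w1 * dr[0] + w0 * dr[1];
                } else {
                  ds[0] += w1 * dr[0];
                }
#pragma GCC ivdep
                for (int i = 1; i < nx - 1; ++i) {
                  T d = dr[i];
                  a0 += xr[i - 1] * d;
                  a1 += xr[i] * d;
                  a2 += xr[i + 1] * d;
                  ds[i] += w2 * dr[i - 1] + w1 * d + w0 * dr[i + 1];
                }
                if (nx > 1) {
                  T d = dr[nx - 1];
                  a0 += xr[nx - 2] * d;
                  a1 += xr[nx - 1] * d;
                  ds[nx - 1] += w2 * dr[nx - 2] + w1 * d;
                }
                dwcol[0] += a0; dwcol[1] += a1; dwcol[2] += a2;
              } else {
                T w = (T)wcol[0];
                T acc = 0;
#pragma GCC ivdep
                for (int i = 0; i < nx; ++i) {
                  acc += xr[i] * dr[i];
                  ds[i] += w * dr[i];
                }
                dwcol[0] += acc;
              }
            }
          }
        }
      }
    }
  }
  for (long v = 0; v < g.n * g.Cin; ++v) dxd[v] = (double)gf[v];
}

// [[Rcpp::export]]
List nn_conv_bw(NumericVector x, IntegerVector xdim, NumericMatrix W,
                IntegerVector ks, NumericVector dy, bool use_double = false) {
  ConvGeom g = conv_geom(xdim, ks);
  int Cout = W.ncol();
  NumericMatrix dW(W.nrow(), Cout);
  NumericVector db(Cout);
  NumericVector dx(g.n * g.Cin);
  if (use_double)
    conv_bw_impl<double>(REAL(x), g, REAL(W), W.nrow(), Cout, REAL(dy),
                         REAL(dW), REAL(db), REAL(dx));
  else
    conv_bw_impl<float>(REAL(x), g, REAL(W), W.nrow(), Cout, REAL(dy),
                        REAL(dW), REAL(db), REAL(dx));
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Max pooling with per-axis factors f = (fx, fy, fz); sizes must divide.
// [[Rcpp::export]]
List nn_pool_fw(NumericVector x, IntegerVector xdim, IntegerVector f) {
  int nx = xdim[0], ny = xdim[1], nz = xdim[2], C = xdim[3];
  int fx = f[0], fy = f[1], fz = f[2];
  int ox = nx / fx, oy = ny / fy, oz = nz / fz;
  if (ox * fx != nx || oy * fy != ny || oz * fz != nz)
    stop("pool: size not divisible by factor");
  long n = (long)nx * ny * nz, no = (long)ox * oy * oz;
  NumericVector y(no * C);
  IntegerVector idx(no * C);
  const double* xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + n * c;
    double* yc = REAL(y) + no * c;
    int* ic = INTEGER(idx) + no * c;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i) {
          double best = -1e300; long bestIdx = -1;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx) {
                long sv = (i * fx + dx) +
                  (long)nx * ((j * fy + dy) + (long)ny * (k * fz + dz));
                if (xc[sv] > best) { best = xc[sv]; bestIdx = sv; }
              }
          long ov = i + (long)ox * (j + (long)oy * k);
          yc[ov] = best;
          ic[ov] = (int)(bestIdx + n * c);
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_pool_bw(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  long nx = (long)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  for (long i = 0; i < idx.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// Nearest-neighbour upsampling by per-axis factors.
// [[Rcpp::export]]
NumericVector nn_upsample_fw(NumericVector x, IntegerVector xdim, IntegerVector f) {
  int nx = xdim[0], ny = xdim[1], nz = xdim[2], C = xdim[3];
  int fx = f[0], fy = f[1], fz = f[2];
  int ox = nx * fx, oy = ny * fy, oz = nz * fz;
  long n = (long)nx * ny * nz, no = (long)ox * oy * oz;
  NumericVector y(no * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = REAL(x) + n * c;
    double* yc = REAL(y) + no * c;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j) {
        const double* row = xc + (long)nx * ((j / fy) + (long)ny * (k / fz));
        double* dst = yc + (long)ox * (j + (long)oy * k);
        for (int i = 0; i < ox; ++i) dst[i] = row[i / fx];
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample_bw(NumericVector dy, IntegerVector xdim, IntegerVector f) {
  int nx = xdim[0], ny = xdim[1], nz = xdim[2], C = xdim[3];
  int fx = f[0], fy = f[1], fz = f[2];
  int ox = nx * fx, oy = ny * fy, oz = nz * fz;
  long n = (long)nx * ny * nz, no = (long)ox * oy * oz;
  NumericVector dx(n * C);
  for (int c = 0; c < C; ++c) {
    double* xc = REAL(dx) + n * c;
    const double* dc = REAL(dy) + no * c;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j) {
        double* row = xc + (long)nx * ((j / fy) + (long)ny * (k / fz));
        const double* src = dc + (long)ox * (j + (long)oy * k);
        for (int i = 0; i < ox; ++i) row[i / fx] += src[i];
      }
  }
  return dx;
}

// Per-channel spatial normalization (batch norm over one sample's spatial
// extent), fused to avoid R-level temporaries.
// [[Rcpp::export]]
List nn_norm_fw(NumericVector x, IntegerVector xdim,
                NumericVector gamma, NumericVector beta, double eps) {
  long n = (long)xdim[0] * xdim[1] * xdim[2];
  int C = xdim[3];
  NumericVector y(n * C), xhat(n * C), istd(C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double* hp = REAL(xhat);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + n * c;
    double* yc = yp + n * c;
    double* hc = hp + n * c;
    double mu = 0.0;
    for (long v = 0; v < n; ++v) mu += xc[v];
    mu /= n;
    double var = 0.0;
    for (long v = 0; v < n; ++v) { double d = xc[v] - mu; var += d * d; }
    var /= n;
    double is = 1.0 / std::sqrt(var + eps);
    istd[c] = is;
    double g = gamma[c], b = beta[c];
    for (long v = 0; v < n; ++v) {
      double h = (xc[v] - mu) * is;
      hc[v] = h;
      yc[v] = g * h + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List nn_norm_bw(NumericVector xhat, IntegerVector xdim, NumericVector gamma,
                NumericVector istd, NumericVector dy) {
  long n = (long)xdim[0] * xdim[1] * xdim[2];
  int C = xdim[3];
  NumericVector dgamma(C), dbeta(C), dx(n * C);
  const double* hp = REAL(xhat);
  const double* dp = REAL(dy);
  double* gp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    const double* hc = hp + n * c;
    const double* dc = dp + n * c;
    double* xc = gp + n * c;
    double sg = 0.0, sb = 0.0;
    for (long v = 0; v < n; ++v) { sg += dc[v] * hc[v]; sb += dc[v]; }
    dgamma[c] = sg; dbeta[c] = sb;
    double a = gamma[c] * istd[c];
    double mb = sb / n, mg = sg / n;
    for (long v = 0; v < n; ++v)
      xc[v] = a * (dc[v] - mb - hc[v] * mg);
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta, _["dx"] = dx);
}

// Fused ReLU (in place on a copy).
// [[Rcpp::export]]
NumericVector nn_relu(NumericVector x) {
  NumericVector y = clone(x);
  double* yp = REAL(y);
  for (long v = 0; v < y.size(); ++v) if (yp[v] < 0) yp[v] = 0;
  return y;
}

// 1x1 convolution (channel mixing): y = x W + b, x: (n x Cin) channel-last.
// [[Rcpp::export]]
NumericVector nn_mix_fw(NumericVector x, IntegerVector xdim,
                        NumericMatrix W, NumericVector b) {
  long n = (long)xdim[0] * xdim[1] * xdim[2];
  int Cin = xdim[3], Cout = W.ncol();
  if (W.nrow() != Cin) stop("mix: weight shape mismatch");
  NumericVector y(n * Cout);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int co = 0; co < Cout; ++co) {
    double* yc = yp + n * co;
    double bb = b[co];
    for (long v = 0; v < n; ++v) yc[v] = bb;
    for (int ci = 0; ci < Cin; ++ci) {
      double w = W(ci, co);
      const double* xc = xp + n * ci;
      for (long v = 0; v < n; ++v) yc[v] += w * xc[v];
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_mix_bw(NumericVector x, IntegerVector xdim, NumericMatrix W,
               NumericVector dy) {
  long n = (long)xdim[0] * xdim[1] * xdim[2];
  int Cin = xdim[3], Cout = W.ncol();
  NumericMatrix dW(Cin, Cout);
  NumericVector db(Cout), dx(n * Cin);
  const double* xp = REAL(x);
  const double* dp = REAL(dy);
  double* gp = REAL(dx);
  for (int co = 0; co < Cout; ++co) {
    const double* dc = dp + n * co;
    double s = 0.0;
    for (long v = 0; v < n; ++v) s += dc[v];
    db[co] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + n * ci;
      double* xg = gp + n * ci;
      double w = W(ci, co);
      double acc = 0.0;
      for (long v = 0; v < n; ++v) {
        acc += xc[v] * dc[v];
        xg[v] += w * dc[v];
      }
      dW(ci, co) = acc;
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// dx = dy * (y > 0), the ReLU mask backward.
// [[Rcpp::export]]
NumericVector nn_relu_bw(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  const double* dp = REAL(dy);
  const double* yp = REAL(y);
  double* xp = REAL(dx);
  for (long v = 0; v < dy.size(); ++v) xp[v] = yp[v] > 0 ? dp[v] : 0.0;
  return dx;
}
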