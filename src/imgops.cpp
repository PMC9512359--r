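// Grid resampling, connected components, surface distances and in-plane
// affine sampling.  Scalar volumes are plain column-major arrays with
// dim = c(nx, ny, nz); world coordinate of voxel (i,j,k) (0-based) is
// origin + index * spacing componentwise.

#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector resample_grid(NumericVector src, IntegerVector sdim,
                            NumericVector sspac, NumericVector sorig,
                            IntegerVector odim, NumericVector ospac,
                            NumericVector oorig, bool nearest) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((long)ox * oy * oz);
  const double* sp = REAL(src);
  long pos = 0;
  for (int k = 0; k < oz; ++k) {
    double wz = oorig[2] + k * ospac[2];
    double uz = (wz - sorig[2]) / sspac[2];
    for (int j = 0; j < oy; ++j) {
      double wy = oorig[1] + j * ospac[1];
      double uy = (wy - sorig[1]) / sspac[1];
      for (int i = 0; i < ox; ++i, ++pos) {
        double wx = oorig[0] + i * ospac[0];
        double ux = (wx - sorig[0]) / sspac[0];
        if (nearest) {
          int si = (int)std::lround(ux), sj = (int)std::lround(uy), sk = (int)std::lround(uz);
          if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz) continue;
          out[pos] = sp[si + (long)nx * (sj + (long)ny * sk)];
        } else {
          int i0 = (int)std::floor(ux), j0 = (int)std::floor(uy), k0 = (int)std::floor(uz);
          double fx = ux - i0, fy = uy - j0, fz = uz - k0;
          double acc = 0.0;
          for (int dk = 0; dk < 2; ++dk) {
            int kk = k0 + dk;
            if (kk < 0 || kk >= nz) continue;
            double wk = dk ? fz : 1.0 - fz;
            for (int dj = 0; dj < 2; ++dj) {
              int jj = j0 + dj;
              if (jj < 0 || jj >= ny) continue;
              double wj = dj ? fy : 1.0 - fy;
              for (int di = 0; di < 2; ++di) {
                int ii = i0 + di;
                if (ii < 0 || ii >= nx) continue;
                double wi = di ? fx : 1.0 - fx;
                acc += wi * wj * wk * sp[ii + (long)nx * (jj + (long)ny * kk)];
              }
            }
          }
          out[pos] = acc;
        }
      }
    }
  }
  return out;
}

// Connected-component labelling with full diagonal connectivity
// (26-connected in 3-D; for nz = 1 this reduces to 8-connected in 2-D).
// [[Rcpp::export]]
IntegerVector cc_label(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((long)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            long u = ii + (long)nx * (jj + (long)ny * kk);
            if (mask[u] != 0 && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
          }
        }
      }
    }
  }
  return lab;
}

// Surface voxels: foreground with at least one of the 6 face neighbours
// background (the volume border counts as background).
// [[Rcpp::export]]
LogicalVector surface_mask(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  LogicalVector out(n);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (long v = 0; v < n; ++v) {
    if (mask[v] == 0) continue;
    int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((long)nx * ny));
    bool surf = false;
    for (int t = 0; t < 6 && !surf; ++t) {
      int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) { surf = true; break; }
      if (mask[ii + (long)nx * (jj + (long)ny * kk)] == 0) surf = true;
    }
    out[v] = surf;
  }
  return out;
}

// For each row of A (world mm), the distance to the nearest row of B.
// [[Rcpp::export]]
NumericVector directed_surface_dists(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int a = 0; a < na; ++a) {
    double ax = A(a, 0), ay = A(a, 1), az = A(a, 2);
    double best = R_PosInf;
    for (int b = 0; b < nb; ++b) {
      double dx = ax - B(b, 0), dy = ay - B(b, 1), dz = az - B(b, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[a] = std::sqrt(best);
  }
  return out;
}

// In-plane rotation about the volume centre followed by translation
// (voxel units), used for training augmentation.  out(v) is sampled at
// R^{-1}(v - shift - c) + c in the source; bilinear in-plane unless nearest.
// [[Rcpp::export]]
NumericVector affine_inplane(NumericVector src, IntegerVector dim,
                             double angle_deg, NumericVector shift_vox,
                             bool nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double th = angle_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  NumericVector out((long)nx * ny * nz);
  const double* sp = REAL(src);
  long pos = 0;
  for (int k = 0; k < nz; ++k) {
    double uz = k - shift_vox[2];
    int k0 = nearest ? (int)std::lround(uz) : (int)std::floor(uz);
    double fz = uz - k0;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++pos) {
        double px = i - shift_vox[0] - cx, py = j - shift_vox[1] - cy;
        double ux = ct * px + st * py + cx;
        double uy = -st * px + ct * py + cy;
        if (nearest) {
          int si = (int)std::lround(ux), sj = (int)std::lround(uy), sk = k0;
          if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz) continue;
          out[pos] = sp[si + (long)nx * (sj + (long)ny * sk)];
        } else {
          int i0 = (int)std::floor(ux), j0 = (int)std::floor(uy);
          double fx = ux - i0, fy = uy - j0;
          double acc = 0.0;
          for (int dk = 0; dk < 2; ++dk) {
            int kk = k0 + dk; if (kk < 0 || kk >= nz) continue;
            double wk = dk ? fz : 1.0 - fz;
            if (wk == 0.0) continue;
            for (int dj = 0; dj < 2; ++dj) {
              int jj = j0 + dj; if (jj < 0 || jj >= ny) continue;
              double wj = dj ? fy : 1.0 - fy;
              for (int di = 0; di < 2; ++di) {
                int ii = i0 + di; if (ii < 0 || ii >= nx) continue;
                double wi = di ? fx : 1.0 - fx;
                acc += wi * wj * wk * sp[ii + (long)nx * (jj + (long)ny * kk)];
              }
            }
          }
          out[pos] = acc;
        }
      }
    }
  }
  return out;
}
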