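// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// separable lower-envelope-of-parabolas algorithm) with anisotropic voxel
// spacing. Distances are between voxel centers, in mm^2.
#include <Rcpp.h>
using namespace Rcpp;

static const double BIG = 1e30;

// One 1D pass: d[q] = min_p ( w2 * (q - p)^2 + f[p] ), w2 = spacing^2.
static void dt1d(const double* f, int n, double w2, double* d,
                 int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      // guard k > 0: with the BIG sentinel and small spacing, s can fall
      // below z[0]; keeping k = 0 and inserting at 1 still yields the
      // correct envelope because the query pass skips dominated segments
      if (k > 0 && s <= z[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (double)(q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(LogicalVector mask, IntegerVector dim,
                          NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  NumericVector out(ntot);
  for (size_t i = 0; i < ntot; ++i) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 0 (x, fastest-varying)
  double w2 = spacing[0] * spacing[0];
  for (int zz = 0; zz < nz; ++zz) {
    for (int yy = 0; yy < ny; ++yy) {
      double* line = out.begin() + (size_t)nx * (yy + (size_t)ny * zz);
      std::copy(line, line + nx, f.begin());
      dt1d(f.data(), nx, w2, d.data(), v.data(), z.data());
      std::copy(d.begin(), d.begin() + nx, line);
    }
  }
  // axis 1 (y)
  w2 = spacing[1] * spacing[1];
  for (int zz = 0; zz < nz; ++zz) {
    for (int xx = 0; xx < nx; ++xx) {
      double* base = out.begin() + xx + (size_t)nx * ny * zz;
      for (int yy = 0; yy < ny; ++yy) f[yy] = base[(size_t)nx * yy];
      dt1d(f.data(), ny, w2, d.data(), v.data(), z.data());
      for (int yy = 0; yy < ny; ++yy) base[(size_t)nx * yy] = d[yy];
    }
  }
  // axis 2 (z)
  w2 = spacing[2] * spacing[2];
  size_t stride = (size_t)nx * ny;
  for (int yy = 0; yy < ny; ++yy) {
    for (int xx = 0; xx < nx; ++xx) {
      double* base = out.begin() + xx + (size_t)nx * yy;
      for (int zz = 0; zz < nz; ++zz) f[zz] = base[stride * zz];
      dt1d(f.data(), nz, w2, d.data(), v.data(), z.data());
      for (int zz = 0; zz < nz; ++zz) base[stride * zz] = d[zz];
    }
  }
  out.attr("dim") = dim;
  return out;
}
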