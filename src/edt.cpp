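#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope-of-parabolas algorithm), separable over the three axes.
// Distances are in voxel units; the morphological ball operations that
// build closed (exposed) surfaces threshold these squared distances.

namespace {

const double INF = std::numeric_limits<double>::infinity();

// assumes at least one finite entry in f
void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
          std::vector<int>& v, std::vector<double>& z) {
  int q0 = 0;
  while (f[q0] == INF) ++q0;
  int k = 0;
  v[0] = q0; z[0] = -INF; z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + q*(double)q) - (f[v[k]] + v[k]*(double)v[k]))
             / (2.0*q - 2.0*v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q*(double)q) - (f[v[k]] + v[k]*(double)v[k]))
        / (2.0*q - 2.0*v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k+1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k+1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq*dq + f[v[k]];
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector squared_edt(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx*ny*nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx*(j + (R_xlen_t)ny*k);
  };
  int nmax = std::max({nx, ny, nz});
  std::vector<double> f(nmax), d(nmax), z(nmax+1);
  std::vector<int> v(nmax);
  // x
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) {
    bool any = false;
    for (int i = 0; i < nx; ++i) { f[i] = g[idx(i,j,k)]; if (f[i] < INF) any = true; }
    if (!any) continue;
    dt1d(f, d, nx, v, z);
    for (int i = 0; i < nx; ++i) g[idx(i,j,k)] = d[i];
  }
  // y
  for (int k = 0; k < nz; ++k) for (int i = 0; i < nx; ++i) {
    bool any = false;
    for (int j = 0; j < ny; ++j) { f[j] = g[idx(i,j,k)]; if (f[j] < INF) any = true; }
    if (!any) continue;
    dt1d(f, d, ny, v, z);
    for (int j = 0; j < ny; ++j) g[idx(i,j,k)] = d[j];
  }
  // z
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    bool any = false;
    for (int k = 0; k < nz; ++k) { f[k] = g[idx(i,j,k)]; if (f[k] < INF) any = true; }
    if (!any) continue;
    dt1d(f, d, nz, v, z);
    for (int k = 0; k < nz; ++k) g[idx(i,j,k)] = d[k];
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = g[i];
  return out;
}
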