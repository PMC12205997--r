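#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Uniform-grid nearest-neighbour structures used for label transfer
// (nearest vertex) and lobe thickness (exact point-to-triangle minimum
// distance). Ring-expansion search with the conservative lower bound
// (ring-1)*cell guarantees exactness; vertex ties resolve to the lowest
// index so label transfer is deterministic.

namespace {

struct Grid {
  double mn[3], cell;
  int n[3];
  std::vector<std::vector<int>> bins;

  void init(const NumericMatrix& V, double cell_size) {
    double mx[3];
    for (int d = 0; d < 3; ++d) { mn[d] = mx[d] = V(0,d); }
    for (int i = 1; i < V.nrow(); ++i) for (int d = 0; d < 3; ++d) {
      mn[d] = std::min(mn[d], V(i,d)); mx[d] = std::max(mx[d], V(i,d));
    }
    cell = cell_size;
    for (int d = 0; d < 3; ++d) {
      n[d] = std::max(1, (int)std::floor((mx[d]-mn[d])/cell) + 1);
      n[d] = std::min(n[d], 512);
    }
    bins.assign((size_t)n[0]*n[1]*n[2], {});
  }
  int clampi(double x, int d) const {
    int i = (int)std::floor((x - mn[d])/cell);
    return std::min(std::max(i, 0), n[d]-1);
  }
  size_t bidx(int i, int j, int k) const {
    return (size_t)i + (size_t)n[0]*(j + (size_t)n[1]*k);
  }
};

// Ericson: closest point on triangle abc to point p
inline double pt_tri_d2(const double* p, const double* a, const double* b,
                        const double* c) {
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) { ab[d]=b[d]-a[d]; ac[d]=c[d]-a[d]; ap[d]=p[d]-a[d]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  auto d2pt = [&](const double* q) {
    double dx=p[0]-q[0], dy=p[1]-q[1], dz=p[2]-q[2];
    return dx*dx+dy*dy+dz*dz;
  };
  if (d1 <= 0 && d2 <= 0) return d2pt(a);
  double bp[3]; for (int d=0; d<3; ++d) bp[d]=p[d]-b[d];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) return d2pt(b);
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1/(d1-d3);
    double q[3]; for (int d=0; d<3; ++d) q[d]=a[d]+t*ab[d];
    return d2pt(q);
  }
  double cp[3]; for (int d=0; d<3; ++d) cp[d]=p[d]-c[d];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) return d2pt(c);
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2/(d2-d6);
    double q[3]; for (int d=0; d<3; ++d) q[d]=a[d]+t*ac[d];
    return d2pt(q);
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4-d3) >= 0 && (d5-d6) >= 0) {
    double t = (d4-d3)/((d4-d3)+(d5-d6));
    double q[3]; for (int d=0; d<3; ++d) q[d]=b[d]+t*(c[d]-b[d]);
    return d2pt(q);
  }
  double denom = 1.0/(va+vb+vc);
  double v = vb*denom, w = vc*denom;
  double q[3]; for (int d=0; d<3; ++d) q[d]=a[d]+ab[d]*v+ac[d]*w;
  return d2pt(q);
}

}  // namespace

// [[Rcpp::export]]
IntegerVector nearest_vertex_idx(NumericMatrix Q, NumericMatrix V) {
  const int nq = Q.nrow(), nv = V.nrow();
  // cell size ~ typical spacing so bins stay small
  double mn[3], mx[3];
  for (int d = 0; d < 3; ++d) { mn[d] = mx[d] = V(0,d); }
  for (int i = 1; i < nv; ++i) for (int d = 0; d < 3; ++d) {
    mn[d] = std::min(mn[d], V(i,d)); mx[d] = std::max(mx[d], V(i,d));
  }
  double diag = std::sqrt((mx[0]-mn[0])*(mx[0]-mn[0]) + (mx[1]-mn[1])*(mx[1]-mn[1])
                          + (mx[2]-mn[2])*(mx[2]-mn[2]));
  double cell = std::max(1e-9, 2.0*diag/std::cbrt((double)nv + 1.0));
  Grid G; G.init(V, cell);
  for (int i = 0; i < nv; ++i)
    G.bins[G.bidx(G.clampi(V(i,0),0), G.clampi(V(i,1),1), G.clampi(V(i,2),2))]
      .push_back(i);

  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q,0), Q(q,1), Q(q,2)};
    int ci = G.clampi(p[0],0), cj = G.clampi(p[1],1), ck = G.clampi(p[2],2);
    double best = R_PosInf; int bidx = -1;
    int maxring = std::max({G.n[0], G.n[1], G.n[2]});
    for (int r = 0; r <= maxring; ++r) {
      if (bidx >= 0 && best <= (double)(r-1)*G.cell*(r-1)*G.cell) break;
      for (int k = std::max(0,ck-r); k <= std::min(G.n[2]-1,ck+r); ++k)
      for (int j = std::max(0,cj-r); j <= std::min(G.n[1]-1,cj+r); ++j)
      for (int i = std::max(0,ci-r); i <= std::min(G.n[0]-1,ci+r); ++i) {
        if (std::max({std::abs(i-ci), std::abs(j-cj), std::abs(k-ck)}) != r)
          continue;
        for (int vi : G.bins[G.bidx(i,j,k)]) {
          double dx=p[0]-V(vi,0), dy=p[1]-V(vi,1), dz=p[2]-V(vi,2);
          double d2 = dx*dx+dy*dy+dz*dz;
          if (d2 < best - 1e-12 || (std::fabs(d2-best) <= 1e-12 && vi < bidx)) {
            best = d2; bidx = vi;
          }
        }
      }
    }
    out[q] = bidx;  // 0-based; caller shifts
  }
  return out;
}

// [[Rcpp::export]]
NumericVector point_to_mesh_distance(NumericMatrix Q, NumericMatrix V,
                                     IntegerMatrix F) {
  const int nq = Q.nrow(), nf = F.nrow();
  // grid over triangle bounding boxes, cell ~ median triangle extent
  std::vector<double> ext(nf);
  double mn[3] = {V(0,0), V(0,1), V(0,2)};
  double mx[3] = {V(0,0), V(0,1), V(0,2)};
  for (int i = 1; i < V.nrow(); ++i) for (int d = 0; d < 3; ++d) {
    mn[d] = std::min(mn[d], V(i,d)); mx[d] = std::max(mx[d], V(i,d));
  }
  for (int t = 0; t < nf; ++t) {
    double e = 0;
    for (int d = 0; d < 3; ++d) {
      double lo = std::min({V(F(t,0),d), V(F(t,1),d), V(F(t,2),d)});
      double hi = std::max({V(F(t,0),d), V(F(t,1),d), V(F(t,2),d)});
      e = std::max(e, hi-lo);
    }
    ext[t] = e;
  }
  std::vector<double> se(ext);
  std::nth_element(se.begin(), se.begin()+nf/2, se.end());
  double cell = std::max(1e-9, 2.0*se[nf/2]);
  Grid G; G.init(V, cell);
  for (int t = 0; t < nf; ++t) {
    int ilo[3], ihi[3];
    for (int d = 0; d < 3; ++d) {
      double lo = std::min({V(F(t,0),d), V(F(t,1),d), V(F(t,2),d)});
      double hi = std::max({V(F(t,0),d), V(F(t,1),d), V(F(t,2),d)});
      ilo[d] = G.clampi(lo, d); ihi[d] = G.clampi(hi, d);
    }
    for (int k = ilo[2]; k <= ihi[2]; ++k)
      for (int j = ilo[1]; j <= ihi[1]; ++j)
        for (int i = ilo[0]; i <= ihi[0]; ++i)
          G.bins[G.bidx(i,j,k)].push_back(t);
  }

  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q,0), Q(q,1), Q(q,2)};
    int ci = G.clampi(p[0],0), cj = G.clampi(p[1],1), ck = G.clampi(p[2],2);
    double best = R_PosInf;
    int maxring = std::max({G.n[0], G.n[1], G.n[2]});
    for (int r = 0; r <= maxring; ++r) {
      double lb = (double)(r-1)*G.cell;
      if (best < R_PosInf && r >= 1 && best <= lb*lb) break;
      for (int k = std::max(0,ck-r); k <= std::min(G.n[2]-1,ck+r); ++k)
      for (int j = std::max(0,cj-r); j <= std::min(G.n[1]-1,cj+r); ++j)
      for (int i = std::max(0,ci-r); i <= std::min(G.n[0]-1,ci+r); ++i) {
        if (std::max({std::abs(i-ci), std::abs(j-cj), std::abs(k-ck)}) != r)
          continue;
        for (int t : G.bins[G.bidx(i,j,k)]) {
          double a[3] = {V(F(t,0),0), V(F(t,0),1), V(F(t,0),2)};
          double b[3] = {V(F(t,1),0), V(F(t,1),1), V(F(t,1),2)};
          double c[3] = {V(F(t,2),0), V(F(t,2),1), V(F(t,2),2)};
          best = std::min(best, pt_tri_d2(p, a, b, c));
        }
      }
    }
    out[q] = std::sqrt(best);
  }
  return out;
}
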