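#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// 3-D quickhull with conflict lists. Returns the triangulated convex hull
// of a point set, outward-oriented. Points within eps of the current hull
// are treated as interior, so exactly-cospherical inputs terminate.

namespace {

struct Face {
  int a, b, c;
  double nx, ny, nz, off;     // plane: n . p - off = 0, n outward
  std::vector<int> conflict;  // points strictly outside this face
  int far_pt = -1;
  double far_d = 0.0;
  bool alive = true;
};

struct Hull {
  const NumericMatrix& P;
  double eps;
  std::vector<Face> faces;
  std::unordered_map<long long, std::pair<int,int>> edges;  // undirected -> 2 faces
  double cx = 0, cy = 0, cz = 0;  // interior reference point

  explicit Hull(const NumericMatrix& pts) : P(pts), eps(0) {}

  long long ekey(int u, int v) const {
    long long lo = std::min(u, v), hi = std::max(u, v);
    return lo * (long long)P.nrow() + hi;
  }
  void link_edge(int u, int v, int f) {
    auto it = edges.find(ekey(u, v));
    if (it == edges.end()) edges[ekey(u, v)] = {f, -1};
    else it->second.second = f;
  }
  void unlink_edge(int u, int v, int f) {
    auto it = edges.find(ekey(u, v));
    if (it == edges.end()) return;
    if (it->second.first == f) it->second.first = it->second.second;
    it->second.second = -1;
    if (it->second.first == -1) edges.erase(it);
  }
  int neighbor(int u, int v, int f) const {
    auto it = edges.find(ekey(u, v));
    if (it == edges.end()) return -1;
    return (it->second.first == f) ? it->second.second : it->second.first;
  }
  double dist(const Face& f, int p) const {
    return f.nx*P(p,0) + f.ny*P(p,1) + f.nz*P(p,2) - f.off;
  }
  void set_plane(Face& f) {
    double ax = P(f.a,0), ay = P(f.a,1), az = P(f.a,2);
    double ux = P(f.b,0)-ax, uy = P(f.b,1)-ay, uz = P(f.b,2)-az;
    double vx = P(f.c,0)-ax, vy = P(f.c,1)-ay, vz = P(f.c,2)-az;
    f.nx = uy*vz - uz*vy; f.ny = uz*vx - ux*vz; f.nz = ux*vy - uy*vx;
    double nrm = std::sqrt(f.nx*f.nx + f.ny*f.ny + f.nz*f.nz);
    if (nrm > 0) { f.nx /= nrm; f.ny /= nrm; f.nz /= nrm; }
    f.off = f.nx*ax + f.ny*ay + f.nz*az;
    // flip to face away from the interior reference point
    if (f.nx*cx + f.ny*cy + f.nz*cz - f.off > 0) {
      std::swap(f.b, f.c);
      f.nx = -f.nx; f.ny = -f.ny; f.nz = -f.nz; f.off = -f.off;
    }
  }
  int add_face(int a, int b, int c) {
    Face f; f.a = a; f.b = b; f.c = c;
    set_plane(f);
    int id = (int)faces.size();
    faces.push_back(std::move(f));
    link_edge(a, b, id); link_edge(b, c, id); link_edge(c, a, id);
    return id;
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix quickhull_faces(NumericMatrix P) {
  const int n = P.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  // initial extremes
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (P(i,0) < P(i0,0)) i0 = i;
    if (P(i,0) > P(i1,0)) i1 = i;
  }
  double diag = 0;
  {
    double mn[3], mx[3];
    for (int d = 0; d < 3; ++d) { mn[d] = mx[d] = P(0,d); }
    for (int i = 1; i < n; ++i) for (int d = 0; d < 3; ++d) {
      mn[d] = std::min(mn[d], P(i,d)); mx[d] = std::max(mx[d], P(i,d));
    }
    diag = std::sqrt((mx[0]-mn[0])*(mx[0]-mn[0]) + (mx[1]-mn[1])*(mx[1]-mn[1])
                     + (mx[2]-mn[2])*(mx[2]-mn[2]));
  }
  if (i0 == i1 || diag == 0) stop("degenerate input: all points coincide");
  // farthest from line i0-i1
  double dx = P(i1,0)-P(i0,0), dy = P(i1,1)-P(i0,1), dz = P(i1,2)-P(i0,2);
  double dl = dx*dx + dy*dy + dz*dz;
  int i2 = -1; double best = -1;
  for (int i = 0; i < n; ++i) {
    double wx = P(i,0)-P(i0,0), wy = P(i,1)-P(i0,1), wz = P(i,2)-P(i0,2);
    double t = (wx*dx + wy*dy + wz*dz)/dl;
    double rx = wx - t*dx, ry = wy - t*dy, rz = wz - t*dz;
    double d2 = rx*rx + ry*ry + rz*rz;
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (best <= 1e-24*diag*diag) stop("degenerate input: points are collinear");
  // farthest from plane i0,i1,i2
  double ux = P(i2,0)-P(i0,0), uy = P(i2,1)-P(i0,1), uz = P(i2,2)-P(i0,2);
  double nx = dy*uz - dz*uy, ny = dz*ux - dx*uz, nz = dx*uy - dy*ux;
  double nn = std::sqrt(nx*nx + ny*ny + nz*nz);
  nx /= nn; ny /= nn; nz /= nn;
  int i3 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(nx*(P(i,0)-P(i0,0)) + ny*(P(i,1)-P(i0,1)) + nz*(P(i,2)-P(i0,2)));
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= 1e-12*diag) stop("degenerate input: points are coplanar");

  Hull H(P);
  H.eps = 1e-10 * diag;
  H.cx = (P(i0,0)+P(i1,0)+P(i2,0)+P(i3,0))/4.0;
  H.cy = (P(i0,1)+P(i1,1)+P(i2,1)+P(i3,1))/4.0;
  H.cz = (P(i0,2)+P(i1,2)+P(i2,2)+P(i3,2))/4.0;
  H.add_face(i0, i1, i2);
  H.add_face(i0, i1, i3);
  H.add_face(i0, i2, i3);
  H.add_face(i1, i2, i3);

  // initial conflict assignment
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    for (int f = 0; f < 4; ++f) {
      double d = H.dist(H.faces[f], p);
      if (d > H.eps) {
        H.faces[f].conflict.push_back(p);
        if (d > H.faces[f].far_d) { H.faces[f].far_d = d; H.faces[f].far_pt = p; }
        break;
      }
    }
  }
  std::vector<int> work = {0, 1, 2, 3};

  std::vector<int> visible, horizon_u, horizon_v, stackv;
  while (!work.empty()) {
    int fid = work.back(); work.pop_back();
    Face& f0 = H.faces[fid];
    if (!f0.alive || f0.conflict.empty()) continue;
    int p = f0.far_pt;

    // BFS over faces visible from p
    visible.clear(); horizon_u.clear(); horizon_v.clear(); stackv.clear();
    std::vector<char> seen(H.faces.size(), 0);
    stackv.push_back(fid); seen[fid] = 1;
    while (!stackv.empty()) {
      int g = stackv.back(); stackv.pop_back();
      visible.push_back(g);
      Face& fg = H.faces[g];
      int vs[3] = {fg.a, fg.b, fg.c};
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e+1)%3];
        int nb = H.neighbor(u, v, g);
        if (nb < 0) continue;
        if (seen[nb]) continue;
        if (H.dist(H.faces[nb], p) > H.eps) {
          seen[nb] = 1; stackv.push_back(nb);
        } else {
          horizon_u.push_back(u); horizon_v.push_back(v);
        }
      }
    }
    // gather conflicts and kill visible faces
    std::vector<int> orphans;
    for (int g : visible) {
      Face& fg = H.faces[g];
      for (int q : fg.conflict) if (q != p) orphans.push_back(q);
      fg.alive = false; fg.conflict.clear();
      H.unlink_edge(fg.a, fg.b, g);
      H.unlink_edge(fg.b, fg.c, g);
      H.unlink_edge(fg.c, fg.a, g);
    }
    // new faces over the horizon
    std::vector<int> created;
    for (size_t e = 0; e < horizon_u.size(); ++e)
      created.push_back(H.add_face(horizon_u[e], horizon_v[e], p));
    // redistribute orphans
    for (int q : orphans) {
      for (int g : created) {
        Face& fg = H.faces[g];
        double d = H.dist(fg, q);
        if (d > H.eps) {
          fg.conflict.push_back(q);
          if (d > fg.far_d) { fg.far_d = d; fg.far_pt = q; }
          break;
        }
      }
    }
    for (int g : created)
      if (!H.faces[g].conflict.empty()) work.push_back(g);
  }

  int nf = 0;
  for (auto& f : H.faces) if (f.alive) ++nf;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (auto& f : H.faces) {
    if (!f.alive) continue;
    // ensure outward orientation w.r.t. interior point
    double d = f.nx*H.cx + f.ny*H.cy + f.nz*H.cz - f.off;
    if (d <= 0) { out(r,0) = f.a; out(r,1) = f.b; out(r,2) = f.c; }
    else        { out(r,0) = f.a; out(r,1) = f.c; out(r,2) = f.b; }
    ++r;
  }
  return out;
}
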