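#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction on a scalar grid by per-cell polygon tracing.
//
// For every grid cell with a sign change, the surface/cube-face
// intersection is a set of segments fully determined by the four corner
// values of each face (ambiguous faces resolved by the bilinear
// asymptotic decider, which also depends only on the face values).
// Segments therefore agree exactly between the two cells sharing a face,
// so chaining them into loops and fanning each loop yields a watertight
// mesh by construction -- unlike table-driven marching cubes, whose
// complementary-case tables can crack binary volumes. Crossing vertices
// lie at the linear interpolation point on each cell edge (edge midpoints
// for binary data at level 0.5); loops with more than three vertices get
// a centroid vertex. Loop orientation is set so normals point down the
// field gradient, i.e. outward for an inside>level convention.

namespace {

const int CO[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                      {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
const int FACES[6][4] = {{0,1,2,3},{4,5,6,7},{0,1,5,4},
                         {3,2,6,7},{0,3,7,4},{1,2,6,5}};

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  std::unordered_map<long long, int> edge_vert;
};

}  // namespace

// [[Rcpp::export]]
List polygon_trace_isosurface(NumericVector field, IntegerVector dims,
                              double level, NumericVector origin,
                              double spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  auto fidx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx*(j + (R_xlen_t)ny*k);
  };
  auto node_pos = [&](int i, int j, int k, double* p) {
    p[0] = ox + (i + 0.5)*spacing;
    p[1] = oy + (j + 0.5)*spacing;
    p[2] = oz + (k + 0.5)*spacing;
  };
  MeshAcc M;

  for (int k = 0; k < nz-1; ++k)
  for (int j = 0; j < ny-1; ++j)
  for (int i = 0; i < nx-1; ++i) {
    double v[8]; bool in[8]; int nin = 0;
    for (int c = 0; c < 8; ++c) {
      v[c] = field[fidx(i+CO[c][0], j+CO[c][1], k+CO[c][2])];
      in[c] = v[c] > level;
      nin += in[c];
    }
    if (nin == 0 || nin == 8) continue;

    // crossing vertex on the cube edge between local corners ca, cb
    auto edge_vertex = [&](int ca, int cb) -> int {
      int ax = CO[ca][0]+i, ay = CO[ca][1]+j, az = CO[ca][2]+k;
      int bx = CO[cb][0]+i, by = CO[cb][1]+j, bz = CO[cb][2]+k;
      int axis = (ax != bx) ? 0 : (ay != by ? 1 : 2);
      int mx = std::min(ax,bx), my = std::min(ay,by), mz = std::min(az,bz);
      long long node = (long long)mx + (long long)nx*((long long)my + (long long)ny*mz);
      long long key = node*3 + axis;
      auto it = M.edge_vert.find(key);
      if (it != M.edge_vert.end()) return it->second;
      double pa[3], pb[3];
      node_pos(ax, ay, az, pa); node_pos(bx, by, bz, pb);
      double va = v[ca], vb = v[cb];
      double t = (vb == va) ? 0.5 : (level - va)/(vb - va);
      if (t < 0.0) t = 0.0; if (t > 1.0) t = 1.0;
      int id = (int)M.vx.size();
      M.vx.push_back(pa[0] + t*(pb[0]-pa[0]));
      M.vy.push_back(pa[1] + t*(pb[1]-pa[1]));
      M.vz.push_back(pa[2] + t*(pb[2]-pa[2]));
      M.edge_vert[key] = id;
      return id;
    };

    // collect undirected segments (pairs of crossing-vertex ids)
    std::vector<std::pair<int,int>> segs;
    for (int f = 0; f < 6; ++f) {
      const int* fc = FACES[f];
      int cross[4], ncross = 0;
      for (int e = 0; e < 4; ++e)
        if (in[fc[e]] != in[fc[(e+1)%4]]) cross[ncross++] = e;
      if (ncross == 2) {
        segs.emplace_back(edge_vertex(fc[cross[0]], fc[(cross[0]+1)%4]),
                          edge_vertex(fc[cross[1]], fc[(cross[1]+1)%4]));
      } else if (ncross == 4) {
        int i0 = in[fc[0]] ? 0 : 1;  // diagonal inside pair fc[i0], fc[i0+2]
        double va = v[fc[i0]], vc = v[fc[i0+2]];
        double vb = v[fc[(i0+1)%4]], vd = v[fc[(i0+3)%4]];
        double s = (va*vc - vb*vd)/(va + vc - vb - vd);
        int ev[4];
        for (int e = 0; e < 4; ++e) ev[e] = edge_vertex(fc[e], fc[(e+1)%4]);
        if (s > level) {  // inside corners joined across the face
          segs.emplace_back(ev[i0 % 4],       ev[(i0+1)%4]);
          segs.emplace_back(ev[(i0+2)%4],     ev[(i0+3)%4]);
        } else {          // inside corners separated
          segs.emplace_back(ev[(i0+3)%4],     ev[i0 % 4]);
          segs.emplace_back(ev[(i0+1)%4],     ev[(i0+2)%4]);
        }
      }
    }
    if (segs.empty()) continue;

    // chain segments into closed loops
    std::unordered_map<int, std::vector<int>> adj;
    for (auto& s : segs) { adj[s.first].push_back(s.second); adj[s.second].push_back(s.first); }
    std::unordered_map<int, bool> used;
    for (auto& s : segs) { used[s.first] = false; used[s.second] = false; }
    for (auto& st : adj) {
      if (used[st.first]) continue;
      std::vector<int> loop;
      int cur = st.first, prev = -1;
      while (true) {
        loop.push_back(cur); used[cur] = true;
        const std::vector<int>& nb = adj[cur];
        int nxt = -1;
        for (int cand : nb) if (cand != prev && !used[cand]) { nxt = cand; break; }
        if (nxt == -1) {
          // close the loop back to start (or give up on defective chains)
          break;
        }
        prev = cur; cur = nxt;
      }
      if (loop.size() < 3) continue;

      // centroid + Newell normal
      double cxl = 0, cyl = 0, czl = 0;
      for (int vid : loop) { cxl += M.vx[vid]; cyl += M.vy[vid]; czl += M.vz[vid]; }
      int L = (int)loop.size();
      cxl /= L; cyl /= L; czl /= L;
      double nxl = 0, nyl = 0, nzl = 0;
      for (int e = 0; e < L; ++e) {
        int a = loop[e], b = loop[(e+1)%L];
        nxl += (M.vy[a]-M.vy[b])*(M.vz[a]+M.vz[b]);
        nyl += (M.vz[a]-M.vz[b])*(M.vx[a]+M.vx[b]);
        nzl += (M.vx[a]-M.vx[b])*(M.vy[a]+M.vy[b]);
      }
      // trilinear gradient at the loop centroid (cell-local coordinates)
      double p0[3]; node_pos(i, j, k, p0);
      double u = (cxl-p0[0])/spacing, vv = (cyl-p0[1])/spacing, w = (czl-p0[2])/spacing;
      u = std::min(1.0, std::max(0.0, u));
      vv = std::min(1.0, std::max(0.0, vv));
      w = std::min(1.0, std::max(0.0, w));
      double gx = 0, gy = 0, gz = 0;
      for (int c = 0; c < 8; ++c) {
        double su = CO[c][0] ? 1.0 : -1.0;
        double sv = CO[c][1] ? 1.0 : -1.0;
        double sw = CO[c][2] ? 1.0 : -1.0;
        double wu = CO[c][0] ? u : 1.0-u;
        double wv = CO[c][1] ? vv : 1.0-vv;
        double ww = CO[c][2] ? w : 1.0-w;
        gx += v[c]*su*wv*ww;
        gy += v[c]*wu*sv*ww;
        gz += v[c]*wu*wv*sw;
      }
      // outward normal points down-gradient (away from the inside region)
      if (nxl*gx + nyl*gy + nzl*gz > 0.0) {
        std::vector<int> rev(loop.rbegin(), loop.rend());
        loop.swap(rev);
      }
      if (L == 3) {
        M.fa.push_back(loop[0]); M.fb.push_back(loop[1]); M.fc.push_back(loop[2]);
      } else {
        int cid = (int)M.vx.size();
        M.vx.push_back(cxl); M.vy.push_back(cyl); M.vz.push_back(czl);
        for (int e = 0; e < L; ++e) {
          M.fa.push_back(loop[e]); M.fb.push_back(loop[(e+1)%L]); M.fc.push_back(cid);
        }
      }
    }
  }

  int nv = (int)M.vx.size(), nf = (int)M.fa.size();
  NumericMatrix Vout(nv, 3);
  IntegerMatrix Fout(nf, 3);
  for (int a = 0; a < nv; ++a) { Vout(a,0) = M.vx[a]; Vout(a,1) = M.vy[a]; Vout(a,2) = M.vz[a]; }
  for (int a = 0; a < nf; ++a) { Fout(a,0) = M.fa[a]; Fout(a,1) = M.fb[a]; Fout(a,2) = M.fc[a]; }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
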