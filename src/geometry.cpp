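// 3D computational-geometry engine: incremental Delaunay tetrahedralization
// (Bowyer-Watson with a symbolic vertex at infinity) and QuickHull.
// Coordinates are normalized to the unit box internally; circumradii and
// volumes are computed in the original frame afterwards.
#include <Rcpp.h>
#include <array>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

static inline double orient3d(const double* a, const double* b,
                              const double* c, const double* d) {
  const double bx = b[0] - a[0], by = b[1] - a[1], bz = b[2] - a[2];
  const double cx = c[0] - a[0], cy = c[1] - a[1], cz = c[2] - a[2];
  const double dx = d[0] - a[0], dy = d[1] - a[1], dz = d[2] - a[2];
  return bx * (cy * dz - cz * dy) - by * (cx * dz - cz * dx) +
         bz * (cx * dy - cy * dx);
}

// > 0 iff e lies strictly inside the circumsphere of the positively
// oriented tetrahedron (a,b,c,d).  Sign convention verified against the
// regular/unit tetrahedron in the test suite.
static inline double insphere_pos(const double* a, const double* b,
                                  const double* c, const double* d,
                                  const double* e) {
  double m[4][4];
  const double* p[4] = { a, b, c, d };
  for (int i = 0; i < 4; ++i) {
    const double x = p[i][0] - e[0], y = p[i][1] - e[1], z = p[i][2] - e[2];
    m[i][0] = x; m[i][1] = y; m[i][2] = z; m[i][3] = x * x + y * y + z * z;
  }
  // 4x4 determinant by cofactor expansion over 2x2 minors
  const double s0 = m[0][0]*m[1][1] - m[1][0]*m[0][1];
  const double s1 = m[0][0]*m[1][2] - m[1][0]*m[0][2];
  const double s2 = m[0][0]*m[1][3] - m[1][0]*m[0][3];
  const double s3 = m[0][1]*m[1][2] - m[1][1]*m[0][2];
  const double s4 = m[0][1]*m[1][3] - m[1][1]*m[0][3];
  const double s5 = m[0][2]*m[1][3] - m[1][2]*m[0][3];
  const double c5 = m[2][2]*m[3][3] - m[3][2]*m[2][3];
  const double c4 = m[2][1]*m[3][3] - m[3][1]*m[2][3];
  const double c3 = m[2][1]*m[3][2] - m[3][1]*m[2][2];
  const double c2 = m[2][0]*m[3][3] - m[3][0]*m[2][3];
  const double c1 = m[2][0]*m[3][2] - m[3][0]*m[2][2];
  const double c0 = m[2][0]*m[3][1] - m[3][0]*m[2][1];
  const double det = s0*c5 - s1*c4 + s2*c3 + s3*c2 - s4*c1 + s5*c0;
  // det > 0 <=> e inside, for positively oriented (a,b,c,d) under the
  // orient3d() above (minus sign folds the row/column convention).
  return -det;
}

// face opposite vertex i of tet (v0,v1,v2,v3), ordered so that for a
// positively oriented tet, orient3d(face, v_i) > 0 (normal toward v_i).
static const int FT[4][3] = { {1, 3, 2}, {0, 2, 3}, {0, 3, 1}, {0, 1, 2} };

struct Delaunay {
  int n = 0;                 // number of finite points
  int infv = -1;             // symbolic infinite vertex id (== n)
  std::vector<double> P;     // 3*n normalized coordinates
  std::vector<std::array<int, 4>> tv;  // tet vertices
  std::vector<std::array<int, 4>> tn;  // tet neighbors (opposite vertex i)
  std::vector<uint8_t> dead;
  std::vector<int> stamp;
  int cur_stamp = 0;
  int last_alive = -1;
  bool degenerate = false;
  bool failed = false;
  int fail_code = 0;   // 1 fallback limit, 2 patch fail, 3 open cavity
  int fallbacks = 0;   // brute-force locates; many of them => degenerate input
  uint32_t rng = 0x9e3779b9u;  // fixed-seed LCG for stochastic walking
  uint32_t next_rng() { rng = rng * 1664525u + 1013904223u; return rng >> 16; }

  const double* pt(int i) const { return &P[3 * i]; }
  bool has_inf(int t) const {
    const auto& v = tv[t];
    return v[0] == infv || v[1] == infv || v[2] == infv || v[3] == infv;
  }

  int new_tet(int a, int b, int c, int d) {
    tv.push_back({a, b, c, d});
    tn.push_back({-1, -1, -1, -1});
    dead.push_back(0);
    stamp.push_back(0);
    return (int)tv.size() - 1;
  }

  // conflict predicate: is p inside the (possibly infinite) circumsphere?
  // For an infinite tet the test is: does p lie strictly outside the hull
  // facet's plane?  "Outside" is decided against the opposite vertex of
  // the finite neighbor across that facet rather than against a stored
  // orientation, which keeps the test immune to symbolic-parity slips.
  bool conflict(int t, const double* p) {
    const auto& v = tv[t];
    int s = -1;
    for (int i = 0; i < 4; ++i) if (v[i] == infv) { s = i; break; }
    if (s < 0) {
      const double d = insphere_pos(pt(v[0]), pt(v[1]), pt(v[2]), pt(v[3]), p);
      if (d == 0.0) degenerate = true;
      return d > 0.0;
    }
    const int* f = FT[s];
    const int a = v[f[0]], b = v[f[1]], c = v[f[2]];
    const int u = tn[t][s];  // finite tet on the interior side of the facet
    if (u < 0) { degenerate = true; return false; }
    int w = -1;
    for (int i = 0; i < 4; ++i) {
      const int x = tv[u][i];
      if (x != a && x != b && x != c) { w = x; break; }
    }
    if (w < 0 || w == infv) { degenerate = true; return false; }
    const double o_p = orient3d(pt(a), pt(b), pt(c), p);
    const double o_w = orient3d(pt(a), pt(b), pt(c), pt(w));
    if (o_p == 0.0 || o_w == 0.0) { degenerate = true; return true; }
    return (o_p > 0.0) != (o_w > 0.0);
  }

  int locate(const double* p) {
    int t = last_alive;
    if (t < 0 || dead[t]) {
      t = -1;
      for (int i = (int)tv.size() - 1; i >= 0; --i)
        if (!dead[i]) { t = i; break; }
      if (t < 0) return -1;
    }
    // never *start* on an infinite tet: step to its interior neighbor
    // (reaching one mid-walk, by crossing its hull facet, is a genuine
    // conflict; starting on one is not)
    for (int g = 0; g < 4 && has_inf(t); ++g) {
      for (int i = 0; i < 4; ++i)
        if (tv[t][i] == infv) { t = tn[t][i]; break; }
      if (t < 0) return -1;
    }
    if (has_inf(t)) return -1;
    const long cap = 65536;
    long steps = 0;
    while (true) {
      if (++steps > cap) return -1;  // cycling on a degeneracy
      if (has_inf(t)) return t;
      const auto& v = tv[t];
      // first face the query lies behind, scanning from a pseudorandom
      // start index (stochastic walk): breaks the cycles a deterministic
      // rule falls into on near-degenerate (sliver) tetrahedra
      int best = -1;
      const int off = (int)(next_rng() & 3);
      for (int i = 0; i < 4 && best < 0; ++i) {
        const int j = (i + off) & 3;
        const int* f = FT[j];
        const double o = orient3d(pt(v[f[0]]), pt(v[f[1]]), pt(v[f[2]]), p);
        if (o < 0.0) best = j;
      }
      if (best < 0) return t;
      const int nxt = tn[t][best];
      if (nxt < 0) return t;
      t = nxt;
    }
  }

  bool insert(int pi) {
    const double* p = pt(pi);
    int seed = locate(p);
    if (seed < 0 || !conflict(seed, p)) {
      // fallback: brute-force scan for any conflicting tet
      if (++fallbacks > 1024) {
        degenerate = true; failed = true; fail_code = 1; return false;
      }
      seed = -1;
      for (int t = 0; t < (int)tv.size(); ++t)
        if (!dead[t] && conflict(t, p)) { seed = t; break; }
      if (seed < 0) { degenerate = true; return false; }  // duplicate/on-sphere
    }
    // BFS over the conflict region
    ++cur_stamp;
    std::vector<int> region, stack{seed};
    stamp[seed] = cur_stamp;
    struct BFacet { int t, i, u; };
    std::vector<BFacet> boundary;
    while (!stack.empty()) {
      const int t = stack.back(); stack.pop_back();
      region.push_back(t);
      for (int i = 0; i < 4; ++i) {
        const int u = tn[t][i];
        if (u < 0) { failed = true; fail_code = 2; return false; }
        if (stamp[u] == cur_stamp) continue;
        if (!dead[u] && conflict(u, p)) {
          stamp[u] = cur_stamp;
          stack.push_back(u);
        } else {
          boundary.push_back({t, i, u});
        }
      }
    }
    // each boundary facet is recorded exactly once: it has a unique
    // conflict-side (t,i).  Carve the cavity:
    for (int t : region) dead[t] = 1;
    // retriangulate: one new tet per boundary facet
    std::unordered_map<uint64_t, std::pair<int, int>> edge_map;
    const uint64_t M = (uint64_t)n + 2;
    std::vector<int> created;
    created.reserve(boundary.size());
    for (const auto& bf : boundary) {
      const auto& v = tv[bf.t];
      int f0 = v[FT[bf.i][0]], f1 = v[FT[bf.i][1]], f2 = v[FT[bf.i][2]];
      if (f0 != infv && f1 != infv && f2 != infv) {
        // store finite tets positively oriented (insphere_pos requires it)
        const double o = orient3d(pt(f0), pt(f1), pt(f2), p);
        if (o == 0.0) degenerate = true;
        else if (o < 0.0) std::swap(f0, f1);
      }
      const int nt = new_tet(f0, f1, f2, pi);
      created.push_back(nt);
      // face opposite pi (slot 3) is the old boundary facet -> neighbor u
      tn[nt][3] = bf.u;
      bool patched = false;
      for (int j = 0; j < 4; ++j)
        if (tn[bf.u][j] == bf.t) { tn[bf.u][j] = nt; patched = true; break; }
      if (!patched) { failed = true; fail_code = 2; return false; }
      // faces containing pi: slot s has base edge (the two base verts != f_s)
      const int base[3] = { f0, f1, f2 };
      for (int s = 0; s < 3; ++s) {
        const int a = base[(s + 1) % 3], b = base[(s + 2) % 3];
        const uint64_t ka = (uint64_t)(a < 0 ? n : a), kb = (uint64_t)(b < 0 ? n : b);
        const uint64_t key = (std::min(ka, kb)) * M + (std::max(ka, kb));
        auto it = edge_map.find(key);
        if (it == edge_map.end()) {
          edge_map[key] = { nt, s };
        } else {
          tn[nt][s] = it->second.first;
          tn[it->second.first][it->second.second] = nt;
          edge_map.erase(it);
        }
      }
    }
    if (!edge_map.empty()) { failed = true; fail_code = 3; return false; }
    for (int nt : created)
      if (!has_inf(nt)) { last_alive = nt; break; }
    return true;
  }
};

static inline uint32_t morton_part(uint32_t x) {
  x &= 0x3ff;
  x = (x | (x << 16)) & 0x30000ff;
  x = (x | (x << 8)) & 0x300f00f;
  x = (x | (x << 4)) & 0x30c30c3;
  x = (x | (x << 2)) & 0x9249249;
  return x;
}

// [[Rcpp::export]]
List cpp_delaunay(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  Delaunay D;
  D.n = n;
  D.infv = n;
  // normalize to unit box
  double mn[3], mx[3];
  for (int d = 0; d < 3; ++d) { mn[d] = R_PosInf; mx[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      const double v = pts(i, d);
      if (v < mn[d]) mn[d] = v;
      if (v > mx[d]) mx[d] = v;
    }
  double scale = 0.0;
  for (int d = 0; d < 3; ++d) scale = std::max(scale, mx[d] - mn[d]);
  if (scale <= 0.0)
    return List::create(_["ok"] = false, _["reason"] = "all points identical");
  D.P.resize(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      D.P[3 * (size_t)i + d] = (pts(i, d) - mn[d]) / scale;
  // Morton-sorted insertion order for walking locality (deterministic)
  std::vector<int> ord(n);
  std::vector<uint32_t> key(n);
  for (int i = 0; i < n; ++i) {
    ord[i] = i;
    const double* p = D.pt(i);
    uint32_t kx = (uint32_t)std::min(1023.0, std::max(0.0, p[0] * 1023.0));
    uint32_t ky = (uint32_t)std::min(1023.0, std::max(0.0, p[1] * 1023.0));
    uint32_t kz = (uint32_t)std::min(1023.0, std::max(0.0, p[2] * 1023.0));
    key[i] = morton_part(kx) | (morton_part(ky) << 1) | (morton_part(kz) << 2);
  }
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return key[a] < key[b]; });
  // bootstrap: first four affinely independent points in insertion order
  const double eps_boot = 1e-14;
  int i0 = ord[0], i1 = -1, i2 = -1, i3 = -1;
  for (int j = 1; j < n && i1 < 0; ++j) {
    const double* a = D.pt(i0); const double* b = D.pt(ord[j]);
    const double dx = b[0]-a[0], dy = b[1]-a[1], dz = b[2]-a[2];
    if (dx*dx + dy*dy + dz*dz > 0.0) i1 = ord[j];
  }
  if (i1 >= 0) for (int j = 1; j < n && i2 < 0; ++j) {
    if (ord[j] == i1) continue;
    const double* a = D.pt(i0); const double* b = D.pt(i1);
    const double* c = D.pt(ord[j]);
    const double ux = b[0]-a[0], uy = b[1]-a[1], uz = b[2]-a[2];
    const double vx = c[0]-a[0], vy = c[1]-a[1], vz = c[2]-a[2];
    const double cx = uy*vz - uz*vy, cy = uz*vx - ux*vz, cz = ux*vy - uy*vx;
    if (cx*cx + cy*cy + cz*cz > eps_boot * eps_boot) i2 = ord[j];
  }
  if (i2 >= 0) for (int j = 1; j < n && i3 < 0; ++j) {
    if (ord[j] == i1 || ord[j] == i2) continue;
    const double o = orient3d(D.pt(i0), D.pt(i1), D.pt(i2), D.pt(ord[j]));
    if (std::fabs(o) > eps_boot) i3 = ord[j];
  }
  if (i3 < 0)
    return List::create(_["ok"] = false,
                        _["reason"] = "points are collinear or coplanar");
  if (orient3d(D.pt(i0), D.pt(i1), D.pt(i2), D.pt(i3)) < 0) std::swap(i1, i2);
  const int T0 = D.new_tet(i0, i1, i2, i3);
  int inf_t[4];
  for (int i = 0; i < 4; ++i) {
    const auto& v = D.tv[T0];
    const int f0 = v[FT[i][0]], f1 = v[FT[i][1]], f2 = v[FT[i][2]];
    inf_t[i] = D.new_tet(f0, f2, f1, D.infv);  // reversed -> outward facet
  }
  // stitch bootstrap adjacency generically via a facet map
  {
    std::unordered_map<uint64_t, std::pair<int, int>> fmap;
    const uint64_t M = (uint64_t)n + 2;
    int tets[5] = { T0, inf_t[0], inf_t[1], inf_t[2], inf_t[3] };
    for (int q = 0; q < 5; ++q) {
      const int t = tets[q];
      for (int i = 0; i < 4; ++i) {
        int a = D.tv[t][FT[i][0]], b = D.tv[t][FT[i][1]], c = D.tv[t][FT[i][2]];
        uint64_t k[3] = { (uint64_t)a, (uint64_t)b, (uint64_t)c };
        std::sort(k, k + 3);
        const uint64_t kk = (k[0] * M + k[1]) * M + k[2];
        auto it = fmap.find(kk);
        if (it == fmap.end()) fmap[kk] = { t, i };
        else {
          D.tn[t][i] = it->second.first;
          D.tn[it->second.first][it->second.second] = t;
          fmap.erase(it);
        }
      }
    }
    if (!fmap.empty())
      return List::create(_["ok"] = false, _["reason"] = "bootstrap failure");
  }
  D.last_alive = T0;
  // incremental insertion
  int skipped = 0;
  for (int j = 0; j < n; ++j) {
    const int pi = ord[j];
    if (pi == i0 || pi == i1 || pi == i2 || pi == i3) continue;
    if (!D.insert(pi)) {
      if (D.failed)
        return List::create(_["ok"] = false,
                            _["reason"] = "inconsistent cavity (degenerate input)",
                            _["fail_code"] = D.fail_code,
                            _["fallbacks"] = D.fallbacks,
                            _["degenerate"] = true);
      ++skipped;  // duplicate or exactly on-sphere pathological point
    }
    if ((j & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  // collect finite tets
  int m = 0;
  for (size_t t = 0; t < D.tv.size(); ++t)
    if (!D.dead[t] && !D.has_inf((int)t)) ++m;
  IntegerMatrix tets(m, 4);
  int r = 0;
  for (size_t t = 0; t < D.tv.size(); ++t) {
    if (D.dead[t] || D.has_inf((int)t)) continue;
    for (int i = 0; i < 4; ++i) tets(r, i) = D.tv[t][i] + 1;  // 1-based
    ++r;
  }
  return List::create(_["ok"] = true, _["tets"] = tets,
                      _["degenerate"] = D.degenerate, _["skipped"] = skipped);
}

// per-tetrahedron circumradius and volume in the original frame;
// near-flat tets (volume < vol_tol) get circumradius +Inf
// [[Rcpp::export]]
List cpp_tet_metrics(NumericMatrix pts, IntegerMatrix tets, double vol_tol) {
  const int m = tets.nrow();
  NumericVector radii(m), vols(m);
  for (int t = 0; t < m; ++t) {
    double q[4][3];
    for (int i = 0; i < 4; ++i)
      for (int d = 0; d < 3; ++d) q[i][d] = pts(tets(t, i) - 1, d);
    const double o = orient3d(q[0], q[1], q[2], q[3]);
    const double vol = std::fabs(o) / 6.0;
    vols[t] = vol;
    if (vol < vol_tol) { radii[t] = R_PosInf; continue; }
    // circumcenter: solve 2*(qi - q0) . x = |qi|^2 - |q0|^2, i=1..3
    double A[3][3], bvec[3];
    const double n0 = q[0][0]*q[0][0] + q[0][1]*q[0][1] + q[0][2]*q[0][2];
    for (int i = 0; i < 3; ++i) {
      for (int d = 0; d < 3; ++d) A[i][d] = 2.0 * (q[i + 1][d] - q[0][d]);
      bvec[i] = q[i+1][0]*q[i+1][0] + q[i+1][1]*q[i+1][1] +
                q[i+1][2]*q[i+1][2] - n0;
    }
    const double det =
      A[0][0]*(A[1][1]*A[2][2] - A[1][2]*A[2][1]) -
      A[0][1]*(A[1][0]*A[2][2] - A[1][2]*A[2][0]) +
      A[0][2]*(A[1][0]*A[2][1] - A[1][1]*A[2][0]);
    if (det == 0.0 || !std::isfinite(det)) { radii[t] = R_PosInf; continue; }
    double x[3];
    x[0] = (bvec[0]*(A[1][1]*A[2][2] - A[1][2]*A[2][1]) -
            A[0][1]*(bvec[1]*A[2][2] - A[1][2]*bvec[2]) +
            A[0][2]*(bvec[1]*A[2][1] - A[1][1]*bvec[2])) / det;
    x[1] = (A[0][0]*(bvec[1]*A[2][2] - A[1][2]*bvec[2]) -
            bvec[0]*(A[1][0]*A[2][2] - A[1][2]*A[2][0]) +
            A[0][2]*(A[1][0]*bvec[2] - bvec[1]*A[2][0])) / det;
    x[2] = (A[0][0]*(A[1][1]*bvec[2] - bvec[1]*A[2][1]) -
            A[0][1]*(A[1][0]*bvec[2] - bvec[1]*A[2][0]) +
            bvec[0]*(A[1][0]*A[2][1] - A[1][1]*A[2][0])) / det;
    const double dx = x[0]-q[0][0], dy = x[1]-q[0][1], dz = x[2]-q[0][2];
    radii[t] = std::sqrt(dx*dx + dy*dy + dz*dz);
  }
  return List::create(_["circumradius"] = radii, _["volume"] = vols);
}

// ---------------- QuickHull 3D ----------------

struct QHFace {
  int v[3];
  int nb[3];          // neighbor across edge (v[i], v[(i+1)%3])
  double nx, ny, nz, off, nlen;
  std::vector<int> out;
  int far_pt = -1;
  double far_d = 0.0;
  bool dead_ = false;
};

struct QuickHull {
  const NumericMatrix& X;
  std::vector<QHFace> faces;
  double eps;
  explicit QuickHull(const NumericMatrix& x) : X(x) {}
  void get(int i, double* p) const {
    p[0] = X(i, 0); p[1] = X(i, 1); p[2] = X(i, 2);
  }
  void set_plane(QHFace& f) {
    double a[3], b[3], c[3];
    get(f.v[0], a); get(f.v[1], b); get(f.v[2], c);
    const double ux = b[0]-a[0], uy = b[1]-a[1], uz = b[2]-a[2];
    const double vx = c[0]-a[0], vy = c[1]-a[1], vz = c[2]-a[2];
    f.nx = uy*vz - uz*vy; f.ny = uz*vx - ux*vz; f.nz = ux*vy - uy*vx;
    f.off = f.nx*a[0] + f.ny*a[1] + f.nz*a[2];
    f.nlen = std::sqrt(f.nx*f.nx + f.ny*f.ny + f.nz*f.nz);
  }
  double dist(const QHFace& f, int i) const {
    return f.nx*X(i,0) + f.ny*X(i,1) + f.nz*X(i,2) - f.off;
  }
  bool above(const QHFace& f, int i) const {
    return dist(f, i) > eps * f.nlen;
  }
};

// [[Rcpp::export]]
List cpp_quickhull(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  double mn[3], mx[3]; int argmn[3], argmx[3];
  for (int d = 0; d < 3; ++d) { mn[d] = R_PosInf; mx[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      const double v = pts(i, d);
      if (v < mn[d]) { mn[d] = v; argmn[d] = i; }
      if (v > mx[d]) { mx[d] = v; argmx[d] = i; }
    }
  double diag = 0.0;
  for (int d = 0; d < 3; ++d) diag += (mx[d]-mn[d])*(mx[d]-mn[d]);
  diag = std::sqrt(diag);
  if (diag <= 0.0)
    return List::create(_["ok"] = false, _["reason"] = "all points identical");
  QuickHull H(pts);
  H.eps = 1e-10 * diag;
  // initial simplex from extreme points
  int cand[6] = { argmn[0], argmx[0], argmn[1], argmx[1], argmn[2], argmx[2] };
  int p0 = -1, p1 = -1; double best = -1.0;
  for (int a = 0; a < 6; ++a) for (int b = a + 1; b < 6; ++b) {
    double d2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      const double dd = pts(cand[a], d) - pts(cand[b], d);
      d2 += dd * dd;
    }
    if (d2 > best) { best = d2; p0 = cand[a]; p1 = cand[b]; }
  }
  if (best <= 0.0)
    return List::create(_["ok"] = false, _["reason"] = "degenerate");
  int p2 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    const double ux = pts(i,0)-pts(p0,0), uy = pts(i,1)-pts(p0,1), uz = pts(i,2)-pts(p0,2);
    const double vx = pts(p1,0)-pts(p0,0), vy = pts(p1,1)-pts(p0,1), vz = pts(p1,2)-pts(p0,2);
    const double cx = uy*vz-uz*vy, cy = uz*vx-ux*vz, cz = ux*vy-uy*vx;
    const double a2 = cx*cx + cy*cy + cz*cz;
    if (a2 > best) { best = a2; p2 = i; }
  }
  if (best <= H.eps * H.eps)
    return List::create(_["ok"] = false, _["reason"] = "points are collinear");
  int p3 = -1; best = 0.0;
  double q0[3], q1[3], q2[3], qq[3];
  H.get(p0, q0); H.get(p1, q1); H.get(p2, q2);
  for (int i = 0; i < n; ++i) {
    H.get(i, qq);
    const double o = orient3d(q0, q1, q2, qq);
    if (std::fabs(o) > std::fabs(best)) { best = o; p3 = i; }
  }
  if (p3 < 0 || std::fabs(best) <= H.eps * H.eps * H.eps)
    return List::create(_["ok"] = false, _["reason"] = "points are coplanar");
  if (best > 0) std::swap(p0, p1);  // make orient3d(p0,p1,p2,p3) < 0 so faces below are outward
  // four outward faces of tet (p0,p1,p2,p3)
  const int fv[4][3] = { {p0,p1,p2}, {p0,p3,p1}, {p1,p3,p2}, {p0,p2,p3} };
  for (int i = 0; i < 4; ++i) {
    QHFace f;
    f.v[0] = fv[i][0]; f.v[1] = fv[i][1]; f.v[2] = fv[i][2];
    f.nb[0] = f.nb[1] = f.nb[2] = -1;
    H.set_plane(f);
    H.faces.push_back(f);
  }
  // orientation sanity: centroid of simplex must be below every face
  {
    double c[3] = {0,0,0};
    const int s[4] = {p0,p1,p2,p3};
    for (int i = 0; i < 4; ++i) { H.get(s[i], qq); for (int d = 0; d < 3; ++d) c[d] += qq[d]/4.0; }
    for (auto& f : H.faces) {
      const double dd = f.nx*c[0]+f.ny*c[1]+f.nz*c[2]-f.off;
      if (dd > 0) { std::swap(f.v[1], f.v[2]); H.set_plane(f); }
    }
  }
  // neighbor stitching via directed-edge map
  auto stitch_all = [&](std::vector<int> idx) {
    std::unordered_map<uint64_t, std::pair<int,int>> em;
    const uint64_t M = (uint64_t)n + 1;
    for (int fi : idx) {
      QHFace& f = H.faces[fi];
      for (int e = 0; e < 3; ++e) {
        const int a = f.v[e], b = f.v[(e+1)%3];
        const uint64_t key = (uint64_t)std::min(a,b) * M + std::max(a,b);
        auto it = em.find(key);
        if (it == em.end()) em[key] = { fi, e };
        else {
          f.nb[e] = it->second.first;
          H.faces[it->second.first].nb[it->second.second] = fi;
          em.erase(it);
        }
      }
    }
    return em.empty();
  };
  if (!stitch_all({0,1,2,3}))
    return List::create(_["ok"] = false, _["reason"] = "bad initial simplex");
  // assign outside sets
  std::vector<int> pending;
  for (int i = 0; i < n; ++i) {
    if (i == p0 || i == p1 || i == p2 || i == p3) continue;
    for (auto& f : H.faces) {
      if (H.above(f, i)) {
        const double d = H.dist(f, i);
        f.out.push_back(i);
        if (d > f.far_d) { f.far_d = d; f.far_pt = i; }
        break;
      }
    }
  }
  // main loop
  for (size_t fi = 0; fi < H.faces.size(); ++fi) {
    Rcpp::checkUserInterrupt();
    if (H.faces[fi].dead_ || H.faces[fi].far_pt < 0) continue;
    const int p = H.faces[fi].far_pt;
    // find visible faces (BFS)
    std::vector<int> vis{(int)fi}, stack{(int)fi};
    H.faces[fi].dead_ = true;
    struct HEdge { int face, e, nb; };
    std::vector<HEdge> horizon;
    while (!stack.empty()) {
      const int t = stack.back(); stack.pop_back();
      for (int e = 0; e < 3; ++e) {
        const int u = H.faces[t].nb[e];
        if (u < 0) return List::create(_["ok"] = false, _["reason"] = "open hull");
        if (H.faces[u].dead_) continue;
        if (H.dist(H.faces[u], p) > H.eps * H.faces[u].nlen) {
          H.faces[u].dead_ = true;
          vis.push_back(u);
          stack.push_back(u);
        } else {
          horizon.push_back({t, e, u});
        }
      }
    }
    // build new faces over horizon edges
    std::vector<int> created;
    std::unordered_map<uint64_t, std::pair<int,int>> em;
    const uint64_t M = (uint64_t)n + 1;
    for (const auto& he : horizon) {
      const QHFace& old = H.faces[he.face];
      const int a = old.v[he.e], b = old.v[(he.e + 1) % 3];
      QHFace f;
      f.v[0] = a; f.v[1] = b; f.v[2] = p;
      f.nb[0] = he.nb; f.nb[1] = f.nb[2] = -1;
      H.set_plane(f);
      const int nfi = (int)H.faces.size();
      H.faces.push_back(f);
      created.push_back(nfi);
      // patch the non-visible neighbor's pointer
      QHFace& nbf = H.faces[he.nb];
      for (int e2 = 0; e2 < 3; ++e2)
        if (nbf.nb[e2] == he.face) { nbf.nb[e2] = nfi; break; }
      // stitch edges (b,p) [e=1] and (p,a) [e=2] among new faces
      for (int e2 = 1; e2 <= 2; ++e2) {
        const int x = H.faces[nfi].v[e2], y = H.faces[nfi].v[(e2+1)%3];
        const uint64_t key = (uint64_t)std::min(x,y) * M + std::max(x,y);
        auto it = em.find(key);
        if (it == em.end()) em[key] = { nfi, e2 };
        else {
          H.faces[nfi].nb[e2] = it->second.first;
          H.faces[it->second.first].nb[it->second.second] = nfi;
          em.erase(it);
        }
      }
    }
    if (!em.empty())
      return List::create(_["ok"] = false, _["reason"] = "broken horizon");
    // reassign outside points of visible faces
    for (int t : vis) {
      for (int i : H.faces[t].out) {
        if (i == p) continue;
        for (int nfi : created) {
          QHFace& f = H.faces[nfi];
          if (H.above(f, i)) {
            const double d = H.dist(f, i);
            f.out.push_back(i);
            if (d > f.far_d) { f.far_d = d; f.far_pt = i; }
            break;
          }
        }
      }
      H.faces[t].out.clear();
      H.faces[t].out.shrink_to_fit();
    }
    fi = (size_t)-1;  // restart scan from the beginning (simple & safe)
  }
  // volume + facets
  double c[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) c[d] += pts(i, d) / n;
  double vol = 0.0, area = 0.0;
  int nf = 0;
  for (const auto& f : H.faces) if (!f.dead_) ++nf;
  IntegerMatrix facets(nf, 3);
  int r = 0;
  for (const auto& f : H.faces) {
    if (f.dead_) continue;
    double a[3], b[3], cc[3];
    H.get(f.v[0], a); H.get(f.v[1], b); H.get(f.v[2], cc);
    vol += orient3d(c, a, b, cc) / 6.0;
    area += 0.5 * f.nlen;
    for (int d = 0; d < 3; ++d) facets(r, d) = f.v[d] + 1;
    ++r;
  }
  return List::create(_["ok"] = true, _["volume"] = vol, _["area"] = area,
                      _["facets"] = facets);
}
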