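// Digital/PL topology on the Freudenthal (6-tetrahedra) decomposition of the
// voxel lattice: connected components, cavity filling, homotopic topology
// correction via simple-point tests on the vertex link, and topology-aware
// isosurface extraction by marching tetrahedra on the same complex.
//
// Key fact exploited throughout: the sublevel set {phi < 0} of the piecewise
// linear interpolant on this complex deformation-retracts onto the full
// subcomplex spanned by the negative voxels, so region topology (as corrected
// here) and extracted-mesh topology provably agree.
#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <cstdint>
#include <functional>
#include <queue>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

struct Off { int x, y, z; };

// The 6 tetrahedra of the unit cube (Freudenthal/Kuhn): chains 0 -> e_{s1}
// -> e_{s1}+e_{s2} -> (1,1,1) over permutations (s1,s2,s3) of the axes.
const int PERMS[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};

void cube_tets(int tets[6][4][3]) {
  for (int t = 0; t < 6; ++t) {
    int p[4][3] = {{0,0,0},{0,0,0},{0,0,0},{1,1,1}};
    p[1][PERMS[t][0]] = 1;
    p[2][PERMS[t][0]] = 1; p[2][PERMS[t][1]] = 1;
    for (int v = 0; v < 4; ++v)
      for (int d = 0; d < 3; ++d) tets[t][v][d] = p[v][d];
  }
}

// Link of the origin in the Freudenthal complex: 14 vertices, 36 edges,
// 24 triangles (a triangulated 2-sphere). Built once by enumerating all
// lattice tetrahedra incident to the origin.
struct LinkTables {
  std::vector<Off> verts;                 // 14 neighbour offsets
  std::vector<std::array<int,2>> edges;   // indices into verts
  std::vector<std::array<int,3>> tris;    // indices into verts
  int index_of(int x, int y, int z) const {
    for (size_t i = 0; i < verts.size(); ++i)
      if (verts[i].x == x && verts[i].y == y && verts[i].z == z) return (int)i;
    return -1;
  }
};

const LinkTables &link_tables() {
  static LinkTables L = [] {
    LinkTables T;
    int tets[6][4][3];
    cube_tets(tets);
    std::vector<std::array<std::array<int,3>,3>> raw_tris;
    for (int mx = -1; mx <= 0; ++mx)
      for (int my = -1; my <= 0; ++my)
        for (int mz = -1; mz <= 0; ++mz)
          for (int t = 0; t < 6; ++t) {
            int corner[4][3];
            int hit = -1;
            for (int v = 0; v < 4; ++v) {
              corner[v][0] = mx + tets[t][v][0];
              corner[v][1] = my + tets[t][v][1];
              corner[v][2] = mz + tets[t][v][2];
              if (!corner[v][0] && !corner[v][1] && !corner[v][2]) hit = v;
            }
            if (hit < 0) continue;
            std::array<std::array<int,3>,3> tri;
            int w = 0;
            for (int v = 0; v < 4; ++v)
              if (v != hit) { tri[w][0]=corner[v][0]; tri[w][1]=corner[v][1]; tri[w][2]=corner[v][2]; ++w; }
            raw_tris.push_back(tri);
          }
    // collect vertices
    for (auto &tri : raw_tris)
      for (int v = 0; v < 3; ++v) {
        bool found = false;
        for (auto &o : T.verts)
          if (o.x == tri[v][0] && o.y == tri[v][1] && o.z == tri[v][2]) { found = true; break; }
        if (!found) T.verts.push_back({tri[v][0], tri[v][1], tri[v][2]});
      }
    auto idx = [&](const std::array<int,3> &p) { return T.index_of(p[0], p[1], p[2]); };
    std::vector<std::array<int,2>> eset;
    for (auto &tri : raw_tris) {
      std::array<int,3> ti = {idx(tri[0]), idx(tri[1]), idx(tri[2])};
      std::sort(ti.begin(), ti.end());
      bool dup = false;
      for (auto &ex : T.tris) if (ex == ti) { dup = true; break; }
      if (!dup) T.tris.push_back(ti);
    }
    for (auto &tri : T.tris)
      for (int e = 0; e < 3; ++e) {
        std::array<int,2> ed = {tri[e], tri[(e+1)%3]};
        if (ed[0] > ed[1]) std::swap(ed[0], ed[1]);
        bool dup = false;
        for (auto &ex : T.edges) if (ex == ed) { dup = true; break; }
        if (!dup) T.edges.push_back(ed);
      }
    return T;
  }();
  return L;
}

// Is the full subcomplex of the link spanned by `in` (bitmask over the 14
// link vertices) nonempty, connected and of Euler characteristic 1?
bool disk_like(uint32_t in) {
  const LinkTables &L = link_tables();
  int nV = 0;
  int root[14];
  for (int i = 0; i < 14; ++i) root[i] = i;
  std::function<int(int)> find = [&](int a) { while (root[a] != a) a = root[a] = root[root[a]]; return a; };
  for (int i = 0; i < 14; ++i) if (in & (1u << i)) ++nV;
  if (nV == 0) return false;
  int nE = 0, nT = 0;
  for (auto &e : L.edges)
    if ((in & (1u << e[0])) && (in & (1u << e[1]))) {
      ++nE;
      int a = find(e[0]), b = find(e[1]);
      if (a != b) root[a] = b;
    }
  for (auto &t : L.tris)
    if ((in & (1u << t[0])) && (in & (1u << t[1])) && (in & (1u << t[2]))) ++nT;
  // connected?
  int comp = -1;
  for (int i = 0; i < 14; ++i)
    if (in & (1u << i)) {
      int r = find(i);
      if (comp < 0) comp = r;
      else if (r != comp) return false;
    }
  return (nV - nE + nT) == 1;
}

struct Grid {
  int ni, nj, nk;
  size_t n() const { return (size_t)ni * nj * nk; }
  bool in(int i, int j, int k) const {
    return i >= 0 && j >= 0 && k >= 0 && i < ni && j < nj && k < nk;
  }
  size_t id(int i, int j, int k) const { return (size_t)i + (size_t)ni * (j + (size_t)nj * k); }
};

// Simple-point test: may voxel (i,j,k) be added to `region` without changing
// its PL topology? Outside-grid neighbours count as background.
bool simple_point(const Grid &g, const std::vector<char> &region, int i, int j, int k) {
  const LinkTables &L = link_tables();
  uint32_t fg = 0, bg = 0;
  for (size_t v = 0; v < L.verts.size(); ++v) {
    int a = i + L.verts[v].x, b = j + L.verts[v].y, c = k + L.verts[v].z;
    bool is_fg = g.in(a, b, c) && region[g.id(a, b, c)];
    if (is_fg) fg |= (1u << v); else bg |= (1u << v);
  }
  return disk_like(fg) && disk_like(bg);
}

std::vector<Off> neighbourhood(int connectivity) {
  std::vector<Off> off;
  if (connectivity == 6) {
    off = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  } else if (connectivity == 26) {
    for (int z = -1; z <= 1; ++z)
      for (int y = -1; y <= 1; ++y)
        for (int x = -1; x <= 1; ++x)
          if (x || y || z) off.push_back({x, y, z});
  } else { // 14: Freudenthal adjacency
    const LinkTables &L = link_tables();
    for (auto &o : L.verts) off.push_back(o);
  }
  return off;
}

} // namespace

// Connected components of a logical mask. connectivity in {6, 14, 26};
// 14 is the Freudenthal complex adjacency. Labels start at 1, ordered by
// decreasing component size; 0 outside the mask.
// [[Rcpp::export]]
IntegerVector cpp_components(LogicalVector mask, IntegerVector dims, int connectivity) {
  Grid g{dims[0], dims[1], dims[2]};
  std::vector<Off> off = neighbourhood(connectivity);
  IntegerVector lab(g.n());
  std::vector<uint32_t> stack;
  int next = 0;
  std::vector<std::pair<size_t,int>> sizes; // (size, label)
  for (size_t s = 0; s < g.n(); ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    size_t sz = 0;
    stack.clear();
    stack.push_back((uint32_t)s);
    lab[s] = next;
    while (!stack.empty()) {
      uint32_t id = stack.back(); stack.pop_back();
      ++sz;
      int i = id % g.ni, j = (id / g.ni) % g.nj, k = id / ((size_t)g.ni * g.nj);
      for (auto &o : off) {
        int a = i + o.x, b = j + o.y, c = k + o.z;
        if (!g.in(a, b, c)) continue;
        size_t q = g.id(a, b, c);
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back((uint32_t)q); }
      }
    }
    sizes.push_back({sz, next});
  }
  // relabel by decreasing size
  std::sort(sizes.begin(), sizes.end(), [](auto &a, auto &b) { return a.first > b.first; });
  std::vector<int> remap(next + 1, 0);
  for (size_t r = 0; r < sizes.size(); ++r) remap[sizes[r].second] = (int)r + 1;
  for (size_t s = 0; s < g.n(); ++s) if (lab[s]) lab[s] = remap[lab[s]];
  lab.attr("dim") = dims;
  return lab;
}

// Homotopic topology correction of a level set. Fills interior cavities,
// then grows a region from the most-interior voxel (minimum phi), admitting
// negative voxels in increasing-phi order only while they are simple points
// of the Freudenthal complex. phi is re-signed so that its negative set is
// exactly the corrected region; flipped voxels are clamped to +/- kappa.
// [[Rcpp::export]]
List cpp_correct_topology(NumericVector phi, IntegerVector dims, double kappa,
                          IntegerVector seed_voxel = IntegerVector::create()) {
  Grid g{dims[0], dims[1], dims[2]};
  size_t n = g.n();
  NumericVector out = clone(phi);
  // 1. cavity fill: background components (14-adjacency) not touching the
  // grid border become foreground at -kappa.
  LogicalVector bgmask(n);
  for (size_t s = 0; s < n; ++s) bgmask[s] = out[s] >= 0;
  IntegerVector bglab = cpp_components(bgmask, dims, 14);
  int nbg = 0;
  for (size_t s = 0; s < n; ++s) nbg = std::max(nbg, (int)bglab[s]);
  std::vector<char> touches(nbg + 1, 0);
  for (int k = 0; k < g.nk; ++k)
    for (int j = 0; j < g.nj; ++j)
      for (int i = 0; i < g.ni; ++i)
        if (i == 0 || j == 0 || k == 0 || i == g.ni-1 || j == g.nj-1 || k == g.nk-1) {
          int l = bglab[g.id(i, j, k)];
          if (l) touches[l] = 1;
        }
  int n_filled = 0;
  for (size_t s = 0; s < n; ++s)
    if (bglab[s] && !touches[bglab[s]]) { out[s] = -kappa; ++n_filled; }
  // 2. homotopic growth
  std::vector<char> region(n, 0);
  std::vector<char> queued(n, 0);
  using QE = std::pair<double, uint32_t>;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  // seed: global minimum, or a caller-specified voxel (e.g. the most
  // interior voxel of a hemisphere mask)
  size_t seed = 0;
  double mn = R_PosInf;
  if (seed_voxel.size() == 3) {
    seed = g.id(seed_voxel[0], seed_voxel[1], seed_voxel[2]);
    mn = out[seed];
  } else {
    for (size_t s = 0; s < n; ++s)
      if (out[s] < mn) { mn = out[s]; seed = s; }
  }
  if (!(mn < 0)) stop("level set has no negative voxel at the seed");
  const LinkTables &L = link_tables();
  auto push_neighbours = [&](size_t id) {
    int i = id % g.ni, j = (id / g.ni) % g.nj, k = id / ((size_t)g.ni * g.nj);
    for (auto &o : L.verts) {
      int a = i + o.x, b = j + o.y, c = k + o.z;
      if (!g.in(a, b, c)) continue;
      size_t q = g.id(a, b, c);
      if (!region[q] && out[q] < 0) {
        pq.push({out[q], (uint32_t)q});
        queued[q] = 1;
      }
    }
  };
  region[seed] = 1;
  push_neighbours(seed);
  while (!pq.empty()) {
    auto [val, id] = pq.top();
    pq.pop();
    if (region[id]) continue;
    int i = id % g.ni, j = (id / g.ni) % g.nj, k = id / ((size_t)g.ni * g.nj);
    if (!simple_point(g, region, i, j, k)) continue; // re-pushed if a neighbour joins later
    region[id] = 1;
    push_neighbours(id);
  }
  // 3. re-sign
  int n_flipped = 0;
  for (size_t s = 0; s < n; ++s) {
    bool neg = out[s] < 0;
    bool in = region[s];
    if (neg && !in) { out[s] = kappa; ++n_flipped; }
    else if (!neg && in) { out[s] = -kappa; ++n_flipped; } // cannot occur: growth stays in {phi<0}
  }
  LogicalVector reg(n);
  for (size_t s = 0; s < n; ++s) reg[s] = region[s] != 0;
  out.attr("dim") = dims;
  reg.attr("dim") = dims;
  return List::create(_["phi"] = out, _["region"] = reg,
                      _["n_filled"] = n_filled, _["n_flipped"] = n_flipped);
}

// Marching tetrahedra on the Freudenthal decomposition. Vertices at linear
// zero crossings on tetrahedral edges (welded via global edge keys, hence
// watertight); triangles oriented with normals pointing towards positive phi
// (outside). Returns world-mm vertices via the affine.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector phi, IntegerVector dims, NumericMatrix affine) {
  Grid g{dims[0], dims[1], dims[2]};
  int tets[6][4][3];
  cube_tets(tets);
  // adjusted sign: exact zeros treated as inside (shifted by a tiny negative)
  auto val = [&](size_t id) {
    double v = phi[id];
    return v == 0.0 ? -1e-12 : v;
  };
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> VX, VY, VZ; // index coords
  std::vector<std::array<int,3>> faces;
  auto vertex_on_edge = [&](size_t ida, size_t idb) {
    uint64_t a = ida, b = idb;
    if (a > b) std::swap(a, b);
    uint64_t key = (a << 32) | b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double fa = val(a), fb = val(b);
    double t = fa / (fa - fb);
    int ia = a % g.ni, ja = (a / g.ni) % g.nj, ka = a / ((size_t)g.ni * g.nj);
    int ib = b % g.ni, jb = (b / g.ni) % g.nj, kb = b / ((size_t)g.ni * g.nj);
    VX.push_back(ia + t * (ib - ia));
    VY.push_back(ja + t * (jb - ja));
    VZ.push_back(ka + t * (kb - ka));
    int idx = (int)VX.size() - 1;
    edge_vertex[key] = idx;
    return idx;
  };
  auto emit = [&](int p1, int p2, int p3, const double d[3]) {
    // orient so normal . d > 0 (d points to the positive side)
    double ux = VX[p2]-VX[p1], uy = VY[p2]-VY[p1], uz = VZ[p2]-VZ[p1];
    double vx = VX[p3]-VX[p1], vy = VY[p3]-VY[p1], vz = VZ[p3]-VZ[p1];
    double nx = uy*vz - uz*vy, ny = uz*vx - ux*vz, nz = ux*vy - uy*vx;
    if (nx*d[0] + ny*d[1] + nz*d[2] >= 0) faces.push_back({p1+1, p2+1, p3+1});
    else faces.push_back({p1+1, p3+1, p2+1});
  };
  for (int k = 0; k + 1 < g.nk; ++k)
    for (int j = 0; j + 1 < g.nj; ++j)
      for (int i = 0; i + 1 < g.ni; ++i)
        for (int t = 0; t < 6; ++t) {
          size_t cid[4];
          double f[4];
          double ci[4][3];
          for (int v = 0; v < 4; ++v) {
            int a = i + tets[t][v][0], b = j + tets[t][v][1], c = k + tets[t][v][2];
            cid[v] = g.id(a, b, c);
            f[v] = val(cid[v]);
            ci[v][0] = a; ci[v][1] = b; ci[v][2] = c;
          }
          int neg[4], pos[4], nn = 0, np = 0;
          for (int v = 0; v < 4; ++v) {
            if (f[v] < 0) neg[nn++] = v; else pos[np++] = v;
          }
          if (nn == 0 || nn == 4) continue;
          // direction towards positive side (exact for the linear field)
          double cpos[3] = {0,0,0}, cneg[3] = {0,0,0};
          for (int v = 0; v < np; ++v)
            for (int d = 0; d < 3; ++d) cpos[d] += ci[pos[v]][d] / np;
          for (int v = 0; v < nn; ++v)
            for (int d = 0; d < 3; ++d) cneg[d] += ci[neg[v]][d] / nn;
          double dir[3] = {cpos[0]-cneg[0], cpos[1]-cneg[1], cpos[2]-cneg[2]};
          if (nn == 1) {
            int p1 = vertex_on_edge(cid[neg[0]], cid[pos[0]]);
            int p2 = vertex_on_edge(cid[neg[0]], cid[pos[1]]);
            int p3 = vertex_on_edge(cid[neg[0]], cid[pos[2]]);
            emit(p1, p2, p3, dir);
          } else if (nn == 3) {
            int p1 = vertex_on_edge(cid[pos[0]], cid[neg[0]]);
            int p2 = vertex_on_edge(cid[pos[0]], cid[neg[1]]);
            int p3 = vertex_on_edge(cid[pos[0]], cid[neg[2]]);
            emit(p1, p2, p3, dir);
          } else { // 2-2: planar quad, split into two triangles
            int pac = vertex_on_edge(cid[neg[0]], cid[pos[0]]);
            int pad = vertex_on_edge(cid[neg[0]], cid[pos[1]]);
            int pbd = vertex_on_edge(cid[neg[1]], cid[pos[1]]);
            int pbc = vertex_on_edge(cid[neg[1]], cid[pos[0]]);
            emit(pac, pad, pbd, dir);
            emit(pac, pbd, pbc, dir);
          }
        }
  if (faces.empty()) stop("no zero crossing: surface outside grid");
  int nv = (int)VX.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = affine(0,0)*VX[v] + affine(0,1)*VY[v] + affine(0,2)*VZ[v] + affine(0,3);
    V(v, 1) = affine(1,0)*VX[v] + affine(1,1)*VY[v] + affine(1,2)*VZ[v] + affine(1,3);
    V(v, 2) = affine(2,0)*VX[v] + affine(2,1)*VY[v] + affine(2,2)*VZ[v] + affine(2,3);
  }
  // world orientation: flip faces if the affine reverses handedness
  double det =
    affine(0,0)*(affine(1,1)*affine(2,2)-affine(1,2)*affine(2,1)) -
    affine(0,1)*(affine(1,0)*affine(2,2)-affine(1,2)*affine(2,0)) +
    affine(0,2)*(affine(1,0)*affine(2,1)-affine(1,1)*affine(2,0));
  IntegerMatrix Fm((int)faces.size(), 3);
  for (size_t fi = 0; fi < faces.size(); ++fi) {
    if (det >= 0) {
      Fm(fi,0)=faces[fi][0]; Fm(fi,1)=faces[fi][1]; Fm(fi,2)=faces[fi][2];
    } else {
      Fm(fi,0)=faces[fi][0]; Fm(fi,1)=faces[fi][2]; Fm(fi,2)=faces[fi][1];
    }
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// Expose the simple-point decision for oracle tests on tiny grids.
// [[Rcpp::export]]
bool cpp_is_simple(LogicalVector region, IntegerVector dims, IntegerVector voxel) {
  Grid g{dims[0], dims[1], dims[2]};
  std::vector<char> reg(g.n());
  for (size_t s = 0; s < g.n(); ++s) reg[s] = region[s] != 0;
  return simple_point(g, reg, voxel[0], voxel[1], voxel[2]);
}

// Counts (V, E, F, T) of the full Freudenthal subcomplex spanned by a voxel
// set, for exhaustive Euler-characteristic oracles on small grids.
// [[Rcpp::export]]
IntegerVector cpp_subcomplex_counts(LogicalVector mask, IntegerVector dims) {
  Grid g{dims[0], dims[1], dims[2]};
  int tets[6][4][3];
  cube_tets(tets);
  long nV = 0, nE = 0, nF = 0, nT = 0;
  for (size_t s = 0; s < g.n(); ++s) if (mask[s]) ++nV;
  // enumerate simplices cube by cube; each tet contributes its faces, with
  // dedup handled by counting only simplices whose lexicographically smallest
  // containing-tet... instead: enumerate edges/triangles globally via offsets.
  const LinkTables &L = link_tables();
  // edges: each vertex pairs with "positive" half of its 14 neighbours
  for (int k = 0; k < g.nk; ++k)
    for (int j = 0; j < g.nj; ++j)
      for (int i = 0; i < g.ni; ++i) {
        if (!mask[g.id(i, j, k)]) continue;
        for (auto &o : L.verts) {
          if (o.z > 0 || (o.z == 0 && (o.y > 0 || (o.y == 0 && o.x > 0)))) {
            int a = i + o.x, b = j + o.y, c = k + o.z;
            if (g.in(a, b, c) && mask[g.id(a, b, c)]) ++nE;
          }
        }
      }
  // triangles and tets: enumerate per cube (each tet unique to a cube; each
  // triangle either interior to one cube or shared by two -> count triangles
  // via tets' faces with dedup by canonical containing cube)
  std::vector<std::array<std::array<int,3>,3>> tri_offsets; // canonical triangle list per cube
  {
    // build unique triangle list within a cube from its 6 tets; a triangle on
    // a shared cube face (all coords with some axis equal to 0) is counted by
    // the cube for which it lies on the 0-face, not the 1-face.
    std::vector<std::array<std::array<int,3>,3>> all;
    for (int t = 0; t < 6; ++t)
      for (int drop = 0; drop < 4; ++drop) {
        std::array<std::array<int,3>,3> tri;
        int w = 0;
        for (int v = 0; v < 4; ++v)
          if (v != drop) { tri[w][0]=tets[t][v][0]; tri[w][1]=tets[t][v][1]; tri[w][2]=tets[t][v][2]; ++w; }
        std::sort(tri.begin(), tri.end());
        all.push_back(tri);
      }
    std::sort(all.begin(), all.end());
    all.erase(std::unique(all.begin(), all.end()), all.end());
    for (auto &tri : all) {
      bool on_one_face = false;
      for (int d = 0; d < 3; ++d)
        if (tri[0][d] == 1 && tri[1][d] == 1 && tri[2][d] == 1) on_one_face = true;
      if (!on_one_face) tri_offsets.push_back(tri); // counted by the cube whose 1-face it is NOT on
    }
  }
  for (int k = 0; k + 1 < g.nk || k < g.nk; ++k) {
    if (k >= g.nk) break;
    for (int j = 0; j < g.nj; ++j)
      for (int i = 0; i < g.ni; ++i) {
        // triangles anchored at cube (i,j,k); offsets may reach i+1 etc.
        for (auto &tri : tri_offsets) {
          bool ok = true;
          for (int v = 0; v < 3 && ok; ++v) {
            int a = i + tri[v][0], b = j + tri[v][1], c = k + tri[v][2];
            if (!g.in(a, b, c) || !mask[g.id(a, b, c)]) ok = false;
          }
          if (ok) ++nF;
        }
        if (i + 1 < g.ni && j + 1 < g.nj && k + 1 < g.nk) {
          for (int t = 0; t < 6; ++t) {
            bool ok = true;
            for (int v = 0; v < 4 && ok; ++v) {
              int a = i + tets[t][v][0], b = j + tets[t][v][1], c = k + tets[t][v][2];
              if (!mask[g.id(a, b, c)]) ok = false;
            }
            if (ok) ++nT;
          }
        }
      }
  }
  return IntegerVector::create(_["V"] = (int)nV, _["E"] = (int)nE,
                               _["F"] = (int)nF, _["T"] = (int)nT);
}
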