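#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <map>
#include <set>
#include <algorithm>
using namespace Rcpp;

// Quadric edge-collapse decimation (Garland & Heckbert error quadrics,
// lazy min-heap, link-condition and normal-flip guards).

namespace {

struct Quadric {
  double q[10]; // symmetric 4x4: 11,12,13,14,22,23,24,33,34,44
  Quadric() { std::fill(q, q + 10, 0.0); }
  void add_plane(double a, double b, double c, double d, double area) {
    double s = area;
    q[0] += s*a*a; q[1] += s*a*b; q[2] += s*a*c; q[3] += s*a*d;
    q[4] += s*b*b; q[5] += s*b*c; q[6] += s*b*d;
    q[7] += s*c*c; q[8] += s*c*d; q[9] += s*d*d;
  }
  Quadric operator+(const Quadric& o) const {
    Quadric r;
    for (int i = 0; i < 10; ++i) r.q[i] = q[i] + o.q[i];
    return r;
  }
  double eval(const double* v) const {
    double x = v[0], y = v[1], z = v[2];
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z + q[9];
  }
  // minimise v'Qv over v: solve A v = -b with A the 3x3 block
  bool optimal(double* v) const {
    double a11 = q[0], a12 = q[1], a13 = q[2];
    double a22 = q[4], a23 = q[5], a33 = q[7];
    double b1 = -q[3], b2 = -q[6], b3 = -q[8];
    double det = a11*(a22*a33 - a23*a23) - a12*(a12*a33 - a23*a13)
               + a13*(a12*a23 - a22*a13);
    double scale = std::max({std::fabs(a11), std::fabs(a22), std::fabs(a33), 1e-12});
    if (std::fabs(det) < 1e-10 * scale * scale * scale) return false;
    double inv = 1.0 / det;
    v[0] = inv * (b1*(a22*a33 - a23*a23) + b2*(a13*a23 - a12*a33) + b3*(a12*a23 - a13*a22));
    v[1] = inv * (b1*(a23*a13 - a12*a33) + b2*(a11*a33 - a13*a13) + b3*(a12*a13 - a11*a23));
    v[2] = inv * (b1*(a12*a23 - a22*a13) + b2*(a12*a13 - a11*a23) + b3*(a11*a22 - a12*a12));
    return true;
  }
};

struct HeapEntry {
  double cost;
  int u, v, ver_u, ver_v;
  double pos[3];
  bool operator<(const HeapEntry& o) const { return cost > o.cost; } // min-heap
};

} // namespace

// [[Rcpp::export]]
List cpp_decimate(NumericMatrix Vm, IntegerMatrix Fm, int target) {
  int nv = Vm.nrow(), nf = Fm.nrow();
  std::vector<std::array<double,3>> V(nv);
  for (int i = 0; i < nv; ++i) for (int k = 0; k < 3; ++k) V[i][k] = Vm(i, k);
  std::vector<std::array<int,3>> F(nf);
  for (int i = 0; i < nf; ++i) for (int k = 0; k < 3; ++k) F[i][k] = Fm(i, k) - 1;

  // manifoldness check: every undirected edge on at most 2 faces
  {
    std::map<std::pair<int,int>, int> ecount;
    for (int i = 0; i < nf; ++i) {
      for (int k = 0; k < 3; ++k) {
        int a = F[i][k], b = F[i][(k + 1) % 3];
        if (a == b) stop("degenerate face in input mesh");
        ecount[{std::min(a,b), std::max(a,b)}]++;
      }
    }
    for (auto& kv : ecount)
      if (kv.second > 2) stop("non-manifold input mesh (edge on >2 faces)");
  }

  std::vector<char> v_alive(nv, 1), f_alive(nf, 1);
  std::vector<std::vector<int>> vf(nv); // incident faces
  for (int i = 0; i < nf; ++i) for (int k = 0; k < 3; ++k) vf[F[i][k]].push_back(i);

  // vertex quadrics from area-weighted face planes
  std::vector<Quadric> Q(nv);
  for (int i = 0; i < nf; ++i) {
    const double *a = V[F[i][0]].data(), *b = V[F[i][1]].data(), *c = V[F[i][2]].data();
    double e1[3], e2[3], n[3];
    for (int k = 0; k < 3; ++k) { e1[k] = b[k]-a[k]; e2[k] = c[k]-a[k]; }
    n[0] = e1[1]*e2[2] - e1[2]*e2[1];
    n[1] = e1[2]*e2[0] - e1[0]*e2[2];
    n[2] = e1[0]*e2[1] - e1[1]*e2[0];
    double nn = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    if (nn < 1e-14) continue;
    double area = 0.5 * nn;
    for (int k = 0; k < 3; ++k) n[k] /= nn;
    double d = -(n[0]*a[0] + n[1]*a[1] + n[2]*a[2]);
    for (int k = 0; k < 3; ++k) Q[F[i][k]].add_plane(n[0], n[1], n[2], d, area);
  }

  std::vector<int> version(nv, 0);
  std::priority_queue<HeapEntry> heap;

  auto push_edge = [&](int u, int v) {
    if (u > v) std::swap(u, v);
    Quadric s = Q[u] + Q[v];
    HeapEntry h;
    h.u = u; h.v = v; h.ver_u = version[u]; h.ver_v = version[v];
    double opt[3];
    if (s.optimal(opt)) {
      h.pos[0] = opt[0]; h.pos[1] = opt[1]; h.pos[2] = opt[2];
      h.cost = s.eval(opt);
    } else {
      double mid[3] = {0.5*(V[u][0]+V[v][0]), 0.5*(V[u][1]+V[v][1]), 0.5*(V[u][2]+V[v][2])};
      const double* cands[3] = {V[u].data(), V[v].data(), mid};
      double best = 1e300; int bi = 0;
      for (int i = 0; i < 3; ++i) {
        double cst = s.eval(cands[i]);
        if (cst < best) { best = cst; bi = i; }
      }
      for (int k = 0; k < 3; ++k) h.pos[k] = cands[bi][k];
      h.cost = best;
    }
    heap.push(h);
  };

  {
    std::set<std::pair<int,int>> seen;
    for (int i = 0; i < nf; ++i) {
      for (int k = 0; k < 3; ++k) {
        int a = F[i][k], b = F[i][(k+1)%3];
        auto key = std::make_pair(std::min(a,b), std::max(a,b));
        if (seen.insert(key).second) push_edge(key.first, key.second);
      }
    }
  }

  auto neighbors = [&](int u) {
    std::set<int> nb;
    for (int fi : vf[u]) {
      if (!f_alive[fi]) continue;
      for (int k = 0; k < 3; ++k) if (F[fi][k] != u) nb.insert(F[fi][k]);
    }
    return nb;
  };

  int alive = nv;
  while (alive > target && !heap.empty()) {
    HeapEntry h = heap.top();
    heap.pop();
    int u = h.u, v = h.v;
    if (!v_alive[u] || !v_alive[v]) continue;
    if (h.ver_u != version[u] || h.ver_v != version[v]) continue;

    // faces sharing edge (u,v)
    std::vector<int> shared;
    for (int fi : vf[u]) {
      if (!f_alive[fi]) continue;
      bool has_v = F[fi][0] == v || F[fi][1] == v || F[fi][2] == v;
      if (has_v) shared.push_back(fi);
    }
    if (shared.empty()) continue; // no longer adjacent

    // link condition: common neighbours must be exactly the shared-face apexes
    std::set<int> nu = neighbors(u), nv_ = neighbors(v), common;
    std::set_intersection(nu.begin(), nu.end(), nv_.begin(), nv_.end(),
                          std::inserter(common, common.begin()));
    if ((int)common.size() != (int)shared.size()) continue;

    // normal-flip guard for surviving faces of u and v
    bool flip = false;
    for (int pass = 0; pass < 2 && !flip; ++pass) {
      int w = pass == 0 ? u : v;
      for (int fi : vf[w]) {
        if (!f_alive[fi]) continue;
        if (std::find(shared.begin(), shared.end(), fi) != shared.end()) continue;
        double before[3], after[3];
        double pt[3][3], pt2[3][3];
        for (int k = 0; k < 3; ++k) {
          int vi = F[fi][k];
          for (int d = 0; d < 3; ++d) {
            pt[k][d] = V[vi][d];
            pt2[k][d] = (vi == w || vi == u || vi == v) ? h.pos[d] : V[vi][d];
          }
        }
        auto nrm = [](double p[3][3], double* out) {
          double e1[3], e2[3];
          for (int d = 0; d < 3; ++d) { e1[d] = p[1][d]-p[0][d]; e2[d] = p[2][d]-p[0][d]; }
          out[0] = e1[1]*e2[2]-e1[2]*e2[1];
          out[1] = e1[2]*e2[0]-e1[0]*e2[2];
          out[2] = e1[0]*e2[1]-e1[1]*e2[0];
        };
        nrm(pt, before); nrm(pt2, after);
        double dot = before[0]*after[0] + before[1]*after[1] + before[2]*after[2];
        double na = std::sqrt(after[0]*after[0]+after[1]*after[1]+after[2]*after[2]);
        if (dot <= 0.0 || na < 1e-14) { flip = true; break; }
      }
    }
    if (flip) continue;

    // perform collapse: v merges into u at h.pos
    for (int k = 0; k < 3; ++k) V[u][k] = h.pos[k];
    for (int fi : shared) f_alive[fi] = 0;
    for (int fi : vf[v]) {
      if (!f_alive[fi]) continue;
      for (int k = 0; k < 3; ++k) if (F[fi][k] == v) F[fi][k] = u;
      vf[u].push_back(fi);
    }
    v_alive[v] = 0;
    Q[u] = Q[u] + Q[v];
    version[u]++; version[v]++;
    alive--;
    for (int nb : neighbors(u)) push_edge(u, nb);
  }

  // compact output
  std::vector<int> remap(nv, -1);
  int nvo = 0;
  for (int i = 0; i < nv; ++i) if (v_alive[i]) remap[i] = nvo++;
  NumericMatrix Vo(nvo, 3);
  for (int i = 0; i < nv; ++i)
    if (v_alive[i]) for (int k = 0; k < 3; ++k) Vo(remap[i], k) = V[i][k];
  std::vector<std::array<int,3>> fo;
  for (int i = 0; i < nf; ++i) {
    if (!f_alive[i]) continue;
    int a = remap[F[i][0]], b = remap[F[i][1]], c = remap[F[i][2]];
    if (a == b || b == c || a == c) continue;
    fo.push_back({a + 1, b + 1, c + 1});
  }
  IntegerMatrix Fo(fo.size(), 3);
  for (size_t i = 0; i < fo.size(); ++i)
    for (int k = 0; k < 3; ++k) Fo(i, k) = fo[i][k];
  return List::create(_["vertices"] = Vo, _["faces"] = Fo);
}
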