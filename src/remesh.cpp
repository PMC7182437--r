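#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <set>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Incremental isotropic remeshing (split / collapse / flip / tangential
// relaxation with back-projection onto the input surface), after
// Botsch & Kobbelt's "A remeshing approach to multiresolution modeling".

namespace {

typedef std::array<double,3> P3;
typedef std::array<int,3> T3;

double dist(const P3& a, const P3& b) {
  double dx = a[0]-b[0], dy = a[1]-b[1], dz = a[2]-b[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// closest point on triangle, see closest.cpp
double closest_on_tri(const double* p, const double* a, const double* b,
                      const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k]=b[k]-a[k]; ac[k]=c[k]-a[k]; ap[k]=p[k]-a[k]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int k=0;k<3;++k) out[k]=a[k]; }
  else {
    double bp[3]; for (int k=0;k<3;++k) bp[k]=p[k]-b[k];
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0 && d4 <= d3) { for (int k=0;k<3;++k) out[k]=b[k]; }
    else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1/(d1-d3);
        for (int k=0;k<3;++k) out[k]=a[k]+v*ab[k];
      } else {
        double cp[3]; for (int k=0;k<3;++k) cp[k]=p[k]-c[k];
        double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
        double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
        if (d6 >= 0 && d5 <= d6) { for (int k=0;k<3;++k) out[k]=c[k]; }
        else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2/(d2-d6);
            for (int k=0;k<3;++k) out[k]=a[k]+w*ac[k];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0 && (d4-d3) >= 0 && (d5-d6) >= 0) {
              double w = (d4-d3)/((d4-d3)+(d5-d6));
              for (int k=0;k<3;++k) out[k]=b[k]+w*(c[k]-b[k]);
            } else {
              double den = 1.0/(va+vb+vc);
              double v = vb*den, w = vc*den;
              for (int k=0;k<3;++k) out[k]=a[k]+ab[k]*v+ac[k]*w;
            }
          }
        }
      }
    }
  }
  double dx=p[0]-out[0], dy=p[1]-out[1], dz=p[2]-out[2];
  return dx*dx+dy*dy+dz*dz;
}

struct Surface {
  std::vector<double> tri, lo, hi;
  int nf;
  Surface(const std::vector<P3>& V, const std::vector<T3>& F) {
    nf = F.size();
    tri.resize(9*nf); lo.resize(3*nf); hi.resize(3*nf);
    for (int i = 0; i < nf; ++i) {
      for (int j = 0; j < 3; ++j)
        for (int k = 0; k < 3; ++k) tri[9*i+3*j+k] = V[F[i][j]][k];
      for (int k = 0; k < 3; ++k) {
        lo[3*i+k] = std::min({tri[9*i+k], tri[9*i+3+k], tri[9*i+6+k]});
        hi[3*i+k] = std::max({tri[9*i+k], tri[9*i+3+k], tri[9*i+6+k]});
      }
    }
  }
  void project(P3& p) const {
    double best = std::numeric_limits<double>::infinity();
    double q[3] = {p[0], p[1], p[2]}, cand[3], bp[3] = {p[0], p[1], p[2]};
    for (int i = 0; i < nf; ++i) {
      double lb = 0;
      for (int k = 0; k < 3; ++k) {
        double d = 0;
        if (q[k] < lo[3*i+k]) d = lo[3*i+k]-q[k];
        else if (q[k] > hi[3*i+k]) d = q[k]-hi[3*i+k];
        lb += d*d;
        if (lb >= best) break;
      }
      if (lb >= best) continue;
      double d2 = closest_on_tri(q, &tri[9*i], &tri[9*i+3], &tri[9*i+6], cand);
      if (d2 < best) { best = d2; bp[0]=cand[0]; bp[1]=cand[1]; bp[2]=cand[2]; }
    }
    p[0]=bp[0]; p[1]=bp[1]; p[2]=bp[2];
  }
};

struct Mesh {
  std::vector<P3> V;
  std::vector<T3> F;
  std::vector<char> f_alive;

  void compact() {
    std::vector<char> used(V.size(), 0);
    std::vector<T3> nf;
    for (size_t i = 0; i < F.size(); ++i) {
      if (!f_alive[i]) continue;
      nf.push_back(F[i]);
      for (int k = 0; k < 3; ++k) used[F[i][k]] = 1;
    }
    std::vector<int> remap(V.size(), -1);
    std::vector<P3> nv;
    for (size_t i = 0; i < V.size(); ++i)
      if (used[i]) { remap[i] = nv.size(); nv.push_back(V[i]); }
    for (auto& f : nf) for (int k = 0; k < 3; ++k) f[k] = remap[f[k]];
    V = nv; F = nf;
    f_alive.assign(F.size(), 1);
  }

  std::map<std::pair<int,int>, std::vector<int>> edge_faces() const {
    std::map<std::pair<int,int>, std::vector<int>> ef;
    for (size_t i = 0; i < F.size(); ++i) {
      if (!f_alive[i]) continue;
      for (int k = 0; k < 3; ++k) {
        int a = F[i][k], b = F[i][(k+1)%3];
        ef[{std::min(a,b), std::max(a,b)}].push_back(i);
      }
    }
    return ef;
  }
};

void split_pass(Mesh& M, double high) {
  auto ef = M.edge_faces();
  std::vector<std::pair<double, std::pair<int,int>>> longe;
  for (auto& kv : ef) {
    double L = dist(M.V[kv.first.first], M.V[kv.first.second]);
    if (L > high) longe.push_back({L, kv.first});
  }
  std::sort(longe.rbegin(), longe.rend());
  for (auto& le : longe) {
    int u = le.second.first, v = le.second.second;
    if (dist(M.V[u], M.V[v]) <= high) continue;
    // faces currently containing edge u,v
    std::vector<int> fs;
    for (size_t i = 0; i < M.F.size(); ++i) {
      if (!M.f_alive[i]) continue;
      const T3& f = M.F[i];
      bool hu=false, hv=false;
      for (int k = 0; k < 3; ++k) { if (f[k]==u) hu=true; if (f[k]==v) hv=true; }
      if (hu && hv) fs.push_back(i);
    }
    if (fs.empty()) continue;
    P3 mid = {0.5*(M.V[u][0]+M.V[v][0]), 0.5*(M.V[u][1]+M.V[v][1]),
              0.5*(M.V[u][2]+M.V[v][2])};
    int w = M.V.size();
    M.V.push_back(mid);
    for (int fi : fs) {
      T3 f = M.F[fi];
      // cyclic order: find position of u followed by v or v followed by u
      for (int k = 0; k < 3; ++k) {
        int a = f[k], b = f[(k+1)%3], c = f[(k+2)%3];
        if ((a == u && b == v) || (a == v && b == u)) {
          M.f_alive[fi] = 0;
          M.F.push_back({a, w, c}); M.f_alive.push_back(1);
          M.F.push_back({w, b, c}); M.f_alive.push_back(1);
          break;
        }
      }
    }
  }
}

void collapse_pass(Mesh& M, double low, double high) {
  M.compact();
  int nv = M.V.size();
  std::vector<std::vector<int>> vfm(nv);
  for (size_t i = 0; i < M.F.size(); ++i)
    for (int k = 0; k < 3; ++k) vfm[M.F[i][k]].push_back(i);
  std::vector<char> v_alive(nv, 1);

  auto neighbors = [&](int u) {
    std::set<int> nb;
    for (int fi : vfm[u]) {
      if (!M.f_alive[fi]) continue;
      for (int k = 0; k < 3; ++k) if (M.F[fi][k] != u) nb.insert(M.F[fi][k]);
    }
    return nb;
  };

  auto ef = M.edge_faces();
  for (auto& kv : ef) {
    int u = kv.first.first, v = kv.first.second;
    if (!v_alive[u] || !v_alive[v]) continue;
    double L = dist(M.V[u], M.V[v]);
    if (L >= low) continue;
    std::vector<int> shared;
    for (int fi : vfm[u]) {
      if (!M.f_alive[fi]) continue;
      const T3& f = M.F[fi];
      bool hv = f[0]==v || f[1]==v || f[2]==v;
      if (hv) shared.push_back(fi);
    }
    if (shared.empty()) continue;
    std::set<int> nu = neighbors(u), nvv = neighbors(v), common;
    std::set_intersection(nu.begin(), nu.end(), nvv.begin(), nvv.end(),
                          std::inserter(common, common.begin()));
    if ((int)common.size() != (int)shared.size()) continue;
    P3 mid = {0.5*(M.V[u][0]+M.V[v][0]), 0.5*(M.V[u][1]+M.V[v][1]),
              0.5*(M.V[u][2]+M.V[v][2])};
    // keep the mesh from growing new long edges
    bool ok = true;
    for (int nb : nu) if (nb != v && dist(mid, M.V[nb]) > high) { ok = false; break; }
    if (ok) for (int nb : nvv) if (nb != u && dist(mid, M.V[nb]) > high) { ok = false; break; }
    if (!ok) continue;
    M.V[u] = mid;
    for (int fi : shared) M.f_alive[fi] = 0;
    for (int fi : vfm[v]) {
      if (!M.f_alive[fi]) continue;
      for (int k = 0; k < 3; ++k) if (M.F[fi][k] == v) M.F[fi][k] = u;
      vfm[u].push_back(fi);
    }
    v_alive[v] = 0;
  }
  M.compact();
}

void flip_pass(Mesh& M) {
  M.compact();
  int nv = M.V.size();
  std::vector<int> val(nv, 0);
  for (auto& f : M.F) for (int k = 0; k < 3; ++k) val[f[k]]++;
  // valence counts each face corner; true valence for closed manifold equals
  // the number of incident faces == number of incident edges
  auto ef = M.edge_faces();
  std::set<std::pair<int,int>> edges;
  for (auto& kv : ef) edges.insert(kv.first);
  for (auto& kv : ef) {
    if (kv.second.size() != 2) continue;
    int f1 = kv.second[0], f2 = kv.second[1];
    if (!M.f_alive[f1] || !M.f_alive[f2]) continue;
    int u = kv.first.first, v = kv.first.second;
    // earlier flips may have moved this edge out of the snapshot faces
    auto has_edge = [&](int fi) {
      bool hu = false, hv = false;
      for (int k = 0; k < 3; ++k) {
        if (M.F[fi][k] == u) hu = true;
        if (M.F[fi][k] == v) hv = true;
      }
      return hu && hv;
    };
    if (!has_edge(f1) || !has_edge(f2)) continue;
    // apexes
    int a = -1, b = -1;
    for (int k = 0; k < 3; ++k) {
      if (M.F[f1][k] != u && M.F[f1][k] != v) a = M.F[f1][k];
      if (M.F[f2][k] != u && M.F[f2][k] != v) b = M.F[f2][k];
    }
    if (a < 0 || b < 0 || a == b) continue;
    if (edges.count({std::min(a,b), std::max(a,b)})) continue; // would duplicate
    auto dev = [&](int vu, int vv, int va, int vb) {
      auto sq = [](int x) { return (double)x * x; };
      return sq(val[vu]-6) + sq(val[vv]-6) + sq(val[va]-6) + sq(val[vb]-6);
    };
    double before = dev(val[u], val[v], val[a], val[b]);
    double after  = dev(val[u]-1, val[v]-1, val[a]+1, val[b]+1);
    if (after >= before) continue;
    // rebuild the two faces preserving orientation: f1 contains (u,v) in some
    // cyclic direction; new faces (u,a?,b?) keep consistent winding
    T3 g1 = M.F[f1];
    bool uv_order = false; // true if f1 traverses u->v
    for (int k = 0; k < 3; ++k)
      if (g1[k] == u && g1[(k+1)%3] == v) uv_order = true;
    if (uv_order) {
      M.F[f1] = {u, b, a};
      M.F[f2] = {v, a, b};
    } else {
      M.F[f1] = {u, a, b};
      M.F[f2] = {v, b, a};
    }
    val[u]--; val[v]--; val[a]++; val[b]++;
    // refresh edge bookkeeping lazily: remove old edge, add new
    edges.erase({std::min(u,v), std::max(u,v)});
    edges.insert({std::min(a,b), std::max(a,b)});
  }
}

void relax_pass(Mesh& M, const Surface& S) {
  M.compact();
  int nv = M.V.size();
  std::vector<P3> acc(nv, {0,0,0});
  std::vector<int> cnt(nv, 0);
  auto ef = M.edge_faces();
  for (auto& kv : ef) {
    int u = kv.first.first, v = kv.first.second;
    for (int k = 0; k < 3; ++k) {
      acc[u][k] += M.V[v][k];
      acc[v][k] += M.V[u][k];
    }
    cnt[u]++; cnt[v]++;
  }
  for (int i = 0; i < nv; ++i) {
    if (cnt[i] == 0) continue;
    P3 p;
    for (int k = 0; k < 3; ++k)
      p[k] = M.V[i][k] + 0.6 * (acc[i][k]/cnt[i] - M.V[i][k]);
    S.project(p);
    M.V[i] = p;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_remesh(NumericMatrix Vm, IntegerMatrix Fm, double target_edge,
                int iterations) {
  Mesh M;
  M.V.resize(Vm.nrow());
  for (int i = 0; i < Vm.nrow(); ++i)
    for (int k = 0; k < 3; ++k) M.V[i][k] = Vm(i, k);
  M.F.resize(Fm.nrow());
  for (int i = 0; i < Fm.nrow(); ++i)
    for (int k = 0; k < 3; ++k) M.F[i][k] = Fm(i, k) - 1;
  M.f_alive.assign(M.F.size(), 1);
  Surface S(M.V, M.F);
  double high = 4.0/3.0 * target_edge, low = 4.0/5.0 * target_edge;
  for (int it = 0; it < iterations; ++it) {
    split_pass(M, high);
    collapse_pass(M, low, high);
    flip_pass(M);
    relax_pass(M, S);
    Rcpp::checkUserInterrupt();
  }
  M.compact();
  NumericMatrix Vo(M.V.size(), 3);
  for (size_t i = 0; i < M.V.size(); ++i)
    for (int k = 0; k < 3; ++k) Vo(i, k) = M.V[i][k];
  IntegerMatrix Fo(M.F.size(), 3);
  for (size_t i = 0; i < M.F.size(); ++i)
    for (int k = 0; k < 3; ++k) Fo(i, k) = M.F[i][k] + 1;
  return List::create(_["vertices"] = Vo, _["faces"] = Fo);
}
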