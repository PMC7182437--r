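#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p (Ericson, Real-Time Collision
// Detection). Writes result into out[3], returns squared distance.
static double closest_on_triangle(const double* p, const double* a,
                                  const double* b, const double* c,
                                  double* out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
  } else {
    double bp[3];
    for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      for (int k = 0; k < 3; ++k) out[k] = b[k];
    } else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
      } else {
        double cp[3];
        for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
        double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
        double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          for (int k = 0; k < 3; ++k) out[k] = c[k];
        } else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
            }
          }
        }
      }
    }
  }
  double dx = p[0]-out[0], dy = p[1]-out[1], dz = p[2]-out[2];
  return dx*dx + dy*dy + dz*dz;
}

// For each query point, the closest point on the triangle set, its
// distance and the triangle index (1-based). Brute force over triangles
// with per-triangle bounding-box early rejection.
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  // triangle data and AABBs, contiguous
  std::vector<double> tri(9 * nf), lo(3 * nf), hi(3 * nf);
  for (int i = 0; i < nf; ++i) {
    for (int j = 0; j < 3; ++j) {
      int vi = F(i, j) - 1;
      for (int k = 0; k < 3; ++k) tri[9*i + 3*j + k] = V(vi, k);
    }
    for (int k = 0; k < 3; ++k) {
      double a = tri[9*i + k], b = tri[9*i + 3 + k], c = tri[9*i + 6 + k];
      lo[3*i + k] = std::min(a, std::min(b, c));
      hi[3*i + k] = std::max(a, std::max(b, c));
    }
  }
  NumericMatrix CP(np, 3);
  NumericVector D(np);
  IntegerVector FI(np);
  double q[3], best_pt[3], cand[3];
  for (int ip = 0; ip < np; ++ip) {
    q[0] = P(ip, 0); q[1] = P(ip, 1); q[2] = P(ip, 2);
    double best = std::numeric_limits<double>::infinity();
    int best_f = -1;
    for (int i = 0; i < nf; ++i) {
      // lower bound from AABB
      double lb = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = 0.0;
        if (q[k] < lo[3*i + k]) d = lo[3*i + k] - q[k];
        else if (q[k] > hi[3*i + k]) d = q[k] - hi[3*i + k];
        lb += d * d;
        if (lb >= best) break;
      }
      if (lb >= best) continue;
      double d2 = closest_on_triangle(q, &tri[9*i], &tri[9*i+3], &tri[9*i+6],
                                      cand);
      if (d2 < best) {
        best = d2;
        best_f = i;
        best_pt[0] = cand[0]; best_pt[1] = cand[1]; best_pt[2] = cand[2];
      }
    }
    CP(ip, 0) = best_pt[0]; CP(ip, 1) = best_pt[1]; CP(ip, 2) = best_pt[2];
    D[ip] = std::sqrt(best);
    FI[ip] = best_f + 1;
  }
  return List::create(_["points"] = CP, _["dist"] = D, _["face"] = FI);
}
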