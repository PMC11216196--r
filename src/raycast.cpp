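// BVH construction and first-hit ray casting against a triangle soup.
//
// The BVH is an axis-aligned bounding-box tree built by median split on the
// face-centroid longest axis, leaves holding <= 4 faces.  Traversal finds the
// nearest Moller-Trumbore intersection with t > t_min; when two hits are
// closer than 1e-12 along the ray the lower face index wins, so results are
// deterministic regardless of traversal order.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
#include <cmath>

using namespace Rcpp;

namespace {

const double TIE_EPS = 1e-12;   // tie band on t for deterministic face choice
const double BARY_EPS = 1e-12;  // slack on barycentric bounds (shared edges)
const double DET_EPS = 1e-14;   // ray parallel-to-plane cutoff

struct Tri {
  double ax, ay, az, e1x, e1y, e1z, e2x, e2y, e2z;
};

// Moller-Trumbore, no backface culling.  Returns true and fills t,u,v when
// the ray origin+s*dir intersects the triangle at s = t > t_min.
inline bool mt_intersect(const Tri& tr,
                         const double* o, const double* d,
                         double t_min, double& t, double& u, double& v) {
  const double px = d[1] * tr.e2z - d[2] * tr.e2y;
  const double py = d[2] * tr.e2x - d[0] * tr.e2z;
  const double pz = d[0] * tr.e2y - d[1] * tr.e2x;
  const double det = tr.e1x * px + tr.e1y * py + tr.e1z * pz;
  if (std::fabs(det) < DET_EPS) return false;
  const double inv = 1.0 / det;
  const double tx = o[0] - tr.ax, ty = o[1] - tr.ay, tz = o[2] - tr.az;
  u = (tx * px + ty * py + tz * pz) * inv;
  if (u < -BARY_EPS || u > 1.0 + BARY_EPS) return false;
  const double qx = ty * tr.e1z - tz * tr.e1y;
  const double qy = tz * tr.e1x - tx * tr.e1z;
  const double qz = tx * tr.e1y - ty * tr.e1x;
  v = (d[0] * qx + d[1] * qy + d[2] * qz) * inv;
  if (v < -BARY_EPS || u + v > 1.0 + BARY_EPS) return false;
  t = (tr.e2x * qx + tr.e2y * qy + tr.e2z * qz) * inv;
  return t > t_min;
}

// Robust slab test: does the ray hit box [bmin,bmax] somewhere in
// [t_min, t_max]?  Zero direction components handled explicitly.
inline bool box_hit(const double* bmin, const double* bmax,
                    const double* o, const double* d,
                    double t_min, double t_max) {
  double t0 = t_min, t1 = t_max;
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(d[k]) < 1e-300) {
      if (o[k] < bmin[k] || o[k] > bmax[k]) return false;
    } else {
      const double inv = 1.0 / d[k];
      double near = (bmin[k] - o[k]) * inv;
      double far = (bmax[k] - o[k]) * inv;
      if (near > far) std::swap(near, far);
      if (near > t0) t0 = near;
      if (far < t1) t1 = far;
      if (t0 > t1) return false;
    }
  }
  return true;
}

}  // namespace

// Build a BVH over faces (m x 3, 1-based vertex indices into vertices m x 3).
// Returns flat parallel arrays describing the node tree plus the face
// permutation `order` (1-based into the input face matrix).  Inner node i has
// children left[i], right[i] (1-based node ids); leaves have left = -1 and
// faces order[start[i] .. start[i]+count[i]-1].
// [[Rcpp::export]]
List cpp_bvh_build(NumericMatrix vertices, IntegerMatrix faces,
                   int leaf_size = 4) {
  const int m = faces.nrow();
  if (m < 1) stop("mesh has no faces to index");
  const int nv = vertices.nrow();

  std::vector<double> fmin(3 * m), fmax(3 * m), fcen(3 * m);
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < 3; ++k) {
      fmin[3 * i + k] = R_PosInf;
      fmax[3 * i + k] = R_NegInf;
    }
    for (int c = 0; c < 3; ++c) {
      const int vi = faces(i, c) - 1;
      if (vi < 0 || vi >= nv) stop("face vertex index out of range");
      for (int k = 0; k < 3; ++k) {
        const double x = vertices(vi, k);
        if (x < fmin[3 * i + k]) fmin[3 * i + k] = x;
        if (x > fmax[3 * i + k]) fmax[3 * i + k] = x;
      }
    }
    for (int k = 0; k < 3; ++k)
      fcen[3 * i + k] = 0.5 * (fmin[3 * i + k] + fmax[3 * i + k]);
  }

  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;

  std::vector<double> nmin, nmax;
  std::vector<int> left, right, start, count;

  std::function<int(int, int)> build = [&](int lo, int hi) -> int {
    const int node = static_cast<int>(left.size());
    nmin.insert(nmin.end(), {R_PosInf, R_PosInf, R_PosInf});
    nmax.insert(nmax.end(), {R_NegInf, R_NegInf, R_NegInf});
    left.push_back(-1);
    right.push_back(-1);
    start.push_back(lo);
    count.push_back(hi - lo);

    double cmin[3] = {R_PosInf, R_PosInf, R_PosInf};
    double cmax[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = lo; i < hi; ++i) {
      const int f = order[i];
      for (int k = 0; k < 3; ++k) {
        if (fmin[3 * f + k] < nmin[3 * node + k]) nmin[3 * node + k] = fmin[3 * f + k];
        if (fmax[3 * f + k] > nmax[3 * node + k]) nmax[3 * node + k] = fmax[3 * f + k];
        if (fcen[3 * f + k] < cmin[k]) cmin[k] = fcen[3 * f + k];
        if (fcen[3 * f + k] > cmax[k]) cmax[k] = fcen[3 * f + k];
      }
    }

    if (hi - lo <= leaf_size) return node;

    int axis = 0;
    double ext = cmax[0] - cmin[0];
    for (int k = 1; k < 3; ++k) {
      if (cmax[k] - cmin[k] > ext) { ext = cmax[k] - cmin[k]; axis = k; }
    }
    // Fully deterministic ordering: centroid coordinate, face index tie-break.
    std::sort(order.begin() + lo, order.begin() + hi, [&](int a, int b) {
      if (fcen[3 * a + axis] != fcen[3 * b + axis])
        return fcen[3 * a + axis] < fcen[3 * b + axis];
      return a < b;
    });
    const int mid = lo + (hi - lo) / 2;
    const int l = build(lo, mid);
    const int r = build(mid, hi);
    left[node] = l;
    right[node] = r;
    return node;
  };
  build(0, m);

  const int nn = static_cast<int>(left.size());
  NumericMatrix node_min(nn, 3), node_max(nn, 3);
  IntegerVector lft(nn), rgt(nn), st(nn), ct(nn), ord(m);
  for (int i = 0; i < nn; ++i) {
    for (int k = 0; k < 3; ++k) {
      node_min(i, k) = nmin[3 * i + k];
      node_max(i, k) = nmax[3 * i + k];
    }
    lft[i] = left[i] < 0 ? -1 : left[i] + 1;
    rgt[i] = right[i] < 0 ? -1 : right[i] + 1;
    st[i] = start[i] + 1;
    ct[i] = count[i];
  }
  for (int i = 0; i < m; ++i) ord[i] = order[i] + 1;

  return List::create(_["node_min"] = node_min, _["node_max"] = node_max,
                      _["left"] = lft, _["right"] = rgt,
                      _["start"] = st, _["count"] = ct,
                      _["order"] = ord, _["n_faces"] = m);
}

// First-hit casting of a batch of rays.  Returns n x 8 matrix:
// face (1-based index into `faces`, NA on miss), t, hit x/y/z, b0, b1, b2.
// [[Rcpp::export]]
NumericMatrix cpp_raycast(NumericMatrix vertices, IntegerMatrix faces,
                          List bvh, NumericMatrix origins,
                          NumericMatrix directions, double t_min) {
  const int m = faces.nrow();
  NumericMatrix node_min = bvh["node_min"], node_max = bvh["node_max"];
  IntegerVector left = bvh["left"], right = bvh["right"];
  IntegerVector start = bvh["start"], count = bvh["count"], ord = bvh["order"];
  if (as<int>(bvh["n_faces"]) != m)
    stop("BVH was built for a different face set");

  std::vector<Tri> tris(m);
  for (int i = 0; i < m; ++i) {
    const int a = faces(i, 0) - 1, b = faces(i, 1) - 1, c = faces(i, 2) - 1;
    Tri& t = tris[i];
    t.ax = vertices(a, 0); t.ay = vertices(a, 1); t.az = vertices(a, 2);
    t.e1x = vertices(b, 0) - t.ax; t.e1y = vertices(b, 1) - t.ay; t.e1z = vertices(b, 2) - t.az;
    t.e2x = vertices(c, 0) - t.ax; t.e2y = vertices(c, 1) - t.ay; t.e2z = vertices(c, 2) - t.az;
  }

  const int nn = node_min.nrow();
  std::vector<double> bmin(3 * nn), bmax(3 * nn);
  for (int i = 0; i < nn; ++i)
    for (int k = 0; k < 3; ++k) {
      bmin[3 * i + k] = node_min(i, k);
      bmax[3 * i + k] = node_max(i, k);
    }

  const int n = origins.nrow();
  NumericMatrix out(n, 8);
  std::vector<int> stack;
  stack.reserve(64);

  for (int r = 0; r < n; ++r) {
    const double o[3] = {origins(r, 0), origins(r, 1), origins(r, 2)};
    const double d[3] = {directions(r, 0), directions(r, 1), directions(r, 2)};
    double best_t = R_PosInf, best_u = 0, best_v = 0;
    int best_f = -1;

    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      const int node = stack.back();
      stack.pop_back();
      // keep tie candidates alive: prune only past best_t + tie band
      const double t_hi = (best_f < 0) ? R_PosInf : best_t + TIE_EPS;
      if (!box_hit(&bmin[3 * node], &bmax[3 * node], o, d, t_min, t_hi))
        continue;
      if (left[node] < 0) {
        const int lo = start[node] - 1, hi = lo + count[node];
        for (int i = lo; i < hi; ++i) {
          const int f = ord[i] - 1;
          double t, u, v;
          if (!mt_intersect(tris[f], o, d, t_min, t, u, v)) continue;
          const bool take =
              best_f < 0 || t < best_t - TIE_EPS ||
              (std::fabs(t - best_t) < TIE_EPS && f < best_f);
          if (take) { best_t = t; best_u = u; best_v = v; best_f = f; }
        }
      } else {
        stack.push_back(left[node] - 1);
        stack.push_back(right[node] - 1);
      }
    }

    if (best_f < 0) {
      out(r, 0) = NA_REAL;
      for (int k = 1; k < 8; ++k) out(r, k) = NA_REAL;
    } else {
      out(r, 0) = best_f + 1;
      out(r, 1) = best_t;
      for (int k = 0; k < 3; ++k) out(r, 2 + k) = o[k] + best_t * d[k];
      out(r, 5) = 1.0 - best_u - best_v;
      out(r, 6) = best_u;
      out(r, 7) = best_v;
    }
  }
  return out;
}
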