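// 3-D convex hull (incremental quickhull), point-in-hull tests, and
// nearest-point-on-hull-surface projection.
//
// The fitted sensitivities are trusted only inside the convex hull of the
// voxels used in the least-squares fit; exterior voxels are evaluated at the
// Euclidean-closest point on the hull surface. No installed R package
// provides a 3-D hull, so the geometry is implemented here.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
inline Vec3 scale(const Vec3& a, double s) {
  return {a.x * s, a.y * s, a.z * s};
}
inline Vec3 add(const Vec3& a, const Vec3& b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}

struct Face {
  int a, b, c;          // vertex indices into the point set
  Vec3 n;               // outward unit normal
  double off;           // plane offset: dot(n, p) == off on the face
  bool alive;
  std::vector<int> outside;  // indices of points outside this face
};

inline double face_dist(const Face& f, const Vec3& p) {
  return dot(f.n, p) - f.off;
}

Face make_face(int a, int b, int c, const std::vector<Vec3>& P,
               const Vec3& interior) {
  Face f;
  f.a = a; f.b = b; f.c = c;
  Vec3 n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
  double ln = norm(n);
  if (ln > 0) n = scale(n, 1.0 / ln);
  // orient outward (away from a fixed interior point)
  if (dot(n, sub(interior, P[a])) > 0) {
    std::swap(f.b, f.c);
    n = scale(n, -1.0);
  }
  f.n = n;
  f.off = dot(n, P[f.a]);
  f.alive = true;
  return f;
}

}  // namespace

// Returns list(faces = m x 3 one-based indices into the original points,
//              normals = m x 3, offsets = m, vertices = unique indices).
// [[Rcpp::export(name = ".quickhull3_cpp")]]
List quickhull3_cpp(const NumericMatrix& pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<Vec3> P(n);
  double ext = 0;
  for (int i = 0; i < n; ++i) P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
  for (int k = 0; k < 3; ++k) {
    double lo = pts(0, k), hi = pts(0, k);
    for (int i = 1; i < n; ++i) {
      lo = std::min(lo, pts(i, k));
      hi = std::max(hi, pts(i, k));
    }
    ext = std::max(ext, hi - lo);
  }
  const double tol = 1e-9 * std::max(ext, 1.0);

  // --- initial simplex: farthest pair along x, then line, then plane ---
  int i0 = 0, i1 = 0;
  double best = -1;
  // farthest pair among the six axis-extreme points
  std::vector<int> extremes;
  for (int k = 0; k < 3; ++k) {
    int lo = 0, hi = 0;
    for (int i = 1; i < n; ++i) {
      if (pts(i, k) < pts(lo, k)) lo = i;
      if (pts(i, k) > pts(hi, k)) hi = i;
    }
    extremes.push_back(lo);
    extremes.push_back(hi);
  }
  for (size_t a = 0; a < extremes.size(); ++a)
    for (size_t b = a + 1; b < extremes.size(); ++b) {
      double d = norm(sub(P[extremes[a]], P[extremes[b]]));
      if (d > best) { best = d; i0 = extremes[a]; i1 = extremes[b]; }
    }
  if (best < tol) stop("convex hull degenerate: all points coincide");

  Vec3 dir = scale(sub(P[i1], P[i0]), 1.0 / best);
  int i2 = -1;
  best = tol;
  for (int i = 0; i < n; ++i) {
    Vec3 v = sub(P[i], P[i0]);
    Vec3 perp = sub(v, scale(dir, dot(v, dir)));
    double d = norm(perp);
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) stop("convex hull degenerate: points are collinear");

  Vec3 nrm = cross(sub(P[i1], P[i0]), sub(P[i2], P[i0]));
  nrm = scale(nrm, 1.0 / norm(nrm));
  int i3 = -1;
  best = tol;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, sub(P[i], P[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("convex hull degenerate: points are coplanar");

  Vec3 interior = scale(add(add(P[i0], P[i1]), add(P[i2], P[i3])), 0.25);

  std::vector<Face> faces;
  faces.push_back(make_face(i0, i1, i2, P, interior));
  faces.push_back(make_face(i0, i1, i3, P, interior));
  faces.push_back(make_face(i0, i2, i3, P, interior));
  faces.push_back(make_face(i1, i2, i3, P, interior));

  // assign points to the first face they are outside of
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (auto& f : faces)
      if (face_dist(f, P[i]) > tol) { f.outside.push_back(i); break; }
  }

  // --- incremental expansion ---
  bool progress = true;
  while (progress) {
    progress = false;
    for (size_t fi = 0; fi < faces.size(); ++fi) {
      if (!faces[fi].alive || faces[fi].outside.empty()) continue;
      progress = true;
      // farthest outside point of this face
      int pbest = faces[fi].outside[0];
      double dbest = -1;
      for (int i : faces[fi].outside) {
        double d = face_dist(faces[fi], P[i]);
        if (d > dbest) { dbest = d; pbest = i; }
      }
      const Vec3 p = P[pbest];

      // visible faces and orphaned points
      std::vector<int> visible;
      std::vector<int> orphans;
      for (size_t fj = 0; fj < faces.size(); ++fj) {
        if (!faces[fj].alive) continue;
        if (face_dist(faces[fj], p) > tol) {
          visible.push_back((int)fj);
          faces[fj].alive = false;
          orphans.insert(orphans.end(), faces[fj].outside.begin(),
                         faces[fj].outside.end());
          faces[fj].outside.clear();
        }
      }

      // horizon: edges of visible faces shared with exactly one visible face
      std::map<std::pair<int, int>, int> edge_count;
      auto note = [&](int a, int b) {
        auto key = std::minmax(a, b);
        edge_count[{key.first, key.second}]++;
      };
      for (int fj : visible) {
        note(faces[fj].a, faces[fj].b);
        note(faces[fj].b, faces[fj].c);
        note(faces[fj].c, faces[fj].a);
      }
      std::vector<std::pair<int, int>> horizon;
      for (auto& e : edge_count)
        if (e.second == 1) horizon.push_back(e.first);

      std::vector<int> fresh;
      for (auto& e : horizon) {
        faces.push_back(make_face(e.first, e.second, pbest, P, interior));
        fresh.push_back((int)faces.size() - 1);
      }

      // reassign orphaned points
      for (int i : orphans) {
        if (i == pbest) continue;
        for (int fj : fresh)
          if (face_dist(faces[fj], P[i]) > tol) {
            faces[fj].outside.push_back(i);
            break;
          }
      }
      break;  // restart scan (faces vector was modified)
    }
  }

  int m = 0;
  for (auto& f : faces) if (f.alive) ++m;
  IntegerMatrix F(m, 3);
  NumericMatrix N(m, 3);
  NumericVector off(m);
  std::vector<bool> used(n, false);
  int r = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    F(r, 0) = f.a + 1; F(r, 1) = f.b + 1; F(r, 2) = f.c + 1;
    N(r, 0) = f.n.x; N(r, 1) = f.n.y; N(r, 2) = f.n.z;
    off[r] = f.off;
    used[f.a] = used[f.b] = used[f.c] = true;
    ++r;
  }
  std::vector<int> verts;
  for (int i = 0; i < n; ++i) if (used[i]) verts.push_back(i + 1);
  return List::create(_["faces"] = F, _["normals"] = N, _["offsets"] = off,
                      _["vertex_indices"] = wrap(verts));
}

// Signed "outsideness": max over faces of dot(normal, p) - offset.
// <= 0 means inside or on the hull.
// [[Rcpp::export(name = ".hull_signed_dist_cpp")]]
NumericVector hull_signed_dist_cpp(const NumericMatrix& pts,
                                   const NumericMatrix& normals,
                                   const NumericVector& offsets) {
  const int n = pts.nrow(), m = normals.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = -std::numeric_limits<double>::infinity();
    for (int f = 0; f < m; ++f) {
      double d = normals(f, 0) * pts(i, 0) + normals(f, 1) * pts(i, 1) +
                 normals(f, 2) * pts(i, 2) - offsets[f];
      if (d > best) best = d;
    }
    out[i] = best;
  }
  return out;
}

namespace {
// closest point on triangle (a, b, c) to p  (Ericson, Real-Time Collision
// Detection, 5.1.5)
Vec3 closest_on_triangle(const Vec3& p, const Vec3& a, const Vec3& b,
                         const Vec3& c) {
  Vec3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  Vec3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return add(a, scale(ab, v));
  }
  Vec3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return add(a, scale(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return add(b, scale(sub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return add(a, add(scale(ab, v), scale(ac, w)));
}
}  // namespace

// Nearest point on the triangulated hull surface for each query point.
// verts: hull vertex coordinates; faces: one-based indices into verts.
// [[Rcpp::export(name = ".hull_project_cpp")]]
NumericMatrix hull_project_cpp(const NumericMatrix& pts,
                               const NumericMatrix& verts,
                               const IntegerMatrix& faces) {
  const int n = pts.nrow(), m = faces.nrow();
  std::vector<Vec3> V(verts.nrow());
  for (int i = 0; i < verts.nrow(); ++i)
    V[i] = {verts(i, 0), verts(i, 1), verts(i, 2)};
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    Vec3 p = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = std::numeric_limits<double>::infinity();
    Vec3 bq = p;
    for (int f = 0; f < m; ++f) {
      Vec3 q = closest_on_triangle(p, V[faces(f, 0) - 1], V[faces(f, 1) - 1],
                                   V[faces(f, 2) - 1]);
      Vec3 dq = sub(p, q);
      double d = dot(dq, dq);
      if (d < best) { best = d; bq = q; }
    }
    out(i, 0) = bq.x; out(i, 1) = bq.y; out(i, 2) = bq.z;
  }
  return out;
}
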