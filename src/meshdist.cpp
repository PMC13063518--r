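#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Closest point on triangle (a, b, c) to point p (Ericson, Real-Time
// Collision Detection, ch. 5). Returns squared distance; fills cp (closest
// point) and bary (barycentric coords w.r.t. a, b, c).
static double closest_point_tri(const double *p, const double *a,
                                const double *b, const double *c,
                                double *cp, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double u = -1, v = -1; // barycentric weights of b and c
  if (d1 <= 0.0 && d2 <= 0.0) { u = 0; v = 0; }
  double bp[3], cp_[3];
  double d3 = 0, d4 = 0, d5 = 0, d6 = 0;
  if (u < 0) {
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0.0 && d4 <= d3) { u = 1; v = 0; }
  }
  if (u < 0) {
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) { u = d1 / (d1 - d3); v = 0; }
  }
  if (u < 0) {
    for (int i = 0; i < 3; ++i) cp_[i] = p[i] - c[i];
    d5 = ab[0] * cp_[0] + ab[1] * cp_[1] + ab[2] * cp_[2];
    d6 = ac[0] * cp_[0] + ac[1] * cp_[1] + ac[2] * cp_[2];
    if (d6 >= 0.0 && d5 <= d6) { u = 0; v = 1; }
  }
  if (u < 0) {
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) { u = 0; v = d2 / (d2 - d6); }
  }
  if (u < 0) {
    double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      u = 1.0 - w; v = w;
    }
  }
  if (u < 0) {
    double va = d3 * d6 - d5 * d4;
    double vb = d5 * d2 - d1 * d6;
    double vc = d1 * d4 - d3 * d2;
    double denom = va + vb + vc;
    u = vb / denom;
    v = vc / denom;
  }
  double d2sum = 0.0;
  for (int i = 0; i < 3; ++i) {
    cp[i] = a[i] + u * ab[i] + v * ac[i];
    double d = p[i] - cp[i];
    d2sum += d * d;
  }
  bary[0] = 1.0 - u - v;
  bary[1] = u;
  bary[2] = v;
  return d2sum;
}

// For each query point, the exact minimum distance to a triangle mesh.
// Returns distance, index (1-based) of the closest face, the closest point,
// and its barycentric coordinates in that face.
// [[Rcpp::export(name = ".mesh_closest_cpp")]]
List mesh_closest_cpp(NumericMatrix query, NumericMatrix vertices,
                      IntegerMatrix faces) {
  int nq = query.nrow(), nf = faces.nrow();
  if (nf == 0) stop("mesh has no faces");
  NumericVector dist(nq);
  IntegerVector face_id(nq);
  NumericMatrix closest(nq, 3), bary(nq, 3);
  // cache triangle vertex coordinates contiguously
  std::vector<double> tri(9 * nf);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      int vi = faces(f, k) - 1;
      for (int i = 0; i < 3; ++i) tri[9 * f + 3 * k + i] = vertices(vi, i);
    }
  for (int q = 0; q < nq; ++q) {
    double p[3] = {query(q, 0), query(q, 1), query(q, 2)};
    double best = DBL_MAX, bcp[3] = {0, 0, 0}, bb[3] = {0, 0, 0};
    int bf = 0;
    double cp[3], ba[3];
    for (int f = 0; f < nf; ++f) {
      const double *t = &tri[9 * f];
      double d2 = closest_point_tri(p, t, t + 3, t + 6, cp, ba);
      if (d2 < best) {
        best = d2;
        bf = f;
        for (int i = 0; i < 3; ++i) { bcp[i] = cp[i]; bb[i] = ba[i]; }
      }
    }
    dist[q] = std::sqrt(best);
    face_id[q] = bf + 1;
    for (int i = 0; i < 3; ++i) { closest(q, i) = bcp[i]; bary(q, i) = bb[i]; }
  }
  return List::create(_["distance"] = dist, _["face"] = face_id,
                      _["point"] = closest, _["bary"] = bary);
}
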