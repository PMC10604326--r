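#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Closest point on a triangle (Ericson, Real-Time Collision Detection).
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i=0;i<3;++i) out[i]=a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i] = a[i] + v*ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i] = a[i] + w*ac[i];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i] = b[i] + w*(c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
}

// For each query point, the closest point on the mesh surface (V, F).
// Brute force over faces with per-face bounding-box rejection; ties are
// broken by the lowest face index (strict '<' keeps the first best).
// [[Rcpp::export(name = ".closest_point_mesh")]]
List closest_point_mesh(NumericMatrix query, NumericMatrix V, IntegerMatrix F) {
  const int nq = query.nrow(), nf = F.nrow();
  NumericMatrix pts(nq, 3);
  NumericVector dist(nq);
  IntegerVector face(nq);

  // face vertex coordinates and bounding boxes, contiguous
  std::vector<double> tv(9 * nf), lo(3 * nf), hi(3 * nf);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      for (int d = 0; d < 3; ++d) tv[9*f + 3*k + d] = V(vi, d);
    }
    for (int d = 0; d < 3; ++d) {
      double a = tv[9*f + d], b = tv[9*f + 3 + d], c = tv[9*f + 6 + d];
      lo[3*f + d] = std::min(a, std::min(b, c));
      hi[3*f + d] = std::max(a, std::max(b, c));
    }
  }

  for (int q = 0; q < nq; ++q) {
    double p[3] = { query(q, 0), query(q, 1), query(q, 2) };
    double best = DBL_MAX, bestpt[3] = {0, 0, 0};
    int bestf = -1;
    for (int f = 0; f < nf; ++f) {
      // squared distance to bbox lower bound
      double dbox = 0.0;
      for (int d = 0; d < 3; ++d) {
        double lod = lo[3*f + d], hid = hi[3*f + d];
        double e = (p[d] < lod) ? lod - p[d] : (p[d] > hid ? p[d] - hid : 0.0);
        dbox += e * e;
      }
      if (dbox >= best) continue;
      double cpt[3];
      closest_on_tri(p, &tv[9*f], &tv[9*f + 3], &tv[9*f + 6], cpt);
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double e = cpt[d] - p[d];
        d2 += e * e;
      }
      if (d2 < best) {
        best = d2;
        bestf = f;
        for (int d = 0; d < 3; ++d) bestpt[d] = cpt[d];
      }
    }
    for (int d = 0; d < 3; ++d) pts(q, d) = bestpt[d];
    dist[q] = std::sqrt(best);
    face[q] = bestf + 1;
  }
  return List::create(_["point"] = pts, _["distance"] = dist,
                      _["face"] = face);
}
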