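#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Closest point on a triangle (Ericson, Real-Time Collision Detection, 5.1.5).
// Handles interior, edge and vertex regions exactly.
static inline void closest_on_tri(const double *p,
                                  const double *a, const double *b,
                                  const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

static inline double dist3(const double *p, const double *q) {
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// [[Rcpp::export]]
NumericVector cpp_point_tri_closest(NumericVector p, NumericMatrix tri) {
  double a[3], b[3], c[3], q[3], out[3];
  for (int i = 0; i < 3; ++i) {
    a[i] = tri(0, i); b[i] = tri(1, i); c[i] = tri(2, i); q[i] = p[i];
  }
  closest_on_tri(q, a, b, c, out);
  NumericVector res(4);
  res[0] = dist3(q, out);
  res[1] = out[0]; res[2] = out[1]; res[3] = out[2];
  return res;
}

// Brute-force closest point on a triangle soup for each query row.
// [[Rcpp::export]]
List cpp_closest_on_mesh_brute(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  int nq = Q.nrow(), nf = F.nrow();
  NumericVector dist(nq);
  NumericMatrix closest(nq, 3);
  IntegerVector face(nq);
  double a[3], b[3], c[3], q[3], out[3];
  for (int i = 0; i < nq; ++i) {
    q[0] = Q(i, 0); q[1] = Q(i, 1); q[2] = Q(i, 2);
    double best = std::numeric_limits<double>::infinity();
    double bp[3] = {0, 0, 0};
    int bf = -1;
    for (int f = 0; f < nf; ++f) {
      int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
      for (int k = 0; k < 3; ++k) {
        a[k] = V(ia, k); b[k] = V(ib, k); c[k] = V(ic, k);
      }
      closest_on_tri(q, a, b, c, out);
      double d = dist3(q, out);
      if (d < best) { best = d; bp[0] = out[0]; bp[1] = out[1]; bp[2] = out[2]; bf = f; }
    }
    dist[i] = best;
    closest(i, 0) = bp[0]; closest(i, 1) = bp[1]; closest(i, 2) = bp[2];
    face[i] = bf + 1;
  }
  return List::create(_["distance"] = dist, _["point"] = closest, _["face"] = face);
}

// Uniform-grid accelerated closest point on a triangle soup. Triangles are
// binned by AABB; queries expand Chebyshev rings of cells until the ring's
// lower distance bound exceeds the best distance found, which guarantees the
// result equals the brute-force minimum.
// [[Rcpp::export]]
List cpp_closest_on_mesh_grid(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  int nq = Q.nrow(), nf = F.nrow(), nv = V.nrow();

  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = std::numeric_limits<double>::infinity();
    hi[k] = -std::numeric_limits<double>::infinity();
  }
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) {
      if (V(i, k) < lo[k]) lo[k] = V(i, k);
      if (V(i, k) > hi[k]) hi[k] = V(i, k);
    }
  double ext[3], maxext = 0.0;
  for (int k = 0; k < 3; ++k) {
    ext[k] = hi[k] - lo[k];
    if (ext[k] > maxext) maxext = ext[k];
  }
  if (maxext <= 0.0) maxext = 1.0;
  // aim for O(nf) cells, capped per axis
  double cell = maxext / std::max(4.0, std::min(64.0, std::cbrt((double)nf)));
  int dim[3];
  for (int k = 0; k < 3; ++k) {
    dim[k] = std::max(1, (int)std::ceil(ext[k] / cell + 1e-12));
    if (dim[k] > 128) dim[k] = 128;
  }
  double csz[3];
  for (int k = 0; k < 3; ++k) csz[k] = (ext[k] > 0.0) ? ext[k] / dim[k] : 1.0;
  double minc = std::min(csz[0], std::min(csz[1], csz[2]));

  int ncell = dim[0] * dim[1] * dim[2];
  std::vector< std::vector<int> > bins(ncell);
  for (int f = 0; f < nf; ++f) {
    double tlo[3], thi[3];
    for (int k = 0; k < 3; ++k) {
      double va = V(F(f,0), k), vb = V(F(f,1), k), vc = V(F(f,2), k);
      tlo[k] = std::min(va, std::min(vb, vc));
      thi[k] = std::max(va, std::max(vb, vc));
    }
    int c0[3], c1[3];
    for (int k = 0; k < 3; ++k) {
      c0[k] = std::min(dim[k]-1, std::max(0, (int)std::floor((tlo[k]-lo[k]) / csz[k])));
      c1[k] = std::min(dim[k]-1, std::max(0, (int)std::floor((thi[k]-lo[k]) / csz[k])));
    }
    for (int x = c0[0]; x <= c1[0]; ++x)
      for (int y = c0[1]; y <= c1[1]; ++y)
        for (int z = c0[2]; z <= c1[2]; ++z)
          bins[(x * dim[1] + y) * dim[2] + z].push_back(f);
  }

  NumericVector dist(nq);
  NumericMatrix closest(nq, 3);
  IntegerVector face(nq);
  std::vector<int> stamp(nf, -1);
  double a[3], b[3], c[3], q[3], out[3];

  int maxdim = std::max(dim[0], std::max(dim[1], dim[2]));

  for (int i = 0; i < nq; ++i) {
    q[0] = Q(i, 0); q[1] = Q(i, 1); q[2] = Q(i, 2);
    // distance from query to the grid's bounding box (0 when inside)
    double d0 = 0.0;
    int qc[3];
    for (int k = 0; k < 3; ++k) {
      double dk = 0.0;
      if (q[k] < lo[k]) dk = lo[k] - q[k];
      else if (q[k] > hi[k]) dk = q[k] - hi[k];
      d0 += dk * dk;
      qc[k] = std::min(dim[k]-1, std::max(0, (int)std::floor((q[k]-lo[k]) / csz[k])));
    }
    d0 = std::sqrt(d0);

    double best = std::numeric_limits<double>::infinity();
    double bp[3] = {0, 0, 0};
    int bf = -1;

    for (int r = 0; r <= maxdim; ++r) {
      // every cell in ring r is at least max(d0, (r-1)*minc) away from the query
      double bound = std::max(d0, r > 0 ? (r - 1) * minc : 0.0);
      if (bf >= 0 && best <= bound) break;
      int x0 = qc[0]-r, x1 = qc[0]+r;
      int y0 = qc[1]-r, y1 = qc[1]+r;
      int z0 = qc[2]-r, z1 = qc[2]+r;
      for (int x = std::max(0, x0); x <= std::min(dim[0]-1, x1); ++x)
        for (int y = std::max(0, y0); y <= std::min(dim[1]-1, y1); ++y)
          for (int z = std::max(0, z0); z <= std::min(dim[2]-1, z1); ++z) {
            // only the shell of the ring
            if (x != x0 && x != x1 && y != y0 && y != y1 && z != z0 && z != z1)
              continue;
            const std::vector<int> &tris = bins[(x * dim[1] + y) * dim[2] + z];
            for (size_t t = 0; t < tris.size(); ++t) {
              int f = tris[t];
              if (stamp[f] == i) continue;
              stamp[f] = i;
              int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
              for (int k = 0; k < 3; ++k) {
                a[k] = V(ia, k); b[k] = V(ib, k); c[k] = V(ic, k);
              }
              closest_on_tri(q, a, b, c, out);
              double d = dist3(q, out);
              if (d < best) {
                best = d; bp[0] = out[0]; bp[1] = out[1]; bp[2] = out[2]; bf = f;
              }
            }
          }
    }
    dist[i] = best;
    closest(i, 0) = bp[0]; closest(i, 1) = bp[1]; closest(i, 2) = bp[2];
    face[i] = bf + 1;
  }
  return List::create(_["distance"] = dist, _["point"] = closest, _["face"] = face);
}

// Nearest neighbour among target points for each query row.
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix Q, NumericMatrix P) {
  int nq = Q.nrow(), np = P.nrow();
  NumericVector dist(nq);
  IntegerVector idx(nq);
  for (int i = 0; i < nq; ++i) {
    double qx = Q(i,0), qy = Q(i,1), qz = Q(i,2);
    double best = std::numeric_limits<double>::infinity();
    int bi = -1;
    for (int j = 0; j < np; ++j) {
      double dx = qx - P(j,0), dy = qy - P(j,1), dz = qz - P(j,2);
      double d = dx*dx + dy*dy + dz*dz;
      if (d < best) { best = d; bi = j; }
    }
    dist[i] = std::sqrt(best);
    idx[i] = bi + 1;
  }
  return List::create(_["distance"] = dist, _["index"] = idx);
}
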