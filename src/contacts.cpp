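// Extended-radius constrained power-diagram contact surfaces.
//
// For every atom pair whose solvent-extended spheres overlap, the contact
// surface is the face shared by their additively-weighted (power/Laguerre)
// Voronoi cells, with each cell constrained to the atom's extended sphere
// (vdW radius + 1.4 A water probe).  The face lives on the radical plane of
// the two spheres: a disc clipped by the half-planes contributed by every
// proximal third atom's radical plane.  The clipped region is a convex
// polygon-with-arcs whose area is computed exactly (polygon clipping plus
// circular-segment integration).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct P2 { double x, y; };

static inline double cross2(const P2 &a, const P2 &b) {
  return a.x * b.y - a.y * b.x;
}
static inline double dot2(const P2 &a, const P2 &b) {
  return a.x * b.x + a.y * b.y;
}

// signed area of the intersection of triangle (origin, a, b) with the disc
// of radius r centered at the origin
static double seg_area(const P2 &a, const P2 &b, double r) {
  const double eps = 1e-12;
  double ra = std::sqrt(dot2(a, a)), rb = std::sqrt(dot2(b, b));
  bool ina = ra <= r + eps, inb = rb <= r + eps;
  P2 d = {b.x - a.x, b.y - a.y};
  double A = dot2(d, d);
  if (A < eps) return 0.0;
  double B = 2.0 * dot2(a, d);
  double C = dot2(a, a) - r * r;
  double disc = B * B - 4.0 * A * C;
  double tri = 0.5 * cross2(a, b);
  double sector_full = 0.5 * r * r * std::atan2(cross2(a, b), dot2(a, b));
  if (ina && inb) return tri;
  if (disc <= 0.0) return sector_full;
  double sq = std::sqrt(disc);
  double t1 = (-B - sq) / (2.0 * A), t2 = (-B + sq) / (2.0 * A);
  P2 m1 = {a.x + t1 * d.x, a.y + t1 * d.y};
  P2 m2 = {a.x + t2 * d.x, a.y + t2 * d.y};
  if (ina && !inb) {
    // leave the disc at t2
    double sec = 0.5 * r * r * std::atan2(cross2(m2, b), dot2(m2, b));
    return 0.5 * cross2(a, m2) + sec;
  }
  if (!ina && inb) {
    double sec = 0.5 * r * r * std::atan2(cross2(a, m1), dot2(a, m1));
    return sec + 0.5 * cross2(m1, b);
  }
  // both endpoints outside
  if (t1 > eps && t2 < 1.0 - eps && t2 > t1) {
    double s1 = 0.5 * r * r * std::atan2(cross2(a, m1), dot2(a, m1));
    double s2 = 0.5 * r * r * std::atan2(cross2(m2, b), dot2(m2, b));
    return s1 + 0.5 * cross2(m1, m2) + s2;
  }
  return sector_full;
}

static double poly_disc_area(const std::vector<P2> &poly, double r) {
  double s = 0.0;
  size_t n = poly.size();
  for (size_t k = 0; k < n; ++k)
    s += seg_area(poly[k], poly[(k + 1) % n], r);
  return std::fabs(s);
}

// clip convex polygon by half-plane  A x + B y + C <= 0
static void clip_halfplane(std::vector<P2> &poly, double A, double B,
                           double C) {
  std::vector<P2> out;
  size_t n = poly.size();
  if (n == 0) return;
  out.reserve(n + 2);
  for (size_t k = 0; k < n; ++k) {
    const P2 &p = poly[k];
    const P2 &q = poly[(k + 1) % n];
    double fp = A * p.x + B * p.y + C;
    double fq = A * q.x + B * q.y + C;
    if (fp <= 0) out.push_back(p);
    if ((fp < 0 && fq > 0) || (fp > 0 && fq < 0)) {
      double t = fp / (fp - fq);
      out.push_back({p.x + t * (q.x - p.x), p.y + t * (q.y - p.y)});
    }
  }
  poly.swap(out);
}

// [[Rcpp::export]]
List contact_areas_cpp(NumericMatrix coords, NumericVector radii) {
  int n = coords.nrow();
  if (n < 1) stop("need at least one atom");
  std::vector<double> X(n), Y(n), Z(n), R(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    X[i] = coords(i, 0); Y[i] = coords(i, 1); Z[i] = coords(i, 2);
    R[i] = radii[i];
    if (R[i] > rmax) rmax = R[i];
  }
  // cell list at the occluder-reach cutoff: an atom m can occlude the face
  // of pair (i, j) only if its extended sphere reaches the face disc, which
  // lies within R[i] of atom i, so |cm - ci| < R[i] + rho + R[m] <= 3 rmax
  const double reach_cut = 3.0 * rmax + 1e-9;
  double xmin = X[0], ymin = Y[0], zmin = Z[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, X[i]); ymin = std::min(ymin, Y[i]);
    zmin = std::min(zmin, Z[i]);
  }
  auto cell_of = [&](double x, double m) {
    return (int)std::floor((x - m) / reach_cut);
  };
  int ncx = 1, ncy = 1, ncz = 1;
  for (int i = 0; i < n; ++i) {
    ncx = std::max(ncx, cell_of(X[i], xmin) + 1);
    ncy = std::max(ncy, cell_of(Y[i], ymin) + 1);
    ncz = std::max(ncz, cell_of(Z[i], zmin) + 1);
  }
  std::vector<std::vector<int> > cells((size_t)ncx * ncy * ncz);
  for (int i = 0; i < n; ++i) {
    int cx = cell_of(X[i], xmin), cy = cell_of(Y[i], ymin),
        cz = cell_of(Z[i], zmin);
    cells[(size_t)(cx * ncy + cy) * ncz + cz].push_back(i);
  }
  std::vector<int> nbr;   // atoms within reach_cut of atom i (incl. i)
  std::vector<int> out_i, out_j;
  std::vector<double> out_a;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    int cx = cell_of(X[i], xmin), cy = cell_of(Y[i], ymin),
        cz = cell_of(Z[i], zmin);
    for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int ax = cx + dx, ay = cy + dy, az = cz + dz;
        if (ax < 0 || ay < 0 || az < 0 || ax >= ncx || ay >= ncy ||
            az >= ncz) continue;
        const std::vector<int> &cl = cells[(size_t)(ax * ncy + ay) * ncz + az];
        for (size_t q = 0; q < cl.size(); ++q) {
          int m = cl[q];
          double ddx = X[m] - X[i], ddy = Y[m] - Y[i], ddz = Z[m] - Z[i];
          if (ddx * ddx + ddy * ddy + ddz * ddz < reach_cut * reach_cut)
            nbr.push_back(m);
        }
      }
    for (size_t jj = 0; jj < nbr.size(); ++jj) {
      int j = nbr[jj];
      if (j <= i) continue;
      double dx = X[j] - X[i], dy = Y[j] - Y[i], dz = Z[j] - Z[i];
      double d2 = dx * dx + dy * dy + dz * dz;
      double rs = R[i] + R[j];
      if (d2 >= rs * rs) continue;
      double d = std::sqrt(d2);
      if (d < 1e-6) stop("degenerate geometry: coincident atom centers");
      // radical plane of the two extended spheres
      double t = (d2 + R[i] * R[i] - R[j] * R[j]) / (2.0 * d);
      double rho2 = R[i] * R[i] - t * t;
      if (rho2 <= 0.0) continue;
      double rho = std::sqrt(rho2);
      double ux = dx / d, uy = dy / d, uz = dz / d;
      // plane center and in-plane basis
      double px = X[i] + t * ux, py = Y[i] + t * uy, pz = Z[i] + t * uz;
      double e1x, e1y, e1z;
      if (std::fabs(ux) < 0.9) { e1x = 0; e1y = -uz; e1z = uy; }
      else { e1x = -uz; e1y = 0; e1z = ux; }
      double nrm = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
      e1x /= nrm; e1y /= nrm; e1z /= nrm;
      double e2x = uy * e1z - uz * e1y;
      double e2y = uz * e1x - ux * e1z;
      double e2z = ux * e1y - uy * e1x;
      // initial polygon: square circumscribing the disc
      std::vector<P2> poly = {
        {-rho, -rho}, {rho, -rho}, {rho, rho}, {-rho, rho}};
      // occlusion by all other proximal atoms
      for (size_t mm = 0; mm < nbr.size() && !poly.empty(); ++mm) {
        int m = nbr[mm];
        if (m == i || m == j) continue;
        double wx = X[m] - X[i], wy = Y[m] - Y[i], wz = Z[m] - Z[i];
        double qx = X[m] - px, qy = Y[m] - py, qz = Z[m] - pz;
        double q2 = qx * qx + qy * qy + qz * qz;
        double reach = R[m] + rho;
        if (q2 >= reach * reach) continue;
        // keep pow_i(x) <= pow_m(x):  2 x.(cm-ci) + |ci|^2-|cm|^2
        //                              - Ri^2 + Rm^2 <= 0  on the plane
        double A = 2.0 * (wx * e1x + wy * e1y + wz * e1z);
        double B = 2.0 * (wx * e2x + wy * e2y + wz * e2z);
        // constant term evaluated at plane center p0 (a=b=0)
        double pw = (px - X[i]) * wx + (py - Y[i]) * wy + (pz - Z[i]) * wz;
        double C = 2.0 * pw - (wx * wx + wy * wy + wz * wz)
                   - R[i] * R[i] + R[m] * R[m];
        clip_halfplane(poly, A, B, C);
      }
      if (poly.empty()) continue;
      double area = poly_disc_area(poly, rho);
      if (area > 1e-9) {
        out_i.push_back(i + 1);
        out_j.push_back(j + 1);
        out_a.push_back(area);
      }
    }
  }
  return List::create(_["i"] = out_i, _["j"] = out_j, _["area"] = out_a);
}
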