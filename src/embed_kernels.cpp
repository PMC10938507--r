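// Numerical kernels for distance-geometry embedding and force-field
// relaxation. All energies are in arbitrary comparative units; gradients are
// analytic so the L-BFGS driver in R stays cheap.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Triangle-inequality smoothing of a distance-bounds matrix (in place on
// copies): upper bounds by Floyd shortest paths, lower bounds by the inverse
// triangle inequality. Returns list(L, U, feasible).
// [[Rcpp::export]]
List cpp_smooth_bounds(NumericMatrix Lin, NumericMatrix Uin) {
  int n = Lin.nrow();
  NumericMatrix L(clone(Lin)), U(clone(Uin));
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      if (i == k) continue;
      double uik = U(i, k);
      for (int j = 0; j < n; ++j) {
        if (j == i || j == k) continue;
        double via = uik + U(k, j);
        if (via < U(i, j)) { U(i, j) = via; U(j, i) = via; }
      }
    }
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      if (i == k) continue;
      for (int j = 0; j < n; ++j) {
        if (j == i || j == k) continue;
        double lo = L(i, k) - U(k, j);
        if (lo > L(i, j)) { L(i, j) = lo; L(j, i) = lo; }
      }
    }
  bool feasible = true;
  for (int i = 0; i < n && feasible; ++i)
    for (int j = i + 1; j < n; ++j)
      if (L(i, j) > U(i, j) + 1e-9) { feasible = false; break; }
  return List::create(_["L"] = L, _["U"] = U, _["feasible"] = feasible);
}

static inline void add_vol_grad(NumericVector &g, const NumericVector &x,
                                int a, int b, int c, int d, double coef,
                                int n) {
  // V = det[B-A, C-A, D-A]; accumulate coef * dV/dxyz
  double bx = x[b] - x[a], by = x[b + n] - x[a + n], bz = x[b + 2 * n] - x[a + 2 * n];
  double cx = x[c] - x[a], cy = x[c + n] - x[a + n], cz = x[c + 2 * n] - x[a + 2 * n];
  double dx = x[d] - x[a], dy = x[d + n] - x[a + n], dz = x[d + 2 * n] - x[a + 2 * n];
  // dV/dB = C x D, dV/dC = D x B, dV/dD = B x C (A as origin)
  double gbx = cy * dz - cz * dy, gby = cz * dx - cx * dz, gbz = cx * dy - cy * dx;
  double gcx = dy * bz - dz * by, gcy = dz * bx - dx * bz, gcz = dx * by - dy * bx;
  double gdx = by * cz - bz * cy, gdy = bz * cx - bx * cz, gdz = bx * cy - by * cx;
  g[b] += coef * gbx; g[b + n] += coef * gby; g[b + 2 * n] += coef * gbz;
  g[c] += coef * gcx; g[c + n] += coef * gcy; g[c + 2 * n] += coef * gcz;
  g[d] += coef * gdx; g[d + n] += coef * gdy; g[d + 2 * n] += coef * gdz;
  g[a] -= coef * (gbx + gcx + gdx);
  g[a + n] -= coef * (gby + gcy + gdy);
  g[a + 2 * n] -= coef * (gbz + gcz + gdz);
}

static inline double signed_volume(const NumericVector &x, int a, int b,
                                   int c, int d, int n) {
  double bx = x[b] - x[a], by = x[b + n] - x[a + n], bz = x[b + 2 * n] - x[a + 2 * n];
  double cx = x[c] - x[a], cy = x[c + n] - x[a + n], cz = x[c + 2 * n] - x[a + 2 * n];
  double dx = x[d] - x[a], dy = x[d + n] - x[a + n], dz = x[d + 2 * n] - x[a + 2 * n];
  return bx * (cy * dz - cz * dy) - by * (cx * dz - cz * dx) + bz * (cx * dy - cy * dx);
}

// Distance-bounds + chirality error and gradient for coordinates x
// (length 3n, column-major xyz blocks). chiral: matrix with rows
// (n1, n2, n3, n4, target_sign, vmin) -- 1-based indices, volume about n1.
// [[Rcpp::export]]
List cpp_dg_error(NumericVector x, NumericMatrix L, NumericMatrix U,
                  NumericMatrix chiral, double w_chiral) {
  int n = L.nrow();
  double f = 0.0;
  NumericVector g(3 * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = x[i + n] - x[j + n], dz = x[i + 2 * n] - x[j + 2 * n];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) + 1e-12;
      double viol = 0.0;
      if (d < L(i, j)) viol = d - L(i, j);
      else if (d > U(i, j)) viol = d - U(i, j);
      if (viol != 0.0) {
        f += viol * viol;
        double c = 2.0 * viol / d;
        g[i] += c * dx; g[i + n] += c * dy; g[i + 2 * n] += c * dz;
        g[j] -= c * dx; g[j + n] -= c * dy; g[j + 2 * n] -= c * dz;
      }
    }
  }
  for (int r = 0; r < chiral.nrow(); ++r) {
    int a = (int)chiral(r, 0) - 1, b = (int)chiral(r, 1) - 1;
    int c = (int)chiral(r, 2) - 1, d = (int)chiral(r, 3) - 1;
    double s = chiral(r, 4), vmin = chiral(r, 5);
    double V = signed_volume(x, a, b, c, d, n);
    double short_ = vmin - s * V;        // want s*V >= vmin
    if (short_ > 0.0) {
      f += w_chiral * short_ * short_;
      add_vol_grad(g, x, a, b, c, d, -2.0 * w_chiral * short_ * s, n);
    }
  }
  return List::create(_["f"] = f, _["g"] = g);
}

// Harmonic force field: bonds (i, j, r0, k), angles (i, j, k, theta0, kth)
// with j the apex, nonbonded repulsion pairs (i, j, sigma, k), chirality as
// in cpp_dg_error, and planarity rows (a, n1, n2, n3, k) keeping a in the
// plane of its three neighbors. Indices 1-based.
// [[Rcpp::export]]
List cpp_ff_energy(NumericVector x, NumericMatrix bonds, NumericMatrix angles,
                   NumericMatrix nb, NumericMatrix chiral, double w_chiral,
                   NumericMatrix planar, int natoms) {
  int n = natoms;
  double f = 0.0;
  NumericVector g(3 * n);
  for (int r = 0; r < bonds.nrow(); ++r) {
    int i = (int)bonds(r, 0) - 1, j = (int)bonds(r, 1) - 1;
    double r0 = bonds(r, 2), kb = bonds(r, 3);
    double dx = x[i] - x[j], dy = x[i + n] - x[j + n], dz = x[i + 2 * n] - x[j + 2 * n];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz) + 1e-12;
    double dev = d - r0;
    f += kb * dev * dev;
    double c = 2.0 * kb * dev / d;
    g[i] += c * dx; g[i + n] += c * dy; g[i + 2 * n] += c * dz;
    g[j] -= c * dx; g[j + n] -= c * dy; g[j + 2 * n] -= c * dz;
  }
  for (int r = 0; r < angles.nrow(); ++r) {
    int i = (int)angles(r, 0) - 1, j = (int)angles(r, 1) - 1, k = (int)angles(r, 2) - 1;
    double th0 = angles(r, 3), kth = angles(r, 4);
    double ax = x[i] - x[j], ay = x[i + n] - x[j + n], az = x[i + 2 * n] - x[j + 2 * n];
    double bx = x[k] - x[j], by = x[k + n] - x[j + n], bz = x[k + 2 * n] - x[j + 2 * n];
    double na = std::sqrt(ax * ax + ay * ay + az * az) + 1e-12;
    double nb_ = std::sqrt(bx * bx + by * by + bz * bz) + 1e-12;
    double cosv = (ax * bx + ay * by + az * bz) / (na * nb_);
    if (cosv > 1.0) cosv = 1.0; else if (cosv < -1.0) cosv = -1.0;
    double th = std::acos(cosv);
    double dev = th - th0;
    f += kth * dev * dev;
    double sinv = std::sqrt(1.0 - cosv * cosv);
    if (sinv < 1e-6) sinv = 1e-6;
    double coef = -2.0 * kth * dev / sinv;   // dE/dcos
    // dcos/da = b/(na*nb) - cos * a/na^2, similarly for b
    double dax = bx / (na * nb_) - cosv * ax / (na * na);
    double day = by / (na * nb_) - cosv * ay / (na * na);
    double daz = bz / (na * nb_) - cosv * az / (na * na);
    double dbx = ax / (na * nb_) - cosv * bx / (nb_ * nb_);
    double dby = ay / (na * nb_) - cosv * by / (nb_ * nb_);
    double dbz = az / (na * nb_) - cosv * bz / (nb_ * nb_);
    g[i] += coef * dax; g[i + n] += coef * day; g[i + 2 * n] += coef * daz;
    g[k] += coef * dbx; g[k + n] += coef * dby; g[k + 2 * n] += coef * dbz;
    g[j] -= coef * (dax + dbx);
    g[j + n] -= coef * (day + dby);
    g[j + 2 * n] -= coef * (daz + dbz);
  }
  for (int r = 0; r < nb.nrow(); ++r) {
    int i = (int)nb(r, 0) - 1, j = (int)nb(r, 1) - 1;
    double sigma = nb(r, 2), kr = nb(r, 3);
    double dx = x[i] - x[j], dy = x[i + n] - x[j + n], dz = x[i + 2 * n] - x[j + 2 * n];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz) + 1e-12;
    if (d < sigma) {
      double dev = sigma - d;
      f += kr * dev * dev;
      double c = -2.0 * kr * dev / d;
      g[i] += c * dx; g[i + n] += c * dy; g[i + 2 * n] += c * dz;
      g[j] -= c * dx; g[j + n] -= c * dy; g[j + 2 * n] -= c * dz;
    }
  }
  for (int r = 0; r < chiral.nrow(); ++r) {
    int a = (int)chiral(r, 0) - 1, b = (int)chiral(r, 1) - 1;
    int c = (int)chiral(r, 2) - 1, d = (int)chiral(r, 3) - 1;
    double s = chiral(r, 4), vmin = chiral(r, 5);
    double V = signed_volume(x, a, b, c, d, n);
    double short_ = vmin - s * V;
    if (short_ > 0.0) {
      f += w_chiral * short_ * short_;
      add_vol_grad(g, x, a, b, c, d, -2.0 * w_chiral * short_ * s, n);
    }
  }
  for (int r = 0; r < planar.nrow(); ++r) {
    int a = (int)planar(r, 0) - 1, b = (int)planar(r, 1) - 1;
    int c = (int)planar(r, 2) - 1, d = (int)planar(r, 3) - 1;
    double kp = planar(r, 4);
    double V = signed_volume(x, a, b, c, d, n);
    f += kp * V * V;
    add_vol_grad(g, x, a, b, c, d, 2.0 * kp * V, n);
  }
  return List::create(_["f"] = f, _["g"] = g);
}
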