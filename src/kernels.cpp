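#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Distance kernels operate on a coordinate block laid out as an
// natoms x 3 x nframes array (column-major, as R stores it) and use the
// minimum-image convention for orthorhombic boxes. All lengths in nm.

static inline double pair_dist2(const double* xyz, int natoms, int frame,
                                int a, int b, const double* box, bool periodic) {
  double d2 = 0.0;
  for (int d = 0; d < 3; ++d) {
    double delta = xyz[a + natoms * (d + 3 * frame)] -
                   xyz[b + natoms * (d + 3 * frame)];
    if (periodic) {
      double L = box[d];
      delta -= L * std::round(delta / L);
    }
    d2 += delta * delta;
  }
  return d2;
}

// Brute-force per-residue minimum distance to a target atom set.
// resAtoms: list of 0-based atom index vectors, one per residue.
// Returns nframes x nres matrix of minimum distances.
// [[Rcpp::export(name = ".cpp_min_dist_brute")]]
NumericMatrix cpp_min_dist_brute(NumericVector coords, IntegerVector dims,
                                 List resAtoms, IntegerVector targetIdx,
                                 NumericMatrix box, bool periodic) {
  int natoms = dims[0], nframes = dims[2];
  int nres = resAtoms.size(), ntarg = targetIdx.size();
  const double* xyz = REAL(coords);
  NumericMatrix out(nframes, nres);
  std::vector<std::vector<int>> ridx(nres);
  for (int r = 0; r < nres; ++r)
    ridx[r] = as<std::vector<int>>(resAtoms[r]);
  for (int f = 0; f < nframes; ++f) {
    const double* bx = periodic ? &box(f, 0) : nullptr;
    double brow[3];
    if (periodic) { brow[0] = box(f, 0); brow[1] = box(f, 1); brow[2] = box(f, 2); }
    for (int r = 0; r < nres; ++r) {
      double best = std::numeric_limits<double>::infinity();
      for (size_t i = 0; i < ridx[r].size(); ++i) {
        int a = ridx[r][i];
        for (int j = 0; j < ntarg; ++j) {
          double d2 = pair_dist2(xyz, natoms, f, a, targetIdx[j],
                                 periodic ? brow : nullptr, periodic);
          if (d2 < best) best = d2;
        }
      }
      out(f, r) = std::sqrt(best);
      (void)bx;
    }
  }
  return out;
}

// --- cell-list grid for exact nearest-neighbour queries ------------------

struct Grid {
  int nc[3];
  double cell[3], origin[3], L[3];
  bool periodic;
  std::vector<std::vector<int>> cells;
  bool usable;

  int cell_of(double x, int d) const {
    int c = (int)std::floor((x - origin[d]) / cell[d]);
    if (periodic) {
      c %= nc[d];
      if (c < 0) c += nc[d];
    } else {
      if (c < 0) c = 0;
      if (c >= nc[d]) c = nc[d] - 1;
    }
    return c;
  }
  int flat(int i, int j, int k) const { return i + nc[0] * (j + nc[1] * k); }
};

static void build_grid(Grid& g, const double* xyz, int natoms, int frame,
                       const std::vector<int>& idx, const double* box,
                       bool periodic, double target_cell) {
  g.periodic = periodic;
  if (periodic) {
    for (int d = 0; d < 3; ++d) {
      g.L[d] = box[d];
      g.origin[d] = 0.0;
      g.nc[d] = std::max(1, (int)std::floor(box[d] / target_cell));
      g.cell[d] = box[d] / g.nc[d];
    }
    // minimum-image bookkeeping through a wrapped grid needs >= 3 cells/dim
    g.usable = g.nc[0] >= 3 && g.nc[1] >= 3 && g.nc[2] >= 3;
  } else {
    double lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::numeric_limits<double>::infinity();
      hi[d] = -std::numeric_limits<double>::infinity();
    }
    for (size_t i = 0; i < idx.size(); ++i)
      for (int d = 0; d < 3; ++d) {
        double v = xyz[idx[i] + natoms * (d + 3 * frame)];
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    for (int d = 0; d < 3; ++d) {
      double span = std::max(hi[d] - lo[d], 1e-9);
      g.origin[d] = lo[d];
      g.L[d] = span;
      g.nc[d] = std::max(1, std::min(64, (int)std::floor(span / target_cell)));
      g.cell[d] = span / g.nc[d];
    }
    g.usable = true;
  }
  if (!g.usable) return;
  g.cells.assign((size_t)g.nc[0] * g.nc[1] * g.nc[2], {});
  for (size_t i = 0; i < idx.size(); ++i) {
    int a = idx[i];
    double x = xyz[a + natoms * (0 + 3 * frame)];
    double y = xyz[a + natoms * (1 + 3 * frame)];
    double z = xyz[a + natoms * (2 + 3 * frame)];
    if (periodic) {
      x -= g.L[0] * std::floor(x / g.L[0]);
      y -= g.L[1] * std::floor(y / g.L[1]);
      z -= g.L[2] * std::floor(z / g.L[2]);
    }
    g.cells[g.flat(g.cell_of(x, 0), g.cell_of(y, 1), g.cell_of(z, 2))].push_back(a);
  }
}

// exact min distance from one atom to grid contents via expanding shells
static double grid_min_dist(const Grid& g, const double* xyz, int natoms,
                            int frame, int a, const double* box, bool periodic) {
  double q[3];
  for (int d = 0; d < 3; ++d) {
    q[d] = xyz[a + natoms * (d + 3 * frame)];
    if (periodic) q[d] -= g.L[d] * std::floor(q[d] / g.L[d]);
  }
  int qc[3] = { g.cell_of(q[0], 0), g.cell_of(q[1], 1), g.cell_of(q[2], 2) };
  double cmin = std::min(g.cell[0], std::min(g.cell[1], g.cell[2]));
  double best = std::numeric_limits<double>::infinity();
  int smax = std::max(g.nc[0], std::max(g.nc[1], g.nc[2]));
  auto visit = [&](int di, int dj, int dk, bool& visited_any) {
    int ci = qc[0] + di, cj = qc[1] + dj, ck = qc[2] + dk;
    if (g.periodic) {
      // each dim offset must stay within a single image of the cell
      // lattice; for even cell counts -nc/2 and +nc/2 alias, keep one
      if (std::abs(di) > g.nc[0] / 2 || std::abs(dj) > g.nc[1] / 2 ||
          std::abs(dk) > g.nc[2] / 2)
        return;
      if ((g.nc[0] % 2 == 0 && di == -g.nc[0] / 2) ||
          (g.nc[1] % 2 == 0 && dj == -g.nc[1] / 2) ||
          (g.nc[2] % 2 == 0 && dk == -g.nc[2] / 2))
        return;
      ci %= g.nc[0]; if (ci < 0) ci += g.nc[0];
      cj %= g.nc[1]; if (cj < 0) cj += g.nc[1];
      ck %= g.nc[2]; if (ck < 0) ck += g.nc[2];
    } else {
      if (ci < 0 || cj < 0 || ck < 0 || ci >= g.nc[0] || cj >= g.nc[1] ||
          ck >= g.nc[2])
        return;
    }
    visited_any = true;
    const std::vector<int>& bucket = g.cells[g.flat(ci, cj, ck)];
    for (size_t m = 0; m < bucket.size(); ++m) {
      double d2 = pair_dist2(xyz, natoms, frame, a, bucket[m], box, periodic);
      if (d2 < best) best = d2;
    }
  };
  for (int s = 0; s <= smax; ++s) {
    if (s >= 1 && std::isfinite(best) &&
        (double)(s - 1) * cmin >= std::sqrt(best))
      break;
    bool visited_any = false;
    if (s == 0) {
      visit(0, 0, 0, visited_any);
    } else {
      // enumerate the shell surface only: top/bottom, front/back, sides
      for (int di = -s; di <= s; ++di)
        for (int dj = -s; dj <= s; ++dj) {
          visit(di, dj, s, visited_any);
          visit(di, dj, -s, visited_any);
        }
      for (int di = -s; di <= s; ++di)
        for (int dk = -(s - 1); dk <= s - 1; ++dk) {
          visit(di, s, dk, visited_any);
          visit(di, -s, dk, visited_any);
        }
      for (int dj = -(s - 1); dj <= s - 1; ++dj)
        for (int dk = -(s - 1); dk <= s - 1; ++dk) {
          visit(s, dj, dk, visited_any);
          visit(-s, dj, dk, visited_any);
        }
    }
    if (!visited_any && s > 0 && std::isfinite(best)) break;
  }
  return best;  // squared
}

// Cell-list accelerated per-residue minimum distance; exact (expanding-shell
// search with a conservative lower bound). Falls back to brute force per
// frame when the box is too small to host a wrapped grid.
// [[Rcpp::export(name = ".cpp_min_dist_cell")]]
NumericMatrix cpp_min_dist_cell(NumericVector coords, IntegerVector dims,
                                List resAtoms, IntegerVector targetIdx,
                                NumericMatrix box, bool periodic,
                                double cellSize) {
  int natoms = dims[0], nframes = dims[2];
  int nres = resAtoms.size();
  const double* xyz = REAL(coords);
  NumericMatrix out(nframes, nres);
  std::vector<std::vector<int>> ridx(nres);
  for (int r = 0; r < nres; ++r)
    ridx[r] = as<std::vector<int>>(resAtoms[r]);
  std::vector<int> tidx = as<std::vector<int>>(targetIdx);

  for (int f = 0; f < nframes; ++f) {
    double brow[3] = {0, 0, 0};
    if (periodic) { brow[0] = box(f, 0); brow[1] = box(f, 1); brow[2] = box(f, 2); }
    Grid g;
    build_grid(g, xyz, natoms, f, tidx, brow, periodic, cellSize);
    for (int r = 0; r < nres; ++r) {
      double best = std::numeric_limits<double>::infinity();
      for (size_t i = 0; i < ridx[r].size(); ++i) {
        int a = ridx[r][i];
        double d2;
        if (g.usable) {
          d2 = grid_min_dist(g, xyz, natoms, f, a, periodic ? brow : nullptr,
                             periodic);
        } else {
          d2 = std::numeric_limits<double>::infinity();
          for (size_t j = 0; j < tidx.size(); ++j) {
            double t = pair_dist2(xyz, natoms, f, a, tidx[j],
                                  periodic ? brow : nullptr, periodic);
            if (t < d2) d2 = t;
          }
        }
        if (d2 < best) best = d2;
      }
      out(f, r) = std::sqrt(best);
    }
  }
  return out;
}

// Per-frame count of atom pairs (one from A, one from B) closer than cutoff.
// [[Rcpp::export(name = ".cpp_pair_count_brute")]]
NumericVector cpp_pair_count_brute(NumericVector coords, IntegerVector dims,
                                   IntegerVector idxA, IntegerVector idxB,
                                   double cutoff, NumericMatrix box,
                                   bool periodic) {
  int natoms = dims[0], nframes = dims[2];
  const double* xyz = REAL(coords);
  double c2 = cutoff * cutoff;
  NumericVector out(nframes);
  for (int f = 0; f < nframes; ++f) {
    double brow[3] = {0, 0, 0};
    if (periodic) { brow[0] = box(f, 0); brow[1] = box(f, 1); brow[2] = box(f, 2); }
    long count = 0;
    for (int i = 0; i < idxA.size(); ++i)
      for (int j = 0; j < idxB.size(); ++j) {
        double d2 = pair_dist2(xyz, natoms, f, idxA[i], idxB[j],
                               periodic ? brow : nullptr, periodic);
        if (d2 < c2) ++count;
      }
    out[f] = (double)count;
  }
  return out;
}

// Cell-list pair counting at fixed cutoff (cell edge >= cutoff, 27-cell scan).
// [[Rcpp::export(name = ".cpp_pair_count_cell")]]
NumericVector cpp_pair_count_cell(NumericVector coords, IntegerVector dims,
                                  IntegerVector idxA, IntegerVector idxB,
                                  double cutoff, NumericMatrix box,
                                  bool periodic) {
  int natoms = dims[0], nframes = dims[2];
  const double* xyz = REAL(coords);
  double c2 = cutoff * cutoff;
  NumericVector out(nframes);
  std::vector<int> aidx = as<std::vector<int>>(idxA);
  std::vector<int> bidx = as<std::vector<int>>(idxB);
  for (int f = 0; f < nframes; ++f) {
    double brow[3] = {0, 0, 0};
    if (periodic) { brow[0] = box(f, 0); brow[1] = box(f, 1); brow[2] = box(f, 2); }
    Grid g;
    build_grid(g, xyz, natoms, f, bidx, brow, periodic, cutoff);
    long count = 0;
    if (!g.usable) {
      for (size_t i = 0; i < aidx.size(); ++i)
        for (size_t j = 0; j < bidx.size(); ++j)
          if (pair_dist2(xyz, natoms, f, aidx[i], bidx[j],
                         periodic ? brow : nullptr, periodic) < c2)
            ++count;
    } else {
      for (size_t i = 0; i < aidx.size(); ++i) {
        int a = aidx[i];
        double q[3];
        for (int d = 0; d < 3; ++d) {
          q[d] = xyz[a + natoms * (d + 3 * f)];
          if (periodic) q[d] -= g.L[d] * std::floor(q[d] / g.L[d]);
        }
        int qc[3] = { g.cell_of(q[0], 0), g.cell_of(q[1], 1), g.cell_of(q[2], 2) };
        // cell edge may be < cutoff in a dim when nc was clamped; widen the
        // scan, but never beyond the grid itself (degenerate spans give
        // tiny cells and huge nominal reach)
        int reach[3];
        for (int d = 0; d < 3; ++d) {
          double r = std::ceil(cutoff / g.cell[d]);
          reach[d] = (r > g.nc[d]) ? g.nc[d] : std::max(1, (int)r);
        }
        for (int di = -reach[0]; di <= reach[0]; ++di)
          for (int dj = -reach[1]; dj <= reach[1]; ++dj)
            for (int dk = -reach[2]; dk <= reach[2]; ++dk) {
              int ci = qc[0] + di, cj = qc[1] + dj, ck = qc[2] + dk;
              if (g.periodic) {
                if (std::abs(di) > g.nc[0] / 2 || std::abs(dj) > g.nc[1] / 2 ||
                    std::abs(dk) > g.nc[2] / 2)
                  continue;
                if ((g.nc[0] % 2 == 0 && di == -g.nc[0] / 2) ||
                    (g.nc[1] % 2 == 0 && dj == -g.nc[1] / 2) ||
                    (g.nc[2] % 2 == 0 && dk == -g.nc[2] / 2))
                  continue;
                ci %= g.nc[0]; if (ci < 0) ci += g.nc[0];
                cj %= g.nc[1]; if (cj < 0) cj += g.nc[1];
                ck %= g.nc[2]; if (ck < 0) ck += g.nc[2];
              } else {
                if (ci < 0 || cj < 0 || ck < 0 || ci >= g.nc[0] ||
                    cj >= g.nc[1] || ck >= g.nc[2])
                  continue;
              }
              const std::vector<int>& bucket = g.cells[g.flat(ci, cj, ck)];
              for (size_t m = 0; m < bucket.size(); ++m)
                if (pair_dist2(xyz, natoms, f, a, bucket[m],
                               periodic ? brow : nullptr, periodic) < c2)
                  ++count;
            }
      }
    }
    out[f] = (double)count;
  }
  return out;
}

// Shrake-Rupley accessible surface. coords: natoms x 3 (single frame).
// spoints: npoints x 3 unit vectors. A test point on atom i's expanded
// sphere is buried if strictly inside another expanded sphere; a point
// lying exactly on another sphere's surface (|d - R_j| <= tol) is owned by
// the lower-indexed atom, so coincident duplicates do not double count.
// [[Rcpp::export(name = ".cpp_sasa")]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, NumericMatrix spoints) {
  int n = coords.nrow(), np = spoints.nrow();
  const double tol = 1e-10;
  NumericVector area(n);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;
  for (int i = 0; i < n; ++i) {
    // neighbours able to bury points of sphere i
    std::vector<int> nbr;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d2 = 0;
      for (int d = 0; d < 3; ++d) {
        double delta = coords(i, d) - coords(j, d);
        d2 += delta * delta;
      }
      double reach = R[i] + R[j];
      if (d2 < reach * reach) nbr.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < np; ++p) {
      double pt[3];
      for (int d = 0; d < 3; ++d) pt[d] = coords(i, d) + R[i] * spoints(p, d);
      bool buried = false;
      for (size_t m = 0; m < nbr.size(); ++m) {
        int j = nbr[m];
        double d2 = 0;
        for (int d = 0; d < 3; ++d) {
          double delta = pt[d] - coords(j, d);
          d2 += delta * delta;
        }
        double dd = std::sqrt(d2);
        if (dd < R[j] - tol) { buried = true; break; }
        if (std::fabs(dd - R[j]) <= tol && j < i) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * ((double)acc / np);
  }
  return area;
}
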