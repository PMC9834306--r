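#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley accessible areas, one value per atom.
//
// coords: n x 3 Cartesian coordinates (Angstrom)
// radii:  n van der Waals radii (Angstrom)
// probe:  solvent probe radius (Angstrom)
// pts:    m x 3 unit vectors (the test sphere; deterministic lattice)
//
// A test point on atom i's expanded sphere (radius r_i + probe) is accessible
// iff it lies outside the expanded sphere of every other atom. Per-atom area =
// 4*pi*(r_i + probe)^2 * accessible fraction.
// [[Rcpp::export]]
NumericVector sasa_atom_areas(NumericMatrix coords, NumericVector radii,
                              double probe, NumericMatrix pts) {
  const int n = coords.nrow();
  const int m = pts.nrow();
  NumericVector area(n);
  std::vector<int> nbr;
  nbr.reserve(n);

  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);

    // neighbours whose expanded sphere can intersect atom i's expanded sphere
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double rj = radii[j] + probe;
      const double dx = coords(j, 0) - xi;
      const double dy = coords(j, 1) - yi;
      const double dz = coords(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double rr = ri + rj;
      if (d2 < rr * rr) nbr.push_back(j);
    }

    int acc = 0;
    for (int p = 0; p < m; ++p) {
      const double px = xi + ri * pts(p, 0);
      const double py = yi + ri * pts(p, 1);
      const double pz = zi + ri * pts(p, 2);
      bool free_point = true;
      for (size_t k = 0; k < nbr.size(); ++k) {
        const int j = nbr[k];
        const double rj = radii[j] + probe;
        const double dx = px - coords(j, 0);
        const double dy = py - coords(j, 1);
        const double dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) {
          free_point = false;
          break;
        }
      }
      if (free_point) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)m;
  }
  return area;
}
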