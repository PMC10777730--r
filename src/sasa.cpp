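#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Deterministic quasi-uniform unit-sphere dots (golden-spiral lattice).
static std::vector<double> sphere_dots(int n) {
  std::vector<double> d(3 * (size_t)n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - (2.0 * i + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * i;
    d[3 * (size_t)i]     = r * std::cos(th);
    d[3 * (size_t)i + 1] = r * std::sin(th);
    d[3 * (size_t)i + 2] = z;
  }
  return d;
}

// Shrake-Rupley exposed area per surface bead.
//
// coords: N x 3 (nm); radii: length N (nm); probe: probe radius (nm);
// surface0 / occluder0: 0-based indices into the bead table. A dot on
// surface bead i is exposed iff it is NOT strictly inside the expanded
// sphere (radius r_j + probe) of any occluder j != i; boundary dots count
// as exposed. Area_i = 4*pi*(r_i+probe)^2 * exposed_i / n_dots.
// [[Rcpp::export(name = ".sr_area")]]
NumericVector sr_area(NumericMatrix coords, NumericVector radii,
                      double probe, int n_dots,
                      IntegerVector surface0, IntegerVector occluder0) {
  const int N = coords.nrow();
  if (radii.size() != N) stop("radii length must match coordinate rows");
  for (int i = 0; i < N; ++i) {
    if (!(radii[i] > 0)) stop("all bead radii must be positive");
  }
  if (probe < 0) stop("probe radius must be >= 0");
  if (n_dots < 32) stop("n_dots must be >= 32");

  std::vector<double> dots = sphere_dots(n_dots);
  const int ns = surface0.size(), no = occluder0.size();
  NumericVector area(ns);

  std::vector<double> Rexp((size_t)N);
  for (int i = 0; i < N; ++i) Rexp[(size_t)i] = radii[i] + probe;

  std::vector<int> nb; nb.reserve((size_t)no);
  for (int si = 0; si < ns; ++si) {
    const int i = surface0[si];
    const double Ri = Rexp[(size_t)i];
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);

    // candidate occluders: expanded spheres that can reach bead i's surface
    nb.clear();
    for (int oj = 0; oj < no; ++oj) {
      const int j = occluder0[oj];
      if (j == i) continue;
      const double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
                   dz = coords(j, 2) - zi;
      const double lim = Ri + Rexp[(size_t)j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }

    int exposed = 0;
    if (nb.empty()) {
      exposed = n_dots;
    } else {
      for (int d = 0; d < n_dots; ++d) {
        const double px = xi + Ri * dots[3 * (size_t)d];
        const double py = yi + Ri * dots[3 * (size_t)d + 1];
        const double pz = zi + Ri * dots[3 * (size_t)d + 2];
        bool occ = false;
        for (size_t k = 0; k < nb.size(); ++k) {
          const int j = nb[k];
          const double dx = px - coords(j, 0), dy = py - coords(j, 1),
                       dz = pz - coords(j, 2);
          const double Rj = Rexp[(size_t)j];
          if (dx * dx + dy * dy + dz * dz < Rj * Rj) { occ = true; break; }
        }
        if (!occ) ++exposed;
      }
    }
    area[si] = 4.0 * M_PI * Ri * Ri * (double)exposed / (double)n_dots;
  }
  return area;
}
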