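#include <Rcpp.h>
#include "raytrace.h"
using namespace Rcpp;

static Grid grid_from_list(List g) {
  Grid gr;
  gr.nx = as<int>(g["nx"]); gr.ny = as<int>(g["ny"]); gr.nz = as<int>(g["nz"]);
  gr.dx = as<double>(g["dx"]); gr.dy = as<double>(g["dy"]); gr.dz = as<double>(g["dz"]);
  gr.x0 = as<double>(g["x0"]); gr.y0 = as<double>(g["y0"]); gr.z0 = as<double>(g["z0"]);
  return gr;
}

// Back-to-back photon transport of annihilation points to a cylindrical ring
// scanner.  Directions are isotropic for multi-ring scanners; a single-ring
// scanner is treated as a 2D system with in-plane directions.  Detection is
// front-face: each photon is assigned the crystal whose angular/axial bin
// contains its intersection with the detector cylinder.  Events whose pair
// of crystals is closer (circularly) than `min_sector_diff` are rejected.
// Optional attenuation: the event survives with probability exp(-integral of
// mu along the full line of response between the two crystal centers).
//
// Returns, per accepted event, the canonical detector pair (a < b by
// flattened index ring*n_crystals + crystal), the geometric time difference
// dt = (d_a - d_b)/c (positive when crystal a is farther from the emission),
// and the 1-based row index of the originating point.
// [[Rcpp::export]]
List cpp_emit_and_detect(NumericMatrix points, double ring_radius,
                         int n_crystals, int n_rings, double pitch_axial,
                         int min_sector_diff, bool planar,
                         Nullable<NumericVector> mu_img,
                         Nullable<List> mu_grid) {
  const int n = points.nrow();
  const double dphi = 2.0 * M_PI / n_crystals;
  const double zmin = -0.5 * n_rings * pitch_axial;
  const bool use_att = mu_img.isNotNull() && mu_grid.isNotNull();
  Grid g;
  NumericVector mu;
  if (use_att) { g = grid_from_list(mu_grid.get()); mu = mu_img.get(); }

  std::vector<int> ra, ca, rb, cb, src;
  std::vector<double> dt;
  RNGScope scope;

  for (int i = 0; i < n; ++i) {
    const double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double ux, uy, uz;
    if (planar) {
      const double phi = 2.0 * M_PI * unif_rand();
      ux = std::cos(phi); uy = std::sin(phi); uz = 0.0;
    } else {
      uz = 2.0 * unif_rand() - 1.0;
      const double phi = 2.0 * M_PI * unif_rand();
      const double s = std::sqrt(std::max(0.0, 1.0 - uz * uz));
      ux = s * std::cos(phi); uy = s * std::sin(phi);
    }
    const double a2 = ux * ux + uy * uy;
    if (a2 < 1e-14) continue;           // (near-)axial ray never meets the ring
    const double b = px * ux + py * uy;
    const double c0 = px * px + py * py - ring_radius * ring_radius;
    const double disc = b * b - a2 * c0;
    if (disc <= 0.0 || c0 >= 0.0) continue; // point outside the ring
    const double sq = std::sqrt(disc);
    const double t1 = (-b + sq) / a2;   // photon along +u
    const double t2 = (b + sq) / a2;    // photon along -u

    const double z1 = pz + t1 * uz, z2 = pz - t2 * uz;
    const int ring1 = (int)std::floor((z1 - zmin) / pitch_axial);
    const int ring2 = (int)std::floor((z2 - zmin) / pitch_axial);
    if (ring1 < 0 || ring1 >= n_rings || ring2 < 0 || ring2 >= n_rings) continue;

    const double a1x = px + t1 * ux, a1y = py + t1 * uy;
    const double a2x = px - t2 * ux, a2y = py - t2 * uy;
    int c1 = (int)std::lround(std::atan2(a1y, a1x) / dphi);
    int c2 = (int)std::lround(std::atan2(a2y, a2x) / dphi);
    c1 = ((c1 % n_crystals) + n_crystals) % n_crystals;
    c2 = ((c2 % n_crystals) + n_crystals) % n_crystals;

    int dc = std::abs(c1 - c2);
    dc = std::min(dc, n_crystals - dc);
    if (dc < min_sector_diff) continue;

    // canonical ordering: a < b by flattened index
    long f1 = (long)ring1 * n_crystals + c1;
    long f2 = (long)ring2 * n_crystals + c2;
    double d_first = t1, d_second = t2;
    int rra = ring1, cca = c1, rrb = ring2, ccb = c2;
    if (f1 > f2) {
      std::swap(rra, rrb); std::swap(cca, ccb); std::swap(d_first, d_second);
    } else if (f1 == f2) {
      continue; // both photons in the same crystal: not a usable pair
    }

    if (use_att) {
      // survival along the full LOR between the two crystal centers
      const double phia = dphi * cca, phib = dphi * ccb;
      double pa[3] = { ring_radius * std::cos(phia), ring_radius * std::sin(phia),
                       zmin + (rra + 0.5) * pitch_axial };
      double pb[3] = { ring_radius * std::cos(phib), ring_radius * std::sin(phib),
                       zmin + (rrb + 0.5) * pitch_axial };
      const double surv = std::exp(-line_integral(g, mu.begin(), pa, pb));
      if (unif_rand() >= surv) continue;
    }

    ra.push_back(rra); ca.push_back(cca);
    rb.push_back(rrb); cb.push_back(ccb);
    dt.push_back((d_first - d_second) / C_MM_PER_PS);
    src.push_back(i + 1);
  }

  return List::create(
    _["ring_a"] = IntegerVector(ra.begin(), ra.end()),
    _["crystal_a"] = IntegerVector(ca.begin(), ca.end()),
    _["ring_b"] = IntegerVector(rb.begin(), rb.end()),
    _["crystal_b"] = IntegerVector(cb.begin(), cb.end()),
    _["geometric_dt_ps"] = NumericVector(dt.begin(), dt.end()),
    _["emission"] = IntegerVector(src.begin(), src.end()));
}
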