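#pragma once
#include <cmath>
#include <algorithm>
#include <limits>

// Reconstruction / attenuation grid. `x0,y0,z0` is the most-negative corner;
// voxels are indexed x-fastest (linear index = ix + nx*(iy + ny*iz), 0-based).
struct Grid {
  int nx, ny, nz;
  double dx, dy, dz;
  double x0, y0, z0;
  long nvox() const { return (long)nx * ny * nz; }
};

// Exact voxel traversal of the segment p1 -> p2 (incremental Siddon /
// Amanatides-Woo).  Calls emit(linear_index, length_mm, iv[3], t_mid) for
// every voxel the segment crosses; intersection lengths sum to the in-grid
// chord length.  t_mid is the parametric midpoint of the voxel's segment in
// [0,1] of the full p1->p2 segment (used for TOF projections).
template <typename F>
inline void traverse_ray(const Grid& g, const double* p1, const double* p2, F&& emit) {
  double d[3] = { p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2] };
  const double len = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  if (len <= 0.0) return;
  const double lo[3] = { g.x0, g.y0, g.z0 };
  const double dd[3] = { g.dx, g.dy, g.dz };
  const int    n[3]  = { g.nx, g.ny, g.nz };
  const double hi[3] = { g.x0 + n[0]*dd[0], g.y0 + n[1]*dd[1], g.z0 + n[2]*dd[2] };

  double tmin = 0.0, tmax = 1.0;
  for (int k = 0; k < 3; ++k) {
    if (d[k] != 0.0) {
      double t1 = (lo[k] - p1[k]) / d[k];
      double t2 = (hi[k] - p1[k]) / d[k];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    } else if (p1[k] <= lo[k] || p1[k] >= hi[k]) {
      return; // parallel ray outside the slab
    }
  }
  if (tmax <= tmin) return;

  int    iv[3], step[3];
  double tnext[3], tdelta[3];
  for (int k = 0; k < 3; ++k) {
    double q = p1[k] + tmin * d[k];
    int i = (int)std::floor((q - lo[k]) / dd[k]);
    if (i < 0) i = 0;
    if (i >= n[k]) i = n[k] - 1;
    iv[k] = i;
    if (d[k] > 0.0) {
      step[k]   = 1;
      tdelta[k] = dd[k] / d[k];
      tnext[k]  = ((lo[k] + (i + 1) * dd[k]) - p1[k]) / d[k];
    } else if (d[k] < 0.0) {
      step[k]   = -1;
      tdelta[k] = -dd[k] / d[k];
      tnext[k]  = ((lo[k] + i * dd[k]) - p1[k]) / d[k];
    } else {
      step[k]   = 0;
      tdelta[k] = 0.0;
      tnext[k]  = std::numeric_limits<double>::infinity();
    }
  }

  double t = tmin;
  while (t < tmax - 1e-13) {
    int k = 0;
    if (tnext[1] < tnext[k]) k = 1;
    if (tnext[2] < tnext[k]) k = 2;
    double tn = std::min(tnext[k], tmax);
    double seg = (tn - t) * len;
    if (seg > 0.0) {
      long idx = iv[0] + (long)n[0] * (iv[1] + (long)n[1] * iv[2]);
      emit(idx, seg, iv, 0.5 * (t + tn));
    }
    t = tn;
    if (tnext[k] <= tmax) {
      iv[k] += step[k];
      if (iv[k] < 0 || iv[k] >= n[k]) break;
      tnext[k] += tdelta[k];
    }
  }
}

// Line integral of a voxelized image along the segment p1 -> p2 (mm * value).
inline double line_integral(const Grid& g, const double* img,
                            const double* p1, const double* p2) {
  double s = 0.0;
  traverse_ray(g, p1, p2, [&](long idx, double seg, const int*, double) {
    s += img[idx] * seg;
  });
  return s;
}

// Standard normal CDF.
inline double phi_cdf(double x) { return 0.5 * std::erfc(-x * M_SQRT1_2); }

// Speed of light in mm per picosecond.
constexpr double C_MM_PER_PS = 0.299792458;
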