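#include <Rcpp.h>
#include "raytrace.h"
using namespace Rcpp;

static Grid grid_from_list_r(List g) {
  Grid gr;
  gr.nx = as<int>(g["nx"]); gr.ny = as<int>(g["ny"]); gr.nz = as<int>(g["nz"]);
  gr.dx = as<double>(g["dx"]); gr.dy = as<double>(g["dy"]); gr.dz = as<double>(g["dz"]);
  gr.x0 = as<double>(g["x0"]); gr.y0 = as<double>(g["y0"]); gr.z0 = as<double>(g["z0"]);
  return gr;
}

// Voxels crossed by the segment p1 -> p2 with exact intersection lengths.
// [[Rcpp::export]]
List cpp_siddon(List grid, NumericVector p1, NumericVector p2) {
  Grid g = grid_from_list_r(grid);
  std::vector<int> ix, iy, iz;
  std::vector<double> len;
  traverse_ray(g, p1.begin(), p2.begin(),
               [&](long, double seg, const int* iv, double) {
                 ix.push_back(iv[0]); iy.push_back(iv[1]); iz.push_back(iv[2]);
                 len.push_back(seg);
               });
  return List::create(_["ix"] = IntegerVector(ix.begin(), ix.end()),
                      _["iy"] = IntegerVector(iy.begin(), iy.end()),
                      _["iz"] = IntegerVector(iz.begin(), iz.end()),
                      _["length_mm"] = NumericVector(len.begin(), len.end()));
}

// [[Rcpp::export]]
double cpp_line_integral(List grid, NumericVector img, NumericVector p1,
                         NumericVector p2) {
  Grid g = grid_from_list_r(grid);
  return line_integral(g, img.begin(), p1.begin(), p2.begin());
}

// Sensitivity image s_j = sum over admissible detector pairs of a_ij * p_ij.
// TOF weights sum out over the bins (telescoping CDF differences), so s_j is
// TOF-independent.  `centers` holds one row per flattened detector index
// (ring * n_crystals + crystal).
// [[Rcpp::export]]
NumericVector cpp_sensitivity(NumericMatrix centers, int n_crystals,
                              int min_sector_diff, List grid,
                              Nullable<NumericVector> mu_img) {
  Grid g = grid_from_list_r(grid);
  const int nd = centers.nrow();
  const bool use_att = mu_img.isNotNull();
  NumericVector mu;
  if (use_att) mu = mu_img.get();
  NumericVector s((long)g.nvox());

  for (int i = 0; i < nd; ++i) {
    const double pa[3] = { centers(i, 0), centers(i, 1), centers(i, 2) };
    const int ci = i % n_crystals;
    for (int j = i + 1; j < nd; ++j) {
      int dc = std::abs(ci - j % n_crystals);
      dc = std::min(dc, n_crystals - dc);
      if (dc < min_sector_diff) continue;
      const double pb[3] = { centers(j, 0), centers(j, 1), centers(j, 2) };
      double att = 1.0;
      if (use_att) att = std::exp(-line_integral(g, mu.begin(), pa, pb));
      traverse_ray(g, pa, pb, [&](long idx, double seg, const int*, double) {
        s[idx] += att * seg;
      });
    }
    Rcpp::checkUserInterrupt();
  }
  return s;
}

// List-mode MLEM with per-event TOF kernels.
//
// Per event the system-matrix row is p_ij * K_ij * a_i, where p_ij is the
// Siddon intersection length, a_i the attenuation survival factor of the
// LOR, and K_ij the TOF weight of the bin [k_t, k_t + bin_w) containing the
// event's measured time difference:
//   K = w1 * (Phi((k_{t+1}-v)/sig1) - Phi((k_t-v)/sig1))
//     + (1-w1) * (Phi((k_{t+1}-v)/sig2) - Phi((k_t-v)/sig2))
// with v the signed TOF projection of the voxel center on the LOR.  The
// caller resolves the reconstruction model into per-event (sig1, sig2, w1):
// mixture kernels use w1 = alpha of the event's kernel, decomposed and
// single-Gaussian models use w1 = 1, and tof = false drops K entirely.
//
// Rows are precomputed once (they do not change across iterations) and the
// multiplicative update is then iterated:
//   lambda_j <- (lambda_j / s_j) * sum_i w_ij / (sum_k w_ik lambda_k).
// Voxels with |v - dt| > trunc_nsig * max(sigma) are excluded from TOF rows
// (negligible kernel mass).
// [[Rcpp::export]]
List cpp_lm_mlem(NumericMatrix pa, NumericMatrix pb, NumericVector dt,
                 NumericVector sig1, NumericVector sig2, NumericVector w1,
                 bool tof, List grid, Nullable<NumericVector> mu_img,
                 double bin_w, double trunc_nsig, NumericVector sens,
                 int n_iter, IntegerVector save_iters) {
  Grid g = grid_from_list_r(grid);
  const int n_ev = pa.nrow();
  const long nv = g.nvox();
  const bool use_att = mu_img.isNotNull();
  NumericVector mu;
  if (use_att) mu = mu_img.get();

  // ---- precompute sparse rows (float values to halve memory) ----
  std::vector<std::size_t> rp(n_ev + 1, 0);
  std::vector<int> col;
  std::vector<float> val;
  col.reserve((std::size_t)n_ev * 64);
  val.reserve((std::size_t)n_ev * 64);

  for (int i = 0; i < n_ev; ++i) {
    const double A[3] = { pa(i, 0), pa(i, 1), pa(i, 2) };
    const double B[3] = { pb(i, 0), pb(i, 1), pb(i, 2) };
    double u[3] = { B[0] - A[0], B[1] - A[1], B[2] - A[2] };
    const double L = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
    u[0] /= L; u[1] /= L; u[2] /= L;
    const double smid = 0.5 * L;
    double att = 1.0;
    if (use_att) att = std::exp(-line_integral(g, mu.begin(), A, B));

    double s1 = 1.0, s2 = 1.0, a1 = 1.0, k0 = 0.0, vmax = 0.0;
    if (tof) {
      s1 = sig1[i]; s2 = sig2[i]; a1 = w1[i];
      k0 = bin_w * std::floor(dt[i] / bin_w);
      const double smax = (a1 < 1.0) ? std::max(s1, s2) : s1;
      vmax = trunc_nsig * smax + bin_w;
    }
    traverse_ray(g, A, B, [&](long idx, double seg, const int* iv, double tmid) {
      double K = 1.0;
      if (tof) {
        // TOF projection of the voxel center onto the LOR axis
        const double cx = g.x0 + (iv[0] + 0.5) * g.dx - A[0];
        const double cy = g.y0 + (iv[1] + 0.5) * g.dy - A[1];
        const double cz = g.z0 + (iv[2] + 0.5) * g.dz - A[2];
        const double s = cx * u[0] + cy * u[1] + cz * u[2];
        const double v = 2.0 * (s - smid) / C_MM_PER_PS;
        (void)tmid;
        if (std::fabs(v - dt[i]) > vmax) return;
        K = a1 * (phi_cdf((k0 + bin_w - v) / s1) - phi_cdf((k0 - v) / s1));
        if (a1 < 1.0)
          K += (1.0 - a1) * (phi_cdf((k0 + bin_w - v) / s2) - phi_cdf((k0 - v) / s2));
      }
      const double w = att * seg * K;
      if (w > 0.0) { col.push_back((int)idx); val.push_back((float)w); }
    });
    rp[i + 1] = col.size();
    if (i % 8192 == 0) Rcpp::checkUserInterrupt();
  }

  // ---- iterate ----
  std::vector<double> lambda(nv, 0.0), num(nv), y(n_ev);
  for (long j = 0; j < nv; ++j) lambda[j] = sens[j] > 0.0 ? 1.0 : 0.0;

  const int n_save = save_iters.size();
  NumericMatrix images(nv, n_save);
  NumericVector loglik(n_iter), conserv(n_iter);
  IntegerVector used(n_iter);

  for (int it = 0; it < n_iter; ++it) {
    std::fill(num.begin(), num.end(), 0.0);
    int n_used = 0;
    for (int i = 0; i < n_ev; ++i) {
      double yi = 0.0;
      for (std::size_t k = rp[i]; k < rp[i + 1]; ++k) yi += (double)val[k] * lambda[col[k]];
      y[i] = yi;
      if (yi <= 0.0) continue;
      ++n_used;
      const double inv = 1.0 / yi;
      for (std::size_t k = rp[i]; k < rp[i + 1]; ++k) num[col[k]] += (double)val[k] * inv;
    }
    double tot = 0.0;
    for (long j = 0; j < nv; ++j) {
      if (sens[j] > 0.0) lambda[j] = lambda[j] / sens[j] * num[j];
      tot += lambda[j] * sens[j];
    }
    conserv[it] = tot;
    used[it] = n_used;
    // log-likelihood of the updated image (same skipped-event set)
    double ll = -tot;
    for (int i = 0; i < n_ev; ++i) {
      if (y[i] <= 0.0) continue;
      double yi = 0.0;
      for (std::size_t k = rp[i]; k < rp[i + 1]; ++k) yi += (double)val[k] * lambda[col[k]];
      if (yi > 0.0) ll += std::log(yi);
    }
    loglik[it] = ll;
    for (int s = 0; s < n_save; ++s)
      if (save_iters[s] == it + 1)
        for (long j = 0; j < nv; ++j) images(j, s) = lambda[j];
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["images"] = images, _["loglik"] = loglik,
                      _["conservation"] = conserv, _["events_used"] = used,
                      _["n_events"] = n_ev);
}
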