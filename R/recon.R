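#' Siddon ray tracing through a voxel grid
#'
#' Exact voxel intersection lengths of the segment `p1 -> p2`: exactly the
#' voxels the segment crosses, with lengths summing to the in-grid chord
#' length.  This is the geometric projector `p_ij` of the list-mode MLEM
#' system model.
#'
#' @param grid a [voxel_grid()].
#' @param p1,p2 xyz endpoints, mm (must differ).
#' @return data.frame with 0-based indices `ix, iy, iz`, the 1-based linear
#'   `voxel` index (x fastest) and `length_mm`.
#' @export
siddon_path <- function(grid, p1, p2) {
  stopifnot(inherits(grid, "voxel_grid"), length(p1) == 3, length(p2) == 3)
  if (all(p1 == p2)) stop("degenerate ray: p1 == p2")
  res <- cpp_siddon(grid_as_list(grid), as.numeric(p1), as.numeric(p2))
  data.frame(ix = res$ix, iy = res$iy, iz = res$iz,
             voxel = res$ix + grid$nx * (res$iy + grid$ny * res$iz) + 1L,
             length_mm = res$length_mm)
}

#' TOF projection of points onto a line of response
#'
#' Signed time coordinate of the orthogonal projection of `points` onto the
#' LOR axis: `t = 2 * (s - s_mid) / c`, where `s` is the arc length from
#' `p1`.  The sign matches the simulator's convention (`delta_t = t_a -
#' t_b`): points displaced toward `p2` (detector b) get positive times.
#'
#' @param points n x 3 matrix (or length-3 vector) of positions, mm.
#' @param p1,p2 LOR endpoints (detector a and b), mm.
#' @return numeric vector of times in ps.
#' @export
tof_projection <- function(points, p1, p2) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  u <- p2 - p1
  len <- sqrt(sum(u^2))
  stopifnot(len > 0)
  u <- u / len
  s <- (points[, 1] - p1[1]) * u[1] + (points[, 2] - p1[2]) * u[2] +
    (points[, 3] - p1[3]) * u[3]
  2 * (s - len / 2) / c_mm_per_ps()
}

#' @rdname tof_projection
#' @param grid a [voxel_grid()].
#' @param voxel 1-based linear voxel index (vectorized).
#' @export
voxel_tof_projection <- function(grid, voxel, p1, p2) {
  tof_projection(voxel_center_from_index(grid, voxel), p1, p2)
}

#' Reconstruction model
#'
#' Which timing kernel the TOF weights use:
#' * `"mixture"` - the double-Gaussian mixture kernel identified by each
#'   event's `kernel_id` (covers both the multi-kernel and the
#'   single-mixture reconstructions, since the latter simply has
#'   `kernel_id = 1` on every event);
#' * `"decomposed"` - the single Gaussian component (fast or slow) that was
#'   actually applied to each pair during simulation, via the stored
#'   component flag;
#' * `"gaussian"` - one Gaussian of `gaussian_fwhm_ps` for all events;
#' * `"none"` - non-TOF weights (1 for every voxel on the LOR).
#'
#' @param mode one of `"mixture"`, `"decomposed"`, `"gaussian"`, `"none"`.
#' @param bank [kernel_bank()] (needed for mixture/decomposed).
#' @param gaussian_fwhm_ps FWHM for the `"gaussian"` mode, ps.
#' @return object of class `recon_model`.
#' @export
recon_model <- function(mode = c("mixture", "decomposed", "gaussian", "none"),
                        bank = NULL, gaussian_fwhm_ps = 213) {
  mode <- match.arg(mode)
  if (mode %in% c("mixture", "decomposed")) {
    if (is.null(bank)) bank <- default_kernel_bank()
    stopifnot(inherits(bank, "kernel_bank"))
  }
  structure(list(mode = mode, bank = bank,
                 gaussian_fwhm_ps = gaussian_fwhm_ps),
            class = "recon_model")
}

#' Reconstruction configuration
#'
#' @param grid [voxel_grid()] for the image.
#' @param n_iterations MLEM iterations (>= 1).
#' @param model a [recon_model()].
#' @param tof_bin_ps TOF bin width, ps (default 1).
#' @param attenuation_image optional 3D mu array on `grid`; enters as the
#'   multiplicative survival factor in both the sensitivity and the forward
#'   model.
#' @param save_iterations iteration numbers whose images are kept (the final
#'   iteration is always included).
#' @param trunc_nsigma voxels with TOF projection farther than this many
#'   (widest-component) sigmas from the measured time difference are dropped
#'   from TOF rows; 5 keeps all but ~3e-7 of the kernel mass.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(grid, n_iterations, model, tof_bin_ps = 1,
                         attenuation_image = NULL, save_iterations = NULL,
                         trunc_nsigma = 5) {
  stopifnot(inherits(grid, "voxel_grid"), n_iterations >= 1,
            inherits(model, "recon_model"), tof_bin_ps > 0)
  save_iterations <- sort(unique(c(as.integer(save_iterations),
                                   as.integer(n_iterations))))
  save_iterations <- save_iterations[save_iterations >= 1 &
                                     save_iterations <= n_iterations]
  structure(list(grid = grid, n_iterations = as.integer(n_iterations),
                 model = model, tof_bin_ps = tof_bin_ps,
                 attenuation_image = attenuation_image,
                 save_iterations = save_iterations,
                 trunc_nsigma = trunc_nsigma),
            class = "recon_config")
}

# resolve a recon model into per-event (sigma1, sigma2, w1); w1 is the
# mixing weight of sigma1 and equals 1 for single-component models
resolve_event_kernels <- function(model, events) {
  n <- nrow(events)
  if (model$mode == "none")
    return(list(sig1 = numeric(n), sig2 = numeric(n), w1 = numeric(n),
                tof = FALSE))
  if (model$mode == "gaussian") {
    s <- fwhm_to_sigma(model$gaussian_fwhm_ps)
    return(list(sig1 = rep(s, n), sig2 = rep(s, n), w1 = rep(1, n),
                tof = TRUE))
  }
  tab <- as.data.frame(model$bank)
  kid <- events$kernel_id
  if (any(kid < 1 | kid > nrow(tab)))
    stop("events carry kernel ids outside the reconstruction bank")
  sf <- fwhm_to_sigma(tab$fwhm_fast_ps[kid])
  ss <- fwhm_to_sigma(tab$fwhm_slow_ps[kid])
  if (model$mode == "mixture")
    return(list(sig1 = sf, sig2 = ss, w1 = tab$alpha_fast[kid], tof = TRUE))
  # decomposed: use the component actually applied during simulation
  if (is.null(events$component) || any(events$component == 0L))
    stop("decomposed reconstruction needs per-event component flags")
  list(sig1 = ifelse(events$component == 1L, sf, ss),
       sig2 = ifelse(events$component == 1L, sf, ss),
       w1 = rep(1, n), tof = TRUE)
}

#' TOF bin weight of a voxel for one event
#'
#' The per-voxel TOF weight is the kernel mass falling in the TOF bin
#' `[k_t, k_t + bin)` that contains the event's measured time difference,
#' evaluated at the voxel's TOF projection `v`:
#' `K = alpha * (cdf_F(k_{t+1} - v) - cdf_F(k_t - v)) +
#'  (1 - alpha) * (cdf_S(k_{t+1} - v) - cdf_S(k_t - v))`.
#' Summed over all TOF bins the weights telescope to 1 for every voxel and
#' kernel; non-TOF weights are identically 1.
#'
#' @param model a [recon_model()].
#' @param event one event as a list/row with `delta_t_ps`, `kernel_id`,
#'   `component`.
#' @param v_ps TOF projections of voxel centers (vectorized), ps.
#' @param bin_ps TOF bin width, ps.
#' @param bin_start optional left edge of the bin; defaults to the edge of
#'   the bin containing `delta_t_ps` on the grid anchored at 0.
#' @return numeric vector of weights.
#' @export
tof_weight <- function(model, event, v_ps, bin_ps = 1, bin_start = NULL) {
  stopifnot(inherits(model, "recon_model"))
  if (model$mode == "none") return(rep(1, length(v_ps)))
  ev <- as.data.frame(event)
  par <- resolve_event_kernels(model, ev)
  k0 <- if (is.null(bin_start)) bin_ps * floor(ev$delta_t_ps / bin_ps)
        else bin_start
  k1 <- k0 + bin_ps
  w <- par$w1 * (pnorm((k1 - v_ps) / par$sig1) - pnorm((k0 - v_ps) / par$sig1))
  if (par$w1 < 1)
    w <- w + (1 - par$w1) *
      (pnorm((k1 - v_ps) / par$sig2) - pnorm((k0 - v_ps) / par$sig2))
  w
}

#' Sensitivity image
#'
#' Per-voxel total detection sensitivity `s_j = sum over admissible detector
#' pairs of a_ij * p_ij` (attenuation survival times intersection length).
#' TOF weights sum out over the bins, so the sensitivity is TOF-independent
#' and shared by all reconstruction models on the same scanner and grid.
#'
#' @param scanner a [ring_scanner()].
#' @param grid a [voxel_grid()].
#' @param attenuation_image optional 3D mu array on `grid`.
#' @param min_sector_difference admissibility rule; defaults to the
#'   scanner's.
#' @return 3D array `s_j`, strictly positive inside the scanner
#'   field of view.
#' @export
sensitivity_image <- function(scanner, grid, attenuation_image = NULL,
                              min_sector_difference =
                                scanner$min_sector_difference) {
  stopifnot(inherits(scanner, "ring_scanner"), inherits(grid, "voxel_grid"))
  centers <- all_crystal_centers(scanner)
  mu <- if (is.null(attenuation_image)) NULL else as.numeric(attenuation_image)
  s <- cpp_sensitivity(centers, scanner$n_crystals_per_ring,
                       as.integer(min_sector_difference), grid_as_list(grid),
                       mu)
  array(s, c(grid$nx, grid$ny, grid$nz))
}

#' List-mode TOF MLEM reconstruction
#'
#' Multiplicative EM update per iteration,
#' `lambda_j <- (lambda_j / s_j) * sum_i p_it;jp / (sum_k p_it;kp lambda_k)`,
#' with the per-event system row `p_it;jp = a_i * p_ij * K_it;jp` combining
#' the Siddon intersection length, the optional attenuation survival factor,
#' and the TOF bin weight of the configured timing model (see
#' [tof_weight()]).  The initial image is 1 inside the sensitivity support;
#' nonnegativity is preserved by construction, the list-mode Poisson
#' log-likelihood is nondecreasing and, after every update,
#' `sum_j lambda_j s_j` equals the number of events used.  Events with zero
#' forward projection are skipped and counted.  All events are visited once
#' per iteration (MLEM, no subsets) and no post-filtering is applied.
#'
#' @param lm a `listmode` object (or anything with `events` and `scanner`).
#' @param config a [recon_config()].
#' @param sensitivity optional precomputed [sensitivity_image()] (it is
#'   model-independent, so one image can serve several reconstructions).
#' @return object of class `mlem_result`: `images` (named list of 3D arrays
#'   by saved iteration), `image` (final iteration), `loglik`,
#'   `conservation` and `events_used` per iteration, `n_events`,
#'   `n_skipped`, plus the `config` and `sensitivity` used.
#' @export
lm_mlem <- function(lm, config, sensitivity = NULL) {
  stopifnot(inherits(config, "recon_config"))
  events <- lm$events
  if (nrow(events) == 0) stop("no events to reconstruct")
  scanner <- lm$scanner
  if (is.null(sensitivity))
    sensitivity <- sensitivity_image(scanner, config$grid,
                                     config$attenuation_image)
  pa <- crystal_center(scanner, events$ring_a, events$crystal_a)
  pb <- crystal_center(scanner, events$ring_b, events$crystal_b)
  par <- resolve_event_kernels(config$model, events)
  mu <- if (is.null(config$attenuation_image)) NULL
        else as.numeric(config$attenuation_image)
  res <- cpp_lm_mlem(pa, pb, events$delta_t_ps, par$sig1, par$sig2, par$w1,
                     par$tof, grid_as_list(config$grid), mu,
                     config$tof_bin_ps, config$trunc_nsigma,
                     as.numeric(sensitivity), config$n_iterations,
                     as.integer(config$save_iterations))
  dims <- c(config$grid$nx, config$grid$ny, config$grid$nz)
  images <- lapply(seq_along(config$save_iterations),
                   function(i) array(res$images[, i], dims))
  names(images) <- as.character(config$save_iterations)
  structure(list(images = images,
                 image = images[[length(images)]],
                 loglik = res$loglik,
                 conservation = res$conservation,
                 events_used = res$events_used,
                 n_events = res$n_events,
                 n_skipped = res$n_events - res$events_used[1],
                 config = config,
                 sensitivity = sensitivity),
            class = "mlem_result")
}

#' @export
print.mlem_result <- function(x, ...) {
  cat(sprintf(
    "MLEM result: %d iterations (%s model), %d events (%d skipped)\n",
    x$config$n_iterations, x$config$model$mode, x$n_events, x$n_skipped))
  invisible(x)
}

#' Calibrate an image to activity-concentration units
#'
#' Scales the image so that its mean over a reference region equals a known
#' activity concentration (the standard background-mean calibration applied
#' after the final iteration).
#'
#' @param image 3D array.
#' @param reference_region_mask logical array or integer voxel indices.
#' @param reference_kBq_cc known concentration of the reference region.
#' @return the scaled image, with the scale factor in attribute
#'   `"calibration_scale"`.
#' @export
calibrate <- function(image, reference_region_mask, reference_kBq_cc) {
  m <- mean(image[reference_region_mask])
  if (!is.finite(m) || m <= 0)
    stop("calibration failed: reference region mean is not positive")
  scale <- reference_kBq_cc / m
  out <- image * scale
  attr(out, "calibration_scale") <- scale
  out
}
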