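#' Acquisition configuration
#'
#' Bundles everything the simulator needs: phantom, scanner, grid, duration
#' and the timing model applied to coincidence pairs.
#'
#' Timing models: `"mixture_bank"` draws one of the bank's timing categories
#' per pair (uniformly by default) and then the fast or slow component by
#' the category's abundance; `"single_mixture"` uses the bank's first kernel
#' for every pair; `"single_gaussian"` applies one Gaussian of
#' `gaussian_fwhm_ps`; `"none"` leaves the geometric time difference
#' untouched.
#'
#' @param phantom a [phantom_spec()].
#' @param scanner a [ring_scanner()].
#' @param grid a [voxel_grid()] used to rasterize the phantom (and the
#'   attenuation map when `attenuation = TRUE`).
#' @param duration_s acquisition time in seconds (default 150).
#' @param timing_model see Details.
#' @param bank [kernel_bank()] for the mixture models.
#' @param gaussian_fwhm_ps FWHM for `"single_gaussian"` (default 213 ps, a
#'   LYSO-like clinical coincidence resolution).
#' @param attenuation if `TRUE`, events survive with probability
#'   `exp(-integral of mu)` along the full line of response.
#' @param seed integer seed recorded in the provenance header and applied
#'   before sampling.
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(phantom, scanner, grid, duration_s = 150,
                               timing_model = c("mixture_bank",
                                                "single_mixture",
                                                "single_gaussian", "none"),
                               bank = default_kernel_bank(),
                               gaussian_fwhm_ps = 213,
                               attenuation = FALSE, seed = NULL) {
  timing_model <- match.arg(timing_model)
  stopifnot(inherits(phantom, "phantom_spec"), inherits(scanner, "ring_scanner"),
            inherits(grid, "voxel_grid"), duration_s > 0)
  if (timing_model %in% c("mixture_bank", "single_mixture"))
    stopifnot(inherits(bank, "kernel_bank"))
  structure(list(phantom = phantom, scanner = scanner, grid = grid,
                 duration_s = duration_s, timing_model = timing_model,
                 bank = bank, gaussian_fwhm_ps = gaussian_fwhm_ps,
                 attenuation = isTRUE(attenuation), seed = seed),
            class = "acquisition_config")
}

#' Sample annihilation points from an activity image
#'
#' The number of decays is Poisson with mean `total activity x duration`
#' (1 kBq/cc = 1000 decays/s/cc); each decay's voxel is drawn proportional
#' to `voxel activity x voxel volume` and the position is uniform within the
#' voxel.
#'
#' @param activity 3D activity array (kBq/cc) on `grid`.
#' @param grid the [voxel_grid()].
#' @param duration_s acquisition time, s.
#' @return n x 3 matrix of emission points (mm); zero rows for an inactive
#'   image.
#' @export
sample_emissions <- function(activity, grid, duration_s) {
  stopifnot(all(activity >= 0), duration_s > 0)
  # kBq/cc * mm^3 = decays/s (1 kBq/cc = 1 decay/s/mm^3)
  rates <- as.numeric(activity) * voxel_volume_mm3(grid)
  total <- sum(rates) * duration_s
  if (total == 0) return(matrix(numeric(0), 0, 3,
                                dimnames = list(NULL, c("x", "y", "z"))))
  n <- rpois(1, total)
  if (n == 0) return(matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("x", "y", "z"))))
  idx <- sample.int(length(rates), n, replace = TRUE, prob = rates)
  centers <- voxel_center_from_index(grid, idx)
  jitter <- cbind(runif(n, -0.5, 0.5) * grid$dx,
                  runif(n, -0.5, 0.5) * grid$dy,
                  runif(n, -0.5, 0.5) * grid$dz)
  out <- centers + jitter
  colnames(out) <- c("x", "y", "z")
  out
}

#' Transport annihilation photon pairs to the detector ring
#'
#' Each point emits two back-to-back 511 keV photons along a random
#' direction (isotropic for multi-ring scanners; in-plane for single-ring
#' scanners, which the package treats as 2D systems).  A pair is kept when
#' both photons hit crystals within the axial extent and the crystal pair
#' satisfies the scanner's minimum sector difference.  The geometric time
#' difference is `(d_a - d_b)/c`, positive when detector `a` is farther from
#' the emission point; detector pairs are canonically ordered (`a < b` by
#' flattened index).
#'
#' @param points n x 3 matrix of emission points (mm).
#' @param scanner a [ring_scanner()].
#' @param mu optional 3D attenuation array; with `grid`, events then survive
#'   with probability `exp(-integral of mu)` along the LOR.
#' @param grid [voxel_grid()] for `mu`.
#' @return data.frame with `ring_a, crystal_a, ring_b, crystal_b,
#'   geometric_dt_ps, emission` (1-based row of `points`).
#' @export
emit_and_detect <- function(points, scanner, mu = NULL, grid = NULL) {
  stopifnot(inherits(scanner, "ring_scanner"), is.matrix(points),
            ncol(points) == 3)
  mu_vec <- NULL
  grid_list <- NULL
  if (!is.null(mu)) {
    stopifnot(inherits(grid, "voxel_grid"))
    mu_vec <- as.numeric(mu)
    grid_list <- grid_as_list(grid)
  }
  res <- cpp_emit_and_detect(points, scanner$ring_radius_mm,
                             scanner$n_crystals_per_ring, scanner$n_rings,
                             scanner$crystal_pitch_axial_mm,
                             scanner$min_sector_difference,
                             scanner$n_rings == 1L, mu_vec, grid_list)
  as.data.frame(res)
}

#' Apply a timing spread at the coincidence-pair level
#'
#' For the `"mixture_bank"` model, a uniform draw picks which timing
#' category applies to the pair; a second draw against the category's
#' abundance ratio picks the fast or slow component; the measured time
#' difference is the geometric one plus a zero-mean Gaussian draw of the
#' selected component.  `"single_mixture"` fixes the category to the bank's
#' first kernel, `"single_gaussian"` adds one Gaussian of the configured
#' FWHM, and `"none"` is the identity.  The applied kernel and component are
#' returned so reconstruction can use them (decomposed model).
#'
#' @param geometric_dt_ps numeric vector of geometric time differences.
#' @inheritParams acquisition_config
#' @return data.frame with `delta_t_ps`, `kernel_id` (0 when no bank kernel
#'   applies) and `component` (0 = n/a, 1 = fast, 2 = slow).
#' @export
apply_timing_spread <- function(geometric_dt_ps,
                                timing_model = c("mixture_bank",
                                                 "single_mixture",
                                                 "single_gaussian", "none"),
                                bank = default_kernel_bank(),
                                gaussian_fwhm_ps = 213) {
  timing_model <- match.arg(timing_model)
  n <- length(geometric_dt_ps)
  if (timing_model == "none")
    return(data.frame(delta_t_ps = geometric_dt_ps,
                      kernel_id = rep(0L, n), component = rep(0L, n)))
  if (timing_model == "single_gaussian") {
    spread <- rnorm(n, 0, fwhm_to_sigma(gaussian_fwhm_ps))
    return(data.frame(delta_t_ps = geometric_dt_ps + spread,
                      kernel_id = rep(0L, n), component = rep(0L, n)))
  }
  stopifnot(inherits(bank, "kernel_bank"))
  kid <- if (timing_model == "single_mixture") rep(1L, n)
         else sample.int(length(bank$kernels), n, replace = TRUE,
                         prob = bank$category_probs)
  tab <- as.data.frame(bank)
  alpha <- tab$alpha_fast[kid]
  fast <- runif(n) < alpha
  sigma <- ifelse(fast, fwhm_to_sigma(tab$fwhm_fast_ps[kid]),
                  fwhm_to_sigma(tab$fwhm_slow_ps[kid]))
  data.frame(delta_t_ps = geometric_dt_ps + rnorm(n, 0, sigma),
             kernel_id = as.integer(tab$kernel_id[kid]),
             component = ifelse(fast, 1L, 2L))
}

#' Simulate a list-mode acquisition
#'
#' Full chain: rasterize the phantom, sample annihilation points, transport
#' the back-to-back photons to the ring, and apply the configured timing
#' spread per accepted coincidence pair.  Only true coincidences are
#' produced (no scatter, randoms or multiple coincidences).  Repeated calls
#' with distinct seeds give independent noise realizations; the same seed
#' reproduces the event list exactly.
#'
#' @param config an [acquisition_config()].
#' @return object of class `listmode`: `events` data.frame (`ring_a,
#'   crystal_a, ring_b, crystal_b, delta_t_ps, kernel_id, component,
#'   geometric_dt_ps`), the `scanner`, and a provenance `header` (seed,
#'   config hash, emission/accepted counts, timing model).
#' @export
simulate_acquisition <- function(config) {
  stopifnot(inherits(config, "acquisition_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  maps <- rasterize_phantom(config$phantom, config$grid)
  points <- sample_emissions(maps$activity, config$grid, config$duration_s)
  det <- emit_and_detect(points, config$scanner,
                         mu = if (config$attenuation) maps$mu else NULL,
                         grid = config$grid)
  spread <- apply_timing_spread(det$geometric_dt_ps, config$timing_model,
                                config$bank, config$gaussian_fwhm_ps)
  events <- data.frame(det[c("ring_a", "crystal_a", "ring_b", "crystal_b")],
                       delta_t_ps = spread$delta_t_ps,
                       kernel_id = spread$kernel_id,
                       component = spread$component,
                       geometric_dt_ps = det$geometric_dt_ps)
  if (nrow(events) == 0) warning("zero accepted coincidences")
  hash_cfg <- config[c("duration_s", "timing_model", "gaussian_fwhm_ps",
                       "attenuation")]
  header <- list(seed = config$seed,
                 config_hash = rlang::hash(hash_cfg),
                 timing_model = config$timing_model,
                 gaussian_fwhm_ps = config$gaussian_fwhm_ps,
                 duration_s = config$duration_s,
                 n_emissions = nrow(points),
                 n_accepted = nrow(events))
  structure(list(events = events, scanner = config$scanner, header = header),
            class = "listmode")
}

#' @export
print.listmode <- function(x, ...) {
  cat(sprintf("listmode: %d events (%s model, seed %s)\n",
              nrow(x$events), x$header$timing_model,
              if (is.null(x$header$seed)) "none" else x$header$seed))
  invisible(x)
}

#' Randomly thin a list-mode dataset to a target event count
#'
#' Uniform subsampling without replacement, preserving event order.  Used to
#' build count-matched datasets (e.g. a "low" subset matching a lower
#' sensitivity scanner).
#'
#' @param lm a `listmode` object.
#' @param n_keep number of events to keep (must not exceed the available
#'   count).
#' @return a `listmode` with `n_keep` events.
#' @export
thin_listmode <- function(lm, n_keep) {
  stopifnot(inherits(lm, "listmode"), n_keep >= 0,
            n_keep <= nrow(lm$events))
  keep <- sort(sample.int(nrow(lm$events), n_keep))
  lm$events <- lm$events[keep, , drop = FALSE]
  rownames(lm$events) <- NULL
  lm$header$thinned_from <- lm$header$n_accepted
  lm$header$n_accepted <- n_keep
  lm
}
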