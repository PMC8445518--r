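#' NEMA-style regions of interest
#'
#' Deterministic ROI placement from a NEMA phantom specification (sphere
#' centers and diameters are taken from the phantom, not estimated from the
#' image).  For every sphere: one circular ROI of the sphere's inner
#' diameter on the central transaxial slice; one half-diameter ROI for the
#' bias analysis; and `n_background` equally sized background ROIs.  Voxel
#' membership is center-in-circle, consistent with the rasterization
#' convention.
#'
#' Background ROIs are placed on a fixed polar candidate lattice inside the
#' body and kept when they stay at least 15 mm from the body edge and do
#' not overlap any sphere or wall; of the valid candidates, `n_background`
#' evenly spaced ones (by radius, then angle) are retained, so the layout
#' is deterministic given the phantom.
#'
#' @param phantom a [nema_iq_phantom()] (must carry the `"nema"` attribute).
#' @param grid a [voxel_grid()].
#' @param n_background background ROIs per sphere size (default 60).
#' @param edge_margin_mm minimum distance between a background ROI and the
#'   body edge (default 15).
#' @return object of class `roi_set`: per sphere, the voxel-index vectors of
#'   the sphere ROI, the half-diameter ROI and each background ROI, plus
#'   sphere metadata.
#' @export
place_rois <- function(phantom, grid, n_background = 60,
                       edge_margin_mm = 15) {
  info <- attr(phantom, "nema")
  if (is.null(info)) stop("phantom does not carry NEMA layout metadata")
  stopifnot(inherits(grid, "voxel_grid"))
  slice <- (grid$nz + 1L) %/% 2L
  sph <- info$spheres
  wall <- info$wall_mm

  rois <- vector("list", nrow(sph))
  for (i in seq_len(nrow(sph))) {
    r_roi <- sph$diameter_mm[i] / 2
    main <- circle_roi_voxels(grid, c(sph$x[i], sph$y[i]), r_roi, slice)
    if (length(main) < 5)
      stop("grid too coarse: smallest ROI contains fewer than 5 voxels")
    half <- circle_roi_voxels(grid, c(sph$x[i], sph$y[i]), r_roi / 2, slice)

    # candidate background centers on a polar lattice
    r_keep_max <- info$body_radius_mm - edge_margin_mm - r_roi
    if (r_keep_max <= 0) stop("background ROIs do not fit inside the body")
    cand_r <- seq(0, r_keep_max, by = 3)
    cand <- do.call(rbind, lapply(cand_r, function(rr) {
      if (rr == 0) return(cbind(0, 0))
      ang <- seq(0, 2 * pi, length.out = max(8, round(2 * pi * rr / 6)) + 1)
      ang <- ang[-length(ang)]
      cbind(rr * cos(ang), rr * sin(ang))
    }))
    dmin <- rep(Inf, nrow(cand))
    for (k in seq_len(nrow(sph))) {
      d <- sqrt((cand[, 1] - sph$x[k])^2 + (cand[, 2] - sph$y[k])^2) -
        (sph$diameter_mm[k] / 2 + wall + r_roi)
      dmin <- pmin(dmin, d)
    }
    ok <- which(dmin > 0)
    if (length(ok) < n_background)
      stop(sprintf("only %d valid background positions for the %.0f mm ROI",
                   length(ok), sph$diameter_mm[i]))
    pick <- ok[round(seq(1, length(ok), length.out = n_background))]
    bg <- lapply(pick, function(p)
      circle_roi_voxels(grid, cand[p, ], r_roi, slice))

    rois[[i]] <- list(sphere = sph$sphere[i], diameter_mm = sph$diameter_mm[i],
                      hot = sph$hot[i], center = c(sph$x[i], sph$y[i]),
                      roi = main, half_roi = half, background = bg)
  }
  structure(list(rois = rois, slice = slice, grid = grid,
                 hot_ratio = info$hot_ratio,
                 background_kBq_cc = info$background_kBq_cc),
            class = "roi_set")
}

# 1-based linear voxel indices whose centers fall inside a circle on a slice
circle_roi_voxels <- function(grid, center_xy, radius_mm, slice) {
  ax <- grid_axes(grid)
  inx <- which((ax$x - center_xy[1])^2 <= radius_mm^2)
  res <- integer(0)
  for (ix in inx) {
    iny <- which((ax$x[ix] - center_xy[1])^2 + (ax$y - center_xy[2])^2 <=
                   radius_mm^2)
    if (length(iny))
      res <- c(res, ix + grid$nx * (iny - 1L) +
                 grid$nx * grid$ny * (slice - 1L))
  }
  sort(res)
}

#' Background mask for calibration
#'
#' All voxels inside the phantom body (shrunk by `margin_mm`) that are at
#' least `margin_mm` away from every sphere's outer wall, on all slices the
#' body covers.  Used as the reference region when calibrating
#' reconstructions to kBq/cc.
#'
#' @inheritParams place_rois
#' @param margin_mm clearance from spheres and body edge, mm.
#' @return logical 3D array.
#' @export
nema_background_mask <- function(phantom, grid, margin_mm = 10) {
  info <- attr(phantom, "nema")
  if (is.null(info)) stop("phantom does not carry NEMA layout metadata")
  ax <- grid_axes(grid)
  dims <- c(grid$nx, grid$ny, grid$nz)
  cx <- array(rep(ax$x, times = grid$ny * grid$nz), dims)
  cy <- array(rep(rep(ax$y, each = grid$nx), times = grid$nz), dims)
  cz <- array(rep(ax$z, each = grid$nx * grid$ny), dims)
  m <- (cx^2 + cy^2 <= (info$body_radius_mm - margin_mm)^2) &
    (abs(cz) <= info$body_half_length_mm)
  sph <- info$spheres
  for (k in seq_len(nrow(sph))) {
    r_excl <- sph$diameter_mm[k] / 2 + info$wall_mm + margin_mm
    m <- m & ((cx - sph$x[k])^2 + (cy - sph$y[k])^2 + (cz - sph$z[k])^2 >
                r_excl^2)
  }
  m
}

#' NEMA figures of merit
#'
#' Contrast recovery coefficient for hot spheres
#' `CRC = 100 * (mu_H/mu_B - 1) / (ratio - 1)` and cold spheres
#' `CRC = 100 * (1 - mu_C/mu_B)`; background variability
#' `BV = 100 * SD(background ROI means) / mean(background ROI means)`
#' (N-1 denominator); contrast-to-noise ratio
#' `CNR = (mu_H - mu_B) / sqrt(sigma_H^2 + sigma_B^2)` where `sigma_B` is
#' the average SD over the background ROIs.
#'
#' @param mu_h,mu_c,mu_b ROI means (hot sphere, cold sphere, background).
#' @param activity_ratio true hot:background activity ratio (> 1).
#' @param background_means vector of background ROI means.
#' @param sigma_h,sigma_b SDs of the sphere ROI and (average over)
#'   background ROIs.
#' @return percent (CRC, BV) or a dimensionless value (CNR).
#' @examples
#' crc_hot(4, 1, 4)                    # 100: perfect recovery
#' background_variability(c(9, 11))    # 14.14
#' cnr(4, 1, 0.5, 0.5)                 # 4.243
#' @export
crc_hot <- function(mu_h, mu_b, activity_ratio) {
  if (activity_ratio == 1) stop("hot CRC undefined at activity ratio 1")
  stopifnot(mu_b > 0)
  100 * (mu_h / mu_b - 1) / (activity_ratio - 1)
}

#' @rdname crc_hot
#' @export
crc_cold <- function(mu_c, mu_b) {
  stopifnot(mu_b > 0)
  100 * (1 - mu_c / mu_b)
}

#' @rdname crc_hot
#' @export
background_variability <- function(background_means) {
  if (length(background_means) < 2)
    stop("need at least 2 background ROIs")
  m <- mean(background_means)
  if (m == 0) stop("background mean is zero")
  100 * sd(background_means) / m
}

#' @rdname crc_hot
#' @export
cnr <- function(mu_h, mu_b, sigma_h, sigma_b) {
  denom <- sqrt(sigma_h^2 + sigma_b^2)
  if (denom == 0) stop("CNR undefined: both SDs are zero")
  (mu_h - mu_b) / denom
}

#' Per-sphere metrics of one reconstructed image
#'
#' @param image 3D array on the ROI set's grid.
#' @param roi_set a [place_rois()] result.
#' @return data.frame with one row per sphere: ROI means/SDs, background
#'   mean/SD, `crc_pct`, `bv_pct`, `cnr`.
#' @export
sphere_metrics <- function(image, roi_set) {
  stopifnot(inherits(roi_set, "roi_set"),
            length(image) == with(roi_set$grid, nx * ny * nz))
  rows <- lapply(roi_set$rois, function(r) {
    mu_roi <- mean(image[r$roi])
    sd_roi <- sd(image[r$roi])
    bg_means <- vapply(r$background, function(v) mean(image[v]), numeric(1))
    bg_sds <- vapply(r$background, function(v) sd(image[v]), numeric(1))
    mu_b <- mean(bg_means)
    sd_b <- mean(bg_sds)
    data.frame(sphere = r$sphere, diameter_mm = r$diameter_mm, hot = r$hot,
               mu_roi = mu_roi, sd_roi = sd_roi, mu_bg = mu_b, sd_bg = sd_b,
               crc_pct = if (r$hot) crc_hot(mu_roi, mu_b, roi_set$hot_ratio)
                         else crc_cold(mu_roi, mu_b),
               bv_pct = background_variability(bg_means),
               # CNR is undefined (NA) on noise-free images with zero SDs
               cnr = if (sd_roi == 0 && sd_b == 0) NA_real_
                     else cnr(mu_roi, mu_b, sd_roi, sd_b))
  })
  do.call(rbind, rows)
}

#' Half-diameter bias analysis across noise realizations
#'
#' For every sphere, the mean of the half-diameter ROI is computed on each
#' realization's (calibrated) image; the bias is the deviation of the
#' across-realization mean from the expected activity concentration,
#' `100 * (mean - expected) / expected`, reported with the standard error
#' over realizations (`SD / sqrt(n)`).
#'
#' @param images list of 3D arrays, one per noise realization (>= 2).
#' @param roi_set a [place_rois()] result.
#' @param expected_kBq_cc expected concentration per sphere (scalar or one
#'   per sphere); defaults to the phantom's hot/background concentrations.
#' @return data.frame with per-sphere `mean_kBq_cc`, `expected_kBq_cc`,
#'   `bias_pct`, `se_kBq_cc`.
#' @export
bias_analysis <- function(images, roi_set, expected_kBq_cc = NULL) {
  stopifnot(inherits(roi_set, "roi_set"))
  if (length(images) < 2)
    stop("bias analysis needs at least 2 noise realizations")
  ns <- length(roi_set$rois)
  if (is.null(expected_kBq_cc)) {
    expected_kBq_cc <- vapply(roi_set$rois, function(r)
      if (r$hot) roi_set$hot_ratio * roi_set$background_kBq_cc else 0,
      numeric(1))
  }
  expected_kBq_cc <- rep_len(expected_kBq_cc, ns)
  rows <- lapply(seq_len(ns), function(i) {
    r <- roi_set$rois[[i]]
    means <- vapply(images, function(img) mean(img[r$half_roi]), numeric(1))
    m <- mean(means)
    exp_i <- expected_kBq_cc[i]
    data.frame(sphere = r$sphere, diameter_mm = r$diameter_mm, hot = r$hot,
               mean_kBq_cc = m, expected_kBq_cc = exp_i,
               bias_pct = if (exp_i != 0) 100 * (m - exp_i) / exp_i else NA,
               se_kBq_cc = sd(means) / sqrt(length(means)))
  })
  do.call(rbind, rows)
}

#' Metrics across models and iterations
#'
#' Tabulates [sphere_metrics()] for a set of reconstructions at their saved
#' iterations: the data behind contrast-recovery-vs-background-variability
#' and CNR-vs-iteration curves.
#'
#' @param results named list of [lm_mlem()] results (names are model
#'   labels), all on the ROI set's grid.
#' @param roi_set a [place_rois()] result.
#' @param iterations iteration numbers to include (default: all saved).
#' @return data.frame with columns `model`, `iteration` and the
#'   [sphere_metrics()] columns.
#' @export
metrics_over_iterations <- function(results, roi_set, iterations = NULL) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  rows <- list()
  for (model in names(results)) {
    res <- results[[model]]
    its <- names(res$images)
    if (!is.null(iterations)) its <- intersect(its, as.character(iterations))
    for (it in its) {
      if (!identical(dim(res$images[[it]]),
                     c(roi_set$grid$nx, roi_set$grid$ny, roi_set$grid$nz)))
        stop("image grid does not match the ROI grid")
      m <- sphere_metrics(res$images[[it]], roi_set)
      m$model <- model
      m$iteration <- as.integer(it)
      rows[[length(rows) + 1]] <- m
    }
  }
  out <- do.call(rbind, rows)
  out[c("model", "iteration", setdiff(names(out), c("model", "iteration")))]
}
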