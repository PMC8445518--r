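#' Shape-based digital phantoms
#'
#' A phantom is an ordered list of geometric regions, each carrying an
#' activity concentration (kBq/cc) and a 511 keV linear attenuation
#' coefficient (per mm).  Later regions override earlier ones where they
#' overlap, which lets a sphere punch a hole into a background cylinder.
#'
#' @param regions list of regions built by [region_cylinder()],
#'   [region_sphere()] or [region_shell()].
#' @return object of class `phantom_spec`.
#' @seealso [nema_iq_phantom()], [rasterize_phantom()]
#' @export
phantom_spec <- function(regions) {
  stopifnot(is.list(regions),
            all(vapply(regions, inherits, logical(1), "phantom_region")))
  structure(list(regions = regions), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom with %d regions\n", length(x$regions)))
  invisible(x)
}

new_region <- function(type, center, activity_kBq_cc, mu_per_mm, ...) {
  stopifnot(length(center) == 3, activity_kBq_cc >= 0, mu_per_mm >= 0)
  structure(c(list(type = type, center = as.numeric(center),
                   activity_kBq_cc = activity_kBq_cc, mu_per_mm = mu_per_mm),
              list(...)),
            class = "phantom_region")
}

#' @rdname phantom_spec
#' @param center xyz center, mm.
#' @param radius_mm,inner_radius_mm,outer_radius_mm radii, mm.
#' @param half_length_mm cylinder half-length along z, mm.
#' @param activity_kBq_cc activity concentration, kBq/cc.
#' @param mu_per_mm 511 keV linear attenuation coefficient, per mm.
#' @export
region_cylinder <- function(center, radius_mm, half_length_mm,
                            activity_kBq_cc, mu_per_mm = 0) {
  stopifnot(radius_mm > 0, half_length_mm > 0)
  new_region("cylinder", center, activity_kBq_cc, mu_per_mm,
             radius_mm = radius_mm, half_length_mm = half_length_mm)
}

#' @rdname phantom_spec
#' @export
region_sphere <- function(center, radius_mm, activity_kBq_cc, mu_per_mm = 0) {
  stopifnot(radius_mm > 0)
  new_region("sphere", center, activity_kBq_cc, mu_per_mm,
             radius_mm = radius_mm)
}

#' @rdname phantom_spec
#' @export
region_shell <- function(center, inner_radius_mm, outer_radius_mm,
                         activity_kBq_cc, mu_per_mm = 0) {
  stopifnot(outer_radius_mm > inner_radius_mm, inner_radius_mm >= 0)
  new_region("shell", center, activity_kBq_cc, mu_per_mm,
             inner_radius_mm = inner_radius_mm,
             outer_radius_mm = outer_radius_mm)
}

region_mask <- function(region, cx, cy, cz) {
  dx <- cx - region$center[1]
  dy <- cy - region$center[2]
  dz <- cz - region$center[3]
  switch(region$type,
    cylinder = (dx^2 + dy^2 <= region$radius_mm^2) &
               (abs(dz) <= region$half_length_mm),
    sphere = dx^2 + dy^2 + dz^2 <= region$radius_mm^2,
    shell = {
      r2 <- dx^2 + dy^2 + dz^2
      r2 <= region$outer_radius_mm^2 & r2 > region$inner_radius_mm^2
    },
    stop("unknown region type: ", region$type))
}

#' Rasterize a phantom onto a voxel grid
#'
#' Voxel membership is decided by the voxel-center point (no partial-volume
#' weighting); later regions override earlier ones; voxels outside all
#' regions are zero.
#'
#' @param phantom a [phantom_spec()].
#' @param grid a [voxel_grid()].
#' @return list with 3D arrays `activity` (kBq/cc) and `mu` (per mm).
#' @export
rasterize_phantom <- function(phantom, grid) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(grid, "voxel_grid"))
  ax <- grid_axes(grid)
  dims <- c(grid$nx, grid$ny, grid$nz)
  cx <- array(rep(ax$x, times = grid$ny * grid$nz), dims)
  cy <- array(rep(rep(ax$y, each = grid$nx), times = grid$nz), dims)
  cz <- array(rep(ax$z, each = grid$nx * grid$ny), dims)
  activity <- array(0, dims)
  mu <- array(0, dims)
  for (region in phantom$regions) {
    m <- region_mask(region, cx, cy, cz)
    activity[m] <- region$activity_kBq_cc
    mu[m] <- region$mu_per_mm
  }
  list(activity = activity, mu = mu)
}

#' NEMA image-quality phantom
#'
#' The standard image-quality layout: a water-filled body cylinder at a warm
#' background activity, six spheres of inner diameter `scale * {10, 13, 17,
#' 22, 28, 37}` mm centered on the 114.4 mm pitch circle in the central
#' transaxial plane.  The four smallest spheres are hot at
#' `hot_ratio * background`; the two largest are water-filled and cold (zero
#' activity).  Every sphere is surrounded by a cold 1 mm wall shell
#' representing the container.  All regions get the attenuation of water at
#' 511 keV.
#'
#' The body cylinder radius (default 110 mm) is a desk-scale choice that
#' keeps the phantom inside the default 128 x 128 x 2 mm reconstruction
#' grid; the activity concentration and sphere layout follow the standard
#' phantom.
#'
#' @param scale global linear scale applied to sphere diameters, the pitch
#'   circle and the body (wall thickness stays 1 mm).
#' @param background_kBq_cc background activity concentration (default
#'   11.38 kBq/cc).
#' @param hot_ratio hot-sphere to background activity ratio (default 4).
#' @param body_radius_mm,body_half_length_mm body cylinder size before
#'   `scale` is applied.
#' @param wall_mm sphere wall thickness, mm (not scaled).
#' @param mu_per_mm attenuation coefficient assigned to all regions.
#' @return a [phantom_spec()] with attribute `"nema"`: a data.frame of
#'   sphere centers, diameters, activities and hot flags, plus body
#'   geometry, used by the ROI tools.
#' @examples
#' ph <- nema_iq_phantom()
#' attr(ph, "nema")$spheres$diameter_mm
#' @export
nema_iq_phantom <- function(scale = 1, background_kBq_cc = 11.38,
                            hot_ratio = 4, body_radius_mm = 110,
                            body_half_length_mm = 90, wall_mm = 1,
                            mu_per_mm = .MU_WATER_511_MM) {
  stopifnot(scale > 0, background_kBq_cc >= 0, hot_ratio >= 0)
  diameters <- scale * c(10, 13, 17, 22, 28, 37)
  radii <- diameters / 2
  pitch_radius <- scale * 114.4 / 2
  angles <- seq(0, by = pi / 3, length.out = 6)
  centers <- cbind(pitch_radius * cos(angles), pitch_radius * sin(angles), 0)
  hot <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  activities <- ifelse(hot, hot_ratio * background_kBq_cc, 0)

  # adjacent spheres (with their walls) must not touch
  for (i in 1:6) {
    j <- if (i == 6) 1L else i + 1L
    gap <- sqrt(sum((centers[i, ] - centers[j, ])^2)) -
      (radii[i] + radii[j] + 2 * wall_mm)
    if (gap <= 0)
      stop("scale too small: spheres ", i, " and ", j, " overlap")
  }

  body_r <- scale * body_radius_mm
  if (max(pitch_radius + radii + wall_mm) >= body_r)
    stop("spheres do not fit inside the body cylinder")

  regions <- list(region_cylinder(c(0, 0, 0), body_r,
                                  scale * body_half_length_mm,
                                  background_kBq_cc, mu_per_mm))
  for (i in 1:6) {
    regions <- c(regions,
                 list(region_shell(centers[i, ], radii[i], radii[i] + wall_mm,
                                   0, mu_per_mm),
                      region_sphere(centers[i, ], radii[i], activities[i],
                                    mu_per_mm)))
  }
  ph <- phantom_spec(regions)
  attr(ph, "nema") <- list(
    spheres = data.frame(sphere = 1:6, diameter_mm = diameters,
                         x = centers[, 1], y = centers[, 2], z = centers[, 3],
                         hot = hot, activity_kBq_cc = activities),
    background_kBq_cc = background_kBq_cc, hot_ratio = hot_ratio,
    wall_mm = wall_mm, body_radius_mm = body_r,
    body_half_length_mm = scale * body_half_length_mm)
  ph
}

#' Point-source phantom
#'
#' A small active sphere, by default at the isocenter: the configuration
#' used for timing-fidelity studies.
#'
#' @param activity_kBq_cc activity concentration.
#' @param position xyz center, mm.
#' @param radius_mm source radius, mm.
#' @return a [phantom_spec()].
#' @export
point_source_phantom <- function(activity_kBq_cc = 1000,
                                 position = c(0, 0, 0), radius_mm = 2) {
  phantom_spec(list(region_sphere(position, radius_mm, activity_kBq_cc)))
}
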