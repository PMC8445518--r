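#' Cylindrical ring scanner
#'
#' Detector geometry: `n_crystals_per_ring` crystals uniformly spaced in
#' azimuth (no blocks or gaps) on `n_rings` rings.  Crystal 0 of every ring
#' is centered at azimuth 0 and indices increase counterclockwise viewed
#' from +z; ring 0 is the most-negative-z ring and the scanner is centered
#' axially on the isocenter.  All detector indices are 0-based.
#'
#' The default is the desk-scale 2D system used throughout the package: one
#' ring of 360 crystals at the 424 mm front-face radius of the full-size
#' scanner (666 crystals of 4 mm pitch per ring, 48 rings), which remains
#' available as `full_ring_scanner()`.
#'
#' @param n_crystals_per_ring crystals per ring (>= 8).
#' @param n_rings number of rings.
#' @param ring_radius_mm radius to the crystal front face, mm.
#' @param crystal_pitch_transaxial_mm,crystal_pitch_axial_mm crystal pitch, mm.
#' @param crystal_depth_mm crystal depth, mm (bookkeeping only; detection is
#'   front-face).
#' @param min_sector_difference minimum circular crystal-index difference for
#'   a pair of singles to count as a coincidence.  Default scales the
#'   83-sector rule of the 666-crystal ring: `round(83/666 * n)`.
#' @return object of class `ring_scanner`.
#' @examples
#' s <- ring_scanner()
#' crystal_center(s, 0, 0)    # (424, 0, 0)
#' @export
ring_scanner <- function(n_crystals_per_ring = 360, n_rings = 1,
                         ring_radius_mm = 424,
                         crystal_pitch_transaxial_mm = 4,
                         crystal_pitch_axial_mm = 4,
                         crystal_depth_mm = 20,
                         min_sector_difference = NULL) {
  stopifnot(n_crystals_per_ring >= 8, n_rings >= 1, ring_radius_mm > 0,
            crystal_pitch_axial_mm > 0)
  if (is.null(min_sector_difference))
    min_sector_difference <- round(83 / 666 * n_crystals_per_ring)
  structure(list(n_crystals_per_ring = as.integer(n_crystals_per_ring),
                 n_rings = as.integer(n_rings),
                 ring_radius_mm = ring_radius_mm,
                 crystal_pitch_transaxial_mm = crystal_pitch_transaxial_mm,
                 crystal_pitch_axial_mm = crystal_pitch_axial_mm,
                 crystal_depth_mm = crystal_depth_mm,
                 min_sector_difference = as.integer(min_sector_difference)),
            class = "ring_scanner")
}

#' @rdname ring_scanner
#' @export
full_ring_scanner <- function() {
  ring_scanner(n_crystals_per_ring = 666, n_rings = 48,
               ring_radius_mm = 666 * 4 / (2 * pi),
               crystal_pitch_axial_mm = 4)
}

#' @export
print.ring_scanner <- function(x, ...) {
  cat(sprintf(
    "ring scanner: %d crystals/ring x %d rings, radius %.1f mm, axial extent %.1f mm\n",
    x$n_crystals_per_ring, x$n_rings, x$ring_radius_mm, axial_extent(x)))
  invisible(x)
}

#' @rdname ring_scanner
#' @param scanner a `ring_scanner`.
#' @export
axial_extent <- function(scanner) scanner$n_rings * scanner$crystal_pitch_axial_mm

#' Crystal center positions
#'
#' Front-face center of crystal `crystal` on ring `ring` (both 0-based,
#' vectorized).  Crystal 0 sits at azimuth 0, i.e. at (R, 0, z).
#'
#' @param scanner a [ring_scanner()].
#' @param ring,crystal 0-based indices (recycled to a common length).
#' @return an n x 3 matrix of xyz positions in mm.
#' @export
crystal_center <- function(scanner, ring, crystal) {
  n <- max(length(ring), length(crystal))
  ring <- rep_len(as.integer(ring), n)
  crystal <- rep_len(as.integer(crystal), n)
  if (any(ring < 0 | ring >= scanner$n_rings))
    stop("ring index out of range")
  if (any(crystal < 0 | crystal >= scanner$n_crystals_per_ring))
    stop("crystal index out of range")
  phi <- 2 * pi * crystal / scanner$n_crystals_per_ring
  z <- (ring + 0.5) * scanner$crystal_pitch_axial_mm - axial_extent(scanner) / 2
  cbind(x = scanner$ring_radius_mm * cos(phi),
        y = scanner$ring_radius_mm * sin(phi),
        z = z)
}

# centers for every flattened detector index ring * n_crystals + crystal
all_crystal_centers <- function(scanner) {
  idx <- 0:(scanner$n_rings * scanner$n_crystals_per_ring - 1L)
  crystal_center(scanner, idx %/% scanner$n_crystals_per_ring,
                 idx %% scanner$n_crystals_per_ring)
}

#' Reconstruction voxel grid
#'
#' A right-handed grid centered on the scanner isocenter; voxel (0,0,0) sits
#' at the most-negative corner and images are indexed `[x, y, z]`.
#'
#' @param nx,ny,nz voxel counts.
#' @param voxel_size_mm length-3 vector `(dx, dy, dz)` in mm.
#' @return object of class `voxel_grid` with fields `nx, ny, nz, dx, dy, dz`
#'   and the most-negative corner `x0, y0, z0`.
#' @examples
#' g <- voxel_grid(128, 128, 1, c(2, 2, 2))
#' @export
voxel_grid <- function(nx = 128, ny = 128, nz = 1, voxel_size_mm = c(2, 2, 2)) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, length(voxel_size_mm) == 3,
            all(voxel_size_mm > 0))
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 dx = voxel_size_mm[1], dy = voxel_size_mm[2],
                 dz = voxel_size_mm[3],
                 x0 = -nx * voxel_size_mm[1] / 2,
                 y0 = -ny * voxel_size_mm[2] / 2,
                 z0 = -nz * voxel_size_mm[3] / 2),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel grid %d x %d x %d, voxel %.3g x %.3g x %.3g mm\n",
              x$nx, x$ny, x$nz, x$dx, x$dy, x$dz))
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid a `voxel_grid`.
#' @return `grid_axes()`: list of voxel-center coordinates along x, y, z.
#' @export
grid_axes <- function(grid) {
  list(x = grid$x0 + (seq_len(grid$nx) - 0.5) * grid$dx,
       y = grid$y0 + (seq_len(grid$ny) - 0.5) * grid$dy,
       z = grid$z0 + (seq_len(grid$nz) - 0.5) * grid$dz)
}

#' @rdname voxel_grid
#' @export
voxel_volume_mm3 <- function(grid) grid$dx * grid$dy * grid$dz

# plain list the C++ side understands
grid_as_list <- function(grid) unclass(grid)

# center coordinates of given 1-based linear voxel indices, n x 3
voxel_center_from_index <- function(grid, index) {
  index <- as.integer(index) - 1L
  ix <- index %% grid$nx
  iy <- (index %/% grid$nx) %% grid$ny
  iz <- index %/% (grid$nx * grid$ny)
  cbind(x = grid$x0 + (ix + 0.5) * grid$dx,
        y = grid$y0 + (iy + 0.5) * grid$dy,
        z = grid$z0 + (iz + 0.5) * grid$dz)
}
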