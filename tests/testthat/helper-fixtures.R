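# small geometries shared across tests

tiny_scanner <- function(n_crystals = 32, radius = 60, min_sector = 4) {
  ring_scanner(n_crystals_per_ring = n_crystals, n_rings = 1,
               ring_radius_mm = radius, crystal_pitch_axial_mm = 4,
               min_sector_difference = min_sector)
}

desk_scanner <- function() ring_scanner()

desk_grid <- function() voxel_grid(128, 128, 1, c(2, 2, 2))

# brute-force mean over a voxel-index ROI using an explicit loop
brute_roi_mean <- function(image, voxels) {
  tot <- 0
  for (v in voxels) tot <- tot + image[v]
  tot / length(voxels)
}

# dense-sampling approximation to Siddon: chop the ray into n points and
# assign each segment to the voxel containing its midpoint
dense_ray_lengths <- function(grid, p1, p2, n = 1e4) {
  t <- (seq_len(n) - 0.5) / n
  px <- p1[1] + t * (p2[1] - p1[1])
  py <- p1[2] + t * (p2[2] - p1[2])
  pz <- p1[3] + t * (p2[3] - p1[3])
  step <- sqrt(sum((p2 - p1)^2)) / n
  ix <- floor((px - grid$x0) / grid$dx)
  iy <- floor((py - grid$y0) / grid$dy)
  iz <- floor((pz - grid$z0) / grid$dz)
  ok <- ix >= 0 & ix < grid$nx & iy >= 0 & iy < grid$ny & iz >= 0 & iz < grid$nz
  idx <- ix[ok] + grid$nx * (iy[ok] + grid$ny * iz[ok]) + 1
  tapply(rep(step, length(idx)), idx, sum)
}
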