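#' Read and write images
#'
#' Reconstructed and rasterized images are written as NIfTI with the grid's
#' voxel size in the header, so they open in standard medical-imaging
#' viewers.
#'
#' @param image 3D array on `grid`.
#' @param grid the [voxel_grid()] the image lives on.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_image()` returns the path written (oro.nifti appends the
#'   extension) invisibly; `read_image()` returns a 3D array with the voxel
#'   size in attribute `"voxel_size_mm"`.
#' @export
write_image <- function(image, grid, path) {
  stopifnot(inherits(grid, "voxel_grid"),
            identical(dim(image), c(grid$nx, grid$ny, grid$nz)))
  gz <- !grepl("\\.nii$", path)
  root <- sub("\\.nii(\\.gz)?$", "", path)
  img <- oro.nifti::nifti(array(as.numeric(image), dim(image)),
                          pixdim = c(1, grid$dx, grid$dy, grid$dz),
                          datatype = 16)  # float32
  oro.nifti::writeNIfTI(img, root, gzipped = gz)
  invisible(paste0(root, if (gz) ".nii.gz" else ".nii"))
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- oro.nifti::readNIfTI(path)
  dims <- c(dim(img), 1L, 1L)[1:3]
  out <- array(as.numeric(img), dims)
  attr(out, "voxel_size_mm") <- oro.nifti::pixdim(img)[2:4]
  out
}

#' Read and write phantom specification files
#'
#' Phantoms are stored as structured key-value (YAML) files: either a
#' `nema` block with the [nema_iq_phantom()] arguments, or a `regions` list
#' where each entry has a `type` (`cylinder`, `sphere`, `shell`), a
#' `center`, the radii/half-length for its type, an `activity_kBq_cc` and
#' an optional `mu_per_mm`.
#'
#' @param path file path.
#' @param phantom a [phantom_spec()].
#' @return `read_phantom_spec()` returns a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  if (!is.null(spec$nema))
    return(do.call(nema_iq_phantom, spec$nema))
  if (is.null(spec$regions)) stop("phantom file needs 'nema' or 'regions'")
  regions <- lapply(spec$regions, function(r) {
    mu <- if (is.null(r$mu_per_mm)) 0 else r$mu_per_mm
    switch(r$type,
      cylinder = region_cylinder(unlist(r$center), r$radius_mm,
                                 r$half_length_mm, r$activity_kBq_cc, mu),
      sphere = region_sphere(unlist(r$center), r$radius_mm,
                             r$activity_kBq_cc, mu),
      shell = region_shell(unlist(r$center), r$inner_radius_mm,
                           r$outer_radius_mm, r$activity_kBq_cc, mu),
      stop("unknown region type in phantom file: ", r$type))
  })
  phantom_spec(regions)
}

#' @rdname read_phantom_spec
#' @export
write_phantom_spec <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_spec"))
  regions <- lapply(phantom$regions, function(r) {
    out <- unclass(r)
    out$center <- as.list(out$center)
    out
  })
  yaml::write_yaml(list(regions = regions), path)
  invisible(path)
}
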