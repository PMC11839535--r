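# BinaryMask3D: a 3-D boolean occupancy array with voxel-size metadata.
# Fractal estimation works on the voxel lattice; voxel size is carried as
# metadata only (analyses assume isotropic acquisition).

#' Construct a 3-D binary mask
#'
#' @param occupancy 3-D logical (or coercible) array of voxel occupancy.
#' @param voxel_size_mm Positive voxel edge lengths, length 3.
#' @param origin Integer voxel offset of the array corner in a parent volume.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(occupancy, voxel_size_mm = c(1, 1, 1),
                        origin = c(0L, 0L, 0L)) {
  if (is.null(dim(occupancy)) || length(dim(occupancy)) != 3)
    stop_fm("occupancy must be a 3-D array")
  occ <- array(as.logical(occupancy), dim = dim(occupancy))
  if (anyNA(occ)) stop_fm("occupancy contains NA")
  stopifnot(length(voxel_size_mm) == 3, all(voxel_size_mm > 0),
            length(origin) == 3)
  structure(list(occupancy = occ,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 origin = as.integer(round(origin))),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground, voxel %s mm\n",
              paste(dim(x$occupancy), collapse = "x"),
              sum(x$occupancy),
              paste(format(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask A `binary_mask`.
#' @return Integer count.
#' @export
mask_volume <- function(mask) sum(mask$occupancy)

as_mask <- function(x) {
  if (inherits(x, "binary_mask")) return(x)
  binary_mask(x)
}

check_nonempty <- function(mask, what = "mask") {
  if (mask_volume(mask) == 0) stop_fm("%s is empty (no foreground voxels)", what)
  invisible(mask)
}

#' Extract the boundary surface of a mask
#'
#' A foreground voxel belongs to the surface when at least one of its six
#' face-adjacent neighbors is background or lies outside the array.
#'
#' @param mask A non-empty `binary_mask`.
#' @return A `binary_mask` of the same shape containing only surface voxels.
#' @export
extract_surface <- function(mask) {
  mask <- as_mask(mask)
  check_nonempty(mask)
  occ <- mask$occupancy
  d <- dim(occ)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  ix <- 2:(d[1] + 1); iy <- 2:(d[2] + 1); iz <- 2:(d[3] + 1)
  interior <- pad[ix - 1, iy, iz] & pad[ix + 1, iy, iz] &
              pad[ix, iy - 1, iz] & pad[ix, iy + 1, iz] &
              pad[ix, iy, iz - 1] & pad[ix, iy, iz + 1]
  binary_mask(occ & !interior, mask$voxel_size_mm, mask$origin)
}

#' Topological skeleton of a mask
#'
#' Iterative 3-D thinning that deletes simple border voxels (checked with the
#' standard two-condition characterization: one 26-connected foreground
#' component in the 26-neighborhood, one 6-connected background component in
#' the 18-neighborhood) while preserving curve endpoints, so the skeleton is
#' a subset of the mask with the same number of 26-connected components.
#' Already-thin structures (curves one voxel thick) are left unchanged.
#'
#' @param mask A non-empty `binary_mask`.
#' @return A `binary_mask` containing the skeleton voxels.
#' @export
extract_skeleton <- function(mask) {
  mask <- as_mask(mask)
  check_nonempty(mask)
  occ <- mask$occupancy
  out <- thin3d_cpp(as.integer(occ), dim(occ))
  binary_mask(array(out == 1L, dim(occ)), mask$voxel_size_mm, mask$origin)
}

#' Label connected components of a mask
#'
#' @param mask A `binary_mask` (or logical array).
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Integer array of component labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- as_mask(mask)
  occ <- mask$occupancy
  lab <- label_components_cpp(as.integer(occ), dim(occ), as.integer(connectivity))
  n <- attr(lab, "n_components")
  lab <- array(lab, dim(occ))
  attr(lab, "n_components") <- n
  lab
}

#' Number of connected components of a mask
#' @inheritParams label_components
#' @return Integer.
#' @export
n_components <- function(mask, connectivity = 26) {
  attr(label_components(mask, connectivity), "n_components")
}
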