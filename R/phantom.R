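# Fractal phantoms: deterministic voxel objects of known dimension, used in
# place of segmented brain structures to validate the box-counting estimator.
# The Menger sponge is anchored at the array corner so that a corner-anchored
# grid with sizes r = 3^k reproduces its closed-form counts N(3^k) = 20^(L-k).

PHANTOM_KINDS <- c("menger_sponge", "solid_cube", "plane_sheet", "rod",
                   "single_voxel")

#' Specify a deterministic voxel phantom
#'
#' @param kind One of `"menger_sponge"`, `"solid_cube"`, `"plane_sheet"`,
#'   `"rod"`, `"single_voxel"`.
#' @param level_or_side Recursion level (sponge) or side length in voxels
#'   (other kinds); ignored for `single_voxel`.
#' @param pad Background margin, in voxels, added on every side.
#' @param voxel_budget Maximum number of voxels the padded volume may hold.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(kind, level_or_side = 1, pad = 0,
                         voxel_budget = 2^24) {
  kind <- match.arg(kind, PHANTOM_KINDS)
  if (!is_count(level_or_side)) stop_fm("level_or_side must be a positive integer")
  if (!is.numeric(pad) || pad < 0 || pad != round(pad))
    stop_fm("pad must be a non-negative integer")
  structure(list(kind = kind, level_or_side = as.integer(level_or_side),
                 pad = as.integer(pad), voxel_budget = voxel_budget),
            class = "phantom_spec")
}

menger_occupancy <- function(level) {
  # keep the 20 of 27 subcells having at most one middle coordinate
  keep <- array(TRUE, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    if (sum(c(i, j, k) == 2) >= 2) keep[i, j, k] <- FALSE
  occ <- array(TRUE, c(1, 1, 1))
  for (l in seq_len(level)) occ <- kronecker(occ, keep) > 0
  array(as.logical(occ), dim = rep(3^level, 3))
}

#' Generate a phantom mask
#'
#' Deterministic construction; a Menger sponge at level L has side `3^L` and
#' exactly `20^L` foreground voxels, a solid cube of side s has `s^3`, a
#' sheet `s^2`, a rod `s`, and a single voxel 1.
#'
#' @param spec A [phantom_spec()].
#' @return A `binary_mask`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$level_or_side
  core <- switch(spec$kind,
    menger_sponge = {
      side <- 3^s
      if ((side + 2 * spec$pad)^3 > spec$voxel_budget)
        stop_fm("menger_sponge level %d exceeds the voxel budget (%g voxels)",
                s, spec$voxel_budget)
      menger_occupancy(s)
    },
    solid_cube  = array(TRUE, c(s, s, s)),
    plane_sheet = array(TRUE, c(s, s, 1)),
    rod         = array(TRUE, c(s, 1, 1)),
    single_voxel = array(TRUE, c(1, 1, 1)))
  if (prod(dim(core) + 2L * spec$pad) > spec$voxel_budget)
    stop_fm("phantom exceeds the voxel budget (%g voxels)", spec$voxel_budget)
  if (spec$pad > 0) {
    d <- dim(core) + 2L * spec$pad
    occ <- array(FALSE, d)
    occ[spec$pad + seq_len(dim(core)[1]),
        spec$pad + seq_len(dim(core)[2]),
        spec$pad + seq_len(dim(core)[3])] <- core
  } else {
    occ <- core
  }
  binary_mask(occ)
}
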