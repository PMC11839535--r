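# Synthetic labeled volume + scalar map fixture generator: disjoint
# axis-aligned boxes carry integer labels 1..K in the atlas and constant
# values in the scalar map, so downstream ROI means have known answers.

#' Build a label atlas and matching scalar map from axis-aligned boxes
#'
#' @param shape Volume dimensions, length-3 positive integers.
#' @param roi_boxes List of boxes; each box is `list(lo = c(x,y,z),
#'   hi = c(x,y,z))` in 1-based voxel coordinates, inclusive. Boxes must be
#'   pairwise disjoint and lie inside `shape`.
#' @param roi_values Numeric vector, one scalar value per box.
#' @param roi_names Optional character names for the labels (default
#'   `roi1..roiK`).
#' @return List with `atlas` (a [label_atlas()]) and `map` (3-D numeric
#'   array, 0 outside every box).
#' @export
make_labeled_volume <- function(shape, roi_boxes, roi_values,
                                roi_names = NULL) {
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (length(roi_boxes) != length(roi_values))
    stop_fm("need one value per box (%d boxes, %d values)",
            length(roi_boxes), length(roi_values))
  if (is.null(roi_names))
    roi_names <- sprintf("roi%d", seq_along(roi_boxes))
  shape <- as.integer(shape)
  labels <- array(0L, shape)
  map <- array(0, shape)
  for (k in seq_along(roi_boxes)) {
    b <- roi_boxes[[k]]
    lo <- as.integer(b$lo); hi <- as.integer(b$hi)
    if (any(lo < 1) || any(hi > shape) || any(lo > hi))
      stop_fm("box %d (%s..%s) does not fit inside shape %s", k,
              paste(lo, collapse = ","), paste(hi, collapse = ","),
              paste(shape, collapse = ","))
    sl <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
    if (any(labels[sl[[1]], sl[[2]], sl[[3]]] != 0L))
      stop_fm("box %d overlaps an earlier box", k)
    labels[sl[[1]], sl[[2]], sl[[3]]] <- k
    map[sl[[1]], sl[[2]], sl[[3]]] <- roi_values[[k]]
  }
  atlas <- label_atlas(labels, stats::setNames(seq_along(roi_boxes), roi_names))
  list(atlas = atlas, map = map)
}

#' Write an atlas/map pair as NIfTI-1 volumes
#'
#' @param vol Output of [make_labeled_volume()].
#' @param atlas_path,map_path Output paths (`.nii` or `.nii.gz`).
#' @param names_path Optional path for a JSON label-name table.
#' @return Invisibly, the paths written.
#' @export
write_labeled_volume <- function(vol, atlas_path, map_path,
                                 names_path = NULL) {
  write_nifti(vol$atlas$labels, atlas_path, datatype = "int32")
  write_nifti(vol$map, map_path, datatype = "float64")
  if (!is.null(names_path))
    jsonlite::write_json(as.list(vol$atlas$names), names_path,
                         auto_unbox = TRUE)
  invisible(c(atlas_path, map_path, names_path))
}

#' Read an atlas/map pair from NIfTI-1 volumes
#'
#' @param atlas_path,map_path NIfTI files as written by
#'   [write_labeled_volume()].
#' @param names_path JSON label-name table, or `NULL` to name labels
#'   `roi<k>` for every nonzero label present.
#' @return List with `atlas` and `map` as in [make_labeled_volume()].
#' @export
read_labeled_volume <- function(atlas_path, map_path, names_path = NULL) {
  lab <- read_nifti(atlas_path)
  map <- read_nifti(map_path)
  if (!identical(dim(lab$data), dim(map$data)))
    stop_fm("atlas and map have different shapes")
  if (!is.null(names_path)) {
    nm <- jsonlite::read_json(names_path)
    names_vec <- stats::setNames(as.integer(unlist(nm)), names(nm))
  } else {
    labs <- sort(setdiff(unique(as.vector(lab$data)), 0))
    names_vec <- stats::setNames(as.integer(labs), paste0("roi", labs))
  }
  list(atlas = label_atlas(array(as.integer(lab$data), dim(lab$data)),
                           names_vec),
       map = map$data)
}
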