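# ROI-mean fractional anisotropy.
#
# Consumes a precomputed scalar FA map and an integer label atlas sharing the
# same voxel grid; upstream preprocessing (tensor fitting, registration) is
# out of scope, and a grid mismatch is an error rather than a silent
# resample.

#' The 18 white-matter ROI names of the DTI feature block
#'
#' Bilateral corticospinal tract, superior longitudinal fasciculus, cingulum,
#' inferior occipital fasciculus, corona radiata, inferior longitudinal
#' fasciculus and caudate, the three corpus callosum segments, and the middle
#' cerebellar peduncle.
#'
#' @return Character vector of length 18.
#' @export
jhu_roi_names <- function() {
  c("cst_l", "cst_r", "slf_l", "slf_r",
    "cc_genu", "cc_body", "cc_splenium",
    "caudate_l", "caudate_r", "cingulum_l", "cingulum_r",
    "inf_occ_fasc_l", "inf_occ_fasc_r",
    "corona_radiata_l", "corona_radiata_r",
    "inf_long_fasc_l", "inf_long_fasc_r", "mcp")
}

#' Construct a label atlas
#'
#' @param labels 3-D integer array; 0 is background.
#' @param names Named integer vector mapping ROI names to label values, e.g.
#'   `c(cst_l = 1, cst_r = 2)`. Every named label must occur in the array.
#' @return A `label_atlas` object.
#' @export
label_atlas <- function(labels, names) {
  if (is.null(dim(labels)) || length(dim(labels)) != 3)
    stop_fm("labels must be a 3-D array")
  labels <- array(as.integer(labels), dim(labels))
  stopifnot(is.numeric(names), !is.null(base::names(names)))
  present <- unique(as.vector(labels))
  missing <- names[!names %in% present]
  if (length(missing) > 0)
    stop_fm("named labels absent from the atlas: %s",
            paste(sprintf("%s=%d", base::names(missing), missing), collapse = ", "))
  structure(list(labels = labels, names = as.integer(names) |>
                   stats::setNames(base::names(names))),
            class = "label_atlas")
}

#' ROI-mean scalar values from a map and a label atlas
#'
#' Arithmetic mean of the scalar map over the voxels carrying each requested
#' label. Non-finite voxels are excluded from the mean and counted in the
#' `n_nan` column with a warning. FA values outside [0, 1] are flagged with a
#' warning, not an error (the map may be any scalar).
#'
#' @param map 3-D numeric array (e.g. an FA map), same shape as the atlas.
#' @param atlas A [label_atlas()].
#' @param rois ROI names to extract; defaults to every named label.
#' @return A data.frame with columns `roi`, `label`, `mean_fa`, `n_voxels`,
#'   `n_nan`.
#' @export
mean_fa_by_roi <- function(map, atlas, rois = NULL) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (is.null(dim(map)) || !identical(dim(map), dim(atlas$labels)))
    stop_fm("map shape (%s) does not match atlas shape (%s)",
            paste(dim(map), collapse = "x"),
            paste(dim(atlas$labels), collapse = "x"))
  if (is.null(rois)) rois <- names(atlas$names)
  if (length(rois) == 0)
    stop_fm("no ROIs requested and the atlas has no named labels")
  unknown <- setdiff(rois, names(atlas$names))
  if (length(unknown) > 0)
    stop_fm("unknown ROI name(s): %s", paste(unknown, collapse = ", "))
  out <- lapply(rois, function(roi) {
    lab <- atlas$names[[roi]]
    vals <- map[atlas$labels == lab]
    if (length(vals) == 0)
      stop_fm("ROI '%s' (label %d) has zero voxels in the atlas", roi, lab)
    bad <- !is.finite(vals)
    if (any(bad))
      warning(sprintf("ROI '%s': %d non-finite voxel(s) excluded from mean",
                      roi, sum(bad)), call. = FALSE)
    ok <- vals[!bad]
    data.frame(roi = roi, label = lab,
               mean_fa = if (length(ok)) mean(ok) else NA_real_,
               n_voxels = length(vals), n_nan = sum(bad),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  inrange <- res$mean_fa[is.finite(res$mean_fa)]
  if (length(inrange) && any(inrange < 0 | inrange > 1))
    warning("some ROI means lie outside the nominal FA range [0, 1]",
            call. = FALSE)
  rownames(res) <- NULL
  res
}
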