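# Box-counting fractal dimension.
#
# An object is covered by axis-aligned grids of cubes with side r voxels and
# the number N(r) of occupied cubes is recorded over a schedule of sizes.
# The power law N(r) = K r^-FD gives, after log transform,
#   ln N = FD * ln(1/r) + ln K,
# so FD is the slope of the ordinary least-squares fit of ln N on ln(1/r).

#' Box-size schedule for a mask
#'
#' The default dyadic schedule is r = 1, 2, 4, ... up to half the largest
#' bounding-box side, extended (by further doubling) to at least four sizes.
#' The `"pow3"` schedule r = 1, 3, 9, ... up to the largest side matches the
#' exact self-similarity of the corner-anchored Menger sponge.
#'
#' @param mask A `binary_mask`.
#' @param schedule `"dyadic"` or `"pow3"`.
#' @param min_sizes Minimum number of sizes in the schedule.
#' @return Integer vector of box sides, strictly increasing.
#' @export
box_sizes <- function(mask, schedule = c("dyadic", "pow3"), min_sizes = 4) {
  mask <- as_mask(mask)
  check_nonempty(mask)
  bb <- mask_bbox(mask)
  side <- max(bb$dim)
  schedule <- match.arg(schedule)
  base <- if (schedule == "dyadic") 2 else 3
  limit <- if (schedule == "dyadic") max(side / 2, 1) else side
  sizes <- base^(0:ceiling(log(max(side, base), base)))
  sizes <- sizes[sizes <= limit]
  while (length(sizes) < min_sizes)
    sizes <- c(sizes, base^length(sizes))
  as.integer(sizes)
}

mask_bbox <- function(mask) {
  w <- which(mask$occupancy, arr.ind = TRUE)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  list(lo = lo, hi = hi, dim = hi - lo + 1L, coords = w)
}

#' Count occupied boxes over a schedule of sizes
#'
#' For each size r the tight foreground bounding box is partitioned into an
#' axis-aligned grid of r-cubes and cells containing at least one foreground
#' voxel are counted. With `offset_policy = "corner"` the grid is anchored at
#' the bounding-box corner (deterministic); `"min_over_offsets"` takes the
#' minimum count over grids shifted by 0 or floor(r/2) voxels per axis,
#' which reduces quantization bias at the cost of a small search.
#'
#' @param mask A non-empty `binary_mask`.
#' @param sizes_r Box sides in voxels (>= 2 values, all >= 1); defaults to
#'   [box_sizes()] of the mask.
#' @param offset_policy `"corner"` or `"min_over_offsets"`.
#' @return A `box_count_series`: list with `sizes_r`, `counts_N`,
#'   `foreground`, `offset_policy`.
#' @export
box_count <- function(mask, sizes_r = NULL,
                      offset_policy = c("corner", "min_over_offsets")) {
  mask <- as_mask(mask)
  check_nonempty(mask)
  offset_policy <- match.arg(offset_policy)
  if (is.null(sizes_r)) sizes_r <- box_sizes(mask)
  sizes_r <- as.integer(sizes_r)
  if (length(sizes_r) < 2) stop_fm("need at least 2 box sizes")
  if (any(sizes_r < 1)) stop_fm("box sizes must be >= 1")
  if (is.unsorted(sizes_r, strictly = TRUE))
    stop_fm("box sizes must be strictly increasing")
  bb <- mask_bbox(mask)
  if (min(sizes_r) > max(bb$dim))
    stop_fm("degenerate series: every box size exceeds the mask extent (%d)",
            max(bb$dim))
  coords <- sweep(bb$coords, 2, bb$lo)  # 0-based within bounding box
  count_at <- function(r, off) {
    cell <- floor(sweep(coords, 2, off, `+`) / r)
    dims <- apply(cell, 2, max) + 1
    key <- cell[, 1] + dims[1] * (cell[, 2] + dims[2] * cell[, 3])
    length(unique(key))
  }
  counts <- vapply(sizes_r, function(r) {
    if (offset_policy == "corner" || r == 1) return(count_at(r, c(0, 0, 0)))
    shifts <- unique(c(0L, r %/% 2L))
    grid <- expand.grid(x = shifts, y = shifts, z = shifts)
    min(apply(grid, 1, function(o) count_at(r, as.numeric(o))))
  }, numeric(1))
  structure(list(sizes_r = sizes_r, counts_N = as.integer(counts),
                 foreground = mask_volume(mask),
                 offset_policy = offset_policy),
            class = "box_count_series")
}

#' @export
print.box_count_series <- function(x, ...) {
  cat("<box_count_series>\n")
  print(data.frame(r = x$sizes_r, N = x$counts_N))
  invisible(x)
}

#' Fit a fractal dimension to a box-count series
#'
#' Ordinary least squares of ln N on ln(1/r); the slope is the fractal
#' dimension and the intercept the log prefactor ln K. Estimates outside
#' [0, 3] (possible for noisy finite-size series) are flagged with a warning
#' but returned.
#'
#' @param series A `box_count_series`, or anything with `sizes_r` /
#'   `counts_N` components.
#' @return An `fd_estimate`: list with `fd`, `log_prefactor`, `r_squared`,
#'   `n_points`.
#' @export
fit_fd <- function(series) {
  r <- as.numeric(series$sizes_r)
  N <- as.numeric(series$counts_N)
  keep <- N > 0
  r <- r[keep]; N <- N[keep]
  if (length(unique(r)) < 2)
    stop_fm("singular fit: need at least 2 distinct box sizes with positive counts")
  x <- log(1 / r)
  y <- log(N)
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - (intercept + slope * x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else max(0, min(1, 1 - sum(res^2) / sst))
  if (slope < -1e-9 || slope > 3 + 1e-9)
    warning(sprintf("fitted FD %.3f lies outside [0, 3]", slope), call. = FALSE)
  structure(list(fd = slope, log_prefactor = intercept, r_squared = r2,
                 n_points = length(r)),
            class = "fd_estimate")
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat(sprintf("<fd_estimate> FD = %.4f (ln K = %.3f, r^2 = %.4f, %d sizes)\n",
              x$fd, x$log_prefactor, x$r_squared, x$n_points))
  invisible(x)
}

#' Fractal dimension features for a set of ROIs
#'
#' For each ROI mask, computes the box-counting fractal dimension of the
#' requested structural features: the full voxel object (`"general"`), its
#' boundary voxels (`"surface"`, see [extract_surface()]) and its thinned
#' medial representation (`"skeleton"`, see [extract_skeleton()]).
#'
#' @param masks Named list of non-empty `binary_mask` objects.
#' @param features Subset of `c("general", "surface", "skeleton")`.
#' @param schedule Size schedule passed to [box_sizes()].
#' @param offset_policy Grid anchoring passed to [box_count()].
#' @return A data.frame with columns `roi`, `feature`, `fd`, `r_squared`,
#'   `n_points`. A feature whose derived mask is empty yields `NA` with a
#'   warning rather than an error.
#' @export
roi_fd_features <- function(masks, features = c("general", "surface", "skeleton"),
                            schedule = "dyadic", offset_policy = "corner") {
  stopifnot(is.list(masks))
  if (length(masks) > 0 && is.null(names(masks)))
    stop_fm("masks must be a named list")
  features <- intersect(c("general", "surface", "skeleton"), features)
  rows <- list()
  for (roi in names(masks)) {
    mask <- as_mask(masks[[roi]])
    check_nonempty(mask, sprintf("mask '%s'", roi))
    for (ft in features) {
      sub <- switch(ft, general = mask,
                    surface = extract_surface(mask),
                    skeleton = extract_skeleton(mask))
      if (mask_volume(sub) == 0) {
        warning(sprintf("feature '%s' of ROI '%s' is empty; recording NA",
                        ft, roi), call. = FALSE)
        est <- list(fd = NA_real_, r_squared = NA_real_, n_points = NA_integer_)
      } else {
        est <- fit_fd(box_count(sub, box_sizes(sub, schedule),
                                offset_policy))
      }
      rows[[length(rows) + 1]] <- data.frame(
        roi = roi, feature = ft, fd = est$fd, r_squared = est$r_squared,
        n_points = est$n_points, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(roi = character(), feature = character(), fd = numeric(),
                      r_squared = numeric(), n_points = integer()))
  do.call(rbind, rows)
}
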