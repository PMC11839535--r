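# Synthetic two-group cohort with a planted rank-1 cross-block covariance.
#
# Each subject carries a latent score t ~ N(0, 1); the imaging row is
# effect * t * salience_img + N(0, noise_sd) and the behavioral row is
# effect * t * salience_beh + N(0, noise_sd). A single latent direction
# mirrors the one significant latent component the cross-block analysis is
# expected to recover; effect = 0 yields independent blocks for null
# calibration.

#' Default behavioral measure names
#' @return Character vector: BBS, COP, TMT, SDMT, SCWT.
#' @export
behavior_measure_names <- function() c("BBS", "COP", "TMT", "SDMT", "SCWT")

default_imaging_names <- function(n_imaging) {
  if (n_imaging == 34)
    c(paste0("fa_", jhu_roi_names()), sprintf("fd_f%02d", 1:16))
  else sprintf("img_f%02d", seq_len(n_imaging))
}

default_salience <- function(p, support = min(6L, p)) {
  v <- numeric(p)
  v[seq_len(support)] <- 1
  v / sqrt(sum(v^2))
}

#' Specify a synthetic cohort
#'
#' @param n_subjects Number of subjects (default 18, as 8 controls + 10
#'   patients).
#' @param n_imaging Number of imaging features (default 34 = 18 FA + 16 FD).
#' @param n_behavior Number of behavioral measures (default 5).
#' @param effect Scale of the planted latent signal; 0 gives independent
#'   blocks.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param salience_img,salience_beh Unit-norm planted salience directions;
#'   defaults put equal weight on the first `min(6, n_imaging)` imaging
#'   features and on all behavioral measures.
#' @param group_sizes Sizes of the HC and TBI groups (must sum to
#'   `n_subjects`).
#' @param group_shift Optional per-measure mean shift added to the second
#'   (TBI) group's behavioral rows, length `n_behavior` (default none); used
#'   to plant group differences for the group-comparison tests.
#' @param seed Integer seed driving all randomness of the generator.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 18, n_imaging = 34, n_behavior = 5,
                        effect = 1, noise_sd = 1,
                        salience_img = NULL, salience_beh = NULL,
                        group_sizes = c(8, 10), group_shift = NULL,
                        seed = 1) {
  stopifnot(is_count(n_subjects), is_count(n_imaging), is_count(n_behavior),
            effect >= 0, noise_sd > 0, length(group_sizes) == 2,
            all(group_sizes >= 1))
  if (sum(group_sizes) != n_subjects)
    stop_fm("group_sizes (%s) must sum to n_subjects (%d)",
            paste(group_sizes, collapse = "+"), n_subjects)
  if (is.null(salience_img)) salience_img <- default_salience(n_imaging)
  if (is.null(salience_beh)) salience_beh <- default_salience(n_behavior, n_behavior)
  check_unit <- function(v, p, what) {
    if (length(v) != p) stop_fm("%s must have length %d", what, p)
    if (abs(sqrt(sum(v^2)) - 1) > 1e-8)
      stop_fm("%s must have unit Euclidean norm", what)
    v
  }
  salience_img <- check_unit(salience_img, n_imaging, "salience_img")
  salience_beh <- check_unit(salience_beh, n_behavior, "salience_beh")
  if (!is.null(group_shift) && length(group_shift) != n_behavior)
    stop_fm("group_shift must have length n_behavior (%d)", n_behavior)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_imaging = as.integer(n_imaging),
                 n_behavior = as.integer(n_behavior),
                 effect = effect, noise_sd = noise_sd,
                 salience_img = salience_img, salience_beh = salience_beh,
                 group_sizes = as.integer(group_sizes),
                 group_shift = group_shift, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_matrices` object: list with imaging block `X`
#'   (subjects x features), behavioral block `Y` (subjects x measures),
#'   `group` (factor HC/TBI), `subject_ids`, `feature_names`,
#'   `measure_names`, and the generating `spec`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  feature_names <- default_imaging_names(spec$n_imaging)
  measure_names <- if (spec$n_behavior == 5) behavior_measure_names()
  else sprintf("beh_m%02d", seq_len(spec$n_behavior))
  with_seed(sub_seed(spec$seed, "cohort"), {
    t_lat <- rnorm(n)
    X <- spec$effect * tcrossprod(t_lat, spec$salience_img) +
      matrix(rnorm(n * spec$n_imaging, sd = spec$noise_sd), n)
    Y <- spec$effect * tcrossprod(t_lat, spec$salience_beh) +
      matrix(rnorm(n * spec$n_behavior, sd = spec$noise_sd), n)
  })
  group <- factor(rep(c("HC", "TBI"), spec$group_sizes),
                  levels = c("HC", "TBI"))
  if (!is.null(spec$group_shift))
    Y[group == "TBI", ] <- sweep(Y[group == "TBI", , drop = FALSE], 2,
                                 spec$group_shift, `+`)
  colnames(X) <- feature_names
  colnames(Y) <- measure_names
  structure(list(X = X, Y = Y, group = group,
                 subject_ids = sprintf("S%02d", seq_len(n)),
                 feature_names = feature_names,
                 measure_names = measure_names, spec = spec),
            class = "cohort_matrices")
}

#' @export
print.cohort_matrices <- function(x, ...) {
  cat(sprintf("<cohort_matrices> %d subjects (%s), X %dx%d, Y %dx%d\n",
              nrow(x$X), paste(table(x$group), names(table(x$group)),
                               collapse = " + "),
              nrow(x$X), ncol(x$X), nrow(x$Y), ncol(x$Y)))
  invisible(x)
}

#' Write a cohort to CSV
#'
#' One row per subject: `subject_id`, `group`, the behavioral measures, then
#' the imaging features.
#'
#' @param cohort A `cohort_matrices` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- data.frame(subject_id = cohort$subject_ids,
                   group = as.character(cohort$group),
                   cohort$Y, cohort$X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path CSV as written by [write_cohort_csv()].
#' @param measure_names Columns forming the behavioral block; all remaining
#'   non-id columns form the imaging block.
#' @return A `cohort_matrices` object (without a generating `spec`).
#' @export
read_cohort_csv <- function(path, measure_names = behavior_measure_names()) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("subject_id", "group", measure_names)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_fm("cohort CSV is missing column(s): %s", paste(miss, collapse = ", "))
  feats <- setdiff(names(df), need)
  structure(list(
    X = as.matrix(df[, feats, drop = FALSE]),
    Y = as.matrix(df[, measure_names, drop = FALSE]),
    group = factor(df$group, levels = c("HC", "TBI")),
    subject_ids = as.character(df$subject_id),
    feature_names = feats, measure_names = measure_names, spec = NULL),
    class = "cohort_matrices")
}
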