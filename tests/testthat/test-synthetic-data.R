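# Generators: phantoms, cohorts, COP traces, labeled volumes.

test_that("phantom voxel counts match their closed forms", {
  cases <- list(
    list(kind = "menger_sponge", n = 1, expect = 20),
    list(kind = "menger_sponge", n = 2, expect = 400),
    list(kind = "menger_sponge", n = 3, expect = 8000),
    list(kind = "solid_cube", n = 32, expect = 32^3),
    list(kind = "solid_cube", n = 5, expect = 125),
    list(kind = "plane_sheet", n = 7, expect = 49),
    list(kind = "rod", n = 20, expect = 20),
    list(kind = "single_voxel", n = 1, expect = 1))
  for (cs in cases) {
    m <- make_phantom(phantom_spec(cs$kind, cs$n))
    expect_equal(mask_volume(m), cs$expect,
                 info = sprintf("%s(%d)", cs$kind, cs$n))
  }
})

test_that("padding adds an untouched background margin", {
  m <- make_phantom(phantom_spec("solid_cube", 4, pad = 2))
  expect_equal(dim(m$occupancy), c(8, 8, 8))
  expect_equal(mask_volume(m), 64)
  border <- m$occupancy
  border[3:6, 3:6, 3:6] <- FALSE
  expect_false(any(border))
})

test_that("oversized phantoms hit the voxel budget", {
  expect_error(make_phantom(phantom_spec("menger_sponge", 9)), "budget")
  expect_error(make_phantom(phantom_spec("solid_cube", 300,
                                         voxel_budget = 1e6)), "budget")
})

test_that("cohort generation is seed-reproducible and seed-sensitive", {
  sp <- cohort_spec(seed = 5)
  c1 <- make_cohort(sp)
  c2 <- make_cohort(sp)
  expect_identical(c1$X, c2$X)
  expect_identical(c1$Y, c2$Y)
  c3 <- make_cohort(cohort_spec(seed = 6))
  expect_false(identical(c1$X, c3$X))
  expect_equal(dim(c1$X), c(18, 34))
  expect_equal(dim(c1$Y), c(18, 5))
  expect_equal(as.vector(table(c1$group)), c(8, 10))
  expect_equal(c1$measure_names, c("BBS", "COP", "TMT", "SDMT", "SCWT"))
  expect_equal(sum(startsWith(c1$feature_names, "fa_")), 18)
  expect_equal(sum(startsWith(c1$feature_names, "fd_")), 16)
})

test_that("effect = 0 gives independent blocks (cross-correlations shrink)", {
  mean_abs_cor <- function(n, seed) {
    half <- n %/% 2
    co <- make_cohort(cohort_spec(n_subjects = n,
                                  group_sizes = c(half, n - half),
                                  effect = 0, noise_sd = 1, seed = seed))
    mean(abs(cor(co$X, co$Y)))
  }
  small <- mean(vapply(1:5, function(s) mean_abs_cor(20, s), numeric(1)))
  large <- mean(vapply(1:5, function(s) mean_abs_cor(400, s), numeric(1)))
  expect_lt(large, small)
  expect_lt(large, 0.06)  # ~ sqrt(2/pi)/sqrt(n) for n = 400
})

test_that("planted effect drives the leading cross-covariance direction", {
  # simulation check of the rank-1 model: strong effect, large n
  cos_sim <- vapply(1:20, function(s) {
    sp <- planted_cohort(seed = s)
    co <- make_cohort(sp)
    Xz <- scale(co$X); Yz <- scale(co$Y)
    v1 <- svd(crossprod(Yz, Xz))$v[, 1]
    abs(sum(v1 * sp$salience_img))
  }, numeric(1))
  expect_gt(median(cos_sim), 0.9)
})

test_that("cohort_spec validates saliences and group sizes", {
  expect_error(cohort_spec(group_sizes = c(5, 5)), "sum to n_subjects")
  expect_error(cohort_spec(salience_img = rep(1, 34)), "unit Euclidean norm")
  expect_error(cohort_spec(salience_img = rep(0.5, 2)), "length 34")
})

test_that("cohort CSV round-trips", {
  tmp <- withr::local_tempdir()
  co <- make_cohort(cohort_spec(seed = 3))
  p <- file.path(tmp, "cohort.csv")
  write_cohort_csv(co, p)
  rt <- read_cohort_csv(p)
  expect_equal(unname(rt$X), unname(co$X), tolerance = 1e-12)
  expect_equal(unname(rt$Y), unname(co$Y), tolerance = 1e-12)
  expect_equal(as.character(rt$group), as.character(co$group))
  expect_equal(rt$feature_names, co$feature_names)
})

test_that("COP trace follows the stated drift + sinusoid + noise model", {
  # all-zero trace
  z <- make_cop_trace(cop_trace_spec(amplitude = 0, drift_slope = 0,
                                     noise_sd = 0))
  expect_true(all(z$samples == 0))
  # pure response: analytic sinusoid on the perturbation window, 0 outside
  sp <- cop_trace_spec(amplitude = 1.5, noise_sd = 0, perturb_onset_s = 1,
                       duration_s = 6)
  tr <- make_cop_trace(sp)
  fs <- sp$sampling_rate_hz
  t <- (seq_along(tr$samples) - 1) / fs
  expected <- ifelse(t >= 1 & t <= 5, 1.5 * sin(2 * pi * 0.5 * (t - 1)), 0)
  expect_equal(tr$samples, expected, tolerance = 1e-12)
  expect_equal(tr$onset_index, 101L)
  # determinism under noise
  n1 <- make_cop_trace(cop_trace_spec(noise_sd = 0.1, seed = 9))
  n2 <- make_cop_trace(cop_trace_spec(noise_sd = 0.1, seed = 9))
  expect_identical(n1$samples, n2$samples)
  # timing invariant
  expect_error(cop_trace_spec(duration_s = 3, perturb_onset_s = 0),
               "does not fit")
  expect_error(cop_trace_spec(sampling_rate_hz = 20), ">= 50")
})

test_that("COP trial CSV round-trips with metadata", {
  tmp <- withr::local_tempdir()
  tr <- make_cop_trace(cop_trace_spec(noise_sd = 0.05, seed = 2))
  p <- file.path(tmp, "trial.csv")
  write_cop_csv(tr, p)
  rt <- read_cop_csv(p)
  expect_equal(rt$samples, tr$samples, tolerance = 1e-9)
  expect_equal(rt$sampling_rate_hz, tr$sampling_rate_hz)
  expect_equal(rt$onset_index, tr$onset_index)
})

test_that("labeled volumes put the right values in the right boxes", {
  vol <- make_labeled_volume(
    shape = c(10, 10, 10),
    roi_boxes = list(list(lo = c(1, 1, 1), hi = c(4, 4, 4)),
                     list(lo = c(6, 6, 6), hi = c(9, 9, 9))),
    roi_values = c(0.2, 0.7))
  tab <- mean_fa_by_roi(vol$map, vol$atlas)
  expect_equal(tab$mean_fa, c(0.2, 0.7))
  expect_equal(tab$n_voxels, c(64, 64))
  # single box
  v1 <- make_labeled_volume(c(5, 5, 5),
                            list(list(lo = c(2, 2, 2), hi = c(4, 4, 4))), 0.5)
  expect_equal(mean_fa_by_roi(v1$map, v1$atlas)$mean_fa, 0.5)
  # overlap is an error
  expect_error(make_labeled_volume(
    c(10, 10, 10),
    list(list(lo = c(1, 1, 1), hi = c(5, 5, 5)),
         list(lo = c(5, 5, 5), hi = c(9, 9, 9))), c(1, 2)), "overlaps")
  # empty atlas: construction fine, queries fail
  v0 <- make_labeled_volume(c(4, 4, 4), list(), numeric(0))
  expect_error(mean_fa_by_roi(v0$map, v0$atlas), "no ROIs")
})

test_that("labeled volumes survive the NIfTI round-trip", {
  tmp <- withr::local_tempdir()
  vol <- make_labeled_volume(
    c(12, 12, 12),
    list(list(lo = c(2, 2, 2), hi = c(5, 5, 5)),
         list(lo = c(7, 7, 7), hi = c(11, 11, 11))),
    c(0.35, 0.65), roi_names = c("left", "right"))
  write_labeled_volume(vol, file.path(tmp, "atlas.nii.gz"),
                       file.path(tmp, "map.nii.gz"),
                       file.path(tmp, "labels.json"))
  rt <- read_labeled_volume(file.path(tmp, "atlas.nii.gz"),
                            file.path(tmp, "map.nii.gz"),
                            file.path(tmp, "labels.json"))
  expect_equal(mean_fa_by_roi(rt$map, rt$atlas)$mean_fa, c(0.35, 0.65))
  expect_equal(names(rt$atlas$names), c("left", "right"))
})
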