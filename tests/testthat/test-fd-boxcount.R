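# Box-counting fractal dimension: surface/skeleton extraction, counting,
# log-log fitting, per-ROI feature tables.

test_that("extract_surface matches the brute-force neighbor oracle", {
  set.seed(401)
  shapes <- list(
    cube_mask(3)$occupancy,
    cube_mask(10)$occupancy,
    array(runif(6 * 7 * 5) > 0.5, c(6, 7, 5)),
    make_phantom(phantom_spec("menger_sponge", 2))$occupancy)
  for (occ in shapes) {
    if (!any(occ)) next
    got <- extract_surface(binary_mask(occ))$occupancy
    expect_identical(got, surface_oracle(occ))
  }
  # headline counts
  expect_equal(mask_volume(extract_surface(cube_mask(3))), 26)
  expect_equal(mask_volume(extract_surface(cube_mask(10))), 488)
  sv <- make_phantom(phantom_spec("single_voxel"))
  expect_equal(mask_volume(extract_surface(sv)), 1)
  expect_error(extract_surface(binary_mask(array(FALSE, c(2, 2, 2)))),
               "empty")
})

test_that("extract_skeleton thins while preserving topology", {
  # idempotent on a 1-voxel-thick rod
  rod <- make_phantom(phantom_spec("rod", 20))
  expect_identical(extract_skeleton(rod)$occupancy, rod$occupancy)
  # single voxel survives
  sv <- make_phantom(phantom_spec("single_voxel"))
  expect_equal(mask_volume(extract_skeleton(sv)), 1)
  # subset of the mask, fewer voxels on solids
  cube <- cube_mask(8)
  sk <- extract_skeleton(cube)
  expect_true(all(cube$occupancy[sk$occupancy]))
  expect_lt(mask_volume(sk), mask_volume(cube))
  expect_gt(mask_volume(sk), 0)
  # component count preserved (26-connectivity)
  tc <- two_cube_mask()
  expect_equal(n_components(tc), 2)
  expect_equal(n_components(extract_skeleton(tc)), 2)
  expect_equal(n_components(extract_skeleton(cube)), 1)
  expect_error(extract_skeleton(binary_mask(array(FALSE, c(2, 2, 2)))),
               "empty")
})

test_that("box counts match exact tilings and closed forms", {
  # corner-anchored level-3 sponge at r = 3^k: N = 20^(3-k)
  m3 <- make_phantom(phantom_spec("menger_sponge", 3))
  bc <- box_count(m3, c(1, 3, 9, 27))
  expect_equal(bc$counts_N, c(8000L, 400L, 20L, 1L))
  # solid cube side 8, exact dyadic tiling
  bc8 <- box_count(cube_mask(8), c(1, 2, 4, 8))
  expect_equal(bc8$counts_N, c(512L, 64L, 8L, 1L))
  # single voxel: N = 1 at every size
  sv <- make_phantom(phantom_spec("single_voxel"))
  expect_equal(box_count(sv, c(1, 2, 5))$counts_N, c(1L, 1L, 1L))
})

test_that("box-count invariants hold across random masks", {
  set.seed(402)
  for (rep in 1:5) {
    occ <- array(runif(15^3) > 0.6, c(15, 15, 15))
    if (!any(occ)) next
    m <- binary_mask(occ)
    for (policy in c("corner", "min_over_offsets")) {
      bc <- box_count(m, c(1, 2, 3, 5, 8), offset_policy = policy)
      expect_true(all(diff(bc$counts_N) <= 0))           # non-increasing
      expect_equal(bc$counts_N[1], mask_volume(m))       # N(1) = foreground
      expect_true(all(bc$counts_N >= mask_volume(m) / bc$sizes_r^3 - 1e-9))
    }
  }
})

test_that("box counting errors on degenerate inputs", {
  sheet <- make_phantom(phantom_spec("plane_sheet", 4))
  expect_error(box_count(sheet, c(8, 16)), "degenerate")
  expect_error(box_count(cube_mask(4), c(2)), "at least 2")
  expect_error(box_count(cube_mask(4), c(2, 2, 4)), "strictly increasing")
})

test_that("fit_fd recovers exact slopes and flags pathologies", {
  # exactly collinear sponge series
  est <- fit_fd(list(sizes_r = c(1, 3, 9, 27), counts_N = c(8000, 400, 20, 1)))
  expect_equal(est$fd, log(20) / log(3), tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  expect_equal(exp(est$log_prefactor), 8000, tolerance = 1e-9)
  # cube: N = (8/r)^3 -> slope exactly 3
  est3 <- fit_fd(list(sizes_r = c(1, 2, 4, 8), counts_N = c(512, 64, 8, 1)))
  expect_equal(est3$fd, 3, tolerance = 1e-12)
  # flat series -> 0
  est0 <- fit_fd(list(sizes_r = c(1, 2, 4), counts_N = c(1, 1, 1)))
  expect_equal(est0$fd, 0)
  expect_error(fit_fd(list(sizes_r = c(2), counts_N = c(5))), "singular")
  expect_warning(
    fit_fd(list(sizes_r = c(1, 2), counts_N = c(1, 100))), "outside")
})

test_that("fitted FD is translation invariant", {
  base <- array(FALSE, c(40, 40, 40))
  base[3:10, 5:12, 7:14] <- TRUE
  set.seed(403)
  base[sample(which(base))[1:100]] <- FALSE  # carve an irregular object
  fds <- vapply(list(c(0, 0, 0), c(4, 8, 2), c(16, 3, 11)), function(sh) {
    occ <- array(FALSE, c(40, 40, 40))
    w <- which(base, arr.ind = TRUE)
    occ[sweep(w, 2, sh, `+`)] <- TRUE
    fit_fd(box_count(binary_mask(occ), c(1, 2, 4, 8)))$fd
  }, numeric(1))
  expect_equal(fds[2], fds[1], tolerance = 1e-12)
  expect_equal(fds[3], fds[1], tolerance = 1e-12)
})

test_that("dyadic schedules span 1 .. half the bounding side (>= 4 sizes)", {
  expect_equal(box_sizes(cube_mask(32)), c(1L, 2L, 4L, 8L, 16L))
  expect_equal(box_sizes(cube_mask(8)), c(1L, 2L, 4L, 8L))  # extended to 4
  m3 <- make_phantom(phantom_spec("menger_sponge", 3))
  expect_equal(box_sizes(m3), c(1L, 2L, 4L, 8L))
  expect_equal(box_sizes(m3, "pow3"), c(1L, 3L, 9L, 27L))
})

test_that("roi_fd_features computes all features and honors frozen oracles", {
  tab <- roi_fd_features(list(cortexA = cube_mask(32)),
                         features = c("general", "surface"))
  gen <- tab$fd[tab$feature == "general"]
  expect_gte(gen, 2.85); expect_lte(gen, 3 + 1e-9)
  # surface of the cube: closed-form counts N(r) = m^3 - (m-2)^3, m = 32/r,
  # fitted by an independent OLS oracle
  r <- c(1, 2, 4, 8, 16)
  N_oracle <- (32 / r)^3 - (32 / r - 2)^3
  expect_equal(tab$fd[tab$feature == "surface"],
               ols_fd_oracle(r, N_oracle), tolerance = 1e-10)
  # empty feature set -> empty table
  empty <- roi_fd_features(list(a = cube_mask(4)), features = character(0))
  expect_equal(nrow(empty), 0)
  # general >= skeleton for solid convex phantoms
  tab2 <- roi_fd_features(list(cube = cube_mask(12),
                               rod = make_phantom(phantom_spec("rod", 20))))
  for (roi in c("cube", "rod")) {
    sub <- tab2[tab2$roi == roi, ]
    expect_gte(sub$fd[sub$feature == "general"],
               sub$fd[sub$feature == "skeleton"] - 1e-9)
  }
})

test_that("dyadic sponge estimate is frozen at its quantization-biased value", {
  # corner-anchored dyadic counting absorbs the size-1 holes at r = 2, so the
  # level-3 sponge reads low; the pow3 schedule is exact (see acceptance).
  m3 <- make_phantom(phantom_spec("menger_sponge", 3))
  expect_equal(fit_fd(box_count(m3))$fd, 2.348824, tolerance = 1e-6)
})
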