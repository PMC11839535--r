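# Shared fixtures, all built in code at test time.

cube_mask <- function(side) make_phantom(phantom_spec("solid_cube", side))

two_cube_mask <- function(side = 5, gap = 3) {
  nx <- 2 * side + gap
  occ <- array(FALSE, c(nx, side, side))
  occ[seq_len(side), , ] <- TRUE
  occ[(side + gap + 1):nx, , ] <- TRUE
  binary_mask(occ)
}

# brute-force surface oracle: check the 6 face neighbors of every voxel
surface_oracle <- function(occ) {
  d <- dim(occ)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!occ[i, j, k]) next
    nb <- c(
      i == 1 || !occ[i - 1, j, k], i == d[1] || !occ[i + 1, j, k],
      j == 1 || !occ[i, j - 1, k], j == d[2] || !occ[i, j + 1, k],
      k == 1 || !occ[i, j, k - 1], k == d[3] || !occ[i, j, k + 1])
    out[i, j, k] <- any(nb)
  }
  out
}

# independent OLS of ln N on ln(1/r), written without the package's fit code
ols_fd_oracle <- function(r, N) {
  x <- log(1 / r); y <- log(N)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  slope
}

planted_cohort <- function(seed, n = 100, effect = 3) {
  half <- n %/% 2
  cohort_spec(n_subjects = n, group_sizes = c(half, n - half),
              effect = effect, noise_sd = 1, seed = seed)
}

null_cohort_spec <- function(seed) {
  cohort_spec(effect = 0, noise_sd = 1, seed = seed)
}
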