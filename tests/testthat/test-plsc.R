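# Cross-block SVD, permutation inference, bootstrap stability, scores.

test_that("preprocessing z-scores columns and names offenders", {
  set.seed(501)
  X <- matrix(rnorm(60, 5, 3), 12); Y <- matrix(rnorm(36, -2, 0.5), 12)
  pre <- plsc_preprocess(X, Y)
  expect_equal(colMeans(pre$Xz), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(pre$Yz, 2, sd), rep(1, 3), tolerance = 1e-12)
  # already standardized input is a fixed point
  pre2 <- plsc_preprocess(pre$Xz, pre$Yz)
  expect_equal(unname(pre2$Xz[, ]), unname(pre$Xz[, ]), tolerance = 1e-12)
  Xc <- X; Xc[, 3] <- 7; colnames(Xc) <- paste0("f", 1:5)
  expect_error(plsc_preprocess(Xc, Y), "f3")
  Xna <- X; Xna[2, 2] <- NA
  expect_error(plsc_preprocess(Xna, Y), "missing")
  expect_error(plsc_preprocess(X[1:2, ], Y[1:2, ]), "at least 3")
})

test_that("fit_plsc matches independent oracles", {
  set.seed(502)
  # singular values vs direct eigendecomposition, random 8x4 / 8x3 blocks
  for (rep in 1:10) {
    pre <- plsc_preprocess(matrix(rnorm(32), 8), matrix(rnorm(24), 8))
    m <- fit_plsc(pre$Xz, pre$Yz)
    R <- t(pre$Yz) %*% pre$Xz
    ev <- eigen(R %*% t(R), symmetric = TRUE)$values
    expect_equal(m$singular_values, sqrt(pmax(ev, 0)), tolerance = 1e-10)
    expect_equal(sum(m$cov_explained), 1, tolerance = 1e-12)
    expect_equal(unname(colSums(m$U^2)), rep(1, ncol(m$U)), tolerance = 1e-12)
    expect_equal(unname(colSums(m$V^2)), rep(1, ncol(m$V)), tolerance = 1e-12)
    expect_true(all(diff(m$singular_values) <= 1e-12))
    # sign convention: largest |entry| of each V column positive
    for (l in seq_len(ncol(m$V)))
      expect_gt(m$V[which.max(abs(m$V[, l])), l], 0)
  }
  # Y = X on a fixed 6x5 matrix: V1 is the top eigenvector of (X'X)^2
  H <- matrix(c(2, -1, 0, 3, 1,
                1, 4, -2, 0, 2,
                -3, 2, 1, 1, 0,
                0, 1, 3, -2, 1,
                2, 0, -1, 1, 3,
                -1, -2, 2, 2, -1), 6, 5, byrow = TRUE)
  pre <- plsc_preprocess(H, H)
  m <- fit_plsc(pre$Xz, pre$Yz)
  G <- t(pre$Xz[, ]) %*% pre$Xz[, ]
  v_oracle <- eigen(G %*% G, symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(m$V[, 1] * v_oracle)), 1, tolerance = 1e-10)
  # covariance-explained closed form for singular values (2, 1, 1)
  m2 <- fit_plsc(rbind(diag(c(2, 1, 1)), 0), rbind(diag(3), 0))
  expect_equal(m2$singular_values, c(2, 1, 1))
  expect_equal(m2$cov_explained, c(4, 1, 1) / 6)
  expect_error(fit_plsc(matrix(0, 4, 3), matrix(rnorm(8), 4)), "degenerate")
})

test_that("fit_plsc is equivariant under feature permutation", {
  set.seed(503)
  pre <- plsc_preprocess(matrix(rnorm(80), 10), matrix(rnorm(30), 10))
  m <- fit_plsc(pre$Xz, pre$Yz)
  perm <- sample(ncol(pre$Xz))
  mp <- fit_plsc(pre$Xz[, perm], pre$Yz)
  expect_equal(mp$singular_values, m$singular_values, tolerance = 1e-12)
  expect_equal(abs(unname(mp$V)), abs(unname(m$V[perm, ])), tolerance = 1e-9)
})

test_that("planted saliences are recovered on strong-signal cohorts", {
  cos_v <- numeric(10); cos_u <- numeric(10)
  for (s in 1:10) {
    sp <- planted_cohort(seed = 600 + s)
    co <- make_cohort(sp)
    pre <- plsc_preprocess(co$X, co$Y)
    m <- fit_plsc(pre$Xz, pre$Yz)
    cos_v[s] <- abs(sum(m$V[, 1] * sp$salience_img))
    cos_u[s] <- abs(sum(m$U[, 1] * sp$salience_beh))
  }
  expect_gt(median(cos_v), 0.95)
  expect_gt(median(cos_u), 0.95)
})

test_that("permutation p-values are deterministic, bounded, and detect signal", {
  co <- make_cohort(cohort_spec(n_subjects = 40, group_sizes = c(20, 20),
                                effect = 3, noise_sd = 1, seed = 9))
  pre <- plsc_preprocess(co$X, co$Y)
  p1 <- plsc_permutation(pre$Xz, pre$Yz, n_perm = 500, seed = 4)
  p2 <- plsc_permutation(pre$Xz, pre$Yz, n_perm = 500, seed = 4)
  expect_identical(p1, p2)
  expect_lte(p1[1], 0.01)  # planted rank-1 signal
  expect_true(all(p1 > 0 & p1 <= 1))
  expect_gte(min(p1), 1 / 501)  # add-one estimator floor
  expect_error(plsc_permutation(pre$Xz, pre$Yz, n_perm = 50), ">= 100")
})

test_that("bootstrap stability flags planted structure, not noise", {
  sp <- planted_cohort(seed = 11)
  co <- make_cohort(sp)
  bs1 <- plsc_bootstrap(co$X, co$Y, n_boot = 150, seed = 5)
  bs2 <- plsc_bootstrap(co$X, co$Y, n_boot = 150, seed = 5)
  expect_identical(bs1$stable_img, bs2$stable_img)
  planted <- which(sp$salience_img != 0)
  expect_true(all(bs1$stable_img[planted, 1]))
  noise <- setdiff(seq_len(34), planted)
  expect_gt(mean(!bs1$stable_img[noise, 1]), 0.75)
  # an infinite threshold stabilizes nothing
  bs_inf <- plsc_bootstrap(co$X, co$Y, n_boot = 150, seed = 5,
                           threshold = Inf)
  expect_false(any(bs_inf$stable_img))
  expect_false(any(bs_inf$stable_beh))
  expect_error(plsc_bootstrap(co$X, co$Y, n_boot = 10), ">= 100")
})

test_that("scores and loadings satisfy the projection identities", {
  set.seed(504)
  co <- make_cohort(cohort_spec(n_subjects = 30, group_sizes = c(15, 15),
                                effect = 2, noise_sd = 1, seed = 21))
  pre <- plsc_preprocess(co$X, co$Y)
  m <- plsc_scores_loadings(fit_plsc(pre$Xz, pre$Yz), pre$Xz, pre$Yz,
                            co$X, co$Y)
  expect_equal(unname(m$scores_img), unname(pre$Xz[, ] %*% m$V),
               tolerance = 1e-12)
  expect_equal(unname(m$scores_beh), unname(pre$Yz[, ] %*% m$U),
               tolerance = 1e-12)
  # a feature proportional to its score loads at +/- 1
  X2 <- cbind(co$X, proxy = 2 * m$scores_img[, 1] + 3)
  pre2 <- plsc_preprocess(X2, co$Y)
  m2 <- plsc_scores_loadings(fit_plsc(pre2$Xz, pre2$Yz), pre2$Xz, pre2$Yz,
                             X2, co$Y)
  expect_equal(abs(unname(m2$loadings_img["proxy", 1])), 1, tolerance = 0.05)
  # planted model: imaging and behavioral scores of LC1 co-vary positively
  expect_gt(cor(m$scores_img[, 1], m$scores_beh[, 1]), 0)
})

test_that("the one-call wrapper assembles a complete model", {
  co <- make_cohort(cohort_spec(effect = 2, noise_sd = 1, seed = 31))
  m <- plsc(co$X, co$Y, n_perm = 200, n_boot = 120, seed = 2)
  expect_s3_class(m, "plsc_model")
  for (fld in c("perm_p", "bsr_img", "bsr_beh", "stable_img", "stable_beh",
                "scores_img", "scores_beh", "loadings_img", "loadings_beh"))
    expect_false(is.null(m[[fld]]), info = fld)
  expect_identical(m$stable_img, abs(m$bsr_img) >= 2)
  expect_equal(dim(m$scores_img), c(18, 5))
})
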