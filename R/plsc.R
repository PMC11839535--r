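# Behavioral partial least squares correlation (PLSC).
#
# Both blocks are column z-scored, the cross-block covariance
#   R = Yz' Xz   (measures x features)
# is decomposed by SVD, R = U D V', pairing behavioral saliences (columns of
# U) with imaging saliences (columns of V). Component l explains
# d_l^2 / sum(d^2) of the cross-block covariance. Significance of each
# component comes from permuting the rows of Y (add-one permutation p), and
# the reliability of individual salience elements from bootstrap resampling
# of subjects: the bootstrap stability ratio (BSR) is the original element
# divided by its bootstrap standard error, with |BSR| >= 2 marking a stable
# feature.

#' Column-wise z-scoring of the two blocks
#'
#' @param X,Y Numeric matrices sharing the row (subject) dimension.
#' @return List with `Xz` and `Yz`, each with column mean 0 and SD 1.
#' @export
plsc_preprocess <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop_fm("X and Y must have the same number of rows (%d vs %d)",
            nrow(X), nrow(Y))
  if (nrow(X) < 3) stop_fm("need at least 3 subjects, got %d", nrow(X))
  if (anyNA(X) || anyNA(Y)) stop_fm("missing values in the input blocks")
  zscore <- function(M, block) {
    s <- apply(M, 2, sd)
    if (any(s == 0)) {
      nm <- colnames(M)[s == 0]
      if (is.null(nm)) nm <- paste0("col", which(s == 0))
      stop_fm("constant column(s) in %s: %s", block, paste(nm, collapse = ", "))
    }
    scale(M, center = TRUE, scale = s)
  }
  list(Xz = zscore(X, "X"), Yz = zscore(Y, "Y"))
}

svd_cross_cov <- function(Xz, Yz) {
  R <- crossprod(Yz, Xz)  # measures x features
  s <- svd(R)
  list(R = R, U = s$u, V = s$v, d = s$d)
}

apply_sign_convention <- function(U, V) {
  for (l in seq_len(ncol(V))) {
    j <- which.max(abs(V[, l]))
    if (V[j, l] < 0) { V[, l] <- -V[, l]; U[, l] <- -U[, l] }
  }
  list(U = U, V = V)
}

#' Fit the PLSC decomposition
#'
#' @param Xz,Yz Preprocessed (z-scored) blocks from [plsc_preprocess()].
#' @return A `plsc_model` with `U` (behavioral saliences, measures x
#'   components), `V` (imaging saliences, features x components),
#'   `singular_values` (non-increasing), `cov_explained` (fractions summing
#'   to 1) and the cross-block matrix `R`. Component signs follow a fixed
#'   convention: the largest-magnitude element of each imaging salience is
#'   positive.
#' @export
fit_plsc <- function(Xz, Yz) {
  Xz <- as.matrix(Xz); Yz <- as.matrix(Yz)
  if (nrow(Xz) != nrow(Yz)) stop_fm("blocks must share the subject dimension")
  dec <- svd_cross_cov(Xz, Yz)
  if (all(dec$d < .Machine$double.eps * max(dim(dec$R)) * 10))
    stop_fm("degenerate cross-block covariance: all singular values are zero")
  sgn <- apply_sign_convention(dec$U, dec$V)
  rownames(sgn$U) <- colnames(Yz)
  rownames(sgn$V) <- colnames(Xz)
  structure(list(U = sgn$U, V = sgn$V, singular_values = dec$d,
                 cov_explained = dec$d^2 / sum(dec$d^2), R = dec$R),
            class = "plsc_model")
}

#' @export
print.plsc_model <- function(x, ...) {
  cat(sprintf("<plsc_model> %d component(s)\n", length(x$singular_values)))
  df <- data.frame(singular_value = x$singular_values,
                   cov_explained = x$cov_explained)
  if (!is.null(x$perm_p)) df$perm_p <- x$perm_p
  print(df, digits = 4)
  invisible(x)
}

#' Permutation test for latent component significance
#'
#' The rows of the behavioral block are permuted relative to the imaging
#' block and the decomposition is re-run; since column z-scoring is invariant
#' to row permutation, permuting the z-scored block is equivalent to
#' re-preprocessing the permuted raw block. The per-component p-value uses
#' the add-one estimator p = (1 + #\{perm d >= observed d\}) / (1 + n_perm).
#'
#' @param Xz,Yz Preprocessed blocks.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @return Numeric vector of p-values, one per component.
#' @export
plsc_permutation <- function(Xz, Yz, n_perm = 1000, seed = 1) {
  if (n_perm < 100)
    stop_fm("n_perm must be >= 100 for a stable p-value (got %d)", n_perm)
  Xz <- as.matrix(Xz); Yz <- as.matrix(Yz)
  obs <- svd_cross_cov(Xz, Yz)$d
  n <- nrow(Yz)
  exceed <- numeric(length(obs))
  with_seed(sub_seed(seed, "plsc_perm"), {
    for (b in seq_len(n_perm)) {
      dperm <- svd(crossprod(Yz[sample.int(n), , drop = FALSE], Xz),
                   nu = 0, nv = 0)$d
      exceed <- exceed + (dperm >= obs)
    }
  })
  (1 + exceed) / (1 + n_perm)
}

#' Bootstrap stability ratios for salience elements
#'
#' Subjects are resampled with replacement; each resample is re-standardized
#' and re-decomposed, components are sign-aligned to the original model by
#' the inner product of their saliences, and the elementwise bootstrap SE is
#' formed. BSR = original salience / bootstrap SE; elements with
#' `|BSR| >= threshold` are flagged stable. Resamples producing a constant
#' column are redrawn (counted in a warning).
#'
#' @param X,Y Raw (unstandardized) blocks.
#' @param n_boot Number of bootstrap resamples (>= 100; default 500).
#' @param seed Integer seed.
#' @param threshold Stability threshold on |BSR| (default 2).
#' @return List with `bsr_img`, `bsr_beh`, `stable_img`, `stable_beh`,
#'   `se_img`, `se_beh`, `n_redrawn`.
#' @export
plsc_bootstrap <- function(X, Y, n_boot = 500, seed = 1, threshold = 2) {
  if (n_boot < 100)
    stop_fm("n_boot must be >= 100 for stable standard errors (got %d)", n_boot)
  X <- as.matrix(X); Y <- as.matrix(Y)
  pre <- plsc_preprocess(X, Y)
  orig <- fit_plsc(pre$Xz, pre$Yz)
  k <- length(orig$singular_values)
  n <- nrow(X)
  Vs <- array(NA_real_, c(nrow(orig$V), k, n_boot))
  Us <- array(NA_real_, c(nrow(orig$U), k, n_boot))
  n_redrawn <- 0
  with_seed(sub_seed(seed, "plsc_boot"), {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        ok <- all(apply(X[idx, , drop = FALSE], 2, sd) > 0) &&
          all(apply(Y[idx, , drop = FALSE], 2, sd) > 0)
        if (ok) break
        n_redrawn <- n_redrawn + 1
      }
      preb <- plsc_preprocess(X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
      dec <- svd_cross_cov(preb$Xz, preb$Yz)
      for (l in seq_len(k)) {
        s <- sign(sum(dec$V[, l] * orig$V[, l]) + sum(dec$U[, l] * orig$U[, l]))
        if (s == 0) s <- 1
        Vs[, l, b] <- s * dec$V[, l]
        Us[, l, b] <- s * dec$U[, l]
      }
    }
  })
  if (n_redrawn > 0)
    warning(sprintf("%d bootstrap resample(s) redrawn due to constant columns",
                    n_redrawn), call. = FALSE)
  se_img <- apply(Vs, c(1, 2), sd)
  se_beh <- apply(Us, c(1, 2), sd)
  bsr_img <- orig$V / se_img
  bsr_beh <- orig$U / se_beh
  dimnames(bsr_img) <- dimnames(orig$V)
  dimnames(bsr_beh) <- dimnames(orig$U)
  list(bsr_img = bsr_img, bsr_beh = bsr_beh,
       stable_img = abs(bsr_img) >= threshold,
       stable_beh = abs(bsr_beh) >= threshold,
       se_img = se_img, se_beh = se_beh, n_redrawn = n_redrawn)
}

#' Composite scores and loadings
#'
#' Scores project each block onto its saliences (`scores_img = Xz V`,
#' `scores_beh = Yz U`); loadings are the Pearson correlations between each
#' raw column and the corresponding score column.
#'
#' @param model A fitted `plsc_model`.
#' @param Xz,Yz Preprocessed blocks used in the fit.
#' @param X_raw,Y_raw Raw blocks for the loading correlations (default: the
#'   preprocessed blocks, which give identical correlations up to scaling).
#' @return The model, completed with `scores_img`, `scores_beh`,
#'   `loadings_img`, `loadings_beh`.
#' @export
plsc_scores_loadings <- function(model, Xz, Yz, X_raw = Xz, Y_raw = Yz) {
  stopifnot(inherits(model, "plsc_model"))
  Xz <- as.matrix(Xz); Yz <- as.matrix(Yz)
  model$scores_img <- Xz %*% model$V
  model$scores_beh <- Yz %*% model$U
  model$loadings_img <- cor(as.matrix(X_raw), model$scores_img)
  model$loadings_beh <- cor(as.matrix(Y_raw), model$scores_beh)
  model
}

#' Full behavioral PLSC analysis
#'
#' Preprocessing, decomposition, permutation significance, bootstrap
#' stability, scores and loadings in one call.
#'
#' @param X Imaging block (subjects x features).
#' @param Y Behavioral block (subjects x measures).
#' @param n_perm Number of permutations (default 1000).
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param bsr_threshold Stability threshold on |BSR| (default 2).
#' @param seed Integer seed for both resampling schemes.
#' @return A completed `plsc_model` with `perm_p`, `bsr_img`, `bsr_beh`,
#'   `stable_img`, `stable_beh`, scores and loadings.
#' @export
plsc <- function(X, Y, n_perm = 1000, n_boot = 500, bsr_threshold = 2,
                 seed = 1) {
  pre <- plsc_preprocess(X, Y)
  model <- fit_plsc(pre$Xz, pre$Yz)
  model$perm_p <- plsc_permutation(pre$Xz, pre$Yz, n_perm = n_perm,
                                   seed = seed)
  bs <- plsc_bootstrap(X, Y, n_boot = n_boot, seed = seed,
                       threshold = bsr_threshold)
  model[names(bs)] <- bs
  model$bsr_threshold <- bsr_threshold
  plsc_scores_loadings(model, pre$Xz, pre$Yz, as.matrix(X), as.matrix(Y))
}
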