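# Balance and neuropsychological group statistics.
#
# cop_displacement() implements the posturography statistic: per-trial
# epoching at the perturbation onset, zero-phase low-pass filtering (10 Hz),
# linear detrending, sample-wise averaging across trials, then the cumulative
# absolute anterior/posterior displacement over the first 2 s of the epoch.
#
# Between-group comparisons use the Welch t statistic with Satterthwaite
# degrees of freedom computed from group summary statistics, alongside the
# pooled-SD standardized mean difference (Cohen's d). Both operate on
# summaries so that printed group tables can be re-analyzed directly.

# --- zero-phase Butterworth low-pass ---------------------------------------

#' Butterworth low-pass filter coefficients
#'
#' Classic analog Butterworth prototype mapped with the bilinear transform
#' (frequency prewarped), unity DC gain.
#'
#' @param cutoff_hz -3 dB cutoff frequency.
#' @param fs Sampling rate, Hz; requires `cutoff_hz < fs / 2`.
#' @param order Filter order (default 4).
#' @return List with numerator `b` and denominator `a` (length `order + 1`,
#'   `a[1] = 1`).
#' @export
butter_lowpass <- function(cutoff_hz, fs, order = 4) {
  stopifnot(cutoff_hz > 0, fs > 0, is_count(order))
  if (cutoff_hz >= fs / 2)
    stop_fm("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
            cutoff_hz, fs / 2)
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  k <- seq_len(order)
  poles_s <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  poles_z <- (2 * fs + poles_s) / (2 * fs - poles_s)
  poly_from_roots <- function(r) {
    p <- 1
    for (root in r) p <- c(p, 0) - c(0, p * root)
    p
  }
  a <- Re(poly_from_roots(poles_z))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  gain <- sum(a) / sum(b)  # H(z=1) = 1
  list(b = b * gain, a = a)
}

lfilter_zi <- function(b, a) {
  # steady-state initial conditions for a step input (direct form II
  # transposed), so filtfilt is transient-free on constant extensions
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  if (n == 1) return(numeric(0))
  A <- rbind(-a[-1], cbind(diag(1, n - 2, n - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(A), B)
}

#' Zero-phase filtering (forward-backward)
#'
#' Applies the filter forward and backward with odd-reflection edge padding
#' and steady-state initial conditions, giving zero phase distortion and a
#' squared magnitude response. Straight lines pass through unchanged (up to
#' numerical tolerance).
#'
#' @param coef List with `b` and `a`, e.g. from [butter_lowpass()].
#' @param x Numeric signal.
#' @return Filtered signal of the same length.
#' @export
filtfilt_fm <- function(coef, x) {
  b <- coef$b; a <- coef$a
  nord <- max(length(a), length(b)) - 1
  padlen <- min(3 * nord, length(x) - 1)
  if (length(x) <= padlen)
    stop_fm("signal too short (%d samples) for the filter order", length(x))
  ext <- c(2 * x[1] - x[(padlen + 1):2], x,
           2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter_cpp(b, a, ext, zi * ext[1])
  y <- rev(lfilter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + length(x))]
}

detrend_linear <- function(x) {
  t <- seq_along(x)
  tc <- t - mean(t)
  x - mean(x) - tc * sum(tc * x) / sum(tc^2)
}

# --- COP displacement ------------------------------------------------------

#' Center-of-pressure displacement after a platform perturbation
#'
#' For each trial: extract the epoch starting at the perturbation onset,
#' low-pass filter (zero-phase Butterworth), remove the least-squares linear
#' trend; then average the processed epochs sample-wise across trials and sum
#' the absolute consecutive differences over the first `window_s` seconds.
#' The statistic is invariant to constant offsets and to linear drift within
#' each trial.
#'
#' @param trials List of `cop_trial` objects sharing one sampling rate.
#' @param cutoff_hz Low-pass cutoff (default 10 Hz).
#' @param window_s Path-length window from the onset (default 2 s).
#' @param epoch_s Epoch length from the onset used for filtering/detrending
#'   (default 4 s, the full two-cycle perturbation); must be >= `window_s`
#'   and fit within every trial.
#' @param filter_order Butterworth order (default 4).
#' @return Cumulative displacement in the trace units (cm), a single number.
#' @export
cop_displacement <- function(trials, cutoff_hz = 10, window_s = 2,
                             epoch_s = 4, filter_order = 4) {
  if (inherits(trials, "cop_trial")) trials <- list(trials)
  stopifnot(length(trials) >= 1)
  if (!all(vapply(trials, inherits, logical(1), "cop_trial")))
    stop_fm("trials must be cop_trial objects")
  fs <- vapply(trials, function(t) t$sampling_rate_hz, numeric(1))
  if (length(unique(fs)) != 1)
    stop_fm("mixed sampling rates across trials: %s",
            paste(unique(fs), collapse = ", "))
  fs <- fs[1]
  if (window_s > epoch_s)
    stop_fm("window_s (%g) exceeds epoch_s (%g)", window_s, epoch_s)
  n_ep <- round(epoch_s * fs) + 1
  coef <- butter_lowpass(cutoff_hz, fs, filter_order)
  epochs <- lapply(trials, function(tr) {
    last <- tr$onset_index + n_ep - 1
    if (last > length(tr$samples))
      stop_fm("epoch of %gs does not fit after the onset (trial has %g s left)",
              epoch_s, (length(tr$samples) - tr$onset_index) / fs)
    ep <- tr$samples[tr$onset_index:last]
    detrend_linear(filtfilt_fm(coef, ep))
  })
  avg <- Reduce(`+`, epochs) / length(epochs)
  n_win <- round(window_s * fs) + 1
  sum(abs(diff(avg[seq_len(min(n_win, length(avg)))])))
}

# --- group statistics ------------------------------------------------------

#' Welch two-sample t test from summary statistics
#'
#' Two-tailed; degrees of freedom by the Satterthwaite approximation. The
#' statistic is oriented as group 2 minus group 1.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A `group_stats` list with `t`, `df`, `p`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  if (v1 + v2 == 0)
    stop_fm("undefined statistic: both group SDs are zero")
  tstat <- (mean2 - mean1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  structure(list(t = tstat, df = df, p = max(p, .Machine$double.xmin)),
            class = "group_stats")
}

#' Pooled-SD standardized mean difference (Cohen's d)
#'
#' `(mean2 - mean1) / s_pooled`, pooling variances with `n - 1` weights.
#'
#' @inheritParams welch_t
#' @return A single number.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop_fm("undefined statistic: pooled SD is zero")
  (mean2 - mean1) / sp
}

#' Printed group summary table of the behavioral measures
#'
#' The per-group mean, SD and size of the five behavioral measures (8
#' controls, 10 patients) as printed in the study's demographic table, for
#' summary-statistic re-analysis.
#'
#' @return Data frame with columns `measure`, `mean_hc`, `sd_hc`, `n_hc`,
#'   `mean_tbi`, `sd_tbi`, `n_tbi`.
#' @export
table1_behavior_summary <- function() {
  data.frame(
    measure  = c("BBS", "COP", "TMT", "SDMT", "SCWT"),
    mean_hc  = c(56, 8.7, 41.8, 36.4, 38.9),
    sd_hc    = c(0, 2.6, 21.1, 7.8, 8.1),
    n_hc     = 8L,
    mean_tbi = c(50.2, 10.6, 41.6, 32.7, 53.1),
    sd_tbi   = c(5.6, 3.9, 6.2, 5.9, 10.6),
    n_tbi    = 10L,
    stringsAsFactors = FALSE)
}

group_stats_row <- function(measure, mean_hc, sd_hc, n_hc, mean_tbi, sd_tbi,
                            n_tbi) {
  w <- welch_t(mean_hc, sd_hc, n_hc, mean_tbi, sd_tbi, n_tbi)
  d <- tryCatch(cohens_d(mean_hc, sd_hc, n_hc, mean_tbi, sd_tbi, n_tbi),
                error = function(e) NA_real_)
  data.frame(measure = measure, mean_hc = mean_hc, sd_hc = sd_hc, n_hc = n_hc,
             mean_tbi = mean_tbi, sd_tbi = sd_tbi, n_tbi = n_tbi,
             t = w$t, df = w$df, p = w$p, d = d, stringsAsFactors = FALSE)
}

#' Between-group comparison of every behavioral measure
#'
#' Welch t test and pooled-SD standardized mean difference per measure, in
#' the fixed orientation TBI minus HC. Accepts either a `cohort_matrices`
#' object (per-group summaries are computed from the behavioral block) or a
#' summary data frame in the layout of [table1_behavior_summary()]. The five
#' tests are reported uncorrected.
#'
#' @param x A `cohort_matrices` object or summary data frame.
#' @return Data frame, one row per measure, with summary statistics, `t`,
#'   `df`, `p` and `d`.
#' @export
compare_groups <- function(x) {
  if (inherits(x, "cohort_matrices")) {
    groups <- levels(droplevels(x$group))
    if (length(unique(x$group)) != 2)
      stop_fm("need exactly two groups, got: %s",
              paste(unique(x$group), collapse = ", "))
    if (any(table(x$group) < 2))
      stop_fm("each group needs at least 2 subjects")
    hc <- x$Y[x$group == "HC", , drop = FALSE]
    tb <- x$Y[x$group == "TBI", , drop = FALSE]
    summ <- data.frame(
      measure = x$measure_names,
      mean_hc = colMeans(hc), sd_hc = apply(hc, 2, sd), n_hc = nrow(hc),
      mean_tbi = colMeans(tb), sd_tbi = apply(tb, 2, sd), n_tbi = nrow(tb),
      stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    need <- c("measure", "mean_hc", "sd_hc", "n_hc", "mean_tbi", "sd_tbi",
              "n_tbi")
    miss <- setdiff(need, names(x))
    if (length(miss) > 0)
      stop_fm("summary table is missing column(s): %s",
              paste(miss, collapse = ", "))
    summ <- x
  } else {
    stop_fm("x must be a cohort_matrices object or a summary data frame")
  }
  out <- do.call(rbind, lapply(seq_len(nrow(summ)), function(i)
    group_stats_row(summ$measure[i], summ$mean_hc[i], summ$sd_hc[i],
                    summ$n_hc[i], summ$mean_tbi[i], summ$sd_tbi[i],
                    summ$n_tbi[i])))
  rownames(out) <- NULL
  out
}
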