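# Synthetic center-of-pressure traces for platform-perturbation trials:
# a 0.5 Hz two-cycle sinusoidal response riding on an optional linear drift
# plus Gaussian measurement noise, with the perturbation onset recorded.

#' Specify a synthetic COP trace
#'
#' Defaults mirror the high-amplitude posterior perturbation protocol: a
#' 0.5 Hz sinusoid lasting two cycles (4 s) with 2 cm amplitude, sampled at
#' 100 Hz within a 6 s trial (1 s of quiet stance before onset).
#'
#' @param duration_s Trial length in seconds.
#' @param sampling_rate_hz Sampling rate (>= 50 Hz so a 10 Hz low-pass is
#'   meaningful).
#' @param perturb_onset_s Perturbation onset time, seconds from trial start.
#' @param perturb_freq_hz Sinusoid frequency (default 0.5 Hz).
#' @param n_cycles Number of sinusoid cycles (default 2).
#' @param amplitude Sinusoid amplitude, cm.
#' @param drift_slope Linear drift, cm per second.
#' @param noise_sd Gaussian noise SD, cm (0 for a noiseless trace).
#' @param seed Integer seed for the noise stream.
#' @return A `cop_trace_spec` list.
#' @export
cop_trace_spec <- function(duration_s = 6, sampling_rate_hz = 100,
                           perturb_onset_s = 1, perturb_freq_hz = 0.5,
                           n_cycles = 2, amplitude = 2, drift_slope = 0,
                           noise_sd = 0.05, seed = 1) {
  stopifnot(duration_s > 0, sampling_rate_hz > 0, perturb_onset_s >= 0,
            perturb_freq_hz > 0, is_count(n_cycles), amplitude >= 0,
            noise_sd >= 0)
  if (sampling_rate_hz < 50)
    stop_fm("sampling_rate_hz must be >= 50 (got %g)", sampling_rate_hz)
  if (perturb_onset_s + n_cycles / perturb_freq_hz > duration_s)
    stop_fm("perturbation (onset %gs + %g cycles at %g Hz) does not fit in %gs",
            perturb_onset_s, n_cycles, perturb_freq_hz, duration_s)
  structure(list(duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
                 perturb_onset_s = perturb_onset_s,
                 perturb_freq_hz = perturb_freq_hz,
                 n_cycles = as.integer(n_cycles), amplitude = amplitude,
                 drift_slope = drift_slope, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cop_trace_spec")
}

#' Construct a COP trial from samples
#'
#' @param samples Numeric COP positions, cm.
#' @param sampling_rate_hz Sampling rate, Hz (>= 50).
#' @param onset_index 1-based sample index of the perturbation onset; at
#'   least 2 s of samples must remain from the onset.
#' @return A `cop_trial` object.
#' @export
cop_trial <- function(samples, sampling_rate_hz, onset_index = 1L) {
  stopifnot(is.numeric(samples), length(samples) > 1, sampling_rate_hz >= 50,
            is_count(onset_index))
  if (onset_index + round(2 * sampling_rate_hz) > length(samples))
    stop_fm("trial too short: onset at sample %d leaves < 2 s of data",
            onset_index)
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 onset_index = as.integer(onset_index)),
            class = "cop_trial")
}

#' Generate a synthetic COP trial
#'
#' The trace is `drift_slope * t + response + noise`, where the response is
#' `amplitude * sin(2 pi f (t - onset))` on the perturbation window and 0
#' elsewhere.
#'
#' @param spec A [cop_trace_spec()].
#' @return A `cop_trial`.
#' @export
make_cop_trace <- function(spec) {
  stopifnot(inherits(spec, "cop_trace_spec"))
  fs <- spec$sampling_rate_hz
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  onset <- spec$perturb_onset_s
  stop_t <- onset + spec$n_cycles / spec$perturb_freq_hz
  resp <- ifelse(t >= onset & t <= stop_t,
                 spec$amplitude * sin(2 * pi * spec$perturb_freq_hz * (t - onset)),
                 0)
  noise <- if (spec$noise_sd > 0)
    with_seed(sub_seed(spec$seed, "cop"), rnorm(n, sd = spec$noise_sd))
  else numeric(n)
  cop_trial(spec$drift_slope * t + resp + noise, fs,
            onset_index = as.integer(round(onset * fs)) + 1L)
}

#' Write a COP trial to CSV
#'
#' Columns `time_s`, `cop`; the sampling rate and onset index are stored in
#' `#`-comment header lines so the file is self-describing.
#'
#' @param trial A `cop_trial`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cop_csv <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz=%.10g", trial$sampling_rate_hz),
               sprintf("# onset_index=%d", trial$onset_index)), con)
  write.csv(data.frame(time_s = (seq_along(trial$samples) - 1) /
                         trial$sampling_rate_hz,
                       cop = trial$samples),
            con, row.names = FALSE)
  invisible(path)
}

#' Read a COP trial from CSV
#'
#' @param path CSV as written by [write_cop_csv()]. If the comment header is
#'   absent, the sampling rate is inferred from the `time_s` column and the
#'   onset defaults to the first sample.
#' @return A `cop_trial`.
#' @export
read_cop_csv <- function(path) {
  hdr <- readLines(path, n = 5)
  meta <- grep("^#", hdr, value = TRUE)
  get_meta <- function(key, default) {
    m <- grep(paste0("^# *", key, "="), meta, value = TRUE)
    if (length(m) == 0) return(default)
    as.numeric(sub(paste0("^# *", key, "="), "", m[1]))
  }
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_s", "cop") %in% names(df)))
    stop_fm("COP CSV must have columns time_s, cop: %s", path)
  fs_inferred <- 1 / stats::median(diff(df$time_s))
  fs <- get_meta("sampling_rate_hz", fs_inferred)
  onset <- as.integer(get_meta("onset_index", 1))
  cop_trial(df$cop, fs, onset)
}
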