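#' Platform perturbation parameters
#'
#' Parameter set for a single transient horizontal translation of the
#' support surface. Defaults describe the stimulus used throughout the
#' package: a 3 cm translation completed in 210 ms, delivered at
#' inter-trial intervals of 4-8 s. Posterior translations are negative
#' by convention, anterior positive.
#'
#' Trial-to-trial variability defaults reflect a well-servoed platform:
#' the commanded amplitude is reproduced essentially exactly while the
#' realized rise time jitters by a few milliseconds.
#'
#' @param amplitude_cm translation amplitude in cm (> 0).
#' @param duration_ms rise time of the translation in ms (> 0).
#' @param direction `"posterior"` or `"anterior"`.
#' @param iti_range_s length-2 inter-trial interval range in seconds.
#' @param onset_jitter_sd_ms SD of the onset-time jitter in ms.
#' @param duration_sd_ms trial-to-trial SD of the realized rise time.
#' @param sensor_noise_sd_cm SD of additive potentiometer noise in cm.
#' @return an object of class `ps_platform_params`.
#' @export
platform_params <- function(amplitude_cm = 3, duration_ms = 210,
                            direction = "posterior",
                            iti_range_s = c(4, 8),
                            onset_jitter_sd_ms = 10,
                            duration_sd_ms = 3,
                            sensor_noise_sd_cm = 0.01) {
  check_scalar_num(amplitude_cm, "amplitude_cm", positive = TRUE)
  check_scalar_num(duration_ms, "duration_ms", positive = TRUE)
  direction <- match_direction(direction)
  if (length(iti_range_s) != 2L || any(iti_range_s <= 0) ||
      iti_range_s[1] > iti_range_s[2])
    abort_ps("`iti_range_s` must be an ordered positive pair",
             "ps_invalid_parameter")
  check_scalar_num(onset_jitter_sd_ms, "onset_jitter_sd_ms", min = 0)
  check_scalar_num(duration_sd_ms, "duration_sd_ms", min = 0)
  check_scalar_num(sensor_noise_sd_cm, "sensor_noise_sd_cm", min = 0)
  structure(list(amplitude_cm = amplitude_cm, duration_ms = duration_ms,
                 direction = direction, iti_range_s = as.numeric(iti_range_s),
                 onset_jitter_sd_ms = onset_jitter_sd_ms,
                 duration_sd_ms = duration_sd_ms,
                 sensor_noise_sd_cm = sensor_noise_sd_cm),
            class = "ps_platform_params")
}

# Smoothed-trapezoid (raised-cosine ramp) displacement profile, unit
# amplitude, rising over `duration_ms`, then holding.
platform_profile <- function(t_ms, duration_ms) {
  s <- pmin(pmax(t_ms / duration_ms, 0), 1)
  0.5 * (1 - cos(pi * s))
}

#' Generate one platform potentiometer trace
#'
#' Synthesizes the displacement trace of a single support-surface
#' translation: a raised-cosine ramp of total excursion `amplitude_cm`
#' completed within `duration_ms`, signed by direction (posterior
#' negative), held thereafter, with additive potentiometer noise.
#'
#' @param params a [platform_params()] object.
#' @param sample_rate sampling rate in Hz (>= 100).
#' @param n_samples total trace length in samples.
#' @param onset_sample 1-based sample index of perturbation onset.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param noise logical; set `FALSE` for a noise-free commanded profile.
#' @return list with `displacement_cm` (numeric vector), `onset_sample`,
#'   `amplitude_cm` and `duration_ms` actually realized (truth values).
#' @export
generate_platform_trajectory <- function(params, sample_rate = 1000,
                                         n_samples = 1000, onset_sample = 201,
                                         seed = NULL, noise = TRUE) {
  stopifnot(inherits(params, "ps_platform_params"))
  check_scalar_num(sample_rate, "sample_rate", min = 100)
  if (!is.null(seed)) set.seed(seed)
  sign <- if (params$direction == "posterior") -1 else 1
  dur <- params$duration_ms
  amp <- params$amplitude_cm
  if (noise && params$duration_sd_ms > 0)
    dur <- max(10, dur + stats::rnorm(1, 0, params$duration_sd_ms))
  t_ms <- (seq_len(n_samples) - onset_sample) * 1000 / sample_rate
  x <- sign * amp * platform_profile(t_ms, dur)
  if (noise && params$sensor_noise_sd_cm > 0)
    x <- x + stats::rnorm(n_samples, 0, params$sensor_noise_sd_cm)
  list(displacement_cm = x, onset_sample = onset_sample,
       amplitude_cm = amp, duration_ms = dur)
}

#' Generate a continuous multi-perturbation potentiometer recording
#'
#' Concatenates `n_trials` translations separated by inter-trial
#' intervals drawn uniformly from the configured range, with Gaussian
#' onset jitter, into one continuous trace, and returns the true onset
#' sample indices for use as a detection oracle.
#'
#' @param params a [platform_params()] object.
#' @param n_trials number of perturbations.
#' @param sample_rate sampling rate in Hz.
#' @param seed integer seed.
#' @param noise logical, as in [generate_platform_trajectory()].
#' @return list with `displacement_cm`, `sample_rate`, `onset_samples`
#'   (true onsets) and per-trial truth (`amplitude_cm`, `duration_ms`).
#' @export
generate_platform_recording <- function(params, n_trials, sample_rate = 1000,
                                        seed = NULL, noise = TRUE) {
  stopifnot(inherits(params, "ps_platform_params"))
  check_scalar_num(n_trials, "n_trials", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  itis <- stats::runif(n_trials, params$iti_range_s[1], params$iti_range_s[2])
  if (noise && params$onset_jitter_sd_ms > 0)
    itis <- itis + stats::rnorm(n_trials, 0, params$onset_jitter_sd_ms) / 1000
  onsets <- as.integer(round(cumsum(pmax(itis, 1.5)) * sample_rate))
  n <- onsets[n_trials] + as.integer(2 * sample_rate)
  x <- numeric(n)
  amps <- durs <- numeric(n_trials)
  sign <- if (params$direction == "posterior") -1 else 1
  for (k in seq_len(n_trials)) {
    dur <- params$duration_ms
    if (noise && params$duration_sd_ms > 0)
      dur <- max(10, dur + stats::rnorm(1, 0, params$duration_sd_ms))
    amps[k] <- params$amplitude_cm
    durs[k] <- dur
    # each translation returns to baseline well before the next onset,
    # via a slow raised-cosine return starting 1 s after onset
    t_ms <- (seq_len(n) - onsets[k]) * 1000 / sample_rate
    pulse <- platform_profile(t_ms, dur) * (1 - platform_profile(t_ms - 1000, 800))
    x <- x + sign * params$amplitude_cm * pulse
  }
  if (noise && params$sensor_noise_sd_cm > 0)
    x <- x + stats::rnorm(n, 0, params$sensor_noise_sd_cm)
  list(displacement_cm = x, sample_rate = sample_rate,
       onset_samples = onsets, amplitude_cm = amps, duration_ms = durs)
}

#' Characterize one detected platform translation
#'
#' Re-estimates amplitude, rise duration and mean velocity of a detected
#' translation from a potentiometer trace, mirroring how the commanded
#' stimulus is verified against the recorded trajectory.
#'
#' Amplitude is the plateau median (window 1.25-1.75 x nominal duration
#' after onset) minus the pre-onset baseline median; duration is the
#' time from 5% to 95% of that excursion; mean velocity is amplitude
#' divided by duration.
#'
#' @param trace potentiometer displacement vector (cm).
#' @param sample_rate Hz.
#' @param onset_sample detected onset (1-based).
#' @param nominal_duration_ms rise time used to place the plateau window.
#' @return list with `amplitude_cm` (signed), `duration_ms`,
#'   `mean_velocity_m_s`, `peak_acceleration_m_s2`.
#' @export
platform_metrics <- function(trace, sample_rate, onset_sample,
                             nominal_duration_ms = 210) {
  n <- length(trace)
  i_base <- max(1, onset_sample - as.integer(0.08 * sample_rate)):max(1, onset_sample - 1)
  w0 <- onset_sample + as.integer(1.25 * nominal_duration_ms * sample_rate / 1000)
  w1 <- onset_sample + as.integer(1.75 * nominal_duration_ms * sample_rate / 1000)
  if (w1 > n) abort_ps("trace too short after onset for characterization",
                       "ps_bounds_error")
  base <- stats::median(trace[i_base])
  plat <- stats::median(trace[w0:w1])
  amp <- plat - base
  dev <- trace[onset_sample:w1] - base
  frac <- dev / amp
  i05 <- which(frac >= 0.05)[1]
  i95 <- which(frac >= 0.95)[1]
  # 5-95% rise time, rescaled to the full ramp assuming smooth
  # (raised-cosine) kinematics: that shape spends 71.28% of its
  # duration between the 5% and 95% levels
  dur_ms <- if (is.na(i05) || is.na(i95)) NA_real_ else
    (i95 - i05) * 1000 / sample_rate / 0.7128
  vel <- if (is.na(dur_ms) || dur_ms <= 0) NA_real_ else
    abs(amp) / 100 / (dur_ms / 1000)
  # wide-step central differences (10 ms) keep sensor noise from
  # swamping the second derivative
  h <- max(1L, as.integer(0.01 * sample_rate))
  seg <- trace[max(1, onset_sample - 5 * h):w1] / 100  # m
  k <- seq_len(length(seg) - 2 * h) + h
  v <- (seg[k + h] - seg[k - h]) / (2 * h / sample_rate)
  kk <- seq_len(length(v) - 2 * h) + h
  acc <- (v[kk + h] - v[kk - h]) / (2 * h / sample_rate)
  list(amplitude_cm = amp, duration_ms = dur_ms, mean_velocity_m_s = vel,
       peak_acceleration_m_s2 = max(abs(acc), na.rm = TRUE))
}
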