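# Synthetic surface-EMG model.
#
# Background EMG is modelled as band-limited (10-500 Hz at 1 kHz)
# Gaussian noise whose time-varying envelope sigma(t) encodes muscle
# activation: the expected rectified amplitude of N(0, sigma^2) noise is
# sigma * sqrt(2/pi), so any target mean rectified amplitude profile is
# realized exactly in expectation. Reflex bursts are Gaussian envelope
# bumps centred on the subject's reflex-peak latencies; the belated
# response is a smoothed plateau running from 120 ms to the trial's COP
# peak. Evoked potentials (M-wave, H-reflex) are biphasic Gabor wavelets
# added to the soleus channel.

#' Band-limited Gaussian noise
#'
#' White Gaussian noise restricted to `band` by hard FFT masking and
#' rescaled to unit variance. Used as the carrier for all synthetic EMG.
#'
#' @param n number of samples.
#' @param sr sampling rate in Hz.
#' @param band length-2 passband in Hz.
#' @return numeric vector, approximately unit variance.
#' @keywords internal
bandlimited_noise <- function(n, sr, band = c(10, 500)) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * sr / n
  f <- pmin(f, sr - f)  # two-sided frequency axis
  keep <- f >= band[1] & f <= min(band[2], sr / 2)
  X <- stats::fft(x)
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Reflex burst specification
#'
#' @param phase_label one of `"SLR"`, `"MLR"`, `"LLR"`, `"BMR"`.
#' @param center_latency_ms burst centre in ms after perturbation onset;
#'   must lie inside the phase's analysis window.
#' @param width_ms Gaussian SD of the burst envelope (> 0); for BMR,
#'   the raised-cosine edge length of the plateau.
#' @param gain dimensionless envelope gain (>= 0); used when bursts are
#'   specified relative to background rather than via amplitude targets.
#' @return a `ps_burst_spec` list.
#' @export
reflex_burst_spec <- function(phase_label, center_latency_ms, width_ms,
                              gain = 1) {
  phase_label <- match.arg(phase_label, c("SLR", "MLR", "LLR", "BMR"))
  win <- switch(phase_label, SLR = c(30, 60), MLR = c(60, 85),
                LLR = c(85, 120), BMR = c(120, 500))
  check_scalar_num(center_latency_ms, "center_latency_ms",
                   min = win[1], max = win[2])
  check_scalar_num(width_ms, "width_ms", positive = TRUE)
  check_scalar_num(gain, "gain", min = 0)
  structure(list(phase_label = phase_label,
                 center_latency_ms = center_latency_ms,
                 width_ms = width_ms, gain = gain),
            class = "ps_burst_spec")
}

#' @keywords internal
default_burst_latencies <- function() c(SLR = 45, MLR = 72, LLR = 100)

#' @keywords internal
default_burst_widths <- function() c(SLR = 7, MLR = 6, LLR = 9, BMR = 20)

# Unit envelopes for the four post-perturbation components, evaluated on
# the epoch time axis (ms relative to onset).
burst_envelopes <- function(t_ms, latencies = default_burst_latencies(),
                            widths = default_burst_widths(),
                            bmr_end_ms = 344) {
  env <- cbind(
    SLR = exp(-0.5 * ((t_ms - latencies["SLR"]) / widths["SLR"])^2),
    MLR = exp(-0.5 * ((t_ms - latencies["MLR"]) / widths["MLR"])^2),
    LLR = exp(-0.5 * ((t_ms - latencies["LLR"]) / widths["LLR"])^2),
    BMR = platform_profile(t_ms - 120, widths["BMR"]) *
      (1 - platform_profile(t_ms - bmr_end_ms, widths["BMR"] * 4))
  )
  colnames(env) <- c("SLR", "MLR", "LLR", "BMR")
  env
}

# Solve for component amplitudes so that the mean rectified amplitude of
# the synthesized EMG over each analysis window equals `target_amp_mv`
# (named: PRE, SLR, MLR, LLR, BMR). Returns the amplitude profile m(t)
# in mV on the epoch axis.
amplitude_profile <- function(t_ms, target_amp_mv, latencies, widths,
                              bmr_end_ms) {
  env <- burst_envelopes(t_ms, latencies, widths, bmr_end_ms)
  wins <- list(SLR = c(30, 60), MLR = c(60, 85), LLR = c(85, 120),
               BMR = c(120, bmr_end_ms))
  pre <- target_amp_mv[["PRE"]]
  M <- matrix(0, 4, 4, dimnames = list(names(wins), colnames(env)))
  b <- numeric(4)
  for (w in seq_along(wins)) {
    sel <- t_ms >= wins[[w]][1] & t_ms < wins[[w]][2]
    M[w, ] <- colMeans(env[sel, , drop = FALSE])
    b[w] <- target_amp_mv[[names(wins)[w]]] - pre
  }
  a <- tryCatch(solve(M, b), error = function(e) rep(0, 4))
  m <- pre + as.numeric(env %*% a)
  pmax(m, 0)
}

#' Biphasic Gabor wavelet with calibrated peak-to-peak amplitude
#'
#' @param t_ms epoch time axis (ms).
#' @param center_ms wavelet centre.
#' @param sigma_ms Gaussian envelope SD.
#' @param freq_hz carrier frequency.
#' @param p2p_mv desired peak-to-peak amplitude; the wavelet is scaled
#'   so its realized max - min equals this exactly on the given axis.
#' @return numeric vector on `t_ms`.
#' @keywords internal
gabor_wave <- function(t_ms, center_ms, sigma_ms, freq_hz, p2p_mv) {
  w <- exp(-0.5 * ((t_ms - center_ms) / sigma_ms)^2) *
    sin(2 * pi * freq_hz * (t_ms - center_ms) / 1000)
  span <- max(w) - min(w)
  if (span <= 0) return(w * 0)
  w * (p2p_mv / span)
}

#' Generate one multichannel EMG trial epoch
#'
#' Synthesizes the six EMG channels (SOL, MG, TA, RF, BF, GMAX) of a
#' single perturbation trial on a 1 kHz epoch grid. Per-muscle activation
#' is specified as the target mean rectified amplitude (mV) in each of
#' the five analysis windows; the generator calibrates its envelopes so
#' these targets hold in expectation. If `stim_phase != "none"`, a
#' stimulation artifact, an M-wave and a biphasic H-reflex are inserted
#' into the SOL channel at physiologically ordered latencies after the
#' stimulus (artifact < M < H).
#'
#' @param condition `"predicted"`, `"unpredicted"` or `"cheated"`.
#' @param direction `"posterior"` or `"anterior"`.
#' @param stim_phase `"none"`, `"SLR"`, `"MLR"` or `"LLR"`.
#' @param target_amp_mv muscles x phases matrix (rownames SOL..GMAX,
#'   colnames PRE..BMR) of target mean rectified amplitudes in mV.
#' @param latencies named reflex-peak latencies (ms), default 45/72/100.
#' @param bmr_end_ms end of the belated-response window (the trial's COP
#'   peak latency).
#' @param h_p2p_mv H-reflex peak-to-peak amplitude to insert (mV).
#' @param m_p2p_mv M-wave peak-to-peak amplitude to insert (mV).
#' @param n_samples epoch length in samples at `sr`.
#' @param onset_sample 1-based index of perturbation onset.
#' @param sr sampling rate (Hz).
#' @param seed optional integer seed.
#' @return list: `emg` (n_samples x 6 matrix, mV), `truth` (list with
#'   stim time, inserted amplitudes, amplitude profiles).
#' @export
generate_emg_trial <- function(condition, direction, stim_phase,
                               target_amp_mv,
                               latencies = default_burst_latencies(),
                               bmr_end_ms = 344,
                               h_p2p_mv = 2, m_p2p_mv = 1,
                               n_samples = 1000, onset_sample = 201,
                               sr = 1000, seed = NULL) {
  condition <- match_condition(condition)
  direction <- match_direction(direction)
  stim_phase <- match_stim_phase(stim_phase)
  stopifnot(is.matrix(target_amp_mv),
            all(ps_muscles() %in% rownames(target_amp_mv)),
            all(ps_phases() %in% colnames(target_amp_mv)))
  if (!is.null(seed)) set.seed(seed)
  t_ms <- (seq_len(n_samples) - onset_sample) * 1000 / sr
  emg <- matrix(0, n_samples, length(ps_muscles()),
                dimnames = list(NULL, ps_muscles()))
  profiles <- list()
  for (mus in ps_muscles()) {
    tgt <- target_amp_mv[mus, ps_phases()]
    if (all(tgt == 0)) {  # silent channel stays exactly flat
      profiles[[mus]] <- rep(0, n_samples)
      next
    }
    m <- amplitude_profile(t_ms, as.list(tgt), latencies,
                           default_burst_widths(), bmr_end_ms)
    # before the analysed epoch, hold the PRE level
    m[t_ms < -100] <- max(target_amp_mv[mus, "PRE"], 0)
    sigma <- m * sqrt(pi / 2)
    emg[, mus] <- sigma * bandlimited_noise(n_samples, sr)
    profiles[[mus]] <- m
  }
  truth <- list(condition = condition, direction = direction,
                stim_phase = stim_phase, latencies = latencies,
                bmr_end_ms = bmr_end_ms, amplitude_profiles = profiles,
                stim_time_ms = NA_real_, h_p2p_mv = NA_real_,
                m_p2p_mv = NA_real_)
  if (stim_phase != "none") {
    stim_ms <- unname(latencies[[stim_phase]])
    emg[, "SOL"] <- emg[, "SOL"] +
      gabor_wave(t_ms, stim_ms + 1, 0.5, 800, 6) +          # artifact
      gabor_wave(t_ms, stim_ms + 13, 2.5, 150, m_p2p_mv) +  # M-wave
      gabor_wave(t_ms, stim_ms + 38, 3.5, 100, h_p2p_mv)    # H-reflex
    truth$stim_time_ms <- stim_ms
    truth$h_p2p_mv <- h_p2p_mv
    truth$m_p2p_mv <- m_p2p_mv
  }
  list(emg = emg, truth = truth, t_ms = t_ms, onset_sample = onset_sample,
       sr = sr)
}

#' Generate maximal-voluntary-contraction recordings for one subject
#'
#' Emulates the normalization protocol: for each muscle, three isometric
#' 3 s holds recorded at 1 kHz, each a plateau-activation segment with a
#' 300 ms rise and fall and small rep-to-rep amplitude variation. The
#' per-muscle nominal mean rectified plateau amplitude is the truth value
#' against which extraction is validated.
#'
#' @param mvc_mean_mv named vector (SOL..GMAX) of nominal mean rectified
#'   plateau amplitudes in mV.
#' @param n_reps repetitions per muscle (default 3).
#' @param duration_s hold duration (default 3 s).
#' @param sr sampling rate (Hz).
#' @param rep_sd relative SD of rep-to-rep amplitude scaling.
#' @param seed optional integer seed.
#' @return list with `recordings` (n x (muscles*reps) matrix, columns
#'   `SOL_r1`, ...), `sr`, and `truth` (nominal amplitudes).
#' @export
generate_mvc_recordings <- function(mvc_mean_mv, n_reps = 3, duration_s = 3,
                                    sr = 1000, rep_sd = 0.05, seed = NULL) {
  stopifnot(all(ps_muscles() %in% names(mvc_mean_mv)))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(duration_s * sr)
  t_ms <- (seq_len(n) - 1) * 1000 / sr
  envelope <- platform_profile(t_ms, 300) *
    (1 - platform_profile(t_ms - (duration_s * 1000 - 300), 300))
  out <- matrix(0, n, length(ps_muscles()) * n_reps)
  cols <- character(ncol(out))
  k <- 0
  for (mus in ps_muscles()) {
    for (r in seq_len(n_reps)) {
      k <- k + 1
      cols[k] <- sprintf("%s_r%d", mus, r)
      scale <- mvc_mean_mv[[mus]] * max(0.5, stats::rnorm(1, 1, rep_sd))
      sigma <- scale * sqrt(pi / 2) * pmax(envelope, 1e-6)
      out[, k] <- sigma * bandlimited_noise(n, sr)
    }
  }
  colnames(out) <- cols
  list(recordings = out, sr = sr, truth = mvc_mean_mv)
}
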