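# Recruitment-curve calibration and per-trial H/M extraction.

#' Calibrate stimulation intensity from a recruitment curve
#'
#' Returns the stimulation intensity, on the ascending limb of the
#' H-recruitment curve (intensities at or below the H maximum), at which
#' linear interpolation of H equals `target_fraction` of the maximal
#' M-wave. With multiple crossings the lowest intensity is returned.
#'
#' @param curve a `ps_recruitment_curve`.
#' @param target_fraction target H amplitude as a fraction of M-max,
#'   default 0.25.
#' @return the calibrated intensity (same units as the curve grid).
#' @export
calibrate_intensity <- function(curve, target_fraction = 0.25) {
  stopifnot(inherits(curve, "ps_recruitment_curve"))
  check_scalar_num(target_fraction, "target_fraction", min = 0, max = 1)
  asc <- seq_len(which.max(curve$h_mv))
  if (length(asc) < 2 && target_fraction > 0)
    abort_ps("recruitment curve has no ascending H limb", "ps_invalid_parameter")
  target <- target_fraction * curve$m_max_mv
  h <- curve$h_mv[asc]
  x <- curve$intensity[asc]
  if (max(h) < target)
    abort_ps(sprintf(
      "H never reaches %.0f%% of M-max on the ascending limb (max achievable: %.1f%%)",
      100 * target_fraction, 100 * max(h) / curve$m_max_mv),
      "ps_unreachable_target", max_fraction = max(h) / curve$m_max_mv)
  # lowest crossing: first index where h >= target
  i <- which(h >= target)[1]
  if (i == 1L || h[i] == target) return(x[i])
  x[i - 1] + (target - h[i - 1]) / (h[i] - h[i - 1]) * (x[i] - x[i - 1])
}

#' Peak-to-peak amplitude in a half-open window
#'
#' `max - min` of the raw (unrectified) signal within `[window[1],
#' window[2])` ms; invariant to any constant offset.
#'
#' @param epoch signal vector (mV).
#' @param window length-2 ms window, half-open, relative to onset.
#' @param onset_sample 1-based epoch index of t = 0.
#' @param sr sampling rate in Hz.
#' @return amplitude in mV.
#' @export
peak_to_peak <- function(epoch, window, onset_sample = 101, sr = 1000) {
  idx <- window_indices(window[1], window[2], onset_sample, sr)
  if (length(idx) == 0)
    abort_ps("empty peak-to-peak window", "ps_bounds_error")
  if (idx[1] < 1 || idx[length(idx)] > length(epoch))
    abort_ps("peak-to-peak window outside epoch", "ps_bounds_error")
  x <- epoch[idx]
  max(x) - min(x)
}

#' Extract H-reflex and M-wave amplitudes from one stimulated trial
#'
#' The M-wave is measured in `[stim+5, stim+25)` ms and the H-reflex in
#' `[stim+25, stim+55)` ms after the stimulus (defaults; standard soleus
#' latencies), both as peak-to-peak of the raw SOL trace. Trials whose
#' search windows are saturated by the stimulus artifact are flagged.
#'
#' @param trial a `ps_trial_epoch` with `stim_phase != "none"` and a
#'   known `stim_time_ms`.
#' @param m_window,h_window ms offsets from the stimulus, half-open.
#' @param saturation_mv amplitudes above this are treated as artifact
#'   contamination and flagged (default 25 mV).
#' @return list: `subject`, `condition`, `stim_phase`, `h_mv`, `m_mv`,
#'   `flagged`.
#' @export
extract_hm <- function(trial, m_window = c(5, 25), h_window = c(25, 55),
                       saturation_mv = 25) {
  if (identical(trial$stim_phase, "none") || is.na(trial$stim_time_ms))
    abort_ps("extract_hm requires a stimulated trial with a known stimulus time",
             "ps_precondition_error")
  stim <- trial$stim_time_ms
  sol <- trial$emg[, "SOL"]
  m <- peak_to_peak(sol, stim + m_window, trial$onset_sample, trial$sr_fast)
  h <- peak_to_peak(sol, stim + h_window, trial$onset_sample, trial$sr_fast)
  flagged <- m > saturation_mv || h > saturation_mv
  list(subject = trial$subject, condition = trial$condition,
       stim_phase = trial$stim_phase, trial = trial$trial,
       h_mv = h, m_mv = m, flagged = flagged)
}

#' H/M table for a set of trials
#'
#' Runs [extract_hm()] on every stimulated trial; flagged (saturated)
#' trials are excluded. Adds per-subject x phase normalization to the
#' predicted-condition mean (`h_pct_predicted`, `m_pct_predicted`) when
#' predicted-condition trials are present.
#'
#' @param trials list of `ps_trial_epoch` objects.
#' @return data.frame: subject, condition, stim_phase, trial, h_mv,
#'   m_mv, h_pct_predicted, m_pct_predicted.
#' @export
hm_table <- function(trials) {
  rows <- list()
  for (tr in trials) {
    if (identical(tr$stim_phase, "none")) next
    r <- extract_hm(tr)
    if (r$flagged) next
    rows[[length(rows) + 1]] <- as.data.frame(r[c("subject", "condition",
                                                  "stim_phase", "trial",
                                                  "h_mv", "m_mv")],
                                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  out$h_pct_predicted <- NA_real_
  out$m_pct_predicted <- NA_real_
  for (sid in unique(out$subject)) for (ph in unique(out$stim_phase)) {
    sel <- out$subject == sid & out$stim_phase == ph
    base <- out[sel & out$condition == "predicted", ]
    if (nrow(base)) {
      out$h_pct_predicted[sel] <- out$h_mv[sel] / mean(base$h_mv) * 100
      out$m_pct_predicted[sel] <- out$m_mv[sel] / mean(base$m_mv) * 100
    }
  }
  out
}
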