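# Phase-windowed EMG quantification.
#
# Analysis windows (ms relative to perturbation onset, half-open):
#   PRE [-100, 0), SLR [30, 60), MLR [60, 85), LLR [85, 120),
#   BMR [120, cop_peak_index). The 0-30 ms gap is deliberate: it
#   contains no reflex activity of interest.

#' Build the five analysis windows for one trial
#'
#' @param cop_peak_index_ms the trial's COP peak latency in ms; must lie
#'   in (120, 500]. It closes the belated-muscle-response window.
#' @return a `ps_phase_windows` object: named list of `c(start, end)`
#'   pairs in ms.
#' @export
build_phase_windows <- function(cop_peak_index_ms) {
  check_scalar_num(cop_peak_index_ms, "cop_peak_index_ms")
  if (cop_peak_index_ms <= 120 || cop_peak_index_ms > 500)
    abort_ps(sprintf(
      "COP peak at %.0f ms leaves no belated-response window (need (120, 500])",
      cop_peak_index_ms), "ps_degenerate_bmr")
  structure(list(PRE = c(-100, 0), SLR = c(30, 60), MLR = c(60, 85),
                 LLR = c(85, 120), BMR = c(120, cop_peak_index_ms)),
            class = "ps_phase_windows")
}

#' Rectified EMG integral over a half-open window
#'
#' Riemann integral of `|signal|` over `[window[1], window[2])` ms, in
#' mV*s: the rectangular sum over the samples inside the half-open
#' window (equivalently, the trapezoidal rule plus the two half-sample
#' closing strips). Adjacent windows therefore tile exactly:
#' `[a,b) + [b,c) = [a,c)`.
#'
#' @param epoch EMG epoch vector (mV).
#' @param window length-2 numeric, ms relative to onset, half-open.
#' @param onset_sample 1-based epoch index of t = 0 (default 101).
#' @param sr sampling rate in Hz (default 1000).
#' @return iEMG in mV*s.
#' @export
rectified_integral <- function(epoch, window, onset_sample = 101, sr = 1000) {
  idx <- window_indices(window[1], window[2], onset_sample, sr)
  if (length(idx) == 0 || idx[1] < 1 || idx[length(idx)] > length(epoch))
    abort_ps(sprintf("window [%g, %g) ms outside epoch", window[1], window[2]),
             "ps_bounds_error")
  sum(abs(epoch[idx])) / sr
}

#' Convert an iEMG value to time-normalized and MVC-normalized form
#'
#' @param iemg_mvs rectified integral in mV*s.
#' @param duration_ms window duration in ms (> 0).
#' @param mvc a `ps_mvc_reference` from [extract_mvc_reference()].
#' @param muscle muscle label to normalize against.
#' @return list with `iemg_mvs`, `mean_mv` (iEMG / duration) and
#'   `pct_mvc` (mean amplitude as % of the MVC reference amplitude).
#' @export
normalize_features <- function(iemg_mvs, duration_ms, mvc, muscle) {
  check_scalar_num(duration_ms, "duration_ms", positive = TRUE)
  ref <- mvc$mean_mv[[muscle]]
  if (is.null(ref) || !is.finite(ref) || ref <= 0)
    abort_ps(sprintf("MVC reference for %s is zero or missing", muscle),
             "ps_zero_mvc")
  mean_mv <- iemg_mvs / (duration_ms / 1000)
  list(iemg_mvs = iemg_mvs, mean_mv = mean_mv,
       pct_mvc = mean_mv / ref * 100)
}

#' Extract the MVC normalization reference
#'
#' For each muscle, selects the repetition whose rectified peak is
#' largest and integrates `|signal|` over the 100 ms surrounding that
#' peak (50 ms before to 50 ms after); the reference is the mean
#' rectified amplitude of that window. Windows clipped by a recording
#' edge use the available duration, with a warning.
#'
#' @param mvc_trials named list (per muscle) of matrices, one column per
#'   MVC repetition, at `sr` Hz.
#' @param sr sampling rate in Hz.
#' @return a `ps_mvc_reference`: list with `mean_mv` and `iemg_mvs`
#'   (named per muscle) and `selected_rep`.
#' @export
extract_mvc_reference <- function(mvc_trials, sr = 1000) {
  mean_mv <- iemg <- numeric(0)
  sel <- integer(0)
  half <- as.integer(0.05 * sr)
  for (mus in names(mvc_trials)) {
    m <- mvc_trials[[mus]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    peaks <- apply(abs(m), 2, max)
    if (all(peaks == 0))
      abort_ps(sprintf("all MVC repetitions for %s are zero", mus),
               "ps_zero_mvc")
    best <- which.max(peaks)
    x <- abs(m[, best])
    ip <- which.max(x)
    i0 <- ip - half; i1 <- ip + half - 1L
    if (i0 < 1 || i1 > length(x)) {
      warning(sprintf(
        "MVC peak for %s within 50 ms of a recording edge; window clipped",
        mus), call. = FALSE)
      i0 <- max(1L, i0); i1 <- min(length(x), i1)
    }
    dur_s <- (i1 - i0 + 1) / sr
    integral <- sum(x[i0:i1]) / sr
    mean_mv[mus] <- integral / dur_s
    iemg[mus] <- integral
    sel[mus] <- best
  }
  structure(list(mean_mv = mean_mv, iemg_mvs = iemg, selected_rep = sel),
            class = "ps_mvc_reference")
}

#' Detect individual reflex-peak latencies from familiarization trials
#'
#' Ensemble-averages the rectified soleus traces of unstimulated
#' posterior trials, smooths with a 15 ms moving average, and returns
#' the argmax latency within each of the SLR/MLR/LLR windows (ties to
#' the earliest sample). These latencies time the peripheral nerve
#' stimulation in the main protocol. The kernel is deliberately
#' narrower than the narrowest (25 ms) analysis window: wider kernels
#' mix neighbouring reflex components into each window and drag the
#' argmax to the window edge.
#'
#' @param trials list of `ps_trial_epoch` objects with an EMG matrix.
#' @param muscle channel to use (default `"SOL"`).
#' @param min_trials minimum number of trials required (default 2).
#' @return a `ps_reflex_latencies`: named vector `c(SLR=, MLR=, LLR=)`
#'   in ms, with attribute `low_confidence` when the ensemble is flat.
#' @export
detect_reflex_peaks <- function(trials, muscle = "SOL", min_trials = 2) {
  if (length(trials) < min_trials)
    abort_ps(sprintf("need at least %d trials, got %d", min_trials,
                     length(trials)), "ps_invalid_parameter")
  sr <- trials[[1]]$sr_fast
  ens <- rowMeans(vapply(trials, function(tr) abs(tr$emg[, muscle]),
                         numeric(nrow(trials[[1]]$emg))))
  k <- as.integer(0.015 * sr)
  sm <- stats::filter(ens, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  onset <- trials[[1]]$onset_sample
  wins <- list(SLR = c(30, 60), MLR = c(60, 85), LLR = c(85, 120))
  out <- vapply(wins, function(w) {
    idx <- window_indices(w[1], w[2], onset, sr)
    (idx[which.max(sm[idx])] - onset) * 1000 / sr
  }, numeric(1))
  flat <- max(ens) <= 0 || stats::sd(ens) < 1e-12
  structure(out, class = "ps_reflex_latencies", low_confidence = flat)
}

#' Phase-windowed EMG feature table for a set of trials
#'
#' Applies the window construction, rectified integration and both
#' normalizations to every unstimulated trial, one row per trial x
#' muscle x phase. Stimulated trials are excluded (their soleus trace
#' carries evoked potentials); trials whose COP peak precedes 120 ms
#' contribute no BMR row.
#'
#' @param trials list of `ps_trial_epoch` objects (EMG + COP present).
#' @param mvc a `ps_mvc_reference`.
#' @param bmr_end optional fixed BMR endpoint (ms); default `NULL` uses
#'   each trial's own COP peak latency.
#' @return data.frame: subject, condition, direction, trial, muscle,
#'   phase, iemg_mvs, mean_mv, pct_mvc.
#' @export
emg_feature_table <- function(trials, mvc, bmr_end = NULL) {
  rows <- list()
  for (tr in trials) {
    if (!identical(tr$stim_phase, "none")) next
    cm <- if (!is.null(tr[["cop"]]))
      cop_metrics(tr[["cop"]], tr$cop_onset_sample, sr = tr$sr_cop) else NULL
    end_bmr <- bmr_end %||% (if (!is.null(cm)) cm$peak_index_ms else 344)
    wins <- tryCatch(build_phase_windows(end_bmr),
                     ps_degenerate_bmr = function(e) {
                       w <- build_phase_windows(344)
                       w["BMR"] <- list(NULL)
                       w
                     })
    for (mus in colnames(tr$emg)) {
      for (ph in names(wins)) {
        w <- wins[[ph]]
        if (is.null(w)) next
        ie <- rectified_integral(tr$emg[, mus], w, tr$onset_sample, tr$sr_fast)
        f <- normalize_features(ie, w[2] - w[1], mvc, mus)
        rows[[length(rows) + 1]] <- data.frame(
          subject = tr$subject, condition = tr$condition,
          direction = tr$direction, trial = tr$trial, muscle = mus,
          phase = ph, iemg_mvs = f$iemg_mvs, mean_mv = f$mean_mv,
          pct_mvc = f$pct_mvc, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows) %||% data.frame()
}
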