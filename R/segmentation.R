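# Onset detection on the potentiometer channel and fixed 600 ms epoching.
#
# Epoch convention: every analysed trial covers [-100, +500) ms around
# perturbation onset; on the 1 kHz grid that is 600 samples with sample
# 101 (1-based) at t = 0, on the 100 Hz COP grid 60 samples with sample
# 11 at t = 0. All phase windows are half-open [start, end) in ms.

#' Detect perturbation onsets in a potentiometer trace
#'
#' Candidate onsets are samples where displacement first leaves a
#' baseline band (baseline median +/- `threshold_fraction` x full
#' excursion), with a refractory period between detections. Each
#' candidate is then refined by fitting the square root of the early
#' displacement deviation against time and extrapolating to zero, which
#' removes the threshold-crossing lag of smooth (quadratic-start) ramps.
#' Onsets too close to either edge for a full [-100, +500) ms epoch are
#' dropped with a warning.
#'
#' @param x potentiometer displacement vector (cm).
#' @param sample_rate sampling rate in Hz.
#' @param threshold_fraction detection band half-width as a fraction of
#'   the full excursion, in (0, 1). Default 0.05.
#' @param refractory_s minimum separation between onsets in seconds.
#' @return integer vector of onset sample indices (1-based).
#' @export
detect_onsets <- function(x, sample_rate, threshold_fraction = 0.05,
                          refractory_s = 1) {
  check_scalar_num(threshold_fraction, "threshold_fraction")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    abort_ps("`threshold_fraction` must be in (0, 1)", "ps_invalid_parameter")
  n <- length(x)
  if (n < 0.7 * sample_rate)
    abort_ps("trace shorter than one epoch", "ps_invalid_parameter")
  baseline <- stats::median(x)
  exc <- max(x) - min(x)
  noise_sd <- stats::mad(diff(x)) / sqrt(2)
  if (exc <= 10 * max(noise_sd, 1e-12) || exc == 0)
    abort_ps("no perturbation found: trace is flat relative to its noise",
             "ps_no_perturbation")
  dev <- abs(x - baseline)
  thr <- threshold_fraction * exc
  above <- dev > thr
  rising <- which(above & !c(FALSE, above[-n]))
  refr <- as.integer(refractory_s * sample_rate)
  half <- as.integer(0.5 * sample_rate)
  onsets <- integer(0)
  last <- -refr
  for (i in rising) {
    if (i - last < refr) next
    # confirm a real excursion: the deviation must keep building to at
    # least half the full excursion within 500 ms (rejects threshold
    # chatter on the slow return to baseline)
    if (max(dev[i:min(n, i + half)]) < 0.5 * exc) next
    onsets <- c(onsets, i)
    last <- i
  }
  # refine each crossing: sqrt(deviation) is locally linear in time for
  # a smooth ramp; extrapolate its [2%, 15%] band to zero deviation
  refined <- vapply(onsets, function(i0) {
    lo <- max(1L, i0 - as.integer(0.3 * sample_rate))
    seg <- dev[lo:min(n, i0 + as.integer(0.2 * sample_rate))]
    band <- which(seg >= 0.02 * exc & seg <= 0.15 * exc)
    band <- band[band <= which.max(seg >= 0.15 * exc)]
    if (length(band) < 3) return(as.numeric(i0))
    fit <- stats::lm.fit(cbind(1, band), sqrt(seg[band]))
    t0 <- -fit$coefficients[1] / fit$coefficients[2]
    as.numeric(lo - 1 + t0)
  }, numeric(1))
  refined <- as.integer(round(refined))
  pre <- as.integer(0.1 * sample_rate)
  post <- as.integer(0.5 * sample_rate)
  ok <- refined - pre >= 1 & refined + post - 1 <= n
  if (any(!ok))
    warning(sprintf("%d onset(s) too close to a recording edge were dropped",
                    sum(!ok)), call. = FALSE)
  refined[ok]
}

#' Cut one trial record to the 600 ms analysis epoch
#'
#' Cuts all fast (1 kHz) channels to `[-100, +500)` ms around the onset
#' sample (600 samples, onset at index 101) and the 100 Hz COP channel
#' to its own grid at the sample nearest onset (60 samples, onset at
#' index 11); no resampling.
#'
#' @param rec a trial record (from the generator, [read_trial()], or
#'   [import_trial_tsv()]).
#' @return a `ps_trial_epoch` (same fields, epoch-length channels,
#'   `onset_sample = 101`, `cop_onset_sample = 11`), or `NULL` with a
#'   warning when the record is too short for a full epoch.
#' @export
epoch_trial <- function(rec) {
  pre1k <- 100L; post1k <- 500L
  o <- rec$onset_sample
  nfast <- if (!is.null(rec$platform)) length(rec$platform)
           else if (!is.null(rec$emg)) nrow(rec$emg)
           else if (!is.null(rec$joints)) nrow(rec$joints) else NA_integer_
  if (!is.na(nfast)) {
    if (o - pre1k < 1 || o + post1k - 1 > nfast) {
      warning(sprintf("trial %s/%s dropped: incomplete epoch around sample %d",
                      rec$subject %||% "?", rec$trial %||% "?", o),
              call. = FALSE)
      return(NULL)
    }
    idx <- (o - pre1k):(o + post1k - 1)
    if (!is.null(rec$platform)) rec$platform <- rec$platform[idx]
    if (!is.null(rec$emg)) rec$emg <- rec$emg[idx, , drop = FALSE]
    if (!is.null(rec$joints)) rec$joints <- rec$joints[idx, , drop = FALSE]
  }
  if (!is.null(rec[["cop"]])) {
    oc <- rec$cop_onset_sample
    if (oc - 10 < 1 || oc + 49 > length(rec[["cop"]])) {
      warning("trial dropped: incomplete COP epoch", call. = FALSE)
      return(NULL)
    }
    rec$cop <- rec[["cop"]][(oc - 10):(oc + 49)]
    rec$cop_onset_sample <- 11L
  }
  rec$onset_sample <- 101L
  class(rec) <- "ps_trial_epoch"
  rec
}

#' Segment a continuous recording into trial epochs
#'
#' @param recording list with `sr_fast` (Hz), optional fast channels
#'   (`platform` vector, `emg` matrix, `joints` matrix, all on the same
#'   1 kHz grid), optional `cop` vector with `sr_cop`.
#' @param onsets onset sample indices on the fast grid, typically from
#'   [detect_onsets()].
#' @param metadata optional data.frame with one row per onset (joined by
#'   onset order) carrying condition/direction/stim_phase labels.
#' @return list of `ps_trial_epoch` objects (dropped-edge trials are
#'   omitted, with a warning).
#' @export
segment <- function(recording, onsets, metadata = NULL) {
  if (!is.null(metadata) && nrow(metadata) != length(onsets))
    abort_ps(sprintf(
      "metadata has %d rows but %d onsets were supplied; unmatched entries: %s",
      nrow(metadata), length(onsets),
      paste(utils::head(abs(seq_len(max(nrow(metadata), length(onsets)))), 5),
            collapse = ", ")), "ps_metadata_mismatch")
  sr_fast <- recording$sr_fast %||% 1000
  sr_cop <- recording$sr_cop %||% 100
  out <- list()
  for (k in seq_along(onsets)) {
    o <- onsets[k]
    rec <- list(subject = recording$subject %||% NA_character_,
                condition = NA_character_, direction = NA_character_,
                stim_phase = "none", trial = k,
                sr_fast = sr_fast, sr_cop = sr_cop,
                onset_sample = as.integer(o),
                cop_onset_sample = as.integer(round((o - 1) * sr_cop / sr_fast)) + 1L,
                stim_time_ms = NA_real_)
    if (!is.null(metadata)) {
      for (f in intersect(c("subject", "condition", "direction", "stim_phase",
                            "stim_time_ms"), names(metadata)))
        rec[[f]] <- metadata[[f]][k]
    }
    rec$platform <- recording$platform
    rec$emg <- recording$emg
    rec$joints <- recording$joints
    rec$cop <- recording[["cop"]]
    ep <- epoch_trial(rec)
    if (!is.null(ep)) out[[length(out) + 1]] <- ep
  }
  out
}

#' Import a trial from a plain multi-column TSV
#'
#' The documented import path for user data: a TSV with a header row, a
#' `time_ms` column (0 = perturbation onset) and any subset of the
#' channel labels `PLATFORM`, `SOL`, `MG`, `TA`, `RF`, `BF`, `GMAX`,
#' `ANKLE`, `KNEE`, `HIP` on a 1 kHz grid; an optional companion file
#' with `time_ms` and `COP_AP` carries the 100 Hz COP trace.
#'
#' @param path TSV path (1 kHz channels).
#' @param cop_path optional COP TSV path.
#' @return a trial record suitable for [epoch_trial()].
#' @export
import_trial_tsv <- function(path, cop_path = NULL) {
  dt <- data.table::fread(path, sep = "\t")
  if (!"time_ms" %in% names(dt))
    abort_ps("TSV must contain a `time_ms` column", "ps_io_error")
  onset <- which.min(abs(dt$time_ms))
  rec <- list(subject = NA_character_, condition = NA_character_,
              direction = NA_character_, stim_phase = "none", trial = 1L,
              sr_fast = 1000, sr_cop = 100,
              onset_sample = as.integer(onset), stim_time_ms = NA_real_)
  if ("PLATFORM" %in% names(dt)) rec$platform <- dt$PLATFORM
  emg_cols <- intersect(ps_muscles(), names(dt))
  if (length(emg_cols)) rec$emg <- as.matrix(dt[, emg_cols, with = FALSE])
  j_cols <- intersect(c("ANKLE", "KNEE", "HIP"), names(dt))
  if (length(j_cols)) rec$joints <- as.matrix(dt[, j_cols, with = FALSE])
  if (!is.null(cop_path)) {
    cdt <- data.table::fread(cop_path, sep = "\t")
    rec$cop <- cdt$COP_AP
    rec$cop_onset_sample <- as.integer(which.min(abs(cdt$time_ms)))
  }
  rec
}
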