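# Centre-of-pressure and joint-goniometry summaries per trial.

#' COP displacement metrics for one trial epoch
#'
#' Computes, from the 100 Hz COP epoch: the starting position right
#' before the translation (sample nearest -1 ms, `cop_onset_cm`), the
#' positions at +90 and +120 ms (nearest samples), the signed peak
#' excursion (`cop_peak_cm`: the deviation from onset with the largest
#' absolute value in [0, 500), so a trial that starts with an anterior
#' lean still yields its posterior peak with sign intact) and the peak
#' latency (`peak_index_ms`, ties to the earliest sample). `cop_90_cm` /
#' `cop_120_cm` are onset-referenced differences; the absolute positions
#' are returned alongside (`*_abs`).
#'
#' @param cop COP epoch vector (cm) at `sr` Hz.
#' @param onset_sample 1-based epoch index of t = 0 (default 11).
#' @param sr sampling rate in Hz (default 100).
#' @return a `ps_cop_metrics` list.
#' @export
cop_metrics <- function(cop, onset_sample = 11, sr = 100) {
  if (is.null(cop) || !length(cop))
    abort_ps("missing COP channel", "ps_missing_channel")
  onset_v <- cop[nearest_sample(-1, onset_sample, sr)]
  v90 <- cop[nearest_sample(90, onset_sample, sr)]
  v120 <- cop[nearest_sample(120, onset_sample, sr)]
  idx <- window_indices(0, 500, onset_sample, sr)
  idx <- idx[idx >= 1 & idx <= length(cop)]
  dev <- cop[idx] - onset_v
  ipk <- idx[which.max(abs(dev))]  # which.max: earliest tie wins
  peak <- cop[ipk] - onset_v
  structure(list(cop_onset_cm = onset_v,
                 cop_90_cm = v90 - onset_v, cop_120_cm = v120 - onset_v,
                 cop_90_abs_cm = v90, cop_120_abs_cm = v120,
                 cop_peak_cm = peak,
                 peak_index_ms = (ipk - onset_sample) * 1000 / sr),
            class = "ps_cop_metrics")
}

#' Joint-kinematic summary for one trial epoch
#'
#' Onset angle at t = 0, excursion (largest absolute deviation from the
#' onset angle within [0, 500) ms, reported as a magnitude) and the
#' latency of that extremum. Angles outside [0, 360] degrees raise a
#' data-quality flag rather than an error.
#'
#' @param angle joint-angle epoch (degrees) at `sr` Hz.
#' @param joint `"ankle"`, `"knee"` or `"hip"`.
#' @param onset_sample 1-based epoch index of t = 0 (default 101).
#' @param sr sampling rate in Hz (default 1000).
#' @return a `ps_joint_kinematics` list: `joint`, `onset_deg`,
#'   `excursion_deg`, `peak_index_ms`, `quality_flag`.
#' @export
joint_kinematics <- function(angle, joint, onset_sample = 101, sr = 1000) {
  joint <- match.arg(joint, c("ankle", "knee", "hip"))
  onset_v <- angle[onset_sample]
  idx <- window_indices(0, 500, onset_sample, sr)
  idx <- idx[idx >= 1 & idx <= length(angle)]
  dev <- angle[idx] - onset_v
  ipk <- idx[which.max(abs(dev))]
  structure(list(joint = joint, onset_deg = onset_v,
                 excursion_deg = abs(angle[ipk] - onset_v),
                 peak_index_ms = (ipk - onset_sample) * 1000 / sr,
                 quality_flag = any(angle < 0 | angle > 360)),
            class = "ps_joint_kinematics")
}

#' Kinematic summary table for a set of trials
#'
#' One row per trial with the COP metrics and, when goniometry is
#' present, per-joint onset/excursion/latency columns.
#'
#' @param trials list of `ps_trial_epoch` objects.
#' @return data.frame in tidy wide-per-trial form.
#' @export
kinematics_table <- function(trials) {
  rows <- list()
  for (tr in trials) {
    row <- data.frame(subject = tr$subject, condition = tr$condition,
                      direction = tr$direction, stim_phase = tr$stim_phase,
                      trial = tr$trial, stringsAsFactors = FALSE)
    if (!is.null(tr[["cop"]])) {
      cm <- cop_metrics(tr[["cop"]], tr$cop_onset_sample, tr$sr_cop)
      row$cop_onset_cm <- cm$cop_onset_cm
      row$cop_90_cm <- cm$cop_90_cm
      row$cop_120_cm <- cm$cop_120_cm
      row$cop_peak_cm <- cm$cop_peak_cm
      row$cop_peak_index_ms <- cm$peak_index_ms
    }
    if (!is.null(tr$joints)) {
      for (j in colnames(tr$joints)) {
        jk <- joint_kinematics(tr$joints[, j], tolower(j), tr$onset_sample,
                               tr$sr_fast)
        row[[sprintf("%s_onset_deg", tolower(j))]] <- jk$onset_deg
        row[[sprintf("%s_excursion_deg", tolower(j))]] <- jk$excursion_deg
        row[[sprintf("%s_peak_index_ms", tolower(j))]] <- jk$peak_index_ms
      }
    }
    rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) return(data.frame())
  data.table::rbindlist(rows, fill = TRUE) |> as.data.frame()
}
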