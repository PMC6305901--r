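# Default condition-effect tables for the synthetic cohort.
#
# These are the generator's stated world: per-condition subject-level
# means and between-subject SDs for every kinematic and neuromuscular
# summary the pipeline extracts, with the anticipation gradient
# (predicted -> unpredicted -> cheated) built in. Posterior COP
# displacement is negative by convention; anterior positive.

ps_conditions <- function() c("predicted", "unpredicted", "cheated")

#' Default kinematic effect table
#'
#' Subject-level means and SDs (per condition) for the centre-of-pressure
#' and joint-goniometry summaries of posterior-perturbation trials:
#' COP position at onset, 90 ms and 120 ms, signed peak excursion and its
#' latency, and per-joint onset angle, excursion and peak latency.
#'
#' @return a data.frame with columns `variable`, `condition`, `mean`, `sd`.
#' @export
effect_table_kinematics <- function() {
  tab <- rbind(
    c("cop_onset_cm",        -0.7, 0.5,  -0.1, 0.1,   0.7, 0.2),
    c("cop_90_cm",           -1.4, 0.5,  -1.5, 0.6,  -1.1, 0.4),
    c("cop_120_cm",          -2.1, 0.9,  -2.5, 0.7,  -2.5, 0.6),
    c("cop_peak_cm",         -2.5, 0.7,  -3.1, 0.9,  -3.7, 1.1),
    c("cop_peak_index_ms",  230,  44,   287,  65,   344,  73),
    c("hip_onset_deg",      179.0, 6.7, 179.1, 5.9, 179.5, 4.8),
    c("hip_excursion_deg",    1.2, 0.9,   4.6, 2.6,   6.1, 2.7),
    c("hip_peak_index_ms",  225,  95,   278,  89,   346, 120),
    c("knee_onset_deg",     178.3, 2.9, 178.6, 3.0, 178.9, 3.0),
    c("knee_excursion_deg",   1.5, 1.2,   4.1, 2.8,   5.9, 3.0),
    c("knee_peak_index_ms", 230, 109,   268, 107,   290, 111),
    c("ankle_onset_deg",     96.4, 4.4,  95.9, 4.5,  95.0, 4.2),
    c("ankle_excursion_deg",  2.0, 0.5,   4.7, 2.3,   7.1, 2.8),
    c("ankle_peak_index_ms",192,  69,   216,  77,   227,  85)
  )
  out <- data.frame(
    variable = rep(tab[, 1], each = 3),
    condition = rep(ps_conditions(), nrow(tab)),
    mean = as.numeric(t(tab[, c(2, 4, 6)])),
    sd = as.numeric(t(tab[, c(3, 5, 7)])),
    stringsAsFactors = FALSE
  )
  out
}

#' Default neuromuscular effect table
#'
#' Subject-level mean and between-subject SD of phase-windowed EMG
#' activity, in % of MVC, for the six recorded muscles across the three
#' anticipation conditions. Encodes the condition structure the
#' generator emulates: the pre-activation switch to TA under cheating,
#' the progressive LLR/BMR facilitation of the plantar flexors, the BMR
#' recruitment of the proximal muscles, and near-null thigh effects.
#'
#' @return a data.frame with columns `muscle`, `phase`, `condition`,
#'   `mean_pct`, `sd_pct`.
#' @export
effect_table_emg <- function() {
  # mean, sd for predicted / unpredicted / cheated, per muscle x phase
  raw <- list(
    SOL = list(PRE = c(0.18, 0.08, 0.18, 0.06, 0.14, 0.07),
               SLR = c(0.27, 0.10, 0.20, 0.09, 0.12, 0.06),
               MLR = c(0.30, 0.12, 0.35, 0.14, 0.21, 0.12),
               LLR = c(0.41, 0.14, 0.58, 0.16, 0.65, 0.20),
               BMR = c(0.34, 0.15, 0.46, 0.19, 0.61, 0.17)),
    MG  = list(PRE = c(0.14, 0.09, 0.12, 0.09, 0.08, 0.04),
               SLR = c(0.22, 0.08, 0.19, 0.07, 0.12, 0.09),
               MLR = c(0.25, 0.12, 0.29, 0.14, 0.21, 0.10),
               LLR = c(0.33, 0.27, 0.43, 0.25, 0.39, 0.21),
               BMR = c(0.37, 0.23, 0.45, 0.47, 0.51, 0.26)),
    TA  = list(PRE = c(0.05, 0.04, 0.12, 0.05, 0.31, 0.12),
               SLR = c(0.07, 0.06, 0.06, 0.04, 0.28, 0.21),
               MLR = c(0.06, 0.04, 0.05, 0.03, 0.09, 0.08),
               LLR = c(0.04, 0.03, 0.07, 0.06, 0.04, 0.03),
               BMR = c(0.06, 0.05, 0.09, 0.05, 0.03, 0.03)),
    GMAX = list(PRE = c(0.21, 0.09, 0.22, 0.08, 0.19, 0.11),
                SLR = c(0.18, 0.07, 0.20, 0.08, 0.18, 0.07),
                MLR = c(0.23, 0.10, 0.21, 0.10, 0.24, 0.12),
                LLR = c(0.20, 0.11, 0.22, 0.09, 0.27, 0.11),
                BMR = c(0.26, 0.13, 0.31, 0.17, 0.40, 0.15)),
    RF  = list(PRE = c(0.12, 0.07, 1.04, 0.67, 1.00, 0.65),
               SLR = c(0.13, 0.09, 1.04, 0.69, 1.07, 0.84),
               MLR = c(0.10, 0.11, 1.04, 0.68, 0.97, 0.66),
               LLR = c(0.14, 0.07, 1.02, 0.65, 1.06, 0.64),
               BMR = c(0.17, 0.11, 0.15, 0.09, 0.19, 0.13)),
    BF  = list(PRE = c(0.12, 0.08, 0.10, 0.05, 0.12, 0.09),
               SLR = c(0.14, 0.10, 0.11, 0.07, 0.10, 0.10),
               MLR = c(0.16, 0.09, 0.18, 0.12, 0.15, 0.11),
               LLR = c(0.20, 0.12, 0.25, 0.16, 0.34, 0.17),
               BMR = c(0.23, 0.13, 0.28, 0.12, 0.39, 0.19))
  )
  rows <- list()
  for (mus in names(raw)) for (ph in names(raw[[mus]])) {
    v <- raw[[mus]][[ph]]
    rows[[length(rows) + 1]] <- data.frame(
      muscle = mus, phase = ph, condition = ps_conditions(),
      mean_pct = v[c(1, 3, 5)], sd_pct = v[c(2, 4, 6)],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Default H-reflex modulation factors
#'
#' Multiplicative condition x phase factors on the calibrated H-reflex
#' amplitude (predicted = 1 by definition). The pattern encodes the
#' phase-specific modulation of spinal excitability: suppression in the
#' short-latency window and progressive facilitation in the long-latency
#' window from predicted to unpredicted to cheated, with the
#' medium-latency window facilitated for unpredicted but back at
#' baseline when the direction was wrongly cued.
#'
#' @return a 3 x 3 matrix, rows `SLR`, `MLR`, `LLR`, columns conditions.
#' @export
h_modulation_defaults <- function() {
  m <- rbind(SLR = c(1.00, 0.85, 0.70),
             MLR = c(1.00, 1.15, 1.00),
             LLR = c(1.00, 1.20, 1.40))
  colnames(m) <- ps_conditions()
  m
}

#' Default latent rank-correlation targets
#'
#' Per-condition targets for the Gaussian-copula subject model, expressed
#' as the Spearman correlation of each subject-level variable with the
#' signed COP peak excursion (`cop_peak_cm`), plus the anchor correlation
#' between COP onset position and COP peak. One shared standard-normal
#' latent per subject and condition carries the structure; each
#' variable's loading is derived from its target (see the methods
#' vignette for the construction and its reach).
#'
#' @return list with `anchor` (named vector: Spearman target for
#'   (cop_onset, cop_peak) per condition) and `vs_peak` (data.frame:
#'   `condition`, `variable`, `rho`).
#' @export
correlation_targets_defaults <- function() {
  vs_peak <- rbind(
    data.frame(condition = "predicted",
               variable = "emg_SOL_PRE", rho = -0.523),
    data.frame(condition = "unpredicted",
               variable = c("h_MLR", "emg_SOL_MLR", "emg_SOL_LLR",
                            "emg_MG_LLR", "emg_MG_BMR"),
               rho = c(-0.616, -0.676, -0.610, -0.715, 0.877)),
    data.frame(condition = "cheated",
               variable = c("emg_TA_PRE", "h_LLR", "emg_SOL_LLR",
                            "emg_MG_LLR", "emg_MG_BMR", "emg_GMAX_BMR"),
               rho = c(0.601, -0.747, -0.622, -0.589, -0.716, 0.620))
  )
  list(anchor = c(predicted = -0.699, unpredicted = 0, cheated = 0.771),
       peak_index = c(predicted = -0.5, unpredicted = -0.5, cheated = -0.5),
       vs_peak = vs_peak)
}

#' Convert a Spearman correlation target to the latent Pearson scale
#'
#' For a Gaussian copula, a population Spearman correlation `rho`
#' requires latent Pearson correlation `2 * sin(pi * rho / 6)`.
#'
#' @param rho Spearman correlation in `[-1, 1]`.
#' @return latent Pearson correlation.
#' @export
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)
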