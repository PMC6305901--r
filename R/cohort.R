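# Whole-cohort forward model: subjects x conditions x trials.
#
# Subject-level summaries (COP, joint and EMG phase activity, H-reflex
# modulation) are drawn per condition from the configured mean +/- SD
# with a shared standard-normal latent per subject carrying the target
# rank-correlation structure (Gaussian copula, single-factor loading
# construction). Trials are then synthesized around the subject values
# with independent within-subject jitter, so the pipeline's ensemble
# estimates recover both the configured means and the configured
# correlations.

#' Cohort generator configuration
#'
#' The defaults are the study conditions the generator emulates: 29
#' subjects; per condition 40 posterior trials split 10/10/10/10 across
#' stimulation phases (none/SLR/MLR/LLR) plus 40 anterior trials; effect
#' tables carrying the anticipation gradient; H-reflex base amplitude at
#' 25% of M-max with phase x condition modulation; and the latent
#' rank-correlation targets.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_phase posterior trials per stimulation phase.
#' @param n_anterior anterior (bookkeeping-only) trials per condition.
#' @param conditions subset of the three anticipation conditions.
#' @param directions subset of `c("posterior", "anterior")`.
#' @param stim_phases subset of `c("none", "SLR", "MLR", "LLR")`.
#' @param channels subset of `c("PLATFORM", "COP", "JOINT", "EMG")`;
#'   restricting channels skips the corresponding waveform synthesis.
#' @param kinematics,emg effect tables, see [effect_table_kinematics()]
#'   and [effect_table_emg()].
#' @param h_modulation 3 x 3 phase-by-condition matrix of H factors.
#' @param correlations latent targets, see
#'   [correlation_targets_defaults()].
#' @param platform a [platform_params()] object (posterior template).
#' @param mvc_mean_mv named nominal MVC mean rectified amplitudes (mV).
#' @param m_max_mv maximal M-wave (mV); the base H amplitude is
#'   `h_base_fraction * m_max_mv`.
#' @param h_base_fraction calibrated H amplitude as a fraction of M-max.
#' @param m_p2p_mv mean M-wave amplitude during trials (mV).
#' @param h_subject_rel_sd,h_trial_rel_sd between-/within-subject
#'   relative SD of H amplitudes.
#' @param m_trial_rel_sd within-subject relative SD of M amplitudes.
#' @param cop_onset_trial_sd_cm,cop_peak_trial_sd_cm,cop_index_trial_sd_ms
#'   within-subject trial SDs of the COP summaries.
#' @param cop_noise_sd_cm COP sensor noise SD (cm).
#' @param joint_noise_sd_deg goniometer noise SD (degrees).
#' @param emg_trial_rel_sd within-subject relative SD of the per-trial
#'   EMG amplitude targets.
#' @param seed integer root seed.
#' @return an object of class `ps_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 29, trials_per_phase = 10,
                          n_anterior = 40,
                          conditions = ps_conditions(),
                          directions = c("posterior", "anterior"),
                          stim_phases = c("none", "SLR", "MLR", "LLR"),
                          channels = c("PLATFORM", "COP", "JOINT", "EMG"),
                          kinematics = effect_table_kinematics(),
                          emg = effect_table_emg(),
                          h_modulation = h_modulation_defaults(),
                          correlations = correlation_targets_defaults(),
                          platform = platform_params(),
                          mvc_mean_mv = c(SOL = 0.45, MG = 0.50, TA = 0.40,
                                          RF = 0.55, BF = 0.50, GMAX = 0.35),
                          m_max_mv = 8, h_base_fraction = 0.25,
                          m_p2p_mv = 1,
                          h_subject_rel_sd = 0.12, h_trial_rel_sd = 0.08,
                          m_trial_rel_sd = 0.05,
                          cop_onset_trial_sd_cm = 0.1,
                          cop_peak_trial_sd_cm = 0.3,
                          cop_index_trial_sd_ms = 20,
                          cop_noise_sd_cm = 0.03,
                          joint_noise_sd_deg = 0.1,
                          emg_trial_rel_sd = 0.10,
                          seed = 1L) {
  check_scalar_num(n_subjects, "n_subjects", positive = TRUE)
  check_scalar_num(trials_per_phase, "trials_per_phase", positive = TRUE)
  check_scalar_num(n_anterior, "n_anterior", min = 0)
  conditions <- match.arg(conditions, ps_conditions(), several.ok = TRUE)
  directions <- match.arg(directions, c("posterior", "anterior"),
                          several.ok = TRUE)
  stim_phases <- match.arg(stim_phases, c("none", "SLR", "MLR", "LLR"),
                           several.ok = TRUE)
  channels <- match.arg(channels, c("PLATFORM", "COP", "JOINT", "EMG"),
                        several.ok = TRUE)
  if (any(kinematics$sd < 0) || any(emg$sd_pct < 0))
    abort_ps("effect-table SDs must be >= 0", "ps_invalid_parameter")
  if (any(abs(correlations$vs_peak$rho) > 1) ||
      any(abs(correlations$anchor) > 1))
    abort_ps("rank-correlation targets must lie in [-1, 1]",
             "ps_invalid_parameter")
  structure(list(
    n_subjects = as.integer(n_subjects),
    trials_per_phase = as.integer(trials_per_phase),
    n_anterior = as.integer(n_anterior),
    conditions = conditions, directions = directions,
    stim_phases = stim_phases, channels = channels,
    kinematics = kinematics, emg = emg, h_modulation = h_modulation,
    correlations = correlations, platform = platform,
    mvc_mean_mv = mvc_mean_mv, m_max_mv = m_max_mv,
    h_base_fraction = h_base_fraction, m_p2p_mv = m_p2p_mv,
    h_subject_rel_sd = h_subject_rel_sd, h_trial_rel_sd = h_trial_rel_sd,
    m_trial_rel_sd = m_trial_rel_sd,
    cop_onset_trial_sd_cm = cop_onset_trial_sd_cm,
    cop_peak_trial_sd_cm = cop_peak_trial_sd_cm,
    cop_index_trial_sd_ms = cop_index_trial_sd_ms,
    cop_noise_sd_cm = cop_noise_sd_cm,
    joint_noise_sd_deg = joint_noise_sd_deg,
    emg_trial_rel_sd = emg_trial_rel_sd,
    seed = as.integer(seed)), class = "ps_cohort_config")
}

# Loadings of the single-factor copula for one condition. Returns a
# named vector of loadings on the shared latent; unlisted variables
# load 0 (independent).
factor_loadings <- function(correlations, condition) {
  anchor <- correlations$anchor[[condition]]
  r_anchor <- spearman_to_pearson(anchor)
  lam_peak <- if (abs(r_anchor) > 0) sqrt(abs(r_anchor)) else 0.95
  lam <- c(cop_peak_cm = lam_peak)
  lam["cop_onset_cm"] <- if (abs(r_anchor) > 0) r_anchor / lam_peak else 0
  idx <- correlations$peak_index[[condition]] %||% 0
  lam["cop_peak_index_ms"] <- spearman_to_pearson(idx) / lam_peak
  vp <- correlations$vs_peak
  vp <- vp[vp$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(vp))) {
    l <- spearman_to_pearson(vp$rho[i]) / lam_peak
    if (abs(l) > 1)
      abort_ps(sprintf(
        "correlation target (%s, cop_peak_cm) = %.3f in condition '%s' is not attainable with the shared-factor copula",
        vp$variable[i], vp$rho[i], condition), "ps_correlation_infeasible")
    lam[vp$variable[i]] <- l
  }
  lam
}

# Draw subject-level values for one subject x condition. Returns a
# named numeric vector covering all kinematic variables, emg_<MUS>_<PH>
# (in %MVC) and h_<PHASE> (multiplicative H factors).
draw_subject_level <- function(config, condition, z_shared) {
  lam <- factor_loadings(config$correlations, condition)
  kin <- config$kinematics[config$kinematics$condition == condition, ]
  emg <- config$emg[config$emg$condition == condition, ]
  hmod <- config$h_modulation[, condition]
  vars <- c(kin$variable,
            sprintf("emg_%s_%s", emg$muscle, emg$phase),
            sprintf("h_%s", rownames(config$h_modulation)))
  means <- c(kin$mean, emg$mean_pct, hmod)
  sds <- c(kin$sd, emg$sd_pct, hmod * config$h_subject_rel_sd)
  names(means) <- names(sds) <- vars
  l <- ifelse(vars %in% names(lam), lam[vars], 0)
  eps <- stats::rnorm(length(vars))
  x <- means + sds * (l * z_shared + sqrt(pmax(0, 1 - l^2)) * eps)
  names(x) <- vars
  # physiological floors/ceilings
  em <- grepl("^emg_", vars)
  x[em] <- pmax(x[em], 0.01 * means[em])
  x[grepl("^h_", vars)] <- pmax(x[grepl("^h_", vars)], 0.05)
  x["cop_peak_index_ms"] <- min(max(x["cop_peak_index_ms"], 140), 480)
  for (j in c("hip", "knee", "ankle")) {
    x[sprintf("%s_excursion_deg", j)] <- max(x[sprintf("%s_excursion_deg", j)], 0.05)
    x[sprintf("%s_peak_index_ms", j)] <-
      min(max(x[sprintf("%s_peak_index_ms", j)], 100), 480)
  }
  x
}

# Smooth unit excursion profile peaking exactly at t = index_ms and
# partially recovering thereafter.
excursion_profile <- function(t_ms, index_ms) {
  platform_profile(t_ms, index_ms) * (1 - 0.35 * platform_profile(t_ms - index_ms, 400))
}

# Synthesize one trial around subject-level values. `sub` is the named
# subject-level vector; returns a trial record (list).
synth_trial <- function(config, sub, subject_id, condition, direction,
                        stim_phase, trial_no, mvc_mv = config$mvc_mean_mv) {
  n1k <- 1000L; onset1k <- 201L
  n100 <- 100L; onset100 <- 21L
  rec <- list(subject = subject_id, condition = condition,
              direction = direction, stim_phase = stim_phase,
              trial = trial_no, sr_fast = 1000, sr_cop = 100,
              onset_sample = onset1k, cop_onset_sample = onset100,
              stim_time_ms = NA_real_)
  # per-trial kinematic truth
  peak <- sub[["cop_peak_cm"]] + stats::rnorm(1, 0, config$cop_peak_trial_sd_cm)
  onsetv <- sub[["cop_onset_cm"]] + stats::rnorm(1, 0, config$cop_onset_trial_sd_cm)
  index <- min(max(sub[["cop_peak_index_ms"]] +
                     stats::rnorm(1, 0, config$cop_index_trial_sd_ms), 140), 480)
  if (direction == "anterior") { peak <- -peak; onsetv <- -onsetv }
  rec$truth <- list(cop_onset_cm = onsetv, cop_peak_cm = peak,
                    cop_peak_index_ms = index)
  if ("PLATFORM" %in% config$channels) {
    pl <- config$platform
    pl$direction <- direction
    tr <- generate_platform_trajectory(pl, 1000, n1k, onset1k, noise = TRUE)
    rec$platform <- tr$displacement_cm
  }
  if ("COP" %in% config$channels) {
    t_ms <- (seq_len(n100) - onset100) * 10
    cop <- onsetv + peak * excursion_profile(t_ms, index) +
      stats::rnorm(n100, 0, config$cop_noise_sd_cm)
    rec$cop <- cop
  }
  if ("JOINT" %in% config$channels) {
    t_ms <- (seq_len(n1k) - onset1k)
    joints <- matrix(0, n1k, 3, dimnames = list(NULL, c("ANKLE", "KNEE", "HIP")))
    for (j in c("ankle", "knee", "hip")) {
      exc <- max(0.02, sub[[sprintf("%s_excursion_deg", j)]] *
                   max(0.2, stats::rnorm(1, 1, 0.15)))
      idx <- min(max(sub[[sprintf("%s_peak_index_ms", j)]] +
                       stats::rnorm(1, 0, 20), 100), 480)
      ang <- sub[[sprintf("%s_onset_deg", j)]] -
        exc * excursion_profile(t_ms, idx) +
        stats::rnorm(n1k, 0, config$joint_noise_sd_deg)
      joints[, toupper(j)] <- ang
    }
    rec$joints <- joints
  }
  if ("EMG" %in% config$channels) {
    tgt <- matrix(0, length(ps_muscles()), length(ps_phases()),
                  dimnames = list(ps_muscles(), ps_phases()))
    for (mus in ps_muscles()) for (ph in ps_phases()) {
      pct <- sub[[sprintf("emg_%s_%s", mus, ph)]] *
        max(0.2, stats::rnorm(1, 1, config$emg_trial_rel_sd))
      tgt[mus, ph] <- pct / 100 * mvc_mv[[mus]]
    }
    h_p2p <- m_p2p <- NA_real_
    if (stim_phase != "none") {
      h_p2p <- config$h_base_fraction * config$m_max_mv *
        sub[[sprintf("h_%s", stim_phase)]] *
        max(0.2, stats::rnorm(1, 1, config$h_trial_rel_sd))
      m_p2p <- config$m_p2p_mv * max(0.2, stats::rnorm(1, 1, config$m_trial_rel_sd))
    }
    et <- generate_emg_trial(condition, direction, stim_phase, tgt,
                             bmr_end_ms = index, h_p2p_mv = h_p2p,
                             m_p2p_mv = m_p2p, n_samples = n1k,
                             onset_sample = onset1k)
    rec$emg <- et$emg
    rec$stim_time_ms <- et$truth$stim_time_ms
    rec$truth$h_p2p_mv <- h_p2p
    rec$truth$m_p2p_mv <- m_p2p
    rec$truth$emg_target_amp_mv <- tgt
  }
  rec
}

#' Generate a synthetic cohort
#'
#' Draws subject-level summaries from the copula model and synthesizes
#' every trial. Per subject and condition the posterior trials are split
#' `trials_per_phase` per stimulation phase (none/SLR/MLR/LLR by
#' default) and `n_anterior` unstimulated anterior trials are added.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()] object.
#' @param out_dir optional directory: subjects are written to disk as
#'   they are generated (see [write_cohort()] for the layout) and their
#'   waveforms dropped from memory, keeping large cohorts tractable.
#' @return an object of class `ps_cohort`: list with `config`,
#'   `subject_truth` (long data.frame of subject-level values),
#'   `metadata` (one row per trial) and, when `out_dir` is `NULL`,
#'   `subjects` (per-subject list of trial records and MVC recordings).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "ps_cohort_config"))
  for (cond in config$conditions) factor_loadings(config$correlations, cond)
  keep <- is.null(out_dir)
  if (!keep) init_cohort_dir(out_dir, config)
  subjects <- list()
  truth_rows <- list()
  meta_rows <- list()
  stim_levels <- intersect(c("none", "SLR", "MLR", "LLR"), config$stim_phases)
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("s%02d", s)
    set.seed(child_seed(config$seed, 1000 + s))
    mvc <- NULL
    mvc_sub <- config$mvc_mean_mv  # subject's own MVC level: the
    if ("EMG" %in% config$channels) {  # reference all %MVC values use
      mvc_sub <- config$mvc_mean_mv * pmax(0.5, stats::rnorm(
        length(config$mvc_mean_mv), 1, 0.08))
      names(mvc_sub) <- names(config$mvc_mean_mv)
      mvc <- generate_mvc_recordings(mvc_sub)
    }
    trials <- list()
    for (cond in config$conditions) {
      z <- stats::rnorm(1)
      sub <- draw_subject_level(config, cond, z)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        subject = sid, condition = cond, variable = names(sub),
        value = unname(sub), stringsAsFactors = FALSE)
      plan <- NULL
      if ("posterior" %in% config$directions)
        plan <- data.frame(direction = "posterior",
                           stim_phase = rep(stim_levels,
                                            each = config$trials_per_phase),
                           stringsAsFactors = FALSE)
      if ("anterior" %in% config$directions && config$n_anterior > 0)
        plan <- rbind(plan, data.frame(direction = "anterior",
                                       stim_phase = rep("none", config$n_anterior),
                                       stringsAsFactors = FALSE))
      if (is.null(plan) || nrow(plan) == 0) next
      for (k in seq_len(nrow(plan))) {
        tr <- synth_trial(config, sub, sid, cond, plan$direction[k],
                          plan$stim_phase[k], k, mvc_mv = mvc_sub)
        meta_rows[[length(meta_rows) + 1]] <- data.frame(
          subject = sid, condition = cond, direction = plan$direction[k],
          stim_phase = plan$stim_phase[k], trial = k,
          onset_sample = tr$onset_sample,
          cop_onset_sample = tr$cop_onset_sample,
          stim_time_ms = tr$stim_time_ms, stringsAsFactors = FALSE)
        trials[[length(trials) + 1]] <- tr
      }
    }
    if (keep) {
      subjects[[sid]] <- list(mvc = mvc, trials = trials)
    } else {
      write_subject(out_dir, sid, mvc, trials)
    }
  }
  cohort <- structure(list(
    config = config,
    subject_truth = do.call(rbind, truth_rows),
    metadata = do.call(rbind, meta_rows),
    subjects = if (keep) subjects else NULL,
    dir = out_dir), class = "ps_cohort")
  if (!keep) finalize_cohort_dir(out_dir, cohort)
  cohort
}

#' @export
print.ps_cohort <- function(x, ...) {
  cat(sprintf("<ps_cohort> %d subjects, %d trials (%s)\n",
              x$config$n_subjects, nrow(x$metadata),
              paste(x$config$conditions, collapse = "/")))
  invisible(x)
}
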