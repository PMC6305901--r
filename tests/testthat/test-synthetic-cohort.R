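# Forward model: platform trajectories, EMG trials, recruitment curves,
# whole cohorts.

test_that("platform trajectory realizes the commanded excursion", {
  pp <- platform_params()
  tr <- generate_platform_trajectory(pp, noise = FALSE)
  # posterior is negative; plateau minus baseline equals -amplitude
  expect_equal(tr$displacement_cm[1000] - tr$displacement_cm[1], -3)
  expect_equal(tr$displacement_cm[100], 0)  # before onset
  ant <- generate_platform_trajectory(platform_params(direction = "anterior"),
                                      noise = FALSE)
  expect_equal(ant$displacement_cm[1000], 3)
  # rise completed within the commanded duration
  i_end <- 201 + 210
  expect_equal(tr$displacement_cm[i_end], -3, tolerance = 1e-12)
})

test_that("degenerate platform parameters are rejected", {
  expect_error(platform_params(amplitude_cm = 0), class = "ps_invalid_parameter")
  expect_error(platform_params(duration_ms = -5), class = "ps_invalid_parameter")
  expect_error(platform_params(iti_range_s = c(8, 4)), class = "ps_invalid_parameter")
})

test_that("noisy ensemble re-estimates the commanded amplitude within 2 SE", {
  pp <- platform_params()
  rec <- generate_platform_recording(pp, 40, seed = 7)
  onsets <- detect_onsets(rec$displacement_cm, rec$sample_rate)
  expect_length(onsets, 40)
  amps <- vapply(onsets, function(o)
    abs(platform_metrics(rec$displacement_cm, rec$sample_rate, o)$amplitude_cm),
    numeric(1))
  se <- sd(amps) / sqrt(length(amps))
  expect_lt(abs(mean(amps) - 3), 2 * se + 1e-9)
})

test_that("EMG trial generator calibrates window amplitudes and zero case", {
  tgt <- matrix(0, 6, 5, dimnames = list(
    c("SOL", "MG", "TA", "RF", "BF", "GMAX"),
    c("PRE", "SLR", "MLR", "LLR", "BMR")))
  # all-zero targets -> exactly flat channels
  et0 <- generate_emg_trial("predicted", "posterior", "none", tgt, seed = 1)
  expect_true(all(et0$emg == 0))
  # nontrivial targets: realized window means match in expectation
  tgt["SOL", ] <- c(2, 3, 4, 6, 5) * 1e-3
  tgt["TA", ] <- c(4, 1, 1, 1, 1) * 1e-3
  set.seed(5)
  means <- replicate(40, {
    et <- generate_emg_trial("cheated", "posterior", "none", tgt,
                             bmr_end_ms = 344)
    sapply(list(PRE = c(-100, 0), SLR = c(30, 60), MLR = c(60, 85),
                LLR = c(85, 120), BMR = c(120, 344)), function(w) {
      idx <- which((seq_len(1000) - 201) >= w[1] & (seq_len(1000) - 201) < w[2])
      mean(abs(et$emg[idx, "SOL"]))
    })
  })
  got <- rowMeans(means)
  se <- apply(means, 1, sd) / sqrt(ncol(means))
  expect_true(all(abs(got - tgt["SOL", ]) < 3 * se + 1e-6))
  # TA pre-activation exceeds SOL's under a cheated-style pre-set
  et <- generate_emg_trial("cheated", "posterior", "none", tgt, seed = 8)
  pre_idx <- which((seq_len(1000) - 201) >= -100 & (seq_len(1000) - 201) < 0)
  expect_gt(mean(abs(et$emg[pre_idx, "TA"])), mean(abs(et$emg[pre_idx, "SOL"])))
})

test_that("stimulated trials insert ordered artifact/M/H with scaled H", {
  tgt <- matrix(1e-4, 6, 5, dimnames = list(
    c("SOL", "MG", "TA", "RF", "BF", "GMAX"),
    c("PRE", "SLR", "MLR", "LLR", "BMR")))
  et1 <- generate_emg_trial("predicted", "posterior", "LLR", tgt,
                            h_p2p_mv = 2, m_p2p_mv = 1, seed = 2)
  et2 <- generate_emg_trial("cheated", "posterior", "LLR", tgt,
                            h_p2p_mv = 2 * 1.4, m_p2p_mv = 1, seed = 2)
  expect_equal(et1$truth$stim_time_ms, 100)  # LLR peak latency default
  # extract with the analysis windows; noise floor is ~1e-4 so the
  # configured modulation factor is recovered essentially exactly
  h1 <- peak_to_peak(et1$emg[, "SOL"], 100 + c(25, 55), 201, 1000)
  h2 <- peak_to_peak(et2$emg[, "SOL"], 100 + c(25, 55), 201, 1000)
  expect_equal(h2 / h1, 1.4, tolerance = 0.02)
  m1 <- peak_to_peak(et1$emg[, "SOL"], 100 + c(5, 25), 201, 1000)
  expect_equal(m1, 1, tolerance = 0.02)
  expect_error(generate_emg_trial("nonsense", "posterior", "none", tgt))
})

test_that("recruitment curve generator honours its invariants", {
  par <- hm_curve_params()
  grid <- seq(0.5, 3, length.out = 80)
  cur <- generate_hm_curve_samples(par, grid)
  expect_true(all(diff(cur$m_mv) >= -1e-12))          # monotone M
  expect_true(all(cur$m_mv <= par$m_max_mv + 1e-9))   # saturation bound
  expect_equal(max(cur$m_mv), par$m_max_mv, tolerance = 5e-3)
  # H is unimodal with its maximum at h_peak_intensity
  i_pk <- which.max(cur$h_mv)
  expect_equal(grid[i_pk], par$h_peak_intensity, tolerance = 0.05)
  expect_true(all(diff(cur$h_mv[seq_len(i_pk)]) >= -1e-9))
  expect_true(all(diff(cur$h_mv[i_pk:length(grid)]) <= 1e-9))
  expect_error(generate_hm_curve_samples(par, numeric(0)),
               class = "ps_invalid_parameter")
  expect_error(generate_hm_curve_samples(par, c(2, 1)),
               class = "ps_invalid_parameter")
})

test_that("cohort bookkeeping matches the protocol and is deterministic", {
  cfg <- tiny_cohort_config()
  co <- generate_cohort(cfg)
  md <- co$metadata
  post <- md[md$direction == "posterior", ]
  counts <- table(post$subject, post$condition, post$stim_phase)
  expect_true(all(counts == cfg$trials_per_phase))
  ant <- md[md$direction == "anterior", ]
  expect_true(all(table(ant$subject, ant$condition) == cfg$n_anterior))
  expect_true(all(ant$stim_phase == "none"))
  # determinism: identical config => identical cohort
  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)
})

test_that("ensemble recovery: cohort means match configured effect tables", {
  cfg <- cohort_config(n_subjects = 24, trials_per_phase = 1, n_anterior = 0,
                       conditions = c("predicted", "cheated"),
                       stim_phases = "none", channels = "COP", seed = 33)
  co <- generate_cohort(cfg)
  truth <- truth_summary(co)
  kin <- effect_table_kinematics()
  for (cond in c("predicted", "cheated")) {
    for (v in c("cop_onset_cm", "cop_peak_cm", "ankle_excursion_deg",
                "emg_SOL_LLR", "emg_TA_PRE")) {
      x <- truth$value[truth$condition == cond & truth$variable == v]
      row <- kin[kin$variable == v & kin$condition == cond, ]
      target <- if (nrow(row)) row$mean else
        subset(effect_table_emg(),
               sprintf("emg_%s_%s", muscle, phase) == v &
                 condition == cond)$mean_pct
      se <- sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - target), 3 * se + 1e-9)
    }
  }
})

test_that("copula targets propagate to subject-level rank correlations", {
  # oracle: for a bivariate Gaussian copula with latent Pearson r, the
  # expected sample Spearman at size n is
  #   E[r_s] = 6 / (pi (n + 1)) * (asin(r) + (n - 2) asin(r / 2))
  # (the population value 0.771 is approached only as n -> infinity)
  n <- 12
  r_lat <- spearman_to_pearson(0.771)
  expected <- 6 / (pi * (n + 1)) * (asin(r_lat) + (n - 2) * asin(r_lat / 2))
  rs <- vapply(1:60, function(k) {
    cfg <- cohort_config(n_subjects = n, trials_per_phase = 1,
                         n_anterior = 0, conditions = "cheated",
                         stim_phases = "none", channels = "COP",
                         seed = child_seed(77, k))
    truth <- truth_summary(generate_cohort(cfg))
    on <- truth$value[truth$variable == "cop_onset_cm"]
    pk <- truth$value[truth$variable == "cop_peak_cm"]
    cor(on, pk, method = "spearman")
  }, numeric(1))
  mc <- 3 * sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs) - expected), mc + 0.01)
})

test_that("infeasible correlation targets raise a named error", {
  bad <- correlation_targets_defaults()
  bad$vs_peak <- rbind(bad$vs_peak,
                       data.frame(condition = "predicted",
                                  variable = "emg_MG_PRE", rho = 0.99))
  expect_error(generate_cohort(cohort_config(n_subjects = 1,
                                             correlations = bad)),
               regexp = "emg_MG_PRE", class = "ps_correlation_infeasible")
})

test_that("MVC recordings carry a plateau at the nominal amplitude", {
  mvc <- generate_mvc_recordings(c(SOL = 0.5, MG = 0.5, TA = 0.4, RF = 0.5,
                                   BF = 0.5, GMAX = 0.4), seed = 3)
  x <- abs(mvc$recordings[1000:2000, "SOL_r1"])
  expect_equal(mean(x), 0.5, tolerance = 0.12)  # rep scaling is +/-5%
  expect_equal(dim(mvc$recordings), c(3000, 18))
})
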