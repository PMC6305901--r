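# Recruitment-curve calibration and H/M extraction.

test_that("calibration hits the target fraction of M-max", {
  cur <- generate_hm_curve_samples(hm_curve_params(),
                                   seq(0.8, 2.5, length.out = 50))
  i <- calibrate_intensity(cur)
  h_at <- approx(cur$intensity, cur$h_mv, i)$y
  expect_equal(h_at / cur$m_max_mv, 0.25, tolerance = 0.01)
  # on the ascending limb
  expect_lt(i, cur$intensity[which.max(cur$h_mv)])
  # target 0 -> lowest grid intensity (curve origin)
  expect_equal(calibrate_intensity(cur, 0), cur$intensity[1])
  # monotone in the target fraction
  i2 <- calibrate_intensity(cur, 0.4)
  expect_gt(i2, i)
  # unreachable target reports the achievable fraction
  err <- tryCatch(calibrate_intensity(cur, 0.99), condition = identity)
  expect_s3_class(err, "ps_unreachable_target")
  expect_lt(err$max_fraction, 0.99)
})

test_that("interpolated calibration agrees with dense brute force", {
  par <- hm_curve_params()
  grid <- seq(0.8, 2.5, length.out = 50)
  cur <- generate_hm_curve_samples(par, grid)
  i <- calibrate_intensity(cur)
  dense <- seq(0.8, 2.5, length.out = 20000)
  dc <- generate_hm_curve_samples(par, dense)
  target <- 0.25 * cur$m_max_mv
  asc <- seq_len(which.max(dc$h_mv))
  i_brute <- dense[asc][which(dc$h_mv[asc] >= target)[1]]
  expect_lt(abs(i - i_brute), diff(grid[1:2]))
})

test_that("peak_to_peak closed forms and offset invariance", {
  sr <- 1000
  t <- (seq_len(600) - 101) / sr
  s <- 1.7 * sin(2 * pi * 20 * t)
  # sampling at 1 kHz can miss the continuous extremum by cos(pi/50)
  expect_equal(peak_to_peak(s, c(0, 100), 101, sr), 2 * 1.7, tolerance = 5e-3)
  expect_equal(peak_to_peak(rep(3, 600), c(0, 100), 101, sr), 0)
  expect_equal(peak_to_peak(s + 42, c(0, 100), 101, sr),
               peak_to_peak(s, c(0, 100), 101, sr))
  expect_error(peak_to_peak(s, c(50, 50), 101, sr), class = "ps_bounds_error")
})

test_that("inserted H wavelet amplitude is recovered within 2%", {
  tgt <- matrix(0, 6, 5, dimnames = list(
    c("SOL", "MG", "TA", "RF", "BF", "GMAX"),
    c("PRE", "SLR", "MLR", "LLR", "BMR")))
  et <- generate_emg_trial("predicted", "posterior", "MLR", tgt,
                           h_p2p_mv = 1.6, m_p2p_mv = 0.9, seed = 4)
  stim <- et$truth$stim_time_ms
  h <- peak_to_peak(et$emg[, "SOL"], stim + c(25, 55), 201, 1000)
  m <- peak_to_peak(et$emg[, "SOL"], stim + c(5, 25), 201, 1000)
  expect_equal(h, 1.6, tolerance = 0.02)
  expect_equal(m, 0.9, tolerance = 0.02)
})

test_that("extract_hm enforces its contract and recovers modulation", {
  cfg <- cohort_config(n_subjects = 3, trials_per_phase = 4, n_anterior = 0,
                       conditions = c("predicted", "cheated"),
                       channels = c("COP", "EMG"), seed = 5)
  co <- generate_cohort(cfg)
  eps <- unlist(lapply(co$subjects, function(s) lapply(s$trials, epoch_trial)),
                recursive = FALSE)
  unstim <- eps[[which(vapply(eps, function(e) e$stim_phase == "none",
                              logical(1)))[1]]]
  expect_error(extract_hm(unstim), class = "ps_precondition_error")
  hm <- hm_table(eps)
  # bookkeeping: one row per stimulated, unflagged trial
  n_stim <- sum(co$metadata$stim_phase != "none")
  expect_equal(nrow(hm), n_stim)
  # LLR cheated/predicted ratio approximates the configured 1.4 factor;
  # per-subject truth has 12% between-subject spread, so compare to the
  # generator's own subject-level values
  truth <- truth_summary(co)
  want <- mean(truth$value[truth$variable == "h_LLR" &
                             truth$condition == "cheated"]) /
    mean(truth$value[truth$variable == "h_LLR" &
                       truth$condition == "predicted"])
  a <- aggregate(h_mv ~ condition, hm[hm$stim_phase == "LLR", ], mean)
  got <- a$h_mv[a$condition == "cheated"] / a$h_mv[a$condition == "predicted"]
  expect_equal(got, want, tolerance = 0.05)
  # M amplitudes constant across conditions within noise
  am <- aggregate(m_mv ~ condition, hm, mean)
  expect_lt(abs(diff(am$m_mv)), 0.1)
  # normalization: predicted rows average to 100 per subject x phase
  pred <- hm[hm$condition == "predicted", ]
  a100 <- aggregate(h_pct_predicted ~ subject + stim_phase, pred, mean)
  expect_true(all(abs(a100$h_pct_predicted - 100) < 1e-9))
})
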