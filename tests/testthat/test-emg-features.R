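# Phase windows, rectified integrals, normalization, MVC reference,
# reflex-peak detection.

test_that("phase windows tile correctly and reject degenerate peaks", {
  w <- build_phase_windows(344)
  expect_equal(w$BMR, c(120, 344))
  expect_equal(w$PRE, c(-100, 0))
  # boundaries: PRE then the 0-30 ms gap, then contiguous windows
  ends <- c(w$SLR[2], w$MLR[2])
  starts <- c(w$MLR[1], w$LLR[1])
  expect_equal(starts, ends)
  expect_equal(w$SLR[1] - w$PRE[2], 30)
  expect_error(build_phase_windows(120), class = "ps_degenerate_bmr")
  expect_error(build_phase_windows(501), class = "ps_degenerate_bmr")
})

test_that("rectified integral: closed forms, oracle, additivity", {
  sr <- 1000
  epoch <- rep(2, 600)   # constant +2 mV
  expect_equal(rectified_integral(epoch, c(30, 60), 101, sr), 0.06)
  expect_equal(rectified_integral(-epoch, c(30, 60), 101, sr), 0.06)
  expect_error(rectified_integral(epoch, c(400, 600), 101, sr),
               class = "ps_bounds_error")
  set.seed(12)
  for (k in 1:5) {
    x <- rnorm(600)
    w <- sort(sample(seq(-100, 499), 2))
    if (w[1] == w[2]) w[2] <- w[2] + 1
    got <- rectified_integral(x, w, 101, sr)
    want <- oracle_rectified_integral(x, w[1], w[2], 101, sr)
    expect_equal(got, want, tolerance = 1e-9)
    # additivity over a split point
    m <- floor(mean(w))
    if (m > w[1] && m < w[2]) {
      s <- rectified_integral(x, c(w[1], m), 101, sr) +
        rectified_integral(x, c(m, w[2]), 101, sr)
      expect_equal(s, got, tolerance = 1e-9)
    }
  }
})

test_that("normalization arithmetic and homogeneity", {
  mvc <- structure(list(mean_mv = c(SOL = 2)), class = "ps_mvc_reference")
  f <- normalize_features(0.06, 30, mvc, "SOL")
  expect_equal(f$mean_mv, 2)       # 0.06 mV*s over 30 ms
  expect_equal(f$pct_mvc, 100)     # identical to the reference
  f2 <- normalize_features(0.12, 30, mvc, "SOL")
  expect_equal(f2$pct_mvc, 200)    # doubling raw EMG doubles %MVC
  # scaling EMG and MVC together leaves %MVC unchanged
  mvc10 <- structure(list(mean_mv = c(SOL = 20)), class = "ps_mvc_reference")
  expect_equal(normalize_features(0.6, 30, mvc10, "SOL")$pct_mvc, f$pct_mvc)
  expect_error(normalize_features(0.06, 30,
                                  structure(list(mean_mv = c(SOL = 0)),
                                            class = "ps_mvc_reference"),
                                  "SOL"),
               regexp = "SOL", class = "ps_zero_mvc")
})

test_that("MVC reference selects the largest trial, order-invariantly", {
  n <- 3000
  mk <- function(peak) { x <- rep(0.1, n); x[1500] <- peak; x }
  trials <- list(SOL = cbind(mk(1), mk(2), mk(3)))
  ref <- extract_mvc_reference(trials)
  expect_equal(unname(ref$selected_rep["SOL"]), 3L)
  perm <- list(SOL = trials$SOL[, c(3, 1, 2)])
  ref2 <- extract_mvc_reference(perm)
  expect_equal(ref$mean_mv, ref2$mean_mv)
  # peak near the edge: clipped window, manual integral agrees
  edge <- rep(0.1, n); edge[20] <- 5
  expect_warning(ref3 <- extract_mvc_reference(list(SOL = cbind(edge))),
                 "clipped")
  manual <- sum(abs(edge[1:(20 + 49)])) / 1000 / ((20 + 49) / 1000)
  expect_equal(unname(ref3$mean_mv["SOL"]), manual)
  expect_error(extract_mvc_reference(list(SOL = cbind(rep(0, n)))),
               class = "ps_zero_mvc")
})

test_that("reflex peaks are recovered from familiarization ensembles", {
  # noise-free-ish ensemble with bursts at the default 45/72/100 ms
  tgt <- matrix(1e-3, 6, 5, dimnames = list(
    c("SOL", "MG", "TA", "RF", "BF", "GMAX"),
    c("PRE", "SLR", "MLR", "LLR", "BMR")))
  tgt["SOL", c("SLR", "MLR", "LLR")] <- c(8, 10, 12) * 1e-3
  set.seed(3)
  trials <- lapply(1:20, function(i) {
    et <- generate_emg_trial("predicted", "posterior", "none", tgt)
    structure(list(emg = et$emg[101:700, , drop = FALSE], sr_fast = 1000,
                   onset_sample = 101L, stim_phase = "none"),
              class = "ps_trial_epoch")
  })
  pk <- detect_reflex_peaks(trials)
  expect_true(abs(pk[["SLR"]] - 45) <= 6)
  expect_true(abs(pk[["MLR"]] - 72) <= 6)
  expect_true(abs(pk[["LLR"]] - 100) <= 6)
  # latencies always inside their windows by construction
  expect_true(pk[["SLR"]] >= 30 && pk[["SLR"]] < 60)
  expect_true(pk[["MLR"]] >= 60 && pk[["MLR"]] < 85)
  expect_true(pk[["LLR"]] >= 85 && pk[["LLR"]] < 120)
  # flat ensemble: earliest sample per window, flagged
  flat <- lapply(1:3, function(i)
    structure(list(emg = matrix(0, 600, 6,
                                dimnames = list(NULL, rownames(tgt))),
                   sr_fast = 1000, onset_sample = 101L, stim_phase = "none"),
              class = "ps_trial_epoch"))
  pf <- detect_reflex_peaks(flat)
  expect_equal(as.numeric(pf), c(30, 60, 85))
  expect_true(attr(pf, "low_confidence"))
  expect_error(detect_reflex_peaks(flat[1]), class = "ps_invalid_parameter")
})

test_that("feature table excludes stimulated trials and degenerate BMR", {
  cfg <- cohort_config(n_subjects = 1, trials_per_phase = 2, n_anterior = 0,
                       conditions = "predicted", seed = 21)
  co <- generate_cohort(cfg)
  s1 <- co$subjects$s01
  eps <- lapply(s1$trials, epoch_trial)
  mvc <- extract_mvc_reference(lapply(
    setNames(nm = c("SOL", "MG", "TA", "RF", "BF", "GMAX")),
    function(m) s1$mvc$recordings[, grep(paste0("^", m, "_r"),
                                         colnames(s1$mvc$recordings))]))
  ft <- emg_feature_table(eps, mvc)
  # only the unstimulated trials contribute
  stim_ids <- unique(co$metadata$trial[co$metadata$stim_phase != "none"])
  expect_false(any(ft$trial %in% stim_ids))
  expect_true(all(ft$iemg_mvs >= 0) && all(ft$pct_mvc >= 0))
  # per-trial BMR endpoint equals the trial's COP peak latency
  tr1 <- eps[[which(vapply(eps, function(e) e$stim_phase == "none",
                           logical(1)))[1]]]
  cm <- cop_metrics(tr1$cop, tr1$cop_onset_sample, tr1$sr_cop)
  bmr <- ft[ft$trial == tr1$trial & ft$muscle == "SOL" & ft$phase == "BMR", ]
  manual <- rectified_integral(tr1$emg[, "SOL"], c(120, cm$peak_index_ms),
                               tr1$onset_sample, tr1$sr_fast)
  expect_equal(bmr$iemg_mvs, manual)
})
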