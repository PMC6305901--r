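# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: explicit loops, full enumeration, and
# textbook formulas only.

# Dense Riemann-sum oracle for the rectified integral over a half-open
# window: explicit loop over samples whose time lies in [a, b).
oracle_rectified_integral <- function(epoch, a_ms, b_ms, onset_sample, sr) {
  total <- 0
  for (i in seq_along(epoch)) {
    t <- (i - onset_sample) * 1000 / sr
    if (t >= a_ms - 1e-12 && t < b_ms - 1e-12) total <- total + abs(epoch[i]) / sr
  }
  total
}

# Hand-computed sums-of-squares decomposition for a balanced one-way
# repeated-measures design (subjects x k levels, one value per cell).
oracle_rm_anova_1w <- function(df, dv, factor) {
  subs <- sort(unique(as.character(df$subject)))
  levs <- sort(unique(as.character(df[[factor]])))
  n <- length(subs); k <- length(levs)
  Y <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sel <- df$subject == subs[i] & df[[factor]] == levs[j]
    Y[i, j] <- mean(df[[dv]][sel])
  }
  gm <- mean(Y)
  m_lev <- colMeans(Y); m_sub <- rowMeans(Y)
  ss_eff <- n * sum((m_lev - gm)^2)
  ss_err <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_err <- ss_err + (Y[i, j] - m_lev[j] - m_sub[i] + gm)^2
  F <- (ss_eff / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(F = F, pes = ss_eff / (ss_eff + ss_err),
       ss_effect = ss_eff, ss_error = ss_err)
}

# All permutations of 1..n (n <= 7 in tests), recursively.
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# Exhaustive two-sided permutation p for Spearman's rho, no ties.
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  robs <- cor(rx, ry)
  P <- oracle_perms(n)
  rs <- apply(P, 1, function(p) cor(rx, ry[p]))
  mean(abs(rs) >= abs(robs) - 1e-12)
}

# Plain Benjamini-Hochberg rejections (step-up without the c(m) term).
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Minimal cohort configs used by several files (small and fast).
tiny_cohort_config <- function(...) {
  cohort_config(n_subjects = 2, trials_per_phase = 2, n_anterior = 2,
                seed = 101, ...)
}

null_correlations <- function() {
  list(anchor = c(predicted = 0, unpredicted = 0, cheated = 0),
       peak_index = c(predicted = 0, unpredicted = 0, cheated = 0),
       vs_peak = data.frame(condition = character(0),
                            variable = character(0), rho = numeric(0)))
}

# Subject-level summary table straight from generator truth (bypasses
# waveform extraction; used where only the statistics are under test).
truth_summary <- function(cohort) {
  df <- cohort$subject_truth
  names(df) <- c("subject", "condition", "variable", "value")
  df
}
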