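# Condition normalization, rmANOVA, Spearman, FDR.

test_that("normalize_to_predicted arithmetic and monotone invariance", {
  df <- expand.grid(subject = c("s1", "s2"),
                    condition = c("predicted", "cheated"),
                    variable = "v", stringsAsFactors = FALSE)
  df$value <- c(10, 20, 20, 50)  # predicted s1/s2, cheated s1/s2
  out <- normalize_to_predicted(df)
  expect_equal(out$pct_predicted[out$condition == "predicted"], c(100, 100))
  expect_equal(out$pct_predicted[out$condition == "cheated"], c(200, 250))
  # zero predicted mean: variable excluded and reported
  df0 <- rbind(df, data.frame(subject = c("s1", "s1"),
                              condition = c("predicted", "cheated"),
                              variable = "z", value = c(0, 4)))
  out0 <- normalize_to_predicted(df0)
  expect_true("z" %in% attr(out0, "excluded"))
  expect_false(any(out0$variable == "z" & out0$condition == "cheated" &
                     is.finite(out0$pct_predicted) == FALSE))
  # when the predicted-condition reference is common to all subjects,
  # normalization is a monotone rescaling and rank correlations within
  # a condition are unchanged (per-subject references reweight subjects
  # and do not have this property in general)
  set.seed(1)
  n <- 12
  d2 <- data.frame(subject = rep(sprintf("s%d", 1:n), 4),
                   condition = rep(c("predicted", "cheated"), each = 2 * n),
                   variable = rep(rep(c("a", "b"), each = n), 2),
                   value = abs(rnorm(4 * n)) + 0.5)
  d2$value[d2$condition == "predicted"] <-
    rep(c(2, 5), each = n)  # common reference per variable
  o2 <- normalize_to_predicted(d2)
  ch <- o2[o2$condition == "cheated", ]
  raw_r <- cor(ch$value[ch$variable == "a"], ch$value[ch$variable == "b"],
               method = "spearman")
  nrm_r <- cor(ch$pct_predicted[ch$variable == "a"],
               ch$pct_predicted[ch$variable == "b"], method = "spearman")
  expect_equal(raw_r, nrm_r)
})

test_that("rm_anova matches the hand-computed SS oracle to 1e-8", {
  set.seed(42)
  n <- 8
  df <- expand.grid(subject = sprintf("s%d", 1:n), cond = c("a", "b", "c"))
  df$value <- round(rnorm(nrow(df), rep(c(10, 12, 15), each = n), 2), 4)
  res <- rm_anova(df, dv = "value", within = "cond")
  ora <- oracle_rm_anova_1w(df, "value", "cond")
  expect_equal(res$F, ora$F, tolerance = 1e-8)
  expect_equal(res$pes, ora$pes, tolerance = 1e-8)
  expect_equal(res$ss_effect, ora$ss_effect, tolerance = 1e-8)
  expect_equal(res$ss_error, ora$ss_error, tolerance = 1e-8)
})

test_that("rm_anova reproduces independently validated statistics", {
  # expected values frozen from an independent implementation
  # (pingouin 0.6.1: rm_anova / sphericity / epsilon) on this fixture
  set.seed(42)
  n <- 8
  df <- expand.grid(subject = sprintf("s%d", 1:n), cond = c("a", "b", "c"))
  df$value <- round(rnorm(nrow(df), rep(c(10, 12, 15), each = n), 2), 4)
  res <- rm_anova(df, dv = "value", within = "cond")
  expect_equal(res$F, 4.242959, tolerance = 1e-6)
  expect_equal(res$mauchly_W, 0.8781714, tolerance = 1e-6)
  expect_equal(res$mauchly_p, 0.6772325, tolerance = 1e-6)
  expect_equal(res$gg_epsilon, 0.8914017, tolerance = 1e-6)
  expect_false(res$gg_applied)  # Mauchly p > 0.05 here
  expect_equal(res$p, res$p_uncorrected)
})

test_that("rm_anova two-factor decomposition and edge cases", {
  set.seed(7)
  df2 <- expand.grid(subject = sprintf("s%d", 1:6), A = c("p", "u", "c"),
                     B = c("PRE", "SLR", "MLR", "LLR"))
  df2$value <- round(rnorm(nrow(df2),
                           5 + as.integer(df2$A) +
                             0.5 * as.integer(df2$B) * as.integer(df2$A),
                           1.5), 4)
  res <- rm_anova(df2, dv = "value", within = c("A", "B"))
  expect_equal(res$effect, c("A", "B", "A:B"))
  # frozen from the same independent implementation
  expect_equal(res$F, c(51.285086, 11.007297, 3.848862), tolerance = 1e-6)
  expect_equal(res$gg_epsilon[1:2], c(0.9415114, 0.6999768), tolerance = 1e-6)
  expect_equal(res$pes[1], 0.9111665, tolerance = 1e-6)
  # the oracle for the A main effect: collapse over B, then one-way SS
  coll <- aggregate(value ~ subject + A, df2, mean)
  ora <- oracle_rm_anova_1w(coll, "value", "A")
  # SS on collapsed means scale by the number of B levels
  expect_equal(res$ss_effect[1], 4 * ora$ss_effect, tolerance = 1e-8)
  expect_equal(res$F[1], ora$F, tolerance = 1e-8)
  # all cells equal -> F = 0, pes = 0
  dfc <- df2; dfc$value <- 5
  resc <- rm_anova(dfc, dv = "value", within = c("A", "B"))
  expect_true(all(resc$F == 0) && all(resc$pes == 0))
  # two-level factor: epsilon is vacuously 1
  df3 <- df2[df2$A != "c", ]
  res3 <- rm_anova(df3, dv = "value", within = "A")
  expect_equal(res3$gg_epsilon, 1)
  # unbalanced designs name the offending subjects
  expect_error(rm_anova(df2[-1, ], dv = "value", within = c("A", "B")),
               regexp = "s1", class = "ps_unbalanced")
})

test_that("spearman_cor: closed forms and exhaustive-permutation oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_cor(x, x^3)$r, 1)
  expect_equal(spearman_cor(x, -x)$r, -1)
  und <- spearman_cor(x, rep(2, 6))
  expect_true(und$undefined)
  expect_error(spearman_cor(1:3, 1:3), class = "ps_invalid_parameter")
  set.seed(2)
  for (n in c(5, 6, 7)) {
    x <- rnorm(n); y <- rnorm(n)
    got <- spearman_cor(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p, oracle_spearman_p(x, y))
  }
  # t approximation for larger samples
  x <- rnorm(29); y <- 0.5 * x + rnorm(29)
  got <- spearman_cor(x, y)
  expect_equal(got$method, "t-approximation")
  r <- got$r
  tval <- r * sqrt((29 - 2) / (1 - r^2))
  expect_equal(got$p, 2 * pt(abs(tval), 27, lower.tail = FALSE))
  # invariance under strictly monotone transforms
  expect_equal(spearman_cor(exp(x), y)$r, r)
})

test_that("fdr_by: boundary behaviour and BH-subset property", {
  # single test: c(1) = 1 so BY is a plain alpha test
  expect_true(fdr_by(0.04, q = 0.05)$reject)
  expect_false(fdr_by(0.06, q = 0.05)$reject)
  # all p = 1 -> nothing rejected
  expect_false(any(fdr_by(rep(1, 10))$reject))
  expect_equal(nrow(fdr_by(numeric(0))), 0)
  # matches the reference step-up transform and is a BH subset
  set.seed(3)
  for (k in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    res <- fdr_by(p, q = 0.05)
    expect_equal(res$p_adjusted, p.adjust(p, method = "BY"))
    bh <- oracle_bh_reject(p, 0.05)
    expect_true(all(!res$reject | bh))  # BY rejections are a BH subset
    # step-up consistency: reject exactly the adjusted-p <= q set
    expect_equal(res$reject, res$p_adjusted <= 0.05)
  }
})

test_that("partial eta squared is invariant to affine outcome transforms", {
  set.seed(4)
  df <- expand.grid(subject = sprintf("s%d", 1:10), cond = c("a", "b", "c"))
  df$value <- rnorm(30, rep(c(1, 2, 3), each = 10))
  r1 <- rm_anova(df, dv = "value", within = "cond")
  df$value <- 7 - 3.2 * df$value
  r2 <- rm_anova(df, dv = "value", within = "cond")
  expect_equal(r1$pes, r2$pes, tolerance = 1e-10)
  expect_equal(r1$F, r2$F, tolerance = 1e-10)
})
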