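# Statistical inference: condition normalization, repeated-measures
# ANOVA with sphericity handling, Spearman correlations, and
# false-discovery-rate control under arbitrary dependence.

#' Normalize outcomes to the predicted condition
#'
#' Divides every value by the same subject's predicted-condition mean of
#' that variable and multiplies by 100, so predicted rows become 100 by
#' construction. Variables whose predicted mean is zero for a subject
#' are flagged and excluded from the normalized output.
#'
#' @param df long data.frame with columns `subject`, `condition`, a
#'   variable identifier and a value column.
#' @param value name of the value column (default `"value"`).
#' @param variable name of the variable-identifier column.
#' @return `df` with an added `pct_predicted` column; excluded rows are
#'   dropped and reported in `attr(, "excluded")`.
#' @export
normalize_to_predicted <- function(df, value = "value", variable = "variable") {
  stopifnot(all(c("subject", "condition", variable, value) %in% names(df)))
  key <- interaction(df$subject, df[[variable]], drop = TRUE)
  pred_mean <- tapply(df[[value]][df$condition == "predicted"],
                      key[df$condition == "predicted"], mean)
  base <- pred_mean[as.character(key)]
  if (anyNA(base))
    abort_ps("some subject x variable cells lack predicted-condition values",
             "ps_missing_predicted")
  zero <- base == 0
  out <- df[!zero, , drop = FALSE]
  out$pct_predicted <- as.numeric(out[[value]] / base[!zero] * 100)
  attr(out, "excluded") <- unique(df[[variable]][zero])
  out
}

orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# One within-subject effect from its contrast scores U (n x q):
# F test with its own error term, partial eta squared, Mauchly test and
# Greenhouse-Geisser epsilon.
effect_from_scores <- function(U, effect, scale2 = 1) {
  n <- nrow(U); q <- ncol(U)
  ubar <- colMeans(U)
  ss_eff <- n * sum(ubar^2)
  resid <- sweep(U, 2, ubar)
  ss_err <- sum(resid^2)
  df1 <- q; df2 <- q * (n - 1)
  # guard against pure floating-point residue (e.g. all cells equal):
  # anything below squared-machine-precision of the data scale is zero
  tol <- 1e-26 * max(scale2, .Machine$double.xmin) * n * q
  if (ss_eff < tol) ss_eff <- 0
  if (ss_err < tol) ss_err <- 0
  F <- if (ss_eff == 0) 0 else if (ss_err == 0) Inf else
    (ss_eff / df1) / (ss_err / df2)
  pes <- if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0
  if (q == 1L) {
    eps <- 1; W <- 1; p_mauchly <- NA_real_
  } else {
    S <- stats::cov(U)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    eps <- if (sum(ev^2) > 0) sum(ev)^2 / (q * sum(ev^2)) else 1
    if (n - 1 <= q) {
      # contrast covariance is singular: Mauchly's W is undefined
      W <- NA_real_; p_mauchly <- NA_real_
    } else {
      W <- if (mean(ev) > 0) prod(ev / mean(ev)) else 0
      d <- 1 - (2 * q^2 + q + 2) / (6 * q * (n - 1))
      chi2 <- -(n - 1) * d * log(max(W, .Machine$double.xmin))
      p_mauchly <- stats::pchisq(chi2, q * (q + 1) / 2 - 1, lower.tail = FALSE)
    }
  }
  p_unc <- stats::pf(F, df1, df2, lower.tail = FALSE)
  corrected <- !is.na(p_mauchly) && p_mauchly < 0.05
  p <- if (corrected) stats::pf(F, eps * df1, eps * df2, lower.tail = FALSE)
       else p_unc
  data.frame(effect = effect, F = F, df1 = df1, df2 = df2,
             p = p, p_uncorrected = p_unc, mauchly_W = W,
             mauchly_p = p_mauchly, gg_epsilon = eps,
             gg_applied = corrected, pes = pes,
             ss_effect = ss_eff, ss_error = ss_err,
             stringsAsFactors = FALSE)
}

#' Repeated-measures ANOVA for one or two within-subject factors
#'
#' Univariate rmANOVA on a balanced long table. Replicate observations
#' within a subject x cell are averaged first. Each effect (main
#' effects and, with two factors, their interaction) is tested against
#' its own subject-interaction error term; Mauchly's sphericity test is
#' computed from orthonormal contrast scores and the Greenhouse-Geisser
#' correction is applied to the degrees of freedom when Mauchly's
#' p < 0.05. Partial eta squared is `SS_effect / (SS_effect +
#' SS_error)`.
#'
#' @param df long data.frame with a `subject` column, the factor
#'   columns and a value column.
#' @param dv name of the value column.
#' @param within character vector of 1 or 2 within-factor column names
#'   (e.g. `"anticipation"`, `"phase"`, `"muscle_group"`).
#' @return data.frame with one row per effect: F, df, p (sphericity
#'   corrected when applicable), Mauchly statistics, epsilon, partial
#'   eta squared and the sums of squares.
#' @export
rm_anova <- function(df, dv = "value", within) {
  stopifnot(length(within) %in% 1:2, all(c("subject", within, dv) %in% names(df)))
  agg <- stats::aggregate(df[[dv]],
                          by = c(list(subject = df$subject),
                                 lapply(within, function(f) df[[f]])),
                          FUN = mean)
  names(agg) <- c("subject", within, "y")
  levs <- lapply(within, function(f) sort(unique(as.character(agg[[f]]))))
  n_cells <- prod(lengths(levs))
  counts <- table(agg$subject)
  bad <- names(counts)[counts != n_cells]
  if (length(bad))
    abort_ps(paste0("unbalanced design; incomplete subjects: ",
                    paste(bad, collapse = ", ")), "ps_unbalanced")
  subjects <- sort(unique(as.character(agg$subject)))
  n <- length(subjects)
  if (n < 2) abort_ps("need at least 2 subjects", "ps_invalid_parameter")
  # cell-mean matrix, cells ordered with the LAST factor varying fastest
  key <- do.call(paste, c(lapply(rev(within), function(f) as.character(agg[[f]])),
                          sep = "\r"))
  cell_levels <- do.call(paste, c(expand.grid(rev(levs),
                                              stringsAsFactors = FALSE),
                                  sep = "\r"))
  Y <- matrix(NA_real_, n, n_cells, dimnames = list(subjects, NULL))
  Y[cbind(match(as.character(agg$subject), subjects),
          match(key, cell_levels))] <- agg$y
  res <- list()
  scale2 <- mean(Y^2)
  if (length(within) == 1L) {
    k <- length(levs[[1]])
    U <- Y %*% orthonormal_contrasts(k)
    res[[1]] <- effect_from_scores(U, within[1], scale2)
  } else {
    a <- length(levs[[1]]); b <- length(levs[[2]])
    Ca <- orthonormal_contrasts(a); Cb <- orthonormal_contrasts(b)
    ja <- matrix(1 / sqrt(a), a, 1); jb <- matrix(1 / sqrt(b), b, 1)
    res[[1]] <- effect_from_scores(Y %*% kronecker(Ca, jb), within[1], scale2)
    res[[2]] <- effect_from_scores(Y %*% kronecker(ja, Cb), within[2], scale2)
    res[[3]] <- effect_from_scores(Y %*% kronecker(Ca, Cb),
                                   paste(within, collapse = ":"), scale2)
  }
  out <- do.call(rbind, res)
  class(out) <- c("ps_anova", class(out))
  out
}

# --- Spearman -------------------------------------------------------

perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, factorial(n), n)
  r <- nrow(sub)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * r + 1L):(i * r)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], r, n - 1L)
  }
  out
}

# Exact two-sided p for Spearman rho without ties, by full enumeration
# of the n! rank permutations (cached per n).
ps_spearman_cache <- new.env(parent = emptyenv())
spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  key <- as.character(n)
  if (is.null(ps_spearman_cache[[key]])) {
    base <- seq_len(n)
    if (n <= 8) {
      P <- perm_matrix(n)
      s <- as.numeric((P - matrix(base, nrow(P), n, byrow = TRUE))^2 %*%
                        rep(1, n))
    } else {
      # enumerate by leading element to bound memory
      sub <- perm_matrix(n - 1L)
      s <- numeric(0)
      for (i in seq_len(n)) {
        rest <- seq_len(n)[-i]
        P <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
        s <- c(s, as.numeric((P - matrix(base, nrow(P), n, byrow = TRUE))^2 %*%
                               rep(1, n)))
      }
    }
    rho <- 1 - 6 * s / (n * (n^2 - 1))
    ps_spearman_cache[[key]] <- rho
  }
  rho_null <- ps_spearman_cache[[key]]
  rho_obs <- 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  mean(abs(rho_null) >= abs(rho_obs) - 1e-12)
}

#' Spearman rank correlation with small-sample exact p
#'
#' Midrank-tie Spearman correlation with a two-tailed p-value: exact by
#' full permutation enumeration for n <= 10 without ties, and the
#' t-distribution approximation otherwise (the n = 29 regime of the
#' subject-level analyses). Zero variance in either variable yields an
#' undefined-correlation flag instead of a value.
#'
#' @param x,y paired numeric vectors, n >= 4 complete pairs.
#' @return a `ps_correlation`: list with `r`, `p`, `n`, `method`,
#'   `undefined`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort_ps("need at least 4 complete pairs", "ps_invalid_parameter")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, n = n,
                          method = "undefined", undefined = TRUE),
                     class = "ps_correlation"))
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    p <- spearman_exact_p(rx, ry)
    method <- "exact"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    p <- min(p, 1)
    method <- "t-approximation"
  }
  structure(list(r = r, p = p, n = n, method = method, undefined = FALSE),
            class = "ps_correlation")
}

#' Benjamini-Yekutieli false-discovery-rate control
#'
#' Step-up procedure valid under arbitrary dependence: reject the
#' `k` smallest p-values where `k` is the largest index with
#' `p_(k) <= k * q / (m * c(m))` and `c(m) = sum_{i=1..m} 1/i`.
#' Adjusted p-values are the usual monotone step-up transforms (equal
#' to `p.adjust(method = "BY")`).
#'
#' @param p vector of p-values in `[0, 1]` (NAs are carried through and
#'   never rejected).
#' @param q FDR level, default 0.05.
#' @return data.frame with `p`, `p_adjusted`, `reject`.
#' @export
fdr_by <- function(p, q = 0.05) {
  if (!length(p)) return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                                    reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    abort_ps("p-values must lie in [0, 1]", "ps_invalid_parameter")
  ok <- !is.na(p)
  m <- sum(ok)
  out <- data.frame(p = p, p_adjusted = NA_real_, reject = FALSE)
  if (m == 0) return(out)
  cm <- sum(1 / seq_len(m))
  o <- order(p[ok])
  ps <- p[ok][o]
  adj <- rev(cummin(rev(pmin(1, m * cm * ps / seq_len(m)))))
  thresh <- seq_len(m) * q / (m * cm)
  k <- which(ps <= thresh)
  rej <- logical(m)
  if (length(k)) rej[seq_len(max(k))] <- TRUE
  idx <- which(ok)[o]
  out$p_adjusted[idx] <- adj
  out$reject[idx] <- rej
  out
}
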