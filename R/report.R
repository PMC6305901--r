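# Subject-level aggregation, correlation families and summary tables.

#' Aggregate trial tables to subject-level summaries
#'
#' Collapses the per-trial kinematic, EMG-feature and H/M tables to one
#' value per subject x condition x variable (the unit of all
#' between-condition statistics): COP and joint summaries from posterior
#' trials, `emg_<MUSCLE>_<PHASE>` as mean %MVC from unstimulated
#' posterior trials, and `h_<PHASE>` / `m_<PHASE>` as mean amplitudes
#' from stimulated trials.
#'
#' @param kin per-trial table from [kinematics_table()], or `NULL`.
#' @param features per-trial table from [emg_feature_table()], or `NULL`.
#' @param hm per-trial table from [hm_table()], or `NULL`.
#' @return long data.frame: `subject`, `condition`, `variable`, `value`.
#' @export
subject_summaries <- function(kin = NULL, features = NULL, hm = NULL) {
  rows <- list()
  agg <- function(df, by, val) {
    a <- stats::aggregate(df[[val]], by = lapply(by, function(f) df[[f]]),
                          FUN = mean)
    names(a) <- c(by, "value")
    a
  }
  if (!is.null(kin) && nrow(kin)) {
    kp <- kin[kin$direction == "posterior", , drop = FALSE]
    vars <- setdiff(names(kp), c("subject", "condition", "direction",
                                 "stim_phase", "trial"))
    for (v in vars) {
      a <- agg(kp[!is.na(kp[[v]]), ], c("subject", "condition"), v)
      a$variable <- v
      rows[[length(rows) + 1]] <- a
    }
  }
  if (!is.null(features) && nrow(features)) {
    fp <- features[features$direction == "posterior", , drop = FALSE]
    a <- stats::aggregate(fp$pct_mvc,
                          by = list(subject = fp$subject,
                                    condition = fp$condition,
                                    muscle = fp$muscle, phase = fp$phase),
                          FUN = mean)
    a$variable <- sprintf("emg_%s_%s", a$muscle, a$phase)
    a$value <- a$x
    rows[[length(rows) + 1]] <- a[, c("subject", "condition", "value", "variable")]
  }
  if (!is.null(hm) && nrow(hm)) {
    for (col in c("h_mv", "m_mv")) {
      a <- stats::aggregate(hm[[col]],
                            by = list(subject = hm$subject,
                                      condition = hm$condition,
                                      phase = hm$stim_phase), FUN = mean)
      a$variable <- sprintf("%s_%s", substr(col, 1, 1), a$phase)
      a$value <- a$x
      rows[[length(rows) + 1]] <- a[, c("subject", "condition", "value", "variable")]
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, lapply(rows, function(r)
    r[, c("subject", "condition", "variable", "value")]))
  rownames(out) <- NULL
  out
}

#' Spearman correlation family with FDR control
#'
#' Computes subject-level Spearman correlations for a set of variable
#' pairs within one condition and controls the false discovery rate of
#' the whole family with the Benjamini-Yekutieli step-up procedure.
#'
#' @param summary_long long table from [subject_summaries()].
#' @param condition condition to analyse.
#' @param pairs data.frame with columns `var1`, `var2`.
#' @param q FDR level (default 0.05).
#' @return data.frame: `condition`, `var1`, `var2`, `n`, `r`, `p`,
#'   `p_adjusted`, `significant`.
#' @export
run_correlations <- function(summary_long, condition, pairs, q = 0.05) {
  dat <- summary_long[summary_long$condition == condition, , drop = FALSE]
  wide <- stats::reshape(dat[, c("subject", "variable", "value")],
                         idvar = "subject", timevar = "variable",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    v1 <- pairs$var1[i]; v2 <- pairs$var2[i]
    if (!v1 %in% names(wide) || !v2 %in% names(wide) ||
        sum(stats::complete.cases(wide[[v1]], wide[[v2]])) < 4)
      return(data.frame(condition = condition, var1 = v1, var2 = v2,
                        n = 0L, r = NA_real_, p = NA_real_))
    ct <- spearman_cor(wide[[v1]], wide[[v2]])
    data.frame(condition = condition, var1 = v1, var2 = v2, n = ct$n,
               r = ct$r, p = ct$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  fdr <- fdr_by(out$p, q)
  out$p_adjusted <- fdr$p_adjusted
  out$significant <- fdr$reject
  out
}

#' Condition summary tables
#'
#' Per-condition mean +/- SD of every subject-level variable, columns
#' ordered predicted / unpredicted / cheated, with significance markers
#' (`*`) attached only where the supplied FDR decisions are positive.
#' Writes a machine-readable TSV and a human-readable text rendering.
#'
#' @param summary_long long table from [subject_summaries()].
#' @param significant optional character vector of variable names to
#'   mark as significant.
#' @param out_dir optional output directory; when given,
#'   `summary_table.tsv` and `summary_table.txt` are written there.
#' @return the summary data.frame, invisibly when writing.
#' @export
report_tables <- function(summary_long, significant = character(0),
                          out_dir = NULL) {
  conds <- intersect(ps_conditions(), unique(summary_long$condition))
  vars <- unique(summary_long$variable)
  rows <- lapply(vars, function(v) {
    row <- data.frame(variable = v, stringsAsFactors = FALSE)
    for (cond in conds) {
      x <- summary_long$value[summary_long$variable == v &
                                summary_long$condition == cond]
      row[[paste0(cond, "_mean")]] <- mean(x)
      row[[paste0(cond, "_sd")]] <- stats::sd(x)
    }
    row$significant <- v %in% significant
    row
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(tab, file.path(out_dir, "summary_table.tsv"), sep = "\t")
    txt <- c(sprintf("%-28s %s", "variable",
                     paste(sprintf("%-20s", conds), collapse = " ")),
             vapply(seq_len(nrow(tab)), function(i) {
               cells <- vapply(conds, function(cond)
                 sprintf("%7.3f +/- %6.3f", tab[[paste0(cond, "_mean")]][i],
                         tab[[paste0(cond, "_sd")]][i]), character(1))
               sprintf("%-28s %s%s", tab$variable[i],
                       paste(sprintf("%-20s", cells), collapse = " "),
                       if (tab$significant[i]) " *" else "")
             }, character(1)))
    writeLines(txt, file.path(out_dir, "summary_table.txt"))
    return(invisible(tab))
  }
  tab
}
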