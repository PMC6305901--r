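# End-to-end orchestration: generate -> segment -> features / H-reflex /
# kinematics -> statistics, from one declarative configuration and one
# root seed, with structured logs and a manifest of produced files.

#' Run configuration for the full pipeline
#'
#' @param cohort a [cohort_config()] object (carries the root seed).
#' @param out_dir output directory for all stages.
#' @param detection_threshold onset-detection threshold fraction.
#' @param fdr_q FDR level for the correlation family.
#' @param correlation_pairs data.frame (`var1`, `var2`) per-condition
#'   correlation family; default: COP onset and peak, plus every EMG /
#'   H variable against the COP peak.
#' @return a `ps_run_config`.
#' @export
run_config <- function(cohort = cohort_config(), out_dir,
                       detection_threshold = 0.05, fdr_q = 0.05,
                       correlation_pairs = NULL) {
  stopifnot(inherits(cohort, "ps_cohort_config"))
  check_scalar_num(detection_threshold, "detection_threshold")
  if (detection_threshold <= 0 || detection_threshold >= 1)
    abort_ps("`detection_threshold` must be in (0, 1)", "ps_invalid_parameter")
  check_scalar_num(fdr_q, "fdr_q", min = 0, max = 1)
  structure(list(cohort = cohort, out_dir = out_dir,
                 detection_threshold = detection_threshold, fdr_q = fdr_q,
                 correlation_pairs = correlation_pairs),
            class = "ps_run_config")
}

#' Load a run configuration from JSON
#'
#' Declarative pipeline configuration: a JSON object with optional
#' fields `seed`, `n_subjects`, `trials_per_phase`, `n_anterior`,
#' `conditions`, `directions`, `stim_phases`, `channels`,
#' `detection_threshold`, `fdr_q`, `out_dir`. Unknown fields are
#' rejected so that typos fail before any stage runs.
#'
#' @param path JSON file path.
#' @param out_dir overrides the configured output directory.
#' @return a `ps_run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("seed", "n_subjects", "trials_per_phase", "n_anterior",
               "conditions", "directions", "stim_phases", "channels",
               "detection_threshold", "fdr_q", "out_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    abort_ps(paste0("unknown configuration field(s): ",
                    paste(unknown, collapse = ", ")), "ps_schema_violation")
  cc_args <- cfg[intersect(names(cfg), c("seed", "n_subjects",
                                         "trials_per_phase", "n_anterior",
                                         "conditions", "directions",
                                         "stim_phases", "channels"))]
  cohort <- do.call(cohort_config, cc_args)
  run_config(cohort = cohort,
             out_dir = out_dir %||% cfg$out_dir %||%
               abort_ps("no out_dir configured", "ps_schema_violation"),
             detection_threshold = cfg$detection_threshold %||% 0.05,
             fdr_q = cfg$fdr_q %||% 0.05)
}

log_stage <- function(log_path, stage, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  cat(jsonlite::toJSON(list(time = format(Sys.time()), stage = stage,
                            message = msg), auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE)
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order: cohort generation (written
#' to disk), epoch segmentation, MVC extraction and EMG features,
#' H-reflex extraction, COP/joint kinematics, subject-level aggregation,
#' rmANOVA + correlation statistics and summary tables. Any stage
#' failure halts with the stage name. Rerunning with an identical
#' configuration reproduces identical outputs.
#'
#' @param config a `ps_run_config`.
#' @return the run manifest (list of stages, output files, md5 hashes,
#'   seed), also written to `manifest.json` in the output directory.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "ps_run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  stages <- character(0)
  run_stage <- function(name, fn) {
    log_stage(log_path, name, "start")
    r <- tryCatch(fn(), error = function(e) {
      log_stage(log_path, name, paste("FAILED:", conditionMessage(e)))
      abort_ps(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "ps_stage_failure")
    })
    log_stage(log_path, name, "done")
    stages <<- c(stages, name)
    r
  }
  cohort_dir <- file.path(out, "cohort")
  cohort <- run_stage("generate", function()
    generate_cohort(config$cohort, out_dir = cohort_dir))
  cdir <- run_stage("load", function() read_cohort(cohort_dir))

  epochs_by_subject <- function(sid) {
    md <- cdir$metadata[cdir$metadata$subject == sid, , drop = FALSE]
    eps <- list()
    for (i in seq_len(nrow(md))) {
      rec <- read_trial(cdir, md[i, , drop = FALSE])
      ep <- epoch_trial(rec)
      if (!is.null(ep)) eps[[length(eps) + 1]] <- ep
    }
    eps
  }
  subjects <- unique(cdir$metadata$subject)
  seg_res <- run_stage("segment+features", function() {
    feat <- list(); kin <- list(); hm <- list()
    for (sid in subjects) {
      eps <- epochs_by_subject(sid)
      kin[[sid]] <- kinematics_table(eps)
      if ("EMG" %in% config$cohort$channels) {
        mvc_rec <- read_mvc(cdir, sid)
        if (!is.null(mvc_rec)) {
          mvc <- extract_mvc_reference(mvc_rec)
          ft <- emg_feature_table(eps, mvc)
          if (nrow(ft)) feat[[sid]] <- ft
        }
        ht <- hm_table(eps)
        if (nrow(ht)) hm[[sid]] <- ht
      }
    }
    list(features = if (length(feat)) do.call(rbind, feat) else NULL,
         kin = if (length(kin)) data.table::rbindlist(kin, fill = TRUE) |>
           as.data.frame() else NULL,
         hm = if (length(hm)) do.call(rbind, hm) else NULL)
  })
  tables <- run_stage("tables", function() {
    for (nm in c("features", "kin", "hm")) {
      df <- seg_res[[nm]]
      if (!is.null(df) && nrow(df))
        data.table::fwrite(df, file.path(out, paste0(nm, ".tsv")), sep = "\t")
    }
    subject_summaries(seg_res$kin, seg_res$features, seg_res$hm)
  })
  stats_res <- run_stage("stats", function() {
    res <- list()
    if (length(config$cohort$conditions) >= 2 && !is.null(tables) &&
        nrow(tables)) {
      dat <- tables[tables$variable == "cop_peak_cm", , drop = FALSE]
      names(dat)[names(dat) == "condition"] <- "anticipation"
      res$anova_cop_peak <- tryCatch(
        rm_anova(dat, dv = "value", within = "anticipation"),
        error = function(e) NULL)
    }
    pairs <- config$correlation_pairs %||% default_correlation_pairs(tables)
    res$correlations <- do.call(rbind, lapply(
      intersect(ps_conditions(), unique(tables$condition)),
      function(cond) run_correlations(tables, cond, pairs, config$fdr_q)))
    res
  })
  run_stage("report", function() {
    data.table::fwrite(tables, file.path(out, "subject_summaries.tsv"),
                       sep = "\t")
    if (!is.null(stats_res$correlations))
      data.table::fwrite(stats_res$correlations,
                         file.path(out, "correlations.tsv"), sep = "\t")
    if (!is.null(stats_res$anova_cop_peak))
      data.table::fwrite(stats_res$anova_cop_peak,
                         file.path(out, "anova_cop_peak.tsv"), sep = "\t")
    sig <- character(0)
    report_tables(tables, sig, out_dir = out)
  })
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("run_log|manifest", files)]
  manifest <- list(stages = stages, seed = config$cohort$seed,
                   n_files = length(files),
                   files = stats::setNames(as.list(unname(tools::md5sum(files))),
                                           sub(paste0("^", out, "/?"), "", files)),
                   version = as.character(utils::packageVersion("perturbstance")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

default_correlation_pairs <- function(summary_long) {
  vars <- unique(summary_long$variable)
  others <- setdiff(vars[grepl("^(emg_|h_)", vars)], character(0))
  rbind(data.frame(var1 = "cop_onset_cm", var2 = "cop_peak_cm"),
        if (length(others)) data.frame(var1 = others, var2 = "cop_peak_cm"))
}
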