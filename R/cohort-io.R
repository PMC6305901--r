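# On-disk cohort layout (all plain text):
#
#   DIR/config.json              generator configuration (declarative)
#   DIR/metadata.tsv             one row per trial, with file paths
#   DIR/truth_subject.tsv        subject-level truth for test oracles
#   DIR/subjects/s01/*.tsv       per-trial time series; fast channels
#                                (1 kHz) in <stem>.tsv with a time_ms
#                                column, COP (100 Hz) in <stem>_cop.tsv
#   DIR/subjects/s01/mvc.tsv     MVC recordings, columns SOL_r1..GMAX_r3

trial_stem <- function(condition, direction, stim_phase, trial) {
  sprintf("%s_%s_%s_t%02d", substr(condition, 1, 4), substr(direction, 1, 4),
          stim_phase, trial)
}

init_cohort_dir <- function(dir, config) {
  dir.create(file.path(dir, "subjects"), recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  cfg$platform <- unclass(cfg$platform)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

write_trial_record <- function(rec, subj_dir) {
  stem <- trial_stem(rec$condition, rec$direction, rec$stim_phase, rec$trial)
  n <- NULL
  fast <- list()
  if (!is.null(rec$platform)) { fast$PLATFORM <- rec$platform; n <- length(rec$platform) }
  if (!is.null(rec$emg)) { for (m in colnames(rec$emg)) fast[[m]] <- rec$emg[, m]; n <- nrow(rec$emg) }
  if (!is.null(rec$joints)) { for (j in colnames(rec$joints)) fast[[j]] <- rec$joints[, j]; n <- nrow(rec$joints) }
  file <- cop_file <- NA_character_
  if (length(fast)) {
    t_ms <- (seq_len(n) - rec$onset_sample) * 1000 / rec$sr_fast
    dt <- data.table::as.data.table(c(list(time_ms = t_ms), fast))
    file <- file.path(basename(subj_dir), paste0(stem, ".tsv"))
    data.table::fwrite(dt, file.path(dirname(subj_dir), file), sep = "\t")
  }
  if (!is.null(rec[["cop"]])) {
    t_ms <- (seq_along(rec[["cop"]]) - rec$cop_onset_sample) * 1000 / rec$sr_cop
    dt <- data.table::data.table(time_ms = t_ms, COP_AP = rec[["cop"]])
    cop_file <- file.path(basename(subj_dir), paste0(stem, "_cop.tsv"))
    data.table::fwrite(dt, file.path(dirname(subj_dir), cop_file), sep = "\t")
  }
  c(file = file, cop_file = cop_file)
}

write_subject <- function(dir, sid, mvc, trials) {
  subj_dir <- file.path(dir, "subjects", sid)
  dir.create(subj_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(mvc)) {
    n <- nrow(mvc$recordings)
    dt <- data.table::as.data.table(cbind(time_ms = (seq_len(n) - 1) * 1000 / mvc$sr,
                                          mvc$recordings))
    data.table::fwrite(dt, file.path(subj_dir, "mvc.tsv"), sep = "\t")
  }
  for (tr in trials) write_trial_record(tr, subj_dir)
  invisible(NULL)
}

finalize_cohort_dir <- function(dir, cohort) {
  md <- cohort$metadata
  md$file <- file.path("subjects", md$subject,
                       paste0(trial_stem(md$condition, md$direction,
                                         md$stim_phase, md$trial), ".tsv"))
  md$cop_file <- sub("\\.tsv$", "_cop.tsv", md$file)
  if (!"EMG" %in% cohort$config$channels &&
      !"PLATFORM" %in% cohort$config$channels &&
      !"JOINT" %in% cohort$config$channels) md$file <- NA_character_
  if (!"COP" %in% cohort$config$channels) md$cop_file <- NA_character_
  data.table::fwrite(md, file.path(dir, "metadata.tsv"), sep = "\t")
  data.table::fwrite(cohort$subject_truth, file.path(dir, "truth_subject.tsv"),
                     sep = "\t")
  invisible(NULL)
}

#' Write an in-memory cohort to disk
#'
#' @param cohort a `ps_cohort` generated with `out_dir = NULL`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ps_cohort"), !is.null(cohort$subjects))
  init_cohort_dir(dir, cohort$config)
  for (sid in names(cohort$subjects))
    write_subject(dir, sid, cohort$subjects[[sid]]$mvc,
                  cohort$subjects[[sid]]$trials)
  finalize_cohort_dir(dir, cohort)
  invisible(dir)
}

#' Read a cohort directory
#'
#' Loads metadata, configuration and truth tables; trial time series are
#' read lazily with [read_trial()].
#'
#' @param dir cohort directory written by [generate_cohort()] or
#'   [write_cohort()].
#' @return an object of class `ps_cohort_dir`.
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path))
    abort_ps(sprintf("no metadata.tsv under '%s'", dir), "ps_io_error")
  md <- as.data.frame(data.table::fread(meta_path, sep = "\t"))
  truth <- NULL
  tp <- file.path(dir, "truth_subject.tsv")
  if (file.exists(tp)) truth <- as.data.frame(data.table::fread(tp, sep = "\t"))
  cfg <- NULL
  cp <- file.path(dir, "config.json")
  if (file.exists(cp)) cfg <- jsonlite::read_json(cp, simplifyVector = TRUE)
  structure(list(dir = dir, metadata = md, subject_truth = truth,
                 config = cfg), class = "ps_cohort_dir")
}

#' Read one trial's time series from a cohort directory
#'
#' Reconstructs a trial record (fast 1 kHz channels plus the 100 Hz COP
#' trace) from its TSV files and the metadata row.
#'
#' @param cohort a `ps_cohort_dir` from [read_cohort()].
#' @param row metadata row index (or a one-row data.frame).
#' @return a trial record list as produced by the generator.
#' @export
read_trial <- function(cohort, row) {
  md <- if (is.data.frame(row)) row else cohort$metadata[row, , drop = FALSE]
  rec <- list(subject = md$subject, condition = md$condition,
              direction = md$direction, stim_phase = md$stim_phase,
              trial = md$trial, sr_fast = 1000, sr_cop = 100,
              onset_sample = md$onset_sample,
              cop_onset_sample = md$cop_onset_sample,
              stim_time_ms = md$stim_time_ms)
  if (!is.na(md$file) && nzchar(md$file)) {
    dt <- data.table::fread(file.path(cohort$dir, md$file), sep = "\t")
    if (!"time_ms" %in% names(dt))
      abort_ps(sprintf("trial file '%s' lacks a time_ms column", md$file),
               "ps_io_error")
    if ("PLATFORM" %in% names(dt)) rec$platform <- dt$PLATFORM
    emg_cols <- intersect(ps_muscles(), names(dt))
    if (length(emg_cols)) rec$emg <- as.matrix(dt[, emg_cols, with = FALSE])
    j_cols <- intersect(c("ANKLE", "KNEE", "HIP"), names(dt))
    if (length(j_cols)) rec$joints <- as.matrix(dt[, j_cols, with = FALSE])
  }
  if (!is.null(md$cop_file) && !is.na(md$cop_file) && nzchar(md$cop_file)) {
    f <- file.path(cohort$dir, md$cop_file)
    if (file.exists(f)) {
      dt <- data.table::fread(f, sep = "\t")
      rec$cop <- dt$COP_AP
    }
  }
  rec
}

#' Read a subject's MVC recordings from a cohort directory
#'
#' @param cohort a `ps_cohort_dir`.
#' @param subject subject id, e.g. `"s01"`.
#' @return list of per-muscle matrices (columns = repetitions), or
#'   `NULL` when the subject has no MVC file.
#' @export
read_mvc <- function(cohort, subject) {
  f <- file.path(cohort$dir, "subjects", subject, "mvc.tsv")
  if (!file.exists(f)) return(NULL)
  dt <- data.table::fread(f, sep = "\t")
  out <- list()
  for (mus in ps_muscles()) {
    cols <- grep(sprintf("^%s_r", mus), names(dt), value = TRUE)
    if (length(cols)) out[[mus]] <- as.matrix(dt[, cols, with = FALSE])
  }
  out
}
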