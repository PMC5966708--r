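#' Write a synthetic cohort to plain-text files
#'
#' One directory per cohort: per participant-task an eye-tracker TSV
#' (`<participant>_<task>_eye.tsv`, columns `timestamp_ms`, `pupil_mm` with an
#' empty field for missing samples) and a GSR CSV (`..._gsr.csv`, columns
#' `second`, `microsiemens`); cohort-level `performance.csv`,
#' `latent_labels.csv` and `config.yaml`. Task ids have `/` replaced by `-` in
#' filenames.
#'
#' @param cohort a `"bci_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bci_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$recordings)) {
    for (tid in names(cohort$recordings[[pid]])) {
      rec <- cohort$recordings[[pid]][[tid]]
      stem <- file.path(dir, paste0(pid, "_", gsub("/", "-", tid)))
      eye <- data.frame(timestamp_ms = rec$time_ms,
                        pupil_mm = ifelse(is.na(rec$pupil_mm), "",
                                          format(rec$pupil_mm, digits = 10)))
      utils::write.table(eye, paste0(stem, "_eye.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      gsr <- data.frame(second = seq_along(rec$gsr_us),
                        microsiemens = rec$gsr_us)
      write.csv(gsr, paste0(stem, "_gsr.csv"), row.names = FALSE)
    }
  }
  perf <- cohort$features[, c("participant", "task", "performance_pct")]
  write.csv(perf, file.path(dir, "performance.csv"), row.names = FALSE)
  write.csv(cohort$latent, file.path(dir, "latent_labels.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg$tasks <- lapply(cfg$tasks, function(tk) lapply(unclass(tk), as.vector))
  yaml::write_yaml(lapply(unclass(cfg), as.vector), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `"bci_cohort"` (without the drawn feature table: run
#'   [build_feature_table()] to re-extract features from the signals).
#' @export
read_cohort <- function(dir) {
  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  tasks <- lapply(cfg_raw$tasks, function(tk)
    task_spec(tk$task_id, tk$task_type, tk$duration_s,
              unlist(tk$center_risky), unlist(tk$center_safe),
              unlist(tk$feature_sd), unlist(tk$feature_min),
              unlist(tk$feature_max),
              tk$perf_mean, tk$perf_sd, tk$perf_min, tk$perf_max,
              tk$blink_dir_risky, tk$gsr_dir_risky))
  config <- generator_config(
    n_participants = cfg_raw$n_participants, tasks = tasks,
    noise_scale = cfg_raw$noise_scale, mixture_weight = cfg_raw$mixture_weight,
    gsr_convention = cfg_raw$gsr_convention,
    shared_propensity = cfg_raw$shared_propensity,
    baseline_pupil_mm = cfg_raw$baseline_pupil_mm,
    baseline_gsr_us = cfg_raw$baseline_gsr_us,
    blink_run_len = cfg_raw$blink_run_len,
    sample_interval_ms = cfg_raw$sample_interval_ms)
  perf <- read.csv(file.path(dir, "performance.csv"), stringsAsFactors = FALSE)
  latent <- read.csv(file.path(dir, "latent_labels.csv"), stringsAsFactors = FALSE)
  pids <- unique(perf$participant)
  recordings <- vector("list", length(pids)); names(recordings) <- pids
  for (pid in pids) {
    recs <- vector("list", length(tasks)); names(recs) <- names(tasks)
    for (tid in names(tasks)) {
      stem <- file.path(dir, paste0(pid, "_", gsub("/", "-", tid)))
      eye <- utils::read.table(paste0(stem, "_eye.tsv"), sep = "\t", header = TRUE,
                               colClasses = c("numeric", "character"))
      pupil <- suppressWarnings(as.numeric(eye$pupil_mm))
      gsr <- read.csv(paste0(stem, "_gsr.csv"))
      recs[[tid]] <- structure(list(
        participant_id = pid, task_id = tid,
        time_ms = eye$timestamp_ms, pupil_mm = pupil,
        gsr_us = gsr$microsiemens,
        duration_s = tasks[[tid]]$duration_s,
        performance_pct = perf$performance_pct[perf$participant == pid &
                                               perf$task == tid]),
        class = "session_recording")
    }
    recordings[[pid]] <- recs
  }
  structure(list(recordings = recordings, features = NULL, latent = latent,
                 gsr_feasibility = NULL, config = config),
            class = "bci_cohort")
}

#' Write / read a feature table as CSV
#'
#' @param features feature table data frame.
#' @param path CSV path.
#' @return the path (write) or the table (read).
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
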