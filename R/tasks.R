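#' Define one BCI task for the synthetic-cohort generator
#'
#' A task spec carries everything the generator needs for one task: the feature
#' centers of the two latent cognitive states (risky and safe), the per-state
#' spread, hard truncation bounds, the task-performance distribution, and the
#' tagging directions expected for the risky state. Feature triples are always
#' ordered (pupil dilation %, blink rate per second, normalized GSR).
#'
#' @param task_id identifier, e.g. `"P300/1"`.
#' @param task_type one of `"P300"`, `"SSVEP"`, `"MI1"`, `"MI2"`; determines the
#'   risky-direction rule used when tagging clusters.
#' @param duration_s task length in seconds (must exceed the 1 s pupil baseline).
#' @param center_risky,center_safe numeric(3) feature centers of the two states.
#' @param feature_sd numeric(3) per-state standard deviation (before the
#'   generator's `noise_scale` multiplier).
#' @param feature_min,feature_max numeric(3) truncation bounds for drawn features.
#' @param perf_mean,perf_sd,perf_min,perf_max task-performance distribution (%).
#' @param blink_dir_risky,gsr_dir_risky `"increase"` or `"decrease"`: the side of
#'   the blink-rate / GSR center expected for the risky state, used only as
#'   tie-breakers when tagging clusters.
#' @return an object of class `"task_spec"`.
#' @export
task_spec <- function(task_id, task_type, duration_s,
                      center_risky, center_safe, feature_sd,
                      feature_min, feature_max,
                      perf_mean, perf_sd, perf_min = 0, perf_max = 100,
                      blink_dir_risky = c("increase", "decrease"),
                      gsr_dir_risky = c("increase", "decrease")) {
  task_type <- match.arg(task_type, c("P300", "SSVEP", "MI1", "MI2"))
  blink_dir_risky <- match.arg(blink_dir_risky)
  gsr_dir_risky <- match.arg(gsr_dir_risky)
  check_number(duration_s, "duration_s", lower = 1 + 1e-9)
  for (v in list(center_risky, center_safe, feature_sd, feature_min, feature_max))
    if (length(v) != 3L || !all(is.finite(v)))
      stop_bad("feature triples must be finite numeric(3)")
  if (any(feature_sd < 0)) stop_bad("feature_sd must be nonnegative")
  if (any(feature_min > feature_max)) stop_bad("feature_min exceeds feature_max")
  for (cen in list(center_risky, center_safe))
    if (any(cen < feature_min | cen > feature_max))
      stop_bad("'%s': state centers must lie inside [feature_min, feature_max]", task_id)
  check_number(perf_mean, "perf_mean"); check_number(perf_sd, "perf_sd", lower = 0)
  check_number(perf_min, "perf_min", 0, 100); check_number(perf_max, "perf_max", 0, 100)
  if (perf_min > perf_max) stop_bad("perf_min exceeds perf_max")
  nm <- c("pupil_pct", "blink_rate", "gsr_norm")
  structure(list(
    task_id = task_id, task_type = task_type, duration_s = duration_s,
    center_risky = stats::setNames(center_risky, nm),
    center_safe = stats::setNames(center_safe, nm),
    feature_sd = stats::setNames(feature_sd, nm),
    feature_min = stats::setNames(feature_min, nm),
    feature_max = stats::setNames(feature_max, nm),
    perf_mean = perf_mean, perf_sd = perf_sd,
    perf_min = perf_min, perf_max = perf_max,
    blink_dir_risky = blink_dir_risky, gsr_dir_risky = gsr_dir_risky),
    class = "task_spec")
}

#' Default six-task battery calibrated to the study summary tables
#'
#' Two P300 spelling tasks, two SSVEP direction-following tasks and two Motor
#' Imagery tasks. State centers are the published per-task cluster centers,
#' per-state spreads are half the published global standard deviation (so the
#' mixture's pooled spread stays near the published value while the states
#' remain separable), truncation bounds are the published min/max, and the
#' performance distributions follow the published performance table. The risky
#' state is cognitive loading for P300 and MI/2 and drowsiness for SSVEP and
#' MI/1. All tasks default to 200 s: the magnitude of the published normalized
#' GSR (~0.005 per second of task) pins the effective task length near 200 s
#' under the divide-by-duration-twice convention.
#'
#' @param duration_s common task duration in seconds.
#' @return named list of [task_spec()] objects.
#' @export
default_task_specs <- function(duration_s = 200) {
  half <- function(x) x / 2
  list(
    "P300/1" = task_spec("P300/1", "P300", duration_s,
      center_risky = c(20.84, 0.08, 0.0047), center_safe = c(5.76, 0.06, 0.0046),
      feature_sd = half(c(8.75, 0.052, 0.003)),
      feature_min = c(-3.72, 0.02, 0.001), feature_max = c(36.93, 0.30, 0.020),
      perf_mean = 56.29, perf_sd = 32.36, perf_min = 0, perf_max = 100,
      blink_dir_risky = "increase", gsr_dir_risky = "increase"),
    "P300/2" = task_spec("P300/2", "P300", duration_s,
      center_risky = c(32.36, 0.07, 0.0058), center_safe = c(11.41, 0.09, 0.0071),
      feature_sd = half(c(12.604, 0.07, 0.008)),
      feature_min = c(-9.96, 0.04, 0.003), feature_max = c(51.95, 0.407, 0.062),
      perf_mean = 29.36, perf_sd = 25.87, perf_min = 0, perf_max = 88.89,
      blink_dir_risky = "decrease", gsr_dir_risky = "increase"),
    "SSVEP/1" = task_spec("SSVEP/1", "SSVEP", duration_s,
      center_risky = c(-7.21, 0.05, 0.0040), center_safe = c(32.99, 0.15, 0.0085),
      feature_sd = half(c(12.069, 0.062, 0.003)),
      feature_min = c(-23.67, 0.02, 0.0003), feature_max = c(50.68, 0.257, 0.024),
      perf_mean = 70.99, perf_sd = 9.95, perf_min = 53, perf_max = 100,
      blink_dir_risky = "decrease", gsr_dir_risky = "decrease"),
    "SSVEP/2" = task_spec("SSVEP/2", "SSVEP", duration_s,
      center_risky = c(-10.55, 0.04, 0.0044), center_safe = c(5.59, 0.07, 0.0042),
      feature_sd = half(c(9.409, 0.04, 0.002)),
      feature_min = c(-31.75, 0.017, 0.0004), feature_max = c(28.37, 0.224, 0.022),
      perf_mean = 71.21, perf_sd = 9.25, perf_min = 56, perf_max = 100,
      blink_dir_risky = "decrease", gsr_dir_risky = "decrease"),
    "MI/1" = task_spec("MI/1", "MI1", duration_s,
      center_risky = c(-7.35, 0.04, 0.0039), center_safe = c(7.76, 0.10, 0.0041),
      feature_sd = half(c(9.026, 0.104, 0.002)),
      feature_min = c(-23.28, 0.02, 0.001), feature_max = c(22.16, 0.48, 0.010),
      perf_mean = 75.66, perf_sd = 3.94, perf_min = 68, perf_max = 85,
      blink_dir_risky = "decrease", gsr_dir_risky = "decrease"),
    "MI/2" = task_spec("MI/2", "MI2", duration_s,
      center_risky = c(14.82, 0.07, 0.0048), center_safe = c(-1.48, 0.05, 0.0040),
      feature_sd = half(c(9.589, 0.067, 0.002)),
      feature_min = c(-20.62, 0.02, 0.001), feature_max = c(40.63, 0.35, 0.021),
      perf_mean = 76.76, perf_sd = 6.72, perf_min = 70, perf_max = 100,
      blink_dir_risky = "increase", gsr_dir_risky = "increase"))
}

#' Configuration for the synthetic-cohort generator
#'
#' @param n_participants cohort size (the study cohort had 70).
#' @param tasks named list of [task_spec()] objects; defaults to the six-task
#'   battery of [default_task_specs()].
#' @param noise_scale multiplier on each task's per-state feature spread;
#'   0 gives degenerate state-center cohorts.
#' @param mixture_weight probability that a participant-task is in the risky
#'   latent state.
#' @param gsr_convention `"per_second_mean"` (sum of per-second ratios divided
#'   by task length once) or `"per_second_mean_over_duration"` (divided twice;
#'   the convention matching the magnitude of the published normalized GSR,
#'   hence the generator default).
#' @param shared_propensity in `[0, 1)`: 0 draws each participant-task state
#'   independently; larger values draw a participant-level risky propensity
#'   from a Beta distribution with mean `mixture_weight` and intra-participant
#'   correlation `shared_propensity`, inducing cross-task dependence.
#' @param baseline_pupil_mm resting pupil diameter used when rendering signals.
#' @param baseline_gsr_us nominal participant-mean skin conductance (microsiemens).
#' @param blink_run_len eye-tracker samples blanked per blink event (8 samples
#'   at 17 ms is about 136 ms).
#' @param sample_interval_ms eye-tracker sampling interval.
#' @return an object of class `"generator_config"`.
#' @export
generator_config <- function(n_participants = 70,
                             tasks = default_task_specs(),
                             noise_scale = 1,
                             mixture_weight = 0.5,
                             gsr_convention = c("per_second_mean_over_duration",
                                                "per_second_mean"),
                             shared_propensity = 0,
                             baseline_pupil_mm = 4.0,
                             baseline_gsr_us = 2.0,
                             blink_run_len = 8L,
                             sample_interval_ms = 17) {
  gsr_convention <- match.arg(gsr_convention)
  check_number(n_participants, "n_participants", lower = 1)
  check_number(noise_scale, "noise_scale", lower = 0)
  check_number(mixture_weight, "mixture_weight", 0, 1)
  check_number(shared_propensity, "shared_propensity", 0, 1 - 1e-9)
  check_number(baseline_pupil_mm, "baseline_pupil_mm", lower = 1e-9)
  check_number(baseline_gsr_us, "baseline_gsr_us", lower = 1e-9)
  check_number(blink_run_len, "blink_run_len", lower = 1)
  check_number(sample_interval_ms, "sample_interval_ms", lower = 1e-9)
  if (length(tasks) < 1L || !all(vapply(tasks, inherits, TRUE, "task_spec")))
    stop_bad("'tasks' must be a nonempty list of task_spec objects")
  if (is.null(names(tasks)))
    names(tasks) <- vapply(tasks, `[[`, "", "task_id")
  structure(list(
    n_participants = as.integer(n_participants), tasks = tasks,
    noise_scale = noise_scale, mixture_weight = mixture_weight,
    gsr_convention = gsr_convention, shared_propensity = shared_propensity,
    baseline_pupil_mm = baseline_pupil_mm, baseline_gsr_us = baseline_gsr_us,
    blink_run_len = as.integer(blink_run_len),
    sample_interval_ms = sample_interval_ms),
    class = "generator_config")
}
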