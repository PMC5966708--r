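#' Tag the two clusters of a task as risky (0) and safe (1)
#'
#' The risky cognitive state depends on the task's nature: P300 spelling and
#' the feedback-laden second Motor Imagery task are threatened by excessive
#' cognitive loading, so the cluster with the *higher* pupil-dilation center is
#' risky; the monotonous SSVEP tasks and the first Motor Imagery task are
#' threatened by drowsiness, so the cluster with the *lower* pupil-dilation
#' center is risky. Pupil dilation is the primary indicator; an exact pupil tie
#' falls back to the GSR center compared in the task's expected risky
#' direction, then to blink rate; a full three-way tie is an error rather than
#' a guess.
#'
#' @param solution a `"cluster_solution"` with `k = 2`.
#' @param task_type `"P300"`, `"SSVEP"`, `"MI1"` or `"MI2"`.
#' @param gsr_dir_risky,blink_dir_risky `"increase"`/`"decrease"` tie-breaker
#'   directions; defaults follow the expected physiological effects for the
#'   task type (P300 and MI/2: increases risky; SSVEP and MI/1: decreases).
#' @return integer vector `c("1" = tag, "2" = tag)` mapping cluster index to
#'   0 (risky) / 1 (safe).
#' @export
tag_clusters <- function(solution, task_type,
                         gsr_dir_risky = NULL, blink_dir_risky = NULL) {
  stopifnot(inherits(solution, "cluster_solution"))
  if (solution$k != 2) stop_bad("tagging requires k = 2 clusters, got k = %d", solution$k)
  task_type <- match.arg(task_type, c("P300", "SSVEP", "MI1", "MI2"))
  loading <- task_type %in% c("P300", "MI2")
  if (is.null(gsr_dir_risky)) gsr_dir_risky <- if (loading) "increase" else "decrease"
  if (is.null(blink_dir_risky)) blink_dir_risky <- if (loading) "increase" else "decrease"

  pick <- function(v, want_high) {
    if (v[1] == v[2]) return(NA_integer_)
    if (want_high) which.max(v) else which.min(v)
  }
  cen <- solution$centers
  risky <- pick(cen[, "pupil_pct"], want_high = loading)
  if (is.na(risky))
    risky <- pick(cen[, "gsr_norm"], want_high = gsr_dir_risky == "increase")
  if (is.na(risky))
    risky <- pick(cen[, "blink_rate"], want_high = blink_dir_risky == "increase")
  if (is.na(risky))
    stop_bad("cluster tagging unresolved: pupil, GSR and blink centers all tie")
  tags <- c(1L, 1L); tags[risky] <- 0L
  stats::setNames(tags, as.character(1:2))
}

#' Three-way task-performance class
#'
#' Below 70% is bad, 70 to 90% (inclusive) good, above 90% excellent. Only the
#' 70% boundary enters the risk classification.
#'
#' @param performance_pct performance values in `[0, 100]` (vectorized).
#' @return factor with levels bad, good, excellent.
#' @export
performance_class <- function(performance_pct) {
  if (any(!is.finite(performance_pct)) ||
      any(performance_pct < 0 | performance_pct > 100))
    stop_bad("performance must lie in [0, 100]")
  cls <- ifelse(performance_pct < 70, "bad",
         ifelse(performance_pct <= 90, "good", "excellent"))
  factor(cls, levels = c("bad", "good", "excellent"))
}

#' Per-task risk class
#'
#' Low risk requires the combination of a risk-free cognitive state (tag 1) and
#' high performance (at least `perf_threshold`, default 70%); every other
#' combination is high risk.
#'
#' @param cognitive_tag 0 (risky) or 1 (safe), vectorized.
#' @param performance_pct task performance in percent, vectorized.
#' @param perf_threshold minimum performance for the low-risk class.
#' @return factor with levels high, low.
#' @export
task_risk <- function(cognitive_tag, performance_pct, perf_threshold = 70) {
  if (!all(cognitive_tag %in% c(0L, 1L))) stop_bad("cognitive tags must be 0 or 1")
  low <- cognitive_tag == 1L & performance_pct >= perf_threshold
  factor(ifelse(low, "low", "high"), levels = c("high", "low"))
}

#' General risk class across tasks
#'
#' A participant is low risk overall when at least `low_threshold` of their
#' `n_tasks` task risk classes are low (the 50% cut-off: 3 or more of 6).
#'
#' @param task_risks character/factor vector of `"high"`/`"low"`, length
#'   `n_tasks`.
#' @param low_threshold minimum number of low-risk tasks.
#' @param n_tasks expected number of tasks.
#' @return `"high"` or `"low"`.
#' @export
general_risk <- function(task_risks, low_threshold = 3, n_tasks = 6) {
  if (length(task_risks) != n_tasks)
    stop_bad("expected %d task risk classes, got %d", n_tasks, length(task_risks))
  if (!all(as.character(task_risks) %in% c("high", "low")))
    stop_bad("task risks must be 'high' or 'low'")
  if (sum(task_risks == "low") >= low_threshold) "low" else "high"
}

#' Build per-participant risk profiles for a cohort
#'
#' Applies cluster tagging, the per-task risk rule and the general-risk rule to
#' a clustered cohort.
#'
#' @param features feature table with columns participant, task, and
#'   `performance_pct` (as produced by [build_feature_table()] or
#'   [generate_feature_table()]).
#' @param solutions named list of k = 2 `"cluster_solution"` objects, one per
#'   task, with assignments in the feature table's participant order.
#' @param task_types named character vector mapping task id to task type;
#'   defaults to the six-task battery's types.
#' @param perf_threshold,low_threshold rule parameters (defaults 70%, 3 of n).
#' @return an object of class `"risk_profiles"`: list with `per_task` (long
#'   data frame: participant, task, cognitive_tag, performance_pct,
#'   performance_class, task_risk), `general` (participant, low_count,
#'   general_risk), and `summary` (counts).
#' @export
build_risk_profiles <- function(features, solutions,
                                task_types = NULL,
                                perf_threshold = 70, low_threshold = 3) {
  if (is.null(task_types))
    task_types <- vapply(default_task_specs(), `[[`, "", "task_type")
  tasks <- names(solutions)
  if (!all(tasks %in% unique(features$task)))
    stop_bad("solutions and feature table tasks disagree")
  pids <- unique(features$participant)
  per_task <- list()
  for (tid in tasks) {
    sub <- features[features$task == tid, , drop = FALSE]
    sub <- sub[match(pids, sub$participant), , drop = FALSE]
    if (any(is.na(sub$participant)))
      stop_bad("missing recording for task %s", tid)
    sol <- solutions[[tid]]
    if (length(sol$assignments) != length(pids))
      stop_bad("solution for %s has %d assignments but cohort has %d participants",
               tid, length(sol$assignments), length(pids))
    tags <- tag_clusters(sol, task_types[[tid]])
    tag <- tags[as.character(sol$assignments)]
    per_task[[tid]] <- data.frame(
      participant = pids, task = tid, cognitive_tag = as.integer(tag),
      performance_pct = sub$performance_pct,
      performance_class = performance_class(sub$performance_pct),
      task_risk = task_risk(tag, sub$performance_pct, perf_threshold),
      stringsAsFactors = FALSE)
  }
  per_task <- do.call(rbind, per_task)
  rownames(per_task) <- NULL
  low_count <- tapply(per_task$task_risk == "low", per_task$participant, sum)
  low_count <- low_count[pids]
  general <- data.frame(
    participant = pids, low_count = as.integer(low_count),
    general_risk = factor(ifelse(low_count >= low_threshold, "low", "high"),
                          levels = c("high", "low")),
    stringsAsFactors = FALSE)
  structure(list(
    per_task = per_task, general = general,
    summary = list(
      n = length(pids),
      general = table(general$general_risk),
      task_risk = table(per_task$task, per_task$task_risk))),
    class = "risk_profiles")
}

#' @export
print.risk_profiles <- function(x, ...) {
  cat(sprintf("Risk profiles for %d participants: %d high / %d low general risk\n",
              x$summary$n, x$summary$general[["high"]], x$summary$general[["low"]]))
  invisible(x)
}
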