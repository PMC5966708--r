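# Internal: draw latent states, feature targets and performances for one cohort.
# Vectorized over participants within each task; draw order is fixed so results
# are reproducible given the RNG state.
draw_feature_targets <- function(config) {
  n <- config$n_participants
  pid <- sprintf("S%02d", seq_len(n))
  prop <- if (config$shared_propensity > 0) {
    r <- config$shared_propensity
    a <- config$mixture_weight * (1 / r - 1)
    b <- (1 - config$mixture_weight) * (1 / r - 1)
    rbeta(n, a, b)
  } else rep(config$mixture_weight, n)
  rows <- lapply(config$tasks, function(tk) {
    z <- rbinom(n, 1L, prop) # 1 = risky
    feat <- vapply(1:3, function(d) {
      cen <- ifelse(z == 1L, tk$center_risky[d], tk$center_safe[d])
      rtruncnorm(n, cen, config$noise_scale * tk$feature_sd[d],
                 tk$feature_min[d], tk$feature_max[d])
    }, numeric(n))
    feat <- matrix(feat, nrow = n)
    perf <- rtruncnorm(n, tk$perf_mean, tk$perf_sd, tk$perf_min, tk$perf_max)
    data.frame(participant = pid, task = tk$task_id,
               pupil_pct = feat[, 1], blink_rate = feat[, 2], gsr_norm = feat[, 3],
               performance_pct = perf,
               state = ifelse(z == 1L, "risky", "safe"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant), , drop = FALSE]
}

#' Draw a feature-level synthetic cohort
#'
#' Fast path for feature-space experiments: draws, for every participant-task,
#' a latent cognitive state (risky with probability `mixture_weight`), a
#' feature triple from a truncated normal around that state's center, and a
#' task performance, without rendering raw signals. Deterministic given `seed`.
#'
#' @param config a [generator_config()].
#' @param seed integer seed for all randomness.
#' @return list with `features` (data frame: participant, task, pupil_pct,
#'   blink_rate, gsr_norm, performance_pct) and `latent` (participant, task,
#'   state).
#' @export
generate_feature_table <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  check_number(seed, "seed")
  set.seed(seed)
  tab <- draw_feature_targets(config)
  list(features = tab[, c("participant", "task", "pupil_pct", "blink_rate",
                          "gsr_norm", "performance_pct")],
       latent = tab[, c("participant", "task", "state")])
}

#' Render raw signals that extract back to a target feature triple
#'
#' Constructs one session recording — an eye-tracker pupil stream and a
#' per-second GSR series — whose feature extraction returns the requested
#' values. The pupil stream holds the baseline diameter for the first second
#' and `baseline_mm * (1 + pupil_pct/100)` afterwards; blinks are realized as
#' contiguous runs of missing samples placed uniformly at random after the
#' baseline second (count = `round(blink_rate * duration)`, so the recoverable
#' rate is quantized to that grid); the GSR series is a constant level chosen
#' so that the configured normalization convention returns `gsr_norm` given
#' the participant's overall GSR mean `overall_gsr_mean`.
#'
#' @param target named numeric: `pupil_pct`, `blink_rate`, `gsr_norm`.
#' @param spec a [task_spec()] (supplies the duration).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param baseline_mm resting pupil diameter (mm).
#' @param overall_gsr_mean the participant-level mean conductance the GSR level
#'   is solved against; extraction recovers `gsr_norm` exactly when the
#'   participant's realized overall mean equals this value (the cohort
#'   generator arranges that by renormalizing targets).
#' @param blink_run_len missing samples per blink event.
#' @param sample_interval_ms eye-tracker sampling interval.
#' @param gsr_convention see [generator_config()].
#' @param performance_pct optional task performance to carry along.
#' @param participant_id,task_id identifiers carried on the recording.
#' @return an object of class `"session_recording"`: list with `time_ms`,
#'   `pupil_mm` (NA = missing sample), `gsr_us` (one value per second),
#'   `duration_s`, `performance_pct`, ids.
#' @export
invert_features_to_signals <- function(target, spec, seed = NULL,
                                       baseline_mm = 4.0, overall_gsr_mean = 2.0,
                                       blink_run_len = 8L, sample_interval_ms = 17,
                                       gsr_convention = c("per_second_mean_over_duration",
                                                          "per_second_mean"),
                                       performance_pct = NA_real_,
                                       participant_id = NA_character_,
                                       task_id = spec$task_id) {
  stopifnot(inherits(spec, "task_spec"))
  gsr_convention <- match.arg(gsr_convention)
  if (!is.null(seed)) set.seed(seed)
  p <- target[["pupil_pct"]]; br <- target[["blink_rate"]]; g <- target[["gsr_norm"]]
  if (!is.finite(p) || p <= -100) stop_bad("pupil_pct target must exceed -100")
  if (!is.finite(br) || br < 0) stop_bad("blink_rate target must be nonnegative")
  if (!is.finite(g) || g <= 0) stop_bad("gsr_norm target must be positive")
  d <- spec$duration_s
  time_ms <- seq(0, d * 1000 - sample_interval_ms, by = sample_interval_ms)
  n <- length(time_ms)
  base_idx <- time_ms < 1000
  pupil <- ifelse(base_idx, baseline_mm, baseline_mm * (1 + p / 100))

  m <- round(br * d)                   # blink events to place
  L <- as.integer(blink_run_len)
  rest <- which(!base_idx)
  n_r <- length(rest)
  if (m > 0) {
    slack <- n_r - m * L - (m - 1L)    # free samples once runs + gaps reserved
    if (slack < 0 || n_r - m * L < 1L)
      stop_bad("cannot place %d blink runs of %d samples in %d remainder samples; use a longer duration", m, L, n_r)
    s <- sort(sample.int(slack + 1L, m, replace = TRUE)) - 1L
    starts <- s + (seq_len(m) - 1L) * (L + 1L)   # 0-based offsets into remainder
    miss <- rest[as.vector(outer(seq_len(L) - 1L, starts, `+`)) + 1L]
    pupil[miss] <- NA_real_
  }

  level <- switch(gsr_convention,
    per_second_mean = g * overall_gsr_mean,
    per_second_mean_over_duration = g * overall_gsr_mean * d)
  if (level <= 0) stop_bad("derived GSR level is nonpositive")
  structure(list(participant_id = participant_id, task_id = task_id,
                 time_ms = time_ms, pupil_mm = pupil,
                 gsr_us = rep(level, round(d)), duration_s = d,
                 performance_pct = performance_pct),
            class = "session_recording")
}

#' Generate a full synthetic cohort of raw recordings
#'
#' Composes [generate_feature_table()] and [invert_features_to_signals()] over
#' the participant-by-task grid. Latent states are retained for recovery
#' experiments. Two reconciliations tie the recorded feature targets to what
#' extraction can actually return: blink rates are quantized to the achievable
#' grid `round(rate * duration) / duration`, and each participant's GSR targets
#' are renormalized onto the feasible manifold (for any recording set, the
#' duration-weighted mean of the once-divided normalized GSR is identically 1,
#' so six arbitrary targets are never jointly invertible; the common rescaling
#' factor is reported per participant in `gsr_feasibility`). The `features`
#' table holds these realized values, making the extraction round trip exact.
#'
#' @inheritParams generate_feature_table
#' @return an object of class `"bci_cohort"`: list with `recordings` (list of
#'   lists, `recordings[[participant]][[task]]`), `features`, `latent`,
#'   `gsr_feasibility`, and the `config` echo.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  check_number(seed, "seed")
  set.seed(seed)
  tab <- draw_feature_targets(config)
  tasks <- config$tasks
  dur <- vapply(tasks, `[[`, 0, "duration_s")
  pids <- unique(tab$participant)

  recordings <- vector("list", length(pids)); names(recordings) <- pids
  wfac <- stats::setNames(numeric(length(pids)), pids)
  for (pid in pids) {
    sel <- tab$participant == pid
    sub <- tab[sel, , drop = FALSE]
    sub <- sub[match(names(tasks), sub$task), , drop = FALSE]
    # feasibility renormalization of GSR targets (common factor per participant)
    w <- switch(config$gsr_convention,
      per_second_mean = sum(dur * sub$gsr_norm) / sum(dur),
      per_second_mean_over_duration = sum(dur^2 * sub$gsr_norm) / sum(dur))
    sub$gsr_norm <- sub$gsr_norm / w
    sub$blink_rate <- round(sub$blink_rate * dur) / dur
    wfac[pid] <- w
    recs <- vector("list", length(tasks)); names(recs) <- names(tasks)
    for (j in seq_along(tasks)) {
      recs[[j]] <- invert_features_to_signals(
        c(pupil_pct = sub$pupil_pct[j], blink_rate = sub$blink_rate[j],
          gsr_norm = sub$gsr_norm[j]),
        spec = tasks[[j]],
        baseline_mm = config$baseline_pupil_mm,
        overall_gsr_mean = config$baseline_gsr_us,
        blink_run_len = config$blink_run_len,
        sample_interval_ms = config$sample_interval_ms,
        gsr_convention = config$gsr_convention,
        performance_pct = sub$performance_pct[j],
        participant_id = pid, task_id = names(tasks)[j])
    }
    recordings[[pid]] <- recs
    tab[sel, ] <- sub[order(match(sub$task, tab$task[sel])), , drop = FALSE]
  }
  structure(list(recordings = recordings,
                 features = tab[, c("participant", "task", "pupil_pct",
                                    "blink_rate", "gsr_norm", "performance_pct")],
                 latent = tab[, c("participant", "task", "state")],
                 gsr_feasibility = wfac,
                 config = config),
            class = "bci_cohort")
}

#' @export
print.bci_cohort <- function(x, ...) {
  cat(sprintf("Synthetic BCI cohort: %d participants x %d tasks (%s)\n",
              length(x$recordings), length(x$config$tasks),
              x$config$gsr_convention))
  invisible(x)
}
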