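# Small task specs / cohorts used across tests. Durations are short so signal
# rendering stays cheap; feature geometry mirrors the default battery.

tiny_task <- function(task_id = "T1", task_type = "P300", duration_s = 60,
                      center_risky = c(20, 0.10, 0.006),
                      center_safe = c(5, 0.05, 0.004)) {
  task_spec(task_id, task_type, duration_s,
            center_risky = center_risky, center_safe = center_safe,
            feature_sd = c(2, 0.01, 0.0005),
            feature_min = c(-50, 0, 0.0001), feature_max = c(80, 0.5, 0.05),
            perf_mean = 75, perf_sd = 10, perf_min = 0, perf_max = 100)
}

tiny_config <- function(n = 4, n_tasks = 3, duration_s = 60, ...) {
  tasks <- lapply(seq_len(n_tasks), function(j)
    tiny_task(task_id = paste0("T", j),
              task_type = c("P300", "SSVEP", "MI2")[(j - 1) %% 3 + 1]))
  generator_config(n_participants = n, tasks = tasks, ...)
}

# Directly constructed pupil stream: constant diameter with optional missing runs.
pupil_stream <- function(duration_s, value = 4, interval_ms = 17,
                         missing_runs = list()) {
  t <- seq(0, duration_s * 1000 - interval_ms, by = interval_ms)
  p <- rep(value, length(t))
  for (r in missing_runs) p[r] <- NA
  list(time_ms = t, pupil_mm = p)
}

# O(n^2) loop-based silhouette oracle, independent of the package's
# matrix-algebra implementation.
silhouette_oracle <- function(X, cl) {
  X <- as.matrix(X); cl <- as.integer(factor(cl))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    d <- function(j) sqrt(sum((X[i, ] - X[j, ])^2))
    own <- setdiff(which(cl == cl[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, d, 0))
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g)
      mean(vapply(which(cl == g), d, 0)), 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Exhaustive best 2-partition by within-cluster sum of squares.
best_2partition_ss <- function(X) {
  X <- as.matrix(X); n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    g <- as.integer(intToBits(code))[1:n]
    if (all(g == 0) || all(g == 1)) next
    ss <- 0
    for (v in 0:1) {
      sub <- X[g == v, , drop = FALSE]
      ss <- ss + sum(sweep(sub, 2, colMeans(sub))^2)
    }
    best <- min(best, ss)
  }
  best
}
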