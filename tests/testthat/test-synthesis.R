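test_that("feature tables are deterministic given the seed and respect truncation", {
  cfg <- tiny_config(n = 12, noise_scale = 2)
  a <- generate_feature_table(cfg, seed = 99)
  b <- generate_feature_table(cfg, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, generate_feature_table(cfg, seed = 100)))

  for (s in 1:5) {
    g <- generate_feature_table(cfg, seed = s)
    for (tk in cfg$tasks) {
      sub <- g$features[g$features$task == tk$task_id, ]
      expect_true(all(sub$pupil_pct >= tk$feature_min[1] &
                      sub$pupil_pct <= tk$feature_max[1]))
      expect_true(all(sub$blink_rate >= tk$feature_min[2] &
                      sub$blink_rate <= tk$feature_max[2]))
      expect_true(all(sub$gsr_norm >= tk$feature_min[3] &
                      sub$gsr_norm <= tk$feature_max[3]))
      expect_true(all(sub$performance_pct >= tk$perf_min &
                      sub$performance_pct <= tk$perf_max))
    }
  }
})

test_that("zero noise with all-risky mixture pins features to the risky centers", {
  cfg <- generator_config(n_participants = 5, noise_scale = 0, mixture_weight = 1)
  g <- generate_feature_table(cfg, seed = 1)
  p1 <- g$features[g$features$task == "P300/1", ]
  expect_equal(p1$pupil_pct, rep(20.84, 5))
  expect_equal(p1$blink_rate, rep(0.08, 5))
  expect_equal(p1$gsr_norm, rep(0.0047, 5))
  expect_true(all(g$latent$state == "risky"))
})

test_that("feature sample means track the mixture-weighted center average", {
  cfg <- tiny_config(n = 70, n_tasks = 1)
  tk <- cfg$tasks[[1]]
  mix_mean <- (tk$center_risky + tk$center_safe) / 2
  draws <- sapply(1:60, function(s) {
    g <- generate_feature_table(cfg, seed = 1000 + s)
    colMeans(g$features[, c("pupil_pct", "blink_rate", "gsr_norm")])
  })
  grand <- rowMeans(draws)
  # 60 seeds x 70 participants; se includes the mixture's between-state spread
  se <- sqrt((tk$feature_sd^2 + (tk$center_risky - tk$center_safe)^2 / 4) /
             (60 * 70))
  expect_true(all(abs(grand - mix_mean) < 3 * se))
})

test_that("signal inversion realizes the requested pupil and blink structure", {
  spec <- tiny_task(duration_s = 60)
  rec <- invert_features_to_signals(
    c(pupil_pct = 10, blink_rate = 0.05, gsr_norm = 0.005),
    spec, seed = 4, baseline_mm = 4.0)
  base <- rec$time_ms < 1000
  expect_equal(mean(rec$pupil_mm[base], na.rm = TRUE), 4.0)
  expect_equal(mean(rec$pupil_mm[!base], na.rm = TRUE), 4.4)
  runs <- rle(is.na(rec$pupil_mm))
  expect_identical(sum(runs$values), 3L)           # round(0.05 * 60)
  expect_true(all(runs$lengths[runs$values] == 8))
  expect_false(anyNA(rec$pupil_mm[base]))
})

test_that("infeasible blink placement fails with a duration hint", {
  spec <- tiny_task(duration_s = 2)
  expect_error(
    invert_features_to_signals(c(pupil_pct = 0, blink_rate = 10, gsr_norm = 0.005),
                               spec, seed = 1),
    "longer duration")
})

test_that("cohorts cover the grid and zero-noise cohorts collapse to two rows per task", {
  cfg <- tiny_config(n = 2, n_tasks = 3, duration_s = 30)
  co <- generate_cohort(cfg, seed = 5)
  expect_length(co$recordings, 2)
  expect_length(unlist(co$recordings, recursive = FALSE), 6)
  expect_identical(nrow(co$latent), 6L)

  cfg0 <- tiny_config(n = 8, n_tasks = 2, noise_scale = 0)
  co0 <- generate_cohort(cfg0, seed = 6)
  ft <- build_feature_table(co0)
  for (tid in unique(ft$task)) {
    sub <- ft[ft$task == tid, c("pupil_pct", "blink_rate")]
    expect_lte(nrow(unique(sub)), 2)
  }
})

test_that("extraction inverts cohort synthesis within 1% relative error", {
  for (s in c(2, 7)) {
    co <- generate_cohort(tiny_config(n = 3, n_tasks = 3), seed = s)
    ft <- build_feature_table(co)
    tgt <- co$features
    expect_identical(ft$participant, tgt$participant)
    expect_true(all(abs(ft$pupil_pct - tgt$pupil_pct) <=
                    0.01 * pmax(abs(tgt$pupil_pct), 1e-8)))
    expect_true(all(abs(ft$blink_rate - tgt$blink_rate) <=
                    0.01 * pmax(tgt$blink_rate, 1e-8)))
    expect_true(all(abs(ft$gsr_norm - tgt$gsr_norm) <=
                    0.01 * tgt$gsr_norm))
  }
})

test_that("GSR targets are renormalized onto the feasible manifold", {
  co <- generate_cohort(tiny_config(n = 4, n_tasks = 3), seed = 9)
  dur <- vapply(co$config$tasks, `[[`, 0, "duration_s")
  for (pid in names(co$recordings)) {
    g <- co$features$gsr_norm[co$features$participant == pid]
    expect_equal(sum(dur^2 * g) / sum(dur), 1, tolerance = 1e-10)
  }
  # the calibrated default battery keeps the renormalization factor near 1
  # (its spread reflects the between-state variance of the six GSR targets)
  co_def <- generate_cohort(generator_config(n_participants = 8), seed = 10)
  expect_true(all(co_def$gsr_feasibility > 0.5 & co_def$gsr_feasibility < 1.6))
  expect_lt(abs(mean(co_def$gsr_feasibility) - 1), 0.2)
})

test_that("shared propensity induces cross-task state correlation", {
  cfg_ind <- generator_config(n_participants = 200, shared_propensity = 0)
  cfg_cor <- generator_config(n_participants = 200, shared_propensity = 0.8)
  risky_frac <- function(g) tapply(g$latent$state == "risky", g$latent$participant, mean)
  v_ind <- var(risky_frac(generate_feature_table(cfg_ind, seed = 21)))
  v_cor <- var(risky_frac(generate_feature_table(cfg_cor, seed = 21)))
  expect_gt(v_cor, v_ind * 2)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_participants = 0), "n_participants")
  expect_error(generator_config(mixture_weight = 1.5), "mixture_weight")
  expect_error(generator_config(noise_scale = -1), "noise_scale")
  expect_error(generator_config(noise_scale = NaN), "noise_scale")
  expect_error(tiny_task(duration_s = 0.5), "duration_s")
  expect_error(task_spec("X", "P300", 10, c(99, .1, .005), c(5, .05, .004),
                         c(1, .01, .001), c(-50, 0, 1e-4), c(80, .5, .05),
                         75, 10), "centers")
})
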