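test_that("paired t columns reproduce the published NASA-TLX rows to 0.005", {
  for (i in seq_len(nrow(reported_tlx))) {
    row <- reported_tlx[i, ]
    r <- paired_t_from_summary(row$mean_diff, row$sd_diff, row$n)
    expect_equal(r$se, row$se, tolerance = 0.005)
    expect_equal(r$t, row$t, tolerance = 0.005)
    expect_equal(r$ci_low, row$ci_low, tolerance = 0.005)
    expect_equal(r$ci_high, row$ci_high, tolerance = 0.005)
    expect_identical(r$df, 69)
    expect_lt(r$p, 0.001)
  }
})

test_that("paired t matches hand computation and the sign-flip symmetry", {
  # diffs {1,2,3}: mean 2, sd 1, se 1/sqrt(3)
  r <- paired_t_from_summary(2, 1, 3)
  expect_equal(r$se, 0.5774, tolerance = 1e-4)
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_identical(r$df, 2)

  a <- paired_t_from_summary(-7.3, 4.1, 25)
  b <- paired_t_from_summary(7.3, 4.1, 25)
  expect_equal(a$t, -b$t)
  expect_equal(a$ci_low, -b$ci_high)
  expect_equal(a$ci_high, -b$ci_low)
  expect_equal(a$p, b$p)
  expect_true(a$ci_low <= a$mean_diff && a$mean_diff <= a$ci_high)

  expect_error(paired_t_from_summary(1, 0, 10), "sd_diff")
  expect_error(paired_t_from_summary(1, 2, 1), "n")
})

test_that("confusion metrics reproduce every printed percent cell", {
  checks <- list(
    logistic = list(recall = c(100.0, 100.0), overall = 100.0, marg = c(84.3, 15.7)),
    chaid = list(recall = c(100.0, 36.4), overall = 90.0, marg = c(94.3, 5.7)),
    cart = list(recall = c(100.0, 100.0), overall = 100.0, marg = c(84.3, 15.7)),
    quest = list(recall = c(100.0, 18.2), overall = 87.1, marg = c(97.1, 2.9)),
    ann_batch = list(recall = c(100.0, 100.0), overall = 100.0, marg = c(84.3, 15.7)),
    ann_online = list(recall = c(98.3, 90.9), overall = 97.1, marg = c(84.3, 15.7)),
    ann_minibatch = list(recall = c(100.0, 90.9), overall = 98.6, marg = c(85.7, 14.3)))
  for (nm in names(checks)) {
    m <- confusion_metrics(reported_confusions[[nm]])
    expect_equal(unname(m$recall), checks[[nm]]$recall, tolerance = 0.05)
    expect_equal(m$overall, checks[[nm]]$overall, tolerance = 0.05)
    expect_equal(unname(m$predicted_marginal_pct), checks[[nm]]$marg,
                 tolerance = 0.05)
  }
})

test_that("confusion metrics handle perfect and degenerate tables", {
  m <- confusion_metrics(matrix(c(10, 0, 0, 10), 2))
  expect_equal(unname(m$recall), c(100, 100))
  expect_equal(m$overall, 100)
  empty_low <- confusion_metrics(matrix(c(8, 0, 2, 0), 2))
  expect_true(is.na(empty_low$recall[2]))
  expect_equal(empty_low$overall, 80)
  expect_error(confusion_metrics(matrix(0, 2, 2)), "positive total")
})

test_that("logistic coefficients match the reference fit on non-separable data", {
  set.seed(30)
  n <- 120
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  fit <- logistic_fit(X, y, ridge_eps = 1e-10)
  ref <- glm(y ~ X, family = binomial)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$ll, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$ll_null,
               as.numeric(logLik(glm(y ~ 1, family = binomial))), tolerance = 1e-8)
  expect_gte(fit$ll, fit$ll_null)
})

test_that("complete separation flags and classifies perfectly at both cut-offs", {
  x <- c(-3, -2, -1, -0.5, 0.5, 1, 2, 3)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  fit <- suppressWarnings(logistic_fit(cbind(x = x), y))
  expect_true(fit$separation)
  cm50 <- logistic_classify(fit, cutoff = 0.5)
  cm70 <- logistic_classify(fit, cutoff = 0.7)
  expect_identical(cm50, cm70)
  expect_equal(confusion_metrics(cm50)$overall, 100)
  expect_equal(nagelkerke_r2(fit$ll_null, min(fit$ll, 0), fit$n), 1,
               tolerance = 1e-6)
})

test_that("cut-off moves borderline probabilities between classes", {
  fake <- structure(list(fitted = rep(0.6, 10), y = rep(c(0, 1), 5)),
                    class = "logit_model")
  cm5 <- logistic_classify(fake, cutoff = 0.5)
  expect_equal(sum(cm5[, "low"]), 10)
  cm7 <- logistic_classify(fake, cutoff = 0.7)
  expect_equal(sum(cm7[, "high"]), 10)
})

test_that("Nagelkerke R2 covers the null, perfect and hand-computed cases", {
  expect_equal(nagelkerke_r2(-40, -40, 70), 0)
  expect_equal(nagelkerke_r2(-40, -1e-12, 70), 1, tolerance = 1e-6)
  # n = 4, LL0 = ln(1/16), LL1 = ln(1/4): Cox-Snell 0.5, max 0.75
  expect_equal(nagelkerke_r2(log(1 / 16), log(1 / 4), 4), 2 / 3, tolerance = 1e-12)
  expect_error(nagelkerke_r2(0, 0, 10), "single-class")
  expect_error(nagelkerke_r2(-5, -8, 10), "below")
})

test_that("omnibus chi-square reproduces the printed value and closed forms", {
  ll_null <- 59 * log(59 / 70) + 11 * log(11 / 70)
  om <- omnibus_test(ll_null, 0, 24)
  expect_equal(om$chi_square, 60.886, tolerance = 1e-3)
  expect_identical(om$df, 24L)
  expect_lt(om$p, 0.001)
  expect_equal(omnibus_test(-12.3, -12.3, 5)$chi_square, 0)
  # balanced 35/35 split, perfect model: -2 * 70 * ln(1/2)
  expect_equal(omnibus_test(70 * log(0.5), 0, 24)$chi_square, 140 * log(2))
  # consistency with Nagelkerke: R2 = 1 iff chi-square = -2 * LL0
  expect_equal(nagelkerke_r2(ll_null, 0, 70), 1)
  expect_equal(omnibus_test(ll_null, 0, 24)$chi_square, -2 * ll_null)
})

test_that("null labels give near-zero Nagelkerke R2", {
  set.seed(31)
  r2 <- replicate(8, {
    X <- matrix(rnorm(100 * 2), ncol = 2)
    y <- rep(c(0, 1), 50)[sample(100)]
    f <- logistic_fit(X, y)
    nagelkerke_r2(f$ll_null, min(f$ll, 0), f$n)
  })
  expect_lt(mean(r2), 0.05)
  expect_true(all(r2 < 0.2))
})

test_that("consistency report reaches full agreement on label-revealing data", {
  # labels identical to a threshold of one feature: every classifier must hit 100%
  set.seed(32)
  cfg <- generator_config(n_participants = 24)
  g <- generate_feature_table(cfg, seed = 33)
  feats <- g$features
  x <- feats$pupil_pct[feats$task == "P300/1"]
  gen <- data.frame(participant = unique(feats$participant),
                    general_risk = ifelse(x > median(x), "low", "high"))
  rep <- consistency_report(feats, gen, seed = 2, mlp_modes = "batch",
                            mlp_epochs = 400)
  expect_equal(unname(rep$agreement_pct), rep(100, 3), tolerance = 1e-9)
  expect_equal(rep$logistic$nagelkerke, 1, tolerance = 1e-6)
  expect_true(rep$logistic$separation)
  expect_identical(rep$logistic$omnibus$df, 24L)
})

test_that("consistency report rejects single-class labels", {
  g <- generate_feature_table(generator_config(n_participants = 6), seed = 3)
  gen <- data.frame(participant = unique(g$features$participant),
                    general_risk = "high")
  expect_error(consistency_report(g$features, gen), "one general risk class")
})

test_that("shuffled labels leave logistic training agreement near chance", {
  # permutation null in a regime where training fit cannot memorize
  # (4 predictors, 80 cases): agreement stays well below the signal regime
  set.seed(34)
  accs <- replicate(10, {
    X <- matrix(rnorm(80 * 4), ncol = 4)
    y <- sample(rep(c(0, 1), 40))
    f <- logistic_fit(X, y)
    mean((f$fitted >= 0.5) == (y == 1))
  })
  expect_lt(mean(accs), 0.7)
  expect_gte(min(accs), 0.4)
})
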