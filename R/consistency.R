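#' Paired t-test from summary statistics
#'
#' Reconstructs every column of a paired t-test row (standard error, t, df,
#' 95% confidence interval, two-sided p) from the mean and standard deviation
#' of the paired differences and the sample size — the closed form behind the
#' published NASA-TLX comparisons.
#'
#' @param mean_diff mean of the paired differences.
#' @param sd_diff standard deviation of the paired differences (> 0).
#' @param n number of pairs (>= 2).
#' @param conf_level confidence level (default 0.95).
#' @return list: `mean_diff`, `sd_diff`, `se`, `ci_low`, `ci_high`, `t`, `df`,
#'   `p`.
#' @export
paired_t_from_summary <- function(mean_diff, sd_diff, n, conf_level = 0.95) {
  check_number(mean_diff, "mean_diff")
  check_number(sd_diff, "sd_diff", lower = 1e-300)
  check_number(n, "n", lower = 2)
  se <- sd_diff / sqrt(n)
  df <- n - 1
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  tval <- mean_diff / se
  list(mean_diff = mean_diff, sd_diff = sd_diff, se = se,
       ci_low = mean_diff - tcrit * se, ci_high = mean_diff + tcrit * se,
       t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

# 24-column design matrix: for each task (in feature-table order) the four
# variables pupil, blink, GSR, performance.
design_matrix <- function(features) {
  tasks <- unique(features$task)
  pids <- unique(features$participant)
  cols <- list()
  for (tid in tasks) {
    sub <- features[features$task == tid, , drop = FALSE]
    sub <- sub[match(pids, sub$participant), , drop = FALSE]
    for (v in c("pupil_pct", "blink_rate", "gsr_norm", "performance_pct"))
      cols[[paste(tid, v, sep = ".")]] <- sub[[v]]
  }
  X <- do.call(cbind, cols)
  rownames(X) <- pids
  X
}

#' Classifier-consistency report against the rule-based risk classes
#'
#' Re-derives the rule-based general risk classes with three independent
#' classifiers, each trained on the full cohort (training accuracy measures
#' label consistency, not generalization, exactly as in the validation it
#' mirrors): binary logistic regression (enter method, cut-offs 0.50 and 0.70,
#' Nagelkerke R-squared, omnibus test), an unrestricted Gini CART tree, and a
#' tanh/softmax network in one or more training modes. Inputs are the 24
#' variables (6 tasks x pupil, blink rate, normalized GSR, performance).
#'
#' @param features feature table (participant, task, three features,
#'   performance_pct) covering every participant-task.
#' @param general data frame with `participant` and `general_risk`
#'   (`"high"`/`"low"`), as in [build_risk_profiles()]`$general`.
#' @param seed seed for the network.
#' @param cutoffs logistic probability cut-offs.
#' @param mlp_modes network training modes to run.
#' @param mlp_epochs training epochs for each network.
#' @return object of class `"consistency_report"`: per-method confusion
#'   matrices with percent summaries, logistic `nagelkerke` / `omnibus` /
#'   `separation`, and `agreement_pct` per method.
#' @export
consistency_report <- function(features, general, seed = 1,
                               cutoffs = c(0.5, 0.7),
                               mlp_modes = c("batch", "online", "minibatch"),
                               mlp_epochs = 1000) {
  X <- design_matrix(features)
  general <- general[match(rownames(X), general$participant), , drop = FALSE]
  if (anyNA(general$participant)) stop_bad("general risk labels incomplete")
  y <- as.integer(as.character(general$general_risk) == "low")
  if (length(unique(y)) < 2)
    stop_bad("all participants share one general risk class; consistency is undefined")
  obs <- ifelse(y == 1, "low", "high")

  lr <- suppressWarnings(logistic_fit(X, y))
  lr_tables <- lapply(cutoffs, function(co) {
    cm <- logistic_classify(lr, cutoff = co)
    c(list(cutoff = co), confusion_metrics(cm))
  })
  names(lr_tables) <- paste0("cutoff_", format(cutoffs))

  tree <- cart_fit(X, y)
  cm_cart <- confusion_matrix2(obs, ifelse(cart_predict(tree, X) == 1, "low", "high"))

  mlps <- lapply(mlp_modes, function(md) {
    m <- mlp_fit(X, y, mode = md, seed = seed, epochs = mlp_epochs)
    cm <- confusion_matrix2(obs, ifelse(m$fitted >= 0.5, "low", "high"))
    c(list(mode = md, final_loss = m$loss[length(m$loss)]), confusion_metrics(cm))
  })
  names(mlps) <- mlp_modes

  agreement <- c(
    logistic = lr_tables[[1]]$overall,
    cart = confusion_metrics(cm_cart)$overall,
    vapply(mlps, function(m) m$overall, 0))
  names(agreement)[-(1:2)] <- paste0("mlp_", mlp_modes)

  structure(list(
    logistic = list(model = lr, tables = lr_tables,
                    nagelkerke = nagelkerke_r2(lr$ll_null, min(lr$ll, 0), lr$n),
                    omnibus = omnibus_test(lr$ll_null, lr$ll, ncol(X)),
                    separation = lr$separation),
    cart = c(list(tree = tree, depth = cart_depth(tree$root)),
             confusion_metrics(cm_cart)),
    mlp = mlps,
    agreement_pct = agreement,
    n = nrow(X)), class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Consistency with the rule-based classes (n = %d):\n", x$n))
  for (nm in names(x$agreement_pct))
    cat(sprintf("  %-14s %.1f%%\n", nm, x$agreement_pct[[nm]]))
  cat(sprintf("  logistic Nagelkerke R2 = %.3f, omnibus chi2(%d) = %.3f%s\n",
              x$logistic$nagelkerke, x$logistic$omnibus$df,
              x$logistic$omnibus$chi_square,
              if (x$logistic$separation) " [complete separation]" else ""))
  invisible(x)
}
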