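# Published cohort-level summary tables, shipped as inputs: the raw data were
# never deposited, so these printed numbers are what the closed-form
# reproductions and the generator calibration consume.

#' Published NASA-TLX paired-difference summaries
#'
#' Mean and standard deviation of the within-participant NASA-TLX differences
#' (first minus second task of each type) for the 70-participant cohort,
#' together with the printed derived columns for comparison.
#'
#' @format data frame with columns `comparison`, `mean_diff`, `sd_diff`, `n`,
#'   and the printed `se`, `ci_low`, `ci_high`, `t`, `df`.
#' @export
reported_tlx <- data.frame(
  comparison = c("P300/1 - P300/2", "SSVEP/1 - SSVEP/2", "MI/1 - MI/2"),
  mean_diff = c(-18.000, -8.929, -12.439),
  sd_diff = c(13.418, 9.217, 10.116),
  n = 70,
  se = c(1.604, 1.102, 1.209),
  ci_low = c(-21.199, -11.127, -14.851),
  ci_high = c(-14.800, -6.731, -10.026),
  t = c(-11.223, -8.105, -10.287),
  df = 69,
  stringsAsFactors = FALSE)

#' Published silhouette scores and display percentages
#'
#' The 18 (cluster count, silhouette, percentage) rows of the published model
#' selection table, six tasks by k in 2..4.
#'
#' @format data frame with columns `task`, `k`, `silhouette`, `percentage`.
#' @export
reported_silhouettes <- data.frame(
  task = rep(c("P300/1", "P300/2", "SSVEP/1", "SSVEP/2", "MI/1", "MI/2"), each = 3),
  k = rep(2:4, times = 6),
  silhouette = c(0.65, 0.57, 0.64, 0.60, 0.54, 0.59, 0.78, 0.59, 0.60,
                 0.59, 0.58, 0.55, 0.59, 0.59, 0.58, 0.60, 0.52, 0.60),
  percentage = c(82.50, 78.50, 82, 80, 77, 79.50, 89, 79.50, 80,
                 79.50, 79, 77.50, 79.50, 79.50, 79, 80, 76, 80))

#' Published classification tables of the consistency checks
#'
#' Count cells of the published 2x2 classification tables (rows observed
#' high/low risk, columns predicted), for binary logistic regression, the
#' three decision-tree algorithms, and the three network training modes. The
#' CHAID and QUEST counts are carried purely as arithmetic fixtures for
#' [confusion_metrics()].
#'
#' @format named list of 2x2 integer matrices.
#' @export
reported_confusions <- local({
  cm <- function(hh, hl, lh, ll)
    matrix(c(hh, lh, hl, ll), 2, 2,
           dimnames = list(observed = c("high", "low"),
                           predicted = c("high", "low")))
  list(logistic = cm(59, 0, 0, 11),
       chaid = cm(59, 0, 7, 4),
       cart = cm(59, 0, 0, 11),
       quest = cm(59, 0, 9, 2),
       ann_batch = cm(59, 0, 0, 11),
       ann_online = cm(58, 1, 1, 10),
       ann_minibatch = cm(59, 0, 1, 10))
})

#' Published general-risk split
#'
#' 59 of 70 participants were assigned to the high general-risk class and 11
#' to the low class.
#'
#' @format named integer vector.
#' @export
reported_split <- c(high = 59L, low = 11L)
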