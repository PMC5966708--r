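#' Binary logistic regression by IRLS with a tiny ridge
#'
#' Enter-method fit: all columns of `X` enter the model at once. Newton/IRLS
#' steps are stabilized by adding `ridge_eps` to the diagonal of the weighted
#' normal equations. Under complete separation the likelihood has no finite
#' maximizer; the fit then stops at `max_iter` with the `separation` flag set
#' and a perfect training classification table, mirroring how the usual
#' commercial implementation reports such models (Nagelkerke R-squared 1.0).
#'
#' @param X numeric design matrix without intercept column.
#' @param y binary response: 0/1 vector, logical, or factor whose *second*
#'   level is the positive class.
#' @param max_iter IRLS iteration cap.
#' @param ridge_eps ridge added for numerical safety.
#' @param tol convergence tolerance on the coefficient step.
#' @return object of class `"logit_model"`: `coefficients` (intercept first),
#'   `fitted` (P(positive)), `ll`, `ll_null`, `n`, `converged`, `separation`,
#'   `y`, `iter`.
#' @export
logistic_fit <- function(X, y, max_iter = 100, ridge_eps = 1e-8, tol = 1e-10) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_bad("y must be binary")
  n <- nrow(X)
  if (length(y) != n) stop_bad("X and y sizes disagree")
  if (length(unique(y)) < 2) stop_bad("y is constant; nothing to fit")
  scl <- apply(X, 2, sd)
  if (any(scl == 0))
    warning("constant column(s) in the design matrix: ",
            paste(which(scl == 0), collapse = ", "), call. = FALSE)
  if (anyDuplicated(t(X)))
    warning("duplicated column(s) in the design matrix", call. = FALSE)

  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pbar <- mean(y)
  ll_null <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  loglik <- function(beta) {
    mu <- pmin(pmax(plogis(drop(Xd %*% beta)), 1e-15), 1 - 1e-15)
    sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  beta <- c(stats::qlogis(pbar), numeric(p - 1)) # start at the null model
  ll <- ll_null
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    eta <- drop(Xd %*% beta)
    mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtW <- t(Xd * w)
    H <- XtW %*% Xd + diag(ridge_eps, p)
    beta_new <- tryCatch(drop(solve(H, XtW %*% z)),
                         error = function(e)
                           stop_bad("singular IRLS system beyond ridge rescue: %s",
                                    conditionMessage(e)))
    # step-halve toward the Newton point so the likelihood never decreases
    dir <- beta_new - beta
    t_step <- 1
    repeat {
      cand <- beta + t_step * dir
      ll_cand <- loglik(cand)
      if (ll_cand >= ll - 1e-12 || t_step < 1e-8) break
      t_step <- t_step / 2
    }
    if (ll_cand < ll) break            # no ascent direction left
    step <- max(abs(t_step * dir))
    beta <- cand
    ll <- ll_cand
    if (step < tol) { converged <- TRUE; break }
  }
  mu <- pmin(pmax(plogis(drop(Xd %*% beta)), 1e-15), 1 - 1e-15)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  separation <- all((mu >= 0.5) == (y == 1)) && ll > -1e-4
  structure(list(coefficients = stats::setNames(beta, colnames(Xd)),
                 fitted = mu, ll = ll, ll_null = ll_null, n = n,
                 converged = converged, separation = separation,
                 y = y, iter = iter),
            class = "logit_model")
}

#' Classification table of a fitted logistic model
#'
#' Predicts the positive (low-risk) class when its fitted probability reaches
#' the cut-off, and cross-tabulates observed against predicted classes.
#'
#' @param model a `"logit_model"`.
#' @param cutoff probability cut-off (the study used 0.50 and 0.70).
#' @param labels length-2 class names, negative class first.
#' @return 2x2 confusion matrix (rows observed, cols predicted).
#' @export
logistic_classify <- function(model, cutoff = 0.5, labels = c("high", "low")) {
  stopifnot(inherits(model, "logit_model"))
  check_number(cutoff, "cutoff", 0, 1)
  pred <- ifelse(model$fitted >= cutoff, labels[2], labels[1])
  obs <- ifelse(model$y == 1, labels[2], labels[1])
  confusion_matrix2(obs, pred, labels)
}

#' Nagelkerke pseudo R-squared
#'
#' Rescaled Cox-Snell R-squared:
#' `(1 - exp(2 (LL0 - LL1) / n)) / (1 - exp(2 LL0 / n))`,
#' 0 when the model adds nothing and 1 in the perfect-fit limit `LL1 -> 0`.
#'
#' @param ll_null log-likelihood of the intercept-only model.
#' @param ll_model log-likelihood of the fitted model (`>= ll_null`).
#' @param n number of cases.
#' @return value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(ll_null, ll_model, n) {
  check_number(ll_null, "ll_null", upper = 0)
  check_number(ll_model, "ll_model", upper = 1e-9)
  check_number(n, "n", lower = 1)
  if (ll_null == 0) stop_bad("degenerate single-class response: null likelihood is 1")
  if (ll_model < ll_null - 1e-8) stop_bad("ll_model below ll_null")
  (1 - exp(2 * (ll_null - ll_model) / n)) / (1 - exp(2 * ll_null / n))
}

#' Omnibus likelihood-ratio test of a logistic model
#'
#' Chi-square `-2 (LL0 - LL1)` on `n_predictors` degrees of freedom against
#' the intercept-only model.
#'
#' @inheritParams nagelkerke_r2
#' @param n_predictors number of predictors entered (the model block's df).
#' @return list with `chi_square`, `df`, `p`.
#' @export
omnibus_test <- function(ll_null, ll_model, n_predictors) {
  chi <- -2 * (ll_null - ll_model)
  list(chi_square = chi, df = as.integer(n_predictors),
       p = pchisq(chi, n_predictors, lower.tail = FALSE))
}
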