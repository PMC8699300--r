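# Weighted logistic regression by iteratively reweighted least squares.
#
# A lean IRLS keeps leave-one-out screening of thousands of variables
# tractable (a formula/glm round trip per fold would dominate the runtime)
# and gives explicit control over the divergence behaviour under complete
# separation, which the reporting convention handles upstream.  glm() is
# used as an independent cross-check in the test-suite.

fit_weighted_logistic <- function(X, y, w, maxit = 100L, tol = 1e-8) {
  # standardise non-intercept columns for conditioning; map back at the end
  p <- ncol(X)
  ctr <- c(0, colMeans(X[, -1, drop = FALSE]))
  scl <- c(1, apply(X[, -1, drop = FALSE], 2, stats::sd))
  scl[scl == 0] <- 1
  Z <- X
  if (p > 1) {
    Z[, -1] <- sweep(sweep(X[, -1, drop = FALSE], 2, ctr[-1]), 2,
                     scl[-1], "/")
  }
  beta <- rep(0, p)
  wbar <- sum(w * y) / sum(w)
  beta[1] <- log(wbar / (1 - wbar))
  dev_old <- Inf; converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- 1 / (1 + exp(-eta))
    W <- w * mu * (1 - mu)
    W <- pmax(W, 1e-10)
    z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-10)
    XtW <- t(Z * W)
    beta_new <- tryCatch(
      solve(XtW %*% Z, XtW %*% z),
      error = function(e) NULL
    )
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    dev <- -2 * sum(w * (y * log(pmax(mu, 1e-12)) +
                           (1 - y) * log(pmax(1 - mu, 1e-12))))
    if (is.finite(dev_old) && abs(dev_old - dev) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  # back-transform to the original predictor scale
  b <- beta
  if (p > 1) {
    b[-1] <- beta[-1] / scl[-1]
    b[1] <- beta[1] - sum(beta[-1] * ctr[-1] / scl[-1])
  }
  list(beta = b, converged = converged)
}

predict_logistic <- function(beta, X) {
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  1 / (1 + exp(-eta))
}

#' ROC AUC with DeLong's confidence interval
#'
#' The AUC is the Mann-Whitney probability estimate (ties counted half);
#' the variance comes from DeLong's structural-components estimator and the
#' Wald interval is truncated to `[0, 1]`.  When the AUC equals 1 the
#' interval is degenerate at (1, 1) and is therefore not reported.
#'
#' @param pred numeric prediction scores.
#' @param labels 0/1 (or logical) class labels; 1 is the positive class.
#' @param level confidence level.
#' @return list: `auc` (percent), `ci` (percent, length-2 or `NULL` when
#'   AUC = 1), `var` (variance of the AUC on the 0-1 scale).
#' @export
delong_auc_ci <- function(pred, labels, level = 0.95) {
  y <- as.integer(labels)
  px <- pred[y == 1]; py <- pred[y == 0]
  m <- length(px); n <- length(py)
  stopifnot(m >= 1, n >= 1)
  psi <- outer(px, py, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)  # structural components of the positives
  v01 <- colMeans(psi)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  v <- s10 / m + s01 / n
  if (auc == 1) {
    return(list(auc = 100, ci = NULL, var = v))
  }
  z <- qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(v), 0), 1)
  list(auc = 100 * auc, ci = 100 * ci, var = v)
}

#' Balanced-weight leave-one-out cross-validated logistic regression
#'
#' Each held-out sample is predicted from a logistic model fitted on the
#' remaining samples with class-balancing weights (each training sample
#' weighted by `N_train / (2 * n_group,train)`, recomputed inside every
#' fold so both classes carry equal total weight).  Held-out probabilities
#' are classified at 0.5 and summarised by unweighted accuracy, sensitivity
#' and specificity, plus the DeLong AUC of the held-out scores.  When any
#' single predictor completely separates the full data, the published
#' reporting convention applies: accuracy, sensitivity, specificity and AUC
#' are all reported as 100% without fitting.
#'
#' @param vm a [build_variable_matrix()] result (or any tibble with
#'   `sample_id`, `group` and the predictor columns).
#' @param contrast positive group label (`"PCa"`, `"HD"` or `"BPH"`); the
#'   other groups form the negative pool.
#' @param predictors character vector of column names; single-position
#'   unmethylated names (e.g. `"GSTP1.T3"`) are rewritten to complements.
#' @param threshold classification threshold on the held-out probability.
#' @return list: `accuracy`, `sensitivity`, `specificity`, `auc` (all
#'   percent), `auc_ci` (percent or `NULL`), `separated` (logical),
#'   `predictions` (tibble of held-out probabilities, `NULL` when the
#'   separation convention fired).
#' @export
loocv_logistic <- function(vm, contrast, predictors, threshold = 0.5) {
  dat <- predictor_frame(vm, predictors)
  y <- as.integer(vm$group == contrast)
  stopifnot(sum(y) >= 1, sum(1 - y) >= 1)
  for (v in colnames(dat)) {
    sep <- separation_metrics(dat[y == 1, v], dat[y == 0, v])
    if (sep$complete_separation) {
      return(list(accuracy = 100, sensitivity = 100, specificity = 100,
                  auc = 100, auc_ci = NULL, separated = TRUE,
                  predictions = NULL))
    }
  }
  N <- length(y)
  X <- cbind(1, as.matrix(dat))
  prob <- numeric(N)
  for (i in seq_len(N)) {
    yi <- y[-i]
    wi <- ifelse(yi == 1, 1 / sum(yi == 1), 1 / sum(yi == 0)) * (N - 1) / 2
    fit <- fit_weighted_logistic(X[-i, , drop = FALSE], yi, wi)
    prob[i] <- predict_logistic(fit$beta, X[i, , drop = FALSE])
  }
  cls <- as.integer(prob >= threshold)
  dl <- delong_auc_ci(prob, y)
  list(
    accuracy = 100 * mean(cls == y),
    sensitivity = 100 * mean(cls[y == 1] == 1),
    specificity = 100 * mean(cls[y == 0] == 0),
    auc = dl$auc, auc_ci = dl$ci, separated = FALSE,
    predictions = tibble(sample_id = vm$sample_id, group = vm$group,
                         truth = y, prob = prob)
  )
}

# resolve predictor names (rewriting single-T complements) to a numeric frame
predictor_frame <- function(vm, predictors) {
  out <- matrix(NA_real_, nrow = nrow(vm), ncol = length(predictors),
                dimnames = list(NULL, predictors))
  for (v in predictors) {
    if (v %in% names(vm)) {
      out[, v] <- vm[[v]]
    } else {
      spec <- parse_variable_name(v)
      if (!isTRUE(spec$complement) || !(sub("\\.T", ".C", v) %in% names(vm))) {
        abort_schema(sprintf("unknown predictor '%s'", v))
      }
      out[, v] <- 1 - vm[[sub("\\.T", ".C", v)]]
    }
  }
  as.data.frame(out)
}

#' Greedy forward selection of predictors by LOOCV accuracy
#'
#' At each step the candidate maximising the leave-one-out accuracy of the
#' grown model is added; ties are broken by higher cross-validated AUC and
#' then by canonical variable order.  Selection stops at `max_predictors`
#' or as soon as no addition improves the accuracy.
#'
#' @inheritParams loocv_logistic
#' @param candidates candidate variable names (default: all enumerated
#'   variables of the matrix).
#' @param max_predictors maximum model size.
#' @return tibble with one row per accepted step: `step`, `variable`,
#'   `cv_accuracy`, `cv_sensitivity`, `cv_specificity`, `cv_auc`.
#' @export
forward_select <- function(vm, contrast, candidates = NULL,
                           max_predictors = 3L) {
  candidates <- candidates %||% variable_names(vm)
  chosen <- character(0)
  rows <- list()
  best_acc <- -Inf
  for (step in seq_len(max_predictors)) {
    step_best <- NULL
    for (v in setdiff(candidates, chosen)) {
      res <- loocv_logistic(vm, contrast, c(chosen, v))
      if (is.null(step_best) ||
          res$accuracy > step_best$res$accuracy ||
          (res$accuracy == step_best$res$accuracy &&
             res$auc > step_best$res$auc)) {
        step_best <- list(v = v, res = res)
      }
    }
    if (is.null(step_best) || step_best$res$accuracy <= best_acc) break
    best_acc <- step_best$res$accuracy
    chosen <- c(chosen, step_best$v)
    rows[[step]] <- tibble(
      step = step, variable = step_best$v,
      cv_accuracy = step_best$res$accuracy,
      cv_sensitivity = step_best$res$sensitivity,
      cv_specificity = step_best$res$specificity,
      cv_auc = step_best$res$auc
    )
    if (best_acc == 100) break
  }
  bind_rows(rows)
}
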