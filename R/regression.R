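# Per-participant regression models scored by 10-fold cross-validated
# variation explained: R^2 for gaze durations (OLS), McFadden R^2 for
# skipping (maximum-likelihood logistic regression). No regularization, no
# mixed effects: one model per participant, aggregated across participants.

#' Held-out predictions from k-fold cross-validation
#'
#' Folds are assigned at random by row with a fixed seed (stratified by
#' outcome for the binomial case so every training fold sees both classes).
#' Models are ordinary least squares or maximum-likelihood logistic
#' regression with an intercept and no regularization. Alongside the model
#' prediction, each held-out row carries the training fold's null
#' prediction (mean outcome, or event rate), which the scoring functions
#' need.
#'
#' @param table data.frame for a single participant.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor columns.
#' @param family "gaussian" (identity link) or "binomial" (logistic).
#' @param k_folds number of folds (default 10).
#' @param seed fold-assignment seed; the same seed yields the same folds,
#'   which shared-fold variation partitioning relies on.
#' @return data.frame with columns `y`, `pred`, `null_pred`, `fold`.
#' @export
fit_predict_cv <- function(table, outcome, predictors,
                           family = c("gaussian", "binomial"),
                           k_folds = 10L, seed = 1L) {
  family <- match.arg(family)
  n <- nrow(table)
  if (n < k_folds)
    stop_readobs(sprintf("%d rows is fewer than %d folds", n, k_folds),
                 "readobs_cv_error")
  y <- table[[outcome]]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(table[, predictors, drop = FALSE]))
  fold <- with_seed(seed, assign_folds(y, k_folds,
                                       stratify = family == "binomial"))
  pred <- null_pred <- numeric(n)
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- !tr
    if (family == "gaussian") {
      fit <- stats::lm.fit(X[tr, , drop = FALSE], y[tr])
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred[te] <- X[te, , drop = FALSE] %*% beta
      null_pred[te] <- mean(y[tr])
    } else {
      if (length(unique(y[tr])) < 2L)
        stop_readobs("training fold outcome is constant", "readobs_cv_error")
      fit <- suppressWarnings(stats::glm.fit(
        X[tr, , drop = FALSE], y[tr], family = stats::binomial(),
        control = list(epsilon = 1e-8, maxit = 500L)))
      if (!fit$converged)
        stop_readobs(sprintf(
          "logistic fit did not converge (n = %d, event rate %.3f)",
          sum(tr), mean(y[tr])), "readobs_cv_error")
      eta <- X[te, , drop = FALSE] %*%
        ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred[te] <- stats::plogis(eta)
      null_pred[te] <- mean(y[tr])
    }
  }
  data.frame(y = y, pred = pred, null_pred = null_pred, fold = fold)
}

assign_folds <- function(y, k, stratify = FALSE) {
  n <- length(y)
  fold <- integer(n)
  if (stratify) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

#' Cross-validated R-squared from pooled held-out losses
#'
#' `1 - SS_res / SS_tot`, with the residual sum of squares pooled over all
#' held-out predictions and the total sum of squares computed against each
#' fold's training-mean prediction. Negative values indicate a model
#' predicting worse than the null.
#'
#' @param y outcomes.
#' @param pred held-out model predictions.
#' @param null_pred held-out training-fold mean predictions.
#' @return scalar R^2 (at most 1, possibly negative).
#' @export
score_r2 <- function(y, pred, null_pred) {
  ss_tot <- sum((y - null_pred)^2)
  if (ss_tot == 0)
    stop_readobs("zero total sum of squares", "readobs_score_error")
  1 - sum((y - pred)^2) / ss_tot
}

#' Cross-validated McFadden R-squared
#'
#' `1 - L_M / L_null` where both losses are pooled held-out negative
#' log-likelihoods; the null model is an intercept-only fit on each
#' training fold. Probabilities are clipped at 1e-12.
#'
#' @param y 0/1 outcomes.
#' @param prob held-out model probabilities.
#' @param null_rate held-out training-fold event rates.
#' @return scalar McFadden R^2 (at most 1, possibly negative).
#' @export
score_mcfadden <- function(y, prob, null_rate) {
  nll <- function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  l_null <- nll(null_rate)
  if (l_null == 0)
    stop_readobs("null model has zero loss", "readobs_score_error")
  1 - nll(prob) / l_null
}

#' Cross-validated score of one model specification
#'
#' @inheritParams fit_predict_cv
#' @return scalar score (R^2 or McFadden R^2 depending on family).
#' @export
cv_score <- function(table, outcome, predictors, family = "gaussian",
                     k_folds = 10L, seed = 1L) {
  cv <- fit_predict_cv(table, outcome, predictors, family, k_folds, seed)
  if (family == "gaussian") score_r2(cv$y, cv$pred, cv$null_pred)
  else score_mcfadden(cv$y, cv$pred, cv$null_pred)
}

#' Scores for every combination of explanation sets
#'
#' Fits the 3 (or 7) models needed for two- (three-)way variation
#' partitioning: each set alone plus every union, all with identical fold
#' assignments so score differences reflect predictors, not folds.
#'
#' @param table single-participant predictor table.
#' @param outcome outcome column name.
#' @param sets named list of predictor-column vectors (2 or 3 sets;
#'   must be disjoint).
#' @inheritParams fit_predict_cv
#' @return named numeric vector of scores: `"A"`, `"B"`, `"AB"`, ... with
#'   set names joined by `+` in the element names' attribute `labels`.
#' @export
score_model_combinations <- function(table, outcome, sets,
                                     family = "gaussian",
                                     k_folds = 10L, seed = 1L) {
  stopifnot(length(sets) %in% c(2L, 3L), !is.null(names(sets)))
  if (any(duplicated(unlist(sets))))
    stop_readobs("explanation sets must be disjoint", "readobs_bad_sets")
  letters_ <- c("A", "B", "C")[seq_along(sets)]
  combos <- unlist(lapply(seq_along(sets), function(m)
    utils::combn(seq_along(sets), m, simplify = FALSE)), recursive = FALSE)
  out <- numeric(length(combos))
  names(out) <- vapply(combos, function(ix)
    paste(letters_[ix], collapse = ""), "")
  for (i in seq_along(combos)) {
    preds <- unlist(sets[combos[[i]]], use.names = FALSE)
    out[i] <- cv_score(table, outcome, preds, family, k_folds, seed)
  }
  attr(out, "labels") <- names(sets)
  out
}

#' Regressive refixation of skipped words vs pre-skip identifiability
#'
#' Among first-pass-skipped tokens, fits a logistic regression of whether
#' the token was later regressively fixated on its (standardized)
#' parafoveal posterior entropy before skipping. A positive coefficient
#' means words that were hard to identify parafoveally are more likely to
#' be fetched back -- the compensation signature.
#'
#' @param table data.frame of skipped tokens with columns
#'   `later_regressive_fixation` and `parafoveal_entropy` (z-scored).
#' @return list with `coefficient` (slope), `intercept`, `n`.
#' @export
fit_skipped_refixation_model <- function(table) {
  if (nrow(table) == 0L)
    stop_readobs("no skipped tokens", "readobs_no_data")
  y <- table$later_regressive_fixation
  if (length(unique(y)) < 2L)
    stop_readobs("refixation outcome is constant (separation)",
                 "readobs_degenerate")
  X <- cbind(1, table$parafoveal_entropy)
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = list(epsilon = 1e-8, maxit = 500L)))
  if (!fit$converged)
    stop_readobs("logistic fit did not converge", "readobs_cv_error")
  list(intercept = fit$coefficients[1], coefficient = fit$coefficients[2],
       n = length(y))
}
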