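# Group-level inference across participants: equal-tail bootstrap t-tests,
# model-derived effect sizes in ms, and the contextual vs non-contextual
# observer comparison.

#' Equal-tail bootstrap t-test against zero
#'
#' The null distribution is built by mean-centering the per-participant
#' values and resampling with replacement; the p value is the equal-tail
#' probability of a t statistic as or more extreme than the observed one,
#' computed without assuming symmetry (twice the smaller tail, capped at
#' 1). The confidence interval is the percentile interval of the
#' resampled (uncentered) means.
#'
#' @param values per-participant statistics (length >= 2, nonzero
#'   variance).
#' @param n_boot number of bootstrap resamples (default 1e4).
#' @param seed RNG seed.
#' @param conf_level CI level (default 0.95).
#' @return object of class `readobs_bootstrap`: `mean`, `t`, `p`,
#'   `ci` (length 2), `n`, `n_boot`, `conf_level`.
#' @export
bootstrap_t_test <- function(values, n_boot = 1e4L, seed = 1L,
                             conf_level = 0.95) {
  n <- length(values)
  if (n < 2L) stop_readobs("need at least 2 values", "readobs_stats_error")
  s <- stats::sd(values)
  if (s == 0) stop_readobs("zero variance", "readobs_zero_variance")
  m <- mean(values)
  t_obs <- m / (s / sqrt(n))
  centered <- values - m
  res <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    null_mat <- matrix(centered[idx], nrow = n)
    null_means <- colMeans(null_mat)
    null_sds <- sqrt(colMeans(null_mat^2) - null_means^2) * sqrt(n / (n - 1))
    t_null <- null_means / (null_sds / sqrt(n))
    boot_mat <- matrix(values[idx], nrow = n)
    list(t_null = t_null[is.finite(t_null)], boot_means = colMeans(boot_mat))
  })
  p_low <- mean(res$t_null <= t_obs)
  p_high <- mean(res$t_null >= t_obs)
  p <- min(1, 2 * min(p_low, p_high))
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(res$boot_means, c(alpha, 1 - alpha)))
  structure(list(mean = m, t = t_obs, p = p, ci = ci, n = n,
                 n_boot = n_boot, conf_level = conf_level),
            class = "readobs_bootstrap")
}

#' @export
print.readobs_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<bootstrap t-test> mean %.4g (t = %.3f, n = %d), %d%% CI [%.4g, %.4g], p = %.4g\n",
    x$mean, x$t, x$n, round(100 * x$conf_level), x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' Model-derived preview benefit in ms
#'
#' Expected difference in gaze duration after a preview of average
#' informativeness versus after no preview at all (posterior entropy equal
#' to the prior entropy). Both entropies are put on the participant's
#' z-scale for parafoveal entropy and multiplied by the regression weight;
#' the sign convention makes informative previews yield positive benefit.
#'
#' @param beta_parafoveal regression weight of (z-scored) parafoveal
#'   entropy, in ms per SD.
#' @param mean_posterior_entropy the participant's mean parafoveal
#'   posterior entropy (bits).
#' @param prior_entropy the no-preview entropy: the observer's prior
#'   entropy (bits).
#' @param sd_entropy the participant's SD of parafoveal entropy (bits),
#'   from the stored standardization moments.
#' @return benefit in ms.
#' @export
preview_benefit <- function(beta_parafoveal, mean_posterior_entropy,
                            prior_entropy, sd_entropy) {
  if (!is.finite(sd_entropy) || sd_entropy <= 0)
    stop_readobs("missing or invalid standardization moments",
                 "readobs_missing_moments")
  delta_z <- (mean_posterior_entropy - prior_entropy) / sd_entropy
  -delta_z * beta_parafoveal
}

#' Model-derived predictability benefit in ms
#'
#' Expected gaze-duration difference between low- and high-probability
#' words, with probability bins defined by cloze cutoffs transformed to
#' surprisal: low-probability words have surprisal above
#' `-log2(cloze_low)`, high-probability words below `-log2(cloze_high)`.
#' The difference of mean z-scored surprisal between the bins is
#' multiplied by the current-word surprisal weight.
#'
#' @param beta_surprisal weight of (z-scored) current-word surprisal, in
#'   ms per SD.
#' @param surprisal raw surprisal values for the participant (bits).
#' @param mean_surprisal,sd_surprisal the participant's standardization
#'   moments for surprisal.
#' @param cloze_low,cloze_high cloze-probability cutoffs (defaults 0.02
#'   and 0.25).
#' @return benefit in ms.
#' @export
predictability_benefit <- function(beta_surprisal, surprisal,
                                   mean_surprisal = mean(surprisal),
                                   sd_surprisal = stats::sd(surprisal),
                                   cloze_low = 0.02, cloze_high = 0.25) {
  stopifnot(cloze_low > 0, cloze_high < 1, cloze_low < cloze_high)
  lo_cut <- -log2(cloze_low)   # high surprisal = low probability
  hi_cut <- -log2(cloze_high)
  low_bin <- surprisal > lo_cut
  high_bin <- surprisal < hi_cut
  if (!any(low_bin) || !any(high_bin))
    stop_readobs("empty surprisal bin at the given cutoffs",
                 "readobs_empty_bin")
  z <- (surprisal - mean_surprisal) / sd_surprisal
  (mean(z[low_bin]) - mean(z[high_bin])) * beta_surprisal
}

#' Compare contextual and non-contextual observers by model fit
#'
#' Paired comparison of per-participant cross-validated scores of the full
#' model equipped with parafoveal entropy from the contextual versus the
#' non-contextual observer (shared folds). Positive mean difference means
#' the non-contextual observer fits better.
#'
#' @param scores_contextual,scores_noncontextual named numeric vectors of
#'   per-participant scores (names = participants, matched).
#' @inheritParams bootstrap_t_test
#' @return a `readobs_bootstrap` on the differences
#'   (non-contextual minus contextual).
#' @export
compare_observers <- function(scores_contextual, scores_noncontextual,
                              n_boot = 1e4L, seed = 1L) {
  if (length(scores_contextual) != length(scores_noncontextual))
    stop_readobs("mismatched participants", "readobs_stats_error")
  if (!is.null(names(scores_contextual)) &&
      !is.null(names(scores_noncontextual))) {
    if (!setequal(names(scores_contextual), names(scores_noncontextual)))
      stop_readobs("mismatched participants", "readobs_stats_error")
    scores_noncontextual <-
      scores_noncontextual[names(scores_contextual)]
  }
  bootstrap_t_test(scores_noncontextual - scores_contextual,
                   n_boot = n_boot, seed = seed)
}
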