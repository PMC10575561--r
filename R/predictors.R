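# Linguistic prediction features and assembly of the standardized
# per-token predictor tables for the skipping and gaze-duration analyses.

#' Surprisal of a word in bits
#'
#' `-log2(p)`. For words spanning multiple provider tokens, pass the
#' constituent token probabilities; the joint probability is their product,
#' so surprisal is additive across constituents.
#'
#' @param p probability (or vector of constituent token probabilities),
#'   each in (0, 1].
#' @return surprisal in bits.
#' @export
word_surprisal <- function(p) {
  if (any(p <= 0) || any(p > 1))
    stop_readobs("probabilities must be in (0, 1]", "readobs_bad_probability")
  -sum(log2(p))
}

#' Predictive (prior) entropy of a next-word distribution
#'
#' Entropy in bits of the distribution represented as a nucleus plus a flat
#' tail: the `n_tail` non-nucleus words share the residual mass equally.
#' This mirrors the representation used for the contextual observer prior.
#'
#' @param nucleus_probs nucleus probabilities (need not sum to 1).
#' @param n_tail number of flat-tail words carrying the residual mass
#'   (0 if the nucleus is the full support).
#' @return entropy in bits.
#' @export
predictive_entropy <- function(nucleus_probs, n_tail = 0L) {
  if (length(nucleus_probs) == 0L)
    stop_readobs("empty distribution", "readobs_bad_distribution")
  tail_mass <- 1 - sum(nucleus_probs)
  p <- nucleus_probs
  if (n_tail > 0L) p <- c(p, rep(tail_mass / n_tail, n_tail))
  if (abs(sum(p) - 1) > 1e-6)
    stop_readobs("distribution not normalized within 1e-6",
                 "readobs_bad_distribution")
  entropy_bits(p / sum(p))
}

#' Assemble per-token predictor tables for both analyses
#'
#' Joins first-pass measures, observer outputs and language-model features
#' on (participant, text_id, word_index) and builds the two analysis
#' tables. Skipping rows carry the skip outcome with predictive entropy,
#' parafoveal (posterior) entropy, word length and launch distance.
#' Duration rows (first-pass fixated tokens only) carry gaze duration with
#' surprisal lags 0-2, parafoveal entropy, word class, length,
#' log-frequency lags 0-2 and the landing offsets. Spillover lags use the
#' two preceding text words regardless of whether they were fixated; rows
#' whose lagged words are unavailable are dropped.
#'
#' @param measures filtered measures from [apply_exclusions()]; the
#'   `skipping` and `duration` elements.
#' @param observer token table from [observe_tokens()] (posterior entropies).
#' @param lm_features data.frame keyed by (text_id, word_index) with
#'   `surprisal_bits` and `entropy_bits` per text word.
#' @param lexicon a `readobs_lexicon` supplying log-frequencies.
#' @return list with data.frames `skipping` and `duration`.
#' @export
assemble_predictors <- function(measures, observer, lm_features, lexicon) {
  obs <- data.table::as.data.table(
    observer[, c("participant", "text_id", "word_index",
                 "posterior_entropy_bits", "prior_entropy_bits")])
  lmf_full <- data.table::as.data.table(
    lm_features[, intersect(c("text_id", "word_index", "word",
                              "surprisal_bits", "entropy_bits"),
                            names(lm_features))])
  lmf <- lmf_full[, c("text_id", "word_index", "surprisal_bits",
                      "entropy_bits")]
  logfreq <- stats::setNames(log(lexicon$frequencies), lexicon$words)

  join_obs <- function(tab) {
    tab <- data.table::as.data.table(tab)
    out <- merge(tab, obs, by = c("participant", "text_id", "word_index"),
                 all.x = TRUE, sort = FALSE)
    if (anyNA(out$posterior_entropy_bits))
      stop_readobs("missing observer output for retained token(s); pipeline ordering bug",
                   "readobs_join_error")
    out
  }
  lag_of <- function(tab, col, lag) {
    key <- data.table::data.table(text_id = tab$text_id,
                                  word_index = tab$word_index - lag)
    lmf[key, on = c("text_id", "word_index")][[col]]
  }

  skip <- join_obs(measures$skipping)
  skip <- merge(skip, lmf, by = c("text_id", "word_index"), all.x = TRUE,
                sort = FALSE)
  skipping <- data.frame(
    participant = skip$participant, text_id = skip$text_id,
    word_index = skip$word_index,
    skip = as.integer(skip$skipped_first_pass),
    predictive_entropy = skip$entropy_bits,
    parafoveal_entropy = skip$posterior_entropy_bits,
    length = skip$length,
    launch_distance = skip$launch_distance)
  skipping <- skipping[stats::complete.cases(skipping), , drop = FALSE]

  dur <- join_obs(measures$duration)
  dur <- merge(dur, lmf, by = c("text_id", "word_index"), all.x = TRUE,
               sort = FALSE)
  duration <- data.frame(
    participant = dur$participant, text_id = dur$text_id,
    word_index = dur$word_index,
    gaze_duration = dur$gaze_duration_ms,
    surprisal = dur$surprisal_bits,
    surprisal_lag1 = lag_of(dur, "surprisal_bits", 1L),
    surprisal_lag2 = lag_of(dur, "surprisal_bits", 2L),
    parafoveal_entropy = dur$posterior_entropy_bits,
    word_class = dur$word_class,
    length = dur$length,
    log_frequency = unname(logfreq[dur$word]),
    log_frequency_lag1 = unname(logfreq[lag_of_word(dur, lmf_full, 1L)]),
    log_frequency_lag2 = unname(logfreq[lag_of_word(dur, lmf_full, 2L)]),
    landing_offset_chars = dur$landing_offset_chars,
    landing_offset_frac = dur$landing_offset_frac,
    stringsAsFactors = FALSE)
  duration <- duration[stats::complete.cases(duration), , drop = FALSE]
  list(skipping = skipping, duration = duration)
}

# word string of the token `lag` text positions back (via the LM feature
# table, which covers every text word).
lag_of_word <- function(tab, lmf, lag) {
  key <- data.table::data.table(text_id = tab$text_id,
                                word_index = tab$word_index - lag)
  lmf2 <- lmf
  if (!"word" %in% names(lmf2)) return(rep(NA_character_, nrow(tab)))
  lmf2[key, on = c("text_id", "word_index")]$word
}

#' Z-score continuous predictors within participant
#'
#' Each continuous predictor is transformed to participant-specific
#' z-scores; the outcome column is untouched and `word_class` (if present)
#' is expanded to 0/1 indicator contrasts against its first level. The
#' per-participant means and SDs are attached as attribute `"moments"` for
#' effect-size back-transformation.
#'
#' @param table a predictor table from [assemble_predictors()].
#' @param predictors character vector of continuous predictor columns;
#'   default: all numeric columns except outcomes and keys.
#' @return the standardized table with attribute `moments`.
#' @export
standardize_within_participant <- function(table, predictors = NULL) {
  keys <- c("participant", "text_id", "word_index", "skip", "gaze_duration")
  if (is.null(predictors))
    predictors <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], keys)
  moments <- list()
  for (pp in unique(table$participant)) {
    rows <- table$participant == pp
    m <- s <- stats::setNames(numeric(length(predictors)), predictors)
    for (col in predictors) {
      x <- table[[col]][rows]
      if (length(unique(x)) < 2L)
        stop_readobs(sprintf(
          "zero-variance predictor '%s' for participant '%s'", col, pp),
          "readobs_zero_variance")
      # population SD: z-scores of [1,2,3] are +-sqrt(3/2)
      m[col] <- mean(x); s[col] <- sqrt(mean((x - mean(x))^2))
      table[[col]][rows] <- (x - m[col]) / s[col]
    }
    moments[[as.character(pp)]] <- data.frame(predictor = predictors,
                                              mean = unname(m), sd = unname(s))
  }
  if ("word_class" %in% names(table)) {
    wc <- factor(table$word_class)
    for (lev in levels(wc)[-1]) {
      table[[paste0("word_class_", lev)]] <- as.numeric(wc == lev)
    }
    table$word_class <- NULL
  }
  attr(table, "moments") <- moments
  table
}

#' Invert the participant z-transform for one predictor
#'
#' @param z z-scored values.
#' @param moments the `moments` attribute from
#'   [standardize_within_participant()].
#' @param participant participant id.
#' @param predictor predictor name.
#' @return values on the original scale.
#' @export
unstandardize <- function(z, moments, participant, predictor) {
  mm <- moments[[as.character(participant)]]
  row <- mm[mm$predictor == predictor, ]
  if (nrow(row) != 1L)
    stop_readobs("no stored moments for this participant/predictor",
                 "readobs_missing_moments")
  z * row$sd + row$mean
}
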