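# Contextual observer prior: truncate a next-word distribution to its
# nucleus, convert nucleus probabilities to implied pseudofrequencies over
# the observer vocabulary (flat tail with pseudocount 1), and express the
# result as prior log-odds.

#' Nucleus truncation of a next-word distribution
#'
#' Keeps the smallest set of top-probability words whose cumulative
#' probability reaches `mass`. Ties in probability are broken by
#' lexicographic word order so the truncation is deterministic.
#'
#' @param probabilities named numeric vector (word -> probability);
#'   non-negative, summing to at most 1 (+1e-6).
#' @param mass cumulative probability threshold in (0, 1); default 0.95.
#' @return list with `words`, `probs` (sorted descending) and `k`.
#' @export
nucleus_truncate <- function(probabilities, mass = 0.95) {
  if (mass >= 1 || mass <= 0)
    stop_readobs("nucleus mass must be in (0, 1)", "readobs_bad_mass")
  if (any(probabilities < 0) || sum(probabilities) > 1 + 1e-6)
    stop_readobs("probabilities must be >= 0 and sum to at most 1",
                 "readobs_bad_distribution")
  w <- names(probabilities)
  if (is.null(w)) stop_readobs("probabilities must be named by word",
                               "readobs_bad_distribution")
  o <- order(-probabilities, w)
  p <- as.numeric(probabilities[o])
  cum <- cumsum(p)
  k <- which(cum >= mass)[1]
  if (is.na(k)) k <- length(p)  # distribution sums to < mass: keep all
  list(words = w[o][seq_len(k)], probs = p[seq_len(k)], k = k)
}

#' Implied pseudofrequencies of nucleus words
#'
#' With the tail of the distribution assumed flat at pseudocount 1 over the
#' `V - k` non-nucleus words of the observer vocabulary, the nucleus
#' probabilities imply frequencies `P_i * (V - k) / (1 - sum(P))`, so that
#' the nucleus carries its truncated probability mass relative to the tail.
#'
#' @param nucleus_probs numeric nucleus probabilities (descending).
#' @param V observer vocabulary size.
#' @param k nucleus size, `k < V`.
#' @return numeric vector of implied frequencies, one per nucleus word.
#' @export
implied_frequencies <- function(nucleus_probs, V, k = length(nucleus_probs)) {
  if (k >= V)
    stop_readobs("nucleus size must be smaller than the vocabulary",
                 "readobs_bad_nucleus")
  s <- sum(nucleus_probs)
  if (s >= 1)
    stop_readobs(
      "nucleus probabilities sum to >= 1; lower the nucleus mass so a tail remains",
      "readobs_bad_nucleus")
  nucleus_probs * (V - k) / (1 - s)
}

#' Build a contextual prior over the observer lexicon
#'
#' Nucleus words are mapped into the lexicon; nucleus words absent from the
#' lexicon are dropped, their mass implicitly joining the flat tail (the
#' retained probabilities are deliberately not renormalized). All
#' non-nucleus lexicon words receive pseudocount 1. The result is log-odds
#' against the lexicon's reference word, exactly as
#' [frequency_prior_logodds()] computes them from counts.
#'
#' @param lm_distribution named probability vector (word -> probability)
#'   from a next-word provider.
#' @param lexicon a `readobs_lexicon`.
#' @param mass nucleus mass threshold (default 0.95).
#' @return numeric log-odds vector of length `V - 1`.
#' @export
build_contextual_prior <- function(lm_distribution, lexicon, mass = 0.95) {
  nuc <- nucleus_truncate(lm_distribution, mass)
  keep <- match(nuc$words, lexicon$words)
  freq <- rep(1, lexicon$V)
  if (all(is.na(keep))) {
    warning("no nucleus word is in the observer lexicon; using a flat prior")
  } else {
    # Eq.-literal: implied frequencies use the original nucleus probs and
    # original (V, k); dropped words keep tail pseudocount 1.
    fr <- implied_frequencies(nuc$probs, lexicon$V, nuc$k)
    ok <- !is.na(keep)
    freq[keep[ok]] <- fr[ok]
  }
  lf <- log(freq)
  lf[-lexicon$reference_index] - lf[lexicon$reference_index]
}
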