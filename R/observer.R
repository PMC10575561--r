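# Bayesian ideal observer of parafoveal word identification.
#
# Noisy letter evidence is drawn from a multivariate Gaussian centred on the
# true word's letter vector with diagonal covariance Sigma(eps) =
# lambda(eps)^noise_exponent * I per letter slot, where lambda is the
# perceptual-span sensory quality at that slot's eccentricity. Beliefs are
# log-odds against a reference word and are updated additively, so a chain
# of T updates depends on the percepts only through their sum -- which the
# batched entropy computation exploits.

#' Perceptual span parameters
#'
#' @param sigma span width in character units (default 3).
#' @param Lambda sensory-quality scaling factor (default 1).
#' @param noise_exponent exponent `e` so the sampling variance at
#'   eccentricity `eps` is `lambda(eps)^e`; default `-1/2`.
#' @return object of class `readobs_span`.
#' @export
perceptual_span <- function(sigma = 3, Lambda = 1, noise_exponent = -0.5) {
  stopifnot(sigma > 0, Lambda > 0)
  structure(list(sigma = sigma, Lambda = Lambda,
                 noise_exponent = noise_exponent),
            class = "readobs_span")
}

#' Observer sampling configuration
#'
#' @param T_samples visual samples per inference run (default 50).
#' @param repeats independent runs whose posterior entropies are averaged
#'   (default 3).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return object of class `readobs_observer_config`.
#' @export
observer_config <- function(T_samples = 50L, repeats = 3L, seed = NULL) {
  stopifnot(T_samples >= 0, repeats >= 1)
  structure(list(T_samples = as.integer(T_samples),
                 repeats = as.integer(repeats), seed = seed),
            class = "readobs_observer_config")
}

#' Sensory quality of a letter at a given eccentricity
#'
#' Integral of a zero-mean Gaussian perceptual span (SD `sigma`) over the
#' unit-width bounding box of a letter centred at eccentricity `eccentricity`
#' characters from fixation, scaled by `Lambda`. Symmetric in eccentricity
#' and strictly decreasing in its magnitude.
#'
#' @param eccentricity numeric vector, character units (positive rightward).
#' @param span a [perceptual_span()].
#' @return numeric vector of lambda values in `(0, Lambda]`.
#' @export
sensory_quality <- function(eccentricity, span = perceptual_span()) {
  span$Lambda * (stats::pnorm((eccentricity + 0.5) / span$sigma) -
                 stats::pnorm((eccentricity - 0.5) / span$sigma))
}

# Slot-wise sampling variances for a word previewed at a given launch
# distance: slot j (0-based) sits at eccentricity launch_distance + j.
# lambda is floored at 1e-12 so the variance is finite ("capped") at extreme
# eccentricity; there the evidence contribution is numerically negligible.
slot_variances <- function(launch_distance, l_max, span) {
  ecc <- launch_distance + seq_len(l_max) - 1
  lam <- pmax(sensory_quality(ecc, span), 1e-12)
  lam^span$noise_exponent
}

#' Draw one noisy visual sample of a word
#'
#' Each of the `26 * l_max` dimensions is Gaussian around the true letter
#' vector; all 26 dimensions of a letter slot share that slot's variance
#' `lambda(eps_slot)^noise_exponent` (diagonal covariance).
#'
#' @param true_vector encoding of the previewed word (length `26 * l_max`).
#' @param eccentricities one eccentricity per letter slot (length `l_max`).
#' @param span a [perceptual_span()].
#' @return percept vector of length `26 * l_max`.
#' @export
sample_percept <- function(true_vector, eccentricities, span = perceptual_span()) {
  l_max <- length(true_vector) %/% 26L
  if (length(eccentricities) != l_max)
    stop_readobs("need one eccentricity per letter slot", "readobs_dim_error")
  lam <- pmax(sensory_quality(eccentricities, span), 1e-12)
  v <- rep(lam^span$noise_exponent, each = 26L)
  stats::rnorm(length(true_vector), mean = true_vector, sd = sqrt(v))
}

#' Initialize a belief state from prior log-odds
#'
#' @param prior_logodds numeric vector of length `V - 1`, log-odds of each
#'   non-reference word against the lexicon's reference word.
#' @param lexicon a `readobs_lexicon`.
#' @return object of class `readobs_belief`.
#' @export
belief_state <- function(prior_logodds, lexicon) {
  stopifnot(inherits(lexicon, "readobs_lexicon"),
            length(prior_logodds) == lexicon$V - 1L,
            all(is.finite(prior_logodds)))
  structure(list(logodds = as.numeric(prior_logodds), lexicon = lexicon),
            class = "readobs_belief")
}

# Shared evidence computation: log-odds increment for each non-reference
# word given the (possibly summed) percept s over n_samples samples.
#   delta_i = n * (q_v - q_i)/2 + (y_i - y_v)' Sigma^-1 s
# where q_i = y_i' Sigma^-1 y_i reduces, for one-hot rows, to the cumulative
# sum of slot precisions over the word's occupied slots.
logodds_increment <- function(percept_sum, n_samples, lexicon, variances) {
  inv_slot <- 1 / variances
  q_cum <- c(0, cumsum(inv_slot))
  q <- q_cum[lexicon$lengths + 1L]
  w <- rep(inv_slot, each = 26L) * percept_sum
  Yw <- as.numeric(lexicon$encoding %*% w)
  ref <- lexicon$reference_index
  n_samples * (q[ref] - q[-ref]) / 2 + (Yw[-ref] - Yw[ref])
}

#' Update a belief state with one visual sample
#'
#' Adds the log-odds likelihood of the percept (difference of two Gaussian
#' log-densities, one centred on each candidate word and one on the
#' reference word) to the current log-odds.
#'
#' @param belief a [belief_state()].
#' @param percept vector from [sample_percept()] (length `d`).
#' @param span a [perceptual_span()].
#' @param eccentricities per-slot eccentricities used to generate the
#'   percept (length `l_max`).
#' @return updated `readobs_belief`.
#' @export
update_belief <- function(belief, percept, span, eccentricities) {
  lex <- belief$lexicon
  if (length(percept) != lex$d)
    stop_readobs(sprintf("percept has %d dims, lexicon d = %d",
                         length(percept), lex$d), "readobs_dim_error")
  if (length(eccentricities) != lex$l_max)
    stop_readobs("need one eccentricity per letter slot", "readobs_dim_error")
  lam <- pmax(sensory_quality(eccentricities, span), 1e-12)
  variances <- lam^span$noise_exponent
  belief$logodds <- belief$logodds +
    logodds_increment(percept, 1L, lex, variances)
  belief
}

#' Posterior word probabilities from log-odds
#'
#' Softmax over `c(logodds, 0)` with max-subtraction for overflow safety;
#' the final entry is the reference word.
#'
#' @param x numeric log-odds vector (length `V - 1`) or a `readobs_belief`.
#' @return probability vector of length `V`, summing to 1.
#' @export
posterior_distribution <- function(x) {
  if (inherits(x, "readobs_belief")) x <- x$logodds
  z <- c(x, 0)
  z <- z - max(z)
  w <- exp(z)
  w / sum(w)
}

#' Shannon entropy in bits
#'
#' @param p probability vector (non-negative, sums to 1 within 1e-9).
#' @return entropy in bits, with `0 * log(0) = 0`.
#' @export
entropy_bits <- function(p) {
  if (any(p < 0))
    stop_readobs("negative probabilities", "readobs_bad_distribution")
  if (abs(sum(p) - 1) > 1e-9)
    stop_readobs("probabilities do not sum to 1", "readobs_bad_distribution")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Parafoveal preview entropy of a word token
#'
#' Runs `repeats` independent chains of `T_samples` noisy samples and belief
#' updates from the supplied prior, with slot eccentricities
#' `launch_distance + 0:(l_max - 1)`, and averages the per-run posterior
#' entropies. Because belief updates are additive in the percepts, each run
#' is computed exactly from the Gaussian sufficient statistic (the percept
#' sum), which equals chaining the `T_samples` individual updates.
#'
#' @param word the previewed word; must be in the lexicon.
#' @param launch_distance character offset from the prior fixation location
#'   to the word's first character (positive rightward).
#' @param prior_logodds prior log-odds vector (length `V - 1`), e.g. from
#'   [frequency_prior_logodds()] or [build_contextual_prior()].
#' @param lexicon a `readobs_lexicon`.
#' @param span a [perceptual_span()].
#' @param config an [observer_config()]; when `config$seed` is non-NULL,
#'   repeat `r` uses seed `derive_seed(seed, r)`.
#' @return list of class `readobs_observer_output` with `prior_entropy`,
#'   `posterior_entropy`, `info_gain` (bits), `eccentricity`, `word`, and
#'   the per-repeat entropies.
#' @export
preview_entropy <- function(word, launch_distance, prior_logodds, lexicon,
                            span = perceptual_span(),
                            config = observer_config()) {
  idx <- match(word, lexicon$words)
  if (is.na(idx))
    stop_readobs(sprintf("word '%s' not in lexicon", word), "readobs_oov")
  prior_p <- posterior_distribution(prior_logodds)
  prior_H <- entropy_bits(prior_p)
  Tn <- config$T_samples
  ent <- numeric(config$repeats)
  if (Tn == 0L) {
    ent[] <- prior_H
  } else {
    variances <- slot_variances(launch_distance, lexicon$l_max, span)
    sd_dim <- sqrt(Tn * rep(variances, each = 26L))
    true_vec <- lexicon$encoding[idx, ]
    for (r in seq_len(config$repeats)) {
      draw <- function() stats::rnorm(lexicon$d, Tn * true_vec, sd_dim)
      s <- if (is.null(config$seed)) draw()
           else with_seed(derive_seed(config$seed, r), draw())
      x <- prior_logodds + logodds_increment(s, Tn, lexicon, variances)
      ent[r] <- entropy_bits(posterior_distribution(x))
    }
  }
  post_H <- mean(ent)
  structure(list(word = word, eccentricity = launch_distance,
                 prior_entropy = prior_H, posterior_entropy = post_H,
                 info_gain = prior_H - post_H, repeat_entropies = ent,
                 n_repeats = config$repeats, T_samples = Tn),
            class = "readobs_observer_output")
}

#' @export
print.readobs_observer_output <- function(x, ...) {
  cat(sprintf(
    "<observer output> '%s' at %.2f chars: prior %.3f -> posterior %.3f bits (gain %.3f)\n",
    x$word, x$eccentricity, x$prior_entropy, x$posterior_entropy, x$info_gain))
  invisible(x)
}

#' Compute preview entropies for a table of word tokens
#'
#' Vectorized driver over a token table; one RNG stream per
#' (participant, text, word-token) derived from `master_seed` by stable
#' hashing, so outputs are reproducible and order-independent.
#' Out-of-lexicon tokens get `NA` outputs and `oov = TRUE` rather than an
#' error; callers decide exclusion.
#'
#' @param tokens data.frame with columns `participant`, `text_id`,
#'   `word_index`, `word`, `launch_distance`.
#' @param lexicon a `readobs_lexicon`.
#' @param span a [perceptual_span()].
#' @param config an [observer_config()] (its `seed` field is ignored).
#' @param prior either a single log-odds vector used for every token (the
#'   non-contextual case) or a function `(row_index) -> log-odds` supplying
#'   a per-token contextual prior.
#' @param master_seed integer master seed.
#' @return the token table with columns `prior_entropy_bits`,
#'   `posterior_entropy_bits`, `info_gain_bits`, `oov` appended.
#' @export
observe_tokens <- function(tokens, lexicon, span = perceptual_span(),
                           config = observer_config(), prior,
                           master_seed = 1L) {
  n <- nrow(tokens)
  fixed_prior <- !is.function(prior)
  if (fixed_prior) {
    prior_H0 <- entropy_bits(posterior_distribution(prior))
  }
  priorH <- postH <- rep(NA_real_, n)
  oov <- logical(n)
  for (i in seq_len(n)) {
    p_i <- if (fixed_prior) prior else prior(i)
    cfg <- config
    cfg$seed <- derive_seed(master_seed, tokens$participant[i],
                            tokens$text_id[i], tokens$word_index[i])
    out <- tryCatch(
      preview_entropy(tokens$word[i], tokens$launch_distance[i], p_i,
                      lexicon, span, cfg),
      readobs_oov = function(e) NULL)
    if (is.null(out)) { oov[i] <- TRUE; next }
    priorH[i] <- out$prior_entropy
    postH[i] <- out$posterior_entropy
  }
  tokens$prior_entropy_bits <- priorH
  tokens$posterior_entropy_bits <- postH
  tokens$info_gain_bits <- priorH - postH
  tokens$oov <- oov
  tokens
}
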