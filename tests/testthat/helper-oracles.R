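# Independent oracles and small fixture builders used across tests.
# These deliberately re-derive quantities by brute force, not via the
# package's own computational path.

# Decode a letter vector: argmax per 26-block, stopping at the first
# all-zero block.
oracle_decode <- function(v) {
  l_max <- length(v) %/% 26L
  out <- character(0)
  for (j in seq_len(l_max)) {
    block <- v[(26 * (j - 1) + 1):(26 * j)]
    if (all(block == 0)) break
    out <- c(out, letters[which.max(block)])
  }
  paste(out, collapse = "")
}

# Brute-force Bayesian posterior over the lexicon given a sequence of
# percepts: explicit multivariate-normal densities per candidate word,
# prior x likelihood, normalized.
oracle_posterior <- function(percepts, prior_probs, lexicon, variances) {
  var_dim <- rep(variances, each = 26L)
  loglik <- sapply(seq_len(lexicon$V), function(i) {
    mu <- lexicon$encoding[i, ]
    sum(vapply(percepts, function(s)
      sum(stats::dnorm(s, mean = mu, sd = sqrt(var_dim), log = TRUE)), 1))
  })
  w <- log(prior_probs) + loglik
  w <- exp(w - max(w))
  w / sum(w)
}

# Tiny deterministic lexicon for observer tests.
tiny_lexicon <- function() {
  build_lexicon(c("ab", "ba", "a", "b"), c(4, 3, 2, 1))
}

# A hand-built single-line toy corpus: words at known coordinates, with a
# supplied fixation sequence given as word indices (or exact x positions).
toy_corpus <- function(words, fix_x, fix_dur = NULL, line_id = 1L,
                       fix_line = NULL, blink = NULL,
                       participant = "p1", text_id = "t1") {
  len <- nchar(words)
  fc <- cumsum(c(0, head(len, -1) + 1))
  n <- length(fix_x)
  wtab <- data.frame(participant = participant, text_id = text_id,
                     line_id = line_id, word_index = seq_along(words),
                     word = words, first_char = fc,
                     word_class = "noun", stringsAsFactors = FALSE)
  ftab <- data.frame(participant = participant, text_id = text_id,
                     line_id = if (is.null(fix_line)) line_id
                               else fix_line,
                     order = seq_len(n), x_char = fix_x,
                     duration_ms = fix_dur %||% rep(200, n),
                     blink_adjacent = blink %||% integer(n),
                     stringsAsFactors = FALSE)
  list(words = wtab, fixations = ftab)
}

# x-coordinate of the centre of word j in a toy corpus
toy_centre <- function(words, j) {
  len <- nchar(words)
  fc <- cumsum(c(0, head(len, -1) + 1))
  fc[j] + (len[j] - 1) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
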