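# Vocabulary representation: padded one-hot letter encodings and the
# non-contextual (frequency) prior over word identity.

#' Encode a word as a padded one-hot letter vector
#'
#' Each letter slot occupies a 26-dimensional block ('a' = first dimension);
#' slot `j` (0-based) of the word sets index `26 * j + rank(letter)`. Slots
#' beyond the word's length are all-zero padding, so word length is itself
#' (noisily) observable to the ideal observer through the zero blocks.
#'
#' @param word lowercase alphabetic string.
#' @param l_max maximum word length; the vector has `26 * l_max` dimensions.
#' @return numeric vector of length `26 * l_max`.
#' @export
encode_word <- function(word, l_max) {
  stopifnot(length(word) == 1L, is.character(word))
  if (!grepl("^[a-z]+$", word))
    stop_readobs(sprintf("word '%s' is not lowercase alphabetic", word),
                 "readobs_bad_word")
  n <- nchar(word)
  if (n > l_max)
    stop_readobs(sprintf("word '%s' longer than l_max = %d", word, l_max),
                 "readobs_bad_word")
  v <- numeric(26L * l_max)
  idx <- 26L * (seq_len(n) - 1L) + utf8ToInt(word) - 96L
  v[idx] <- 1
  v
}

# Inverse of encode_word: argmax per 26-block, stopping at all-zero blocks.
decode_letter_vector <- function(v) {
  l_max <- length(v) %/% 26L
  out <- character(0)
  for (j in seq_len(l_max)) {
    block <- v[(26L * (j - 1L) + 1L):(26L * j)]
    if (all(block == 0)) break
    out <- c(out, intToUtf8(96L + which.max(block)))
  }
  paste(out, collapse = "")
}

#' Build a lexicon with letter-vector encodings
#'
#' The lexicon is the ideal observer's hypothesis space: a `V x d` matrix of
#' letter-vector encodings (`d = 26 * l_max`) plus a positive frequency per
#' word. The last word of the input order is the designated reference word
#' for all log-odds belief representations; inference results are invariant
#' to this arbitrary choice.
#'
#' @param words character vector of unique lowercase alphabetic words.
#' @param frequencies positive numeric vector, one entry per word; any scale.
#' @return object of class `readobs_lexicon` with fields `words`,
#'   `frequencies`, `lengths`, `l_max`, `V`, `d`, `encoding`,
#'   `reference_index`.
#' @export
build_lexicon <- function(words, frequencies) {
  if (length(words) != length(frequencies))
    stop_readobs("words and frequencies must have equal length",
                 "readobs_bad_lexicon")
  if (length(words) < 2L)
    stop_readobs("a lexicon needs at least 2 words", "readobs_bad_lexicon")
  bad <- words[!grepl("^[a-z]+$", words)]
  if (length(bad))
    stop_readobs(sprintf("non-alphabetic word(s): %s",
                         paste(utils::head(bad, 5), collapse = ", ")),
                 "readobs_bad_lexicon")
  dup <- unique(words[duplicated(words)])
  if (length(dup))
    stop_readobs(sprintf("duplicate word(s): %s",
                         paste(utils::head(dup, 5), collapse = ", ")),
                 "readobs_bad_lexicon")
  if (any(!is.finite(frequencies) | frequencies <= 0))
    stop_readobs("all frequencies must be finite and > 0",
                 "readobs_bad_lexicon")
  lengths <- nchar(words)
  l_max <- max(lengths)
  d <- 26L * l_max
  V <- length(words)
  enc <- matrix(0, nrow = V, ncol = d)
  # vectorized one-hot fill: row i gets ones at 26*(j-1) + rank(letter_j)
  rows <- rep.int(seq_len(V), lengths)
  slot <- unlist(lapply(lengths, seq_len)) - 1L
  letter <- unlist(lapply(words, function(w) utf8ToInt(w) - 96L))
  enc[cbind(rows, 26L * slot + letter)] <- 1
  structure(list(words = words, frequencies = as.numeric(frequencies),
                 lengths = lengths, l_max = l_max, V = V, d = d,
                 encoding = enc, reference_index = V),
            class = "readobs_lexicon")
}

#' @export
print.readobs_lexicon <- function(x, ...) {
  cat(sprintf("<readobs_lexicon> V = %d words, l_max = %d (d = %d)\n",
              x$V, x$l_max, x$d))
  invisible(x)
}

#' Frequency prior as log-odds against the reference word
#'
#' Entry `i` is `log(freq_i) - log(freq_ref)` for the `V - 1` non-reference
#' words; invariant under rescaling all frequencies by a constant. This is
#' the initial belief state of the non-contextual observer.
#'
#' @param lexicon a `readobs_lexicon`.
#' @return numeric vector of length `V - 1`.
#' @export
frequency_prior_logodds <- function(lexicon) {
  stopifnot(inherits(lexicon, "readobs_lexicon"))
  lf <- log(lexicon$frequencies)
  lf[-lexicon$reference_index] - lf[lexicon$reference_index]
}

#' Read a two-column word/frequency TSV into a lexicon
#'
#' @param path TSV file `word<TAB>frequency`, UTF-8.
#' @param header logical; skip a single header line if `TRUE`.
#' @return a `readobs_lexicon`.
#' @export
read_lexicon <- function(path, header = FALSE) {
  tab <- utils::read.delim(path, header = header, col.names = c("word", "frequency"),
                           colClasses = c("character", "numeric"),
                           quote = "", comment.char = "")
  build_lexicon(tab$word, tab$frequency)
}

#' @rdname read_lexicon
#' @param lexicon a `readobs_lexicon` to serialize.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(data.frame(word = lexicon$words,
                                frequency = lexicon$frequencies),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
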