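# Canonical fixation-report ingestion, first-pass measure extraction, and
# the data-selection filters.
#
# Coordinates are 0-based character units, global within a line. A word of
# length L starting at first_char occupies cells first_char .. first_char +
# L - 1; its bounding box extends half a character beyond the outer cells
# (boundary halfway to the neighbouring character).

#' Read a canonical corpus TSV pair
#'
#' `words.tsv` columns: participant, text_id, line_id, word_index, word,
#' first_char, word_class. `fixations.tsv` columns: participant, text_id,
#' line_id, order, x_char, duration_ms, blink_adjacent. Both UTF-8 with a
#' header row.
#'
#' @param words_path,fixations_path file paths.
#' @return list with data.frames `words` and `fixations`, validated.
#' @export
read_corpus <- function(words_path, fixations_path) {
  words <- utils::read.delim(words_path, header = TRUE, quote = "",
                             comment.char = "",
                             colClasses = c(word = "character",
                                            participant = "character"))
  fix <- utils::read.delim(fixations_path, header = TRUE, quote = "",
                           comment.char = "",
                           colClasses = c(participant = "character"))
  validate_corpus(words, fix)
  list(words = words, fixations = fix)
}

#' @rdname read_corpus
#' @param corpus list with `words` and `fixations` data.frames.
#' @param dir output directory (created if absent).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(corpus$words, file.path(dir, "words.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$fixations, file.path(dir, "fixations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

validate_corpus <- function(words, fixations) {
  need_w <- c("participant", "text_id", "line_id", "word_index", "word",
              "first_char", "word_class")
  need_f <- c("participant", "text_id", "line_id", "order", "x_char",
              "duration_ms", "blink_adjacent")
  miss <- setdiff(need_w, names(words))
  if (length(miss))
    stop_readobs(paste("words table missing column(s):",
                       paste(miss, collapse = ", ")), "readobs_parse_error")
  miss <- setdiff(need_f, names(fixations))
  if (length(miss))
    stop_readobs(paste("fixations table missing column(s):",
                       paste(miss, collapse = ", ")), "readobs_parse_error")
  if (nrow(fixations)) {
    if (any(fixations$duration_ms <= 0))
      stop_readobs("non-positive fixation duration", "readobs_parse_error")
    bad <- which(stats::ave(fixations$order,
                            fixations$participant, fixations$text_id,
                            FUN = function(o) c(1, diff(o))) <= 0)
    if (length(bad))
      stop_readobs(sprintf(
        "fixation order not strictly increasing at row(s) %s",
        paste(utils::head(bad, 5), collapse = ", ")), "readobs_parse_error")
  }
  if (nrow(words)) {
    dt <- data.table::as.data.table(words)
    data.table::setorder(dt, participant, text_id, word_index)
    bad <- dt[, {
      if (.N > 1L) any(first_char[-1] < first_char[-.N] + nchar(word[-.N]))
      else FALSE
    }, by = c("participant", "text_id", "line_id")]$V1
    if (any(bad))
      stop_readobs("overlapping or unordered word spans", "readobs_parse_error")
  }
  invisible(TRUE)
}

#' First-pass reading measures per word token
#'
#' Classifies every token, the first time the eyes cross it while no later
#' word has yet been fixated, as first-pass fixated or first-pass skipped.
#' Gaze duration is the sum of the maximal initial run of fixations on a
#' token (ending when a fixation leaves it in either direction). Launch
#' distance is the token's first character minus the coordinate of the last
#' fixation before the crossing saccade. Tokens first crossed by a saccade
#' whose source and target line ids differ (return sweep) are left
#' unscored. Initially skipped tokens that later receive any fixation get
#' `later_regressive_fixation = 1`.
#'
#' @param fixations fixation table (see [read_corpus()]), sorted by order
#'   within (participant, text_id).
#' @param words word-token table.
#' @return data.frame with one row per token: `status`
#'   ("fixated"/"skipped"/NA for unscored), `skipped_first_pass`,
#'   `gaze_duration_ms`, `launch_distance`, `landing_offset_chars`,
#'   `landing_offset_frac`, `later_regressive_fixation`, `blink`,
#'   `sweep_crossed` plus the token identity columns.
#' @export
first_pass_measures <- function(fixations, words) {
  wdt <- data.table::as.data.table(words)
  data.table::setorder(wdt, participant, text_id, word_index)
  fdt <- data.table::as.data.table(fixations)
  data.table::setorder(fdt, participant, text_id, order)
  groups <- unique(wdt[, c("participant", "text_id")])
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    pp <- groups$participant[g]; tt <- groups$text_id[g]
    w <- wdt[wdt$participant == pp & wdt$text_id == tt, ]
    f <- fdt[fdt$participant == pp & fdt$text_id == tt, ]
    out[[g]] <- first_pass_one(f, w)
  }
  as.data.frame(data.table::rbindlist(out))
}

# single (participant, text) pass
first_pass_one <- function(f, w) {
  n <- nrow(w)
  len <- nchar(w$word)
  fc <- w$first_char
  centre <- fc + (len - 1) / 2
  status <- rep(NA_character_, n)
  gaze <- launch <- land_c <- rep(NA_real_, n)
  later_reg <- integer(n)
  blink <- logical(n)
  sweep_flag <- logical(n)

  res <- data.frame(
    participant = w$participant, text_id = w$text_id, line_id = w$line_id,
    word_index = w$word_index, word = w$word, length = len,
    word_class = w$word_class, stringsAsFactors = FALSE)
  if (nrow(f) == 0L) {
    res$status <- status; res$skipped_first_pass <- NA_integer_
    res$gaze_duration_ms <- gaze; res$launch_distance <- launch
    res$landing_offset_chars <- land_c
    res$landing_offset_frac <- land_c
    res$later_regressive_fixation <- later_reg
    res$blink <- blink; res$sweep_crossed <- sweep_flag
    return(res)
  }

  # assign fixations to tokens: inside the half-character-extended span,
  # else nearest token within half a character, else dropped
  low <- fc - 0.5; high <- fc + len - 0.5
  assign_word <- function(x) {
    j <- which(x >= low & x < high)
    if (length(j)) return(j[1])
    d <- pmin(abs(x - low), abs(x - high))
    j <- which.min(d)
    if (d[j] <= 0.5) j else NA_integer_
  }
  wi <- vapply(f$x_char, assign_word, 1L)
  keep <- !is.na(wi)
  f <- f[keep, ]; wi <- wi[keep]
  if (nrow(f) == 0L) {
    res$status <- status; res$skipped_first_pass <- NA_integer_
    res$gaze_duration_ms <- gaze; res$launch_distance <- launch
    res$landing_offset_chars <- land_c; res$landing_offset_frac <- land_c
    res$later_regressive_fixation <- later_reg
    res$blink <- blink; res$sweep_crossed <- sweep_flag
    return(res)
  }

  R <- 0L            # rightmost token fixated so far
  fp_open <- NA_integer_  # token whose first-pass run is still open
  prev_x <- NA_real_; prev_line <- NA; prev_blink <- FALSE
  for (k in seq_len(nrow(f))) {
    j <- wi[k]
    x <- f$x_char[k]; dur <- f$duration_ms[k]
    bl <- as.logical(f$blink_adjacent[k])
    if (j > R) {
      sweep <- !is.na(prev_line) && f$line_id[k] != prev_line
      crossed <- seq_len(n)[seq_len(n) > R & seq_len(n) < j]
      for (s in crossed) {
        status[s] <- if (sweep) "sweep" else "skipped"
        sweep_flag[s] <- sweep
        launch[s] <- fc[s] - prev_x
        blink[s] <- blink[s] || bl || prev_blink
      }
      status[j] <- if (sweep) "sweep" else "fixated"
      sweep_flag[j] <- sweep
      launch[j] <- fc[j] - prev_x
      land_c[j] <- x - centre[j]
      gaze[j] <- dur
      blink[j] <- blink[j] || bl || prev_blink
      fp_open <- j
      R <- j
    } else if (!is.na(fp_open) && j == fp_open) {
      gaze[j] <- gaze[j] + dur       # refixation within the first-pass run
      blink[j] <- blink[j] || bl
    } else {
      if (!is.na(status[j]) && status[j] == "skipped")
        later_reg[j] <- 1L
      fp_open <- NA_integer_
    }
    if (!is.na(fp_open) && fp_open != j) fp_open <- NA_integer_
    prev_x <- x; prev_line <- f$line_id[k]; prev_blink <- bl
  }
  gaze[!is.na(status) & status != "fixated"] <- NA_real_
  res$status <- status
  res$skipped_first_pass <- ifelse(is.na(status), NA_integer_,
                                   as.integer(status == "skipped"))
  res$gaze_duration_ms <- gaze
  res$launch_distance <- launch
  res$landing_offset_chars <- land_c
  res$landing_offset_frac <- land_c / len
  res$later_regressive_fixation <- later_reg
  res$blink <- blink
  res$sweep_crossed <- sweep_flag
  res
}

#' Apply the data-selection filters
#'
#' Drops, with a per-rule exclusion log: (a) tokens with non-alphabetic
#' characters after lowercasing; (b) tokens adjacent to blink-flagged
#' fixations; (c) tokens with absolute launch distance above `max_launch`
#' (or undefined launch); (e) tokens first crossed via a line transition or
#' never crossed; optionally (f) tokens absent from `lexicon`. For the
#' duration table additionally (d) gaze durations outside
#' `[min_gaze, max_gaze]` ms; the skipping table is unaffected by (d).
#' Rule counts are tallied independently (a token may trip several rules).
#'
#' @param measures output of [first_pass_measures()].
#' @param max_launch launch-distance cap in characters (default 24,
#'   applied to magnitude).
#' @param min_gaze,max_gaze gaze-duration window in ms (default 70, 900).
#' @param lexicon optional `readobs_lexicon`; tokens not in it are dropped.
#' @return list with `skipping`, `duration` (filtered data.frames) and
#'   `log` (named integer exclusion counts).
#' @export
apply_exclusions <- function(measures, max_launch = 24,
                             min_gaze = 70, max_gaze = 900, lexicon = NULL) {
  m <- measures
  m$word <- tolower(m$word)
  non_alpha <- grepl("[^a-z]", m$word)
  blink <- m$blink
  unscored <- is.na(m$status)
  sweep <- !unscored & m$status == "sweep"
  launch_bad <- is.na(m$launch_distance) | abs(m$launch_distance) > max_launch
  oov <- if (is.null(lexicon)) rep(FALSE, nrow(m))
         else !(m$word %in% lexicon$words)
  drop_common <- non_alpha | blink | unscored | sweep | launch_bad | oov
  skipping <- m[!drop_common & m$status %in% c("skipped", "fixated"), ,
                drop = FALSE]
  fixated <- !drop_common & !is.na(m$status) & m$status == "fixated"
  gaze_bad <- fixated &
    (m$gaze_duration_ms < min_gaze | m$gaze_duration_ms > max_gaze)
  duration <- m[fixated & !gaze_bad, , drop = FALSE]
  log <- c(non_alphabetic = sum(non_alpha),
           blink_adjacent = sum(blink),
           launch_out_of_range = sum(launch_bad),
           return_sweep_or_unscored = sum(unscored | sweep),
           out_of_lexicon = sum(oov),
           gaze_duration_out_of_range = sum(gaze_bad))
  list(skipping = skipping, duration = duration, log = log)
}
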