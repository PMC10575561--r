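# Synthetic reading corpora with known ground truth: Zipfian lexicons,
# a bigram next-word provider standing in for the language model, and a
# left-to-right saccade generator with length/distance-driven skipping,
# preferred landing positions left of word centre, gaze durations linear in
# surprisal / preview entropy / log-frequency, and optional regressive
# refixation of poorly-previewed skipped words.

#' Generate a Zipfian lexicon of random letter strings
#'
#' Frequencies are proportional to `rank^(-zipf_exponent)`. Word lengths
#' grow (noisily) with rank so that longer words are rarer, reproducing the
#' length-frequency anticorrelation of natural lexicons.
#'
#' @param V vocabulary size (>= 10).
#' @param zipf_exponent Zipf exponent (default 1).
#' @param length_range integer range of word lengths (default 2 to 8).
#' @param seed RNG seed.
#' @return a `readobs_lexicon`.
#' @export
make_lexicon <- function(V, zipf_exponent = 1, length_range = c(2L, 8L),
                         seed = 1L) {
  stopifnot(V >= 10)
  with_seed(seed, {
    freq <- seq_len(V)^(-zipf_exponent)
    lmin <- length_range[1]; lmax <- length_range[2]
    base <- lmin + (lmax - lmin) * (seq_len(V) / V)^0.7
    lens <- pmin(pmax(round(base + stats::rnorm(V, 0, 1)), lmin), lmax)
    words <- character(V)
    seen <- new.env(hash = TRUE)
    for (i in seq_len(V)) {
      for (try in seq_len(200L)) {
        w <- paste(letters[sample.int(26L, lens[i], replace = TRUE)],
                   collapse = "")
        if (is.null(seen[[w]])) break
        if (try == 200L)
          stop_readobs("cannot generate enough unique words for this length spec",
                       "readobs_infeasible")
      }
      seen[[w]] <- TRUE
      words[i] <- w
    }
    build_lexicon(words, freq)
  })
}

#' Synthetic bigram next-word provider
#'
#' Each context word's next-word distribution is drawn from a Dirichlet
#' whose mean is the unigram (frequency) distribution; `concentration`
#' scales the Dirichlet parameters, so smaller values give spikier,
#' more informative contexts. Stands in for the external language model:
#' exposes next-word distributions, nucleus truncations, and per-token
#' surprisal/entropy for sampled text.
#'
#' @param lexicon a `readobs_lexicon`.
#' @param concentration Dirichlet scale (default 0.3; total concentration
#'   `concentration * V`).
#' @param seed RNG seed.
#' @param text_freq_log_sd SD (natural-log units) of the deviation between
#'   the text's realized unigram distribution and the lexicon's reference
#'   frequencies. Real frequency norms never match a specific text's
#'   statistics exactly; 0 gives a perfectly matched marginal.
#' @return object of class `readobs_lm` with the bigram matrix.
#' @export
synthetic_lm <- function(lexicon, concentration = 0.3, seed = 1L,
                         text_freq_log_sd = 0) {
  V <- lexicon$V
  p_ref <- lexicon$frequencies / sum(lexicon$frequencies)
  out <- with_seed(seed, {
    p <- if (text_freq_log_sd > 0) {
      q <- exp(log(p_ref) + stats::rnorm(V, 0, text_freq_log_sd))
      q / sum(q)
    } else p_ref
    alpha <- concentration * V * p
    g <- matrix(stats::rgamma(V * V, shape = rep(alpha, each = V)), nrow = V)
    g <- pmax(g, 1e-12)
    list(B = g / rowSums(g), p = p)
  })
  B <- out$B
  colnames(B) <- lexicon$words
  rownames(B) <- lexicon$words
  structure(list(lexicon = lexicon, bigram = B, unigram = out$p,
                 concentration = concentration,
                 text_freq_log_sd = text_freq_log_sd),
            class = "readobs_lm")
}

#' Next-word distribution of the synthetic provider
#'
#' @param lm a `readobs_lm`.
#' @param context_word previous word, or `NULL` for the unigram
#'   (text-initial) distribution.
#' @return named probability vector over the lexicon.
#' @export
lm_next_distribution <- function(lm, context_word = NULL) {
  if (is.null(context_word))
    return(stats::setNames(lm$unigram, lm$lexicon$words))
  i <- match(context_word, lm$lexicon$words)
  if (is.na(i))
    stop_readobs(sprintf("context word '%s' not in lexicon", context_word),
                 "readobs_oov")
  lm$bigram[i, ]
}

#' Sample a text from the synthetic provider
#'
#' @param lm a `readobs_lm`.
#' @param n_words text length.
#' @param seed RNG seed.
#' @return character vector of words.
#' @export
lm_sample_text <- function(lm, n_words, seed = 1L) {
  with_seed(seed, {
    V <- lm$lexicon$V
    out <- character(n_words)
    i <- sample.int(V, 1L, prob = lm$unigram)
    out[1] <- lm$lexicon$words[i]
    for (t in seq_len(n_words - 1L)) {
      i <- sample.int(V, 1L, prob = lm$bigram[i, ])
      out[t + 1L] <- lm$lexicon$words[i]
    }
    out
  })
}

#' Per-token language-model features for a text
#'
#' Surprisal of each token under the provider and the predictive entropy of
#' each token's context distribution, computed on the nucleus + flat-tail
#' representation at the given mass. Nucleus truncations are cached per
#' context word.
#'
#' @param lm a `readobs_lm`.
#' @param text character vector of words.
#' @param text_id text identifier for the output table.
#' @param mass nucleus mass (default 0.95).
#' @param keep_nucleus keep the nucleus as a list-column (for serialization
#'   to a nucleus file)?
#' @return data.frame with `text_id`, `word_index` (1-based), `word`,
#'   `surprisal_bits`, `entropy_bits` (+ `nucleus` list-column).
#' @export
lm_token_features <- function(lm, text, text_id = "t1", mass = 0.95,
                              keep_nucleus = FALSE) {
  V <- lm$lexicon$V
  n <- length(text)
  idx <- match(text, lm$lexicon$words)
  if (anyNA(idx))
    stop_readobs("text contains out-of-lexicon words", "readobs_oov")
  cache <- vector("list", V + 1L)  # slot V+1 = unigram context
  get_ctx <- function(ci) {
    if (is.null(cache[[ci]])) {
      probs <- if (ci > V) stats::setNames(lm$unigram, lm$lexicon$words)
               else lm$bigram[ci, ]
      nuc <- nucleus_truncate(probs, mass)
      H <- predictive_entropy(nuc$probs, n_tail = V - nuc$k)
      cache[[ci]] <<- list(nucleus = nuc, entropy = H, probs = probs)
    }
    cache[[ci]]
  }
  sur <- ent <- numeric(n)
  nucs <- if (keep_nucleus) vector("list", n) else NULL
  for (t in seq_len(n)) {
    ci <- if (t == 1L) V + 1L else idx[t - 1L]
    ctx <- get_ctx(ci)
    sur[t] <- word_surprisal(unname(ctx$probs[idx[t]]))
    ent[t] <- ctx$entropy
    if (keep_nucleus)
      nucs[[t]] <- stats::setNames(ctx$nucleus$probs, ctx$nucleus$words)
  }
  out <- data.frame(text_id = text_id, word_index = seq_len(n), word = text,
                    surprisal_bits = sur, entropy_bits = ent,
                    stringsAsFactors = FALSE)
  if (keep_nucleus) out$nucleus <- nucs
  out
}

#' Generator parameters for simulated readers
#'
#' Defaults emulate natural first-pass reading: a skip rule driven by word
#' length and launch distance (optionally by predictive/parafoveal
#' entropy), preferred landing position at 40% of word length (left of
#' centre) with launch-dependent scatter, gaze durations linear in
#' surprisal (lags 0-2), parafoveal entropy, log-frequency (lags 0-2),
#' word-class offsets and absolute landing offset plus Gaussian noise
#' resampled into the plausibility window, and regressive refixation of
#' skipped words driven by their pre-skip parafoveal entropy.
#'
#' @param ... overrides of the defaults listed in the function body.
#' @return list of class `readobs_generator_params`.
#' @export
generator_params <- function(...) {
  p <- list(
    n_participants = 5L, words_per_participant = 500L,
    V = 300L, zipf_exponent = 1, length_range = c(2L, 8L),
    lm_concentration = 0.3, text_freq_log_sd = 1,
    skip_intercept = 1.0, skip_length = -0.55, skip_launch = -0.28,
    skip_predictive_entropy = 0, skip_parafoveal_entropy = 0,
    landing_frac = 0.4, landing_sd_base = 0.8, landing_sd_slope = 0.12,
    dur_intercept = 230, dur_surprisal = c(3, 1.5, 0.6),
    dur_parafoveal = 4, dur_logfreq = c(-3, -1.2, -0.5),
    dur_class_offsets = c(func = 0, noun = 6, verb = 3, adj = 9),
    dur_landing_abs = 5, dur_sd = 40,
    dur_window = c(70, 900),
    comp_intercept = -2.5, comp_slope = 0.6,
    blink_rate = 0,
    duration_entropy_prior = "frequency",
    master_seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad))
    stop_readobs(paste("unknown generator parameter(s):",
                       paste(bad, collapse = ", ")), "readobs_bad_params")
  p[names(over)] <- over
  structure(p, class = "readobs_generator_params")
}

# word classes assigned once per lexicon: the most frequent fifth are
# function words, the rest split among content classes by hashed draw.
assign_word_classes <- function(lexicon, seed) {
  V <- lexicon$V
  rank <- rank(-lexicon$frequencies, ties.method = "first")
  cls <- with_seed(seed, ifelse(
    rank <= ceiling(0.2 * V), "func",
    sample(c("noun", "verb", "adj"), V, replace = TRUE,
           prob = c(0.5, 0.3, 0.2))))
  stats::setNames(cls, lexicon$words)
}

#' Simulate one reader over a text
#'
#' Performs a strictly left-to-right first pass: from each fixation the
#' next word is skipped with probability `plogis` of the skip linear form;
#' fixated words get a Gaussian landing position around the preferred
#' fraction of word length and a gaze duration from the duration linear
#' form plus noise (resampled into the plausibility window). Afterwards,
#' skipped words are optionally refixated regressively with probability
#' `plogis(comp_intercept + comp_slope * pre-skip parafoveal entropy)`.
#' When entropy terms are active, the generator uses the same ideal
#' observer machinery (and the same hashed per-token seeds) as the
#' analysis.
#'
#' @param text character vector of words (single line).
#' @param lexicon a `readobs_lexicon`.
#' @param lm a `readobs_lm` (for surprisal/entropy in the linear forms).
#' @param params a [generator_params()].
#' @param span a [perceptual_span()].
#' @param participant participant id string.
#' @param text_id text id string.
#' @param observer_cfg an [observer_config()] (seed field ignored;
#'   per-token seeds are derived from `params$master_seed`).
#' @param word_classes named class vector from the study driver.
#' @param lm_features optional precomputed [lm_token_features()] table.
#' @return list with `words`, `fixations` (canonical schema) and
#'   `truth` (per-token latents: skip probabilities, drawn features,
#'   noiseless duration form).
#' @export
simulate_reader <- function(text, lexicon, lm, params = generator_params(),
                            span = perceptual_span(), participant = "p1",
                            text_id = "t1",
                            observer_cfg = observer_config(),
                            word_classes = NULL, lm_features = NULL) {
  n <- length(text)
  idx <- match(text, lexicon$words)
  len <- lexicon$lengths[idx]
  fc <- cumsum(c(0, utils::head(len, -1) + 1))  # one space between words
  centre <- fc + (len - 1) / 2
  if (is.null(word_classes))
    word_classes <- assign_word_classes(
      lexicon, derive_seed(params$master_seed, "classes"))
  if (is.null(lm_features))
    lm_features <- lm_token_features(lm, text, text_id)
  sur <- lm_features$surprisal_bits
  pent <- lm_features$entropy_bits
  logfreq <- log(lexicon$frequencies)[idx]
  cls <- word_classes[text]
  cls_off <- params$dur_class_offsets[cls]

  freq_prior <- frequency_prior_logodds(lexicon)
  need_par <- params$dur_parafoveal != 0 ||
    params$skip_parafoveal_entropy != 0 || params$comp_slope != 0
  contextual <- identical(params$duration_entropy_prior, "contextual")

  par_ent <- rep(NA_real_, n)   # posterior entropy at first crossing
  skip_p <- rep(NA_real_, n)
  launch_at_cross <- rep(NA_real_, n)
  skipped <- rep(NA_integer_, n)
  landing <- gaze <- form <- rep(NA_real_, n)
  reg_p <- rep(NA_real_, n)
  regressed <- integer(n)

  obs_entropy <- function(j, launch) {
    cfg <- observer_cfg
    cfg$seed <- derive_seed(params$master_seed, participant, text_id, j)
    prior <- if (contextual) {
      ctx <- if (j == 1L) NULL else text[j - 1L]
      build_contextual_prior(lm_next_distribution(lm, ctx), lexicon)
    } else freq_prior
    preview_entropy(text[j], launch, prior, lexicon, span, cfg)$posterior_entropy
  }
  lagv <- function(v, j, k) if (j > k) v[j - k] else 0

  rng_seed <- derive_seed(params$master_seed, participant, text_id, "sim")
  with_seed(rng_seed, {
    fix_x <- numeric(0); fix_dur <- numeric(0)
    land_word <- function(j, launch) {
      sd_l <- params$landing_sd_base +
        params$landing_sd_slope * max(launch, 0)
      x <- fc[j] + params$landing_frac * len[j] + stats::rnorm(1, 0, sd_l)
      min(max(x, fc[j] - 0.4), fc[j] + len[j] - 0.6)
    }
    dur_word <- function(j, x) {
      f <- params$dur_intercept +
        params$dur_surprisal[1] * sur[j] +
        params$dur_surprisal[2] * lagv(sur, j, 1L) +
        params$dur_surprisal[3] * lagv(sur, j, 2L) +
        params$dur_parafoveal * (if (need_par) par_ent[j] else 0) +
        params$dur_logfreq[1] * logfreq[j] +
        params$dur_logfreq[2] * lagv(logfreq, j, 1L) +
        params$dur_logfreq[3] * lagv(logfreq, j, 2L) +
        cls_off[j] +
        params$dur_landing_abs * abs(x - centre[j])
      form[j] <<- f
      repeat {
        d <- f + stats::rnorm(1, 0, params$dur_sd)
        if (d >= params$dur_window[1] && d <= params$dur_window[2]) return(d)
      }
    }
    # first word is always fixated (no launch site exists before it)
    landing[1] <- fc[1] + params$landing_frac * len[1]
    if (need_par) par_ent[1] <- obs_entropy(1L, 1)
    skipped[1] <- 0L
    gaze[1] <- dur_word(1L, landing[1])
    fix_x <- landing[1]; fix_dur <- gaze[1]
    cur_x <- landing[1]
    j <- 2L
    while (j <= n) {
      launch <- fc[j] - cur_x
      launch_at_cross[j] <- launch
      if (need_par) par_ent[j] <- obs_entropy(j, launch)
      eta <- params$skip_intercept +
        params$skip_length * len[j] +
        params$skip_launch * launch +
        params$skip_predictive_entropy * pent[j] +
        params$skip_parafoveal_entropy *
          (if (need_par) par_ent[j] else 0)
      skip_p[j] <- stats::plogis(eta)
      # the final word is always fixated, so every token is crossed during
      # the pass and later compensation fixations are true regressions
      if (j == n) skip_p[j] <- NA_real_
      if (!is.na(skip_p[j]) && stats::runif(1) < skip_p[j]) {
        skipped[j] <- 1L
      } else {
        skipped[j] <- 0L
        landing[j] <- land_word(j, launch)
        gaze[j] <- dur_word(j, landing[j])
        fix_x <- c(fix_x, landing[j]); fix_dur <- c(fix_dur, gaze[j])
        cur_x <- landing[j]
      }
      j <- j + 1L
    }
    # compensation: regressive refixation of poorly-previewed skipped words
    if (params$comp_slope != 0 || params$comp_intercept > -Inf) {
      for (s in which(skipped == 1L)) {
        reg_p[s] <- stats::plogis(params$comp_intercept +
                                  params$comp_slope *
                                  (if (need_par) par_ent[s] else 0))
        if (stats::runif(1) < reg_p[s]) {
          regressed[s] <- 1L
          fix_x <- c(fix_x, centre[s])
          fix_dur <- c(fix_dur, 150 + abs(stats::rnorm(1, 0, 40)))
        }
      }
    }
    blink <- if (params$blink_rate > 0)
      as.integer(stats::runif(length(fix_x)) < params$blink_rate)
      else integer(length(fix_x))
    words <- data.frame(
      participant = participant, text_id = text_id, line_id = 1L,
      word_index = seq_len(n), word = text, first_char = fc,
      word_class = unname(cls), stringsAsFactors = FALSE)
    fixations <- data.frame(
      participant = participant, text_id = text_id, line_id = 1L,
      order = seq_along(fix_x), x_char = fix_x,
      duration_ms = fix_dur, blink_adjacent = blink,
      stringsAsFactors = FALSE)
    truth <- data.frame(
      participant = participant, text_id = text_id,
      word_index = seq_len(n), word = text, length = len,
      word_class = unname(cls),
      surprisal_bits = sur, predictive_entropy_bits = pent,
      parafoveal_entropy_bits = par_ent,
      log_frequency = logfreq,
      launch_distance = launch_at_cross,
      skip_prob = skip_p, skipped = skipped,
      landing = landing, duration_form = form, gaze_duration_ms = gaze,
      regress_prob = reg_p, regressed = regressed,
      stringsAsFactors = FALSE)
    list(words = words, fixations = fixations, truth = truth)
  })
}

#' Generate a complete synthetic study
#'
#' Independent simulated readers over per-participant texts sampled from
#' the same synthetic provider. Optionally writes the canonical corpus
#' TSVs, the nucleus JSONL per text, a ground-truth TSV and a manifest of
#' all seeds and parameters.
#'
#' @param params a [generator_params()].
#' @param span a [perceptual_span()].
#' @param observer_cfg an [observer_config()].
#' @param out_dir optional output directory.
#' @return list with `lexicon`, `lm`, `corpus` (words + fixations),
#'   `truth`, `lm_features`, `word_classes`, `params`, `manifest`.
#' @export
generate_study <- function(params = generator_params(),
                           span = perceptual_span(),
                           observer_cfg = observer_config(),
                           out_dir = NULL) {
  lex_seed <- derive_seed(params$master_seed, "lexicon")
  lm_seed <- derive_seed(params$master_seed, "lm")
  lexicon <- make_lexicon(params$V, params$zipf_exponent,
                          params$length_range, lex_seed)
  lm <- synthetic_lm(lexicon, params$lm_concentration, lm_seed,
                     params$text_freq_log_sd)
  word_classes <- assign_word_classes(
    lexicon, derive_seed(params$master_seed, "classes"))
  words <- fixations <- truth <- lmf <- vector("list", params$n_participants)
  for (p in seq_len(params$n_participants)) {
    pid <- sprintf("p%02d", p)
    tid <- sprintf("t%02d", p)
    text <- lm_sample_text(lm, params$words_per_participant,
                           derive_seed(params$master_seed, pid, "text"))
    feats <- lm_token_features(lm, text, tid)
    sim <- simulate_reader(text, lexicon, lm, params, span, pid, tid,
                           observer_cfg, word_classes, feats)
    words[[p]] <- sim$words; fixations[[p]] <- sim$fixations
    truth[[p]] <- sim$truth; lmf[[p]] <- feats
  }
  study <- list(
    lexicon = lexicon, lm = lm,
    corpus = list(
      words = as.data.frame(data.table::rbindlist(words)),
      fixations = as.data.frame(data.table::rbindlist(fixations))),
    truth = as.data.frame(data.table::rbindlist(truth)),
    lm_features = as.data.frame(data.table::rbindlist(lmf)),
    word_classes = word_classes, params = params,
    manifest = list(master_seed = params$master_seed,
                    lexicon_seed = lex_seed, lm_seed = lm_seed,
                    params = unclass(params)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_corpus(study$corpus, out_dir)
    write_lexicon(lexicon, file.path(out_dir, "lexicon.tsv"))
    utils::write.table(study$truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_nucleus_study(lm, study$lm_features,
                        file.path(out_dir, "nucleus.jsonl"))
    jsonlite::write_json(study$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  study
}

#' Write per-token nucleus records as JSON lines
#'
#' One record per corpus token:
#' `{"text_id": ..., "token_index": ..., "word": ..., "nucleus":
#' [[word, prob], ...], "surprisal_bits": ..., "entropy_bits": ...}`.
#'
#' @param lm a `readobs_lm` used to recompute nuclei per context.
#' @param lm_features table from [lm_token_features()].
#' @param path output file.
#' @export
write_nucleus_study <- function(lm, lm_features, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  cache <- new.env(hash = TRUE)
  # context word = previous token within the same text
  ord <- order(lm_features$text_id, lm_features$word_index)
  lm_features <- lm_features[ord, ]
  ctx_all <- c(".init", utils::head(lm_features$word, -1))
  ctx_all[lm_features$word_index == 1L] <- ".init"
  for (i in seq_len(nrow(lm_features))) {
    tid <- lm_features$text_id[i]
    wi <- lm_features$word_index[i]
    ctx_word <- ctx_all[i]
    nuc <- cache[[ctx_word]]
    if (is.null(nuc)) {
      probs <- lm_next_distribution(lm, if (ctx_word == ".init") NULL
                                        else ctx_word)
      nuc <- nucleus_truncate(probs)
      cache[[ctx_word]] <- nuc
    }
    rec <- list(text_id = tid, token_index = wi,
                word = lm_features$word[i],
                nucleus = mapply(function(w, p) list(w, p),
                                 nuc$words, nuc$probs,
                                 SIMPLIFY = FALSE, USE.NAMES = FALSE),
                surprisal_bits = lm_features$surprisal_bits[i],
                entropy_bits = lm_features$entropy_bits[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a nucleus JSONL file
#'
#' @param path JSONL file from [write_nucleus_study()] (or an external
#'   provider following the same schema).
#' @return data.frame with `text_id`, `word_index`, `word`,
#'   `surprisal_bits`, `entropy_bits` and a `nucleus` list-column of
#'   named probability vectors.
#' @export
read_nucleus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  data.frame(
    text_id = vapply(recs, function(r) as.character(r$text_id), ""),
    word_index = vapply(recs, function(r) as.integer(r$token_index), 1L),
    word = vapply(recs, function(r) r$word, ""),
    surprisal_bits = vapply(recs, function(r) r$surprisal_bits, 1),
    entropy_bits = vapply(recs, function(r) r$entropy_bits, 1),
    stringsAsFactors = FALSE) -> out
  out$nucleus <- lapply(recs, function(r)
    stats::setNames(vapply(r$nucleus, function(x) x[[2]], 1),
                    vapply(r$nucleus, function(x) x[[1]], "")))
  out
}
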