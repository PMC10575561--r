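test_that("surprisal is -log2(p), additive over constituent tokens", {
  expect_equal(word_surprisal(0.25), 2)
  expect_equal(word_surprisal(1), 0)
  expect_equal(word_surprisal(c(0.5, 0.5)), 2)  # joint of multi-token word
  expect_equal(word_surprisal(c(0.5, 0.25)),
               word_surprisal(0.5) + word_surprisal(0.25))
  expect_error(word_surprisal(0), class = "readobs_bad_probability")
})

test_that("predictive entropy on nucleus + flat tail", {
  expect_equal(predictive_entropy(rep(1 / 8, 8)), 3)
  expect_equal(predictive_entropy(1), 0)
  expect_equal(predictive_entropy(c(0.5, 0.45), n_tail = 2),
               entropy_bits(c(0.5, 0.45, 0.025, 0.025)))
  expect_error(predictive_entropy(numeric(0)),
               class = "readobs_bad_distribution")
  expect_error(predictive_entropy(c(0.5, 0.1)),
               class = "readobs_bad_distribution")
})

test_that("within-participant standardization and its inverse", {
  tab <- data.frame(participant = rep(c("a", "b"), each = 3),
                    gaze_duration = c(1, 2, 3, 4, 5, 6),
                    x = c(1, 2, 3, 10, 20, 60))
  std <- standardize_within_participant(tab, "x")
  expect_equal(std$x[1:3], c(-1, 0, 1) * 1.224744871391589,
               tolerance = 1e-12)
  expect_equal(mean(std$x[4:6]), 0)
  expect_equal(mean(std$x[4:6]^2), 1)  # population z-scores
  # outcome untouched
  expect_equal(std$gaze_duration, tab$gaze_duration)
  m <- attr(std, "moments")
  back <- unstandardize(std$x[4:6], m, "b", "x")
  expect_equal(back, tab$x[4:6], tolerance = 1e-12)

  tab$x[1:3] <- 7
  expect_error(standardize_within_participant(tab, "x"),
               "participant 'a'.*'x'|'x'.*participant 'a'",
               class = "readobs_zero_variance")
})

test_that("word_class expands to indicator contrasts", {
  tab <- data.frame(participant = "a", gaze_duration = 1:6,
                    x = c(1, 2, 3, 1, 2, 4),
                    word_class = rep(c("func", "noun", "verb"), 2))
  std <- standardize_within_participant(tab, "x")
  expect_false("word_class" %in% names(std))
  expect_setequal(grep("^word_class_", names(std), value = TRUE),
                  c("word_class_noun", "word_class_verb"))
  expect_equal(std$word_class_noun, as.numeric(tab$word_class == "noun"))
})

test_that("assembled tables respect lag availability and skip status", {
  study <- generate_study(generator_params(
    n_participants = 2, words_per_participant = 120, V = 80,
    master_seed = 31))
  m <- first_pass_measures(study$corpus$fixations, study$corpus$words)
  filt <- apply_exclusions(m, lexicon = study$lexicon)
  tokens <- filt$skipping[, c("participant", "text_id", "word_index",
                              "word", "launch_distance")]
  obs <- observe_tokens(tokens, study$lexicon,
                        config = observer_config(T_samples = 10),
                        prior = frequency_prior_logodds(study$lexicon),
                        master_seed = 31)
  tabs <- assemble_predictors(filt, obs, study$lm_features, study$lexicon)

  # every retained token appears in exactly one skipping row
  key_skip <- with(tabs$skipping, paste(participant, text_id, word_index))
  key_filt <- with(filt$skipping, paste(participant, text_id, word_index))
  expect_identical(sort(key_skip), sort(unique(key_skip)))
  expect_true(all(key_skip %in% key_filt))

  # skipped tokens never enter the duration table
  skipped_keys <- key_filt[filt$skipping$skipped_first_pass == 1]
  key_dur <- with(tabs$duration, paste(participant, text_id, word_index))
  expect_length(intersect(skipped_keys, key_dur), 0L)

  # no duration row for tokens without a lag-2 text word
  expect_true(all(tabs$duration$word_index >= 3))

  # missing observer output for a retained token is a pipeline bug
  obs_broken <- obs[-1, ]
  expect_error(assemble_predictors(filt, obs_broken, study$lm_features,
                                   study$lexicon),
               class = "readobs_join_error")
})

test_that("predictive entropy tracks realized surprisal across contexts", {
  lex <- make_lexicon(100, seed = 71)
  lm <- synthetic_lm(lex, concentration = 0.2, seed = 72)
  text <- lm_sample_text(lm, 1500, 73)
  f <- lm_token_features(lm, text)
  # contexts with lower predictive entropy should realize lower surprisal
  expect_gt(cor(f$entropy_bits, f$surprisal_bits), 0)
})
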