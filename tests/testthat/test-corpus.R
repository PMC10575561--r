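test_that("first-pass classification matches the hand-worked sequence", {
  # five words; fixation sequence w1, w3, w4, w2, w5:
  # w2 is first-pass skipped and later regressively fixated; w5 keeps
  # first-pass status because no word beyond it was fixated before
  words <- c("aaa", "bbb", "ccc", "ddd", "eee")
  x <- vapply(c(1, 3, 4, 2, 5), function(j) toy_centre(words, j), 1)
  corp <- toy_corpus(words, x)
  m <- first_pass_measures(corp$fixations, corp$words)
  expect_equal(m$status, c("fixated", "skipped", "fixated", "fixated",
                           "fixated"))
  expect_equal(m$skipped_first_pass, c(0L, 1L, 0L, 0L, 0L))
  expect_equal(m$later_regressive_fixation, c(0L, 1L, 0L, 0L, 0L))
  # w2's launch: from the fixation on w1 (the fixation before the
  # crossing saccade onto w3)
  expect_equal(m$launch_distance[2], 4 - x[1])
  # w5's launch: last fixation before crossing was the regression on w2
  expect_equal(m$launch_distance[5], 16 - x[4])
})

test_that("gaze duration sums the initial run of fixations only", {
  words <- c("aaa", "bbb", "ccc", "ddd")
  cx <- function(j) toy_centre(words, j)
  # two consecutive fixations on w3 (120, 80), then w4, then back to w3
  corp <- toy_corpus(words, c(cx(1), cx(3), cx(3) + 0.5, cx(4), cx(3)),
                     fix_dur = c(100, 120, 80, 90, 300))
  m <- first_pass_measures(corp$fixations, corp$words)
  expect_equal(m$gaze_duration_ms[3], 200)
  expect_equal(m$status[2], "skipped")
  expect_equal(m$gaze_duration_ms[4], 90)
})

test_that("landing position is measured from the word centre", {
  words <- c("aa", "bbbb")
  corp <- toy_corpus(words, c(0.5, 4))  # w2 spans chars 3..6, centre 4.5
  m <- first_pass_measures(corp$fixations, corp$words)
  expect_equal(m$landing_offset_chars[2], -0.5)
  expect_equal(m$landing_offset_frac[2], -0.125)
})

test_that("line transitions leave tokens unscored", {
  words <- c("aaa", "bbb", "ccc", "ddd")
  cx <- function(j) toy_centre(words, j)
  corp <- toy_corpus(words, c(cx(1), cx(3), cx(4)),
                     fix_line = c(1, 2, 2),
                     line_id = 1L)
  corp$words$line_id <- c(1, 1, 2, 2)
  m <- first_pass_measures(corp$fixations, corp$words)
  # w2 and w3 first crossed by the line-crossing saccade: not scored
  expect_equal(m$status[2], "sweep")
  expect_equal(m$status[3], "sweep")
  expect_equal(m$status[4], "fixated")
})

test_that("exclusion filters match the printed thresholds", {
  words <- c("the", "quick", "brown", "fox", "jumps", "over", "a", "lazy",
             "dog", "now")
  n <- length(words)
  len <- nchar(words)
  fc <- cumsum(c(0, head(len, -1) + 1))
  centre <- fc + (len - 1) / 2
  corp <- toy_corpus(words, centre, fix_dur = rep(200, n))
  m <- first_pass_measures(corp$fixations, corp$words)
  m$word[3] <- "don't"             # non-alphabetic
  m$gaze_duration_ms[5] <- 65      # below 70 ms
  m$gaze_duration_ms[6] <- 950     # above 900 ms
  m$launch_distance[8] <- 25       # beyond 24 characters
  m$blink[9] <- TRUE
  filt <- apply_exclusions(m)
  keys_skip <- filt$skipping$word_index
  keys_dur <- filt$duration$word_index
  # 65 ms gaze: dropped from duration only
  expect_true(5 %in% keys_skip)
  expect_false(5 %in% keys_dur)
  expect_false(6 %in% keys_dur)
  # launch 25: dropped from both
  expect_false(8 %in% keys_skip)
  expect_false(8 %in% keys_dur)
  # non-alphabetic: dropped from both
  expect_false(3 %in% keys_skip)
  # blink-adjacent dropped
  expect_false(9 %in% keys_skip)
  expect_equal(unname(filt$log["non_alphabetic"]), 1L)
  expect_equal(unname(filt$log["gaze_duration_out_of_range"]), 2L)
  expect_equal(unname(filt$log["launch_out_of_range"]),
               sum(is.na(m$launch_distance) | abs(m$launch_distance) > 24))
})

test_that("the corpus TSV pair round-trips and validates", {
  study <- generate_study(generator_params(
    n_participants = 1, words_per_participant = 50, V = 50,
    master_seed = 77))
  dir <- withr::local_tempdir()
  write_corpus(study$corpus, dir)
  back <- read_corpus(file.path(dir, "words.tsv"),
                      file.path(dir, "fixations.tsv"))
  expect_equal(back$words$word, study$corpus$words$word)
  expect_equal(back$fixations$x_char, study$corpus$fixations$x_char,
               tolerance = 1e-9)

  # shuffled fixation order is a structured parse error
  bad <- study$corpus$fixations
  bad$order <- rev(bad$order)
  utils::write.table(bad, file.path(dir, "fixations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_corpus(file.path(dir, "words.tsv"),
                           file.path(dir, "fixations.tsv")),
               class = "readobs_parse_error")

  # empty tables are fine
  empty_w <- study$corpus$words[0, ]
  empty_f <- study$corpus$fixations[0, ]
  utils::write.table(empty_w, file.path(dir, "words.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(empty_f, file.path(dir, "fixations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_silent(read_corpus(file.path(dir, "words.tsv"),
                            file.path(dir, "fixations.tsv")))
})

test_that("first-pass measures recover the generator's own labels", {
  study <- generate_study(generator_params(
    n_participants = 3, words_per_participant = 300, V = 100,
    master_seed = 5))
  m <- first_pass_measures(study$corpus$fixations, study$corpus$words)
  mm <- merge(m, study$truth, by = c("participant", "word_index"))
  scored <- !is.na(mm$status)
  expect_true(all(mm$skipped_first_pass[scored] == mm$skipped[scored]))
  fx <- scored & mm$skipped == 0
  expect_equal(mm$gaze_duration_ms.x[fx], mm$gaze_duration_ms.y[fx],
               tolerance = 1e-9)
  expect_equal(mm$later_regressive_fixation[scored], mm$regressed[scored])
  crossed <- scored & mm$word_index > 1
  expect_equal(mm$launch_distance.x[crossed], mm$launch_distance.y[crossed],
               tolerance = 1e-9)
})
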