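span3 <- perceptual_span(sigma = 3, Lambda = 1)

test_that("sensory quality matches the normal-CDF integral", {
  expect_equal(sensory_quality(0, span3), 2 * pnorm(1 / 6) - 1,
               tolerance = 1e-12)
  expect_equal(sensory_quality(5, span3), sensory_quality(-5, span3))
  expect_lt(sensory_quality(8, span3), sensory_quality(2, span3))
  # scaling factor is multiplicative
  expect_equal(sensory_quality(2, perceptual_span(3, Lambda = 0.5)),
               0.5 * sensory_quality(2, span3))
})

test_that("sample_percept has the stated mean and covariance", {
  lex <- tiny_lexicon()
  true_vec <- lex$encoding[1, ]  # "ab"
  # eccentricities chosen so lambda = 1 in the first slot => variance 1
  sp <- perceptual_span(sigma = 3, Lambda = 1 / sensory_quality(0, span3))
  n <- 1e5
  set.seed(11)
  draws <- replicate(n, sample_percept(true_vec, c(0, 4), sp)[1])
  expect_equal(mean(draws), true_vec[1], tolerance = 0.02)
  expect_equal(var(draws), 1, tolerance = 0.02)

  set.seed(7); a <- sample_percept(true_vec, c(0, 1), span3)
  set.seed(7); b <- sample_percept(true_vec, c(0, 1), span3)
  expect_identical(a, b)
  expect_error(sample_percept(true_vec, c(0, 1, 2), span3),
               class = "readobs_dim_error")
})

test_that("identical encodings keep zero relative log-odds", {
  # candidate words with identical encodings accrue zero relative evidence
  # for any percept (likelihood terms cancel); built by overwriting one
  # encoding since build_lexicon itself rejects duplicates
  lexa <- build_lexicon(c("ab", "ba"), c(1, 1))
  bel <- belief_state(0, lexa)
  set.seed(3)
  pct <- sample_percept(lexa$encoding[1, ], c(1, 2), span3)
  up <- update_belief(bel, pct, span3, c(1, 2))
  # same percept presented for a lexicon where both words are "ab"
  # (simulated by zero difference in encodings): increment must be 0
  lexb <- lexa
  lexb$encoding[2, ] <- lexb$encoding[1, ]
  belb <- belief_state(0, lexb)
  upb <- update_belief(belb, pct, span3, c(1, 2))
  expect_equal(upb$logodds, 0)
  expect_false(isTRUE(all.equal(up$logodds, 0)))
})

test_that("T = 0 returns the prior exactly", {
  lex <- tiny_lexicon()
  pri <- frequency_prior_logodds(lex)
  out <- preview_entropy("ab", 2, pri, lex, span3,
                         observer_config(T_samples = 0, seed = 1))
  expect_equal(out$posterior_entropy,
               entropy_bits(posterior_distribution(pri)))
  expect_equal(out$info_gain, 0)
})

test_that("chained single-sample updates match brute-force Bayes", {
  # V = 4, l_max = 2 lexicon; 5 percepts; compare the log-odds path with
  # explicit Gaussian-density Bayes on the same percepts
  lex <- tiny_lexicon()
  pri <- frequency_prior_logodds(lex)
  ecc <- c(1.5, 2.5)
  lam <- pmax(sensory_quality(ecc, span3), 1e-12)
  variances <- lam^(-0.5)
  set.seed(21)
  percepts <- lapply(1:5, function(i)
    sample_percept(lex$encoding[2, ], ecc, span3))
  bel <- belief_state(pri, lex)
  for (s in percepts) bel <- update_belief(bel, s, span3, ecc)
  p_pkg <- posterior_distribution(bel)
  p_oracle <- oracle_posterior(percepts, lex$frequencies / sum(lex$frequencies),
                               lex, variances)
  expect_lt(max(abs(p_pkg - p_oracle)), 1e-9)
})

test_that("posterior_distribution and entropy_bits worked examples", {
  expect_equal(posterior_distribution(0), c(0.5, 0.5))
  expect_equal(posterior_distribution(log(3)), c(0.75, 0.25))
  set.seed(2)
  x <- rnorm(999, 0, 5)
  expect_equal(sum(posterior_distribution(x)), 1, tolerance = 1e-12)
  # overflow safety
  expect_equal(posterior_distribution(c(1000, 999))[1:2],
               c(1, exp(-1)) / (1 + exp(-1) + 0), tolerance = 1e-6)

  expect_equal(entropy_bits(rep(0.25, 4)), 2)
  expect_equal(entropy_bits(c(1, 0, 0)), 0)
  expect_equal(entropy_bits(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(entropy_bits(c(-0.1, 1.1)),
               class = "readobs_bad_distribution")
})

test_that("preview entropy approaches the prior far outside the span", {
  lex <- make_lexicon(100, seed = 8)
  pri <- frequency_prior_logodds(lex)
  out <- preview_entropy(lex$words[10], 24, pri, lex, span3,
                         observer_config(seed = 4))
  expect_equal(out$info_gain, 0, tolerance = 0.05)
})

test_that("close preview of a short word is near-certain identification", {
  lex <- make_lexicon(100, length_range = c(2L, 6L), seed = 8)
  w <- lex$words[nchar(lex$words) == 3][1]
  pri <- frequency_prior_logodds(lex)
  out <- preview_entropy(w, 1, pri, lex, span3, observer_config(seed = 4))
  expect_lt(out$posterior_entropy, 0.1)
})

test_that("posterior entropy is the arithmetic mean over repeats", {
  lex <- tiny_lexicon()
  pri <- frequency_prior_logodds(lex)
  out <- preview_entropy("ba", 3, pri, lex, span3,
                         observer_config(repeats = 3, seed = 9))
  expect_equal(out$posterior_entropy, mean(out$repeat_entropies))
  expect_length(out$repeat_entropies, 3)
  # deterministic under a fixed seed
  out2 <- preview_entropy("ba", 3, pri, lex, span3,
                          observer_config(repeats = 3, seed = 9))
  expect_identical(out$posterior_entropy, out2$posterior_entropy)
})

test_that("out-of-lexicon words raise a structured signal", {
  lex <- tiny_lexicon()
  expect_error(preview_entropy("zz", 1, frequency_prior_logodds(lex), lex,
                               span3, observer_config(seed = 1)),
               class = "readobs_oov")
})

test_that("mean posterior entropy is non-decreasing in launch distance", {
  lex <- make_lexicon(60, seed = 14)
  pri <- frequency_prior_logodds(lex)
  cfg <- observer_config(T_samples = 20, repeats = 1)
  launches <- c(1, 4, 8, 14)
  set.seed(31)
  words <- sample(lex$words, 120, replace = TRUE)
  means <- vapply(launches, function(L) {
    mean(vapply(seq_along(words), function(i) {
      cfgi <- cfg; cfgi$seed <- derive_seed(77, L, i)
      preview_entropy(words[i], L, pri, lex, span3, cfgi)$posterior_entropy
    }, 1))
  }, 1)
  expect_true(all(diff(means) >= -1e-6))
  # and info gain is positive within the span
  expect_gt(entropy_bits(posterior_distribution(pri)) - means[1], 0)
})

test_that("the percept raises the true word's posterior probability", {
  lex <- make_lexicon(60, seed = 14)
  pri <- frequency_prior_logodds(lex)
  prior_p <- posterior_distribution(pri)
  ecc <- 3 + seq_len(lex$l_max) - 1
  set.seed(5)
  idx <- sample(lex$V, 50, replace = TRUE)
  post_p <- vapply(idx, function(i) {
    bel <- belief_state(pri, lex)
    for (t in 1:20) {
      pct <- sample_percept(lex$encoding[i, ], ecc, span3)
      bel <- update_belief(bel, pct, span3, ecc)
    }
    posterior_distribution(bel)[i]
  }, 1)
  expect_gt(mean(post_p), mean(prior_p[idx]))
})

test_that("increasing T does not increase mean posterior entropy", {
  lex <- make_lexicon(50, seed = 19)
  pri <- frequency_prior_logodds(lex)
  set.seed(41)
  words <- sample(lex$words, 100, replace = TRUE)
  mean_ent <- function(Tn) {
    mean(vapply(seq_along(words), function(i) {
      cfg <- observer_config(T_samples = Tn, repeats = 1,
                             seed = derive_seed(55, i))
      preview_entropy(words[i], 4, pri, lex, span3, cfg)$posterior_entropy
    }, 1))
  }
  ents <- vapply(c(5, 20, 50), mean_ent, 1)
  expect_true(all(diff(ents) <= 1e-6))
})
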