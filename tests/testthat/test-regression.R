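make_lin_table <- function(n, beta = c(2, -1), sigma = 0, seed = 1,
                           binary = FALSE) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- 1 + beta[1] * x1 + beta[2] * x2
  y <- if (binary) rbinom(n, 1, plogis(eta))
       else eta + rnorm(n, 0, sigma)
  data.frame(y = y, x1 = x1, x2 = x2)
}

test_that("noiseless linear outcomes are predicted exactly", {
  tab <- make_lin_table(200, sigma = 0)
  cv <- fit_predict_cv(tab, "y", c("x1", "x2"), "gaussian", 10, seed = 3)
  expect_lt(max(abs(cv$y - cv$pred)), 1e-8)
  expect_equal(score_r2(cv$y, cv$pred, cv$null_pred), 1, tolerance = 1e-10)
})

test_that("cross-validated score of pure noise is near zero", {
  set.seed(4)
  tab <- data.frame(y = rnorm(1e4), x1 = rnorm(1e4), x2 = rnorm(1e4))
  s <- cv_score(tab, "y", c("x1", "x2"), "gaussian", 10, seed = 5)
  expect_equal(s, 0, tolerance = 0.02)

  tabb <- data.frame(y = rbinom(1e4, 1, 0.3), x1 = rnorm(1e4))
  sb <- cv_score(tabb, "y", "x1", "binomial", 10, seed = 5)
  expect_equal(sb, 0, tolerance = 0.02)
})

test_that("fold assignment and predictions are seed-deterministic", {
  tab <- make_lin_table(500, sigma = 1)
  a <- fit_predict_cv(tab, "y", c("x1", "x2"), "gaussian", 10, seed = 11)
  b <- fit_predict_cv(tab, "y", c("x1", "x2"), "gaussian", 10, seed = 11)
  expect_identical(a, b)
  c <- fit_predict_cv(tab, "y", c("x1", "x2"), "gaussian", 10, seed = 12)
  expect_false(identical(a$fold, c$fold))
})

test_that("R2 and McFadden scoring formulas behave at the landmarks", {
  y <- c(1, 2, 3, 4)
  expect_equal(score_r2(y, y, rep(2.5, 4)), 1)
  expect_equal(score_r2(y, rep(2.5, 4), rep(2.5, 4)), 0)
  expect_lt(score_r2(y, c(4, 3, 2, 1), rep(2.5, 4)), 0)
  expect_error(score_r2(y, y, y), class = "readobs_score_error")

  yb <- c(0, 0, 1, 1)
  expect_equal(score_mcfadden(yb, rep(0.5, 4), rep(0.5, 4)), 0)
  expect_gt(score_mcfadden(yb, c(0.01, 0.01, 0.99, 0.99), rep(0.5, 4)),
            0.9)
  expect_lt(score_mcfadden(yb, c(0.9, 0.9, 0.1, 0.1), rep(0.5, 4)), 0)
})

test_that("binomial CV errors on degenerate training outcomes", {
  tab <- data.frame(y = c(rep(0, 11), 1), x1 = rnorm(12))
  expect_error(fit_predict_cv(tab, "y", "x1", "binomial", 10, seed = 1),
               class = "readobs_cv_error")
  expect_error(fit_predict_cv(tab[1:5, ], "y", "x1", "gaussian", 10, 1),
               class = "readobs_cv_error")
})

test_that("implanted coefficients are recovered within 3 SE", {
  # scaled-down recovery sweep: OLS and logistic on generated data
  hits <- 0L; total <- 0L
  for (s in 1:15) {
    tab <- make_lin_table(2000, beta = c(2, -1), sigma = 1, seed = s)
    fit <- summary(lm(y ~ x1 + x2, tab))$coefficients
    hits <- hits + sum(abs(fit[2:3, "Estimate"] - c(2, -1)) <
                         3 * fit[2:3, "Std. Error"])
    tabb <- make_lin_table(2000, beta = c(1, -0.5), seed = 100 + s,
                           binary = TRUE)
    fitb <- summary(glm(y ~ x1 + x2, binomial, tabb))$coefficients
    hits <- hits + sum(abs(fitb[2:3, "Estimate"] - c(1, -0.5)) <
                         3 * fitb[2:3, "Std. Error"])
    total <- total + 4L
  }
  expect_gte(hits / total, 0.95)
})

test_that("a pure-noise predictor barely moves the CV score", {
  tab <- make_lin_table(1e4, sigma = 1, seed = 9)
  tab$noise <- rnorm(1e4)
  s0 <- cv_score(tab, "y", c("x1", "x2"), "gaussian", 10, seed = 2)
  s1 <- cv_score(tab, "y", c("x1", "x2", "noise"), "gaussian", 10, seed = 2)
  expect_lt(abs(s1 - s0), 0.005)
})

test_that("skipped-word refixation model recovers the compensation slope", {
  # implant: P(regressive refixation) = plogis(-1 + 0.8 * z-entropy)
  n_part <- 12
  betas <- numeric(n_part)
  for (p in seq_len(n_part)) {
    set.seed(p + 400)
    z <- rnorm(400)
    y <- rbinom(400, 1, plogis(-1 + 0.8 * z))
    fit <- fit_skipped_refixation_model(
      data.frame(later_regressive_fixation = y, parafoveal_entropy = z))
    betas[p] <- fit$coefficient
  }
  expect_gte(mean(betas > 0), 0.95)

  # null generator: slope concentrates near zero
  set.seed(77)
  z <- rnorm(4000)
  y <- rbinom(4000, 1, 0.3)
  fit0 <- fit_skipped_refixation_model(
    data.frame(later_regressive_fixation = y, parafoveal_entropy = z))
  expect_equal(fit0$coefficient, 0, tolerance = 0.15)

  expect_error(fit_skipped_refixation_model(
    data.frame(later_regressive_fixation = rep(1, 10),
               parafoveal_entropy = rnorm(10))),
    class = "readobs_degenerate")
  expect_error(fit_skipped_refixation_model(
    data.frame(later_regressive_fixation = integer(0),
               parafoveal_entropy = numeric(0))),
    class = "readobs_no_data")
})
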