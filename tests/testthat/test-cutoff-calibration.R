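# independent concordance oracle: P(S_pos > S_neg) + P(tie)/2 by brute force
concordance_oracle <- function(scores, labels) {
  sp <- scores[labels]; sn <- scores[!labels]
  g <- outer(sp, sn, ">"); t <- outer(sp, sn, "==")
  mean(g + 0.5 * t)
}

test_that("trapezoidal AUC equals the Mann-Whitney concordance on random data", {
  withr::local_seed(101)
  for (i in 1:200) {
    d <- random_roc_data(sample(4:50, 1))
    curve <- roc_curve(d$scores, d$labels)
    expect_equal(curve$auc, concordance_oracle(d$scores, d$labels),
                 tolerance = 1e-12)
    # monotone sweep with pinned endpoints
    expect_true(all(diff(curve$sensitivity) <= 1e-15))
    expect_true(all(diff(curve$specificity) >= -1e-15))
    expect_equal(c(curve$sensitivity[1], curve$specificity[1]), c(1, 0))
    expect_equal(c(curve$sensitivity[18], curve$specificity[18]), c(0, 1))
  }
})

test_that("AUC boundary cases", {
  expect_equal(roc_curve(c(9, 10, 3, 4), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_curve(c(5, 5), c(TRUE, FALSE))$auc, 0.5)
  expect_error(roc_curve(c(1, 2), c(TRUE, TRUE)), "negative")
  expect_error(roc_curve(c(1, 2), c(FALSE, FALSE)), "positive")
})

test_that("missing pairs are dropped, counted, and do not change the curve", {
  s <- c(9, 10, 3, 4, NA, 7); y <- c(TRUE, TRUE, FALSE, FALSE, TRUE, NA)
  curve <- roc_curve(s, y)
  expect_equal(curve$n_dropped, 2)
  expect_equal(curve$auc, 1)
})

test_that("equal weights reproduce the unweighted ROC exactly", {
  withr::local_seed(7)
  d <- random_roc_data(60)
  u <- roc_curve(d$scores, d$labels)
  w <- roc_curve(d$scores, d$labels, weights = rep(2.5, 60))
  expect_equal(w$sensitivity, u$sensitivity, tolerance = 1e-15)
  expect_equal(w$specificity, u$specificity, tolerance = 1e-15)
  expect_equal(w$auc, u$auc, tolerance = 1e-15)
})

test_that("AUC matches pROC on random data", {
  skip_if_not_installed("pROC")
  withr::local_seed(17)
  for (i in 1:20) {
    d <- random_roc_data(80)
    ours <- roc_curve(d$scores, d$labels)$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = d$labels, predictor = d$scores,
      levels = c(FALSE, TRUE), direction = "<"
    )))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("Youden selection agrees with a brute-force sweep, lower tie-break", {
  withr::local_seed(23)
  for (i in 1:200) {
    d <- random_roc_data(sample(4:50, 1))
    curve <- roc_curve(d$scores, d$labels)
    sel <- select_cutoff(curve, "youden")
    j <- curve$sensitivity + curve$specificity - 1
    # ties, including floating-point ties, resolve to the lowest threshold
    expect_identical(sel$cutoff,
                     curve$thresholds[which(j >= max(j) - 1e-10)[1]])
  }
  # hand-built unique maximum
  d <- list(scores = c(10, 9, 9, 2, 3, 3), labels = rep(c(TRUE, FALSE), each = 3))
  sel <- select_cutoff(roc_curve(d$scores, d$labels))
  expect_identical(sel$cutoff, 4L + 0L)  # any t in 4..9 is perfect; lowest wins
  expect_equal(sel$sensitivity, 1)
  expect_equal(sel$specificity, 1)
})

test_that("corner rule is available and recorded", {
  d <- random_roc_data(50)
  sel <- select_cutoff(roc_curve(d$scores, d$labels), "corner")
  expect_identical(sel$selection_rule, "corner")
  expect_true(sel$cutoff %in% 0:17)
  expect_true(sel$sensitivity_ci[1] <= sel$sensitivity &&
                sel$sensitivity <= sel$sensitivity_ci[2])
  expect_true(sel$specificity_ci[1] <= sel$specificity &&
                sel$specificity <= sel$specificity_ci[2])
})

test_that("selection on synthetic scores matches an independent re-implementation", {
  s <- score_respondents(generate_survey(small_config(n_per_cell = 800)))
  sel <- select_cutoff(roc_curve(s$phc, s$gold), "youden")
  # independent sweep written from the definitions, not via roc_curve
  ok <- !is.na(s$phc) & !is.na(s$gold)
  phc <- s$phc[ok]; gold <- s$gold[ok]
  best <- -Inf; best_t <- NA
  for (t in 0:17) {
    sens <- mean(phc[gold] >= t); spec <- mean(phc[!gold] < t)
    if (sens + spec - 1 > best) { best <- sens + spec - 1; best_t <- t }
  }
  expect_identical(sel$cutoff, best_t)
})

test_that("structurally, sensitivity is perfect at thresholds up to 6", {
  # gold-positive needs two items at rescaled >= 3, hence PHC >= 6
  s <- score_respondents(generate_survey(small_config(n_per_cell = 500)))
  curve <- roc_curve(s$phc, s$gold)
  expect_true(all(curve$sensitivity[curve$thresholds <= 6] == 1))
})

test_that("Wilson interval matches the closed form and its boundaries", {
  # hand evaluation of the textbook formula at k = 8, n = 10
  z <- qnorm(0.975); p <- 0.8; n <- 10
  hand <- (p + z^2 / (2 * n) + c(-1, 1) * z *
             sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  expect_equal(proportion_ci(8, 10), hand, tolerance = 1e-12)
  expect_equal(proportion_ci(10, 10)[2], 1)
  expect_equal(proportion_ci(0, 10)[1], 0)
  expect_error(proportion_ci(1, 0), "n >= 1")
  expect_error(proportion_ci(5, 3), "k <= n")
})

test_that("bootstrap AUC interval behaves as a percentile interval", {
  s <- c(rep(10, 15), rep(2, 15)); y <- rep(c(TRUE, FALSE), each = 15)
  expect_equal(auc_ci(s, y, n_boot = 200, seed = 1), c(1, 1))
  withr::local_seed(31)
  d <- random_roc_data(120)
  point <- roc_curve(d$scores, d$labels)$auc
  ci <- auc_ci(d$scores, d$labels, n_boot = 400, seed = 5)
  expect_true(ci[1] <= point && point <= ci[2])
  expect_identical(ci, auc_ci(d$scores, d$labels, n_boot = 400, seed = 5))
  expect_error(auc_ci(d$scores, d$labels, n_boot = 50), "n_boot")
})

test_that("bootstrap interval narrows with sample size", {
  gen <- function(n, seed) {
    withr::with_seed(seed, {
      y <- runif(n) < 0.4
      s <- pmin(16, pmax(0, round(6 + 4 * y + rnorm(n, 0, 2.5))))
      list(s = s, y = y)
    })
  }
  small <- gen(300, 1); big <- gen(8000, 2)
  w_small <- diff(auc_ci(small$s, small$y, n_boot = 300, seed = 3))
  w_big <- diff(auc_ci(big$s, big$y, n_boot = 300, seed = 3))
  expect_lt(w_big, w_small / 2)
})

test_that("cluster bootstrap resamples whole classes reproducibly", {
  s <- score_respondents(generate_survey(small_config(n_per_cell = 300)))
  ci <- auc_ci(s$phc, s$gold, cluster = s$cluster, n_boot = 200, seed = 2)
  expect_true(ci[1] <= ci[2])
  expect_identical(
    ci, auc_ci(s$phc, s$gold, cluster = s$cluster, n_boot = 200, seed = 2))
})
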