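test_that("generation is deterministic given config and seed", {
  cfg <- small_config(n_per_cell = 100, seed = 11)
  d1 <- generate_survey(cfg)
  d2 <- generate_survey(cfg)
  expect_identical(d1, d2)
  cfg2 <- small_config(n_per_cell = 100, seed = 12)
  expect_false(identical(generate_survey(cfg2), d1))
  # generation must not disturb the session RNG state
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_survey(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("degenerate ladder noise pins every ls at the intercept", {
  cfg <- small_config(n_per_cell = 50, ls_noise_sd = 1e-9, ls_slope = 0,
                      ls_intercept = 8)
  d <- generate_survey(cfg)
  expect_true(all(d$ls == 8L))
})

test_that("saturated thresholds force all items to 'rarely/never'", {
  far <- list(
    feeling_low = c(50, 60, 70, 80), irritability = c(50, 60, 70, 80),
    nervousness = c(50, 60, 70, 80), sleep_difficulty = c(50, 60, 70, 80)
  )
  d <- generate_survey(small_config(n_per_cell = 50, item_thresholds = far))
  for (nm in c("feeling_low", "irritability", "nervousness",
               "sleep_difficulty")) {
    expect_true(all(d[[nm]] == 5L))
  }
  s <- score_respondents(d)
  expect_true(all(s$phc == 0))
})

test_that("generated cell means recover the analytic expectation", {
  cfg <- small_config(n_per_cell = 3000, seed = 21,
                      n_strata = 5, clusters_per_stratum = 8)
  total_sd <- sqrt(cfg$sigma_theta^2 + cfg$cluster_sd^2)
  s <- score_respondents(generate_survey(cfg))
  des <- survey_design()
  est <- group_estimates(s, "phc", des)
  mu_map <- cfg$mu
  truth <- expected_phc(
    mu_map$mu[match(paste(est$gender, est$age_group),
                    paste(mu_map$gender, mu_map$age_group))],
    total_sd, cfg$item_discriminations, cfg$item_thresholds
  )
  expect_true(all(abs(est$estimate - truth) <= 3 * est$se))
  # ladder side of the model too
  est_ls <- group_estimates(s, "ls", des)
  truth_ls <- expected_ls(
    mu_map$mu[match(paste(est_ls$gender, est_ls$age_group),
                    paste(mu_map$gender, mu_map$age_group))],
    total_sd, cfg$ls_intercept, cfg$ls_slope, cfg$ls_noise_sd
  )
  expect_true(all(abs(est_ls$estimate - truth_ls) <= 3 * est_ls$se))
})

test_that("raising a cell's latent mean raises expected PHC, lowers expected LS", {
  mus <- seq(-1, 2, by = 0.25)
  ephc <- expected_phc(mus, 1.02)
  expect_true(all(diff(ephc) > 0))
  els <- expected_ls(mus, 1.02, intercept = 8, slope = 0.5, noise_sd = 1.6)
  expect_true(all(diff(els) < 0))
  # and empirically, holding everything else (including the seed) fixed
  mu_lo <- one_wave_mu(); mu_hi <- one_wave_mu()
  mu_hi$mu[6] <- mu_hi$mu[6] + 1
  d_lo <- score_respondents(generate_survey(
    small_config(n_per_cell = 2000, seed = 5, mu = mu_lo)))
  d_hi <- score_respondents(generate_survey(
    small_config(n_per_cell = 2000, seed = 5, mu = mu_hi)))
  cell <- function(d) d[d$gender == "girl" & d$age_group == 15, ]
  expect_gt(mean(cell(d_hi)$phc), mean(cell(d_lo)$phc))
  expect_lt(mean(cell(d_hi)$ls_valid), mean(cell(d_lo)$ls_valid))
})

test_that("class random effects induce an ICC that grows with cluster_sd", {
  icc_of <- function(cluster_sd) {
    cfg <- small_config(n_per_cell = 4000, seed = 31,
                        cluster_sd = cluster_sd)
    s <- score_respondents(generate_survey(cfg))
    g <- s[s$gender == "girl" & s$age_group == 15, ]
    fit <- stats::aov(phc ~ cluster, data = g)
    ms <- summary(fit)[[1]]$`Mean Sq`
    k <- nrow(g) / length(unique(g$cluster))
    (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  }
  icc_small <- icc_of(0.15)
  icc_large <- icc_of(0.8)
  expect_gt(icc_small, 0)
  expect_gt(icc_large, icc_small)
})

test_that("weights are positive and mean-one within each wave", {
  cfg <- generator_config(
    n_per_cell = 300,
    mu = rbind(one_wave_mu(wave = "2010"), one_wave_mu(wave = "2014")),
    waves = c("2010", "2014"), n_strata = 3, clusters_per_stratum = 4,
    seed = 3
  )
  d <- generate_survey(cfg)
  expect_true(all(d$weight > 0))
  for (wv in unique(d$wave)) {
    expect_equal(mean(d$weight[d$wave == wv]), 1, tolerance = 1e-12)
  }
  # weight_cv = 0 gives equal weights
  d0 <- generate_survey(small_config(n_per_cell = 50, weight_cv = 0))
  expect_true(all(d0$weight == 1))
})

test_that("missingness injection follows the requested rates", {
  d <- generate_survey(small_config(n_per_cell = 500))
  expect_identical(inject_missingness(d, 0, 0, seed = 1), d)
  d_all <- inject_missingness(d, 1, 1, seed = 1)
  expect_true(all(is.na(d_all$feeling_low)) && all(is.na(d_all$ls)))
  expect_identical(nrow(d_all), nrow(d))
  # observed rate within 3 binomial SDs of the target
  d_some <- inject_missingness(d, 0.1, 0.1, seed = 2)
  n_items <- 4 * nrow(d)
  obs <- sum(is.na(d_some[, c("feeling_low", "irritability", "nervousness",
                              "sleep_difficulty")])) / n_items
  expect_lt(abs(obs - 0.1), 3 * sqrt(0.1 * 0.9 / n_items))
  expect_error(inject_missingness(d, -0.1, 0), "item_rate")
  expect_error(inject_missingness(d, 0, 1.5), "ls_rate")
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(small_config(sigma_theta = -1), "sigma_theta")
  expect_error(small_config(weight_cv = -0.1), "weight_cv")
  expect_error(small_config(ls_noise_sd = 0), "ls_noise_sd")
  expect_error(small_config(n_per_cell = 0), "n_per_cell")
  bad_th <- default_item_thresholds()
  bad_th$nervousness <- c(0, 0, 1, 2)  # not strictly increasing
  expect_error(small_config(item_thresholds = bad_th), "item_thresholds")
  mu_short <- one_wave_mu()[-3, ]
  expect_error(small_config(mu = mu_short), "mu")
})

test_that("configurations round-trip through YAML unchanged", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- small_config(n_per_cell = 77, seed = 9)
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back, cfg, tolerance = 1e-12)
  # the calibrated default, including its target table
  path2 <- withr::local_tempfile(fileext = ".yaml")
  dcfg <- default_config(n_per_cell = 10, seed = 4)
  write_generator_config(dcfg, path2)
  back2 <- read_generator_config(path2)
  expect_equal(back2$mu, dcfg$mu, tolerance = 1e-9)
  expect_equal(back2$targets, dcfg$targets, tolerance = 1e-9)
  expect_identical(generate_survey(back2), generate_survey(dcfg))
})

test_that("the default configuration stores the published target table", {
  cfg <- default_config(n_per_cell = 10)
  tg <- cfg$targets
  g15 <- tg[tg$gender == "girl" & tg$age_group == 15, ]
  expect_equal(g15$phc_target[order(g15$wave)], c(7.5, 8.6, 9.1))
  expect_equal(g15$ls_target[order(g15$wave)], c(6.9, 6.7, 6.9))
  b11 <- tg[tg$gender == "boy" & tg$age_group == 11, ]
  expect_equal(b11$phc_target[order(b11$wave)], c(5.1, 5.0, 5.9))
  # calibration solves the analytic expectations to the targets
  total_sd <- sqrt(cfg$sigma_theta^2 + cfg$cluster_sd^2)
  cells <- dplyr::left_join(cfg$mu, cfg$ls_intercept,
                            by = c("wave", "gender", "age_group"))
  cells <- dplyr::left_join(cells, tg, by = c("wave", "gender", "age_group"))
  expect_equal(expected_phc(cells$mu, total_sd), cells$phc_target,
               tolerance = 1e-7)
  expect_equal(
    expected_ls(cells$mu, total_sd, cells$ls_intercept, cfg$ls_slope,
                cfg$ls_noise_sd),
    cells$ls_target, tolerance = 1e-7
  )
})
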