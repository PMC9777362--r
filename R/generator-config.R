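#' Build a synthetic survey generator configuration
#'
#' Defines the data-generating process for an HBSC-like repeated
#' cross-sectional survey. Each respondent carries a latent symptom
#' severity \eqn{\theta = \mu_{cell} + b_{cluster} + e}, with
#' \eqn{b_{cluster} \sim N(0, \sigma_b^2)} a school-class random effect and
#' \eqn{e \sim N(0, \sigma_\theta^2)} individual variation. The four
#' psychological symptom items follow a logistic graded-response model on
#' the rescaled 0--4 scale, \eqn{P(S_i \ge k) = \mathrm{logit}^{-1}(a_i(\theta -
#' t_{ik}))}, and the Cantril ladder is a linear-in-\eqn{\theta} rounded and
#' clipped score, so higher severity lowers expected life satisfaction.
#'
#' @param n_per_cell Respondents generated per (wave, gender, age) cell.
#' @param mu Data frame with columns `wave`, `gender`, `age_group`, `mu`
#'   giving the latent severity mean of every cell in
#'   `waves` x \{boy, girl\} x \{11, 13, 15\}.
#' @param waves Ordered character vector of survey wave labels.
#' @param sigma_theta Individual latent SD (> 0).
#' @param item_discriminations Named positive numeric vector, one slope per
#'   item, names `feeling_low`, `irritability`, `nervousness`,
#'   `sleep_difficulty`.
#' @param item_thresholds Named list, one strictly increasing numeric(4) of
#'   latent thresholds per item (cut points between the 5 ordinal levels).
#' @param ls_intercept Either a single number or a data frame with columns
#'   `wave`, `gender`, `age_group`, `ls_intercept`: the expected ladder
#'   score at latent severity 0 (per cell when a data frame).
#' @param ls_slope Drop in expected ladder score per unit latent severity.
#' @param ls_noise_sd SD of the ladder's residual noise (> 0).
#' @param n_strata Number of strata per wave.
#' @param clusters_per_stratum School classes per stratum (per wave and age).
#' @param cluster_sd SD of the between-class random effect (> 0).
#' @param weight_cv Coefficient of variation of the lognormal design
#'   weights (>= 0; 0 gives equal weights).
#' @param seed Integer RNG seed; generation is fully deterministic given
#'   the configuration.
#'
#' @return An object of class `generator_config`.
#' @seealso [default_config()], [generate_survey()]
#' @export
generator_config <- function(n_per_cell = 1000L,
                             mu = NULL,
                             waves = hbsc_waves,
                             sigma_theta = 1,
                             item_discriminations = c(
                               feeling_low = 1.3, irritability = 1.2,
                               nervousness = 1.1, sleep_difficulty = 1.0
                             ),
                             item_thresholds = default_item_thresholds(),
                             ls_intercept = 8,
                             ls_slope = 0.5,
                             ls_noise_sd = 1.6,
                             n_strata = 20L,
                             clusters_per_stratum = 15L,
                             cluster_sd = 0.2,
                             weight_cv = 0.3,
                             seed = 1L) {
  if (is.null(mu)) {
    mu <- expand_cells(waves)
    mu$mu <- 0
  }
  if (is.data.frame(mu)) mu <- tibble::as_tibble(mu)
  if (is.data.frame(ls_intercept)) {
    ls_intercept <- tibble::as_tibble(ls_intercept)
  }
  config <- structure(
    list(
      n_per_cell = as.integer(n_per_cell),
      waves = as.character(waves),
      mu = mu,
      sigma_theta = sigma_theta,
      item_discriminations = item_discriminations,
      item_thresholds = item_thresholds,
      ls_intercept = ls_intercept,
      ls_slope = ls_slope,
      ls_noise_sd = ls_noise_sd,
      n_strata = as.integer(n_strata),
      clusters_per_stratum = as.integer(clusters_per_stratum),
      cluster_sd = cluster_sd,
      weight_cv = weight_cv,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_config(config)
  config
}

# all (wave, gender, age) cells in canonical order
expand_cells <- function(waves) {
  cells <- expand.grid(
    age_group = hbsc_ages, gender = hbsc_genders, wave = as.character(waves),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  tibble::as_tibble(cells[, c("wave", "gender", "age_group")])
}

default_item_thresholds <- function() {
  list(
    feeling_low      = c(-0.40, 0.40, 1.10, 1.90),
    irritability     = c(-0.90, 0.00, 0.80, 1.70),
    nervousness      = c(-1.10, -0.30, 0.60, 1.50),
    sleep_difficulty = c(-0.70, 0.10, 0.90, 1.80)
  )
}

config_error <- function(field, msg) {
  stop(sprintf("invalid generator configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

#' Validate a generator configuration
#'
#' Checks every structural invariant of the configuration and fails with an
#' error naming the offending field.
#'
#' @param config A `generator_config` object.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("expected a 'generator_config' object", call. = FALSE)
  }
  if (!is.numeric(config$n_per_cell) || length(config$n_per_cell) != 1 ||
      is.na(config$n_per_cell) || config$n_per_cell < 1) {
    config_error("n_per_cell", "must be a positive integer")
  }
  if (length(config$waves) < 1 || anyDuplicated(config$waves)) {
    config_error("waves", "must be a non-empty vector of unique labels")
  }
  for (f in c("sigma_theta", "ls_noise_sd", "cluster_sd")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      config_error(f, "must be a single positive number")
    }
  }
  if (!is.numeric(config$weight_cv) || length(config$weight_cv) != 1 ||
      is.na(config$weight_cv) || config$weight_cv < 0) {
    config_error("weight_cv", "must be a single non-negative number")
  }
  for (f in c("n_strata", "clusters_per_stratum")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1) {
      config_error(f, "must be a positive integer")
    }
  }
  a <- config$item_discriminations
  if (!is.numeric(a) || length(a) != 4 || !setequal(names(a), item_names) ||
      any(is.na(a)) || any(a <= 0)) {
    config_error("item_discriminations",
                 "must be 4 positive numbers named after the items")
  }
  th <- config$item_thresholds
  if (!is.list(th) || !setequal(names(th), item_names)) {
    config_error("item_thresholds", "must be a list named after the items")
  }
  for (nm in item_names) {
    t <- th[[nm]]
    if (!is.numeric(t) || length(t) != 4 || any(is.na(t)) ||
        any(diff(t) <= 0)) {
      config_error("item_thresholds",
                   sprintf("for '%s' must be 4 strictly increasing numbers", nm))
    }
  }
  check_cell_map(config$mu, "mu", config$waves)
  if (is.data.frame(config$ls_intercept)) {
    check_cell_map(config$ls_intercept, "ls_intercept", config$waves)
  } else if (!is.numeric(config$ls_intercept) ||
             length(config$ls_intercept) != 1 || is.na(config$ls_intercept)) {
    config_error("ls_intercept", "must be a number or a per-cell data frame")
  }
  if (!is.numeric(config$ls_slope) || length(config$ls_slope) != 1 ||
      is.na(config$ls_slope)) {
    config_error("ls_slope", "must be a single number")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1 ||
      is.na(config$seed)) {
    config_error("seed", "must be a single integer")
  }
  invisible(config)
}

# a per-cell map must cover waves x genders x ages exactly once
check_cell_map <- function(map, field, waves) {
  value_col <- field
  needed <- c("wave", "gender", "age_group", value_col)
  if (!is.data.frame(map) || !all(needed %in% names(map))) {
    config_error(field, sprintf(
      "must be a data frame with columns %s", paste(needed, collapse = ", ")
    ))
  }
  cells <- expand_cells(waves)
  key <- function(d) paste(d$wave, d$gender, d$age_group)
  if (anyDuplicated(key(map))) {
    config_error(field, "has duplicated (wave, gender, age_group) rows")
  }
  missing_cells <- setdiff(key(cells), key(map))
  if (length(missing_cells) > 0) {
    config_error(field, sprintf(
      "is missing cell(s): %s", paste(missing_cells, collapse = "; ")
    ))
  }
  if (any(is.na(map[[value_col]]))) {
    config_error(field, "contains missing values")
  }
  invisible(map)
}

# canonical per-cell parameter table: wave, gender, age_group, mu, ls_intercept
config_cells <- function(config) {
  cells <- expand_cells(config$waves)
  cells <- dplyr::left_join(cells, config$mu,
                            by = c("wave", "gender", "age_group"))
  if (is.data.frame(config$ls_intercept)) {
    cells <- dplyr::left_join(cells, config$ls_intercept,
                              by = c("wave", "gender", "age_group"))
  } else {
    cells$ls_intercept <- config$ls_intercept
  }
  cells
}

## ---- analytic expectations under the generative model ----

gauss_hermite <- function(n = 60) {
  key <- paste0("gh", n)
  if (is.null(the[[key]])) the[[key]] <- pracma::gaussHermite(n)
  the[[key]]
}

# E[sum of rescaled item scores | theta] under the graded-response model
expected_phc_given_theta <- function(theta, discriminations, thresholds) {
  out <- numeric(length(theta))
  for (nm in names(thresholds)) {
    a <- discriminations[[nm]]
    for (t in thresholds[[nm]]) out <- out + plogis(a * (theta - t))
  }
  out
}

#' Analytic expected PHC score of a cell
#'
#' Integrates the graded-response expectation over the marginal latent
#' distribution \eqn{N(\mu, \sigma_\theta^2 + \sigma_b^2)} by Gauss-Hermite
#' quadrature. Serves as the exact benchmark that generated cell means must
#' recover up to Monte Carlo error.
#'
#' @param mu Latent severity mean(s).
#' @param total_sd Marginal latent SD, `sqrt(sigma_theta^2 + cluster_sd^2)`.
#' @param discriminations,thresholds Item parameters as in
#'   [generator_config()].
#' @return Expected 0--16 PHC score, vectorised over `mu`.
#' @export
expected_phc <- function(mu, total_sd,
                         discriminations = c(
                           feeling_low = 1.3, irritability = 1.2,
                           nervousness = 1.1, sleep_difficulty = 1.0
                         ),
                         thresholds = default_item_thresholds()) {
  gh <- gauss_hermite(60)
  vapply(mu, function(m) {
    theta <- m + sqrt(2) * total_sd * gh$x
    sum(gh$w * expected_phc_given_theta(theta, discriminations, thresholds)) /
      sqrt(pi)
  }, numeric(1))
}

#' Analytic expected ladder score of a cell
#'
#' The pre-rounding ladder value is Normal with mean
#' `intercept - slope * mu` and SD `sqrt(slope^2 total_sd^2 + noise_sd^2)`;
#' after integer rounding and clipping to 0..10 the expectation has the
#' closed form \eqn{E[LS] = \sum_{v=1}^{10} P(L \ge v - 1/2)}.
#'
#' @param mu Latent severity mean(s).
#' @param total_sd Marginal latent SD.
#' @param intercept,slope,noise_sd Ladder model parameters as in
#'   [generator_config()].
#' @return Expected 0--10 ladder score, vectorised over `mu` (and
#'   `intercept`).
#' @export
expected_ls <- function(mu, total_sd, intercept, slope, noise_sd) {
  m <- intercept - slope * mu
  s <- sqrt(slope^2 * total_sd^2 + noise_sd^2)
  sapply(m, function(mm) sum(pnorm((mm - (1:10 - 0.5)) / s)))
}

## ---- packaged default configuration, calibrated to published targets ----

# Cell-level calibration targets: national HBSC estimates of mean PHC and
# mean LS for Italian adolescents by wave, gender and age group.
calibration_targets <- function() {
  tg <- expand_cells(hbsc_waves)
  phc <- c(
    # wave 2010: boys 11/13/15, girls 11/13/15
    5.1, 5.2, 5.7, 5.3, 6.6, 7.5,
    # 2014
    5.0, 5.3, 5.8, 5.5, 7.7, 8.6,
    # 2018
    5.9, 6.0, 6.4, 6.4, 8.2, 9.1
  )
  ls <- c(
    8.0, 7.7, 7.4, 8.1, 7.4, 6.9,
    7.9, 7.6, 7.2, 7.8, 7.0, 6.7,
    8.0, 7.7, 7.3, 8.0, 7.4, 6.9
  )
  tg$phc_target <- phc
  tg$ls_target <- ls
  tg
}

#' The packaged default generator configuration
#'
#' Returns a configuration whose per-cell latent means and ladder
#' intercepts are calibrated, by numerical root finding on the analytic
#' expectations ([expected_phc()], [expected_ls()]), so that every
#' (wave, gender, age) cell's expected PHC and LS equal the published
#' national estimates for Italian adolescents in the 2010/2014/2018 HBSC
#' waves (e.g. girls aged 15: PHC 7.5, 8.6, 9.1 and LS 6.9, 6.7, 6.9).
#' The target table is attached as `config$targets`.
#'
#' @param n_per_cell Respondents per cell (default 1000).
#' @param seed RNG seed stored in the configuration.
#' @return A calibrated `generator_config` with a `targets` element.
#' @export
default_config <- function(n_per_cell = 1000L, seed = 20101418L) {
  if (is.null(the$default_calibration)) {
    the$default_calibration <- calibrate_config(calibration_targets())
  }
  cal <- the$default_calibration
  config <- generator_config(
    n_per_cell = n_per_cell,
    mu = cal$mu,
    ls_intercept = cal$ls_intercept,
    seed = seed
  )
  config$targets <- cal$targets
  config
}

# Solve, cell by cell, for the latent mean hitting the PHC target and then
# the ladder intercept hitting the LS target. Both expectations are strictly
# monotone in the solved parameter, so uniroot is safe.
calibrate_config <- function(targets,
                             sigma_theta = 1, cluster_sd = 0.2,
                             discriminations = c(
                               feeling_low = 1.3, irritability = 1.2,
                               nervousness = 1.1, sleep_difficulty = 1.0
                             ),
                             thresholds = default_item_thresholds(),
                             ls_slope = 0.5, ls_noise_sd = 1.6) {
  total_sd <- sqrt(sigma_theta^2 + cluster_sd^2)
  mu <- vapply(targets$phc_target, function(tg) {
    uniroot(function(m) expected_phc(m, total_sd, discriminations,
                                     thresholds) - tg,
            interval = c(-6, 6), tol = 1e-10)$root
  }, numeric(1))
  ls_int <- mapply(function(m, tg) {
    uniroot(function(b) expected_ls(m, total_sd, b, ls_slope,
                                    ls_noise_sd) - tg,
            interval = c(-10, 25), tol = 1e-10)$root
  }, mu, targets$ls_target)
  mu_map <- targets[, c("wave", "gender", "age_group")]
  mu_map$mu <- mu
  int_map <- targets[, c("wave", "gender", "age_group")]
  int_map$ls_intercept <- ls_int
  list(mu = mu_map, ls_intercept = int_map, targets = targets)
}

## ---- configuration serialization (flat YAML) ----

#' Write a generator configuration to a YAML file
#'
#' @param config A `generator_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  validate_config(config)
  x <- unclass(config)
  x$item_discriminations <- as.list(x$item_discriminations)
  x$mu <- as.list(as.data.frame(x$mu))
  if (is.data.frame(x$ls_intercept)) {
    x$ls_intercept <- as.list(as.data.frame(x$ls_intercept))
  }
  if (!is.null(x$targets)) x$targets <- as.list(as.data.frame(x$targets))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a generator configuration from a YAML file
#'
#' @param path Path to a file written by [write_generator_config()].
#' @return A validated `generator_config`.
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  as_cell_df <- function(l) {
    d <- tibble::as_tibble(lapply(l, unlist))
    d$age_group <- as.integer(d$age_group)
    d$wave <- as.character(d$wave)
    d
  }
  x$mu <- as_cell_df(x$mu)
  if (is.list(x$ls_intercept) && !is.null(x$ls_intercept$wave)) {
    x$ls_intercept <- as_cell_df(x$ls_intercept)
  }
  x$item_discriminations <- unlist(x$item_discriminations)[item_names]
  x$item_thresholds <- lapply(x$item_thresholds, unlist)[item_names]
  targets <- if (!is.null(x$targets)) as_cell_df(x$targets)
  config <- generator_config(
    n_per_cell = x$n_per_cell, mu = x$mu, waves = x$waves,
    sigma_theta = x$sigma_theta,
    item_discriminations = x$item_discriminations,
    item_thresholds = x$item_thresholds,
    ls_intercept = x$ls_intercept, ls_slope = x$ls_slope,
    ls_noise_sd = x$ls_noise_sd, n_strata = x$n_strata,
    clusters_per_stratum = x$clusters_per_stratum,
    cluster_sd = x$cluster_sd, weight_cv = x$weight_cv, seed = x$seed
  )
  if (!is.null(targets)) config$targets <- targets
  config
}
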