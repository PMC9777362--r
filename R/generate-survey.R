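#' Generate a synthetic HBSC-like survey
#'
#' Draws `n_per_cell` respondents for every (wave, gender, age) cell of the
#' configuration. Within each wave and age group, respondents are spread
#' over `n_strata * clusters_per_stratum` school classes in near-equal
#' blocks; boys and girls of a cell share classes, and every class carries
#' a common latent random effect, which induces a positive intraclass
#' correlation in the symptom scores. Item responses come from the logistic
#' graded-response model, the ladder score from the rounded/clipped linear
#' map, and design weights are i.i.d. lognormal normalised to mean 1 within
#' each wave. Output is fully deterministic given the configuration
#' (including its `seed`); the global RNG state is left untouched.
#'
#' @param config A valid [generator_config()].
#' @return A tibble with one row per respondent and columns
#'   `respondent_id`, `wave`, `age_group`, `gender`, `stratum`, `cluster`,
#'   `weight`, the four item columns (original 1..5 codes, 1 = "about
#'   every day" ... 5 = "rarely/never"), and `ls` (0..10 ladder score).
#' @export
generate_survey <- function(config) {
  validate_config(config)
  withr::with_seed(config$seed, generate_survey_impl(config))
}

generate_survey_impl <- function(config) {
  cells <- config_cells(config)
  n <- config$n_per_cell
  n_cells <- nrow(cells)
  n_clusters <- config$n_strata * config$clusters_per_stratum

  df <- cells[rep(seq_len(n_cells), each = n), ]
  df$within_id <- rep(seq_len(n), times = n_cells)

  # contiguous near-equal blocks of respondents per class, same layout in
  # every cell; classes are shared across genders within (wave, age)
  cluster_idx <- sort(rep_len(seq_len(n_clusters), n))
  df$cluster_idx <- rep(cluster_idx, times = n_cells)
  stratum_idx <- (df$cluster_idx - 1L) %/% config$clusters_per_stratum + 1L
  df$stratum <- sprintf("%s-s%02d", df$wave, stratum_idx)
  df$cluster <- sprintf("%s-a%d-s%02d-c%03d", df$wave, df$age_group,
                        stratum_idx, df$cluster_idx)

  # class random effects, one draw per distinct class
  eff <- unique(df[, c("wave", "age_group", "cluster")])
  eff$cluster_eff <- rnorm(nrow(eff), 0, config$cluster_sd)
  df <- dplyr::left_join(df, eff, by = c("wave", "age_group", "cluster"))

  n_total <- nrow(df)
  theta <- df$mu + df$cluster_eff + rnorm(n_total, 0, config$sigma_theta)

  # one uniform per item; S >= k iff u < P(S >= k), which couples the
  # cumulative probabilities monotonically
  for (nm in item_names) {
    a <- config$item_discriminations[[nm]]
    t <- config$item_thresholds[[nm]]
    u <- runif(n_total)
    s <- (u < plogis(a * (theta - t[1]))) + (u < plogis(a * (theta - t[2]))) +
         (u < plogis(a * (theta - t[3]))) + (u < plogis(a * (theta - t[4])))
    df[[nm]] <- 5L - as.integer(s)
  }

  ls_star <- df$ls_intercept - config$ls_slope * theta +
    rnorm(n_total, 0, config$ls_noise_sd)
  df$ls <- as.integer(pmin(10, pmax(0, round(ls_star))))

  if (config$weight_cv > 0) {
    sdlog <- sqrt(log1p(config$weight_cv^2))
    w <- rlnorm(n_total, meanlog = 0, sdlog = sdlog)
    df$weight <- w / stats::ave(w, df$wave, FUN = mean)
  } else {
    df$weight <- rep(1, n_total)
  }

  df$respondent_id <- sprintf("%s-%s-%02d-%05d", df$wave, df$gender,
                              df$age_group, df$within_id)
  tibble::as_tibble(df[, c(
    "respondent_id", "wave", "age_group", "gender", "stratum", "cluster",
    "weight", item_names, "ls"
  )])
}

#' Set item responses and ladder scores missing at random
#'
#' Utility for exercising missing-data rules downstream: each of the four
#' item responses and the ladder score is independently blanked with the
#' given rate. The number and order of records is unchanged.
#'
#' @param records Respondent tibble as produced by [generate_survey()].
#' @param item_rate,ls_rate Missingness probabilities in \[0, 1\].
#' @param seed Integer RNG seed.
#' @return The records with missing values injected.
#' @export
inject_missingness <- function(records, item_rate, ls_rate, seed = 1L) {
  for (nm in c("item_rate", "ls_rate")) {
    r <- get(nm)
    if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r > 1) {
      stop(sprintf("'%s' must be a single probability in [0, 1]", nm),
           call. = FALSE)
    }
  }
  withr::with_seed(as.integer(seed), {
    n <- nrow(records)
    for (nm in item_names) {
      records[[nm]][runif(n) < item_rate] <- NA_integer_
    }
    records$ls[runif(n) < ls_rate] <- NA_integer_
  })
  records
}
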