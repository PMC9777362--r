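# compact generator configurations and fixtures shared across tests

one_wave_mu <- function(mu_values = c(0, 0.2, 0.4, 0.1, 0.5, 0.8),
                        wave = "2010") {
  m <- expand.grid(
    age_group = c(11L, 13L, 15L), gender = c("boy", "girl"),
    wave = wave, stringsAsFactors = FALSE
  )[, c("wave", "gender", "age_group")]
  m$mu <- mu_values
  m
}

small_config <- function(n_per_cell = 200, seed = 1, mu = one_wave_mu(),
                         n_strata = 3, clusters_per_stratum = 4, ...) {
  generator_config(
    n_per_cell = n_per_cell, mu = mu, waves = "2010",
    n_strata = n_strata, clusters_per_stratum = clusters_per_stratum,
    seed = seed, ...
  )
}

# all 625 complete response patterns of the four 1..5 items
all_item_patterns <- function() {
  expand.grid(
    feeling_low = 1:5, irritability = 1:5,
    nervousness = 1:5, sleep_difficulty = 1:5
  )
}

# random ROC datasets with both classes guaranteed
random_roc_data <- function(n) {
  scores <- sample(0:16, n, replace = TRUE)
  labels <- runif(n) < 0.4
  if (!any(labels)) labels[1] <- TRUE
  if (all(labels)) labels[1] <- FALSE
  list(scores = scores, labels = labels)
}
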