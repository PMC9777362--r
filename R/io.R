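respondent_schema <- function() {
  c("respondent_id", "wave", "age_group", "gender", "stratum", "cluster",
    "weight", item_names, "ls")
}

#' Read a respondent-level CSV
#'
#' Reads the canonical respondent schema (`respondent_id, wave,
#' age_group, gender, stratum, cluster, weight, feeling_low,
#' irritability, nervousness, sleep_difficulty, ls`; missing encoded as
#' an empty field), preserving row order. Item codes outside 1..5 and
#' ladder values outside 0..10 are set missing with one warning per
#' column reporting the count; a missing required column or an
#' unparseable row is an error naming the column or line.
#'
#' @param path Path to the CSV file.
#' @return Respondent tibble.
#' @export
read_respondents <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  missing_cols <- setdiff(respondent_schema(), header)
  if (length(missing_cols) > 0) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  types <- readr::cols(
    respondent_id = readr::col_character(),
    wave = readr::col_character(),
    age_group = readr::col_integer(),
    gender = readr::col_character(),
    stratum = readr::col_character(),
    cluster = readr::col_character(),
    weight = readr::col_double(),
    feeling_low = readr::col_integer(),
    irritability = readr::col_integer(),
    nervousness = readr::col_integer(),
    sleep_difficulty = readr::col_integer(),
    ls = readr::col_integer(),
    .default = readr::col_guess()
  )
  data <- readr::read_csv(path, col_types = types, na = c("", "NA"),
                          progress = FALSE)
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    stop(sprintf("unparseable value at line %d, column %d (expected %s)",
                 probs$row[1], probs$col[1], probs$expected[1]),
         call. = FALSE)
  }
  for (nm in item_names) {
    bad <- !is.na(data[[nm]]) & (data[[nm]] < 1L | data[[nm]] > 5L)
    if (any(bad)) {
      warning(sprintf("%d value(s) in '%s' outside 1..5 set to missing",
                      sum(bad), nm), call. = FALSE)
      data[[nm]][bad] <- NA_integer_
    }
  }
  bad_ls <- !is.na(data$ls) & (data$ls < 0L | data$ls > 10L)
  if (any(bad_ls)) {
    warning(sprintf("%d value(s) in 'ls' outside 0..10 set to missing",
                    sum(bad_ls)), call. = FALSE)
    data$ls[bad_ls] <- NA_integer_
  }
  if (any(!is.na(data$weight) & data$weight <= 0)) {
    stop("non-positive design weight(s) found", call. = FALSE)
  }
  data
}

#' Write a respondent-level CSV
#'
#' Writes the canonical schema with missing values encoded as empty
#' fields; byte-identical output for identical input.
#'
#' @param data Respondent tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_respondents <- function(data, path) {
  readr::write_csv(data, path, na = "", progress = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' Exactly one of `generator` (a [generator_config()]) or `input_csv`
#' must be supplied. The pipeline seed drives generation (it overrides
#' the generator's stored seed) and the bootstrap; it is required when
#' generating.
#'
#' @param generator Optional [generator_config()].
#' @param input_csv Optional path to an existing respondent CSV.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; required with a generator.
#' @param cutoffs A [cutoff_pair()] used for classification and trends.
#' @param design A [survey_design()].
#' @param roc_weighted Apply design weights in the ROC sweep?
#' @param selection_rule Cutoff selection rule (`"youden"` or
#'   `"corner"`).
#' @param n_boot Bootstrap resamples for the AUC CI.
#' @param min_items Minimum answered items for a PHC score.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, input_csv = NULL, out_dir,
                            seed = NULL, cutoffs = cutoff_pair(),
                            design = survey_design(), roc_weighted = FALSE,
                            selection_rule = "youden", n_boot = 500L,
                            min_items = 4L) {
  if (is.null(generator) == is.null(input_csv)) {
    stop("supply exactly one of 'generator' or 'input_csv'", call. = FALSE)
  }
  if (!is.null(generator)) {
    validate_config(generator)
    if (is.null(seed)) {
      stop("'seed' is required when generating data", call. = FALSE)
    }
  }
  if (is.null(seed)) seed <- 1L
  structure(
    list(generator = generator, input_csv = input_csv, out_dir = out_dir,
         seed = as.integer(seed), cutoffs = cutoffs, design = design,
         roc_weighted = isTRUE(roc_weighted),
         selection_rule = selection_rule, n_boot = as.integer(n_boot),
         min_items = as.integer(min_items)),
    class = "pipeline_config"
  )
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full dual-factor analysis pipeline
#'
#' Executes simulate/read, score, calibrate, classify, estimate and
#' trends in sequence, writing every intermediate product plus a
#' manifest recording the seed and every convention in force, so each
#' number in the outputs is reproducible. Identical configuration and
#' seed give byte-identical outputs. Any stage failure aborts with the
#' stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("expected a 'pipeline_config' object", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  respondents <- stage("simulate", {
    if (!is.null(config$generator)) {
      gen <- config$generator
      gen$seed <- config$seed
      d <- generate_survey(gen)
    } else {
      d <- read_respondents(config$input_csv)
    }
    write_respondents(d, out("respondents.csv"))
    d
  })

  scored <- stage("score", {
    d <- score_respondents(respondents, min_items = config$min_items)
    write_respondents(d, out("scored.csv"))
    d
  })

  calibration <- stage("calibrate", {
    w <- if (config$roc_weighted) scored[[config$design$weight]]
    curve <- roc_curve(scored$phc, scored$gold, w)
    sel <- select_cutoff(curve, rule = config$selection_rule)
    ci <- auc_ci(scored$phc, scored$gold, w,
                 cluster = scored[[config$design$cluster]],
                 n_boot = config$n_boot, seed = config$seed + 1L)
    report <- list(
      threshold_table = data.frame(
        threshold = curve$thresholds,
        sensitivity = curve$sensitivity,
        specificity = curve$specificity
      ),
      auc = curve$auc, auc_ci = ci,
      n_pos = curve$n_pos, n_neg = curve$n_neg,
      cutoff = sel$cutoff,
      sensitivity = sel$sensitivity, sensitivity_ci = sel$sensitivity_ci,
      specificity = sel$specificity, specificity_ci = sel$specificity_ci,
      selection_rule = sel$selection_rule,
      weighted = config$roc_weighted
    )
    write_report_json(report, out("calibration.json"))
    report
  })

  classified <- stage("classify", {
    d <- scored
    d$quadrant <- classify_quadrant(d$ls_valid, d$phc, config$cutoffs)
    readr::write_csv(d, out("classified.csv"), na = "", progress = FALSE)
    summary <- quadrant_distribution(d, config$cutoffs, config$design)
    readr::write_csv(summary, out("quadrant_summary.csv"), na = "",
                     progress = FALSE)
    list(data = d, summary = summary)
  })

  estimates <- stage("estimate", {
    est <- dplyr::bind_rows(
      group_estimates(scored, "phc", config$design),
      group_estimates(scored, "ls", config$design)
    )
    readr::write_csv(est, out("estimates.csv"), na = "", progress = FALSE)
    est
  })

  trends <- stage("trends", {
    tr <- build_trajectories(estimates, config$cutoffs)
    readr::write_csv(tr$points, out("trajectories.csv"), na = "",
                     progress = FALSE)
    write_report_json(
      list(
        points = as.data.frame(lapply(tr$points, function(x)
          if (is.factor(x)) as.character(x) else x)),
        jumps = as.data.frame(lapply(tr$jumps, function(x)
          if (is.factor(x)) as.character(x) else x)),
        wave_order = tr$wave_order
      ),
      out("trajectories.json")
    )
    tr
  })

  manifest <- stage("manifest", {
    m <- list(
      package = "dualfactor",
      version = as.character(utils::packageVersion("dualfactor")),
      seed = config$seed,
      input = if (is.null(config$input_csv)) "generated"
              else config$input_csv,
      n_respondents = nrow(respondents),
      conventions = list(
        ls_cutoff = config$cutoffs$ls_cutoff,
        phc_cutoff = config$cutoffs$phc_cutoff,
        ls_inclusive = config$cutoffs$ls_inclusive,
        phc_inclusive = config$cutoffs$phc_inclusive,
        test_positive = "score >= threshold",
        selection_rule = config$selection_rule,
        roc_weighted = config$roc_weighted,
        lonely_psu = config$design$lonely_psu,
        ci = "normal, estimate +/- 1.96 SE",
        variance = "Taylor linearization, with-replacement PSUs, no FPC",
        min_items = config$min_items,
        n_boot = config$n_boot
      ),
      outputs = c("respondents.csv", "scored.csv", "calibration.json",
                  "classified.csv", "quadrant_summary.csv",
                  "estimates.csv", "trajectories.csv",
                  "trajectories.json", "manifest.json")
    )
    write_report_json(m, out("manifest.json"))
    m
  })

  invisible(list(
    respondents = respondents, scored = scored, calibration = calibration,
    classified = classified, estimates = estimates, trends = trends,
    manifest = manifest
  ))
}
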