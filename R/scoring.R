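#' Reverse and rescale an original item response code
#'
#' The questionnaire codes symptom frequency from 1 ("about every day") to
#' 5 ("rarely/never"). Analysis uses the reversed, 0-based scale where
#' higher means more frequent complaints: 5 -> 0, 4 -> 1, 3 -> 2, 2 -> 3,
#' 1 -> 4. The mapping is the bijection `rescaled = 5 - code`.
#'
#' @param code Integer vector of original codes in 1..5; `NA` passes
#'   through.
#' @return Integer vector of rescaled 0..4 scores.
#' @export
rescale_item <- function(code) {
  if (!is.numeric(code) && !all(is.na(code))) {
    stop("item response codes must be numeric", call. = FALSE)
  }
  code <- as.numeric(code)
  bad <- !is.na(code) & (code %% 1 != 0 | code < 1 | code > 5)
  if (any(bad)) {
    stop(sprintf("item response code(s) outside 1..5: %s",
                 paste(unique(code[bad]), collapse = ", ")), call. = FALSE)
  }
  5L - as.integer(code)
}

#' Psychological health complaints (PHC) sum score
#'
#' Sums the four rescaled 0--4 item scores into the 0--16 PHC measure;
#' higher values indicate more numerous and more frequent psychological
#' complaints. Scoring is complete-case by default: the score is missing
#' unless all `min_items` (default all 4) items are answered. With
#' `min_items < 4` the available-item mean is prorated to the 0--16 range
#' (`4 * mean(rescaled)`), which can be non-integer.
#'
#' @param feeling_low,irritability,nervousness,sleep_difficulty Original
#'   1..5 response codes (vectors of equal length; `NA` allowed).
#' @param min_items Minimum number of answered items required for a score.
#' @return A tibble with columns `value` (PHC score or `NA`) and
#'   `n_items_used`.
#' @export
phc_score <- function(feeling_low, irritability, nervousness,
                      sleep_difficulty, min_items = 4L) {
  if (min_items < 1 || min_items > 4) {
    stop("'min_items' must be between 1 and 4", call. = FALSE)
  }
  m <- cbind(rescale_item(feeling_low), rescale_item(irritability),
             rescale_item(nervousness), rescale_item(sleep_difficulty))
  n_used <- rowSums(!is.na(m))
  value <- 4 * rowMeans(m, na.rm = TRUE)
  value[n_used < min_items] <- NA_real_
  value[n_used == 0] <- NA_real_
  tibble::tibble(value = value, n_items_used = as.integer(n_used))
}

#' Gold-standard multiple-complaints label
#'
#' The dichotomous criterion used to calibrate the continuous PHC cutoff:
#' positive when the respondent reports at least two of the four symptoms
#' "more than once a week" or more often, i.e. at least two original codes
#' <= 2 (rescaled scores >= 3). Missing whenever any item is missing.
#'
#' @inheritParams phc_score
#' @return Logical vector (`TRUE` = positive), `NA` where any item is
#'   missing.
#' @export
gold_standard <- function(feeling_low, irritability, nervousness,
                          sleep_difficulty) {
  m <- cbind(rescale_item(feeling_low), rescale_item(irritability),
             rescale_item(nervousness), rescale_item(sleep_difficulty))
  out <- rowSums(m >= 3) >= 2
  out[rowSums(is.na(m)) > 0] <- NA
  out
}

#' Validate raw Cantril ladder responses
#'
#' Keeps integer values 0..10 (0 = worst possible life, 10 = best
#' possible life); anything else becomes missing, with a single warning
#' reporting how many values were dropped.
#'
#' @param raw Vector of raw responses (numeric or character).
#' @return Integer vector with invalid entries set to `NA`.
#' @export
validate_ls <- function(raw) {
  x <- suppressWarnings(as.numeric(as.character(raw)))
  valid <- !is.na(x) & x %% 1 == 0 & x >= 0 & x <= 10
  n_invalid <- sum(!valid & !is.na(raw) & !(as.character(raw) %in% ""))
  if (n_invalid > 0) {
    warning(sprintf("%d ladder response(s) outside 0..10 set to missing",
                    n_invalid), call. = FALSE)
  }
  out <- rep(NA_integer_, length(x))
  out[valid] <- as.integer(x[valid])
  out
}

#' Score a respondent table
#'
#' Appends the analysis variables to a respondent-level table: `phc`
#' (0--16 sum score), `n_items_used`, `gold` (gold-standard label) and
#' `ls_valid` (validated ladder score).
#'
#' @param data Respondent tibble with the four item columns and `ls`.
#' @param min_items Passed to [phc_score()].
#' @return `data` with the four scoring columns appended.
#' @export
score_respondents <- function(data, min_items = 4L) {
  missing_cols <- setdiff(c(item_names, "ls"), names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("scoring requires column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  sc <- phc_score(data$feeling_low, data$irritability, data$nervousness,
                  data$sleep_difficulty, min_items = min_items)
  data$phc <- sc$value
  data$n_items_used <- sc$n_items_used
  data$gold <- gold_standard(data$feeling_low, data$irritability,
                             data$nervousness, data$sleep_difficulty)
  data$ls_valid <- validate_ls(data$ls)
  data
}
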