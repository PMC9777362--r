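#' Dual-factor cutoff pair
#'
#' The two thresholds that split the (life satisfaction, PHC) plane into
#' the four dual-factor states. Defaults follow the HBSC protocol value
#' for the ladder (6) and the ROC-calibrated PHC value (8). The boundary
#' conventions are explicit: with `ls_inclusive = TRUE`, "high LS" means
#' `ls >= ls_cutoff` (and analogously for PHC), so a point exactly at
#' (6, 8) is high on both axes.
#'
#' @param ls_cutoff Ladder threshold in \[0, 10\] (default 6).
#' @param phc_cutoff PHC threshold in \[0, 16\] (default 8).
#' @param ls_inclusive,phc_inclusive Whether the cutoff value itself
#'   counts as "high" on each axis (default `TRUE`).
#' @return An object of class `cutoff_pair`.
#' @export
cutoff_pair <- function(ls_cutoff = 6, phc_cutoff = 8,
                        ls_inclusive = TRUE, phc_inclusive = TRUE) {
  if (!is.numeric(ls_cutoff) || length(ls_cutoff) != 1 ||
      is.na(ls_cutoff) || ls_cutoff < 0 || ls_cutoff > 10) {
    stop("'ls_cutoff' must be a number in [0, 10]", call. = FALSE)
  }
  if (!is.numeric(phc_cutoff) || length(phc_cutoff) != 1 ||
      is.na(phc_cutoff) || phc_cutoff < 0 || phc_cutoff > 16) {
    stop("'phc_cutoff' must be a number in [0, 16]", call. = FALSE)
  }
  structure(
    list(ls_cutoff = ls_cutoff, phc_cutoff = phc_cutoff,
         ls_inclusive = isTRUE(ls_inclusive),
         phc_inclusive = isTRUE(phc_inclusive)),
    class = "cutoff_pair"
  )
}

#' Classify (LS, PHC) pairs into the four dual-factor states
#'
#' High subjective well-being with low mental illness is Flourishing
#' (complete mental health); high well-being with high illness is
#' Struggling (incomplete mental illness); low well-being with low
#' illness is Languishing (incomplete mental health); low well-being with
#' high illness is Floundering (complete mental illness). Accepts
#' real-valued inputs so that group means can be placed in the same
#' frame as individual respondents.
#'
#' @param ls Life-satisfaction values (0..10 scale).
#' @param phc PHC values (0..16 scale).
#' @param cutoffs A [cutoff_pair()].
#' @return Factor with levels Flourishing, Struggling, Languishing,
#'   Floundering; `NA` where either input is missing.
#' @export
classify_quadrant <- function(ls, phc, cutoffs = cutoff_pair()) {
  if (!inherits(cutoffs, "cutoff_pair")) {
    stop("expected a 'cutoff_pair' object", call. = FALSE)
  }
  if (length(ls) != length(phc)) {
    stop("'ls' and 'phc' must have the same length", call. = FALSE)
  }
  high_ls <- if (cutoffs$ls_inclusive) ls >= cutoffs$ls_cutoff
             else ls > cutoffs$ls_cutoff
  high_phc <- if (cutoffs$phc_inclusive) phc >= cutoffs$phc_cutoff
              else phc > cutoffs$phc_cutoff
  lab <- rep(NA_character_, length(ls))
  ok <- !is.na(high_ls) & !is.na(high_phc)
  lab[ok & high_ls & !high_phc] <- "Flourishing"
  lab[ok & high_ls & high_phc] <- "Struggling"
  lab[ok & !high_ls & !high_phc] <- "Languishing"
  lab[ok & !high_ls & high_phc] <- "Floundering"
  factor(lab, levels = quadrant_levels)
}

#' Weighted quadrant distribution by group
#'
#' For every (wave, gender, age) cell, the weighted proportion of
#' classified respondents in each of the four states. Proportions sum to
#' one within a cell over the classified records. With a survey design,
#' standard errors come from the Taylor-linearised ratio estimator
#' applied to the state indicator.
#'
#' @param data Scored respondent tibble (needs `phc` and `ls_valid` or
#'   `ls` columns plus the grouping and design columns).
#' @param cutoffs A [cutoff_pair()].
#' @param design Optional [survey_design()] specification; when supplied,
#'   SEs and normal 95% CIs are attached.
#' @param by Grouping columns (default wave, gender, age group).
#' @return Tibble with one row per group x quadrant: `proportion`, `se`,
#'   `ci_lower`, `ci_upper`, `n` (classified records), `n_clusters`.
#' @export
quadrant_distribution <- function(data, cutoffs = cutoff_pair(),
                                  design = NULL,
                                  by = c("wave", "gender", "age_group")) {
  ls_col <- if ("ls_valid" %in% names(data)) "ls_valid" else "ls"
  if (!all(c("phc", ls_col) %in% names(data))) {
    stop("'data' must be scored (phc and ls columns)", call. = FALSE)
  }
  data$.quadrant <- classify_quadrant(data[[ls_col]], data$phc, cutoffs)
  w_col <- if (!is.null(design)) design$weight else "weight"
  if (!w_col %in% names(data)) data[[w_col]] <- 1

  groups <- dplyr::group_split(dplyr::group_by(
    data, dplyr::across(dplyr::all_of(by))
  ))
  res <- lapply(groups, function(g) {
    keys <- g[1, by, drop = FALSE]
    cls <- g[!is.na(g$.quadrant), ]
    out <- keys[rep(1, length(quadrant_levels)), , drop = FALSE]
    out$quadrant <- factor(quadrant_levels, levels = quadrant_levels)
    out$n <- nrow(cls)
    if (nrow(cls) == 0) {
      out$proportion <- NA_real_
      out$se <- NA_real_; out$ci_lower <- NA_real_; out$ci_upper <- NA_real_
      out$n_clusters <- 0L
      return(out)
    }
    w <- cls[[w_col]]
    est <- vapply(quadrant_levels, function(q) {
      weighted_mean(as.numeric(cls$.quadrant == q), w)
    }, numeric(1))
    out$proportion <- unname(est)
    if (!is.null(design)) {
      se <- vapply(quadrant_levels, function(q) {
        linearized_se(as.numeric(cls$.quadrant == q), w,
                      cls[[design$stratum]], cls[[design$cluster]],
                      lonely_psu = design$lonely_psu)
      }, numeric(1))
      out$se <- unname(se)
      out$ci_lower <- pmax(0, out$proportion - 1.96 * out$se)
      out$ci_upper <- pmin(1, out$proportion + 1.96 * out$se)
      out$n_clusters <- length(unique(cls[[design$cluster]]))
    } else {
      out$se <- NA_real_; out$ci_lower <- NA_real_; out$ci_upper <- NA_real_
      out$n_clusters <- length(unique(if ("cluster" %in% names(cls))
        cls$cluster else character(0)))
    }
    out
  })
  out <- dplyr::bind_rows(res)
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(by, "quadrant"))))
}
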