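#' Survey design specification
#'
#' Names the columns that carry the complex-sampling structure and fixes
#' how single-PSU strata are handled by the variance estimator.
#'
#' @param stratum,cluster,weight Column names in the respondent table.
#' @param lonely_psu `"adjust"` (default: centre a lone PSU at the grand
#'   mean), `"collapse"` (pool all single-PSU strata into one pseudo
#'   stratum) or `"fail"`.
#' @return An object of class `survey_design_spec`.
#' @export
survey_design <- function(stratum = "stratum", cluster = "cluster",
                          weight = "weight",
                          lonely_psu = c("adjust", "collapse", "fail")) {
  structure(
    list(stratum = stratum, cluster = cluster, weight = weight,
         lonely_psu = match.arg(lonely_psu)),
    class = "survey_design_spec"
  )
}

#' Weighted mean
#'
#' \eqn{\sum w_i y_i / \sum w_i} over the pairwise-complete observations.
#'
#' @param values Numeric vector (`NA` allowed).
#' @param weights Positive weights; `NULL` for equal weights.
#' @return The weighted mean, or `NA` (with a warning reporting the
#'   count of dropped values) when nothing is observed.
#' @export
weighted_mean <- function(values, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values)) {
    stop("'weights' must match 'values' in length", call. = FALSE)
  }
  keep <- !is.na(values) & !is.na(weights)
  if (!any(keep)) {
    warning(sprintf("all %d value(s) missing; estimate is NA",
                    length(values)), call. = FALSE)
    return(NA_real_)
  }
  sum(weights[keep] * values[keep]) / sum(weights[keep])
}

#' Taylor-linearised standard error of a weighted mean
#'
#' Design-based SE of the ratio estimator \eqn{\hat y = \sum w y / \sum w}
#' under stratified single-stage cluster sampling, treating PSUs
#' (clusters) as sampled with replacement within strata and applying no
#' finite-population correction. With per-PSU linearised totals
#' \eqn{z_{hj} = \sum_{i \in hj} w_i (y_i - \hat y) / \sum w},
#' \deqn{\widehat{Var} = \sum_h \frac{n_h}{n_h - 1}
#'   \sum_j (z_{hj} - \bar z_h)^2.}
#' In the degenerate design (one stratum, one respondent per cluster,
#' equal weights) this reduces exactly to the simple-random-sampling
#' \eqn{s/\sqrt{n}} formula, including the \eqn{n/(n-1)} convention.
#' Strata holding a single PSU are handled per `lonely_psu`: `"adjust"`
#' scores the lone PSU against the grand PSU mean, `"collapse"` pools all
#' lone strata into one pseudo stratum, `"fail"` raises an error.
#'
#' @param values Numeric outcome vector (`NA` dropped pairwise with its
#'   weight).
#' @param weights Positive design weights.
#' @param stratum,cluster Stratum and cluster identifiers per observation.
#' @param lonely_psu Single-PSU-stratum rule (see above).
#' @return The standard error (>= 0).
#' @export
linearized_se <- function(values, weights, stratum, cluster,
                          lonely_psu = c("adjust", "collapse", "fail")) {
  lonely_psu <- match.arg(lonely_psu)
  n <- length(values)
  stopifnot(length(weights) == n, length(stratum) == n, length(cluster) == n)
  keep <- !is.na(values) & !is.na(weights)
  y <- values[keep]; w <- weights[keep]
  st <- as.character(stratum[keep]); cl <- as.character(cluster[keep])
  psu <- paste(st, cl, sep = "\r")
  if (length(unique(psu)) < 2) {
    stop("degenerate design: fewer than 2 clusters", call. = FALSE)
  }
  W <- sum(w)
  yhat <- sum(w * y) / W
  u <- w * (y - yhat) / W
  z <- rowsum(u, psu, reorder = TRUE)[, 1]
  psu_stratum <- st[match(names(z), psu)]

  n_h <- table(psu_stratum)
  lone <- names(n_h)[n_h == 1]
  if (length(lone) > 0 && lonely_psu == "fail") {
    stop(sprintf("degenerate design: stratum with a single cluster (%s)",
                 paste(lone, collapse = ", ")), call. = FALSE)
  }
  if (length(lone) > 0 && lonely_psu == "collapse") {
    if (length(lone) < 2) {
      stop("cannot collapse a single lone-PSU stratum; use 'adjust'",
           call. = FALSE)
    }
    psu_stratum[psu_stratum %in% lone] <- ".collapsed"
    n_h <- table(psu_stratum)
    lone <- character(0)
  }

  v <- 0
  z_grand <- mean(z)
  for (h in names(n_h)) {
    zh <- z[psu_stratum == h]
    if (length(zh) == 1) {
      # lonely_psu == "adjust": score against the grand PSU mean
      v <- v + (zh - z_grand)^2
    } else {
      v <- v + length(zh) / (length(zh) - 1) * sum((zh - mean(zh))^2)
    }
  }
  sqrt(v)
}

#' Design-based group estimates
#'
#' One weighted mean with linearised SE and normal 95% CI
#' (estimate +/- 1.96 SE) per (wave, gender, age) cell, for either the
#' PHC score or the validated ladder score. Groups with no observed
#' values are reported with missing estimates; output rows are ordered by
#' wave, gender, age group.
#'
#' @param data Scored respondent tibble.
#' @param statistic `"phc"` or `"ls"`.
#' @param design A [survey_design()]; pass `NULL` for equal-weight,
#'   independence-based estimation (SE of the mean).
#' @param by Grouping columns.
#' @return Tibble with columns `statistic`, the group keys, `estimate`,
#'   `se`, `ci_lower`, `ci_upper`, `n` (non-missing values), `n_clusters`.
#' @export
group_estimates <- function(data, statistic = c("phc", "ls"),
                            design = survey_design(),
                            by = c("wave", "gender", "age_group")) {
  statistic <- match.arg(statistic)
  col <- if (statistic == "phc") "phc"
         else if ("ls_valid" %in% names(data)) "ls_valid" else "ls"
  if (!col %in% names(data)) {
    stop(sprintf("column '%s' not found; score the data first", col),
         call. = FALSE)
  }
  groups <- dplyr::group_split(dplyr::group_by(
    data, dplyr::across(dplyr::all_of(by))
  ))
  res <- lapply(groups, function(g) {
    out <- g[1, by, drop = FALSE]
    out$statistic <- statistic
    y <- g[[col]]
    n_obs <- sum(!is.na(y))
    out$n <- n_obs
    if (n_obs == 0) {
      out$estimate <- NA_real_; out$se <- NA_real_
      out$ci_lower <- NA_real_; out$ci_upper <- NA_real_
      out$n_clusters <- 0L
      return(out)
    }
    if (is.null(design)) {
      out$estimate <- mean(y, na.rm = TRUE)
      out$se <- sd(y[!is.na(y)]) / sqrt(n_obs)
      out$n_clusters <- NA_integer_
    } else {
      w <- g[[design$weight]]
      out$estimate <- weighted_mean(y, w)
      out$se <- tryCatch(
        linearized_se(y, w, g[[design$stratum]], g[[design$cluster]],
                      lonely_psu = design$lonely_psu),
        error = function(e) NA_real_
      )
      out$n_clusters <- length(unique(g[[design$cluster]][!is.na(y)]))
    }
    out$ci_lower <- out$estimate - 1.96 * out$se
    out$ci_upper <- out$estimate + 1.96 * out$se
    out
  })
  out <- dplyr::bind_rows(res)
  out <- out[, c("statistic", by, "estimate", "se", "ci_lower", "ci_upper",
                 "n", "n_clusters")]
  dplyr::arrange(out, dplyr::across(dplyr::all_of(by)))
}
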