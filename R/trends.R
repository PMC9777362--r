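#' Group trajectories through the dual-factor frame
#'
#' Places every gender-age group's per-wave (PHC mean, LS mean) point in
#' the dual-factor plane, classifies the mean points with the same cutoff
#' rule used for individuals, and records a "jump" wherever the state of
#' consecutive waves differs. A group missing a wave is emitted with a
#' gap and no jump is inferred across the gap.
#'
#' @param estimates Output of [group_estimates()] for both statistics
#'   (`"phc"` and `"ls"`), row-bound.
#' @param cutoffs A [cutoff_pair()].
#' @param wave_order Chronological wave order; defaults to the sorted
#'   unique waves present.
#' @return An object of class `dual_factor_trajectories`: a list with
#'   `points` (one row per group x wave with both means, their CIs and
#'   the quadrant of the mean point), `jumps` (one row per detected state
#'   change: group, wave_from, wave_to, quadrant_from, quadrant_to), the
#'   cutoffs and the wave order.
#' @export
build_trajectories <- function(estimates, cutoffs = cutoff_pair(),
                               wave_order = NULL) {
  needed <- c("statistic", "wave", "gender", "age_group", "estimate",
              "ci_lower", "ci_upper")
  if (!all(needed %in% names(estimates))) {
    stop(sprintf("'estimates' must have columns: %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  if (!all(c("phc", "ls") %in% estimates$statistic)) {
    stop("'estimates' must contain both 'phc' and 'ls' statistics",
         call. = FALSE)
  }
  if (is.null(wave_order)) wave_order <- sort(unique(estimates$wave))

  pts <- tidyr::pivot_wider(
    estimates[, needed],
    names_from = "statistic",
    values_from = c("estimate", "ci_lower", "ci_upper")
  )
  pts <- dplyr::rename(pts,
    phc_mean = "estimate_phc", ls_mean = "estimate_ls",
    phc_ci_lower = "ci_lower_phc", phc_ci_upper = "ci_upper_phc",
    ls_ci_lower = "ci_lower_ls", ls_ci_upper = "ci_upper_ls"
  )
  pts$wave_index <- match(pts$wave, wave_order)
  pts$quadrant <- classify_quadrant(pts$ls_mean, pts$phc_mean, cutoffs)
  pts <- dplyr::arrange(pts, .data$gender, .data$age_group, .data$wave_index)
  pts <- pts[, c("gender", "age_group", "wave", "wave_index", "phc_mean",
                 "phc_ci_lower", "phc_ci_upper", "ls_mean", "ls_ci_lower",
                 "ls_ci_upper", "quadrant")]

  jumps <- dplyr::bind_rows(lapply(
    dplyr::group_split(dplyr::group_by(pts, .data$gender, .data$age_group)),
    function(g) {
      g <- g[order(g$wave_index), ]
      if (nrow(g) < 2) return(NULL)
      a <- g[-nrow(g), ]; b <- g[-1, ]
      consecutive <- b$wave_index - a$wave_index == 1
      changed <- consecutive & !is.na(a$quadrant) & !is.na(b$quadrant) &
        a$quadrant != b$quadrant
      if (!any(changed)) return(NULL)
      tibble::tibble(
        gender = a$gender[changed], age_group = a$age_group[changed],
        wave_from = a$wave[changed], wave_to = b$wave[changed],
        quadrant_from = a$quadrant[changed],
        quadrant_to = b$quadrant[changed]
      )
    }
  ))
  if (nrow(jumps) == 0) {
    jumps <- tibble::tibble(
      gender = character(0), age_group = integer(0),
      wave_from = character(0), wave_to = character(0),
      quadrant_from = factor(character(0), levels = quadrant_levels),
      quadrant_to = factor(character(0), levels = quadrant_levels)
    )
  }
  structure(
    list(points = pts, jumps = jumps, cutoffs = cutoffs,
         wave_order = wave_order),
    class = "dual_factor_trajectories"
  )
}

#' @export
print.dual_factor_trajectories <- function(x, ...) {
  cat(sprintf("Dual-factor trajectories: %d group-wave points, %d jump(s)\n",
              nrow(x$points), nrow(x$jumps)))
  if (nrow(x$jumps) > 0) print(x$jumps)
  invisible(x)
}

#' Between-wave shift in group means
#'
#' Difference (wave_b minus wave_a) of the weighted group means, for each
#' gender-age group and statistic present. Waves are repeated
#' cross-sections and treated as independent, so the SE of the difference
#' is \eqn{\sqrt{SE_a^2 + SE_b^2}}; CIs are normal.
#'
#' @param estimates Output of [group_estimates()] (one or both
#'   statistics).
#' @param wave_a,wave_b The two wave labels to compare.
#' @return Tibble with one row per group x statistic: `shift`, `se`,
#'   `ci_lower`, `ci_upper`.
#' @export
mean_shift <- function(estimates, wave_a, wave_b) {
  for (wv in c(wave_a, wave_b)) {
    if (!wv %in% estimates$wave) {
      stop(sprintf("wave '%s' not present in the estimates", wv),
           call. = FALSE)
    }
  }
  a <- estimates[estimates$wave == wave_a, ]
  b <- estimates[estimates$wave == wave_b, ]
  m <- dplyr::inner_join(
    a[, c("statistic", "gender", "age_group", "estimate", "se")],
    b[, c("statistic", "gender", "age_group", "estimate", "se")],
    by = c("statistic", "gender", "age_group"), suffix = c("_a", "_b")
  )
  tibble::tibble(
    statistic = m$statistic, gender = m$gender, age_group = m$age_group,
    wave_from = wave_a, wave_to = wave_b,
    shift = m$estimate_b - m$estimate_a,
    se = sqrt(m$se_a^2 + m$se_b^2),
    ci_lower = m$estimate_b - m$estimate_a -
      1.96 * sqrt(m$se_a^2 + m$se_b^2),
    ci_upper = m$estimate_b - m$estimate_a +
      1.96 * sqrt(m$se_a^2 + m$se_b^2)
  )
}
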