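#' Scaled median absolute deviation
#'
#' Robust spread estimate: `1.4826 * median(|x - median(x)|)`. The factor
#' 1.4826 makes the estimator consistent for the standard deviation under
#' normality.
#'
#' @param values non-empty numeric vector.
#' @return The scaled MAD.
#' @export
scaled_mad <- function(values) {
  if (length(values) == 0) stop("scaled_mad of empty vector", call. = FALSE)
  stats::mad(values, constant = 1.4826)
}

#' Relative median or mean difference between diagnostic groups
#'
#' The percent difference of the amyloid-positive group relative to the
#' amyloid-negative group:
#' `100 * (center(pos) - center(neg)) / center(neg)`.
#'
#' @param pos,neg numeric vectors for the Abeta-positive and Abeta-negative
#'   groups (non-empty).
#' @param center `"median"` or `"mean"`.
#' @return Percent difference (unrounded).
#' @export
relative_difference <- function(pos, neg, center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  f <- if (center == "median") median else mean
  cn <- f(neg)
  if (cn == 0) stop("relative difference undefined: center(neg) = 0",
                    call. = FALSE)
  100 * (f(pos) - cn) / cn
}

#' Cohen's d (pooled SD, negative-minus-positive orientation)
#'
#' Standardized mean difference `(mean(neg) - mean(pos)) / s_pooled` with
#' `s_pooled^2 = ((n_neg-1) s_neg^2 + (n_pos-1) s_pos^2) / (n_neg+n_pos-2)`.
#' The orientation gives d > 0 for markers that are lower in the
#' amyloid-positive group (the Abeta1-42/1-40 ratio) and d < 0 for markers
#' that are elevated (pTau181, the AT-term).
#'
#' @param pos,neg numeric vectors, each of length >= 2.
#' @param hedges_correction if `TRUE`, apply the Hedges small-sample factor
#'   `1 - 3/(4(n_neg+n_pos) - 9)`. Off by default.
#' @return Cohen's d.
#' @export
cohens_d <- function(pos, neg, hedges_correction = FALSE) {
  n_pos <- length(pos); n_neg <- length(neg)
  if (n_pos < 2 || n_neg < 2) {
    stop("cohens_d needs at least 2 observations per group", call. = FALSE)
  }
  sp2 <- ((n_neg - 1) * var(neg) + (n_pos - 1) * var(pos)) /
    (n_neg + n_pos - 2)
  if (sp2 <= 0) stop("cohens_d undefined: pooled SD is zero", call. = FALSE)
  d <- (mean(neg) - mean(pos)) / sqrt(sp2)
  if (hedges_correction) d <- d * (1 - 3 / (4 * (n_neg + n_pos) - 9))
  d
}

#' All three effect-size measures for one marker
#'
#' @param pos,neg numeric vectors for the two diagnostic groups.
#' @param hedges_correction passed to [cohens_d()].
#' @return An `effect_size_triple`: relative median difference (%), relative
#'   mean difference (%), Cohen's d, group sizes, and the d orientation tag.
#' @export
effect_size_triple <- function(pos, neg, hedges_correction = FALSE) {
  structure(list(
    median_diff_pct = relative_difference(pos, neg, "median"),
    mean_diff_pct = relative_difference(pos, neg, "mean"),
    cohens_d = cohens_d(pos, neg, hedges_correction),
    n_pos = length(pos), n_neg = length(neg),
    orientation = "neg_minus_pos_for_d"
  ), class = "effect_size_triple")
}

#' @export
print.effect_size_triple <- function(x, ...) {
  cat(sprintf(
    "effect sizes (n_neg = %d, n_pos = %d):\n  median diff: %.1f%%\n  mean diff:   %.1f%%\n  Cohen's d:  %.3f (neg - pos)\n",
    x$n_neg, x$n_pos, x$median_diff_pct, x$mean_diff_pct, x$cohens_d))
  invisible(x)
}

#' Derived biomarker scores for one measurement method
#'
#' Computes the plasma Abeta1-42/1-40 ratio and the combined amyloid/tau score
#' ("AT-term") `(Abeta1-40 / Abeta1-42) * pTau181`, which unites both marker
#' families so that a single cutpoint separates the diagnostic groups.
#'
#' @param ab40,ab42,ptau181 positive concentrations (pg/mL), vectorized.
#' @return list with `ab_ratio` and `at_term`.
#' @export
derive_panel <- function(ab40, ab42, ptau181) {
  if (any(c(ab40, ab42, ptau181) <= 0, na.rm = TRUE)) {
    stop("analyte concentrations must be strictly positive", call. = FALSE)
  }
  list(ab_ratio = ab42 / ab40, at_term = (ab40 / ab42) * ptau181)
}

#' Add derived ratio and AT-term columns to a cohort
#'
#' @param cohort a `cohort_table`.
#' @return The cohort with columns `direct_ratio`, `direct_at`, `ip_ratio`,
#'   `ip_at` appended.
#' @export
add_derived_panels <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  d <- derive_panel(cohort$direct_ab40, cohort$direct_ab42,
                    cohort$direct_ptau181)
  i <- derive_panel(cohort$ip_ab40, cohort$ip_ab42, cohort$ip_ptau181)
  cohort$direct_ratio <- d$ab_ratio
  cohort$direct_at <- d$at_term
  cohort$ip_ratio <- i$ab_ratio
  cohort$ip_at <- i$at_term
  cohort
}

#' Dilution accounting for the immunoprecipitation workflow
#'
#' Tracks how the IP workup dilutes the analyte relative to the plasma input:
#' a `plasma_volume` input yields an `eluate_volume` eluate that is topped up
#' with `diluent_added`; an `aliquot_taken` portion is then brought to
#' `aliquot_final` before measurement. At 100% analytical recovery the
#' measured concentration is
#' `(plasma_volume / (eluate_volume + diluent_added)) *
#'  (aliquot_taken / aliquot_final)` of the plasma concentration.
#'
#' For the Abeta workflow (200 uL plasma, 38 uL eluate + 190 uL diluent,
#' 60 uL diluted to 300 uL) this gives an overall ~5.7-fold dilution; for the
#' Tau workflow (400, 38 + 75, 50 to 250) the expected measured fraction is
#' 1/1.4 = 71%.
#'
#' @param plasma_volume,eluate_volume,diluent_added,aliquot_taken,aliquot_final
#'   volumes in microlitres, all strictly positive except `diluent_added`
#'   which may be zero.
#' @return list with `overall_factor` (fold dilution) and `expected_fraction`
#'   (percent of the plasma concentration expected at full recovery).
#' @export
dilution_factor <- function(plasma_volume, eluate_volume, diluent_added,
                            aliquot_taken, aliquot_final) {
  stopifnot(plasma_volume > 0, eluate_volume > 0, diluent_added >= 0,
            aliquot_taken > 0, aliquot_final > 0,
            aliquot_taken <= eluate_volume + diluent_added)
  rel <- (plasma_volume / (eluate_volume + diluent_added)) *
    (aliquot_taken / aliquot_final)
  list(overall_factor = 1 / rel, expected_fraction = 100 * rel)
}

# markers analysed group-wise in the effect table, in report order
.effect_table_vars <- function() {
  data.frame(
    variable = rep(c("ab40", "ab42", "ab_ratio", "ptau181", "at_term"), 2),
    method = rep(c("direct", "ip"), each = 5),
    stringsAsFactors = FALSE)
}

.marker_column <- function(variable, method) {
  switch(variable,
         ab40 = paste0(method, "_ab40"),
         ab42 = paste0(method, "_ab42"),
         ptau181 = paste0(method, "_ptau181"),
         ab_ratio = paste0(method, "_ratio"),
         at_term = paste0(method, "_at"),
         stop("unknown marker variable: ", variable, call. = FALSE))
}

#' Group-wise effect-size table for the full marker panel
#'
#' Per marker (Abeta1-40, Abeta1-42, Abeta1-42/1-40 ratio, pTau181, AT-term)
#' and method (direct plasma, IP eluate): median, mean and scaled MAD per
#' diagnostic group, a two-tailed Mann-Whitney p-value, the relative median
#' and mean differences (%) and Cohen's d.
#'
#' @param cohort a dichotomized `cohort_table`.
#' @return data frame with one row per marker x method.
#' @export
effect_table <- function(cohort) {
  cohort <- add_derived_panels(cohort)
  gs <- .group_split(cohort)
  spec <- .effect_table_vars()
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    col <- .marker_column(spec$variable[i], spec$method[i])
    xn <- gs$neg[[col]]; xp <- gs$pos[[col]]
    es <- effect_size_triple(xp, xn)
    data.frame(
      variable = spec$variable[i], method = spec$method[i],
      median_neg = median(xn), mean_neg = mean(xn), mad_neg = scaled_mad(xn),
      median_pos = median(xp), mean_pos = mean(xp), mad_pos = scaled_mad(xp),
      p_value = mann_whitney_test(xp, xn)$p_value,
      median_diff_pct = es$median_diff_pct,
      mean_diff_pct = es$mean_diff_pct,
      cohens_d = es$cohens_d,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
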