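#' @importFrom stats median mad sd var cov rnorm rlnorm runif
#'   pnorm dnorm uniroot wilcox.test fisher.test cor.test shapiro.test
#'   glm binomial coef complete.cases setNames
NULL

# Canonical per-subject fields. Concentrations are pg/mL; the ratio is
# dimensionless. direct_* are measurements in untreated EDTA plasma, ip_* in
# the immunoprecipitation eluate.
.mandatory_fields <- c(
  "subject_id", "age", "sex",
  "direct_ab40", "direct_ab42", "direct_ptau181",
  "ip_ab40", "ip_ab42", "ip_ptau181"
)
.optional_fields <- c(
  "apoe4_carrier", "csf_ab42", "csf_ab40", "csf_ttau", "csf_ptau181", "group"
)
.concentration_fields <- c(
  "direct_ab40", "direct_ab42", "direct_ptau181",
  "ip_ab40", "ip_ab42", "ip_ptau181",
  "csf_ab42", "csf_ab40", "csf_ttau", "csf_ptau181"
)

.group_levels <- c("abeta_neg", "abeta_pos")

#' Construct a cohort table
#'
#' A `cohort_table` is a validated data frame with one row per study subject,
#' holding the plasma analyte panel (Abeta1-40, Abeta1-42, pTau181) measured
#' by the two paired methods (direct plasma and IP eluate), optional CSF
#' analytes and covariates, and the diagnostic group label
#' (`abeta_neg`/`abeta_pos`).
#'
#' @param data data frame with canonical column names (see Details).
#' @param metadata named list of provenance information (source file or
#'   simulation config and seed) stored as an attribute.
#'
#' @details Mandatory columns: `subject_id`, `age`, `sex` (`"female"`/`"male"`)
#'   and the six plasma analytes `direct_ab40`, `direct_ab42`,
#'   `direct_ptau181`, `ip_ab40`, `ip_ab42`, `ip_ptau181`. Optional:
#'   `apoe4_carrier` (logical), `csf_ab42`, `csf_ab40`, `csf_ttau`,
#'   `csf_ptau181` (pg/mL) and `group`. All concentrations must be strictly
#'   positive where present and `subject_id` unique.
#'
#' @return An object of class `cohort_table` (a data frame).
#' @export
cohort_table <- function(data, metadata = list()) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(.mandatory_fields, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (anyDuplicated(data$subject_id)) {
    stop("duplicated subject_id in cohort", call. = FALSE)
  }
  data$sex <- as.character(data$sex)
  bad_sex <- !data$sex %in% c("female", "male")
  if (any(bad_sex)) {
    stop("invalid sex value(s) in row(s): ",
         paste(which(bad_sex), collapse = ", "), call. = FALSE)
  }
  for (f in intersect(.concentration_fields, names(data))) {
    v <- data[[f]]
    if (!is.numeric(v)) stop("column ", f, " is not numeric", call. = FALSE)
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0) {
      stop("validation error: non-positive ", f, " in row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(data$group)) {
    data$group <- as.character(data$group)
    bad <- !is.na(data$group) & !data$group %in% .group_levels
    if (any(bad)) {
      stop("invalid group label(s); expected abeta_neg/abeta_pos",
           call. = FALSE)
    }
  }
  structure(data,
            metadata = metadata,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  md <- attr(x, "metadata")
  cat("cohort_table:", nrow(x), "subjects\n")
  if (!is.null(x$group) && !all(is.na(x$group))) {
    tb <- table(factor(x$group, levels = .group_levels))
    cat("  groups: abeta_neg =", tb[["abeta_neg"]],
        ", abeta_pos =", tb[["abeta_pos"]], "\n")
  } else {
    cat("  groups: not assigned\n")
  }
  if (length(md) > 0) {
    cat("  metadata:", paste(names(md), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a cohort from a delimited text file
#'
#' Reads a comma-separated file (header row required, decimal point) into a
#' [cohort_table()]. Column names can be remapped through `schema`.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical field names
#'   to the column names used in the file, e.g.
#'   `c(direct_ab42 = "AB42_plasma")`. Unmapped canonical fields are looked up
#'   under their own names.
#' @return A `cohort_table`; `metadata` records the source path.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  canonical <- c(.mandatory_fields, .optional_fields)
  colmap <- setNames(canonical, canonical)
  if (!is.null(schema)) {
    stopifnot(!is.null(names(schema)))
    unknown <- setdiff(names(schema), canonical)
    if (length(unknown) > 0) {
      stop("schema maps unknown field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    colmap[names(schema)] <- unname(schema)
  }
  missing_mand <- .mandatory_fields[!colmap[.mandatory_fields] %in% names(raw)]
  if (length(missing_mand) > 0) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(colmap[missing_mand], collapse = ", "), call. = FALSE)
  }
  present <- canonical[colmap[canonical] %in% names(raw)]
  data <- raw[, colmap[present], drop = FALSE]
  names(data) <- present
  if ("apoe4_carrier" %in% names(data)) {
    data$apoe4_carrier <- as.logical(data$apoe4_carrier)
  }
  cohort_table(data, metadata = list(source = path))
}

#' Write a cohort to CSV (with a JSON metadata sidecar)
#'
#' Inverse of [read_cohort()]: writes the canonical columns to `path` and the
#' cohort metadata (provenance, simulation seed) to `<path>.meta.json`.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  md <- attr(cohort, "metadata")
  if (length(md) > 0) {
    jsonlite::write_json(md, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Dichotomize a cohort by the CSF Abeta42/40 ratio
#'
#' Assigns the diagnostic group from the CSF Abeta42/40 ratio: subjects with
#' ratio at or below `cutoff` are labelled `abeta_pos`, all others
#' `abeta_neg`. The clinical cutoff for amyloid positivity is 0.050; exact
#' equality counts as positive.
#'
#' @param cohort a `cohort_table` with `csf_ab42` and `csf_ab40` present for
#'   every subject.
#' @param cutoff positive ratio cutoff (default 0.050).
#' @return The cohort with `group` filled in.
#' @export
dichotomize_by_csf <- function(cohort, cutoff = 0.050) {
  stopifnot(inherits(cohort, "cohort_table"), cutoff > 0)
  miss <- is.na(cohort$csf_ab42) | is.na(cohort$csf_ab40) |
    is.null(cohort$csf_ab42) | is.null(cohort$csf_ab40)
  if (is.null(cohort$csf_ab42) || is.null(cohort$csf_ab40)) {
    stop("CSF Abeta42 and Abeta40 are required for dichotomization",
         call. = FALSE)
  }
  if (any(miss)) {
    stop("missing CSF value(s) for subject(s): ",
         paste(cohort$subject_id[miss], collapse = ", "), call. = FALSE)
  }
  ratio <- cohort$csf_ab42 / cohort$csf_ab40
  cohort$group <- ifelse(ratio <= cutoff, "abeta_pos", "abeta_neg")
  attr(cohort, "metadata")$dichotomized <- list(by = "csf_ab42/csf_ab40",
                                                cutoff = cutoff)
  cohort
}

#' Floor values at a limit of quantification
#'
#' Replaces every value below the limit of quantification by the limit itself
#' (the convention used for the one CSF pTau181 measurement below 15.6 pg/mL).
#' Idempotent and monotone.
#'
#' @param values numeric vector (may be empty; `NA`s pass through).
#' @param loq positive limit of quantification, same units as `values`.
#' @return list with `values` (floored vector) and `n_replaced`.
#' @export
apply_loq_floor <- function(values, loq = 15.6) {
  stopifnot(is.numeric(loq), length(loq) == 1, loq > 0)
  below <- !is.na(values) & values < loq
  values[below] <- loq
  list(values = values, n_replaced = sum(below))
}

.group_split <- function(cohort) {
  if (is.null(cohort$group) || any(is.na(cohort$group))) {
    stop("cohort groups are not assigned; run dichotomize_by_csf() first",
         call. = FALSE)
  }
  list(neg = cohort[cohort$group == "abeta_neg", , drop = FALSE],
       pos = cohort[cohort$group == "abeta_pos", , drop = FALSE])
}

#' Baseline summary of a dichotomized cohort
#'
#' Produces the baseline characteristics table: numeric variables as
#' median, mean and scaled MAD per group with a two-tailed Mann-Whitney test;
#' categorical variables as counts and percentages per group with a two-tailed
#' Fisher exact test. Percentages are rounded to 1 decimal, mirroring the
#' printed report style.
#'
#' @param cohort a dichotomized `cohort_table`.
#' @param variables character vector of cohort columns to summarize. Numeric
#'   columns are treated as continuous; character/logical/factor columns as
#'   categorical (one row per level; logicals report the `TRUE` level).
#' @return A `baseline_summary` data frame.
#' @export
summarize_baseline <- function(cohort, variables) {
  stopifnot(inherits(cohort, "cohort_table"))
  unknown <- setdiff(variables, names(cohort))
  if (length(unknown) > 0) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  gs <- .group_split(cohort)
  rows <- list()
  for (v in variables) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      keep <- !is.na(x)
      xn <- gs$neg[[v]][!is.na(gs$neg[[v]])]
      xp <- gs$pos[[v]][!is.na(gs$pos[[v]])]
      p <- mann_whitney_test(xp, xn)$p_value
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_, type = "numeric",
        n_all = sum(keep), n_neg = length(xn), n_pos = length(xp),
        median_all = median(x[keep]), mad_all = scaled_mad(x[keep]),
        mean_all = mean(x[keep]),
        median_neg = median(xn), mad_neg = scaled_mad(xn),
        mean_neg = mean(xn),
        median_pos = median(xp), mad_pos = scaled_mad(xp),
        mean_pos = mean(xp),
        count_all = NA_real_, percent_all = NA_real_,
        count_neg = NA_real_, percent_neg = NA_real_,
        count_pos = NA_real_, percent_pos = NA_real_,
        p_value = p, test = "mann_whitney",
        stringsAsFactors = FALSE)
    } else {
      xf <- if (is.logical(x)) factor(x, levels = c(FALSE, TRUE)) else factor(x)
      keep <- !is.na(xf)
      gneg <- cohort$group[keep] == "abeta_neg"
      tab <- table(xf[keep], factor(cohort$group[keep],
                                    levels = .group_levels))
      p <- if (nrow(tab) >= 2 && all(colSums(tab) > 0) &&
               all(rowSums(tab) > 0)) {
        fisher_exact_test(as.matrix(tab))
      } else NA_real_
      levs <- rownames(tab)
      if (is.logical(x)) levs <- "TRUE"
      for (lv in levs) {
        in_lv <- as.character(xf[keep]) == lv
        cn <- sum(in_lv & gneg); cp <- sum(in_lv & !gneg)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv, type = "categorical",
          n_all = sum(keep), n_neg = sum(gneg), n_pos = sum(!gneg),
          median_all = NA_real_, mad_all = NA_real_, mean_all = NA_real_,
          median_neg = NA_real_, mad_neg = NA_real_, mean_neg = NA_real_,
          median_pos = NA_real_, mad_pos = NA_real_, mean_pos = NA_real_,
          count_all = cn + cp,
          percent_all = round(100 * (cn + cp) / sum(keep), 1),
          count_neg = cn, percent_neg = round(100 * cn / sum(gneg), 1),
          count_pos = cp, percent_pos = round(100 * cp / sum(!gneg), 1),
          p_value = p, test = "fisher",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("baseline_summary", "data.frame")
  out
}
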