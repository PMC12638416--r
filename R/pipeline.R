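# End-to-end orchestration: baseline table, effect-size table, paired
# bootstrap tests, single-value ROC + Youden statistics, pairwise DeLong
# comparisons, cross-validated multivariate logistic models, mixture
# cutpoints and correlation/Deming analyses, assembled into one report.

#' Analysis configuration
#'
#' @param seed master seed; per-stage seeds are derived as
#'   `seed + stage offset` (bootstrap +1000, cross-validation +2000, mixture
#'   +3000) so one integer reproduces the whole run.
#' @param n_replicates bootstrap replications per comparison.
#' @param k cross-validation folds.
#' @param loq limit of quantification applied to CSF pTau181 (pg/mL).
#' @param csf_cutoff CSF Abeta42/40 dichotomization cutoff.
#' @param include_at_term include the AT-term rows/models.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(seed = 1L, n_replicates = 1000, k = 10,
                            loq = 15.6, csf_cutoff = 0.050,
                            include_at_term = TRUE) {
  structure(list(seed = as.integer(seed), n_replicates = n_replicates,
                 k = k, loq = loq, csf_cutoff = csf_cutoff,
                 include_at_term = include_at_term),
            class = "analysis_config")
}

.roc_markers <- function(include_at) {
  v <- c("ab_ratio", "ptau181", if (include_at) "at_term")
  expand.grid(variable = v, method = c("direct", "ip"),
              stringsAsFactors = FALSE)
}

#' Run the full diagnostic analysis on a cohort
#'
#' Executes, in order: baseline summary; derived panels (Abeta1-42/1-40
#' ratio, AT-term) for both methods; the group-wise effect-size table with
#' Mann-Whitney p-values; 0.632-bootstrap comparisons of Cohen's d
#' (direct vs IP) for the ratio, pTau181 and the AT-term; single-value ROC
#' with Youden-point classification for the six markers; pairwise DeLong
#' tests (direct vs IP per marker); cross-validated logistic models (IP
#' ratio alone, + IP pTau181, + ApoE4, all three, AT-term, AT-term + ApoE4);
#' mixture cutpoints for both ratio methods; and direct-vs-IP and CSF-plasma
#' correlations with Deming fits. Any stage failure aborts with a
#' stage-labelled error.
#'
#' @param cohort a `cohort_table`; if `group` is absent it is derived with
#'   [dichotomize_by_csf()].
#' @param config an [analysis_config()].
#' @return An `analysis_report` list; `provenance` records config, seeds,
#'   stage timings and package version.
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(config, "analysis_config"))
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  cohort <- stage("prepare", {
    if (is.null(cohort$group) || any(is.na(cohort$group))) {
      cohort <- dichotomize_by_csf(cohort, config$csf_cutoff)
    }
    if (!is.null(cohort$csf_ptau181)) {
      fl <- apply_loq_floor(cohort$csf_ptau181, config$loq)
      cohort$csf_ptau181 <- fl$values
    }
    add_derived_panels(cohort)
  })

  baseline <- stage("baseline", {
    vars <- intersect(c("age", "sex", "apoe4_carrier", "csf_ab42",
                        "csf_ab40", "csf_ttau", "csf_ptau181"),
                      names(cohort))
    vars <- vars[vapply(vars, function(v) !all(is.na(cohort[[v]])),
                        logical(1))]
    summarize_baseline(cohort, vars)
  })

  effects <- stage("effect_table", {
    tab <- effect_table(cohort)
    if (!config$include_at_term) tab <- tab[tab$variable != "at_term", ]
    tab
  })

  boot_markers <- c("ab_ratio", "ptau181",
                    if (config$include_at_term) "at_term")
  bootstrap_tests <- stage("bootstrap", {
    out <- lapply(seq_along(boot_markers), function(i) {
      v <- boot_markers[i]
      bootstrap_difference_test(
        cohort[[.marker_column(v, "direct")]],
        cohort[[.marker_column(v, "ip")]],
        cohort$group, estimator = "cohens_d",
        n_replicates = config$n_replicates,
        seed = config$seed + 1000L + i)
    })
    names(out) <- boot_markers
    out
  })

  roc_spec <- .roc_markers(config$include_at_term)
  rocs <- stage("roc", {
    out <- lapply(seq_len(nrow(roc_spec)), function(i) {
      col <- .marker_column(roc_spec$variable[i], roc_spec$method[i])
      roc <- empirical_roc_auc(cohort[[col]], cohort$group)
      list(variable = roc_spec$variable[i], method = roc_spec$method[i],
           roc = roc, youden = youden_classification(roc))
    })
    names(out) <- paste(roc_spec$variable, roc_spec$method, sep = "_")
    out
  })

  delong <- stage("delong", {
    out <- lapply(boot_markers, function(v) {
      delong_paired_test(cohort[[.marker_column(v, "direct")]],
                         cohort[[.marker_column(v, "ip")]],
                         cohort$group)
    })
    names(out) <- boot_markers
    out
  })

  multivariate <- stage("multivariate", {
    has_apoe <- !is.null(cohort$apoe4_carrier) &&
      !all(is.na(cohort$apoe4_carrier))
    models <- list(ratio_ip = c("ip_ratio"),
                   ratio_ptau_ip = c("ip_ratio", "ip_ptau181"))
    if (has_apoe) {
      models$ratio_apoe4 <- c("ip_ratio", "apoe4")
      models$ratio_ptau_apoe4 <- c("ip_ratio", "ip_ptau181", "apoe4")
    }
    if (config$include_at_term) {
      models$at_term_ip <- c("ip_at")
      if (has_apoe) models$at_term_apoe4 <- c("ip_at", "apoe4")
    }
    out <- vector("list", length(models))
    names(out) <- names(models)
    for (i in seq_along(models)) {
      feats <- models[[i]]
      df <- data.frame(row.names = seq_len(nrow(cohort)))
      for (f in feats) {
        df[[f]] <- if (f == "apoe4") as.numeric(cohort$apoe4_carrier) else
          cohort[[f]]
      }
      keep <- complete.cases(df)
      out[[i]] <- cv_logistic_scores(df[keep, , drop = FALSE],
                                     cohort$group[keep],
                                     k = config$k,
                                     seed = config$seed + 2000L + i)
      out[[i]]$features <- feats
      out[[i]]$n_used <- sum(keep)
    }
    out
  })

  cutpoints <- stage("cutpoints", {
    out <- lapply(c(direct = "direct_ratio", ip = "ip_ratio"), function(col) {
      fit <- fit_two_gaussian_equal_sd(cohort[[col]],
                                       seed = config$seed + 3000L)
      list(fit = fit, cutpoint = intersection_cutpoint(fit))
    })
    out
  })

  correlations <- stage("correlations", {
    pairs <- list(
      direct_vs_ip_ab40 = c("direct_ab40", "ip_ab40"),
      direct_vs_ip_ab42 = c("direct_ab42", "ip_ab42"),
      direct_vs_ip_ptau181 = c("direct_ptau181", "ip_ptau181"),
      direct_vs_ip_ratio = c("direct_ratio", "ip_ratio"))
    if (!is.null(cohort$csf_ab42) && !is.null(cohort$csf_ab40)) {
      cohort$csf_ratio <- cohort$csf_ab42 / cohort$csf_ab40
      pairs$csf_vs_direct_ratio <- c("csf_ratio", "direct_ratio")
      pairs$csf_vs_ip_ratio <- c("csf_ratio", "ip_ratio")
    }
    if (!is.null(cohort$csf_ptau181)) {
      pairs$csf_vs_direct_ptau181 <- c("csf_ptau181", "direct_ptau181")
      pairs$csf_vs_ip_ptau181 <- c("csf_ptau181", "ip_ptau181")
    }
    lapply(pairs, function(p) {
      x <- cohort[[p[1]]]; y <- cohort[[p[2]]]
      list(x = p[1], y = p[2],
           pearson = pearson_corr(x, y),
           deming = deming_regression(x, y))
    })
  })

  structure(list(
    baseline = baseline,
    effect_table = effects,
    bootstrap_tests = bootstrap_tests,
    roc_table = rocs,
    delong = delong,
    multivariate = multivariate,
    cutpoints = cutpoints,
    correlations = correlations,
    provenance = list(
      n = nrow(cohort),
      n_neg = sum(cohort$group == "abeta_neg"),
      n_pos = sum(cohort$group == "abeta_pos"),
      config = unclass(config),
      cohort_metadata = attr(cohort, "metadata"),
      timings = timings,
      package_version = as.character(utils::packageVersion("ipiadx")))
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report:", x$provenance$n, "subjects (",
      x$provenance$n_neg, "neg /", x$provenance$n_pos, "pos )\n")
  cat("  single-value ROC AUCs:\n")
  for (nm in names(x$roc_table)) {
    cat(sprintf("    %-18s %.3f\n", nm, x$roc_table[[nm]]$roc$auc))
  }
  cat("  bootstrap (Cohen's d, IP - direct) p-values:\n")
  for (nm in names(x$bootstrap_tests)) {
    cat(sprintf("    %-18s %.4g\n", nm, x$bootstrap_tests[[nm]]$p_value))
  }
  cat(sprintf("  mixture cutpoint (IP ratio): %.4g\n",
              x$cutpoints$ip$cutpoint))
  invisible(x)
}

.roc_table_df <- function(report) {
  rows <- lapply(names(report$roc_table), function(nm) {
    e <- report$roc_table[[nm]]
    y <- e$youden
    data.frame(variable = e$variable, method = e$method,
               auc = e$roc$auc, auc_se = e$roc$auc_se,
               ci_low = e$roc$ci95[1], ci_high = e$roc$ci95[2],
               tp = y$tp, tn = y$tn, fp = y$fp, fn = y$fn,
               ppv = y$ppv, npv = y$npv,
               sensitivity = y$sensitivity, specificity = y$specificity,
               accuracy = y$accuracy, threshold = y$threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.cv_table_df <- function(report) {
  rows <- lapply(names(report$multivariate), function(nm) {
    e <- report$multivariate[[nm]]
    y <- e$youden
    data.frame(model = nm, features = paste(e$features, collapse = "+"),
               n_used = e$n_used,
               auc = e$roc$auc, ci_low = e$roc$ci95[1],
               ci_high = e$roc$ci95[2],
               tp = y$tp, tn = y$tn, fp = y$fp, fn = y$fn,
               ppv = y$ppv, npv = y$npv,
               sensitivity = y$sensitivity, specificity = y$specificity,
               accuracy = y$accuracy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.report_json <- function(report) {
  rt <- report$roc_table
  list(
    provenance = report$provenance,
    bootstrap_tests = lapply(report$bootstrap_tests, function(b) {
      list(estimator = b$estimator, observed_diff = b$observed_diff,
           n_replicates = b$n_replicates, shapiro_p = b$shapiro_p,
           p_value = b$p_value, degenerate = b$degenerate, seed = b$seed)
    }),
    delong = lapply(report$delong, unclass),
    roc = lapply(rt, function(e) {
      list(variable = e$variable, method = e$method, auc = e$roc$auc,
           auc_se = e$roc$auc_se, ci95 = e$roc$ci95,
           direction = e$roc$direction,
           youden = unclass(e$youden))
    }),
    multivariate = lapply(report$multivariate, function(e) {
      list(features = e$features, n_used = e$n_used, auc = e$roc$auc,
           ci95 = e$roc$ci95, youden = unclass(e$youden))
    }),
    cutpoints = lapply(report$cutpoints, function(e) {
      f <- e$fit
      list(weight_1 = f$weight_1, weight_2 = f$weight_2,
           mean_1 = f$mean_1, mean_2 = f$mean_2,
           shared_sd = f$shared_sd, log_likelihood = f$log_likelihood,
           converged = f$converged, poorly_separated = f$poorly_separated,
           cutpoint = e$cutpoint)
    }),
    correlations = lapply(report$correlations, function(e) {
      list(x = e$x, y = e$y, rho = e$pearson$rho,
           p_value = e$pearson$p_value, n = e$pearson$n,
           deming_slope = e$deming$slope,
           deming_intercept = e$deming$intercept,
           lambda = e$deming$lambda)
    })
  )
}

#' Write an analysis report to disk
#'
#' Writes the table analogues as CSV (`table1.csv` baseline, `table2.csv`
#' effect sizes, `table3.csv` single-value ROC/Youden, `table4.csv`
#' cross-validated models), a JSON master report (`report.json`), plot-ready
#' ROC curve exports (`roc_curves.csv`) and a stage-timing log (`log.txt`).
#' Nothing is written until the output set is fully assembled; an existing
#' output file aborts the write unless `overwrite = TRUE`.
#'
#' @param report an `analysis_report`.
#' @param out_dir output directory (created if needed).
#' @param overwrite allow overwriting existing outputs.
#' @return Character vector of the written paths, invisibly.
#' @export
write_report <- function(report, out_dir, overwrite = FALSE) {
  stopifnot(inherits(report, "analysis_report"))
  files <- c("table1.csv", "table2.csv", "table3.csv", "table4.csv",
             "report.json", "roc_curves.csv", "log.txt")
  paths <- file.path(out_dir, files)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  existing <- paths[file.exists(paths)]
  if (length(existing) > 0 && !overwrite) {
    stop("refusing to overwrite existing output(s): ",
         paste(basename(existing), collapse = ", "),
         " (use overwrite = TRUE)", call. = FALSE)
  }
  # assemble everything before touching the filesystem
  t3 <- .roc_table_df(report)
  t4 <- .cv_table_df(report)
  js <- .report_json(report)
  curves <- do.call(rbind, lapply(names(report$roc_table), function(nm) {
    e <- report$roc_table[[nm]]
    data.frame(marker = nm, threshold = e$roc$thresholds,
               sensitivity = e$roc$sensitivity,
               specificity = e$roc$specificity,
               stringsAsFactors = FALSE)
  }))
  log_lines <- c(
    sprintf("ipiadx %s", report$provenance$package_version),
    sprintf("n = %d (neg %d / pos %d)", report$provenance$n,
            report$provenance$n_neg, report$provenance$n_pos),
    sprintf("master seed = %d", report$provenance$config$seed),
    vapply(names(report$provenance$timings), function(s)
      sprintf("stage %-14s %8.3f s", s, report$provenance$timings[[s]]),
      character(1)))

  utils::write.csv(as.data.frame(report$baseline), paths[1],
                   row.names = FALSE)
  utils::write.csv(report$effect_table, paths[2], row.names = FALSE)
  utils::write.csv(t3, paths[3], row.names = FALSE)
  utils::write.csv(t4, paths[4], row.names = FALSE)
  jsonlite::write_json(js, paths[5], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  utils::write.csv(curves, paths[6], row.names = FALSE)
  writeLines(log_lines, paths[7])
  invisible(paths)
}
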