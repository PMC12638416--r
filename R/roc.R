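# Empirical ROC analysis with DeLong variance components. Scores are
# oriented internally so that larger oriented scores indicate the
# amyloid-positive class; `direction` records the polarity on the original
# scale.

.as_pos_indicator <- function(groups) {
  if (is.logical(groups)) return(groups)
  if (is.numeric(groups)) return(groups != 0)
  groups <- as.character(groups)
  if (!all(groups %in% .group_levels)) {
    stop("groups must be abeta_neg/abeta_pos labels (or logical/0-1)",
         call. = FALSE)
  }
  groups == "abeta_pos"
}

# per-subject DeLong placement values for oriented scores
.delong_placements <- function(scores, pos) {
  xp <- scores[pos]; xn <- scores[!pos]
  v10 <- vapply(xp, function(s) mean((s > xn) + 0.5 * (s == xn)), numeric(1))
  v01 <- vapply(xn, function(s) mean((xp > s) + 0.5 * (xp == s)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Empirical ROC curve and AUC with DeLong standard error
#'
#' The AUC equals the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) pairs ordered correctly, ties counted 1/2. The
#' standard error comes from the DeLong per-subject placement values and the
#' 95% CI is the normal-approximation interval truncated to `[0, 1]`.
#'
#' @param scores per-subject marker values (finite).
#' @param groups group labels (`abeta_neg`/`abeta_pos`, logical, or 0/1 with
#'   1 = positive).
#' @param direction `"auto"` (default) picks the polarity giving AUC >= 0.5;
#'   `"higher_in_pos"` / `"lower_in_pos"` force it.
#' @return A `roc_result` with `thresholds`, `sensitivity`, `specificity`
#'   (per threshold, on the original score scale), `auc`, `auc_se`, `ci95`,
#'   `direction`, and a `zero_variance` flag (constant scores give AUC 0.5).
#' @export
empirical_roc_auc <- function(scores, groups,
                              direction = c("auto", "higher_in_pos",
                                            "lower_in_pos")) {
  direction <- match.arg(direction)
  pos <- .as_pos_indicator(groups)
  stopifnot(length(scores) == length(pos), all(is.finite(scores)))
  if (!any(pos) || all(pos)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  auc_for <- function(s) .delong_placements(s, pos)$auc
  if (direction == "auto") {
    direction <- if (auc_for(scores) >= 0.5) "higher_in_pos" else
      "lower_in_pos"
  }
  oriented <- if (direction == "higher_in_pos") scores else -scores
  pl <- .delong_placements(oriented, pos)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  zero_var <- length(unique(scores)) == 1
  auc <- if (zero_var) 0.5 else pl$auc
  v <- var(pl$v10) / n_pos + var(pl$v01) / n_neg
  se <- sqrt(max(v, 0))
  # staircase: classify positive when oriented score >= threshold
  thr_or <- sort(unique(oriented))
  cand <- c(-Inf, thr_or, Inf)
  sens <- vapply(cand, function(t) mean(oriented[pos] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(oriented[!pos] < t), numeric(1))
  thresholds <- if (direction == "higher_in_pos") cand else -cand
  structure(list(
    thresholds = thresholds, sensitivity = sens, specificity = spec,
    auc = auc, auc_se = se,
    ci95 = c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se)),
    direction = direction, zero_variance = zero_var,
    n_pos = n_pos, n_neg = n_neg,
    scores = scores, pos = pos
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC (n_neg = %d, n_pos = %d, %s): AUC %.3f (95%% CI %.3f-%.3f)\n",
    x$n_neg, x$n_pos, x$direction, x$auc, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects. The
#' variance of the AUC difference uses the DeLong structural components with
#' the covariance term induced by the pairing. Each marker is oriented to its
#' favorable polarity (AUC >= 0.5) before comparison.
#'
#' @param scores_a,scores_b per-subject scores for the two markers.
#' @param groups shared group labels.
#' @return A `delong_comparison`: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, groups) {
  pos <- .as_pos_indicator(groups)
  stopifnot(length(scores_a) == length(pos),
            length(scores_b) == length(pos))
  orient <- function(s) {
    if (.delong_placements(s, pos)$auc >= 0.5) s else -s
  }
  pa <- .delong_placements(orient(scores_a), pos)
  pb <- .delong_placements(orient(scores_b), pos)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  S <- s10 / n_pos + s01 / n_neg
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, z = z,
                 p_value = if (is.infinite(z)) 0 else
                   2 * (1 - pnorm(abs(z)))),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong paired test: AUC %.3f vs %.3f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p_value))
  invisible(x)
}

#' Classification statistics from a confusion matrix
#'
#' @param tp,tn,fp,fn non-negative counts (true/false positives/negatives);
#'   `tp + fn > 0` and `tn + fp > 0`.
#' @param threshold optional score threshold to record.
#' @return A `confusion_stats` list with the counts, sensitivity,
#'   specificity, accuracy, PPV and NPV (`NA` with an `undefined` flag when a
#'   predictive-value denominator is zero).
#' @export
confusion_stats <- function(tp, tn, fp, fn, threshold = NA_real_) {
  tp <- unname(tp); tn <- unname(tn); fp <- unname(fp); fn <- unname(fn)
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("empty confusion table", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("confusion_stats requires tp+fn > 0 and tn+fp > 0", call. = FALSE)
  }
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / sum(counts),
    ppv = ppv, npv = npv,
    undefined = is.na(ppv) || is.na(npv),
    threshold = threshold
  ), class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf(
    "confusion (tp %d, tn %d, fp %d, fn %d): sens %.3f, spec %.3f, acc %.3f, ppv %.3f, npv %.3f\n",
    x$tp, x$tn, x$fp, x$fn, x$sensitivity, x$specificity, x$accuracy,
    x$ppv, x$npv))
  invisible(x)
}

#' Classification at the Youden point of a ROC curve
#'
#' Finds the threshold maximizing Youden's J = sensitivity + specificity - 1
#' over the ROC staircase and returns the confusion statistics of the induced
#' classifier. Ties in J are broken toward the threshold with the higher
#' specificity. J is a rank statistic, invariant to monotone score
#' transforms.
#'
#' @param roc a `roc_result` (scores and labels are carried inside it).
#' @return A `confusion_stats`; `threshold` is on the original score scale
#'   (subjects are called positive at scores >= threshold when the direction
#'   is `higher_in_pos`, <= threshold otherwise).
#' @export
youden_classification <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  pos <- roc$pos
  oriented <- if (roc$direction == "higher_in_pos") roc$scores else
    -roc$scores
  # candidate cuts: midpoints between adjacent unique values plus extremes
  u <- sort(unique(oriented))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  stats_at <- function(cut) {
    pred <- oriented >= cut
    c(tp = sum(pred & pos), tn = sum(!pred & !pos),
      fp = sum(pred & !pos), fn = sum(!pred & pos))
  }
  tab <- vapply(cand, stats_at, numeric(4))
  sens <- tab["tp", ] / (tab["tp", ] + tab["fn", ])
  spec <- tab["tn", ] / (tab["tn", ] + tab["fp", ])
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(spec[best])]
  thr <- if (roc$direction == "higher_in_pos") cand[best] else -cand[best]
  confusion_stats(tab["tp", best], tab["tn", best],
                  tab["fp", best], tab["fn", best], threshold = thr)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit (binomial GLM; the fit is by IRLS) with
#' explicit separation reporting: separable data drive coefficients toward
#' infinity and fitted probabilities to 0/1, which is flagged rather than
#' silently regularized.
#'
#' @param features numeric matrix or data frame of predictors (one row per
#'   subject); an intercept is always added.
#' @param groups group labels; the positive class is modelled.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return list with `coefficients`, `converged`, `separation`, `iter` and
#'   `fitted`.
#' @export
fit_logistic_irls <- function(features, groups, max_iter = 100, tol = 1e-10) {
  pos <- .as_pos_indicator(groups)
  X <- as.matrix(features)
  if (ncol(X) > 0) {
    const <- apply(X, 2, function(c) var(c) == 0)
    if (any(const)) {
      stop("constant feature(s): ",
           paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    }
  }
  if (length(pos) <= ncol(X) + 1) {
    stop("need n > number of features + 1", call. = FALSE)
  }
  df <- data.frame(.y = as.numeric(pos), X)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial(),
        control = list(maxit = max_iter, epsilon = tol)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged && !sep_warn) {
    stop("IRLS did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  }
  list(coefficients = coef(fit), converged = fit$converged,
       separation = sep_warn, iter = fit$iter,
       fitted = unname(fit$fitted.values), model = fit)
}

#' Out-of-fold logistic-regression scores with stratified k-fold CV
#'
#' Stratified k-fold cross-validation for a logistic classifier: subjects are
#' partitioned into k folds preserving the class ratio (fold sizes differ by
#' at most one per class), the model is fitted on k-1 folds and the held-out
#' fold is scored, so every subject receives exactly one out-of-fold
#' predicted probability. The pooled out-of-fold scores are then summarized
#' with [empirical_roc_auc()] and [youden_classification()], avoiding the
#' optimism of resubstitution ROC curves.
#'
#' @param features numeric matrix or data frame of predictors.
#' @param groups group labels.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return A `cv_roc_result`: `fold_assignment`, `oof_scores`, `roc`,
#'   `youden` (a `confusion_stats`), and `coefficients` per fold.
#' @export
cv_logistic_scores <- function(features, groups, k = 10, seed = 1) {
  pos <- .as_pos_indicator(groups)
  X <- as.matrix(features)
  n <- length(pos)
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  folds <- integer(n)
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(pos == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  oof <- rep(NA_real_, n)
  coefs <- vector("list", k)
  for (f in seq_len(k)) {
    train <- folds != f
    if (length(unique(pos[train])) < 2) {
      stop("fold ", f, " leaves a single-class training set", call. = FALSE)
    }
    fit <- fit_logistic_irls(X[train, , drop = FALSE], pos[train])
    coefs[[f]] <- fit$coefficients
    eta <- cbind(1, X[!train, , drop = FALSE]) %*% fit$coefficients
    oof[!train] <- 1 / (1 + exp(-eta))
  }
  roc <- empirical_roc_auc(oof, pos, direction = "higher_in_pos")
  structure(list(fold_assignment = folds, oof_scores = oof, roc = roc,
                 youden = youden_classification(roc),
                 coefficients = coefs, k = k, seed = seed),
            class = "cv_roc_result")
}

#' @export
print.cv_roc_result <- function(x, ...) {
  cat(sprintf("%d-fold CV logistic ROC: AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$k, x$roc$auc, x$roc$ci95[1], x$roc$ci95[2]))
  invisible(x)
}
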