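test_that("AUC equals exhaustive pair counting on small random instances", {
  expect_equal(empirical_roc_auc(c(2, 4, 1, 3),
                                 c(TRUE, TRUE, FALSE, FALSE),
                                 direction = "higher_in_pos")$auc, 0.75)
  set.seed(20)
  for (i in 1:40) {
    n_pos <- sample(2:6, 1); n_neg <- sample(2:6, 1)
    scores <- round(rnorm(n_pos + n_neg), sample(0:1, 1))  # ties likely
    pos <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    roc <- empirical_roc_auc(scores, pos, direction = "higher_in_pos")
    expect_equal(roc$auc, auc_brute(scores, pos))
  }
})

test_that("perfect separation yields AUC 1 and a zero-error Youden point", {
  pos <- make_groups(4, 4) == "abeta_pos"
  roc <- empirical_roc_auc(c(1, 2, 3, 4, 11, 12, 13, 14), pos)
  expect_equal(roc$auc, 1)
  y <- youden_classification(roc)
  expect_equal(y$fp + y$fn, 0)
  expect_equal(y$sensitivity + y$specificity - 1, 1)
})

test_that("auto direction picks the favorable polarity and records it", {
  pos <- make_groups(5, 5) == "abeta_pos"
  lower_in_pos <- c(10, 9, 8, 7, 6, 1, 2, 3, 4, 5)
  roc <- empirical_roc_auc(lower_in_pos, pos)
  expect_equal(roc$direction, "lower_in_pos")
  expect_equal(roc$auc, 1)
  # constant scores: zero-variance AUC 0.5
  rc <- empirical_roc_auc(rep(3, 10), pos)
  expect_true(rc$zero_variance)
  expect_equal(rc$auc, 0.5)
})

test_that("ROC staircase is monotone and the CI is truncated to [0, 1]", {
  set.seed(23)
  scores <- rnorm(40); pos <- rep(c(TRUE, FALSE), 20)
  roc <- empirical_roc_auc(scores, pos)
  ord <- order(roc$thresholds * ifelse(roc$direction == "higher_in_pos",
                                       1, -1))
  expect_true(all(diff(roc$sensitivity[ord]) <= 1e-12))
  expect_true(all(diff(roc$specificity[ord]) >= -1e-12))
  expect_gte(roc$ci95[1], 0)
  expect_lte(roc$ci95[2], 1)
})

test_that("DeLong variance matches the brute-force placement oracle and
           pROC on small instances", {
  set.seed(26)
  for (i in 1:15) {
    n_pos <- sample(3:5, 1); n_neg <- sample(3:5, 1)
    scores <- rnorm(n_pos + n_neg)
    pos <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    roc <- empirical_roc_auc(scores, pos, direction = "higher_in_pos")
    expect_equal(roc$auc_se^2, delong_var_brute(scores, pos))
  }
  skip_if_not_installed("pROC")
  set.seed(27)
  scores <- rnorm(40); pos <- rep(c(TRUE, FALSE), 20)
  roc <- empirical_roc_auc(scores, pos, direction = "higher_in_pos")
  pr <- pROC::roc(response = as.numeric(pos), predictor = scores,
                  direction = "<", quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(pr)))
  expect_equal(roc$auc_se^2, as.numeric(pROC::var(pr)))
})

test_that("paired DeLong test: identity, rank invariance, pROC agreement", {
  set.seed(30)
  pos <- rep(c(TRUE, FALSE), c(12, 15))
  a <- rnorm(27) + pos
  same <- delong_paired_test(a, a, pos)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  # a monotone transform changes nothing rank-based
  mono <- delong_paired_test(a, exp(a / 2), pos)
  expect_equal(mono$z, 0)
  expect_equal(mono$p_value, 1)
  b <- a + rnorm(27, 0, 0.8)
  dl <- delong_paired_test(a, b, pos)
  expect_gte(dl$p_value, 0)
  expect_lte(dl$p_value, 1)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(as.numeric(pos), a, direction = "<", quiet = TRUE)
  rb <- pROC::roc(as.numeric(pos), b, direction = "<", quiet = TRUE)
  pt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(dl$p_value, pt$p.value)
})

test_that("confusion statistics reproduce the published classification
           rows", {
  # Abeta1-42/1-40 in the IP eluate at the Youden point
  cs <- confusion_stats(tp = 32, tn = 32, fp = 7, fn = 0)
  expect_equal(round(cs$sensitivity, 3), 1.000)
  expect_equal(round(cs$specificity, 3), 0.821)
  expect_equal(round(cs$accuracy, 3), 0.901)
  expect_equal(round(cs$ppv, 3), 0.821)
  expect_equal(round(cs$npv, 3), 1.000)
  # pTau181 in the Tau-IP eluate
  cs2 <- confusion_stats(28, 35, 4, 4)
  expect_equal(round(cs2$accuracy, 3), 0.887)
  expect_equal(round(cs2$sensitivity, 3), 0.875)
  expect_equal(round(cs2$specificity, 3), 0.897)
  # perfect 2-subject case
  cs3 <- confusion_stats(1, 1, 0, 0)
  expect_equal(cs3$accuracy, 1)
  expect_equal(cs3$ppv, 1)
  expect_error(confusion_stats(0, 0, 0, 0), "empty")
})

test_that("full published confusion rows reproduce all five statistics at
           3 decimals", {
  rows <- list(
    list(c(30, 32, 7, 2), c(0.811, 0.941, 0.938, 0.821, 0.873)),
    list(c(32, 32, 7, 0), c(0.821, 1.000, 1.000, 0.821, 0.901)),
    list(c(25, 31, 8, 7), c(0.758, 0.816, 0.781, 0.795, 0.789)),
    list(c(28, 35, 4, 4), c(0.875, 0.897, 0.875, 0.897, 0.887)),
    list(c(29, 28, 11, 3), c(0.725, 0.903, 0.906, 0.718, 0.803)),
    list(c(30, 35, 4, 2), c(0.882, 0.946, 0.938, 0.897, 0.915)))
  for (r in rows) {
    cs <- confusion_stats(r[[1]][1], r[[1]][2], r[[1]][3], r[[1]][4])
    got <- round(c(cs$ppv, cs$npv, cs$sensitivity, cs$specificity,
                   cs$accuracy), 3)
    expect_equal(got, r[[2]])
  }
})

test_that("Youden maximization matches the exhaustive threshold oracle and
           is invariant to monotone transforms", {
  set.seed(33)
  for (i in 1:20) {
    n_pos <- sample(3:8, 1); n_neg <- sample(3:8, 1)
    scores <- round(rnorm(n_pos + n_neg), 1)
    pos <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    roc <- empirical_roc_auc(scores, pos, direction = "higher_in_pos")
    y <- youden_classification(roc)
    expect_equal(y$sensitivity + y$specificity - 1,
                 youden_brute(scores, pos))
    # count identities
    expect_equal(y$tp + y$fn, n_pos)
    expect_equal(y$tn + y$fp, n_neg)
    # monotone transform leaves J unchanged
    roc2 <- empirical_roc_auc(exp(scores), pos,
                              direction = "higher_in_pos")
    y2 <- youden_classification(roc2)
    expect_equal(y2$sensitivity + y2$specificity,
                 y$sensitivity + y$specificity)
  }
})

test_that("duplicating one subject into both groups perturbs the AUC within
           the pair-counting sensitivity bound", {
  # exact arithmetic: the duplicated pair contributes placements a (against
  # the negatives) and b (against the positives) plus the 1/2 self-tie, so
  # |AUC' - AUC| <= (n_pos + n_neg + 0.5) / ((n_pos + 1) (n_neg + 1))
  set.seed(36)
  for (i in 1:10) {
    scores <- rnorm(20); pos <- rep(c(TRUE, FALSE), 10)
    auc0 <- empirical_roc_auc(scores, pos, "higher_in_pos")$auc
    s <- sample(20, 1)
    scores1 <- c(scores, scores[s], scores[s])
    pos1 <- c(pos, TRUE, FALSE)
    auc1 <- empirical_roc_auc(scores1, pos1, "higher_in_pos")$auc
    expect_lte(abs(auc1 - auc0), 20.5 / (11 * 11) + 1e-12)
    # and the perturbed AUC still equals exhaustive pair counting
    expect_equal(auc1, auc_brute(scores1, pos1))
  }
})

test_that("logistic IRLS: prevalence logit, score equations, separation", {
  groups <- make_groups(39, 32)
  fit <- fit_logistic_irls(matrix(numeric(0), 71, 0), groups)
  expect_equal(unname(fit$coefficients[1]), log(32 / 39), tolerance = 1e-8)
  # gradient of the log-likelihood vanishes at the fit
  set.seed(40)
  X <- cbind(x1 = rnorm(71), x2 = rnorm(71))
  pos <- as.numeric(groups == "abeta_pos")
  fit2 <- fit_logistic_irls(X, groups)
  mu <- fit2$fitted
  grad <- t(cbind(1, X)) %*% (pos - mu)
  expect_true(all(abs(grad) < 1e-6))
  expect_false(fit2$separation)
  # a perfectly separable feature raises the separation flag
  sep_x <- matrix(c(rnorm(39, -4), rnorm(32, 4)), ncol = 1)
  fit3 <- fit_logistic_irls(sep_x, groups)
  expect_true(fit3$separation)
  expect_error(fit_logistic_irls(matrix(1, 71, 1), groups), "constant")
})

test_that("stratified CV folds balance size and class and score every
           subject once", {
  set.seed(44)
  groups <- make_groups(39, 32)
  X <- matrix(rnorm(71), ncol = 1)
  cv <- cv_logistic_scores(X, groups, k = 10, seed = 3)
  expect_equal(sort(unique(cv$fold_assignment)), 1:10)
  sizes <- table(cv$fold_assignment)
  expect_lte(max(sizes) - min(sizes), 2)  # <= 1 per class
  pos_per_fold <- table(cv$fold_assignment[groups == "abeta_pos"])
  expect_lte(max(pos_per_fold) - min(pos_per_fold), 1)
  expect_true(all(!is.na(cv$oof_scores)))
  expect_length(cv$coefficients, 10)
  # determinism under the seed
  cv2 <- cv_logistic_scores(X, groups, k = 10, seed = 3)
  expect_identical(cv$oof_scores, cv2$oof_scores)
})

test_that("an informative feature yields a high out-of-fold AUC", {
  set.seed(48)
  groups <- make_groups(50, 50)
  x <- c(rnorm(50, 0), rnorm(50, 3))  # 3 SD apart
  cv <- cv_logistic_scores(matrix(x, ncol = 1), groups, k = 10, seed = 5)
  expect_gt(cv$roc$auc, 0.95)
})
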