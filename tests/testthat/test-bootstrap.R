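test_that("the 0.632/0.368 refinement weights are exact", {
  expect_equal(refined_estimate(1, 0), 0.632)
  expect_equal(refined_estimate(0, 1), 0.368)
  expect_equal(refined_estimate(2.7, 2.7), 2.7)
  expect_equal(refined_estimate(c(1, 0), c(0, 1)), c(0.632, 0.368))
})

test_that("identical methods give a degenerate null result", {
  set.seed(70)
  groups <- make_groups(20, 15)
  a <- rlnorm(35, 0, 0.4) + (groups == "abeta_pos")
  bt <- bootstrap_difference_test(a, a, groups, "cohens_d",
                                  n_replicates = 200, seed = 1)
  expect_equal(bt$observed_diff, 0)
  expect_true(all(bt$refined_diffs == 0))
  expect_true(bt$degenerate)
  expect_equal(bt$p_value, 1)
})

test_that("bootstrap test is deterministic under a seed and symmetric in
           the method labels", {
  set.seed(73)
  groups <- make_groups(39, 32)
  shift <- (groups == "abeta_pos") * 1.2
  a <- rlnorm(71, 0, 0.4) + shift
  b <- a * 0.8 + rnorm(71, 0, 0.2) + 0.4 * shift
  b <- b - min(b) + 0.1
  t1 <- bootstrap_difference_test(a, b, groups, "cohens_d",
                                  n_replicates = 300, seed = 42)
  t2 <- bootstrap_difference_test(a, b, groups, "cohens_d",
                                  n_replicates = 300, seed = 42)
  expect_identical(t1$refined_diffs, t2$refined_diffs)
  expect_identical(t1$p_value, t2$p_value)
  # relabeling A and B flips the sign but not the two-sided p-value
  t3 <- bootstrap_difference_test(b, a, groups, "cohens_d",
                                  n_replicates = 300, seed = 42)
  expect_equal(t3$observed_diff, -t1$observed_diff)
  expect_equal(t3$p_value, t1$p_value)
  expect_length(t1$refined_diffs, 300)
  # the Shapiro diagnostic is reported but does not gate the p-value
  expect_true(is.finite(t1$shapiro_p))
})

test_that("stratified resampling preserves the group sizes in every
           replicate", {
  # estimator that records resampled group sizes via the values themselves:
  # use median_diff_pct on group-constant values, which is 100*(pos/neg - 1)
  groups <- make_groups(10, 6)
  a <- ifelse(groups == "abeta_pos", 2, 1)
  set.seed(1)
  b <- ifelse(groups == "abeta_pos", 3, 1)
  bt <- bootstrap_difference_test(a, b, groups, "median_diff_pct",
                                  n_replicates = 150, seed = 5)
  # group-constant values: every stratified resample reproduces the same
  # effect sizes exactly, so every refined difference equals the observed one
  expect_true(all(abs(bt$refined_diffs - bt$observed_diff) < 1e-12))
  expect_equal(bt$observed_diff, 200 - 100)
  # with a 2-subject group, stratification keeps both subjects in every
  # replicate, so Cohen's d is always computable; an unstratified resample
  # of the same cohort would frequently lose the small group entirely
  set.seed(6)
  g2 <- make_groups(2, 30)
  x <- rlnorm(32, 0, 0.3) + (g2 == "abeta_pos")
  y <- rlnorm(32, 0, 0.3) + (g2 == "abeta_pos") * 1.3
  expect_no_error(bootstrap_difference_test(x, y, g2, "cohens_d",
                                            n_replicates = 200, seed = 9))
})

test_that("p-values stabilize as the number of replicates grows", {
  set.seed(79)
  groups <- make_groups(39, 32)
  shift <- (groups == "abeta_pos") * 0.8
  a <- rlnorm(71, 0, 0.4) + shift
  b <- a + rnorm(71, 0, 0.3)
  b <- b - min(b) + 0.1
  p1 <- bootstrap_difference_test(a, b, groups, "cohens_d",
                                  n_replicates = 2000, seed = 101)$p_value
  p2 <- bootstrap_difference_test(a, b, groups, "cohens_d",
                                  n_replicates = 2000, seed = 202)$p_value
  expect_lt(abs(p1 - p2), 0.02)
})

test_that("one-sided alternatives partition the two-sided evidence", {
  set.seed(82)
  groups <- make_groups(25, 20)
  a <- rlnorm(45, 0, 0.3) + (groups == "abeta_pos") * 0.5
  b <- rlnorm(45, 0, 0.3) + (groups == "abeta_pos") * 1.0
  pg <- bootstrap_difference_test(a, b, groups, "cohens_d", 200, seed = 3,
                                  alternative = "greater")$p_value
  pl <- bootstrap_difference_test(a, b, groups, "cohens_d", 200, seed = 3,
                                  alternative = "less")$p_value
  expect_equal(pg + pl, 1)
})

test_that("estimator tags dispatch to the matching effect-size measure", {
  set.seed(85)
  groups <- make_groups(30, 25)
  a <- rlnorm(55, 0, 0.3) + (groups == "abeta_pos") * 0.6
  b <- rlnorm(55, 0, 0.3) + (groups == "abeta_pos") * 0.9
  for (est in c("cohens_d", "median_diff_pct", "mean_diff_pct")) {
    bt <- bootstrap_difference_test(a, b, groups, est, 150, seed = 8)
    pos <- groups == "abeta_pos"
    expected <- switch(est,
      cohens_d = cohens_d(b[pos], b[!pos]) - cohens_d(a[pos], a[!pos]),
      median_diff_pct =
        relative_difference(b[pos], b[!pos], "median") -
        relative_difference(a[pos], a[!pos], "median"),
      mean_diff_pct =
        relative_difference(b[pos], b[!pos], "mean") -
        relative_difference(a[pos], a[!pos], "mean"))
    expect_equal(bt$observed_diff, expected)
  }
})
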