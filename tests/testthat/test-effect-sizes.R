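test_that("scaled MAD matches hand computation and scale equivariance", {
  expect_equal(scaled_mad(c(1, 2, 3, 4, 5)), 1.4826)
  expect_equal(scaled_mad(rep(7, 10)), 0)
  set.seed(3)
  x <- rlnorm(40)
  expect_equal(scaled_mad(2 + 3 * x), 3 * scaled_mad(x))
  expect_equal(scaled_mad(-2 * x), 2 * scaled_mad(x))
  expect_error(scaled_mad(numeric(0)), "empty")
})

test_that("relative differences reproduce the published pTau181 contrasts", {
  # group medians as printed for pTau181, direct plasma and IP eluate
  expect_equal(round(relative_difference(2.55, 1.45, "median"), 1), 75.9)
  expect_equal(round(relative_difference(0.755, 0.380, "median"), 1), 98.7)
  expect_equal(relative_difference(c(1, 2, 3), c(1, 2, 3), "median"), 0)
  expect_error(relative_difference(1, 0, "mean"), "undefined")
  # invariant to a common positive scale factor
  set.seed(8)
  p <- rlnorm(15); n <- rlnorm(20)
  expect_equal(relative_difference(3.7 * p, 3.7 * n, "mean"),
               relative_difference(p, n, "mean"))
})

test_that("relative differences applied to all printed group centers match
           the printed effect columns", {
  # (pos, neg, printed %) triples from the published group-wise table,
  # restricted to rows whose printed centers carry enough digits to
  # reproduce the printed percentage exactly at 1 decimal
  median_cases <- list(
    c(293.8, 303.7, -3.3), c(22.6, 29.0, -22.1),
    c(2.55, 1.45, 75.9), c(32.34, 15.32, 111.1),
    c(3.10, 3.80, -18.4), c(0.755, 0.380, 98.7))
  for (cs in median_cases) {
    expect_equal(round(relative_difference(cs[1], cs[2], "median"), 1),
                 cs[3])
  }
  mean_cases <- list(
    c(24.6, 30.2, -18.4), c(2.71, 1.58, 71.8),
    c(0.859, 0.415, 107.0), c(35.10, 17.32, 102.7),
    c(3.13, 3.94, -20.5))
  for (cs in mean_cases) {
    # printed means are themselves rounded, so allow last-digit wobble
    expect_equal(relative_difference(cs[1], cs[2], "mean"), cs[3],
                 tolerance = 0.01)
  }
})

test_that("Cohen's d: hand-computed value, antisymmetry, invariances", {
  # neg = {1,2,3}, pos = {3,4,5}: pooled SD 1, d = (2 - 4)/1 = -2
  expect_equal(cohens_d(pos = c(3, 4, 5), neg = c(1, 2, 3)), -2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(5)
  p <- rnorm(12, 1); n <- rnorm(15)
  expect_equal(cohens_d(p, n), -cohens_d(n, p))
  # affine invariance (positive slope)
  expect_equal(cohens_d(2 + 3 * p, 2 + 3 * n), cohens_d(p, n))
  expect_error(cohens_d(rep(1, 3), rep(1, 4)), "pooled SD")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
  # Hedges correction shrinks toward zero by the documented factor
  expect_equal(cohens_d(p, n, hedges_correction = TRUE),
               cohens_d(p, n) * (1 - 3 / (4 * 27 - 9)))
})

test_that("Cohen's d magnitude grows with the gap between group means", {
  set.seed(21)
  base <- rnorm(30)
  gaps <- seq(0, 3, by = 0.5)
  ds <- vapply(gaps, function(g) abs(cohens_d(base + g, base)), numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("derived panel: ratio and AT-term arithmetic and invariances", {
  p <- derive_panel(300, 30, 2)
  expect_equal(p$ab_ratio, 0.1)
  expect_equal(p$at_term, 20)
  # equal peptide concentrations make the AT-term equal pTau181
  expect_equal(derive_panel(50, 50, 1.7)$at_term, 1.7)
  # AT-term invariant to a common scale on both peptides
  expect_equal(derive_panel(600, 60, 2)$at_term, 20)
  expect_error(derive_panel(0, 30, 2), "positive")
})

test_that("IP dilution arithmetic reproduces the published factors", {
  ab <- dilution_factor(plasma_volume = 200, eluate_volume = 38,
                        diluent_added = 190, aliquot_taken = 60,
                        aliquot_final = 300)
  expect_equal(round(ab$overall_factor, 1), 5.7)
  tau <- dilution_factor(400, 38, 75, 50, 250)
  expect_equal(round(tau$expected_fraction), 71)
  expect_equal(round(tau$overall_factor, 1), 1.4)
  none <- dilution_factor(50, 50, 0, 10, 10)
  expect_equal(none$overall_factor, 1)
  expect_equal(none$expected_fraction, 100)
})

test_that("effect_size_triple carries all three measures with the d
           orientation tag", {
  set.seed(13)
  n <- rlnorm(39, 0.4, 0.25); p <- rlnorm(32, 0.9, 0.35)
  es <- effect_size_triple(p, n)
  expect_equal(es$median_diff_pct, relative_difference(p, n, "median"))
  expect_equal(es$mean_diff_pct, relative_difference(p, n, "mean"))
  expect_equal(es$cohens_d, cohens_d(p, n))
  expect_equal(es$orientation, "neg_minus_pos_for_d")
  # elevated marker in the positive group gives negative d, positive diffs
  expect_lt(es$cohens_d, 0)
  expect_gt(es$median_diff_pct, 0)
})
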