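---
title: "Statistical methods for evaluating IP-enhanced plasma Alzheimer biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for evaluating IP-enhanced plasma Alzheimer biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipiadx)
```

## The scientific problem

Blood-based biomarkers for Alzheimer's disease — the plasma Abeta1-42/1-40
ratio and phosphorylated tau (pTau181) — are attractive because they avoid
lumbar puncture and PET imaging, but direct plasma immunoassays suffer from
matrix effects: abundant plasma proteins interfere with antibody binding and
compress the diagnostic contrast. Pre-analytical immunoprecipitation (IP)
pulls the analyte out of plasma onto antibody-coupled magnetic beads and
measures it in a clean eluate. `ipiadx` implements the statistical machinery
needed to judge whether this pre-analytical clean-up actually improves a
biomarker: paired effect-size estimation, a 0.632-bootstrap test for
differences of effect sizes between two methods measured on the same
subjects, empirical ROC analysis with the DeLong paired AUC test,
Youden-point classification, cross-validated multivariate logistic models,
unsupervised Gaussian-mixture cutpoints, and Deming errors-in-variables
regression.

Subjects are dichotomized by their CSF Abeta42/40 ratio at the clinical
cutoff 0.050 into amyloid-positive (ratio <= 0.050) and amyloid-negative
groups; equality counts as positive because the clinical rule is stated as
an inclusive inequality. One CSF pTau181 convention is inherited from
clinical practice: values below the 15.6 pg/mL limit of quantification are
floored to the limit (`apply_loq_floor()`), everywhere, including
correlation analyses.

## Effect sizes and their comparison between paired methods

For each marker and method the package reports three effect measures for
the amyloid-positive (`pos`) vs amyloid-negative (`neg`) contrast:

* relative median difference (%): `100 * (median(pos) - median(neg)) / median(neg)`;
* relative mean difference (%): the same with means;
* Cohen's d with pooled SD, oriented as `(mean(neg) - mean(pos)) / s_pooled`.

The d orientation is anchored to the sign convention of the published
summary tables (positive for the Abeta ratio, which falls in amyloid-positive
subjects; negative for pTau181 and the AT-term, which rise). No Hedges
small-sample correction is applied by default — the commonly used `effsize`
default — but `hedges_correction = TRUE` is available. Spread is summarized
by the scaled MAD (`1.4826 * median(|x - median|)`), a robust SD analogue.

### The 0.632 bootstrap test

To test whether an effect size differs between the direct assay (A) and the
IP-eluate assay (B) measured on the same subjects,
`bootstrap_difference_test()` resamples subjects with replacement — pairs of
(A, B) values travel together — stratified within diagnostic group so every
replicate keeps the original group sizes (unstratified resampling at n = 71
would occasionally produce unusably lopsided groups; an unstratified mode
exists for sensitivity analysis). Per replicate the effect-size difference
`E_B - E_A` is refined with the Efron 0.632 weights against the
original-cohort difference:

```
refined = 0.632 * resampled + 0.368 * observed
```

A normal distribution is fitted to the refined differences (mean `m`,
SD `s`). The refinement contracts the bootstrap scatter around the observed
difference by exactly the factor 0.632 while leaving its centre unchanged,
so the fitted SD is normalised back before the tail is evaluated:

```
z = m / (s / 0.632),    p = 2 * (1 - pnorm(|z|))
```

Without this normalisation the test would reject a true null about 20% of
the time at the nominal 5% level (`P(|Z| > 1.96 * 0.632) = 0.215`); with
it, the measured type-I error over 500 simulated null cohorts is about 5%
(see `tests/testthat/test-acceptance.R`). A Shapiro-Wilk p-value of the
refined differences is reported as a normality diagnostic only; it never
gates the test. A one-sided alternative is available but off by default,
since the directionality of the published comparison is not stated.

## ROC analysis

`empirical_roc_auc()` computes the empirical AUC as the Mann-Whitney pair
statistic (ties 1/2) with the DeLong placement-based standard error and a
normal 95% CI truncated to [0, 1]. Marker polarity differs across the panel
(the Abeta ratio is *lower*, pTau181 and the AT-term *higher* in
amyloid-positive subjects), so the direction is auto-detected as the
polarity giving AUC >= 0.5 and recorded in the result; an explicit override
exists. `delong_paired_test()` compares two correlated AUCs on the same
subjects, including the covariance of the placement values induced by the
pairing.

Classification statistics are evaluated at the Youden point (the threshold
maximizing sensitivity + specificity - 1). Ties in J are broken toward the
threshold with the higher specificity — the published tables do not
disclose a tie rule, and in a screening-adjacent setting the
higher-specificity cut is the conservative choice.

Multivariate models are unpenalized logistic regressions (fitted by IRLS
via the binomial GLM); separation is detected and reported rather than
silently regularized. Because resubstitution ROC curves are optimistic,
`cv_logistic_scores()` uses seeded stratified 10-fold cross-validation and
pools the out-of-fold predicted probabilities into a single ROC curve
("tenfold" and "10 leave-out" cross-validation are read as the same
stratified 10-fold procedure). Under a pure-noise feature the mean
out-of-fold AUC is 0.50 (calibration checked over 100 simulations); no
multiple-testing correction is applied anywhere, mirroring the uncorrected
pairwise comparisons of the original analysis.

## Mixture cutpoint

`fit_two_gaussian_equal_sd()` fits a two-component Gaussian mixture to the
pooled, unlabelled marker values by EM with a *single pooled SD* in the
M-step (the similar-variance precondition read as equality; an unequal-SD
mode exists, in which the intersection is solved as the quadratic root
between the means). Initialization is a median split plus nine seeded
random starts, keeping the best log-likelihood; starts that collapse are
discarded. The diagnostic cutpoint is the analytic intersection of the two
weighted densities:

```
x* = (mu1 + mu2)/2 + sd^2 * log(w1/w2) / (mu2 - mu1)
```

On default simulated cohorts the IP-eluate ratio cutpoint falls between the
two group medians in ~97% of seeds, and typically lands near 0.11 — close
to the Youden cut of the same marker, as observed in the source data. A
poorly-separated flag (components closer than two SDs) and the mean
posterior assignment certainty are reported so that unimodal inputs are
surfaced, not hidden.

## Association analyses

Method agreement and CSF-plasma relations use Pearson correlation (t-test
p-values) and Deming errors-in-variables regression, appropriate when both
variables are measured with error. The error-variance ratio `lambda` is not
identifiable from the data and the source analysis does not state one, so
the default is `lambda = 1` (orthogonal regression, the method-comparison
default), exposed as an argument; `lambda -> Inf` recovers OLS of y on x.
Group comparisons use the two-tailed Mann-Whitney test (exact null
distribution when `n_x * n_y <= 400` without ties, otherwise the tie- and
continuity-corrected normal approximation) and the two-tailed Fisher exact
test with the probability-mass convention for the second tail.

## The synthetic cohort generator

No subject-level data were deposited with the source study, so
`generate_cohort()` simulates cohorts with the statistical structure the
analysis assumes; `default_paper_config()` encodes the published study
conditions: 39 amyloid-negative and 32 amyloid-positive subjects; per-group
medians and scaled MADs for all six analyte x method pairs; pooled
cross-method Pearson correlations 0.810 (Abeta1-40), 0.791 (Abeta1-42) and
0.910 (pTau181); ApoE4 carrier frequencies 7/39 and 25/32; 40/71 female;
per-group age and CSF marginals.

Design choices, in order of consequence:

* **Marginal family: lognormal.** Concentrations are positive and the
  published group means exceed the medians throughout (right skew); the
  lognormal is the standard minimal model with both properties. The median
  identity (`median = exp(meanlog)`) pins `meanlog`; `sdlog` is solved
  numerically so the *population* scaled MAD matches the target to 1e-6
  relative tolerance (`calibrate_lognormal()`).
* **Cross-method dependence: Gaussian copula calibrated on pooled
  moments.** The published correlations are computed over all 71 subjects,
  pooling two separated groups. The latent correlation (shared by both
  groups) is therefore solved — using exact bivariate-lognormal mixture
  moments and `uniroot` — so the *pooled* original-scale Pearson
  correlation matches the target. Calibrating within groups instead would
  overshoot the pooled value for well-separated analytes such as pTau181.
  An unattainable target raises an error naming the analyte.
* **The Abeta pair is dependent within subject.** The ratio and the AT-term
  are always *derived* from the simulated analytes, never simulated
  directly, preserving the internal consistency of the panel. Independent
  Abeta1-40/1-42 draws would make the derived ratio about 2.5x more
  dispersed than the published ratio rows; the within-method latent pair
  correlation is therefore calibrated (closed form on the log scale,
  clipped to 0.999) so the derived ratio reproduces the published ratio
  spread. The published amyloid-positive IP ratio spread sits right at the
  boundary of what a lognormal pair permits (the implied correlation is
  ~0.998). The full six-variable latent correlation matrix follows a
  generative model with the IP pair at the core — the eluate being the
  matrix-effect-cleaned signal — and the direct measurements as attenuated
  counterparts with correlated assay noise; this construction is positive
  semidefinite by design, so no repair step distorts the calibrated
  entries. pTau181 is independent of the Abeta pair within subject (no
  between-family correlation is published).
* **CSF block.** The CSF Abeta42/40 ratio is simulated directly from its
  published per-group marginals, truncated at the 0.050 cutoff by rejection
  so simulated group labels always agree with `dichotomize_by_csf()`;
  CSF Abeta40 comes from its own marginal and CSF Abeta42 is derived as
  ratio x Abeta40 (independent Abeta42/Abeta40 draws would put roughly a
  quarter of amyloid-positive subjects on the wrong side of the cutoff).
  The implied Abeta42 medians stay within ~5% of the published row. t-Tau
  and CSF pTau181 are independent lognormal marginals.
* **Covariates.** Age is normal per group (median/MAD as mean/SD), sex and
  ApoE4 are Bernoulli draws at the published frequencies, all independent
  of the analytes — no covariate-analyte dependence is modelled in the
  source analysis.

What the generator does *not* emulate: longitudinal structure, assay batch
effects, heavy-tailed outliers beyond the lognormal, any measurement-error
model beyond the copula-linked marginals, and covariate-analyte dependence
(notably age and ApoE4 are known to correlate with amyloid status in real
cohorts beyond the group frequencies used here). Passing tests on these
cohorts therefore demonstrate correctness and calibration of the
*statistical machinery* under the published summary structure, not
performance claims about real plasma data.

## Numerical choices and problem sizes

* Calibration root-finds (`uniroot`) run at tolerances of 1e-10 to 1e-12;
  the lognormal MAD calibration is verified to 1e-6 relative.
* EM convergence uses a relative log-likelihood tolerance of 1e-10 with a
  1000-iteration cap and collapse guards (vanishing weight or SD restarts
  the fit from a different initialization).
* Degenerate inputs are surfaced explicitly: constant scores yield AUC 0.5
  with a zero-variance flag; an all-identical bootstrap yields a degeneracy
  flag with p = 1; a zero Deming covariance yields a degenerate fit rather
  than a fabricated slope.
* The test suite sizes its simulations to run in about a minute on one
  CPU: type-I calibration uses 500 null cohorts at 200 bootstrap
  replicates, CV calibration 100 simulations at n = 200, marginal/copula
  calibration one cohort of 10^4 per group, and the mixture-cutpoint
  property 60 seeded cohorts of 71 subjects. These sizes give Monte-Carlo
  standard errors comfortably inside the asserted tolerances (e.g. ~0.01
  for a 0.05 rejection rate over 500 simulations).
* Per-stage seeds in `run_full_analysis()` are derived from one master
  seed by fixed offsets, so a single integer reproduces the whole report.

## Known limitations

* The bootstrap p-value is a normal-tail approximation; no BCa or
  percentile intervals are provided (the source procedure is a normal-fit
  test, not an interval method).
* The mixture model is restricted to two components; no model-count
  selection is attempted, and on unimodal data the fit is flagged rather
  than refused.
* Deming regression reports no standard errors; it is used descriptively,
  as in the source analysis.
* Simulated cohorts reproduce published *summaries*; subject-level
  features of the real cohort (outliers, covariate structure) are
  unknowable from the publication, so analyses that depend on them — e.g.
  the exact published AUCs and bootstrap p-values — are reproducible only
  in distribution, not numerically.

## A worked run

```{r example, eval = FALSE}
cohort <- generate_cohort(seed = 11)
report <- run_full_analysis(cohort, analysis_config(seed = 11))
report
write_report(report, "results")
```
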