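# ipiadx

Statistical evaluation of pre-analytical immunoprecipitation (IP) for
blood-based Alzheimer's disease biomarkers.

## What this package is for

Plasma Abeta1-42/1-40 and pTau181 are promising blood biomarkers of brain
amyloid pathology, but direct plasma immunoassays are vulnerable to matrix
effects. One remedy is a pre-analytical clean-up: immunoprecipitate the
analyte onto antibody-coupled magnetic beads and measure it in the eluate
(IP followed by immunoassay, "IP-IA"). Deciding whether that extra step
*helps diagnostically* is a statistics problem about paired methods on the
same subjects, and `ipiadx` implements the full toolkit for it:

* **Effect sizes** per marker and method for the amyloid-positive vs
  amyloid-negative contrast (groups defined by CSF Abeta42/40 <= 0.050):
  relative median difference `100 * (med_pos - med_neg)/med_neg`, relative
  mean difference, and Cohen's d with pooled SD, oriented neg - pos.
* **A 0.632-bootstrap test** for the difference of effect sizes between two
  paired methods: subjects resampled with replacement (stratified by
  group), each replicate's difference refined as
  `0.632 * resampled + 0.368 * observed`, a normal fit to the refined
  differences, and a two-sided p-value from
  `z = m / (s / 0.632)` (the SD is normalised back for the 0.632
  contraction, which keeps the test at its nominal level).
* **ROC analysis**: empirical AUC (Mann-Whitney pair statistic), DeLong
  placement variance and the paired DeLong test for correlated AUCs,
  classification at the Youden point, and stratified 10-fold
  cross-validated logistic-regression ROC for multivariate panels.
* **Unsupervised cutpoints**: a two-component Gaussian mixture with shared
  SD fitted by EM on the pooled values, with the analytic intersection
  `x* = (mu1 + mu2)/2 + sd^2 * log(w1/w2)/(mu2 - mu1)` as threshold.
* **Method agreement**: Pearson correlation and Deming errors-in-variables
  regression (default variance ratio `lambda = 1`).
* **A calibrated cohort simulator**: lognormal marginals matched to
  published per-group medians/MADs, a Gaussian copula matched to the
  published pooled cross-method correlations, and covariate frequencies of
  the 71-subject (39 negative / 32 positive) reference cohort — so the
  whole pipeline is testable without access to subject-level data.

## A worked example

```r
library(ipiadx)

cohort <- generate_cohort(seed = 11)          # 71 subjects, 39 neg / 32 pos
report <- run_full_analysis(cohort, analysis_config(seed = 11))
report
```

```
analysis_report: 71 subjects ( 39 neg / 32 pos )
  single-value ROC AUCs:
    ab_ratio_direct    0.957
    ptau181_direct     0.902
    at_term_direct     0.964
    ab_ratio_ip        0.982
    ptau181_ip         0.971
    at_term_ip         0.990
  bootstrap (Cohen's d, IP - direct) p-values:
    ab_ratio           0.6719
    ptau181            0.01879
    at_term            0.1844
  mixture cutpoint (IP ratio): 0.1163
```

Reading this: on this simulated cohort every marker separates the groups
well (AUCs 0.90-0.99); the 0.632-bootstrap comparison finds a significant
gain in the pTau181 standardized effect size after IP (p = 0.019) but not
for the Abeta ratio; and the unsupervised mixture fit on the IP-eluate
Abeta1-42/1-40 ratio puts the diagnostic threshold at 0.116, between the
two group medians (0.097 and 0.119). `write_report(report, "results")`
writes the four table analogues as CSV, a JSON master report, plot-ready
ROC curves and a timing log.

A thin command-line wrapper with verbs `simulate`, `effects`,
`compare-effects`, `roc`, `cutpoint`, `assoc` and `run-all` is installed at
`inst/cli/ipiadx.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ipiadx.R", package="ipiadx"))')" \
  simulate --seed 7 --out cohort.csv
```

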