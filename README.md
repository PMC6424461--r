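# multihitr

Estimate how many carcinogenic mutations ("hits") a cancer requires, from
the distribution of per-tumor somatic mutation counts.

Most instances of cancer arise when some small combination of *h* specific
somatic mutations is completed — and there are very many (*k*) alternative
combinations that would do. `multihitr` implements the multi-combination
multi-hit model of carcinogenesis: with *G* possible fixable somatic
mutations in the assayed region, the probability that *m* accumulated
mutations complete one given combination is the inclusion–exclusion
probability

P<sub>h</sub>(m) = 1 − Σ<sub>i=1..h</sub> (−1)<sup>i+1</sup> C(h,i) ((G−i)/G)<sup>m</sup> (m ≥ h),

the probability that *any* of the *k* combinations is complete is
P<sub>k</sub>(m) = 1 − (1 − P<sub>h</sub>(m))<sup>k</sup>, and the
probability that the *m*-th mutation is the carcinogenic one is
P(m) = P<sub>k</sub>(m) − P<sub>k</sub>(m−1). Because the model is indexed
by accumulated mutations rather than age, it needs no assumption about the
highly variable somatic mutation rate. Fitting *h* and *k* amounts to
minimizing the RMSD between the observed cohort distribution of mutation
counts (percent of samples per bin of 100 mutations, 0–5000) and the
binned model mass.

The package is aimed at cancer genomicists with per-sample somatic
mutation counts — typically derived from MAF files of matched tumor/normal
whole-exome calls — who want to estimate hit numbers, compare cancer types
or subtypes, and quantify uncertainty. It provides:

* numerically exact evaluation of P<sub>h</sub>, P<sub>k</sub>, P(m) from
  tiny *G* up to exome scale (`prob_single_combination()`,
  `prob_any_combination()`, `prob_increment()`, `evaluate_curve()`);
* MAF ingestion and per-sample counting (`read_maf()`,
  `count_mutations_per_sample()`, `group_cohort()`);
* RMSD grid fitting of (h, k), two-component mixtures of hit numbers,
  percentile-bootstrap CIs for *h*, subsample-stability and
  *G*-sensitivity checks (`fit_single()`, `fit_mixture()`,
  `bootstrap_hit_ci()`, `subsample_stability()`, `sensitivity_G()`);
* synthetic cohort simulation from the model (`sample_cohort()`,
  `parameter_recovery_experiment()`);
* burden-vs-age and hits-vs-stem-cell-division correlation analyses
  (`burden_age_correlation()`, `pearson_with_p()`, `fisher_z_interval()`);
* tidyverse-native interfaces: tibbles in and out, `tidy()`/`glance()` on
  fits, `autoplot()` figures, and a command-line front end
  (`inst/cli/multihit.R`).

## Worked example

Simulate a 500-sample cohort from a known 3-hit model and re-estimate its
parameters:

```r
library(multihitr)

cohort <- sample_cohort(multihit_params(h = 3, k = 9e14),
                        n_samples = 500, seed = 42)
fit <- fit_single(cohort)
fit
#> <multihit_fit> n = 500 samples
#>   optimal model: h = 3 hits, k = 1e+15 combinations, RMSD = 0.43%

tidy(fit)
#> # A tibble: 9 × 4
#>       h       k  rmsd best
#>   <int>   <dbl> <dbl> <lgl>
#> 1     1 6.59e 4 2.89  FALSE
#> 2     2 9.56e 9 1.39  FALSE
#> 3     3 1   e15 0.433 TRUE
#> 4     4 9.41e19 1.01  FALSE
#> 5     5 9.41e24 1.81  FALSE
#> 6     6 9.41e29 2.52  FALSE
#> 7     7 1   e35 3.15  FALSE
#> 8     8 1.06e40 3.70  FALSE
#> 9     9 3.16e36 4.00  FALSE
```

The fitted number of hits is 3 (correct), the fitted number of
combinations 1e15 is within one mantissa step of the true 9e14, and the
per-h profile shows the RMSD rising steeply away from the optimum —
exactly the profile used to read off the estimate. The fit at 0.43%
RMSD means the model's binned distribution deviates from the observed
one by under half a percentage point per bin on average.

Uncertainty in the hit number, by percentile bootstrap:

```r
ci <- bootstrap_hit_ci(cohort, n_boot = 200, seed = 7)
sprintf("95%% CI for h: %d-%d", ci$h_low, ci$h_high)
#> [1] "95% CI for h: 3-3"
```

`autoplot(fit)` overlays the fitted curve on the observed histogram.
Starting from variant calls instead, `read_maf()` +
`count_mutations_per_sample()` produce the same cohort tibble (a small
synthetic MAF ships in `inst/extdata/synthetic-example.maf`), and the
correlation helpers reproduce interval calculations such as

```r
fisher_z_interval(0.522, n = 8)
#> # A tibble: 1 × 2
#>   ci_low ci_high
#>    <dbl>   <dbl>
#> 1 -0.289   0.897
```

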