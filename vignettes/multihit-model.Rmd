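---
title: "Estimating the number of carcinogenic hits from somatic mutation burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the number of carcinogenic hits from somatic mutation burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multihitr)
```

## The model

Carcinogenesis is modeled as the completion of any one of `k` alternative
combinations of `h` specific somatic mutations ("hits"), out of `G`
possible somatic mutations that can become fixed in the assayed genome
region. Mutations accumulate one at a time, each equally likely at any of
the `G` loci. Three quantities follow:

* `P_h(m)` — the probability that `m` accumulated mutations include all
  `h` loci of one given combination. By inclusion–exclusion,
  `P_h(m) = 1 − Σ_{i=1..h} (−1)^{i+1} C(h,i) ((G−i)/G)^m` for `m ≥ h`,
  and 0 below `h`.
* `P_k(m) = 1 − (1 − P_h(m))^k` — the probability that at least one of the
  `k` combinations is complete. Treating combinations as independent is an
  approximation; it is good when `G ≫ m` (two random combinations rarely
  share a locus), and `P_k` → 1 as `m` grows, which bounds how much the
  dependence can matter in the tail. No sharper error bound is available,
  so we document the approximation rather than correct it.
* `P(m) = P_k(m) − P_k(m−1)` — the probability that the `m`-th mutation is
  the one that completes a combination. `P_k(0)` is defined as 0, so
  `P(1) = P_k(1)`.

The model deliberately involves no mutation *rate*: it is indexed by the
number of accumulated mutations, not by age, which is what makes the
estimate robust to the orders-of-magnitude variation in mutation rate
between individuals. Consistent with that motivation, the package also
provides the burden-versus-age correlation analysis
(`burden_age_correlation()`), which in real cohorts shows only weak
correlation.

Fitting compares the observed distribution of per-sample mutation counts
(percent of samples per bin of 100 mutations, over 0–5000) with the binned
model mass `100 · (P_k(b·100) − P_k((b−1)·100))` and minimizes their RMSD
over a grid of `(h, k)`.

## Numerical evaluation

Direct double-precision evaluation of the alternating inclusion–exclusion
sum is unusable in the regime that matters: at `G ≈ 1e8` the terms are
O(1) while `P_h` can be ~1e-40, so every significant digit cancels.
`prob_single_combination()` instead runs a forward recurrence over the
number of distinct target loci already hit (states `0..h`; a new target
locus is hit with probability `(h−s)/G` per draw). All terms are
non-negative — no cancellation — and the recurrence is mathematically
identical to the inclusion–exclusion sum, not an approximation. Against a
150-digit arbitrary-precision evaluation of the exact sum it agrees to
relative error below 1e−12 across `G ∈ {1e6, 1.0725e8, 8.58e8}`,
`h ∈ 1..9`, `m ≤ 5000`, and at small `G` it reproduces exhaustive
enumeration exactly. A widely used alternative, the identity
`P_h ≈ (1 − (1−1/G)^m)^h`, is accurate to O(h²m/G²) only for `G ≫ mh` and
fails at small `G`; the recurrence costs the same and is exact everywhere,
so the package uses one scheme for all regimes.

`P_k` is evaluated as `-expm1(k * log1p(-P_h))`: `k·P_h` is the only
well-scaled quantity when `P_h ~ 1e-40` and `k ~ 1e40`. `k` is treated as
a positive real (the search spans 1e3–1e48 and the expression is smooth in
`k`).

Two numerical points that surface in testing are worth recording. First,
the naive expression `1 − ((G−1)/G)^m` for the one-hit closed form loses
about eight significant digits at `G ≈ 1e8` in double precision; its
stable form is `-expm1(m·log1p(−1/G))`, and that is what the package's
tests compare against. Second, an arbitrary-precision oracle for `P_h`
needs comfortably more digits than the answer's smallness: at
`(G = 8.58e8, h = 9, m = 10)`, `P_h ≈ 1e−72`, so a 60-digit evaluation of
the alternating sum retains no correct digits; the frozen reference values
were computed at 150 digits.

## Default parameters

* `G = 3.25e9 × 2 × 1.1 × 1.5 / 100 = 1.0725e8`
  (`default_genome_target_count()`): a ~3.25 Gbp diploid genome, ~1.5%
  exome, and on average 1.1 fixable mutations per locus. This matches
  whole-exome somatic calls; whole-genome data would need a
  correspondingly larger `G`. Fits are insensitive to even an 8-fold
  change in `G` (`sensitivity_G()`).
* Binning: width 100, 50 bins (counts 0–5000). Bin 1 covers 0–100
  inclusive; bin `b` covers `100(b−1)+1 … 100b`. Samples above 5000
  (hypermutators) are excluded from the comparison with a warning — the
  model mass beyond 5000 is likewise simply absent, not renormalized — and
  `n_bins` can be widened instead.
* `k` search: for `h = 1..9` the RMSD minima lie in known decade ranges
  (1e3–1e6 up to 1e37–1e48); the coarse grid takes mantissas 1–9 in every
  decade of the range, matching the single-digit-mantissa resolution at
  which `k` estimates are conventionally reported, followed by 20
  log-spaced refinement points within ±0.5 decade of the coarse minimum
  (the refinement is allowed to step slightly outside the published range
  edge, since the ranges merely bracket where minima occur).
* Ties within 1e−9 RMSD are broken toward smaller `h`, then smaller `k`
  (parsimony; the choice only matters on degenerate inputs).
* Cohorts below 200 samples warn: subsampling experiments show fits are
  stable above that size and erratic below it.
* Mixture fitting: all pairs `hi < hj` from 1..9 and shares
  `a ∈ {10, …, 90}`; both components' `k` are searched jointly on the
  coarse grid (via a quadratic expansion of the mixture residual, so the
  joint search is a matrix product, not a double loop), then refined
  alternately one pass each. Reported shares are multiples of 10 by
  construction.
* Bootstrap CI for `h`: percentile method, resampling samples with
  replacement (default 1000 resamples), refitting on the coarse grid only
  for speed. This is a deliberately minimal reading of "95% CI" — the
  upstream procedure is not specified in detail — and is flagged in the
  result's `method` field.

## The synthetic-data generator

`sample_cohort()` draws counts from the model itself by inverse-CDF
sampling of `P(m)/P_k(m_max)` on `1..m_max` (truncated and renormalized,
so the generative distribution equals the fitted one on the fitting
range). Mixtures draw each sample's component first; an optional
hypermutator fraction is drawn uniformly from `(m_max, 10·m_max]` to
exercise overflow handling. One seeded stream, consumed in a documented
order (components, hypermutator flags, counts), makes cohorts bitwise
reproducible.

What the generator emulates: cohort sizes of 200–1000, integer counts
concentrated in 0–5000 with model-determined mode and variance, optional
two-component structure and a hypermutator tail. What it does not emulate:
per-locus mutability heterogeneity (CpG sites, repeats), mutational
signatures, germline hits, subclonal structure, or measurement error in
variant calling. Passing recovery tests therefore show that the estimation
machinery inverts the model correctly at realistic sample sizes — not that
the model is true of any real cohort.

## Verification strategy and problem sizes

The test suite checks, at desk scale:

* exact agreement of `P_h` with exhaustive enumeration (`G ≤ 6`, `m ≤ 6`),
  and with the 150-digit inclusion–exclusion oracle at exome scale
  (≤ 1e−6 relative, observed < 1e−12);
* telescoping conservation `Σ P(m) = P_k(M)` to 1e−12 at the fitted
  `(h, k)` scales;
* parameter recovery: 20 simulated cohorts of 500 samples for each of
  `h ∈ {2, 3, 5, 8}` at reported-`k` magnitudes, requiring ≥ 90% correct
  `h`. Five hundred samples and 20 replicates keep the full suite under a
  minute while leaving the ≥ 90% bar meaningful;
* mixture recovery on a 40% 3-hit + 60% 8-hit mix, 5 cohorts of 500: the
  modal fitted pair must be (3, 8) with share within ±10 points. A single
  cohort is occasionally better fit by (3, 9) — the 8- and 9-hit curves
  are close at this size, which is also why single-model recovery at
  `h = 8` hovers near 90% and why confidence intervals for high-hit
  cancer types are wide — so the property is asserted over replicates
  rather than one draw;
* bootstrap CI coverage, subsample stability at 80%, and `G`-sensitivity
  at factors {1, 8} on simulated cohorts.

`scripts/acceptance.R` re-runs the same computations from scratch under a
caller-supplied seed and writes the resulting numbers as JSON.

## Known limitations

* The independence approximation in `P_k` is uncorrected (see above).
* Estimates are of the *average* number of hits; a cohort mixing subtypes
  with different `h` is summarized either by one average or by a
  two-component mixture, never more components.
* Counts above 5000 do not inform the fit.
* With fewer than ~200 samples the binned distribution is too noisy for a
  stable estimate; the package warns but does not refuse.
* If some hits are germline (not somatic), the somatic estimate
  understates the total number of hits required.
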