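---
title: "Methods and design of mirprospect"
author: "mirprospect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mirprospect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirprospect)
```

# The analysis problem

A prospective matched case-control design asks whether baseline blood
miRNA profiles differ between patients who later develop cancer (a
small cohort 2) and matched patients who do not (a large cohort 1).
Three statistical features dominate the design: the feature count (on
the order of 2549 miRNAs) far exceeds the sample count (~534), the
cohorts are strongly unbalanced (~33 vs ~501), and the covariates
(age, gender, smoking history, pack-years) are matched rather than
randomized. Every module of this package exists to handle one of those
features: dual test families with FDR control for the p >> n problem,
Welch tests, class-weighted classifiers and an unbalanced power solver
for the 15:1 imbalance, and explicit confounder screens plus balance
tests for the matching.

# Preprocessing

Raw probe intensities go through four steps, each an explicit state
transition of the `expr_matrix` container (`raw` → `collapsed` →
`normalized` → `log2`), so an operation applied to the wrong stage
fails loudly rather than silently:

1. **Background subtraction** (`subtract_background`): scalar or
   per-sample background, result clamped at a floor (default 1
   intensity unit) so the later log is defined. The default background
   is 0 — the generator already produces background-free data, and
   array vendors' background models differ enough that we leave the
   value to the user rather than invent one.
2. **Replicate collapsing** (`collapse_replicates`): the per-array
   expression of a miRNA is the median of its replicate probes —
   robust to a single failed spot, and the convention used by the
   motivating protocol.
3. **Quantile normalization** (`quantile_normalize`, via
   `limma::normalizeQuantiles(ties = TRUE)`): every sample receives
   the common distribution of per-rank column means; tied values share
   the mean of their tied ranks' reference values. Two consequences
   worth knowing: the operation is idempotent and exactly
   distribution-equalizing on tie-free data, while tied columns end up
   with averaged values (the standard deterministic convention).
4. **log2 transform**. The package normalizes on the linear scale and
   then takes logs by default; both orders occur in microarray
   practice, so `normalize_expression(log_after_normalize = FALSE)`
   exposes the other one and makes the choice auditable.

The Shapiro–Wilk screen (`normality_screen`) reports, per miRNA, the
normality p-value on the linear and the log2 scale. On log-normal
intensities the linear scale is rejected almost everywhere while the
log scale is rejected at roughly the nominal rate — the empirical
justification for running both a parametric and a rank-based test
downstream rather than trusting either distributional assumption.

# Differential expression

`run_diffexp` computes per miRNA:

* a two-tailed unpaired t-test. **Welch by default**: with 33 vs 501
  samples the pooled-variance assumption buys nothing and costs
  robustness; the pooled form remains available (`var_equal = TRUE`)
  and is what the two-level ANOVA identity (F = t²) refers to.
* an exact tie-aware Wilcoxon–Mann–Whitney test. For total n up to
  `exact_limit` (default 50) the permutation distribution of the rank
  sum is computed exactly by dynamic programming on the observed
  mid-ranks (doubled to integers), so ties need no approximation; the
  two-tailed p is twice the smaller tail, capped at 1. Above the limit
  the normal approximation with tie and continuity correction takes
  over; at n = 60 the two routes agree to a few thousandths. Counts
  stay below 2^53 throughout the exact range, so double arithmetic is
  itself exact.
* Benjamini–Hochberg adjustment, **within each test family
  separately** — each family is its own multiple-testing universe and
  the outputs report raw and adjusted values for both.
* the fold change as the linear-scale ratio of cohort medians oriented
  cohort 1 / cohort 2 (down-regulation in the cancer cohort gives a
  fold change above 1, matching how such results are usually phrased),
  and the signed log2 fold change as cohort 2 − cohort 1 for volcano
  plots. Reporting both removes the usual orientation ambiguity.
* the ROC-AUC via the Mann–Whitney identity (ties count one half) —
  used later as the enrichment ranking criterion and as the classifier
  metric.

The concordance of the two families is summarized as the Pearson
correlation of the raw p-value vectors (computed on p, not −log p; the
choice matters little on planted data and is fixed for determinism).

# Cutoff-free enrichment

Given a universe of m ranked miRNAs and a category with l of them, the
running sum starts at 0 and, scanning the ranking from the top, adds
m − l on a member and subtracts l otherwise; it ends at exactly 0, and
the statistic is the maximum prefix value. The exact p-value is the
fraction of all `choose(m, l)` arrangements whose maximum reaches the
observed one.

The key observation behind the dynamic program: after i positions with
j hits the prefix sum is j·m − i·l — it depends only on (i, j), not on
the path. Arrangements whose every prefix stays *below* the observed
maximum B are therefore counted by a lattice recursion
`f(i, j) = f(i−1, j−1) + f(i−1, j)` with cells satisfying
`j·m − i·l ≥ B` zeroed out, and the p-value is one minus the final
count over `choose(m, l)`. Counting runs in log space (log-sum-exp per
cell), so m = 2549 with l in the hundreds is exact to floating
precision and takes well under a second; the complement is taken with
`expm1`, keeping tiny p-values accurate.

Numerical and convention choices:

* The count includes arrangements *attaining* B (`convention = "geq"`),
  the standard validity convention for permutation p-values — the
  minimum attainable p is `1/choose(m, l)` and p = 0 is impossible. A
  strict-exceedance variant (`"gt"`) is provided because the verbal
  description of such statistics is often ambiguous on this point.
* The statistic is one-sided toward the top of the ranking. Depletion
  is tested by reversing the ranking, not by a two-sided variant.
* Categories are intersected with the measured universe before l is
  computed; categories that end up empty or universe-sized are skipped
  with a warning since the statistic degenerates.
* Observed maxima are validated against the step lattice; a value not
  of the form j·m − i·l is rejected as an input error.

The set-based companion (`enrich_set_based`) is the upper-tail
hypergeometric test of a hard significant/not-significant split
against the universe; both raw p and BH q are emitted for each method
because published category counts are often reported on raw p.

# Confounder screens and the history analysis

`anova_screen` (one-way equal-variance ANOVA per miRNA) serves
categorical covariates; `correlation_screen` (Pearson) serves
continuous ones; both BH-adjust across miRNAs and drop degenerate
levels or missing values with warnings (pairwise-complete exclusion —
the simplest defensible policy when missingness is not modeled).
`cohort_balance_tests` mirrors the matching table: Welch t for age and
pack-years, Fisher's exact 2×2 for gender, chi-square for the
three-level smoking status with an exact fallback whenever an expected
cell drops below 5.

The four-group history analysis crosses prior cancer history with
later cancer development (1: neither, 2: developed only, 3: history
only, 4: both). A per-miRNA four-group ANOVA detects expression
structure invisible to the two-cohort split (a shift confined to group
3 is the canonical example), and the "extreme" comparison of groups 1
vs 4 reuses the full differential expression machinery including its
volcano export.

# Classification protocol

The classifier contract is an additive tree ensemble with logistic
loss, per-sample class weights, and tunable leaf and tree counts;
`xgboost` (histogram method, loss-guided growth, `max_leaves`) is the
implementation. The protocol around it is what matters scientifically:

* stratified k-fold cross-validation, repeated (defaults 5 × 5), fold
  shuffles derived from `seed + repeat`, everything single-threaded
  and bit-reproducible;
* ANOVA-F feature ranking recomputed **inside every training fold** —
  the test suite demonstrates, on pure noise, the optimism you get by
  selecting on the full data first;
* class weights `total/(2·n_c)`, so a 501:33 imbalance weights the
  minority ~15.2:1; the suite shows this improves balanced accuracy
  under strong imbalance;
* grid defaults: signature sizes 2–13, leaves {7, 15, 31}, trees
  {50, 100, 200} (learning rate 0.3). The protocol fixes the *shape*
  of the search, and these are conventional values for cohort-sized
  tabular data;
* model selection by mean cross-validated AUC, never accuracy —
  accuracy is inflated by imbalance and is reported only as context;
  ties go to the smaller model. The reported signature comes from
  refitting the winning configuration on the whole dataset (the
  cross-validation metrics remain the honest performance estimate).

`pairwise_group_classification` applies the same protocol to pairs of
history groups.

# Power

`solve_effect_size` finds the smallest Cohen's d at which the
two-sided two-sample t-test reaches the requested power, by root
finding (tolerance 1e-8 in power) on the noncentral-t power function
with noncentrality `d·sqrt(n1·n2/(n1+n2))` — exact for the t-test and
valid for unbalanced designs, which base R's `power.t.test` does not
cover (the two agree at equal n, which the tests use as an oracle).
At the motivating design this yields d ≈ 0.9 for 33 vs 33 and
d ≈ 0.65 for 33 vs 500 (alpha 0.05, power 0.95). A closed-form normal
approximation mode exists for cross-checking; its gap to the exact
answer is ~0.016 at n = 33 per group and only closes to two decimals
around n ≈ 200 per group, so the noncentral route is the default. A
Monte-Carlo check (10⁵ simulated tests) confirms the solved d
reproduces the requested power within ±0.01.

# The synthetic cohort generator

`simulate_cohort` emulates the statistical structure the analysis
assumes — it is a first-class, tested module, not a fixture:

* per-miRNA baselines: log2 means uniform on [4, 14] and log2 SDs
  uniform on [0.5, 1.5], giving log-normal linear intensities with
  realistic dynamic range and no single "true" distribution on either
  scale (matching what normality screens find on real arrays);
* planted effects: a fraction `frac_de` (default 1%) of miRNAs get a
  case-vs-control mean shift of `effect_size_d` (default 1.5) times
  their own log2 SD, signed so that `frac_down` (default 199/269 ≈
  0.74) point down in cases — the down-dominant pattern the motivating
  data showed. Planting on the log scale keeps Cohen's d interpretable
  and connects directly to the power module;
* replicate probes (default 3) are log-scale noisy copies (SD 0.25) of
  the latent sample value, plus an optional additive background;
* covariates are drawn identically in both cohorts — the matched
  design — with pooled values typical of an elderly COPD cohort (age
  ~N(67, 7.7), pack-years ~N(48, 37) truncated at 0, 35% female,
  smoking never/past/present ≈ 4/72/24%). Couplings between
  expression and age, smoking or history group 3 are off by default
  and can be switched on to exercise the confounder screens;
* the four history groups are drawn conditionally on the fixed cohort
  sizes from a 4-vector of group probabilities (default ≈ 15% prior
  cancer history in both cohorts);
* one category set samples planted miRNAs with elevated probability (a
  positive control with known direction — note that with down-dominant
  effects it concentrates at the *bottom* of an AUC-descending
  ranking, so the enrichment positive control reverses the ranking or
  plants up-regulated effects); the remaining sets are random.

Everything is a deterministic function of the seed.

What the generator does **not** emulate: array spatial artifacts,
batch effects, scanner saturation, correlated miRNA co-expression
blocks, missing covariates, or informative matching failures. Passing
tests therefore certify the statistical machinery under the model's
assumptions — independence across miRNAs above all — not performance
on any real cohort; in particular, BH's FDR control under dependence,
while theoretically robust to positive regression dependence, is only
exercised here under independence.

# Problem sizes used by the test suite

Unit tests run at deliberately small dimensions (tens to hundreds of
miRNAs, tens of samples) with exhaustive brute-force oracles wherever
enumeration is feasible (all running-sum p-values up to m = 12, all
tied Wilcoxon cases up to n = 12). The end-to-end checks use the
study's own dimensions — 2549 miRNAs, 33 vs 501 samples — with 20 null
cohorts for the false-discovery check and three planted cohorts for
the recovery check, sizes chosen to keep the whole suite in the
few-minute range while leaving the estimates' granularity meaningfully
finer than the thresholds they are compared against.

# Known limitations

* The exact Wilcoxon enumeration is limited to total n ≤ ~50 by memory
  of the rank-sum DP table; beyond it the corrected normal
  approximation is used (the motivating design, n = 534, sits firmly
  in that regime, as it did in the original analyses).
* The enrichment DP returns p-values accurate to floating precision;
  for p below ~1e-15 only the order of magnitude is meaningful.
* `normality_screen` inherits Shapiro–Wilk's 3–5000 sample limit.
* The power solver treats the t-test as the analysis; it does not
  model the multiplicity adjustment (a per-miRNA, not family-wise,
  design quantity — as such calculations are conventionally done).
* Group medians, not means, define fold changes; on heavily tied data
  medians can make the linear fold change exactly 1 even when tails
  differ.
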