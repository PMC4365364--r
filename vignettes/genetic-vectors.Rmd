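---
title: "Genetic-vector analysis: model, exact statistics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-vector analysis: model, exact statistics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gva)
```

## The model

Case-control association screens usually test one marker at a time, or
phase haplotypes and test those. This package takes a third route: fix an
ordered panel of $N$ three-state markers (biallelic SNP genotypes, or any
categorical variable with three levels such as the count of HLA-DRB1
shared-epitope alleles), and characterize every individual by the full
ordered tuple of their genotype states,
$$\nu = (\gamma_1, \gamma_2, \dots, \gamma_N), \qquad \gamma_i \in \{1,2,3\}.$$
We call this tuple the individual's *genetic vector* (GV). Individuals
with identical tuples form a GV group; in real cohorts the number of
occupied groups is far smaller than the number of individuals, and the
group frequencies are heavy-tailed. Because a person has exactly one GV,
the genotype–phenotype assignment is unambiguous: no dominance model, no
phasing, and any genotype–genotype interaction among the panel markers is
carried along automatically, because the combination itself is the unit of
analysis.

A GV is conveniently summarized by its *index matrix*: the $3 \times N$
binary matrix with a single 1 per column marking the state taken at each
marker (`index_matrix()`). Count-weighted averages of index matrices over
any set of individuals are column-stochastic *genotype-frequency maps*
(`frequency_map()`, `contrast_average()`), and co-occurrence rates of
state pairs come from the same bookkeeping (`pair_rate()`).

Each group $\nu$ holds $n_\nu^h$ controls and $n_\nu^s$ cases out of
cohort totals $N_h$ and $N_s$, giving the per-group odds ratio
$$\mathrm{OR}_\nu = \frac{n_\nu^s\,(N_h - n_\nu^h)}{n_\nu^h\,(N_s - n_\nu^s)},$$
identical to the odds-ratio of the per-group frequencies
$p_\nu^\alpha = n_\nu^\alpha / N_\alpha$. Groups with $n_\nu^h = 0$ or
$n_\nu^s = 0$ ("zero GVs": solely sick / solely healthy) have no finite
odds ratio and are treated separately throughout.

## Exact null of the per-group odds ratio

The statistical question for one group of fixed size
$n_\nu^t = n_\nu^h + n_\nu^s$ is how large an odds ratio chance alone
would produce. Conditioning on $(N_h, N_s, n_\nu^t)$, the number of cases
$k$ in the group follows the hypergeometric law of Fisher's exact test,
and each admissible $k$ maps to an odds ratio
$$\mathrm{OR}(k) = \frac{k\,(N_h - n_\nu^t + k)}{(n_\nu^t - k)(N_s - k)},$$
strictly increasing in $k$, equal to 0 at the all-control edge and
infinite at the all-case edge. `or_distribution()` materializes this
discrete distribution; it depends only on the three integers, so groups of
equal size share one null.

The distribution is markedly asymmetric and, for small groups, very
coarse, so normal-theory intervals are inappropriate. Two exact criteria
are used instead:

* **Fluctuation thresholds** (`or_thresholds()`): the smallest support
  value whose strict upper tail has mass at most $\alpha$ (default 0.05),
  and the mirrored lower threshold. Discreteness means the achieved tail
  is at most $\alpha$, and for tiny groups possibly only the empty tail
  qualifies; that situation is flagged rather than hidden.
* **Tail probability** (`tail_prob()`): the exact probability that the
  randomized odds ratio strictly exceeds (or falls below) the observed
  one, the natural exact confidence measure per group.

Moments (`mean_or()`, `var_or()`) are taken as the literal interior sum
over $k = 1 \dots n_\nu^t - 1$ with raw hypergeometric weights: the
$k = 0$ term contributes nothing and the infinite-OR endpoint is excluded
so the mean exists; the weights are deliberately not renormalized after
the exclusion, and the excluded endpoint mass is always reported
separately. For a worked example at $N_h = 779$, $N_s = 1500$,
$n^t = 37$ this yields a mean randomized OR of 1.0929 and an upper 5%
threshold of 1.90 — an observed OR of 4.36 for a group of 4 controls and
33 cases is therefore far outside its fluctuation band.

```{r example}
d <- or_distribution(N_h = 779, N_s = 1500, n_t = 37)
mean_or(d)
or_thresholds(d, alpha = 0.05)
odds_ratio(4, 33, 779, 1500)
```

## Two-cohort screening pipeline

`gva(a, b, alpha, totals, crop)` runs the whole procedure and returns a
classed fit:

1. group each cohort (`gv_table()`), align on the common vector set
   (`align_cohorts()`, `common_basis()`);
2. set aside vectors that are zero GVs in either cohort;
3. compute per-group statistics per cohort (`gv_stats()`);
4. stratify common non-zero vectors by effect direction into
   $\Omega_{11}$ (risk in both), $\Omega_{22}$ (protective in both) and
   the two discordant classes (`stratify_omega()`);
5. keep only vectors beyond the threshold *in both cohorts*
   (`select_consistent()`): risk vectors above both upper thresholds,
   protective vectors below both lower thresholds;
6. average the index matrices of the selected groups with count weights
   (`contrast_average()`) and difference the resulting profiles;
7. profile zero GVs separately (`zero_gv_matrices()`).

Replication in an independent cohort, not significance in one, is the
selection criterion; single-cohort outliers are reported but never enter
the contrast profiles.

### Parameters that matter

* `alpha` (default 0.05): per-tail accuracy of the thresholds.
  Selection is monotone in it — shrinking `alpha` never adds vectors. No
  multiplicity correction across groups is applied; the fit reports raw
  tails and the number of screened groups so users can adjust (e.g.
  Bonferroni over `length(fit$analysis)`).
* `totals` (default `"filtered"`): the null for each group conditions on
  the totals of the screening set (common, zero-free vectors), matching
  the worked example above; `"raw"` conditions on full cohort sizes.
  With pre-grouped subset tables whose totals were set explicitly,
  `"raw"` preserves those totals.
* `crop`: re-running on a marker subset merges groups with identical
  projections (counts are conserved); markers whose removal leaves the
  contrast unchanged are uninformative for it.

### Conventions at the boundaries

* An odds ratio of exactly 1 (possible with integer counts) falls on the
  protective side of the stratification; occurrences are counted in
  `fit$omega$boundary`.
* The protective-side criterion uses the lower tail of the same
  cohort-specific distribution, not the reciprocal of the upper
  threshold — the distribution's asymmetry makes those differ.
* The infinite-OR endpoint is excluded from upper tails and thresholds by
  default (its mass is reported); `tail_prob(..., include_inf = TRUE)`
  includes it.
* Threshold ties are accepted: a support value whose strict tail equals
  `alpha` exactly becomes the threshold.

## Numerical policy

Probabilities come from `dhyper()`, which works in log space and is
stable for cohort sizes well beyond $10^5$; tests cross-check it against
direct binomial-coefficient ratios wherever those are exactly
representable in doubles. Odds ratios are formed from integer counts
whose products stay below $2^{53}$ for any realistic cohort, so the count
and frequency forms agree to machine precision. Tables are ordered
lexicographically by state tuple, making every report and serialization
deterministic.

## The synthetic generator

`generate_pair(sim_config(...))` draws paired cohorts from a shared pool
of distinct vectors with power-law base frequencies (default Zipf
exponent 1, matching the observed few-groups-carry-most-people
structure), tilts case frequencies per vector as
$p^s_\nu \propto p^h_\nu \cdot \mathrm{OR}_\nu$ so planted odds ratios
hold in expectation under the count definition, perturbs cohort B's base
frequencies by a log-normal factor (default sd 0.2) to emulate
between-population differences, and can plant case-only/control-only
groups. Defaults of 1000 controls and 1500 cases per cohort over 150
vectors give group-size and overlap structure comparable to real
screens. Everything is driven by one mandatory seed and is
byte-reproducible.

What the generator does **not** emulate: linkage disequilibrium or any
marker–marker correlation within a vector, Hardy–Weinberg structure,
population stratification, genotyping error, or missingness. Passing
simulation tests therefore demonstrates correctness of the grouping and
the exact statistics under the stated sampling model, not robustness to
those real-data features.

Simulation scale used in the shipped tests: the recovery study runs 100
replicate pairs (cohorts of 1000/1500, 60-vector pool, one group planted
at OR 5 with expected size ≈ 40) and requires the planted group to be
selected in at least 90% of replicates; null calibration uses 40
replicate pairs and checks that per-group upper-tail flags stay within
sampling noise of $\alpha$. These sizes keep the whole suite to a few
minutes while leaving the checks well-powered.

## Missing data and input handling

A genetic vector exists only as a complete product of states, so
individuals with any missing or unrecognized call are excluded from
grouping — flagged and counted, never silently dropped
(`complete_genotypes()`). Heterozygote SNP labels match regardless of
allele order ("CA" ≡ "AC"). VCF input maps diploid GT fields by
alternate-allele dose and ignores phasing; multiallelic panel records are
rejected rather than reinterpreted. Published pre-grouped count tables
enter through `gv_table_from_counts()` with explicit cohort totals, which
is how the shipped `contrast_fixtures()` reconstruct the reference
rheumatoid-arthritis contrast groups.

## Known limitations

* As the panel grows, groups shrink towards singletons and the exact
  statistics lose power; cropping is the built-in mitigation, but
  choosing the panel is the analyst's task.
* No multiple-testing correction is built in (by design; see above).
* Zero-GV profiles rest on few individuals; the package computes them
  and their cross-cohort consistency flags but draws no significance
  statement from them.
* Markers are strictly three-state; multiallelic extensions are out of
  scope.
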