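---
title: "Methods: call-aware paired fold-change analysis of the extended Warburg network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: call-aware paired fold-change analysis of the extended Warburg network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warburgDE)
```

## The model

`warburgDE` analyses paired tumor / adjacent-normal microarray studies in
which each probe set carries a MAS5-style signal intensity and a detection
call (`P`resent / `M`arginal / `A`bsent). The unit of inference is the
per-patient signed fold change

$$\mathrm{FC}_i = \begin{cases} T_i/N_i & T_i/N_i \ge 1\\ -\,N_i/T_i & \text{otherwise,}\end{cases}$$

a convention in which magnitude is always at least 1 and direction lives in
the sign; a ratio of exactly 1 maps to $+1$ (the convention reserves the
negative branch for ratios strictly below one). The implicit model is
multiplicative: intensities are treated as log-normal, so ratios — not
differences — are the meaningful contrast, and all averaging and testing of
mixed-direction genes happens on the natural-log scale where the ratios are
approximately normal.

**Call filter.** A patient pair contributes to a gene only if it has usable
data. The rule implemented is: exclude the pair when *both* its tumor and
normal calls are Absent. A stricter reading — exclude when either call is
Absent — is available (`strict_calls = TRUE`) but off by default, because
the both-absent reading is the only one consistent with the worked examples
the package's golden fixture encodes (a gene with five Absent/Absent pairs
among nine retains four patients, one with three such pairs retains six,
and so on). When every pair is excluded the gene is still summarized from
all pairs but flagged `reliable = FALSE`: a fold change of two numbers the
scanner could not distinguish from background is reported, not trusted.

**Averaging.** All-positive rows are averaged arithmetically. Rows with any
negative value are averaged geometrically: negatives are converted to
positive reciprocals, the `ln` values are averaged and exponentiated, and a
sub-unity result is re-expressed as a negative reciprocal. The asymmetry is
deliberate and follows the source procedure: an all-positive row is
approximately log-normal around a positive effect and its arithmetic mean is
the conventional summary, whereas a mixed row is not normally distributed on
the ratio scale at all.

**Testing.** Significance is a two-tailed one-sample t-test of the log fold
changes against zero, $t = \bar x / (s/\sqrt n)$ with $n-1$ degrees of
freedom, computed on exactly the patients that survived the call filter. No
multiple-testing correction is applied to the `significant` column — the
analysis is a focused interrogation of ~70 pre-specified network genes, not
a genome-wide screen — but a Benjamini–Hochberg FDR column is emitted for
reference and never drives classification. Genes are classified `over` /
`under` / `unchanged` by the strict rule $|\mathrm{avgFC}| > 2$; exactly 2
is `unchanged`.

Degenerate inputs are flagged rather than thrown: fewer than two usable
patients gives `flag = "n_too_small"`, identical log fold changes give
`flag = "zero_variance"`, both with `NA` p-values — never $p = 0$.

## Probe-set selection

Genes interrogated by several probe sets get one representative, chosen by a
strict lexicographic priority:

1. **reliability** — at least 50% of all samples have a Present call
   (the boundary itself, e.g. 10 of 20, counts as reliable);
2. **suffix** — `_at` designs outrank `_s_at`, which outrank `_x_at`,
   which outrank anything else;
3. **mean intensity** across all samples, higher first;
4. smallest probe identifier, as a deterministic tie-break.

Two points here were genuinely open and are package decisions. First,
`_s_at` is ranked above `_x_at`: both are penalized relative to `_at`, and
`_x_at` designs are the more promiscuous cross-hybridizers by platform
design, so they rank last. Second, Marginal calls do *not* count toward the
Present fraction (the criterion names Present calls specifically); a
`count_marginal` flag flips this. The reliability fraction is computed over
*all* samples, matching the all-samples phrasing of the intensity criterion.
For data sets shipped without calls, `mode = "intensity_only"` maximizes
mean intensity alone — the documented fallback used for confirmation
cohorts — and is provably insensitive to any call information.

## Clustering QC

Sample quality control is hierarchical clustering of the gene-level
intensity matrix: Euclidean distances between samples, average linkage
(UPGMA). Intensities are clustered raw by default because the procedure
being reimplemented names only the distance and the linkage; `log2` and
standardization are exposed as options, and the package's own synthetic
demonstrations use `log2` (Euclidean distance on raw MAS5 intensities is
dominated by the handful of brightest genes). Average linkage admits no
inversions, and the implementation asserts non-decreasing merge heights on
every run.

The dendrogram judgment "one patient's tumor tracks everyone else's
normals" is operationalized as a two-cluster cut: the cluster holding the
majority of tumor samples is the tumor group, and any patient whose tumor
sample lands in the normal group (or vice versa) is flagged discordant and,
by default, excluded from the fit (`exclude_discordant`). This is an
artifact definition of a visual judgment and is labelled as such in the
concordance report. A degenerate tree (all merge heights equal) yields an
indeterminate report instead of an arbitrary split.

## The curated network

The packaged network (140 nodes, 153 edges) is a curated reconstruction of
the extended aerobic-glycolysis map: glycolysis, gluconeogenesis, the
pentose phosphate pathway, the TCA cycle, serine/glycine synthesis,
fructose utilization, the PKM splicing regulators, glutamine utilization and
the initial steps of fatty acid synthesis, with gene nodes named by HGNC
symbol and metabolite nodes for readability of the exports. It is assembled
from the stated pathway composition of the study the package reimplements,
not parsed from any pathway-database interchange file; the exact node/edge
inventory of the original hand-merged map is not machine-readable, so the
file ships as a documented curation. Overlay is by exact HGNC symbol match
(no alias resolution), never mutates topology, and reports both network
genes without a summary and summaries without a network node. Exports (SIF,
node-attribute TSV, GraphML) are byte-deterministic given identical inputs.

## The synthetic-data generator

The simulator emulates the statistical shape the analysis assumes, so every
stage is testable without any external download:

| parameter | default | meaning |
|---|---|---|
| `n_patients` | 10 | tumor/normal pairs |
| `baseline_log_intensity` | `(log 500, 1.2)` | per-gene ln baseline, shared across patients |
| `patient_baseline_sd` | 0.3 | patient deviation from the gene baseline (ln scale) |
| `effect_profile` | see below | pathway-level `(mean, sd)` of per-patient ln-FC |
| `measurement_noise_sd` | 0.35 | extra ln-scale noise on the tumor signal |
| `absent_threshold` / `marginal_band` | 50 / 80 | call boundaries on the intensity scale |
| `random_absent_rate` | 0.01 | sporadic Absent calls regardless of signal |
| `probes_per_gene_prob` | (.5, .3, .2) | 1–3 probe sets per gene |
| `attenuation` | (0.3, 0.1) | signal of the `_s_at` / `_x_at` duplicates |

Normal signals are log-normal around a *shared* per-gene baseline — this is
what makes samples of one tissue resemble each other across patients, and
hence what lets a two-cluster cut separate tissue rather than patient; the
patient-level deviation (0.3) is kept below the baseline spread (1.2) for
the same reason. Tumor signals multiply the patient's normal signal by
`exp(effect + noise)`. The default effect profile encodes the direction
pattern of a renal Warburg shift — glycolysis up (`ln 3`), gluconeogenesis
strongly down (`-ln 8`), serine/glycine down (`-ln 4`), TCA mildly down,
PPP null — with per-patient spreads of 0.3–0.6 on the ln scale, in line
with the wide patient scatter visible in the fixture tables. Calls derive
from signal level (Absent below 50, Marginal to 80) plus a 1% sporadic
Absent rate, so the call filter is exercised both systematically (planted
all-absent genes) and sporadically.

What the simulator does **not** model: array effects and normalization
(out of scope — inputs are assumed MAS5-summarized and comparable),
probe-level sequence effects, correlated genes within a pathway, and
batch structure. Passing tests on synthetic data therefore demonstrate the
correctness of the pipeline's arithmetic and logic under the stated model,
not robustness to normalization artifacts in real arrays.

## Numerical choices and test design

* Averages recomputed from the packaged fixture are compared at ±0.02
  absolute: the fixture's per-patient inputs are printed to two decimals,
  and propagation of that rounding through nine-value means stays inside
  this band. p-values are compared at 2% relative, and only for rows where
  all nine patients contribute; rows with excluded patients are reported
  but not graded, because the source tables' p-values for those rows follow
  a fixed eight-degrees-of-freedom convention (verifiable from the printed
  values) rather than the per-row $n-1$ this package implements, which is
  the statistically defensible choice.
* Four fixture rows are known-discrepant and documented in
  `golden_known_discrepancies()`: two averages where the source applied the
  other averaging branch than its own rule prescribes (HK1, ME2), one
  p-value reachable only from the unrounded inputs (ACLY), and one p-value
  inconsistent with its own row at any rounding (ACACB).
* Brute-force oracles back the two algorithmic steps with published
  behaviour but no published data: UPGMA is checked against a direct
  enumeration of cluster-pair means on random instances with up to eight
  samples, and probe selection against an explicit pairwise-comparison
  oracle on 1000 random candidate sets.
* Monte-Carlo test sizes are chosen to keep the default suite around half a
  minute: 2000 null genes for the type-I check (binomial two-sigma band
  ±0.0097 around 0.05), 50 replicates for the planted-effect power and
  recovery checks, 40-gene instances for the bias-versus-noise sweep.
* All randomized tests fix their seeds; the simulator is byte-reproducible
  given a seed.

## Limitations

The package reimplements a fold-change-and-t-test analysis faithfully,
including its statistically old-fashioned corners: no moderation of
variances across genes (as an empirical-Bayes pipeline would do), no paired
test on the raw intensities, no multiple-testing control on the headline
classification, and a hard two-fold threshold. These are properties of the
method being reproduced, not recommendations. The clustering figure of the
original study cannot be reproduced bit-for-bit without its raw data, so
clustering correctness is established by oracle equivalence and planted
structure instead. Nine or ten patients is a small cohort; the simulator's
consistency checks show the estimator's bias vanishing with noise, not that
any particular real-data estimate is unbiased.
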