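# warburgDE

Paired tumor/normal differential expression over the extended Warburg-effect
network.

Many tumors shift their glucose metabolism toward aerobic glycolysis (the
Warburg effect): glucose is fermented to lactate even with ample oxygen. In
clear cell renal cell carcinoma (CCRCC) this shift is expected almost by
construction — VHL loss constitutively activates HIF-1, which transactivates
essentially every glycolytic gene. `warburgDE` implements the analysis a
bench-facing bioinformatician needs to quantify that shift from paired
microarray data: per-patient tumor/normal fold changes aware of MAS5
Present/Marginal/Absent detection calls, sign-aware averaging, significance
testing on the log scale, representative probe-set selection, hierarchical
clustering for sample quality control, and overlay of the per-gene results
onto a curated metabolic network spanning glycolysis, gluconeogenesis, the
pentose phosphate pathway, the TCA cycle, serine/glycine synthesis, fructose
and glutamine utilization, and the first steps of fatty acid synthesis.

## The statistic

For patient *i*, the signed fold change of a gene is

```
FC_i = T_i / N_i            if T_i / N_i >= 1
     = -(N_i / T_i)         otherwise
```

where `T_i`, `N_i` are the MAS5 signal intensities in tumor and adjacent
normal tissue, so `|FC| >= 1` always and the sign carries the direction. A
patient pair is excluded from a gene when **both** of its calls are Absent;
if that removes every patient the gene is still summarized but flagged
unreliable. The average fold change is the arithmetic mean when all
per-patient values are positive; with any negative value, negatives are
converted to positive reciprocals and the mean is taken on the `ln` scale,

```
avgFC = exp( mean( ln FC*_i ) ),   reported as -1/avgFC when < 1
```

Significance is a two-tailed one-sample t-test of `ln FC_i` against zero
(`t = mean / (sd / sqrt(n))`, `df = n - 1`), uncorrected for multiple
testing; genes with `|avgFC| > 2` are called over- or under-expressed.

Representative probe sets (for genes measured by several) are chosen
lexicographically: at least 50% Present calls first, then probe-set suffix
(`_at` before `_s_at` before `_x_at`), then highest mean intensity — with an
intensity-only fallback for data sets shipped without calls.

## Worked example

The package ships the per-patient fold-change tables of the ten-patient
CCRCC study it reimplements (fixture `gse6344_tables_fc.tsv`); the pipeline
can enter at that stage:

```r
library(warburgDE)
gm  <- golden_fc_matrix()
fit <- warburg_de_fc(gm$fc, exclude = gm$exclude, all_absent = gm$all_absent)
fit
#> Paired tumor/normal differential expression: 71 genes, 9 patients
#> DE rule |avg FC| > 2, alpha = 0.05 (uncorrected)
#>   over-expressed: 16   under-expressed: 26   unchanged: 29
#>   1 gene(s) flagged unreliable (all calls Absent)

head(as.data.frame(summary(fit))[, c("gene","avg_fc","n_used","p_value","de_class")], 8)
#>    gene     avg_fc n_used      p_value de_class
#> 1  G6PC -53.844560      9 8.382332e-06    under
#> 2 ALDOB -43.746761      9 2.548427e-05    under
#> 3  ENO2  33.793333      9 3.532194e-06     over
#> 4 PSAT1 -21.388540      9 2.205399e-05    under
#> 5   HK2  20.880000      9 3.523940e-05     over
#> 6  PDK1  10.016667      9 2.065416e-06     over
#> 7  PCK1  -8.963427      8 3.883051e-05    under
#> 8  PKLR  -8.514252      3 1.979877e-02    under
```

Reading: glucose-6-phosphatase (`G6PC`, gluconeogenesis) is ~54-fold down in
tumor tissue while neuron-specific enolase (`ENO2`, glycolysis) is ~34-fold
up — the glycolysis-up / gluconeogenesis-down signature of a Warburg shift.
`PCK1` uses eight patients (one value excluded per the source table's
footnote) and `PKLR` only three (the other six pairs were Absent/Absent).

`golden_check()` recomputes every row of the packaged tables and diffs it
against the printed averages and p-values:

```r
table(golden_check()$status)
#> known_discrepancy              pass
#>                 4                68
```

The four documented discrepancies (`HK1`, `ME2`, `ACLY`, `ACACB`) are rows
of the source tables that are internally inconsistent with their own printed
per-patient values; see `?golden_known_discrepancies`.

A full synthetic run — simulate paired arrays with calls, select probes,
cluster-QC the samples, fit, and overlay on the packaged network:

```r
res <- run_pipeline(list(simulate = list(config = simulation_config(), seed = 1)))
res$overlay                       # annotated network, exportable via export_cytoscape()
pathway_report(res$overlay, "glycolysis")
```

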