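# epialleler

Single-molecule, locus-specific DNA methylation analysis of dual-barcoded
bisulfite amplicon sequencing, aimed at cell-free DNA (cfDNA) liquid-biopsy
biomarker studies.

## The problem

Tumor-derived cfDNA is a 0.1–1% minority in blood plasma, and its aberrant
CpG methylation is *heterogeneous*: different molecules of the same locus
carry different combinations of methylated positions.  Averaged
per-position methylation levels blur that structure.  This package instead
counts **epialleles** — each sequenced molecule's full CpG state vector —
and screens the proportions of molecules with given *joint* methylation
statuses for their power to discriminate patient groups.

For a locus with *n* CpGs (indexed 1..n, 5′→3′) the variable family is

* `GENE.Ci` — the proportion of retained molecules methylated (`C`) at
  position *i*, and
* `GENE.Ci.Cj`, `GENE.Ci.Tj`, `GENE.Ti.Cj`, `GENE.Ti.Tj` — the four
  joint-status proportions for every pair *i* < *j* (`T` = unmethylated),

i.e. *n* + 2*n*(*n*−1) variables per locus; the bundled three-locus
prostate design (GSTP1 17 CpGs, RNF219 17 CpGs, KIAA1539 5 CpGs) gives
2·(17 + 4·17·16/2) + 5 + 4·5·4/2 = **1167 variables** over a cohort of
20 PCa / 17 BPH / 18 HD samples.

Per variable and one-vs-rest contrast the package computes: the **exact
Mann–Whitney** p-value (shift-algorithm permutation distribution,
mid-ranks for ties) with **Bonferroni** adjustment over the 3 × 1167
family; sensitivity at 100% specificity and the converse; the separation
**cutoff** (geometric mean of the closest cross-group pair under complete
separation, arithmetic mean when one value is zero, Youden-optimal
threshold otherwise) with its boundary **ratio**; balanced-weight
**leave-one-out logistic regression** (fold weights N/(2·n_g), threshold
0.5, the 100%-without-fitting convention under complete separation); and
the **DeLong** ROC-AUC confidence interval (suppressed at AUC = 1).
A WGBS module re-screens the same variable family as binary
per-read presence calls on low-coverage call tables, with the
chi-square/Fisher expected-count-≥5 rule and a ×561 per-locus adjustment.

Upstream, the read-processing module turns raw amplicon FASTQ into
per-molecule pattern tables: dual 8-bp barcode demultiplexing with
chimeric-pair exclusion, reference-anchored CpG state calling, and the
per-read bisulfite conversion-rate filter (≥ 0.95, unrecognized sites
excluded).  A calibrated synthetic-cohort generator with known ground
truth makes the whole pipeline testable without any patient data; the
bundled reference inserts are synthetic stand-ins with the published
lengths and CpG counts.

## Worked example

```r
library(epialleler)
library(dplyr)

design <- demo_design()                      # loci, barcodes, 55-sample cohort
model  <- default_calibrated_model(design)   # published-mean-calibrated mixture
cohort <- simulate_pattern_cohort(model, design, seed = 7)
vm     <- build_variable_matrix(cohort$table, design)

screen <- compare_all(vm, contrasts = "PCa", cv = FALSE, mw = "screened")
glance(screen)
#> # A tibble: 1 × 5
#>   contrast n_variables n_significant n_complete_separation m_adjust
#>   <chr>          <int>         <int>                 <int>    <int>
#> 1 PCa             1167           457                   302     1167

filter_report(screen, "table4") |>
  select(variable, p_adj, mean_pos, mean_neg, sens_at_spec100, cutoff,
         complete_separation) |>
  head(5)
#>   variable    p_adj mean_pos mean_neg sens_at_spec100 cutoff complete_separation
#> 1 GSTP1.C1 4.62e-12     5.94    0.204             100   1.17 TRUE
#> 2 GSTP1.C2 4.62e-12     5.94    0.207             100   1.13 TRUE
#> 3 GSTP1.C3 4.62e-12     8.25    0.209             100   1.39 TRUE
#> 4 GSTP1.C4 4.62e-12     5.96    0.205             100   1.16 TRUE
#> 5 GSTP1.C5 4.62e-12     5.95    0.195             100   1.15 TRUE

loocv_logistic(vm, "PCa", "GSTP1.C9")[c("accuracy", "auc")]
#> $accuracy
#> [1] 100
#> $auc
#> [1] 100
```

Reading the output: the tumor contrast flags hundreds of the 1167
variables after Bonferroni adjustment (`p_adj` is the raw exact p × 1167
here, since one contrast was screened).  `mean_pos`/`mean_neg` are group
means in percent — e.g. molecules methylated at GSTP1 position 3 make up
~8.2% of the PCa pool but ~0.2% elsewhere — and `cutoff` is the estimated
decision threshold in percent, with complete separation meaning a
threshold classifies every sample correctly.  The LOOCV block reports the
cross-validated classification of a single-marker model; under complete
separation the conventional 100% report applies.

The end-to-end path from FASTQ works the same way:

```r
sim <- simulate_cohort(model, design, reads_per_sample = 200, seed = 7)
pt  <- process_reads(sim$files, design)      # demultiplex, call, filter
exclusion_tallies(pt)                        # per-disposition read accounting
```

or in one call via `run_pipeline(list(simulate = list(seed = 7), ...))`,
which writes the pattern table, variable matrix, comparison report,
figure-data exports and a run manifest to an output directory.

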