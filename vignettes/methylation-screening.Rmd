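---
title: "Single-molecule methylation screening of bisulfite amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule methylation screening of bisulfite amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epialleler)
library(dplyr)
```

## The problem

Cell-free DNA (cfDNA) in blood plasma is a mixture of fragments shed by many
tissues; in cancer patients a small fraction (typically 0.1–1%) derives from
the tumor.  Tumor DNA often carries aberrant CpG methylation at specific
loci, but that methylation is *heterogeneous*: different molecules of the
same locus carry different combinations of methylated positions.  Averaged
per-position methylation levels therefore blur exactly the signal that
distinguishes a rare tumor-derived molecule from the background.

This package works at single-molecule resolution instead.  Targeted
bisulfite amplicon sequencing reads each molecule's full CpG state vector
(its *epiallele*), and the analysis asks how often molecules with a given
joint methylation status occur in each patient.  The package covers the
full path from raw dual-barcoded amplicon reads to group-discrimination
statistics, plus a binary re-screen for low-coverage whole-genome bisulfite
sequencing (WGBS) call tables, and a calibrated synthetic-cohort generator
so that the entire pipeline is testable without access to patient data.

The bundled demonstration design mirrors a three-locus prostate-cancer
assay — GSTP1 (17 CpGs, 142 bp insert), RNF219 (17 CpGs, 161 bp) and
KIAA1539 (5 CpGs, 89 bp) — over a cohort of 20 prostate-cancer patients
(PCa), 17 benign-hyperplasia patients (BPH) and 18 healthy donors (HD).
The reference inserts shipped with the package are **synthetic** sequences
fabricated to those lengths and CpG counts: the assay's true amplicon
sequences are not published, and nothing in this package asserts real
genomic sequence.

## The variable family

For a locus with $n$ CpGs indexed $1..n$ in 5′→3′ order, the family
contains

* $n$ single-position variables `GENE.Ci`: the proportion of retained
  molecules methylated at position $i$;
* $4\binom{n}{2}$ joint-status variables `GENE.Ci.Cj`, `GENE.Ci.Tj`,
  `GENE.Ti.Cj`, `GENE.Ti.Tj` for every unordered pair $i<j$, where `C`
  means methylated and `T` unmethylated,

for $n + 2n(n-1)$ variables per locus; the three-locus design yields
$2(17 + 4\cdot\tbinom{17}{2}) + 5 + 4\tbinom{5}{2} = 1167$ variables.
Single-position unmethylated variables are not enumerated separately (they
equal $1-\mathrm{C}i$ and would double-count the family), but the parser
accepts names like `GSTP1.T3` and rewrites them as complements so they can
be used as model predictors.

All variables at a locus share one denominator — the number of retained
reads — because any read with an unrecognized site is excluded upstream,
so every retained read has a complete state vector.  This gives the exact
identities used as invariants in the test-suite:
$\mathrm{C}i\mathrm{C}j + \mathrm{C}i\mathrm{T}j + \mathrm{T}i\mathrm{C}j +
\mathrm{T}i\mathrm{T}j = 1$ and
$\mathrm{C}i\mathrm{C}j + \mathrm{C}i\mathrm{T}j = \mathrm{C}i$.

## Read processing

Reads are fixed-structure amplicons: an 8-bp sample barcode, the forward
primer, the insert, the reverse-complemented reverse primer, and a second
8-bp barcode.  Processing proceeds in deterministic stages:

1. **Orientation and locus.**  The forward primer is matched at offset 9
   (up to 2 mismatches); if no locus matches, the reverse complement of the
   read is tried.  Reads matching no locus are `EXCLUDED_UNASSIGNED`.
2. **Demultiplexing.**  The terminal 8-mers are matched *exactly* against
   the X- and Y-code lists in the locus's orientation (the X-codes sit on
   the reverse primer for GSTP1/RNF219 and on the forward primer for
   KIAA1539).  A pair of known codes never assigned to any sample is a PCR
   chimera (`EXCLUDED_CHIMERA`); the barcode allocation gives the PCa and
   HD groups disjoint code sets, so cross-group chimeras are always
   detectable.  An 8-mer matching no code leaves the read unassigned.
3. **State calling.**  Because the amplicons are fixed, the dominant path
   is gapless: the insert is compared directly against the
   bisulfite-converted reference with CpG and non-CpG-cytosine positions
   wildcarded.  A read whose length differs from the expected insert, or
   whose mismatch rate over non-wildcard positions exceeds 10%, falls back
   to a banded global alignment (match +1, mismatch −1, gap −2, band 10)
   against the converted reference; alignment identity below 70% excludes
   the read.  At each CpG, `C` calls methylated, `T` unmethylated, and any
   other base or a gap is an unrecognized site.
4. **Filtering.**  The per-read conversion rate is the fraction of the
   reference's non-CpG cytosines read as `T`.  A read is retained iff its
   conversion rate is at least 0.95 — the threshold is *inclusive*, reading
   "minimal rate" as an attained lower bound — and it has no unrecognized
   site.  Exclusion reasons are mutually exclusive with fixed precedence
   (unassigned > chimera > conversion > unrecognized), so the dispositions
   always partition the input read count exactly; this conservation is
   asserted by tests on every synthetic run.

The conversion-rate denominator counts the reference's alignable non-CpG
cytosines.  In the bundled design all non-CpG cytosines lie between the
primers, which sidesteps the question of whether primer-synthesised bases
should count; for custom designs with cytosines in primer regions the
denominator convention is the documented one above.

## Group comparison statistics

Each of the three one-vs-rest contrasts (PCa vs rest, HD vs rest, BPH vs
rest) applies the same machinery per variable:

* **Exact Mann–Whitney test.**  The permutation null distribution of the
  rank-sum statistic, with mid-ranks for ties, is computed by a
  shift-algorithm dynamic program over doubled mid-ranks (integers even
  under ties).  The two-sided p-value is defined as
  $P(|W - \mathbb{E}W| \ge |w_{obs} - \mathbb{E}W|)$ — the symmetric
  distance-from-the-mean rule, not tail-doubling; the two agree for
  symmetric null distributions and the distance rule remains exact and
  well-defined under ties.  The test-suite verifies equality with full
  enumeration of all label assignments for every cohort size up to 12.
* **Bonferroni adjustment** multiplies by the family size
  $m = 3 \times 1167$, capped at 1, with significance declared at adjusted
  $p < 0.05$.  Covariates such as PSA run through the same machinery but do
  not enlarge $m$: the family is defined by the methylation variables.
* **Separation metrics.**  All midpoint thresholds are scanned in both
  orientations (the positive group may sit high or low), yielding the best
  sensitivity at 100% specificity and the converse.  *Complete separation*
  means some threshold achieves both at 100%.
* **Cutoff and ratio.**  Under complete separation the cutoff is the
  geometric mean of the two closest cross-group values — the arithmetic
  mean when one of them is zero — and the ratio of the larger to the
  smaller boundary value is reported when both are nonzero.  Otherwise the
  cutoff is the threshold maximising sensitivity + specificity and no
  ratio is reported.
* **Cross-validation.**  Leave-one-out: each sample is predicted by a
  logistic regression fitted on the remaining 54 with class-balancing
  weights $w_g = N_{train}/(2 n_{g,train})$, recomputed inside every fold
  so no information leaks from the held-out sample.  Held-out
  probabilities are classified at 0.5; accuracy, sensitivity and
  specificity are unweighted proportions.  When any single predictor
  completely separates the full data the conventional report is
  100/100/100/100 without fitting — a deliberate reporting convention for
  separable data, under which a maximum-likelihood fit would not converge
  anyway.
* **DeLong AUC.**  The AUC of the held-out scores is the pairwise
  Mann–Whitney probability (ties counted half); its variance comes from
  DeLong's structural-components estimator and the Wald interval is
  truncated to $[0,1]$.  At AUC = 1 the interval is degenerate at (1, 1)
  and is suppressed.
* **Forward selection** greedily adds the variable maximising LOOCV
  accuracy of the grown model, breaking ties by higher cross-validated AUC
  and then canonical variable order, stopping when no addition improves
  accuracy or at the size cap (default 3).

The logistic fits use a dedicated iteratively-reweighted-least-squares
routine (iteration cap 100, deviance tolerance $10^{-8}$, internal
standardisation of predictors) rather than a formula interface: a screen
touches tens of thousands of fold fits, and the lean path keeps the full
screen inside desk-scale runtimes while matching `glm()` coefficients to
five decimals on converged problems (asserted in the tests).

### Bulk screening and the exact test

`compare_all()` computes the exact test for every variable by default.
For bulk type-I-error experiments (hundreds of cohort replicates) the
`"screened"` mode and `count_significant()` first apply a tie-corrected
normal approximation and recompute the exact test for any variable whose
approximate p falls within two orders of magnitude of the decision
boundary.  Decisions at the Bonferroni threshold ($p < 0.05/3501 \approx
1.4\times10^{-5}$) are taken on exact p-values either way; the
approximation only skips exact computation where the p-value is orders of
magnitude away from mattering.

### Report presets

The presets reproduce the published report filters: adjusted $p < 0.005$
with sensitivity above 70% at 100% specificity; adjusted $p < 10^{-10}$
with complete separation; and adjusted $p < 3.5\times10^{-8}$.

## The WGBS binary re-screen

Short-read WGBS covers only a subset of a locus's CpGs per read, so the
same variable names become *binary per read*: a read is evaluable for a
variable iff it covers all of the variable's positions, and "present"
iff its states match the variable's statuses there (other covered
positions are ignored — the natural reading of pattern presence, noted as
a documented choice).  Reads are pooled across samples within the normal
and cancer groups; each variable gets a 2×2 pattern-by-group table, tested
with the Pearson chi-square test (no continuity correction — the plain
statistic is the default reading, with a `correct` flag for the Yates
variant) when all four expected counts are at least 5 and the two-sided
Fisher exact test otherwise.  P-values are adjusted by the locus's own
enumeration count (561 for a 17-CpG locus).  Tables with a zero margin
carry no information and are reported as $p = 1$ with a degenerate flag.

## The synthetic cohort generator

The generator defines the study conditions for every statistical test in
the package.  A cohort is drawn from an epiallele mixture model: each
(group, locus) has classes — a per-CpG methylation probability vector plus
a weight — and molecules are drawn per sample from the mixture.

**Calibration.**  The default model is anchored to the published group
means: in GSTP1, a fully methylated class plus a C3+C9 marker class give
the PCa group an expected `GSTP1.C9` of 8.35% against 0.160% in HD and
BPH, while C13-type classes bring `GSTP1.T3.T13` to 99.5% in HD versus
88.5% in the tumor groups; in RNF219, a scattered 1% single-position class
at every CpG keeps single-position variables non-discriminative while a
fully methylated class at 0.2% weight in HD/PCa versus 0.005% in BPH makes
every pairwise-CC variable a BPH marker in the 0.005–0.2% regime, with
separation cutoffs landing near 0.05%; KIAA1539 is identical across
groups and serves as a built-in negative control.  Cohort sizes are
18/17/20 (HD/BPH/PCa).

**Noise.**  Three independent per-base Bernoulli processes, the simplest
model that exercises the read filters: conversion failure at non-CpG
cytosines (default 0.01, the process the ≥0.95 filter screens),
inappropriate conversion of methylated CpGs (0.005), and sequencing
substitution error (0.001, of which one third flips C↔T and two thirds
produce unrecognized bases at CpG positions).  Chimeric reads carrying
unused barcode pairs are injected at 1%.

**Coverage.**  Reads per sample×locus are drawn uniformly from
5,000–20,000 — scaled down from the tens-of-thousands coverage of the real
assay while preserving the regime in which 0.005–0.2% epialleles are
detectable as counts of a few to a few dozen molecules.

**Between-patient dispersion.**  Class weights are jittered per sample by
a multiplicative log-normal factor (sd 0.2 on the log scale) and
renormalised.  A Dirichlet jitter would be the textbook choice, but a
Dirichlet component with concentration proportional to a weight of
$5\times10^{-5}$ is numerically degenerate (its draws are almost always
exactly zero or enormous relative to the mean); the log-normal factor
keeps the coefficient of variation uniform across classes of very
different sizes.  The real cohort's between-patient dispersion is unknown
— published tables report group means, not variances — so printed
patient-level sensitivities are *not* reproducible in principle; what the
calibrated simulation preserves, and what the acceptance checks assert, is
the qualitative separation structure: which markers separate which groups,
at cutoffs of the right order.

**Two serialisation depths.**  `simulate_pattern_cohort()` applies the
noise processes directly to CpG state vectors and returns pattern tables;
`simulate_cohort()` additionally serialises every molecule to a barcoded
FASTQ read.  Under the substitution-only noise model the two paths are
distributionally identical downstream of read processing, which the
noiseless-recovery tests confirm exactly; statistical experiments
therefore use the pattern path at full coverage, while the FASTQ path
exercises demultiplexing, alignment and filtering end to end at smaller
read counts.  Both are deterministic given a seed.

**What the generator does not emulate:** PCR duplicates and jackpot
amplification, cycle-dependent quality profiles, indel sequencing errors,
cfDNA fragment-length structure, and the real cohort's dispersion (above).
Passing tests on synthetic data therefore demonstrate the correctness of
the pipeline's computations and the recoverability of calibrated signal
structure — not clinical performance on real cfDNA.

**PSA covariate.**  `simulate_psa_covariate()` draws per-sample total PSA
from group-wise log-normal distributions matched to the cohort
description (17.5 ± 12.3 ng/mL in PCa, 10.7 ± 8.5 in BPH, 1.2 ± 0.7 in
HD), so the covariate pathway (screened alongside, excluded from the
Bonferroni family, reported on its raw scale) can be exercised.

## Numerical choices

* Proportions are `count/total` IEEE doubles.  Threshold scans use exact
  midpoint comparisons on these values; the only systematically tied value
  across samples is exactly 0, which doubles represent exactly, so cutoff
  and separation decisions are deterministic without a rational-arithmetic
  layer.
* The exact-test dynamic program works on doubled mid-ranks (dropping to
  plain ranks when no ties are present); subset counts stay below
  $\binom{55}{20} \approx 3\times10^{14}$, inside the exact-integer range
  of doubles.
* Logistic regression: IRLS with cap 100, deviance tolerance $10^{-8}$,
  linear predictors clamped at ±30 to keep weights finite under
  quasi-separation; under fold separability predictions saturate and
  classification is unaffected.
* WGBS fragments are resampled until they cover at least one CpG, matching
  the definition of an informative read.

## Problem sizes used by the test-suite

The package's own verification runs at sizes chosen to make every check
sharp but desk-scale: oracle recounts on 200-read fixtures; exact-test
enumeration up to 12 samples; one full calibrated cohort at the default
5,000–20,000 coverage for the screen-structure checks; 100 null-model
replicates at 1,000 reads/sample for the family-wise-error control check;
and FASTQ round trips at 25–60 reads/sample.  `scripts/acceptance.R`
re-runs the main computations from scratch and writes the measured
quantities as JSON.

## Known limitations

* The fabricated reference inserts make the pipeline self-contained but
  mean the bundled design cannot be used to analyse real reads from the
  published assay; supply a design file with the true sequences via
  `load_design()` for that.
* Only the bisulfite top (sense) strand is modelled, as an amplicon design
  with fixed primers defines a single converted strand.
* Pair merging (`merge_pairs()`) is provided for paired-end input, but the
  simulator emits merged reads; the merge path is exercised only by its
  unit tests.
* Per-sample WGBS inference is out of scope: the re-screen pools reads
  within groups, as low per-sample fragment counts (tens of reads) make
  per-sample proportions meaningless.
* Triple-and-higher joint-status variables are not enumerated; the family
  is deliberately the printed single + pairwise one.
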