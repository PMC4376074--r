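---
title: "Methods: multigenerational persistence analysis of germline methylation screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multigenerational persistence analysis of germline methylation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtrace)
library(dplyr)
```

## The question the pipeline answers

Endocrine disruptors (vinclozolin, bisphenol A, DEHP) given to pregnant
mice during the window in which fetal male germ cells (prospermatogonia,
"MGCs") establish their DNA methylation patterns could, in principle,
leave epigenetic scars that survive germline reprogramming and reach
grandchildren that were never exposed. methtrace implements the
computational side of testing that claim: enrichment-array peak calling,
a four-level intersection framework for persistence, region-average
methylation scoring at imprinted DMRs and retrotransposon flanks,
allele-specific (SNuPE) quantification with calibration and
Bonferroni-familied group tests, and an overlap/direction analysis of
differential-expression hit lists. Because the headline result of such a
screen is typically *negative* — no surviving hits at the most stringent
level — the package is built around auditable thresholds and
synthetic-data generators that make every stage testable end to end.

## Array model and peak calling

The methylated CpG island recovery assay (MIRA) reports, per tiling-array
probe, the normalized log2 ratio of the methylation-enriched fraction
over input DNA. The analysis model is deliberately simple:

* A probe is **positive** when its value lies strictly above the 95th
  percentile of all probes on the same array
  (`positivity_threshold()`). The percentile uses the sorted-order
  linear-interpolation convention, and "above" is strict, so a constant
  array yields no positives. The threshold is computed per sample over
  all probes of that array, never pooled across samples: arrays differ
  in dynamic range, and a per-array quantile makes the positive set
  invariant to overall intensity shifts.
* A **peak** (`call_peaks()`) is a maximal run of four or more positive
  probes allowing at most one interior non-positive probe (the "gap");
  the gap must be flanked by positives, boundary probes are positive,
  the count of four refers to positive probes only, and runs never cross
  chromosome boundaries. This is the most literal reading of a
  gap-tolerant run rule, and the suite verifies it on >1,000 random
  arrays against an exhaustive search over all windows.
* **Consensus peaks** (`consensus_peaks()`) across replicates are the
  interval *intersections* of per-replicate peaks that overlap in all
  replicates — the conservative choice for downstream testing, since a
  consensus region is signal-supported in every replicate.

## The level-1 test and its contingency table

`level1_test(A, B)` discovers consensus peaks in group A and compares
replicate-averaged signal against group B at the same locations. A
region is called changed when both conditions hold:

* effect: |mean log2 difference| >= log2(1.05), the "±5%" cutoff read on
  the linear MIRA/input fold-change scale (a 1.05-fold increase or
  0.95-fold decrease);
* significance: a two-sided Fisher's exact test P < 0.05.

The Fisher 2×2 table is not specified by the screening design itself, so
the package fixes one construction and isolates it in a single internal
function (`peak_positivity_table()`) so alternatives can be swapped: it
counts probes inside the peak that are positive versus non-positive,
classifying each probe per replicate against that replicate's own
array-wide threshold and pooling counts over replicates, for A versus B.
No multiple-testing correction is applied at level 1: the design
deliberately uses permissive per-test cutoffs so that the higher-level
intersections carry the stringency.

Because peak discovery happens in A, `bidirectional_level1()` runs every
comparison in both orientations (treated-as-A and control-as-A); the two
lists are distinct tests and are reported as a pair.

## Levels 2–4: persistence by intersection

`intersect_calls()` declares two passed calls "common" when their
regions overlap by at least 1 bp (the matching rule is otherwise
unspecified in screens of this kind; 1-bp overlap is the weakest
assumption, and merged regions are reported as the intersection
interval). Level 2 pairs the same treated-vs-control comparison across
generations, level 3 across germ-cell stages. `tgi_level4()` requires a
region to overlap passed calls in all four germline samples — G1R MGCs,
G1R sperm, G2R MGCs, G2R sperm — the footprint a truly transgenerational
change must leave. Direction concordance is binary on the sign of the
mean difference; magnitudes are not compared.

`direction_enrichment()` supports the overlap analyses: for the 2×2
table of up/down membership of common hits in two lists it reports each
cell's fold enrichment (observed over expected under row–column
independence) with a two-sided Fisher P, plus an exact binomial test of
the same-direction count against 0.5. Enrichment folds on real data
depend on the study's gene lists and are not reproducible from
summaries; the package's tests therefore exercise the machinery on
constructed tables and Monte-Carlo nulls.

## Region-average scoring

`region_mean()` averages probe values over named regions — imprinted
DMRs carrying their expected parental sign (paternally methylated DMRs
positive in the male germline, maternally methylated DMRs negative) and
unique 1-kb IAP-flanking regions. A probe belongs to a region when its
interval *midpoint* lies inside; midpoint containment avoids double
counting probes straddling borders. `region_change_test()` applies a
two-sample, two-sided, equal-variance Student's t-test to per-replicate
region means with the same ±5% cutoff, and additionally evaluates the
two imprint-specific aberration screens (MAT DMR gaining methylation,
PAT DMR losing it). Degenerate zero-variance comparisons are given
P = 1 when means are equal and P = 0 with a warning otherwise, so that
constant fixtures behave predictably. Repeat-masking is out of scope:
IAP flank coordinates are an input.

## The SNuPE arm: calibration and group comparison

Primer-extension allelotyping measures the percentage of signal carried
by the maternal allele at a SNP. Instruments incorporate the two
extension products with unequal efficiency, so a known 50:50 standard (a
true heterozygote for DNA; an equimolar RNA mix for transcription) is
measured under the same conditions and used by `skew_correct()`:
observed maternal:paternal odds are divided by the standard's odds and
mapped back to a percentage. The odds scale was chosen because it is the
unique monotone correction that fixes both endpoints (0 and 100 pass
through) and maps the standard to exactly 50 — and because preferential
incorporation biases peak *ratios*, not differences. The synthetic
generator (`simulate_allelotypes()`) applies the same skew on the
generative side, so correction composed with generation recovers true
fractions exactly at zero noise; the suite verifies this over a grid of
99 fractions × 5 skew ratios. `linearity_check()` regresses corrected
mixing-series observations (default design 0, 10, 30, 50, 70, 90, 100%
maternal) on truth and flags assays with R² below 0.95.

`compare_groups()` implements the comparison-table procedure: per SNP ×
organ stratum, each treatment is tested against vehicle ("oil") with an
equal-variance two-sided Student's t-test on raw replicate values (never
reconstructed from table summaries); rows carry the difference, the
treated-group SD, change flags (`gt5`: |difference| > 5 and P < 0.05;
`gt10`: additionally > 10), the baseline parental-bias class of the
control mean (`classify_baseline()`: ≥80% maternal = MAT, ≤20% = PAT,
otherwise NO/erased — boundaries read as inclusive), and a Bonferroni
call at alpha/m for the declared family size. `bonferroni_alpha()`
reports thresholds rounded half-up at four decimals (0.05/28 = 0.0018,
0.05/56 = 0.0009, 0.05/33 = 0.0015) while internal comparisons use the
unrounded value.

## Expression overlap

`differential_expression()` is a per-gene two-group equal-variance t
contrast with Benjamini–Hochberg FDR — a documented stand-in for the
original factorial ANOVA, whose exact model matrix is unpublished; for
the two-group contrasts exercised here the results coincide with a
linear-model contrast. Three cutoff profiles mirror the screening tiers:
strict (1.5-fold, FDR q < 0.05), relaxed1 (1.5-fold, raw P < 0.05),
relaxed2 (1.05-fold, raw P < 0.05). `g1_g2_overlap()` collapses multiple
probes to one transcript by best P value, counts common passing
transcripts and the same-direction subset, and delegates enrichment
statistics to `direction_enrichment()`. Benjamini–Hochberg was chosen
for "FDR" because it is the field default when no procedure is named.

## What the generators emulate — and what they do not

`simulate_methylome()` reproduces the *structure* the analysis assumes:
uniformly spaced probes (default 100 bp — tiling density is platform
configuration, not a modelling claim), Gaussian log2-ratio noise, a
shared array design for all groups, spiked methylated regions elevated
in every group, and a treatment effect added in the treated groups
selected by a persistence scenario along the germline chain
G1R MGC → G1R sperm → G2R MGC → G2R sperm:

| scenario | groups carrying the effect |
|---|---|
| `none` | G1R MGC only (immediate effect, no persistence) |
| `g1_only` | + G1R sperm (maintained within the exposed generation) |
| `g1_and_sperm` | + G2R MGC (transmitted, lost before G2R sperm) |
| `full_tgi` | all four (true transgenerational inheritance) |

The scenarios are cumulative because an epigenetic change can only reach
a later stage of the chain through the earlier ones; `none` still shifts
G1R MGCs because exposure acts directly on them.

For spike-in recovery experiments the natural configuration sets
`methylated_region_log2_mean = 0`: the level-1 Fisher table registers a
treated-vs-control difference only where control probes sit *below* the
positivity threshold, so recovery is tested on regions that gain
methylation under treatment. Regions constitutively methylated in all
groups (the default, emulating imprinted DMRs) are the right input for
region-average analyses but are invisible to the positivity-based
contingency test — a real property of the published rule, not an
artifact of the generator.

`simulate_dmr_panel()` generates the imprinted-DMR sign structure (PAT
DMRs at +1, MAT DMRs at −1 by default) with optional class-specific
treatment shifts; `simulate_expression()` produces log-scale expression
with an additive sex effect on a designated subset (sex is the dominant
axis of variation in germ-cell transcriptomes) and treatment effects on
a disjoint truth subset.

None of the generators model probe-sequence effects, dye bias, spatial
artifacts, inter-litter correlation, or the reciprocal-cross genome
composition of real allelotyping material. Passing tests therefore
demonstrate that the *analysis rules* behave as specified under their
own statistical assumptions — not that those assumptions hold on any
particular array data set.

## Numerical choices and problem sizes

* Percentile type 7 (linear interpolation) with strict exceedance;
  per-array thresholds.
* Ties and zero-variance cases: see the degenerate conventions above.
* Genomic coordinates are 0-based half-open (BED convention) internally
  and on disk; interval set operations go through IRanges.
* The test suite runs the peak-caller oracle on 1,000 random arrays of
  up to 200 probes, the null calibration on 1,000 simulated regions
  (260,000 probes, three replicates per group), and spike-in recovery on
  20 regions across a 10,000-probe design — sizes at which every
  property is measurable in well under a minute each on one core, while
  binomial confidence bands stay tight enough to be meaningful.
* `scripts/acceptance.R` re-runs these analyses from scratch under a
  caller-supplied seed and writes the resulting quantities as JSON.

## Known limitations

* The Fisher contingency construction at level 1 is one defensible
  choice among several (probe-level pooling ignores within-replicate
  correlation); it is isolated so alternatives can be swapped and
  compared.
* The DE module is a two-group contrast, not a full factorial model;
  interaction effects are out of scope.
* Consensus-peak intersection can split one replicate's peak into
  multiple consensus regions when other replicates disagree about its
  extent; downstream counts treat these as separate regions.
* `design_counts()` covers the three documented bookkeeping quantities;
  screens whose factor composition is not fully specified cannot be
  reproduced as counts and are not attempted.
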