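---
title: "Dissecting a cistrome by DNA binding cooperativity"
author: "coopcis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a cistrome by DNA binding cooperativity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopcis)
```

## The problem

p53 binds DNA as a tetramer whose adjacent DNA-binding domains interact
through an H1-helix double salt bridge (residues E180/R181). The strength
of this interaction -- DNA binding cooperativity -- tunes which response
elements the tetramer can occupy. Point mutants dissect the spectrum:
`EE` (R181E) and `RR` (E180R) homotetramers have reduced cooperativity,
wild type (`WT`) is intermediate, and co-expressed EE+RR heterotetramers
(`EERR`) exceed wild type. Profiling all four genotypes by ChIP-seq, plus
a GFP control and sequencing input, yields a nested family of cistromes:
high-affinity sites are bound even by the weak mutants, low-affinity
sites only by the cooperative species.

`coopcis` implements the complete downstream analysis of such a design:
count processing and filtering, presence calling and classification,
motif characterization, expression integration, cross-study overlap, and
patient-survival stratification -- together with a synthetic-data
generator so that every stage is testable without the original data.

## Peak processing

Peaks arrive as BED-style intervals (0-based half-open) with one raw
count column per sample. Read starts are capped at 28 per position and
strand (`cap_read_starts()`), a compromise between PCR-duplicate removal
and library saturation. Counts are normalized to reads per million
mapped (`normalize_counts()`). A peak qualifies for a genotype when it
has at least 50 combined raw reads *and* at least 2-fold normalized
enrichment over both GFP and input (`filter_peaks()`). Whether the
50-read minimum refers to raw or normalized counts is genuinely open; we
apply it to raw combined counts as the conservative reading, and the
threshold is configurable. A fold comparison against a zero control is
taken as satisfied by any positive signal, the limit of the ratio
condition. Interval unions across samples (`union_peaks()`) merge
intervals sharing at least one base pair and sum constituent counts per
sample, forming combined tag counts per region.

## Presence calling and classification

The core classifier (`call_presence()`) ranks the four genotypes at each
peak by normalized count and scans the three adjacent ranked pairs for
the first at-least-2-fold drop; the genotypes above that first gap are
called binding, and if no gap exists all four are. Decisions worth
stating explicitly:

* "at least two fold" is inclusive -- a ratio of exactly 2 is a gap;
* a positive count directly above a zero count is a gap; two zeros are
  not;
* ranking ties are broken by the fixed order EERR > WT > RR > EE
  (descending designed cooperativity). With equal counts the ratio is 1,
  so the tie order can never manufacture a gap;
* only adjacent pairs are compared ("difference to the previous" taken
  literally), and the controls never participate.

`assign_class()` maps the bound set to a class with precedence
EE > RR > WT > EERR, encoding the nesting: `EE_CLASS` and `RR_CLASS`
form the LOW cooperativity group (high-affinity sites), `WT_CLASS` and
`EERR_ONLY` the HIGH group. A biologically unexpected bound set such as
`{EE}` alone still maps to `EE_CLASS`. At the gene level
(`label_genes()`), a gene with any LOW peak is a LOW cooperativity gene.

## Annotation

Peaks are anchored at their interval midpoint (the anchor is not
specified upstream; the midpoint is the natural choice for roughly
symmetric peaks) and annotated to the gene with the nearest most-5'
TSS, ties resolved by the lexicographically smaller gene id. Genomic
regions follow the precedence PROMOTER > GENE_BODY > DISTAL >
INTERGENIC with default windows of 5 kb upstream / 1 kb downstream of
the TSS for promoters and 50 kb around gene spans for distal regions.
The exact window sizes behind the published region scheme are not
stated; these defaults are conventional for promoter-proximal analyses
and are configurable (`coop_config()`) and logged.

## Response-element scanning

The p53 element is two decameric half-sites RRRCWWGYYY (R = A/G,
W = A/T, Y = C/T), optionally separated by a spacer. `build_matrix()`
encodes the degenerate consensus (1 inside the positional class, 0
outside) or a pseudocounted log-odds matrix from training 10-mers.
`scan_fullsites()` evaluates every placement of two half-sites with
spacers 0-13 on both strands and reports the arg-max, with the
deterministic tie-break smallest offset, then smallest spacer, then the
plus strand. There is no spacer penalty by default (a linear one is
available), `N` scores 0, and scores are reported normalized to the
maximum achievable so that group comparisons are matrix-independent.
The published analysis used the p53MH scoring table, which is not
reproduced here; absolute mean scores are therefore not comparable
across scanners, while the group contrasts (spacer distributions,
perfect fractions, core usage) are.

A hit is *perfect* when its spacer is 0 and all 20 bases lie in their
degenerate class -- a stated stand-in for the published perfect/
non-canonical split, whose precise criterion is not documented. When no
full-site reaches the score threshold (default 0.8 normalized), the best
single half-site is reported and flagged, reflecting that the
lowest-affinity site class resembles half-sites more than full-sites.
The CWWG core (positions 4-7 of each half-site, with CATG the
torsionally most flexible and highest-affinity) and the central W bases
(consensus positions 5 and 15) are typed per hit.

## Expression integration

Expression arrives as per-genotype log2 fold-changes versus the GFP
control. "More than 2-fold" is strict on the log2 scale; a gene is UP or
DOWN overall when any genotype passes, and genes passing in both
directions are flagged DISCORDANT rather than dropped.
`bound_and_regulated()` joins regulated genes to their peaks and reports
distinct gene and site counts; `walking_average()` (default window 25,
centered, truncated at the edges -- the published window is not stated)
smooths expression along a binding-strength ranking;
`repressed_peak_fraction()` quantifies how rarely repressed genes carry
a binding site.

## Cross-study overlap

Two peaks are common when they share at least one base pair; half-open
adjacency shares none. Overlap is counted per anchor peak -- one anchor
peak overlapping several reference peaks counts once -- because the
published comparisons report peak-set percentages; whether those counts
were anchor-side or union-side is not stated, and anchor-side is our
choice. The interval engine is required by its tests to agree exactly
with an all-pairs brute-force oracle.

## Survival stratification

Patient expression matrices are mean-centered per gene across samples
in log scale; each patient's genes are then ranked by centered value
(ties broken by gene id for determinism). The single-sample enrichment
score is the classic unweighted KS-style running sum: +1/|S| at set
members, -1/(N-|S|) elsewhere, with the signed extreme as the score,
always in [-1, 1] and dependent on ranks only. Whether the upstream
per-patient GSEA used weighted or unweighted sums is not restated in the
source; the unweighted form is the default and a rank-weighted variant
would be a straightforward extension. Patients split by score sign; a
score of exactly 0 (no enrichment) goes to the DOWN group.

Kaplan-Meier estimation and the log-rank test are delegated to the
`survival` package (product-limit estimator; hypergeometric variance at
tied event times; events processed before censorings at ties). Cohorts
with an empty group or no events are reported "not testable" rather
than raising.

The Monte-Carlo signature null draws random gene sets of the observed
size (default 10,000), reruns enrichment, stratification and the
log-rank test for each, and computes the add-one empirical p-value
`(1 + #{null >= observed}) / (1 + n)`. The published description
("used the obtained Kaplan-Meier estimates to calculate p-values") is
ambiguous about the comparison statistic; we use the log-rank chi-square
and record the choice here. Untestable iterations score 0, which is
conservative for the observed set.

## The synthetic-data generator

The generator's defaults are the study conditions, chosen once:

* **Class mix** 88 : 1579 : 3145 : 375, the observed cistrome
  composition, over 2000 peaks by default.
* **Occupancy model**: each site draws a required-cooperativity
  threshold from its class; genotype g binds iff its cooperativity
  level (0.25, 0.5, 0.75, 1 for EE, RR, WT, EERR) reaches it. This step
  function makes truth classes well defined for recovery tests;
  binding is nested by construction.
* **Counts**: negative-binomial (dispersion 0.05, i.e. NB size 20,
  reflecting moderate ChIP-seq overdispersion at strong peaks) around
  5 reads per million at bound sites versus 0.1 rpm background, scaled
  by per-sample library sizes set to the study's stated mapped-read
  totals (31.2M EE, 84.1M RR, 88.6M WT, 100.4M EERR, 37.6M GFP, 34.3M
  input). Site strength declines with the required threshold, so
  wild-type binding is strongest at LOW sites. `dispersion = 0` gives
  deterministic counts -- the exact noiseless limit.
* **Sequences**: one embedded element per 200-bp peak; LOW sites are
  perfect with probability 0.5 and CATG-cored with probability 0.8,
  HIGH sites 0.15 and 0.3, degraded elements carry spacers with
  probability 0.85 and 1-3 out-of-class mismatches. These rates were
  set from the published group contrasts (about half of low-cooperativity
  motifs perfect and spacer-free; under 20% perfect and 70-80%
  spacered among high-cooperativity motifs).
* **Expression**: activation delta 2.5 log2 units scaled by relative
  cooperativity for genotypes that bind the gene's site, noise sd 0.4;
  60 peak-free repressed genes with delta 2 scaled by the square of
  relative cooperativity (a rising mediator), emulating indirect
  repression.
* **Cohort**: 200 patients, unit-variance gene-set activity shifting
  set genes by 1 sd, exponential survival with hazard
  `0.1 * exp(-0.8 z)` on the high-set activity, 30% censoring.

What the generator does *not* emulate: spatial read profiles and
fragment-length effects, chromatin context, correlated gene-gene
expression structure, batch effects, and continuous (Hill-type)
occupancy -- so passing recovery tests demonstrates the classifier's
correctness under the nested-threshold model, not robustness to every
feature of real data.

## Numerical choices and problem sizes

All generators take a single seed and are reproducible; derived seeds
stay below 2^31. The test-suite calibrations use 1000 null cohorts of
60 patients for the log-rank type-I rate, 500 repeats of a 99-iteration
Monte-Carlo null for p-value uniformity, 200 random 200-bp sequences
for scanner-oracle equivalence, and 500-peak sets for the overlap
oracle -- sizes at which the checks are statistically meaningful while
the whole suite runs in minutes on one core. The acceptance script runs
the default 2000-peak study and a 1000-iteration Monte-Carlo null.

## Known limitations

Peak calling itself (the upstream FDR model), genome liftover, read
alignment and microarray preprocessing are out of scope: the pipeline
starts from peak intervals with counts, sequences and log2
fold-changes, and inputs must share one genome build (declared in the
configuration). The published cistrome totals mix 5187 and 5188 across
figures; the class counts sum to 5187 and that is the value the
composition fixture reproduces. The motif scanner's absolute scores are
not comparable to p53MH scores; only normalized, within-study group
contrasts are reported.
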