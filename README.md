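# coopcis

Cooperativity-resolved analysis of transcription-factor cistromes.

p53 binds its response elements as a tetramer stabilized by inter-molecular
H1-helix salt bridges (E180/R181) — *DNA binding cooperativity*. Mutants
with reduced (`EE` = R181E, `RR` = E180R), intermediate (wild type, `WT`)
or increased (co-expressed `EE/RR` heterotetramers, `EERR`) cooperativity
occupy nested subsets of the genome: high-affinity sites are bound by all
genotypes, low-affinity sites only by the cooperative ones. `coopcis`
implements the full downstream analysis of such a multi-genotype ChIP-seq
plus expression design:

- **Peak processing** — read-start capping, reads-per-million
  normalization, the ≥50-read and ≥2-fold-over-control filters, interval
  unions across samples.
- **Cooperativity classification** — the rank-gap presence caller: at each
  peak the four genotypes are ranked by normalized count and the first
  adjacent pair differing by ≥2-fold defines the bound set; classes
  (`EE_CLASS` > `RR_CLASS` > `WT_CLASS` > `EERR_ONLY`) split the cistrome
  into LOW (high-affinity) and HIGH (low-affinity) cooperativity groups.
- **Annotation** — nearest gene by most-5′ TSS distance; promoter / gene
  body / distal / intergenic region calls.
- **Motif scanning** — a spacer-tolerant scanner for the bipartite element
  RRRCWWGYYY (×2, spacer 0–13 bp) on both strands, with perfect /
  non-canonical calls, CWWG-core typing and half-site fallback.
- **Expression integration** — `>2-fold` regulated-gene calling,
  bound-and-regulated joins, walking-average curves, repressed-gene peak
  fractions.
- **Overlap meta-analysis** — cross-study common peaks under the ≥1-bp
  rule, overlap percentages, cooperativity composition of overlap subsets.
- **Survival stratification** — per-patient unweighted enrichment scores
  (running sum, ±1/|S| vs −1/(N−|S|), signed extreme), sign-based
  grouping, Kaplan–Meier / log-rank (via the `survival` package), and a
  Monte-Carlo null of random same-size gene signatures with add-one
  empirical p-values.
- **Synthetic data** — generators for peaks/counts, sequences, expression
  and survival cohorts with the study's statistical structure and known
  truth labels.

## Worked example

```r
library(coopcis)

p   <- sim_params(n_peaks = 500, seed = 7)   # study-structured simulation
sim <- simulate_peaks(p)
pk  <- normalize_counts(sim$peaks, p$library_sizes)
pk  <- filter_peaks(pk)                      # >=50 reads, >=2-fold vs controls
pk  <- classify_peaks(pk)                    # rank-gap presence + class
str(class_composition(pk$class))
#> List of 7
#>  $ EE_CLASS : int 7
#>  $ RR_CLASS : int 163
#>  $ WT_CLASS : int 290
#>  $ EERR_ONLY: int 40
#>  $ LOW      : int 170
#>  $ HIGH     : int 330
#>  $ total    : int 500
```

The class counts partition the 500 simulated peaks; LOW (= EE + RR
classes) are the high-affinity sites bound even by weak-cooperativity
p53. Against the generator's truth labels this run recovers the class of
98% of peaks. Scanning the simulated peak sequences separates the groups
by motif quality, as in the real cistrome:

```r
sq   <- simulate_sequences(sim$truth, p)
tops <- scan_peaks(sq$seqs)
summarize_motifs(tops[match(sim$truth$peak_id, tops$seq_id), ],
                 sim$truth$true_group)[, c("group", "n", "mean_score",
                                           "perfect_frac", "spacer0_frac")]
#>   group   n mean_score perfect_frac spacer0_frac
#> 1   LOW 171  0.9570175    0.4327485    0.5087719
#> 2  HIGH 329  0.8986322    0.1519757    0.2613982
```

About half of the LOW-group elements are perfect, spacer-free consensus
full-sites; HIGH-group elements are mostly degraded and spacered —
binding there needs cooperativity.

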