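# cobindTargets

Genome-wide integration of ChIP-seq co-binding with mutant RNA-seq to
call the direct target genes of a pair of cooperating transcription
factors — the motivating case being a Smad (SMA-3) and its
Schnurri-family partner (SMA-9) in the *C. elegans* BMP pathway. The
package is for regulatory-genomics analysts who have two peak sets, DE
tables from the corresponding mutants, and a TSS annotation, and who
want to know which genes each factor directly regulates, in which
direction, and which targets the two factors share.

## What it computes

* **Co-binding geometry.** Peaks reduce to centroids
  (`floor((start+end)/2)`); per-chromosome nearest-neighbor
  inter-centroid distances are summarized by the midpoint (median) of
  their empirical CDF and compared against a seeded uniform
  randomization of peak positions. Overlap of the two peak sets
  (shared bp, adjacency excluded) is partitioned into per-factor
  overlapped/exclusive counts plus the number of overlap *events*
  (connected components of the bipartite overlap graph).
* **Conditional shared DEGs.** Genes significant in one comparison
  (FDR ≤ 0.01) form a stratum within which the other comparison's raw
  p-values are re-adjusted by Benjamini–Hochberg — recovering shared
  targets that a naive double cutoff misses.
* **Direct-target calling.** Peaks within 3 kb of a TSS contribute a
  distance-decay regulatory potential
  `S_g = Σ exp(-(0.5 + 4 d/w))`; DEGs with `S_g > 0` are ranked by
  score and by DE significance, ordered by the normalized rank product
  `(rank_rp/n)(rank_de/n)`; one-sided KS tests on score distributions
  call the factor activator, repressor, or dual.
* **Target classes.** Called targets partition into co-regulated
  (concordant / antagonistic) and factor-exclusive classes, requiring
  shared-DEG, overlapping-pair and common-peak-call evidence jointly
  for co-regulation.
* **HOT sites.** Distinct other factors from a modERN-style compendium
  within ±400 bp of each peak center; ≥ 15 flags a high-occupancy
  target site.
* **Phenotype screen.** Glass' Δ = (mean control − mean mutant) / SD
  control, so smaller bodies give positive Δ.
* **Synthetic studies.** A deterministic generator
  (`simulateStudy()`) plants co-binding fraction, target classes,
  hotspots and effect sizes with a full truth table, so every stage is
  testable without external data.

See the vignette (`vignettes/cobinding-target-analysis.Rmd`) for the
models, parameter defaults, and design decisions.

## Worked example

A full synthetic study with the default configuration (2000 peaks per
factor, co-binding fraction 0.7, 200 planted direct targets in five
classes), analyzed end to end:

```r
library(cobindTargets)

cfg <- synthConfig(seed = 7)
sim <- simulateStudy(cfg)
res <- runFullAnalysis(sim$peaksA, sim$peaksB, sim$degA, sim$degB,
                       sim$tss, compendium = sim$compendium,
                       phenotypes = sim$phenotypes,
                       controlGenotype = "control",
                       chromLengths = cfg$chromLengths,
                       nRandomSeeds = 20, seed = 11)
r <- res$report
```

which prints (selected fields):

```
observed NN midpoint: 63 bp
randomized NN midpoint: 5167.5 bp
overlap events: 1379
overlap fraction A: 0.7105
DEGs A down/up: 145 45   B down/up: 112 90
shared DEGs: 67
direct targets A/B/common: 141 144 45
verdict A: activator   verdict B: dual
     coreg_concordant    coreg_antagonistic           A_exclusive
                   39                     6                    96
B_exclusive_activated B_exclusive_repressed
                   47                    52
HOT fraction A: 0.211
```

Reading: the observed inter-centroid midpoint (63 bp) sits two orders
of magnitude below the randomized null (~5.2 kb), the signature of
planted co-binding; the measured overlap fraction 0.7105 recovers the
planted ρ = 0.7; factor A is called a pure activator and factor B dual
(it both activates and represses), matching the planted wiring; and
the class table recovers the planted 35:5:74:40:46 mix plus decoy
pickups. The strongest calls look like:

```r
head(res$beta$callsA[, c("gene_id", "score", "log2fc", "fdr",
                         "rank_product", "direction")], 3)
#>      gene_id     score    log2fc           fdr rank_product direction
#> 58  gene0820 0.5555039 -1.478814 1.112537e-308  0.001810774 activated
#> 102 gene1517 0.8485908 -2.482981 7.266142e-120  0.001810774 activated
#> 55  gene0739 0.3368896 -2.771352 1.112537e-308  0.003571249 activated
```

With real data, replace the simulated objects with
`readPeakTable()`, `readDegTable()`, `readTssTable()`,
`readTfCompendium()` and `readPhenotypes()`;
`reproducePublishedCounts()` recomputes a study's printed summary
counts from TSV exports of its supplementary tables.

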