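---
title: "Integrating transcription-factor co-binding with mutant expression:
  methods and design notes"
author: "cobindTargets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating co-binding with mutant expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobindTargets)
```

# The analysis problem

A Smad transcription factor and its Schnurri-family partner bind DNA both
jointly and independently, and a binding event near a gene does not by
itself establish regulation. `cobindTargets` implements a genome-wide
integration of two evidence streams — ChIP-seq peak sets for the two
factors, and RNA-seq differential expression (DE) from the corresponding
loss-of-function mutants — to decide, per gene, whether it is a *direct*
target, of *which* factor(s), and in *which direction*. The package also
quantifies the co-binding geometry itself, screens peaks against a
multi-factor compendium for high-occupancy-target (HOT) artifacts, and
summarizes downstream phenotype screens with Glass' effect sizes.

All coordinates are held 1-based inclusive internally; BED input/output
converts at the boundary. Chromosome labels are compared as exact
strings — no "chr"-prefix normalization — so that peak and TSS sources
must genuinely agree.

# Peak geometry

Each peak is reduced to its **centroid**, `floor((start + end)/2)`. The
floor (rather than rounding) makes the reduction deterministic for
even-width peaks. For co-binding, the package computes, per chromosome,
the nearest-neighbor distance from each centroid of one factor to the
other factor's centroids (the minimum over the full distance matrix);
the distribution's **midpoint** is the 50% point of its empirical CDF,
i.e. the median. Ties in the nearest-neighbor search resolve to the
lower coordinate, again for determinism.

The positional null **re-draws every centroid uniformly** within a
per-chromosome range, preserving per-chromosome counts, under an
explicit seed. Two range conventions are supported, because "within the
size range of the chromosome" is genuinely ambiguous: the full
chromosome length (default; WS245 lengths are bundled for worm data)
and the observed min–max coordinate range per chromosome. The choice is
echoed in the run report. Under planted co-binding the observed
midpoint falls far below the null's; the package asserts this ordering
property in its tests over repeated null draws.

The nearest-neighbor *direction* also needs a convention: the published
description names pairs without fixing a direction. The default is
A-to-B with A the smaller peak set; both directions and their union are
exposed (`direction` argument), and the flag is recorded in the run
report so a reproduction attempt can try all three.

**Overlap** of two peaks means sharing at least one base pair
(adjacency is not overlap). Beyond per-factor overlapped/exclusive
counts, `overlapPartition()` reports `n_events`, the number of
connected components of the bipartite overlap graph, so one wide peak
overlapping two partners counts as a single co-binding event. This
definition reconciles a single "overlap count" with two per-factor
overlap fractions whose products with the set sizes differ slightly —
exactly the arithmetic seen in real peak sets.

# Conditional shared DEGs (stratified re-testing)

Naively intersecting two DEG lists at a strict genome-wide FDR
underestimates the shared program: a gene solidly significant in one
comparison may sit just past the cutoff in the other only because the
second comparison paid the full genome-wide multiplicity price.
`loaSharedDegs()` implements the conditional remedy: genes significant
in comparison 1 (FDR ≤ 0.01 by default) form stratum S1; within S1 (and
separately its complement) comparison 2's **raw p-values** are
re-adjusted by Benjamini–Hochberg; S1 genes re-passing 0.01 are shared.
Both orderings are run and the union is reported (the intersection is
also returned). One threshold serves both the stratification and the
final call by default, since the procedure is described with a single
FDR; the two are independently settable.

Genes absent from one table are placed in stratum S2 (treated as
non-DE) rather than dropped, with a count reported — DEG exports do not
always list the full tested universe, and dropping unlisted genes would
silently shrink the background.

Two properties are worth stating precisely, because the intuitive
phrasing is subtly wrong. BH adjustment within a stratum is *not*
monotone under arbitrary shrinkage of the stratum: removing the
stratum's *largest* p-value can lower the survivors' adjusted values
(p = {0.01, 0.02} adjusts to {0.02, 0.02}, but {0.01} alone to 0.01).
What does hold, and what the tests assert, is (i) adjusted ≥ raw p
always, and (ii) removing the stratum members with the *smallest*
p-values never decreases any survivor's adjusted p. The companion
claim — the conditional shared set contains the naive double-cutoff
intersection — is not a theorem either, but holds whenever S1 is
enriched for small second-comparison p-values, which is the regime the
procedure exists for; it is verified on generator output across seeds.

# Direct-target calling

`assignPeaksToGenes()` links a peak to a gene when
|centroid − TSS| ≤ 3 kb (closed boundary; a centroid exactly at the
window edge is assigned). Strand determines only where the TSS is; the
distance is unsigned, and a peak may serve several genes. The TSS
annotation accepts either a 4-column table or GFF3 gene features, from
which the strand-aware 5′ end is taken; one TSS per gene is enforced at
ingestion, so a multi-TSS annotation must be reduced (most-upstream per
strand is the convention we recommend) before import.

The **regulatory potential** of gene *g* is

$$S_g = \sum_{\text{peaks } i} e^{-(0.5 + 4\Delta_i)},
  \qquad \Delta_i = d_i / w \in [0, 1],$$

with *d* the centroid–TSS distance and *w* the window. The kernel gives
`exp(-0.5) ≈ 0.607` at the TSS and `exp(-4.5) ≈ 0.011` at the edge.
The published integration method defines this decay against a 100 kb
window; here Δ is renormalized to the 3 kb window actually used, and
both normalizations are selectable (`windowBp` of `decayWeight()`).
The weight is strictly decreasing and scores are additive over peaks.

**Calls**: candidates are DEGs (FDR ≤ 0.05) with *S* > 0. Candidates
are ranked by descending score and by ascending raw p (the DE-rank key
can be switched to |log2FC|), and ordered by the normalized rank
product `(rank_rp/n)(rank_de/n) ∈ (0, 1]`. All rank ties break
lexicographically on gene id — scores arriving at machine-identical
values must not make the output order depend on input order. The rank
product is invariant to any strictly monotone transform of the scores,
which the tests assert.

**Verdict**: one-sided two-sample KS tests compare the score
distribution of up-DEGs, and separately down-DEGs, against non-DEG
background, with the alternative that DEG scores are stochastically
larger. Significance of only the down set (down in the mutant) makes
the factor an *activator*; only the up set, a *repressor*; both,
*dual*; any group under 5 genes returns *none* with a warning. Under
score/DE independence each one-sided test fires at ≈ α, which the test
suite checks by simulation (200 replicates, binomial CI).

# Target classes

`classifyTargets()` partitions the union of called targets into five
mutually exclusive classes. *Co-regulated* requires all three lines of
evidence simultaneously: membership in the conditional shared-DEG set,
at least one overlapping A/B peak pair inside the gene's window, and a
call from the common-peak pass (direct-target calling re-run on the
merged overlap events against the shared genes). Missing any one
demotes the gene to an exclusive class — which is why genes flanked by
overlapping peaks but DE in only one mutant land in exclusive classes.
Co-regulated genes split into *concordant* and *antagonistic* by
log2FC sign agreement across the two comparisons; remaining A calls
are `A_exclusive` (not sign-split, though up-in-mutant-A members
trigger a warning, since a pure-activator factor should have none);
remaining B calls split by sign into activated/repressed.

Two routing choices were genuinely open and are fixed as follows: a
gene called by both per-factor passes but failing a co-regulation
criterion goes to `A_exclusive` (deterministic precedence; its
`called_B` evidence column still records the B call), and a
common-pass-only leftover is routed by which single comparison is
significant. The common-peak pass needs one DE statistic per shared
gene; comparison A's values are used, a choice recorded here because
any single table must be picked and shared genes are significant-ish
in both by construction.

# HOT sites

`tfCooccupancy()` counts, for each focal peak, the distinct other
factors in a compendium with at least one peak intersecting
[centroid − 400, centroid + 400]; 15 or more flags a HOT site.
Intersection (not center-in-window) is the default because a factor
whose peak covers the window's edge does occupy the site's region;
center-in-window is available as `method = "center"`. Multiple peaks
of one factor count once, and a compendium entry matching the focal
factor's label is excluded. `hotFraction()` is monotone non-increasing
in the threshold, and the sweep implementation is checked against
brute-force window counting.

# Phenotype effect sizes

`glassDelta()` computes
`(mean(control) − mean(treatment)) / sd(control)` with the sample SD.
The published description of the statistic states the subtraction in
the opposite order while also stating that larger values mean smaller
bodies; those conflict, and the sign is fixed to the interpretation
(smaller bodies ⇒ positive Δ) since the screen's reading depends on
it. A `flipSign` flag restores the literal order. Glass' Δ (control SD
only in the denominator) is preferred over Cohen's d here because
mutant arms routinely change variance as well as mean. Δ is invariant
under common rescaling (unit change), asserted in tests. ANOVA/Dunnett
machinery is deliberately not reimplemented; a Welch p-value is
emitted for convenience only.

At the screen's arm size (n = 30) the sampling SE of Δ̂ near Δ = 2 is
≈ 0.37, so single-table recovery checks would be noise-dominated; the
tests therefore assert near-unbiasedness (Monte-Carlo mean over
replicate tables within 0.3, bias < 0.05 at δ = 1 with n = 50) plus a
3-SE bound on individual draws.

# The synthetic study

`simulateStudy()` generates every pipeline input with known truth. The
defaults are the package's reference conditions and are not adjusted
per analysis:

* **Genome**: six 5 Mb chromosomes (30 Mb), 2000 genes on a TSS grid
  with 6 kb minimum spacing (twice the window, so neighbouring genes'
  assignment windows cannot collide). A real worm genome is ~100 Mb
  with ~20k genes; the scale-down keeps unit runtimes in seconds while
  preserving the peak-density regime (chance A/B co-overlap ~1%, small
  against the planted 0.7).
* **Peaks**: 2000 per factor, widths Normal(400, 80) and
  Normal(250, 50) truncated at 50 bp, matching the two factors' mean
  widths. A fraction ρ = 0.7 of A peaks gets a B partner offset by
  Normal(0, 60 bp); planted co-regulated pairs count toward ρ.
* **Targets**: 200 direct-target genes in the five classes at
  35:5:74:40:46 — proportional to the published 114:15:238:129:150
  split — each with a functional peak centroid within 1 kb of its TSS;
  plus 110 decoy DEGs without peaks (indirect targets), a third of
  them shared.
* **DE tables**: planted genes draw |log2FC| from truncated
  Normal(2, 0.5) with the class-appropriate sign (activated-by-factor
  ⇒ negative in that factor's mutant) and raw p from Beta(a, 1) with
  a = 0.005; nulls are Uniform(0,1) with Normal(0, 0.2) log2FC; FDR is
  BH per table. The shape a = 0.005 places planted genes decisively
  below genome-wide significance (P(p > 0.01) ≈ 2%), i.e. the
  low-noise regime the recovery analyses are defined on. P-values are
  generated directly rather than via simulated counts because DE
  fitting is out of scope — the pipeline consumes tables.
* **Compendium**: 30 factors, 100 background peaks each; 20% of focal
  peaks sit in planted hotspots occupied by 20 factors.
* **Phenotypes**: control Normal(1000 µm, 50 µm), arms with planted
  Δ ∈ {2, 1.5, 0}, 30 animals per arm.

Determinism is strict: each generator stage draws from a fixed offset
of the config seed through a private RNG stream, so identical configs
give byte-identical outputs and the caller's RNG state is untouched.

What the generator does *not* emulate: correlated replicate structure
and dispersion estimation (p-values are drawn, not fitted), peak-width
/ binding-strength correlation, signal-dependent peak-calling dropout,
clustered gene families, and HOT-site effects on DE. Passing recovery
tests therefore demonstrate correctness of the integration logic under
clean conditions, not robustness to every pathology of real ChIP/RNA
data.

# Orchestration and problem sizes

`runFullAnalysis()` chains the stages, echoes every threshold, seed
and decision flag into a JSON run report, writes all result tables as
TSV, and fails with the offending stage's name. The test suite runs
the unit stages on a 3 × 2 Mb / 400-gene configuration and the
end-to-end recovery checks on the full default study with 3–20
randomization replicates; the acceptance script
(`scripts/acceptance.R`) uses the default study with 20 replicates and
finishes in well under a minute.

Reproducing the published summary counts (peak totals, overlap
fractions, distance midpoints, DEG counts, shared and per-class
totals) is implemented in `reproducePublishedCounts()`, which consumes
TSV exports of the study's supplementary tables; those exports are
external data and are not redistributed with the package.

# Known limitations

* One TSS per gene; genes regulated from distal elements beyond the
  3 kb window are invisible to the caller (a limitation shared with
  the window-based integration it implements).
* The common-peak pass inherits comparison A's p-values for ranking;
  rank products across the two per-factor passes are not calibrated
  against each other.
* The conditional re-testing treats the two comparisons as
  independent; shared technical structure (same WT pool) would make
  the stratum enrichment optimistic.
* `n_events` counts components, so chains of mutually overlapping
  peaks collapse into one event by design.
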