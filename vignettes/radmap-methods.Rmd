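---
title: "Linkage mapping from ddRAD tags in an outbred F1 cross: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage mapping from ddRAD tags in an outbred F1 cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmap)
```

## The problem

`radmap` implements a complete double-digest RADseq (ddRAD) linkage-mapping
workflow for a cross-pollinated F1 design: two outbred parents — here a
near-homozygous maternal parent and a much more heterozygous paternal
parent, as in lotus — are crossed, 51 progeny are genotyped by sequencing
restriction-site-associated tags, and the resulting markers are used to

1. compare marker-scoring strategies against three dialects of the same
   draft assembly (unmasked scaffolds, repeat-masked scaffolds, gene
   models),
2. build parental genetic maps under the pseudo-testcross model,
3. anchor, order and orient assembly scaffolds into chromosome-scale
   megascaffolds, and
4. scan a genome for within-genome heterozygosity.

Because the original sequencing data are not required, the package ships a
first-class simulator that generates genomes, parental haplotypes, F1
gametes and barcoded reads with the statistical structure this analysis
assumes. Every downstream stage is exercised end-to-end against that
simulator in the test suite.

## Genetic model

### Pseudo-testcross segregation

In an outbred F1, a locus heterozygous in one parent and homozygous in the
other segregates 1:1 like a testcross. CP (cross-pollinator) coding is
used throughout: paternal testcross markers are `nn x np` (progeny `nn` or
`np`), maternal testcross markers `lm x ll`, and loci heterozygous in both
parents for the same allele pair are intercross markers `hk x hk`
segregating 1:2:1. Intercross markers segregate through both parents and
contribute to both parental maps; testcross markers only to the map of
their heterozygous parent.

### Two-point estimation

For two same-parent testcross markers with `N` progeny informative for
both and `R` recombinant under the better phase, the maximum-likelihood
recombination fraction is `r = R/N` and the linkage LOD is

    LOD = (N - R) log10(2(1 - r)) + R log10(2 r),

with `LOD = N log10 2` at `r = 0` (the limit) and `LOD = 0` at `r = 0.5`.
Pairs involving intercross markers have no closed form; the package
maximizes the joint progeny-class multinomial likelihood numerically over
`r` for every parental phase combination and keeps the best phase. A
likelihood grid search written independently in the test suite agrees with
the estimator to within 0.001 across hundreds of random pairs.

### Grouping, ordering, distances

Linkage groups are connected components of the graph whose edges are
marker pairs with `LOD >= 5.0` and `r <= 0.25` — the thresholds under
which the published map was grouped. (The alternative grouping radius of
`r <= 0.40` mentioned for the mapping software's configuration is exposed
as `rf_max` but is not the default.)

Ordering within a group minimizes the weighted least-squares criterion of
regression mapping: non-negative inter-marker gaps are fitted so that
fitted additive distances disagree minimally, weighted by LOD, with the
observed pairwise Kosambi distances. Two starting orders are built — the
classical incremental insertion in decreasing order of total linkage
information, and a spectral seriation by the Fiedler vector of the LOD
affinity graph — each polished by ripple passes over sliding windows of
three and by 2-opt segment reversals, and the lower-cost order wins. The
spectral start matters: pure greedy insertion occasionally locks into a
"folded" order (the two chromosome arms interleaved) that window-3 ripples
cannot repair, and on such data the fold costs far more than the true
order under the same criterion.

Map positions are cumulative Kosambi distances over adjacent pairs,

    d = 25 ln((1 + 2r) / (1 - 2r))  cM,

with shortest-path distances through intermediate markers filling any gap
without a direct estimate.

### Recombination bins

Markers with identical segregation patterns carry no ordering information
relative to one another and are collapsed into recombination bins before
mapping. The similarity score between two markers is the count of progeny
with identical calls plus the count where either call is missing,
evaluated under both phase alignments; two markers share a bin only when
the score equals the number of progeny, and a marker joins a bin only if
it is compatible with *every* member (conflict veto), which keeps
missing-tolerant scoring from chaining incompatible markers. The
criterion is deliberately exact — zero observed recombinants — rather
than a score threshold, which makes binning deterministic and
order-invariant (markers are processed in canonical genomic order). An
error-tolerant variant is intentionally not offered.

## Marker discovery

Reads are demultiplexed by exact barcode prefix (4–8 bp, longest first;
the simulator emits prefix-free barcode sets), trimmed to 92 bp tags, and
dropped when five or more bases fall below Q20. Tags are aligned by
seed-and-verify: four non-overlapping 23-mers tile a 92 bp tag, so any
alignment with at most three edit events retains an exact seed; seed hits
are verified under the marker-model budget of at most two mismatches plus
at most one contiguous indel of 1–2 bp, with alignment score
`mismatches + 2 x indel bases`. A tag is used only when a single locus
attains the strictly best score. The single-indel-event model is
deliberate: allowing two independent 1-bp gaps would let an adjacent
insertion–deletion pair absorb a third mismatch as a fake 2-bp gap and
defeat the mismatch budget.

Unique alignments are pooled into clusters per (scaffold, position,
strand). The depth window of 4–200 reads guards against undersampled loci
and collapsed repeats and is applied to the pooled *parental* panel, the
discovery panel, matching how the filter is used during marker discovery;
progeny depth is handled separately at genotyping.

Alleles are discovered on the parental panel (the two deep samples): a
tag sequence is an allele when it reaches 25% of some parent's reads with
at least two supporting reads, and loci presenting more than two alleles
are discarded as diploidy violations (collapsed paralogs). Each sample's
genotype is then called from its two allele counts; a sample is
heterozygous when both alleles reach 25% of its allele-classified reads.
The denominator choice matters: a read carrying a sequencing error
anywhere in its 92 bp matches neither allele, so using raw depth as the
denominator would bias calls toward allele dropout by roughly the
per-read error probability; allele-classified reads are the AD-field
convention of standard callers.

Marker-quality filters, each tested on both sides of its boundary:

* progeny calls need depth >= 3, and a locus is kept only when more than
  90% of progeny are callable;
* integrity: at most 10% missing calls;
* segregation distortion: testcross markers are dropped beyond 3:1,
  markers with an expected 3:1 ratio (dominant-coded intercross) beyond
  10:1; fully coded intercross markers are checked under both dominant
  collapses, and markers with fewer than 10 informative calls are dropped
  as unratable (the ratio is unstable below that).

External SSR-style CP genotype tables can be merged; they bypass the
sequencing-depth machinery but still face the integrity and distortion
filters.

## The simulator

### What it emulates

* **Genome**: scaffolds tiled with copies of a few repeat families
  (default 40% repeat content at desk scale; the assembly being emulated
  is 57% repetitive) plus gene intervals covering ~5% of bases. Each
  family consensus carries one implanted ddRAD locus — a rare-cutter site
  with a frequent-cutter site a retained-fragment length downstream —
  because real repeat families (LTRs, LINEs) carry restriction-fragment
  loci in essentially every element, and those loci are precisely what
  makes repeats a source of colliding markers.
* **Parents**: heterozygous SNPs and 1–2 bp indels (9:1) placed uniformly
  at 0.03% (maternal) and 0.37% (paternal), the twelve-fold
  heterozygosity contrast of the study system.
* **Repeat collisions**: half of multi-copy repeat copies receive, on the
  variant paternal haplotype, a non-allelic gene-conversion tract
  (donor-copy sequence plus one novel substitution, tract up to 1.5 kb).
  Reads from a converted tract align uniquely to the donor copy and
  create a segregating marker at the wrong physical position — the
  mechanism behind mis-anchored markers when repeats are left unmasked.
  Pure substitution divergence between copies cannot do this under a
  best-unique-hit aligner (reads always score best at their own copy or
  tie and are discarded), which is why conversion is modeled explicitly.
  The conversion fraction was chosen once so that the share of
  mis-anchored unmasked markers lands near the published ~15%.
* **Cross**: crossovers are a Poisson process along each scaffold with no
  interference (default 0.9 cM/Mb, i.e. roughly 1.1 Mb per cM), one
  independent maternal and paternal gamete per progeny. Under this
  process the recombinant fraction between positions `d` cM apart is the
  Haldane value `(1 - e^(-2d/100))/2` — at 10 cM, 0.0906 — which is what
  simulator truth checks use; Kosambi remains the estimation-side map
  function, mirroring the published analysis.
* **Reads**: 100 bp, barcode + genomic bases from the rare-cutter end of
  200–500 bp fragments. Depth is drawn once per (sample, locus) as a
  negative binomial (mean 30, size 10 by default) and split binomially
  between the individual's two chromosomes; the two alleles of a locus
  share fragment length and context and co-amplify, so their depths are
  coupled. (Independent per-chromosome draws would put a dispersion floor
  on the allele ratio and produce het-dropout rates no AD-based caller
  exhibits.) A chromosome whose cut site was destroyed by a variant
  contributes no reads — allele dropout. Errors are i.i.d. substitutions
  at 0.001/base over the whole read, so barcode errors produce genuine
  ambiguous reads; parents get twice the progeny depth.

### What it does not emulate

No PCR duplicates, no adaptor chimeras, no quality-by-cycle decay, no
reference-vs-sample structural divergence beyond the conversion model, no
interference in crossover placement. Passing tests therefore demonstrate
that the analysis machinery is correct under the stated statistical
structure, not that it is robust to every artifact of real libraries.

### Default problem sizes

Tests and the acceptance script run at desk scale, chosen as the smallest
sizes at which each phenomenon is comfortably observable: marker-level
recovery studies use 5 linkage groups x 40 markers at n = 51 (bins
collapse to ~30 per group at this density, since adjacent markers 2.5 cM
apart co-segregate in ~28% of samples of 51 meioses); sequence-level
reference comparisons use 3 x 400 kb scaffolds at 40% repeat content. The
default read depth (30x progeny, 60x parents) emulates the deeply covered
loci that survive the published coverage filter; at shallow depth,
binomial allele sampling alone miscalls several percent of heterozygotes,
and co-segregating markers then no longer bin.

## Known limitations

* Desk-scale sequence-level maps are dropout-dominated: with ~50 bins on
  a 0.5 cM truth scaffold, even a 0.5% per-call error rate contributes
  ~1 cM per adjacent pair, so estimated lengths from the read-level
  pipeline are upper bounds. Map-length accuracy is therefore validated
  at marker level, where the generator matches the estimator's
  assumptions exactly.
* Ordering at n = 51 is noise-limited: on some simulated groups the
  wrong order genuinely fits the observed recombination fractions better
  than the truth (lower WLS cost), and no optimizer can undo that;
  recovery targets are aggregates over datasets.
* The maternal map of a 0.03%-heterozygosity parent is sparse by
  construction; the package builds it the same way but no acceptance
  property is attached to its density.
* Linkage groups are never merged: when one chromosome yields two groups
  separated by a large marker gap, both are reported (the published map
  has 9 groups for 8 chromosomes for exactly this reason; no join rule
  exists to encode).
* Scaffolds are atomic during anchoring: minority-group markers are
  logged as conflicts but never split a scaffold.

## Numerical and edge-case choices

* Recombination fractions are capped at 0.4999 before Kosambi conversion
  (0.5 maps to infinity); `kosambi_cm(0.5)` itself reports `Inf`.
* Alignment ties (equal best score at two loci) are ambiguous, never
  broken arbitrarily; uniqueness requires a strictly better score.
* Concordance purity ties break toward the lower linkage-group index.
* Scaffold orientation needs at least two distinct cM positions and a
  non-zero physical-genetic rank correlation; otherwise the scaffold is
  written unoriented (as `+` in the AGP, per convention).
* AGP output is v2.1 with fixed 100-N inter-scaffold gaps ("scaffold",
  linkage "yes", evidence "map"); gap length is configurable.
* Scaffolds are ordered by the *mean* cM of their modal-group markers
  (the choice between first-marker and mean-marker position is not
  documented for the original analysis; the mean is less sensitive to a
  single misplaced bin).
* Heterozygosity windows are anchored at 0 with 500 kb length and 250 kb
  step; the truncated terminal window keeps its true length in the
  density denominator, and the genome summary is the unweighted mean
  over scaffolds — that is the convention that reproduces the published
  per-scaffold column average (0.33/kb) from its entries; a
  length-weighted alternative is available but non-default.
* The read-quality rule drops a read when sub-Q20 bases number five *or
  more* (the conservative reading of "appearing five nucleotides below
  Q20").

## Reproducing the analysis

`run_pipeline()` drives simulation, read processing, alignment, marker
discovery, binning, mapping, anchoring and the megascaffold statistics
from one `pipeline_config()`; `compare_references()` runs the same
processed reads against all three reference dialects. `scripts/acceptance.R`
recomputes the published-table arithmetic and the simulation-based
performance numbers from scratch; see the README for how to run it.
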