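---
title: "Chromatin accessibility dynamics across desiccation stages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin accessibility dynamics across desiccation stages: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thsdyn)
```

## The biological problem

Resurrection plants such as *Haberlea rhodopensis* survive near-complete
loss of cellular water and recover on rehydration. A desiccation time
course is typically staged by relative water content (RWC): watered
control (C), moderate (~50% RWC, D1), severe (~20% RWC, D2) and fully
dry (~6% RWC, D3). ATAC-seq on nuclei from these stages reveals
transposase hypersensitive sites (THSs) — open-chromatin intervals
accessible to Tn5 — whose gain and loss across stages traces the
regulatory program of desiccation tolerance.

`thsdyn` implements the downstream analysis of such an experiment as a
reusable, fully testable pipeline: stage phenotyping from chlorophyll
fluorescence, insertion-level QC, peak calling, reproducibility-filtered
consensus THSs with cross-stage partitioning, promoter motif enrichment,
and integration with expression fold changes through a bipartite
correlation network. A synthetic-data generator with planted ground
truth makes every stage testable without any sequencing data.

## Stage classification from OJIP transients

Fast chlorophyll-*a* fluorescence rise curves (OJIP transients) are a
cheap, non-destructive phenotype of photosynthetic stress. Curves are
classified with a two-layer model: a hexagonal self-organizing map (SOM)
whose prototype lattice is trained by online Kohonen updates, plus a
label layer that assigns each node a stage by majority vote of the
training curves it attracts (ties break toward the earlier stage in the
order C < D1 < D2 < D3; nodes attracting no curve take the label of
their nearest training curve). Classification returns the label of the
best-matching unit — the prototype at minimal Euclidean distance, with
deterministic (row, col) tie-breaking.

Defaults: 4×4 hexagonal grid, Gaussian neighborhood with radius
decaying linearly 2 → 0.5, learning rate 0.5 → 0.01, 500 epochs,
prototypes initialized from randomly drawn training curves under a
seed. Curves are min-max normalized per curve before training because
absolute fluorescence amplitude depends on leaf optics; classification
therefore rests on curve *shape* (the relative J, I and P step
contributions), not amplitude. For very small lattices (2×2) the
default starting radius spans the whole map and can merge classes; the
radius is exposed as a parameter and ~0.8 works well there. An
alternative reading of "predefined nodes" — fixing node labels *before*
training — would give a supervised SOM; we use post-hoc labeling, which
is the common construction and is what the tests pin down.

## Insertion-level QC

Each aligned fragment contributes two transposition events. Because Tn5
cuts with a 9-bp stagger, the standard correction shifts the plus-strand
end by +4 and the minus-strand end by −5; both offsets are parameters,
so the ±2 bp convention reported in some studies is equally expressible
(`plus_offset = 2, minus_offset = -2`). Out-of-bounds positions are
clipped and counted.

* **Fragment-length histogram** — the mixture of sub-nucleosomal
  (<100 bp) and mono/di/tri-nucleosomal fragments produces the
  characteristic periodic decay with modes near 180 and 360 bp.
* **TSS profile** — insertions are collected on strand-oriented
  coordinates around each TSS (upstream negative). The enrichment ratio
  is the mean signal over ±50 bp divided by the mean over the outer
  100 bp of each ±2 kb flank; an all-zero profile has ratio 0 by
  convention. The flank width is not standardized anywhere, so it is
  pinned here for testability.
* **Replicate clustergram** — Pearson correlation of log2(x+1) counts
  per consensus interval, clustered by average linkage on 1 − r.
  ("log2-transformed Pearson correlation" is ambiguous; correlation *on
  log2 counts* is the only reading that avoids log of negative r.)
  Zero-variance samples are excluded with a warning.

## Peak calling

A deliberately minimal single-sample caller emulating the
shift/extension windowing of insertion-based callers: every insertion at
position $p$ contributes a unit pileup element on
$[p + s, p + s + e)$ with shift $s = -100$ and extension $e = 200$ by
default. The background rate at a position is
$\lambda_{\mathrm{local}} = \max(\lambda_{\mathrm{genome}},
\lambda_{1k}, \lambda_{5k}, \lambda_{10k})$, running means of the same
pileup (the genome-wide floor prevents zero-rate blowups in empty
regions), and the per-position p-value is the upper Poisson tail
$P(X \ge \mathrm{cov}) , X \sim \mathrm{Pois}(\lambda_{\mathrm{local}})$,
computed in log space to avoid underflow.

Multiple testing is handled at desk scale by applying
Benjamini–Hochberg over *candidate* positions — the leftmost points of
coverage local-maxima runs — rather than all base pairs. Every position
lies on the hill of some candidate whose p-value is at most its own, so
rounding a position's p down to the candidate grid assigns it the q of
its dominating candidate; positions with q below the cutoff are merged
(gaps ≤ 30 bp), peaks shorter than `extsize/2` are dropped, the summit
is the leftmost coverage maximum and the score is −log10 p there. This
is a documented simplification of the exact per-base BH stack used by
production callers; the planted-recovery and null-calibration tests
bound its behavior (sensitivity ≥ 0.9, FDR ≤ 0.1 on the standard
planted fixture; ≥ 95/100 uniform runs yield zero peaks at q < 0.05).
The effective genome size is always the true toy genome length, never a
borrowed constant from another organism.

## Consensus THSs and stage partitioning

A peak is reproducible when, in at least one other replicate (two
replicates total by default), some peak overlaps it by at least 50% *of
its own length*. The denominator choice matters: the asymmetric rule is
the weaker, more inclusive reading of "minimal overlap 50%", and a
reciprocal mode is available behind a flag. A retained peak is merged
together with the peaks that supported it, so a short reproducible peak
carries its wider cross-replicate evidence into the condition-level
span.

Condition-level peaks are union-merged across all four stages into
consensus THSs; presence per condition needs ≥ 1 bp overlap. The exact
subset of present conditions (the Venn partition) maps onto named stage
groups: `{C}` watered-unique, `{C,D1}` watered→moderate, `{C,D1,D2}`
watered→severe, `{D2,D3}` severe→dry, all four constitutive, anything
else "other". Partition counts always sum to the THS total.

Counts per THS and sample are insertion counts within the interval;
fold changes are computed on CPM-normalized counts as
$\log_2((\bar{x}_{D} + 1)/(\bar{x}_{C} + 1))$ with condition means and
pseudocount 1 (both pinned choices — the normalization is not
standardized for this statistic).

Annotation anchors each THS at its midpoint (consensus intervals have
no single summit), picks the nearest gene by strand-aware signed TSS
distance (ties to the lexicographically smaller id) and assigns a
category with gene-body priority: 5'UTR-proxy (first transcribed exon
upstream of the start codon), Exon, Intron, then upstream promoter bins
(0–1, 1–2, 2–3 kb], Downstream ≤ 1 kb past the 3' end, else distal
intergenic. Term over-representation on the annotated gene sets is a
generic upper-tail hypergeometric test with BH correction; term
content (GO/KEGG or anything else) is supplied by the user.

## Promoter motif enrichment

Promoters are the 3000 bp upstream of the start codon on the coding
strand (reverse-complemented for minus-strand genes; clipped windows are
flagged). Negatives are per-sequence dinucleotide shuffles via the
Eulerian-path (Altschul–Erikson) construction, which preserves exact
mono- and dinucleotide counts and is deterministic under a seed.

The discriminative scan tests every exact word of length 3–8 present in
at least two positive sequences by a one-sided Fisher exact test on
per-sequence binary hits (both strands by default), generalizes the best
word one IUPAC wildcard position at a time while the p-value improves,
and reports motifs in increasing E-value — the p-value times the number
of distinct exact words tested — while E < 0.05. Reported sites are
masked (N) in the positives and the scan repeats. Note a statistical
constraint the generator respects: at 3 kb a hexamer is present in most
sequences by chance, so per-sequence presence carries no signal for
6-mers; planted words must be ≥ 8 bp for the binary-hit statistic to
see them. (The W-box core TTGAC(C/T) is still recoverable on shorter
constructed windows, as the tests demonstrate.)

Discovered words are matched against a bundled PWM library of plant TF
motifs (W-box/WRKY, ABRE/bZIP, MYB core, HD-ZIP, Dof/C2H2, GATA). The
library is synthetic — matrices constructed from the published consensus
words, not exported from any database — and is clearly labelled as such.
Similarity is the maximal ungapped log-odds alignment over offsets
(≥ 3 overlapping columns) and strands; the match p-value is an
empirical null over position-shuffled word matrices, each scored with
the same best-of-library rule so the selection step does not inflate
the observed score. These permutation p-values are discrete and
conservative by construction.

## ATAC–RNA integration

Each gene contributes two nodes: an ATAC node carrying its per-stage
accessibility log2-FC profile (averaged over its THSs) and an RNA node
carrying its expression log2-FC profile. Edges connect an ATAC node to
an RNA node when the squared Euclidean distance of their profiles falls
below 0.01; ATAC–ATAC and RNA–RNA pairs are never evaluated, so the
network is bipartite by construction, and both self-pairs and
cross-gene pairs are tested.

The raw-scale distance with a 0.01 threshold connects essentially
nothing for typical log2-FC magnitudes, so the default scales each
profile to unit Euclidean norm before the distance — the threshold then
measures angular agreement (d² = 2(1 − cos θ) < 0.01 means θ ≲ 5.7°) —
and a `"raw"` mode preserves the literal reading. Zero-norm profiles
(genes with identical accessibility in all stages) cannot be scaled and
are excluded with a warning. Enriched motifs with a PWM match are linked
to the matched TF's expression profile when present.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with planted ground truth sufficient to score every stage:

* i.i.d. uniform ACGT background; genes non-overlapping with ≥ 4 kb
  clearance so 3-kb promoters never truncate;
* accessible regions of 300 bp centred 200 bp upstream of TSSs
  (matching the promoter-proximal predominance of THSs) plus intergenic
  decoys; each region carries a condition subset drawn from the
  canonical partitions so all named stage groups occur;
* fragment lengths from a 0.45/0.30/0.15/0.10 mixture of
  nucleosome-free (mean 60 bp) and mono/di/tri-nucleosomal components
  at a 180-bp period, reproducing the periodic decay between 200 and
  800 bp;
* fragment midpoints enriched 20-fold inside regions accessible in the
  sample's condition, uniform elsewhere; Poisson replicate totals
  around 50 000 fragments per sample;
* an 8-bp W-box-bearing word (`CTTGACCT`) planted in 80% of
  accessible promoters and 5% of the rest;
* expression profiles that are a convex mix of the gene's accessibility
  profile (weight = coupling, default 0.9) and Gaussian noise, so
  coupling 1 copies accessibility exactly and coupling 0 is
  independent;
* four monotone O-J-I-P prototype transients on a log-time grid whose
  variable fluorescence shrinks and whose relative J-step grows from C
  to D3, with 5% multiplicative noise.

Default scale: 2 chromosomes × 500 kb, 80 genes, 48 accessible regions,
4 conditions × 3 replicates. One global seed fans out to per-stage child
seeds by fixed offsets, so stages rerun independently are reproducible.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequencing error and mappability, GC and Tn5
sequence bias, cross-species alignment artifacts, organellar
contamination, overlapping genes and isoform diversity, realistic motif
degeneracy, and biological replicate variance beyond Poisson counting.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
interval-algebra checks use ≤ 1000 intervals on 100-kb toy genomes
against per-base brute-force oracles; the peak-caller null uses 100
seeded runs of 1000 insertions on 1 Mb; planted recovery uses 50
regions, 20× enrichment and 100 k fragments on 1 Mb; the SOM check uses
200 curves; the end-to-end run uses the default generator scale above.
All randomness flows from explicit seeds; all coordinates are 0-based
half-open internally, with conversion only at the GFF3 boundary;
Poisson tails are computed in log space; BH-adjusted values are never
below their p-values by construction.

## Known limitations

The peak caller has no paired-end fragment model, broad-peak mode or
control subtraction. The motif scan is exact-word based with single
wildcard refinements — no EM optimization of PWMs and no genome-wide
PWM scanning. The network is a hard-threshold distance graph, not a
statistical model of coupling; its edge set at the default threshold is
sensitive to angular noise in recovered fold changes, which is why the
fully end-to-end self-edge recall is lower than on directly constructed
profiles. Real-data headline counts from any particular experiment
depend on the underlying sequencing data and genome and are out of
scope here.
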