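---
title: "gliaMarks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gliaMarks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gliaMarks` identifies candidate Müller-glia-specific genes from sorted
retinal cell fractions and characterizes their promoter histone
modifications. This vignette documents the model behind each stage, the
parameters that matter, the numerical conventions, and what the bundled
synthetic data can and cannot demonstrate.

## Promoter histone scoring

For one ChIP sample with matched input, the per-gene score is built in five
steps:

1. **Window counting.** Tags (5′ read ends, 0-based) are counted in
   1050-bp windows sliding by 50 bp. Windows are genome-global, starting at
   0 on every chromosome and tiling `[0, chrom_length)`; a window holds a
   tag when `start <= pos < start + 1050`, so any tag at least 1000 bp into
   the chromosome is seen by exactly 1050/50 = 21 windows. Anchoring
   windows to the genome rather than to each TSS makes the track a single
   genome-wide object that all genes share.
2. **Library normalization.** Counts are divided by the library's total tag
   count, making scores comparable across sequencing depths (duplicating a
   library leaves the normalized track bit-identical).
3. **Input subtraction.** The input track, normalized the same way, is
   subtracted window-wise. Depleted windows go negative here.
4. **log2 transform.** `v -> log2(max(v, 0) + epsilon)` with
   `epsilon = 1e-9` by default. Flooring at zero before the offset maps
   all depleted/neutral windows onto a common floor of `log2(epsilon)`
   while preserving the ordering of enriched windows; `epsilon` is a
   configuration knob recorded in the output parameters. Alternatives
   (dropping non-positive windows, or offsetting without flooring) either
   discard grid positions or let deeply negative differences dominate
   averages, so the floor is the default.
5. **TSS averaging.** Each window is represented by its center
   (`start + 525`); a gene's score is the mean over windows whose center
   lies within TSS ± 5 kb, boundaries inclusive. The TSS is `tx_start` on
   the plus strand and `tx_end − 1` on the minus strand; small-RNA genes
   (miRNA, snoRNA, ...) are excluded before scoring. Genes on chromosomes
   without a track, or whose interval captures no window center, are
   flagged missing and dropped from the matrix with a report.

Scores from all test samples are assembled into a gene × sample matrix and
**quantile normalized**: the rank-*i* value in each column is replaced by
the mean over columns of their rank-*i* values; tied values receive the
mean of the tied ranks' reference values (average-rank convention). On
tie-free input the transform is idempotent, preserves within-column ranks
exactly, and equalizes the column value multisets; with ties the per-column
multisets can differ slightly because tie groups average different
reference runs, which is inherent to the averaging convention.

## Fold-change gating and set algebra

A gene enters the EGFP-positive-specific set (EPG) at a timepoint when
`(FPKM_pos + c) / (FPKM_neg + c) > fold`, strict inequality, with
`fold = 2` and pseudocount `c = 0.1` FPKM by default; the reciprocal rule
defines the ENG set. The pseudocount is the least intrusive policy for
zero-FPKM denominators; an optional `min_fpkm` floor (default 0 = off) can
additionally require detectable expression. Gating is antisymmetric under
swapping the fractions and monotone in the threshold, and every set-algebra
call asserts inclusion–exclusion internally.

The progenitor-shared candidate set is the intersection of the P1 and P4
EPGs; the P4-specific variant of the workflow instead takes the P4-only
difference set. Both sets are then restricted to genes with usable histone
coverage before clustering.

## Clustering

- **k-means** (expression, default k = 4) runs Lloyd's algorithm via
  `stats::kmeans` on `log2(FPKM + 1)` rows from a seeded
  k-means++-style initialization. The log offset of 1 keeps zero FPKM at
  zero and compresses the dynamic range the way expression analyses
  conventionally do. Initialization scans candidate points in canonical
  lexicographic row order, so the result is invariant to input row
  permutation at a fixed seed. Output labels `0..k−1` are ordered by
  descending cluster mean, making cluster identities reproducible across
  runs.
- **Hierarchical clustering** (histone values) uses Euclidean distance with
  Ward linkage (`ward.D2`) and cuts the tree at the requested k. Linkage
  and distance are deliberate choices — Ward on Euclidean matches the
  compact, variance-minimizing clusters the workflow expects — and columns
  are not rescaled before clustering, since all columns are already on the
  common quantile-normalized scale. Labels `C1..Ck` are ordered by
  descending cluster mean over a configurable column subset (the pipeline
  uses the Cd73_P H3K27me3 columns), so `C1` is always the
  repressive-mark-high cluster. Rows are sorted canonically before
  `hclust` so gene order cannot change the result through distance ties.

## Representative-gene selection

Per cluster: genes are ranked by the sum of their H3K27me3 scores over four
configured fraction/stage columns; the top 18 form the candidate pool (the
whole cluster when smaller). The pool is re-ranked by
`(s1 − s2)² + (s3 − s4)²` — the squared fraction differences at the two
stages — and the top 3 are returned from the small end (`smallest_diff`,
for clusters whose fractions behave alike) or the large end
(`largest_diff`, for clusters with fraction-specific modification). The
two squared differences are combined by summation by default (`max` is
available); summation treats both stages symmetrically and is the natural
reading of "difference at both stages". The top-18 stage is applied per
cluster, the only reading under which every cluster yields three genes.
All ties break lexicographically by gene id, so selection is fully
deterministic.

## Statistics

Group comparisons use the classical pooled-variance Student's t
(two-sided; Welch available behind a flag) and the point-biserial effect
size: the absolute Pearson correlation between the pooled values and a 0/1
group indicator, which satisfies `r = sqrt(t² / (t² + df))`. Effect sizes
are banded at `r > 0.5` (strong) and `0.3 < r <= 0.5` (moderate), with
boundary values falling into the lower band. No multiple-testing
correction is applied, matching the workflow this package systematizes.
Category enrichment is a plain per-cluster fraction of genes carrying an
exact label (default "transcription regulator") from a flat gene→category
table; no ontology expansion is attempted.

## The synthetic-data generator

`simulation_config()` defaults describe the emulated study: 2,000 genes on
2 chromosomes, 5% small RNAs, six expression samples (E15, E18, and
EGFP−/EGFP+ at P1 and P4), and H3K4me3/H3K27me3 + input tag libraries for
Cd73_P and Cd73_N fractions at P2, P5 and P8 (~2 × 10⁵ tags each). Planted
structure: 150 Müller-like genes at baseline FPKM in progenitors and EGFP+
samples but 4-fold down in EGFP− samples; 150 rod-like genes 4-fold down
everywhere except P4 EGFP−; and a 60-gene TF-like subset of the Müller set
with 8-fold H3K27me3 tag-rate enrichment in TSS ± 2 kb in Cd73_P libraries
(and, for all Müller genes, H3K4me3 enrichment in Cd73_N). Multiplicative
lognormal noise (σ = 0.25) hits every expression cell; ChIP tags are drawn
from a piecewise-constant intensity rescaled so expected totals equal the
library size.

Generator design choices:

- **Chromosome length is 16 Mb** so that 2,000 genes fit on a jittered grid
  with pairwise TSS spacing ≥ 15 kb. The spacing guarantees a planted
  promoter signal cannot bleed into a neighbour's scored ± 5 kb interval —
  a deliberate simplification relative to real genomes, where promoters
  crowd and signals overlap.
- **Enrichment sits in ± 2 kb around the TSS**, well inside the scored
  ± 5 kb window, so the scoring procedure captures it fully.
- **`frac_histone_blank` (default 0.1)** marks a random tenth of genes as
  lacking usable histone coverage; the pipeline excludes them from scoring.
  Real promoter dropout of roughly this magnitude is what makes the
  "restrict to measured genes" stage necessary at all.
- Recovery of the planted Müller set is evaluated on the **P1 ∩ P4
  intersection gate** — the workflow's actual definition of the
  progenitor-shared set. A single-timepoint gate at the default noise level
  passes ~2.5% of the ~1,700 background genes and cannot reach high
  precision; requiring both timepoints squares the background pass rate,
  exactly as the two-timepoint design intends.

What the generator does **not** emulate: overlapping genes and shared
promoters, non-uniform background (GC/mappability structure), fragment-length
effects, replicate structure, and FPKM estimation noise that correlates
across samples. Passing tests therefore demonstrate the correctness and
internal consistency of the computational chain under the stated
assumptions — not robustness to every artifact of real ChIP-seq.

## Problem sizes and determinism

The test suite verifies the scoring chain against a brute-force
per-gene window enumeration on 20 random instances of ≤ 25 genes and
≤ 2,500 tags, agreement of Ward merges with an exhaustive minimal-merge
oracle at n ≤ 8, representative selection against an independent
reimplementation on 100 random instances including ties, and
planted-structure recovery over ten full simulation seeds at the default
configuration — sizes chosen to exercise every code path while keeping the
suite fast enough to run on every change. All randomness flows from
explicit seeds: generators derive fixed per-stage streams from the master
seed, and clustering keeps a private RNG so package calls never disturb the
caller's `.Random.seed`.

## Known limitations

- Published cluster identities from the original retinal dataset cannot be
  reproduced exactly: the upstream software choices (GeneSpring k-means,
  unspecified hierarchical linkage) are not fully documented, so this
  package fixes its own deterministic conventions and records them in
  every output manifest.
- Whether the original analysis floored, offset, or dropped non-positive
  input-subtracted values before log2, and whether its windows were
  genome-global or TSS-anchored, is not stated in the source methods; the
  epsilon-floor and genome-global windows are this package's documented
  conventions.
- The gene→category table is a flat stand-in for a commercial pathway
  knowledge base; only exact label matches count.
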