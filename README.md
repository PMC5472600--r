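# gliaMarks

Müller glia — the retina's intrinsic glial cells — arise from the same
progenitors as retinal neurons, and the genes that stay glia-specific are
marked early by promoter histone modifications. `gliaMarks` implements, as a
tested and reusable R pipeline, the computational chain used to find such
genes from bulk data on sorted retinal cell fractions:

1. **Promoter histone scoring** from ChIP-seq tag libraries: tags are counted
   in 1050-bp windows sliding by 50 bp, divided by the library size, the
   matched input is subtracted window-wise, values move to log2 scale, and
   the windows whose centers fall within TSS ± 5 kb are averaged per gene
   (RefSeq-style genes, small RNAs excluded). Gene × sample score matrices
   are quantile normalized across samples.
2. **Fold-change gating**: a gene is specific to the EGFP-positive (glia-like)
   fraction when expressed at > 2-fold of the opposing fraction (strict
   inequality, pseudocount 0.1 FPKM), evaluated independently at two
   postnatal timepoints, with Venn set algebra over the resulting sets.
3. **Clustering**: seeded k-means (Lloyd, k-means++-style init) of
   log2(FPKM + 1) expression, and Ward/Euclidean hierarchical clustering of
   gene sets on their H3K4me3/H3K27me3 promoter scores.
4. **Representative-gene selection** for ChIP-qPCR follow-up: per cluster,
   the top 18 genes by summed H3K27me3 over four fraction/stage samples,
   re-ranked by the summed squared between-fraction differences, top 3 kept
   from the configured end.
5. **Statistics**: per-cluster transcription-factor (category) fractions,
   pooled-variance Student's t, and the point-biserial effect size
   r = |cor(value, group)| banded at r > 0.5 (strong) and r > 0.3 (moderate).

A synthetic-data generator plants a Müller-like gene set (high in EGFP+ and
in E15/E18 progenitors), a rod-like set (rising only in P4 EGFP−), and a
TF-like subset carrying elevated H3K27me3 specifically in the Cd73-positive
fraction, with full ground truth — so the whole workflow is testable end to
end without any external download.

## Worked example

```r
library(gliaMarks)
report <- run_pipeline(simulation_config(), pipeline_params(k_hier = 2))
print(report)
#> pipeline_report
#>   gate sizes: epg_p1=197, epg_p4=181, epg_common=147, epg_union=231,
#>               p4_only=34, target_set=147, histone_restricted=134
#>   clusters: 2 ( hierarchical )
#>   top-cluster H3K27me3 Cd73_P vs rest: r = 0.869 ( strong )
report$enrichment
#>   cluster n_genes n_category  fraction n_unannotated
#> 1      C1      58         57 0.9827586             1
#> 2      C2      76          0 0.0000000            76
```

Reading: of 2,000 simulated genes, 197 and 181 pass the > 2-fold
EGFP-positive gate at P1 and P4; 147 pass at both timepoints (the
Müller-glia candidate set; 150 were planted). 134 of them have usable
histone coverage, and cutting the Ward tree at k = 2 isolates a 58-gene
cluster that is simultaneously the highest in Cd73_P H3K27me3 (effect size
r = 0.87, "strong") and almost pure transcription regulators — the planted
bivalent-TF structure, recovered. `report$representatives` lists the three
genes per cluster that the two-stage procedure would send to ChIP-qPCR.

The same machinery runs stage by stage (`count_window_tags()`,
`subtract_input()`, `quantile_normalize()`, `fold_change_gate()`,
`hierarchical_histone()`, `select_representatives()`, ...) on user-supplied
BED/TSV files; see the function documentation and
`vignette("gliaMarks-methods")`. A command-line wrapper lives at
`inst/scripts/run-pipeline.R`.

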