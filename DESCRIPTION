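Package: gliaMarks
Title: TSS-Anchored Histone Signal Scoring and Gene-Set Analysis for
    Muller Glia Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies Muller-glia-specific genes and their promoter
    histone-modification signatures from bulk RNA-seq and ChIP-seq of
    sorted retinal cell fractions. Implements sliding-window ChIP tag
    counting with input subtraction and log2 transform, TSS +/- 5 kb
    signal averaging with quantile normalization, fold-change gene-set
    gating with Venn set algebra, k-means clustering of expression and
    hierarchical clustering of promoter histone values, a deterministic
    representative-gene selection procedure, per-cluster category
    (transcription-factor) enrichment, and pooled t / point-biserial
    effect-size statistics. A synthetic-data generator with planted gene
    sets and ground truth exercises the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    optparse
Config/testthat/edition: 3
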