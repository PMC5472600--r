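#' Analysis parameters for the full pipeline
#'
#' @param fold Fold-change gate threshold (default 2).
#' @param pseudocount Gate pseudocount in FPKM (default 0.1).
#' @param k_hier Number of hierarchical clusters (default 7; the
#'   P4-specific variant of the workflow uses 6).
#' @param gene_set Which gated set is clustered: `"common"` (genes
#'   upregulated in the EGFP-positive fraction at both P1 and P4) or
#'   `"p4_only"`.
#' @param width,step,flank,epsilon Histone-scoring parameters.
#' @param category_label Category queried for enrichment.
#' @param rep_modes Optional named mode vector for
#'   [select_representatives()]; defaults to `largest_diff` for every
#'   cluster (for k = 7, the classic split — smallest for C1, C2, C4, C5,
#'   largest for C3, C6, C7 — can be supplied explicitly).
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(fold = 2, pseudocount = 0.1, k_hier = 7L,
                            gene_set = c("common", "p4_only"),
                            width = 1050L, step = 50L, flank = 5000L,
                            epsilon = 1e-9,
                            category_label = "transcription regulator",
                            rep_modes = NULL) {
  gene_set <- match.arg(gene_set)
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full Muller-glia gene-discovery workflow
#'
#' Executes the stages in order on a synthetic dataset: small-RNA
#' filtering, fold-change gating at P1 and P4, Venn set algebra, promoter
#' histone scoring of all covered genes, restriction of the gated set to
#' histone-covered genes, hierarchical clustering on the histone values,
#' per-cluster summaries, transcription-factor enrichment, representative
#' gene selection, and a cluster-level effect-size comparison of
#' H3K27me3 between the Cd73_P and Cd73_N fractions.
#'
#' @param config A [simulation_config()] describing the input dataset.
#' @param params A [pipeline_params()].
#' @param outdir Optional directory; when given, every stage artifact and
#'   a parameter manifest are written there.
#' @return A `pipeline_report` list: `sizes` (all gate/Venn/coverage
#'   counts), `gates`, `venn`, `histone` (the `tss_signal_matrix`),
#'   `partition`, `summaries`, `enrichment`, `representatives`,
#'   `comparison`, `truth`, and `manifest` (every tunable and seed).
#' @export
run_pipeline <- function(config = simulation_config(),
                         params = pipeline_params(), outdir = NULL) {
  ann <- generate_annotation(config)
  expr <- generate_expression(config, ann$truth, ann$genes)
  libs <- generate_chip(config, ann$truth, ann$genes)

  filtered <- filter_small_rnas(ann$genes)
  expr_f <- expr[filtered$gene_id, , drop = FALSE]

  gate_p1 <- fold_change_gate(expr_f, "P1_P", "P1_N",
                              fold = params$fold, pseudocount = params$pseudocount)
  gate_p4 <- fold_change_gate(expr_f, "P4_P", "P4_N",
                              fold = params$fold, pseudocount = params$pseudocount)
  venn <- set_algebra(gate_p1$epg, gate_p4$epg)

  covered_genes <- filtered[!filtered$gene_id %in% ann$truth$histone_blank_genes, ,
                            drop = FALSE]
  histone <- compute_histone_matrix(
    match_test_input(libs), covered_genes, sim_chrom_lengths(config),
    width = params$width, step = params$step, flank = params$flank,
    epsilon = params$epsilon
  )

  target_set <- switch(params$gene_set, common = venn$intersection,
                       p4_only = venn$b_only)
  restricted <- restrict_to_measured(target_set, histone)

  k27_p_cols <- grep("^H3K27me3_Cd73_P", colnames(histone$scores), value = TRUE)
  k27_n_cols <- grep("^H3K27me3_Cd73_N", colnames(histone$scores), value = TRUE)
  partition <- hierarchical_histone(
    histone$scores[restricted, , drop = FALSE], k = params$k_hier,
    order_samples = k27_p_cols
  )
  summaries <- cluster_summary(partition, histone$scores[restricted, , drop = FALSE])
  enrichment <- category_fraction(partition, ann$categories,
                                  label = params$category_label)

  rep_modes <- params$rep_modes
  if (is.null(rep_modes)) {
    labs <- sort(unique(partition$assignment))
    rep_modes <- stats::setNames(rep("largest_diff", length(labs)), labs)
  }
  rep_cfg <- representative_config(
    sum_samples = c("H3K27me3_Cd73_N_P2", "H3K27me3_Cd73_P_P2",
                    "H3K27me3_Cd73_N_P5", "H3K27me3_Cd73_P_P5"),
    modes = rep_modes
  )
  representatives <- select_representatives(histone, partition, rep_cfg)

  # top-K27 cluster (C1) vs the rest, on Cd73_P H3K27me3 promoter values
  top_genes <- names(partition$assignment)[partition$assignment == "C1"]
  rest_genes <- setdiff(names(partition$assignment), top_genes)
  comparison <- compare_groups(list(genes = top_genes, samples = k27_p_cols),
                               list(genes = rest_genes, samples = k27_p_cols),
                               matrix = histone$scores)

  sizes <- c(epg_p1 = length(gate_p1$epg), epg_p4 = length(gate_p4$epg),
             epg_common = venn$sizes[["intersection"]],
             epg_union = venn$sizes[["union"]],
             p4_only = venn$sizes[["b_only"]],
             target_set = length(target_set),
             histone_restricted = length(restricted))
  stopifnot(sizes[["epg_union"]] ==
              sizes[["epg_p1"]] + sizes[["epg_p4"]] - sizes[["epg_common"]])

  manifest <- list(
    seed = config$seed, n_genes = config$n_genes,
    width = params$width, step = params$step, flank = params$flank,
    epsilon = params$epsilon, fold = params$fold,
    pseudocount = params$pseudocount, k_hier = params$k_hier,
    gene_set = params$gene_set, linkage = "ward.D2",
    rep_modes = as.list(rep_modes),
    rep_sum_samples = rep_cfg$sum_samples,
    category_label = params$category_label,
    simulation = unclass(config)
  )

  report <- structure(
    list(sizes = sizes, gates = list(P1 = gate_p1, P4 = gate_p4), venn = venn,
         histone = histone, partition = partition, summaries = summaries,
         enrichment = enrichment, representatives = representatives,
         comparison = comparison, truth = ann$truth, categories = ann$categories,
         manifest = manifest),
    class = "pipeline_report"
  )
  if (!is.null(outdir)) write_pipeline_outputs(report, expr, ann, outdir)
  report
}

write_pipeline_outputs <- function(report, expr, ann, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_gene_annotation_bed(ann$genes, file.path(outdir, "genes.bed"))
  write_category_tsv(ann$categories, file.path(outdir, "categories.tsv"))
  write_matrix_tsv(expr, file.path(outdir, "expr.tsv"))
  write_matrix_tsv(report$histone$scores, file.path(outdir, "histone_normalized.tsv"))
  write_matrix_tsv(report$histone$raw, file.path(outdir, "histone_raw.tsv"))
  jsonlite::write_json(
    list(P1 = list(epg = report$gates$P1$epg, eng = report$gates$P1$eng),
         P4 = list(epg = report$gates$P4$epg, eng = report$gates$P4$eng),
         sizes = as.list(report$sizes)),
    file.path(outdir, "gates.json"), auto_unbox = TRUE
  )
  jsonlite::write_json(
    list(method = report$partition$method, k = report$partition$k,
         linkage = report$partition$linkage,
         assignment = as.list(report$partition$assignment)),
    file.path(outdir, "partition.json"), auto_unbox = TRUE
  )
  utils::write.table(report$enrichment, file.path(outdir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summaries, file.path(outdir, "cluster_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$representatives,
                       file.path(outdir, "representatives.json"))
  jsonlite::write_json(report$comparison, file.path(outdir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  write_truth(report$truth, file.path(outdir, "truth.json"))
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat("  gate sizes:", paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "), "\n")
  cat("  clusters:", x$partition$k, "(", x$partition$method, ")\n")
  cat("  top-cluster H3K27me3 Cd73_P vs rest: r =",
      format(x$comparison$r, digits = 3), "(", x$comparison$band, ")\n")
  invisible(x)
}
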