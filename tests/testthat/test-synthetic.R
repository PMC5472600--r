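small_config <- function(seed = 5L, ...) {
  simulation_config(seed = seed, n_genes = 120L, n_chroms = 2L,
                    chrom_length = 1.2e6, n_muller = 20L, n_rod = 15L,
                    n_tf_k27 = 8L, library_size = 2e4, ...)
}

test_that("annotation generation honours counts, spacing and determinism", {
  cfg <- small_config(frac_small_rna = 0.1)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$genes), 120L)
  expect_equal(sum(ann$genes$biotype != "protein_coding"), 12L)
  spacings <- unlist(tapply(gene_tss(ann$genes), ann$genes$chrom,
                            function(x) diff(sort(x))))
  expect_gte(min(spacings), 15000)
  expect_length(ann$truth$muller_genes, 20L)
  expect_length(ann$truth$tf_k27_genes, 8L)
  expect_true(all(ann$truth$tf_k27_genes %in% ann$truth$muller_genes))
  expect_length(intersect(ann$truth$muller_genes, ann$truth$rod_genes), 0)
  expect_true(all(ann$truth$tf_k27_genes %in% names(ann$categories)))

  again <- generate_annotation(small_config(frac_small_rna = 0.1))
  expect_identical(ann, again)
  other_seed <- generate_annotation(small_config(seed = 6L, frac_small_rna = 0.1))
  expect_false(identical(ann$truth$muller_genes, other_seed$truth$muller_genes))
})

test_that("annotation generation rejects an over-packed genome", {
  expect_error(generate_annotation(simulation_config(n_genes = 500L,
                                                     n_chroms = 1L,
                                                     chrom_length = 1e6)),
               "chrom budget")
})

test_that("noiseless expression reproduces the planted fold changes exactly", {
  cfg <- small_config(expr_noise_sigma = 0)
  ann <- generate_annotation(cfg)
  expr <- generate_expression(cfg, ann$truth, ann$genes)
  mul <- ann$truth$muller_genes
  rod <- ann$truth$rod_genes
  expect_equal(expr[mul, "P4_P"] / expr[mul, "P4_N"],
               stats::setNames(rep(4, length(mul)), mul))
  expect_equal(expr[mul, "E18"], expr[mul, "P4_P"])
  expect_equal(expr[rod, "P4_N"] / expr[rod, "P4_P"],
               stats::setNames(rep(4, length(rod)), rod))
  bg <- setdiff(rownames(expr), c(mul, rod))
  expect_equal(expr[bg, "P1_P"], expr[bg, "P4_N"])
  expect_true(all(expr >= 0))
})

test_that("Muller genes share progenitor-level expression at default noise", {
  cfg <- simulation_config(seed = 2L)
  ann <- generate_annotation(cfg)
  expr <- generate_expression(cfg, ann$truth, ann$genes)
  mul <- ann$truth$muller_genes
  ratio <- mean(expr[mul, "E18"]) / mean(expr[mul, "P4_P"])
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("ChIP generation is deterministic with totals near the library size", {
  cfg <- small_config()
  ann <- generate_annotation(cfg)
  libs <- generate_chip(cfg, ann$truth, ann$genes)
  expect_length(libs, 18L)  # 2 marks x 2 fractions x 3 stages + 6 inputs
  totals <- vapply(libs, function(l) l$total_tags, integer(1))
  expect_true(all(abs(totals - cfg$library_size) < 6 * sqrt(cfg$library_size)))
  libs2 <- generate_chip(cfg, ann$truth, ann$genes)
  expect_identical(libs, libs2)
  pairs <- match_test_input(libs)
  expect_length(pairs, 12L)
  expect_true(all(vapply(pairs, function(p) {
    p$input$antibody == "input" && p$test$fraction == p$input$fraction &&
      p$test$stage == p$input$stage
  }, logical(1))))
})

test_that("unenriched libraries are statistically flat against input", {
  cfg <- small_config(chip_enrichment_fold = 1)
  ann <- generate_annotation(cfg)
  libs <- generate_chip(cfg, ann$truth, ann$genes)
  hm <- compute_histone_matrix(match_test_input(libs)[1:4],
                               filter_small_rnas(ann$genes),
                               sim_chrom_lengths(cfg))
  tf <- intersect(ann$truth$tf_k27_genes, rownames(hm$raw))
  bg <- setdiff(rownames(hm$raw), ann$truth$tf_k27_genes)
  for (col in colnames(hm$raw)) {
    res <- students_t(hm$raw[tf, col], hm$raw[bg, col])
    expect_gt(res$p, 0.001)
  }
})

test_that("ground truth round-trips through JSON", {
  for (seed in c(1L, 2L, 3L)) {
    truth <- generate_annotation(small_config(seed = seed))$truth
    path <- withr::local_tempfile(fileext = ".json")
    write_truth(truth, path)
    back <- read_truth(path)
    expect_equal(back$muller_genes, truth$muller_genes)
    expect_equal(back$tf_k27_genes, truth$tf_k27_genes)
    expect_equal(back$histone_blank_genes, truth$histone_blank_genes)
    expect_equal(back$muller_fold, truth$muller_fold)
  }
})

test_that("every generated file parses cleanly with the package readers", {
  cfg <- small_config()
  outdir <- withr::local_tempdir()
  ds <- expect_no_warning(write_synthetic_dataset(cfg, outdir))
  genes <- expect_no_warning(read_gene_annotation(file.path(outdir, "genes.bed"),
                                                  "bed6plus"))
  expect_equal(genes$gene_id, ds$genes$gene_id)
  expect_equal(genes$tx_start, ds$genes$tx_start)
  expr <- expect_no_warning(read_expression_tsv(file.path(outdir, "expr.tsv")))
  expect_equal(expr, ds$expression, tolerance = 1e-12)
  cats <- expect_no_warning(read_category_tsv(file.path(outdir, "categories.tsv")))
  expect_equal(cats, ds$categories)
  lib <- expect_no_warning(read_tag_bed(
    file.path(outdir, "chip", "H3K27me3_Cd73_P_P2.bed"), sample_id = "x"
  ))
  expect_equal(sort(lib$pos), sort(ds$libraries$H3K27me3_Cd73_P_P2$pos))
})
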