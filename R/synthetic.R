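#' Configuration for the synthetic retinal dataset
#'
#' The generator emulates the data layout of the study design: six bulk
#' expression samples (whole retina E15/E18 plus EGFP-sorted positive and
#' negative fractions at P1 and P4) and H3K4me3/H3K27me3 ChIP tag
#' libraries with matched inputs for two sorted fractions (Cd73_P,
#' Cd73_N) at three stages (P2, P5, P8).  Planted structure: a
#' progenitor-shared "Muller" gene set high in EGFP-positive samples and
#' in E15/E18, a "rod" set rising only in P4 EGFP-negative cells, and a
#' transcription-factor-like subset of the Muller set carrying elevated
#' H3K27me3 specifically in the Cd73_P fraction.
#'
#' @param seed Integer master seed.
#' @param n_genes Total genes (default 2000).
#' @param n_chroms Number of chromosomes (default 2).
#' @param chrom_length Length of each chromosome in bp (default 16 Mb,
#'   sized so 2000 genes fit at >= 15 kb TSS spacing).
#' @param frac_small_rna Fraction of genes given small-RNA biotypes
#'   (default 0.05).
#' @param n_muller,n_rod,n_tf_k27 Planted set sizes (defaults 150, 150,
#'   60; the TF set is a subset of the Muller set).
#' @param expr_noise_sigma Lognormal sd of multiplicative expression
#'   noise (default 0.25).
#' @param muller_fold True expression fold change of planted genes
#'   (default 4).
#' @param chip_background_rate Background ChIP tag rate, tags/kb, before
#'   rescaling to the library size (default 0.5).
#' @param chip_enrichment_fold Tag-rate fold in enriched promoter
#'   intervals (default 8).
#' @param library_size Expected tags per ChIP library (default 2e5).
#' @param frac_histone_blank Fraction of genes without usable histone
#'   coverage, excluded from ChIP-seq scoring as in real promoter
#'   dropout (default 0.1).
#' @param tf_background_frac Fraction of non-planted genes labelled
#'   transcription regulators in the category table (default 0.05).
#' @param enrich_flank Half-width of the enriched promoter interval
#'   around the TSS, bp (default 2000, inside the scored +/- 5 kb).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 20170615L, n_genes = 2000L, n_chroms = 2L,
                              chrom_length = 16e6, frac_small_rna = 0.05,
                              n_muller = 150L, n_rod = 150L, n_tf_k27 = 60L,
                              expr_noise_sigma = 0.25, muller_fold = 4,
                              chip_background_rate = 0.5,
                              chip_enrichment_fold = 8, library_size = 2e5,
                              frac_histone_blank = 0.1,
                              tf_background_frac = 0.05, enrich_flank = 2000L) {
  stopifnot(n_muller + n_rod <= n_genes, n_tf_k27 <= n_muller,
            muller_fold > 1, chip_enrichment_fold >= 1,
            n_genes > 0L, n_chroms > 0L, library_size > 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Chromosome lengths implied by a simulation config
#' @param config A `simulation_config`.
#' @return Named numeric vector `chr1 .. chrN`.
#' @export
sim_chrom_lengths <- function(config) {
  stats::setNames(rep(config$chrom_length, config$n_chroms),
                  paste0("chr", seq_len(config$n_chroms)))
}

#' Generate the synthetic gene annotation, categories and ground truth
#'
#' Genes are laid on a jittered grid with pairwise TSS spacing >= 15 kb,
#' so a planted promoter signal cannot bleed into a neighbour's scored
#' +/- 5 kb interval.  Strands are drawn 50/50; `frac_small_rna` of genes
#' receive small-RNA biotypes; the planted Muller/rod/TF sets are drawn
#' from protein-coding genes.
#'
#' @param config A `simulation_config`.
#' @return List with `genes` (a `gene_annotation`), `categories` (named
#'   vector, see [category_fraction()]) and `truth` (a `ground_truth`
#'   list of planted gene-id sets).
#' @export
generate_annotation <- function(config) {
  with_sim_seed(config$seed, 1L, {
    per_chrom <- diff(floor(seq(0, config$n_genes, length.out = config$n_chroms + 1L)))
    spacing <- floor(config$chrom_length / max(per_chrom))
    if (spacing < 15000L) {
      stop("n_genes too large for chrom budget: TSS spacing would be ",
           spacing, " bp (< 15 kb)")
    }
    jmax <- min(500L, (spacing - 15000L) %/% 2L)
    rows <- lapply(seq_len(config$n_chroms), function(ci) {
      n <- per_chrom[ci]
      if (n == 0L) return(NULL)
      tss <- spacing %/% 2L + (seq_len(n) - 1L) * spacing +
        sample.int(2L * jmax + 1L, n, replace = TRUE) - jmax - 1L
      data.frame(chrom = paste0("chr", ci), tss = tss, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    n <- nrow(rows)
    rows$gene_id <- sprintf("g%04d", seq_len(n))
    rows$strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- sample(2000:20000, n, replace = TRUE)
    rows$tx_start <- ifelse(rows$strand == "+", rows$tss,
                            pmax(rows$tss + 1L - len, 0L))
    rows$tx_end <- ifelse(rows$strand == "+",
                          pmin(rows$tss + len, config$chrom_length),
                          rows$tss + 1L)
    rows$biotype <- "protein_coding"
    n_small <- round(config$frac_small_rna * n)
    small_idx <- sample.int(n, n_small)
    rows$biotype[small_idx] <- sample(c("miRNA", "snoRNA", "snRNA"),
                                      n_small, replace = TRUE)
    coding <- rows$gene_id[rows$biotype == "protein_coding"]
    planted <- sample(coding, config$n_muller + config$n_rod)
    muller <- sort(planted[seq_len(config$n_muller)])
    rod <- sort(planted[config$n_muller + seq_len(config$n_rod)])
    tf_k27 <- sort(sample(muller, config$n_tf_k27))
    non_planted <- setdiff(rows$gene_id, c(muller, rod))
    bg_tf <- sample(non_planted, round(config$tf_background_frac * length(non_planted)))
    categories <- stats::setNames(rep("transcription regulator",
                                      length(tf_k27) + length(bg_tf)),
                                  c(tf_k27, bg_tf))
    categories <- categories[order(names(categories))]
    rows$category <- ifelse(rows$gene_id %in% names(categories),
                            "transcription regulator", NA_character_)
    not_small <- rows$gene_id[rows$biotype == "protein_coding"]
    blank <- sort(sample(not_small, round(config$frac_histone_blank * length(not_small))))
    genes <- rows[, c("gene_id", "chrom", "strand", "tx_start", "tx_end",
                      "biotype", "category")]
    rownames(genes) <- NULL
    class(genes) <- c("gene_annotation", "data.frame")
    truth <- structure(
      list(muller_genes = muller, rod_genes = rod, tf_k27_genes = tf_k27,
           histone_blank_genes = blank,
           muller_fold = config$muller_fold,
           chip_enrichment_fold = config$chip_enrichment_fold),
      class = "ground_truth"
    )
    list(genes = genes, categories = categories, truth = truth)
  })
}

#' Generate the synthetic expression matrix
#'
#' Baseline FPKM is lognormal with median ~10.  Muller genes sit at
#' baseline in E15, E18, P1_P and P4_P and at `baseline / muller_fold` in
#' P1_N and P4_N; rod genes are at `baseline / muller_fold` everywhere
#' except P4_N; every cell then receives independent multiplicative
#' lognormal noise of sd `expr_noise_sigma`.
#'
#' @param config A `simulation_config`.
#' @param truth A `ground_truth` from [generate_annotation()].
#' @param genes The matching `gene_annotation`.
#' @return FPKM matrix, genes x samples `E15, E18, P1_N, P1_P, P4_N,
#'   P4_P`.
#' @export
generate_expression <- function(config, truth, genes) {
  samples <- c("E15", "E18", "P1_N", "P1_P", "P4_N", "P4_P")
  with_sim_seed(config$seed, 2L, {
    n <- nrow(genes)
    baseline <- stats::rlnorm(n, meanlog = log(10), sdlog = 0.8)
    factor <- matrix(1, nrow = n, ncol = length(samples),
                     dimnames = list(genes$gene_id, samples))
    is_mul <- genes$gene_id %in% truth$muller_genes
    is_rod <- genes$gene_id %in% truth$rod_genes
    factor[is_mul, c("P1_N", "P4_N")] <- 1 / config$muller_fold
    factor[is_rod, setdiff(samples, "P4_N")] <- 1 / config$muller_fold
    noise <- if (config$expr_noise_sigma > 0) {
      matrix(exp(stats::rnorm(n * length(samples), 0, config$expr_noise_sigma)),
             nrow = n)
    } else 1
    baseline * factor * noise
  })
}

#' Generate the synthetic ChIP and input tag libraries
#'
#' Background tags fall uniformly at `chip_background_rate` tags/kb.
#' Planted TF genes get `chip_enrichment_fold` times the background tag
#' rate in TSS +/- `enrich_flank` in the Cd73_P H3K27me3 libraries at all
#' three stages; Muller genes get the same H3K4me3 enrichment in Cd73_N
#' libraries.  Input libraries are background-only.  All intensities are
#' rescaled so each library's total is Poisson around `library_size`.
#'
#' @param config A `simulation_config`.
#' @param truth A `ground_truth`.
#' @param genes The matching `gene_annotation`.
#' @return Named list of `tag_library` — tests named
#'   `<mark>_<fraction>_<stage>` and inputs `input_<fraction>_<stage>`.
#' @export
generate_chip <- function(config, truth, genes) {
  fractions <- c("Cd73_P", "Cd73_N")
  stages <- c("P2", "P5", "P8")
  tss <- gene_tss(genes)
  enriched_for <- function(mark, fraction) {
    ids <- if (mark == "H3K27me3" && fraction == "Cd73_P") truth$tf_k27_genes
           else if (mark == "H3K4me3" && fraction == "Cd73_N") truth$muller_genes
           else character(0)
    ids
  }
  libs <- list()
  with_sim_seed(config$seed, 3L, {
    for (fraction in fractions) for (stage in stages) {
      for (mark in c("H3K4me3", "H3K27me3")) {
        id <- paste(mark, fraction, stage, sep = "_")
        ids <- enriched_for(mark, fraction)
        libs[[id]] <- sample_tag_library(
          config, genes, tss[ids], id,
          antibody = mark, fraction = fraction, stage = stage
        )
      }
      id <- paste("input", fraction, stage, sep = "_")
      libs[[id]] <- sample_tag_library(
        config, genes, numeric(0), id,
        antibody = "input", fraction = fraction, stage = stage
      )
    }
    libs
  })
}

# Draw one library from a piecewise-constant tag intensity: background 1x
# everywhere, chip_enrichment_fold x in TSS +/- enrich_flank of the given
# genes, rescaled so the expected total is library_size.
sample_tag_library <- function(config, genes, enriched_tss, sample_id,
                               antibody, fraction, stage) {
  lens <- sim_chrom_lengths(config)
  segs <- list()
  for (cn in names(lens)) {
    len <- lens[[cn]]
    et <- sort(enriched_tss[genes$chrom[match(names(enriched_tss), genes$gene_id)] == cn])
    starts <- pmax(et - config$enrich_flank, 0)
    ends <- pmin(et + config$enrich_flank, len)
    # background gaps between enriched intervals (TSS spacing keeps them disjoint)
    bg_starts <- c(0, ends)
    bg_ends <- c(starts, len)
    keep <- bg_ends > bg_starts
    segs[[cn]] <- data.frame(
      chrom = cn,
      start = c(bg_starts[keep], starts),
      end = c(bg_ends[keep], ends),
      rate = c(rep(1, sum(keep)), rep(config$chip_enrichment_fold, length(starts)))
    )
  }
  segs <- do.call(rbind, segs)
  mass <- (segs$end - segs$start) * segs$rate
  n_total <- stats::rpois(1L, config$library_size)
  counts <- as.vector(stats::rmultinom(1L, n_total, mass))
  chrom <- rep(segs$chrom, counts)
  seg_start <- rep(segs$start, counts)
  seg_len <- rep(segs$end - segs$start, counts)
  pos <- seg_start + floor(stats::runif(n_total) * seg_len)
  tag_library(chrom, pos, sample_id = sample_id, antibody = antibody,
              fraction = fraction, stage = stage)
}

#' Pair each test ChIP library with its matched input
#'
#' @param libs Named library list from [generate_chip()].
#' @return List of `list(test = , input = )` pairs, one per test library,
#'   matched on fraction and stage.
#' @export
match_test_input <- function(libs) {
  tests <- libs[vapply(libs, function(l) l$antibody != "input", logical(1L))]
  lapply(tests, function(test) {
    input_id <- paste("input", test$fraction, test$stage, sep = "_")
    if (is.null(libs[[input_id]])) stop("no matched input for ", test$sample_id)
    list(test = test, input = libs[[input_id]])
  })
}

#' Serialize / read ground truth
#'
#' @param truth A `ground_truth`.
#' @param path JSON path.
#' @return `path` invisibly; `read_truth()` returns the `ground_truth`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("muller_genes", "rod_genes", "tf_k27_genes", "histone_blank_genes")) {
    raw[[f]] <- as.character(raw[[f]])
  }
  structure(raw, class = "ground_truth")
}

#' Write a complete synthetic dataset to disk
#'
#' Produces `genes.bed`, `categories.tsv`, `expr.tsv`, `truth.json` and
#' one BED per ChIP/input library under `chip/`.
#'
#' @param config A `simulation_config`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the in-memory dataset (annotation, categories,
#'   truth, expression, libraries).
#' @export
write_synthetic_dataset <- function(config, outdir) {
  dir.create(file.path(outdir, "chip"), recursive = TRUE, showWarnings = FALSE)
  ann <- generate_annotation(config)
  expr <- generate_expression(config, ann$truth, ann$genes)
  libs <- generate_chip(config, ann$truth, ann$genes)
  write_gene_annotation_bed(ann$genes, file.path(outdir, "genes.bed"))
  write_category_tsv(ann$categories, file.path(outdir, "categories.tsv"))
  write_matrix_tsv(expr, file.path(outdir, "expr.tsv"))
  write_truth(ann$truth, file.path(outdir, "truth.json"))
  for (id in names(libs)) {
    write_tag_bed(libs[[id]], file.path(outdir, "chip", paste0(id, ".bed")))
  }
  invisible(list(genes = ann$genes, categories = ann$categories,
                 truth = ann$truth, expression = expr, libraries = libs))
}

# Run code under a deterministic per-stage RNG seed without disturbing
# the caller's RNG state.
with_sim_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed + offset * 1000L)
  code
}
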