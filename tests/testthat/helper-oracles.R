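# Independent oracles and small fixture builders shared across tests.

# Minimal gene annotation from TSS positions (plus-strand unless stated).
make_genes <- function(tss, chrom = "chr1", strand = "+",
                       ids = sprintf("t%03d", seq_along(tss)),
                       biotype = "protein_coding") {
  strand <- rep_len(strand, length(tss))
  df <- data.frame(
    gene_id = ids, chrom = rep_len(chrom, length(tss)), strand = strand,
    tx_start = ifelse(strand == "+", tss, tss - 999L),
    tx_end = ifelse(strand == "+", tss + 1000L, tss + 1L),
    biotype = rep_len(biotype, length(tss)), category = NA_character_,
    stringsAsFactors = FALSE
  )
  class(df) <- c("gene_annotation", "data.frame")
  df
}

make_library <- function(pos, chrom = "chr1", sample_id = "s1") {
  tag_library(rep_len(chrom, length(pos)), pos, sample_id = sample_id)
}

# A window track with the default grid and given per-window values.
new_track_for_test <- function(values, chrom = "chr1") {
  structure(list(chrom = chrom, width = 1050L, step = 50L,
                 values = as.numeric(values)),
            class = "window_track")
}

# Brute-force promoter scoring: per gene, enumerate candidate windows
# directly, count tags by interval membership on the raw position vector,
# and redo normalization / subtraction / log2 / averaging by hand.
oracle_gene_score <- function(test, input, gene, chrom_len,
                              width = 1050, step = 50, flank = 5000,
                              epsilon = 1e-9) {
  tss <- if (gene$strand == "+") gene$tx_start else gene$tx_end - 1L
  starts <- seq(0, by = step, length.out = ceiling(chrom_len / step))
  starts <- starts[starts + width / 2 >= tss - flank &
                   starts + width / 2 <= tss + flank]
  if (length(starts) == 0L) return(NA_real_)
  pt <- test$pos[test$chrom == gene$chrom]
  pi <- input$pos[input$chrom == gene$chrom]
  vals <- vapply(starts, function(s) {
    ct <- sum(pt >= s & pt < s + width) / test$total_tags
    ci <- sum(pi >= s & pi < s + width) / input$total_tags
    log2(max(ct - ci, 0) + epsilon)
  }, numeric(1))
  mean(vals)
}

# Independent quantile normalization: rank-range based, with tied values
# taking the mean of the tied ranks' reference values.
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    vapply(seq_along(col), function(i) mean(ref[lo[i]:hi[i]]), numeric(1))
  })
  dimnames(out) <- dimnames(m)
  out
}

oracle_histone_matrix <- function(pairs, genes, chrom_lengths, ...) {
  raw <- vapply(pairs, function(p) {
    vapply(seq_len(nrow(genes)), function(i) {
      oracle_gene_score(p$test, p$input, genes[i, ],
                        chrom_lengths[[genes$chrom[i]]], ...)
    }, numeric(1))
  }, numeric(nrow(genes)))
  raw <- matrix(raw, nrow = nrow(genes),
                dimnames = list(genes$gene_id,
                                vapply(pairs, function(p) p$test$sample_id,
                                       character(1))))
  oracle_quantile_normalize(raw)
}

# Exhaustive greedy Ward agglomeration: recompute every pairwise merge
# cost from cluster members at each step and take the minimum.
oracle_ward_partition <- function(x, k) {
  clusters <- as.list(seq_len(nrow(x)))
  ward_cost <- function(a, b) {
    ca <- colMeans(x[a, , drop = FALSE])
    cb <- colMeans(x[b, , drop = FALSE])
    length(a) * length(b) / (length(a) + length(b)) * sum((ca - cb)^2)
  }
  while (length(clusters) > k) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        d <- ward_cost(clusters[[i]], clusters[[j]])
        if (d < best[1]) best <- c(d, j, i)
      }
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  memb <- integer(nrow(x))
  for (i in seq_along(clusters)) memb[clusters[[i]]] <- i
  stats::setNames(memb, rownames(x))
}

# Same grouping up to relabelling?
same_partition <- function(a, b) {
  a <- a[sort(names(a))]
  b <- b[sort(names(b))]
  tab <- table(a, b)
  sum(tab > 0) == length(unique(a)) && length(unique(a)) == length(unique(b))
}

# Brute-force representative selection: repeated single-best extraction
# instead of vectorized sorting.
oracle_representatives <- function(x, assignment, config) {
  ss <- config$sum_samples
  out <- list()
  for (lab in sort(unique(assignment))) {
    genes <- sort(names(assignment)[assignment == lab])
    pool <- genes
    cand <- character(0)
    while (length(cand) < min(config$top_n_sum, length(genes))) {
      s <- rowSums(x[pool, ss, drop = FALSE])
      best <- pool[s == max(s)]
      best <- sort(best)[1L]  # lexicographic tie-break
      cand <- c(cand, best)
      pool <- setdiff(pool, best)
    }
    d1 <- (x[cand, ss[1]] - x[cand, ss[2]])^2
    d2 <- (x[cand, ss[3]] - x[cand, ss[4]])^2
    d <- if (config$combine == "sum") d1 + d2 else pmax(d1, d2)
    names(d) <- cand
    sel <- character(0)
    pool <- cand
    while (length(sel) < min(config$top_n_select, length(cand))) {
      target <- if (config$modes[[lab]] == "smallest_diff") min(d[pool]) else max(d[pool])
      best <- sort(pool[d[pool] == target])[1L]
      sel <- c(sel, best)
      pool <- setdiff(pool, best)
    }
    out[[lab]] <- sel
  }
  out
}

# Adjusted Rand index between two labelled partitions.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Four well-separated Gaussian blobs on a log2 scale, returned as
# FPKM-like values that kmeans_expression's log2(FPKM + 1) transform maps
# back onto the blob geometry.
blob_matrix <- function(n = 200L, k = 4L, sep = 5, sigma = 0.1, seed = 99L) {
  set.seed(seed)
  truth <- rep(seq_len(k), length.out = n)
  centers <- 1 + matrix(c(0, 0, sep, 0, 0, sep, sep, sep), ncol = 2, byrow = TRUE)
  x <- centers[truth, ] + matrix(stats::rnorm(2 * n, 0, sigma), ncol = 2)
  m <- 2^x - 1
  dimnames(m) <- list(sprintf("g%03d", seq_len(n)), c("s1", "s2"))
  list(m = m, truth = truth)
}
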