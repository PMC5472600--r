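#' Read a gene annotation (BED6+ or GTF subset)
#'
#' Parses gene models into a data frame with 0-based half-open coordinates.
#' The BED dialect expects the standard six columns followed by the gene
#' biotype in column 7 and an optional category label (e.g.
#' `"transcription regulator"`) in column 8.  The GTF dialect accepts
#' `gene`-feature lines only and converts their 1-based inclusive
#' coordinates; `gene_id`, `gene_biotype` and optional `category` are taken
#' from the attribute field.
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed6plus"` or `"gtf_subset"`.
#' @return A `gene_annotation` data frame with columns `gene_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `biotype`, `category` (`NA` when
#'   absent).  Coordinates are 0-based half-open.
#' @seealso [gene_tss()], [filter_small_rnas()]
#' @export
read_gene_annotation <- function(path, dialect = c("bed6plus", "gtf_subset")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("no annotation records in ", path)
  parsed <- switch(dialect,
    bed6plus  = parse_bed_genes(lines),
    gtf_subset = parse_gtf_genes(lines)
  )
  dup <- unique(parsed$gene_id[duplicated(parsed$gene_id)])
  if (length(dup) > 0L) {
    stop("duplicated gene_id in annotation: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  bad <- parsed$tx_start >= parsed$tx_end
  if (any(bad)) {
    stop("tx_start >= tx_end for gene(s): ",
         paste(utils::head(parsed$gene_id[bad], 5), collapse = ", "))
  }
  class(parsed) <- c("gene_annotation", "data.frame")
  parsed
}

parse_bed_genes <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 7L)) {
    stop("malformed BED6+ gene line ", which(n < 7L)[1L],
         ": expected >= 7 tab-separated fields")
  }
  get <- function(i) vapply(fields, `[`, character(1L), i)
  strand <- get(6L)
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand '", strand[!strand %in% c("+", "-")][1L],
         "' on line ", which(!strand %in% c("+", "-"))[1L])
  }
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer coordinate on line ", which(is.na(start) | is.na(end))[1L])
  }
  if (any(start < 0L)) stop("negative coordinate on line ", which(start < 0L)[1L])
  category <- rep(NA_character_, length(lines))
  has8 <- n >= 8L
  category[has8] <- vapply(fields[has8], `[`, character(1L), 8L)
  data.frame(
    gene_id = get(4L), chrom = get(1L), strand = strand,
    tx_start = start, tx_end = end, biotype = get(7L),
    category = category, stringsAsFactors = FALSE
  )
}

parse_gtf_genes <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 9L)) {
    stop("malformed GTF line ", which(n < 9L)[1L], ": expected 9 tab-separated fields")
  }
  get <- function(i) vapply(fields, `[`, character(1L), i)
  feature <- get(3L)
  keep <- feature == "gene"
  if (!any(keep)) stop("no 'gene' feature lines found")
  fields <- fields[keep]
  line_no <- which(keep)
  get <- function(i) vapply(fields, `[`, character(1L), i)
  strand <- get(7L)
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand '", strand[!strand %in% c("+", "-")][1L],
         "' on line ", line_no[!strand %in% c("+", "-")][1L])
  }
  start1 <- suppressWarnings(as.integer(get(4L)))
  end1 <- suppressWarnings(as.integer(get(5L)))
  if (anyNA(start1) || anyNA(end1)) {
    stop("non-integer coordinate on line ", line_no[is.na(start1) | is.na(end1)][1L])
  }
  attrs <- get(9L)
  gene_id <- gtf_attr(attrs, "gene_id")
  if (anyNA(gene_id)) stop("missing gene_id attribute on line ", line_no[is.na(gene_id)][1L])
  biotype <- gtf_attr(attrs, "gene_biotype")
  biotype[is.na(biotype)] <- "protein_coding"
  data.frame(
    gene_id = gene_id, chrom = get(1L), strand = strand,
    tx_start = start1 - 1L, tx_end = end1, biotype = biotype,
    category = gtf_attr(attrs, "category"), stringsAsFactors = FALSE
  )
}

gtf_attr <- function(attrs, key) {
  pat <- paste0(key, "\\s+\"([^\"]*)\"")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, character(1L))
}

#' Transcription start sites of annotated genes
#'
#' The TSS is `tx_start` for plus-strand genes and `tx_end - 1` for
#' minus-strand genes (0-based).
#'
#' @param genes A `gene_annotation` data frame.
#' @return Named integer vector of TSS positions, one per gene.
#' @export
gene_tss <- function(genes) {
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
  names(tss) <- genes$gene_id
  tss
}

#' Write a gene annotation as BED6+ (biotype in column 7, category in 8)
#'
#' @param genes A `gene_annotation` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation_bed <- function(genes, path) {
  category <- genes$category
  has_cat <- !is.na(category)
  lines <- paste(genes$chrom, genes$tx_start, genes$tx_end, genes$gene_id,
                 0L, genes$strand, genes$biotype, sep = "\t")
  lines[has_cat] <- paste(lines[has_cat], category[has_cat], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Exclude small-RNA genes from an annotation
#'
#' Non-coding small RNAs (miRNA and the like) are removed before any
#' expression or promoter-signal analysis; only the remaining genes enter
#' the analyzed universe.
#'
#' @param genes A `gene_annotation` data frame.
#' @param excluded_biotypes Character vector of biotypes to drop.
#' @return The filtered annotation, with attributes `n_before` and
#'   `n_after` recording the counts.
#' @export
filter_small_rnas <- function(genes,
                              excluded_biotypes = c("miRNA", "snoRNA", "snRNA",
                                                    "rRNA", "tRNA", "scaRNA",
                                                    "misc_RNA")) {
  keep <- !(genes$biotype %in% excluded_biotypes)
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("all genes excluded by biotype filter")
  attr(out, "n_before") <- nrow(genes)
  attr(out, "n_after") <- nrow(out)
  out
}
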