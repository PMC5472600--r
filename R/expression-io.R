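#' Read a gene-by-sample expression (FPKM) table
#'
#' The file must have a header row of sample ids, a first column of gene
#' ids, and a fully numeric body; missing values are not allowed.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with gene-id rownames and sample-id colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("expression table needs a gene_id column and >= 1 sample")
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids)) stop("duplicated gene_id in expression table")
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric expression value at gene '", gene_ids[idx[1L]],
         "', sample '", colnames(body)[idx[2L]], "'")
  }
  dimnames(num) <- list(gene_ids, colnames(body))
  num
}

#' Write a labelled gene-by-sample matrix as TSV
#'
#' Values are written with 15 significant digits so that a
#' write-then-read round trip through [read_expression_tsv()] reproduces
#' the matrix to near machine precision.
#'
#' @param matrix Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param id_column Header for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path, id_column = "gene_id") {
  if ((nrow(matrix) > 0L && is.null(rownames(matrix))) || is.null(colnames(matrix))) {
    stop("matrix must have rownames and colnames")
  }
  body <- apply(matrix, 2L, function(col) format(col, digits = 15, trim = TRUE,
                                                 scientific = NA))
  body <- matrix(body, nrow = nrow(matrix))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(matrix)), collapse = "\t"), con)
  if (nrow(matrix) > 0L) {
    writeLines(paste(rownames(matrix),
                     apply(body, 1L, paste, collapse = "\t"),
                     sep = if (ncol(matrix) > 0L) "\t" else ""), con)
  }
  invisible(path)
}

#' Read a flat gene-to-category annotation table
#'
#' Stands in for a pathway-knowledge-base export: two tab-separated
#' columns, `gene_id` and `category` (e.g. `"transcription regulator"`).
#'
#' @param path Path to a TSV file (header optional, detected from the
#'   first line).
#' @return Named character vector mapping gene id to category label.
#' @export
read_category_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("category table needs gene_id and category columns")
  if (identical(tolower(df[1L, 1L]), "gene_id")) df <- df[-1L, , drop = FALSE]
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a gene-to-category table
#'
#' @param categories Named character vector (names are gene ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_category_tsv <- function(categories, path) {
  writeLines(c("gene_id\tcategory",
               paste(names(categories), categories, sep = "\t")), path)
  invisible(path)
}
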