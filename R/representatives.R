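#' Configuration for representative-gene selection
#'
#' Encodes the two-stage selection used to pick genes for ChIP-qPCR
#' validation: per cluster, rank genes by the summed H3K27me3 level over
#' four fraction/stage samples, keep the top `top_n_sum`, then rank the
#' candidates by the summed squared between-fraction differences and keep
#' `top_n_select` from whichever end the cluster's mode dictates
#' (`smallest_diff` for clusters whose fractions behave alike,
#' `largest_diff` for clusters with fraction-specific modification).
#'
#' @param sum_samples Ordered ids of the four columns entering the sum;
#'   positions 1/2 and 3/4 are the (negative, positive) fraction pairs at
#'   the two stages whose differences are squared.
#' @param top_n_sum Candidate-pool size per cluster (default 18).
#' @param top_n_select Genes returned per cluster (default 3).
#' @param modes Named character vector, cluster label ->
#'   `"smallest_diff"` or `"largest_diff"`.
#' @param combine How the two squared differences are combined: `"sum"`
#'   (default) or `"max"`.
#' @return A `representative_config` list.
#' @export
representative_config <- function(sum_samples, top_n_sum = 18L,
                                  top_n_select = 3L, modes,
                                  combine = c("sum", "max")) {
  combine <- match.arg(combine)
  if (length(sum_samples) != 4L) stop("sum_samples must name exactly 4 columns")
  if (top_n_select > top_n_sum) stop("top_n_select must be <= top_n_sum")
  if (!all(modes %in% c("smallest_diff", "largest_diff"))) {
    stop("modes must be 'smallest_diff' or 'largest_diff'")
  }
  structure(list(sum_samples = sum_samples, top_n_sum = as.integer(top_n_sum),
                 top_n_select = as.integer(top_n_select), modes = modes,
                 combine = combine),
            class = "representative_config")
}

#' Select representative genes per cluster
#'
#' For each cluster: (1) score every gene by the sum of its H3K27me3
#' values over the four configured samples; (2) keep the cluster's top
#' `top_n_sum` genes by descending score (all genes when the cluster is
#' smaller); (3) compute the squared fraction differences
#' `(s1 - s2)^2 + (s3 - s4)^2` over the configured sample pairs; (4)
#' return the top `top_n_select` by ascending difference
#' (`smallest_diff`) or descending difference (`largest_diff`).  All ties
#' are broken lexicographically by gene id, so the output is
#' deterministic.
#'
#' @param matrix H3K27me3 `tss_signal_matrix` or plain gene-by-sample
#'   matrix covering the four `sum_samples` columns.
#' @param partition A `cluster_partition` over the matrix genes.
#' @param config A [representative_config()].
#' @return Named list, cluster label -> ordered character vector of
#'   selected gene ids (length `min(top_n_select, cluster size)`).
#' @export
select_representatives <- function(matrix, partition, config) {
  x <- if (inherits(matrix, "tss_signal_matrix")) matrix$scores else matrix
  miss <- setdiff(config$sum_samples, colnames(x))
  if (length(miss) > 0L) stop("missing sample column(s): ", paste(miss, collapse = ", "))
  labels <- sort(unique(partition$assignment))
  no_mode <- setdiff(labels, names(config$modes))
  if (length(no_mode) > 0L) stop("no selection mode for cluster(s): ",
                                 paste(no_mode, collapse = ", "))
  ss <- config$sum_samples
  out <- lapply(labels, function(lab) {
    genes <- names(partition$assignment)[partition$assignment == lab]
    if (length(genes) == 0L) stop("empty cluster ", lab)
    genes <- genes[genes %in% rownames(x)]
    sub <- x[genes, ss, drop = FALSE]
    s <- rowSums(sub)
    # top_n_sum by descending sum, gene-id tie-break
    cand <- genes[order(-s, genes)][seq_len(min(config$top_n_sum, length(genes)))]
    d1 <- (x[cand, ss[1L]] - x[cand, ss[2L]])^2
    d2 <- (x[cand, ss[3L]] - x[cand, ss[4L]])^2
    d <- if (config$combine == "sum") d1 + d2 else pmax(d1, d2)
    ord <- if (config$modes[[lab]] == "smallest_diff") order(d, cand)
           else order(-d, cand)
    cand[ord][seq_len(min(config$top_n_select, length(cand)))]
  })
  names(out) <- labels
  out
}
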